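# Shared fixtures and independent oracles. The oracles deliberately take
# the dumbest possible route (per-column scans, memoized recursion,
# exhaustive subset search) and share no code with the package internals.

toy_alignment <- function(...) {
  x <- c(...)
  new_alignment(names(x), unname(x))
}

.oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# brute-force per-column scan: invariant columns of a species
oracle_invariant <- function(aln, map, species) {
  rows <- strsplit(aln$residues, "")
  names(rows) <- aln$ids
  focal <- rows[names(map)[map == species]]
  out <- character()
  for (col in seq_len(aln$L)) {
    states <- unique(vapply(focal, `[`, character(1), col))
    if (length(states) == 1L && states %in% c("A", "C", "G", "T"))
      out[as.character(col)] <- states
  }
  out
}

# brute-force strictly diagnostic columns
oracle_diagnostic <- function(aln, map, species) {
  inv <- oracle_invariant(aln, map, species)
  rows <- strsplit(aln$residues, "")
  names(rows) <- aln$ids
  bg <- rows[names(map)[map != species]]
  keep <- character()
  for (col in names(inv)) {
    base <- inv[[col]]
    bad <- FALSE
    for (b in bg) {
      s <- b[as.integer(col)]
      if (s != "-" && base %in% .oracle_iupac[[s]]) { bad <- TRUE; break }
    }
    if (!bad) keep[col] <- base
  }
  keep
}

# brute-force diagnosis: runs of consecutive invariant columns holding at
# least one diagnostic column
oracle_diagnosis_regions <- function(aln, map, species) {
  inv <- oracle_invariant(aln, map, species)
  dg <- oracle_diagnostic(aln, map, species)
  cols <- as.integer(names(inv))
  if (length(dg) == 0L) return(list())
  regions <- list()
  i <- 1L
  while (i <= length(cols)) {
    j <- i
    while (j < length(cols) && cols[j + 1L] == cols[j] + 1L) j <- j + 1L
    run <- cols[i:j]
    dp <- intersect(run, as.integer(names(dg)))
    if (length(dp) > 0L)
      regions[[length(regions) + 1L]] <-
        list(start = min(run), end = max(run),
             motif = paste(inv[as.character(run)], collapse = ""),
             diagnostic_positions = sort(dp))
    i <- j + 1L
  }
  regions
}

region_coords <- function(d)
  lapply(d$regions, function(r)
    list(start = r$start, end = r$end, motif = r$motif,
         diagnostic_positions = as.integer(r$diagnostic_positions)))

# memoized top-down recursion for the global alignment score
oracle_nw_score <- function(q, r, match = 1, mismatch = -1, gap = -2) {
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  memo <- new.env(parent = emptyenv())
  f <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (i == 0L && j == 0L) 0
      else if (i == 0L) j * gap
      else if (j == 0L) i * gap
      else max(f(i - 1L, j - 1L) + if (qc[i] == rc[j]) match else mismatch,
               f(i - 1L, j) + gap,
               f(i, j - 1L) + gap)
    memo[[key]] <- v
    v
  }
  f(length(qc), length(rc))
}

# exhaustive minimal set cover size
oracle_min_cover_size <- function(sets, universe) {
  n <- length(sets)
  for (k in seq_len(n)) {
    for (combo in utils::combn(n, k, simplify = FALSE)) {
      if (setequal(intersect(unique(unlist(sets[combo])), universe),
                   universe))
        return(k)
    }
  }
  Inf
}

# random small alignment with species labels, for property loops
random_labeled_alignment <- function(n_species = 3L, n_per = 2L, L = 20L) {
  ids <- character(); seqs <- character(); sp <- character()
  for (s in seq_len(n_species)) {
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    for (i in seq_len(n_per)) {
      row <- base
      nmut <- sample(0:3, 1)
      if (nmut > 0) {
        at <- sample(L, nmut)
        row[at] <- sample(c("A", "C", "G", "T", "-", "R", "N"), nmut,
                          replace = TRUE)
      }
      id <- sprintf("s%d_%d", s, i)
      ids <- c(ids, id); seqs <- c(seqs, paste(row, collapse = ""))
      sp <- c(sp, paste0("sp", s))
    }
  }
  list(aln = new_alignment(ids, seqs), map = stats::setNames(sp, ids))
}

focal_species_names <- c("T. shetlandica", "T. lavesquei", "T. atlantis",
                         "T. irinae", "T. williamsae", "T. gracilis")
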