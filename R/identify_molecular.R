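# Placement of unaligned queries into reference alignment coordinates and
# identification against diagnosis profiles, plus distance/clustering
# utilities used for synthetic validation.

#' Majority-rule consensus of an alignment
#'
#' Gap-majority columns are kept with consensus state `-`. Ties are broken
#' alphabetically with `A < C < G < T < '-'` (ambiguity codes after), so
#' the consensus is deterministic.
#'
#' @param alignment A `coi_alignment`.
#' @return Character scalar of length `L`.
#' @export
consensus_sequence <- function(alignment) {
  m <- aln_matrix(alignment)
  pref <- c(ALN_BASES, "-", sort(ALN_AMBIG))
  cons <- apply(m, 2, function(col) {
    tab <- table(col)
    syms <- names(tab)[tab == max(tab)]
    syms[order(match(syms, pref))][1]
  })
  paste(cons, collapse = "")
}

#' Place an unaligned query onto reference coordinates
#'
#' Globally aligns the query against the majority-rule consensus of the
#' reference alignment (match +1, mismatch -1, linear gap penalty) with
#' deterministic tie-breaking (diagonal, then up, then left) and returns
#' the mapping from query positions to 1-based reference columns. No
#' reverse-complement or reading-frame search is attempted: queries are
#' assumed to be forward-strand barcodes.
#'
#' The default gap penalty is -8, not the conventional -2: the marker is a
#' protein-coding barcode in which indels are essentially absent within a
#' genus, and a cheap gap lets chance self-similar windows near a species'
#' diagnostic motif win a one-column shift over the correct ungapped
#' placement, corrupting exactly the columns identification depends on.
#' Real indels (e.g. a truncated or deleted stretch) are still mapped,
#' because the alternative is a run of mismatches that costs more.
#'
#' @param query Character scalar, raw (unaligned) nucleotide sequence of
#'   length at least 50.
#' @param reference A `coi_alignment`.
#' @param match,mismatch,gap Alignment scores.
#' @param consensus Optional precomputed [consensus_sequence()] of
#'   `reference` (saves recomputation in batch identification).
#' @return List of class `coi_coordmap` with `query_id`-free fields `map`
#'   (integer vector, one entry per query position, `NA` when unmapped)
#'   and `score`.
#' @export
align_query_to_coords <- function(query, reference,
                                  match = 1, mismatch = -1, gap = -8,
                                  consensus = NULL) {
  stopifnot(inherits(reference, "coi_alignment"))
  query <- normalize_residues(gsub("-", "", query, fixed = TRUE))
  if (nchar(query) < 50L)
    stop("query shorter than 50 nt: fragments are unsupported", call. = FALSE)
  cons <- if (is.null(consensus)) consensus_sequence(reference) else consensus
  res <- nw_align_map(query, cons, match, mismatch, gap)
  mp <- res$map
  stopifnot(all(diff(mp[!is.na(mp)]) > 0L))
  structure(list(map = mp, score = res$score, query = query),
            class = "coi_coordmap")
}

#' Identify a query sequence against diagnosis profiles
#'
#' The query is placed onto reference coordinates with
#' [align_query_to_coords()]; for each species profile, a region is matched
#' iff every one of its columns maps from the query and the query state is
#' compatible with the motif base (a query ambiguity code containing the
#' motif base counts as a match; an unmapped column counts as a mismatch,
#' flagged `absent`). The verdict is `assigned` iff exactly one species
#' matches all of its regions, `ambiguous` for several, `unassigned` for
#' none.
#'
#' @param query Character scalar, raw nucleotide sequence.
#' @param profiles List of `coi_diagnosis` objects.
#' @param reference A `coi_alignment` (coordinate system of the profiles).
#' @param query_id Optional label for reporting.
#' @param consensus Optional precomputed [consensus_sequence()] of the
#'   reference.
#' @return List of class `coi_identification`: `query_id`, `verdict`
#'   (`"assigned"`, `"ambiguous"` or `"unassigned"`), `species` (label or
#'   vector of labels or `NA`), `scores` (data frame: species,
#'   regions_matched, regions_total) and `mismatches` (data frame: species,
#'   region, column, expected, observed, kind).
#' @export
identify_query <- function(query, profiles, reference, query_id = "query",
                           consensus = NULL) {
  if (length(profiles) == 0L)
    stop("no diagnosis profiles supplied", call. = FALSE)
  L <- reference$L
  for (d in profiles)
    if (length(d$regions) > 0L &&
        max(vapply(d$regions, `[[`, integer(1), "end")) > L)
      stop("profile region exceeds reference length", call. = FALSE)
  cm <- align_query_to_coords(query, reference, consensus = consensus)
  qchars <- strsplit(cm$query, "", fixed = TRUE)[[1]]
  # reference column -> query state ('' when unmapped)
  col_state <- character(L)
  ok <- !is.na(cm$map)
  col_state[cm$map[ok]] <- qchars[ok]

  scores <- data.frame(species = character(), regions_matched = integer(),
                       regions_total = integer())
  mism <- data.frame(species = character(), region = integer(),
                     column = integer(), expected = character(),
                     observed = character(), kind = character())
  for (d in profiles) {
    matched <- 0L
    for (k in seq_along(d$regions)) {
      r <- d$regions[[k]]
      motif <- strsplit(r$motif, "", fixed = TRUE)[[1]]
      hit <- TRUE
      for (col in r$start:r$end) {
        obs <- col_state[col]
        expd <- motif[col - r$start + 1L]
        if (!nzchar(obs)) {
          hit <- FALSE
          mism <- rbind(mism, data.frame(species = d$species, region = k,
            column = col, expected = expd, observed = "", kind = "absent"))
        } else if (!state_matches(obs, expd)) {
          hit <- FALSE
          mism <- rbind(mism, data.frame(species = d$species, region = k,
            column = col, expected = expd, observed = obs, kind = "state"))
        }
      }
      if (hit) matched <- matched + 1L
    }
    scores <- rbind(scores, data.frame(species = d$species,
      regions_matched = matched, regions_total = length(d$regions)))
  }
  full <- scores$species[scores$regions_matched == scores$regions_total &
                           scores$regions_total > 0L]
  verdict <- if (length(full) == 1L) "assigned"
             else if (length(full) > 1L) "ambiguous" else "unassigned"
  structure(list(query_id = query_id, verdict = verdict,
                 species = if (length(full)) full else NA_character_,
                 scores = scores, mismatches = mism),
            class = "coi_identification")
}

#' @export
print.coi_identification <- function(x, ...) {
  cat(sprintf("coi_identification '%s': %s", x$query_id, x$verdict))
  if (x$verdict != "unassigned")
    cat(" ->", paste(x$species, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Uncorrected pairwise p-distance matrix
#'
#' Distances are computed over columns at which both sequences carry a
#' plain base (A/C/G/T); gaps and ambiguity codes are excluded pairwise. A
#' pair with zero comparable columns gets `NA` and a warning.
#'
#' @param alignment A `coi_alignment` with at least 2 sequences.
#' @return Symmetric numeric matrix with zero diagonal, dimnames the
#'   sequence ids.
#' @export
p_distance_matrix <- function(alignment) {
  n <- length(alignment$ids)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  m <- aln_matrix(alignment)
  plain <- matrix(m %in% ALN_BASES, nrow = n)
  D <- matrix(0, n, n, dimnames = list(alignment$ids, alignment$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- plain[i, ] & plain[j, ]
      if (!any(comp)) {
        warning("no comparable columns between '", alignment$ids[i],
                "' and '", alignment$ids[j], "'", call. = FALSE)
        D[i, j] <- D[j, i] <- NA_real_
      } else {
        D[i, j] <- D[j, i] <- mean(m[i, comp] != m[j, comp])
      }
    }
  }
  D
}

#' Single-linkage clustering at a distance threshold
#'
#' Ids are connected when their distance is strictly below `t`; clusters
#' are the connected components, ordered by their smallest member id
#' (members sorted within cluster), so output is invariant to input order.
#'
#' @param matrix Complete symmetric distance matrix with dimnames.
#' @param t Threshold in (0, 1). Default 0.04, a conventional COI barcode
#'   cutoff; used here for synthetic validation only, not as species
#'   delimitation.
#' @return List of character vectors of ids.
#' @export
cluster_by_threshold <- function(matrix, t = 0.04) {
  if (!(t > 0 && t < 1)) stop("threshold must be in (0,1)", call. = FALSE)
  if (any(is.na(matrix))) {
    bad <- which(is.na(matrix), arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    stop("missing distances for pairs: ",
         paste(sprintf("(%s,%s)", rownames(matrix)[bad[, 1]],
                       colnames(matrix)[bad[, 2]]), collapse = ", "),
         call. = FALSE)
  }
  ids <- rownames(matrix)
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (matrix[i, j] < t) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- unname(split(ids, roots))
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, `[`, character(1), 1L))]
}
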