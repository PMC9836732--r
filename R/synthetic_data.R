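# Synthetic alignments with planted, known diagnostic structure, and
# synthetic specimen morphology records drawn from the published
# per-species ranges. Everything is reproducible from the seed.

#' Build a simulation configuration
#'
#' The defaults emulate the structure of the study system: a ~660-column
#' COI alignment over six species with the published per-species specimen
#' counts, a few planted diagnostic regions per species
#' (within-species-invariant, between-species-exclusive columns embedded in
#' invariant context), low intraspecific noise confined to non-diagnostic
#' columns, and moderate interspecific background divergence.
#'
#' @param species Character vector of species labels (>= 2).
#' @param n_per_species Integer vector of sequence counts (recycled).
#' @param L Alignment columns.
#' @param regions_per_species Planted regions per species (used when
#'   `regions` is `NULL`).
#' @param region_length Integer range for planted region lengths.
#' @param noise Per-column, per-sequence intraspecific substitution
#'   probability at non-diagnostic columns.
#' @param divergence Per-column probability that a free background column
#'   carries an interspecific substitution.
#' @param regions Optional list (named by species) of lists of
#'   `list(start, end, motif, diagnostic_positions)` to plant verbatim;
#'   `NULL` places regions automatically.
#' @param adversarial If `TRUE`, planted diagnostic columns are also
#'   exposed to noise (exercises verification failure paths).
#' @param seed Mandatory integer seed.
#' @return List of class `coi_sim_config`.
#' @export
sim_config <- function(species = c("T. shetlandica", "T. lavesquei",
                                   "T. atlantis", "T. irinae",
                                   "T. williamsae", "T. gracilis"),
                       n_per_species = c(30L, 17L, 15L, 6L, 20L, 20L),
                       L = 660L,
                       regions_per_species = 3L,
                       region_length = c(8L, 25L),
                       noise = 0.005,
                       divergence = 0.1,
                       regions = NULL,
                       adversarial = FALSE,
                       seed) {
  if (missing(seed) || is.null(seed))
    stop("seed is mandatory", call. = FALSE)
  if (length(species) < 2L)
    stop("need at least 2 species", call. = FALSE)
  n_per_species <- rep_len(as.integer(n_per_species), length(species))
  stopifnot(noise >= 0, noise <= 1, divergence >= 0, divergence <= 1,
            L >= 1L, all(n_per_species >= 1L))
  structure(list(species = species, n_per_species = n_per_species,
                 L = as.integer(L),
                 regions_per_species = as.integer(regions_per_species),
                 region_length = as.integer(region_length),
                 noise = noise, divergence = divergence, regions = regions,
                 adversarial = isTRUE(adversarial),
                 seed = as.integer(seed)),
            class = "coi_sim_config")
}

# auto-place non-overlapping regions (>= 2-column gaps so every region has
# free flanking columns) and pick diagnostic subsets
place_regions <- function(config) {
  total <- config$regions_per_species * length(config$species)
  lens <- sample(seq(config$region_length[1], config$region_length[2]),
                 total, replace = TRUE)
  need <- sum(lens) + 3L * total
  if (need > config$L - 2L)
    stop("alignment too short for requested planted regions", call. = FALSE)
  # lay regions left-to-right with random slack
  slack <- config$L - 2L - need
  gaps <- 3L + diff(c(0L, sort(sample(0:slack, total, replace = TRUE))))
  starts <- integer(total)
  pos <- 1L
  for (i in seq_len(total)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + lens[i]
  }
  owner <- rep(seq_along(config$species), each = config$regions_per_species)
  owner <- sample(owner)  # interleave species along the alignment
  out <- lapply(seq_along(config$species), function(si) {
    idx <- which(owner == si)
    lapply(idx, function(i) {
      span <- starts[i]:(starts[i] + lens[i] - 1L)
      ndiag <- max(1L, round(length(span) / 4))
      list(start = starts[i], end = starts[i] + lens[i] - 1L, motif = NULL,
           diagnostic_positions = sort(sample(span, ndiag)))
    })
  })
  names(out) <- config$species
  out
}

#' Generate an alignment with planted diagnostic structure
#'
#' Builds a random ancestral sequence; gives each species a distinct base
#' at each of its planted diagnostic columns, guaranteed absent from all
#' other species at that column; plants within-species polymorphism at the
#' columns flanking each region so that region boundaries are recoverable;
#' adds interspecific background divergence at free columns (never creating
#' spurious single-species diagnostic columns); and finally applies
#' intraspecific noise, which by default never touches any planted
#' diagnostic column. Fully reproducible from the seed.
#'
#' @param config A [sim_config()].
#' @return List with `alignment` (a `coi_alignment`), `map` (named species
#'   vector) and `truth` (list of `coi_diagnosis`, one per species, marking
#'   the planted regions).
#' @export
generate_alignment <- function(config) {
  stopifnot(inherits(config, "coi_sim_config"))
  set.seed(config$seed)
  L <- config$L
  nsp <- length(config$species)
  ancestral <- sample(ALN_BASES, L, replace = TRUE)

  regions <- config$regions
  if (is.null(regions)) regions <- place_regions(config)
  regions <- regions[config$species]

  # bounds validation
  for (si in seq_len(nsp)) {
    for (r in regions[[si]]) {
      if (r$start < 1L || r$end > L)
        stop("planted region outside [1, L]", call. = FALSE)
      for (dc in r$diagnostic_positions) {
        if (dc < r$start || dc > r$end)
          stop("diagnostic position outside its region", call. = FALSE)
      }
    }
  }

  # choose motifs: context columns inherit the ancestral state, diagnostic
  # columns get a base distinct from the ancestral one (and from any base
  # already claimed there by another species)
  claimed <- new.env(parent = emptyenv())
  for (si in seq_len(nsp)) {
    for (ri in seq_along(regions[[si]])) {
      r <- regions[[si]][[ri]]
      span <- r$start:r$end
      motif <- if (!is.null(r$motif))
        strsplit(normalize_residues(r$motif), "", fixed = TRUE)[[1]]
      else ancestral[span]
      if (length(motif) != length(span))
        stop("planted motif length does not match region span",
             call. = FALSE)
      for (dc in r$diagnostic_positions) {
        k <- dc - r$start + 1L
        key <- as.character(dc)
        taken <- if (!is.null(claimed[[key]])) claimed[[key]] else character()
        if (is.null(r$motif)) {
          avail <- setdiff(ALN_BASES, c(ancestral[dc], taken))
          if (length(avail) == 0L)
            stop("planted conflict at column ", dc,
                 ": no base left to make it diagnostic", call. = FALSE)
          motif[k] <- sample(avail, 1L)
        } else {
          if (motif[k] %in% taken)
            stop("planted conflict at column ", dc, ": two species demand ",
                 "state ", motif[k], call. = FALSE)
          if (motif[k] == ancestral[dc])
            ancestral[dc] <- sample(setdiff(ALN_BASES, c(motif[k], taken)),
                                    1L)
        }
        claimed[[key]] <- c(taken, motif[k])
      }
      regions[[si]][[ri]]$motif <- paste(motif, collapse = "")
    }
  }

  spans <- unlist(lapply(regions, function(rs)
    unlist(lapply(rs, function(r) r$start:r$end))))
  diag_cols <- unlist(lapply(regions, function(rs)
    unlist(lapply(rs, function(r) r$diagnostic_positions))))
  flanks <- unlist(lapply(regions, function(rs)
    unlist(lapply(rs, function(r) c(r$start - 1L, r$end + 1L)))))
  flanks <- flanks[flanks >= 1L & flanks <= L]
  free <- setdiff(seq_len(L), c(spans, flanks))

  # interspecific background divergence at free columns; any state carried
  # by exactly one species is made polymorphic within that species so it
  # can never masquerade as a diagnostic column
  # columns are drawn at twice the nominal rate because a coin-flip split
  # makes a random species pair differ at only half of them: `divergence`
  # is then the expected pairwise background p-distance between species
  div_cols <- free[stats::runif(length(free)) < min(1, 2 * config$divergence)]
  div_state <- matrix(rep(ancestral, each = nsp), nrow = nsp)
  poly <- list()  # species index -> columns needing forced polymorphism
  for (col in div_cols) {
    derived <- sample(setdiff(ALN_BASES, ancestral[col]), 1L)
    pick <- stats::runif(nsp) < 0.5
    if (!any(pick)) pick[sample.int(nsp, 1L)] <- TRUE
    div_state[pick, col] <- derived
    for (state in unique(div_state[, col])) {
      who <- which(div_state[, col] == state)
      if (length(who) == 1L) {
        if (config$n_per_species[who] >= 2L) {
          # a gap in one sequence breaks invariance without inflating
          # within-species p-distance (gaps are excluded pairwise)
          poly[[length(poly) + 1L]] <- c(who, col)
        } else {
          # singleton species cannot be made polymorphic: park it with the
          # other group instead
          other <- setdiff(unique(div_state[, col]), state)[1]
          div_state[who, col] <- other
        }
      }
    }
  }

  ids <- character(0); seqs <- character(0); sp_of <- character(0)
  all_rows <- list()
  row_id <- 0L
  for (si in seq_len(nsp)) {
    base_seq <- div_state[si, ]
    for (r in regions[[si]]) {
      motif <- strsplit(r$motif, "", fixed = TRUE)[[1]]
      base_seq[r$start:r$end] <- motif
    }
    n <- config$n_per_species[si]
    rows <- matrix(rep(base_seq, n), nrow = n, byrow = TRUE)
    # within-species polymorphism at the flanks of own regions breaks
    # invariance there, so the maximal invariant run equals the planted
    # span. A substituted base (not a gap) is used: a gap adjacent to a
    # region makes the DP placement of that sequence's own query ambiguous
    # at exactly the columns identification needs.
    if (n >= 2L) {
      own_flanks <- unlist(lapply(regions[[si]], function(r)
        c(r$start - 1L, r$end + 1L)))
      own_flanks <- own_flanks[own_flanks >= 1L & own_flanks <= L]
      own_flanks <- setdiff(own_flanks, spans)  # never damage a motif
      for (col in own_flanks)
        rows[2L, col] <- sample(setdiff(ALN_BASES, rows[2L, col]), 1L)
    }
    all_rows[[si]] <- rows
  }
  # forced gap from singleton divergence states
  for (p in poly)
    all_rows[[p[1]]][2L, p[2]] <- "-"
  # intraspecific noise at non-diagnostic columns (all diagnostic columns
  # of every species are protected unless adversarial)
  protected <- if (config$adversarial) integer() else diag_cols
  noise_cols <- setdiff(seq_len(L), protected)
  for (si in seq_len(nsp)) {
    rows <- all_rows[[si]]
    if (config$noise > 0) {
      hits <- which(matrix(stats::runif(nrow(rows) * length(noise_cols)) <
                             config$noise, nrow = nrow(rows)),
                    arr.ind = TRUE)
      for (h in seq_len(nrow(hits))) {
        i <- hits[h, 1]; col <- noise_cols[hits[h, 2]]
        rows[i, col] <- sample(setdiff(ALN_BASES, rows[i, col]), 1L)
      }
    }
    tag <- gsub("[^A-Za-z0-9]+", "_", config$species[si])
    for (i in seq_len(nrow(rows))) {
      row_id <- row_id + 1L
      ids <- c(ids, sprintf("%s_%02d", tag, i))
      seqs <- c(seqs, paste(rows[i, ], collapse = ""))
      sp_of <- c(sp_of, config$species[si])
    }
  }
  alignment <- new_alignment(ids, seqs)
  map <- stats::setNames(sp_of, ids)
  truth <- lapply(seq_len(nsp), function(si)
    new_diagnosis(config$species[si],
                  lapply(regions[[si]], function(r)
                    new_region(r$start, r$end, r$motif,
                               r$diagnostic_positions)),
                  source = "computed",
                  provenance = aln_fingerprint(alignment)))
  names(truth) <- config$species
  list(alignment = alignment, map = map, truth = truth)
}

# ---- specimens ------------------------------------------------------------

#' Load the default per-species morphology parameter table
#'
#' @param path JSON resource path.
#' @return Named list of per-species parameter lists.
#' @export
default_specimen_ranges <- function(path = system.file("extdata",
    "specimen_ranges.json", package = "coidiag")) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  out <- x$species
  names(out) <- vapply(out, function(sp) sp$name, character(1))
  out
}

mg_stain_template <- function(pattern, j_segments = integer()) {
  st <- rep("none", 18L)
  if (pattern == "1") {
    st[1:6] <- "solid"; st[7:14] <- "striped"
  } else if (pattern == "2") {
    st[1:5] <- "solid"; st[6] <- "white"; st[7:14] <- "striped"
  } else if (pattern == "9") {
    st[1:6] <- "solid"; st[7:18] <- "striped"
  } else stop("unknown MG pattern template '", pattern, "'", call. = FALSE)
  new_mg_stain(st, j_segments)
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

#' Generate synthetic specimen morphology records
#'
#' Continuous and integer characters are sampled uniformly within each
#' species' published range; categorical characters are fixed to the
#' species' published states. Body length and abdominal chaetiger count are
#' coupled through a Gaussian copula with configurable positive dependence.
#' Depths are sampled within the published bathymetric ranges.
#'
#' @param ranges Parameter table from [default_specimen_ranges()] (or a
#'   subset of it).
#' @param n Specimens per species (scalar or named vector).
#' @param seed Mandatory integer seed.
#' @param coupling Copula correlation between body length and abdominal
#'   chaetiger count, in `[0, 1)`. Default 0.7 (a clear positive
#'   size-count relationship).
#' @return List of [new_specimen()] objects with `species` set.
#' @export
generate_specimens <- function(ranges = default_specimen_ranges(), n = 20L,
                               seed, coupling = 0.7) {
  if (missing(seed) || is.null(seed))
    stop("seed is mandatory", call. = FALSE)
  if (any(n <= 0)) stop("n must be positive", call. = FALSE)
  set.seed(as.integer(seed))
  if (is.null(names(n)))
    n <- stats::setNames(rep_len(as.integer(n), length(ranges)),
                         names(ranges))
  out <- list()
  for (spname in names(ranges)) {
    sp <- ranges[[spname]]
    k <- n[[spname]]
    z1 <- stats::rnorm(k)
    z2 <- coupling * z1 + sqrt(1 - coupling^2) * stats::rnorm(k)
    u_len <- stats::pnorm(z1)
    u_abd <- stats::pnorm(z2)
    len <- sp$body_length_mm[1] +
      u_len * diff(sp$body_length_mm)
    abd <- as.integer(round(sp$abdominal_chaetigers[1] +
      u_abd * diff(sp$abdominal_chaetigers)))
    lam <- as.integer(round(runif_range(k, sp$lamellae)))
    fil <- runif_range(k, sp$filament_um)
    dep <- runif_range(k, sp$depth_m)
    fus <- runif_range(k, sp$fusion_fraction)
    tteeth <- as.integer(round(runif_range(k, sp$thoracic_uncinus$teeth)))
    ateeth <- as.integer(round(runif_range(k, sp$abdominal_uncinus$teeth)))
    for (i in seq_len(k)) {
      out[[length(out) + 1L]] <- new_specimen(
        species = spname,
        body_length_mm = len[i],
        complete = isTRUE(sp$complete),
        abdominal_chaetiger_count = abd[i],
        white_venter_chaetigers = as.integer(unlist(sp$white_venter)),
        geniculate_chaetigers = as.integer(unlist(sp$geniculate_chaetigers)),
        ciliated_papilla_present = isTRUE(sp$ciliated_papilla),
        papillae_on_lamellae = FALSE,
        branchiae = new_branchiae(fus[i], isTRUE(sp$reduced_lobes),
                                  lamellae_count = lam[i],
                                  ventral_filament_length_um = fil[i],
                                  fifth_lobe_present =
                                    isTRUE(sp$fifth_lobe_present)),
        thoracic_uncinus = new_uncinus(sp$thoracic_uncinus$rostrum,
                                       sp$thoracic_uncinus$capitium,
                                       tteeth[i],
                                       sp$thoracic_uncinus$size,
                                       sp$thoracic_uncinus$rows),
        abdominal_uncinus = new_uncinus(sp$abdominal_uncinus$rostrum,
                                        sp$abdominal_uncinus$capitium,
                                        ateeth[i],
                                        sp$abdominal_uncinus$size,
                                        sp$abdominal_uncinus$rows),
        mg = mg_stain_template(sp$mg_pattern,
                               as.integer(unlist(sp$mg_j_segments))),
        depth_m = dep[i],
        notochaetae_tc1_relative = sp$notochaetae_tc1,
        glandular_region_tc3 = sp$glandular_tc3,
        ciliary_tufts_present = isTRUE(sp$ciliary_tufts),
        upper_lip_elongated = FALSE)
    }
  }
  out
}
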