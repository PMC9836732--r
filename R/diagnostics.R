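# Extraction, verification, minimization, parsing and formatting of
# per-species diagnostic nucleotide combinations.
#
# A column is focal-invariant for a species when every focal sequence
# carries the same plain base (A/C/G/T: gaps and ambiguity codes
# disqualify). It is strictly diagnostic when, additionally, no background
# sequence can match that base: a background IUPAC code whose set contains
# the focal base counts as a potential match and disqualifies the column
# (the diagnoses are meant to be unequivocal), while a background gap never
# matches and never disqualifies.

#' Construct a diagnostic region
#'
#' @param start,end 1-based inclusive alignment columns, `start <= end`.
#' @param motif Character string over A/C/G/T of length `end - start + 1`.
#' @param diagnostic_positions Integer vector of 1-based columns within
#'   `[start, end]` that are strictly diagnostic (the "underlined" sites).
#' @return A list of class `coi_region`.
#' @export
new_region <- function(start, end, motif, diagnostic_positions) {
  start <- as.integer(start); end <- as.integer(end)
  diagnostic_positions <- sort(unique(as.integer(diagnostic_positions)))
  if (start > end) stop("region start > end", call. = FALSE)
  if (nchar(motif) != end - start + 1L)
    stop("motif length does not match region span", call. = FALSE)
  if (length(diagnostic_positions) == 0L)
    stop("region needs at least one diagnostic position", call. = FALSE)
  if (any(diagnostic_positions < start | diagnostic_positions > end))
    stop("diagnostic positions outside region span", call. = FALSE)
  structure(list(start = start, end = end, motif = motif,
                 diagnostic_positions = diagnostic_positions),
            class = "coi_region")
}

#' Construct a species diagnosis
#'
#' A diagnosis is the ordered, non-overlapping set of diagnostic regions
#' that jointly characterize one species against the rest of an alignment.
#'
#' @param species Species label.
#' @param regions List of [new_region()] objects, ascending by start,
#'   non-overlapping.
#' @param source `"computed"` (from an alignment) or `"parsed"` (from a
#'   printed diagnosis block).
#' @param provenance Alignment fingerprint (list with `n`, `L`, `digest`) or
#'   a source-text label.
#' @return Object of class `coi_diagnosis`.
#' @export
new_diagnosis <- function(species, regions = list(),
                          source = c("computed", "parsed"),
                          provenance = NULL) {
  source <- match.arg(source)
  if (length(regions) > 0L) {
    starts <- vapply(regions, `[[`, integer(1), "start")
    ends <- vapply(regions, `[[`, integer(1), "end")
    o <- order(starts)
    regions <- regions[o]; starts <- starts[o]; ends <- ends[o]
    if (length(regions) > 1L && any(starts[-1] <= ends[-length(ends)]))
      stop("diagnosis regions overlap", call. = FALSE)
  }
  structure(list(species = species, regions = regions, source = source,
                 provenance = provenance),
            class = "coi_diagnosis")
}

#' @export
print.coi_diagnosis <- function(x, ...) {
  cat(sprintf("coi_diagnosis for '%s' (%s): %d region(s)\n",
              x$species, x$source, length(x$regions)))
  if (length(x$regions) > 0L)
    cat(" ", format_diagnosis_block(x), "\n")
  invisible(x)
}

aln_fingerprint <- function(alignment) {
  payload <- paste(c(alignment$ids, alignment$residues), collapse = "\n")
  list(n = length(alignment$ids), L = alignment$L,
       digest = sprintf("sum%.0f-n%d", sum(utf8ToInt(payload)),
                        nchar(payload)))
}

#' Columns invariant within a focal species
#'
#' Returns the alignment columns at which every focal sequence carries the
#' same plain base. Columns where any focal sequence has a gap or an
#' ambiguity code are excluded.
#'
#' @param alignment A `coi_alignment`.
#' @param map Named character vector from [read_species_map()].
#' @param species Focal species label.
#' @return Named character vector: names are column numbers, values the
#'   shared base.
#' @export
compute_focal_invariant_columns <- function(alignment, map, species) {
  idx <- split_focal(alignment, map, species)
  m <- aln_matrix(alignment)
  focal <- m[idx$focal, , drop = FALSE]
  same <- colSums(focal == focal[rep(1L, nrow(focal)), , drop = FALSE]) ==
    nrow(focal)
  plain <- focal[1L, ] %in% ALN_BASES
  cols <- which(same & plain)
  stats::setNames(focal[1L, cols], cols)
}

#' Strictly diagnostic columns of a focal species
#'
#' Subset of the focal-invariant columns at which no background sequence can
#' match the focal base. A background ambiguity code compatible with the
#' focal base disqualifies the column; a background gap does not.
#'
#' @inheritParams compute_focal_invariant_columns
#' @return Named character vector (column number -> diagnostic base).
#' @export
compute_strict_diagnostic_columns <- function(alignment, map, species) {
  idx <- split_focal(alignment, map, species)
  if (length(idx$background) == 0L)
    stop("no background sequences: diagnosis requires at least 2 species",
         call. = FALSE)
  inv <- compute_focal_invariant_columns(alignment, map, species)
  if (length(inv) == 0L) return(inv)
  m <- aln_matrix(alignment)
  bg <- m[idx$background, as.integer(names(inv)), drop = FALSE]
  ok <- vapply(seq_along(inv), function(j) {
    !any(vapply(bg[, j], state_matches, logical(1), base = inv[[j]]))
  }, logical(1))
  inv[ok]
}

# does observed state (possibly ambiguous) potentially match a plain base?
# gap never matches.
state_matches <- function(state, base) {
  if (state == "-") return(FALSE)
  base %in% IUPAC_SETS[[state]]
}

#' Assemble the diagnosis of a species
#'
#' Regions are the maximal runs of consecutive focal-invariant columns that
#' contain at least one strictly diagnostic column; the motif is the shared
#' focal states over the run, mixing diagnostic sites with invariant
#' context, as in printed diagnosis blocks. A species with no strictly
#' diagnostic column yields an empty diagnosis with a warning. A species
#' represented by a single sequence is permitted (invariance is then
#' trivial) but a low-support warning is emitted.
#'
#' @inheritParams compute_focal_invariant_columns
#' @return A [new_diagnosis()] with `source = "computed"`.
#' @export
assemble_diagnosis <- function(alignment, map, species) {
  idx <- split_focal(alignment, map, species)
  if (length(idx$focal) == 1L)
    warning("species '", species, "' has a single sequence: ",
            "within-species invariance is unsupported", call. = FALSE)
  inv <- compute_focal_invariant_columns(alignment, map, species)
  diag <- compute_strict_diagnostic_columns(alignment, map, species)
  prov <- aln_fingerprint(alignment)
  if (length(diag) == 0L) {
    warning("no strictly diagnostic column for species '", species, "'",
            call. = FALSE)
    return(new_diagnosis(species, list(), "computed", prov))
  }
  inv_cols <- as.integer(names(inv))
  diag_cols <- as.integer(names(diag))
  # maximal runs of consecutive invariant columns
  run_id <- cumsum(c(1L, diff(inv_cols) != 1L))
  regions <- list()
  for (r in unique(run_id)) {
    cols <- inv_cols[run_id == r]
    dp <- intersect(cols, diag_cols)
    if (length(dp) == 0L) next
    regions[[length(regions) + 1L]] <- new_region(
      min(cols), max(cols),
      paste(inv[run_id == r], collapse = ""), dp)
  }
  new_diagnosis(species, regions, "computed", prov)
}

#' Verify a diagnostic combination against a labeled alignment
#'
#' Checks that (a) every focal sequence matches every region motif exactly
#' over its span and (b) every background sequence is excluded by at least
#' one region at one or more diagnostic columns (background state not
#' compatible with the diagnostic base; gaps exclude). Region coordinates
#' exceeding the alignment length give a `malformed` verdict.
#'
#' @param diagnosis A `coi_diagnosis`.
#' @inheritParams compute_focal_invariant_columns
#' @return List of class `coi_validation` with `verdict` (`"pass"`,
#'   `"fail"` or `"malformed"`), `focal_failures` (data frame),
#'   `unexcluded` (background ids not excluded by any region) and
#'   `evidence` (data frame: background id, region index, column).
#' @export
verify_combination <- function(diagnosis, alignment, map) {
  stopifnot(inherits(diagnosis, "coi_diagnosis"))
  idx <- split_focal(alignment, map, diagnosis$species)
  regs <- diagnosis$regions
  out <- list(verdict = "pass",
              focal_failures = data.frame(id = character(), region = integer()),
              unexcluded = character(),
              evidence = data.frame(id = character(), region = integer(),
                                    column = integer()))
  class(out) <- "coi_validation"
  if (length(regs) == 0L) {
    out$verdict <- "fail"
    out$unexcluded <- alignment$ids[idx$background]
    return(out)
  }
  if (any(vapply(regs, `[[`, integer(1), "end") > alignment$L)) {
    out$verdict <- "malformed"
    return(out)
  }
  m <- aln_matrix(alignment)
  # (a) focal sequences match motifs exactly
  for (k in seq_along(regs)) {
    r <- regs[[k]]
    span <- r$start:r$end
    motif <- strsplit(r$motif, "", fixed = TRUE)[[1]]
    for (i in idx$focal) {
      if (!all(m[i, span] == motif))
        out$focal_failures <- rbind(out$focal_failures,
          data.frame(id = alignment$ids[i], region = k))
    }
  }
  # (b) background exclusion evidence at diagnostic columns
  excluded <- logical(length(idx$background))
  for (k in seq_along(regs)) {
    r <- regs[[k]]
    motif <- strsplit(r$motif, "", fixed = TRUE)[[1]]
    for (bi in seq_along(idx$background)) {
      i <- idx$background[bi]
      for (col in r$diagnostic_positions) {
        base <- motif[col - r$start + 1L]
        if (!state_matches(m[i, col], base)) {
          excluded[bi] <- TRUE
          out$evidence <- rbind(out$evidence,
            data.frame(id = alignment$ids[i], region = k, column = col))
          break
        }
      }
    }
  }
  out$unexcluded <- alignment$ids[idx$background][!excluded]
  if (nrow(out$focal_failures) > 0L || length(out$unexcluded) > 0L)
    out$verdict <- "fail"
  out
}

#' @export
print.coi_validation <- function(x, ...) {
  cat("coi_validation: verdict =", x$verdict, "\n")
  if (nrow(x$focal_failures) > 0L)
    cat("  focal failures:", nrow(x$focal_failures), "\n")
  if (length(x$unexcluded) > 0L)
    cat("  unexcluded background:", paste(x$unexcluded, collapse = ", "), "\n")
  invisible(x)
}

# exclusion set of one region against background rows (by row index)
region_exclusion_set <- function(region, m, background) {
  motif <- strsplit(region$motif, "", fixed = TRUE)[[1]]
  keep <- logical(length(background))
  for (bi in seq_along(background)) {
    i <- background[bi]
    for (col in region$diagnostic_positions) {
      if (!state_matches(m[i, col], motif[col - region$start + 1L])) {
        keep[bi] <- TRUE
        break
      }
    }
  }
  background[keep]
}

#' Greedy minimization of a diagnostic combination
#'
#' Retains a subset of regions, chosen greedily (the region excluding the
#' largest number of not-yet-excluded background sequences first; ties
#' broken by smaller start coordinate), such that every background sequence
#' remains excluded by at least one retained region. The input must pass
#' [verify_combination()].
#'
#' @inheritParams verify_combination
#' @return A `coi_diagnosis` whose regions are a subset of the input's.
#' @export
minimal_combination <- function(diagnosis, alignment, map) {
  rep0 <- verify_combination(diagnosis, alignment, map)
  if (rep0$verdict != "pass")
    stop("diagnosis does not verify (verdict: ", rep0$verdict,
         "); cannot minimize", call. = FALSE)
  idx <- split_focal(alignment, map, diagnosis$species)
  m <- aln_matrix(alignment)
  excl <- lapply(diagnosis$regions, region_exclusion_set, m = m,
                 background = idx$background)
  remaining <- idx$background
  chosen <- integer()
  starts <- vapply(diagnosis$regions, `[[`, integer(1), "start")
  while (length(remaining) > 0L) {
    gains <- vapply(excl, function(e) length(intersect(e, remaining)),
                    integer(1))
    gains[chosen] <- -1L
    best <- which(gains == max(gains))
    best <- best[which.min(starts[best])]
    chosen <- c(chosen, best)
    remaining <- setdiff(remaining, excl[[best]])
  }
  new_diagnosis(diagnosis$species, diagnosis$regions[sort(chosen)],
                diagnosis$source, diagnosis$provenance)
}

#' Parse a printed diagnosis block
#'
#' Parses the printed dialect of comma-separated entries
#' `"start-end: MOTIF"` or `"pos: MOTIF"` (en dash or hyphen, arbitrary
#' whitespace tolerated, including inside ranges). Since the printed
#' underlining that marks which motif sites are strictly diagnostic is not
#' machine-readable, `diagnostic_positions` of every parsed region is set
#' to the full span. Entries whose motif length differs from the span are
#' flagged (`span_length_mismatch`) but kept verbatim; overlapping or
#' non-monotonic entries are flagged, never repaired.
#'
#' @param text Character scalar (or vector of lines) with the block.
#' @param species Optional species label attached to the result.
#' @return List with `diagnosis` (a `coi_diagnosis`, `source = "parsed"`)
#'   and `report` (data frame: entry, start, end, motif, flag).
#' @export
parse_diagnosis_block <- function(text, species = "unknown") {
  text <- paste(text, collapse = " ")
  # printed blocks carry en dashes; declare the bytes as UTF-8 so parsing
  # is locale-independent (fixtures are UTF-8 files)
  Encoding(text) <- "UTF-8"
  if (!nzchar(trimws(text)))
    stop("empty diagnosis block", call. = FALSE)
  # entry separators: comma, and the stray cedilla typo seen in print
  pieces <- strsplit(text, "[,\u00b8]")[[1]]
  pieces <- trimws(pieces)
  pieces <- pieces[nzchar(pieces)]
  rx <- "^([0-9]+)\\s*(?:[\u2013\u2014-]\\s*([0-9]+))?\\s*:\\s*([ACGTUacgtu]+)$"
  report <- data.frame(entry = character(), start = integer(),
                       end = integer(), motif = character(),
                       flag = character(), stringsAsFactors = FALSE)
  regions <- list()
  seen_any <- FALSE
  last_end <- -Inf
  for (p in pieces) {
    mt <- regmatches(p, regexec(rx, p))[[1]]
    if (length(mt) == 0L) {
      report <- rbind(report, data.frame(entry = p, start = NA_integer_,
        end = NA_integer_, motif = NA_character_, flag = "unparseable"))
      next
    }
    seen_any <- TRUE
    start <- as.integer(mt[2])
    end <- if (nzchar(mt[3])) as.integer(mt[3]) else start
    motif <- normalize_residues(mt[4])
    flag <- ""
    if (end < start) {
      flag <- "non_monotonic"
    } else if (nchar(motif) != end - start + 1L) {
      flag <- "span_length_mismatch"
    } else if (start <= last_end) {
      flag <- "overlaps_previous"
    }
    if (!nzchar(flag)) {
      regions[[length(regions) + 1L]] <-
        new_region(start, end, motif, start:end)
      last_end <- max(last_end, end)
    }
    report <- rbind(report, data.frame(entry = p, start = start, end = end,
                                       motif = motif, flag = flag))
  }
  if (!seen_any)
    stop("no parseable diagnosis entry in block", call. = FALSE)
  diagnosis <- new_diagnosis(species, regions, "parsed",
                             provenance = "parsed text block")
  list(diagnosis = diagnosis, report = report)
}

#' Format a diagnosis in the printed dialect
#'
#' Canonical text: entries joined by `", "`, ranges as
#' `"start–end: MOTIF"` and single columns as `"pos: X"`.
#' `parse_diagnosis_block(format_diagnosis_block(d))` reproduces the
#' coordinates and motifs of `d` exactly.
#'
#' @param diagnosis A `coi_diagnosis`.
#' @return Character scalar (empty string, with a warning, for an empty
#'   diagnosis).
#' @export
format_diagnosis_block <- function(diagnosis) {
  stopifnot(inherits(diagnosis, "coi_diagnosis"))
  if (length(diagnosis$regions) == 0L) {
    warning("formatting an empty diagnosis", call. = FALSE)
    return("")
  }
  entries <- vapply(diagnosis$regions, function(r) {
    if (r$start == r$end) sprintf("%d: %s", r$start, r$motif)
    else sprintf("%d\u2013%d: %s", r$start, r$end, r$motif)
  }, character(1))
  paste(entries, collapse = ", ")
}

#' Serialize diagnosis profiles to JSON
#'
#' @param profiles List of `coi_diagnosis` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diagnosis_profiles <- function(profiles, path) {
  x <- lapply(profiles, function(d) {
    list(species = d$species, source = d$source,
         regions = lapply(d$regions, function(r)
           list(start = r$start, end = r$end, motif = r$motif,
                diagnostic_positions = r$diagnostic_positions)))
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read diagnosis profiles from JSON
#'
#' @param path Path written by [write_diagnosis_profiles()].
#' @return List of `coi_diagnosis` objects.
#' @export
read_diagnosis_profiles <- function(path) {
  x <- jsonlite::read_json(path)
  lapply(x, function(d) {
    regions <- lapply(d$regions, function(r)
      new_region(r$start, r$end, r$motif, unlist(r$diagnostic_positions)))
    new_diagnosis(d$species, regions,
                  if (identical(d$source, "parsed")) "parsed" else "computed",
                  provenance = "profile file")
  })
}
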