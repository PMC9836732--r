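#' @useDynLib coidiag, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Internal alphabet: bases, gap, IUPAC ambiguity codes. '.' is deliberately
# not allowed; 'U' is normalized to 'T' on ingestion.
ALN_BASES <- c("A", "C", "G", "T")
ALN_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
ALN_ALPHABET <- c(ALN_BASES, "-", ALN_AMBIG)

# IUPAC code -> set of bases it may stand for
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Construct an aligned-sequence set
#'
#' An alignment is an ordered set of equal-length residue strings over the
#' nucleotide alphabet (A, C, G, T, gap `-`, and IUPAC ambiguity codes),
#' indexed by 1-based inclusive column coordinates throughout the package.
#'
#' @param ids Character vector of unique, nonempty sequence identifiers.
#' @param residues Character vector of residue strings, parallel to `ids`.
#'   Residues are uppercase-normalized and `U` is mapped to `T`.
#' @return An object of class `coi_alignment` with fields `ids`, `residues`
#'   and `L` (column count).
#' @export
new_alignment <- function(ids, residues) {
  ids <- as.character(ids)
  residues <- normalize_residues(as.character(residues))
  if (length(ids) == 0L)
    stop("alignment must contain at least one sequence", call. = FALSE)
  if (length(ids) != length(residues))
    stop("ids and residues must have equal length", call. = FALSE)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("sequence ids must be nonempty", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  lens <- nchar(residues)
  if (length(unique(lens)) != 1L) {
    tab <- table(lens)
    modal <- as.integer(names(tab)[which.max(tab)])
    bad <- ids[lens != modal]
    stop("ragged alignment: sequences differ in length (offending ids: ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  if (lens[1] == 0L)
    stop("alignment length must be positive", call. = FALSE)
  check_alphabet(ids, residues)
  structure(list(ids = ids, residues = residues, L = as.integer(lens[1])),
            class = "coi_alignment")
}

# Uppercase, map U/u to T. Idempotent.
normalize_residues <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

check_alphabet <- function(ids, residues) {
  for (i in seq_along(residues)) {
    ch <- strsplit(residues[i], "", fixed = TRUE)[[1]]
    bad <- which(!(ch %in% ALN_ALPHABET))
    if (length(bad) > 0L)
      stop(sprintf("illegal symbol '%s' in sequence '%s' at position %d",
                   ch[bad[1]], ids[i], bad[1]), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.coi_alignment <- function(x, ...) {
  cat(sprintf("coi_alignment: %d sequences x %d columns\n",
              length(x$ids), x$L))
  show <- utils::head(x$ids, 5L)
  for (id in show)
    cat(sprintf("  %s  %s%s\n", id,
                substr(x$residues[match(id, x$ids)], 1, 40),
                if (x$L > 40) "..." else ""))
  if (length(x$ids) > 5L) cat(sprintf("  ... and %d more\n", length(x$ids) - 5L))
  invisible(x)
}

# alignment as a character matrix (rows = sequences, cols = columns)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$residues, "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

#' Read an aligned FASTA file
#'
#' Residues are uppercase-normalized with `U` mapped to `T`; record order is
#' preserved. Ragged record lengths, empty files and symbols outside the
#' nucleotide/IUPAC/gap alphabet are errors.
#'
#' @param path Path to a FASTA file of aligned sequences.
#' @return A [new_alignment()] object.
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not parseable as FASTA: ", path,
                                           call. = FALSE))
  if (length(set) == 0L)
    stop("FASTA file contains no records: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  new_alignment(ids, as.character(set))
}

#' Write an alignment to FASTA
#'
#' Lines are wrapped at 70 columns. Reading the written file back
#' reproduces the alignment exactly (ids, order, residues).
#'
#' @param alignment A `coi_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "coi_alignment"))
  set <- Biostrings::BStringSet(alignment$residues)
  names(set) <- alignment$ids
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}

#' Read a sequence-id to species map
#'
#' The file is tab-separated with two columns (sequence id, species label);
#' lines starting with `#` and blank lines are ignored. Duplicate consistent
#' rows are deduplicated; a duplicate id mapped to two species is an error.
#'
#' @param path Path to the TSV file.
#' @return Named character vector: names are sequence ids, values species
#'   labels.
#' @export
read_species_map <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    stop("species map contains no data rows: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, integer(1))
  if (any(nf < 2L))
    stop("species map row missing a column: line '",
         lines[which(nf < 2L)[1]], "'", call. = FALSE)
  ids <- vapply(parts, `[`, character(1), 1L)
  sp <- vapply(parts, `[`, character(1), 2L)
  keep <- !duplicated(paste(ids, sp, sep = "\r"))
  ids <- ids[keep]; sp <- sp[keep]
  if (anyDuplicated(ids)) {
    bad <- unique(ids[duplicated(ids)])
    stop("conflicting species assignment for id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stats::setNames(sp, ids)
}

#' Write a species map TSV
#' @param map Named character vector (id -> species).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_species_map <- function(map, path) {
  writeLines(paste(names(map), unname(map), sep = "\t"), path)
  invisible(path)
}

# split an alignment's row indices into focal / background for one species
split_focal <- function(alignment, map, species) {
  sp <- unname(map[alignment$ids])
  if (!species %in% sp)
    stop("species '", species, "' has no sequences in the alignment/map",
         call. = FALSE)
  list(focal = which(!is.na(sp) & sp == species),
       background = which(!is.na(sp) & sp != species))
}
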