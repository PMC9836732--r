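# Access to packaged plain-text resources.

#' Path to a packaged printed diagnosis block
#'
#' The package ships, verbatim, the six printed per-species diagnosis
#' blocks (coordinate-range/motif listings) as plain-text fixtures for the
#' parser and validator.
#'
#' @param species One of `"shetlandica"`, `"lavesquei"`, `"atlantis"`,
#'   `"irinae"`, `"williamsae"`, `"gracilis"`; omit to list all.
#' @return File path(s).
#' @export
diagnosis_block_path <- function(species = NULL) {
  dir <- system.file("extdata", "diagnosis_blocks", package = "coidiag")
  if (is.null(species)) return(list.files(dir, full.names = TRUE))
  f <- file.path(dir, paste0(species, ".txt"))
  if (!file.exists(f)) stop("no diagnosis block for '", species, "'",
                            call. = FALSE)
  f
}

#' Path to a packaged material-examined listing
#'
#' @inheritParams diagnosis_block_path
#' @return File path(s).
#' @export
material_examined_path <- function(species = NULL) {
  dir <- system.file("extdata", "material_examined", package = "coidiag")
  if (is.null(species)) return(list.files(dir, full.names = TRUE))
  f <- file.path(dir, paste0(species, ".txt"))
  if (!file.exists(f)) stop("no material-examined listing for '", species,
                            "'", call. = FALSE)
  f
}
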