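# Parsing of museum specimen listings ("material examined" paragraphs) and
# occurrence summaries.

MUSEUM_PREFIXES <- c("ZMBN", "GNM", "NTNU-VM")

# normalize dash variants (en/em dash) to plain hyphen
normalize_dashes <- function(x) gsub("[\u2013\u2014]", "-", x)

#' Parse a material-examined listing into specimen records
#'
#' Recognizes registration codes with the museum prefixes ZMBN, GNM and
#' NTNU-VM (en dash and hyphen variants tolerated) grouped under region
#' labels of the form `Region (CODE1, CODE2, ...)`; a bare number inside a
#' group inherits the prefix of the preceding code. Holotype and paratype
#' markers set the record role. Each code yields one specimen. Stated
#' counts such as `"30 specimens"` or `"Paratypes (16 specimens)"` are
#' recorded and compared with the number of codes found; a mismatch is
#' reported, not reconciled.
#'
#' @param text Character scalar or vector of lines.
#' @return Data frame of class `coi_registry` with columns `code`,
#'   `museum`, `region`, `role`, `count`; attributes `stated_counts`
#'   (named integer) and `count_mismatch` (logical).
#' @export
parse_material_examined <- function(text) {
  text <- paste(text, collapse = " ")
  Encoding(text) <- "UTF-8"  # listings carry en dashes; locale-independent
  text <- normalize_dashes(text)
  if (!nzchar(trimws(text)))
    stop("empty material-examined text", call. = FALSE)
  records <- data.frame(code = character(), museum = character(),
                        region = character(), role = character(),
                        count = integer(), stringsAsFactors = FALSE)
  # stated specimen counts ("30 specimens", "Paratypes (16 specimens)")
  stated <- integer()
  m <- regmatches(text, gregexpr("([0-9]+)\\s+specimens?", text))[[1]]
  if (length(m) > 0L)
    stated <- as.integer(sub("\\s+specimens?$", "", m))

  # holotype outside parenthetical groups: "Holotype: ZMBN116322"
  hol <- regmatches(text,
    regexec("Holotypes?\\s*[:.]?\\s*((ZMBN|GNM|NTNU-?VM)\\s?-?\\s?[0-9]{4,6})",
            text, ignore.case = TRUE))[[1]]
  holotype_code <- if (length(hol) > 0L) gsub("\\s", "", hol[2]) else NULL

  # paratype scope: everything after a "Paratype" marker is paratype role
  # until the listing ends (the printed layout puts paratypes last)
  para_at <- regexpr("Paratypes?", text, ignore.case = TRUE)

  # labeled parenthetical groups
  grp_rx <- "([A-Za-z][A-Za-z \u00e9\u00e8'-]*?)\\s*\\(([^()]*)\\)"
  gm <- gregexpr(grp_rx, text)
  groups <- regmatches(text, gm)[[1]]
  offsets <- gm[[1]]
  for (gi in seq_along(groups)) {
    parts <- regmatches(groups[gi], regexec(grp_rx, groups[gi]))[[1]]
    region <- trimws(parts[2])
    content <- parts[3]
    if (!grepl("[0-9]{4,6}", content)) next  # e.g. "(16 specimens)"
    role <- if (!is.null(holotype_code) && para_at > 0 &&
                offsets[gi] > para_at) "paratype" else "non_type"
    tokens <- trimws(strsplit(content, ",", fixed = TRUE)[[1]])
    prefix <- NA_character_
    for (tok in tokens) {
      tk <- gsub("\\s", "", tok)
      mt <- regmatches(tk, regexec("^(ZMBN|GNM|NTNU-?VM)([0-9]{4,6})$", tk))[[1]]
      if (length(mt) > 0L) {
        prefix <- toupper(sub("NTNUVM", "NTNU-VM", gsub("-", "", mt[2])))
        if (prefix == "NTNUVM") prefix <- "NTNU-VM"
        records <- rbind(records, data.frame(
          code = paste0(sub("NTNU-?VM", "NTNU-VM", mt[2]), mt[3]),
          museum = prefix, region = region, role = role, count = 1L))
      } else if (grepl("^[0-9]{4,6}$", tk)) {
        if (is.na(prefix)) next  # bare number with no prefix context
        records <- rbind(records, data.frame(
          code = paste0(prefix, tk), museum = prefix, region = region,
          role = role, count = 1L))
      }
    }
  }
  if (!is.null(holotype_code)) {
    museum <- regmatches(holotype_code,
                         regexpr("^(ZMBN|GNM|NTNU-?VM)", holotype_code))
    records <- rbind(data.frame(code = holotype_code,
                                museum = sub("NTNUVM", "NTNU-VM", museum),
                                region = "type locality", role = "holotype",
                                count = 1L),
                     records)
  }
  if (nrow(records) == 0L)
    stop("no registration codes found in text", call. = FALSE)
  # normalize NTNU prefixes in codes
  records$code <- sub("^NTNUVM", "NTNU-VM", records$code)
  records$code <- sub("^NTNU-?VM", "NTNU-VM", records$code)
  records$museum <- sub("^NTNU-?VM", "NTNU-VM", records$museum)
  attr(records, "stated_counts") <- stated
  attr(records, "count_mismatch") <-
    length(stated) > 0L && !any(stated == nrow(records))
  class(records) <- c("coi_registry", "data.frame")
  records
}

#' Extract holotype length and width from a measurement sentence
#'
#' Parses phrases like `"34.0 mm long and 2.0 mm wide"`; values are
#' returned in millimetres (cm inputs converted).
#'
#' @param text Character scalar.
#' @return Named numeric vector `c(length_mm = ..., width_mm = ...)`;
#'   `width_mm` is `NA` when only a length phrase is present.
#' @export
parse_holotype_measurements <- function(text) {
  text <- paste(text, collapse = " ")
  to_mm <- function(v, unit) if (tolower(unit) == "cm") v * 10 else v
  lm <- regmatches(text,
    regexec("([0-9]+(?:\\.[0-9]+)?)\\s*(mm|cm)\\s+long", text))[[1]]
  wm <- regmatches(text,
    regexec("([0-9]+(?:\\.[0-9]+)?)\\s*(mm|cm)\\s+wide", text))[[1]]
  if (length(lm) == 0L && length(wm) == 0L)
    stop("no length/width measurement phrase found", call. = FALSE)
  len <- if (length(lm) > 0L) to_mm(as.numeric(lm[2]), lm[3]) else NA_real_
  wid <- if (length(wm) > 0L) to_mm(as.numeric(wm[2]), wm[3]) else NA_real_
  c(length_mm = len, width_mm = wid)
}

#' Fractions of specimens above and below a depth cutoff
#'
#' "Above" is interpreted numerically on the depth value: above the cutoff
#' means shallower (`depth < cutoff`). Both orientations are returned to
#' sidestep the ambiguity of verbal usage. Records are weighted by their
#' specimen count; records without depth are excluded and reported.
#'
#' @param records Data frame with columns `depth_m` and optionally `count`
#'   (default 1), e.g. an augmented [parse_material_examined()] result.
#' @param cutoff_m Depth cutoff in metres (default 200).
#' @return List with `fraction_above` (depth < cutoff),
#'   `fraction_below` (depth >= cutoff), `n_with_depth`, `n_without_depth`.
#' @export
depth_fraction <- function(records, cutoff_m = 200) {
  depth <- records$depth_m
  count <- if (!is.null(records$count)) records$count else rep(1L, length(depth))
  has <- !is.na(depth)
  if (!any(has))
    stop("no records carry a depth: statistic undefined", call. = FALSE)
  w <- count[has]; d <- depth[has]
  list(fraction_above = sum(w[d < cutoff_m]) / sum(w),
       fraction_below = sum(w[d >= cutoff_m]) / sum(w),
       n_with_depth = sum(w),
       n_without_depth = sum(count[!has]))
}
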