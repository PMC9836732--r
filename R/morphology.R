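# Morphological identification system: uncini / branchiae / Methyl-Green
# typologies, the taxon-by-character matrix, and the dichotomous key engine.

#' Construct an uncinus measurement
#'
#' @param rostrum_length,capitium_length Positive lengths (arbitrary but
#'   identical units); the rostrum is the main fang, the capitium the crest
#'   of smaller teeth above it.
#' @param first_row_tooth_count Integer >= 1, teeth in the first capitium
#'   row.
#' @param first_row_tooth_size `"large"`, `"mid"` or `"small"`.
#' @param capitium_row_count Integer >= 1 (default 1).
#' @return Object of class `coi_uncinus`.
#' @export
new_uncinus <- function(rostrum_length, capitium_length,
                        first_row_tooth_count,
                        first_row_tooth_size = c("large", "mid", "small"),
                        capitium_row_count = 1L) {
  first_row_tooth_size <- match.arg(first_row_tooth_size)
  stopifnot(rostrum_length > 0, capitium_length > 0,
            first_row_tooth_count >= 1, capitium_row_count >= 1)
  structure(list(rostrum_length = rostrum_length,
                 capitium_length = capitium_length,
                 first_row_tooth_count = as.integer(first_row_tooth_count),
                 first_row_tooth_size = first_row_tooth_size,
                 capitium_row_count = as.integer(capitium_row_count)),
            class = "coi_uncinus")
}

#' Construct a branchiae observation
#'
#' @param fusion_fraction Fraction of lobe length fused, in `[0, 1]`.
#' @param reduced_lobes Logical: dorsal lobes reduced in size.
#' @param lamellae_count Integer >= 0 (optional).
#' @param ventral_filament_length_um Filament length in micrometres
#'   (optional).
#' @param fifth_lobe_present Logical or `NA`: anterior projection of the
#'   dorsal lobes.
#' @return Object of class `coi_branchiae`.
#' @export
new_branchiae <- function(fusion_fraction, reduced_lobes,
                          lamellae_count = NA_integer_,
                          ventral_filament_length_um = NA_real_,
                          fifth_lobe_present = NA) {
  stopifnot(fusion_fraction >= 0, fusion_fraction <= 1,
            is.logical(reduced_lobes))
  if (!is.na(lamellae_count)) stopifnot(lamellae_count >= 0)
  structure(list(fusion_fraction = fusion_fraction,
                 reduced_lobes = reduced_lobes,
                 lamellae_count = as.integer(lamellae_count),
                 ventral_filament_length_um = ventral_filament_length_um,
                 fifth_lobe_present = fifth_lobe_present),
            class = "coi_branchiae")
}

#' Construct a Methyl-Green staining observation
#'
#' @param segment_states Character vector of length 18, one state per body
#'   segment (SG 1..18), each `"solid"`, `"striped"`, `"white"` or
#'   `"none"`.
#' @param j_region_segments Integer vector of segments bearing a J-shaped
#'   glandular region (possibly empty).
#' @return Object of class `coi_mg_stain`.
#' @export
new_mg_stain <- function(segment_states, j_region_segments = integer()) {
  if (length(segment_states) != 18L)
    stop("segment_states must have length 18", call. = FALSE)
  if (!all(segment_states %in% c("solid", "striped", "white", "none")))
    stop("illegal segment state", call. = FALSE)
  structure(list(segment_states = segment_states,
                 j_region_segments = as.integer(j_region_segments)),
            class = "coi_mg_stain")
}

#' Construct a specimen morphology record
#'
#' All fields are optional; unknown values (`NA`) match anything in the
#' matrix identifier and make the corresponding key predicates
#' undecidable.
#'
#' @param species True/assumed species label (optional, used by the
#'   synthetic generator and summary statistics).
#' @param body_length_mm,depth_m Numeric.
#' @param complete Logical: specimen complete (posterior end present).
#' @param abdominal_chaetiger_count Integer.
#' @param white_venter_chaetigers Integer set of thoracic chaetigers (TC)
#'   with white ventral colouration (empty = none).
#' @param geniculate_chaetigers Integer set of TC bearing geniculate
#'   chaetae.
#' @param ciliated_papilla_present,papillae_on_lamellae,ciliary_tufts_present,upper_lip_elongated
#'   Logical or `NA`.
#' @param branchiae A [new_branchiae()] or `NULL`.
#' @param thoracic_uncinus,abdominal_uncinus A [new_uncinus()] or `NULL`.
#' @param mg A [new_mg_stain()] or `NULL`.
#' @param notochaetae_tc1_relative `"similar"`, `"longer"`, `"shorter"`,
#'   `"absent"` or `NA`: TC 1 notochaetae relative to subsequent ones.
#' @param glandular_region_tc3 `"round"`, `"oval"`, `"J_shaped"`,
#'   `"absent"` or `NA`.
#' @param glandular_tc3_mg_stain `"white"`, `"blue"` or `NA`: staining
#'   reaction of the TC 3 glandular region.
#' @return Object of class `coi_specimen`.
#' @export
new_specimen <- function(species = NA_character_,
                         body_length_mm = NA_real_,
                         complete = NA,
                         abdominal_chaetiger_count = NA_integer_,
                         white_venter_chaetigers = integer(),
                         geniculate_chaetigers = 6L,
                         ciliated_papilla_present = NA,
                         papillae_on_lamellae = NA,
                         branchiae = NULL,
                         thoracic_uncinus = NULL,
                         abdominal_uncinus = NULL,
                         mg = NULL,
                         depth_m = NA_real_,
                         notochaetae_tc1_relative = NA_character_,
                         glandular_region_tc3 = NA_character_,
                         glandular_tc3_mg_stain = NA_character_,
                         ciliary_tufts_present = NA,
                         upper_lip_elongated = NA) {
  wv <- as.integer(white_venter_chaetigers)
  gc <- as.integer(geniculate_chaetigers)
  if (length(wv) && any(wv < 1L | wv > 18L))
    stop("TC indices must be in 1..18", call. = FALSE)
  if (!is.na(abdominal_chaetiger_count) && abdominal_chaetiger_count < 0)
    stop("counts must be nonnegative", call. = FALSE)
  structure(list(species = species, body_length_mm = body_length_mm,
                 complete = complete,
                 abdominal_chaetiger_count =
                   as.integer(abdominal_chaetiger_count),
                 white_venter_chaetigers = wv,
                 geniculate_chaetigers = gc,
                 ciliated_papilla_present = ciliated_papilla_present,
                 papillae_on_lamellae = papillae_on_lamellae,
                 branchiae = branchiae,
                 thoracic_uncinus = thoracic_uncinus,
                 abdominal_uncinus = abdominal_uncinus,
                 mg = mg, depth_m = depth_m,
                 notochaetae_tc1_relative = notochaetae_tc1_relative,
                 glandular_region_tc3 = glandular_region_tc3,
                 glandular_tc3_mg_stain = glandular_tc3_mg_stain,
                 ciliary_tufts_present = ciliary_tufts_present,
                 upper_lip_elongated = upper_lip_elongated),
            class = "coi_specimen")
}

# ---- typology classifiers -------------------------------------------------

# Numeric thresholds rendering the verbal type definitions decidable. The
# nominal ratios are 2:1 (thoracic type 1), 1:1 (types 3/4), 1/0.7
# (abdominal 1A) and 1/0.9 (abdominal 2); the cut points sit between them.
TYPOLOGY_THRESHOLDS <- list(rvc_type1_min = 1.5, abdominal_cr_cut = 0.8,
                            fusion_type4_max = 0.15, fusion_type1_min = 0.8,
                            fusion_type2_min = 0.3)

#' Classify a thoracic uncinus
#'
#' Type 1: rostrum about twice the capitium (RvC >= 1.5) with 2-3 large
#' first-row teeth, subsequent ones much smaller. Type 3: 4-5 mid-sized
#' first-row teeth. Type 4: 5-7 small teeth with the remaining ones similar
#' in size in at least two rows. Conflicting counts (e.g. 5 teeth) are
#' resolved by the tooth-size class. Total: anything else is `"unknown"`.
#'
#' @param m A [new_uncinus()].
#' @param thresholds Numeric thresholds (see `TYPOLOGY_THRESHOLDS`).
#' @return `"1"`, `"3"`, `"4"` or `"unknown"`.
#' @export
classify_thoracic_uncinus <- function(m, thresholds = TYPOLOGY_THRESHOLDS) {
  stopifnot(inherits(m, "coi_uncinus"))
  rvc <- m$rostrum_length / m$capitium_length
  n <- m$first_row_tooth_count
  sz <- m$first_row_tooth_size
  if (sz == "large" && n %in% 2:3 && rvc >= thresholds$rvc_type1_min)
    return("1")
  if (sz == "mid" && n %in% 4:5) return("3")
  if (sz == "small" && n %in% 5:7 && m$capitium_row_count >= 2L) return("4")
  "unknown"
}

#' Classify an abdominal uncinus
#'
#' Type 1A: capitium clearly shorter than the rostrum (capitium/rostrum
#' <= 0.8, nominal 1/0.7) with 3-5 large first-row teeth. Type 2: capitium
#' nearly as long as the rostrum (ratio > 0.8, nominal 1/0.9) with 4-5
#' teeth followed by smaller ones. Anything else is `"unknown"`; the
#' boundary ratio 0.8 belongs to type 1A.
#'
#' @inheritParams classify_thoracic_uncinus
#' @return `"1A"`, `"2"` or `"unknown"`.
#' @export
classify_abdominal_uncinus <- function(m, thresholds = TYPOLOGY_THRESHOLDS) {
  stopifnot(inherits(m, "coi_uncinus"))
  cr <- m$capitium_length / m$rostrum_length
  n <- m$first_row_tooth_count
  if (cr <= thresholds$abdominal_cr_cut && n %in% 3:5 &&
      m$first_row_tooth_size == "large")
    return("1A")
  if (cr > thresholds$abdominal_cr_cut && n %in% 4:5) return("2")
  "unknown"
}

#' Classify branchiae by lobe fusion
#'
#' Type 1: large lobes almost completely fused (fusion >= 0.8). Type 2:
#' lobes fused for about half their length (fusion in \[0.3, 0.8)). Type 3:
#' lobes fused only at the base (fusion < 0.3). Type 4: small, unfused and
#' reduced dorsal lobes (reduced lobes with fusion < 0.15).
#'
#' @param b A [new_branchiae()].
#' @param thresholds Numeric thresholds (see `TYPOLOGY_THRESHOLDS`).
#' @return `"1"`, `"2"`, `"3"` or `"4"`.
#' @export
classify_branchiae <- function(b, thresholds = TYPOLOGY_THRESHOLDS) {
  stopifnot(inherits(b, "coi_branchiae"))
  if (isTRUE(b$reduced_lobes) &&
      b$fusion_fraction < thresholds$fusion_type4_max) return("4")
  if (b$fusion_fraction >= thresholds$fusion_type1_min) return("1")
  if (b$fusion_fraction >= thresholds$fusion_type2_min) return("2")
  "3"
}

#' Classify a Methyl-Green staining pattern
#'
#' Pattern templates: pattern 1 has SG 1-6 solid and SG 7-14 striped with
#' no J-shaped glandular region; pattern 2 has SG 1-5 solid, SG 6 white
#' and SG 7-14 striped with no J region; pattern 9 has SG 1-6 solid
#' (SG 6 dark solid) and SG 7 onward striped and requires a J-shaped
#' glandular region. SG 15-18 are ignored. A stain satisfying no template
#' is `"other"`.
#'
#' @param s A [new_mg_stain()].
#' @return `"1"`, `"2"`, `"9"` or `"other"`.
#' @export
classify_mg_pattern <- function(s) {
  stopifnot(inherits(s, "coi_mg_stain"))
  st <- s$segment_states
  has_j <- length(s$j_region_segments) > 0L
  solid16 <- all(st[1:6] == "solid")
  striped714 <- all(st[7:14] == "striped")
  if (has_j && solid16 && striped714) return("9")
  if (!has_j && solid16 && striped714) return("1")
  if (!has_j && all(st[1:5] == "solid") && st[6] == "white" && striped714)
    return("2")
  "other"
}

# ---- derived specimen features -------------------------------------------

# logical helpers returning NA for unknowns
.feat_size_class <- function(len) {
  if (is.na(len)) return(NA_character_)
  if (len < 20) "small" else if (len <= 40) "medium" else "large"
}

# Derive the feature list key predicates and the matrix identifier consume.
specimen_features <- function(s) {
  stopifnot(inherits(s, "coi_specimen"))
  wv <- s$white_venter_chaetigers
  white_venter <- if (is.null(wv)) NA_character_
    else if (length(wv) == 0L) "none"
    else if (setequal(wv, 1:4)) "TC1-4"
    else if (setequal(wv, 4L)) "TC4"
    else "other"
  gset <- s$geniculate_chaetigers
  glandular_present <- if (is.na(s$glandular_region_tc3)) NA
    else s$glandular_region_tc3 != "absent"
  list(
    branchiae_type = if (is.null(s$branchiae)) NA_character_
                     else classify_branchiae(s$branchiae),
    thoracic_uncini_type = if (is.null(s$thoracic_uncinus)) NA_character_
                           else classify_thoracic_uncinus(s$thoracic_uncinus),
    abdominal_uncini_type = if (is.null(s$abdominal_uncinus)) NA_character_
                            else classify_abdominal_uncinus(s$abdominal_uncinus),
    abdominal_cr_ratio = if (is.null(s$abdominal_uncinus)) NA_real_
      else s$abdominal_uncinus$capitium_length /
           s$abdominal_uncinus$rostrum_length,
    mg_pattern = if (is.null(s$mg)) NA_character_
                 else classify_mg_pattern(s$mg),
    white_venter = white_venter,
    white_venter_present = if (is.na(white_venter)) NA
                           else white_venter != "none",
    size_class = .feat_size_class(s$body_length_mm),
    body_length_mm = s$body_length_mm,
    fifth_lobe_present = if (is.null(s$branchiae)) NA
                         else s$branchiae$fifth_lobe_present,
    notochaetae_tc1 = s$notochaetae_tc1_relative,
    geniculate_tc5 = if (length(gset) == 0L) NA else 5L %in% gset,
    geniculate_chaetae = if (length(gset) == 0L) NA_character_
      else if (setequal(gset, 6L)) "TC6"
      else if (setequal(gset, 5:6)) "TC5-6" else "other",
    papillae_on_lamellae = s$papillae_on_lamellae,
    ciliated_papilla = s$ciliated_papilla_present,
    ciliary_tufts = s$ciliary_tufts_present,
    upper_lip_elongated = s$upper_lip_elongated,
    glandular_tc3 = s$glandular_region_tc3,
    glandular_tc3_present = glandular_present,
    glandular_tc3_mg_stain = s$glandular_tc3_mg_stain,
    depth_m = s$depth_m
  )
}

# ---- character matrix ----------------------------------------------------

#' Load a taxon-by-character matrix
#'
#' The default resource encodes the discriminating characters of the six
#' focal Northeast Atlantic species (branchiae type, papillae on lamellae
#' margins, ciliated papilla dorsal to the thoracic notopodia, geniculate
#' chaetae position, thoracic and abdominal uncini types), augmented with
#' the white ventral colouration character from the species remarks, since
#' the tabulated characters alone do not separate the two species that
#' differ only in colouration extent.
#'
#' @param path JSON resource path; default the packaged matrix.
#' @return Object of class `coi_character_matrix`: `taxa`, `characters`
#'   (data frame name/domain) and `states` (taxon x character matrix).
#' @export
load_character_matrix <- function(path = system.file("extdata",
    "character_matrix.json", package = "coidiag")) {
  x <- jsonlite::read_json(path)
  taxa <- unlist(x$taxa)
  chars <- vapply(x$characters, function(ch) ch$name, character(1))
  domains <- lapply(x$characters, function(ch) unlist(ch$domain))
  states <- do.call(rbind, lapply(x$states, function(row)
    unlist(row, use.names = FALSE)))
  rownames(states) <- taxa
  colnames(states) <- chars
  for (j in seq_along(chars)) {
    bad <- !(states[, j] %in% c(domains[[j]], "unknown"))
    if (any(bad))
      stop("matrix state outside declared domain for character '",
           chars[j], "'", call. = FALSE)
  }
  structure(list(taxa = taxa,
                 characters = data.frame(name = chars,
                                         stringsAsFactors = FALSE),
                 domains = domains, states = states),
            class = "coi_character_matrix")
}

#' Identify a specimen against a character matrix
#'
#' Returns every taxon whose matrix states are consistent with the
#' specimen's derived character states; unknowns (on either side) match
#' anything. A matrix character without a derivation rule from specimen
#' fields is a configuration error.
#'
#' @param specimen A [new_specimen()].
#' @param matrix A [load_character_matrix()].
#' @return Character vector of consistent taxa.
#' @export
matrix_identify <- function(specimen, matrix = load_character_matrix()) {
  feats <- specimen_features(specimen)
  known <- c("branchiae_type", "papillae_on_lamellae", "ciliated_papilla",
             "geniculate_chaetae", "thoracic_uncini_type",
             "abdominal_uncini_type", "white_venter", "mg_pattern")
  for (ch in matrix$characters$name)
    if (!ch %in% known)
      stop("no derivation rule for matrix character '", ch, "'",
           call. = FALSE)
  keep <- rep(TRUE, length(matrix$taxa))
  for (ch in matrix$characters$name) {
    obs <- feats[[ch]]
    # logical features compared against yes/no matrix states
    if (is.logical(obs)) obs <- if (is.na(obs)) NA_character_
                                else if (obs) "yes" else "no"
    if (is.na(obs) || identical(obs, "unknown")) next
    st <- matrix$states[, ch]
    keep <- keep & (st == obs | st == "unknown")
  }
  matrix$taxa[keep]
}

# ---- dichotomous key engine ----------------------------------------------

#' Load a dichotomous key
#'
#' The default resource mirrors, couplet for couplet, the published key to
#' the Northeast Atlantic species of the genus: 18 numbered couplets, each
#' with two leads carrying predicates over derived specimen features and a
#' target (another couplet or a taxon set; two terminals legitimately hold
#' more than one species, distinguishable only genetically or by
#' geography/bathymetry). The key graph is validated at load: targets must
#' exist, the graph from couplet 1 must be acyclic and every couplet
#' reachable.
#'
#' @param path JSON resource path; default the packaged key.
#' @return Object of class `coi_key`.
#' @export
load_key <- function(path = system.file("extdata", "identification_key.json",
                                        package = "coidiag")) {
  x <- jsonlite::read_json(path)
  couplets <- list()
  for (cp in x$couplets) {
    leads <- lapply(cp$leads, function(ld) {
      preds <- lapply(ld$predicates, function(p)
        list(field = p$field, op = p$op,
             value = if (is.list(p$value)) unlist(p$value) else p$value))
      target <- if (!is.null(ld$couplet)) list(couplet = ld$couplet)
                else list(taxa = unlist(ld$taxa))
      list(predicates = preds, target = target)
    })
    couplets[[as.character(cp$number)]] <- leads
  }
  key <- structure(list(couplets = couplets), class = "coi_key")
  validate_key(key)
  key
}

validate_key <- function(key) {
  nums <- as.integer(names(key$couplets))
  for (nm in names(key$couplets)) {
    for (ld in key$couplets[[nm]]) {
      tg <- ld$target
      if (!is.null(tg$couplet)) {
        if (!as.character(tg$couplet) %in% names(key$couplets))
          stop("key lead points to missing couplet ", tg$couplet,
               call. = FALSE)
      } else if (length(tg$taxa) == 0L) {
        stop("key lead with empty taxon set", call. = FALSE)
      }
    }
  }
  # acyclicity + reachability by DFS from couplet 1
  colors <- stats::setNames(rep(0L, length(nums)), names(key$couplets))
  visit <- function(nm) {
    if (colors[[nm]] == 1L) stop("cycle in key at couplet ", nm,
                                 call. = FALSE)
    if (colors[[nm]] == 2L) return(invisible())
    colors[[nm]] <<- 1L
    for (ld in key$couplets[[nm]])
      if (!is.null(ld$target$couplet))
        visit(as.character(ld$target$couplet))
    colors[[nm]] <<- 2L
  }
  visit("1")
  unreachable <- names(colors)[colors != 2L]
  if (length(unreachable) > 0L)
    stop("unreachable couplet(s): ", paste(unreachable, collapse = ", "),
         call. = FALSE)
  invisible(key)
}

# evaluate one predicate against a feature list: TRUE/FALSE/NA
eval_predicate <- function(p, feats) {
  v <- feats[[p$field]]
  if (is.null(v)) return(NA)
  if (length(v) == 1L && is.na(v)) return(NA)
  switch(p$op,
    eq = identical(as.character(v), as.character(p$value)),
    ne = !identical(as.character(v), as.character(p$value)),
    "in" = as.character(v) %in% as.character(p$value),
    is_true = isTRUE(v),
    is_false = isFALSE(v),
    gt = v > p$value,
    ge = v >= p$value,
    lt = v < p$value,
    le = v <= p$value,
    stop("unknown predicate op '", p$op, "'", call. = FALSE))
}

eval_lead <- function(lead, feats) {
  vals <- vapply(lead$predicates, function(p) {
    r <- eval_predicate(p, feats)
    if (is.na(r)) NA else r
  }, logical(1))
  if (any(!vals, na.rm = TRUE)) return(FALSE)
  if (anyNA(vals)) return(NA)
  TRUE
}

# all taxa reachable from a couplet
reachable_taxa <- function(key, from = 1L) {
  seen <- character()
  stack <- as.character(from)
  done <- character()
  while (length(stack) > 0L) {
    nm <- stack[[1L]]; stack <- stack[-1L]
    if (nm %in% done) next
    done <- c(done, nm)
    for (ld in key$couplets[[nm]]) {
      if (!is.null(ld$target$couplet))
        stack <- c(stack, as.character(ld$target$couplet))
      else seen <- union(seen, ld$target$taxa)
    }
  }
  sort(seen)
}

#' Traverse the dichotomous key with a specimen
#'
#' Starting at couplet 1, both leads of each couplet are evaluated against
#' the specimen's derived features. When exactly one lead is satisfied it
#' is followed; otherwise (both satisfied, neither satisfied, or
#' undecidable due to unknown characters) traversal stops and the union of
#' all taxa reachable from the current couplet is returned together with
#' the partial path.
#'
#' @param specimen A [new_specimen()].
#' @param key A [load_key()].
#' @return List with `taxa` (character vector), `path` (data frame:
#'   couplet, lead) and `resolved` (logical: reached a terminal lead).
#' @export
key_traverse <- function(specimen, key = load_key()) {
  feats <- specimen_features(specimen)
  path <- data.frame(couplet = integer(), lead = character())
  current <- "1"
  repeat {
    leads <- key$couplets[[current]]
    ev <- vapply(leads, function(ld) {
      r <- eval_lead(ld, feats)
      if (is.na(r)) NA else r
    }, logical(1))
    sat <- which(!is.na(ev) & ev)
    if (length(sat) != 1L) {
      return(list(taxa = reachable_taxa(key, current), path = path,
                  resolved = FALSE))
    }
    lead_name <- c("a", "b")[sat]
    path <- rbind(path, data.frame(couplet = as.integer(current),
                                   lead = lead_name))
    tg <- leads[[sat]]$target
    if (!is.null(tg$couplet)) {
      current <- as.character(tg$couplet)
    } else {
      return(list(taxa = sort(tg$taxa), path = path, resolved = TRUE))
    }
  }
}

#' Cross-check a key against a character matrix
#'
#' Asserts that every taxon named in the key is reachable from couplet 1,
#' reports terminal leads holding more than one taxon, and labels as
#' "non-morphological" the terminals whose predicates rest on
#' depth/geography rather than morphology.
#'
#' @param key A [load_key()].
#' @param matrix A [load_character_matrix()] (its taxa are checked for
#'   presence in the key).
#' @return List with `reachable` (all key taxa reachable from couplet 1),
#'   `taxa`, `missing_matrix_taxa`, `multi_taxon_terminals` (data frame:
#'   couplet, lead, taxa) and `non_morphological_terminals`.
#' @export
key_consistency_check <- function(key = load_key(),
                                  matrix = load_character_matrix()) {
  all_named <- character()
  multi <- data.frame(couplet = integer(), lead = character(),
                      taxa = character())
  nonmorph <- data.frame(couplet = integer(), lead = character(),
                         taxa = character())
  for (nm in names(key$couplets)) {
    leads <- key$couplets[[nm]]
    for (k in seq_along(leads)) {
      tg <- leads[[k]]$target
      if (is.null(tg$taxa)) next
      all_named <- union(all_named, tg$taxa)
      if (length(tg$taxa) > 1L)
        multi <- rbind(multi, data.frame(couplet = as.integer(nm),
          lead = c("a", "b")[k], taxa = paste(tg$taxa, collapse = " / ")))
      fields <- vapply(leads[[k]]$predicates, function(p) p$field,
                       character(1))
      if (any(fields %in% "depth_m"))
        nonmorph <- rbind(nonmorph, data.frame(couplet = as.integer(nm),
          lead = c("a", "b")[k], taxa = paste(tg$taxa, collapse = " / ")))
    }
  }
  reach <- reachable_taxa(key, 1L)
  list(reachable = setequal(all_named, reach),
       taxa = sort(all_named),
       missing_matrix_taxa = setdiff(matrix$taxa, all_named),
       multi_taxon_terminals = multi,
       non_morphological_terminals = nonmorph)
}

# ---- abdominal chaetigers vs body length ---------------------------------

#' Per-species ranges and correlation of abdominal chaetigers vs length
#'
#' Complete specimens are used; incomplete ones are excluded except for
#' species flagged exempt (by default the deep-sea species known only from
#' incomplete material). Returns per-species min/max of both variables and
#' the Pearson correlation over the pooled usable specimens.
#'
#' @param specimens List of [new_specimen()] with `species` set.
#' @param exempt_species Species whose incomplete specimens are still
#'   used.
#' @return List with `ranges` (data frame) and `correlation` (Pearson r,
#'   `NA` when fewer than 3 usable points or a variable has zero
#'   variance).
#' @export
abdominal_vs_length_stats <- function(specimens,
                                      exempt_species = "T. irinae") {
  sp <- vapply(specimens, function(s) s$species, character(1))
  len <- vapply(specimens, function(s) s$body_length_mm, numeric(1))
  abd <- vapply(specimens, function(s)
    as.numeric(s$abdominal_chaetiger_count), numeric(1))
  comp <- vapply(specimens, function(s) isTRUE(s$complete), logical(1))
  usable <- (comp | sp %in% exempt_species) & !is.na(len) & !is.na(abd)
  ranges <- do.call(rbind, lapply(sort(unique(sp[usable])), function(x) {
    i <- usable & sp == x
    data.frame(species = x, n = sum(i),
               length_min = min(len[i]), length_max = max(len[i]),
               abdominal_min = min(abd[i]), abdominal_max = max(abd[i]))
  }))
  r <- NA_real_
  if (sum(usable) >= 3L) {
    if (stats::sd(len[usable]) == 0 || stats::sd(abd[usable]) == 0) {
      warning("zero variance: correlation undefined", call. = FALSE)
    } else {
      r <- stats::cor(len[usable], abd[usable])
    }
  } else {
    warning("fewer than 3 usable specimens: correlation undefined",
            call. = FALSE)
  }
  list(ranges = ranges, correlation = r, n_used = sum(usable))
}
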