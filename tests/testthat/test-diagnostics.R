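simple_map <- function(aln, species) stats::setNames(species, aln$ids)

test_that("focal-invariant columns follow the definition", {
  aln <- toy_alignment(f1 = "ACGT", f2 = "ACGA", b1 = "TTTT")
  map <- c(f1 = "X", f2 = "X", b1 = "Y")
  expect_equal(compute_focal_invariant_columns(aln, map, "X"),
               c(`1` = "A", `2` = "C", `3` = "G"))

  aln <- toy_alignment(f1 = "AC-T", f2 = "ACAT", b1 = "GGGG")
  map <- c(f1 = "X", f2 = "X", b1 = "Y")
  expect_equal(compute_focal_invariant_columns(aln, map, "X"),
               c(`1` = "A", `2` = "C", `4` = "T"))

  expect_error(compute_focal_invariant_columns(aln, map, "Z"),
               "no sequences")
})

test_that("planted variable column is the only non-invariant one (oracle)", {
  set.seed(42)
  base <- paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE),
                collapse = "")
  v <- strsplit(base, "")[[1]]
  v[6] <- setdiff(c("A", "C", "G", "T"), v[6])[1]
  aln <- toy_alignment(f1 = base, f2 = base, f3 = paste(v, collapse = ""),
                       b1 = "GGGGGGGGGG")
  map <- c(f1 = "X", f2 = "X", f3 = "X", b1 = "Y")
  inv <- compute_focal_invariant_columns(aln, map, "X")
  expect_length(inv, 9L)
  expect_false("6" %in% names(inv))
  expect_identical(inv, oracle_invariant(aln, map, "X"))
})

test_that("strict diagnosticity respects the ambiguity compatibility rule", {
  aln <- toy_alignment(f1 = "A", f2 = "A", b1 = "C", b2 = "G")
  map <- c(f1 = "X", f2 = "X", b1 = "Y", b2 = "Y")
  expect_equal(compute_strict_diagnostic_columns(aln, map, "X"),
               c(`1` = "A"))

  # background R (= A/G) can match focal A, so the column is disqualified
  aln <- toy_alignment(f1 = "A", f2 = "A", b1 = "R")
  map <- c(f1 = "X", f2 = "X", b1 = "Y")
  expect_length(compute_strict_diagnostic_columns(aln, map, "X"), 0L)

  # a background gap neither matches nor disqualifies
  aln <- toy_alignment(f1 = "A", f2 = "A", b1 = "-", b2 = "C")
  map <- c(f1 = "X", f2 = "X", b1 = "Y", b2 = "Y")
  expect_equal(compute_strict_diagnostic_columns(aln, map, "X"),
               c(`1` = "A"))

  expect_error(compute_strict_diagnostic_columns(
    toy_alignment(f1 = "A"), c(f1 = "X"), "X"), "background")
})

test_that("planted autapomorphies are recovered exactly (oracle)", {
  # 12-column toy, 3 species x 2 seqs, 2 planted autapomorphies each
  base <- rep("A", 12)
  mk <- function(cols, state) {
    v <- base; v[cols] <- state; paste(v, collapse = "")
  }
  aln <- toy_alignment(
    x1 = mk(c(1, 4), "C"), x2 = mk(c(1, 4), "C"),
    y1 = mk(c(6, 9), "G"), y2 = mk(c(6, 9), "G"),
    z1 = mk(c(11, 12), "T"), z2 = mk(c(11, 12), "T"))
  map <- c(x1 = "X", x2 = "X", y1 = "Y", y2 = "Y", z1 = "Z", z2 = "Z")
  expect_equal(compute_strict_diagnostic_columns(aln, map, "X"),
               c(`1` = "C", `4` = "C"))
  for (sp in c("X", "Y", "Z"))
    expect_identical(compute_strict_diagnostic_columns(aln, map, sp),
                     oracle_diagnostic(aln, map, sp))
})

test_that("regions are maximal invariant runs containing a diagnostic column", {
  # invariant columns 5-9 with diagnostic column 7; column 4 variable
  f1 <- "ACGAACGTACG"; f2 <- "ACGTACGTACG"   # differ at col 4
  b1 <- "ACGAACTTACG"; b2 <- "ACGTACTTACG"   # differ from focal at col 7
  aln <- toy_alignment(f1 = f1, f2 = f2, b1 = b1, b2 = b2)
  map <- c(f1 = "X", f2 = "X", b1 = "Y", b2 = "Y")
  d <- assemble_diagnosis(aln, map, "X")
  expect_length(d$regions, 1L)
  r <- d$regions[[1]]
  expect_equal(r$start, 5L)
  expect_equal(r$end, 11L)  # run extends to the end of the alignment
  expect_equal(r$diagnostic_positions, 7L)
  expect_equal(substr(r$motif, 7 - r$start + 1, 7 - r$start + 1), "G")
})

test_that("a diagnostic column with variable flanks yields a single-column region", {
  # analogous to the printed single-position entry "306: C"
  f1 <- "AACAA"; f2 <- "TACAG"   # only columns 2-4 invariant... col 3 diagnostic
  b1 <- "AATAA"; b2 <- "TATAG"
  aln <- toy_alignment(f1 = f1, f2 = f2, b1 = b1, b2 = b2)
  map <- c(f1 = "X", f2 = "X", b1 = "Y", b2 = "Y")
  d <- assemble_diagnosis(aln, map, "X")
  expect_length(d$regions, 1L)
  expect_equal(d$regions[[1]][c("start", "end", "motif")],
               list(start = 2L, end = 4L, motif = "ACA"))
  expect_equal(d$regions[[1]]$diagnostic_positions, 3L)
})

test_that("assemble_diagnosis equals the brute-force oracle on small alignments", {
  set.seed(7)
  for (case in 1:30) {
    x <- random_labeled_alignment(n_species = sample(2:4, 1),
                                  n_per = sample(1:2, 1),
                                  L = sample(10:30, 1))
    for (sp in unique(x$map)) {
      d <- suppressWarnings(assemble_diagnosis(x$aln, x$map, sp))
      expect_identical(region_coords(d),
                       oracle_diagnosis_regions(x$aln, x$map, sp))
      # soundness: a nonempty computed diagnosis passes verification
      if (length(d$regions) > 0L)
        expect_equal(verify_combination(d, x$aln, x$map)$verdict, "pass")
    }
  }
})

test_that("adding a background sequence never enlarges the strict set", {
  set.seed(11)
  for (case in 1:10) {
    x <- random_labeled_alignment(n_species = 3, n_per = 2, L = 25)
    before <- compute_strict_diagnostic_columns(x$aln, x$map, "sp1")
    extra <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
                   collapse = "")
    aln2 <- new_alignment(c(x$aln$ids, "extra"),
                          c(x$aln$residues, extra))
    map2 <- c(x$map, extra = "sp9")
    after <- compute_strict_diagnostic_columns(aln2, map2, "sp1")
    expect_true(all(names(after) %in% names(before)))
  }
})

test_that("verification passes on provenance and fails on a forced counterexample", {
  g <- generate_alignment(sim_config(species = c("A", "B", "C"),
                                     n_per_species = 4, L = 80,
                                     regions_per_species = 2,
                                     region_length = c(4L, 8L), seed = 5))
  d <- assemble_diagnosis(g$alignment, g$map, "A")
  expect_equal(verify_combination(d, g$alignment, g$map)$verdict, "pass")

  # mutate one background sequence to equal a focal sequence
  focal_id <- names(g$map)[g$map == "A"][1]
  bg_id <- names(g$map)[g$map == "B"][1]
  res2 <- g$alignment$residues
  res2[match(bg_id, g$alignment$ids)] <-
    g$alignment$residues[match(focal_id, g$alignment$ids)]
  aln2 <- new_alignment(g$alignment$ids, res2)
  rep2 <- verify_combination(d, aln2, g$map)
  expect_equal(rep2$verdict, "fail")
  expect_true(bg_id %in% rep2$unexcluded)

  # coordinates beyond L give a malformed verdict
  dbad <- new_diagnosis("A", list(new_region(79, 99,
    paste(rep("A", 21), collapse = ""), 79)), "computed")
  expect_equal(verify_combination(dbad, g$alignment, g$map)$verdict,
               "malformed")
})

test_that("printed regions planted on synthetic sequences verify as pass", {
  blk <- readLines(diagnosis_block_path("lavesquei"), warn = FALSE)
  d <- parse_diagnosis_block(blk, species = "T. lavesquei")$diagnosis
  expect_gt(length(d$regions), 0L)
  set.seed(3)
  L <- 660L
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  focal <- base
  for (r in d$regions)
    focal[r$start:r$end] <- strsplit(r$motif, "")[[1]]
  bg <- focal
  for (r in d$regions) {
    # background differs at every diagnostic column of every region
    for (col in r$diagnostic_positions)
      bg[col] <- setdiff(c("A", "C", "G", "T"), bg[col])[1]
  }
  aln <- toy_alignment(f1 = paste(focal, collapse = ""),
                       f2 = paste(focal, collapse = ""),
                       b1 = paste(bg, collapse = ""))
  map <- c(f1 = "T. lavesquei", f2 = "T. lavesquei", b1 = "other")
  expect_equal(verify_combination(d, aln, map)$verdict, "pass")
})

test_that("minimization is a greedy set cover with the documented tie-break", {
  # three single-column regions with exclusion sets {s1,s2}, {s2,s3}, {s3}
  aln <- toy_alignment(f1 = "AAA", f2 = "AAA",
                       s1 = "CAA", s2 = "CCA", s3 = "ACC")
  map <- c(f1 = "X", f2 = "X", s1 = "Y", s2 = "Y", s3 = "Z")
  regs <- list(new_region(1, 1, "A", 1), new_region(2, 2, "A", 2),
               new_region(3, 3, "A", 3))
  d <- new_diagnosis("X", regs, "computed")
  m <- minimal_combination(d, aln, map)
  expect_equal(vapply(m$regions, `[[`, integer(1), "start"), c(1L, 2L))
  expect_equal(verify_combination(m, aln, map)$verdict, "pass")
  # brute force confirms the minimum cover size is 2
  sets <- list(c("s1", "s2"), c("s2", "s3"), "s3")
  expect_equal(oracle_min_cover_size(sets, c("s1", "s2", "s3")), 2)

  # two regions each excluding everything: smaller start wins
  aln2 <- toy_alignment(f1 = "AA", f2 = "AA", b1 = "CC", b2 = "GG")
  map2 <- c(f1 = "X", f2 = "X", b1 = "Y", b2 = "Y")
  d2 <- new_diagnosis("X", list(new_region(1, 1, "A", 1),
                                new_region(2, 2, "A", 2)), "computed")
  m2 <- minimal_combination(d2, aln2, map2)
  expect_length(m2$regions, 1L)
  expect_equal(m2$regions[[1]]$start, 1L)

  # single region: identity
  d3 <- new_diagnosis("X", list(new_region(1, 1, "A", 1)), "computed")
  expect_length(minimal_combination(d3, aln2, map2)$regions, 1L)

  # failing input is a precondition error
  dfail <- new_diagnosis("X", list(new_region(1, 1, "T", 1)), "computed")
  expect_error(minimal_combination(dfail, aln2, map2), "does not verify")
})

test_that("the block parser handles the printed dialect and its typos", {
  p <- parse_diagnosis_block("78–99: TCAACCCGGTGCTTACCTCGGT")
  expect_equal(p$report$flag, "")
  r <- p$diagnosis$regions[[1]]
  expect_equal(c(r$start, r$end), c(78L, 99L))
  expect_equal(nchar(r$motif), 22L)
  expect_equal(r$diagnostic_positions, 78:99)

  # plain hyphen and whitespace inside ranges are tolerated
  p2 <- parse_diagnosis_block("288- 292: CGTTA, 306: C")
  expect_equal(p2$report$flag, c("", ""))
  expect_equal(p2$diagnosis$regions[[2]][c("start", "end", "motif")],
               list(start = 306L, end = 306L, motif = "C"))

  # span/length mismatch is flagged, not repaired, and does not abort
  p3 <- parse_diagnosis_block("558–591: CCGT, 615–630: TCCAGCTGGTGGTGGT")
  expect_equal(p3$report$flag, c("span_length_mismatch", ""))
  expect_equal(p3$report$start[1], 558L)
  expect_equal(p3$report$end[1], 591L)
  expect_length(p3$diagnosis$regions, 1L)

  expect_error(parse_diagnosis_block("   "), "empty")
  expect_error(parse_diagnosis_block("no entries here"), "no parseable")
})

test_that("all six packaged printed blocks parse, with known flags", {
  flags <- list()
  for (f in diagnosis_block_path()) {
    sp <- sub("\\.txt$", "", basename(f))
    p <- parse_diagnosis_block(readLines(f, warn = FALSE), species = sp)
    expect_gt(length(p$diagnosis$regions), 5L)
    flags[[sp]] <- p$report$flag[p$report$flag != ""]
  }
  expect_equal(sort(flags$atlantis), "span_length_mismatch")   # 558-591: CCGT
  expect_true("span_length_mismatch" %in% flags$shetlandica)   # 78-98, 288-292
  expect_true("span_length_mismatch" %in% flags$irinae)        # 426 missing end
  expect_true("span_length_mismatch" %in% flags$gracilis)      # 450-545: TACA
})

test_that("parse/format are inverse on flag-free diagnoses", {
  d <- new_diagnosis("X", list(new_region(306, 306, "C", 306),
                               new_region(333, 342, "CGTCTACCCT", 333:342)),
                     "parsed")
  txt <- format_diagnosis_block(d)
  expect_equal(txt, "306: C, 333–342: CGTCTACCCT")
  back <- parse_diagnosis_block(txt)$diagnosis
  expect_identical(region_coords(back), region_coords(d))

  # computed diagnoses round-trip coordinates and motifs too
  g <- generate_alignment(sim_config(species = c("A", "B", "C"),
                                     n_per_species = 3, L = 100,
                                     regions_per_species = 3,
                                     region_length = c(3L, 7L), seed = 21))
  for (sp in c("A", "B", "C")) {
    d <- assemble_diagnosis(g$alignment, g$map, sp)
    back <- parse_diagnosis_block(format_diagnosis_block(d))$diagnosis
    expect_equal(vapply(back$regions, `[[`, integer(1), "start"),
                 vapply(d$regions, `[[`, integer(1), "start"))
    expect_equal(vapply(back$regions, `[[`, character(1), "motif"),
                 vapply(d$regions, `[[`, character(1), "motif"))
  }

  expect_warning(txt0 <- format_diagnosis_block(new_diagnosis("X")), "empty")
  expect_equal(txt0, "")
})

test_that("diagnosis profiles survive a JSON round-trip", {
  f <- withr::local_tempfile(fileext = ".json")
  g <- generate_alignment(sim_config(species = c("A", "B"),
                                     n_per_species = 3, L = 60,
                                     regions_per_species = 2,
                                     region_length = c(3L, 6L), seed = 13))
  profs <- lapply(c("A", "B"), function(sp)
    assemble_diagnosis(g$alignment, g$map, sp))
  write_diagnosis_profiles(profs, f)
  back <- read_diagnosis_profiles(f)
  expect_equal(lapply(back, region_coords), lapply(profs, region_coords))
  expect_equal(vapply(back, `[[`, character(1), "species"), c("A", "B"))
})
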