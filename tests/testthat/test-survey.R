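test_that("planted sites are recovered with exact category and span", {
  plants <- data.frame(
    category = c("8mer", "7mer-m8", "3p_only", "3p_microseed"),
    threep_start = c(NA, NA, 11L, 11L),
    threep_end = c(NA, NA, 22L, 22L),
    seed_len = c(NA, NA, NA, 4L),
    offset = c(NA, NA, NA, 2L))
  sim <- genUtrs(40, length = 200, guide = mir155, plants = plants,
                 seed = 17)
  ann <- scanUtrs(sim$utrs, mir155)
  truth <- sim$truth$planted
  expect_identical(nrow(ann), nrow(truth))
  m <- merge(ann, truth, by = "utr_id", suffixes = c("", ".true"))
  expect_identical(nrow(m), nrow(truth))
  expect_identical(m$category, m$category.true)
  expect_identical(m$start, m$start.true)
  expect_identical(m$end, m$end.true)
  # re-validate each annotation against its definition in isolation
  for (i in seq_len(nrow(m))) {
    frag <- substr(sim$utrs[[m$utr_id[i]]], m$start[i], m$end[i])
    if (m$category[i] == "3p_only")
      expect_identical(frag, oracleRc(substr(guideSeq(mir155), 11, 22)))
    if (m$category[i] == "8mer")
      expect_identical(frag,
                       paste0(oracleRc(substr(guideSeq(mir155), 2, 8)), "A"))
  }
})

test_that("a 4-nt seed run at offset +2 makes a microseed, not a 3'-only site", {
  core <- oracleRc(substr(guideSeq(mir155), 11, 22))  # 12-nt 3' match
  seed4 <- oracleRc(substr(guideSeq(mir155), 4, 7))   # m4_7 run
  bridge <- strrep("C", 2 + (11 - 7))                 # offset +2
  utr <- paste0(strrep("C", 30), core, bridge, seed4, strrep("C", 30))
  ann <- scanUtr(utr, mir155)
  expect_identical(ann$category, "3p_microseed")
  # the same 3' match with an inert downstream context is 3'-only
  utr2 <- paste0(strrep("C", 30), core, strrep("C", 40))
  expect_identical(scanUtr(utr2, mir155)$category, "3p_only")
  # a full 6-nt seed match at an in-window offset is canonical with
  # supplementary 3' pairing, not a 3p class
  seed6 <- oracleRc(substr(guideSeq(mir155), 2, 7))
  utr3 <- paste0(strrep("C", 30), core, bridge, seed6, "C",
                 strrep("C", 30))
  ann3 <- scanUtr(utr3, mir155)
  expect_true(any(ann3$category %in%
                    c("6mer", "7mer-A1", "7mer-m8", "8mer") &
                    ann3$supplementary_3p))
  expect_false(any(ann3$category %in% c("3p_only", "3p_microseed")))
})

test_that("chance ratios follow 4^k arithmetic", {
  expect_equal(chanceRatio(6, 10), 1 / 256)
  expect_equal(chanceRatio(7, 7), 1)
  expect_equal(chanceRatio(6, 8), 1 / 16)
})

test_that("survey summary computes proportions, medians and ranges", {
  ann <- data.frame(
    utr_id = "u", mirna = rep(c("a", "b", "c"), c(3, 2, 1)),
    start = 1, end = 7,
    category = c("8mer", "8mer", "3p_only", "6mer", "3p_only", "7mer-m8"),
    supplementary_3p = FALSE, ambiguous = FALSE)
  s <- summarizeSurvey(ann)
  pa <- s$perMirna[s$perMirna$mirna == "a", ]
  expect_equal(pa$prop_canonical, 2 / 3)
  expect_equal(pa$prop_3p_only, 1 / 3)
  med <- s$acrossMirnas
  expect_equal(med$median[med$category == "3p_only"], c(1))
  expect_equal(med$max[med$category == "8mer"], 2)
})

test_that("background site frequencies match the chance expectation", {
  set.seed(18)
  n <- 50; len <- 10000  # 5e5 nt of uniform background
  utrs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
          collapse = ""), character(1))
  names(utrs) <- paste0("u", seq_len(n))
  ann <- scanUtrs(utrs, mir155)
  L <- n * len
  # every canonical annotation corresponds to one match of the 6-nt seed
  # motif (longer classes are refinements of the same match)
  canonical <- sum(ann$category %in% c("6mer", "7mer-A1", "7mer-m8", "8mer"))
  expCan <- n * (len - 5) / 4^6
  expect_lt(abs(canonical - expCan), 3 * sqrt(expCan))
  # 3' classes: sum over registers of the maximal-run probability
  Lg <- guideLength(mir155)
  expP3 <- 0
  for (s in 9:(Lg - 9)) for (e in (s + 9):Lg) {
    width <- e - s + 1
    p <- 4^-width * (if (s > 9) 3 / 4 else 1) * (if (e < Lg) 3 / 4 else 1)
    expP3 <- expP3 + p * n * (len - width + 1)
  }
  p3 <- sum(ann$category %in% c("3p_only", "3p_microseed"))
  expect_lt(abs(p3 - expP3), 3 * sqrt(expP3) + 1)
  # no strand leakage: the reverse complement is an independent background
  rcUtrs <- vapply(utrs[1:10], function(u)
    as.character(Biostrings::reverseComplement(Biostrings::RNAString(u))),
    character(1))
  annRc <- scanUtrs(rcUtrs, mir155)
  c1 <- nrow(ann[ann$utr_id %in% paste0("u", 1:10), ]) / 10
  c2 <- nrow(annRc) / 10
  expect_lt(abs(c1 - c2), 4 * sqrt((c1 + c2) / 10 + 1))
})

test_that("DNA input and XStringSet input are accepted", {
  motif <- paste0(oracleRc(substr(guideSeq(mir155), 2, 8)), "A")
  dna <- chartr("U", "T", paste0(strrep("C", 30), motif, strrep("C", 30)))
  ann <- scanUtr(dna, mir155)
  expect_identical(ann$category, "8mer")
  ss <- Biostrings::DNAStringSet(c(x = dna))
  expect_identical(scanUtrs(ss, mir155)$category, "8mer")
})
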