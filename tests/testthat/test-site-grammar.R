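test_that("offset arithmetic follows bridge minus guide distance", {
  expect_identical(computeOffset(7, 13, 8), 2L)
  expect_identical(computeOffset(7, 13, 6), 0L)
  expect_identical(computeOffset(7, 9, 5), 3L)
  # increasing the bridge by k increases the offset by k
  base <- computeOffset(7, 13, 6)
  for (k in 1:5) expect_identical(computeOffset(7, 13, 6 + k), base + k)
  expect_error(computeOffset(7, 7, 3), "exceed")
  expect_error(computeOffset(7, 5, 3), "exceed")
  expect_error(computeOffset(7, 13, -1), ">= 0")
})

test_that("guide construction normalizes DNA and validates alphabet/length", {
  g <- MirnaGuide("x", "TGAGGTAGTAGGTTGTATAGTT")
  expect_identical(guideSeq(g), guideSeq(let7a))
  expect_identical(guideLength(let7a), 22L)
  expect_error(MirnaGuide("x", "ACGU"), "length")
  expect_error(MirnaGuide("x", strrep("ACGX", 5)), "invalid nucleotide")
})

test_that("canonical classification ranks 8mer > 7mer-m8 > ... correctly", {
  rc27 <- oracleRc(substr(guideSeq(let7a), 2, 7))  # CUACCU? via oracle
  rc28 <- oracleRc(substr(guideSeq(let7a), 2, 8))
  pad <- function(x) paste0("UUUUUU", x, "UUUUUU")
  expect_identical(classifyCanonical(pad(paste0(rc28, "A")), let7a)@category,
                   "8mer")
  expect_identical(classifyCanonical(pad(paste0(rc28, "G")), let7a)@category,
                   "7mer-m8")
  expect_identical(classifyCanonical(pad(paste0(rc27, "A")), let7a)@category,
                   "7mer-A1")
  expect_identical(classifyCanonical(pad(paste0(rc27, "G")), let7a)@category,
                   "6mer")
  rc38 <- oracleRc(substr(guideSeq(let7a), 3, 8))
  expect_identical(classifyCanonical(pad(paste0(rc38, "G")), let7a)@category,
                   "6mer-m8")
  rc26 <- oracleRc(substr(guideSeq(let7a), 2, 6))
  # pad with C so the run cannot extend to g7 (= A, partner U)
  expect_identical(
    classifyCanonical(paste0("CCCCCC", rc26, "A", "CCCCCC"), let7a)@category,
    "6mer-A1")
  expect_identical(classifyCanonical(strrep("A", 30), let7a)@category, "none")
})

test_that("3' match search returns maximal runs only, with correct spans", {
  core <- oracleRc(substr(guideSeq(let7a), 11, 18))
  read <- paste0("GGGG", core, "GGGG")
  m <- findThreePrimeMatches(read, let7a, minLen = 8)
  expect_identical(nrow(m), 1L)
  expect_identical(m$guide_start, 11L)
  expect_identical(m$guide_end, 18L)
  expect_identical(m$target_start, 5L)
  expect_identical(m$target_end, 12L)
  # a full m11_22 match is reported once, not as its sub-registers
  read2 <- paste0("GGGG", oracleRc(substr(guideSeq(let7a), 11, 22)), "GGGG")
  m2 <- findThreePrimeMatches(read2, let7a, minLen = 8)
  expect_identical(nrow(m2), 1L)
  expect_identical(c(m2$guide_start, m2$guide_end), c(11L, 22L))
  expect_identical(nrow(findThreePrimeMatches(strrep("A", 40), let7a,
                                              minLen = 8)), 0L)
})

test_that("compound assignment combines 3' match, bridge and seed", {
  # rc(g11-18) . 6-nt bridge (inert) . rc(g2-7): offset 6 - (11-7) = +2
  read <- paste0("GGGG", oracleRc(substr(guideSeq(let7a), 11, 18)),
                 "AAAAAA", oracleRc(substr(guideSeq(let7a), 2, 7)), "GGGG")
  a <- assignSites(read, let7a)
  expect_identical(a$site, "m11_18|+2|m2_7")
  expect_identical(a$category, "compound")
  d <- assignSite(read, let7a)
  expect_s4_class(d, "SiteDescriptor")
  expect_identical(siteName(d), "m11_18|+2|m2_7")
  # seed-only and empty reads
  expect_identical(
    assignSites(paste0("UUUUUUUUUU",
                       oracleRc(substr(guideSeq(let7a), 2, 8)), "A",
                       strrep("U", 20)), let7a)$site, "8mer")
  expect_identical(assignSites(strrep("C", 40), let7a)$site, "none")
})

test_that("site names round-trip through parse and format", {
  for (nm in c("m13_20|+2|m2_7", "m9_19|+3|m2_5", "m11_23|-4|m3_8",
               "m13_20|+0|m2_8", "m10_20", "8mer", "7mer-A1", "6mer-m8",
               "none"))
    expect_identical(siteName(parseSiteName(nm)), nm)
  d <- parseSiteName("m13_20|+2|m2_7")
  expect_identical(c(d@threepStart, d@threepEnd), c(13L, 20L))
  expect_identical(d@offset, 2L)
  expect_identical(c(d@seedStart, d@seedEnd), c(2L, 7L))
  expect_error(parseSiteName("m13_20|2|m2_7"), "malformed")
  expect_error(parseSiteName("9mer"), "malformed")
  expect_error(parseSiteName("m20_13"), "start > end")
})

test_that("read assignment agrees with the brute-force oracle on random reads", {
  set.seed(42)
  reads <- randRead(400)
  # enrich for non-trivial categories: plant partial guide fragments
  frag <- vapply(1:200, function(i) {
    s <- sample(9:14, 1); e <- min(s + sample(7:12, 1), guideLength(mir155))
    oracleRc(substr(guideSeq(mir155), s, e))
  }, character(1))
  pos <- sample(1:15, 200, replace = TRUE)
  planted <- reads[201:400]
  substr(planted, pos, pos + nchar(frag) - 1L) <- frag
  reads[201:400] <- planted
  got <- assignSites(reads, mir155)
  for (i in seq_along(reads)) {
    exp <- oracleAssign(reads[i], guideSeq(mir155))
    expect_identical(got$site[i], exp$site,
                     label = paste("read", i, reads[i]))
  }
})

test_that("reported segments are Watson-Crick and unextendable", {
  set.seed(7)
  reads <- randRead(300, 40)
  got <- assignSites(reads, mir124)
  gseq <- guideSeq(mir124)
  for (i in which(got$category %in% c("3p_only", "compound"))) {
    gs <- got$threep_start[i]; ge <- got$threep_end[i]
    ts <- got$target_start[i]
    len <- ge - gs + 1L
    expect_identical(substr(reads[i], ts, ts + len - 1L),
                     oracleRc(substr(gseq, gs, ge)))
  }
})

test_that("survey preset drops offset-6mer classes from assignment", {
  rc38 <- oracleRc(substr(guideSeq(let7a), 3, 8))
  read <- paste0("UUUUUU", rc38, "G", strrep("U", 25))
  expect_identical(assignSites(read, let7a)$site, "6mer-m8")
  expect_identical(assignSites(read, let7a, siteConfig("survey"))$site,
                   "none")
})

test_that("wobble flag admits G:U pairs only when enabled", {
  # rc(g13-g22) flanked so neither end can extend by WC pairing
  core <- oracleRc(substr(guideSeq(mir155), 13, 22))
  wc <- paste0("GGGG", core, "CCCCCC")
  pos <- 4 + nchar(core) - 1  # pairs g14 (= U); wobble partner is G
  wob <- wc
  substr(wob, pos, pos) <- "G"
  expect_identical(assignSites(wc, mir155)$site, "m13_22")
  strict <- assignSites(wob, mir155)
  expect_false(!is.na(strict$threep_start) && strict$threep_start <= 13 &&
                 strict$threep_end >= 22)
  loose <- assignSites(wob, mir155, siteConfig("rbns", wobble = TRUE))
  expect_true(loose$threep_start <= 13 && loose$threep_end >= 22)
})
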