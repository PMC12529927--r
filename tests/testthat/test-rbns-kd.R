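makeTable <- function(counts) {
  rbnsCountTable(counts, roles = c("input", rep("bound", ncol(counts) - 1L)))
}

test_that("enrichment is the bound/input proportion ratio", {
  cnt <- rbind(none = c(4900, 4900, 4800), siteA = c(10, 100, 150),
               siteB = c(90, 0, 50))
  colnames(cnt) <- c("input", "b1", "b2")
  e <- enrichment(makeTable(cnt))
  expect_equal(e["siteA", "b1"], (100 / 5000) / (10 / 5000))
  expect_equal(e["none", "b1"], (4900 / 5000) / (4900 / 5000))
  # site absent from input is omitted, not infinite
  cnt2 <- rbind(cnt, siteC = c(0, 10, 10))
  colnames(cnt2) <- colnames(cnt)
  expect_warning(e2 <- enrichment(makeTable(cnt2)), "omitted")
  expect_false("siteC" %in% rownames(e2))
  expect_true(all(is.finite(e2)))
})

test_that("expected bound frequencies are invariant to joint kappa/a scaling", {
  f <- c(siteA = 0.02, siteB = 0.05, none = 0.93)
  kap <- c(siteA = 0.01, siteB = 0.3, none = 1)
  a <- c(1, 0.1, 0.01)
  g1 <- rbnsExpectedFreqs(f, kap, a)
  g2 <- rbnsExpectedFreqs(f, 2 * kap, 2 * a)
  expect_equal(g1, g2, tolerance = 1e-12)
  expect_equal(colSums(g1), rep(1, 3), ignore_attr = TRUE)
  # smaller kappa => larger enrichment g/f at every sample
  expect_true(all(g1["siteA", ] / f["siteA"] > g1["siteB", ] / f["siteB"]))
})

test_that("relative Kd recovery on simulated pools, with kappa['none'] pinned", {
  # abundant classes in the programmed library: compound sites with short
  # seed runs, plus canonical classes from the random half
  kap <- c("m13_20|-5|m7_8" = 0.02, "m13_20|-7|m5_6" = 0.1,
           "6mer-m8" = 0.3, "6mer" = 0.6)
  pools <- genRbnsPools(mir155, kap, aList = c(1, 0.3, 0.1, 0.03),
                        depth = 3e4, seed = 11)
  tab <- countSiteReads(c(list(input = pools$input), pools$bound), mir155)
  fit <- fitRelativeKd(tab, minReads = 30)
  expect_identical(relKd(fit)[["none"]], 1)
  est <- relKd(fit)[names(kap)]
  expect_false(anyNA(est))
  expect_true(all(est / kap < 2 & est / kap > 0.5))
  expect_identical(order(est), order(kap))
  # likelihood at the optimum >= likelihood at the truth
  cnt <- SummarizedExperiment::assay(tab, "counts")
  fitSites <- names(relKd(fit))
  nb <- cnt[fitSites, -1, drop = FALSE]
  f <- fit@inputFreq[fitSites]
  llAt <- function(kv, av) {
    g <- rbnsExpectedFreqs(f, kv, av)
    sum(nb * log(g[, rep(seq_along(av), length.out = ncol(nb))]))
  }
  truthK <- stats::setNames(rep(1, length(fitSites)), fitSites)
  truthK[names(kap)] <- kap
  expect_gte(fit@logLik + 1e-6,
             llAt(truthK, pools$truth$a))
})

test_that("a null site fits kappa close to 1", {
  set.seed(3)
  f <- c(siteX = 0.1, siteY = 0.02, none = 0.88)
  kap <- c(siteX = 1, siteY = 0.05, none = 1)
  a <- c(0.5, 0.1, 0.02)
  g <- rbnsExpectedFreqs(f, kap, a)
  cnt <- cbind(stats::rmultinom(1, 2e5, f),
               vapply(1:3, function(i) stats::rmultinom(1, 2e5, g[, i])[, 1],
                      numeric(3)))
  dimnames(cnt) <- list(names(f), c("input", "b1", "b2", "b3"))
  fit <- fitRelativeKd(makeTable(cnt), minReads = 30)
  expect_lt(abs(log(relKd(fit)[["siteX"]])), log(1.3))
  expect_lt(abs(log(relKd(fit)[["siteY"]] / 0.05)), log(1.5))
  # model self-consistency: refit on expected counts reproduces parameters
  cnt2 <- cbind(round(2e5 * f), round(2e5 * g))
  dimnames(cnt2) <- list(names(f), c("input", "b1", "b2", "b3"))
  fit2 <- fitRelativeKd(makeTable(cnt2), minReads = 30)
  expect_equal(relKd(fit2)[["siteY"]], 0.05, tolerance = 0.05)
})

test_that("low-count sites are reported not-determined", {
  cnt <- rbind(none = c(9000, 9000, 9000), siteA = c(500, 900, 1500),
               rare = c(3, 4, 2))
  colnames(cnt) <- c("input", "b1", "b2")
  fit <- fitRelativeKd(makeTable(cnt), minReads = 50)
  expect_identical(fit@notDetermined, "rare")
  expect_false("rare" %in% names(relKd(fit)))
})

test_that("bootstrap intervals are seeded, ordered and cover the truth", {
  kap <- c("m13_20|-5|m7_8" = 0.05, "6mer-m8" = 0.3)
  pools <- genRbnsPools(mir155, kap, aList = c(1, 0.2, 0.05), depth = 8000,
                        seed = 5)
  tab <- countSiteReads(c(list(input = pools$input), pools$bound), mir155)
  ci1 <- bootstrapCI(tab, nBoot = 30, seed = 9, minReads = 30)
  ci2 <- bootstrapCI(tab, nBoot = 30, seed = 9, minReads = 30)
  expect_identical(kdCI(ci1), kdCI(ci2))
  ci <- kdCI(ci1)
  expect_true(all(ci[, "lo"] <= relKd(ci1)[rownames(ci)] + 1e-9))
  expect_true(all(ci[, "hi"] >= relKd(ci1)[rownames(ci)] - 1e-9))
  for (s in names(kap))
    expect_true(ci[s, "lo"] <= kap[[s]] && kap[[s]] <= ci[s, "hi"])
})

# reads carrying rc(g10-g20) of miR-155 in an inert context: upstream
# poly(A) cannot extend the duplex to g21 (= G) and downstream poly(C)
# cannot seed-pair beyond single nucleotides, so the class is controlled
# entirely by the flank base opposite guide position 9
flankRead <- function(flank) {
  core <- oracleRc(substr(guideSeq(mir155), 10, 20))
  # pad base chosen so the flank+pad junction cannot form a seed dinucleotide
  pad <- if (flank == "G") "G" else "C"
  paste0(strrep("A", 9), core, flank,
         strrep(pad, 40 - 9 - nchar(core) - 1))
}

test_that("flank stratification equals the longer register by construction", {
  set.seed(21)
  flank <- sample(c("A", "C", "G", "U"), 600, replace = TRUE)
  reads <- vapply(flank, flankRead, character(1))
  asn <- assignSites(reads, mir155)
  # guide position 9 of miR-155 is A, so the complementary flank is U and
  # those reads are classified as the longer m9_20 register
  expect_identical(sum(asn$site == "m9_20"), sum(flank == "U"))
  tab <- stratifyByFlank(list(input = reads, bound = reads), mir155,
                         "m10_20")
  cnt <- SummarizedExperiment::assay(tab, "counts")
  expect_identical(cnt["m10_20|flankU", "input"], sum(flank == "U"))
  for (b in c("A", "C", "G"))
    expect_identical(cnt[paste0("m10_20|flank", b), "input"],
                     sum(flank == b))
})

test_that("flank-dependent affinities are recovered after stratification", {
  set.seed(31)
  # 'bg' molecules carry no site and anchor the no-site background
  kapClass <- c(A = 0.05, C = 0.2, G = 0.5, U = 0.5, bg = 1)
  bgRead <- paste0(strrep("A", 20), strrep("C", 20))
  makePool <- function(n)
    sample(names(kapClass), n, replace = TRUE,
           prob = c(rep(0.15, 4), 0.4))
  accept <- function(cls, a) {
    k <- kapClass[cls]
    cls[stats::runif(length(k)) < a / (a + k)]
  }
  toReads <- function(cls)
    ifelse(cls == "bg", bgRead, vapply(cls, flankRead, character(1)))
  input <- toReads(makePool(6000))
  b1 <- toReads(accept(makePool(20000), 0.3))
  b2 <- toReads(accept(makePool(20000), 0.1))
  tab <- stratifyByFlank(list(input = input, b1 = b1, b2 = b2), mir155,
                         "m10_20")
  fit <- fitRelativeKd(tab, minReads = 30)
  kA <- relKd(fit)[["m10_20|flankA"]]
  kU <- relKd(fit)[["m10_20|flankU"]]
  expect_lt(kA, kU)
  expect_lt(kA / 0.05, 3)
  expect_gt(kA / 0.05, 1 / 3)
})
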