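test_that("noiseless saturation curves return the exact Kd", {
  conc <- 1e-12 * 10^seq(0, 4, length.out = 8)
  kd <- 100e-12
  fit <- fitSaturation(conc, conc / (conc + kd), nBoot = 0)
  expect_identical(fit@boundFlag, "measured")
  expect_lt(abs(fit@kd / kd - 1), 1e-3)
  # the fitted curve passes through theta = 0.5 at the Kd
  expect_equal(fit@kd / (fit@kd + fit@kd), 0.5)
  expect_error(fitSaturation(conc[1:3], (conc / (conc + kd))[1:3]),
               "4 concentration")
})

test_that("bound-reporting convention flags weak and saturated targets", {
  conc <- 1e-12 * 10^seq(0, 4, length.out = 8)  # up to 10 nM
  weak <- fitSaturation(conc, conc / (conc + 1e-6))  # max theta ~ 1%
  expect_identical(weak@boundFlag, "lower_bound_10nM")
  expect_identical(weak@kd, 10e-9)
  zero <- fitSaturation(conc, rep(0, 8))
  expect_identical(zero@boundFlag, "lower_bound_10nM")
  conc2 <- 1e-11 * 10^seq(0, 3, length.out = 8)  # lowest point 10 pM
  sat <- fitSaturation(conc2, conc2 / (conc2 + 5e-13))
  expect_identical(sat@boundFlag, "upper_bound_5pM")
  expect_identical(sat@kd, 5e-12)
})

test_that("noisy saturation recovery is accurate with covering intervals", {
  kd <- 70e-12
  conc <- 1e-12 * 10^seq(0, 4, length.out = 8)
  sim <- genBindingData("saturation",
                        list(kd = kd, conc = rep(conc, 3)),
                        noiseSd = 0.03, seed = 8)
  fit <- fitSaturation(sim$data$conc, sim$data$theta, nBoot = 100, seed = 8)
  expect_lt(abs(fit@kd / kd - 1), 0.2)
  expect_true(fit@ci[1] <= kd && kd <= fit@ci[2])
})

test_that("association fits recover kon, pooled across concentrations", {
  kon <- 1e7; aT <- 1e-9; arEq <- 1
  times <- c(5, 15, 30, 60, 120, 300, 600)
  ar <- arEq * (1 - exp(-kon * aT * times))
  fit <- fitAssociation(times, ar, aT)
  expect_lt(abs(fit@kon / kon - 1), 1e-3)
  # half of the equilibrium signal is reached at t = ln2 / (kon A_T)
  tHalf <- log(2) / (kon * aT)
  expect_equal(arEq * (1 - exp(-fit@kon * aT * tHalf)), 0.5,
               tolerance = 1e-3)
  # pooled series sharing one kon
  sim <- genBindingData("kinetics",
                        list(kon = kon, aTotal = c(1e-10, 3e-10, 1e-9),
                             arEq = 0.8, times = times),
                        noiseSd = 0.05, seed = 3)
  pfit <- fitAssociation(sim$data$time, sim$data$ar, sim$data$aTotal)
  expect_lt(abs(log2(pfit@kon / kon)), 1)
  expect_identical(length(pfit@arEq), 3L)
  expect_error(fitAssociation(times, ar, 50e-12), "80 pM")
  expect_warning(fitAssociation(times, rev(ar), aT), "non-increasing")
})

test_that("koff derives from Kd and kon with bound-flag propagation", {
  expect_equal(deriveKoff(100e-12, 1e8)$koff, 1e-2)
  # equal Kd with 10-fold slower kon implies 10-fold slower koff
  expect_equal(deriveKoff(100e-12, 1e7)$koff,
               deriveKoff(100e-12, 1e8)$koff / 10)
  up <- deriveKoff(5e-12, 1e7, boundFlag = "upper_bound_5pM")
  expect_identical(up$flag, "upper_bound")
  expect_equal(up$koff, 5e-5)
  conc <- 1e-12 * 10^seq(0, 4, length.out = 8)
  weak <- fitSaturation(conc, rep(0.01, 8))
  expect_identical(deriveKoff(weak, 1e7)$flag, "lower_bound")
})

test_that("observed free energy follows dG = RT ln(Kd)", {
  expect_identical(deltaGObserved(1), 0)
  expect_equal(deltaGObserved(0.01, 310.15), -2.84, tolerance = 0.005)
  kds <- 10^seq(-4, 0, 0.5)
  expect_true(all(diff(deltaGObserved(kds)) > 0))
})

test_that("nearest-neighbor sums match hand summation from the shipped table", {
  tb <- read.delim(system.file("extdata", "nn_stacks_rna37.tsv",
                               package = "seedless"))
  stacks <- stats::setNames(tb$dg_kcal_mol, tb$stack)
  p <- nnParams()
  # 2-nt duplex: one stack + initiation + terminal penalties
  expect_equal(deltaGPredictedNN("GC"), stacks[["GC"]] + 4.09)
  expect_equal(deltaGPredictedNN("AU"),
               stacks[["AU"]] + 4.09 + 2 * 0.45)
  seg <- "GCAUCGA"
  hand <- sum(stacks[substring(seg, 1:6, 2:7)]) + 4.09 + 0.45  # one AU end
  expect_equal(deltaGPredictedNN(seg), hand)
  # duplex symmetry: the reverse complement strand describes the same duplex
  rc <- as.character(Biostrings::reverseComplement(Biostrings::RNAString(seg)))
  expect_equal(deltaGPredictedNN(seg), deltaGPredictedNN(rc))
  # appending one pair adds exactly one stack term (+/- the AU end delta)
  seg2 <- paste0(seg, "G")
  delta <- stacks[[substring(seg2, 7, 8)]] - 0.45  # A-end replaced by G-end
  expect_equal(deltaGPredictedNN(seg2) - deltaGPredictedNN(seg), delta)
  expect_error(deltaGPredictedNN("G"), "at least 2")
})

test_that("observed-vs-predicted energy comparison separates site families", {
  # seed sites: AGO pre-organization makes observed dG more negative than
  # the solution prediction, with a steeper dependence; 3'-region pairing
  # pays an AGO penalty: observed less negative, shallower slope
  set.seed(9)
  pred <- seq(-12, -6, length.out = 20)
  rec <- rbind(
    data.frame(family = "seed", category = "7mer-m8", dg_pred = pred,
               dg_obs = 1.2 * pred - 2 + rnorm(20, 0, 0.1)),
    data.frame(family = "3p_only", category = "3p_only", dg_pred = pred,
               dg_obs = 0.5 * pred + 1 + rnorm(20, 0, 0.1)),
    data.frame(family = "seed", category = "8mer", dg_pred = pred,
               dg_obs = rep(100, 20)))  # A1 class: must be excluded
  cmp <- compareDeltaG(rec)
  seedRow <- cmp[cmp$family == "seed", ]
  p3Row <- cmp[cmp$family == "3p_only", ]
  expect_identical(seedRow$n, 20L)  # the 8mer rows were dropped
  expect_lt(seedRow$mean_diff, 0)   # obs below prediction
  expect_gt(p3Row$mean_diff, 0)     # obs above prediction
  expect_lt(p3Row$slope, seedRow$slope)
})
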