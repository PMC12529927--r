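#' @include AllClasses.R
NULL

#' Leave-one-out log2 fold changes from a logTPM matrix
#'
#' For each gene, the log2 fold change upon transfecting `mirna` is its
#' log10 TPM in that sample minus the mean of its log10 TPM in all other
#' samples, converted to log2 (factor `log2(10)`).
#'
#' @param mat numeric matrix of log10-transformed TPM values, genes x
#'   samples.
#' @param mirna column name (the transfected miRNA sample).
#' @return named numeric of per-gene log2 fold changes; genes with missing
#'   values are dropped with a message.
#' @export
leaveOneOutFC <- function(mat, mirna) {
  stopifnot(ncol(mat) >= 2L, mirna %in% colnames(mat))
  drop <- !stats::complete.cases(mat)
  if (any(drop))
    message(sum(drop), " gene(s) with missing values dropped")
  mat <- mat[!drop, , drop = FALSE]
  others <- mat[, colnames(mat) != mirna, drop = FALSE]
  (mat[, mirna] - rowMeans(others)) * log2(10)
}

#' Sample UTR-length-matched no-site control genes
#'
#' Matches the control cohort's UTR-length distribution to the site cohort
#' by decile stratification: the pool is cut at the cohort's length
#' deciles and controls are drawn per stratum in proportion to the cohort.
#' Strata with too few candidates are relaxed to the nearest stratum with
#' a warning. Deterministic given `seed`.
#'
#' @param cohortLengths named numeric, UTR lengths of the cohort genes.
#' @param poolLengths named numeric, UTR lengths of candidate no-site
#'   genes.
#' @param seed RNG seed.
#' @param nStrata number of length strata (default 10).
#' @return character vector of control gene names, same size as the
#'   cohort.
#' @export
matchControls <- function(cohortLengths, poolLengths, seed = 1L,
                          nStrata = 10L) {
  stopifnot(length(poolLengths) >= length(cohortLengths))
  set.seed(seed)
  if (length(cohortLengths) == 1L) {
    return(names(poolLengths)[which.min(abs(poolLengths - cohortLengths))])
  }
  br <- unique(stats::quantile(cohortLengths,
                               probs = seq(0, 1, length.out = nStrata + 1L)))
  br[1] <- -Inf; br[length(br)] <- Inf
  if (length(br) < 2L) br <- c(-Inf, Inf)
  cstr <- cut(cohortLengths, br, labels = FALSE)
  pstr <- cut(poolLengths, br, labels = FALSE)
  picked <- character()
  avail <- names(poolLengths)
  for (s in sort(unique(cstr))) {
    need <- sum(cstr == s)
    inS <- avail[pstr[match(avail, names(poolLengths))] == s]
    if (length(inS) < need) {
      warning("stratum ", s, " has ", length(inS), " candidates for ", need,
              " cohort genes; relaxing to nearest lengths")
      mid <- stats::median(cohortLengths[cstr == s])
      inS <- avail[order(abs(poolLengths[avail] - mid))][seq_len(need)]
      take <- inS
    } else {
      take <- sample(inS, need)
    }
    picked <- c(picked, take)
    avail <- setdiff(avail, take)
  }
  picked
}

#' One-sided Kolmogorov-Smirnov test for repression
#'
#' Tests whether the cohort's log2 fold-change distribution is shifted
#' toward repression (stochastically smaller) relative to the controls,
#' i.e. its CDF lies above the control CDF. Small samples (< 5 in either
#' group) are flagged low-power, not rejected.
#'
#' @param cohortFC,controlFC numeric log2 fold changes.
#' @return list with `D` (one-sided statistic), `p`, `lowPower`.
#' @export
ksOneSided <- function(cohortFC, controlFC) {
  stopifnot(length(cohortFC) > 0, length(controlFC) > 0)
  kt <- suppressWarnings(stats::ks.test(cohortFC, controlFC,
                                        alternative = "greater"))
  list(D = unname(kt$statistic), p = kt$p.value,
       lowPower = length(cohortFC) < 5L || length(controlFC) < 5L)
}

#' Cohort-level repression analysis
#'
#' Runs the full per-miRNA cohort comparison: leave-one-out fold changes,
#' length-matched control sampling, and the one-sided KS test, optionally
#' aggregating site-containing and control genes across several miRNAs
#' before testing (used to pool rare site types).
#'
#' @param mat log10 TPM matrix, genes x samples.
#' @param cohorts named list (one element per miRNA/sample name) of gene
#'   identifier vectors carrying the site.
#' @param utrLengths named numeric of UTR lengths for all genes.
#' @param noSiteGenes named list (parallel to `cohorts`) of candidate
#'   no-site gene vectors.
#' @param aggregate pool fold changes across miRNAs before testing.
#' @param seed RNG seed for control matching.
#' @return data.frame (one row per miRNA, or a single `"aggregate"` row):
#'   `cohort_n`, `D`, `p`, `low_power`, `mean_shift`.
#' @export
cohortResponse <- function(mat, cohorts, utrLengths, noSiteGenes,
                           aggregate = FALSE, seed = 1L) {
  allFC <- list(); allCtl <- list(); rows <- list()
  for (m in names(cohorts)) {
    fc <- leaveOneOutFC(mat, m)
    genes <- intersect(cohorts[[m]], names(fc))
    pool <- intersect(noSiteGenes[[m]], names(fc))
    if (!length(genes) || length(pool) < length(genes)) next
    ctl <- matchControls(utrLengths[genes], utrLengths[pool], seed = seed)
    allFC[[m]] <- fc[genes]; allCtl[[m]] <- fc[ctl]
    if (!aggregate) {
      kt <- ksOneSided(fc[genes], fc[ctl])
      rows[[m]] <- data.frame(
        mirna = m, cohort_n = length(genes), D = kt$D, p = kt$p,
        low_power = kt$lowPower,
        mean_shift = mean(fc[genes]) - mean(fc[ctl]))
    }
  }
  if (aggregate) {
    x <- unlist(allFC); y <- unlist(allCtl)
    kt <- ksOneSided(x, y)
    return(data.frame(mirna = "aggregate", cohort_n = length(x), D = kt$D,
                      p = kt$p, low_power = kt$lowPower,
                      mean_shift = mean(x) - mean(y)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
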