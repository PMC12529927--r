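#' @include AllClasses.R AllGenerics.R site-grammar.R
NULL

#' Build an RbnsCountTable
#'
#' @param counts integer matrix, sites x samples, with a `"none"` row. The
#'   first column (or the column flagged by `roles`) is the input sample.
#' @param roles character vector, one of `"input"`/`"bound"` per column;
#'   default: first column input, rest bound.
#' @param labels sample labels (e.g. nominal AGO dilutions); default column
#'   names.
#' @return an [RbnsCountTable-class].
#' @export
rbnsCountTable <- function(counts, roles = NULL, labels = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(roles))
    roles <- c("input", rep("bound", ncol(counts) - 1L))
  if (is.null(labels))
    labels <- if (!is.null(colnames(counts))) colnames(counts) else
      paste0(roles, seq_len(ncol(counts)))
  colnames(counts) <- labels
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(role = roles, label = labels))
  new("RbnsCountTable", se)
}

#' Count site assignments across RBNS samples
#'
#' Classifies each sample's reads with [assignSites()] and tabulates reads
#' per site name, including the `"none"` background.
#'
#' @param readsBySample named list of read vectors; the element named
#'   `"input"` (or the first element) is the input library.
#' @param guide a [MirnaGuide-class].
#' @param config a [SiteConfig-class].
#' @return an [RbnsCountTable-class] over the union of observed sites.
#' @export
countSiteReads <- function(readsBySample, guide,
                           config = siteConfig("rbns")) {
  if (is.null(names(readsBySample)))
    names(readsBySample) <- c("input",
                              paste0("bound", seq_along(readsBySample)[-1]))
  idx <- match("input", names(readsBySample))
  if (is.na(idx)) idx <- 1L
  ord <- c(idx, setdiff(seq_along(readsBySample), idx))
  readsBySample <- readsBySample[ord]
  tabs <- lapply(readsBySample, function(r)
    table(assignSites(r, guide, config)$site))
  sites <- unique(c("none", unlist(lapply(tabs, names))))
  counts <- vapply(tabs, function(tb) {
    v <- integer(length(sites)); names(v) <- sites
    v[names(tb)] <- as.integer(tb)
    v
  }, integer(length(sites)))
  rownames(counts) <- sites
  rbnsCountTable(counts,
                 roles = c("input", rep("bound", ncol(counts) - 1L)),
                 labels = names(readsBySample))
}

rbnsCounts <- function(table) SummarizedExperiment::assay(table, "counts")
rbnsRoles <- function(table) SummarizedExperiment::colData(table)$role

#' Site enrichment across bound samples
#'
#' Enrichment of a site in a bound sample is the proportion of reads
#' assigned to the site in that sample divided by its proportion in the
#' input sample. Sites with zero input proportion at `pseudocount = 0` are
#' omitted (with a warning), not reported as infinite.
#'
#' @param table an [RbnsCountTable-class].
#' @param pseudocount added to every count before forming proportions
#'   (default 0).
#' @return numeric matrix, sites x bound samples.
#' @export
enrichment <- function(table, pseudocount = 0) {
  stopifnot(pseudocount >= 0)
  cnt <- rbnsCounts(table)
  input <- cnt[, rbnsRoles(table) == "input", drop = TRUE] + pseudocount
  bound <- cnt[, rbnsRoles(table) == "bound", drop = FALSE] + pseudocount
  if (sum(input) <= 0) stop("input depth must be > 0")
  fin <- input / sum(input)
  fb <- sweep(bound, 2, colSums(bound), "/")
  keep <- fin > 0
  if (!all(keep))
    warning(sum(!keep), " site(s) absent from input omitted from enrichment")
  fb[keep, , drop = FALSE] / fin[keep]
}

#' Expected bound-sample site frequencies under the occupancy model
#'
#' For input frequencies `f`, relative Kd `kappa` and free-AGO scale `a`,
#' the occupancy of site j in sample i is `p_ij = a_i / (a_i + kappa_j)` and
#' the expected bound frequency is `g_ij = f_j p_ij / sum_k f_k p_ik`.
#'
#' @param f named input frequencies (sum to 1).
#' @param kappa named relative Kd values over the same sites.
#' @param a free-AGO scale per bound sample (no-site-Kd units).
#' @return matrix of expected frequencies, sites x samples.
#' @export
rbnsExpectedFreqs <- function(f, kappa, a) {
  kappa <- kappa[names(f)]
  g <- vapply(a, function(ai) {
    w <- f * ai / (ai + kappa)
    w / sum(w)
  }, numeric(length(f)))
  rownames(g) <- names(f)
  g
}

# Negative log-likelihood and gradient over par = c(log kappa[-none], log a).
rbnsNegLogLik <- function(par, nb, f, J, I, grad = FALSE) {
  logk <- c(par[seq_len(J - 1L)], 0)  # none pinned at log kappa = 0, last
  loga <- par[J:(J + I - 1L)]
  kappa <- exp(logk); a <- exp(loga)
  P <- outer(kappa, a, function(k, ai) ai / (ai + k))  # J x I occupancy
  W <- f * P
  Z <- colSums(W)
  G <- sweep(W, 2, Z, "/")
  nll <- -sum(nb * log(G))
  if (!grad) return(nll)
  N <- colSums(nb)
  Q <- 1 - P                                  # (1 - p_ij)
  WQ <- W * Q
  sumWQ <- colSums(WQ)
  # d ll / d log a_i ; d ll / d log kappa_j
  dA <- colSums(nb * Q) - N * sumWQ / Z
  dK <- -(rowSums(nb * Q) - rowSums(sweep(WQ, 2, N / Z, "*")))
  list(value = nll, gradient = -c(dK[seq_len(J - 1L)], dA))
}

#' Fit relative Kd values by multinomial maximum likelihood
#'
#' Models each bound sample as a multinomial draw over site classes with
#' expected frequencies `g_ij = f_j p_ij / sum_k f_k p_ik`, occupancy
#' `p_ij = a_i / (a_i + kappa_j)`, input frequencies `f` estimated from the
#' input sample with a pseudocount, the no-site class pinned at
#' `kappa = 1`, and a latent free-AGO scale `a_i` per bound sample
#' (no-site-Kd units). Optimized over log-parameters with analytic
#' gradients (L-BFGS-B). The overall scale of (kappa, a) is not identified
#' by the data, which is why the no-site class is pinned.
#'
#' @param table an [RbnsCountTable-class].
#' @param minReads minimum total bound reads for a site to be fitted
#'   (default 50); sites below it are reported in `notDetermined`.
#' @param pseudocount added to input counts for the plug-in frequencies
#'   (default 1).
#' @param maxit optimizer iteration cap.
#' @return a [RelKdFit-class].
#' @export
fitRelativeKd <- function(table, minReads = 50, pseudocount = 1,
                          maxit = 500L) {
  cnt <- rbnsCounts(table)
  if (sum(rbnsRoles(table) == "bound") < 2L)
    stop("need at least 2 bound samples")
  input <- cnt[, rbnsRoles(table) == "input", drop = TRUE]
  nb <- cnt[, rbnsRoles(table) == "bound", drop = FALSE]
  totalBound <- rowSums(nb)
  fit_sites <- rownames(cnt)[totalBound >= minReads | rownames(cnt) == "none"]
  nd <- setdiff(rownames(cnt), fit_sites)
  # conditional multinomial over the retained classes
  ord <- c(setdiff(fit_sites, "none"), "none")
  nbf <- nb[ord, , drop = FALSE]
  f <- (input[ord] + pseudocount)
  f <- f / sum(f)
  J <- length(ord); I <- ncol(nbf)
  # init: kappa from enrichment at the most dilute sample, a at 0.1
  E <- (sweep(nbf + 1, 2, colSums(nbf + 1), "/")) / f
  k0 <- pmin(pmax(1 / E[, I], 1e-4), 1e2)
  par0 <- c(log(k0[seq_len(J - 1L)]), rep(log(0.1), I))
  fn <- function(p) rbnsNegLogLik(p, nbf, f, J, I, grad = FALSE)
  gr <- function(p) rbnsNegLogLik(p, nbf, f, J, I, grad = TRUE)$gradient
  opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      lower = rep(log(1e-8), length(par0)),
                      upper = rep(log(1e8), length(par0)),
                      control = list(maxit = maxit, factr = 1e4))
  if (opt$convergence != 0 && opt$convergence != 1)
    stop("relative-Kd fit failed to converge (code ", opt$convergence,
         "): ", opt$message)
  kappa <- c(exp(opt$par[seq_len(J - 1L)]), 1)
  names(kappa) <- ord
  a <- exp(opt$par[J:(J + I - 1L)])
  names(a) <- colnames(nbf)
  new("RelKdFit", kappa = kappa,
      ci = matrix(numeric(0), 0, 2, dimnames = list(NULL, c("lo", "hi"))),
      freeAgo = a, logLik = -opt$value, inputFreq = f,
      notDetermined = nd, convergence = as.integer(opt$convergence))
}

#' Bootstrap confidence intervals for relative Kd values
#'
#' Resamples reads within each sample (multinomial over site classes) with
#' replacement, refits, and returns percentile 2.5/97.5 intervals.
#' Deterministic given `seed`. Replicates whose refit fails are dropped
#' with a warning; at least 90% must succeed.
#'
#' @param table an [RbnsCountTable-class].
#' @param nBoot number of bootstrap replicates (default 200).
#' @param seed integer RNG seed.
#' @param minReads,pseudocount passed to [fitRelativeKd()].
#' @return a [RelKdFit-class] with the `ci` slot filled.
#' @export
bootstrapCI <- function(table, nBoot = 200L, seed = 1L, minReads = 50,
                        pseudocount = 1) {
  stopifnot(nBoot >= 2L)
  fit <- fitRelativeKd(table, minReads = minReads, pseudocount = pseudocount)
  cnt <- rbnsCounts(table)
  set.seed(seed)
  draws <- matrix(NA_real_, nBoot, length(fit@kappa),
                  dimnames = list(NULL, names(fit@kappa)))
  fails <- 0L
  for (bidx in seq_len(nBoot)) {
    res <- cnt
    for (j in seq_len(ncol(cnt)))
      res[, j] <- stats::rmultinom(1, sum(cnt[, j]), cnt[, j])
    kb <- tryCatch(
      relKd(fitRelativeKd(rbnsCountTable(res, rbnsRoles(table)),
                          minReads = minReads, pseudocount = pseudocount)),
      error = function(e) NULL)
    if (is.null(kb)) { fails <- fails + 1L; next }
    common <- intersect(names(kb), colnames(draws))
    draws[bidx, common] <- kb[common]
  }
  if (fails > 0)
    warning(fails, " bootstrap replicate(s) failed and were dropped")
  if (fails > 0.1 * nBoot)
    stop("more than 10% of bootstrap replicates failed")
  ci <- t(apply(draws, 2, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE))
  colnames(ci) <- c("lo", "hi")
  methods::initialize(fit, ci = ci)
}

#' Stratify a 3'-only register by its flanking target nucleotide
#'
#' Splits a 3'-only site class `mS_E` into four subclasses keyed by the
#' target nucleotide opposite guide position `S - 1` (in target coordinates
#' this base sits immediately 3' of the matched span). Reads classified
#' into the one-position-longer register `m(S-1)_E` are, by definition, the
#' complementary-flank subclass and are folded in. Reads whose flank falls
#' off the read end are excluded and counted.
#'
#' @param readsBySample named list of read vectors (element `"input"` first,
#'   as in [countSiteReads()]).
#' @param guide a [MirnaGuide-class].
#' @param baseSite register name, e.g. `"m10_20"`.
#' @param config a [SiteConfig-class].
#' @return an [RbnsCountTable-class] in which the base register row is
#'   replaced by rows `"mS_E|flankA"` ... `"mS_E|flankU"`; the count of
#'   excluded reads is in `metadata(x)$flank_excluded`.
#' @export
stratifyByFlank <- function(readsBySample, guide, baseSite,
                            config = siteConfig("rbns")) {
  bs <- parseSiteName(baseSite)
  S <- bs@threepStart; E <- bs@threepEnd
  longer <- sprintf("m%d_%d", S - 1L, E)
  compFlank <- chartr("ACGU", "UGCA",
                      substr(guideSeq(guide), S - 1L, S - 1L))
  if (is.null(names(readsBySample)))
    names(readsBySample) <- c("input",
                              paste0("bound", seq_along(readsBySample)[-1]))
  excluded <- 0L
  tabs <- lapply(readsBySample, function(r) {
    asn <- assignSites(r, guide, config)
    base <- asn$site == baseSite
    flank <- rep(NA_character_, nrow(asn))
    fpos <- asn$target_end + 1L
    inRead <- base & fpos <= nchar(r)
    flank[inRead] <- substr(r[inRead], fpos[inRead], fpos[inRead])
    excluded <<- excluded + sum(base & !inRead)
    isLonger <- asn$site == longer & S - 1L >= config@minThreePStart
    flank[isLonger] <- compFlank
    site <- asn$site
    lab <- base | isLonger
    site[lab] <- sprintf("%s|flank%s", baseSite, flank[lab])
    site[lab & is.na(flank)] <- "excluded_flank"
    table(site[site != "excluded_flank"])
  })
  sites <- unique(c("none", paste0(baseSite, "|flank", c("A", "C", "G", "U")),
                    unlist(lapply(tabs, names))))
  counts <- vapply(tabs, function(tb) {
    v <- integer(length(sites)); names(v) <- sites
    v[names(tb)] <- as.integer(tb)
    v
  }, integer(length(sites)))
  rownames(counts) <- sites
  out <- rbnsCountTable(counts,
                        roles = c("input", rep("bound", ncol(counts) - 1L)),
                        labels = names(readsBySample))
  S4Vectors::metadata(out)$flank_excluded <- excluded
  out
}
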