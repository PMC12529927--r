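#' @include AllClasses.R AllGenerics.R
NULL

#' Fit an equilibrium binding curve (fractional saturation)
#'
#' Fits `theta = A / (A + Kd)` to fraction bound versus total AGO-miR
#' concentration by nonlinear least squares. Bound-reporting convention:
#' when binding is negligible across the whole series (max theta below
#' `lowTheta`), a lower bound of 10 nM is reported instead of a point
#' estimate; when binding is already saturated at the lowest concentration
#' (theta >= `highTheta` there), an upper bound of 5 pM is reported.
#' Confidence intervals come from a seeded parametric bootstrap of the
#' residual scatter.
#'
#' @param conc total AGO-miR concentrations, molar (>= 4 points; replicate
#'   concentrations allowed).
#' @param theta fraction bound at each concentration, in \[0, 1\].
#' @param lowTheta,highTheta bound-reporting thresholds (defaults 0.2 and
#'   0.8).
#' @param nBoot case-resampling bootstrap draws for the 95% CI (0 skips
#'   it); the interval is a t-interval on log(Kd) using the bootstrap
#'   standard error, which stays calibrated under heteroscedastic or
#'   clipped noise.
#' @param seed RNG seed for the bootstrap.
#' @return a [SaturationFit-class].
#' @examples
#' conc <- 1e-12 * 10^seq(0, 3.5, length.out = 8)
#' fitSaturation(conc, conc / (conc + 1e-10))@kd
#' @export
fitSaturation <- function(conc, theta, lowTheta = 0.2, highTheta = 0.8,
                          nBoot = 200L, seed = 1L) {
  stopifnot(length(conc) == length(theta), all(conc > 0))
  if (length(unique(conc)) < 4L)
    stop("need at least 4 concentration points")
  o <- order(conc)
  conc <- conc[o]; theta <- theta[o]
  if (any(theta < 0 | theta > 1))
    warning("theta outside [0, 1]; values used as given")
  if (max(theta) < lowTheta)
    return(new("SaturationFit", kd = 10e-9, ci = c(NA_real_, NA_real_),
               boundFlag = "lower_bound_10nM", conc = conc, theta = theta))
  lowest <- conc == min(conc)
  if (mean(theta[lowest]) >= highTheta)
    return(new("SaturationFit", kd = 5e-12, ci = c(NA_real_, NA_real_),
               boundFlag = "upper_bound_5pM", conc = conc, theta = theta))
  fit1 <- function(cc, th) {
    start <- cc[which.min(abs(th - 0.5))]
    f <- minpack.lm::nlsLM(th ~ cc / (cc + kd),
                           start = list(kd = start),
                           lower = 1e-15, upper = 1e-3,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
    stats::coef(f)[["kd"]]
  }
  kd <- fit1(conc, theta)
  ci <- c(NA_real_, NA_real_)
  if (nBoot > 0) {
    set.seed(seed)
    n <- length(theta)
    kb <- vapply(seq_len(nBoot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(fit1(conc[idx], theta[idx]), error = function(e) NA_real_)
    }, numeric(1))
    half <- stats::qt(0.975, df = n - 1) * stats::sd(log(kb), na.rm = TRUE)
    ci <- exp(log(kd) + c(-half, half))
  }
  new("SaturationFit", kd = kd, ci = ci, boundFlag = "measured",
      conc = conc, theta = theta)
}

#' Fit a pseudo-first-order association time course
#'
#' Fits `AR(t) = AR_eq * (1 - exp(-kon * A_T * t))`, optionally pooling
#' several series at different AGO-miR concentrations that share one
#' `kon` (each series keeps its own `AR_eq`). The pseudo-first-order guard
#' requires every `A_T >= 80 pM`.
#'
#' @param times seconds, non-negative.
#' @param ar bound-complex signal at each time.
#' @param aTotal molar AGO-miR concentration: a single value, or one per
#'   point when pooling series.
#' @param series optional series labels (one per point); default: one
#'   series per distinct `aTotal`.
#' @param nBoot within-series case-resampling bootstrap draws for the kon
#'   95% CI, reported as a t-interval on log(kon) (0 skips).
#' @param seed RNG seed for the bootstrap.
#' @return an [AssociationFit-class].
#' @export
fitAssociation <- function(times, ar, aTotal, series = NULL, nBoot = 0L,
                           seed = 1L) {
  stopifnot(length(times) == length(ar), all(times >= 0))
  aTotal <- rep_len(aTotal, length(times))
  if (any(aTotal < 80e-12))
    stop("A_T below 80 pM violates the pseudo-first-order guard")
  if (is.null(series)) series <- factor(format(aTotal, digits = 6))
  series <- factor(series)
  if (length(unique(times)) < 4L) stop("need at least 4 timepoints")
  warn <- character()
  for (s in levels(series)) {
    i <- series == s
    cc <- suppressWarnings(stats::cor(times[i], ar[i]))
    if (is.na(cc) || cc <= 0) {
      warn <- c(warn, paste0("non-increasing signal in series ", s))
    }
  }
  nser <- nlevels(series)
  fit1 <- function(idx) {
    tt <- times[idx]; y <- ar[idx]; at <- aTotal[idx]
    ser <- series[idx]
    model <- function(par) {
      kon <- exp(par[1])
      areq <- exp(par[2:(1 + nser)])[as.integer(ser)]
      areq * (1 - exp(-kon * at * tt))
    }
    areq0 <- pmax(tapply(y, ser, max), 1e-12)
    areq0[is.na(areq0)] <- 1e-12
    p0 <- c(log(1 / (mean(at) * stats::median(tt[tt > 0]))),
            log(areq0))
    stats::optim(p0, function(p) sum((y - model(p))^2),
                 method = "BFGS", control = list(maxit = 500))$par
  }
  par <- fit1(seq_along(ar))
  kon <- unname(exp(par[1]))
  arEq <- stats::setNames(exp(par[2:(1 + nser)]), levels(series))
  ci <- c(NA_real_, NA_real_)
  if (nBoot > 0 || length(warn)) {
    nb <- max(nBoot, 50L)
    set.seed(seed)
    kb <- vapply(seq_len(nb), function(i) {
      idx <- unlist(lapply(levels(series), function(l) {
        w <- which(series == l)
        sample(w, length(w), replace = TRUE)
      }))
      tryCatch(exp(fit1(idx)[1]), error = function(e) NA_real_)
    }, numeric(1))
    half <- stats::qt(0.975, df = length(ar) - 1) *
      stats::sd(log(kb), na.rm = TRUE)
    ci <- exp(log(kon) + c(-half, half))
  }
  if (length(warn)) warning(paste(warn, collapse = "; "),
                            "; reporting wide CI")
  new("AssociationFit", kon = kon, arEq = arEq, ci = ci, warning = warn)
}

#' Derive the dissociation rate from Kd and kon
#'
#' Uses `Kd = koff / kon`, so `koff = Kd * kon`. When the Kd is a reported
#' bound rather than a point estimate, the derived koff inherits the flag.
#'
#' @param kd dissociation constant, molar (or a [SaturationFit-class]).
#' @param kon association rate constant, 1/(M s).
#' @param boundFlag `"measured"`, `"lower_bound_10nM"` or
#'   `"upper_bound_5pM"`; taken from `kd` when it is a fit object.
#' @return list with `koff` (1/s) and `flag`.
#' @export
deriveKoff <- function(kd, kon, boundFlag = "measured") {
  if (methods::is(kd, "SaturationFit")) {
    boundFlag <- kd@boundFlag
    kd <- kd@kd
  }
  stopifnot(kd > 0, kon > 0)
  flag <- switch(boundFlag,
                 measured = "measured",
                 lower_bound_10nM = "lower_bound",
                 upper_bound_5pM = "upper_bound",
                 boundFlag)
  list(koff = kd * kon, flag = flag)
}

#' Observed binding free energy from a relative Kd
#'
#' `dG = R T ln(Kd)` with `R = 1.9872e-3` kcal/(mol K); assay temperature
#' defaults to 37 C (310.15 K).
#'
#' @param relKd dimensionless relative Kd (> 0), vectorized.
#' @param temperature kelvin.
#' @return kcal/mol.
#' @export
deltaGObserved <- function(relKd, temperature = 310.15) {
  stopifnot(all(relKd > 0))
  1.9872e-3 * temperature * log(relKd)
}

#' Nearest-neighbor parameters for Watson-Crick RNA duplexes
#'
#' Loads the packaged stack table (37 C free energies, kcal/mol, keyed by
#' the 5'->3' top-strand dinucleotide of each stack), the duplex initiation
#' term and the terminal-AU penalty.
#'
#' @param file optional path to an alternative stack TSV.
#' @return list with `stacks` (named numeric, 16 entries), `initiation`,
#'   `terminalAU`.
#' @export
nnParams <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "nn_stacks_rna37.tsv",
                        package = "seedless")
  tb <- utils::read.delim(file)
  list(stacks = stats::setNames(tb$dg_kcal_mol, tb$stack),
       initiation = 4.09, terminalAU = 0.45)
}

#' Predicted free energy of a perfect duplex by nearest-neighbor rules
#'
#' Free energy of the duplex between `segment` and its perfect Watson-Crick
#' complement, as two RNAs free in solution: the sum of stack terms over
#' adjacent base pairs, plus duplex initiation, plus a terminal-AU penalty
#' for each helix end closed by an A:U pair.
#'
#' @param segment RNA sequence of one strand (>= 2 nt).
#' @param params parameter list from [nnParams()].
#' @return kcal/mol.
#' @export
deltaGPredictedNN <- function(segment, params = nnParams()) {
  segment <- normalizeRna(segment)
  n <- nchar(segment)
  if (n < 2L) stop("segment must be at least 2 nt")
  di <- substring(segment, seq_len(n - 1L), seq_len(n - 1L) + 1L)
  miss <- setdiff(di, names(params$stacks))
  if (length(miss)) stop("missing stack parameter: ", miss[1])
  ends <- substring(segment, c(1L, n), c(1L, n))
  sum(params$stacks[di]) + params$initiation +
    params$terminalAU * sum(ends %in% c("A", "U"))
}

#' Compare observed and nearest-neighbor-predicted free energies
#'
#' For a table of sites with observed (AGO context) and predicted (free
#' RNA duplex) free energies, fits a line of best fit of observed on
#' predicted per site family and reports slope, intercept and the mean
#' observed-minus-predicted difference. A1-class canonical sites (8mer,
#' 7mer-A1, 6mer-A1) have a non-pairing interaction at position 1 and are
#' excluded.
#'
#' @param records data.frame with columns `family`, `category`, `dg_obs`,
#'   `dg_pred` (kcal/mol).
#' @return data.frame, one row per family: `slope`, `intercept`,
#'   `mean_diff`, `n`.
#' @export
compareDeltaG <- function(records) {
  keep <- !records$category %in% c("8mer", "7mer-A1", "6mer-A1")
  d <- records[keep, , drop = FALSE]
  fams <- unique(d$family)
  out <- do.call(rbind, lapply(fams, function(f) {
    x <- d[d$family == f, , drop = FALSE]
    cf <- stats::coef(stats::lm(dg_obs ~ dg_pred, data = x))
    data.frame(family = f, slope = unname(cf[2]),
               intercept = unname(cf[1]),
               mean_diff = mean(x$dg_obs - x$dg_pred), n = nrow(x))
  }))
  rownames(out) <- NULL
  out
}
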