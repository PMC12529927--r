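#' @include AllClasses.R AllGenerics.R
NULL

#' Fit the multiplicative compound-site affinity model
#'
#' Decomposes `-log10(relative Kd)` of compound sites into the product of a
#' 3'-complementarity coefficient, a seed-complementarity coefficient and an
#' offset coefficient: `y = A[threep] * B[seed] * C[offset]`. Fitting is
#' ordinary least squares in log space (the product becomes an additive
#' categorical model), optionally weighted. The model carries two
#' compensating scale freedoms (`A -> cA, C -> C/c` and likewise for `B`);
#' identifiability is fixed by `max(A) = max(B) = 1`, absorbing the
#' residual scale into `C`. Sites with `y <= 0` (relative Kd >= 1) are
#' excluded and returned in the `rejects` attribute. Min-max rescaled
#' copies in \[0, 1\] are kept per family for display; the absolute
#' magnitude of the raw coefficients has no biochemical meaning.
#'
#' @param decomps data.frame with columns `threep`, `seed`, `offset` (level
#'   labels) and `y` (= `-log10(relative Kd)`), or `neg_log10_kd` as an
#'   alias.
#' @param weights optional per-site weights (e.g. derived from Kd CIs).
#' @return a [MultiplicativeFit-class]; excluded rows are in
#'   `attr(fit, "rejects")`.
#' @export
fitMultiplicative <- function(decomps, weights = NULL) {
  if (!"y" %in% colnames(decomps) && "neg_log10_kd" %in% colnames(decomps))
    decomps$y <- decomps$neg_log10_kd
  stopifnot(all(c("threep", "seed", "offset", "y") %in% colnames(decomps)))
  rejects <- decomps[decomps$y <= 0, , drop = FALSE]
  keep <- decomps$y > 0
  d <- decomps[keep, , drop = FALSE]
  if (!is.null(weights)) weights <- weights[keep]
  d$threep <- factor(d$threep)
  d$seed <- factor(d$seed)
  d$offsetF <- factor(d$offset)
  for (fam in c("threep", "seed", "offsetF")) {
    tb <- table(d[[fam]])
    if (any(tb == 0))
      stop("coefficient level never observed: ", fam, " = ",
           names(tb)[tb == 0][1])
  }
  fit <- stats::lm(log(y) ~ threep + seed + offsetF, data = d,
                   weights = weights)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    bad <- names(cf)[is.na(cf)][1]
    stop("disconnected coefficient design; level not estimable: ", bad)
  }
  lev <- function(fam) levels(d[[fam]])
  eff <- function(fam) {
    ls <- lev(fam)
    v <- c(0, cf[paste0(fam, ls[-1])])
    names(v) <- ls
    v
  }
  la <- eff("threep"); lb <- eff("seed"); lc <- eff("offsetF")
  intercept <- cf[["(Intercept)"]]
  # fix scale: max(A) = max(B) = 1, residual scale into C
  la <- la - max(la)
  lb <- lb - max(lb)
  lc <- lc + intercept + (max(eff("threep")) + max(eff("seed")))
  A <- exp(la); B <- exp(lb); C <- exp(lc)
  mm <- function(v) {
    if (length(v) == 1L || max(v) == min(v)) return(stats::setNames(
      rep(1, length(v)), names(v)))
    (v - min(v)) / (max(v) - min(v))
  }
  pred <- A[as.character(d$threep)] * B[as.character(d$seed)] *
    C[as.character(d$offsetF)]
  # built slot-by-slot: an argument named `C` would partially match the
  # `Class` formal of new()
  out <- new("MultiplicativeFit",
             A = A, B = B,
             Ascaled = mm(A), Bscaled = mm(B), Cscaled = mm(C),
             rPearson = stats::cor(pred, d$y),
             rSpearman = stats::cor(pred, d$y, method = "spearman"),
             fitted = stats::setNames(pred, rownames(d)),
             residuals = stats::setNames(log(d$y) - log(pred), rownames(d)))
  out@C <- C
  methods::validObject(out)
  attr(out, "rejects") <- rejects
  out
}

#' Predict -log10(relative Kd) from a multiplicative fit
#'
#' Returns `A[threep] * B[seed] * C[offset]`. Levels absent from the fit
#' are an error: the model never extrapolates.
#'
#' @param fit a [MultiplicativeFit-class].
#' @param newdata data.frame with columns `threep`, `seed`, `offset`.
#' @return numeric vector of predicted `-log10(relative Kd)`.
#' @export
predictLogKd <- function(fit, newdata) {
  t3 <- as.character(newdata$threep)
  sd <- as.character(newdata$seed)
  of <- as.character(newdata$offset)
  for (chk in list(c("threep", "A"), c("seed", "B"), c("offset", "C"))) {
    vals <- switch(chk[1], threep = t3, seed = sd, offset = of)
    known <- names(slot(fit, chk[2]))
    if (!all(vals %in% known))
      stop("level not seen in fit: ", chk[1], " = ",
           setdiff(vals, known)[1])
  }
  unname(fit@A[t3] * fit@B[sd] * fit@C[of])
}
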