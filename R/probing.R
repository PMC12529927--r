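#' @include AllClasses.R
NULL

#' Per-position signal fractions of a gel lane
#'
#' @param intensities non-negative band intensities, one per guide
#'   position (arbitrary units).
#' @return fractions summing to 1.
#' @export
laneFractions <- function(intensities) {
  if (any(intensities < 0)) stop("intensities must be >= 0")
  total <- sum(intensities)
  if (total <= 0) stop("all-zero lane")
  intensities / total
}

#' Relative probing reactivity
#'
#' `(S - Q) / (N - Q)` where `S` is the per-position signal fraction of the
#' probed sample, `Q` of the pre-quenched negative control, and `N` of the
#' free-guide positive control. Positions where the free-guide ceiling does
#' not exceed the quenched baseline (`N <= Q`) are returned as `NA`
#' (not determined), not as an error.
#'
#' @param s,q,nFree signal fractions (vectorized).
#' @return relative reactivity; 1 = fully accessible, 0 = fully protected.
#' @export
relativeReactivity <- function(s, q, nFree) {
  out <- (s - q) / (nFree - q)
  out[nFree <= q] <- NA_real_
  out
}

#' Reactivity profile from raw lane intensities
#'
#' Runs the full path: per-lane signal fractions, then relative reactivity
#' per position, for one or more replicate sample lanes against shared
#' pre-quenched and free-guide control lanes. Replicates are aggregated as
#' the mean with the range (n = 2) or a t-based 95% confidence interval
#' (n >= 3). Values outside \[0, 1\] (possible with noise) are reported as
#' computed and flagged, not clipped.
#'
#' @param sample matrix of band intensities (positions x replicates) or a
#'   vector for a single lane.
#' @param quenched intensities of the pre-quenched control lane.
#' @param freeGuide intensities of the free-guide control lane.
#' @return data.frame: `position`, `reactivity` (mean), `lo`, `hi`,
#'   `n_rep`, `flag` (`"ok"`, `"out_of_range"` or `"nd"`).
#' @export
reactivityProfile <- function(sample, quenched, freeGuide) {
  sample <- as.matrix(sample)
  q <- laneFractions(quenched)
  nf <- laneFractions(freeGuide)
  stopifnot(nrow(sample) == length(q), length(q) == length(nf))
  reps <- apply(sample, 2, function(lane)
    relativeReactivity(laneFractions(lane), q, nf))
  reps <- matrix(reps, nrow = nrow(sample))
  m <- rowMeans(reps)
  k <- ncol(reps)
  if (k == 1L) {
    lo <- hi <- m
  } else if (k == 2L) {
    lo <- pmin(reps[, 1], reps[, 2]); hi <- pmax(reps[, 1], reps[, 2])
  } else {
    se <- apply(reps, 1, stats::sd) / sqrt(k)
    tq <- stats::qt(0.975, df = k - 1)
    lo <- m - tq * se; hi <- m + tq * se
  }
  flag <- ifelse(is.na(m), "nd",
                 ifelse(m < 0 | m > 1, "out_of_range", "ok"))
  data.frame(position = seq_along(m), reactivity = m, lo = lo, hi = hi,
             n_rep = k, flag = flag)
}
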