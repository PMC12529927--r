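#' @include AllClasses.R AllGenerics.R site-grammar.R
NULL

#' Enumerate contiguous seed-complementarity patterns
#'
#' All contiguous guide windows within positions `1..regionEnd` with length
#' in `[minLen, maxLen]`, ordered by (length, start). The full 2-8 nt set
#' over positions 1-8 has 28 patterns.
#'
#' @param minLen,maxLen pattern length range.
#' @param regionEnd last guide position of the seed region (default 8).
#' @return data.frame with `start`, `end`, `name` (`"mX_Y"`).
#' @examples
#' nrow(enumerateSeedPatterns(2, 8, 8))  # 28
#' @export
enumerateSeedPatterns <- function(minLen = 2L, maxLen = 8L, regionEnd = 8L) {
  stopifnot(minLen >= 1L, minLen <= maxLen, maxLen <= regionEnd)
  out <- do.call(rbind, lapply(seq(minLen, maxLen), function(len) {
    starts <- seq_len(regionEnd - len + 1L)
    data.frame(start = starts, end = starts + len - 1L)
  }))
  out$name <- sprintf("m%d_%d", out$start, out$end)
  out
}

rcSegment <- function(guide, start, end) {
  rnaRevComp(substr(guideSeq(guide), start, end))
}

canonicalMotif <- function(guide, class) {
  switch(class,
    "8mer" = paste0(rcSegment(guide, 2, 8), "A"),
    "7mer-m8" = rcSegment(guide, 2, 8),
    "7mer-A1" = paste0(rcSegment(guide, 2, 7), "A"),
    "6mer" = rcSegment(guide, 2, 7),
    "6mer-m8" = rcSegment(guide, 3, 8),
    "6mer-A1" = paste0(rcSegment(guide, 2, 6), "A"),
    stop("unknown canonical class ", class))
}

# default bridge filler used outside the reporter design (planted survey
# sites): built from dinucleotide transitions that cannot seed-pair
# miR-155 or miR-124
BRIDGE_POOL <- "ACGACGGACGACGGACGACGGACG"

# Deterministic site-specific bridge. Compound sites that differ by one
# seed nucleotide would otherwise be the same physical molecule with the
# bridge absorbing the difference; a per-site bridge keeps every designed
# variant sequence distinct (uniqueness is still verified at build time).
bridgeSeq <- function(key, len) {
  if (len == 0L) return("")
  h <- sum(utf8ToInt(key) * seq_len(nchar(key)))
  idx <- (h * 31L + seq_len(len) * 17L + h %/% 7L) %% 4L + 1L
  paste(c("A", "C", "G", "U")[idx], collapse = "")
}

compoundSiteSeq <- function(guide, threepStart, threepEnd, seedStart,
                            seedEnd, offset, key = NULL) {
  bridge <- offset + (threepStart - seedEnd)
  if (bridge < 0)
    stop("negative target bridge for offset ", offset)
  filler <- if (is.null(key)) substr(BRIDGE_POOL, 1, bridge) else
    bridgeSeq(key, bridge)
  paste0(rcSegment(guide, threepStart, threepEnd), filler,
         rcSegment(guide, seedStart, seedEnd))
}

#' Per-miRNA MPRA site table
#'
#' Builds the site list for one miRNA: every canonical class in several
#' upstream sequence contexts, a set of 3'-only registers, the full
#' compound grid (3' registers x contiguous seed patterns x offsets), and
#' no-site negative controls. With the defaults for miR-155 (3 registers,
#' 28 seed patterns of 2-8 nt, 2 offsets, 20 3'-only sites, 5 upstream
#' sequences, 5 no-site controls) this yields 30 + 20 + 168 + 5 = 223
#' sites.
#'
#' @param guide a [MirnaGuide-class].
#' @param threepRegisters character, 3' registers for the compound grid
#'   (e.g. `c("m13_20", "m13_22", "m11_23")`).
#' @param offsets integer offsets for the compound grid (e.g. `c(0, 2)`).
#' @param seedPatterns data.frame from [enumerateSeedPatterns()].
#' @param threePOnly character vector of 3'-only register names.
#' @param upstreamSeqs canonical-site upstream sequences (>= 1).
#' @param noSiteSeqs no-site control sequences.
#' @return data.frame with `mirna`, `site_name`, `category`, `site_seq`.
#' @export
mpraSiteTable <- function(guide,
                          threepRegisters = c("m13_20", "m13_22", "m11_23"),
                          offsets = c(0L, 2L),
                          seedPatterns = enumerateSeedPatterns(),
                          threePOnly = defaultThreePOnly(guide, 20L),
                          upstreamSeqs = DEFAULT_UPSTREAM,
                          noSiteSeqs = defaultNoSite(guide)) {
  rows <- list()
  for (cls in CANONICAL_LEVELS)
    for (u in seq_along(upstreamSeqs))
      rows[[length(rows) + 1L]] <- data.frame(
        site_name = sprintf("%s.up%d", cls, u), category = "canonical",
        site_seq = paste0(upstreamSeqs[u], canonicalMotif(guide, cls)))
  for (reg in threePOnly) {
    d <- parseSiteName(reg)
    rows[[length(rows) + 1L]] <- data.frame(
      site_name = reg, category = "3p_only",
      site_seq = rcSegment(guide, d@threepStart, d@threepEnd))
  }
  for (reg in threepRegisters) {
    d <- parseSiteName(reg)
    for (i in seq_len(nrow(seedPatterns)))
      for (off in offsets) {
        nm <- sprintf("%s|%+d|%s", reg, off, seedPatterns$name[i])
        rows[[length(rows) + 1L]] <- data.frame(
          site_name = nm, category = "compound",
          site_seq = compoundSiteSeq(guide, d@threepStart, d@threepEnd,
                                     seedPatterns$start[i],
                                     seedPatterns$end[i], off,
                                     key = paste0(guideName(guide), nm)))
      }
  }
  for (u in seq_along(noSiteSeqs))
    rows[[length(rows) + 1L]] <- data.frame(
      site_name = sprintf("no_site.%d", u), category = "no_site",
      site_seq = noSiteSeqs[u])
  out <- do.call(rbind, rows)
  # deterministic collision resolution: a pair of compound sites can come
  # out as the same molecule when the bridge mimics the seed difference;
  # re-derive the later bridge with a salted key until all are distinct
  salt <- 0L
  while (anyDuplicated(out$site_seq) && salt < 100L) {
    salt <- salt + 1L
    for (i in which(duplicated(out$site_seq))) {
      if (out$category[i] != "compound") next
      p <- parseSiteName(out$site_name[i])
      out$site_seq[i] <- compoundSiteSeq(
        guide, p@threepStart, p@threepEnd, p@seedStart, p@seedEnd,
        p@offset, key = paste0(guideName(guide), out$site_name[i], ":",
                               salt))
    }
  }
  if (anyDuplicated(out$site_seq))
    stop("could not build distinct site sequences")
  out <- cbind(mirna = guideName(guide), out)
  rownames(out) <- NULL
  out
}

DEFAULT_UPSTREAM <- c("UCUUCCUU", "CCUUCUUC", "UUCCUCUU", "CUUCUCCU",
                      "UCCUUCUC")
DEFAULT_NOSITE <- c("UCUCCUUCUUCCUCUUCC", "CCUUCCUCUUCUCCUUCU",
                    "UUCUCCUCCUUCUUCCUC", "CUCUUCCUUCCUCUUCUC",
                    "UCCUCUUCUCCUUCCUUC")

# per-guide rotation of the pyrimidine no-site set, so designs for two
# miRNAs never share a physical control molecule
defaultNoSite <- function(guide) {
  o <- sum(utf8ToInt(guideName(guide))) %% 7L + 1L
  vapply(DEFAULT_NOSITE, function(x)
    paste0(substr(x, o + 1L, nchar(x)), substr(x, 1L, o)), character(1),
    USE.NAMES = FALSE)
}

#' Default 3'-only register list
#'
#' Registers within the guide 3' region (start >= 9), lengths >= 8 nt,
#' enumerated by (start, length); the first `n` are returned.
#'
#' @param guide a [MirnaGuide-class].
#' @param n number of registers.
#' @keywords internal
#' @export
defaultThreePOnly <- function(guide, n) {
  L <- guideLength(guide)
  regs <- character()
  for (s in 9:(L - 7L))
    for (e in seq(s + 7L, L))
      regs <- c(regs, sprintf("m%d_%d", s, e))
  utils::head(regs, n)
}

#' Deterministic MPRA context flanks
#'
#' Generates `n` upstream and `n` downstream flanking sequences of length
#' `len` from a fixed seed (pyrimidine-biased composition to avoid
#' incidental guide complementarity).
#'
#' @param n number of contexts.
#' @param len flank length (nt).
#' @param seed RNG seed.
#' @return list with `up` and `down` character vectors.
#' @export
mpraContexts <- function(n = 20L, len = 50L, seed = 101L) {
  set.seed(seed)
  draw <- function()
    paste(sample(c("U", "C", "A", "G"), len, replace = TRUE,
                 prob = c(0.4, 0.4, 0.1, 0.1)), collapse = "")
  list(up = vapply(seq_len(n), function(i) draw(), character(1)),
       down = vapply(seq_len(n), function(i) draw(), character(1)))
}

#' Build the full MPRA design
#'
#' Places every site of every miRNA's site table into every sequence
#' context (paired upstream/downstream 50-nt flanks) and validates that no
#' two variants share a sequence.
#'
#' @param siteTables list of data.frames from [mpraSiteTable()] (one per
#'   miRNA), or a single data.frame.
#' @param contexts list with `up` and `down` flank vectors of equal length
#'   (see [mpraContexts()]).
#' @return an [MpraDesign-class].
#' @export
buildMpraDesign <- function(siteTables, contexts = mpraContexts()) {
  if (is.data.frame(siteTables)) siteTables <- list(siteTables)
  sites <- do.call(rbind, siteTables)
  stopifnot(length(contexts$up) == length(contexts$down))
  nc <- length(contexts$up)
  idx <- rep(seq_len(nrow(sites)), each = nc)
  ctx <- rep(seq_len(nc), times = nrow(sites))
  variants <- data.frame(
    variant_id = sprintf("%s_%s_c%02d", sites$mirna[idx],
                         sites$site_name[idx], ctx),
    mirna = sites$mirna[idx],
    site_name = sites$site_name[idx],
    category = sites$category[idx],
    context = ctx,
    sequence = paste0(contexts$up[ctx], sites$site_seq[idx],
                      contexts$down[ctx]))
  dup <- duplicated(variants$sequence)
  if (any(dup))
    stop("duplicate variant sequences in design: ",
         paste(utils::head(variants$variant_id[dup], 3), collapse = ", "))
  new("MpraDesign", variants = variants, sites = sites)
}

#' Site-level fold changes from MPRA counts
#'
#' Computes counts-per-million per sample, sums CPM per site across its
#' contexts, forms the miRNA-vs-mock fold change per replicate pair, and
#' normalizes each replicate by the median fold change of the no-site
#' sites. Log2 values are reported per replicate with the across-replicate
#' mean and SEM. Sites with zero mock CPM in any replicate are flagged.
#'
#' @param counts integer matrix, variants x samples (rownames =
#'   `variant_id`).
#' @param design an [MpraDesign-class].
#' @param mirSamples,mockSamples column names of the miRNA-transfected and
#'   mock samples; paired in order (replicate i = `mirSamples[i]` vs
#'   `mockSamples[i]`).
#' @return data.frame: `site_name`, `category`, replicate columns
#'   `log2fc_rep*`, `log2fc` (mean), `sem`, `flag`.
#' @export
foldChanges <- function(counts, design, mirSamples, mockSamples) {
  stopifnot(length(mirSamples) == length(mockSamples))
  v <- design@variants
  counts <- counts[v$variant_id, , drop = FALSE]
  cpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
  bySite <- rowsum(cpm, group = v$site_name, reorder = FALSE)
  siteInfo <- v[!duplicated(v$site_name), c("site_name", "category")]
  siteInfo <- siteInfo[match(rownames(bySite), siteInfo$site_name), ]
  nrep <- length(mirSamples)
  fc <- matrix(NA_real_, nrow(bySite), nrep,
               dimnames = list(rownames(bySite),
                               paste0("log2fc_rep", seq_len(nrep))))
  flag <- rep("ok", nrow(bySite))
  for (r in seq_len(nrep)) {
    mock <- bySite[, mockSamples[r]]
    mir <- bySite[, mirSamples[r]]
    bad <- mock <= 0
    flag[bad] <- "zero_mock"
    raw <- ifelse(bad, NA_real_, mir / mock)
    norm <- stats::median(raw[siteInfo$category == "no_site"], na.rm = TRUE)
    fc[, r] <- log2(raw / norm)
  }
  out <- data.frame(site_name = rownames(bySite),
                    category = siteInfo$category, fc,
                    log2fc = rowMeans(fc),
                    sem = apply(fc, 1, stats::sd) / sqrt(nrep),
                    flag = flag)
  rownames(out) <- NULL
  out
}

#' Fold repression from a log2 fold change
#'
#' A site with `log2FC = -1.08` represses `2^1.08 = 2.1`-fold.
#'
#' @param log2fc log2 fold change (miRNA vs mock); repression is negative.
#' @return fold repression (>= 1 for repressed sites).
#' @export
foldRepression <- function(log2fc) 2^(-log2fc)

#' Fit the occupancy-repression model to MPRA fold changes
#'
#' The model predicts fold repression `1 + b * N` for each site, where
#' `N = aFree / (aFree + kappa)` is the fractional AGO-miR occupancy under
#' the fractional saturation equation, `b` is the unit increase in
#' repression per unit occupancy and `aFree` is the free AGO-miR
#' concentration in relative-Kd units. Neither is experimentally
#' accessible, so both are fit globally by least squares on
#' `log2FC = -log2(1 + b N)`.
#'
#' @param log2fc named numeric of site log2 fold changes.
#' @param kappa named numeric of relative Kd values for the same sites.
#' @return an [OccupancyModelFit-class].
#' @export
fitOccupancyModel <- function(log2fc, kappa) {
  common <- intersect(names(log2fc), names(kappa))
  common <- common[!is.na(log2fc[common]) & !is.na(kappa[common])]
  if (length(common) < 5L) stop("need at least 5 sites with kappa")
  k <- kappa[common]; y <- log2fc[common]
  if (max(k) / min(k) < 100)
    stop("degenerate kappa range (< 100-fold)")
  obj <- function(p) {
    b <- exp(p[1]); a <- exp(p[2])
    sum((y - (-log2(1 + b * a / (a + k))))^2)
  }
  opt <- stats::optim(c(log(1), log(stats::median(k))), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  opt <- stats::optim(opt$par, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  b <- exp(opt$par[1]); a <- exp(opt$par[2])
  new("OccupancyModelFit", b = b, aFree = a,
      occupancy = a / (a + k), kappa = k, rss = opt$value)
}

#' Replicate-based confidence intervals for the occupancy model
#'
#' Fits the occupancy-repression model to each replicate's log2 fold
#' changes separately and reports the mean with a t-interval on the log
#' scale (replicates are the unit of inference, which captures shared
#' normalization noise that site-level resampling cannot see).
#'
#' @param repMat numeric matrix of replicate log2 fold changes (rownames =
#'   site names; >= 3 replicate columns).
#' @param kappa named numeric relative Kd values.
#' @param level confidence level (default 0.95).
#' @return data.frame with rows `b` and `a_free`: `estimate`, `lo`, `hi`,
#'   `n_rep`.
#' @export
occupancyModelCI <- function(repMat, kappa, level = 0.95) {
  nrep <- ncol(repMat)
  if (nrep < 3L) stop("need at least 3 replicates")
  lp <- vapply(seq_len(nrep), function(r) {
    y <- repMat[, r]
    names(y) <- rownames(repMat)
    f <- fitOccupancyModel(y, kappa)
    c(log(f@b), log(f@aFree))
  }, numeric(2))
  tq <- stats::qt(1 - (1 - level) / 2, df = nrep - 1)
  est <- rowMeans(lp)
  se <- apply(lp, 1, stats::sd) / sqrt(nrep)
  data.frame(param = c("b", "a_free"),
             estimate = exp(est), lo = exp(est - tq * se),
             hi = exp(est + tq * se), n_rep = nrep)
}

#' Predicted repression curve from an occupancy fit
#'
#' @param fit an [OccupancyModelFit-class].
#' @param kappa relative Kd values at which to evaluate the curve.
#' @return data.frame with `kappa`, `occupancy`, `fold_repression`,
#'   `log2fc_pred`.
#' @export
predictRepression <- function(fit, kappa) {
  N <- fit@aFree / (fit@aFree + kappa)
  data.frame(kappa = kappa, occupancy = N,
             fold_repression = 1 + fit@b * N,
             log2fc_pred = -log2(1 + fit@b * N))
}

#' Detect probable slicing sites
#'
#' A zero-offset compound site that represses significantly better than its
#' positive-offset counterpart is a probable slicing substrate (positive
#' offsets bulge the target between the seed and 3' duplexes, which
#' precludes slicing but tends to improve binding). Each architecture pair
#' is tested by one-way analysis of its replicate log2 fold changes with
#' Tukey's honest-significant-difference post-hoc test, Bonferroni-corrected
#' across all tested pairs; a pair is flagged only when the zero-offset
#' mean is lower (more repressed) and adjusted p < 0.05.
#'
#' @param repMat numeric matrix of replicate log2 fold changes (rownames =
#'   site names, >= 3 replicate columns required per tested site).
#' @param pairs data.frame with columns `zero` and `positive` (site names).
#' @return data.frame: `zero`, `positive`, `mean_diff` (zero minus
#'   positive), `p`, `p_adj`, `flag`.
#' @export
detectSlicing <- function(repMat, pairs) {
  res <- list()
  for (i in seq_len(nrow(pairs))) {
    z <- pairs$zero[i]; p <- pairs$positive[i]
    if (!z %in% rownames(repMat) || !p %in% rownames(repMat)) {
      warning("pair skipped (site missing): ", z, " / ", p)
      next
    }
    zv <- stats::na.omit(repMat[z, ]); pv <- stats::na.omit(repMat[p, ])
    if (length(zv) < 3L || length(pv) < 3L) {
      warning("pair skipped (< 3 replicates): ", z, " / ", p)
      next
    }
    d <- data.frame(y = c(zv, pv),
                    g = factor(rep(c("zero", "positive"),
                                   c(length(zv), length(pv))),
                               levels = c("positive", "zero")))
    tk <- stats::TukeyHSD(stats::aov(y ~ g, data = d))$g
    res[[length(res) + 1L]] <- data.frame(
      zero = z, positive = p,
      mean_diff = unname(tk[1, "diff"]), p = unname(tk[1, "p adj"]))
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(zero = character(), positive = character(),
                      mean_diff = numeric(), p = numeric(),
                      p_adj = numeric(), flag = logical()))
  out$p_adj <- pmin(1, out$p * nrow(out))
  out$flag <- out$mean_diff < 0 & out$p_adj < 0.05
  out
}
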