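#' @useDynLib seedless, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' MirnaGuide: a miRNA guide sequence
#'
#' Holds a guide strand 5'->3' with 1-based positions. The seed is positions
#' 2-7, the subseed 2-5, and the 3' region runs from position 9 (by default)
#' to the guide 3' end. Input sequences may be DNA (T is mapped to U).
#'
#' @slot name single character, guide name.
#' @slot seq single character, normalized RNA sequence (A/C/G/U).
#' @export
setClass("MirnaGuide",
  representation(name = "character", seq = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1L) msg <- c(msg, "'name' must be length 1")
    if (length(object@seq) != 1L) msg <- c(msg, "'seq' must be length 1")
    n <- nchar(object@seq)
    if (n < 18L || n > 26L)
      msg <- c(msg, sprintf("guide length %d outside 18..26 nt", n))
    if (grepl("[^ACGU]", object@seq))
      msg <- c(msg, "guide contains characters outside A/C/G/U")
    if (length(msg)) msg else TRUE
  }
)

#' SiteDescriptor: one classified target site
#'
#' A single site call: either a canonical seed-matched class, a 3'-only
#' register, a compound 3'+seed site with a signed offset, or none. Guide
#' coordinates are 1-based; target spans are 1-based inclusive.
#'
#' @slot category character; one of `"8mer"`, `"7mer-m8"`, `"7mer-A1"`,
#'   `"6mer"`, `"6mer-m8"`, `"6mer-A1"`, `"3p_only"`, `"compound"`, `"none"`.
#' @slot threepStart,threepEnd integer guide positions of the 3' segment
#'   (`NA` when absent).
#' @slot seedStart,seedEnd integer guide positions of the seed segment
#'   (`NA` when absent).
#' @slot offset integer, signed target-bridge minus guide-bridge (`NA` when
#'   not a compound site).
#' @slot targetStart,targetEnd integer target span (`NA` for unplaced
#'   descriptors, e.g. parsed names).
#' @slot ambiguous logical; `TRUE` when the read held several equally ranked
#'   candidates.
#' @export
setClass("SiteDescriptor",
  representation(category = "character",
                 threepStart = "integer", threepEnd = "integer",
                 seedStart = "integer", seedEnd = "integer",
                 offset = "integer",
                 targetStart = "integer", targetEnd = "integer",
                 ambiguous = "logical"),
  prototype(threepStart = NA_integer_, threepEnd = NA_integer_,
            seedStart = NA_integer_, seedEnd = NA_integer_,
            offset = NA_integer_, targetStart = NA_integer_,
            targetEnd = NA_integer_, ambiguous = FALSE),
  validity = function(object) {
    ok <- c("8mer", "7mer-m8", "7mer-A1", "6mer", "6mer-m8", "6mer-A1",
            "3p_only", "compound", "none")
    msg <- character()
    if (!object@category %in% ok)
      msg <- c(msg, paste0("unknown category '", object@category, "'"))
    if (object@category == "compound" &&
        (is.na(object@threepStart) || is.na(object@seedStart) ||
         is.na(object@offset)))
      msg <- c(msg, "compound sites need 3' segment, seed segment and offset")
    if (object@category == "3p_only" && is.na(object@threepStart))
      msg <- c(msg, "3p_only sites need a 3' segment")
    if (length(msg)) msg else TRUE
  }
)

#' SiteConfig: classification parameters
#'
#' Bundles the tunables of read/window classification. Two presets exist:
#' `"rbns"` (3' registers from 8 nt, 3'-only tolerates a seed run of at most
#' 1 nt, compound offsets in \[-8, +16\]) and `"survey"` (3' registers from
#' 10 nt, seed-run tolerance 2 nt, offsets in \[-4, +6\], offset-6mer classes
#' excluded from output).
#'
#' @slot minThreePStart first guide position counted as 3' region (default 9).
#' @slot minThreePLen minimum 3' segment length.
#' @slot maxSeedRun longest contiguous seed run still compatible with a
#'   3'-only call.
#' @slot offsetMin,offsetMax compound-offset search window (nt).
#' @slot maxCompoundSeed longest seed run treated as a compound-site segment.
#' @slot excludeOffset6mer drop 6mer-m8/6mer-A1 calls from output.
#' @slot wobble allow G:U pairs (default `FALSE`; site definitions are
#'   strict Watson-Crick).
#' @export
setClass("SiteConfig",
  representation(minThreePStart = "integer", minThreePLen = "integer",
                 maxSeedRun = "integer", offsetMin = "integer",
                 offsetMax = "integer", maxCompoundSeed = "integer",
                 excludeOffset6mer = "logical", wobble = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@minThreePStart < 2L)
      msg <- c(msg, "minThreePStart must be >= 2")
    if (object@minThreePLen < 1L) msg <- c(msg, "minThreePLen must be >= 1")
    if (object@offsetMin > object@offsetMax)
      msg <- c(msg, "offsetMin > offsetMax")
    if (length(msg)) msg else TRUE
  }
)

#' RbnsCountTable: site-by-sample read counts for an AGO-RBNS series
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one `counts` assay
#' (rows: site names including `"none"`; columns: the input sample followed
#' by the bound samples) and column metadata `role` (`"input"`/`"bound"`)
#' and `label`.
#'
#' @export
setClass("RbnsCountTable", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
      msg <- c(msg, "need a 'counts' assay")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("role", "label") %in% colnames(cd)))
      msg <- c(msg, "colData needs 'role' and 'label'")
    else {
      if (sum(cd$role == "input") != 1L)
        msg <- c(msg, "need exactly one input sample")
      if (sum(cd$role == "bound") < 1L)
        msg <- c(msg, "need at least one bound sample")
    }
    if (!"none" %in% rownames(object))
      msg <- c(msg, "need a 'none' (no-site background) row")
    if ("counts" %in% SummarizedExperiment::assayNames(object)) {
      cnt <- SummarizedExperiment::assay(object, "counts")
      if (any(cnt < 0) || any(cnt != round(cnt)))
        msg <- c(msg, "counts must be non-negative integers")
    }
    if (length(msg)) msg else TRUE
  }
)

#' RelKdFit: maximum-likelihood relative Kd estimates
#'
#' Result of [fitRelativeKd()]: relative Kd per site (no-site background
#' pinned at exactly 1), the latent free-AGO scale of each bound sample in
#' units of the no-site Kd, the maximized multinomial log-likelihood, and
#' (after [bootstrapCI()]) percentile 95% confidence intervals.
#'
#' @slot kappa named numeric, relative Kd per fitted site.
#' @slot ci numeric matrix (sites x 2, `lo`/`hi`) or 0-row before bootstrap.
#' @slot freeAgo named numeric, per-bound-sample free-AGO scale.
#' @slot logLik numeric, log-likelihood at the optimum.
#' @slot inputFreq named numeric, plug-in input frequencies used.
#' @slot notDetermined character, sites below the read-count floor.
#' @slot convergence integer optimizer code (0 = converged).
#' @export
setClass("RelKdFit",
  representation(kappa = "numeric", ci = "matrix", freeAgo = "numeric",
                 logLik = "numeric", inputFreq = "numeric",
                 notDetermined = "character", convergence = "integer"),
  validity = function(object) {
    msg <- character()
    if (!"none" %in% names(object@kappa))
      msg <- c(msg, "'none' must be among fitted sites")
    else if (object@kappa[["none"]] != 1)
      msg <- c(msg, "kappa['none'] must equal 1 exactly")
    if (any(object@kappa <= 0)) msg <- c(msg, "all kappa must be > 0")
    if (any(object@freeAgo <= 0)) msg <- c(msg, "all freeAgo must be > 0")
    if (length(msg)) msg else TRUE
  }
)

#' MultiplicativeFit: compound-site affinity decomposition
#'
#' Multiplicative model of compound-site affinity,
#' `-log10(relative Kd) = A[3'] * B[seed] * C[offset]`, fitted by least
#' squares in log space. Raw coefficients carry two compensating scale
#' freedoms; identifiability is fixed by `max(A) = max(B) = 1` with the
#' residual scale absorbed into `C`. Min-max rescaled copies in \[0, 1\] are
#' kept for display.
#'
#' @slot A,B,C named numeric raw coefficients (3' pattern, seed pattern,
#'   offset).
#' @slot Ascaled,Bscaled,Cscaled min-max rescaled copies.
#' @slot rPearson,rSpearman correlation of predicted vs observed
#'   `-log10(Kd)`.
#' @slot fitted named numeric fitted values; @slot residuals log-scale
#'   residuals.
#' @export
setClass("MultiplicativeFit",
  representation(A = "numeric", B = "numeric", C = "numeric",
                 Ascaled = "numeric", Bscaled = "numeric", Cscaled = "numeric",
                 rPearson = "numeric", rSpearman = "numeric",
                 fitted = "numeric", residuals = "numeric"),
  validity = function(object) {
    if (any(c(object@A, object@B, object@C) <= 0))
      "raw coefficients must be positive" else TRUE
  }
)

#' SaturationFit: equilibrium binding-curve fit
#'
#' Fit of the fractional saturation equation
#' `theta = A / (A + Kd)` over a concentration series, with the
#' bound-reporting convention: negligible binding (max theta below the
#' low-binding threshold) reports a 10 nM lower bound, saturation at the
#' lowest concentration reports a 5 pM upper bound.
#'
#' @slot kd molar dissociation constant (or the reported bound).
#' @slot ci length-2 numeric, bootstrap 95% CI (NA for bound flags).
#' @slot boundFlag `"measured"`, `"lower_bound_10nM"` or `"upper_bound_5pM"`.
#' @slot conc,theta the data the curve was fit to.
#' @export
setClass("SaturationFit",
  representation(kd = "numeric", ci = "numeric", boundFlag = "character",
                 conc = "numeric", theta = "numeric"))

#' AssociationFit: pseudo-first-order association fit
#'
#' Fit of `AR(t) = AR_eq * (1 - exp(-kon * A_T * t))`, optionally pooled
#' over several AGO concentrations sharing one `kon`.
#'
#' @slot kon association rate constant, 1/(M s).
#' @slot arEq named numeric equilibrium signal per series.
#' @slot ci length-2 numeric bootstrap 95% CI for `kon`.
#' @slot warning character, e.g. non-increasing signal.
#' @export
setClass("AssociationFit",
  representation(kon = "numeric", arEq = "numeric", ci = "numeric",
                 warning = "character"))

#' OccupancyModelFit: MPRA occupancy-repression model
#'
#' Global fit of repression `= 1 + b * N`, with fractional occupancy
#' `N = aFree / (aFree + kappa)` and predicted `log2FC = -log2(1 + b N)`.
#'
#' @slot b unit repression per unit occupancy.
#' @slot aFree free AGO-miR concentration in relative-Kd units.
#' @slot occupancy named numeric per-site fractional occupancy.
#' @slot kappa named numeric relative Kd used in the fit.
#' @slot rss residual sum of squares on log2FC.
#' @export
setClass("OccupancyModelFit",
  representation(b = "numeric", aFree = "numeric", occupancy = "numeric",
                 kappa = "numeric", rss = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@b < 0) msg <- c(msg, "b must be >= 0")
    if (object@aFree <= 0) msg <- c(msg, "aFree must be > 0")
    if (length(object@occupancy) &&
        (any(object@occupancy < 0) || any(object@occupancy > 1)))
      msg <- c(msg, "occupancy must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' MpraDesign: reporter-library design
#'
#' Enumerated MPRA variants: every site placed in every sequence context,
#' with per-miRNA category bookkeeping.
#'
#' @slot variants data.frame with columns `variant_id`, `mirna`,
#'   `site_name`, `category`, `context`, `sequence`.
#' @slot sites data.frame with one row per site (`mirna`, `site_name`,
#'   `category`, `site_seq`).
#' @export
setClass("MpraDesign",
  representation(variants = "data.frame", sites = "data.frame"),
  validity = function(object) {
    need <- c("variant_id", "mirna", "site_name", "category", "context",
              "sequence")
    if (!all(need %in% colnames(object@variants)))
      return(paste("variants needs columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(object@variants$sequence))
      return("duplicate variant sequences in design")
    TRUE
  }
)
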