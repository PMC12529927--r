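#' @include AllClasses.R
NULL

#' Guide accessors
#'
#' @param x a [MirnaGuide-class].
#' @return `guideName` the name, `guideSeq` the normalized RNA sequence,
#'   `guideLength` its length in nucleotides.
#' @export
setGeneric("guideName", function(x) standardGeneric("guideName"))

#' @rdname guideName
#' @export
setGeneric("guideSeq", function(x) standardGeneric("guideSeq"))

#' @rdname guideName
#' @export
setGeneric("guideLength", function(x) standardGeneric("guideLength"))

#' Relative Kd accessors
#'
#' @param x a [RelKdFit-class].
#' @return `relKd` the named vector of relative Kd values; `freeAgo` the
#'   per-bound-sample free-AGO scales; `kdCI` the bootstrap interval matrix.
#' @export
setGeneric("relKd", function(x) standardGeneric("relKd"))

#' @rdname relKd
#' @export
setGeneric("freeAgo", function(x) standardGeneric("freeAgo"))

#' @rdname relKd
#' @export
setGeneric("kdCI", function(x) standardGeneric("kdCI"))

#' Serialize a site to its text name
#'
#' Canonical sites serialize to their class keyword (`"8mer"`), 3'-only
#' sites to `"mX_Y"`, and compound sites to `"mX_Y|+k|mA_B"` (3' register,
#' signed offset, seed segment).
#'
#' @param x a [SiteDescriptor-class].
#' @return single character site name.
#' @export
setGeneric("siteName", function(x) standardGeneric("siteName"))

#' @export
setMethod("guideName", "MirnaGuide", function(x) x@name)
#' @export
setMethod("guideSeq", "MirnaGuide", function(x) x@seq)
#' @export
setMethod("guideLength", "MirnaGuide", function(x) nchar(x@seq))

#' @export
setMethod("relKd", "RelKdFit", function(x) x@kappa)
#' @export
setMethod("freeAgo", "RelKdFit", function(x) x@freeAgo)
#' @export
setMethod("kdCI", "RelKdFit", function(x) x@ci)

setMethod("show", "MirnaGuide", function(object) {
  cat("MirnaGuide", object@name, sprintf("(%d nt)\n", nchar(object@seq)))
  cat(" 5'-", object@seq, "-3'\n", sep = "")
  cat(" seed (2-7):", substr(object@seq, 2, 7), "\n")
})

setMethod("show", "SiteDescriptor", function(object) {
  cat("SiteDescriptor:", siteName(object), "\n")
  if (!is.na(object@targetStart))
    cat(sprintf(" target span %d-%d%s\n", object@targetStart,
                object@targetEnd,
                if (object@ambiguous) " (ambiguous)" else ""))
})

setMethod("show", "RelKdFit", function(object) {
  cat("RelKdFit:", length(object@kappa), "sites,",
      length(object@freeAgo), "bound samples\n")
  cat(" logLik:", format(object@logLik), "\n")
  k <- sort(object@kappa)
  top <- utils::head(k[names(k) != "none"], 5)
  for (nm in names(top))
    cat(sprintf("  %-22s kappa = %.4g\n", nm, top[[nm]]))
  if (length(object@notDetermined))
    cat(" not determined:", length(object@notDetermined), "sites\n")
})

setMethod("show", "MultiplicativeFit", function(object) {
  cat("MultiplicativeFit: -log10(Kd) = A[3'] * B[seed] * C[offset]\n")
  cat(sprintf(" %d x %d x %d levels; r_pearson = %.3f, r_spearman = %.3f\n",
              length(object@A), length(object@B), length(object@C),
              object@rPearson, object@rSpearman))
})

setMethod("show", "SaturationFit", function(object) {
  cat("SaturationFit: Kd =", format(object@kd, digits = 3), "M",
      paste0("[", object@boundFlag, "]"), "\n")
})

setMethod("show", "AssociationFit", function(object) {
  cat("AssociationFit: kon =", format(object@kon, digits = 3), "M^-1 s^-1,",
      length(object@arEq), "series\n")
})

setMethod("show", "OccupancyModelFit", function(object) {
  cat(sprintf("OccupancyModelFit: b = %.3g, free AGO-miR = %.3g (rel-Kd units)\n",
              object@b, object@aFree))
})

setMethod("show", "MpraDesign", function(object) {
  cat("MpraDesign:", nrow(object@variants), "variants,",
      nrow(object@sites), "sites,",
      length(unique(object@variants$context)), "contexts\n")
  print(table(object@sites$mirna, object@sites$category))
})
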