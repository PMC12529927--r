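#' @include AllClasses.R AllGenerics.R site-grammar.R
NULL

SURVEY_PRIORITY <- c("3p_microseed" = 1, "3p_only" = 2, "8mer" = 3,
                     "7mer-m8" = 4, "7mer-A1" = 5, "6mer" = 6)

#' Scan a 3' UTR for target sites of one miRNA
#'
#' Annotates every canonical seed-matched site (6mer, 7mer-A1, 7mer-m8,
#' 8mer; offset-6mer classes are excluded under the survey preset), every
#' 3'-only site (>= `minThreePLen` nt of contiguous 3' complementarity and
#' a contiguous seed run of at most `maxSeedRun` nt at offsets within the
#' window) and every 3'+microseed site (same 3' complementarity plus a
#' 3-5 nt contiguous seed run at an in-window offset). A seed run of 6 nt
#' or more at an in-window offset makes the site a canonical site with
#' supplementary 3' pairing (flagged, counted once as canonical).
#' Overlapping candidates are resolved greedily left-most-first with
#' category priority (3' classes, then canonical rank); sites that
#' overlapped a dropped candidate are flagged ambiguous rather than
#' removed.
#'
#' @param utr UTR sequence (character, DNA or RNA; normalized to RNA) or a
#'   named length-1 character for the `utr_id` column.
#' @param guide a [MirnaGuide-class].
#' @param config a [SiteConfig-class]; default `siteConfig("survey")`.
#' @param utrId optional UTR identifier.
#' @return data.frame: `utr_id`, `mirna`, `start`, `end` (1-based
#'   inclusive), `category`, `supplementary_3p`, `ambiguous`.
#' @export
scanUtr <- function(utr, guide, config = siteConfig("survey"),
                    utrId = NULL) {
  if (is.null(utrId))
    utrId <- if (!is.null(names(utr))) names(utr)[1] else "utr1"
  utr <- normalizeRna(unname(utr), allowN = TRUE)
  gseq <- guideSeq(guide)
  L <- guideLength(guide)
  seedRuns <- as.data.frame(cpp_find_runs(utr, gseq, 1L, 8L, 3L,
                                          config@wobble))
  p3Runs <- as.data.frame(cpp_find_runs(utr, gseq, config@minThreePStart, L,
                                        config@minThreePLen, config@wobble))
  ann <- list()
  supplSeedKeys <- character()

  # 3' classes first: each 3' run is typed by the longest in-window seed run
  if (nrow(p3Runs)) for (i in seq_len(nrow(p3Runs))) {
    t <- p3Runs[i, ]
    best <- NULL; bestLen <- 0L
    if (nrow(seedRuns)) for (j in seq_len(nrow(seedRuns))) {
      s <- seedRuns[j, ]
      if (s$target_start <= t$target_end) next
      off <- (s$target_start - t$target_end - 1L) -
        (t$guide_start - s$guide_end)
      if (off < config@offsetMin || off > config@offsetMax) next
      len <- s$guide_end - s$guide_start + 1L
      if (len > bestLen) { bestLen <- len; best <- s }
    }
    if (bestLen >= 6L) {
      supplSeedKeys <- c(supplSeedKeys,
                         paste(best$target_start, best$target_end))
    } else if (bestLen > config@maxSeedRun) {
      ann[[length(ann) + 1L]] <- data.frame(
        start = t$target_start, end = best$target_end,
        category = "3p_microseed", supplementary_3p = FALSE)
    } else {
      ann[[length(ann) + 1L]] <- data.frame(
        start = t$target_start, end = t$target_end,
        category = "3p_only", supplementary_3p = FALSE)
    }
  }

  # canonical sites from seed runs of >= 6 nt
  can <- seedRuns[seedRuns$guide_end - seedRuns$guide_start + 1L >= 5L, ,
                  drop = FALSE]
  if (nrow(can)) for (j in seq_len(nrow(can))) {
    d <- canonicalFromRun(utr, unlist(can[j, ]))
    if (is.null(d)) next
    cls <- CANONICAL_LEVELS[d$rank]
    if (config@excludeOffset6mer && cls %in% c("6mer-m8", "6mer-A1")) next
    suppl <- paste(can$target_start[j], can$target_end[j]) %in% supplSeedKeys
    ann[[length(ann) + 1L]] <- data.frame(
      start = d$sp, end = d$ep, category = cls, supplementary_3p = suppl)
  }

  if (!length(ann))
    return(data.frame(utr_id = character(), mirna = character(),
                      start = integer(), end = integer(),
                      category = character(), supplementary_3p = logical(),
                      ambiguous = logical()))
  ann <- unique(do.call(rbind, ann))
  ann$priority <- SURVEY_PRIORITY[ann$category]
  ann <- ann[order(ann$start, ann$priority, -(ann$end - ann$start)), ]

  # greedy left-most selection; on overlap keep the higher-priority site
  kept <- list(); ambig <- logical()
  for (i in seq_len(nrow(ann))) {
    cur <- ann[i, ]
    placed <- FALSE
    for (k in seq_along(kept)) {
      if (cur$start <= kept[[k]]$end && cur$end >= kept[[k]]$start) {
        if (cur$priority < kept[[k]]$priority) {
          kept[[k]] <- cur
        }
        ambig[k] <- TRUE
        placed <- TRUE
        break
      }
    }
    if (!placed) { kept[[length(kept) + 1L]] <- cur; ambig <- c(ambig, FALSE) }
  }
  out <- do.call(rbind, kept)
  out$ambiguous <- ambig
  out$priority <- NULL
  cbind(utr_id = utrId, mirna = guideName(guide), out)
}

#' Scan many UTRs for many miRNAs
#'
#' @param utrs named character vector or `Biostrings::XStringSet` of 3'
#'   UTR sequences.
#' @param guides list of [MirnaGuide-class] objects.
#' @param config a [SiteConfig-class].
#' @return combined annotation data.frame (see [scanUtr()]).
#' @export
scanUtrs <- function(utrs, guides, config = siteConfig("survey")) {
  if (methods::is(utrs, "XStringSet")) {
    nm <- names(utrs)
    utrs <- stats::setNames(as.character(utrs), nm)
  }
  if (is.null(names(utrs))) names(utrs) <- paste0("utr", seq_along(utrs))
  if (methods::is(guides, "MirnaGuide")) guides <- list(guides)
  out <- list()
  for (g in guides)
    for (u in names(utrs))
      out[[length(out) + 1L]] <- scanUtr(utrs[[u]], g, config, utrId = u)
  do.call(rbind, out)
}

#' Chance-occurrence ratio of two site lengths
#'
#' A site of `kLong` matched nucleotides occurs every `4^kLong` nucleotides
#' by chance; the ratio `4^kShort / 4^kLong` is how much rarer the longer
#' site is than the shorter one (e.g. `chanceRatio(6, 10) = 1/256`).
#'
#' @param kShort,kLong site lengths in matched nucleotides (>= 1).
#' @return `4^(kShort - kLong)`.
#' @export
chanceRatio <- function(kShort, kLong) {
  stopifnot(kShort >= 1, kLong >= 1)
  4^(kShort - kLong)
}

#' Summarize a targetome survey
#'
#' Per-miRNA counts by category and the canonical vs noncanonical
#' proportions, plus cross-miRNA medians and ranges per category.
#'
#' @param annotations data.frame from [scanUtrs()].
#' @return list with `perMirna` (counts and proportions) and `acrossMirnas`
#'   (median, min, max per category).
#' @export
summarizeSurvey <- function(annotations) {
  cats <- c("6mer", "7mer-A1", "7mer-m8", "8mer", "3p_only", "3p_microseed")
  mirnas <- unique(annotations$mirna)
  per <- do.call(rbind, lapply(mirnas, function(m) {
    a <- annotations[annotations$mirna == m, ]
    cnt <- vapply(cats, function(cc) sum(a$category == cc), numeric(1))
    tot <- sum(cnt)
    canonical <- sum(cnt[c("6mer", "7mer-A1", "7mer-m8", "8mer")])
    data.frame(mirna = m, t(cnt), total = tot,
               prop_canonical = if (tot > 0) canonical / tot else NA_real_,
               prop_3p_only = if (tot > 0) cnt[["3p_only"]] / tot else
                 NA_real_,
               check.names = FALSE)
  }))
  across <- do.call(rbind, lapply(cats, function(cc) {
    v <- per[[cc]]
    data.frame(category = cc, median = stats::median(v), min = min(v),
               max = max(v))
  }))
  list(perMirna = per, acrossMirnas = across)
}

#' Read 3' UTR sequences from FASTA
#'
#' @param file FASTA path (DNA or RNA; T normalized to U downstream).
#' @return named character vector of sequences.
#' @export
readUtrs <- function(file) {
  ss <- Biostrings::readBStringSet(file)
  stats::setNames(as.character(ss), names(ss))
}
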