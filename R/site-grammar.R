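#' @include AllClasses.R AllGenerics.R
NULL

CANONICAL_LEVELS <- c("8mer", "7mer-m8", "7mer-A1", "6mer", "6mer-m8",
                      "6mer-A1")
CATEGORY_CODES <- c(CANONICAL_LEVELS, "3p_only", "compound")

#' Normalize a nucleotide string to RNA
#'
#' Upper-cases and maps T to U. Errors on characters outside A/C/G/U/T/N
#' unless `allowN = TRUE`, in which case N is kept.
#'
#' @param x character vector of sequences.
#' @param allowN keep N characters instead of erroring.
#' @return character vector of RNA sequences.
#' @export
normalizeRna <- function(x, allowN = FALSE) {
  x <- chartr("acgutn", "ACGUTN", x)
  x <- chartr("T", "U", x)
  bad <- grepl(if (allowN) "[^ACGUN]" else "[^ACGU]", x)
  if (any(bad))
    stop("invalid nucleotide characters in sequence(s): ",
         paste(utils::head(which(bad), 3), collapse = ", "))
  x
}

#' Reverse complement of an RNA string
#'
#' @param x character vector of RNA sequences (A/C/G/U).
#' @return reverse complements, 5'->3'.
#' @export
rnaRevComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAStringSet(x)))
}

#' Construct a MirnaGuide
#'
#' @param name guide name.
#' @param sequence guide sequence 5'->3'; DNA is accepted (T mapped to U).
#' @return a [MirnaGuide-class].
#' @examples
#' let7 <- MirnaGuide("let-7a", "UGAGGUAGUAGGUUGUAUAGUU")
#' guideLength(let7)
#' @export
MirnaGuide <- function(name, sequence) {
  new("MirnaGuide", name = as.character(name),
      seq = normalizeRna(as.character(sequence)))
}

#' Read guides from FASTA
#'
#' @param file path to a single- or multi-record FASTA of guide sequences.
#' @return named list of [MirnaGuide-class] objects.
#' @export
readGuides <- function(file) {
  ss <- Biostrings::readBStringSet(file)
  out <- lapply(seq_along(ss), function(i)
    MirnaGuide(names(ss)[i], as.character(ss[[i]])))
  names(out) <- names(ss)
  out
}

#' Classification configuration
#'
#' @param preset `"rbns"` (read assignment for bind-n-seq pools) or
#'   `"survey"` (endogenous 3' UTR scanning). Individual parameters can be
#'   overridden; see [SiteConfig-class] for their meaning.
#' @param minThreePStart,minThreePLen,maxSeedRun,offsetMin,offsetMax
#'   parameter overrides.
#' @param maxCompoundSeed,excludeOffset6mer,wobble parameter overrides.
#' @return a [SiteConfig-class].
#' @examples
#' siteConfig("survey")
#' @export
siteConfig <- function(preset = c("rbns", "survey"),
                       minThreePStart = 9L, minThreePLen = NULL,
                       maxSeedRun = NULL, offsetMin = NULL, offsetMax = NULL,
                       maxCompoundSeed = 8L, excludeOffset6mer = NULL,
                       wobble = FALSE) {
  preset <- match.arg(preset)
  def <- switch(preset,
    rbns = list(minThreePLen = 8L, maxSeedRun = 1L, offsetMin = -8L,
                offsetMax = 16L, excludeOffset6mer = FALSE),
    survey = list(minThreePLen = 10L, maxSeedRun = 2L, offsetMin = -4L,
                  offsetMax = 6L, excludeOffset6mer = TRUE))
  pick <- function(x, d) if (is.null(x)) d else as.integer(x)
  new("SiteConfig",
      minThreePStart = as.integer(minThreePStart),
      minThreePLen = pick(minThreePLen, def$minThreePLen),
      maxSeedRun = pick(maxSeedRun, def$maxSeedRun),
      offsetMin = pick(offsetMin, def$offsetMin),
      offsetMax = pick(offsetMax, def$offsetMax),
      maxCompoundSeed = as.integer(maxCompoundSeed),
      excludeOffset6mer = if (is.null(excludeOffset6mer))
        def$excludeOffset6mer else isTRUE(excludeOffset6mer),
      wobble = isTRUE(wobble))
}

#' Offset between a 3' segment and a seed segment
#'
#' The offset is the number of target nucleotides bridging the two matched
#' segments minus the number of guide nucleotides bridging the corresponding
#' guide segments: `bridgeLen - (threePStart - seedEnd)`. Positive offsets
#' bulge the target; negative offsets bulge the guide. For example a 3'
#' segment starting at guide position 13, 8 target nucleotides upstream of a
#' seed match ending at guide position 7, has offset 8 - (13 - 7) = +2.
#'
#' @param seedEnd guide position at which the seed segment ends.
#' @param threePStart guide position at which the 3' segment starts; must be
#'   greater than `seedEnd`.
#' @param bridgeLen number of target nucleotides between the two matched
#'   spans (>= 0).
#' @return integer signed offset in nucleotides, vectorized.
#' @examples
#' computeOffset(7, 13, 8)  # +2
#' @export
computeOffset <- function(seedEnd, threePStart, bridgeLen) {
  seedEnd <- as.integer(seedEnd)
  threePStart <- as.integer(threePStart)
  bridgeLen <- as.integer(bridgeLen)
  if (any(threePStart <= seedEnd))
    stop("threePStart must exceed seedEnd (segments overlap or out of order)")
  if (any(bridgeLen < 0)) stop("bridgeLen must be >= 0")
  bridgeLen - (threePStart - seedEnd)
}

categoryFromCode <- function(code) {
  out <- rep("none", length(code))
  nz <- code > 0L
  out[nz] <- CATEGORY_CODES[code[nz]]
  out
}

descriptorFromRow <- function(row) {
  new("SiteDescriptor",
      category = row$category,
      threepStart = as.integer(row$threep_start),
      threepEnd = as.integer(row$threep_end),
      seedStart = as.integer(row$seed_start),
      seedEnd = as.integer(row$seed_end),
      offset = as.integer(row$offset),
      targetStart = as.integer(row$target_start),
      targetEnd = as.integer(row$target_end),
      ambiguous = isTRUE(row$ambiguous))
}

#' Classify the best canonical seed-matched site in a window
#'
#' Finds the highest-ranked canonical class present in the window, ranking
#' 8mer > 7mer-m8 > 7mer-A1 > 6mer > 6mer-m8 > 6mer-A1, using strict
#' Watson-Crick complementarity. The A1 classes require an A in the target
#' across from guide position 1 regardless of pairing.
#'
#' @param window target subsequence (RNA or DNA).
#' @param guide a [MirnaGuide-class].
#' @return a [SiteDescriptor-class]; category `"none"` when no class
#'   matches.
#' @export
classifyCanonical <- function(window, guide) {
  window <- normalizeRna(window)
  runs <- cpp_find_runs(window, guideSeq(guide), 1L, 8L, 2L, FALSE)
  best <- NULL
  if (nrow(runs)) {
    for (i in seq_len(nrow(runs))) {
      d <- canonicalFromRun(window, runs[i, ])
      if (is.null(d)) next
      if (is.null(best) || d$rank < best$rank ||
          (d$rank == best$rank && d$sp < best$sp)) best <- d
    }
  }
  if (is.null(best))
    return(new("SiteDescriptor", category = "none"))
  new("SiteDescriptor", category = CANONICAL_LEVELS[best$rank],
      seedStart = best$gs, seedEnd = best$ge,
      targetStart = best$sp, targetEnd = best$ep)
}

# R-side canonical ranking of one maximal seed-region run (used for single
# windows; bulk read assignment ranks in C++).
canonicalFromRun <- function(window, run) {
  gs <- run[["guide_start"]]; ge <- run[["guide_end"]]
  const <- run[["target_start"]] + ge
  hasA <- const - 1 >= 1 && const - 1 <= nchar(window) &&
    substr(window, const - 1, const - 1) == "A"
  covers <- function(p, q) gs <= p && ge >= q
  if (covers(2, 8) && hasA)
    list(rank = 1L, gs = 1L, ge = 8L, sp = const - 8L, ep = const - 1L)
  else if (covers(2, 8))
    list(rank = 2L, gs = 2L, ge = 8L, sp = const - 8L, ep = const - 2L)
  else if (covers(2, 7) && hasA)
    list(rank = 3L, gs = 1L, ge = 7L, sp = const - 7L, ep = const - 1L)
  else if (covers(2, 7))
    list(rank = 4L, gs = 2L, ge = 7L, sp = const - 7L, ep = const - 2L)
  else if (covers(3, 8))
    list(rank = 5L, gs = 3L, ge = 8L, sp = const - 8L, ep = const - 3L)
  else if (covers(2, 6) && hasA)
    list(rank = 6L, gs = 1L, ge = 6L, sp = const - 6L, ep = const - 1L)
  else NULL
}

#' Find maximal 3'-region complementary runs in a target sequence
#'
#' Reports every maximal contiguous Watson-Crick complementary run between
#' the target and guide positions `minStart` to the guide 3' end, at its
#' maximal extension (sub-registers of a longer run are not reported).
#'
#' @param read target sequence.
#' @param guide a [MirnaGuide-class].
#' @param minLen minimum run length to report (>= 4).
#' @param minStart first guide position of the 3' region (default 9).
#' @return data.frame with columns `guide_start`, `guide_end`,
#'   `target_start`, `target_end` (all 1-based inclusive).
#' @export
findThreePrimeMatches <- function(read, guide, minLen = 4L, minStart = 9L) {
  if (minLen < 4L) stop("minLen must be >= 4")
  read <- normalizeRna(read)
  m <- cpp_find_runs(read, guideSeq(guide), as.integer(minStart),
                     guideLength(guide), as.integer(minLen), FALSE)
  as.data.frame(m)
}

#' Assign the single best site in each read
#'
#' Applies the full site grammar to each read and returns one call per
#' read, with precedence compound > longest 3' register > canonical rank >
#' none and deterministic left-most tie-breaking. Ties at the top rank are
#' flagged `ambiguous`, never dropped. A compound site is called when a 3'
#' segment lies 5' of a seed run on the read with offset inside the
#' configured window; a 3'-only site tolerates at most
#' `maxSeedRun` nucleotides of contiguous seed pairing at such offsets.
#'
#' @param reads character vector of read sequences (RNA or DNA).
#' @param guide a [MirnaGuide-class].
#' @param config a [SiteConfig-class]; default `siteConfig("rbns")`.
#' @return data.frame with one row per read: `site` (serialized name),
#'   `category`, the guide coordinates of matched segments, `offset`,
#'   `target_start`, `target_end`, `ambiguous`.
#' @examples
#' g <- MirnaGuide("let-7a", "UGAGGUAGUAGGUUGUAUAGUU")
#' assignSites(c("UUUUUUUUUUUUUUUCUACCUCAUUUUU"), g)$site
#' @export
assignSites <- function(reads, guide, config = siteConfig("rbns")) {
  reads <- normalizeRna(reads, allowN = TRUE)
  df <- cpp_assign_reads(reads, guideSeq(guide),
                         config@minThreePStart, config@minThreePLen,
                         config@maxSeedRun, config@offsetMin,
                         config@offsetMax, config@maxCompoundSeed,
                         config@wobble)
  cat <- categoryFromCode(df$category)
  if (config@excludeOffset6mer) {
    drop <- cat %in% c("6mer-m8", "6mer-A1")
    cat[drop] <- "none"
    df$target_start[drop] <- NA_integer_
    df$target_end[drop] <- NA_integer_
  }
  site <- character(length(cat))
  is3p <- cat == "3p_only"
  iscmp <- cat == "compound"
  iscan <- df$category >= 1L & df$category <= 6L & cat != "none"
  site[iscan] <- cat[iscan]
  site[is3p] <- sprintf("m%d_%d", df$threep_start[is3p], df$threep_end[is3p])
  site[iscmp] <- sprintf("m%d_%d|%+d|m%d_%d",
                         df$threep_start[iscmp], df$threep_end[iscmp],
                         df$offset[iscmp],
                         df$seed_start[iscmp], df$seed_end[iscmp])
  site[cat == "none"] <- "none"
  data.frame(site = site, category = cat,
             threep_start = df$threep_start, threep_end = df$threep_end,
             seed_start = df$seed_start, seed_end = df$seed_end,
             offset = df$offset,
             target_start = df$target_start, target_end = df$target_end,
             ambiguous = df$ambiguous)
}

#' @rdname assignSites
#' @param read a single read sequence.
#' @return `assignSite` returns a single [SiteDescriptor-class].
#' @export
assignSite <- function(read, guide, config = siteConfig("rbns")) {
  stopifnot(length(read) == 1L)
  df <- assignSites(read, guide, config)
  descriptorFromRow(df[1, ])
}

#' Parse and format site names
#'
#' The site-name grammar is: a canonical keyword (`"8mer"`, `"7mer-m8"`,
#' `"7mer-A1"`, `"6mer"`, `"6mer-m8"`, `"6mer-A1"`, `"none"`), a 3'-only
#' register `"mX_Y"`, or a compound name `"mX_Y|±k|mA_B"` giving 3'
#' register, signed offset and seed segment. `parseSiteName` and
#' `siteName`/`formatSiteName` are mutual inverses.
#'
#' @param name site name text.
#' @return a [SiteDescriptor-class] (unplaced: no target span).
#' @examples
#' siteName(parseSiteName("m13_20|+2|m2_7"))
#' @export
parseSiteName <- function(name) {
  stopifnot(length(name) == 1L)
  if (name %in% c(CANONICAL_LEVELS, "none"))
    return(new("SiteDescriptor", category = name))
  reg <- "^m([0-9]+)_([0-9]+)$"
  cmp <- "^m([0-9]+)_([0-9]+)\\|([+-][0-9]+)\\|m([0-9]+)_([0-9]+)$"
  if (grepl(reg, name)) {
    v <- as.integer(regmatches(name, regexec(reg, name))[[1]][2:3])
    if (v[1] > v[2]) stop("malformed site name: register '", name,
                          "' has start > end")
    return(new("SiteDescriptor", category = "3p_only",
               threepStart = v[1], threepEnd = v[2]))
  }
  if (grepl(cmp, name)) {
    m <- regmatches(name, regexec(cmp, name))[[1]]
    t3 <- as.integer(m[2:3]); off <- as.integer(m[4]); sd <- as.integer(m[5:6])
    if (t3[1] > t3[2] || sd[1] > sd[2])
      stop("malformed site name: segment start > end in '", name, "'")
    return(new("SiteDescriptor", category = "compound",
               threepStart = t3[1], threepEnd = t3[2],
               seedStart = sd[1], seedEnd = sd[2], offset = off))
  }
  stop("malformed site name: cannot parse token '", name, "'")
}

#' @rdname parseSiteName
#' @param site a [SiteDescriptor-class].
#' @export
formatSiteName <- function(site) {
  switch(site@category,
    "3p_only" = sprintf("m%d_%d", site@threepStart, site@threepEnd),
    "compound" = sprintf("m%d_%d|%+d|m%d_%d", site@threepStart,
                         site@threepEnd, site@offset, site@seedStart,
                         site@seedEnd),
    site@category)
}

#' @export
setMethod("siteName", "SiteDescriptor", function(x) formatSiteName(x))

#' Read RBNS read pools
#'
#' Reads one-sequence-per-line text, FASTA, or FASTQ (by extension:
#' `.fq`/`.fastq` FASTQ, `.fa`/`.fasta` FASTA, anything else plain text).
#'
#' @param file path.
#' @return character vector of sequences (RNA-normalized, N allowed).
#' @export
readReads <- function(file) {
  lower <- tolower(file)
  seqs <- if (grepl("\\.(fq|fastq)$", lower)) {
    as.character(Biostrings::readDNAStringSet(file, format = "fastq"))
  } else if (grepl("\\.(fa|fasta)$", lower)) {
    as.character(Biostrings::readDNAStringSet(file, format = "fasta"))
  } else {
    readLines(file)
  }
  normalizeRna(unname(seqs), allowN = TRUE)
}

#' Quality-filter RBNS reads
#'
#' Keeps reads with unambiguous base calls and (when `constant3p` is given)
#' an exact match of the last `nchar(constant3p)` nucleotides to the 3'
#' constant region.
#'
#' @param reads character vector of reads.
#' @param constant3p optional 3'-constant-region suffix to require
#'   (typically its last four nucleotides).
#' @return filtered character vector.
#' @export
filterReads <- function(reads, constant3p = NULL) {
  keep <- !grepl("N", reads, fixed = TRUE)
  if (!is.null(constant3p)) {
    constant3p <- normalizeRna(constant3p)
    keep <- keep & endsWith(reads, constant3p)
  }
  reads[keep]
}

#' Write a site-assignment table
#'
#' @param assignments data.frame from [assignSites()].
#' @param file output TSV path.
#' @param readIds optional read identifiers.
#' @return the file path, invisibly.
#' @export
writeSiteTable <- function(assignments, file, readIds = NULL) {
  out <- data.frame(
    read_id = if (is.null(readIds)) seq_len(nrow(assignments)) else readIds,
    site_name = assignments$site,
    target_start = assignments$target_start,
    target_end = assignments$target_end,
    ambiguous = assignments$ambiguous)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
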