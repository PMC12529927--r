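#' @include AllClasses.R site-grammar.R rbns-kd.R mpra.R
NULL

randomRna <- function(n, len, prob = rep(0.25, 4)) {
  bases <- c("A", "C", "G", "U")
  m <- matrix(sample(bases, n * len, replace = TRUE, prob = prob),
              nrow = n)
  do.call(paste0, as.data.frame(m))
}

#' Simulate AGO-RBNS read pools with known relative Kd values
#'
#' Emulates the programmed bind-n-seq library: the input pool is a 50/50
#' mixture of fully random 40-mers and programmed molecules carrying a
#' central 8-nt segment complementary to the guide 3' region, and each
#' bound pool is produced by rejection sampling against the equilibrium
#' occupancy model: a molecule classified to site j is retained with
#' probability `a_i / (a_i + kappa_j)` at free-AGO scale `a_i`. Site
#' classes absent from `kappaMap` fall back to the no-site Kd of 1 (their
#' count is recorded in the truth object). Classification uses the same
#' site grammar as the analysis path, so the grammar is exercised on raw
#' sequences exactly as with real data.
#'
#' @param guide a [MirnaGuide-class].
#' @param kappaMap named numeric of true relative Kd values per site name.
#' @param aList numeric, free-AGO scale of each bound sample (no-site-Kd
#'   units).
#' @param depth reads per sample (>= 1e4 recommended).
#' @param seed integer RNG seed.
#' @param randomLen random-region length (default 40).
#' @param programmedFrac programmed-molecule fraction (default 0.5).
#' @param programmedSegment guide positions of the programmed 8-nt match
#'   (default `c(13, 20)`).
#' @param config a [SiteConfig-class] used for classification.
#' @param method `"rejection"` draws per-molecule Bernoulli acceptances;
#'   `"weighted"` classifies a fresh candidate pool and samples reads with
#'   probability proportional to their occupancy, which draws from exactly
#'   the same class distribution at a fixed cost. `"auto"` (default) uses
#'   rejection when the expected acceptance rate is workable (free-AGO
#'   scale at least 0.05) and the weighted scheme for more dilute samples,
#'   whose rejection cost grows as 1/a.
#' @return list: `input` (reads), `bound` (list of read vectors), `truth`
#'   (kappa, a, seed, fallback count, generator tag).
#' @export
genRbnsPools <- function(guide, kappaMap, aList, depth = 1e5, seed = 1L,
                         randomLen = 40L, programmedFrac = 0.5,
                         programmedSegment = c(13L, 20L),
                         config = siteConfig("rbns"),
                         method = c("auto", "rejection", "weighted")) {
  method <- match.arg(method)
  stopifnot(depth >= 1e3, all(aList > 0), all(kappaMap > 0))
  set.seed(seed)
  segSeq <- rcSegment(guide, programmedSegment[1], programmedSegment[2])
  segLen <- nchar(segSeq)
  insertAt <- (randomLen - segLen) %/% 2 + 1L
  makeLib <- function(n) {
    reads <- randomRna(n, randomLen)
    nprog <- round(n * programmedFrac)
    if (nprog > 0) {
      prog <- reads[seq_len(nprog)]
      substr(prog, insertAt, insertAt + segLen - 1L) <- segSeq
      reads[seq_len(nprog)] <- prog
    }
    sample(reads)
  }
  fallback <- 0L
  kappaOf <- function(sites) {
    k <- kappaMap[sites]
    miss <- is.na(k)
    fallback <<- fallback + sum(miss)
    k[miss] <- 1
    unname(k)
  }
  input <- makeLib(depth)
  bound <- lapply(aList, function(ai) {
    if (method == "rejection" || (method == "auto" && ai >= 0.05)) {
      got <- character(0)
      while (length(got) < depth) {
        cand <- makeLib(max(depth, 2e4))
        k <- kappaOf(assignSites(cand, guide, config)$site)
        acc <- stats::runif(length(cand)) < ai / (ai + k)
        got <- c(got, cand[acc])
      }
      got[seq_len(depth)]
    } else {
      cand <- makeLib(max(depth, 2e4))
      k <- kappaOf(assignSites(cand, guide, config)$site)
      w <- ai / (ai + k)
      cand[sample.int(length(cand), depth, replace = TRUE, prob = w)]
    }
  })
  names(bound) <- paste0("a", format(aList, trim = TRUE))
  list(input = input, bound = bound,
       truth = list(kappa = kappaMap, a = aList, seed = seed,
                    depth = depth, random_len = randomLen,
                    programmed_frac = programmedFrac,
                    programmed_segment = programmedSegment,
                    fallback_sites = fallback,
                    generator = "genRbnsPools/0.1.0"))
}

#' Simulate MPRA counts under the occupancy-repression model
#'
#' Inverts the analysis model: mock counts are proportional to a variant
#' abundance profile, miRNA-sample counts to abundance divided by the fold
#' repression `1 + b * N(kappa)`, with negative-binomial noise. The
#' replicate structure emulates two plates in each of two experiments
#' (four replicates per condition).
#'
#' @param design an [MpraDesign-class].
#' @param kappaMap named numeric relative Kd per site name; sites absent
#'   from the map (and `no_site` category) get no repression.
#' @param b,aFree true model parameters.
#' @param depth reads per sample.
#' @param dispersion negative-binomial dispersion (0 gives Poisson;
#'   default 0.05).
#' @param nRep replicates per condition (default 4).
#' @param seed RNG seed.
#' @return list: `counts` (variants x samples), `mirSamples`,
#'   `mockSamples`, `truth`.
#' @export
genMpraCounts <- function(design, kappaMap, b = 3, aFree = 0.01,
                          depth = 2e7, dispersion = 0.05, nRep = 4L,
                          seed = 1L) {
  set.seed(seed)
  v <- design@variants
  abundance <- stats::rlnorm(nrow(v), meanlog = 0, sdlog = 0.25)
  k <- kappaMap[v$site_name]
  k[is.na(k)] <- Inf  # no binding
  N <- aFree / (aFree + k)
  repr <- 1 + b * N
  mockSamples <- paste0("mock_rep", seq_len(nRep))
  mirSamples <- paste0("mir_rep", seq_len(nRep))
  draw <- function(mu) {
    mu <- mu / sum(mu) * depth
    if (dispersion > 0)
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    else stats::rpois(length(mu), mu)
  }
  counts <- cbind(
    vapply(seq_len(nRep), function(r) draw(abundance), numeric(nrow(v))),
    vapply(seq_len(nRep), function(r) draw(abundance / repr),
           numeric(nrow(v))))
  colnames(counts) <- c(mockSamples, mirSamples)
  rownames(counts) <- v$variant_id
  list(counts = counts, mirSamples = mirSamples, mockSamples = mockSamples,
       truth = list(b = b, a_free = aFree, kappa = kappaMap, seed = seed,
                    depth = depth, dispersion = dispersion,
                    generator = "genMpraCounts/0.1.0"))
}

#' Simulate 3' UTRs with planted sites
#'
#' Generates uniform-random background sequences and plants sites of the
#' requested categories at recorded positions. When sites are planted, the
#' background is rejection-sampled until free of accidental sites of the
#' planted categories for the given guide, so plant-and-recover tests are
#' exact.
#'
#' @param n number of UTRs.
#' @param length UTR length (nt), scalar or vector of length `n`.
#' @param guide a [MirnaGuide-class] (required when `plants` given).
#' @param plants data.frame with columns `category` (one of `"8mer"`,
#'   `"7mer-m8"`, `"7mer-A1"`, `"6mer"`, `"3p_only"`, `"3p_microseed"`) and
#'   optionally `threep_start`, `threep_end`, `seed_len`, `offset` for the
#'   3' classes; one planted site per UTR per row index recycled over
#'   UTRs. `NULL` plants nothing.
#' @param seed RNG seed.
#' @param config survey [SiteConfig-class] used for the cleanliness check.
#' @return list: `utrs` (named character), `truth` (data.frame of planted
#'   spans and categories plus generator metadata).
#' @export
genUtrs <- function(n, length = 200L, guide = NULL, plants = NULL,
                    seed = 1L, config = siteConfig("survey")) {
  set.seed(seed)
  lens <- rep_len(length, n)
  utrs <- character(n)
  planted <- list()
  for (i in seq_len(n)) {
    row <- if (!is.null(plants))
      plants[(i - 1L) %% nrow(plants) + 1L, , drop = FALSE] else NULL
    repeat {
      bg <- randomRna(1L, lens[i])
      if (is.null(row)) { utrs[i] <- bg; break }
      clean <- nrow(scanUtr(bg, guide, config)) == 0L
      if (!clean) next
      siteSeq <- plantSiteSeq(guide, row)
      if (nchar(siteSeq) > lens[i])
        stop("planted site longer than UTR (", nchar(siteSeq), " > ",
             lens[i], ")")
      pos <- sample(lens[i] - nchar(siteSeq) + 1L, 1L)
      cand <- paste0(substr(bg, 1, pos - 1L), siteSeq,
                     substr(bg, pos + nchar(siteSeq), lens[i]))
      hits <- scanUtr(cand, guide, config)
      if (nrow(hits) == 1L && hits$category == row$category &&
          hits$start == pos && hits$end == pos + nchar(siteSeq) - 1L) {
        utrs[i] <- cand
        planted[[length(planted) + 1L]] <- data.frame(
          utr_id = paste0("utr", i), category = row$category,
          start = pos, end = pos + nchar(siteSeq) - 1L)
        break
      }
    }
  }
  names(utrs) <- paste0("utr", seq_len(n))
  truth <- if (length(planted)) do.call(rbind, planted) else
    data.frame(utr_id = character(), category = character(),
               start = integer(), end = integer())
  list(utrs = utrs,
       truth = list(planted = truth, seed = seed,
                    generator = "genUtrs/0.1.0"))
}

# target-strand sequence of one plantable site
plantSiteSeq <- function(guide, row) {
  cat <- row$category
  if (cat %in% CANONICAL_LEVELS) return(canonicalMotif(guide, cat))
  t3s <- if (!is.null(row$threep_start) && !is.na(row$threep_start))
    row$threep_start else 11L
  t3e <- if (!is.null(row$threep_end) && !is.na(row$threep_end))
    row$threep_end else min(t3s + 11L, guideLength(guide))
  if (cat == "3p_only") return(rcSegment(guide, t3s, t3e))
  if (cat == "3p_microseed") {
    slen <- if (!is.null(row$seed_len) && !is.na(row$seed_len))
      row$seed_len else 4L
    off <- if (!is.null(row$offset) && !is.na(row$offset)) row$offset else 2L
    se <- 7L; ss <- se - slen + 1L
    bridge <- off + (t3s - se)
    stopifnot(bridge >= 0)
    return(paste0(rcSegment(guide, t3s, t3e),
                  substr(BRIDGE_POOL, 1, bridge),
                  rcSegment(guide, ss, se)))
  }
  stop("cannot plant category ", cat)
}

#' Simulate equilibrium binding or association kinetics data
#'
#' Evaluates the fitted equation forward and adds Gaussian noise.
#' Saturation data are clipped to \[0, 1\] with clip events recorded;
#' kinetics with `A_T` below the 80 pM pseudo-first-order guard draw a
#' warning.
#'
#' @param kind `"saturation"` or `"kinetics"`.
#' @param params for saturation: list with `kd` (molar) and `conc`
#'   (molar vector); for kinetics: `kon` (1/(M s)), `aTotal` (molar),
#'   `arEq`, `times` (s).
#' @param noiseSd Gaussian noise standard deviation (on theta, or
#'   relative for kinetics).
#' @param replicates number of replicate curves.
#' @param seed RNG seed.
#' @return list: `data` (long data.frame) and `truth`.
#' @export
genBindingData <- function(kind = c("saturation", "kinetics"), params,
                           noiseSd = 0, replicates = 1L, seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  clipped <- 0L
  if (kind == "saturation") {
    theta0 <- params$conc / (params$conc + params$kd)
    data <- do.call(rbind, lapply(seq_len(replicates), function(r) {
      th <- theta0 + stats::rnorm(length(theta0), 0, noiseSd)
      clipped <<- clipped + sum(th < 0 | th > 1)
      data.frame(replicate = r, conc = params$conc,
                 theta = pmin(pmax(th, 0), 1))
    }))
  } else {
    if (any(params$aTotal < 80e-12))
      warning("A_T below 80 pM violates the pseudo-first-order guard")
    grid <- expand.grid(time = params$times,
                        aTotal = params$aTotal)
    ar0 <- params$arEq * (1 - exp(-params$kon * grid$aTotal * grid$time))
    data <- do.call(rbind, lapply(seq_len(replicates), function(r) {
      ar <- ar0 * (1 + stats::rnorm(length(ar0), 0, noiseSd))
      data.frame(replicate = r, time = grid$time, aTotal = grid$aTotal,
                 ar = ar)
    }))
  }
  list(data = data,
       truth = c(params, list(kind = kind, noise_sd = noiseSd,
                              clipped = clipped, seed = seed,
                              generator = "genBindingData/0.1.0")))
}

#' Simulate a logTPM expression matrix with planted repression
#'
#' Gene baselines are drawn once, per-sample Gaussian noise is added, and
#' log2 shifts from `shiftMap` are applied (converted to log10) to the
#' cohort genes of the matching sample only.
#'
#' @param nGenes number of genes.
#' @param nMirnas number of miRNA-transfection samples (default 16).
#' @param shiftMap data.frame with columns `mirna` (sample index or name),
#'   `genes` (list-column or comma string of gene indices) and `shift`
#'   (log2), or `NULL` for the null generator.
#' @param noiseSd per-sample noise, log10 units (default 0.1).
#' @param seed RNG seed.
#' @return list: `mat` (genes x samples log10 TPM), `utrLengths` (named,
#'   for control matching), `truth`.
#' @export
genExpression <- function(nGenes = 2000L, nMirnas = 16L, shiftMap = NULL,
                          noiseSd = 0.1, seed = 1L) {
  set.seed(seed)
  genes <- paste0("g", seq_len(nGenes))
  samples <- paste0("mir", seq_len(nMirnas))
  base <- stats::rnorm(nGenes, 1.5, 0.5)
  mat <- matrix(base, nGenes, nMirnas) +
    matrix(stats::rnorm(nGenes * nMirnas, 0, noiseSd), nGenes, nMirnas)
  dimnames(mat) <- list(genes, samples)
  if (!is.null(shiftMap)) {
    for (i in seq_len(nrow(shiftMap))) {
      m <- shiftMap$mirna[i]
      if (is.numeric(m)) m <- samples[m]
      g <- shiftMap$genes[[i]]
      if (is.character(g) && length(g) == 1L && grepl(",", g))
        g <- as.integer(strsplit(g, ",")[[1]])
      if (is.numeric(g)) g <- genes[g]
      mat[g, m] <- mat[g, m] + shiftMap$shift[i] / log2(10)
    }
  }
  utrLengths <- stats::setNames(
    round(stats::rlnorm(nGenes, log(1000), 0.6)), genes)
  list(mat = mat, utrLengths = utrLengths,
       truth = list(shift_map = shiftMap, noise_sd = noiseSd, seed = seed,
                    generator = "genExpression/0.1.0"))
}

#' Serialize a generator truth object to JSON
#'
#' @param truth a `truth` list from any generator.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeTruth <- function(truth, file) {
  jsonlite::write_json(truth, file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(file)
}
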