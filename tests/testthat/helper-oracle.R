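# Independent brute-force site oracle, pure R string matching.
# Enumerates every guide segment and every target position directly; no code
# shared with the package's diagonal scanner.

oracleRc <- function(x) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", x), "")[[1]]), collapse = "")
}

# all maximal WC-complementary runs between read and guide region [gmin,gmax]
oracleMaxRuns <- function(read, gseq, gmin, gmax, minLen) {
  R <- nchar(read); L <- nchar(gseq)
  gmax <- min(gmax, L)
  hits <- list()
  for (gs in gmin:gmax) for (ge in gs:gmax) {
    len <- ge - gs + 1L
    if (len < minLen) next
    pat <- oracleRc(substr(gseq, gs, ge))
    if (len > R) next
    for (t in 1:(R - len + 1L)) {
      if (substr(read, t, t + len - 1L) != pat) next
      # target t pairs guide ge; extending guide past ge pairs read t-1,
      # extending guide below gs pairs read t+len
      extHi <- ge < gmax && t > 1 &&
        substr(read, t - 1L, t - 1L) ==
          chartr("ACGU", "UGCA", substr(gseq, ge + 1L, ge + 1L))
      extLo <- gs > gmin && t + len <= R &&
        substr(read, t + len, t + len) ==
          chartr("ACGU", "UGCA", substr(gseq, gs - 1L, gs - 1L))
      if (!extHi && !extLo)
        hits[[length(hits) + 1L]] <- c(gs = gs, ge = ge, rs = t,
                                       re = t + len - 1L)
    }
  }
  if (!length(hits))
    return(data.frame(gs = integer(), ge = integer(), rs = integer(),
                      re = integer()))
  unique(as.data.frame(do.call(rbind, hits)))
}

oracleCanonicalRank <- function(read, run) {
  C <- run$rs + run$ge
  hasA <- C - 1 >= 1 && C - 1 <= nchar(read) &&
    substr(read, C - 1, C - 1) == "A"
  covers <- function(p, q) run$gs <= p && run$ge >= q
  if (covers(2, 8) && hasA) 1L
  else if (covers(2, 8)) 2L
  else if (covers(2, 7) && hasA) 3L
  else if (covers(2, 7)) 4L
  else if (covers(3, 8)) 5L
  else if (covers(2, 6) && hasA) 6L
  else 0L
}

# single-best-site assignment with the package's documented precedence,
# re-derived from the rules: compound > longest 3' register > canonical > none
oracleAssign <- function(read, gseq, min3pStart = 9L, min3pLen = 8L,
                         maxSeedRun = 1L, offMin = -8L, offMax = 16L) {
  L <- nchar(gseq)
  p3 <- oracleMaxRuns(read, gseq, min3pStart, L, min3pLen)
  sd <- oracleMaxRuns(read, gseq, 1L, 8L, 2L)
  cands <- list()
  if (nrow(p3)) for (i in seq_len(nrow(p3))) for (j in seq_len(nrow(sd))) {
    if (nrow(sd) == 0) break
    t <- p3[i, ]; s <- sd[j, ]
    slen <- s$ge - s$gs + 1L
    if (slen <= maxSeedRun || slen > 8L) next
    if (s$rs <= t$re) next
    off <- (s$rs - t$re - 1L) - (t$gs - s$ge)
    if (off < offMin || off > offMax) next
    cands[[length(cands) + 1L]] <-
      data.frame(t3len = t$ge - t$gs + 1L, slen = slen, trs = t$rs,
                 srs = s$rs, sgs = s$gs, off = off,
                 name = sprintf("m%d_%d|%+d|m%d_%d", t$gs, t$ge, off,
                                s$gs, s$ge))
  }
  if (length(cands)) {
    cd <- do.call(rbind, cands)
    # same precedence key as the implementation, independently applied
    cd <- cd[order(-cd$t3len, -cd$slen, cd$trs, cd$srs, cd$sgs, cd$off), ]
    return(list(category = "compound", site = cd$name[1]))
  }
  if (nrow(p3)) {
    p3$len <- p3$ge - p3$gs + 1L
    p3 <- p3[order(-p3$len, p3$rs), ]
    return(list(category = "3p_only",
                site = sprintf("m%d_%d", p3$gs[1], p3$ge[1])))
  }
  best <- 0L
  if (nrow(sd)) for (j in seq_len(nrow(sd))) {
    rk <- oracleCanonicalRank(read, sd[j, ])
    if (rk > 0L && (best == 0L || rk < best)) best <- rk
  }
  if (best > 0L) {
    cls <- c("8mer", "7mer-m8", "7mer-A1", "6mer", "6mer-m8", "6mer-A1")[best]
    return(list(category = cls, site = cls))
  }
  list(category = "none", site = "none")
}
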