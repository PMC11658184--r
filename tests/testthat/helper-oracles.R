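# Independent oracles. Each reimplements the mathematical definition of an
# operation in plain R, structured differently from the package code, so the
# two routes can be compared on generated cases.

# Exhaustive affine-gap fit-alignment optimum (score only). States track the
# number of reference-consuming columns (capped at min_ref_cols) so that the
# minimum-column requirement is enforced exactly as defined: maximize over
# alignments consuming the whole read except clips, with free reference
# flanks, bounded free 5' clipping, and 3' clips free only at the reference
# terminus.
oracle_fit_score <- function(read, ref, scheme = scoring_scheme()) {
  m <- nchar(read); n <- nchar(ref)
  K <- scheme$min_ref_cols
  NEG <- -1e9
  if (m < 1 || n < K) return(NA_real_)
  rd <- utf8ToInt(read); rf <- utf8ToInt(ref)
  go <- scheme$gap_open; ge <- scheme$gap_extend
  pen <- scheme$clip_penalty; free <- scheme$clip5_max_free
  free3 <- scheme$clip3_max_free
  clip5cost <- function(l) if (l <= free) 0 else pen * (l - free)
  newmat <- function() matrix(NEG, nrow = n + 1, ncol = K)  # row j+1, col k
  Mp <- newmat(); Ip <- newmat(); Dp <- newmat()
  best <- NEG
  for (i in 1:m) {
    Mc <- newmat(); Ic <- newmat(); Dc <- newmat()
    s0 <- clip5cost(i - 1)
    for (j in 1:n) {
      subsc <- if (rd[i] == rf[j]) scheme$match else scheme$mismatch
      Bprev <- pmax(Mp[j, ], Ip[j, ], Dp[j, ])      # row i-1, ref j-1
      predM <- c(s0, Bprev[seq_len(K - 1)])
      predM[K] <- max(predM[K], Bprev[K])
      Mc[j + 1, ] <- predM + subsc
      Ic[j + 1, ] <- pmax(Mp[j + 1, ] + go + ge, Ip[j + 1, ] + ge,
                          Dp[j + 1, ] + go + ge)
      pm <- pmax(Mc[j, ] + go + ge, Ic[j, ] + go + ge, Dc[j, ] + ge)
      predD <- c(NEG, pm[seq_len(K - 1)])
      predD[K] <- max(predD[K], pm[K])
      Dc[j + 1, ] <- predD
    }
    ends <- pmax(Mc[-1, K], Ic[-1, K], Dc[-1, K])
    tail3 <- m - i
    cost3 <- if (tail3 == 0) rep(0, n)
             else c(rep(pen * tail3, n - 1), pen * max(0, tail3 - free3))
    best <- max(best, max(ends + cost3))
    Mp <- Mc; Ip <- Ic; Dp <- Dc
  }
  if (best < -1e8) NA_real_ else best
}

# Brute-force 5' tRF enumerator: thresholds applied literally, then clusters
# grown by repeated pairwise merging (transitive closure) of candidate sets
# whose closest members are within merge_gap.
oracle_trf <- function(offsets, min_dist = 7L, min_frac = 0.05, merge_gap = 3L) {
  n <- length(offsets)
  if (!n) return(data.frame(offset = integer(0), fraction = numeric(0)))
  t <- table(offsets)
  offs <- as.integer(names(t))
  frac <- as.numeric(t) / n
  keep <- offs > min_dist & frac > min_frac
  offs <- offs[keep]; frac <- frac[keep]
  if (!length(offs)) return(data.frame(offset = integer(0), fraction = numeric(0)))
  clusters <- as.list(seq_along(offs))
  repeat {
    merged <- FALSE
    for (a in seq_along(clusters)) {
      if (merged) break
      for (b in seq_along(clusters)) {
        if (a >= b) next
        dmin <- min(abs(outer(offs[clusters[[a]]], offs[clusters[[b]]], "-")))
        if (dmin <= merge_gap) {
          clusters[[a]] <- c(clusters[[a]], clusters[[b]])
          clusters[[b]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  out <- do.call(rbind, lapply(clusters, function(i)
    data.frame(offset = min(offs[i]), fraction = sum(frac[i]))))
  out[order(out$offset), , drop = FALSE]
}

# Brute-force per-column recount of coverage / substitutions / deletions for
# the alignments of one gene, walking each CIGAR string independently.
oracle_column_counts <- function(alns, gene_len) {
  cov <- sub <- del <- rep(0L, gene_len)
  for (i in seq_len(nrow(alns))) {
    cig <- alns$cigar[i]
    pos <- alns$ref_start[i]
    while (nchar(cig)) {
      len <- as.integer(sub("^([0-9]+).*", "\\1", cig))
      op <- sub("^[0-9]+(.).*", "\\1", cig)
      cig <- sub("^[0-9]+.", "", cig)
      if (op %in% c("=", "M", "X", "D")) {
        for (p in (pos + 1):(pos + len)) {
          cov[p] <- cov[p] + 1L
          if (op == "X") sub[p] <- sub[p] + 1L
          if (op == "D") del[p] <- del[p] + 1L
        }
        pos <- pos + len
      }
    }
  }
  list(cov = cov, sub = sub, del = del)
}

# Textbook one-way ANOVA from explicit sums of squares.
oracle_anova <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1
  dfw <- length(all) - length(groups)
  F <- (ssb / dfb) / (ssw / dfw)
  list(F = F, p = stats::pf(F, dfb, dfw, lower.tail = FALSE))
}
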