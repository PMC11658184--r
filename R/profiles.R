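# Sprinzl-anchored positional analytics: read end histograms, RT
# misincorporation matrices, charged-vs-uncharged modification comparison,
# truncation-charging association, and the 5' tRF caller.

# Per-position tallies (coverage, substitutions, deletions, insertions) for
# the alignments of one gene. A deleted position counts as covered;
# insertions are attributed to the 5' flanking reference position.
.position_tallies <- function(alns, gene_len) {
  cov <- sub <- del <- ins <- numeric(gene_len + 1L)
  plain <- alns$n_sub + alns$n_del + alns$n_ins == 0
  # interval accumulation for gap/mismatch-free rows
  if (any(plain)) {
    s <- alns$ref_start[plain]; e <- alns$ref_end[plain]
    add <- numeric(gene_len + 1L)
    for (i in seq_along(s)) {
      add[s[i] + 1L] <- add[s[i] + 1L] + 1
      add[e[i] + 1L] <- add[e[i] + 1L] - 1
    }
    cov <- cov + cumsum(add)
  }
  for (i in which(!plain)) {
    p <- .parse_cigar(alns$cigar[i])
    pos <- alns$ref_start[i]
    for (k in seq_along(p$op)) {
      op <- p$op[k]; len <- p$len[k]
      if (op %in% c("=", "M")) {
        cov[(pos + 1L):(pos + len)] <- cov[(pos + 1L):(pos + len)] + 1
        pos <- pos + len
      } else if (op == "X") {
        idx <- (pos + 1L):(pos + len)
        cov[idx] <- cov[idx] + 1; sub[idx] <- sub[idx] + 1
        pos <- pos + len
      } else if (op == "D") {
        idx <- (pos + 1L):(pos + len)
        cov[idx] <- cov[idx] + 1; del[idx] <- del[idx] + 1
        pos <- pos + len
      } else if (op == "I") {
        ins[max(pos, 1L)] <- ins[max(pos, 1L)] + len
      }
    }
  }
  list(cov = cov[seq_len(gene_len)], sub = sub[seq_len(gene_len)],
       del = del[seq_len(gene_len)], ins = ins[seq_len(gene_len)])
}

#' Histogram of read 5' or 3' mapping positions on the Sprinzl axis
#'
#' Counts reads starting (or ending) at each Sprinzl position of each gene of
#' one genome, normalized per thousand reads mapped to that genome's gene set.
#' Soft-clipped 5' bases do not shift the start: the first
#' reference-consuming column defines it.
#'
#' @param alns Alignment data frame (pre-filtered for ambiguity as desired).
#' @param refset The `trna_reference`.
#' @param genome Genome to profile (`"nuclear"`, `"plastid"`,
#'   `"mitochondrial"`, `"spike_in"`).
#' @param which_end `"five_prime"` (read start) or `"three_prime"` (read end).
#' @return Long data frame `gene_id`, `label`, `count`, `per_thousand`, with
#'   attribute `basis` (total mapped reads of the genome's gene set). Empty
#'   with `basis = 0` when the genome has no mapped reads (undefined profile).
#' @export
end_histogram <- function(alns, refset, genome,
                          which_end = c("five_prime", "three_prime")) {
  which_end <- match.arg(which_end)
  genes <- Filter(function(g) g$genome == genome, refset$genes)
  alns <- alns[alns$mapped & alns$gene_id %in% names(genes), , drop = FALSE]
  basis <- nrow(alns)
  if (basis == 0)
    return(structure(data.frame(gene_id = character(0), label = character(0),
                                count = integer(0), per_thousand = numeric(0)),
                     basis = 0L))
  pos <- if (which_end == "five_prime") alns$ref_start else alns$ref_end - 1L
  rows <- lapply(names(genes), function(gid) {
    sel <- alns$gene_id == gid
    if (!any(sel)) return(NULL)
    t <- table(pos[sel])
    lab <- genes[[gid]]$sprinzl[as.integer(names(t)) + 1L]
    data.frame(gene_id = gid, label = lab, count = as.integer(t),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$per_thousand <- 1000 * out$count / basis
  rownames(out) <- NULL
  structure(out, basis = basis)
}

#' Misincorporation matrix over isodecoder families and Sprinzl positions
#'
#' Each cell is the fraction of covering reads with a substitution or
#' deletion at that position (a deleted position counts as covered);
#' insertions, attributed to the 5' flanking position, are tallied in a
#' separate matrix and excluded from the headline rate. Cells whose coverage
#' does not exceed `min_cov` are masked as `NA`, never reported as 0.
#'
#' @param alns Alignment data frame.
#' @param refset The `trna_reference`.
#' @param min_cov Coverage must be strictly greater than this for a cell to
#'   be reported (default 50).
#' @param level `"isodecoder"` (family rows, pooled counts) or `"gene"`.
#' @return Numeric matrix (rows x Sprinzl labels in canonical order) with
#'   attributes `coverage` and `insertions` (same shape).
#' @export
misincorporation_matrix <- function(alns, refset, min_cov = 50L,
                                    level = c("isodecoder", "gene")) {
  level <- match.arg(level)
  alns <- alns[alns$mapped & !is.na(alns$gene_id), , drop = FALSE]
  per_gene <- lapply(names(refset$genes), function(gid) {
    sub <- alns[alns$gene_id == gid, , drop = FALSE]
    g <- refset$genes[[gid]]
    if (!nrow(sub)) return(NULL)
    t <- .position_tallies(sub, nchar(g$seq))
    data.frame(gene_id = gid, label = g$sprinzl, cov = t$cov, sub = t$sub,
               del = t$del, ins = t$ins, stringsAsFactors = FALSE)
  })
  tall <- do.call(rbind, per_gene)
  if (is.null(tall)) stop("no mapped reads to profile")
  if (level == "isodecoder") {
    key <- vapply(refset$genes, function(g)
      paste(g$genome, g$amino_acid, g$anticodon, sep = "|"), "")
    tall$row <- key[tall$gene_id]
  } else tall$row <- tall$gene_id
  agg <- stats::aggregate(cbind(cov, sub, del, ins) ~ row + label, data = tall, FUN = sum)
  labs <- unique(agg$label)
  labs <- labs[order(sprinzl_rank(labs))]
  rows <- sort(unique(agg$row))
  shape <- function(values) {
    m <- matrix(NA_real_, length(rows), length(labs), dimnames = list(rows, labs))
    m[cbind(match(agg$row, rows), match(agg$label, labs))] <- values
    m
  }
  covm <- shape(agg$cov)
  rate <- shape((agg$sub + agg$del) / pmax(agg$cov, 1))
  rate[is.na(covm) | covm <= min_cov] <- NA_real_
  insm <- shape(agg$ins / pmax(agg$cov, 1))
  insm[is.na(covm) | covm <= min_cov] <- NA_real_
  structure(rate, coverage = covm, insertions = insm,
            class = c("misinc_matrix", "matrix", "array"))
}

#' Compare misincorporation rates between CCA- and CC-ended reads
#'
#' In a periodate-treated library CCA-ended reads are the aminoacylated
#' (protected) molecules and CC-ended reads the uncharged ones; a modification
#' influencing charging would show as a rate difference between the classes.
#' Rates are computed separately on the two read classes and compared across
#' sites passing `min_cov` in both (Pearson correlation and a paired
#' two-sided t-test).
#'
#' @param alns Alignment data frame of one periodate library.
#' @param calls Matching tail calls from [classify_tails()].
#' @param refset The `trna_reference`.
#' @param min_cov Per-class coverage mask.
#' @return List: `sites` (family, label, `rate_cca`, `rate_cc`), `r`, `t`,
#'   `p`, `n_sites`; statistics are `NA` with a `note` when fewer than 3
#'   shared sites are available.
#' @export
compare_cca_cc <- function(alns, calls, refset, min_cov = 50L) {
  ids_cca <- calls$read_id[calls$category == "CCA"]
  ids_cc <- calls$read_id[calls$category == "CC"]
  res <- list(sites = NULL, r = NA_real_, t = NA_real_, p = NA_real_,
              n_sites = 0L, note = NULL)
  a_cca <- alns[alns$read_id %in% ids_cca, , drop = FALSE]
  a_cc <- alns[alns$read_id %in% ids_cc, , drop = FALSE]
  if (!nrow(a_cca) || !nrow(a_cc)) {
    res$note <- "one of the read classes is empty"
    return(res)
  }
  m1 <- misincorporation_matrix(a_cca, refset, min_cov = min_cov)
  m2 <- misincorporation_matrix(a_cc, refset, min_cov = min_cov)
  rows <- intersect(rownames(m1), rownames(m2))
  cols <- intersect(colnames(m1), colnames(m2))
  x <- as.vector(m1[rows, cols, drop = FALSE])
  y <- as.vector(m2[rows, cols, drop = FALSE])
  grid <- expand.grid(family = rows, label = cols, stringsAsFactors = FALSE)
  ok <- !is.na(x) & !is.na(y)
  res$sites <- data.frame(grid[ok, ], rate_cca = x[ok], rate_cc = y[ok],
                          row.names = NULL)
  res$n_sites <- sum(ok)
  if (res$n_sites < 3L) {
    res$note <- "fewer than 3 sites pass coverage in both read classes"
    return(res)
  }
  res$r <- stats::cor(res$sites$rate_cca, res$sites$rate_cc)
  dif <- res$sites$rate_cca - res$sites$rate_cc
  if (stats::sd(dif) == 0) {
    res$t <- 0; res$p <- 1
    res$note <- "zero variance of paired differences"
  } else {
    tt <- stats::t.test(res$sites$rate_cca, res$sites$rate_cc, paired = TRUE)
    res$t <- unname(tt$statistic); res$p <- tt$p.value
  }
  res
}

#' Association between 5' truncation and CCA tail integrity
#'
#' Computes each gene's CCA percentage separately for full-length-start reads
#' (alignment starts at the gene 5' end) and 5'-truncated reads (start
#' strictly 3' of it), then a paired t-test across genes within each genome.
#' In periodate libraries a positive difference for truncated reads suggests
#' hard-stop modifications co-occur with charging.
#'
#' @param alns Alignment data frame.
#' @param calls Matching tail calls.
#' @param refset The `trna_reference`.
#' @param min_reads Per-class minimum reads for a gene to enter the test;
#'   genes failing in either class are dropped and counted.
#' @return List: `per_gene` (gene, genome, the two CCA percentages,
#'   difference), `tests` (per genome: n_genes, mean difference, t, p),
#'   `n_dropped`.
#' @export
truncation_association <- function(alns, calls, refset, min_reads = 100L) {
  alns <- alns[alns$mapped & !is.na(alns$gene_id), , drop = FALSE]
  cat_of <- stats::setNames(calls$category, calls$read_id)
  truncated <- alns$ref_start > 0L
  genomes <- vapply(refset$genes, function(g) g$genome, "")
  rows <- lapply(names(refset$genes), function(gid) {
    sel <- alns$gene_id == gid
    if (!any(sel)) return(NULL)
    cl <- cat_of[alns$read_id[sel]]
    tr <- truncated[sel]
    pc <- function(which) {
      cc <- cl[tr == which]
      cca_percentage(sum(cc == "CCA", na.rm = TRUE), sum(cc == "CC", na.rm = TRUE),
                     length(cc), min_reads = min_reads)
    }
    data.frame(gene_id = gid, genome = genomes[[gid]],
               cca_pct_full_length = pc(FALSE), cca_pct_truncated = pc(TRUE),
               stringsAsFactors = FALSE)
  })
  per_gene <- do.call(rbind, rows)
  if (is.null(per_gene))
    return(list(per_gene = NULL, tests = NULL, n_dropped = 0L))
  ok <- !is.na(per_gene$cca_pct_full_length) & !is.na(per_gene$cca_pct_truncated)
  n_dropped <- sum(!ok)
  kept <- per_gene[ok, , drop = FALSE]
  kept$difference <- kept$cca_pct_truncated - kept$cca_pct_full_length
  tests <- lapply(split(kept, kept$genome), function(s) {
    if (nrow(s) < 2L || stats::sd(s$difference) == 0)
      return(data.frame(genome = s$genome[1], n_genes = nrow(s),
                        mean_diff = mean(s$difference), t = NA_real_, p = NA_real_))
    tt <- stats::t.test(s$cca_pct_truncated, s$cca_pct_full_length, paired = TRUE)
    data.frame(genome = s$genome[1], n_genes = nrow(s),
               mean_diff = mean(s$difference),
               t = unname(tt$statistic), p = tt$p.value)
  })
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL
  rownames(kept) <- NULL
  list(per_gene = kept, tests = tests, n_dropped = n_dropped)
}

#' Call 5' tRNA-derived fragments from 3' end positions of one gene
#'
#' Candidate positions are read 3' ends lying strictly more than `min_dist`
#' nucleotides from the annotated reference 3' end (the mature terminus
#' including CCA) that account for strictly more than `min_frac` of all reads
#' mapping to the gene. Candidates separated by at most `merge_gap`
#' nucleotides are clustered (single linkage); each cluster is reported at
#' its 3'-most above-threshold member with the summed fraction of its
#' above-threshold members.
#'
#' @param alns Alignments of one gene (rows with other genes are dropped).
#' @param gene The `trna_gene`.
#' @param min_dist Strict minimum distance (nt) from the annotated 3' end.
#' @param min_frac Strict minimum read fraction.
#' @param merge_gap Maximum separation merged into one tRF.
#' @param size_min Reads shorter than this are invisible to the library;
#'   offsets beyond `len - size_min` are unobservable, recorded in the
#'   `max_observable_offset` attribute rather than reported as absent.
#' @return Data frame `offset` (nt short of the 3' end), `ref_end` (0-based
#'   half-open alignment end), `fraction` (summed over cluster members),
#'   `members` (comma-separated member offsets); empty when no tRF is called.
#' @export
call_5prime_trfs <- function(alns, gene, min_dist = 7L, min_frac = 0.05,
                             merge_gap = 3L, size_min = 35L) {
  alns <- alns[alns$mapped & !is.na(alns$gene_id) & alns$gene_id == gene$gene_id, ,
               drop = FALSE]
  len <- nchar(gene$seq)
  empty <- structure(
    data.frame(offset = integer(0), ref_end = integer(0), fraction = numeric(0),
               members = character(0)),
    max_observable_offset = len - size_min)
  n <- nrow(alns)
  if (!n) return(empty)
  off <- len - alns$ref_end
  t <- table(off)
  offs <- as.integer(names(t))
  frac <- as.numeric(t) / n
  cand <- offs > min_dist & frac > min_frac
  if (!any(cand)) return(empty)
  co <- sort(offs[cand])
  cf <- frac[cand][order(offs[cand])]
  cluster <- cumsum(c(1L, diff(co) > merge_gap))
  rows <- lapply(split(seq_along(co), cluster), function(i) {
    data.frame(offset = min(co[i]), ref_end = len - min(co[i]),
               fraction = sum(cf[i]),
               members = paste(co[i], collapse = ","), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$offset), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, max_observable_offset = len - size_min)
}
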