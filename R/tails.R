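# 3' tail classification and charging statistics. A read's tail state is
# coordinate-based: the distance between the alignment's 3' end and the
# reference 3' terminus (CCA = intact, CC = one nucleotide short,
# MISSING2PLUS = two or more short). Base identity inside positions 74-76 is
# flagged separately (modification-induced misincorporations must not corrupt
# tail calls). Genes without an encoded/appended CCA (t-elements, stem-loops)
# are classified NONTEMPLATED and report their non-templated 3' addition
# string instead.

#' Classify the 3' tail state of aligned reads
#'
#' @param alns Alignment data frame from [map_reads()] (mapped rows are used).
#' @param refset The `trna_reference`.
#' @return Data frame with `read_id`, `gene_id`, `end_offset` (reference 3'
#'   terminus minus alignment end), `category` (`CCA`/`CC`/`MISSING2PLUS`/
#'   `NONTEMPLATED`), `addition` (non-templated 3' string for CCA-less genes;
#'   `"None"` when empty; `NA` when the read does not reach the reference 3'
#'   end), `tail_mismatch` (mismatched base within positions 74-76) and
#'   `ambiguous`.
#' @export
classify_tails <- function(alns, refset) {
  alns <- alns[alns$mapped & !is.na(alns$gene_id), , drop = FALSE]
  if (!all(alns$gene_id %in% names(refset$genes)))
    stop("alignment refers to gene absent from the reference set")
  lens <- .ref_lens(refset)
  cca_absent <- vapply(refset$genes, function(g) g$cca_status == "absent", TRUE)
  glen <- lens[alns$gene_id]
  end_offset <- glen - alns$ref_end
  absent <- cca_absent[alns$gene_id]
  category <- ifelse(absent, "NONTEMPLATED",
              ifelse(end_offset == 0L, "CCA",
              ifelse(end_offset == 1L, "CC", "MISSING2PLUS")))
  addition <- rep(NA_character_, nrow(alns))
  at_end <- absent & end_offset == 0L
  addition[at_end] <- ifelse(nzchar(alns$clip3_seq[at_end]), alns$clip3_seq[at_end], "None")
  tail_mismatch <- .tail_mismatch_flags(alns, glen)
  out <- data.frame(read_id = alns$read_id, gene_id = alns$gene_id,
                    end_offset = as.integer(end_offset), category = category,
                    addition = addition, tail_mismatch = tail_mismatch,
                    ambiguous = alns$ambiguous, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# flag reads with a mismatch (X) or deletion (D) column within the last 3
# reference positions (74-76) of CCA-bearing genes
.tail_mismatch_flags <- function(alns, glen) {
  flag <- logical(nrow(alns))
  cand <- which(alns$n_sub + alns$n_del > 0 & glen - alns$ref_end < 3L)
  for (i in cand) {
    p <- .parse_cigar(alns$cigar[i])
    refpos <- alns$ref_start[i]
    hit <- FALSE
    for (k in seq_along(p$op)) {
      op <- p$op[k]; len <- p$len[k]
      if (op %in% c("=", "M", "X", "D")) {
        if (op %in% c("X", "D") && refpos + len > glen[i] - 3L) { hit <- TRUE; break }
        refpos <- refpos + len
      }
    }
    flag[i] <- hit
  }
  flag
}

#' Tabulate tail categories per gene for one library
#'
#' @param calls Tail calls from [classify_tails()].
#' @param refset The `trna_reference`.
#' @param library_id,treatment,replicate Library metadata stored in the table.
#' @param exclude_ambiguous Drop ambiguously mapping reads (default `TRUE`,
#'   mirroring gene-level tables; genome-level totals can include them).
#' @return Data frame with one row per gene: counts `n_total`, `n_cca`,
#'   `n_cc`, `n_missing2plus` plus `cca_pct` (CCA / (CCA+CC), `NA` when
#'   below `min_reads`; see [cca_percentage()]) and `noncca_pct`
#'   (MISSING2PLUS / total), and the metadata columns.
#' @param min_reads Minimum reads per gene for a defined `cca_pct`.
#' @export
library_table <- function(calls, refset, library_id = "lib1",
                          treatment = "control", replicate = 1L,
                          exclude_ambiguous = TRUE, min_reads = 100L) {
  if (exclude_ambiguous) calls <- calls[!calls$ambiguous, , drop = FALSE]
  ids <- names(refset$genes)
  cnt <- function(cat) {
    x <- table(factor(calls$gene_id[calls$category == cat], levels = ids))
    as.integer(x)
  }
  n_total <- as.integer(table(factor(calls$gene_id, levels = ids)))
  tab <- data.frame(
    gene_id = ids, library_id = library_id, treatment = treatment,
    replicate = as.integer(replicate), n_total = n_total,
    n_cca = cnt("CCA"), n_cc = cnt("CC"), n_missing2plus = cnt("MISSING2PLUS"),
    stringsAsFactors = FALSE)
  tab$cca_pct <- cca_percentage(tab$n_cca, tab$n_cc, tab$n_total, min_reads = min_reads)
  tab$noncca_pct <- noncca_percentage(tab$n_missing2plus, tab$n_total)
  rownames(tab) <- NULL
  tab
}

#' CCA percentage: intact tails among reads at most one nucleotide short
#'
#' `100 * n_cca / (n_cca + n_cc)`, the aminoacylation proxy: reads lacking
#' more than a single 3' nucleotide are excluded from the denominator.
#' Undefined (NA, not zero) when the grouping unit has fewer than `min_reads`
#' total reads or no CCA/CC reads at all.
#'
#' @param n_cca,n_cc Counts of CCA- and CC-ended reads.
#' @param n_total Total reads in the unit (defaults to `n_cca + n_cc`).
#' @param min_reads Minimum total reads for a defined value.
#' @return Numeric percentage(s) in [0, 100], `NA` where undefined.
#' @export
cca_percentage <- function(n_cca, n_cc, n_total = n_cca + n_cc, min_reads = 100L) {
  denom <- n_cca + n_cc
  out <- ifelse(n_total < min_reads | denom == 0, NA_real_, 100 * n_cca / denom)
  as.numeric(out)
}

#' Fraction of all reads missing two or more 3' nucleotides
#'
#' `100 * n_missing2plus / n_total`; `NA` when `n_total` is zero.
#'
#' @param n_missing2plus,n_total Counts.
#' @return Numeric percentage(s).
#' @export
noncca_percentage <- function(n_missing2plus, n_total) {
  as.numeric(ifelse(n_total == 0, NA_real_, 100 * n_missing2plus / n_total))
}

#' Charging index: periodate CCA percentage relative to control
#'
#' Dividing each gene's CCA percentage under periodate treatment by the
#' corresponding no-periodate control value adjusts for the gene's baseline
#' CCA integrity; under ideal chemistry the index estimates the charged
#' fraction theta. Values above 1 are kept but flagged `capped`.
#'
#' @param periodate_table,control_table Library tables from [library_table()].
#' @return Data frame `gene_id`, `cca_pct_periodate`, `cca_pct_control`,
#'   `charging_index`, `capped`. The index is `NA` where either input is
#'   undefined.
#' @export
charging_index <- function(periodate_table, control_table) {
  m <- merge(periodate_table[, c("gene_id", "cca_pct")],
             control_table[, c("gene_id", "cca_pct")],
             by = "gene_id", suffixes = c("_periodate", "_control"))
  idx <- ifelse(is.na(m$cca_pct_periodate) | is.na(m$cca_pct_control) |
                  m$cca_pct_control == 0,
                NA_real_, m$cca_pct_periodate / m$cca_pct_control)
  data.frame(gene_id = m$gene_id,
             cca_pct_periodate = m$cca_pct_periodate,
             cca_pct_control = m$cca_pct_control,
             charging_index = idx, capped = !is.na(idx) & idx > 1,
             stringsAsFactors = FALSE)
}

#' CCA retention ratio: pre-deacylated versus standard periodate treatment
#'
#' A value of 1 means pre-deacylation did not reduce the CCA percentage
#' (deacylation-resistant aminoacyl esters); 0 means it eliminated CCA tails.
#'
#' @param deacyl_periodate_table,periodate_table Library tables.
#' @return Data frame `gene_id`, `cca_pct_deacyl_periodate`,
#'   `cca_pct_periodate`, `retention_ratio`, `capped`.
#' @export
retention_ratio <- function(deacyl_periodate_table, periodate_table) {
  m <- merge(deacyl_periodate_table[, c("gene_id", "cca_pct")],
             periodate_table[, c("gene_id", "cca_pct")],
             by = "gene_id", suffixes = c("_deacyl_periodate", "_periodate"))
  idx <- ifelse(is.na(m$cca_pct_deacyl_periodate) | is.na(m$cca_pct_periodate) |
                  m$cca_pct_periodate == 0,
                NA_real_, m$cca_pct_deacyl_periodate / m$cca_pct_periodate)
  data.frame(gene_id = m$gene_id,
             cca_pct_deacyl_periodate = m$cca_pct_deacyl_periodate,
             cca_pct_periodate = m$cca_pct_periodate,
             retention_ratio = idx, capped = !is.na(idx) & idx > 1,
             stringsAsFactors = FALSE)
}

#' Family-level CCA summaries
#'
#' Aggregates gene-level counts to isodecoder or isoacceptor families two
#' ways: pooled counts (count-weighted) and the unweighted mean of member-gene
#' CCA percentages. The unweighted mean is the default elsewhere for parity
#' with family-averaged figures; both are returned.
#'
#' @param tab A gene-level [library_table()].
#' @param refset The `trna_reference`.
#' @param level `"isodecoder"` or `"isoacceptor"`.
#' @param min_reads Minimum pooled reads for a defined pooled value.
#' @return Data frame: family key, pooled counts, `cca_pct_pooled`,
#'   `cca_pct_mean` (unweighted across member genes with defined values),
#'   `n_genes`.
#' @export
family_table <- function(tab, refset, level = c("isodecoder", "isoacceptor"),
                         min_reads = 100L) {
  level <- match.arg(level)
  fam <- if (level == "isodecoder") refset$isodecoder_map else refset$isoacceptor_map
  rows <- lapply(names(fam), function(key) {
    sub <- tab[tab$gene_id %in% fam[[key]], , drop = FALSE]
    data.frame(family = key,
               n_total = sum(sub$n_total), n_cca = sum(sub$n_cca),
               n_cc = sum(sub$n_cc), n_missing2plus = sum(sub$n_missing2plus),
               cca_pct_pooled = cca_percentage(sum(sub$n_cca), sum(sub$n_cc),
                                               sum(sub$n_total), min_reads),
               cca_pct_mean = if (all(is.na(sub$cca_pct))) NA_real_
                              else mean(sub$cca_pct, na.rm = TRUE),
               n_genes = nrow(sub), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Histogram of non-templated 3' additions on a CCA-less gene
#'
#' Exact string histogram of the 3' addition observed on each read of a
#' t-element/stem-loop gene (reads not reaching the reference 3' end are
#' excluded), sorted by count descending, with the `"None"` row included.
#'
#' @param calls Tail calls from [classify_tails()].
#' @param refset The `trna_reference`.
#' @param gene_id The CCA-less gene to tabulate.
#' @return Data frame `addition`, `count`.
#' @export
tail_spectrum <- function(calls, refset, gene_id) {
  g <- refset$genes[[gene_id]]
  if (is.null(g)) stop("unknown gene: ", gene_id)
  if (g$cca_status != "absent")
    stop("tail_spectrum is defined only for genes without a reference CCA (got ",
         gene_id, ", cca_status=", g$cca_status, ")")
  sub <- calls[calls$gene_id == gene_id & !is.na(calls$addition), , drop = FALSE]
  if (!nrow(sub))
    return(data.frame(addition = character(0), count = integer(0)))
  t <- sort(table(sub$addition), decreasing = TRUE)
  data.frame(addition = names(t), count = as.integer(t), stringsAsFactors = FALSE,
             row.names = NULL)
}
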