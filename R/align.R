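# Read processing and mapping: pair merging, adapter trimming, fit alignment
# against the reference set, SAM export. The fit aligner tolerates the two RT
# artifacts that break global mappers on tRNA reads: non-templated 5'
# extensions (bounded free 5' soft clipping) and reads running past the
# reference 3' terminus (free 3' clipping at the terminus only).

#' Alignment scoring scheme
#'
#' Match 0, mismatch -5 (the quality-ceiling mismatch penalty), affine gaps
#' costing `gap_open + L * gap_extend` for a gap of `L` bases, up to
#' `clip5_max_free` read bases clippable at the 5' end at zero cost (RT
#' terminal-transferase additions), -5 per additionally clipped base, 3'
#' clips free only past the reference 3' terminus and only up to
#' `clip3_max_free` bases (non-templated tail additions are short; an
#' unbounded free terminal clip would let unrelated reads map by a token
#' terminal seed), and at least `min_ref_cols` reference-consuming columns
#' required (preventing degenerate all-clip alignments).
#'
#' @param match,mismatch,gap_open,gap_extend Column scores (all non-positive
#'   except `match`).
#' @param clip5_max_free Read bases clippable at the 5' end at zero cost.
#' @param clip3_max_free Read bases clippable free past the reference 3'
#'   terminus.
#' @param clip_penalty Per-base penalty for non-free clips.
#' @param min_ref_cols Minimum reference-consuming columns.
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 0L, mismatch = -5L, gap_open = -5L,
                           gap_extend = -3L, clip5_max_free = 5L,
                           clip3_max_free = 8L, clip_penalty = -5L,
                           min_ref_cols = 10L) {
  s <- list(match = as.integer(match), mismatch = as.integer(mismatch),
            gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
            clip5_max_free = as.integer(clip5_max_free),
            clip3_max_free = as.integer(clip3_max_free),
            clip_penalty = as.integer(clip_penalty),
            min_ref_cols = as.integer(min_ref_cols))
  if (s$mismatch > 0 || s$gap_open > 0 || s$gap_extend > 0 || s$clip_penalty > 0)
    stop("penalties must be <= 0")
  if (s$clip5_max_free < 0 || s$clip3_max_free < 0)
    stop("free clip bounds must be >= 0")
  structure(s, class = "scoring_scheme")
}

#' Minimum acceptable alignment score for a read
#'
#' Linear in read length, `-0.7 - 0.7 * read_len`, following the mapper
#' convention `f(x) = b + m * x` for score-min function `L,-0.7,-0.7`.
#'
#' @param read_len Read length (>= 0).
#' @return Numeric threshold.
#' @export
min_score <- function(read_len) -0.7 - 0.7 * read_len

#' Fit-align one read against one gene
#'
#' Returns the maximum-score alignment under the [scoring_scheme()] in which
#' the read is fully consumed except permitted clips and the aligned span may
#' start/end anywhere on the reference. Ties are broken deterministically
#' (fewer clipped bases, then smaller `ref_start`, then a fixed traceback
#' preference).
#'
#' @param read Read sequence (character).
#' @param gene A `trna_gene` or reference sequence string.
#' @param scheme A [scoring_scheme()].
#' @return A list of class `alignment_record` with `score`, 0-based half-open
#'   `ref_start`/`ref_end`, `cigar` (S/=/X/I/D), clip lengths and sequences,
#'   and `n_sub`/`n_del`/`n_ins`; or `NULL` if unalignable.
#' @export
fit_align <- function(read, gene, scheme = scoring_scheme()) {
  ref <- if (inherits(gene, "trna_gene")) gene$seq else gene
  r <- .fit_align_cpp(read, ref, unclass(scheme))
  if (r$unalignable) return(NULL)
  m <- nchar(read)
  structure(list(
    score = r$score, ref_start = r$ref_start, ref_end = r$ref_end,
    cigar = r$cigar, clip5 = r$clip5, clip3 = r$clip3,
    clip5_seq = substr(read, 1L, r$clip5),
    clip3_seq = substr(read, m - r$clip3 + 1L, m),
    n_sub = r$n_sub, n_del = r$n_del, n_ins = r$n_ins
  ), class = "alignment_record")
}

#' Map reads against a reference set
#'
#' Fit-aligns each read against every gene; the best score wins if it clears
#' [min_score()] for the read's length. Reads whose best score is tied across
#' two or more distinct gene sequences are flagged `ambiguous` with the tied
#' gene ids recorded; the reported gene is the first tied id in lexicographic
#' order, so the result does not depend on the order of genes in the set.
#'
#' @param reads Data frame with `read_id` and `seq` (e.g. from [read_fastq()]
#'   or [simulate_library()]).
#' @param refset A `trna_reference`.
#' @param scheme A [scoring_scheme()].
#' @return Data frame with one row per read: `read_id`, `seq`, `gene_id`
#'   (`NA` if unmapped), `score`, 0-based `ref_start`/`ref_end`, `clip5`,
#'   `clip3`, `clip5_seq`, `clip3_seq`, `n_sub`, `n_del`, `n_ins`, `cigar`,
#'   `ambiguous`, `tied_gene_ids` (comma-separated), `mapped`.
#' @export
map_reads <- function(reads, refset, scheme = scoring_scheme()) {
  stopifnot(is.data.frame(reads), all(c("read_id", "seq") %in% names(reads)))
  ids <- sort(names(refset$genes))
  seqs <- vapply(refset$genes[ids], function(g) g$seq, "")
  res <- .map_reads_cpp(reads$seq, unname(seqs), unclass(scheme), -0.7, -0.7)
  gene_id <- ifelse(is.na(res$gene), NA_character_, ids[res$gene])
  tied <- vapply(seq_along(res$tied), function(i) {
    t <- res$tied[[i]]
    if (is.na(t)) return(NA_character_)
    paste(ids[as.integer(strsplit(t, ",")[[1]])], collapse = ",")
  }, "")
  len <- nchar(reads$seq)
  out <- data.frame(
    read_id = reads$read_id, seq = reads$seq, gene_id = gene_id,
    score = res$score, ref_start = res$ref_start, ref_end = res$ref_end,
    clip5 = res$clip5, clip3 = res$clip3,
    clip5_seq = substr(reads$seq, 1L, ifelse(is.na(res$clip5), 0L, res$clip5)),
    clip3_seq = substr(reads$seq, len - ifelse(is.na(res$clip3), -1L, res$clip3) + 1L, len),
    n_sub = res$n_sub, n_del = res$n_del, n_ins = res$n_ins,
    cigar = res$cigar, ambiguous = res$ambiguous, tied_gene_ids = tied,
    mapped = !res$unmapped, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Merge a read pair by ungapped overlap
#'
#' The mate `r2` is reverse-complemented, the best ungapped overlap of at
#' least `min_overlap` bases with at most `max_mismatch` mismatches is merged
#' (smallest mismatch count wins, then the longer overlap); base disagreements
#' are resolved by the higher quality, ties in favour of `r1`.
#'
#' @param r1,r2 Read sequences (r2 given 5' to 3' on the opposite strand).
#' @param q1,q2 Optional per-base quality strings (Phred+33).
#' @param min_overlap Minimum overlap length.
#' @param max_mismatch Maximum mismatches tolerated in the overlap.
#' @return The merged read, or a zero-length character with attribute
#'   `reason` (`"empty"` or `"no_overlap"`) if rejected.
#' @export
merge_pairs <- function(r1, r2, q1 = NULL, q2 = NULL, min_overlap = 30L,
                        max_mismatch = 4L) {
  reject <- function(reason) structure(character(0), reason = reason)
  if (!length(r1) || !length(r2) || !nzchar(r1) || !nzchar(r2))
    return(reject("empty"))
  rc2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r2)))
  qc2 <- if (!is.null(q2)) paste(rev(strsplit(q2, "")[[1]]), collapse = "") else NULL
  l1 <- nchar(r1); l2 <- nchar(rc2)
  if (min(l1, l2) < min_overlap) return(reject("no_overlap"))
  a <- strsplit(r1, "")[[1]]; b <- strsplit(rc2, "")[[1]]
  best <- NULL
  for (o in seq.int(min(l1, l2), min_overlap)) {
    mm <- sum(a[(l1 - o + 1L):l1] != b[1:o])
    if (mm <= max_mismatch && (is.null(best) || mm < best$mm)) best <- list(o = o, mm = mm)
  }
  if (is.null(best)) return(reject("no_overlap"))
  o <- best$o
  ov1 <- a[(l1 - o + 1L):l1]; ov2 <- b[1:o]
  dis <- which(ov1 != ov2)
  if (length(dis) && !is.null(q1) && !is.null(qc2)) {
    qq1 <- utf8ToInt(substr(q1, l1 - o + 1L, l1))
    qq2 <- utf8ToInt(substr(qc2, 1L, o))
    take2 <- dis[qq2[dis] > qq1[dis]]
    ov1[take2] <- ov2[take2]
  }
  paste0(substr(r1, 1L, l1 - o), paste(ov1, collapse = ""),
         substr(rc2, o + 1L, l2))
}

#' Trim the capture-hairpin adapter from a merged read
#'
#' Locates the adapter in the read (rightmost full match, tolerating at most
#' one mismatch per 10 adapter bases) and removes it together with everything
#' 3' of it. Reads without an acceptable adapter hit are rejected, mirroring
#' the exclusion of reads lacking the expected adapter.
#'
#' @param read Read sequence.
#' @param adapter_seq Adapter sequence (non-empty).
#' @return The trimmed insert, or a zero-length character with attribute
#'   `reason` (`"too_short"` or `"no_adapter"`) if rejected.
#' @export
trim_adapter <- function(read, adapter_seq) {
  stopifnot(nzchar(adapter_seq))
  la <- nchar(adapter_seq); lr <- nchar(read)
  if (lr < la) return(structure(character(0), reason = "too_short"))
  allowed <- la %/% 10L
  a <- strsplit(adapter_seq, "")[[1]]
  for (start in seq.int(lr - la + 1L, 1L)) {
    mm <- sum(strsplit(substr(read, start, start + la - 1L), "")[[1]] != a)
    if (mm <= allowed) return(substr(read, 1L, start - 1L))
  }
  structure(character(0), reason = "no_adapter")
}

#' Write alignments as SAM
#'
#' Emits a valid SAM file: `@SQ` lines per gene, 1-based `POS`, CIGAR using
#' `S`/`=`/`X`/`I`/`D`, `NM` = substitutions plus indel bases, and custom tags
#' `XB:i` (ambiguity flag) and `XT:Z` (tied gene ids). Unmapped reads get
#' flag 4.
#'
#' @param alns Alignment data frame from [map_reads()].
#' @param refset The `trna_reference` the alignments refer to.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(alns, refset, path) {
  lens <- .ref_lens(refset)
  known <- names(refset$genes)
  bad <- setdiff(stats::na.omit(unique(alns$gene_id)), known)
  if (length(bad)) stop("unknown gene_id in alignments: ", bad[1])
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", known, lens[known]),
           "@PG\tID:tRNAcharge\tPN:tRNAcharge")
  mapped <- alns$mapped
  rec <- character(nrow(alns))
  nm <- alns$n_sub + alns$n_del + alns$n_ins
  rec[mapped] <- sprintf(
    "%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*\tNM:i:%d\tXB:i:%d%s",
    alns$read_id[mapped], alns$gene_id[mapped], alns$ref_start[mapped] + 1L,
    alns$cigar[mapped], alns$seq[mapped], nm[mapped],
    as.integer(alns$ambiguous[mapped]),
    ifelse(is.na(alns$tied_gene_ids[mapped]), "",
           paste0("\tXT:Z:", alns$tied_gene_ids[mapped])))
  rec[!mapped] <- sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*",
                          alns$read_id[!mapped], alns$seq[!mapped])
  writeLines(c(hdr, rec), path)
  invisible(path)
}

# Parse a CIGAR string into op letters and lengths.
.parse_cigar <- function(cigar) {
  m <- gregexpr("[0-9]+[SXIDM=]", cigar)[[1]]
  parts <- regmatches(cigar, list(m))[[1]]
  n <- nchar(parts)
  list(op = substr(parts, n, n), len = as.integer(substr(parts, 1L, n - 1L)))
}

#' Re-parse a SAM file written by [write_sam()]
#'
#' Reconstructs the alignment table fields used downstream (coordinates,
#' clips, mismatch/indel counts, ambiguity) from the SAM records.
#'
#' @param path SAM path.
#' @return Alignment data frame in the [map_reads()] layout.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t")
  get <- function(i) vapply(f, `[`, "", i)
  flag <- as.integer(get(2))
  seq <- get(10)
  cig <- get(6)
  tag <- function(prefix) vapply(f, function(x) {
    hit <- x[startsWith(x, prefix)]
    if (length(hit)) sub(prefix, "", hit[1]) else NA_character_
  }, "")
  mapped <- bitwAnd(flag, 4L) == 0L
  parsed <- lapply(cig, function(cc) {
    if (cc == "*") return(list(clip5 = NA_integer_, clip3 = NA_integer_,
                               rlen = NA_integer_, n_sub = NA_integer_,
                               n_del = NA_integer_, n_ins = NA_integer_))
    p <- .parse_cigar(cc)
    k <- length(p$op)
    clip5 <- if (p$op[1] == "S") p$len[1] else 0L
    clip3 <- if (p$op[k] == "S" && k > 1L) p$len[k] else 0L
    list(clip5 = clip5, clip3 = clip3,
         rlen = sum(p$len[p$op %in% c("M", "=", "X", "D")]),
         n_sub = sum(p$len[p$op == "X"]), n_del = sum(p$len[p$op == "D"]),
         n_ins = sum(p$len[p$op == "I"]))
  })
  g <- function(n) vapply(parsed, function(x) x[[n]], 1L)
  ref_start <- ifelse(mapped, as.integer(get(4)) - 1L, NA_integer_)
  len <- nchar(seq)
  clip3 <- g("clip3")
  out <- data.frame(
    read_id = get(1), seq = seq,
    gene_id = ifelse(mapped, get(3), NA_character_),
    score = NA_integer_, ref_start = ref_start,
    ref_end = ref_start + g("rlen"),
    clip5 = g("clip5"), clip3 = clip3,
    clip5_seq = substr(seq, 1L, ifelse(is.na(g("clip5")), 0L, g("clip5"))),
    clip3_seq = substr(seq, len - ifelse(is.na(clip3), -1L, clip3) + 1L, len),
    n_sub = g("n_sub"), n_del = g("n_del"), n_ins = g("n_ins"),
    cigar = ifelse(mapped, cig, NA_character_),
    ambiguous = !is.na(tag("XB:i:")) & tag("XB:i:") == "1",
    tied_gene_ids = tag("XT:Z:"), mapped = mapped,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Process raw reads: merge pairs and trim the adapter
#'
#' Convenience wrapper running [merge_pairs()] over paired reads (when `r2`
#' is supplied) and [trim_adapter()] (when `adapter` is supplied), recording
#' per-read outcomes.
#'
#' @param r1 Data frame with `read_id`, `seq` (R1 or pre-merged reads).
#' @param r2 Optional mate data frame in the same order.
#' @param adapter Optional adapter sequence to trim.
#' @param min_overlap,max_mismatch Merge criteria (see [merge_pairs()]).
#' @return List with `reads` (surviving reads data frame) and `summary`
#'   (named counts: processed, merged, merge_rejected, trimmed,
#'   adapter_rejected).
#' @export
process_reads <- function(r1, r2 = NULL, adapter = NULL, min_overlap = 30L,
                          max_mismatch = 4L) {
  n <- nrow(r1)
  seqs <- r1$seq
  merged_n <- NA_integer_
  if (!is.null(r2)) {
    stopifnot(nrow(r2) == n)
    m <- vapply(seq_len(n), function(i) {
      x <- merge_pairs(r1$seq[i], r2$seq[i], min_overlap = min_overlap,
                       max_mismatch = max_mismatch)
      if (length(x)) x else NA_character_
    }, "")
    keep <- !is.na(m)
    seqs <- m[keep]
    ids <- r1$read_id[keep]
    merged_n <- sum(keep)
  } else ids <- r1$read_id
  trimmed_n <- NA_integer_
  if (!is.null(adapter)) {
    t <- vapply(seqs, function(s) {
      x <- trim_adapter(s, adapter)
      if (length(x)) x else NA_character_
    }, "", USE.NAMES = FALSE)
    keep <- !is.na(t) & nzchar(t)
    ids <- ids[keep]
    seqs <- t[keep]
    trimmed_n <- sum(keep)
  }
  list(reads = data.frame(read_id = ids, seq = seqs, stringsAsFactors = FALSE),
       summary = c(processed = n, merged = merged_n,
                   merge_rejected = if (is.na(merged_n)) NA_integer_ else n - merged_n,
                   trimmed = trimmed_n,
                   adapter_rejected = if (is.na(trimmed_n)) NA_integer_ else length(t) - trimmed_n))
}
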