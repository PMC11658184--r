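# Sprinzl coordinate assignment: anchors gene-specific nucleotide positions to
# the canonical cloverleaf numbering (1-76, with D-loop insertion labels 17a/20a/20b
# and "e"-prefixed labels for long variable arms) so positions are comparable
# across genes of different lengths.

# Supported structural variability (anything else is rejected loudly):
#   D-loop 7-11 nt, variable region 4-23 nt; all other elements fixed-length.
.DLOOP_MIN <- 7L
.DLOOP_MAX <- 11L
.VAR_MIN <- 4L
.VAR_MAX <- 23L

#' Canonical ordering of all supported Sprinzl labels
#'
#' Returns every label the package can emit, in canonical 5' to 3' order:
#' acceptor stem (1-7), connector (8-9), D-arm (10-26 with insertion slots
#' 17a/20a/20b), anticodon arm (27-43), variable region (44-48 plus "e" labels
#' for long variable arms), T-arm (49-65), acceptor stem 3' (66-72),
#' discriminator (73) and CCA (74-76).
#'
#' @return Character vector of labels in canonical order.
#' @export
sprinzl_universe <- function() {
  c(as.character(1:16), "17", "17a", "18", "19", "20", "20a", "20b",
    as.character(21:45), "46", "47", paste0("e", 1:20), "48",
    as.character(49:76))
}

.sprinzl_rank_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- stats::setNames(seq_along(sprinzl_universe()), sprinzl_universe())
    tab
  }
})

#' Rank Sprinzl labels in canonical order
#'
#' @param labels Character vector of Sprinzl labels.
#' @return Integer ranks (position in [sprinzl_universe()]); unknown labels
#'   raise an error.
#' @export
sprinzl_rank <- function(labels) {
  r <- .sprinzl_rank_table()[labels]
  if (anyNA(r)) stop("unknown Sprinzl label(s): ", paste(unique(labels[is.na(r)]), collapse = ", "))
  unname(r)
}

# D-loop labels for a loop of length L. Canonical 8-nt loop is 14..21;
# a 7-nt loop lacks "17"; longer loops gain the 17a/20a/20b insertion slots.
.dloop_labels <- function(L) {
  if (L < .DLOOP_MIN || L > .DLOOP_MAX)
    stop("unsupported D-loop length ", L, " (supported: ", .DLOOP_MIN, "-", .DLOOP_MAX, ")")
  switch(as.character(L),
    "7"  = c("14", "15", "16", "18", "19", "20", "21"),
    "8"  = as.character(14:21),
    "9"  = c("14", "15", "16", "17", "17a", "18", "19", "20", "21"),
    "10" = c("14", "15", "16", "17", "17a", "18", "19", "20", "20a", "21"),
    "11" = c("14", "15", "16", "17", "17a", "18", "19", "20", "20a", "20b", "21"))
}

# Variable-region labels for a region of length L. Regions of 4-5 nt use the
# canonical 44-48 numbering (a 4-nt region lacks "47"); longer regions keep the
# 44/45 and 48 anchors and fill the interior with e-labels.
.var_labels <- function(L) {
  if (L < .VAR_MIN || L > .VAR_MAX)
    stop("unsupported variable-region length ", L, " (supported: ", .VAR_MIN, "-", .VAR_MAX, ")")
  if (L == 4L) return(c("44", "45", "46", "48"))
  if (L == 5L) return(as.character(44:48))
  c("44", "45", paste0("e", seq_len(L - 3L)), "48")
}

# Expected segment layout for cloverleaf genes, in order. Lengths are
# (min, max); NA max means fixed.
.CLOVERLEAF_SEGMENTS <- list(
  acceptor5 = c(7L, 7L),
  d_arm     = c(6L + .DLOOP_MIN + 5L, 6L + .DLOOP_MAX + 5L),
  ac_arm    = c(17L, 17L),
  var       = c(.VAR_MIN, .VAR_MAX),
  t_arm     = c(17L, 17L),
  acceptor3 = c(7L, 7L),
  disc      = c(1L, 1L),
  cca       = c(3L, 3L)
)

.segment_labels <- function(label, len) {
  switch(label,
    acceptor5 = as.character(1:7),
    d_arm     = {
      loop_len <- len - 11L
      if (loop_len < .DLOOP_MIN || loop_len > .DLOOP_MAX)
        stop("segment 'd_arm' length ", len, " outside supported range (",
             11L + .DLOOP_MIN, "-", 11L + .DLOOP_MAX, ")")
      c(as.character(8:13), .dloop_labels(loop_len), as.character(22:26))
    },
    ac_arm    = {
      if (len != 17L) stop("segment 'ac_arm' must be 17 nt, got ", len)
      as.character(27:43)
    },
    var       = .var_labels(len),
    t_arm     = {
      if (len != 17L) stop("segment 't_arm' must be 17 nt, got ", len)
      as.character(49:65)
    },
    acceptor3 = {
      if (len != 7L) stop("segment 'acceptor3' must be 7 nt, got ", len)
      as.character(66:72)
    },
    disc      = {
      if (len != 1L) stop("segment 'disc' must be 1 nt, got ", len)
      "73"
    },
    cca       = {
      if (len != 3L) stop("segment 'cca' must be 3 nt, got ", len)
      as.character(74:76)
    },
    stop("unknown segment label: '", label, "'")
  )
}

#' Assign Sprinzl labels to each nucleotide of a tRNA gene
#'
#' For cloverleaf-annotated genes every nucleotide receives one canonical
#' label; missing canonical positions (short D-loops, short variable regions)
#' are skipped, insertions in the D-loop get letter suffixes ("17a", "20a",
#' "20b"), variable regions longer than 5 nt get "e"-prefixed interior labels,
#' the discriminator is "73" and the CCA is "74"/"75"/"76". Genes annotated
#' with a single `linear` segment (t-elements without structural homology,
#' stem-loops) get plain sequence positions as labels.
#'
#' @param gene A `trna_gene` object (see [load_reference()]).
#' @return Character vector of labels, one per nucleotide.
#' @export
assign_sprinzl <- function(gene) {
  seg <- gene$segments
  n <- nchar(gene$seq)
  if (nrow(seg) == 1L && seg$label == "linear") {
    if (gene$cca_status == "absent" && n > 73L)
      stop("linear labelling for CCA-less genes supports at most 73 nt (got ", n, ")")
    return(as.character(seq_len(n)))
  }
  if (any(seg$label == "acceptor5")) {
    want <- names(.CLOVERLEAF_SEGMENTS)
    present <- seg$label
    if (!all(present %in% want))
      stop("unknown segment label(s): ", paste(setdiff(present, want), collapse = ", "))
    # order must follow the canonical layout
    if (!identical(present, want[want %in% present]))
      stop("segments out of canonical order: ", paste(present, collapse = ","))
    core <- setdiff(want, "cca")
    if (!all(core %in% present) && gene$cca_status != "absent")
      stop("missing segment(s): ", paste(setdiff(core, present), collapse = ", "))
    labels <- character(0)
    for (i in seq_len(nrow(seg))) {
      len <- seg$end[i] - seg$start[i]
      labels <- c(labels, .segment_labels(seg$label[i], len))
    }
    if (length(labels) != n)
      stop("segment labels (", length(labels), ") do not cover sequence length (", n, ")")
    return(labels)
  }
  stop("unknown segment label: '", seg$label[1], "'")
}

# Validate that a label vector is strictly increasing in canonical order and unique.
.check_sprinzl_monotone <- function(labels, gene_id = "?") {
  if (anyDuplicated(labels))
    stop("duplicate Sprinzl labels in gene ", gene_id)
  r <- sprinzl_rank(labels)
  if (any(diff(r) <= 0))
    stop("Sprinzl labels not monotone in canonical order for gene ", gene_id)
  invisible(TRUE)
}

#' Map a Sprinzl label to its 0-based sequence position in a gene
#'
#' @param gene A `trna_gene`.
#' @param label A single Sprinzl label.
#' @return 0-based integer position, or `NA` if the gene lacks that label.
#' @export
sprinzl_position <- function(gene, label) {
  i <- match(label, gene$sprinzl)
  if (is.na(i)) return(NA_integer_)
  i - 1L
}

#' Export per-gene Sprinzl maps as TSV
#'
#' One row per nucleotide: gene id, 0-based position, base, Sprinzl label.
#'
#' @param refset A `trna_reference`.
#' @param path Output TSV path.
#' @return Invisibly, the written data frame.
#' @export
write_sprinzl_map <- function(refset, path) {
  rows <- lapply(refset$genes, function(g) {
    data.frame(gene_id = g$gene_id,
               position = seq_len(nchar(g$seq)) - 1L,
               base = strsplit(g$seq, "")[[1]],
               sprinzl = g$sprinzl,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
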