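# Reference handling: load a mature tRNA / tRNA-like reference (FASTA plus a
# tab-separated structural annotation sidecar), normalize 3' ends, assign
# Sprinzl coordinates and group genes into isodecoder/isoacceptor families.

.GENOMES <- c("nuclear", "plastid", "mitochondrial", "spike_in")
.CATEGORIES <- c("canonical", "t_element", "trna_like", "stem_loop")
.CCA_STATUS <- c("encoded", "appended", "absent")

#' Construct a single tRNA gene record
#'
#' Users normally obtain genes through [load_reference()]; this constructor is
#' exposed for building fixtures and simulated references in code.
#'
#' @param gene_id Unique gene identifier.
#' @param seq Mature sequence, 5' to 3', DNA alphabet (U is converted to T).
#' @param genome One of `"nuclear"`, `"plastid"`, `"mitochondrial"`, `"spike_in"`.
#' @param category One of `"canonical"`, `"t_element"`, `"trna_like"`, `"stem_loop"`.
#' @param amino_acid Three-letter amino-acid code (with `"Met(e)"`/`"Met(i)"`
#'   for elongator/initiator Met), or `"---"` for non-canonical genes.
#' @param anticodon Three-nucleotide anticodon, or `""`.
#' @param segments Data frame with columns `label`, `start`, `end`
#'   (0-based half-open spans tiling the sequence).
#' @param cca_status `"encoded"`, `"appended"` or `"absent"`; usually set by
#'   [ensure_cca()].
#' @param source_ids Character vector of source ids collapsed into this gene.
#' @return A `trna_gene` object.
#' @export
trna_gene <- function(gene_id, seq, genome, category, amino_acid = "---",
                      anticodon = "", segments, cca_status = "absent",
                      source_ids = gene_id) {
  seq <- toupper(chartr("Uu", "Tt", seq))
  if (!nzchar(seq)) stop("empty sequence for gene ", gene_id)
  if (grepl("[^ACGT]", seq))
    stop("gene ", gene_id, ": sequence contains non-ACGTU characters")
  genome <- match.arg(genome, .GENOMES)
  category <- match.arg(category, .CATEGORIES)
  cca_status <- match.arg(cca_status, .CCA_STATUS)
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "start", "end") %in% names(segments)))
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  g <- structure(list(
    gene_id = gene_id, source_ids = source_ids, seq = seq, genome = genome,
    category = category, amino_acid = amino_acid, anticodon = toupper(chartr("Uu", "Tt", anticodon)),
    segments = segments, cca_status = cca_status, sprinzl = NULL
  ), class = "trna_gene")
  .validate_segments(g)
  g
}

.validate_segments <- function(g) {
  seg <- g$segments
  n <- nchar(g$seq)
  o <- order(seg$start)
  if (!identical(o, seq_len(nrow(seg)))) stop("gene ", g$gene_id, ": segments not in order")
  if (seg$start[1] != 0L || seg$end[nrow(seg)] != n ||
      (nrow(seg) > 1 && any(seg$start[-1] != seg$end[-nrow(seg)])))
    stop("gene ", g$gene_id, ": segment spans do not tile [0, ", n, ") without gap or overlap")
  if (any(seg$end <= seg$start)) stop("gene ", g$gene_id, ": empty segment span")
  invisible(TRUE)
}

#' Normalize the 3' end of a gene for uniform tail classification
#'
#' Canonical genes (including spike-ins) must end in CCA so that read 3' ends
#' can be classified against positions 74-76: genes already ending in CCA are
#' marked `cca_status = "encoded"` (and, if the annotation did not delimit it,
#' the final 3 nt of the last segment are split into a `cca` segment); genes
#' lacking it get `"CCA"` appended once and `cca_status = "appended"`.
#' Non-canonical genes (t-elements, tRNA-like sequences, stem-loops) are
#' returned unchanged with `cca_status = "absent"` -- their post-transcriptional
#' 3' additions are observed as non-templated tails, not templated alignment.
#'
#' @param gene A `trna_gene`.
#' @return The (possibly modified) `trna_gene`.
#' @export
ensure_cca <- function(gene) {
  if (gene$category != "canonical") {
    gene$cca_status <- "absent"
    if (any(gene$segments$label == "cca"))
      stop("gene ", gene$gene_id, ": non-canonical gene must not carry a 'cca' segment")
    return(gene)
  }
  n <- nchar(gene$seq)
  has_cca_seg <- any(gene$segments$label == "cca")
  if (endsWith(gene$seq, "CCA") && has_cca_seg) {
    gene$cca_status <- "encoded"
    return(gene)
  }
  if (has_cca_seg)
    stop("gene ", gene$gene_id, ": 'cca' segment annotated but sequence does not end in CCA")
  gene$seq <- paste0(gene$seq, "CCA")
  gene$segments <- rbind(gene$segments,
                         data.frame(label = "cca", start = n, end = n + 3L,
                                    stringsAsFactors = FALSE))
  gene$cca_status <- "appended"
  gene
}

.parse_segment_string <- function(s, id) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([A-Za-z0-9_]+):([0-9]+)-([0-9]+)$", parts))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) stop("gene ", id, ": malformed segment span '", parts[bad][1], "'")
  data.frame(label = vapply(m, `[`, "", 2L),
             start = as.integer(vapply(m, `[`, "", 3L)),
             end = as.integer(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' Load and validate a tRNA reference set
#'
#' Reads a FASTA of mature tRNA/tRNA-like sequences plus a tab-separated
#' annotation sidecar (columns: `id`, `genome`, `category`, `amino_acid`,
#' `anticodon`, `segments` -- a semicolon-separated `label:start-end` list of
#' 0-based half-open spans). Sequences are normalized to uppercase DNA
#' (U becomes T); entries with byte-identical sequences are collapsed into one
#' gene carrying all source ids; canonical genes are CCA-normalized via
#' [ensure_cca()]; Sprinzl labels are assigned; isodecoder and isoacceptor
#' families are built.
#'
#' @param fasta_path Path to reference FASTA.
#' @param annotation_path Path to the annotation TSV.
#' @return A `trna_reference` object with elements `genes` (named list of
#'   `trna_gene`), `isodecoder_map` and `isoacceptor_map`.
#' @export
load_reference <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) stop("duplicate FASTA ids: ", ids[duplicated(ids)][1])
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("id", "genome", "category", "amino_acid", "anticodon", "segments")
  if (!all(need %in% names(ann)))
    stop("annotation table missing column(s): ", paste(setdiff(need, names(ann)), collapse = ", "))
  missing <- setdiff(ids, ann$id)
  if (length(missing))
    stop("no annotation row for FASTA id '", missing[1], "'")
  rownames(ann) <- ann$id

  raw <- toupper(chartr("Uu", "Tt", as.character(seqs)))
  names(raw) <- ids
  bad <- grepl("[^ACGT]", raw)
  if (any(bad)) stop("gene ", ids[bad][1], ": sequence contains non-ACGTU characters")

  # collapse byte-identical sequences into one gene carrying all source ids
  groups <- split(ids, factor(raw[ids], levels = unique(raw[ids])))
  genes <- lapply(groups, function(g_ids) {
    id0 <- g_ids[1]
    row <- ann[id0, ]
    trna_gene(gene_id = id0, seq = raw[[id0]], genome = row$genome,
              category = row$category, amino_acid = row$amino_acid,
              anticodon = row$anticodon,
              segments = .parse_segment_string(row$segments, id0),
              source_ids = g_ids)
  })
  genes <- lapply(genes, ensure_cca)
  genes <- lapply(genes, function(g) {
    g$sprinzl <- assign_sprinzl(g)
    .check_sprinzl_monotone(g$sprinzl, g$gene_id)
    if (g$cca_status %in% c("encoded", "appended")) {
      stopifnot(endsWith(g$seq, "CCA"))
      if (!identical(utils::tail(g$sprinzl, 3), c("74", "75", "76")))
        stop("gene ", g$gene_id, ": CCA present but last Sprinzl labels are not 74/75/76")
    } else if (any(g$sprinzl %in% c("74", "75", "76"))) {
      stop("gene ", g$gene_id, ": CCA-less gene carries Sprinzl labels 74-76")
    }
    g
  })
  names(genes) <- vapply(genes, function(g) g$gene_id, "")
  refset <- structure(list(genes = genes), class = "trna_reference")
  fam <- group_families(refset)
  refset$isodecoder_map <- fam$isodecoder_map
  refset$isoacceptor_map <- fam$isoacceptor_map
  refset
}

#' Build a reference set from in-memory genes
#'
#' Applies the same normalization/validation path as [load_reference()]
#' (CCA normalization, Sprinzl assignment, family grouping) to a list of
#' [trna_gene()] objects; used by the simulator and by tests.
#'
#' @param genes List of `trna_gene` objects.
#' @return A `trna_reference`.
#' @export
reference_from_genes <- function(genes) {
  genes <- lapply(genes, ensure_cca)
  genes <- lapply(genes, function(g) {
    g$sprinzl <- assign_sprinzl(g)
    .check_sprinzl_monotone(g$sprinzl, g$gene_id)
    g
  })
  ids <- vapply(genes, function(g) g$gene_id, "")
  if (anyDuplicated(ids)) stop("duplicate gene ids")
  seqs <- vapply(genes, function(g) g$seq, "")
  if (anyDuplicated(seqs)) stop("duplicate sequences; collapse before building the set")
  names(genes) <- ids
  refset <- structure(list(genes = genes), class = "trna_reference")
  fam <- group_families(refset)
  refset$isodecoder_map <- fam$isodecoder_map
  refset$isoacceptor_map <- fam$isoacceptor_map
  refset
}

#' Group genes into isodecoder and isoacceptor families
#'
#' Isodecoder families share (genome, amino acid, anticodon); isoacceptor
#' families share (genome, amino acid). Elongator and initiator Met are kept
#' distinct through their amino-acid labels `"Met(e)"`/`"Met(i)"`.
#'
#' @param refset A `trna_reference`.
#' @return List with `isodecoder_map` and `isoacceptor_map` (named lists of
#'   gene-id vectors).
#' @export
group_families <- function(refset) {
  g <- refset$genes
  iso_key <- vapply(g, function(x) paste(x$genome, x$amino_acid, x$anticodon, sep = "|"), "")
  acc_key <- vapply(g, function(x) paste(x$genome, x$amino_acid, sep = "|"), "")
  ids <- names(g)
  list(isodecoder_map = split(ids, iso_key),
       isoacceptor_map = split(ids, acc_key))
}

#' Write a reference set back to FASTA + annotation TSV
#'
#' Inverse of [load_reference()]; loading the written pair reproduces the set
#' (deduplication is idempotent).
#'
#' @param refset A `trna_reference`.
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly `NULL`.
#' @export
write_reference <- function(refset, fasta_path, annotation_path) {
  genes <- refset$genes
  lines <- unlist(lapply(genes, function(g) c(paste0(">", g$gene_id), g$seq)))
  writeLines(lines, fasta_path)
  ann <- do.call(rbind, lapply(genes, function(g) {
    data.frame(id = g$gene_id, genome = g$genome, category = g$category,
               amino_acid = g$amino_acid, anticodon = g$anticodon,
               segments = paste(sprintf("%s:%d-%d", g$segments$label,
                                        g$segments$start, g$segments$end),
                                collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' @export
print.trna_reference <- function(x, ...) {
  genomes <- table(vapply(x$genes, function(g) g$genome, ""))
  cat("trna_reference:", length(x$genes), "unique sequences\n")
  cat("  genomes:", paste(sprintf("%s=%d", names(genomes), genomes), collapse = ", "), "\n")
  cat("  isodecoder families:", length(x$isodecoder_map),
      "| isoacceptor families:", length(x$isoacceptor_map), "\n")
  invisible(x)
}

#' @export
print.trna_gene <- function(x, ...) {
  cat(sprintf("trna_gene %s [%s/%s] %s-%s, %d nt, CCA %s\n", x$gene_id, x$genome,
              x$category, x$amino_acid, x$anticodon, nchar(x$seq), x$cca_status))
  invisible(x)
}

# internal: named character vector of gene sequences
.ref_seqs <- function(refset) vapply(refset$genes, function(g) g$seq, "")

# internal: named vector of gene lengths
.ref_lens <- function(refset) vapply(refset$genes, function(g) nchar(g$seq), 1L)
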