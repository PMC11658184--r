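# Synthetic reference sets. Generates structurally valid cloverleaf tRNA
# genes (random sequence, fixed element layout, anticodon written at
# positions 34-36), optional t-element / stem-loop entries and an uncharged
# spike-in, so the whole pipeline can be exercised without external data.

.AA_TABLE <- data.frame(
  amino_acid = c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
                 "Ile", "Leu", "Lys", "Met(e)", "Met(i)", "Phe", "Pro", "Ser",
                 "Thr", "Trp", "Tyr", "Val"),
  anticodon = c("AGC", "ACG", "GTT", "GTC", "GCA", "TTG", "TTC", "GCC", "GTG",
                "AAT", "CAA", "TTT", "CAT", "CAT", "GAA", "TGG", "GCT",
                "AGT", "CCA", "GTA", "AAC"),
  stringsAsFactors = FALSE)

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# canonical 73-nt gene body (CCA appended later by ensure_cca):
# acceptor5 7 | d_arm 19 (8-nt D-loop) | ac_arm 17 | var 5 | t_arm 17 |
# acceptor3 7 | disc 1
.CANONICAL_SEGMENTS <- data.frame(
  label = c("acceptor5", "d_arm", "ac_arm", "var", "t_arm", "acceptor3", "disc"),
  start = c(0L, 7L, 26L, 43L, 48L, 65L, 72L),
  end   = c(7L, 26L, 43L, 48L, 65L, 72L, 73L),
  stringsAsFactors = FALSE)

.make_canonical_gene <- function(gene_id, genome, amino_acid, anticodon) {
  body <- strsplit(.rand_dna(73L), "")[[1]]
  body[34:36] <- strsplit(anticodon, "")[[1]]  # Sprinzl 34-36 (0-based 33-35)
  trna_gene(gene_id = gene_id, seq = paste(body, collapse = ""),
            genome = genome, category = "canonical", amino_acid = amino_acid,
            anticodon = anticodon, segments = .CANONICAL_SEGMENTS)
}

#' Generate a synthetic tRNA reference set
#'
#' Builds `n_genes` structurally valid canonical tRNA genes (random sequence,
#' canonical cloverleaf layout with an 8-nt D-loop and 5-nt variable region,
#' anticodon written at Sprinzl 34-36), cycling through genomes and
#' amino-acid/anticodon identities, plus optionally a 73-nt mitochondrial
#' t-element (cloverleaf layout, no CCA) and an uncharged spike-in gene.
#' Sequences are drawn until unique. The RNG state of the caller is left
#' untouched.
#'
#' @param n_genes Number of canonical genes.
#' @param seed Seed for sequence generation.
#' @param genomes Genomes to cycle through for the canonical genes.
#' @param include_t_element Add the CCA-less t-element gene `telem-1`.
#' @param include_spike_in Add the spike-in gene `spike-1`.
#' @return A `trna_reference`.
#' @export
synthetic_reference <- function(n_genes = 10L, seed = 42L,
                                genomes = c("nuclear", "plastid", "mitochondrial"),
                                include_t_element = FALSE,
                                include_spike_in = FALSE) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  genes <- list()
  seen <- character(0)
  for (i in seq_len(n_genes)) {
    row <- .AA_TABLE[(i - 1L) %% nrow(.AA_TABLE) + 1L, ]
    genome <- genomes[(i - 1L) %% length(genomes) + 1L]
    repeat {
      gid <- sprintf("%s-%s%s-%d", substr(genome, 1, 3), row$amino_acid,
                     row$anticodon, i)
      g <- .make_canonical_gene(gid, genome, row$amino_acid, row$anticodon)
      if (!g$seq %in% seen) break
    }
    seen <- c(seen, g$seq)
    genes[[length(genes) + 1L]] <- g
  }
  if (include_t_element) {
    repeat {
      g <- trna_gene("telem-1", .rand_dna(73L), genome = "mitochondrial",
                     category = "t_element", amino_acid = "---", anticodon = "",
                     segments = .CANONICAL_SEGMENTS)
      if (!g$seq %in% seen) break
    }
    seen <- c(seen, g$seq)
    genes[[length(genes) + 1L]] <- g
  }
  if (include_spike_in) {
    row <- .AA_TABLE[.AA_TABLE$amino_acid == "Ile", ]
    repeat {
      g <- .make_canonical_gene("spike-1", "spike_in", row$amino_acid, row$anticodon)
      if (!g$seq %in% seen) break
    }
    genes[[length(genes) + 1L]] <- g
  }
  reference_from_genes(genes)
}
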