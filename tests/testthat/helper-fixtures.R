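# Fixture builders shared across test files. Genes are constructed in code;
# the 76-nt canonical fixture uses the classic yeast Phe tRNA sequence (73-nt
# body; the CCA is appended by the reference normalizer).

PHE_BODY <- "GCGGATTTAGCTCAGTTGGGAGAGCGCCAGACTGAAGATCTGGAGGTCCTGTGTTCGATCCACAGAATTCGCA"

CANON_SEGMENTS <- data.frame(
  label = c("acceptor5", "d_arm", "ac_arm", "var", "t_arm", "acceptor3", "disc"),
  start = c(0L, 7L, 26L, 43L, 48L, 65L, 72L),
  end   = c(7L, 26L, 43L, 48L, 65L, 72L, 73L),
  stringsAsFactors = FALSE)

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

make_canon_gene <- function(id, body = NULL, genome = "nuclear", aa = "Ala",
                            anticodon = NULL) {
  if (is.null(body)) {
    body <- rand_dna(73L)
  }
  if (is.null(anticodon)) anticodon <- substr(body, 34, 36)
  else substr(body, 34, 36) <- anticodon
  trna_gene(id, body, genome = genome, category = "canonical",
            amino_acid = aa, anticodon = anticodon, segments = CANON_SEGMENTS)
}

fixture_gene76 <- function() {
  g <- ensure_cca(make_canon_gene("phe-1", PHE_BODY, aa = "Phe"))
  g$sprinzl <- assign_sprinzl(g)
  g
}

# canonical gene with a 7-nt D-loop (18-nt d_arm, 72-nt body)
make_dloop7_gene <- function(id = "d7-1") {
  seg <- CANON_SEGMENTS
  seg$end[seg$label == "d_arm"] <- 25L
  shift <- seg$label %in% c("ac_arm", "var", "t_arm", "acceptor3", "disc")
  seg$start[shift] <- seg$start[shift] - 1L
  seg$end[shift] <- seg$end[shift] - 1L
  trna_gene(id, rand_dna(72L), genome = "nuclear", category = "canonical",
            amino_acid = "Gly", anticodon = "GCC", segments = seg)
}

# canonical gene with a 13-nt variable arm (81-nt body)
make_longvar_gene <- function(id = "lv-1") {
  seg <- CANON_SEGMENTS
  seg$end[seg$label == "var"] <- 43L + 13L
  shift <- seg$label %in% c("t_arm", "acceptor3", "disc")
  seg$start[shift] <- seg$start[shift] + 8L
  seg$end[shift] <- seg$end[shift] + 8L
  trna_gene(id, rand_dna(81L), genome = "nuclear", category = "canonical",
            amino_acid = "Ser", anticodon = "GCT", segments = seg)
}

make_t_element <- function(id = "telem-1", len = 73L) {
  trna_gene(id, rand_dna(len), genome = "mitochondrial", category = "t_element",
            amino_acid = "---", anticodon = "", segments = CANON_SEGMENTS)
}

# write a reference set's FASTA + annotation pair to tempfiles
write_ref_files <- function(genes_df) {
  fa <- tempfile(fileext = ".fasta")
  ann <- tempfile(fileext = ".tsv")
  writeLines(unlist(lapply(seq_len(nrow(genes_df)), function(i)
    c(paste0(">", genes_df$id[i]), genes_df$seq[i]))), fa)
  utils::write.table(genes_df[, c("id", "genome", "category", "amino_acid",
                                  "anticodon", "segments")],
                     ann, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fa, annotation = ann)
}

CANON_SEG_STRING <- paste(sprintf("%s:%d-%d", CANON_SEGMENTS$label,
                                  CANON_SEGMENTS$start, CANON_SEGMENTS$end),
                          collapse = ";")
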