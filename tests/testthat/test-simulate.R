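test_that("identical config and seed give byte-identical FASTQ and manifest", {
  ref <- synthetic_reference(4, seed = 41)
  cfg <- sim_config(ref, "periodate", n_reads_per_gene = 200, seed = 9, theta = 0.5)
  f1 <- tempfile(fileext = ".fastq"); m1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".fastq"); m2 <- tempfile(fileext = ".tsv")
  simulate_library(cfg, ref, fastq = f1, manifest = m1)
  simulate_library(cfg, ref, fastq = f2, manifest = m2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(unname(tools::md5sum(m1)), unname(tools::md5sum(m2)))
  # different library index -> an independent stream
  s3 <- simulate_library(cfg, ref, library_index = 2L)
  expect_false(identical(s3$reads$seq,
                         simulate_library(cfg, ref)$reads$seq))
})

test_that("manifest fate counts partition the molecules of every gene", {
  ref <- synthetic_reference(5, seed = 42, include_t_element = TRUE)
  cfg <- sim_config(ref, "deacyl_periodate", n_reads_per_gene = 300, seed = 5,
                    theta = 0.7, trf5_prob = 0.1, trf5_bp = 40L,
                    mod_sites = list("nuc-AlaAGC-1" = data.frame(
                      label = "58", stop_prob = 0.3, del_prob = 0.1,
                      pA = 0.5, pC = 0.2, pG = 0.1, pT = 0.1)))
  sim <- simulate_library(cfg, ref)
  tr <- sim$truth
  fates <- tr$n_trf + tr$n_rt_truncated + tr$n_extra_degraded +
    tr$n_terminal_removed + tr$n_charged_protected + tr$n_cc_in_vivo +
    tr$n_intact_uncharged
  expect_identical(fates, tr$n_molecules)
  expect_true(all(tr$n_kept <= tr$n_molecules))
})

test_that("full protection and full removal produce pure CCA / CC libraries", {
  ref <- synthetic_reference(3, seed = 43)
  seqs <- vapply(ref$genes, `[[`, "", "seq")
  # theta = 1, no degradation: every read ends CCA
  cfg1 <- sim_config(ref, "periodate", n_reads_per_gene = 150, seed = 2,
                     theta = 1, extra_degradation = 0, tt_prob = 0)
  r1 <- simulate_library(cfg1, ref)$reads
  expect_true(all(substr(r1$seq, nchar(r1$seq) - 2, nchar(r1$seq)) == "CCA"))
  expect_true(all(r1$seq == seqs[r1$gene_id]))
  # theta = 0, intact uncharged, e = 1: every read ends CC
  cfg2 <- sim_config(ref, "periodate", n_reads_per_gene = 150, seed = 2,
                     theta = 0, cca_intact_uncharged = 1, periodate_eff = 1,
                     extra_degradation = 0, tt_prob = 0)
  r2 <- simulate_library(cfg2, ref)$reads
  expect_true(all(substr(r2$seq, nchar(r2$seq) - 1, nchar(r2$seq)) == "CC"))
  expect_true(all(nchar(r2$seq) == nchar(seqs[r2$gene_id]) - 1L))
})

test_that("treatment chemistry acts on molecule states as specified", {
  ref <- synthetic_reference(2, seed = 44)
  cfg <- sim_config(ref, "periodate", seed = 1, extra_degradation = 0)
  set.seed(1)
  mol <- data.frame(charged = rep(c(TRUE, FALSE), each = 500), trim3 = 0L)
  out <- apply_treatment(mol, cfg)
  expect_true(all(out$trim3[out$charged] == 0L))          # protected
  expect_equal(mean(out$trim3[!out$charged]), 0.98, tolerance = 0.05)
  # e = 1 removes exactly one nucleotide from every uncharged molecule
  cfg1 <- sim_config(ref, "periodate", seed = 1, periodate_eff = 1,
                     extra_degradation = 0)
  out1 <- apply_treatment(data.frame(charged = FALSE, trim3 = 0L)[rep(1, 50), ], cfg1)
  expect_true(all(out1$trim3 == 1L))
  # control applies no terminal removal
  cfg0 <- sim_config(ref, "control", seed = 1, extra_degradation = 0)
  out0 <- apply_treatment(mol, cfg0)
  expect_true(all(out0$trim3 == 0L))
})

test_that("deacylation resistance preserves CCA through the deacyl treatment", {
  ref <- synthetic_reference(2, seed = 45)
  cfg <- sim_config(ref, "deacyl_periodate", seed = 1, deacyl_eff = 1,
                    periodate_eff = 1, extra_degradation = 0,
                    deacyl_resistance = 1)
  set.seed(7)
  out <- apply_treatment(data.frame(charged = TRUE, trim3 = 0L)[rep(1, 200), ],
                         cfg, deacyl_resistance = 1)
  expect_true(all(out$trim3 == 0L))  # fully resistant: nothing removed
  set.seed(7)
  out0 <- apply_treatment(data.frame(charged = TRUE, trim3 = 0L)[rep(1, 200), ],
                          cfg, deacyl_resistance = 0)
  expect_true(all(out0$trim3 == 1L))  # fully deacylated then fully oxidized
})

test_that("reverse transcription reproduces template, stops and misincorporates", {
  set.seed(46)
  g <- fixture_gene76()
  n <- 400L
  # no sites, no terminal transferase: reads equal the molecule
  rt0 <- list(tt_prob = 0, max_5prime_ext = 3L)
  out <- reverse_transcribe(g, rep(0L, n), rep(76L, n), NULL, rt0)
  expect_true(all(out$seq == g$seq))
  # hard stop at Sprinzl 58: all reads start immediately 3' of it
  ms <- data.frame(label = "58", stop_prob = 1, del_prob = 0,
                   pA = 0, pC = 0, pG = 0, pT = 1)
  ms[, c("pA", "pC", "pG", "pT")] <- 0
  base <- substr(g$seq, sprinzl_position(g, "58") + 1, sprinzl_position(g, "58") + 1)
  ms[[paste0("p", base)]] <- 1
  out2 <- reverse_transcribe(g, rep(0L, n), rep(76L, n), ms, rt0)
  expect_true(all(out2$rt_stop))
  expect_true(all(out2$seq == substr(g$seq, sprinzl_position(g, "58") + 2, 76)))
  # site emitting 50% G->C and 25% deletions at 26
  p26 <- sprinzl_position(g, "26")
  refbase <- substr(g$seq, p26 + 1, p26 + 1)
  ms2 <- data.frame(label = "26", stop_prob = 0, del_prob = 0.25,
                    pA = 0, pC = 0, pG = 0, pT = 0)
  ms2[[paste0("p", refbase)]] <- 0.25
  other <- setdiff(c("A", "C", "G", "T"), refbase)[1]
  ms2[[paste0("p", other)]] <- 0.5
  out3 <- reverse_transcribe(g, rep(0L, 4000L), rep(76L, 4000L), ms2, rt0)
  dels <- mean(nchar(out3$seq) == 75L)
  expect_lt(abs(dels - 0.25), 3 * sqrt(0.25 * 0.75 / 4000))
  subs <- mean(substr(out3$seq, p26 + 1, p26 + 1) == other & nchar(out3$seq) == 76L)
  expect_lt(abs(subs - 0.5), 3 * sqrt(0.5 * 0.5 / 4000))
  # terminal transferase appends 1..3 bases 5' of the template
  rt1 <- list(tt_prob = 1, max_5prime_ext = 3L)
  out4 <- reverse_transcribe(g, rep(0L, 200L), rep(76L, 200L), NULL, rt1)
  extra <- nchar(out4$seq) - 76L
  expect_true(all(extra >= 1L & extra <= 3L))
  expect_true(all(substr(out4$seq, extra + 1, extra + 76) == g$seq))
})

test_that("simulated tail states match the closed-form chemistry expectations", {
  ref <- synthetic_reference(2, seed = 47)
  for (treat in c("control", "periodate", "deacyl_periodate")) {
    cfg <- sim_config(ref, treat, n_reads_per_gene = 4000, seed = 11,
                      theta = 0.6, cca_intact_uncharged = 0.9)
    sim <- simulate_library(cfg, ref)
    exp <- expected_tail_fractions(0.6, cfg)
    tr <- sim$truth[1, ]
    for (nm in c("cca", "cc")) {
      obs <- tr[[paste0("n_", nm)]] / tr$n_molecules
      p <- exp[[paste0("p_", nm)]]
      expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / tr$n_molecules) + 1e-9)
    }
  }
})

test_that("paired-end splitting is consistent with merging back", {
  ref <- synthetic_reference(2, seed = 48)
  cfg <- sim_config(ref, "control", n_reads_per_gene = 30, seed = 3,
                    extra_degradation = 0, tt_prob = 0)
  sim <- simulate_library(cfg, ref)
  pp <- split_pairs(sim$reads, overlap = 40L)
  merged <- vapply(seq_len(nrow(pp$r1)), function(i)
    merge_pairs(pp$r1$seq[i], pp$r2$seq[i]), "")
  expect_identical(merged, sim$reads$seq)
})
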