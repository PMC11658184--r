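test_that("5' histograms put full-length mass at label 1 and normalize per thousand", {
  set.seed(81)
  genes <- lapply(1:3, function(i) make_canon_gene(paste0("h-", i)))
  ref <- reference_from_genes(genes)
  # 990 full-length reads spread over genes 1-2, 10 reads of gene 3 starting at 34
  p34 <- sprinzl_position(ref$genes[[3]], "34")
  reads <- data.frame(
    read_id = sprintf("r%d", 1:1000),
    seq = c(rep(ref$genes[[1]]$seq, 495), rep(ref$genes[[2]]$seq, 495),
            rep(substring(ref$genes[[3]]$seq, p34 + 1), 10)))
  alns <- map_reads(reads, ref)
  h <- end_histogram(alns, ref, "nuclear", "five_prime")
  expect_equal(attr(h, "basis"), 1000L)
  expect_identical(sort(unique(h$label)), sort(c("1", "34")))
  expect_equal(h$per_thousand[h$label == "34"], 10)
  # mass conservation: per-thousand values sum to 1000
  expect_equal(sum(h$per_thousand), 1000)
  # 3' histogram of full-length reads sits at 76
  h3 <- end_histogram(alns, ref, "nuclear", "three_prime")
  expect_identical(unique(h3$label), "76")
  # a genome with no mapped reads yields an undefined (empty) profile
  h0 <- end_histogram(alns, ref, "plastid", "five_prime")
  expect_equal(nrow(h0), 0L)
  expect_equal(attr(h0, "basis"), 0L)
})

test_that("a simulated hard stop at 58 moves all 5' starts to label 59", {
  ref <- synthetic_reference(2, seed = 82, genomes = "nuclear")
  gid <- names(ref$genes)[1]
  # truncation at 58 leaves ~18-nt reads: lower the size floor to keep them
  cfg <- sim_config(ref, "control", n_reads_per_gene = 200, seed = 14,
                    extra_degradation = 0, tt_prob = 0, size_min = 12L,
                    mod_sites = stats::setNames(list(data.frame(
                      label = "58", stop_prob = 1, del_prob = 0,
                      pA = 0.25, pC = 0.25, pG = 0.25, pT = 0.25)), gid))
  sim <- simulate_library(cfg, ref)
  alns <- map_reads(sim$reads, ref)
  h <- end_histogram(alns, ref, "nuclear", "five_prime")
  expect_identical(unique(h$label[h$gene_id == gid]), "59")
})

test_that("misincorporation cells match the simulated site and mask low coverage", {
  ref <- synthetic_reference(3, seed = 83, genomes = "nuclear")
  ids <- names(ref$genes)
  g1 <- ref$genes[[1]]
  refbase <- substr(g1$seq, sprinzl_position(g1, "26") + 1,
                    sprinzl_position(g1, "26") + 1)
  ms <- data.frame(label = "26", stop_prob = 0, del_prob = 0.25,
                   pA = 0, pC = 0, pG = 0, pT = 0)
  ms[[paste0("p", refbase)]] <- 0.25
  other <- setdiff(c("A", "C", "G", "T"), refbase)[1]
  ms[[paste0("p", other)]] <- 0.5
  cfg <- sim_config(ref, "control", n_reads_per_gene = 3000, seed = 15,
                    extra_degradation = 0, tt_prob = 0,
                    mod_sites = stats::setNames(list(ms), ids[1]))
  sim <- simulate_library(cfg, ref)
  # shrink the third gene to 40 reads: its whole row must be masked
  keep <- sim$reads$gene_id != ids[3] | seq_len(nrow(sim$reads)) %in%
    which(sim$reads$gene_id == ids[3])[1:40]
  alns <- map_reads(sim$reads[keep, ], ref)
  m <- misincorporation_matrix(alns, ref, min_cov = 50, level = "gene")
  cell <- m[ids[1], "26"]
  expect_lt(abs(cell - 0.75), 3 * sqrt(0.75 * 0.25 / 3000))
  # error-free gene: all unmasked cells are exactly 0
  expect_true(all(m[ids[2], !is.na(m[ids[2], ])] == 0))
  # low-coverage row is fully masked (NA sentinel, never 0)
  expect_true(all(is.na(m[ids[3], ])))
})

test_that("matrix cells equal a brute-force per-column recount on a small fixture", {
  ref <- synthetic_reference(2, seed = 84, genomes = "nuclear")
  ids <- names(ref$genes)
  cfg <- sim_config(ref, "control", n_reads_per_gene = 40, seed = 16,
                    mod_sites = stats::setNames(list(data.frame(
                      label = c("26", "58"), stop_prob = c(0, 0.3),
                      del_prob = c(0.3, 0.1), pA = c(0.2, 0.4), pC = c(0.2, 0.2),
                      pG = c(0.2, 0.2), pT = c(0.1, 0.1))), ids[1]))
  sim <- simulate_library(cfg, ref)
  alns <- map_reads(sim$reads, ref)
  m <- misincorporation_matrix(alns, ref, min_cov = 0, level = "gene")
  for (gid in ids) {
    g <- ref$genes[[gid]]
    sub <- alns[alns$gene_id == gid & alns$mapped, ]
    o <- oracle_column_counts(sub, nchar(g$seq))
    got <- m[gid, g$sprinzl]
    want <- ifelse(o$cov == 0, NA_real_, (o$sub + o$del) / pmax(o$cov, 1))
    expect_equal(unname(got), want)
  }
})

test_that("CCA and CC read classes share rates under a null and split under an alternative", {
  ref <- synthetic_reference(2, seed = 85, genomes = "nuclear")
  ids <- names(ref$genes)
  ms <- data.frame(label = c("26", "58"), stop_prob = 0, del_prob = 0.2,
                   pA = 0.3, pC = 0.2, pG = 0.2, pT = 0.1)
  cfg <- sim_config(ref, "periodate", n_reads_per_gene = 4000, seed = 17,
                    theta = 0.5, cca_intact_uncharged = 1, tt_prob = 0,
                    mod_sites = stats::setNames(list(ms, ms), ids))
  sim <- simulate_library(cfg, ref)
  alns <- map_reads(sim$reads, ref)
  calls <- classify_tails(alns, ref)
  cmp <- compare_cca_cc(alns, calls, ref, min_cov = 50)
  expect_gt(cmp$r, 0.95)
  expect_gt(cmp$p, 0.05)
  expect_gte(cmp$n_sites, 2)
  # disjoint coverage: diagnostic, no statistics
  half <- calls
  none <- compare_cca_cc(alns[0, ], half, ref)
  expect_true(is.na(none$p))
  expect_false(is.null(none$note))
})

test_that("truncation-charging association is null when independent, negative when uncharged-only", {
  ref <- synthetic_reference(4, seed = 86, genomes = "nuclear")
  ids <- names(ref$genes)
  # truncation independent of charging: mean paired difference near zero
  ms_all <- stats::setNames(lapply(ids, function(i) data.frame(
    label = "37", stop_prob = 0.4, del_prob = 0,
    pA = 0.25, pC = 0.25, pG = 0.25, pT = 0.25)), ids)
  cfg <- sim_config(ref, "periodate", n_reads_per_gene = 3000, seed = 18,
                    theta = 0.5, cca_intact_uncharged = 1, tt_prob = 0,
                    extra_degradation = 0, mod_sites = ms_all)
  sim <- simulate_library(cfg, ref)
  alns <- map_reads(sim$reads, ref)
  calls <- classify_tails(alns, ref)
  ta <- truncation_association(alns, calls, ref, min_reads = 100)
  expect_lt(abs(ta$tests$mean_diff), 5)
  expect_gt(ta$tests$p, 0.001)
  # single-gene input: per-genome test undefined, per-gene values still emitted
  one <- alns[alns$gene_id == ids[1], ]
  ta1 <- truncation_association(one, calls, ref, min_reads = 100)
  expect_equal(nrow(ta1$per_gene), 1L)
  expect_true(is.na(ta1$tests$p))
})

test_that("uncharged-only hard stops lower the CCA percentage of truncated reads", {
  # molecules carrying the stop-inducing modification are never charged:
  # simulate charged (protected, full-length) and uncharged (stop-prone)
  # pools separately and merge the libraries
  ref <- synthetic_reference(3, seed = 87, genomes = "nuclear")
  ids <- names(ref$genes)
  ms <- stats::setNames(lapply(ids, function(i) data.frame(
    label = "37", stop_prob = 0.5, del_prob = 0,
    pA = 0.25, pC = 0.25, pG = 0.25, pT = 0.25)), ids)
  charged <- simulate_library(
    sim_config(ref, "periodate", n_reads_per_gene = 1500, seed = 19, theta = 1,
               extra_degradation = 0, tt_prob = 0), ref)
  uncharged <- simulate_library(
    sim_config(ref, "periodate", n_reads_per_gene = 1500, seed = 20, theta = 0,
               cca_intact_uncharged = 1, extra_degradation = 0, tt_prob = 0,
               mod_sites = ms), ref)
  uncharged$reads$read_id <- paste0("u-", uncharged$reads$read_id)
  reads <- rbind(charged$reads, uncharged$reads)
  alns <- map_reads(reads, ref)
  calls <- classify_tails(alns, ref)
  ta <- truncation_association(alns, calls, ref, min_reads = 100)
  expect_true(all(ta$per_gene$cca_pct_truncated < ta$per_gene$cca_pct_full_length))
  expect_lt(ta$tests$mean_diff, 0)
})

test_that("the tRF caller applies thresholds and merges clusters at the 3'-most site", {
  set.seed(88)
  g <- fixture_gene76()
  ref <- reference_from_genes(list(g))
  mk_reads <- function(offsets) {
    data.frame(read_id = sprintf("r%d", seq_along(offsets)),
               seq = substr(rep(g$seq, length(offsets)), 1, 76 - offsets))
  }
  aln_of <- function(offsets) map_reads(mk_reads(offsets), ref)
  # all reads full length: no call
  expect_equal(nrow(call_5prime_trfs(aln_of(rep(0, 50)), g)), 0L)
  # 10% of reads ending 20 nt short: one call at offset 20
  a <- call_5prime_trfs(aln_of(c(rep(0, 90), rep(20, 10))), g)
  expect_equal(a$offset, 20L)
  expect_equal(a$fraction, 0.1)
  # offsets {20, 22, 30}: cluster {20, 22} reported at its 3'-most member
  b <- call_5prime_trfs(aln_of(c(rep(0, 40), rep(20, 20), rep(22, 20), rep(30, 20))), g)
  expect_identical(b$offset, c(20L, 30L))
  expect_equal(b$fraction, c(0.4, 0.2))
  expect_identical(b$members, c("20,22", "30"))
  # distance and fraction thresholds are strict
  c1 <- call_5prime_trfs(aln_of(c(rep(0, 93), rep(7, 7))), g)
  expect_equal(nrow(c1), 0L)  # offset 7 is not > 7
  c2 <- call_5prime_trfs(aln_of(c(rep(0, 95), rep(20, 5))), g)
  expect_equal(nrow(c2), 0L)  # fraction 0.05 is not > 0.05
})

test_that("the tRF caller agrees with a brute-force enumerator on random profiles", {
  set.seed(89)
  g <- fixture_gene76()
  ref <- reference_from_genes(list(g))
  for (rep_i in 1:120) {
    k <- sample(2:6, 1)
    offs <- sample(0:41, k)
    w <- as.numeric(stats::rmultinom(1, 60, stats::rgamma(k, 1) + 0.05))
    offsets <- rep(offs, w)
    if (!length(offsets)) next
    reads <- data.frame(read_id = sprintf("r%d", seq_along(offsets)),
                        seq = substr(rep(g$seq, length(offsets)), 1, 76 - offsets))
    got <- call_5prime_trfs(map_reads(reads, ref), g)
    want <- oracle_trf(offsets)
    expect_equal(got$offset, want$offset)
    expect_equal(got$fraction, want$fraction, tolerance = 1e-12)
  }
})
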