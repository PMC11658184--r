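test_that("tail categories follow the alignment end offset", {
  set.seed(71)
  g <- fixture_gene76()
  te <- make_t_element("te-1")
  ref <- reference_from_genes(list(g, te))
  ten <- nchar(ref$genes[["te-1"]]$seq)
  reads <- data.frame(
    read_id = c("cca", "cc", "miss", "te_ca", "te_none"),
    seq = c(g$seq,                                  # ends at terminal A
            substr(g$seq, 1, 75),                   # one base short
            substr(g$seq, 1, 73),                   # three short
            paste0(ref$genes[["te-1"]]$seq, "CA"),  # non-templated CA
            ref$genes[["te-1"]]$seq))
  calls <- classify_tails(map_reads(reads, ref), ref)
  calls <- calls[match(reads$read_id, calls$read_id), ]
  expect_identical(calls$category,
                   c("CCA", "CC", "MISSING2PLUS", "NONTEMPLATED", "NONTEMPLATED"))
  expect_identical(calls$end_offset, c(0L, 1L, 3L, 0L, 0L))
  expect_identical(calls$addition, c(NA, NA, NA, "CA", "None"))
})

test_that("a mismatch inside positions 74-76 flags the read without changing the call", {
  set.seed(72)
  g <- fixture_gene76()
  ref <- reference_from_genes(list(g))
  r <- g$seq
  substr(r, 75, 75) <- setdiff(c("A", "C", "G", "T"), substr(r, 75, 75))[1]
  calls <- classify_tails(map_reads(data.frame(read_id = "x", seq = r), ref), ref)
  expect_identical(calls$category, "CCA")
  expect_true(calls$tail_mismatch)
})

test_that("category counts partition every simulated library", {
  ref <- synthetic_reference(5, seed = 73, include_t_element = TRUE)
  for (treat in c("control", "periodate")) {
    cfg <- sim_config(ref, treat, n_reads_per_gene = 150, seed = 8, theta = 0.5)
    sim <- simulate_library(cfg, ref)
    calls <- classify_tails(map_reads(sim$reads, ref), ref)
    tab <- library_table(calls, ref, min_reads = 1)
    canon <- tab[vapply(ref$genes[tab$gene_id], function(g)
      g$cca_status != "absent", TRUE), ]
    expect_identical(canon$n_cca + canon$n_cc + canon$n_missing2plus,
                     canon$n_total)
  }
})

test_that("CCA percentage excludes shortened reads and honours the read floor", {
  # arithmetic on the ccmC t-element control counts
  expect_equal(cca_percentage(86, 35, min_reads = 1), 100 * 86 / 121,
               tolerance = 1e-12)
  expect_equal(round(cca_percentage(86, 35, min_reads = 1), 2), 71.07)
  expect_equal(cca_percentage(50, 0, min_reads = 1), 100)
  # heavily degraded reads do not enter the denominator
  expect_equal(cca_percentage(40, 40, n_total = 580, min_reads = 100), 50)
  # undefined (flagged, not zero) below the read floor or without CCA/CC reads
  expect_true(is.na(cca_percentage(3, 2, min_reads = 100)))
  expect_true(is.na(cca_percentage(0, 0, n_total = 500, min_reads = 100)))
})

test_that("non-CCA percentage is the fraction of all reads two or more short", {
  expect_equal(noncca_percentage(0, 100), 0)
  expect_equal(noncca_percentage(25, 100), 25)
  expect_true(is.na(noncca_percentage(0, 0)))
  set.seed(74)
  cats <- sample(c("CCA", "CC", "MISSING2PLUS"), 400, TRUE, prob = c(.5, .2, .3))
  expect_equal(noncca_percentage(sum(cats == "MISSING2PLUS"), length(cats)),
               100 * mean(cats == "MISSING2PLUS"))
})

test_that("charging index and retention ratio divide the right treatments", {
  tab <- function(cca, cc) data.frame(gene_id = "g", n_total = cca + cc,
                                      n_cca = cca, n_cc = cc, n_missing2plus = 0,
                                      cca_pct = cca_percentage(cca, cc, min_reads = 1))
  expect_equal(charging_index(tab(50, 50), tab(50, 50))$charging_index, 1)
  expect_equal(charging_index(tab(50, 50), tab(100, 0))$charging_index, 0.5)
  over <- charging_index(tab(90, 10), tab(50, 50))
  expect_true(over$capped)
  expect_equal(retention_ratio(tab(30, 70), tab(30, 70))$retention_ratio, 1)
  expect_equal(retention_ratio(tab(0, 100), tab(50, 50))$retention_ratio, 0)
  # undefined inputs propagate as NA
  und <- tab(3, 2); und$cca_pct <- NA_real_
  expect_true(is.na(charging_index(tab(50, 50), und)$charging_index))
})

test_that("complete deacylation drives the retention ratio to zero", {
  ref <- synthetic_reference(3, seed = 75)
  mk <- function(treat) {
    cfg <- sim_config(ref, treat, n_reads_per_gene = 600, seed = 12, theta = 0.7,
                      cca_intact_uncharged = 1, deacyl_eff = 1, periodate_eff = 1,
                      extra_degradation = 0)
    sim <- simulate_library(cfg, ref)
    calls <- classify_tails(map_reads(sim$reads, ref), ref)
    library_table(calls, ref, treatment = treat, min_reads = 100)
  }
  rr <- retention_ratio(mk("deacyl_periodate"), mk("periodate"))
  expect_true(all(rr$retention_ratio < 0.02))
})

test_that("family summaries pool counts consistently with member genes", {
  ref <- synthetic_reference(8, seed = 76)
  cfg <- sim_config(ref, "periodate", n_reads_per_gene = 250, seed = 13, theta = 0.5)
  sim <- simulate_library(cfg, ref)
  calls <- classify_tails(map_reads(sim$reads, ref), ref)
  tab <- library_table(calls, ref, min_reads = 1)
  fam <- family_table(tab, ref, "isoacceptor", min_reads = 1)
  for (i in seq_len(nrow(fam))) {
    members <- ref$isoacceptor_map[[fam$family[i]]]
    sub <- tab[tab$gene_id %in% members, ]
    # pooled percentage equals the count-weighted combination of member values
    w <- sub$n_cca + sub$n_cc
    expect_equal(fam$cca_pct_pooled[i],
                 sum(sub$cca_pct * w, na.rm = TRUE) / sum(w[!is.na(sub$cca_pct)]),
                 tolerance = 1e-9)
    expect_equal(fam$n_total[i], sum(sub$n_total))
  }
})

test_that("tail spectra histogram non-templated additions exactly", {
  set.seed(77)
  te <- make_t_element("te-1")
  ref <- reference_from_genes(list(te, make_canon_gene("can-1")))
  ten <- ref$genes[["te-1"]]$seq
  additions <- c(rep("CCA", 3), rep("CA", 2), rep("", 4))
  reads <- data.frame(read_id = sprintf("r%d", seq_along(additions)),
                      seq = paste0(ten, additions))
  calls <- classify_tails(map_reads(reads, ref), ref)
  spec <- tail_spectrum(calls, ref, "te-1")
  expect_identical(spec$addition, c("None", "CCA", "CA"))
  expect_identical(spec$count, c(4L, 3L, 2L))
  expect_error(tail_spectrum(calls, ref, "can-1"), "without a reference CCA")
})

test_that("simulated t-element spectra recover the drawn addition distribution", {
  set.seed(78)
  te <- make_t_element("te-1")
  ref <- reference_from_genes(list(te))
  draw <- sample(c("CCA", "CA", "C", ""), 300, TRUE, prob = c(.5, .25, .15, .1))
  reads <- data.frame(read_id = sprintf("r%d", seq_along(draw)),
                      seq = paste0(ref$genes[["te-1"]]$seq, draw))
  calls <- classify_tails(map_reads(reads, ref), ref)
  spec <- tail_spectrum(calls, ref, "te-1")
  want <- table(ifelse(draw == "", "None", draw))
  expect_identical(stats::setNames(spec$count, spec$addition)[names(want)],
                   stats::setNames(as.integer(want), names(want)))
})
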