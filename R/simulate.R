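# Synthetic MSR-seq library generator. Emulates the charging chemistry the
# analysis assumes: per-gene aminoacylation fractions protect the 3' terminal
# nucleotide from periodate, uncharged molecules lose it with efficiency e,
# off-target degradation removes additional 3' nucleotides, base modifications
# stop the reverse transcriptase or cause misincorporations, the RT appends
# non-templated 5' bases, and a size-selection floor drops short reads.
# Every library carries a ground-truth manifest so downstream estimates can be
# checked against the simulated truth.

.TREATMENTS <- c("control", "periodate", "deacyl_periodate")

#' Build a validated simulation configuration
#'
#' Per-gene parameters may be given as scalars (recycled across genes) or as
#' vectors named by gene id. Chemistry defaults describe the regime the
#' protocol operates in: periodate removal efficiency `periodate_eff = 0.98`
#' (a free 3' end escapes oxidation 2% of the time), deacylation efficiency
#' `deacyl_eff = 0.9`, off-target 3' degradation probability
#' `extra_degradation` of 0.10 in control and 0.35 in periodate-treated
#' libraries with the number of lost nucleotides distributed as
#' 1 + Geometric(`extra_degradation_geom` = 0.5), RT terminal-transferase
#' probability 0.3 adding up to 3 random 5' bases, and a 35 nt size floor.
#'
#' @param refset A `trna_reference` the library will be drawn from.
#' @param treatment `"control"`, `"periodate"` or `"deacyl_periodate"`.
#' @param n_reads_per_gene Molecules simulated per gene.
#' @param seed Integer seed; identical config + seed gives byte-identical output.
#' @param theta Per-gene aminoacylation (charging) fraction in [0, 1].
#' @param cca_intact_uncharged Probability an uncharged molecule carries an
#'   intact CCA in vivo (else it ends in CC).
#' @param deacyl_resistance Per-gene multiplier on deacylation *failure*
#'   (1 = fully resistant, as for slow-deacylating Ile/Thr/Val-type esters).
#' @param trf5_prob,trf5_bp Probability a molecule is a 5' fragment and the
#'   0-based position its span ends before (read covers `[0, trf5_bp)`).
#' @param trf3_prob,trf3_bp Probability a molecule is a 3' fragment and the
#'   0-based position its span starts at (read covers `[trf3_bp, len)`).
#' @param mod_sites Named list (by gene id) of data frames with columns
#'   `label` (Sprinzl label), `stop_prob`, `del_prob`, `pA`, `pC`, `pG`, `pT`.
#'   `del_prob + pA + pC + pG + pT` must equal 1: the p-columns are the
#'   unconditional emission probabilities at the site (mass on the reference
#'   base is a correct emission; mass elsewhere a misincorporation).
#' @param periodate_eff,deacyl_eff,extra_degradation,extra_degradation_geom
#'   Chemistry parameters (see above). `extra_degradation = NULL` selects the
#'   treatment default (control 0.10, otherwise 0.35).
#' @param tt_prob,max_5prime_ext RT terminal-transferase parameters.
#' @param size_min Minimum read length retained.
#' @return A `sim_config` object.
#' @export
sim_config <- function(refset, treatment = c("control", "periodate", "deacyl_periodate"),
                       n_reads_per_gene = 2000L, seed = 1L,
                       theta = 0.5, cca_intact_uncharged = 0.9,
                       deacyl_resistance = 0, trf5_prob = 0, trf5_bp = NA_integer_,
                       trf3_prob = 0, trf3_bp = NA_integer_,
                       mod_sites = list(),
                       periodate_eff = 0.98, deacyl_eff = 0.9,
                       extra_degradation = NULL, extra_degradation_geom = 0.5,
                       tt_prob = 0.3, max_5prime_ext = 3L, size_min = 35L) {
  treatment <- match.arg(treatment)
  ids <- names(refset$genes)
  expand <- function(x, what) {
    if (length(x) == 1L && is.null(names(x))) x <- rep(x, length(ids))
    else if (!is.null(names(x))) {
      if (!all(ids %in% names(x))) stop("missing per-gene value of '", what, "'")
      x <- x[ids]
    } else if (length(x) != length(ids))
      stop("'", what, "' must be scalar, named, or one per gene")
    stats::setNames(x, ids)
  }
  if (is.null(extra_degradation))
    extra_degradation <- if (treatment == "control") 0.10 else 0.35
  prob_ok <- function(x) all(is.finite(x) & x >= 0 & x <= 1)
  theta_scalar <- length(theta) == 1L && is.null(names(theta))
  theta <- expand(theta, "theta")
  if (theta_scalar) {
    # t-elements, stem-loops and spike-ins are never aminoacylated
    unchargeable <- vapply(refset$genes[ids], function(g)
      g$category != "canonical" || g$genome == "spike_in", TRUE)
    theta[unchargeable] <- 0
  }
  genes <- data.frame(
    gene_id = ids,
    theta = theta,
    cca_intact_uncharged = expand(cca_intact_uncharged, "cca_intact_uncharged"),
    deacyl_resistance = expand(deacyl_resistance, "deacyl_resistance"),
    trf5_prob = expand(trf5_prob, "trf5_prob"),
    trf5_bp = as.integer(expand(trf5_bp, "trf5_bp")),
    trf3_prob = expand(trf3_prob, "trf3_prob"),
    trf3_bp = as.integer(expand(trf3_bp, "trf3_bp")),
    stringsAsFactors = FALSE
  )
  if (!prob_ok(genes$theta) || !prob_ok(genes$cca_intact_uncharged) ||
      !prob_ok(genes$deacyl_resistance) || !prob_ok(genes$trf5_prob) ||
      !prob_ok(genes$trf3_prob))
    stop("per-gene probabilities must lie in [0, 1]")
  if (any(genes$trf5_prob + genes$trf3_prob > 1))
    stop("trf5_prob + trf3_prob must not exceed 1")
  lens <- .ref_lens(refset)
  bad5 <- genes$trf5_prob > 0 & (is.na(genes$trf5_bp) | genes$trf5_bp <= 0 | genes$trf5_bp >= lens[ids])
  bad3 <- genes$trf3_prob > 0 & (is.na(genes$trf3_bp) | genes$trf3_bp <= 0 | genes$trf3_bp >= lens[ids])
  if (any(bad5) || any(bad3)) stop("tRF breakpoints must lie strictly inside the gene")
  if (!prob_ok(c(periodate_eff, deacyl_eff, extra_degradation, extra_degradation_geom, tt_prob)))
    stop("chemistry probabilities must lie in [0, 1]")
  for (gid in names(mod_sites)) {
    if (!gid %in% ids) stop("mod_sites entry for unknown gene '", gid, "'")
    ms <- mod_sites[[gid]]
    need <- c("label", "stop_prob", "del_prob", "pA", "pC", "pG", "pT")
    if (!all(need %in% names(ms))) stop("mod_sites for ", gid, " missing columns")
    if (!prob_ok(ms$stop_prob) || !prob_ok(ms$del_prob))
      stop("mod site probabilities must lie in [0, 1]")
    tot <- ms$del_prob + ms$pA + ms$pC + ms$pG + ms$pT
    if (any(abs(tot - 1) > 1e-8))
      stop("mod_sites for ", gid, ": del_prob + pA + pC + pG + pT must equal 1")
    pos <- vapply(ms$label, function(l) sprinzl_position(refset$genes[[gid]], l), 1L)
    if (anyNA(pos)) stop("mod_sites for ", gid, ": label not present in gene")
  }
  if (n_reads_per_gene < 1L) stop("n_reads_per_gene must be positive")
  structure(list(
    seed = as.integer(seed), n_reads_per_gene = as.integer(n_reads_per_gene),
    treatment = treatment, genes = genes, mod_sites = mod_sites,
    chemistry = list(periodate_eff = periodate_eff, deacyl_eff = deacyl_eff,
                     extra_degradation = extra_degradation,
                     extra_degradation_geom = extra_degradation_geom),
    rt = list(tt_prob = tt_prob, max_5prime_ext = as.integer(max_5prime_ext)),
    size_min = as.integer(size_min)
  ), class = "sim_config")
}

#' Apply the treatment chemistry to a table of molecule states
#'
#' Molecule states carry a `charged` flag and the 3' trim already suffered
#' (`trim3`, nucleotides lost from the molecule's own 3' end). For
#' `deacyl_periodate`, charged molecules are deacylated with probability
#' `deacyl_eff * (1 - deacyl_resistance)`. Periodate then removes the terminal
#' nucleotide of every molecule with a free (uncharged) 3' end with probability
#' `periodate_eff`; charged molecules are exempt. Independently, any molecule
#' (charged or not) suffers off-target loss of `1 + Geometric(p)` additional
#' nucleotides with probability `extra_degradation`.
#'
#' @param molecules Data frame with logical `charged` and integer `trim3`.
#' @param config A `sim_config` (its `treatment` and `chemistry` are used).
#' @param deacyl_resistance Per-molecule resistance multiplier (recycled).
#' @return The updated data frame, with logical columns `terminal_removed` and
#'   `extra_degraded` recording what happened.
#' @export
apply_treatment <- function(molecules, config, deacyl_resistance = 0) {
  n <- nrow(molecules)
  ch <- config$chemistry
  molecules$terminal_removed <- FALSE
  molecules$extra_degraded <- FALSE
  if (config$treatment == "deacyl_periodate") {
    p_deacyl <- ch$deacyl_eff * (1 - rep_len(deacyl_resistance, n))
    deacylated <- molecules$charged & (stats::runif(n) < p_deacyl)
    molecules$charged[deacylated] <- FALSE
  }
  if (config$treatment %in% c("periodate", "deacyl_periodate")) {
    hit <- !molecules$charged & (stats::runif(n) < ch$periodate_eff)
    molecules$trim3[hit] <- molecules$trim3[hit] + 1L
    molecules$terminal_removed <- hit
  }
  deg <- stats::runif(n) < ch$extra_degradation
  if (any(deg)) {
    k <- 1L + stats::rgeom(sum(deg), ch$extra_degradation_geom)
    molecules$trim3[deg] <- molecules$trim3[deg] + k
    molecules$extra_degraded <- deg
  }
  molecules
}

#' Reverse-transcribe molecules of one gene into read sequences
#'
#' Scanning 3' to 5', the RT stops at each modified site with its
#' `stop_prob` (the read's 5' end becomes the position immediately 3' of the
#' site); at surviving sites it emits a deletion with `del_prob` or a base
#' drawn from the site's emission probabilities. With probability `tt_prob`
#' the RT's terminal-transferase activity appends 1..`max_5prime_ext` random
#' bases beyond the template 5' end.
#'
#' @param gene A `trna_gene`.
#' @param start,end Integer vectors of 0-based half-open molecule spans.
#' @param mod_sites Data frame as in [sim_config()] (or `NULL`).
#' @param rt List with `tt_prob` and `max_5prime_ext`.
#' @return List with `seq` (character reads) and `rt_stop` (logical: truncated
#'   at a hard-stop site).
#' @export
reverse_transcribe <- function(gene, start, end, mod_sites, rt) {
  n <- length(start)
  rstart <- start
  stopped <- logical(n)
  sub_at <- vector("list", n)  # per-molecule list of (pos, base) edits
  del_at <- vector("list", n)
  if (!is.null(mod_sites) && nrow(mod_sites)) {
    pos <- vapply(mod_sites$label, function(l) sprinzl_position(gene, l), 1L)
    o <- order(pos, decreasing = TRUE)  # 3' -> 5'
    for (i in o) {
      p <- pos[i]
      covered <- (p >= rstart) & (p < end) & !stopped
      if (!any(covered)) next
      idx <- which(covered)
      stops <- stats::runif(length(idx)) < mod_sites$stop_prob[i]
      if (any(stops)) {
        hit <- idx[stops]
        rstart[hit] <- p + 1L
        stopped[hit] <- TRUE
        idx <- idx[!stops]
      }
      if (length(idx)) {
        outcome <- sample(c("del", "A", "C", "G", "T"), length(idx), replace = TRUE,
                          prob = c(mod_sites$del_prob[i], mod_sites$pA[i],
                                   mod_sites$pC[i], mod_sites$pG[i], mod_sites$pT[i]))
        for (j in seq_along(idx)) {
          m <- idx[j]
          if (outcome[j] == "del") del_at[[m]] <- c(del_at[[m]], p)
          else if (outcome[j] != substr(gene$seq, p + 1L, p + 1L))
            sub_at[[m]] <- c(sub_at[[m]], stats::setNames(p, outcome[j]))
        }
      }
    }
  }
  reads <- substring(gene$seq, rstart + 1L, end)
  edit <- which(vapply(sub_at, length, 1L) > 0 | vapply(del_at, length, 1L) > 0)
  for (m in edit) {
    chars <- strsplit(reads[m], "")[[1]]
    offs <- function(p) p - rstart[m] + 1L
    s <- sub_at[[m]]
    if (length(s)) chars[offs(s)] <- names(s)
    d <- del_at[[m]]
    if (length(d)) chars <- chars[-offs(d)]
    reads[m] <- paste(chars, collapse = "")
  }
  tt <- stats::runif(n) < rt$tt_prob
  if (any(tt) && rt$max_5prime_ext > 0) {
    k <- sample.int(rt$max_5prime_ext, sum(tt), replace = TRUE)
    ext <- vapply(k, function(kk)
      paste(sample(c("A", "C", "G", "T"), kk, replace = TRUE), collapse = ""), "")
    reads[tt] <- paste0(ext, reads[tt])
  }
  list(seq = reads, rt_stop = stopped)
}

#' Simulate one sequencing library with ground truth
#'
#' Draws `n_reads_per_gene` molecules per gene: each is a 5'/3' fragment or a
#' full-length molecule; full-length molecules are charged with probability
#' `theta`; uncharged molecules start with an intact CCA with probability
#' `cca_intact_uncharged` (else they end in CC in vivo); the treatment
#' chemistry is applied ([apply_treatment()]); molecules are reverse
#' transcribed ([reverse_transcribe()]); reads shorter than `size_min` are
#' dropped. FASTQ qualities are constant.
#'
#' @param config A `sim_config`.
#' @param refset The `trna_reference` used to build the config.
#' @param fastq Optional path; if given, reads are written as FASTQ.
#' @param manifest Optional path; if given, the truth manifest is written as TSV.
#' @param library_index Integer; each library gets its own RNG stream seeded
#'   from `(seed, library_index)`.
#' @param anonymize If `TRUE`, read names are opaque (`read0000001`); otherwise
#'   they encode gene id and molecule fate for white-box testing.
#' @return List with `reads` (data frame: `read_id`, `seq`, `gene_id`, `fate`),
#'   `truth` (per-gene manifest data frame) and the written paths.
#' @export
simulate_library <- function(config, refset, fastq = NULL, manifest = NULL,
                             library_index = 1L, anonymize = FALSE) {
  stopifnot(inherits(config, "sim_config"), inherits(refset, "trna_reference"))
  lib_seed <- (config$seed * 1009L + as.integer(library_index)) %% 2147483597L
  set.seed(lib_seed)
  n <- config$n_reads_per_gene
  all_reads <- vector("list", nrow(config$genes))
  truth_rows <- vector("list", nrow(config$genes))
  for (gi in seq_len(nrow(config$genes))) {
    par <- config$genes[gi, ]
    gene <- refset$genes[[par$gene_id]]
    len <- nchar(gene$seq)

    u <- stats::runif(n)
    is5 <- u < par$trf5_prob
    is3 <- !is5 & u < par$trf5_prob + par$trf3_prob
    start <- ifelse(is3, par$trf3_bp, 0L)
    full_end <- ifelse(is5, par$trf5_bp, len)
    full_len_mol <- !is5 & !is3

    charged <- full_len_mol & (stats::runif(n) < par$theta)
    # uncharged CCA-carrying molecules may already lack the terminal A in vivo
    has_cca_end <- !is5  # 5' fragments end at an internal breakpoint
    cc_in_vivo <- has_cca_end & !charged & (stats::runif(n) >= par$cca_intact_uncharged)
    trim3 <- ifelse(cc_in_vivo, 1L, 0L)

    mol <- data.frame(charged = charged, trim3 = as.integer(trim3))
    mol <- apply_treatment(mol, config, deacyl_resistance = par$deacyl_resistance)
    end <- pmax(full_end - mol$trim3, start)

    rtres <- reverse_transcribe(gene, start, end, config$mod_sites[[par$gene_id]], config$rt)

    fate <- ifelse(is5 | is3, "trf",
            ifelse(rtres$rt_stop, "rt_truncated",
            ifelse(mol$extra_degraded, "extra_degraded",
            ifelse(mol$terminal_removed, "terminal_removed",
            ifelse(mol$charged, "charged_protected",
            ifelse(cc_in_vivo, "cc_in_vivo", "intact_uncharged"))))))

    # tail state of the molecule itself (before size selection)
    end_off <- len - end
    tail_cat <- ifelse(is5, "no_cca_end",
                ifelse(end_off == 0L, "CCA", ifelse(end_off == 1L, "CC", "MISSING2PLUS")))

    keep <- nchar(rtres$seq) >= config$size_min
    reads <- data.frame(
      gene_id = par$gene_id, seq = rtres$seq, fate = fate,
      tail_cat = tail_cat, kept = keep, stringsAsFactors = FALSE)
    all_reads[[gi]] <- reads

    truth_rows[[gi]] <- data.frame(
      gene_id = par$gene_id, theta = par$theta, n_molecules = n,
      n_trf = sum(fate == "trf"), n_rt_truncated = sum(fate == "rt_truncated"),
      n_extra_degraded = sum(fate == "extra_degraded"),
      n_terminal_removed = sum(fate == "terminal_removed"),
      n_charged_protected = sum(fate == "charged_protected"),
      n_cc_in_vivo = sum(fate == "cc_in_vivo"),
      n_intact_uncharged = sum(fate == "intact_uncharged"),
      n_cca = sum(tail_cat == "CCA"), n_cc = sum(tail_cat == "CC"),
      n_missing2plus = sum(tail_cat == "MISSING2PLUS"),
      n_kept = sum(keep), stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, all_reads)
  reads <- reads[reads$kept, c("gene_id", "seq", "fate", "tail_cat")]
  rownames(reads) <- NULL
  reads$read_id <- if (anonymize) sprintf("read%07d", seq_len(nrow(reads)))
                   else sprintf("%s|m%06d|%s", reads$gene_id, seq_len(nrow(reads)), reads$fate)
  reads <- reads[, c("read_id", "seq", "gene_id", "fate", "tail_cat")]
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL

  if (!is.null(fastq)) write_fastq(reads$seq, reads$read_id, fastq)
  if (!is.null(manifest))
    utils::write.table(truth, manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(reads = reads, truth = truth, fastq = fastq, manifest = manifest))
}

#' Write sequences as FASTQ with constant qualities
#'
#' @param seqs Character vector of read sequences.
#' @param ids Read names.
#' @param path Output path.
#' @param quality_char Constant per-base quality character.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(seqs, ids, path, quality_char = "I") {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  quals <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    strrep(quality_char, n), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a data frame
#'
#' @param path FASTQ path.
#' @return Data frame with `read_id` and `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(x)), seq = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Split merged reads into overlapping paired-end reads
#'
#' Emits R1 as the 5' portion and R2 as the reverse complement of the 3'
#' portion, with at least `overlap` shared bases, for exercising the
#' pair-merging step on simulated data.
#'
#' @param reads Data frame with `read_id` and `seq`.
#' @param overlap Minimum overlap between the two mates (>= 30 recommended,
#'   matching the merge criterion).
#' @return List of two data frames, `r1` and `r2`.
#' @export
split_pairs <- function(reads, overlap = 40L) {
  len <- nchar(reads$seq)
  l1 <- pmin(len, ceiling((len + overlap) / 2))
  r1 <- substr(reads$seq, 1L, l1)
  r2start <- pmax(1L, len - l1 + 1L)
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substr(reads$seq, r2start, len))))
  list(r1 = data.frame(read_id = reads$read_id, seq = r1, stringsAsFactors = FALSE),
       r2 = data.frame(read_id = reads$read_id, seq = r2, stringsAsFactors = FALSE))
}

#' Closed-form expected 3' tail-state fractions under the chemistry model
#'
#' For a gene with charging fraction `theta` and no modification or fragment
#' processes, returns the model's expected probabilities that a molecule ends
#' with an intact CCA, a CC (one nucleotide short), or lacks two or more
#' nucleotides, after the stated treatment, together with the expected CCA
#' percentage among CCA+CC reads. Used to check simulated libraries against
#' their own model and to reason about detection bounds (e.g. the spike-in
#' regime, where the expected CCA percentage follows directly from the
#' periodate efficiency).
#'
#' @param theta Charging fraction.
#' @param config A `sim_config` (chemistry, treatment and
#'   `cca_intact_uncharged` defaults are read from it) or `NULL`.
#' @param treatment,periodate_eff,deacyl_eff,extra_degradation,
#'   extra_degradation_geom,cca_intact_uncharged,deacyl_resistance Overrides.
#' @return Named numeric vector: `p_cca`, `p_cc`, `p_missing2plus`, `cca_pct`.
#' @export
expected_tail_fractions <- function(theta, config = NULL,
                                    treatment = NULL, periodate_eff = NULL,
                                    deacyl_eff = NULL, extra_degradation = NULL,
                                    extra_degradation_geom = NULL,
                                    cca_intact_uncharged = NULL,
                                    deacyl_resistance = 0) {
  pick <- function(x, cfg_val, default) if (!is.null(x)) x else if (!is.null(config)) cfg_val else default
  treatment <- pick(treatment, config$treatment, "periodate")
  e <- pick(periodate_eff, config$chemistry$periodate_eff, 0.98)
  q <- pick(deacyl_eff, config$chemistry$deacyl_eff, 0.9)
  d <- pick(extra_degradation, config$chemistry$extra_degradation,
            if (treatment == "control") 0.10 else 0.35)
  p <- pick(extra_degradation_geom, config$chemistry$extra_degradation_geom, 0.5)
  cint <- pick(cca_intact_uncharged, config$genes$cca_intact_uncharged[1], 0.9)

  th <- theta
  if (treatment == "deacyl_periodate") th <- theta * (1 - q * (1 - deacyl_resistance))
  # extra degradation removes exactly 1 nt w.p. d*p, >=2 w.p. d*(1-p)
  P0 <- 1 - d; P1 <- d * p
  per <- treatment %in% c("periodate", "deacyl_periodate")
  rm1 <- if (per) e else 0  # terminal removal prob for a free 3' end
  # molecules deacylated in the deacyl treatment had intact CCA (protected until now)
  p_uncharged_intact <- if (treatment == "deacyl_periodate" && theta > 0) {
    w_dea <- theta - th  # newly deacylated mass, intact
    w_un <- 1 - theta
    (w_dea + w_un * cint) / (w_dea + w_un)
  } else cint
  un <- 1 - th
  # charged: protected from periodate, still subject to extra degradation
  p_cca <- th * P0
  p_cc <- th * P1
  # uncharged intact branch
  ui <- un * p_uncharged_intact
  p_cca <- p_cca + ui * (1 - rm1) * P0
  p_cc <- p_cc + ui * ((1 - rm1) * P1 + rm1 * P0)
  # uncharged in-vivo-CC branch
  uc <- un * (1 - p_uncharged_intact)
  p_cc <- p_cc + uc * (1 - rm1) * P0
  p_miss <- 1 - p_cca - p_cc
  c(p_cca = p_cca, p_cc = p_cc, p_missing2plus = p_miss,
    cca_pct = 100 * p_cca / (p_cca + p_cc))
}
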