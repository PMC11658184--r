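# Pipeline orchestration and report assembly: runs the full analysis over a
# set of libraries and writes a deterministic bundle of TSV tables plus a
# machine-readable run manifest (timestamps are confined to the log).

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Run the full analysis over a set of libraries
#'
#' For each library: read FASTQ (optionally trim the capture-hairpin
#' adapter), map reads against the reference, classify 3' tails and build the
#' per-gene table. Across libraries: pooled per-treatment tables, charging
#' indices (periodate / control), retention ratios (pre-deacylated /
#' periodate), family summaries, genome-level summaries, Sprinzl end
#' histograms, the misincorporation matrix from control libraries, 5' tRF
#' calls and t-element tail spectra.
#'
#' @param refset A `trna_reference`.
#' @param libraries Data frame with columns `library_id`, `fastq`,
#'   `treatment` (`control`/`periodate`/`deacyl_periodate`), `replicate`.
#' @param adapter Optional adapter sequence to trim before mapping.
#' @param scheme A [scoring_scheme()].
#' @param min_reads,min_cov Reporting thresholds (see [cca_percentage()] and
#'   [misincorporation_matrix()]).
#' @param exclude_ambiguous Drop ambiguously mapped reads from gene-level
#'   tables (they remain in genome-level totals).
#' @return A `charge_run` list with per-library alignments, calls and tables
#'   plus the derived summaries.
#' @export
run_pipeline <- function(refset, libraries, adapter = NULL,
                         scheme = scoring_scheme(), min_reads = 100L,
                         min_cov = 50L, exclude_ambiguous = TRUE) {
  stopifnot(all(c("library_id", "fastq", "treatment", "replicate") %in% names(libraries)))
  libs <- vector("list", nrow(libraries))
  names(libs) <- libraries$library_id
  for (i in seq_len(nrow(libraries))) {
    reads <- read_fastq(libraries$fastq[i])
    if (!is.null(adapter)) reads <- process_reads(reads, adapter = adapter)$reads
    alns <- map_reads(reads, refset, scheme)
    calls <- classify_tails(alns, refset)
    tab <- library_table(calls, refset, library_id = libraries$library_id[i],
                         treatment = libraries$treatment[i],
                         replicate = libraries$replicate[i],
                         exclude_ambiguous = exclude_ambiguous,
                         min_reads = min_reads)
    libs[[i]] <- list(alns = alns, calls = calls, table = tab,
                      treatment = libraries$treatment[i])
  }
  tables <- do.call(rbind, lapply(libs, `[[`, "table"))
  rownames(tables) <- NULL

  pooled <- function(treatment) {
    sel <- Filter(function(l) l$treatment == treatment, libs)
    if (!length(sel)) return(NULL)
    tt <- do.call(rbind, lapply(sel, `[[`, "table"))
    agg <- stats::aggregate(cbind(n_total, n_cca, n_cc, n_missing2plus) ~ gene_id,
                            data = tt, FUN = sum)
    agg$cca_pct <- cca_percentage(agg$n_cca, agg$n_cc, agg$n_total, min_reads)
    agg$noncca_pct <- noncca_percentage(agg$n_missing2plus, agg$n_total)
    agg
  }
  pool_ctrl <- pooled("control")
  pool_per <- pooled("periodate")
  pool_dea <- pooled("deacyl_periodate")

  charging <- if (!is.null(pool_per) && !is.null(pool_ctrl))
    charging_index(pool_per, pool_ctrl) else NULL
  retention <- if (!is.null(pool_dea) && !is.null(pool_per))
    retention_ratio(pool_dea, pool_per) else NULL

  fam_iso <- if (!is.null(pool_per))
    family_table(pool_per, refset, "isodecoder", min_reads) else NULL
  fam_acc <- if (!is.null(pool_per))
    family_table(pool_per, refset, "isoacceptor", min_reads) else NULL

  genomes <- vapply(refset$genes, function(g) g$genome, "")
  genome_summary <- do.call(rbind, lapply(names(libs), function(lid) {
    tab <- libs[[lid]]$table
    do.call(rbind, lapply(unique(genomes), function(gn) {
      sub <- tab[genomes[tab$gene_id] == gn, , drop = FALSE]
      data.frame(library_id = lid, treatment = libs[[lid]]$treatment,
                 genome = gn, n_total = sum(sub$n_total),
                 cca_pct = cca_percentage(sum(sub$n_cca), sum(sub$n_cc),
                                          sum(sub$n_total), min_reads = 1L),
                 noncca_pct = noncca_percentage(sum(sub$n_missing2plus),
                                                sum(sub$n_total)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(genome_summary) <- NULL

  ctrl_alns <- do.call(rbind, lapply(Filter(function(l) l$treatment == "control", libs),
                                     `[[`, "alns"))
  filt <- function(a) if (exclude_ambiguous && !is.null(a)) a[!a$ambiguous, , drop = FALSE] else a
  ctrl_alns <- filt(ctrl_alns)
  misinc <- if (!is.null(ctrl_alns) && any(ctrl_alns$mapped))
    misincorporation_matrix(ctrl_alns, refset, min_cov = min_cov) else NULL

  histograms <- list()
  for (gn in unique(genomes)) {
    if (!is.null(ctrl_alns)) {
      histograms[[paste0("end5_control_", gn)]] <-
        end_histogram(ctrl_alns, refset, gn, "five_prime")
      histograms[[paste0("end3_control_", gn)]] <-
        end_histogram(ctrl_alns, refset, gn, "three_prime")
    }
  }

  trf <- NULL
  if (!is.null(ctrl_alns) && nrow(ctrl_alns)) {
    trf_rows <- lapply(refset$genes, function(g) {
      calls <- call_5prime_trfs(ctrl_alns, g)
      if (!nrow(calls)) return(NULL)
      cbind(gene_id = g$gene_id, calls, stringsAsFactors = FALSE)
    })
    trf <- do.call(rbind, trf_rows)
    if (!is.null(trf)) rownames(trf) <- NULL
  }

  spectra <- list()
  absent <- Filter(function(g) g$cca_status == "absent", refset$genes)
  ctrl_calls <- do.call(rbind, lapply(Filter(function(l) l$treatment == "control", libs),
                                      `[[`, "calls"))
  for (g in absent) {
    spectra[[g$gene_id]] <- if (!is.null(ctrl_calls))
      tail_spectrum(ctrl_calls, refset, g$gene_id)
    else data.frame(addition = character(0), count = integer(0))
  }

  structure(list(
    libraries = libraries, per_library = libs, tables = tables,
    pooled = list(control = pool_ctrl, periodate = pool_per,
                  deacyl_periodate = pool_dea),
    charging_index = charging, retention_ratio = retention,
    family_isodecoder = fam_iso, family_isoacceptor = fam_acc,
    genome_summary = genome_summary, misincorporation = misinc,
    histograms = histograms, trf_calls = trf, tail_spectra = spectra,
    params = list(min_reads = min_reads, min_cov = min_cov,
                  exclude_ambiguous = exclude_ambiguous, adapter = adapter,
                  scheme = unclass(scheme))
  ), class = "charge_run")
}

#' @export
print.charge_run <- function(x, ...) {
  cat("charge_run:", nrow(x$libraries), "libraries,",
      length(unique(x$tables$gene_id)), "genes\n")
  cat("  treatments:", paste(unique(x$libraries$treatment), collapse = ", "), "\n")
  invisible(x)
}

#' Write a run's tables as a report bundle
#'
#' Writes one directory of TSV tables (per-gene library tables, pooled
#' treatment tables, charging/retention ratios, family and genome summaries,
#' end histograms, the misincorporation matrix, tRF calls, t-element tail
#' spectra -- the spectrum file is present with a header even when empty), a
#' machine-readable `run_manifest.json` (inputs, parameters, seed if
#' supplied, package version) and a `run.log`. Identical inputs produce a
#' byte-identical bundle apart from the log.
#'
#' @param run A `charge_run` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest (optional).
#' @return Invisibly, the paths written.
#' @export
build_report <- function(run, out_dir, seed = NULL) {
  if (!inherits(run, "charge_run")) stop("missing upstream artifact: charge_run")
  for (part in c("tables", "genome_summary"))
    if (is.null(run[[part]])) stop("missing upstream artifact: ", part)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    .write_tsv(df, p)
    paths <<- c(paths, p)
  }
  put(run$tables, "library_tables.tsv")
  for (tr in names(run$pooled))
    if (!is.null(run$pooled[[tr]])) put(run$pooled[[tr]], paste0("pooled_", tr, ".tsv"))
  if (!is.null(run$charging_index)) put(run$charging_index, "charging_index.tsv")
  if (!is.null(run$retention_ratio)) put(run$retention_ratio, "retention_ratio.tsv")
  if (!is.null(run$family_isodecoder)) put(run$family_isodecoder, "family_isodecoder.tsv")
  if (!is.null(run$family_isoacceptor)) put(run$family_isoacceptor, "family_isoacceptor.tsv")
  put(run$genome_summary, "genome_summary.tsv")
  if (!is.null(run$misincorporation)) {
    m <- run$misincorporation
    put(data.frame(row = rownames(m), as.data.frame(unclass(m), check.names = FALSE)),
        "misincorporation_matrix.tsv")
  }
  for (nm in names(run$histograms)) {
    h <- run$histograms[[nm]]
    put(as.data.frame(h), paste0(nm, ".tsv"))
  }
  trf <- run$trf_calls
  if (is.null(trf))
    trf <- data.frame(gene_id = character(0), offset = integer(0),
                      ref_end = integer(0), fraction = numeric(0),
                      members = character(0))
  put(trf, "trf_calls.tsv")
  spec_rows <- lapply(names(run$tail_spectra), function(gid) {
    s <- run$tail_spectra[[gid]]
    if (!nrow(s)) return(NULL)
    cbind(gene_id = gid, s, stringsAsFactors = FALSE)
  })
  spec_tab <- do.call(rbind, spec_rows)
  if (is.null(spec_tab))
    spec_tab <- data.frame(gene_id = character(0), addition = character(0),
                           count = integer(0))
  put(spec_tab, "tail_spectra.tsv")

  manifest <- list(
    package = "tRNAcharge",
    version = as.character(utils::packageVersion("tRNAcharge")),
    seed = seed,
    libraries = run$libraries,
    parameters = run$params
  )
  mp <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  paths <- c(paths, mp)
  lp <- file.path(out_dir, "run.log")
  writeLines(c(sprintf("run completed at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               sprintf("wrote %d tables", length(paths))), lp)
  invisible(c(paths, lp))
}
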