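#' Pipeline configuration
#'
#' Collects every stage parameter in one validated list. Two input modes:
#' `demo` runs the built-in synthetic experiment; `files` consumes a
#' transcript-space GTF + FASTA, an RNA-seq count TSV, a sample sheet TSV
#' and one bedGraph of footprint 5'-end coverage per footprint sample
#' (named `<sample_id>.bedgraph` in `coverage_dir`).
#'
#' @param outdir output directory.
#' @param mode `"demo"` or `"files"`.
#' @param seed seed for the demo simulation.
#' @param sim a [sim_config()] for demo mode (its seed is overridden by
#'   `seed`).
#' @param paths named list for files mode: `gtf`, `fasta`, `rna_counts`,
#'   `samples`, `coverage_dir`.
#' @param min_cum,min_mean_rna,min_mean_rfp expression-filter thresholds.
#' @param fdr_diff FDR level for differential ribosome density.
#' @param prior_df dispersion-shrinkage prior weight.
#' @param peak_min_frac,peak_min_cov,peak_rel_height,peak_max_dist TIS
#'   peak-calling parameters.
#' @param fdr_switch FDR level for the TIS switching test.
#' @param control_fdr_min FDR floor defining control genes in the
#'   association test.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, mode = c("demo", "files"), seed = 1L,
                            sim = sim_config(), paths = NULL,
                            min_cum = 10, min_mean_rna = 10,
                            min_mean_rfp = 4, fdr_diff = 0.01,
                            prior_df = 10, peak_min_frac = 0.4,
                            peak_min_cov = 20, peak_rel_height = 0.1,
                            peak_max_dist = 500, fdr_switch = 0.05,
                            control_fdr_min = 0.5) {
  mode <- match.arg(mode)
  if (mode == "files") {
    need <- c("gtf", "fasta", "rna_counts", "samples", "coverage_dir")
    if (is.null(paths) || !all(need %in% names(paths)))
      stop("files mode needs paths: ", paste(need, collapse = ", "))
    missing <- !vapply(paths[need], file.exists, logical(1))
    if (any(missing))
      stop("missing input file(s): ",
           paste(unlist(paths[need][missing]), collapse = ", "))
  }
  sim$seed <- as.integer(seed)
  structure(list(outdir = outdir, mode = mode, seed = as.integer(seed),
                 sim = sim, paths = paths, min_cum = min_cum,
                 min_mean_rna = min_mean_rna, min_mean_rfp = min_mean_rfp,
                 fdr_diff = fdr_diff, prior_df = prior_df,
                 peak_min_frac = peak_min_frac, peak_min_cov = peak_min_cov,
                 peak_rel_height = peak_rel_height,
                 peak_max_dist = peak_max_dist, fdr_switch = fdr_switch,
                 control_fdr_min = control_fdr_min),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: input (simulate or load), region
#' partitioning, QC + metagene, expression filters, differential ribosome
#' density, per-condition TIS peak calling with codon assignment and
#' artifact filtering, TIS switching, ORF classification, and the
#' TIS-regulation association test. Every stage writes a TSV into
#' `cfg$outdir`; the configuration snapshot and a run log (seeds and
#' per-stage counts, no timestamps) make reruns bit-identical. A failing
#' stage leaves a `FAILED_<stage>` marker file and aborts with the stage
#' named.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(cfg$outdir, ...)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  stage <- "config"
  on_fail <- function(e) {
    file.create(p(paste0("FAILED_", stage)))
    stop("pipeline failed in stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    snap <- unclass(cfg)
    snap$outdir <- NULL
    snap$sim <- unclass(snap$sim)
    snap$sim$uorf_spec <- NULL
    yaml::write_yaml(snap, p("config.yaml"))
    note("ribodens pipeline, package version ",
         as.character(utils::packageVersion("ribodens")))
    note("seed: ", cfg$seed, "; mode: ", cfg$mode)

    stage <- "input"
    if (cfg$mode == "demo") {
      sim <- simulate_experiment(cfg$sim)
      models <- sim$models
      chx_cov <- sim$chx_cov
      ht_cov <- sim$ht_cov
      rna <- sim$rna
      samples <- sim$samples
    } else {
      models <- load_annotation(cfg$paths$gtf, cfg$paths$fasta)
      samples <- read_results(cfg$paths$samples)
      rna_smp <- samples[samples$assay == "rna", ]
      rna <- read_counts_tsv(cfg$paths$rna_counts, rna_smp, region = "all")
      read_set <- function(assay) {
        ids <- samples$sample_id[samples$assay == assay]
        out <- lapply(ids, function(sid)
          read_coverage(file.path(cfg$paths$coverage_dir,
                                  paste0(sid, ".bedgraph")), models, sid))
        names(out) <- ids
        out
      }
      chx_cov <- read_set("rfp_chx")
      ht_cov <- read_set("rfp_ht")
    }
    note("input: ", nrow(models), " genes, ", nrow(samples), " samples")

    stage <- "partition"
    chx_samples <- samples[samples$assay == "rfp_chx", ]
    rfp_cds <- region_count_matrix(chx_cov, models, chx_samples, "cds")
    region_tabs <- do.call(rbind, lapply(names(chx_cov), function(sid)
      partition_counts(chx_cov[[sid]], models)))
    write_results(region_tabs, p("region_counts.tsv"))
    note("partition: ", nrow(region_tabs), " (transcript, sample) rows")

    stage <- "qc"
    qc <- qc_summaries(c(chx_cov, ht_cov), models,
                       samples[samples$assay != "rna", ])
    write_results(qc, p("qc.tsv"))
    mg <- metagene(sum_coverage(chx_cov), models, anchor = "start_codon")
    write_results(mg, p("metagene_start.tsv"))
    note("qc: ", nrow(qc), " samples")

    stage <- "filter"
    filt <- apply_filters(rfp_cds, rna, min_cum = cfg$min_cum,
                          min_mean_rna = cfg$min_mean_rna,
                          min_mean_rfp = cfg$min_mean_rfp)
    write_results(filt$report, p("filter_report.tsv"))
    note("filter: ", length(filt$retained), "/", nrow(filt$report),
         " genes retained")

    stage <- "diffdensity"
    keep <- rownames(rfp_cds$counts) %in% filt$retained
    rfp_f <- count_matrix(rfp_cds$counts[keep, , drop = FALSE],
                          rfp_cds$samples, rfp_cds$region)
    rna_f <- count_matrix(rna$counts[keep, , drop = FALSE], rna$samples,
                          rna$region)
    diff <- fit_interaction(rfp_f, rna_f, fdr_threshold = cfg$fdr_diff,
                            prior_df = cfg$prior_df)
    write_results(diff, p("diff_density.tsv"))
    note("diffdensity: ", sum(diff$reg_class == "up"), " up, ",
         sum(diff$reg_class == "down"), " down at FDR ", cfg$fdr_diff)

    stage <- "tis_call"
    chx_pooled <- sum_coverage(chx_cov)
    call_cond <- function(cond) {
      ids <- samples$sample_id[samples$assay == "rfp_ht" &
                                 samples$condition == cond]
      pooled <- sum_coverage(ht_cov[ids], sample_id = cond)
      pk <- call_tis_peaks(pooled, models, min_frac = cfg$peak_min_frac,
                           min_cov = cfg$peak_min_cov,
                           rel_height = cfg$peak_rel_height,
                           max_dist = cfg$peak_max_dist)
      pk <- assign_codon(pk, models)
      filter_artifacts(pk, chx_pooled)
    }
    tis_untr <- call_cond("untreated")
    tis_tm <- call_cond("tm")
    write_results(tis_untr$kept, p("tis_peaks_untreated.tsv"))
    write_results(tis_tm$kept, p("tis_peaks_tm.tsv"))
    write_results(rbind(tis_untr$dropped, tis_tm$dropped),
                  p("tis_peaks_artifacts.tsv"))
    note("tis_call: ", nrow(tis_untr$kept), " peaks untreated (",
         nrow(tis_untr$dropped), " artifacts), ", nrow(tis_tm$kept),
         " peaks tm (", nrow(tis_tm$dropped), " artifacts)")

    stage <- "tis_switch"
    union_peaks <- union_tis(tis_untr$kept, tis_tm$kept)
    pcounts <- peak_sample_counts(union_peaks, ht_cov)
    switch_res <- test_tis_switching(
      pcounts, samples[samples$assay == "rfp_ht", ],
      fdr_threshold = cfg$fdr_switch)
    write_results(switch_res, p("tis_switching.tsv"))
    note("tis_switch: ", nrow(switch_res), " genes tested, ",
         sum(switch_res$significant), " significant at FDR ",
         cfg$fdr_switch)

    stage <- "uorf"
    orfs_untr <- classify_tis_orfs(tis_untr$kept, models, chx_pooled)
    orfs_tm <- classify_tis_orfs(tis_tm$kept, models, chx_pooled)
    write_results(orfs_untr, p("orf_records_untreated.tsv"))
    write_results(orfs_tm, p("orf_records_tm.tsv"))
    note("uorf: ", sum(orfs_untr$orf_class == "uorf"), " / ",
         sum(orfs_tm$orf_class == "uorf"), " plain uORFs (untr/tm)")

    stage <- "association"
    assoc <- tis_regulation_association(diff, tis_untr$kept, tis_tm$kept,
                                        control_fdr_min = cfg$control_fdr_min)
    assoc_df <- as.data.frame(assoc$table)
    names(assoc_df) <- c("reg_class", "tis_status", "n")
    assoc_df$statistic <- assoc$statistic
    assoc_df$df <- assoc$df
    assoc_df$p_value <- assoc$p_value
    assoc_df$method <- assoc$method
    write_results(assoc_df, p("tis_association.tsv"))
    note("association: ", assoc$method, " p = ",
         formatC(assoc$p_value, digits = 4, format = "g"))

    writeLines(log_lines, p("run_log.txt"))
    invisible(list(models = models, diff = diff, tis_untr = tis_untr$kept,
                   tis_tm = tis_tm$kept, switch = switch_res,
                   orfs_untr = orfs_untr, orfs_tm = orfs_tm,
                   assoc = assoc, qc = qc, filter = filt))
  }, error = on_fail)
}

# Union of per-condition peak sets: codon positions within 1 nt collapse to
# one TIS (untreated representative preferred).
union_tis <- function(peaks_untr, peaks_tm) {
  both <- rbind(
    cbind(peaks_untr, cond_origin = "untreated"),
    cbind(peaks_tm, cond_origin = "tm")
  )
  both <- both[!is.na(both$codon_pos), , drop = FALSE]
  keep <- lapply(split(both, both$transcript_id), function(b) {
    b <- b[order(b$codon_pos, factor(b$cond_origin,
                                     levels = c("untreated", "tm"))), ,
           drop = FALSE]
    sel <- integer()
    for (r in seq_len(nrow(b))) {
      if (!length(sel) ||
          all(abs(b$codon_pos[sel] - b$codon_pos[r]) > 1L))
        sel <- c(sel, r)
    }
    b[sel, , drop = FALSE]
  })
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out
}
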