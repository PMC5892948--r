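#' Gene-by-sample count matrix with sample metadata
#'
#' @param counts integer matrix, rows = genes, columns = samples.
#' @param samples data frame with one row per column of `counts`: columns
#'   `sample_id`, `condition` (`untreated`/`tm`), `assay`
#'   (`rna`/`rfp_chx`/`rfp_ht`), `replicate`, `library_size`.
#' @param region which transcript region the counts cover (RFP counts are
#'   CDS-restricted in this pipeline).
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, samples, region = "cds") {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == nrow(samples),
            identical(colnames(counts), samples$sample_id))
  if (any(counts < 0)) stop("negative counts")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (any(samples$library_size <= 0)) stop("library sizes must be positive")
  structure(list(counts = counts, samples = samples, region = region),
            class = "count_matrix")
}

sample_sheet <- function(cfg) {
  grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      condition = c("untreated", "tm"),
                      assay = c("rna", "rfp_chx", "rfp_ht"),
                      stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_%s_r%d", grid$assay, grid$condition,
                            grid$replicate)
  grid[, c("sample_id", "condition", "assay", "replicate")]
}

#' Simulate counts and footprint coverage for a synthetic transcriptome
#'
#' Draws RNA-seq and CHX-footprint CDS counts from negative binomial
#' distributions whose means follow the planted design (abundance x library
#' size for RNA; abundance x translation efficiency x planted interaction
#' effect, treated samples only, for footprints; multiplicative log-normal
#' (replicate, assay) batch effects), then places footprint 5' ends:
#' CHX reads multinomially over ORF codons at -13/-12 from the codon with
#' positional noise, Ht reads at TIS positions in proportion to site weights
#' (annotated start, planted uORFs, first-site accumulation bias, planted
#' switching shifts), plus run-off noise and sharp artifact spikes at the
#' planted arginine/lysine sites.
#'
#' @param models,truth output of [simulate_transcriptome()].
#' @param cfg the same [sim_config()].
#' @param counts_only if `TRUE`, skip coverage placement and return only the
#'   RNA and footprint CDS count matrices (fast path for count-level work).
#' @return A list with `rna` and `rfp_cds` ([count_matrix()] objects),
#'   `chx_cov` and `ht_cov` (named lists of [fiveprime_coverage()]),
#'   `samples` (all assays, realized library sizes), `read_lengths`
#'   (footprint length tallies per sample) and the updated `truth`.
#' @export
simulate_counts <- function(models, truth, cfg, counts_only = FALSE) {
  set.seed(cfg$seed + 7919L)
  genes <- truth$genes
  n <- nrow(genes)
  stopifnot(identical(genes$gene_id, models$gene_id))

  samples <- sample_sheet(cfg)
  samples$target_size <- stats::runif(nrow(samples),
                                      cfg$library_size_range[1],
                                      cfg$library_size_range[2])
  rep_eff <- matrix(stats::rlnorm(cfg$n_replicates * 3L, 0,
                                  cfg$rep_effect_sd),
                    nrow = cfg$n_replicates,
                    dimnames = list(NULL, c("rna", "rfp_chx", "rfp_ht")))

  w_rna <- genes$abundance_w / sum(genes$abundance_w)
  # Footprint output per gene; both conditions are scaled by the untreated
  # total so a planted interaction effect is a true fold change in footprint
  # production (any residual compositional shift flows into the realized
  # library sizes, exactly as it would in a sequencing run).
  t_untr <- genes$abundance_w * genes$te_baseline
  t_tm <- t_untr * 2^genes$te_log2
  w_fp <- cbind(untreated = t_untr / sum(t_untr), tm = t_tm / sum(t_untr))
  size_nb <- ifelse(genes$dispersion > 0, 1 / genes$dispersion, Inf)

  draw_counts <- function(assay, w_by_cond) {
    idx <- which(samples$assay == assay)
    y <- matrix(0L, n, length(idx),
                dimnames = list(genes$gene_id, samples$sample_id[idx]))
    for (k in seq_along(idx)) {
      s <- samples[idx[k], ]
      mu <- w_by_cond[, s$condition] * s$target_size *
        rep_eff[s$replicate, assay]
      y[, k] <- ifelse(mu == 0, 0L,
                       stats::rnbinom(n, mu = mu, size = size_nb))
    }
    y
  }

  y_rna <- draw_counts("rna", cbind(untreated = w_rna, tm = w_rna))
  y_chx <- draw_counts("rfp_chx", w_fp)
  y_ht <- draw_counts("rfp_ht", w_fp)

  if (counts_only) {
    smp_rna <- samples[samples$assay == "rna", ]
    smp_rna$library_size <- as.integer(colSums(y_rna))
    smp_chx <- samples[samples$assay == "rfp_chx", ]
    smp_chx$library_size <- as.integer(colSums(y_chx))
    return(list(
      rna = count_matrix(y_rna, smp_rna, region = "all"),
      rfp_cds = count_matrix(y_chx, smp_chx, region = "cds"),
      truth = truth
    ))
  }

  chx_cov <- place_chx(models, truth, cfg, y_chx, samples)
  ht_cov <- place_ht(models, truth, cfg, y_ht, samples)

  samples$library_size <- NA_integer_
  for (s in seq_len(nrow(samples))) {
    sid <- samples$sample_id[s]
    samples$library_size[s] <- as.integer(switch(
      samples$assay[s],
      rna = sum(y_rna[, sid]),
      rfp_chx = sum(coverage_totals(chx_cov[[sid]])),
      rfp_ht = sum(coverage_totals(ht_cov[[sid]]))
    ))
  }

  read_lengths <- do.call(rbind, lapply(
    which(samples$assay != "rna"), function(s) {
      tot <- samples$library_size[s]
      cnt <- as.vector(stats::rmultinom(1, tot, cfg$read_len_dist))
      data.frame(sample_id = samples$sample_id[s],
                 read_length = as.integer(names(cfg$read_len_dist)),
                 n_reads = cnt, stringsAsFactors = FALSE)
    }))

  smp <- function(assay) {
    out <- samples[samples$assay == assay,
                   c("sample_id", "condition", "assay", "replicate",
                     "library_size")]
    rownames(out) <- NULL
    out
  }
  list(
    rna = count_matrix(y_rna, smp("rna"), region = "all"),
    rfp_cds = count_matrix(y_chx, smp("rfp_chx"), region = "cds"),
    chx_cov = chx_cov, ht_cov = ht_cov,
    samples = samples[, c("sample_id", "condition", "assay", "replicate",
                          "library_size")],
    read_lengths = read_lengths,
    truth = truth
  )
}

# Tabulate read 5'-end positions (0-based, out-of-range dropped) on a
# transcript of length len.
tally_positions <- function(pos, len) {
  pos <- pos[pos >= 0L & pos < len]
  tabulate(pos + 1L, nbins = len)
}

sample_offsets <- function(n, cfg) {
  sample(c(13L, 12L), n, replace = TRUE, prob = cfg$offset_mix)
}

place_chx <- function(models, truth, cfg, y_chx, samples) {
  idx <- which(samples$assay == "rfp_chx")
  uorfs <- truth$uorfs
  out <- list()
  for (k in idx) {
    sid <- samples$sample_id[k]
    vecs <- vector("list", nrow(models))
    names(vecs) <- models$transcript_id
    for (g in seq_len(nrow(models))) {
      len <- models$length[g]
      cs <- models$cds_start[g]
      ncod_cds <- (models$cds_end[g] - cs) %/% 3L
      reads_cds <- y_chx[g, sid]
      u <- uorfs[uorfs$gene_id == models$gene_id[g], , drop = FALSE]
      pos <- place_orf_reads(reads_cds, cs, ncod_cds, len, cfg)
      if (nrow(u)) {
        cds_nt <- models$cds_end[g] - cs
        for (j in seq_len(nrow(u))) {
          orf_nt <- 3L * u$length_codons[j] + 3L
          mu_u <- reads_cds * u$weight[j] * orf_nt / cds_nt
          r_u <- stats::rpois(1, mu_u)
          pos <- c(pos, place_orf_reads(r_u, u$pos[j], u$length_codons[j],
                                        len, cfg))
        }
      }
      vecs[[g]] <- tally_positions(pos, len)
    }
    out[[sid]] <- fiveprime_coverage(vecs, sid, models)
  }
  out
}

place_orf_reads <- function(n_reads, orf_start, n_codons, tx_len, cfg) {
  if (n_reads == 0L) return(integer())
  n_model <- stats::rbinom(1, n_reads, cfg$frame_bias)
  pos <- integer()
  if (n_model > 0L) {
    w <- c(cfg$chx_start_bias, rep(1, n_codons - 1L))
    codon <- sample.int(n_codons, n_model, replace = TRUE, prob = w) - 1L
    pos <- orf_start + 3L * codon - sample_offsets(n_model, cfg)
  }
  if (n_reads - n_model > 0L)
    pos <- c(pos, sample.int(tx_len, n_reads - n_model, replace = TRUE) - 1L)
  pos
}

place_ht <- function(models, truth, cfg, y_ht, samples) {
  idx <- which(samples$assay == "rfp_ht")
  uorfs <- truth$uorfs
  arts <- truth$artifacts
  genes <- truth$genes
  out <- list()
  for (k in idx) {
    sid <- samples$sample_id[k]
    cond <- samples$condition[k]
    vecs <- vector("list", nrow(models))
    names(vecs) <- models$transcript_id
    for (g in seq_len(nrow(models))) {
      len <- models$length[g]
      cs <- models$cds_start[g]
      u <- uorfs[uorfs$gene_id == models$gene_id[g], , drop = FALSE]
      sw <- if (genes$tis_switch[g] && cond == "tm")
        genes$switch_ratio[g] else 1
      site_pos <- c(u$pos, cs)
      site_w <- c(u$weight * sw, 1)
      ord <- order(site_pos)
      site_pos <- site_pos[ord]
      site_w <- site_w[ord]
      site_w[1L] <- site_w[1L] * cfg$ht_first_tis_bias

      reads <- y_ht[g, sid]
      pos <- integer()
      if (reads > 0L) {
        n_noise <- stats::rbinom(1, reads, cfg$ht_noise_rate)
        n_sites <- reads - n_noise
        if (n_sites > 0L) {
          per_site <- as.vector(stats::rmultinom(1, n_sites,
                                                 site_w / sum(site_w)))
          for (j in seq_along(site_pos)) {
            if (per_site[j] > 0L)
              pos <- c(pos, site_pos[j] - sample_offsets(per_site[j], cfg))
          }
        }
        if (n_noise > 0L)
          pos <- c(pos, sample.int(len, n_noise, replace = TRUE) - 1L)
      }
      a <- arts[arts$gene_id == models$gene_id[g], , drop = FALSE]
      if (nrow(a) && reads > 0L) {
        n_art <- stats::rpois(nrow(a), cfg$rk_artifact_strength * reads)
        pos <- c(pos, rep(a$pos, n_art))
      }
      vecs[[g]] <- tally_positions(pos, len)
    }
    out[[sid]] <- fiveprime_coverage(vecs, sid, models)
  }
  out
}

#' One-call synthetic experiment
#'
#' Runs [simulate_transcriptome()] followed by [simulate_counts()].
#'
#' @param cfg a [sim_config()].
#' @param counts_only passed through to [simulate_counts()].
#' @return The [simulate_counts()] result, plus `models` and `cfg`.
#' @export
simulate_experiment <- function(cfg = sim_config(), counts_only = FALSE) {
  tr <- simulate_transcriptome(cfg)
  out <- simulate_counts(tr$models, tr$truth, cfg,
                         counts_only = counts_only)
  out$models <- tr$models
  out$cfg <- cfg
  out
}

#' Write a simulated experiment to disk in standard formats
#'
#' Emits GTF + FASTA annotation, one bedGraph per footprint sample, TSV count
#' matrices and sample sheet, ground-truth TSVs and the configuration as
#' YAML, so the files round-trip through [load_annotation()] and
#' [read_coverage()].
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_annotation(sim$models, p("annotation.gtf"), p("transcripts.fa"))
  for (sid in names(sim$chx_cov))
    write_coverage(sim$chx_cov[[sid]], p(paste0(sid, ".bedgraph")))
  for (sid in names(sim$ht_cov))
    write_coverage(sim$ht_cov[[sid]], p(paste0(sid, ".bedgraph")))
  write_counts_tsv(sim$rna, p("rna_counts.tsv"))
  write_counts_tsv(sim$rfp_cds, p("rfp_cds_counts.tsv"))
  write_results(sim$samples, p("samples.tsv"))
  write_results(sim$truth$genes, p("truth_genes.tsv"))
  write_results(sim$truth$uorfs, p("truth_uorfs.tsv"))
  write_results(sim$truth$artifacts, p("truth_artifacts.tsv"))
  write_results(sim$read_lengths, p("read_lengths.tsv"))
  cfg <- sim$cfg
  cfg$uorf_spec <- NULL
  yaml::write_yaml(unclass(cfg), p("config.yaml"))
  invisible(dir)
}

#' Write / read a count matrix as TSV
#'
#' First column `gene_id`, one column per sample.
#' @param m a [count_matrix()].
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_counts_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m$counts), m$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @param samples sample sheet matching the columns on disk.
#' @param region region tag for the result.
#' @export
read_counts_tsv <- function(path, samples, region = "cds") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene_id
  count_matrix(counts[, samples$sample_id, drop = FALSE], samples, region)
}
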