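#' Configuration for the synthetic footprint generator
#'
#' Defines the study design the generator emulates: three biological
#' replicates of two conditions (untreated vs tunicamycin) assayed by poly(A)
#' RNA-seq, cycloheximide-stabilised ribosome footprints (CHX, elongating
#' ribosomes along ORFs) and harringtonine-stabilised footprints (Ht,
#' initiating ribosomes at start codons). Footprint 5' ends sit 13 nt (minor
#' fraction 12 nt) upstream of the decoded codon, which makes frame 3 the
#' dominant read-start frame.
#'
#' @param n_genes number of genes (one reference transcript each).
#' @param seed integer seed; the same seed yields bit-identical output.
#' @param utr5_len,cds_len,utr3_len length ranges (nt) to sample from; CDS
#'   lengths are rounded to multiples of 3.
#' @param n_replicates biological replicates per condition.
#' @param library_size_range per-sample target library size range (reads).
#' @param rna_abundance `c(meanlog, sdlog)` of the log-normal relative mRNA
#'   abundance.
#' @param dispersion_mean,dispersion_shape gamma-distributed per-gene NB
#'   dispersion (mean ~0.05 mimics replicate biological variability);
#'   `dispersion_shape = Inf` gives every gene the constant dispersion
#'   `dispersion_mean`.
#' @param te_baseline_sdlog log-normal spread of baseline translation
#'   efficiency across genes.
#' @param frac_te_up,frac_te_down fractions of genes with a planted positive /
#'   negative condition-by-assay interaction (translation up-/down-regulated
#'   under stress).
#' @param te_effect_log2 range of planted |interaction| effect sizes (log2).
#' @param rep_effect_sd log-normal sd of the multiplicative (replicate, assay)
#'   batch effect.
#' @param offset_mix probabilities of the 5' end sitting at -13 vs -12 from
#'   the decoded codon.
#' @param frame_bias probability a footprint follows the offset model; the
#'   remainder is placed uniformly on the transcript (positional noise).
#' @param chx_start_bias multiplier on the start codon's read weight in CHX
#'   libraries: scanning complexes keep assembling and reach the start codon
#'   under CHX, so reads accumulate there relative to the ORF body.
#' @param read_len_dist named probabilities over footprint lengths 29-33 nt
#'   (modal 30-32).
#' @param frac_uorf fraction of genes with one randomly planted 5'UTR uORF.
#' @param uorf_start_probs start-codon probabilities for planted uORFs.
#' @param uorf_len_codons range of uORF lengths (codons, start included,
#'   stop excluded).
#' @param uorf_weight range of uORF translation weights relative to the CDS.
#' @param uorf_spec optional explicit data frame of planted ORFs with columns
#'   `gene` (1-based gene index), `start_codon`, `pos` (0-based transcript
#'   coordinate), `length_codons`, `weight` and optionally `allow_overlap`;
#'   overrides random planting for those genes.
#' @param frac_tis_switch fraction of uORF-bearing genes whose uORF TIS usage
#'   shifts under treatment.
#' @param switch_ratio multiplier applied to the uORF TIS weight in treated
#'   samples of switch genes.
#' @param ht_first_tis_bias multiplier on the 5'-most TIS of a transcript in
#'   Ht libraries (scanning complexes keep arriving at the first site during
#'   the drug treatment, so it accumulates).
#' @param ht_noise_rate fraction of Ht reads placed uniformly (residual
#'   elongating/background signal).
#' @param rk_artifact_rate expected number of spurious Ht peak sites per
#'   transcript at arginine/lysine codons.
#' @param rk_artifact_strength expected artifact reads per site and sample,
#'   as a fraction of the gene's Ht reads in that sample (artifact peaks
#'   scale with expression, as pausing-like artifacts do).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 150L,
                       seed = 1L,
                       utr5_len = c(60L, 300L),
                       cds_len = c(300L, 1500L),
                       utr3_len = c(50L, 300L),
                       n_replicates = 3L,
                       library_size_range = c(1e5, 1e6),
                       rna_abundance = c(meanlog = 3, sdlog = 1.2),
                       dispersion_mean = 0.05,
                       dispersion_shape = 2,
                       te_baseline_sdlog = 0.3,
                       frac_te_up = 0.05,
                       frac_te_down = 0.10,
                       te_effect_log2 = c(0.5, 2),
                       rep_effect_sd = 0.1,
                       offset_mix = c(p13 = 0.8, p12 = 0.2),
                       frame_bias = 0.9,
                       chx_start_bias = 5,
                       read_len_dist = c(`29` = 0.10, `30` = 0.25,
                                         `31` = 0.30, `32` = 0.25,
                                         `33` = 0.10),
                       frac_uorf = 0.3,
                       uorf_start_probs = c(ATG = 0.6, CTG = 0.2,
                                            GTG = 0.1, TTG = 0.1),
                       uorf_len_codons = c(3L, 20L),
                       uorf_weight = c(0.05, 0.5),
                       uorf_spec = NULL,
                       frac_tis_switch = 0.05,
                       switch_ratio = 3,
                       ht_first_tis_bias = 2,
                       ht_noise_rate = 0.01,
                       rk_artifact_rate = 0.15,
                       rk_artifact_strength = 0.2) {
  cfg <- list(
    n_genes = as.integer(n_genes), seed = as.integer(seed),
    utr5_len = as.integer(utr5_len), cds_len = as.integer(cds_len),
    utr3_len = as.integer(utr3_len),
    n_replicates = as.integer(n_replicates),
    library_size_range = library_size_range,
    rna_abundance = rna_abundance,
    dispersion_mean = dispersion_mean, dispersion_shape = dispersion_shape,
    te_baseline_sdlog = te_baseline_sdlog,
    frac_te_up = frac_te_up, frac_te_down = frac_te_down,
    te_effect_log2 = te_effect_log2, rep_effect_sd = rep_effect_sd,
    offset_mix = offset_mix / sum(offset_mix), frame_bias = frame_bias,
    chx_start_bias = chx_start_bias,
    read_len_dist = read_len_dist / sum(read_len_dist),
    frac_uorf = frac_uorf, uorf_start_probs = uorf_start_probs,
    uorf_len_codons = as.integer(uorf_len_codons),
    uorf_weight = uorf_weight, uorf_spec = uorf_spec,
    frac_tis_switch = frac_tis_switch, switch_ratio = switch_ratio,
    ht_first_tis_bias = ht_first_tis_bias, ht_noise_rate = ht_noise_rate,
    rk_artifact_rate = rk_artifact_rate,
    rk_artifact_strength = rk_artifact_strength
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fr <- c(cfg$frac_te_up, cfg$frac_te_down, cfg$frame_bias, cfg$frac_uorf,
          cfg$frac_tis_switch, cfg$ht_noise_rate, cfg$offset_mix)
  if (any(fr < 0 | fr > 1)) stop("fractions/probabilities must be in [0, 1]")
  if (cfg$frac_te_up + cfg$frac_te_down > 1)
    stop("frac_te_up + frac_te_down exceeds 1")
  if (any(!is.finite(cfg$te_effect_log2))) stop("effect sizes must be finite")
  if (cfg$n_genes < 1L || cfg$n_replicates < 2L)
    stop("need >= 1 gene and >= 2 replicates")
  if (cfg$utr5_len[1] < 40L)
    stop("minimum 5'UTR length must be >= 40 nt to accommodate -13 offsets")
  invisible(cfg)
}
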