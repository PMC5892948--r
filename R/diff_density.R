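#' Counts-per-million normalisation
#'
#' Divides each column by its library size and scales to one million. When a
#' column's library size equals its raw column sum, the normalised column
#' sums to exactly 1e6.
#'
#' @param m a [count_matrix()].
#' @return A `count_matrix` whose `counts` slot holds CPM values.
#' @export
cpm_normalize <- function(m) {
  stopifnot(all(m$samples$library_size > 0))
  cpm <- sweep(m$counts, 2L, m$samples$library_size, "/") * 1e6
  out <- m
  out$counts <- cpm
  attr(out, "normalized") <- TRUE
  out
}

#' Expression filters for the differential ribosome-density test
#'
#' A gene is retained iff all three rules hold on raw counts:
#' (a) at least half of all samples, RNA and footprint pooled, have at least
#' `min_cum` reads; (b) the mean over all RNA-seq samples is at least
#' `min_mean_rna`; (c) the mean over all footprint samples is at least
#' `min_mean_rfp`. The mean filters guard against poly(A)-selection
#' artifacts (transcripts without a poly(A) tail, e.g. histones, are RNA-seq
#' depleted and would otherwise look translationally regulated).
#'
#' @param rfp,rna [count_matrix()] objects over the same genes.
#' @param min_cum per-sample read threshold for the half-of-samples rule.
#' @param min_mean_rna,min_mean_rfp assay-specific mean-count thresholds.
#' @return List with `retained` (gene ids) and `report` (per-gene pass/fail
#'   of each rule).
#' @export
apply_filters <- function(rfp, rna, min_cum = 10, min_mean_rna = 10,
                          min_mean_rfp = 4) {
  if (!identical(rownames(rfp$counts), rownames(rna$counts)))
    stop("RFP and RNA count matrices must cover identical gene sets")
  pooled <- cbind(rna$counts, rfp$counts)
  n_half <- ncol(pooled) / 2
  pass_cum <- rowSums(pooled >= min_cum) >= n_half
  pass_rna <- rowMeans(rna$counts) >= min_mean_rna
  pass_rfp <- rowMeans(rfp$counts) >= min_mean_rfp
  report <- data.frame(
    gene_id = rownames(pooled),
    pass_cumulative = pass_cum, pass_mean_rna = pass_rna,
    pass_mean_rfp = pass_rfp,
    retained = pass_cum & pass_rna & pass_rfp,
    stringsAsFactors = FALSE
  )
  rownames(report) <- NULL
  list(retained = report$gene_id[report$retained], report = report)
}

#' Descriptive fold-changes from CPM
#'
#' Per gene and assay, `log2((mean CPM treated + c) / (mean CPM untreated
#' + c))` with pseudo-count `c` (CPM units). The pseudo-count only protects
#' the descriptive log-ratio; the GLM never sees it.
#'
#' @param rfp_cpm,rna_cpm CPM-normalised [count_matrix()] objects (see
#'   [cpm_normalize()]).
#' @param pseudo pseudo-count in CPM.
#' @return Data frame `gene_id`, `log2fc_rfp`, `log2fc_rna`.
#' @export
fold_changes <- function(rfp_cpm, rna_cpm, pseudo = 0.5) {
  fc <- function(m) {
    tm <- m$samples$condition == "tm"
    mt <- rowMeans(m$counts[, tm, drop = FALSE])
    mu <- rowMeans(m$counts[, !tm, drop = FALSE])
    log2((mt + pseudo) / (mu + pseudo))
  }
  data.frame(gene_id = rownames(rfp_cpm$counts),
             log2fc_rfp = fc(rfp_cpm), log2fc_rna = fc(rna_cpm),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential ribosome density: condition-by-assay interaction test
#'
#' Per gene, fits a negative-binomial log-linear model to the combined
#' RNA-seq and footprint CDS counts with a `log(library_size)` offset and
#' design `~ replicate + condition * assay`. The interaction coefficient is
#' the change in ribosome density (footprint counts relative to RNA) under
#' treatment; it is tested with a likelihood-ratio chi-squared test on 1
#' degree of freedom against the model without the interaction. Gene-wise
#' dispersions are estimated from adjusted profile likelihoods and shrunk
#' toward the common value with prior weight `prior_df` residual degrees of
#' freedom; p-values are Benjamini-Hochberg adjusted and genes are classed
#' `up`/`down`/`unchanged` at `fdr_threshold`.
#'
#' @param rfp,rna raw-count [count_matrix()] objects over identical genes
#'   (typically pre-filtered with [apply_filters()]).
#' @param fdr_threshold FDR level for the regulation classes.
#' @param prior_df prior weight (residual df) of the common dispersion.
#' @param dispersion `NULL` to estimate and shrink; or a fixed value /
#'   per-gene vector (0 gives the Poisson limit).
#' @param pseudo pseudo-count for the descriptive fold-change columns.
#' @return Data frame with `gene_id`, descriptive `log2fc_rfp`/`log2fc_rna`,
#'   `interaction_log2`, `dispersion`, `lrt_stat`, `p_value`, `fdr`,
#'   `reg_class`, `converged`.
#' @export
fit_interaction <- function(rfp, rna, fdr_threshold = 0.01, prior_df = 10,
                            dispersion = NULL, pseudo = 0.5) {
  if (!identical(rownames(rfp$counts), rownames(rna$counts)))
    stop("RFP and RNA count matrices must cover identical gene sets")
  smp <- rbind(
    data.frame(rna$samples, row.names = NULL),
    data.frame(rfp$samples, row.names = NULL)
  )
  smp$assay_class <- ifelse(smp$assay == "rna", "rna", "rfp")
  cell <- table(smp$condition, smp$assay_class)
  if (any(cell < 2)) stop("need >= 2 replicates per condition x assay cell")

  Y <- cbind(rna$counts, rfp$counts)
  X <- stats::model.matrix(
    ~ factor(replicate) + factor(condition, levels = c("untreated", "tm")) *
      factor(assay_class, levels = c("rna", "rfp")),
    data = smp)
  int_col <- ncol(X)  # the interaction term is the last column
  offset <- log(smp$library_size)
  G <- nrow(Y)

  # Poisson working fits supply the fitted means for dispersion estimation
  if (is.null(dispersion)) {
    Mu <- t(vapply(seq_len(G), function(g)
      nb_fit(Y[g, ], X, offset, phi = 0)$mu, numeric(ncol(Y))))
    disp <- estimate_dispersion(Y, Mu, X, prior_df = prior_df)
    phi <- disp$shrunk
  } else {
    phi <- rep_len(dispersion, G)
  }

  res <- data.frame(gene_id = rownames(Y), interaction_log2 = NA_real_,
                    dispersion = phi, lrt_stat = NA_real_,
                    p_value = NA_real_, converged = FALSE,
                    stringsAsFactors = FALSE)
  X0 <- X[, -int_col, drop = FALSE]
  for (g in seq_len(G)) {
    full <- nb_fit(Y[g, ], X, offset, phi = phi[g])
    null <- nb_fit(Y[g, ], X0, offset, phi = phi[g])
    if (!full$converged || !null$converged) next
    res$interaction_log2[g] <- full$beta[int_col] / log(2)
    res$lrt_stat[g] <- max(0, 2 * (full$loglik - null$loglik))
    res$p_value[g] <- stats::pchisq(res$lrt_stat[g], df = 1,
                                    lower.tail = FALSE)
    res$converged[g] <- TRUE
  }
  if (any(!res$converged))
    warning(sum(!res$converged), " gene(s) did not converge; excluded from ",
            "the FDR family")
  res$fdr <- NA_real_
  ok <- res$converged
  res$fdr[ok] <- stats::p.adjust(res$p_value[ok], method = "BH")
  res$reg_class <- "unchanged"
  res$reg_class[ok & res$fdr < fdr_threshold & res$interaction_log2 > 0] <-
    "up"
  res$reg_class[ok & res$fdr < fdr_threshold & res$interaction_log2 < 0] <-
    "down"

  fcs <- fold_changes(cpm_normalize(rfp), cpm_normalize(rna), pseudo = pseudo)
  out <- merge(fcs, res, by = "gene_id", sort = FALSE)
  out[match(rownames(Y), out$gene_id), , drop = FALSE]
}
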