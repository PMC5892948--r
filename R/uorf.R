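#' Extend a called TIS into an open reading frame
#'
#' Scans in-frame triplets from the assigned start codon until the first
#' stop codon (UAA/UAG/UGA) or the transcript end. `length_codons` counts
#' the start codon and all coding codons, excluding the stop.
#'
#' @param codon_pos 0-based position of the TIS codon.
#' @param model a one-row `transcript_models` (see [get_model()]).
#' @return List `codon_pos`, `stop_pos` (0-based start of the stop codon, or
#'   `NA`), `length_codons`, `incomplete` (no stop before the transcript
#'   end).
#' @export
extend_orf <- function(codon_pos, model) {
  seq <- model$sequence
  len <- model$length
  p <- as.integer(codon_pos)
  stopifnot(p >= 0L, p + 3L <= len)
  n <- 0L
  while (p + 3L <= len) {
    if (codon_at(seq, p) %in% STOP_CODONS) {
      return(list(codon_pos = as.integer(codon_pos), stop_pos = p,
                  length_codons = n, incomplete = FALSE))
    }
    n <- n + 1L
    p <- p + 3L
  }
  list(codon_pos = as.integer(codon_pos), stop_pos = NA_integer_,
       length_codons = n, incomplete = TRUE)
}

#' Classify an ORF relative to the annotated CDS
#'
#' Decision table over TIS region, frame and stop position:
#' \itemize{
#'   \item TIS in 5'UTR, stop before `cds_start`: `uorf`;
#'   \item TIS in 5'UTR, out of frame, stop at/after `cds_start` (or none):
#'     `overlapping_uorf`;
#'   \item TIS in 5'UTR, in frame with the CDS, no in-frame stop before
#'     `cds_start`: `n_terminal_extension`;
#'   \item TIS at the annotated start: `annotated`;
#'   \item TIS inside the CDS, in frame: `internal_in_frame_truncation`;
#'   \item TIS inside the CDS, out of frame: `internal_out_of_frame_orf`;
#'   \item TIS in the 3'UTR: `three_prime_orf`.
#' }
#'
#' @param orf output of [extend_orf()].
#' @param model the one-row `transcript_models` it belongs to.
#' @return A single classification string.
#' @export
classify_orf <- function(orf, model) {
  cs <- model$cds_start
  ce <- model$cds_end
  cp <- orf$codon_pos
  stop_eff <- if (orf$incomplete) Inf else orf$stop_pos
  in_frame <- (cp - cs) %% 3L == 0L
  if (cp == cs) return("annotated")
  if (cp < cs) {
    if (stop_eff < cs) return("uorf")
    if (in_frame) return("n_terminal_extension")
    return("overlapping_uorf")
  }
  if (cp < ce) {
    if (in_frame) return("internal_in_frame_truncation")
    return("internal_out_of_frame_orf")
  }
  "three_prime_orf"
}

#' Extend and classify every called TIS
#'
#' @param peaks assigned peaks (see [assign_codon()]) with valid
#'   `codon_pos`.
#' @param models transcript models.
#' @param chx_cov optional pooled CHX coverage for [chx_support()] ratios.
#' @return Data frame of ORF records: peak columns plus `stop_pos`,
#'   `length_codons`, `incomplete`, `orf_class` and (when CHX coverage is
#'   given) `chx_support`.
#' @export
classify_tis_orfs <- function(peaks, models, chx_cov = NULL) {
  peaks <- peaks[!is.na(peaks$codon_pos), , drop = FALSE]
  if (nrow(peaks) == 0L) {
    peaks$stop_pos <- integer()
    peaks$length_codons <- integer()
    peaks$incomplete <- logical()
    peaks$orf_class <- character()
    return(peaks)
  }
  recs <- lapply(seq_len(nrow(peaks)), function(r) {
    model <- get_model(models, peaks$transcript_id[r])
    orf <- extend_orf(peaks$codon_pos[r], model)
    out <- data.frame(stop_pos = orf$stop_pos,
                      length_codons = orf$length_codons,
                      incomplete = orf$incomplete,
                      orf_class = classify_orf(orf, model),
                      stringsAsFactors = FALSE)
    if (!is.null(chx_cov))
      out$chx_support <- chx_support(orf, chx_cov[[peaks$transcript_id[r]]])
    out
  })
  cbind(peaks, do.call(rbind, recs))
}

#' Relative CHX footprint density inside an ORF
#'
#' Ratio of the mean per-nucleotide CHX 5'-end density within the ORF
#' (start through stop codon inclusive; truncated at the transcript end for
#' incomplete ORFs) to the mean density over the whole transcript. Uniform
#' coverage gives 1; a transcript with zero coverage gives 0.
#'
#' @param orf output of [extend_orf()].
#' @param cov_vec integer coverage vector for the transcript.
#' @return A single ratio.
#' @export
chx_support <- function(orf, cov_vec) {
  len <- length(cov_vec)
  tot <- sum(cov_vec)
  if (tot == 0) return(0)
  end <- if (orf$incomplete) len else min(orf$stop_pos + 3L, len)
  inside <- cov_vec[(orf$codon_pos + 1L):end]
  (sum(inside) / length(inside)) / (tot / len)
}

#' Association between 5'UTR TIS presence and regulation class
#'
#' Builds the 3 x 2 contingency table of regulation class (`up`, `down`,
#' `control`) against presence of at least one canonical 5'UTR TIS called in
#' both conditions (peak codon positions matched within 1 nt), and computes
#' Pearson's chi-squared statistic on 2 degrees of freedom. Control genes
#' are those with `fdr > control_fdr_min` in the differential-density
#' results. If any expected cell count falls below 1 the function falls back
#' to Fisher's exact test and flags it.
#'
#' @param diff [fit_interaction()] result table.
#' @param peaks_untr,peaks_tm assigned peak tables for the two conditions.
#' @param control_fdr_min FDR floor defining unregulated control genes.
#' @return List with `table` (counts), `statistic`, `df`, `p_value`,
#'   `method` (`"pearson"` or `"fisher"`).
#' @export
tis_regulation_association <- function(diff, peaks_untr, peaks_tm,
                                       control_fdr_min = 0.5) {
  has_tis <- genes_with_utr5_tis_both(peaks_untr, peaks_tm)
  grp <- ifelse(diff$reg_class == "up", "up",
                ifelse(diff$reg_class == "down", "down",
                       ifelse(!is.na(diff$fdr) &
                                diff$fdr > control_fdr_min, "control", NA)))
  keep <- !is.na(grp)
  tab <- table(
    factor(grp[keep], levels = c("up", "down", "control")),
    factor(ifelse(diff$gene_id[keep] %in% has_tis, "tis", "no_tis"),
           levels = c("tis", "no_tis"))
  )
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    ft <- stats::fisher.test(tab)
    return(list(table = tab, statistic = NA_real_, df = NA_integer_,
                p_value = ft$p.value, method = "fisher"))
  }
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(table = tab, statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       method = "pearson")
}

#' Genes with a canonical 5'UTR TIS in both conditions
#'
#' @param peaks_untr,peaks_tm assigned peak tables for the two conditions.
#' @param match_nt maximum codon-position distance for two peaks to count as
#'   the same TIS.
#' @return Character vector of gene ids.
#' @export
genes_with_utr5_tis_both <- function(peaks_untr, peaks_tm, match_nt = 1L) {
  sel <- function(p) p[p$region == "utr5" & p$canonical, , drop = FALSE]
  a <- sel(peaks_untr)
  b <- sel(peaks_tm)
  genes <- intersect(unique(a$gene_id), unique(b$gene_id))
  genes[vapply(genes, function(g) {
    pa <- a$codon_pos[a$gene_id == g]
    pb <- b$codon_pos[b$gene_id == g]
    any(vapply(pa, function(x) any(abs(pb - x) <= match_nt), logical(1)))
  }, logical(1))]
}
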