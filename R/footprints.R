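#' Partition 5'-end counts into 5'UTR / CDS / 3'UTR
#'
#' Reads are assigned to a region by the raw position of their 5' end, with
#' no P-site offset correction: a footprint whose 5' end lies 13 nt upstream
#' of the start codon (ribosome on the start codon) is counted as 5'UTR, so
#' the first four protected codons of the CDS contribute to the 5'UTR count.
#' Position `p` maps to 5'UTR if `p < cds_start`, to CDS if
#' `cds_start <= p < cds_end` (stop codon included) and to 3'UTR otherwise.
#'
#' @param cov a single-sample [fiveprime_coverage()] list.
#' @param models a `transcript_models` data frame covering `names(cov)`.
#' @return Data frame with one row per transcript: `gene_id`, `sample_id`,
#'   `counts_utr5`, `counts_cds`, `counts_utr3`.
#' @export
partition_counts <- function(cov, models) {
  i <- match(names(cov), models$transcript_id)
  if (anyNA(i)) stop("coverage for transcript absent from models")
  out <- lapply(seq_along(cov), function(k) {
    v <- cov[[k]]
    cs <- models$cds_start[i[k]]
    ce <- models$cds_end[i[k]]
    len <- length(v)
    data.frame(
      gene_id = models$gene_id[i[k]],
      transcript_id = models$transcript_id[i[k]],
      sample_id = attr(cov, "sample_id"),
      counts_utr5 = if (cs > 0) sum(v[seq_len(cs)]) else 0L,
      counts_cds = sum(v[(cs + 1L):ce]),
      counts_utr3 = if (ce < len) sum(v[(ce + 1L):len]) else 0L,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Region-resolved count matrix from coverage
#'
#' Applies [partition_counts()] to each sample and assembles a
#' [count_matrix()] for one region.
#'
#' @param covs named list of single-sample coverage lists.
#' @param models transcript models.
#' @param samples sample sheet rows matching `names(covs)`.
#' @param region which region's counts to keep.
#' @return A [count_matrix()].
#' @export
region_count_matrix <- function(covs, models, samples,
                                region = c("cds", "utr5", "utr3")) {
  region <- match.arg(region)
  col <- paste0("counts_", region)
  mats <- vapply(names(covs), function(sid) {
    pc <- partition_counts(covs[[sid]], models)
    pc[[col]][match(models$gene_id, pc$gene_id)]
  }, numeric(nrow(models)))
  rownames(mats) <- models$gene_id
  count_matrix(mats[, samples$sample_id, drop = FALSE], samples,
               region = region)
}

#' Frame of a 5'-end position relative to the annotated start
#'
#' Frame 1 is in phase with `cds_start` (the field's 1-based convention);
#' a -12 read start is frame 1, a -13 read start is frame 3.
#'
#' @param pos 0-based 5'-end position(s).
#' @param cds_start 0-based start-codon position.
#' @return Integer frame in `1:3`.
#' @export
frame_of <- function(pos, cds_start) {
  ((pos - cds_start) %% 3L) + 1L
}

#' Metagene profile of read starts around the start or stop codon
#'
#' Aggregates 5'-end counts over transcripts in a window anchored at the
#' annotated start codon (positions -20..+50) or stop codon (-50..+20),
#' split by reading frame. Transcripts whose window extends beyond the
#' transcript are clipped and flagged in the `clipped` attribute.
#'
#' @param covs named list of single-sample coverage lists (summed over
#'   samples), or a single coverage list.
#' @param models transcript models.
#' @param anchor `"start_codon"` or `"stop_codon"`.
#' @param window integer range of positions relative to the anchor.
#' @return Data frame `position`, `frame`, `count`, plus a `clipped`
#'   attribute naming clipped transcripts.
#' @export
metagene <- function(covs, models, anchor = c("start_codon", "stop_codon"),
                     window = NULL) {
  anchor <- match.arg(anchor)
  if (is.null(window))
    window <- if (anchor == "start_codon") -20:50 else -50:20
  if (inherits(covs, "fiveprime_coverage")) covs <- list(covs)
  total <- matrix(0, nrow = length(window), ncol = 3L)
  clipped <- character()
  for (cov in covs) {
    i <- match(names(cov), models$transcript_id)
    for (k in seq_along(cov)) {
      cs <- models$cds_start[i[k]]
      ce <- models$cds_end[i[k]]
      len <- models$length[i[k]]
      anchor_pos <- if (anchor == "start_codon") cs else ce - 3L
      pos <- anchor_pos + window
      ok <- pos >= 0L & pos < len
      if (!all(ok)) clipped <- c(clipped, models$transcript_id[i[k]])
      fr <- frame_of(pos[ok], cs)
      cnt <- cov[[k]][pos[ok] + 1L]
      for (f in 1:3) {
        sel <- fr == f
        total[which(ok)[sel], f] <- total[which(ok)[sel], f] + cnt[sel]
      }
    }
  }
  out <- data.frame(
    position = rep(window, 3L),
    frame = rep(1:3, each = length(window)),
    count = c(total[, 1], total[, 2], total[, 3])
  )
  attr(out, "clipped") <- unique(clipped)
  out
}

#' Per-sample QC summaries
#'
#' One row per sample: total 5'-end counts, read-start frame fractions
#' (relative to the annotated start codon), 5'UTR/CDS count ratio, and the
#' modal footprint length when a read-length tally is supplied.
#'
#' @param covs named list of single-sample coverage lists.
#' @param models transcript models.
#' @param libraries sample sheet (`sample_id`, `library_size`, ...).
#' @param read_lengths optional data frame `sample_id`, `read_length`,
#'   `n_reads`.
#' @return Data frame of per-sample summaries; per-transcript totals are
#'   attached as the `transcript_totals` attribute.
#' @export
qc_summaries <- function(covs, models, libraries, read_lengths = NULL) {
  rows <- lapply(names(covs), function(sid) {
    cov <- covs[[sid]]
    i <- match(names(cov), models$transcript_id)
    fr_counts <- c(0, 0, 0)
    for (k in seq_along(cov)) {
      v <- cov[[k]]
      nz <- which(v > 0L)
      if (length(nz)) {
        fr <- frame_of(nz - 1L, models$cds_start[i[k]])
        fr_counts <- fr_counts + vapply(1:3, function(f)
          sum(v[nz][fr == f]), numeric(1))
      }
    }
    pc <- partition_counts(cov, models)
    tot <- sum(fr_counts)
    frac <- if (tot > 0) fr_counts / tot else c(NA_real_, NA, NA)
    mode_len <- NA_integer_
    if (!is.null(read_lengths)) {
      rl <- read_lengths[read_lengths$sample_id == sid, , drop = FALSE]
      if (nrow(rl))
        mode_len <- rl$read_length[which.max(rl$n_reads)]
    }
    data.frame(
      sample_id = sid, total_reads = tot,
      frame1_frac = frac[1], frame2_frac = frac[2], frame3_frac = frac[3],
      utr5_cds_ratio = sum(pc$counts_utr5) / max(1, sum(pc$counts_cds)),
      modal_read_length = mode_len,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "transcript_totals") <- vapply(covs, coverage_totals,
                                           numeric(nrow(models)))
  out
}
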