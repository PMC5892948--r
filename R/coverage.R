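#' Footprint 5'-end coverage
#'
#' Per-sample coverage is stored as a named list of non-negative integer
#' vectors, one per transcript, indexed by 0-based transcript position: entry
#' `i + 1` of the vector is the number of footprints whose 5' end maps to
#' position `i`. The list carries a `sample_id` attribute. A multi-sample
#' coverage set is a named list of such per-sample lists.
#'
#' @param counts named list of integer vectors (names are transcript ids).
#' @param sample_id sample identifier.
#' @param models optional `transcript_models`; when given, vector lengths are
#'   checked against transcript lengths.
#' @return A `fiveprime_coverage` list.
#' @export
fiveprime_coverage <- function(counts, sample_id, models = NULL) {
  counts <- lapply(counts, function(v) {
    v <- as.integer(round(v))
    if (any(v < 0L)) stop("negative coverage value")
    v
  })
  if (!is.null(models)) {
    for (tx in names(counts)) {
      len <- models$length[match(tx, models$transcript_id)]
      if (is.na(len)) stop("coverage for unknown transcript: ", tx)
      if (length(counts[[tx]]) != len)
        stop("coverage length mismatch for ", tx)
    }
  }
  structure(counts, sample_id = sample_id, class = "fiveprime_coverage")
}

#' Read per-sample 5'-end coverage from bedGraph
#'
#' The bedGraph `chrom` field holds transcript ids; intervals are 0-based
#' half-open and carry integer 5'-end counts. Positions absent from the file
#' are zero; every transcript in `models` gets a dense vector.
#'
#' @param bedgraph path to a bedGraph file.
#' @param models `transcript_models` defining the transcript universe and
#'   lengths.
#' @param sample_id identifier recorded on the result (defaults to the file
#'   name without extension).
#' @return A [fiveprime_coverage()] list covering every model transcript.
#' @export
read_coverage <- function(bedgraph, models,
                          sample_id = sub("\\.[^.]*$", "", basename(bedgraph))) {
  vecs <- lapply(models$length, function(len) integer(len))
  names(vecs) <- models$transcript_id

  info <- file.info(bedgraph)
  if (is.na(info$size)) stop("no such file: ", bedgraph)
  gr <- if (info$size == 0L) GenomicRanges::GRanges() else
    rtracklayer::import(bedgraph, format = "bedGraph")

  if (length(gr)) {
    tx <- as.character(GenomicRanges::seqnames(gr))
    unknown <- setdiff(unique(tx), models$transcript_id)
    if (length(unknown))
      stop("bedGraph refers to unknown transcript(s): ",
           paste(unknown, collapse = ", "))
    val <- gr$score
    if (any(val < 0)) stop("negative value in bedGraph: ", bedgraph)
    if (any(abs(val - round(val)) > 1e-9))
      stop("non-integer count in bedGraph: ", bedgraph)
    # rtracklayer converts to 1-based closed; back to 0-based half-open
    s0 <- GenomicRanges::start(gr) - 1L
    e0 <- GenomicRanges::end(gr)
    len <- models$length[match(tx, models$transcript_id)]
    if (any(e0 > len) || any(s0 < 0L))
      stop("bedGraph interval outside transcript bounds in ", bedgraph)
    for (i in seq_along(gr)) {
      v <- vecs[[tx[i]]]
      v[(s0[i] + 1L):e0[i]] <- v[(s0[i] + 1L):e0[i]] + as.integer(val[i])
      vecs[[tx[i]]] <- v
    }
  }
  fiveprime_coverage(vecs, sample_id, models)
}

#' Write 5'-end coverage to bedGraph
#'
#' Adjacent positions with equal non-zero counts are merged into one interval
#' (run-length encoding); zero positions are omitted.
#'
#' @param cov a [fiveprime_coverage()] list.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_coverage <- function(cov, path) {
  rows <- lapply(names(cov), function(tx) {
    r <- rle(cov[[tx]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # 0-based
    keep <- r$values > 0L
    if (!any(keep)) return(NULL)
    data.frame(chrom = tx, start = starts[keep], end = ends[keep],
               value = r$values[keep], stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    file.create(path)
  } else {
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Total 5'-end count per transcript
#' @param cov a [fiveprime_coverage()] list.
#' @return Named numeric vector of per-transcript totals.
#' @export
coverage_totals <- function(cov) {
  vapply(cov, sum, numeric(1))
}

#' Sum coverage across samples
#'
#' Used to pool the triplicate libraries of one condition before TIS peak
#' calling.
#'
#' @param covs list of [fiveprime_coverage()] lists over the same transcripts.
#' @param sample_id identifier for the pooled result.
#' @return A [fiveprime_coverage()] list.
#' @export
sum_coverage <- function(covs, sample_id = "pooled") {
  stopifnot(length(covs) >= 1L)
  out <- covs[[1L]]
  for (cv in covs[-1L]) {
    stopifnot(identical(names(cv), names(out)))
    out <- Map(`+`, out, cv)
  }
  fiveprime_coverage(out, sample_id)
}
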