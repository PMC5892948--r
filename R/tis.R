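#' Call translation initiation site peaks from Ht coverage
#'
#' Harringtonine stalls initiating ribosomes, so footprint 5' ends pile up
#' 12-13 nt upstream of start codons. Peak calling runs on coverage pooled
#' over the replicates of one condition and applies five rules to every
#' position `p` with its 6-codon window `W(p) = [p, p + 18)` (candidate codon
#' plus five downstream codons, truncated at the transcript end):
#'
#' 1. `count(p) > min_frac` of the total coverage in `W(p)`;
#' 2. total coverage in `W(p)` at least `min_cov`;
#' 3. no single position in `[p + 3, p + 18)` exceeds `count(p)`;
#' 4. `count(p)` at least `rel_height` of the highest candidate passing
#'    rules 1-3 on the transcript;
#' 5. `p` within `max_dist` nt of the annotated CDS interval.
#'
#' Surviving candidates within 1 nt of a stronger one are merged into it
#' (the -13/-12 offset duality splits one initiation event over two
#' adjacent positions).
#'
#' @param ht_cov a single [fiveprime_coverage()] list, typically
#'   [sum_coverage()] over one condition's replicates.
#' @param models transcript models.
#' @param min_frac,min_cov,rel_height,max_dist rule parameters.
#' @return Data frame `transcript_id`, `gene_id`, `peak_pos` (0-based 5'-end
#'   position), `count` (pooled count at the peak).
#' @export
call_tis_peaks <- function(ht_cov, models, min_frac = 0.4, min_cov = 20,
                           rel_height = 0.1, max_dist = 500) {
  i <- match(names(ht_cov), models$transcript_id)
  if (anyNA(i)) stop("coverage for transcript absent from models")
  rows <- lapply(seq_along(ht_cov), function(k) {
    v <- ht_cov[[k]]
    len <- length(v)
    cs <- models$cds_start[i[k]]
    ce <- models$cds_end[i[k]]
    cand <- which(v > 0L) - 1L
    if (!length(cand)) return(NULL)
    pass123 <- vapply(cand, function(p) {
      w_end <- min(p + 18L, len)
      tot <- sum(v[(p + 1L):w_end])
      if (v[p + 1L] <= min_frac * tot) return(FALSE)
      if (tot < min_cov) return(FALSE)
      if (p + 3L < w_end &&
          max(v[(p + 4L):w_end]) > v[p + 1L]) return(FALSE)
      TRUE
    }, logical(1))
    cand <- cand[pass123]
    if (!length(cand)) return(NULL)
    top <- max(v[cand + 1L])
    cand <- cand[v[cand + 1L] >= rel_height * top]
    dist <- ifelse(cand < cs, cs - cand,
                   ifelse(cand >= ce, cand - (ce - 1L), 0L))
    cand <- cand[dist <= max_dist]
    if (!length(cand)) return(NULL)
    cand <- merge_adjacent_peaks(cand, v[cand + 1L])
    data.frame(transcript_id = models$transcript_id[i[k]],
               gene_id = models$gene_id[i[k]],
               peak_pos = cand, count = v[cand + 1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(transcript_id = character(), gene_id = character(),
                      peak_pos = integer(), count = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Greedy merge of surviving candidates within 1 nt: the higher count wins,
# ties go to the upstream position.
merge_adjacent_peaks <- function(pos, count) {
  ord <- order(-count, pos)
  kept <- integer()
  for (p in pos[ord]) {
    if (!any(abs(kept - p) <= 1L)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Assign a start codon to called TIS peaks
#'
#' The stalled ribosome's P-site codon sits ~13 nt downstream of the
#' footprint 5' end. Codons at +13, +12 and +14 are probed in that priority;
#' the first AUG/CUG/GUG/UUG found becomes a canonical TIS at that offset.
#' If none is found the codon at +13 is assigned with `canonical = FALSE`,
#' and the peak is flagged `artifact_rk` when that codon encodes arginine
#' (CGN, AGA, AGG) or lysine (AAA, AAG) -- the codon classes of known
#' harringtonine artifact peaks. The region is derived from the codon
#' position: `utr5`, `annotated_start` (codon exactly at `cds_start`), `cds`
#' or `utr3`.
#'
#' @param peaks output of [call_tis_peaks()].
#' @param models transcript models.
#' @return `peaks` with columns `codon_pos`, `offset`, `codon`, `canonical`,
#'   `region`, `artifact_rk` added.
#' @export
assign_codon <- function(peaks, models) {
  n <- nrow(peaks)
  peaks$codon_pos <- NA_integer_
  peaks$offset <- NA_integer_
  peaks$codon <- NA_character_
  peaks$canonical <- FALSE
  peaks$region <- NA_character_
  peaks$artifact_rk <- FALSE
  if (n == 0L) return(peaks)
  mi <- match(peaks$transcript_id, models$transcript_id)
  for (r in seq_len(n)) {
    seq <- models$sequence[mi[r]]
    len <- models$length[mi[r]]
    p <- peaks$peak_pos[r]
    off <- NA_integer_
    for (o in c(13L, 12L, 14L)) {
      if (p + o + 3L <= len && codon_at(seq, p + o) %in% NUG_CODONS) {
        off <- o
        break
      }
    }
    if (is.na(off)) {
      off <- 13L
      peaks$canonical[r] <- FALSE
    } else {
      peaks$canonical[r] <- TRUE
    }
    cp <- p + off
    peaks$offset[r] <- off
    peaks$codon_pos[r] <- cp
    peaks$codon[r] <- if (cp + 3L <= len) codon_at(seq, cp) else
      NA_character_
    if (!peaks$canonical[r] && !is.na(peaks$codon[r]))
      peaks$artifact_rk[r] <- peaks$codon[r] %in% RK_CODONS
    cs <- models$cds_start[mi[r]]
    ce <- models$cds_end[mi[r]]
    peaks$region[r] <- if (cp < cs) "utr5" else if (cp == cs)
      "annotated_start" else if (cp < ce) "cds" else "utr3"
  }
  peaks
}

#' Per-sample counts at called peaks
#'
#' Extracts per-replicate 5'-end counts for each called TIS, summing the two
#' offset positions (13 and 12 nt upstream of the assigned codon) so both
#' halves of a split peak are counted.
#'
#' @param peaks assigned peaks (see [assign_codon()]).
#' @param covs named list of per-sample [fiveprime_coverage()] lists.
#' @return Long data frame `gene_id`, `transcript_id`, `tis_id` (codon
#'   position), `region`, `sample_id`, `count`.
#' @export
peak_sample_counts <- function(peaks, covs) {
  if (nrow(peaks) == 0L)
    return(data.frame(gene_id = character(), transcript_id = character(),
                      tis_id = integer(), region = character(),
                      sample_id = character(), count = integer(),
                      stringsAsFactors = FALSE))
  rows <- lapply(names(covs), function(sid) {
    cov <- covs[[sid]]
    cnt <- vapply(seq_len(nrow(peaks)), function(r) {
      v <- cov[[peaks$transcript_id[r]]]
      pos <- peaks$codon_pos[r] - c(13L, 12L)
      pos <- pos[pos >= 0L & pos < length(v)]
      sum(v[pos + 1L])
    }, numeric(1))
    data.frame(gene_id = peaks$gene_id, transcript_id = peaks$transcript_id,
               tis_id = peaks$codon_pos, region = peaks$region,
               sample_id = sid, count = as.integer(cnt),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Start-codon composition of called TIS
#'
#' Tallies peaks by start-codon class (AUG, CUG, GUG, UUG, other), overall
#' or per region; fractions within each group sum to 1.
#'
#' @param peaks assigned peaks.
#' @param by_region split by region?
#' @return Data frame `region` (if requested), `codon_class`, `n`, `fraction`.
#' @export
codon_composition <- function(peaks, by_region = TRUE) {
  cls <- ifelse(peaks$canonical, chartr("T", "U", peaks$codon), "other")
  if (by_region) {
    tab <- as.data.frame(table(region = peaks$region, codon_class = cls),
                         stringsAsFactors = FALSE)
    names(tab)[3] <- "n"
    tab <- tab[tab$n > 0 | TRUE, , drop = FALSE]
    tot <- stats::ave(tab$n, tab$region, FUN = sum)
    tab$fraction <- ifelse(tot > 0, tab$n / tot, 0)
  } else {
    tab <- as.data.frame(table(codon_class = cls), stringsAsFactors = FALSE)
    names(tab)[2] <- "n"
    tab$fraction <- tab$n / sum(tab$n)
  }
  tab
}

#' Drop unsupported arginine/lysine artifact peaks
#'
#' Non-canonical peaks on R/K codons without CHX support at the peak
#' position are harringtonine artifacts and are removed; canonical peaks are
#' always kept. Because CHX libraries carry elongation background along the
#' whole CDS, "support" means a local accumulation, not any read: the pooled
#' CHX count within 1 nt of the peak must be at least `min_chx` reads and at
#' least `chx_enrich`-fold the transcript's per-window background density.
#' A peak with zero CHX coverage at the position is always removed.
#'
#' @param peaks assigned peaks.
#' @param chx_covs a pooled CHX [fiveprime_coverage()] list, or a list of
#'   per-sample lists (summed internally).
#' @param min_chx minimum pooled CHX count at the peak required to keep an
#'   R/K peak.
#' @param chx_enrich minimum fold-enrichment of the CHX count over the
#'   transcript's average density in a 3-nt window.
#' @return List with `kept` and `dropped` peak data frames.
#' @export
filter_artifacts <- function(peaks, chx_covs, min_chx = 1, chx_enrich = 5) {
  if (!inherits(chx_covs, "fiveprime_coverage"))
    chx_covs <- sum_coverage(chx_covs)
  if (nrow(peaks) == 0L) return(list(kept = peaks, dropped = peaks))
  supported <- vapply(seq_len(nrow(peaks)), function(r) {
    v <- chx_covs[[peaks$transcript_id[r]]]
    pos <- peaks$peak_pos[r] + (-1L:1L)
    pos <- pos[pos >= 0L & pos < length(v)]
    cnt <- sum(v[pos + 1L])
    background <- 3 * sum(v) / length(v)
    cnt >= min_chx && cnt >= chx_enrich * background
  }, logical(1))
  drop <- peaks$artifact_rk & !peaks$canonical & !supported
  list(kept = peaks[!drop, , drop = FALSE],
       dropped = peaks[drop, , drop = FALSE])
}

#' Test condition-dependent TIS switching
#'
#' For genes with at least `min_tis` called TIS, fits a Poisson log-linear
#' model to the per-replicate peak counts with a `log(library_size)` offset,
#' replicate as a blocking factor, and fixed effects for TIS location,
#' treatment and their interaction. The interaction (does the ratio between
#' TIS change under treatment?) is tested with a chi-squared likelihood-ratio
#' test on `n_tis - 1` degrees of freedom and Benjamini-Hochberg adjusted.
#'
#' @param peak_counts long data frame from [peak_sample_counts()] restricted
#'   to the peaks of interest.
#' @param libraries sample sheet with `sample_id`, `condition`, `replicate`,
#'   `library_size`.
#' @param min_tis minimum number of TIS per gene.
#' @param fdr_threshold FDR level for the `significant` flag.
#' @return Data frame `gene_id`, `n_tis`, `lrt_stat`, `df`, `p_value`,
#'   `fdr`, `significant`.
#' @export
test_tis_switching <- function(peak_counts, libraries, min_tis = 2L,
                               fdr_threshold = 0.05) {
  d <- merge(peak_counts, libraries[, c("sample_id", "condition",
                                        "replicate", "library_size")],
             by = "sample_id")
  rows <- lapply(split(d, d$gene_id), function(g) {
    zero <- vapply(split(g$count, g$tis_id), function(x) all(x == 0),
                   logical(1))
    if (any(zero)) {
      warning("dropping all-zero TIS in gene ", g$gene_id[1])
      g <- g[!zero[as.character(g$tis_id)], , drop = FALSE]
    }
    n_tis <- length(unique(g$tis_id))
    if (n_tis < min_tis) return(NULL)
    g$tis <- factor(g$tis_id)
    g$cond <- factor(g$condition, levels = c("untreated", "tm"))
    g$rep <- factor(g$replicate)
    full <- suppressWarnings(stats::glm(
      count ~ rep + tis * cond, family = stats::poisson(),
      offset = log(library_size), data = g))
    null <- suppressWarnings(stats::glm(
      count ~ rep + tis + cond, family = stats::poisson(),
      offset = log(library_size), data = g))
    lrt <- max(0, as.numeric(2 * (stats::logLik(full) -
                                    stats::logLik(null))))
    df <- n_tis - 1L
    data.frame(gene_id = g$gene_id[1], n_tis = n_tis, lrt_stat = lrt,
               df = df,
               p_value = stats::pchisq(lrt, df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene_id = character(), n_tis = integer(),
                      lrt_stat = numeric(), df = integer(),
                      p_value = numeric(), fdr = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$fdr < fdr_threshold
  out
}
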