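STOP_CODONS <- c("TAA", "TAG", "TGA")
NUG_CODONS <- c("ATG", "CTG", "GTG", "TTG")
# codons decoding arginine or lysine (spurious Ht peak sites)
RK_CODONS <- c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG", "AAA", "AAG")
ALL_CODONS <- as.vector(outer(outer(c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T"), paste0),
                              c("A", "C", "G", "T"), paste0))
NONSTOP_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)
# used for planted ORF bodies: no stop, no internal AUG in the planted frame
ORF_BODY_CODONS <- setdiff(NONSTOP_CODONS, "ATG")

codon_at <- function(seq, pos) substr(seq, pos + 1L, pos + 3L)

#' Generate a synthetic transcriptome with planted ORFs and effects
#'
#' Draws one reference transcript per gene (random 5'UTR/CDS/3'UTR lengths,
#' AUG start, clean in-frame stop), plants upstream ORFs with near-cognate or
#' AUG starts, assigns per-gene abundance, NB dispersion and baseline
#' translation efficiency, and plants condition-by-assay interaction effects
#' (translation up/down under treatment), TIS-switching genes and
#' arginine/lysine Ht artifact sites. All randomness comes from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `models` (a `transcript_models` data frame)
#'   and `truth` (lists `genes`, `uorfs`, `artifacts` recording everything
#'   that was planted).
#' @export
simulate_transcriptome <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_genes
  gene_id <- sprintf("g%04d", seq_len(n))
  transcript_id <- sprintf("tx%04d", seq_len(n))

  utr5 <- sample(cfg$utr5_len[1]:cfg$utr5_len[2], n, replace = TRUE)
  cds <- sample(cfg$cds_len[1]:cfg$cds_len[2], n, replace = TRUE)
  cds <- pmax(6L, (cds %/% 3L) * 3L)
  utr3 <- sample(cfg$utr3_len[1]:cfg$utr3_len[2], n, replace = TRUE)
  len <- utr5 + cds + utr3

  uorf_rows <- list()
  art_rows <- list()
  seqs <- character(n)

  for (i in seq_len(n)) {
    chars <- sample(c("A", "C", "G", "T"), len[i], replace = TRUE)
    cs <- utr5[i]
    ce <- cs + cds[i]
    ncod <- cds[i] %/% 3L
    body <- sample(NONSTOP_CODONS, ncod - 2L, replace = TRUE)
    cds_seq <- paste0("ATG", paste(body, collapse = ""),
                      sample(STOP_CODONS, 1L))
    chars[(cs + 1L):ce] <- strsplit(cds_seq, "")[[1L]]

    plan <- plan_uorfs(i, cs, len[i], cfg)
    for (u in plan) {
      chars <- write_orf(chars, u$pos, u$start_codon, u$length_codons)
      uorf_rows[[length(uorf_rows) + 1L]] <- data.frame(
        gene_id = gene_id[i], transcript_id = transcript_id[i],
        pos = u$pos, start_codon = u$start_codon,
        length_codons = u$length_codons,
        stop_pos = u$pos + 3L * u$length_codons,
        weight = u$weight,
        in_utr5 = u$pos < cs,
        stringsAsFactors = FALSE
      )
    }
    seqs[i] <- paste(chars, collapse = "")
    verify_planted(seqs[i], plan, cs, transcript_id[i])

    arts <- plant_artifact_sites(seqs[i], cs, ce, plan, cfg)
    if (length(arts)) {
      art_rows[[length(art_rows) + 1L]] <- data.frame(
        gene_id = gene_id[i], transcript_id = transcript_id[i],
        pos = arts, stringsAsFactors = FALSE
      )
    }
  }

  models <- as_transcript_models(data.frame(
    gene_id = gene_id, transcript_id = transcript_id, sequence = seqs,
    cds_start = utr5, cds_end = utr5 + cds, stringsAsFactors = FALSE
  ))

  genes <- data.frame(
    gene_id = gene_id, transcript_id = transcript_id,
    abundance_w = stats::rlnorm(n, cfg$rna_abundance[["meanlog"]],
                                cfg$rna_abundance[["sdlog"]]),
    dispersion = if (is.infinite(cfg$dispersion_shape))
      rep(cfg$dispersion_mean, n) else
        stats::rgamma(n, shape = cfg$dispersion_shape,
                      scale = cfg$dispersion_mean / cfg$dispersion_shape),
    te_baseline = stats::rlnorm(n, 0, cfg$te_baseline_sdlog),
    te_log2 = 0, reg_class = "null", tis_switch = FALSE, switch_ratio = 1,
    stringsAsFactors = FALSE
  )

  n_up <- round(cfg$frac_te_up * n)
  n_down <- round(cfg$frac_te_down * n)
  pick <- sample.int(n, n_up + n_down)
  if (n_up > 0) {
    up <- pick[seq_len(n_up)]
    genes$te_log2[up] <- stats::runif(n_up, cfg$te_effect_log2[1],
                                      cfg$te_effect_log2[2])
    genes$reg_class[up] <- "up"
  }
  if (n_down > 0) {
    dn <- pick[n_up + seq_len(n_down)]
    genes$te_log2[dn] <- -stats::runif(n_down, cfg$te_effect_log2[1],
                                       cfg$te_effect_log2[2])
    genes$reg_class[dn] <- "down"
  }

  uorfs <- if (length(uorf_rows)) do.call(rbind, uorf_rows) else
    data.frame(gene_id = character(), transcript_id = character(),
               pos = integer(), start_codon = character(),
               length_codons = integer(), stop_pos = integer(),
               weight = numeric(), in_utr5 = logical(),
               stringsAsFactors = FALSE)
  ug <- unique(uorfs$gene_id[uorfs$in_utr5])
  if (length(ug) && cfg$frac_tis_switch > 0) {
    nsw <- round(cfg$frac_tis_switch * length(ug))
    if (nsw > 0) {
      sw <- sample(ug, nsw)
      genes$tis_switch[genes$gene_id %in% sw] <- TRUE
      genes$switch_ratio[genes$gene_id %in% sw] <- cfg$switch_ratio
    }
  }

  artifacts <- if (length(art_rows)) do.call(rbind, art_rows) else
    data.frame(gene_id = character(), transcript_id = character(),
               pos = integer(), stringsAsFactors = FALSE)

  list(models = models,
       truth = list(genes = genes, uorfs = uorfs, artifacts = artifacts))
}

# Decide which ORFs to plant for gene i (explicit spec wins over random).
plan_uorfs <- function(i, cds_start, tx_len, cfg) {
  if (!is.null(cfg$uorf_spec)) {
    rows <- cfg$uorf_spec[cfg$uorf_spec$gene == i, , drop = FALSE]
    if (nrow(rows)) {
      return(lapply(seq_len(nrow(rows)), function(k) {
        r <- rows[k, ]
        end <- r$pos + 3L * r$length_codons + 3L
        if (end > tx_len)
          stop("planted ORF does not fit transcript (gene ", i, ")")
        overlap_ok <- isTRUE(r$allow_overlap)
        if (r$pos < cds_start && end > cds_start && !overlap_ok)
          stop("planted 5'UTR ORF overlaps the CDS without allow_overlap ",
               "(gene ", i, ")")
        list(pos = as.integer(r$pos), start_codon = r$start_codon,
             length_codons = as.integer(r$length_codons),
             weight = if (is.null(r$weight)) 0.2 else r$weight)
      }))
    }
    return(list())
  }
  if (stats::runif(1) >= cfg$frac_uorf) return(list())
  lmax <- (cds_start - 3L - 15L) %/% 3L
  if (lmax < cfg$uorf_len_codons[1]) return(list())
  L <- sample(cfg$uorf_len_codons[1]:min(cfg$uorf_len_codons[2], lmax), 1L)
  pos_max <- cds_start - 3L * L - 3L
  pos <- sample(15L:pos_max, 1L)
  list(list(pos = pos,
            start_codon = sample(names(cfg$uorf_start_probs), 1L,
                                 prob = cfg$uorf_start_probs),
            length_codons = L,
            weight = stats::runif(1, cfg$uorf_weight[1], cfg$uorf_weight[2])))
}

# Write start codon, stop-free AUG-free body, and a stop codon into chars.
write_orf <- function(chars, pos, start_codon, length_codons) {
  chars[(pos + 1L):(pos + 3L)] <- strsplit(start_codon, "")[[1L]]
  if (length_codons > 1L) {
    body <- sample(ORF_BODY_CODONS, length_codons - 1L, replace = TRUE)
    b0 <- pos + 3L
    chars[(b0 + 1L):(b0 + 3L * (length_codons - 1L))] <-
      strsplit(paste(body, collapse = ""), "")[[1L]]
  }
  sp <- pos + 3L * length_codons
  chars[(sp + 1L):(sp + 3L)] <- strsplit(sample(STOP_CODONS, 1L), "")[[1L]]
  chars
}

verify_planted <- function(seq, plan, cds_start, tx) {
  if (codon_at(seq, cds_start) != "ATG")
    stop("annotated start codon clobbered by a planted ORF on ", tx,
         "; adjust the uorf_spec geometry")
  for (u in plan) {
    if (codon_at(seq, u$pos) != u$start_codon)
      stop("planted start codon clobbered on ", tx)
    internal <- u$pos + 3L * seq_len(u$length_codons - 1L)
    if (u$length_codons > 1L &&
        any(vapply(internal, function(p) codon_at(seq, p),
                   character(1)) %in% STOP_CODONS))
      stop("planted ORF gained an internal stop on ", tx)
    if (!codon_at(seq, u$pos + 3L * u$length_codons) %in% STOP_CODONS)
      stop("planted ORF stop codon clobbered on ", tx)
  }
  invisible(TRUE)
}

# Pick spurious Ht peak sites: R/K codon at +13 and no NUG at +12/+13/+14,
# kept clear of planted TIS peak positions so peaks do not shadow each other.
plant_artifact_sites <- function(seq, cds_start, cds_end, plan, cfg) {
  n_art <- stats::rpois(1, cfg$rk_artifact_rate)
  if (n_art == 0L) return(integer())
  tis_peaks <- c(cds_start - 13L,
                 vapply(plan, function(u) u$pos - 13L, integer(1)))
  cand <- seq(cds_start + 30L, cds_end - 30L, by = 1L)
  if (!length(cand)) return(integer())
  ok <- vapply(cand, function(q) {
    codon_at(seq, q + 13L) %in% RK_CODONS &&
      !any(vapply(12:14, function(o) codon_at(seq, q + o),
                  character(1)) %in% NUG_CODONS) &&
      all(abs(q - tis_peaks) > 21L)
  }, logical(1))
  cand <- cand[ok]
  sites <- integer()
  while (length(cand) && length(sites) < n_art) {
    q <- cand[sample.int(length(cand), 1L)]
    sites <- c(sites, q)
    cand <- cand[abs(cand - q) > 21L]
  }
  sort(sites)
}
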