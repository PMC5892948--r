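# Shared fixture builders and independent oracles. Everything is generated
# in code; no data files.

# A transcript with a controlled layout: random UTRs, ATG + stop-free body +
# stop codon CDS. `cds_codons` includes start and stop codons.
mk_model <- function(utr5 = 60L, cds_codons = 40L, utr3 = 30L,
                     gene_id = "g1", transcript_id = "tx1") {
  stops <- c("TAA", "TAG", "TGA")
  body <- sample(setdiff(ribodens_codons(), stops), cds_codons - 2L,
                 replace = TRUE)
  seq <- paste0(
    paste(sample(c("A", "C", "G", "T"), utr5, replace = TRUE),
          collapse = ""),
    "ATG", paste(body, collapse = ""), sample(stops, 1L),
    paste(sample(c("A", "C", "G", "T"), utr3, replace = TRUE),
          collapse = "")
  )
  transcript_model(gene_id, transcript_id, seq, utr5, utr5 + 3L * cds_codons)
}

ribodens_codons <- function() {
  as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                        paste0), c("A", "C", "G", "T"), paste0))
}

# Coverage with spikes at given 0-based positions.
mk_cov <- function(model, pos, counts, sample_id = "s1") {
  v <- integer(model$length)
  for (k in seq_along(pos)) v[pos[k] + 1L] <- v[pos[k] + 1L] + counts[k]
  out <- list(v)
  names(out) <- model$transcript_id
  fiveprime_coverage(out, sample_id, model)
}

# Independent brute-force TIS peak caller: evaluates the five printed rules
# at every position of the vector, then resolves the -13/-12 duality by
# repeated sweeps (different algorithm from the implementation's greedy
# merge, same contract).
brute_tis <- function(v, cds_start, cds_end, min_frac = 0.4, min_cov = 20,
                      rel_height = 0.1, max_dist = 500) {
  len <- length(v)
  pass123 <- logical(len)
  for (p0 in seq_len(len)) {
    p <- p0 - 1L
    if (v[p0] == 0L) next
    w <- v[p0:min(p0 + 17L, len)]
    tot <- sum(w)
    r1 <- v[p0] > min_frac * tot
    r2 <- tot >= min_cov
    down <- if (length(w) > 3L) max(w[-(1:3)]) else 0L
    r3 <- down <= v[p0]
    pass123[p0] <- r1 && r2 && r3
  }
  cand <- which(pass123) - 1L
  if (!length(cand)) return(integer())
  m <- max(v[cand + 1L])
  cand <- cand[v[cand + 1L] >= rel_height * m]
  d <- vapply(cand, function(p) {
    if (p < cds_start) cds_start - p
    else if (p >= cds_end) p - (cds_end - 1L)
    else 0L
  }, integer(1))
  cand <- cand[d <= max_dist]
  # resolve adjacency: repeatedly drop the weaker of any pair within 1 nt
  repeat {
    if (length(cand) < 2L) break
    drop <- NULL
    for (i in seq_len(length(cand) - 1L)) {
      if (cand[i + 1L] - cand[i] <= 1L) {
        a <- v[cand[i] + 1L]; b <- v[cand[i + 1L] + 1L]
        drop <- if (b > a) i else i + 1L
        break
      }
    }
    if (is.null(drop)) break
    cand <- cand[-drop]
  }
  cand
}

# Independent start-codon assignment oracle: literal probe of the +13, +12,
# +14 codons for A/C/G/T followed by TG.
oracle_assign <- function(seq, p, len = nchar(seq)) {
  probe <- function(o) {
    if (p + o + 3L > len) return(NA_character_)
    substr(seq, p + o + 1L, p + o + 3L)
  }
  for (o in c(13L, 12L, 14L)) {
    cd <- probe(o)
    if (!is.na(cd) && substr(cd, 2L, 3L) == "TG" &&
        substr(cd, 1L, 1L) %in% c("A", "C", "G", "T"))
      return(list(offset = o, codon = cd, canonical = TRUE))
  }
  list(offset = 13L, codon = probe(13L), canonical = FALSE)
}

# Small paired RNA/RFP count matrices with a known per-gene interaction
# effect (log2), NB noise, equal library sizes.
mk_paired_counts <- function(n_genes, effect_log2 = 0, mu_rna = 200,
                             mu_rfp = 200, phi = 0.05, n_rep = 3,
                             lib = 1e6) {
  mk <- function(assay, mu, eff) {
    smp <- expand.grid(replicate = seq_len(n_rep),
                       condition = c("untreated", "tm"),
                       stringsAsFactors = FALSE)
    smp$assay <- assay
    smp$sample_id <- sprintf("%s_%s_r%d", assay, smp$condition,
                             smp$replicate)
    smp$library_size <- lib
    y <- vapply(seq_len(nrow(smp)), function(s) {
      m <- mu * ifelse(smp$condition[s] == "tm", 2^eff, 1)
      if (phi > 0) rnbinom(n_genes, mu = m, size = 1 / phi) else
        rpois(n_genes, m)
    }, numeric(n_genes))
    y <- matrix(y, nrow = n_genes)
    rownames(y) <- sprintf("g%03d", seq_len(n_genes))
    colnames(y) <- smp$sample_id
    count_matrix(y, smp[, c("sample_id", "condition", "assay", "replicate",
                            "library_size")],
                 region = if (assay == "rna") "all" else "cds")
  }
  list(rna = mk("rna", mu_rna, 0),
       rfp = mk("rfp_chx", mu_rfp, effect_log2))
}

# Per-sample two-TIS Ht peak counts for the switching test.
mk_switch_counts <- function(total_per_sample = 400, shift = 1,
                             n_rep = 3, lib = 1e5) {
  smp <- expand.grid(replicate = seq_len(n_rep),
                     condition = c("untreated", "tm"),
                     stringsAsFactors = FALSE)
  smp$sample_id <- sprintf("ht_%s_r%d", smp$condition, smp$replicate)
  smp$library_size <- lib
  rows <- lapply(seq_len(nrow(smp)), function(s) {
    w1 <- ifelse(smp$condition[s] == "tm", shift, 1)
    pr <- c(w1, 1) / (w1 + 1)
    data.frame(gene_id = "g1", transcript_id = "tx1",
               tis_id = c(10L, 110L), region = c("utr5", "annotated_start"),
               sample_id = smp$sample_id[s],
               count = rpois(2, total_per_sample * pr),
               stringsAsFactors = FALSE)
  })
  list(counts = do.call(rbind, rows), libraries = smp)
}
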