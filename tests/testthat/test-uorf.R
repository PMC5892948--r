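# A transcript with fully controlled geometry for ORF-extension tests:
# neutral C background so the only AUG/stop codons are the planted ones.
orf_fixture <- function(utr5 = 90L, cds_codons = 30L, utr3 = 60L,
                        plant = list()) {
  chars <- rep("C", utr5 + 3L * cds_codons + utr3)
  put <- function(chars, pos, codon) {
    chars[(pos + 1L):(pos + 3L)] <- strsplit(codon, "")[[1L]]
    chars
  }
  chars <- put(chars, utr5, "ATG")
  chars <- put(chars, utr5 + 3L * (cds_codons - 1L), "TAA")
  for (p in plant) chars <- put(chars, p$pos, p$codon)
  transcript_model("g1", "tx1", paste(chars, collapse = ""), utr5,
                   utr5 + 3L * cds_codons)
}

test_that("ORF extension scans in-frame to the first stop", {
  # AUG, nine coding codons, then UAA: length 10 codons
  m <- orf_fixture(plant = list(list(pos = 10L, codon = "ATG"),
                                list(pos = 40L, codon = "TAA")))
  orf <- extend_orf(10L, m)
  expect_equal(orf$length_codons, 10L)
  expect_equal(orf$stop_pos, 40L)
  expect_false(orf$incomplete)
  # minimal ORF: start immediately followed by a stop
  m2 <- orf_fixture(plant = list(list(pos = 10L, codon = "ATG"),
                                 list(pos = 13L, codon = "TAG")))
  orf2 <- extend_orf(10L, m2)
  expect_equal(orf2$length_codons, 1L)
  # no stop in frame before the transcript end (frame 1 of a C-run)
  m3 <- orf_fixture(utr3 = 10L)
  orf3 <- extend_orf(m3$cds_start + 1L, m3)
  expect_true(orf3$incomplete)
  expect_true(is.na(orf3$stop_pos))
})

test_that("extended ORFs never contain an internal in-frame stop", {
  cfg <- sim_config(n_genes = 40L, seed = 12L, frac_uorf = 0.8)
  tr <- simulate_transcriptome(cfg)
  u <- tr$truth$uorfs
  for (r in seq_len(nrow(u))) {
    m <- get_model(tr$models, u$transcript_id[r])
    orf <- extend_orf(u$pos[r], m)
    expect_equal(orf$stop_pos, u$stop_pos[r])
    if (orf$length_codons > 1L) {
      internal <- u$pos[r] + 3L * seq_len(orf$length_codons - 1L)
      codons <- substring(m$sequence, internal + 1L, internal + 3L)
      expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
    }
  }
})

test_that("ORF classification reproduces the decision table exhaustively", {
  utr5 <- 90L
  cds_codons <- 30L
  cs <- utr5
  ce <- utr5 + 3L * cds_codons
  cases <- list(
    # TIS in 5'UTR, stop before CDS -> plain uORF (any frame)
    list(tis = 12L, stop = 36L, expect = "uorf"),
    list(tis = 13L, stop = 37L, expect = "uorf"),
    list(tis = 14L, stop = 38L, expect = "uorf"),
    # TIS in 5'UTR, out of frame, stop inside CDS -> overlapping uORF
    list(tis = 13L, stop = cs + 30L + (13L - cs) %% 3L,
         expect = "overlapping_uorf"),
    # TIS in 5'UTR, in frame, no stop before CDS -> N-terminal extension
    list(tis = cs - 60L, stop = NULL, expect = "n_terminal_extension"),
    # TIS at the annotated start
    list(tis = cs, stop = NULL, expect = "annotated"),
    # TIS inside CDS, in frame -> truncated isoform
    list(tis = cs + 30L, stop = NULL,
         expect = "internal_in_frame_truncation"),
    # 9-codon internal out-of-frame ORF
    list(tis = cs + 31L, stop = cs + 31L + 27L,
         expect = "internal_out_of_frame_orf"),
    # TIS in the 3'UTR
    list(tis = ce + 6L, stop = ce + 21L, expect = "three_prime_orf")
  )
  for (k in seq_along(cases)) {
    cse <- cases[[k]]
    plant <- list(list(pos = cse$tis, codon = "ATG"))
    if (!is.null(cse$stop))
      plant <- c(plant, list(list(pos = cse$stop, codon = "TGA")))
    m <- orf_fixture(utr5 = utr5, cds_codons = cds_codons, plant = plant)
    orf <- extend_orf(cse$tis, m)
    expect_equal(classify_orf(orf, m), cse$expect,
                 info = paste("case", k))
  }
})

test_that("classification is a total function over geometry combinations", {
  utr5 <- 30L
  m <- orf_fixture(utr5 = utr5, cds_codons = 10L, utr3 = 21L)
  classes <- c("uorf", "overlapping_uorf", "n_terminal_extension",
               "annotated", "internal_in_frame_truncation",
               "internal_out_of_frame_orf", "three_prime_orf")
  for (tis in 0:(m$length - 3L)) {
    stops <- c(if (tis + 3L <= m$length - 3L)
      seq(tis + 3L, m$length - 3L, by = 3L), Inf)
    for (stop_pos in stops) {
      orf <- list(codon_pos = tis, stop_pos = stop_pos,
                  incomplete = !is.finite(stop_pos))
      got <- classify_orf(orf, m)
      expect_true(got %in% classes)
      # independent re-derivation of the expected class
      cs <- m$cds_start; ce <- m$cds_end
      expected <-
        if (tis == cs) "annotated"
        else if (tis < cs) {
          if (stop_pos < cs) "uorf"
          else if ((tis - cs) %% 3L == 0L) "n_terminal_extension"
          else "overlapping_uorf"
        } else if (tis < ce) {
          if ((tis - cs) %% 3L == 0L) "internal_in_frame_truncation"
          else "internal_out_of_frame_orf"
        } else "three_prime_orf"
      expect_identical(got, expected)
    }
  }
})

test_that("CHX support is the closed-form density ratio", {
  m <- orf_fixture(plant = list(list(pos = 12L, codon = "ATG"),
                                list(pos = 39L, codon = "TAA")))
  orf <- extend_orf(12L, m)
  orf_nt <- orf$stop_pos + 3L - orf$codon_pos
  # coverage only inside the ORF
  v <- integer(m$length)
  v[(orf$codon_pos + 1L):(orf$stop_pos + 3L)] <- 2L
  expect_equal(chx_support(orf, v), m$length / orf_nt)
  # uniform coverage -> 1; empty transcript -> 0
  expect_equal(chx_support(orf, rep(3L, m$length)), 1)
  expect_equal(chx_support(orf, integer(m$length)), 0)
})

test_that("association statistic matches the textbook chi-square", {
  mk_diff <- function(reg, fdr) {
    data.frame(gene_id = sprintf("g%03d", seq_along(reg)),
               reg_class = reg, fdr = fdr, stringsAsFactors = FALSE)
  }
  mk_peaks <- function(genes) {
    data.frame(gene_id = genes, transcript_id = genes,
               peak_pos = 1L, count = 50L, codon_pos = 14L, offset = 13L,
               codon = "ATG", canonical = TRUE, region = "utr5",
               artifact_rk = FALSE, stringsAsFactors = FALSE)
  }
  # counts [[10,40],[10,40],[20,80]]: identical proportions -> stat 0
  reg <- c(rep("up", 50), rep("down", 50), rep("unchanged", 100))
  fdr <- c(rep(0.001, 100), rep(0.9, 100))
  diff <- mk_diff(reg, fdr)
  tis_genes <- diff$gene_id[c(1:10, 51:60, 101:120)]
  res <- tis_regulation_association(diff, mk_peaks(tis_genes),
                                    mk_peaks(tis_genes))
  expect_equal(unname(as.vector(res$table)),
               c(10L, 10L, 20L, 40L, 40L, 80L))
  expect_equal(res$statistic, 0)
  expect_equal(res$df, 2L)
  expect_equal(res$p_value, 1)
  # unbalanced counts: cross-check against stats::chisq.test
  tis_genes2 <- diff$gene_id[c(1:30, 51:55, 101:120)]
  res2 <- tis_regulation_association(diff, mk_peaks(tis_genes2),
                                     mk_peaks(tis_genes2))
  ref <- suppressWarnings(stats::chisq.test(res2$table, correct = FALSE))
  expect_equal(res2$statistic, unname(ref$statistic))
  expect_equal(res2$p_value, unname(ref$p.value))
  # permuting rows/columns leaves the statistic unchanged
  res3 <- tis_regulation_association(diff[rev(seq_len(nrow(diff))), ],
                                     mk_peaks(rev(tis_genes2)),
                                     mk_peaks(tis_genes2))
  expect_equal(res3$statistic, res2$statistic)
})

test_that("a TIS counts only when present in both conditions within 1 nt", {
  pk <- function(gene, pos, region = "utr5", canonical = TRUE) {
    data.frame(gene_id = gene, transcript_id = gene, peak_pos = pos - 13L,
               count = 30L, codon_pos = pos, offset = 13L, codon = "ATG",
               canonical = canonical, region = region,
               artifact_rk = FALSE, stringsAsFactors = FALSE)
  }
  a <- rbind(pk("g1", 20L), pk("g2", 20L), pk("g3", 20L),
             pk("g4", 20L, region = "cds"))
  b <- rbind(pk("g1", 21L), pk("g2", 50L), pk("g4", 20L, region = "cds"))
  got <- genes_with_utr5_tis_both(a, b)
  expect_equal(got, "g1")
})

test_that("association p is uniform when TIS and regulation are unlinked", {
  set.seed(77)
  ps <- replicate(200, {
    n <- 300
    reg <- sample(c("up", "down", "unchanged"), n, replace = TRUE,
                  prob = c(0.15, 0.2, 0.65))
    diff <- data.frame(gene_id = sprintf("g%03d", 1:n), reg_class = reg,
                       fdr = ifelse(reg == "unchanged", 0.95, 0.001),
                       stringsAsFactors = FALSE)
    tis <- diff$gene_id[runif(n) < 0.4]
    peaks <- data.frame(gene_id = tis, transcript_id = tis, peak_pos = 1L,
                        count = 50L, codon_pos = 14L, offset = 13L,
                        codon = "ATG", canonical = TRUE, region = "utr5",
                        artifact_rk = FALSE, stringsAsFactors = FALSE)
    tis_regulation_association(diff, peaks, peaks)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
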