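call_one <- function(model, pos, counts, ...) {
  call_tis_peaks(mk_cov(model, pos, counts), model, ...)
}

test_that("peak rules flip at their printed thresholds", {
  set.seed(1)
  model <- mk_model(utr5 = 100L, cds_codons = 60L, utr3 = 40L)
  cs <- model$cds_start
  # lone spike of 30 satisfies every rule
  expect_equal(call_one(model, cs - 13L, 30L)$peak_pos, cs - 13L)
  # window total 19 vs 20 on a lone spike
  expect_equal(nrow(call_one(model, cs, 19L)), 0L)
  expect_equal(call_one(model, cs, 20L)$peak_pos, cs)
  # first-position fraction boundary: spike over 15 single-read fillers in
  # its window gives fraction a / (a + 15); a = 10 is exactly 40%, a = 11
  # clears it (the fillers' own windows stay below the coverage floor)
  filler <- (cs + 3L):(cs + 17L)
  expect_equal(nrow(call_one(model, c(cs, filler),
                             c(10L, rep(1L, 15L)))), 0L)
  expect_equal(call_one(model, c(cs, filler),
                        c(11L, rep(1L, 15L)))$peak_pos, cs)
  # printed example: candidates of 100 and 8 reads, only the 100 survives
  pk <- call_one(model, c(cs - 60L, cs), c(100L, 8L))
  expect_equal(pk$peak_pos, cs - 60L)
  # true relative-height boundary needs a candidate clearing the coverage
  # floor: 29 < 10% of 300 is dropped, 30 is kept
  pk <- call_one(model, c(cs - 60L, cs), c(300L, 29L))
  expect_equal(pk$peak_pos, cs - 60L)
  pk <- call_one(model, c(cs - 60L, cs), c(300L, 30L))
  expect_equal(pk$peak_pos, c(cs - 60L, cs))
  # downstream-codon dominance: a stronger position in the next 5 codons
  # vetoes the candidate (the stronger one is then called on its own)
  pk <- call_one(model, c(cs, cs + 6L), c(30L, 31L))
  expect_equal(pk$peak_pos, cs + 6L)
  pk <- call_one(model, c(cs, cs + 6L), c(31L, 30L))
  expect_equal(pk$peak_pos, c(cs, cs + 6L))
  # equality does not veto
  pk <- call_one(model, c(cs, cs + 6L), c(30L, 30L))
  expect_equal(pk$peak_pos, c(cs, cs + 6L))
})

test_that("peaks beyond 500 nt of the CDS are rejected", {
  set.seed(2)
  model <- mk_model(utr5 = 600L, cds_codons = 10L, utr3 = 550L)
  cs <- model$cds_start
  ce <- model$cds_end
  expect_equal(call_one(model, cs - 500L, 30L)$peak_pos, cs - 500L)
  expect_equal(nrow(call_one(model, cs - 501L, 30L)), 0L)
  expect_equal(call_one(model, ce - 1L + 500L, 30L)$peak_pos,
               ce - 1L + 500L)
  expect_equal(nrow(call_one(model, ce + 500L, 30L)), 0L)
})

test_that("split -13/-12 peaks merge to the stronger position", {
  set.seed(3)
  model <- mk_model(utr5 = 100L, cds_codons = 60L, utr3 = 40L)
  cs <- model$cds_start
  pk <- call_one(model, c(cs - 13L, cs - 12L), c(60L, 40L))
  expect_equal(pk$peak_pos, cs - 13L)
  pk <- call_one(model, c(cs - 13L, cs - 12L), c(40L, 60L))
  expect_equal(pk$peak_pos, cs - 12L)
})

test_that("peak calling matches the brute-force rule evaluation", {
  set.seed(4)
  for (i in 1:12) {
    model <- mk_model(utr5 = sample(60:90, 1), cds_codons = sample(15:30, 1),
                      utr3 = sample(20:40, 1))
    v <- integer(model$length)
    spikes <- sample.int(model$length, 15L)
    v[spikes] <- rpois(15L, 25)
    v <- v + rbinom(model$length, 2L, 0.1)
    cov <- fiveprime_coverage(list(tx1 = v), "s", model)
    pk <- call_tis_peaks(cov, model)
    expect_equal(pk$peak_pos,
                 brute_tis(v, model$cds_start, model$cds_end),
                 info = paste("fixture", i))
  }
})

test_that("peak calling is idempotent and order-independent", {
  cfg <- sim_config(n_genes = 10L, seed = 44L, frac_uorf = 0.6)
  sim <- simulate_experiment(cfg)
  ids <- sim$samples$sample_id[sim$samples$assay == "rfp_ht" &
                                 sim$samples$condition == "untreated"]
  pooled <- sum_coverage(sim$ht_cov[ids])
  pk1 <- call_tis_peaks(pooled, sim$models)
  pk2 <- call_tis_peaks(pooled, sim$models)
  expect_identical(pk1, pk2)
  shuffled <- fiveprime_coverage(rev(unclass(pooled)), "rev")
  pk3 <- call_tis_peaks(shuffled, sim$models)
  ord <- order(pk3$transcript_id, pk3$peak_pos)
  expect_equal(pk3[ord, ], pk1[order(pk1$transcript_id, pk1$peak_pos), ],
               ignore_attr = TRUE)
})

test_that("start-codon assignment honours the +13/+12/+14 priority", {
  # AUG exactly at +13
  seq <- paste0(strrep("C", 40), "ATG", strrep("C", 60), "TAA",
                strrep("C", 20))
  model <- transcript_model("g1", "tx1", seq, 40L, 106L)
  pk <- data.frame(transcript_id = "tx1", gene_id = "g1",
                   peak_pos = 40L - 13L, count = 50L,
                   stringsAsFactors = FALSE)
  a <- assign_codon(pk, model)
  expect_true(a$canonical)
  expect_equal(a$offset, 13L)
  expect_equal(a$codon, "ATG")
  expect_equal(a$region, "annotated_start")
  # CUG at +12 only (no NUG at +13/+14)
  seq2 <- paste0(strrep("A", 20), "CTGAAA", strrep("A", 30), "ATG",
                 strrep("A", 27), "TAA", strrep("A", 10))
  model2 <- transcript_model("g2", "tx2", seq2, 56L, 89L)
  pk2 <- data.frame(transcript_id = "tx2", gene_id = "g2", peak_pos = 8L,
                    count = 40L, stringsAsFactors = FALSE)
  a2 <- assign_codon(pk2, model2)
  expect_true(a2$canonical)
  expect_equal(a2$offset, 12L)
  expect_equal(a2$codon, "CTG")
  # no NUG anywhere, AAG at +13 -> non-canonical lysine artifact
  seq3 <- paste0(strrep("A", 56), "ATG", strrep("A", 27), "TAA",
                 strrep("A", 10))
  model3 <- transcript_model("g3", "tx3", seq3, 56L, 89L)
  pk3 <- data.frame(transcript_id = "tx3", gene_id = "g3", peak_pos = 2L,
                    count = 40L, stringsAsFactors = FALSE)
  a3 <- assign_codon(pk3, model3)
  expect_false(a3$canonical)
  expect_equal(a3$codon, "AAA")
  expect_true(a3$artifact_rk)
})

test_that("codon composition tallies known mixtures", {
  peaks <- data.frame(
    transcript_id = "tx1", gene_id = "g1", peak_pos = 1:4, count = 10L,
    codon_pos = 14:17, offset = 13L,
    codon = c("ATG", "ATG", "CTG", "AAG"),
    canonical = c(TRUE, TRUE, TRUE, FALSE),
    region = "utr5", artifact_rk = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  comp <- codon_composition(peaks, by_region = FALSE)
  expect_equal(comp$fraction[comp$codon_class == "AUG"], 0.5)
  expect_equal(comp$fraction[comp$codon_class == "CUG"], 0.25)
  expect_equal(comp$fraction[comp$codon_class == "other"], 0.25)
  expect_equal(sum(comp$fraction), 1)
})

test_that("R/K artifact peaks are dropped unless CHX shows a local peak", {
  set.seed(5)
  model <- mk_model(utr5 = 60L, cds_codons = 40L, utr3 = 30L)
  peaks <- data.frame(
    transcript_id = "tx1", gene_id = "g1",
    peak_pos = c(47L, 100L, 130L), count = 50L,
    codon_pos = c(60L, 113L, 143L), offset = 13L,
    codon = c("ATG", "AAA", "AGA"),
    canonical = c(TRUE, FALSE, FALSE),
    region = c("annotated_start", "cds", "cds"),
    artifact_rk = c(FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  # flat CHX background everywhere except a strong local peak at 130
  v <- rep(1L, model$length)
  v[131] <- 100L
  chx <- fiveprime_coverage(list(tx1 = v), "chx", model)
  out <- filter_artifacts(peaks, chx)
  expect_equal(out$dropped$peak_pos, 100L)
  expect_equal(sort(out$kept$peak_pos), c(47L, 130L))
  # zero CHX coverage -> artifact removed; canonical kept regardless
  chx0 <- fiveprime_coverage(list(tx1 = integer(model$length)), "chx",
                             model)
  out0 <- filter_artifacts(peaks, chx0)
  expect_equal(sort(out0$dropped$peak_pos), c(100L, 130L))
  expect_equal(out0$kept$peak_pos, 47L)
  # brute-force set difference
  expect_equal(out$kept$peak_pos,
               setdiff(peaks$peak_pos, out$dropped$peak_pos))
})

test_that("TIS switching finds no signal in balanced ratios", {
  set.seed(6)
  sw <- mk_switch_counts(total_per_sample = 400, shift = 1)
  res <- test_tis_switching(sw$counts, sw$libraries)
  expect_equal(res$df, 1L)
  expect_gt(res$p_value, 0.05)
  expect_false(res$significant)
})

test_that("TIS switching detects a planted 1:1 to 3:1 ratio shift", {
  set.seed(7)
  sw <- mk_switch_counts(total_per_sample = 400, shift = 3)
  res <- test_tis_switching(sw$counts, sw$libraries)
  expect_lt(res$p_value, 0.001)
  expect_true(res$significant)
})

test_that("switching LRT equals twice the log-likelihood difference", {
  set.seed(8)
  sw <- mk_switch_counts(total_per_sample = 300, shift = 2)
  res <- test_tis_switching(sw$counts, sw$libraries)
  # independent refit: saturated-ish means computed by group averages
  d <- merge(sw$counts, sw$libraries[, c("sample_id", "condition",
                                         "replicate", "library_size")],
             by = "sample_id")
  ll <- function(form) {
    fit <- stats::glm(form, family = stats::poisson(),
                      offset = log(library_size), data = d)
    sum(stats::dpois(d$count, fitted(fit), log = TRUE))
  }
  lrt <- 2 * (ll(count ~ factor(replicate) + factor(tis_id) *
                  factor(condition)) -
                ll(count ~ factor(replicate) + factor(tis_id) +
                     factor(condition)))
  expect_equal(res$lrt_stat, lrt, tolerance = 1e-6)
})

test_that("all-zero TIS rows are dropped and lone TIS genes skipped", {
  set.seed(9)
  sw <- mk_switch_counts(total_per_sample = 200, shift = 1)
  sw$counts$count[sw$counts$tis_id == 110L] <- 0L
  expect_warning(res <- test_tis_switching(sw$counts, sw$libraries),
                 "all-zero")
  expect_equal(nrow(res), 0L)
})
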