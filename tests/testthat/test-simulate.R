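test_that("germination simulation is deterministic given its seed", {
  a <- simulate_germination(wl_params(), n_seeds = 100, seed = 42)
  b <- simulate_germination(wl_params(), n_seeds = 100, seed = 42)
  c <- simulate_germination(wl_params(), n_seeds = 100, seed = 43)
  expect_identical(a$observations, b$observations)
  expect_false(identical(a$observations, c$observations))
  expect_identical(a$truth$seed, 42)
})

test_that("generated datasets serialise byte-identically under one seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (writer in list(
    function(d) write_germination_dataset(
      simulate_germination(sd_params(), n_seeds = 50, seed = 3), d),
    function(d) write_expression_dataset(
      simulate_expression(n_lnc = 10, n_mrna = 10, n_planted_pairs = 4,
                          n_planted_de = 2, seed = 3), d),
    function(d) write_annotation_dataset(
      simulate_annotation(n_clean = 4, violations_per_rule = 2, seed = 3), d)
  )) {
    writer(d1)
    writer(d2)
  }
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("a vanishing base-potential spread makes germination a single step", {
  p <- hydrotime_params(-1, 1e-9, 40)
  sim <- simulate_germination(p, psi_levels = 0, n_seeds = 200, seed = 1)
  obs <- sim$observations
  # all seeds share psi_b = -1, so latent time is exactly 40 h: every
  # seed is scored at the 48 h inspection
  expect_true(all(obs$n_germ_cum[obs$time_h < 48] == 0))
  expect_true(all(obs$n_germ_cum[obs$time_h >= 48] == 200))
})

test_that("water potential five sigma below the median base potential blocks germination", {
  p <- sd_params()
  sim <- simulate_germination(p, psi_levels = p$psi_b50 - 5 * p$sigma,
                              n_seeds = 2000, seed = 2)
  expect_true(all(sim$observations$n_germ_cum == 0))
})

test_that("the final germinated fraction approaches the base-potential CDF", {
  # with the censor pushed far out, theta_h/t vanishes and the plateau is
  # Phi((psi - psi_b50) / sigma); binomial-sampling check at large n
  p <- wl_params()
  n <- 1e5
  for (psi in c(0, -0.8)) {
    sim <- simulate_germination(p, psi_levels = psi, n_seeds = n,
                                censor_h = 1e6, interval_h = 1e4, seed = 10)
    final <- max(sim$observations$n_germ_cum) / n
    expected <- pnorm((psi - p$psi_b50) / p$sigma)
    se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(final - expected), 3 * se)
  }
})

test_that("the expression design reproduces the 42-sample time course", {
  sim <- simulate_expression(n_lnc = 5, n_mrna = 5, n_planted_pairs = 2,
                             n_planted_de = 1, seed = 1)
  sm <- sim$samples
  expect_equal(nrow(sm), 42)
  expect_setequal(unique(sm$cultivar), c("WL", "SD"))
  expect_equal(sum(sm$condition == "control"), 24) # 2 cultivars x 4 times x 3
  expect_equal(sum(sm$condition == "drought"), 18) # 2 cultivars x 3 times x 3
  expect_identical(colnames(sim$lnc_counts), sm$sample_id)
  expect_true(all(sim$lnc_counts >= 0))
  expect_true(all(sim$lnc_counts == round(sim$lnc_counts)))
})

test_that("a planted pair's sample correlation sits in the Fisher interval", {
  sim <- simulate_expression(n_lnc = 30, n_mrna = 30, n_planted_pairs = 10,
                             target_r = 0.95, n_planted_de = 0, seed = 13)
  lnc <- log2(sim$lnc_counts + 1)
  mrna <- log2(sim$mrna_counts + 1)
  tr <- sim$truth$planted_pairs
  rs <- mapply(function(a, b) cor(lnc[a, ], mrna[b, ]), tr$lnc_id, tr$mrna_id)
  n <- ncol(lnc)
  z_lo <- atanh(0.95) - qnorm(0.995) / sqrt(n - 3)
  z_hi <- atanh(0.95) + qnorm(0.995) / sqrt(n - 3)
  inside <- rs > tanh(z_lo) & rs < tanh(z_hi)
  expect_gte(mean(inside), 0.8)
})

test_that("without planted pairs no decoy correlation reaches the cutoff", {
  sim <- simulate_expression(n_lnc = 25, n_mrna = 40, n_planted_pairs = 0,
                             n_planted_de = 0, seed = 19)
  r <- cor(t(log2(sim$lnc_counts + 1)), t(log2(sim$mrna_counts + 1)))
  expect_lt(max(abs(r)), 0.9)
})

test_that("annotation fixtures plant exactly the promised violations", {
  sim <- simulate_annotation(n_clean = 7, violations_per_rule = 3, seed = 4)
  expect_length(sim$truth$clean_ids, 7)
  expect_true(all(lengths(sim$truth$violations) == 3))
  expect_equal(nrow(sim$candidates), 7 + 5 * 3)
  # violators are single-rule by construction: e.g. short transcripts
  # still have >= 2 exons, enough reads and non-coding verdicts
  short <- sim$candidates[sim$candidates$transcript_id %in%
                            sim$truth$violations$length, ]
  expect_true(all(short$length_bp < 200))
  expect_true(all(short$exon_count >= 2))
  expect_true(all(short$read_count >= 3))
  # the empty-candidate edge case
  empty <- simulate_annotation(n_clean = 0, violations_per_rule = 1, seed = 4)
  rep <- identify_lncrnas(empty$candidates, empty$reference, empty$calls)
  expect_equal(sum(rep$retained), 0)
})

test_that("every generator ships a self-describing ground-truth ledger", {
  g <- simulate_germination(wl_params(), n_seeds = 10, seed = 1)
  e <- simulate_expression(n_lnc = 5, n_mrna = 5, n_planted_pairs = 2,
                           n_planted_de = 1, seed = 1)
  a <- simulate_annotation(n_clean = 2, violations_per_rule = 1, seed = 1)
  expect_named(g$truth$params, c("psi_b50", "sigma", "theta_h"))
  expect_equal(nrow(e$truth$planted_pairs), 2)
  expect_equal(nrow(e$truth$planted_de), 1)
  expect_named(a$truth$violations,
               c("overlap", "length", "exons", "reads", "coding"))
  for (truth in list(g$truth, e$truth, a$truth))
    expect_true(is.numeric(truth$seed) || is.integer(truth$seed))
})
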