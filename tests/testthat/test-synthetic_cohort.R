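# Synthetic cohort generator: planted visual signal, forward expression
# model, survival simulation, on-disk cohort.

test_that("blob counts track the planted density and M2 level", {
  # at m2 = 0 the mean detected count matches base_density * tissue area
  counts <- t(sapply(1:40, function(s) {
    tl <- render_tile(0, 5, tile_size = 336, seed = s, tissue_cover = 0.5)
    c(det = count_brown_blobs(tl),
      expected = 60 * sum(attr(tl, "tissue_mask")) / 1e6)
  }))
  lambda <- mean(counts[, "expected"])
  # mean of 40 Poisson draws: allow 4 standard errors + slight merge loss
  se <- sqrt(lambda / 40)
  expect_lt(abs(mean(counts[, "det"]) - lambda), 4 * se + 0.05 * lambda)

  # same seed stream, m2 = 1 vs 0: strictly more blobs on average
  c0 <- sapply(1:30, function(s)
    count_brown_blobs(render_tile(0, 5, 336, seed = s, tissue_cover = 0.5)))
  c1 <- sapply(1:30, function(s)
    count_brown_blobs(render_tile(1, 5, 336, seed = s, tissue_cover = 0.5)))
  expect_gt(mean(c1), mean(c0))
})

test_that("m2 level and blob count are positively rank-correlated", {
  set.seed(33)
  m2 <- runif(100)
  cnt <- sapply(seq_along(m2), function(i)
    count_brown_blobs(render_tile(m2[i], 4, 336, seed = 7000 + i,
                                  tissue_cover = 0.5)))
  ct <- cor.test(m2, cnt, method = "spearman", exact = FALSE)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("tiles are deterministic, near-white in background, and a
           zero-tissue tile defeats the tissue filter", {
  t1 <- render_tile(0.4, 3, 336, seed = 12)
  t2 <- render_tile(0.4, 3, 336, seed = 12)
  expect_identical(t1$pixels, t2$pixels)
  mask <- attr(t1, "tissue_mask")
  bg <- t1$pixels[cbind(which(!mask, arr.ind = TRUE), 1)]
  expect_true(all(bg >= 240))
  expect_error(render_tile(0.4, 3, tile_size = 128),
               class = "hemil_invalid_argument")

  white <- render_tile(0.7, 3, 448, seed = 2, tissue_cover = 0)
  expect_true(all(white$pixels >= 240))
  expect_length(suppressMessages(filter_background(tile_image(white))), 0L)
})

test_that("synthesize_expression implements the exact forward model", {
  sig <- generate_signature(60, 4, seed = 5)
  f <- c(0.25, 0.25, 0.3, 0.2)
  expect_equal(synthesize_expression(f, sig, 0),
               drop(unclass(sig) %*% f), ignore_attr = TRUE)
  unit <- c(0, 1, 0, 0)
  expect_equal(unname(synthesize_expression(unit, sig, 0)),
               unname(unclass(sig)[, 2]))
  expect_error(synthesize_expression(c(0.5, 0.5), sig, 0),
               class = "hemil_invalid_argument")
  # deterministic given seed, truncated at zero
  m1 <- synthesize_expression(f, sig, 0.5, seed = 3)
  m2 <- synthesize_expression(f, sig, 0.5, seed = 3)
  expect_identical(m1, m2)
  expect_true(all(m1 >= 0))
})

test_that("simulate_survival calibrates censoring and stays deterministic", {
  s0 <- simulate_survival(rep(c("high", "low"), 100), log(4), 0.02,
                          censor_rate = 0, seed = 1)
  expect_true(all(s0$event == 1))
  big <- simulate_survival(rep(c("high", "low"), 1000), log(4), 0.02,
                           censor_rate = 0.3, seed = 2)
  expect_lt(abs(mean(big$event == 0) - 0.3), 0.035)
  expect_identical(
    simulate_survival(rep("low", 10), 0, 0.05, 0.2, seed = 9),
    simulate_survival(rep("low", 10), 0, 0.05, 0.2, seed = 9))
  expect_error(simulate_survival(character(0), 0, 0.05),
               class = "hemil_invalid_argument")
})

test_that("null and planted hazard ratios behave under the log-rank test", {
  # null: groups agree (p > 0.05) in at least 90% of replicates
  p_null <- sapply(1:50, function(s) {
    rec <- simulate_survival(rep(c("high", "low"), 100), 0, 0.02,
                             censor_rate = 0.2, seed = 100 + s)
    logrank_test(rec)$p
  })
  expect_gte(mean(p_null > 0.05), 0.9)
})

test_that("generate_cohort writes a complete, reproducible bundle", {
  spec <- cohort_spec(n_patients = 2L, tiles_per_patient = 1L,
                      tile_size = 224L, n_genes = 30L, n_celltypes = 3L,
                      zero_inflation_prob = 0, seed = 42L)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  unlink(c(d1, d2), recursive = TRUE)
  c1 <- generate_cohort(spec, d1)
  expect_length(c1$tile_paths, 2L)
  expect_equal(nrow(c1$truth), 2L)
  expect_equal(nrow(c1$survival), 2L)
  expect_equal(dim(c1$expression), c(30L, 2L))
  expect_true(file.exists(c1$manifest_path))
  # byte-identical regeneration
  c2 <- generate_cohort(spec, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("checksum of", f))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("zero inflation reproduces the excluded-patient pathway", {
  # same zero mass as the study (21/86); tiny tiles keep this fast
  spec <- cohort_spec(n_patients = 86L, tile_size = 224L, n_genes = 20L,
                      n_celltypes = 3L, tissue_cover = 0.3, seed = 7L)
  dir <- file.path(tempdir(), "coh86")
  unlink(dir, recursive = TRUE)
  coh <- generate_cohort(spec, dir)
  n_zero <- sum(coh$truth$true_m2_fraction == 0)
  # binomial(86, 21/86): mean 21, sd ~3.9 -- emulated, not asserted exactly
  expect_gt(n_zero, 9)
  expect_lt(n_zero, 33)
  # the label rule is the cohort-mean boundary on the true fraction
  expect_identical(coh$truth$true_label,
                   ifelse(coh$truth$true_m2_fraction >
                            mean(coh$truth$true_m2_fraction), "high", "low"))
  unlink(dir, recursive = TRUE)
})
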