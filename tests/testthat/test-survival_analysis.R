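# Kaplan-Meier, log-rank and Cox proportional hazards.

test_that("KM curve matches the product-limit hand computation", {
  rec <- survival_table(paste0("p", 1:3), c(1, 2, 3), c(1, 1, 1),
                        rep("high", 3))
  km <- km_curve(rec)$high
  expect_equal(km$time, c(1, 2, 3))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  # all censored: survival identically 1
  rec0 <- survival_table(paste0("p", 1:4), 1:4, rep(0, 4), rep("low", 4))
  expect_true(all(km_curve(rec0)$low$survival == 1))
  # duplicating every record leaves the curve unchanged
  rec2 <- survival_table(paste0("q", 1:6), rep(c(1, 2, 3), 2), rep(1, 6),
                         rep("high", 6))
  expect_equal(km_curve(rec2)$high$survival, km$survival)
})

test_that("log-rank test is null on identical groups and validates input", {
  d <- data.frame(patient_id = paste0("p", 1:20),
                  time = rexp(20, 0.1) + 0.1, event = rbinom(20, 1, 0.8))
  rec <- survival_table(rep(d$patient_id, 2), rep(d$time, 2),
                        rep(d$event, 2), rep(c("high", "low"), each = 20))
  lr <- logrank_test(rec)
  expect_equal(lr$chi_square, 0, tolerance = 1e-9)
  expect_equal(lr$p, 1, tolerance = 1e-9)
  one <- survival_table("a", 5, 1, "high")
  expect_error(logrank_test(one), class = "hemil_invalid_argument")
})

test_that("log-rank detects a planted effect with the expected power/size", {
  p_alt <- sapply(1:50, function(s) {
    rec <- simulate_survival(rep(c("high", "low"), 100), log(4), 0.02,
                             censor_rate = 0.2, seed = 500 + s)
    logrank_test(rec)$p
  })
  expect_gte(mean(p_alt < 0.01), 0.95)
  p_null <- sapply(1:50, function(s) {
    rec <- simulate_survival(rep(c("high", "low"), 100), 0, 0.02,
                             censor_rate = 0.2, seed = 900 + s)
    logrank_test(rec)$p
  })
  expect_lte(mean(p_null < 0.05), 0.10)
})

test_that("Cox fit recovers a planted hazard ratio and its CI behaves", {
  fits <- lapply(1:50, function(s) {
    rec <- simulate_survival(rep(c("high", "low"), 150), log(4), 0.02,
                             censor_rate = 0.2, seed = 1300 + s)
    cox_fit(rec, "group")
  })
  hr <- vapply(fits, function(f) f$hazard_ratio[1], numeric(1))
  cover <- vapply(fits, function(f) f$ci_low[1] <= 4 && f$ci_high[1] >= 4,
                  logical(1))
  expect_gte(mean(hr >= 3.0 & hr <= 5.4), 0.9)
  expect_gte(mean(cover), 0.9)
  f1 <- fits[[1]]
  expect_true(f1$ci_low[1] <= f1$hazard_ratio[1] &&
                f1$hazard_ratio[1] <= f1$ci_high[1])
  expect_equal(f1$n, 300L)
})

test_that("a covariate independent of survival has log HR near zero", {
  ok <- sapply(1:50, function(s) {
    rec <- simulate_survival(rep(c("high", "low"), 150), 0, 0.02,
                             censor_rate = 0.2, seed = 1700 + s)
    abs(log(cox_fit(rec, "group")$hazard_ratio[1])) < 0.25
  })
  expect_gte(mean(ok), 0.9)
})

test_that("swapping group labels inverts the hazard ratio", {
  rec <- simulate_survival(rep(c("high", "low"), 80), log(3), 0.03,
                           censor_rate = 0.1, seed = 77)
  hr <- cox_fit(rec, "group")$hazard_ratio[1]
  rec_sw <- rec
  rec_sw$group <- ifelse(rec$group == "high", "low", "high")
  hr_sw <- cox_fit(rec_sw, "group")$hazard_ratio[1]
  expect_equal(hr * hr_sw, 1, tolerance = 1e-6)
})

test_that("log-rank p agrees with the Cox score test on two groups", {
  for (s in 1:5) {
    rec <- simulate_survival(rep(c("high", "low"), 150), log(2), 0.02,
                             censor_rate = 0.2, seed = 2100 + s)
    lr <- logrank_test(rec)
    fit <- attr(cox_fit(rec, "group"), "fit")
    sc <- summary(fit)$sctest
    expect_equal(round(lr$p, 2),
                 round(unname(sc["pvalue"]), 2))
  }
})

test_that("perfect separation raises the monotone-likelihood warning", {
  # every high patient dies before any low patient, huge effect
  rec <- survival_table(paste0("p", 1:20),
                        c(seq(1, 5, length.out = 10),
                          seq(50, 90, length.out = 10)),
                        rep(1, 20), rep(c("high", "low"), each = 10))
  expect_warning(cox_fit(rec, "group"), "separation|monotone")
})

test_that("multivariate Cox reports one row per model term", {
  set.seed(31)
  rec <- simulate_survival(rep(c("high", "low"), 100), log(3), 0.02,
                           censor_rate = 0.2, seed = 55)
  rec$age <- round(rnorm(200, 60, 8))
  rec$stage <- sample(c("II", "III", "IV"), 200, replace = TRUE)
  fit <- cox_fit(rec, c("group", "age", "stage"))
  expect_gte(nrow(fit), 4L)  # group + age + 2 stage indicators
  expect_true(all(fit$ci_low <= fit$hazard_ratio &
                    fit$hazard_ratio <= fit$ci_high))
  expect_error(cox_fit(rec, c("group", "nope")),
               class = "hemil_invalid_argument")
  rec$const <- 1
  expect_error(cox_fit(rec, "const"), class = "hemil_invalid_argument")
})
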