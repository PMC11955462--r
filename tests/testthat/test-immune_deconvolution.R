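# nu-SVR deconvolution, exclusion of zero-M2 samples and mean-boundary
# dichotomization.

test_that("nu_svr agrees with a quadprog solution of the same dual", {
  skip_if_not_installed("quadprog")
  set.seed(9)
  n <- 24; p <- 3
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% c(1, -0.5, 0.3)) + rnorm(n, 0, 0.3)
  cost <- 1; nu <- 0.5
  fit <- nu_svr(X, y, nu = nu, cost = cost)

  # dual in (alpha, alpha*): min 1/2 x' D x - d' x with
  # D = [[K,-K],[-K,K]], d = (y, -y), box [0, C], and the two nu-SVR
  # equality constraints sum(a - a*) = 0, sum(a + a*) = C * nu * n
  K <- tcrossprod(X)
  D <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-7, 2 * n)
  d <- c(y, -y)
  A <- cbind(c(rep(1, n), rep(-1, n)),      # equality: sum(a - a*) = 0
             c(rep(1, n), rep(1, n)),       # equality: sum(a + a*) = C nu n
             diag(2 * n),                   # x >= 0
             -diag(2 * n))                  # x <= C
  b <- c(0, cost * nu * n, rep(0, 2 * n), rep(-cost, 2 * n))
  qp <- quadprog::solve.QP(D, d, A, b, meq = 2)
  beta_qp <- qp$solution[1:n] - qp$solution[(n + 1):(2 * n)]
  w_qp <- drop(crossprod(X, beta_qp))
  expect_equal(fit$w, w_qp, tolerance = 1e-3)
})

test_that("noiseless mixtures round-trip to the planted fractions", {
  sig <- generate_signature(50, 3, seed = 2)
  f <- c(0.2, 0.3, 0.5)
  mix <- synthesize_expression(f, sig, 0)
  est <- estimate_fractions(mix, sig)
  expect_lt(max(abs(est - f)), 1e-3)
  # a pure sample returns the corresponding unit vector
  for (j in 1:3) {
    unit <- as.numeric(seq_len(3) == j)
    est_j <- estimate_fractions(synthesize_expression(unit, sig, 0), sig)
    expect_lt(max(abs(est_j - unit)), 1e-3)
  }
})

test_that("noisy recovery stays accurate and degrades with noise", {
  sig <- generate_signature(50, 5, seed = 4)
  rmse_at <- function(noise_sd, reps = 20) {
    mean(sapply(seq_len(reps), function(s) {
      set.seed(1000 * noise_sd + s)
      g <- rgamma(5, 2); fr <- g / sum(g)
      est <- estimate_fractions(
        synthesize_expression(fr, sig, noise_sd, seed = s), sig)
      sqrt(mean((est - fr)^2))
    }))
  }
  r <- vapply(c(0.02, 0.05, 0.3), rmse_at, numeric(1))
  expect_lt(r[2], 0.05)          # headline accuracy at 5% noise
  expect_true(all(diff(r) > 0))  # RMSE non-decreasing in noise
})

test_that("fractions are scale invariant and inputs are validated", {
  sig <- generate_signature(40, 4, seed = 6)
  mix <- synthesize_expression(c(0.1, 0.2, 0.3, 0.4), sig, 0.05, seed = 2)
  e1 <- estimate_fractions(mix, sig)
  e2 <- estimate_fractions(mix * 137.5, sig)
  expect_lt(max(abs(e1 - e2)), 1e-6)
  expect_error(estimate_fractions(mix[1], sig),
               class = "hemil_invalid_argument")
  expect_error(estimate_fractions(rep(0, 40), sig),
               class = "hemil_invalid_argument")
  expect_error(signature_matrix(cbind(M2 = c(a = 0, b = 0), B = c(1, 2))),
               class = "hemil_invalid_argument")
})

test_that("deconvolve_expression returns a simplex row per sample", {
  sig <- generate_signature(50, 4, seed = 8)
  fr_true <- rbind(c(0.4, 0.3, 0.2, 0.1), c(0.05, 0.05, 0.2, 0.7))
  expr <- sapply(1:2, function(i)
    synthesize_expression(fr_true[i, ], sig, 0.02, seed = i))
  colnames(expr) <- c("s1", "s2")
  ft <- deconvolve_expression(expr, sig)
  expect_equal(rownames(ft), c("s1", "s2"))
  expect_true(all(ft >= 0))
  expect_equal(unname(rowSums(ft)), c(1, 1), tolerance = 1e-9)
  expect_lt(max(abs(ft - fr_true)), 0.05)
})

test_that("zero-M2 exclusion reproduces the 86 -> 65 pathway", {
  set.seed(3)
  m2 <- c(rep(0, 21), runif(65, 0.01, 0.4))
  ft <- matrix(c(m2, 1 - m2), ncol = 2,
               dimnames = list(sprintf("s%02d", 1:86), c("M2", "Other")))
  class(ft) <- c("hemil_fractions", "matrix", "array")
  attr(ft, "m2_celltype") <- "M2"
  kept <- suppressMessages(exclude_zero_m2(ft))
  expect_equal(nrow(kept), 65L)
  expect_true(all(kept[, "M2"] > 0))
  # no zero rows: identity
  expect_equal(nrow(suppressMessages(exclude_zero_m2(kept))), 65L)
  # all-zero: empty with a warning
  zt <- ft[1:21, , drop = FALSE]
  expect_warning(empty <- suppressMessages(exclude_zero_m2(zt)), "zero M2")
  expect_equal(nrow(empty), 0L)
})

test_that("mean-boundary dichotomization follows the stated tie rule", {
  mk <- function(v) {
    m <- matrix(c(v, 1 - v), ncol = 2,
                dimnames = list(paste0("s", seq_along(v)), c("M2", "O")))
    class(m) <- c("hemil_fractions", "matrix", "array")
    attr(m, "m2_celltype") <- "M2"
    m
  }
  lab <- dichotomize_by_mean(mk(c(0.1, 0.3)))
  expect_equal(lab$boundary, 0.2)
  expect_equal(unname(lab$labels), c("low", "high"))
  # all equal -> all low
  expect_true(all(dichotomize_by_mean(mk(rep(0.25, 5)))$labels == "low"))
  # worked example with a tie at the boundary
  lab2 <- dichotomize_by_mean(mk(c(0.0, 0.1, 0.2, 0.5)))
  expect_equal(lab2$boundary, 0.2)
  expect_equal(unname(lab2$labels), c("low", "low", "low", "high"))
  expect_error(dichotomize_by_mean(mk(0.2)), class = "hemil_invalid_argument")
})

test_that("fraction and label tables survive a disk round trip", {
  sig <- generate_signature(30, 3, seed = 1)
  expr <- sapply(1:3, function(i)
    synthesize_expression(c(0.5, 0.3, 0.2), sig, 0.05, seed = i))
  colnames(expr) <- paste0("p", 1:3)
  ft <- deconvolve_expression(expr, sig)
  fp <- tempfile(fileext = ".csv")
  write_fractions(ft, fp)
  back <- read_fractions(fp)
  expect_equal(unclass(back), unclass(ft), tolerance = 1e-12,
               ignore_attr = TRUE)
  labels <- dichotomize_by_mean(ft)
  lp <- tempfile(fileext = ".csv")
  write_labels(labels, lp)
  lb <- read_labels(lp)
  expect_equal(lb$labels, labels$labels)
  expect_equal(lb$boundary, labels$boundary)
  unlink(c(fp, lp, sub("\\.csv$", ".json", lp)))
})
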