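# Simplified CIBERSORT-style deconvolution: estimate per-sample immune-cell
# fractions from bulk expression by linear nu-support-vector regression
# against a gene x cell-type signature matrix, then label samples high/low
# M2 by the cohort mean fraction.
#
# The nu-SVR is solved directly (SMO on the dual) because no SVM package is
# available; the dual has box constraints [0, C] on alpha/alpha* and the two
# nu-SVR equality constraints, handled libsvm-style by pairwise updates
# within the alpha or alpha* group.

#' Linear nu-support-vector regression (SMO solver)
#'
#' Solves the nu-SVR dual for a linear kernel: minimize
#' `1/2 (a - a*)' K (a - a*) - y'(a - a*)` over `a, a* in [0, C]^n` with
#' `sum(a - a*) = 0` and `sum(a + a*) = C * nu * n`, where `K = X X'`.
#' `nu` upper-bounds the fraction of points outside the (implicit)
#' epsilon-tube and lower-bounds the fraction of support vectors.
#'
#' @param X numeric matrix (observations x features).
#' @param y numeric response vector.
#' @param nu tube parameter in (0, 1).
#' @param cost box constraint C (default 1, the usual SVM default).
#' @param tol Karush-Kuhn-Tucker violation tolerance for convergence.
#' @param max_iter iteration cap.
#' @return List with `w` (feature weights), `b` (intercept, least-squares
#'   over the fit), `fitted`, `beta` (dual coefficients `a - a*`),
#'   `iterations`, `converged`.
#' @export
nu_svr <- function(X, y, nu = 0.5, cost = 1, tol = 1e-7, max_iter = 300000L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop_invalid("length(y) must equal nrow(X)")
  if (nu <= 0 || nu >= 1) stop_invalid("nu must lie in (0, 1)")
  K <- tcrossprod(X)
  kdiag <- diag(K)

  # libsvm initialization: spread C * nu * n / 2 over the alphas in order.
  a  <- numeric(n)  # alpha
  as <- numeric(n)  # alpha*
  budget <- cost * nu * n / 2
  for (i in seq_len(n)) {
    a[i] <- as[i] <- min(budget, cost)
    budget <- budget - a[i]
    if (budget <= 0) break
  }
  beta <- a - as
  u <- drop(K %*% beta)           # K beta; gradient for alpha group is u - y
  iter <- 0L
  converged <- FALSE
  tau <- 1e-12

  while (iter < max_iter) {
    iter <- iter + 1L
    g <- u - y                     # alpha-group gradient; alpha* group is -g

    # maximal violating pair within each group
    up_a  <- which(a < cost);  lo_a  <- which(a > 0)
    up_s  <- which(as < cost); lo_s  <- which(as > 0)
    viol_a <- viol_s <- -Inf
    if (length(up_a) && length(lo_a)) {
      i_a <- up_a[which.min(g[up_a])]
      j_a <- lo_a[which.max(g[lo_a])]
      viol_a <- g[j_a] - g[i_a]
    }
    if (length(up_s) && length(lo_s)) {
      i_s <- up_s[which.max(g[up_s])]   # gradient of alpha* group is -g
      j_s <- lo_s[which.min(g[lo_s])]
      viol_s <- g[i_s] - g[j_s]
    }
    if (max(viol_a, viol_s) < tol) { converged <- TRUE; break }

    if (viol_a >= viol_s) { i <- i_a; j <- j_a; star <- FALSE }
    else                  { i <- i_s; j <- j_s; star <- TRUE }
    denom <- max(kdiag[i] + kdiag[j] - 2 * K[i, j], tau)
    if (!star) {
      delta <- (g[j] - g[i]) / denom
      delta <- min(delta, cost - a[i], a[j])
      a[i] <- a[i] + delta; a[j] <- a[j] - delta
      u <- u + delta * (K[, i] - K[, j])
    } else {
      delta <- (g[i] - g[j]) / denom
      delta <- min(delta, cost - as[i], as[j])
      as[i] <- as[i] + delta; as[j] <- as[j] - delta
      u <- u - delta * (K[, i] - K[, j])
    }
  }
  # first-order pair selection can stall short of a very tight target on
  # rank-deficient kernels; only warn when the final Karush-Kuhn-Tucker
  # violation exceeds the customary 1e-3 working tolerance
  if (!converged && max(viol_a, viol_s) > 1e-3)
    warning("nu_svr: SMO did not reach tolerance ", tol, " in ", iter,
            " iterations (violation ", signif(max(viol_a, viol_s), 3), ")")
  beta <- a - as
  w <- drop(crossprod(X, beta))
  b <- mean(y - u)
  list(w = w, b = b, fitted = u + b, beta = beta,
       iterations = iter, converged = converged)
}

#' Build a signature matrix object
#'
#' @param values non-negative numeric matrix, genes x cell types, with
#'   gene ids as row names and cell-type ids as column names.
#' @param m2_celltype name of the column representing M2 macrophages.
#' @return Matrix of class `hemil_signature` with attribute `m2_celltype`.
#' @export
signature_matrix <- function(values, m2_celltype = "M2") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop_invalid("signature needs unique gene ids as row names")
  if (is.null(colnames(values)))
    stop_invalid("signature needs cell-type ids as column names")
  if (!m2_celltype %in% colnames(values))
    stop_invalid("signature has no column '", m2_celltype, "'")
  if (any(colSums(abs(values)) == 0))
    stop_invalid("signature has an all-zero cell-type column")
  structure(values, class = c("hemil_signature", class(values)),
            m2_celltype = m2_celltype)
}

#' Estimate cell-type fractions for one mixture
#'
#' CIBERSORT-style core: the mixture and signature are aligned on shared
#' genes, z-scored (signature by its global mean/sd, mixture by its own),
#' and a linear nu-SVR of the mixture on the signature columns is fitted
#' for each `nu` in `nu_grid`. The fit whose reconstruction has the highest
#' Pearson correlation with the mixture is kept; negative coefficients are
#' clamped to zero and the rest renormalized to sum to one.
#'
#' @param mixture named numeric vector of bulk expression (linear scale).
#' @param signature a [signature_matrix()].
#' @param nu_grid nu values to try (default `c(0.25, 0.5, 0.75)`).
#' @param cost SVR box constraint (default 1, the usual SVM default, under
#'   which noiseless mixtures round-trip essentially exactly after
#'   z-scoring; see the methods vignette).
#' @return Named fraction vector (non-negative, sums to 1) with attributes
#'   `nu` (selected) and `cor` (reconstruction correlation).
#' @export
estimate_fractions <- function(mixture, signature,
                               nu_grid = c(0.25, 0.5, 0.75), cost = 1) {
  if (is.null(names(mixture))) {
    if (length(mixture) != nrow(signature))
      stop_invalid("unnamed mixture must match signature length")
    names(mixture) <- rownames(signature)
  }
  genes <- intersect(names(mixture), rownames(signature))
  if (length(genes) < 2L)
    stop_invalid("fewer than 2 genes shared between mixture and signature")
  if (length(genes) < nrow(signature))
    message(sprintf("estimate_fractions: %d / %d signature genes matched",
                    length(genes), nrow(signature)))
  y <- mixture[genes]
  X <- signature[genes, , drop = FALSE]
  if (all(y == 0) || sd(y) == 0)
    stop_invalid("degenerate mixture: constant or all-zero expression")

  # z-scoring makes the fit scale-invariant in both inputs
  Xz <- (X - mean(X)) / sd(as.vector(X))
  yz <- (y - mean(y)) / sd(y)

  best <- NULL; best_cor <- -Inf; best_nu <- NA_real_
  for (nu in nu_grid) {
    fit <- nu_svr(Xz, yz, nu = nu, cost = cost)
    r <- suppressWarnings(cor(drop(Xz %*% fit$w), yz))
    if (!is.na(r) && r > best_cor) { best <- fit; best_cor <- r; best_nu <- nu }
  }
  w <- best$w
  w[w < 0] <- 0
  if (sum(w) == 0) {
    warning("all deconvolution coefficients non-positive; returning zeros")
    f <- w
  } else f <- w / sum(w)
  names(f) <- colnames(signature)
  structure(f, nu = best_nu, cor = best_cor)
}

#' Deconvolve a bulk expression matrix
#'
#' Applies [estimate_fractions()] to every column (sample) of a
#' genes x samples expression matrix.
#'
#' @param expression numeric matrix, genes x samples, gene ids as row names.
#' @param signature a [signature_matrix()].
#' @param ... passed to [estimate_fractions()].
#' @return Fraction table: samples x cell-types matrix of class
#'   `hemil_fractions` (rows sum to 1), attribute `m2_celltype`.
#' @export
deconvolve_expression <- function(expression, signature, ...) {
  expression <- as.matrix(expression)
  out <- t(vapply(seq_len(ncol(expression)), function(j) {
    as.numeric(estimate_fractions(expression[, j], signature, ...))
  }, numeric(ncol(signature))))
  dimnames(out) <- list(colnames(expression), colnames(signature))
  structure(out, class = c("hemil_fractions", "matrix", "array"),
            m2_celltype = attr(signature, "m2_celltype"))
}

#' Exclude samples without M2 infiltration
#'
#' Drops samples whose estimated M2 fraction is exactly zero (the study's
#' exclusion pathway: such patients carry no positive-class signal).
#'
#' @param fractions samples x cell-types fraction matrix
#'   (`hemil_fractions`).
#' @param celltype M2 column name (defaults to the table's `m2_celltype`
#'   attribute, else `"M2"`).
#' @return The retained sub-table; retained/excluded counts are messaged.
#'   If every sample is zero an empty table is returned with a warning.
#' @export
exclude_zero_m2 <- function(fractions, celltype = NULL) {
  celltype <- celltype %||% attr(fractions, "m2_celltype") %||% "M2"
  if (!celltype %in% colnames(fractions))
    stop_invalid("fraction table has no column '", celltype, "'")
  keep <- fractions[, celltype] > 0
  message(sprintf("exclude_zero_m2: retained %d, excluded %d samples",
                  sum(keep), sum(!keep)))
  if (!any(keep)) warning("all samples have zero M2 fraction")
  fractions[keep, , drop = FALSE]
}

#' Dichotomize samples at the cohort mean fraction
#'
#' The boundary is the arithmetic mean of the chosen cell type's fractions;
#' samples strictly above it are `"high"`, samples at or below it `"low"`
#' (ties at the boundary are low, so "high infiltration" always means
#' strictly above the mean).
#'
#' @inheritParams exclude_zero_m2
#' @return List of class `hemil_labels`: `labels` (named character vector),
#'   `boundary`, `celltype`.
#' @export
dichotomize_by_mean <- function(fractions, celltype = NULL) {
  celltype <- celltype %||% attr(fractions, "m2_celltype") %||% "M2"
  if (!celltype %in% colnames(fractions))
    stop_invalid("fraction table has no column '", celltype, "'")
  f <- fractions[, celltype]
  if (length(f) < 2L) stop_invalid("need at least 2 samples to dichotomize")
  boundary <- mean(f)
  labels <- ifelse(f > boundary, "high", "low")
  names(labels) <- rownames(fractions)
  structure(list(labels = labels, boundary = boundary, celltype = celltype),
            class = "hemil_labels")
}

#' Read / write deconvolution artifacts
#'
#' Fractions travel as long CSV (`sample_id,celltype,fraction`); labels as
#' CSV (`sample_id,label`) with a JSON sidecar recording the boundary.
#'
#' @param fractions,labels objects from [deconvolve_expression()] /
#'   [dichotomize_by_mean()].
#' @param path output path (labels get a `.json` sidecar next to the CSV).
#' @return Input invisibly.
#' @export
write_fractions <- function(fractions, path) {
  df <- data.frame(
    sample_id = rep(rownames(fractions), times = ncol(fractions)),
    celltype  = rep(colnames(fractions), each = nrow(fractions)),
    fraction  = as.vector(fractions)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(fractions)
}

#' @rdname write_fractions
#' @export
read_fractions <- function(path, m2_celltype = "M2") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  samples <- unique(df$sample_id); cts <- unique(df$celltype)
  m <- matrix(NA_real_, length(samples), length(cts),
              dimnames = list(samples, cts))
  m[cbind(match(df$sample_id, samples), match(df$celltype, cts))] <- df$fraction
  structure(m, class = c("hemil_fractions", "matrix", "array"),
            m2_celltype = m2_celltype)
}

#' @rdname write_fractions
#' @export
write_labels <- function(labels, path) {
  write.csv(data.frame(sample_id = names(labels$labels),
                       label = unname(labels$labels)),
            path, row.names = FALSE)
  jsonlite::write_json(
    list(boundary = labels$boundary, celltype = labels$celltype),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(labels)
}

#' @rdname write_fractions
#' @export
read_labels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  side <- sub("\\.csv$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  labels <- df$label; names(labels) <- df$sample_id
  structure(list(labels = labels,
                 boundary = meta$boundary %||% NA_real_,
                 celltype = meta$celltype %||% "M2"),
            class = "hemil_labels")
}
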