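# Synthetic cohort generator. Emulates the statistical structure the
# downstream analysis assumes, fully offline:
#   * tile images whose brown-blob ("macrophage") density rises with a
#     latent per-patient M2 fraction,
#   * bulk expression = signature %*% fractions + truncated Gaussian noise,
#   * exponential survival whose hazard depends on the M2 group with a
#     configurable planted hazard ratio, plus uniform right censoring
#     calibrated to a requested censoring rate.
# Every output is a pure function of (spec, seed).

# run code under a temporary RNG state so generators are deterministic
# without disturbing the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic cohort specification
#'
#' Bundles every knob of the generator. Defaults mirror the study's stated
#' world where one exists (86 patients, 21 of them with zero M2 fraction,
#' i.e. `zero_inflation_prob = 21/86`); the rest are realistic desk-scale
#' choices documented in the methods vignette.
#'
#' @param n_patients cohort size (default 86).
#' @param tiles_per_patient tiles rendered per patient (default 1).
#' @param tile_size tile side in pixels (default 1120 = a 5x5 grid of
#'   224-pixel patches).
#' @param m2_mean,m2_sd mean / sd of the latent M2 fraction before
#'   truncation to (0, 1] (defaults 0.15, 0.08 — CIBERSORT-scale fractions).
#' @param zero_inflation_prob point mass at exactly 0 (default 21/86).
#' @param visual_effect strength of the M2-to-texture link: expected blob
#'   count scales as `1 + visual_effect * m2` (default 3).
#' @param base_density expected macrophage blobs per megapixel of tissue at
#'   `m2 = 0` (default 60).
#' @param tissue_cover target fraction of the tile covered by tissue
#'   (default 0.5; 0 gives a pure-white tile).
#' @param n_genes,n_celltypes size of the signature (defaults 200, 8;
#'   cell types always include `"M2"`).
#' @param expression_noise_sd noise level relative to the signature's
#'   global sd (default 0.05).
#' @param true_log_hr planted log hazard ratio, high vs low M2 (default
#'   `log(4)`, the order of the study's external-cohort estimate).
#' @param baseline_hazard events per month in the low group (default 0.02,
#'   median survival about 35 months).
#' @param censor_rate target fraction of censored patients in `[0, 1)`
#'   (default 0.3).
#' @param seed integer master seed.
#' @return List of class `hemil_cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 86L, tiles_per_patient = 1L,
                        tile_size = 1120L,
                        m2_mean = 0.15, m2_sd = 0.08,
                        zero_inflation_prob = 21 / 86,
                        visual_effect = 3, base_density = 60,
                        tissue_cover = 0.5,
                        n_genes = 200L, n_celltypes = 8L,
                        expression_noise_sd = 0.05,
                        true_log_hr = log(4), baseline_hazard = 0.02,
                        censor_rate = 0.3, seed = 1L) {
  if (n_patients < 1L || tiles_per_patient < 1L)
    stop_invalid("n_patients and tiles_per_patient must be positive")
  if (tile_size < 224L) stop_invalid("tile_size must be >= 224")
  if (m2_mean <= 0 || m2_mean >= 1 || m2_sd <= 0)
    stop_invalid("m2_mean must lie in (0,1) and m2_sd be positive")
  if (zero_inflation_prob < 0 || zero_inflation_prob >= 1)
    stop_invalid("zero_inflation_prob must lie in [0, 1)")
  if (visual_effect < 0 || base_density <= 0)
    stop_invalid("visual_effect must be >= 0 and base_density > 0")
  if (n_celltypes < 2L) stop_invalid("need at least 2 cell types")
  if (expression_noise_sd < 0) stop_invalid("expression_noise_sd must be >= 0")
  if (baseline_hazard <= 0) stop_invalid("baseline_hazard must be > 0")
  if (censor_rate < 0 || censor_rate >= 1)
    stop_invalid("censor_rate must lie in [0, 1)")
  structure(as.list(environment()), class = "hemil_cohort_spec")
}

# draw n latent M2 fractions: point mass at 0 with prob zi, else normal
# truncated to (0, 1] by inverse-CDF sampling
sample_m2_fractions <- function(n, m2_mean, m2_sd, zero_inflation_prob) {
  zero <- runif(n) < zero_inflation_prob
  lo <- pnorm(0, m2_mean, m2_sd); hi <- pnorm(1, m2_mean, m2_sd)
  u <- runif(n, lo, hi)
  f <- m2_mean + m2_sd * qnorm(u)
  f <- pmin(pmax(f, 1e-6), 1)
  f[zero] <- 0
  f
}

# paint filled disks of a given color (with per-disk jitter) into pixels,
# clipped to the tissue mask so the background stays near-white
draw_disks <- function(pixels, centers, radius, color, mask, jitter = 10) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  if (nrow(centers) == 0L) return(pixels)
  for (b in seq_len(nrow(centers))) {
    ci <- centers[b, 1]; cj <- centers[b, 2]
    r <- radius[min(b, length(radius))]
    ii <- max(1, ci - r):min(h, ci + r)
    jj <- max(1, cj - r):min(w, cj + r)
    d2 <- outer((ii - ci)^2, (jj - cj)^2, "+")
    inside <- d2 <= r^2 & mask[ii, jj]
    col <- pmin(pmax(color + rnorm(3, 0, jitter), 0), 235)
    for (ch in 1:3) {
      plane <- pixels[ii, jj, ch]
      plane[inside] <- col[ch]
      pixels[ii, jj, ch] <- plane
    }
  }
  pixels
}

#' Render one synthetic H&E-like tile
#'
#' Draws a near-white background (every background channel value >= 240),
#' eosin-pink tissue regions (a union of random ellipses reaching
#' `tissue_cover`), hematoxylin-purple nuclei, and brown "macrophage" blobs
#' whose expected count per megapixel of tissue is
#' `base_density * (1 + visual_effect * m2_level)`.
#'
#' @param m2_level latent M2 fraction in `[0, 1]`.
#' @param visual_effect strength of the M2-to-blob-density link.
#' @param tile_size side length in pixels (>= 224).
#' @param seed integer seed; the tile is a pure function of the arguments.
#' @param base_density expected blobs per megapixel of tissue at `m2 = 0`.
#' @param tissue_cover target tissue coverage in `[0, 1)`; 0 renders a
#'   pure-white tile.
#' @param source_id identifier stored on the tile.
#' @return `hemil_tile` with attributes `tissue_mask` (logical matrix),
#'   `n_m2_blobs` (blobs drawn), `blob_density` (expected blobs/Mpx) and
#'   `m2_level`.
#' @export
render_tile <- function(m2_level, visual_effect, tile_size = 1120L, seed = 1L,
                        base_density = 60, tissue_cover = 0.5,
                        source_id = "tile") {
  if (tile_size < 224L) stop_invalid("tile_size must be >= 224")
  if (m2_level < 0 || m2_level > 1) stop_invalid("m2_level must lie in [0, 1]")
  h <- w <- as.integer(tile_size)
  with_seed(seed, {
    # background: white with faint scanner noise, never below 240
    pixels <- array(pmin(pmax(250 + rnorm(h * w * 3, 0, 2), 240), 255),
                    c(h, w, 3))
    mask <- matrix(FALSE, h, w)
    if (tissue_cover > 0) {
      rows <- matrix(seq_len(h), h, w)
      cols <- matrix(seq_len(w), h, w, byrow = TRUE)
      tries <- 0L
      while (mean(mask) < tissue_cover && tries < 60L) {
        tries <- tries + 1L
        cy <- runif(1, 0.1, 0.9) * h; cx <- runif(1, 0.1, 0.9) * w
        a <- runif(1, 0.12, 0.28) * h; b <- runif(1, 0.12, 0.28) * w
        th <- runif(1, 0, pi)
        dy <- rows - cy; dx <- cols - cx
        u <- dy * cos(th) + dx * sin(th); v <- -dy * sin(th) + dx * cos(th)
        mask <- mask | (u^2 / a^2 + v^2 / b^2 <= 1)
      }
      # eosin-pink tissue with mild texture; mean RGB ~197 < 220 cutoff
      n_t <- sum(mask)
      base <- c(231, 172, 192)
      for (ch in 1:3) {
        plane <- pixels[, , ch]
        plane[mask] <- pmin(pmax(base[ch] + rnorm(n_t, 0, 6), 0), 235)
        pixels[, , ch] <- plane
      }
      tissue_px <- which(mask)
      mpx <- n_t / 1e6
      # hematoxylin nuclei: dense small purple disks
      n_nuc <- rpois(1, 800 * mpx)  # ~800 nuclei per megapixel of tissue
      if (n_nuc > 0) {
        idx <- tissue_px[sample.int(n_t, min(n_nuc, n_t), replace = TRUE)]
        centers <- cbind((idx - 1L) %% h + 1L, (idx - 1L) %/% h + 1L)
        pixels <- draw_disks(pixels, centers,
                             radius = sample(2:3, n_nuc, replace = TRUE),
                             color = c(110, 70, 150), mask = mask,
                             jitter = 12)
      }
      # macrophage blobs: brown, density tied to the M2 level
      dens <- base_density * (1 + visual_effect * m2_level)
      n_blob <- rpois(1, dens * mpx)
      if (n_blob > 0) {
        idx <- tissue_px[sample.int(n_t, min(n_blob, n_t), replace = TRUE)]
        centers <- cbind((idx - 1L) %% h + 1L, (idx - 1L) %/% h + 1L)
        pixels <- draw_disks(pixels, centers,
                             radius = sample(4:5, n_blob, replace = TRUE),
                             color = c(125, 82, 38), mask = mask,
                             jitter = 8)
      }
    } else {
      n_blob <- 0L
      dens <- 0
    }
    tile <- tile_record(round(pixels), source_id)
    attr(tile, "tissue_mask") <- mask
    attr(tile, "n_m2_blobs") <- if (tissue_cover > 0) n_blob else 0L
    attr(tile, "blob_density") <- if (tissue_cover > 0) dens else 0
    attr(tile, "m2_level") <- m2_level
    tile
  })
}

#' Generate a marker-structured signature matrix
#'
#' Each cell type receives a disjoint set of marker genes expressed about
#' eight-fold above a log-normal baseline, giving well-conditioned columns
#' for deconvolution. The first cell type is always `"M2"`.
#'
#' @param n_genes,n_celltypes dimensions.
#' @param seed integer seed.
#' @return A [signature_matrix()].
#' @export
generate_signature <- function(n_genes = 200L, n_celltypes = 8L, seed = 1L) {
  with_seed(seed, {
    cts <- c("M2", paste0("CT", seq_len(n_celltypes - 1L)))
    base <- matrix(exp(rnorm(n_genes * n_celltypes, 2, 0.5)),
                   n_genes, n_celltypes)
    markers_per <- max(1L, n_genes %/% n_celltypes)
    for (j in seq_len(n_celltypes)) {
      rows <- ((j - 1L) * markers_per + 1L):min(j * markers_per, n_genes)
      base[rows, j] <- base[rows, j] * 8
    }
    dimnames(base) <- list(sprintf("gene_%03d", seq_len(n_genes)), cts)
    signature_matrix(base, m2_celltype = "M2")
  })
}

#' Forward expression model
#'
#' `mixture = signature %*% fractions + N(0, noise_sd * sd(signature))`,
#' truncated at zero. The inverse operation is [estimate_fractions()].
#'
#' @param fractions non-negative fraction vector summing to 1, length
#'   `ncol(signature)`.
#' @param signature a [signature_matrix()].
#' @param noise_sd noise level relative to the signature's global sd.
#' @param seed integer seed.
#' @return Named mixture vector (genes).
#' @export
synthesize_expression <- function(fractions, signature, noise_sd = 0, seed = 1L) {
  if (length(fractions) != ncol(signature))
    stop_invalid("fractions length must equal ncol(signature)")
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8)
    stop_invalid("fractions must be non-negative and sum to 1")
  mix <- drop(signature %*% fractions)
  if (noise_sd > 0) {
    scale <- sd(as.vector(signature))
    mix <- with_seed(seed, pmax(mix + rnorm(length(mix), 0, noise_sd * scale), 0))
  }
  names(mix) <- rownames(signature)
  mix
}

#' Simulate exponential survival with planted group effect
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(true_log_hr * I(label == "high"))`. Censoring
#' times are uniform on `[0, tau]`, with `tau` solved (closed form of the
#' censoring probability under the exponential mixture) so the expected
#' censored fraction equals `censor_rate`.
#'
#' @param labels character vector of `"high"`/`"low"`.
#' @param true_log_hr planted log hazard ratio (high vs low).
#' @param baseline_hazard low-group hazard per month (> 0).
#' @param censor_rate target censored fraction in `[0, 1)`.
#' @param seed integer seed.
#' @param patient_id optional ids (default `P001`, ...).
#' @return A [survival_table()] with columns
#'   `patient_id, time, event, group`.
#' @export
simulate_survival <- function(labels, true_log_hr, baseline_hazard,
                              censor_rate = 0, seed = 1L, patient_id = NULL) {
  n <- length(labels)
  if (n == 0L) stop_invalid("empty label list")
  if (!all(labels %in% c("high", "low")))
    stop_invalid("labels must be 'high' or 'low'")
  if (baseline_hazard <= 0) stop_invalid("baseline_hazard must be > 0")
  if (censor_rate < 0 || censor_rate >= 1)
    stop_invalid("censor_rate must lie in [0, 1)")
  if (is.null(patient_id)) patient_id <- sprintf("P%03d", seq_len(n))
  rate <- baseline_hazard * exp(true_log_hr * (labels == "high"))
  with_seed(seed, {
    t_event <- rexp(n, rate)
    if (censor_rate > 0) {
      p_high <- mean(labels == "high")
      rates <- c(baseline_hazard, baseline_hazard * exp(true_log_hr))
      probs <- c(1 - p_high, p_high)
      # P(censored) = E[P(C < T)] = (1/tau) sum_g pi_g (1 - exp(-l_g tau)) / l_g
      pcens <- function(tau)
        sum(probs * (1 - exp(-rates * tau)) / rates) / tau - censor_rate
      tau <- uniroot(pcens, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
      t_cens <- runif(n, 0, tau)
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    } else {
      event <- rep(1L, n)
      time <- t_event
    }
    survival_table(patient_id, pmax(time, 1e-8), event, labels)
  })
}

#' Generate a complete synthetic cohort on disk
#'
#' Draws a latent M2 fraction per patient (zero-inflated truncated normal),
#' renders tiles whose blob density tracks it, synthesizes signature-based
#' bulk expression and exponential survival, and writes: PNG tiles, a
#' ground-truth CSV, an expression TSV (genes x samples), a signature TSV,
#' a survival CSV and a JSON manifest linking them.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if missing).
#' @return List of class `hemil_cohort`: `truth` (data frame), `expression`
#'   (matrix), `signature`, `survival` (data frame), `labels_true`,
#'   `tile_paths`, `manifest_path`, `spec`.
#' @export
generate_cohort <- function(spec, out_dir) {
  stopifnot(inherits(spec, "hemil_cohort_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  tile_dir <- file.path(out_dir, "tiles")
  dir.create(tile_dir, showWarnings = FALSE)

  pids <- sprintf("P%03d", seq_len(spec$n_patients))
  m2 <- with_seed(derive_seed(spec$seed, "m2_fractions"),
                  sample_m2_fractions(spec$n_patients, spec$m2_mean,
                                      spec$m2_sd, spec$zero_inflation_prob))
  true_label <- ifelse(m2 > mean(m2), "high", "low")

  # tiles
  tile_paths <- character(0)
  blob_density <- numeric(spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    for (k in seq_len(spec$tiles_per_patient)) {
      sid <- sprintf("%s_t%d", pids[i], k)
      tile <- render_tile(m2[i], spec$visual_effect, spec$tile_size,
                          seed = derive_seed(spec$seed, sid),
                          base_density = spec$base_density,
                          tissue_cover = spec$tissue_cover, source_id = sid)
      blob_density[i] <- attr(tile, "blob_density")
      p <- file.path(tile_dir, paste0(sid, ".png"))
      write_tile(tile, p)
      tile_paths <- c(tile_paths, p)
    }
  }

  # expression: full fraction vector per patient; M2 slot = latent fraction,
  # remainder spread over the other cell types by a Dirichlet draw
  signature <- generate_signature(spec$n_genes, spec$n_celltypes,
                                  seed = derive_seed(spec$seed, "signature"))
  expr <- with_seed(derive_seed(spec$seed, "fractions_rest"), {
    sapply(seq_len(spec$n_patients), function(i) {
      g <- stats::rgamma(spec$n_celltypes - 1L, shape = 2)
      fr <- c(m2[i], (1 - m2[i]) * g / sum(g))
      synthesize_expression(fr, signature, spec$expression_noise_sd,
                            seed = derive_seed(spec$seed, paste0("expr_", i)))
    })
  })
  colnames(expr) <- pids

  # survival with clinical covariates
  surv <- simulate_survival(true_label, spec$true_log_hr,
                            spec$baseline_hazard, spec$censor_rate,
                            seed = derive_seed(spec$seed, "survival"),
                            patient_id = pids)
  covs <- with_seed(derive_seed(spec$seed, "covariates"), {
    data.frame(age = round(rnorm(spec$n_patients, 60, 10)),
               stage = sample(c("I", "II", "III", "IV"), spec$n_patients,
                              replace = TRUE, prob = c(.1, .15, .45, .3)))
  })
  surv$age <- covs$age
  surv$stage <- covs$stage

  truth <- data.frame(patient_id = pids, true_m2_fraction = m2,
                      true_label = true_label, blob_density = blob_density)

  truth_path <- file.path(out_dir, "ground_truth.csv")
  expr_path  <- file.path(out_dir, "expression.tsv")
  sig_path   <- file.path(out_dir, "signature.tsv")
  surv_path  <- file.path(out_dir, "survival.csv")
  write.csv(truth, truth_path, row.names = FALSE)
  write.table(data.frame(gene_id = rownames(expr), expr,
                         check.names = FALSE),
              expr_path, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(data.frame(gene_id = rownames(signature),
                         as.data.frame(unclass(signature)),
                         check.names = FALSE),
              sig_path, sep = "\t", row.names = FALSE, quote = FALSE)
  sdf <- as.data.frame(surv)
  names(sdf)[names(sdf) == "time"] <- "time_months"
  write.csv(sdf, surv_path, row.names = FALSE)

  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- list(
    generator = "hemil synthetic cohort",
    seed = spec$seed,
    spec = spec[setdiff(names(spec), "seed")],
    files = list(tiles = basename(tile_paths),
                 ground_truth = basename(truth_path),
                 expression = basename(expr_path),
                 signature = basename(sig_path),
                 survival = basename(surv_path))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  labels_true <- truth$true_label
  names(labels_true) <- pids
  structure(list(truth = truth, expression = expr, signature = signature,
                 survival = surv, labels_true = labels_true,
                 tile_paths = tile_paths, manifest_path = manifest_path,
                 out_dir = out_dir, spec = spec),
            class = "hemil_cohort")
}
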