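# Grad-CAM: channel importances are the spatial average of the target
# class logit's gradient at the chosen (by default last) residual stage's
# output feature maps; the heatmap is the rectified importance-weighted
# sum of those maps, bilinearly upsampled to patch resolution and min-max
# scaled.

# bilinear upsampling of a matrix to (out_h, out_w), align-corners style
upsample_bilinear <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  yi <- if (h == 1L) rep(1, out_h) else seq(1, h, length.out = out_h)
  xi <- if (w == 1L) rep(1, out_w) else seq(1, w, length.out = out_w)
  y0 <- pmax(pmin(floor(yi), h - 1L), 1L); x0 <- pmax(pmin(floor(xi), w - 1L), 1L)
  y1 <- pmin(y0 + 1L, h); x1 <- pmin(x0 + 1L, w)
  fy <- yi - y0; fx <- xi - x0
  m[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
    m[y1, x0, drop = FALSE] * outer(fy, 1 - fx) +
    m[y0, x1, drop = FALSE] * outer(1 - fy, fx) +
    m[y1, x1, drop = FALSE] * outer(fy, fx)
}

#' Grad-CAM heatmap for one patch
#'
#' Computes, for the requested class, `alpha_k = mean_ij dlogit/dA_k(i,j)`
#' over the selected stage's feature maps `A_k`, then
#' `relu(sum_k alpha_k A_k)`, upsampled bilinearly to 224 x 224 and
#' min-max scaled to `[0, 1]`. An all-zero map is returned as-is with a
#' warning rather than divided by zero.
#'
#' @param model a trained `hemil_model`.
#' @param patch a `hemil_normalized_patch` (from [normalize_patch()]).
#' @param target_class `"high"` or `"low"`.
#' @param stage which residual stage's output to use (default: the last —
#'   the standard Grad-CAM choice).
#' @return List of class `hemil_heatmap`: `values` (h x w raw rectified
#'   map), `upsampled` (224 x 224 in `[0, 1]`), `target_class`, `stage`,
#'   `alpha` (channel weights).
#' @export
gradcam <- function(model, patch, target_class = c("high", "low"),
                    stage = model$config$stages) {
  stopifnot(inherits(model, "hemil_model"))
  target_class <- match.arg(target_class)
  if (length(model$config$stages) == 0L || model$config$stages < 1L)
    stop("invalid model: no convolutional stage")
  x <- as.numeric(unclass(patch))
  if (length(x) != 224 * 224 * 3)
    stop_invalid("patch must be 224 x 224 x 3")
  res <- cpp_stage_grad(model$params, unclass(model$config), x,
                        class_idx = if (target_class == "high") 1L else 0L,
                        stage = as.integer(stage))
  A <- res$features   # h x w x K
  G <- res$grad
  alpha <- apply(G, 3, mean)
  hm <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_along(alpha)) hm <- hm + alpha[k] * A[, , k]
  hm[hm < 0] <- 0
  up <- upsample_bilinear(hm, 224L, 224L)
  up[up < 0] <- 0
  if (max(up) > 0) up <- up / max(up)
  else warning("Grad-CAM heatmap is identically zero")
  structure(list(values = hm, upsampled = up, target_class = target_class,
                 stage = stage, alpha = alpha, logits = res$logits),
            class = "hemil_heatmap")
}

# simple blue -> cyan -> yellow -> red colormap on [0, 1], returns 0-255
heat_colormap <- function(v) {
  v <- pmin(pmax(v, 0), 1)
  r <- pmin(pmax(4 * v - 2, 0), 1)
  g <- pmin(pmax(ifelse(v < 0.5, 4 * v, 2 - 2 * v), 0), 1)
  b <- pmin(pmax(2 - 4 * v, 0), 1)
  list(r = r * 255, g = g * 255, b = b * 255)
}

#' Overlay a heatmap on its patch
#'
#' Alpha-blends the colormapped heatmap onto the 8-bit patch:
#' `out = (1 - alpha) * patch + alpha * colormap(heat)`.
#'
#' @param heatmap a `hemil_heatmap`.
#' @param patch the `hemil_patch` the heatmap was computed for.
#' @param alpha blend weight in `[0, 1]` (default 0.4; 0 returns the patch
#'   unchanged, 1 the pure colormap).
#' @return 224 x 224 x 3 numeric array of 8-bit values.
#' @export
overlay_heatmap <- function(heatmap, patch, alpha = 0.4) {
  if (alpha < 0 || alpha > 1) stop_invalid("alpha must lie in [0, 1]")
  cm <- heat_colormap(heatmap$upsampled)
  out <- array(0, c(224, 224, 3))
  px <- patch$pixels
  out[, , 1] <- (1 - alpha) * px[, , 1] + alpha * cm$r
  out[, , 2] <- (1 - alpha) * px[, , 2] + alpha * cm$g
  out[, , 3] <- (1 - alpha) * px[, , 3] + alpha * cm$b
  round(out)
}

#' Write Grad-CAM images
#'
#' Writes the grayscale raw heatmap and the RGB overlay as PNGs named
#' after the patch.
#'
#' @param heatmap a `hemil_heatmap`.
#' @param patch the corresponding `hemil_patch`.
#' @param dir output directory.
#' @param alpha overlay blend weight.
#' @return Character vector of the two paths, invisibly.
#' @export
write_gradcam <- function(heatmap, patch, dir, alpha = 0.4) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  raw_path <- file.path(dir, paste0(patch$patch_id, "_gradcam.png"))
  ovl_path <- file.path(dir, paste0(patch$patch_id, "_overlay.png"))
  png::writePNG(heatmap$upsampled, raw_path)
  png::writePNG(overlay_heatmap(heatmap, patch, alpha) / 255, ovl_path)
  invisible(c(raw_path, ovl_path))
}
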