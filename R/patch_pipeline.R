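# Patch extraction and preprocessing: tiling large RGB images into 224x224
# patches, background removal by a whiteness threshold, and per-channel
# standardization with the usual ImageNet moments.

#' Per-channel standardization constants
#'
#' Channel means and standard deviations (RGB, on the \code{[0, 1]} scale)
#' used by [normalize_patch()]. These are the ImageNet moments that
#' ResNet-style backbones conventionally expect:
#' means (0.485, 0.456, 0.406) and standard deviations (0.229, 0.224, 0.225).
#' @format Numeric vectors of length 3.
#' @name norm-constants
#' @keywords internal
NULL

.patch_mean <- c(0.485, 0.456, 0.406)
.patch_sd   <- c(0.229, 0.224, 0.225)

#' Construct a tile image
#'
#' A tile is an 8-bit RGB image (values 0--255) with a source identifier. It
#' stands in for one region of a whole-slide image; at desk scale a "slide"
#' is simply a set of tiles.
#'
#' @param pixels integer/numeric array of dimension `c(H, W, 3)`, values in
#'   `[0, 255]`.
#' @param source_id character scalar naming the tile's origin.
#' @return An object of class `hemil_tile`.
#' @export
tile_record <- function(pixels, source_id) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stop_invalid("tile pixels must be an H x W x 3 array")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop_invalid("tile pixel values must lie in [0, 255]")
  structure(list(pixels = pixels, source_id = as.character(source_id)),
            class = "hemil_tile")
}

#' Read / write a tile as PNG
#'
#' Thin wrappers over the \pkg{png} package; tiles are stored as 8-bit RGB.
#'
#' @param path file path.
#' @param source_id identifier recorded on the tile; defaults to the file
#'   name without extension.
#' @return `read_tile()` returns a `hemil_tile`; `write_tile()` returns
#'   `path` invisibly.
#' @export
read_tile <- function(path, source_id = sub("\\.[^.]*$", "", basename(path))) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img <- img[, , 1:3, drop = FALSE]  # drop alpha if present
  tile_record(round(img * 255), source_id)
}

#' @rdname read_tile
#' @param tile a `hemil_tile`.
#' @export
write_tile <- function(tile, path) {
  png::writePNG(tile$pixels / 255, path)
  invisible(path)
}

#' Cut a tile into a grid of fixed-size patches
#'
#' Tiles the image with a row-major grid of `tile_size` x `tile_size`
#' windows at the given stride. Partial windows at the right/bottom border
#' are dropped (not padded), so the grid covers only complete windows. The
#' top-left pixel of patch `(r, c)` is image pixel `(r * stride, c * stride)`
#' in 0-based coordinates.
#'
#' @param image a `hemil_tile`.
#' @param tile_size patch side length in pixels (default 224).
#' @param stride grid stride in pixels (default `tile_size`: non-overlapping).
#' @return List of `hemil_patch` records in row-major grid order. Each has
#'   fields `patch_id`, `source_id`, `grid_row`, `grid_col` (0-based),
#'   `pixels` (tile_size x tile_size x 3) and `tissue_fraction`.
#' @export
tile_image <- function(image, tile_size = 224L, stride = tile_size) {
  stopifnot(inherits(image, "hemil_tile"))
  d <- dim(image$pixels)
  if (d[1] < tile_size || d[2] < tile_size)
    stop_invalid("image (", d[1], "x", d[2], ") smaller than tile_size ", tile_size)
  n_rows <- (d[1] - tile_size) %/% stride + 1L
  n_cols <- (d[2] - tile_size) %/% stride + 1L
  out <- vector("list", n_rows * n_cols)
  k <- 0L
  for (r in seq_len(n_rows) - 1L) {
    for (cc in seq_len(n_cols) - 1L) {
      px <- image$pixels[r * stride + seq_len(tile_size),
                         cc * stride + seq_len(tile_size), , drop = FALSE]
      k <- k + 1L
      p <- structure(list(
        patch_id  = sprintf("%s_r%d_c%d", image$source_id, r, cc),
        source_id = image$source_id,
        grid_row  = r, grid_col = cc,
        pixels    = px, tissue_fraction = NA_real_
      ), class = "hemil_patch")
      p$tissue_fraction <- tissue_fraction(p)
      out[[k]] <- p
    }
  }
  out
}

#' Fraction of non-background pixels in a patch
#'
#' H&E background is near-white, so a pixel is counted as tissue when its
#' mean over the three channels is strictly below `whiteness_cutoff`.
#'
#' @param patch a `hemil_patch`.
#' @param whiteness_cutoff mean-RGB threshold in 0--255 (default 220).
#' @return Tissue fraction in `[0, 1]`.
#' @export
tissue_fraction <- function(patch, whiteness_cutoff = 220) {
  px <- patch$pixels
  m <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  mean(m < whiteness_cutoff)
}

#' Drop background patches
#'
#' Retains patches whose tissue fraction is at least `min_tissue_fraction`
#' (i.e. discards patches that are more than `1 - min_tissue_fraction`
#' background), preserving order.
#'
#' @param patches list of `hemil_patch`.
#' @param min_tissue_fraction minimum tissue fraction to keep (default 0.05,
#'   i.e. patches that are >= 95% background are discarded).
#' @param whiteness_cutoff passed to [tissue_fraction()] when a patch has no
#'   cached fraction.
#' @return Filtered list; the number retained is reported via `message()`.
#' @export
filter_background <- function(patches, min_tissue_fraction = 0.05,
                              whiteness_cutoff = 220) {
  if (length(patches) == 0L) return(patches)
  tf <- vapply(patches, function(p) {
    if (is.na(p$tissue_fraction)) tissue_fraction(p, whiteness_cutoff)
    else p$tissue_fraction
  }, numeric(1))
  keep <- tf >= min_tissue_fraction
  message(sprintf("filter_background: retained %d / %d patches",
                  sum(keep), length(patches)))
  patches[keep]
}

#' Standardize a patch for the classifier
#'
#' Maps 8-bit pixels to `(pixel / 255 - mean_c) / sd_c` per channel, with
#' the conventional ImageNet means/standard deviations (see
#' \link{norm-constants}). The transform is affine and invertible
#' ([denormalize_patch()]).
#'
#' @param patch a `hemil_patch` (224 x 224 x 3).
#' @return Numeric array `c(224, 224, 3)` of class `hemil_normalized_patch`;
#'   channel order RGB.
#' @export
normalize_patch <- function(patch) {
  px <- patch$pixels
  out <- array(0, dim(px))
  for (ch in 1:3) out[, , ch] <- (px[, , ch] / 255 - .patch_mean[ch]) / .patch_sd[ch]
  structure(out, class = "hemil_normalized_patch",
            patch_id = patch$patch_id, source_id = patch$source_id)
}

#' @rdname normalize_patch
#' @param values a `hemil_normalized_patch` (or plain array on the
#'   standardized scale).
#' @return `denormalize_patch()` returns the pixel array on the `[0, 1]`
#'   scale.
#' @export
denormalize_patch <- function(values) {
  out <- array(0, dim(values))
  for (ch in 1:3) out[, , ch] <- values[, , ch] * .patch_sd[ch] + .patch_mean[ch]
  out
}

#' Write a patch manifest
#'
#' @param patches list of `hemil_patch`.
#' @param path CSV output path.
#' @return The manifest data frame, invisibly.
#' @export
write_patch_manifest <- function(patches, path) {
  df <- data.frame(
    patch_id  = vapply(patches, `[[`, "", "patch_id"),
    source_id = vapply(patches, `[[`, "", "source_id"),
    grid_row  = vapply(patches, `[[`, 0L, "grid_row"),
    grid_col  = vapply(patches, `[[`, 0L, "grid_col"),
    tissue_fraction = vapply(patches, `[[`, 0, "tissue_fraction")
  )
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
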