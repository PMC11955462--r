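# Patch classifier: configurable residual backbone (ResNet-18 by default),
# patient-level stratified split, SGD-momentum training with
# best-checkpoint selection, and per-patch class probabilities. The
# numerical heavy lifting lives in src/resnet.cpp.

#' Backbone configuration
#'
#' The weighted-layer count is `1 + stages * blocks_per_stage * 2 + 1`
#' (stem conv + two convs per basic block + the final fully connected
#' layer); the default 4 stages x 2 blocks gives the classical
#' 18-layer residual network.
#'
#' @param stages number of residual stages (default 4).
#' @param blocks_per_stage basic blocks per stage (default 2).
#' @param base_width channels of the first stage (default 64; doubles per
#'   stage).
#' @param n_classes output classes (fixed 2 for high/low M2).
#' @param pretrained_weights_path optional path to a weight file saved by
#'   [save_checkpoint()]; loaded instead of random initialization.
#' @param freeze_up_to_stage freeze the stem and stages `1..k` during
#'   training (`-1`, the default, trains everything; the study fine-tuned
#'   only the deeper blocks of a pretrained net).
#' @return List of class `hemil_backbone_config`.
#' @export
backbone_config <- function(stages = 4L, blocks_per_stage = 2L,
                            base_width = 64L, n_classes = 2L,
                            pretrained_weights_path = NULL,
                            freeze_up_to_stage = -1L) {
  if (stages < 1L || blocks_per_stage < 1L || base_width < 1L)
    stop_invalid("stages, blocks_per_stage and base_width must be positive")
  if (n_classes != 2L) stop_invalid("n_classes is fixed at 2")
  structure(list(stages = as.integer(stages),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 base_width = as.integer(base_width),
                 n_classes = 2L,
                 pretrained_weights_path = pretrained_weights_path,
                 freeze_up_to_stage = as.integer(freeze_up_to_stage)),
            class = "hemil_backbone_config")
}

# He-normal conv weight array dim c(kh, kw, cin, cout)
init_conv <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / fan_in)),
        c(kh, kw, cin, cout))
}

init_bn <- function(params, prefix, channels) {
  params[[paste0(prefix, ".gamma")]] <- rep(1, channels)
  params[[paste0(prefix, ".beta")]]  <- rep(0, channels)
  params[[paste0(prefix, ".rm")]]    <- rep(0, channels)
  params[[paste0(prefix, ".rv")]]    <- rep(1, channels)
  params
}

#' Build a residual backbone
#'
#' Initializes all weights (He-normal convolutions, unit-gamma batch norm,
#' small-normal linear head) under the current RNG state, or loads them
#' from `config$pretrained_weights_path`.
#'
#' @param config a [backbone_config()].
#' @param seed optional integer; when given, initialization is performed
#'   under this seed without disturbing the caller's RNG stream.
#' @return Object of class `hemil_model`: list with `params` (named flat
#'   list of weight arrays), `config`, `trained`, `history`.
#' @export
build_backbone <- function(config = backbone_config(), seed = NULL) {
  stopifnot(inherits(config, "hemil_backbone_config"))
  if (!is.null(config$pretrained_weights_path)) {
    model <- load_checkpoint(config$pretrained_weights_path)
    for (f in c("stages", "blocks_per_stage", "base_width", "n_classes")) {
      if (!identical(as.integer(model$config[[f]]), as.integer(config[[f]])))
        stop("pretrained weights were built for a different backbone (",
             f, " mismatch)")
    }
    model$config <- config
    return(model)
  }
  build <- function() {
    params <- list()
    params[["conv1.w"]] <- init_conv(7, 7, 3, config$base_width)
    params <- init_bn(params, "bn1", config$base_width)
    cin <- config$base_width
    for (s in seq_len(config$stages)) {
      cout <- config$base_width * 2^(s - 1L)
      for (b in seq_len(config$blocks_per_stage)) {
        px <- sprintf("s%d.b%d", s, b)
        params[[paste0(px, ".conv1.w")]] <- init_conv(3, 3, cin, cout)
        params <- init_bn(params, paste0(px, ".bn1"), cout)
        params[[paste0(px, ".conv2.w")]] <- init_conv(3, 3, cout, cout)
        params <- init_bn(params, paste0(px, ".bn2"), cout)
        if (s > 1L && b == 1L || cin != cout) {
          params[[paste0(px, ".down.w")]] <- init_conv(1, 1, cin, cout)
          params <- init_bn(params, paste0(px, ".downbn"), cout)
        }
        cin <- cout
      }
    }
    params[["fc.w"]] <- matrix(rnorm(2 * cin, 0, 0.01), 2, cin)
    params[["fc.b"]] <- c(0, 0)
    structure(list(params = params, config = config, trained = FALSE,
                   history = NULL),
              class = "hemil_model")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Count weighted layers
#'
#' Convolutional plus fully connected layers, excluding batch-norm layers
#' and the 1x1 projection shortcuts — the counting convention under which
#' the default backbone has `1 + 4 * 4 + 1 = 18` layers.
#'
#' @param model a `hemil_model`.
#' @return Integer layer count.
#' @export
count_weighted_layers <- function(model) {
  stopifnot(inherits(model, "hemil_model"))
  nm <- names(model$params)
  if (!"fc.w" %in% nm)
    stop("invalid model: final fully connected layer is missing")
  convs <- grepl("\\.conv[0-9]+\\.w$|^conv1\\.w$", nm)
  sum(convs) + 1L
}

#' @export
print.hemil_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "hemil residual backbone: %d stages x %d blocks, base width %d, %d weighted layers%s\n",
    cfg$stages, cfg$blocks_per_stage, cfg$base_width,
    count_weighted_layers(x), if (x$trained) " (trained)" else ""))
  invisible(x)
}

#' Training configuration
#'
#' Defaults follow the study's recipe: cross-entropy loss, SGD with
#' momentum 0.9, learning rate 0.001, 25 epochs, an 80/20 split. Batch
#' size (not stated there) defaults to 32.
#'
#' @param learning_rate SGD learning rate (> 0).
#' @param momentum SGD momentum.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param split_ratio training fraction in (0, 1).
#' @param split_unit `"patient"` (default; whole patients on one side only,
#'   no leakage) or `"patch"`.
#' @param seed integer seed for the split, initialization and shuffling.
#' @return List of class `hemil_train_config`.
#' @export
train_config <- function(learning_rate = 0.001, momentum = 0.9,
                         epochs = 25L, batch_size = 32L, split_ratio = 0.8,
                         split_unit = c("patient", "patch"), seed = 1L) {
  split_unit <- match.arg(split_unit)
  if (learning_rate <= 0) stop_invalid("learning_rate must be > 0")
  if (split_ratio <= 0 || split_ratio >= 1)
    stop_invalid("split_ratio must lie in (0, 1)")
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 split_ratio = split_ratio, split_unit = split_unit,
                 seed = as.integer(seed)),
            class = "hemil_train_config")
}

#' Label-stratified patient split
#'
#' Assigns whole bags (patients) to train or validation, stratified by
#' label so both classes appear on both sides; the training size is
#' `round(split_ratio * n)` with per-class counts by largest remainder.
#' Deterministic given `config$seed`.
#'
#' @param bags list of [bag_record()]s.
#' @param config a [train_config()].
#' @return List `train_bags`, `val_bags` (with `split` fields set).
#' @export
split_cohort <- function(bags, config = train_config()) {
  if (length(bags) < 2L) stop_invalid("need at least 2 bags to split")
  labels <- vapply(bags, `[[`, "", "label")
  if (length(unique(labels)) < 2L)
    stop_invalid("stratification impossible: single-class cohort")
  n <- length(bags)
  n_train <- round(config$split_ratio * n)
  classes <- sort(unique(labels))
  exact <- config$split_ratio * table(labels)[classes]
  base <- floor(exact)
  rem <- n_train - sum(base)
  if (rem > 0) {
    order_rem <- order(exact - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
  }
  idx_train <- integer(0)
  with_seed(config$seed, {
    for (cl in classes) {
      ix <- which(labels == cl)
      idx_train <- c(idx_train, ix[sample.int(length(ix), base[[cl]])])
    }
  })
  assign_split <- function(b, s) { b$split <- s; b }
  list(train_bags = lapply(bags[sort(idx_train)], assign_split, "train"),
       val_bags = lapply(bags[setdiff(seq_len(n), idx_train)],
                         assign_split, "val"))
}

#' Assemble a patch dataset for the classifier
#'
#' Normalizes each patch and flattens it into one column of the design
#' matrix; labels are inherited from the patch's bag.
#'
#' @param patches list of `hemil_patch` (224 x 224 x 3).
#' @param bags list of [bag_record()]s that own the patches; each patch's
#'   `patch_id` must appear in exactly one bag.
#' @return List of class `hemil_patch_dataset`: `x` (matrix, one patch per
#'   column), `y` (0 = low, 1 = high), `patch_id`, `patient_id`.
#' @export
patch_dataset <- function(patches, bags) {
  if (length(patches) == 0L) stop_invalid("empty patch list")
  owner <- unlist(lapply(bags, function(b)
    stats::setNames(rep(b$patient_id, length(b$patch_ids)), b$patch_ids)))
  lab <- unlist(lapply(bags, function(b)
    stats::setNames(rep(b$label, length(b$patch_ids)), b$patch_ids)))
  ids <- vapply(patches, `[[`, "", "patch_id")
  if (!all(ids %in% names(owner)))
    stop_invalid("some patches belong to no bag: ",
                 paste(utils::head(setdiff(ids, names(owner)), 3), collapse = ", "))
  x <- vapply(patches, function(p) as.vector(unclass(normalize_patch(p))),
              numeric(224 * 224 * 3))
  structure(list(x = x, y = as.integer(lab[ids] == "high"),
                 patch_id = ids, patient_id = unname(owner[ids])),
            class = "hemil_patch_dataset")
}

#' Train the patch classifier
#'
#' Cross-entropy loss, SGD with momentum, fixed epoch budget. After every
#' epoch the model is scored on the validation patches and a checkpoint is
#' kept whenever validation accuracy strictly exceeds the running best
#' (ties keep the earlier epoch); the returned model carries those best
#' weights.
#'
#' @param model a `hemil_model` from [build_backbone()].
#' @param train_data,val_data [patch_dataset()]s.
#' @param config a [train_config()].
#' @return The trained `hemil_model` carrying the best-checkpoint weights;
#'   `$history` holds one row per epoch (`epoch, train_loss,
#'   train_accuracy, val_accuracy, is_best`) where `is_best` marks the
#'   single checkpointed epoch, and `$final_params` keeps the last-epoch
#'   weights.
#' @export
train_classifier <- function(model, train_data, val_data,
                             config = train_config()) {
  stopifnot(inherits(model, "hemil_model"),
            inherits(train_data, "hemil_patch_dataset"))
  if (length(train_data$y) == 0L) stop_invalid("empty training set")
  res <- cpp_train(model$params, unclass(model$config),
                   train_data$x, train_data$y,
                   val_data$x, val_data$y,
                   config$learning_rate, config$momentum, config$epochs,
                   config$batch_size, config$seed,
                   model$config$freeze_up_to_stage %||% -1L)
  history <- data.frame(epoch = as.integer(res$epoch),
                        train_loss = res$train_loss,
                        train_accuracy = res$train_accuracy,
                        val_accuracy = res$val_accuracy)
  history$is_best <- history$epoch == res$best_epoch
  model$params <- res$best_params
  model$trained <- TRUE
  model$history <- history
  model$best_epoch <- res$best_epoch
  model$best_val_accuracy <- res$best_val_accuracy
  # weights after the last epoch, for callers who want the fully trained
  # model rather than the first best checkpoint
  model$final_params <- res$final_params
  model
}

#' Per-patch class probabilities
#'
#' Softmax probability of the `"high"` class for every patch, computed in
#' evaluation mode (batch norm uses running statistics); deterministic for
#' fixed weights.
#'
#' @param model a `hemil_model`.
#' @param data a [patch_dataset()].
#' @return Data frame `patch_id, patient_id, prob_high`.
#' @export
predict_patch_probs <- function(model, data) {
  stopifnot(inherits(model, "hemil_model"),
            inherits(data, "hemil_patch_dataset"))
  probs <- cpp_predict(model$params, unclass(model$config), data$x)
  data.frame(patch_id = data$patch_id, patient_id = data$patient_id,
             prob_high = probs[, 2], stringsAsFactors = FALSE)
}

#' Save / load model checkpoints
#'
#' Weights are serialized to an RDS file with a JSON sidecar recording the
#' backbone configuration and, for trained models, the checkpointed epoch
#' and its validation accuracy.
#'
#' @param model a `hemil_model`.
#' @param path output path (`.rds`).
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  meta <- list(stages = model$config$stages,
               blocks_per_stage = model$config$blocks_per_stage,
               base_width = model$config$base_width,
               n_classes = model$config$n_classes,
               trained = model$trained,
               best_epoch = model$best_epoch %||% NA,
               best_val_accuracy = model$best_val_accuracy %||% NA)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "hemil_model"))
    stop("file does not contain a hemil model: ", path)
  model
}
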