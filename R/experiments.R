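# Canned desk-scale experiments: the reference end-to-end configuration
# and a label-shuffled no-signal control over a completed run.

#' Desk-scale end-to-end experiment configuration
#'
#' The reference synthetic experiment: 40 patients, one 448-pixel tile
#' each (four 224-pixel patches), a strong planted visual effect (dense
#' macrophage blobs, wide latent-fraction spread, near-full tissue cover),
#' a reduced residual backbone (2 stages, 1 block, width 16) trained from
#' random initialization for 20 epochs on one CPU (learning rate 0.02,
#' batch 16 -- from-scratch training needs a stronger recipe than the
#' fine-tuning schedule), all four MIL pooling strategies, and the
#' survival arm with a planted hazard ratio of 4. Parameter choices are
#' discussed in the methods vignette.
#'
#' @param out_dir run directory.
#' @param seed global seed.
#' @return A `hemil_run_config`.
#' @export
e2e_demo_config <- function(out_dir, seed = 1L) {
  cfg <- default_run_config(out_dir = out_dir, seed = seed)
  cfg$cohort$n_patients <- 40L
  cfg$cohort$tiles_per_patient <- 1L
  cfg$cohort$tile_size <- 448L
  cfg$cohort$tissue_cover <- 0.95
  cfg$cohort$visual_effect <- 8
  cfg$cohort$base_density <- 400
  cfg$cohort$m2_mean <- 0.15
  cfg$cohort$m2_sd <- 0.15
  cfg$cohort$zero_inflation_prob <- 0
  cfg$cohort$n_genes <- 120L
  cfg$cohort$n_celltypes <- 8L
  cfg$backbone <- list(stages = 2L, blocks_per_stage = 1L, base_width = 16L)
  cfg$training$learning_rate <- 0.02
  cfg$training$batch_size <- 16L
  cfg$training$epochs <- 20L
  cfg$gradcam$n_examples <- 2L
  cfg
}

#' Label-shuffled control experiment
#'
#' Re-trains the classifier of a completed run with bag labels randomly
#' permuted across patients (class counts preserved, split assignments
#' kept), then scores the validation bags against the shuffled labels.
#' With no label-image association left, the bag AUC should hover around
#' chance; it is the negative control for the planted-signal experiment.
#'
#' @param run_dir directory of a completed [run_pipeline()] run.
#' @param seed integer seed for the permutation, re-initialization and
#'   training.
#' @param epochs training epochs for the control fit.
#' @param strategy MIL pooling strategy to score (default `"mean"`).
#' @return Validation-bag AUC under the shuffled labels (scalar).
#' @export
shuffled_label_control <- function(run_dir, seed, epochs = 10L,
                                   strategy = "mean") {
  patches_path <- file.path(run_dir, "patches_filtered.rds")
  bags_path <- file.path(run_dir, "bags.csv")
  model_path <- file.path(run_dir, "model.rds")
  if (!all(file.exists(c(patches_path, bags_path, model_path))))
    stop("run directory lacks patches/bags/model artifacts: ", run_dir)

  bag_df <- read.csv(bags_path, stringsAsFactors = FALSE)
  bag_df <- bag_df[order(bag_df$patient_id), ]
  shuffled <- with_seed(derive_seed(seed, "shuffle"),
                        sample(bag_df$label))
  bag_df$label <- shuffled

  patches <- readRDS(patches_path)
  ids <- vapply(patches, `[[`, "", "patch_id")
  pat <- sub("_t[0-9]+$", "", vapply(patches, `[[`, "", "source_id"))
  mk <- function(rows) {
    bags <- lapply(rows, function(i)
      bag_record(bag_df$patient_id[i], ids[pat == bag_df$patient_id[i]],
                 bag_df$label[i], bag_df$split[i]))
    patch_dataset(patches[pat %in% bag_df$patient_id[rows]], bags)
  }
  tr <- mk(which(bag_df$split == "train"))
  va <- mk(which(bag_df$split == "val"))

  cfg <- load_checkpoint(model_path)$config
  cfg$pretrained_weights_path <- NULL
  model <- build_backbone(cfg, seed = derive_seed(seed, "init"))
  model <- train_classifier(model, tr, va,
                            train_config(epochs = epochs,
                                         seed = derive_seed(seed, "train")))
  preds <- predict_patch_probs(model, va)
  bp <- predict_bags(preds, strategies = strategy)
  val_truth <- stats::setNames(bag_df$label, bag_df$patient_id)
  auc_roc(unname(val_truth[bp$patient_id]), bp$bag_prob)
}
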