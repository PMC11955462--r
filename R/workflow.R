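# Configuration-driven orchestration of the full study loop:
# simulate -> tile (+ background filter) -> deconvolve -> label -> split ->
# train -> predict -> aggregate -> evaluate -> gradcam -> survival.
# Every stage writes its artifacts under the run directory and is recorded
# (with output checksums) in a JSON manifest; completed stages are skipped
# on re-run when their outputs still match the recorded checksums.

PIPELINE_STAGES <- c("simulate", "tile", "deconvolve", "label", "split",
                     "train", "predict", "aggregate", "evaluate",
                     "gradcam", "survival")

#' Default run configuration
#'
#' Nested list covering every pipeline stage; amend it with
#' `modifyList()`-style overrides or load one from YAML/JSON via
#' [read_run_config()]. The global `seed` is re-derived per stage, so each
#' stage is independently reproducible.
#'
#' @param out_dir run directory.
#' @param seed global integer seed.
#' @return Nested list of class `hemil_run_config`.
#' @export
default_run_config <- function(out_dir = "hemil_run", seed = 1L) {
  structure(list(
    out_dir = out_dir,
    seed = as.integer(seed),
    cohort = list(n_patients = 40L, tiles_per_patient = 1L, tile_size = 448L,
                  m2_mean = 0.15, m2_sd = 0.08, zero_inflation_prob = 0,
                  visual_effect = 4, base_density = 60, tissue_cover = 0.6,
                  n_genes = 200L, n_celltypes = 8L,
                  expression_noise_sd = 0.05, true_log_hr = log(4),
                  baseline_hazard = 0.02, censor_rate = 0.3),
    tiling = list(tile_size = 224L, stride = 224L),
    filtering = list(min_tissue_fraction = 0.05, whiteness_cutoff = 220),
    deconvolution = list(nu_grid = c(0.25, 0.5, 0.75), cost = 1),
    labels_from = "deconvolution",   # or "truth" for pure-imaging runs
    backbone = list(stages = 2L, blocks_per_stage = 1L, base_width = 16L),
    training = list(learning_rate = 0.001, momentum = 0.9, epochs = 12L,
                    batch_size = 32L, split_ratio = 0.8,
                    split_unit = "patient"),
    mil = list(strategies = c("mean", "top10", "top100", "max"),
               threshold = 0.5),
    gradcam = list(n_examples = 2L),
    survival = list(covariates = c("group", "age", "stage"))
  ), class = "hemil_run_config")
}

#' Read / write a run configuration (YAML or JSON by extension)
#'
#' @param path configuration file.
#' @return A `hemil_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- utils::modifyList(unclass(default_run_config()), raw)
  class(cfg) <- "hemil_run_config"
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config a `hemil_run_config`.
#' @export
write_run_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(unclass(config), path)
  else jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                            digits = NA, pretty = TRUE)
  invisible(path)
}

validate_run_config <- function(config) {
  required <- c("out_dir", "seed", "cohort", "tiling", "filtering",
                "deconvolution", "labels_from", "backbone", "training",
                "mil", "gradcam", "survival")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("invalid run config; missing fields: ",
         paste(missing, collapse = ", "))
  if (!config$labels_from %in% c("deconvolution", "truth"))
    stop("invalid run config; labels_from must be 'deconvolution' or 'truth'")
  config
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

file_checksums <- function(paths) {
  as.list(stats::setNames(unname(tools::md5sum(paths)), basename(paths)))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in canonical order
#' (`simulate, tile, deconvolve, label, split, train, predict, aggregate,
#' evaluate, gradcam, survival`), writing every intermediate artifact under
#' `config$out_dir` and a `run_manifest.json` recording the configuration
#' hash, per-stage output checksums and metric summaries. A stage whose
#' outputs already exist with matching checksums is not recomputed; a
#' stage whose upstream artifacts are absent raises a dependency error
#' naming the stage to run first.
#'
#' @param config a `hemil_run_config`.
#' @param stages character vector of stages to run, or `"all"`.
#' @return The manifest (list), invisibly. Its `metrics` entry holds one
#'   object per MIL strategy on the validation split.
#' @export
run_pipeline <- function(config = default_run_config(), stages = "all") {
  config <- validate_run_config(config)
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  man_path <- file.path(out, "run_manifest.json")
  manifest <- if (file.exists(man_path))
    jsonlite::read_json(man_path, simplifyVector = FALSE)
  else list(stages = list())
  manifest$config_hash <- config_hash(config)
  manifest$seed <- config$seed

  paths <- list(
    cohort_dir = file.path(out, "cohort"),
    patches = file.path(out, "patches_filtered.rds"),
    patch_manifest = file.path(out, "patch_manifest.csv"),
    fractions = file.path(out, "fractions.csv"),
    labels = file.path(out, "labels.csv"),
    bags = file.path(out, "bags.csv"),
    model = file.path(out, "model.rds"),
    history = file.path(out, "train_history.csv"),
    instance_preds = file.path(out, "instance_predictions.csv"),
    bag_preds = file.path(out, "bag_predictions.csv"),
    metrics = file.path(out, "metrics.json"),
    gradcam_dir = file.path(out, "gradcam"),
    km = file.path(out, "km_curves.csv"),
    cox_uni = file.path(out, "cox_univariate.csv"),
    cox_multi = file.path(out, "cox_multivariate.csv"),
    logrank = file.path(out, "logrank.json")
  )

  done <- function(name, outputs) {
    rec <- manifest$stages[[name]]
    if (is.null(rec)) return(FALSE)
    if (!all(file.exists(outputs))) return(FALSE)
    identical(unname(unlist(rec$checksums)),
              unname(unlist(file_checksums(outputs))))
  }
  record <- function(name, outputs) {
    manifest$stages[[name]] <<- list(status = "completed",
                                     outputs = basename(outputs),
                                     checksums = file_checksums(outputs))
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  need <- function(path, stage, producer) {
    if (!all(file.exists(path)))
      stop("stage '", stage, "' is missing upstream artifacts (",
           paste(basename(path[!file.exists(path)]), collapse = ", "),
           "); run stage '", producer, "' first")
  }

  sseed <- function(stage) derive_seed(config$seed, stage)

  ## ---- simulate -------------------------------------------------------
  if ("simulate" %in% stages) {
    coh_manifest <- file.path(paths$cohort_dir, "manifest.json")
    if (!done("simulate", coh_manifest)) {
      spec <- do.call(cohort_spec, c(config$cohort,
                                     list(seed = sseed("simulate"))))
      generate_cohort(spec, paths$cohort_dir)
      record("simulate", coh_manifest)
    } else message("simulate: up to date, skipping")
  }

  ## ---- tile + filter --------------------------------------------------
  if ("tile" %in% stages) {
    need(file.path(paths$cohort_dir, "manifest.json"), "tile", "simulate")
    if (!done("tile", c(paths$patches, paths$patch_manifest))) {
      tile_files <- list.files(file.path(paths$cohort_dir, "tiles"),
                               full.names = TRUE, pattern = "\\.png$")
      patches <- list()
      for (tf in tile_files) {
        tl <- read_tile(tf)
        patches <- c(patches,
                     tile_image(tl, config$tiling$tile_size,
                                config$tiling$stride))
      }
      patches <- suppressMessages(filter_background(
        patches, config$filtering$min_tissue_fraction,
        config$filtering$whiteness_cutoff))
      saveRDS(patches, paths$patches)
      write_patch_manifest(patches, paths$patch_manifest)
      record("tile", c(paths$patches, paths$patch_manifest))
    } else message("tile: up to date, skipping")
  }

  ## ---- deconvolve -----------------------------------------------------
  if ("deconvolve" %in% stages) {
    expr_path <- file.path(paths$cohort_dir, "expression.tsv")
    sig_path <- file.path(paths$cohort_dir, "signature.tsv")
    need(c(expr_path, sig_path), "deconvolve", "simulate")
    if (!done("deconvolve", paths$fractions)) {
      expr <- as.matrix(read.delim(expr_path, row.names = 1,
                                   check.names = FALSE))
      sig <- signature_matrix(as.matrix(
        read.delim(sig_path, row.names = 1, check.names = FALSE)))
      fr <- deconvolve_expression(expr, sig,
                                  nu_grid = config$deconvolution$nu_grid,
                                  cost = config$deconvolution$cost)
      write_fractions(fr, paths$fractions)
      record("deconvolve", paths$fractions)
    } else message("deconvolve: up to date, skipping")
  }

  ## ---- label ----------------------------------------------------------
  if ("label" %in% stages) {
    if (!done("label", paths$labels)) {
      if (config$labels_from == "deconvolution") {
        need(paths$fractions, "label", "deconvolve")
        fr <- read_fractions(paths$fractions)
      } else {
        truth_path <- file.path(paths$cohort_dir, "ground_truth.csv")
        need(truth_path, "label", "simulate")
        truth <- read.csv(truth_path)
        fr <- matrix(truth$true_m2_fraction, ncol = 1,
                     dimnames = list(truth$patient_id, "M2"))
        class(fr) <- c("hemil_fractions", "matrix", "array")
        attr(fr, "m2_celltype") <- "M2"
      }
      fr <- suppressMessages(exclude_zero_m2(fr))
      labels <- dichotomize_by_mean(fr)
      write_labels(labels, paths$labels)
      record("label", paths$labels)
    } else message("label: up to date, skipping")
  }

  ## ---- split ----------------------------------------------------------
  if ("split" %in% stages) {
    need(c(paths$labels, paths$patch_manifest), "split", "label")
    if (!done("split", paths$bags)) {
      labels <- read_labels(paths$labels)
      pm <- read.csv(paths$patch_manifest)
      pm$patient_id <- sub("_t[0-9]+$", "", pm$source_id)
      pm <- pm[pm$patient_id %in% names(labels$labels), ]
      bags <- lapply(split(pm, pm$patient_id), function(d)
        bag_record(d$patient_id[1], d$patch_id,
                   labels$labels[[d$patient_id[1]]]))
      sp <- split_cohort(bags, train_config(
        split_ratio = config$training$split_ratio,
        split_unit = config$training$split_unit,
        seed = sseed("split")))
      all_bags <- c(sp$train_bags, sp$val_bags)
      bag_df <- data.frame(
        patient_id = vapply(all_bags, `[[`, "", "patient_id"),
        label = vapply(all_bags, `[[`, "", "label"),
        split = vapply(all_bags, `[[`, "", "split"),
        n_patches = vapply(all_bags, function(b) length(b$patch_ids), 0L))
      write.csv(bag_df[order(bag_df$patient_id), ], paths$bags,
                row.names = FALSE)
      record("split", paths$bags)
    } else message("split: up to date, skipping")
  }

  ## ---- train ----------------------------------------------------------
  if ("train" %in% stages) {
    need(c(paths$bags, paths$patches), "train", "split")
    if (!done("train", c(paths$model, paths$history))) {
      ds <- load_split_datasets(paths)
      model <- build_backbone(
        do.call(backbone_config, config$backbone), seed = sseed("init"))
      tcfg <- train_config(
        learning_rate = config$training$learning_rate,
        momentum = config$training$momentum,
        epochs = config$training$epochs,
        batch_size = config$training$batch_size,
        seed = sseed("train"))
      model <- train_classifier(model, ds$train, ds$val, tcfg)
      save_checkpoint(model, paths$model)
      write.csv(model$history, paths$history, row.names = FALSE)
      record("train", c(paths$model, paths$history))
    } else message("train: up to date, skipping")
  }

  ## ---- predict --------------------------------------------------------
  if ("predict" %in% stages) {
    need(c(paths$model, paths$patches, paths$bags), "predict", "train")
    if (!done("predict", paths$instance_preds)) {
      ds <- load_split_datasets(paths)
      model <- load_checkpoint(paths$model)
      preds <- rbind(cbind(predict_patch_probs(model, ds$train),
                           split = "train"),
                     cbind(predict_patch_probs(model, ds$val),
                           split = "val"))
      write.csv(preds, paths$instance_preds, row.names = FALSE)
      record("predict", paths$instance_preds)
    } else message("predict: up to date, skipping")
  }

  ## ---- aggregate ------------------------------------------------------
  if ("aggregate" %in% stages) {
    need(paths$instance_preds, "aggregate", "predict")
    if (!done("aggregate", paths$bag_preds)) {
      preds <- read.csv(paths$instance_preds)
      bp <- do.call(rbind, lapply(split(preds, preds$split), function(d)
        cbind(predict_bags(d, config$mil$strategies, config$mil$threshold),
              split = d$split[1])))
      write.csv(bp, paths$bag_preds, row.names = FALSE)
      record("aggregate", paths$bag_preds)
    } else message("aggregate: up to date, skipping")
  }

  ## ---- evaluate -------------------------------------------------------
  if ("evaluate" %in% stages) {
    need(c(paths$bag_preds, paths$bags), "evaluate", "aggregate")
    if (!done("evaluate", paths$metrics)) {
      bp <- read.csv(paths$bag_preds)
      bag_df <- read.csv(paths$bags)
      truth <- stats::setNames(bag_df$label, bag_df$patient_id)
      metrics <- list()
      for (sp in unique(bp$split)) {
        for (s in config$mil$strategies) {
          d <- bp[bp$split == sp & bp$strategy == s, ]
          m <- suppressWarnings(compute_metrics(
            unname(truth[d$patient_id]), d$predicted_label, d$bag_prob))
          metrics[[sp]][[s]] <- unclass(m)
        }
      }
      jsonlite::write_json(metrics, paths$metrics, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      record("evaluate", paths$metrics)
      manifest$metrics <- metrics$val
    } else message("evaluate: up to date, skipping")
  }

  ## ---- gradcam --------------------------------------------------------
  if ("gradcam" %in% stages && config$gradcam$n_examples > 0) {
    need(c(paths$model, paths$patches, paths$bags), "gradcam", "train")
    model <- load_checkpoint(paths$model)
    patches <- readRDS(paths$patches)
    bag_df <- read.csv(paths$bags)
    val_pat <- bag_df$patient_id[bag_df$split == "val"]
    cand <- Filter(function(p)
      sub("_t[0-9]+$", "", p$source_id) %in% val_pat, patches)
    cand <- utils::head(cand, config$gradcam$n_examples)
    for (p in cand) {
      hm <- suppressWarnings(gradcam(model, normalize_patch(p), "high"))
      write_gradcam(hm, p, paths$gradcam_dir)
    }
    record("gradcam", list.files(paths$gradcam_dir, full.names = TRUE))
  }

  ## ---- survival -------------------------------------------------------
  if ("survival" %in% stages) {
    surv_path <- file.path(paths$cohort_dir, "survival.csv")
    need(c(surv_path, paths$labels), "survival", "label")
    if (!done("survival", c(paths$km, paths$cox_uni, paths$logrank))) {
      sdf <- read.csv(surv_path, stringsAsFactors = FALSE)
      labels <- read_labels(paths$labels)
      sdf <- sdf[sdf$patient_id %in% names(labels$labels), ]
      sdf$group <- unname(labels$labels[sdf$patient_id])
      rec <- survival_table(sdf$patient_id, sdf$time_months, sdf$event,
                            sdf$group, age = sdf$age, stage = sdf$stage)
      write_km(km_curve(rec), paths$km)
      lr <- logrank_test(rec)
      jsonlite::write_json(lr, paths$logrank, auto_unbox = TRUE, digits = NA)
      write_cox(cox_fit(rec, "group"), paths$cox_uni)
      cv <- config$survival$covariates
      cox_m <- tryCatch(cox_fit(rec, cv), error = function(e) NULL)
      if (!is.null(cox_m)) write_cox(cox_m, paths$cox_multi)
      record("survival",
             c(paths$km, paths$cox_uni, paths$logrank,
               if (!is.null(cox_m)) paths$cox_multi))
    } else message("survival: up to date, skipping")
  }

  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

# rebuild train/val patch datasets from the bags table + filtered patches
load_split_datasets <- function(paths) {
  patches <- readRDS(paths$patches)
  bag_df <- read.csv(paths$bags, stringsAsFactors = FALSE)
  ids <- vapply(patches, `[[`, "", "patch_id")
  pat <- sub("_t[0-9]+$", "", vapply(patches, `[[`, "", "source_id"))
  mk <- function(rows) {
    bags <- lapply(rows, function(i) {
      keep <- pat == bag_df$patient_id[i]
      bag_record(bag_df$patient_id[i], ids[keep], bag_df$label[i],
                 bag_df$split[i])
    })
    patch_dataset(patches[pat %in% bag_df$patient_id[rows]], bags)
  }
  list(train = mk(which(bag_df$split == "train")),
       val = mk(which(bag_df$split == "val")))
}
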