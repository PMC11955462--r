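# Independent oracles and fixture builders shared across test files.
# Everything here is deliberately written by a different route than the
# package code it checks.

## ---- brown-blob counter: color-range detector + connected components
## (row-run adjacency graph, igraph) -----------------------------------
count_brown_blobs <- function(tile) {
  px <- tile$pixels
  mask <- px[, , 1] > 80 & px[, , 1] < 170 &
          px[, , 2] > 40 & px[, , 2] < 130 &
          px[, , 3] < 90 & (px[, , 1] - px[, , 3]) > 40
  if (!any(mask)) return(0L)
  runs <- do.call(rbind, lapply(seq_len(ncol(mask)), function(j) {
    r <- rle(mask[, j])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(col = j, start = starts[keep], end = ends[keep])
  }))
  n <- nrow(runs)
  edges <- integer(0)
  for (j in sort(unique(runs$col))) {
    a <- which(runs$col == j); b <- which(runs$col == j + 1)
    if (!length(b)) next
    for (i in a) for (k in b)
      if (runs$start[i] <= runs$end[k] && runs$end[i] >= runs$start[k])
        edges <- c(edges, i, k)
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$no
}

## ---- naive R forward pass for a stages=1, blocks=1 backbone ----------
r_conv <- function(a, w, stride, pad) {
  H <- dim(a)[1]; W <- dim(a)[2]; cin <- dim(a)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; cout <- dim(w)[4]
  OH <- (H + 2 * pad - kh) %/% stride + 1
  OW <- (W + 2 * pad - kw) %/% stride + 1
  ap <- array(0, c(H + 2 * pad, W + 2 * pad, cin))
  ap[pad + seq_len(H), pad + seq_len(W), ] <- a
  out <- array(0, c(OH, OW, cout))
  for (o in seq_len(cout)) for (ci in seq_len(cin))
    for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
      sub <- ap[seq(ki, by = stride, length.out = OH),
                seq(kj, by = stride, length.out = OW), ci]
      out[, , o] <- out[, , o] + w[ki, kj, ci, o] * sub
    }
  out
}
r_bn_eval <- function(a, g, b, rm, rv, eps = 1e-5) {
  for (c in seq_len(dim(a)[3]))
    a[, , c] <- g[c] * (a[, , c] - rm[c]) / sqrt(rv[c] + eps) + b[c]
  a
}
r_relu <- function(a) { a[a < 0] <- 0; a }
r_maxpool <- function(a) {  # 3x3, stride 2, pad 1
  H <- dim(a)[1]; W <- dim(a)[2]; C <- dim(a)[3]
  OH <- (H + 2 - 3) %/% 2 + 1; OW <- (W + 2 - 3) %/% 2 + 1
  out <- array(-Inf, c(OH, OW, C))
  for (c in seq_len(C)) for (oi in seq_len(OH)) for (oj in seq_len(OW)) {
    ii <- ((oi - 1) * 2 - 1 + 1:3); jj <- ((oj - 1) * 2 - 1 + 1:3)
    ii <- ii[ii >= 1 & ii <= H]; jj <- jj[jj >= 1 & jj <= W]
    out[oi, oj, c] <- max(a[ii, jj, c])
  }
  out
}
r_forward_stage1 <- function(params, x) {
  a <- r_relu(r_bn_eval(r_conv(x, params[["conv1.w"]], 2, 3),
                        params[["bn1.gamma"]], params[["bn1.beta"]],
                        params[["bn1.rm"]], params[["bn1.rv"]]))
  a <- r_maxpool(a)
  z1 <- r_relu(r_bn_eval(r_conv(a, params[["s1.b1.conv1.w"]], 1, 1),
                         params[["s1.b1.bn1.gamma"]], params[["s1.b1.bn1.beta"]],
                         params[["s1.b1.bn1.rm"]], params[["s1.b1.bn1.rv"]]))
  z2 <- r_bn_eval(r_conv(z1, params[["s1.b1.conv2.w"]], 1, 1),
                  params[["s1.b1.bn2.gamma"]], params[["s1.b1.bn2.beta"]],
                  params[["s1.b1.bn2.rm"]], params[["s1.b1.bn2.rv"]])
  r_relu(z2 + a)
}

## ---- constructed patches --------------------------------------------
const_patch <- function(col, id = "p1", src = "t1") {
  px <- array(0, c(224, 224, 3))
  for (ch in 1:3) px[, , ch] <- col[ch]
  p <- structure(list(patch_id = id, source_id = src, grid_row = 0L,
                      grid_col = 0L, pixels = px, tissue_fraction = NA_real_),
                 class = "hemil_patch")
  p$tissue_fraction <- tissue_fraction(p)
  p
}

# solid red/blue toy cohort: one patch per patient, trivially separable
make_toy_color <- function(n_per_class = 20, seed = 1, jitter = 5) {
  set.seed(seed)
  patches <- list(); bags <- list()
  for (cls in c("R", "B")) {
    base <- if (cls == "R") c(200, 40, 40) else c(40, 40, 200)
    lab <- if (cls == "R") "high" else "low"
    for (i in seq_len(n_per_class)) {
      pid <- sprintf("%s%02d", cls, i)
      id <- paste0(pid, "_p")
      patches[[length(patches) + 1]] <-
        const_patch(pmin(pmax(base + rnorm(3, 0, jitter), 0), 255),
                    id, paste0(pid, "_t1"))
      bags[[length(bags) + 1]] <- bag_record(pid, id, lab)
    }
  }
  list(patches = patches, bags = bags)
}

toy_datasets <- function(toy, seed = 3) {
  sp <- split_cohort(toy$bags, train_config(seed = seed))
  ids <- vapply(toy$patches, `[[`, "", "patch_id")
  tr_ids <- unlist(lapply(sp$train_bags, `[[`, "patch_ids"))
  va_ids <- unlist(lapply(sp$val_bags, `[[`, "patch_ids"))
  list(train = patch_dataset(toy$patches[ids %in% tr_ids], sp$train_bags),
       val = patch_dataset(toy$patches[ids %in% va_ids], sp$val_bags),
       split = sp)
}

## trained toy model, cached so several test files can reuse it ---------
.toy_cache <- new.env(parent = emptyenv())
trained_toy_model <- function() {
  if (!is.null(.toy_cache$model)) return(.toy_cache$model)
  toy <- make_toy_color(20, seed = 1)
  ds <- toy_datasets(toy, seed = 3)
  model <- build_backbone(
    backbone_config(stages = 2, blocks_per_stage = 1, base_width = 16),
    seed = 11)
  model <- train_classifier(model, ds$train, ds$val,
                            train_config(learning_rate = 0.01, epochs = 10,
                                         batch_size = 16, seed = 5))
  .toy_cache$model <- model
  .toy_cache$datasets <- ds
  model
}
trained_toy_datasets <- function() {
  trained_toy_model()
  .toy_cache$datasets
}
# same toy model with the last-epoch (fully saturated) weights
trained_toy_model_final <- function() {
  m <- trained_toy_model()
  m$params <- m$final_params
  m
}

## MIL aggregation oracle: plain sort-and-slice ------------------------
oracle_aggregate <- function(probs, strategy, k = NULL) {
  s <- sort(probs, decreasing = TRUE)
  switch(strategy,
         mean = sum(probs) / length(probs),
         max = s[1],
         top10 = mean(s[seq_len(min(10, length(s)))]),
         top100 = mean(s[seq_len(min(100, length(s)))]),
         topk = mean(s[seq_len(min(k, length(s)))]))
}

## AUC oracle: brute-force all-pairs counting --------------------------
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == "high"]; neg <- scores[labels != "high"]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

## acceptance aliases ---------------------------------------------------
acceptance_e2e_config <- function(dir, seed) e2e_demo_config(dir, seed)
shuffled_control_auc <- function(dir, seed, epochs = 10L)
  shuffled_label_control(dir, seed = seed, epochs = epochs)
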