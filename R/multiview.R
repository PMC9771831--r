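#' @useDynLib cerebseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

view_axis <- function(plane) {
  switch(plane, sagittal = 1L, coronal = 2L, axial = 3L,
         stop("plane must be one of axial, coronal, sagittal"))
}

# 2D slice of a 3D array perpendicular to the view axis, original axis order
take_slice <- function(arr, plane, i) {
  switch(plane,
         axial = arr[, , i],
         coronal = arr[, i, ],
         sagittal = arr[i, , ])
}

#' Extract 7-channel slice stacks (spatial information aggregation)
#'
#' For every slice along the view axis, stacks the slice with its three
#' preceding and three succeeding neighbors into a 7-channel 2D input;
#' out-of-range neighbor indices are clamped to the nearest valid slice
#' (edge replication).
#'
#' @param volume A [cb_volume()] (typically the 128^3 working crop).
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @return List of class `slice_stacks`: `stacks` (list of H x W x 7
#'   arrays, middle channel = target slice), `plane`, `n`.
#' @export
extract_stacks <- function(volume, plane) {
  arr <- volume$data
  ax <- view_axis(plane)
  n <- dim(arr)[ax]
  if (n < 1) stop("volume has no slices along the view axis")
  stacks <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- pmin(pmax(i + (-3:3), 1L), n)
    first <- take_slice(arr, plane, idx[1])
    st <- array(0, c(dim(first), 7L))
    st[, , 1] <- first
    for (ch in 2:7) st[, , ch] <- take_slice(arr, plane, idx[ch])
    stacks[[i]] <- st
  }
  structure(list(stacks = stacks, plane = plane, n = n,
                 grid = dim(arr)), class = "slice_stacks")
}

# ground-truth label slices matching extract_stacks ordering
extract_label_slices <- function(labels, plane) {
  arr <- labels$data
  n <- dim(arr)[view_axis(plane)]
  lapply(seq_len(n), function(i) take_slice(arr, plane, i))
}

# append positional-encoding channels: normalized in-plane coordinates and
# the normalized slice position along the view axis
prepare_input <- function(stack, slice_pos, use_coords = TRUE) {
  if (!use_coords) return(stack)
  d <- dim(stack)
  H <- d[1]; W <- d[2]
  rr <- matrix(if (H > 1) 2 * (seq_len(H) - 1) / (H - 1) - 1 else 0, H, W)
  cc <- matrix(if (W > 1) 2 * (seq_len(W) - 1) / (W - 1) - 1 else 0, H, W,
               byrow = TRUE)
  out <- array(0, c(H, W, d[3] + 3L))
  out[, , seq_len(d[3])] <- stack
  out[, , d[3] + 1L] <- rr
  out[, , d[3] + 2L] <- cc
  out[, , d[3] + 3L] <- slice_pos
  out
}

#' Reference model configuration
#'
#' Configuration of the small encoder-decoder segmentation network used
#' per anatomical view. Axial and coronal views use the full 28-class set
#' (27 structures + background); the sagittal view, which cannot tell
#' hemispheres apart, uses the lateral-merged 17-class set.
#'
#' @param view `"axial"`, `"coronal"` or `"sagittal"`.
#' @param levels Number of resolution levels (default 2).
#' @param filters Base filter count (default 16, doubled per level).
#' @param competition_enabled Use local competition (pairwise channel
#'   maximum, a maxout) instead of ReLU (default TRUE).
#' @param use_coords Append normalized coordinate channels (in-plane
#'   row/col and slice position) to the 7 intensity channels (default
#'   TRUE); a positional encoding that lets a small network resolve
#'   position-defined structures.
#' @param protocol A [build_protocol()].
#' @return List of class `model_config` with `class_ids` (background
#'   first) and `n_classes` derived from the view.
#' @export
model_config <- function(view, levels = 2L, filters = 16L,
                         competition_enabled = TRUE, use_coords = TRUE,
                         protocol = build_protocol()) {
  view_axis(view)  # validates
  class_ids <- if (view == "sagittal")
    c(0L, merged_lateral_ids(protocol))
  else c(0L, protocol$structures$label_id)
  structure(list(view = view, levels = as.integer(levels),
                 filters = as.integer(filters),
                 competition_enabled = isTRUE(competition_enabled),
                 use_coords = isTRUE(use_coords),
                 class_ids = class_ids,
                 n_classes = length(class_ids),
                 protocol_hash = protocol_hash(protocol)),
            class = "model_config")
}

protocol_hash <- function(protocol) {
  s <- paste(protocol$structures$label_id, protocol$structures$name,
             collapse = ";")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' Build the reference segmentation model
#'
#' A small U-Net: per level two 3x3 convolutions (local-competition maxout
#' or ReLU), 2x2 max-pooling between levels, nearest-neighbor unpooling
#' with skip concatenation on the way up, and a 1x1 softmax head. Weights
#' are He-initialized deterministically from the seed. The model maps a
#' 7-channel slice stack to a per-pixel class-probability field.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for deterministic initialization.
#' @return Object of class `cb_model`.
#' @export
build_reference_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  in_ch <- 7L + if (config$use_coords) 3L else 0L
  ptr <- cnet_create(in_ch, config$n_classes, config$levels, config$filters,
                     config$competition_enabled, as.integer(seed))
  structure(list(ptr = ptr, config = config, seed = as.integer(seed)),
            class = "cb_model")
}

#' @export
print.cb_model <- function(x, ...) {
  cat(sprintf("cb_model [%s]: %d levels x %d filters, %d classes%s\n",
              x$config$view, x$config$levels, x$config$filters,
              x$config$n_classes,
              if (x$config$competition_enabled) ", local competition" else ""))
  invisible(x)
}

#' Extract / restore model weights (checkpointing)
#'
#' Weights round-trip as plain R lists so checkpoints can be stored with
#' `saveRDS()` alongside the model config and protocol hash.
#' @param model A `cb_model`.
#' @return List of per-layer `W`/`b`.
#' @export
model_weights <- function(model) cnet_get_weights(model$ptr)

#' @rdname model_weights
#' @param weights A list previously returned by [model_weights()].
#' @export
restore_weights <- function(model, weights) {
  cnet_set_weights(model$ptr, weights)
  invisible(model)
}

#' Save / load a model checkpoint
#' @param model A `cb_model`.
#' @param path Checkpoint path (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, seed = model$seed,
               weights = model_weights(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_reference_model(ck$config, ck$seed)
  restore_weights(model, ck$weights)
  model
}

#' Stub model for contract testing
#'
#' Wraps a plain R function as a view model satisfying the
#' [predict_view()] contract: `fn(stack, slice_pos)` must return an
#' H x W x C probability array. Useful for probing slice reassembly and
#' aggregation behavior independently of any trained network.
#'
#' @param fn Function of `(stack, slice_pos)` returning H x W x C.
#' @param view `"axial"`, `"coronal"` or `"sagittal"`.
#' @param protocol A [build_protocol()].
#' @return A `cb_model` whose forward pass is `fn`.
#' @export
stub_model <- function(fn, view, protocol = build_protocol()) {
  cfg <- model_config(view, protocol = protocol)
  structure(list(ptr = NULL, fn = fn, config = cfg, seed = NA_integer_),
            class = "cb_model")
}

#' Predict per-voxel class probabilities for one view
#'
#' Runs the model over every slice stack of the view and reassembles the
#' per-slice probability fields into a volume-shaped probability map
#' (unit sum per voxel).
#'
#' @param model A `cb_model` whose view matches the stacks' plane.
#' @param stacks An [extract_stacks()] result.
#' @return Object of class `cb_probs`: `data` (X x Y x Z x C array),
#'   `class_ids`, `view`.
#' @export
predict_view <- function(model, stacks) {
  stopifnot(inherits(model, "cb_model"), inherits(stacks, "slice_stacks"))
  if (model$config$view != stacks$plane)
    stop(sprintf("model view '%s' does not match stack plane '%s'",
                 model$config$view, stacks$plane))
  C <- model$config$n_classes
  grid <- stacks$grid
  out <- array(0, c(grid, C))
  n <- stacks$n
  for (i in seq_len(n)) {
    pos <- if (n > 1) (i - 1) / (n - 1) else 0.5
    if (is.null(model$ptr)) {
      P <- model$fn(stacks$stacks[[i]], pos)
      if (!identical(dim(P)[3], as.integer(C)))
        stop("stub model class count does not match the view's class set")
    } else {
      inp <- prepare_input(stacks$stacks[[i]], pos, model$config$use_coords)
      P <- cnet_forward(model$ptr, inp)
    }
    switch(stacks$plane,
           axial = { out[, , i, ] <- P },
           coronal = { out[, i, , ] <- P },
           sagittal = { out[i, , , ] <- P })
  }
  structure(list(data = out, class_ids = model$config$class_ids,
                 view = stacks$plane), class = "cb_probs")
}

#' Expand sagittal merged-lateral probabilities to the full class set
#'
#' Each merged class's probability is copied to both its left and right
#' full-set classes; background and midline classes pass through; the
#' result is renormalized per voxel.
#'
#' @param probs_merged A `cb_probs` over the merged-lateral class set.
#' @param protocol A [build_protocol()].
#' @return A `cb_probs` over the full 28-class set.
#' @export
expand_sagittal <- function(probs_merged, protocol = build_protocol()) {
  merged_ids <- c(0L, merged_lateral_ids(protocol))
  if (!identical(probs_merged$class_ids, merged_ids))
    stop("probability map is not on the merged-lateral class set")
  full_ids <- c(0L, protocol$structures$label_id)
  d <- dim(probs_merged$data)
  out <- array(0, c(d[1:3], length(full_ids)))
  for (k in seq_along(full_ids)) {
    id <- full_ids[k]
    mid <- if (id == 0L) 0L else min(id, unname(protocol$lr_swap[as.character(id)]))
    out[, , , k] <- probs_merged$data[, , , match(mid, merged_ids)]
  }
  norm <- apply_prob_norm(out)
  structure(list(data = norm, class_ids = full_ids, view = "sagittal"),
            class = "cb_probs")
}

apply_prob_norm <- function(p4) {
  s <- rowSums(matrix(p4, ncol = dim(p4)[4]))
  s[s == 0] <- 1
  array(as.numeric(matrix(p4, ncol = dim(p4)[4]) / s), dim(p4))
}

#' Aggregate view probability maps in probability space
#'
#' Weighted arithmetic mean of the per-view class-probability maps,
#' renormalized per voxel. Default weights (axial, coronal, sagittal) =
#' (1, 1, 0.5): the sagittal view contributes with half weight because
#' its lateral-merged predictions are expanded symmetrically to both
#' hemispheres.
#'
#' @param p_axial,p_coronal,p_sagittal `cb_probs` on the same grid and
#'   full class set (expand sagittal first).
#' @param weights Numeric length-3 aggregation weights.
#' @return Aggregated `cb_probs`.
#' @export
view_aggregate <- function(p_axial, p_coronal, p_sagittal,
                           weights = c(1, 1, 0.5)) {
  ps <- list(p_axial, p_coronal, p_sagittal)
  d <- dim(ps[[1]]$data)
  for (p in ps[-1]) {
    if (!identical(dim(p$data), d)) stop("probability grids differ")
    if (!identical(p$class_ids, ps[[1]]$class_ids))
      stop("probability class sets differ")
  }
  acc <- array(0, d)
  for (i in 1:3) acc <- acc + weights[i] * ps[[i]]$data
  acc <- acc / sum(weights)
  structure(list(data = apply_prob_norm(acc), class_ids = ps[[1]]$class_ids,
                 view = "aggregated"), class = "cb_probs")
}

#' Convert class probabilities to a label map
#'
#' Per-voxel argmax; ties are broken toward the lowest class id
#' (background id 0 first). Invariant under any positive rescaling of the
#' probabilities.
#'
#' @param p A `cb_probs`.
#' @param spacing Voxel spacing for the returned label map.
#' @return A [cb_labels()].
#' @export
probabilities_to_labels <- function(p, spacing = c(1, 1, 1)) {
  d <- dim(p$data)
  m <- matrix(p$data, ncol = d[4])
  idx <- max.col(m, ties.method = "first")
  cb_labels(array(p$class_ids[idx], d[1:3]), spacing)
}
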