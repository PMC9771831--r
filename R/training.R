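#' Training configuration
#'
#' Defaults mirror the published training recipe: 70 epochs, batch size
#' 128, a decoupled-weight-decay adaptive-moment optimizer (AdamW) with
#' weight decay 1e-4 and initial learning rate 0.01, and a
#' reduce-on-plateau schedule monitoring validation macro Dice that
#' multiplies the learning rate by 0.01 after 4 epochs without
#' improvement. (A plateau factor of 0.1 is the more common convention;
#' 0.01 is kept as the documented default here.) Scaled-down experiments
#' override `epochs`, `batch_size`, `lr0` and the sampling fields.
#'
#' @param epochs Number of epochs.
#' @param batch_size Slices per optimizer step.
#' @param lr0 Initial learning rate.
#' @param weight_decay Decoupled weight decay.
#' @param plateau_factor Multiplicative LR factor on plateau.
#' @param plateau_patience Epochs without Dice improvement before a
#'   reduction; after a reduction the counter restarts (cooldown).
#' @param dice_weight Weight of the soft-Dice term in the composite loss.
#' @param dice_smooth Soft-Dice smoothing constant.
#' @param max_grad_norm Global gradient-norm clip per optimizer step
#'   (0 disables).
#' @param slices_per_epoch Slices sampled per volume per epoch (`NULL` =
#'   all slices).
#' @param val_subset Number of validation volumes used for the per-epoch
#'   Dice estimate (`NULL` = all).
#' @param seed RNG seed for batch order and augmentation sampling.
#' @return List of class `train_config`.
#' @export
train_config <- function(epochs = 70L, batch_size = 128L, lr0 = 0.01,
                         weight_decay = 1e-4, plateau_factor = 0.01,
                         plateau_patience = 4L, dice_weight = 1,
                         dice_smooth = 1e-6, max_grad_norm = 5,
                         slices_per_epoch = NULL,
                         val_subset = NULL, seed = 1L) {
  stopifnot(epochs >= 0, batch_size >= 1, lr0 > 0, weight_decay >= 0,
            plateau_factor > 0, plateau_factor < 1, plateau_patience >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr0 = lr0,
                 weight_decay = weight_decay,
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 dice_weight = dice_weight, dice_smooth = dice_smooth,
                 max_grad_norm = max_grad_norm,
                 slices_per_epoch = slices_per_epoch,
                 val_subset = val_subset, seed = as.integer(seed)),
            class = "train_config")
}

#' Composite segmentation loss (reference implementation)
#'
#' Weighted cross-entropy plus a soft-Dice term:
#'   `L = mean_i w[t_i] (-log p_i[t_i]) + dice_weight * (1 - mean_c D_c)`
#' where `D_c = (2 A_c + s) / (B_c + s)` with `A_c` the soft intersection
#' and `B_c` the sum of predicted and target mass of class `c`, averaged
#' over the classes present in the target. Nonnegative; zero iff the
#' prediction is the one-hot target, up to the smoothing constant `s`.
#' The compiled training path evaluates the same expression.
#'
#' @param probs H x W x C probability array (unit sum per pixel).
#' @param target H x W integer matrix of 1-based class indices.
#' @param class_weights Length-C nonnegative weight vector.
#' @param dice_weight Weight of the soft-Dice term.
#' @param smooth Soft-Dice smoothing constant.
#' @return Scalar loss.
#' @export
composite_loss <- function(probs, target, class_weights = NULL,
                           dice_weight = 1, smooth = 1e-6) {
  d <- dim(probs)
  C <- d[3]
  if (is.null(class_weights)) class_weights <- rep(1, C)
  if (length(class_weights) != C)
    stop("class_weights length must equal the class count")
  t <- as.integer(target)
  if (any(t < 1 | t > C)) stop("target contains invalid class indices")
  N <- length(t)
  m <- matrix(probs, ncol = C)
  pt <- m[cbind(seq_len(N), t)]
  ce <- mean(class_weights[t] * (-log(pmax(pt, 1e-12))))
  pres <- sort(unique(t))
  dsum <- 0
  for (c in pres) {
    y <- as.numeric(t == c)
    A <- sum(m[, c] * y)
    B <- sum(m[, c]) + sum(y)
    dsum <- dsum + (2 * A + smooth) / (B + smooth)
  }
  ce + dice_weight * (1 - dsum / length(pres))
}

#' Median-frequency class weights
#'
#' `w_c = median(freq) / freq_c` over the classes of the training label
#' maps; classes absent from the data get weight 0 with a warning.
#'
#' @param label_maps List of [cb_labels()] (or integer arrays).
#' @param class_ids Ordered class ids the weight vector should cover
#'   (background 0 first by convention).
#' @return Numeric weight vector aligned with `class_ids`.
#' @export
median_frequency_weights <- function(label_maps, class_ids) {
  counts <- numeric(length(class_ids))
  names(counts) <- class_ids
  for (lm in label_maps) {
    arr <- label_data(lm)
    tb <- table(factor(as.integer(arr), levels = class_ids))
    counts <- counts + as.numeric(tb)
  }
  if (sum(counts[as.character(setdiff(class_ids, 0))]) == 0)
    stop("training labels contain only background")
  freq <- counts / sum(counts)
  present <- freq > 0
  med <- stats::median(freq[present])
  w <- numeric(length(class_ids))
  w[present] <- med / freq[present]
  if (any(!present))
    warning("classes absent from training data get weight 0: ",
            paste(class_ids[!present], collapse = ", "))
  w
}

#' Reduce-on-plateau learning-rate step
#'
#' Returns `lr * factor` when the best validation Dice seen so far has
#' not improved during the last `patience` epochs, otherwise `lr`
#' unchanged. The training loop restarts the plateau counter after each
#' reduction (cooldown), so reductions are at least `patience` epochs
#' apart.
#'
#' @param history Numeric vector of per-epoch validation Dice.
#' @param lr Current learning rate.
#' @param factor Multiplicative reduction factor.
#' @param patience Epochs without improvement that trigger a reduction.
#' @param since_epoch Ignore improvements before this epoch (used by the
#'   loop to implement the cooldown).
#' @return Updated learning rate.
#' @export
plateau_step <- function(history, lr, factor = 0.01, patience = 4L,
                         since_epoch = 0L) {
  n <- length(history)
  if (n == 0) return(lr)
  # epoch of the last strict improvement of the running best
  run <- cummax(history)
  improved <- c(TRUE, diff(run) > 0)
  last_improve <- max(which(improved))
  anchor <- max(last_improve, since_epoch)
  if (n - anchor >= patience) lr * factor else lr
}

# single 7-channel stack for one slice (edge-replicated neighbors)
stack_for_slice <- function(arr, plane, i) {
  n <- dim(arr)[view_axis(plane)]
  idx <- pmin(pmax(i + (-3:3), 1L), n)
  first <- take_slice(arr, plane, idx[1])
  st <- array(0, c(dim(first), 7L))
  st[, , 1] <- first
  for (ch in 2:7) st[, , ch] <- take_slice(arr, plane, idx[ch])
  st
}

# macro Dice over the given ids, skipping ids absent from both maps
macro_dice <- function(gt_arr, pred_arr, ids) {
  ds <- c()
  for (id in ids) {
    G <- gt_arr == id; P <- pred_arr == id
    if (!any(G) && !any(P)) next
    ds <- c(ds, dice(G, P))
  }
  if (length(ds) == 0) return(NA_real_)
  mean(ds)
}

# view-level labels: lateral-merged for the sagittal model
view_labels <- function(labels, view, protocol) {
  if (view == "sagittal") merge_lateral_labels(labels, protocol) else labels
}

# validation macro Dice of a model over (a subset of) validation volumes
validate_model <- function(model, val_set, protocol, subset = NULL) {
  idx <- seq_along(val_set)
  if (!is.null(subset)) idx <- idx[seq_len(min(subset, length(idx)))]
  ids <- setdiff(model$config$class_ids, 0L)
  ds <- numeric(0)
  for (i in idx) {
    st <- extract_stacks(val_set[[i]]$volume, model$config$view)
    pred <- probabilities_to_labels(predict_view(model, st),
                                    val_set[[i]]$labels$spacing)
    gt <- view_labels(val_set[[i]]$labels, model$config$view, protocol)
    ds <- c(ds, macro_dice(gt$data, pred$data, ids))
  }
  mean(ds, na.rm = TRUE)
}

#' Train a single-view model
#'
#' Slice-level training with on-the-fly augmentation: per epoch and
#' volume, an optional left-right flip (with label-id swap) and additive
#' polynomial bias field are applied volumetrically, then sampled slices
#' are optionally transformed by a random in-slice affine (all 7 stack
#' channels warped with one matrix, labels nearest-neighbor). Validation
#' macro Dice is logged per epoch, drives the reduce-on-plateau schedule,
#' and selects the retained best checkpoint. Fully seed-deterministic
#' (the compiled backend is deterministic by construction).
#'
#' @param model A [build_reference_model()] model.
#' @param train_set,val_set Lists of `(volume, labels)` pairs on the
#'   working crop grid.
#' @param config A [train_config()].
#' @param augmenters An [augmentation_config()], or `NULL` to disable all
#'   on-the-fly augmentation.
#' @param protocol A [build_protocol()].
#' @return List with `model` (best checkpoint restored) and `history`
#'   (data.frame epoch / loss / val_dice / lr).
#' @export
train_view <- function(model, train_set, val_set, config = train_config(),
                       augmenters = augmentation_config(),
                       protocol = build_protocol()) {
  stopifnot(inherits(model, "cb_model"), inherits(config, "train_config"))
  if (length(train_set) == 0 || length(val_set) == 0)
    stop("training and validation sets must be nonempty")
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_dice = numeric(0), lr = numeric(0))
  if (config$epochs == 0) return(list(model = model, history = history))
  set.seed(config$seed)
  view <- model$config$view
  class_ids <- model$config$class_ids
  train_lab <- lapply(train_set, function(s)
    view_labels(s$labels, view, protocol))
  weights <- suppressWarnings(
    median_frequency_weights(train_lab, class_ids))
  lr <- config$lr0
  best <- list(dice = -Inf, weights = NULL)
  last_reduce <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample(seq_along(train_set))
    batch_in <- list(); batch_t <- list()
    losses <- c()
    flush <- function() {
      if (length(batch_in) == 0) return(invisible())
      l <- cnet_train_batch(model$ptr, batch_in, batch_t, weights, lr,
                            config$weight_decay, config$dice_weight,
                            config$dice_smooth, config$max_grad_norm)
      losses <<- c(losses, l)
      batch_in <<- list(); batch_t <<- list()
      invisible()
    }
    for (vi in ord) {
      vol <- train_set[[vi]]$volume
      lab <- train_lab[[vi]]
      if (!is.null(augmenters)) {
        # the flip is volumetric: a sagittal in-plane flip could not realize
        # a left-right mirror, so all three view pipelines share this step
        fl <- random_lr_flip(vol, train_set[[vi]]$labels, protocol,
                             p = augmenters$flip_prob)
        if (fl$flipped) {
          vol <- fl$volume
          lab <- view_labels(fl$labels, view, protocol)
        }
        if (stats::runif(1) < augmenters$bias_prob) {
          field <- sample_bias_field(dim(vol$data),
                                     range = augmenters$bias_range)
          vol <- apply_bias(vol, field)
          # keep training inputs on the loader's clamped [0, 1] scale
          vol$data <- pmin(pmax(vol$data, 0), 1)
        }
      }
      n_slices <- dim(vol$data)[view_axis(view)]
      take <- if (is.null(config$slices_per_epoch)) seq_len(n_slices)
        else sort(sample.int(n_slices, min(config$slices_per_epoch, n_slices)))
      for (i in take) {
        st <- stack_for_slice(vol$data, view, i)
        ls <- take_slice(lab$data, view, i)
        if (!is.null(augmenters) && stats::runif(1) < augmenters$affine_prob) {
          par <- sample_affine(augmenters)
          sp2 <- vol$spacing[setdiff(1:3, view_axis(view))]
          M <- affine_matrix(par, dim(ls), sp2)
          nst <- st
          for (ch in 1:7) nst[, , ch] <- warp_slice_cpp(st[, , ch], ls, M)$image
          ls <- warp_slice_cpp(st[, , 4], ls, M)$labels
          st <- nst
        }
        tcl <- match(as.integer(ls), class_ids)
        if (anyNA(tcl)) stop("label slice contains ids outside the class set")
        inp <- prepare_input(st, if (n_slices > 1) (i - 1) / (n_slices - 1) else 0.5,
                             model$config$use_coords)
        batch_in[[length(batch_in) + 1L]] <- inp
        batch_t[[length(batch_t) + 1L]] <- as.integer(tcl - 1L)
        if (length(batch_in) >= config$batch_size) flush()
      }
    }
    flush()
    vd <- validate_model(model, val_set, protocol, config$val_subset)
    history <- rbind(history, data.frame(epoch = ep,
                                         loss = mean(losses),
                                         val_dice = vd, lr = lr))
    if (vd > best$dice) {
      best$dice <- vd
      best$weights <- model_weights(model)
    }
    new_lr <- plateau_step(history$val_dice, lr, config$plateau_factor,
                           config$plateau_patience, last_reduce)
    if (new_lr < lr) last_reduce <- ep
    lr <- new_lr
  }
  if (!is.null(best$weights)) restore_weights(model, best$weights)
  list(model = model, history = history)
}

#' Pre-train then fine-tune a view model
#'
#' Trains on the pre-training pool, then continues from the resulting
#' parameters on the fine-tuning pool. Both pools must use the same
#' protocol/class set. Stage provenance is attached to the result.
#'
#' @param config A [model_config()] for the view.
#' @param pretrain_set,finetune_set Training pools (lists of
#'   `(volume, labels)`); each needs a matching `*_val` hold-out.
#' @param pretrain_val,finetune_val Validation pools per stage.
#' @param pretrain_config,finetune_config [train_config()]s per stage.
#' @param augmenters Augmentation for the fine-tuning stage.
#' @param pretrain_augmenters Augmentation for the pre-training stage
#'   (defaults to the fine-tuning augmenters).
#' @param protocol A [build_protocol()].
#' @param seed Model initialization seed.
#' @return List with `model`, `stages` (per-stage histories), and
#'   `provenance`.
#' @export
pretrain_then_finetune <- function(config, pretrain_set, pretrain_val,
                                   finetune_set, finetune_val,
                                   pretrain_config, finetune_config,
                                   augmenters = augmentation_config(),
                                   pretrain_augmenters = augmenters,
                                   protocol = build_protocol(), seed = 1L) {
  model <- build_reference_model(config, seed)
  st1 <- train_view(model, pretrain_set, pretrain_val, pretrain_config,
                    pretrain_augmenters, protocol)
  st2 <- train_view(st1$model, finetune_set, finetune_val, finetune_config,
                    augmenters, protocol)
  list(model = st2$model,
       stages = list(pretrain = st1$history, finetune = st2$history),
       provenance = data.frame(
         stage = c("pretrain", "finetune"),
         n_cases = c(length(pretrain_set), length(finetune_set)),
         epochs = c(pretrain_config$epochs, finetune_config$epochs)))
}

#' Write a training history as TSV
#' @param history The `history` data.frame from [train_view()].
#' @param path Output path.
#' @export
write_history_tsv <- function(history, path) {
  utils::write.table(history, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
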