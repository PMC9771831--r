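#' Scaled-down experiment suite
#'
#' Desk-scale counterparts of the full training and ablation experiments:
#' phantom cohorts at 64^3 (48^3 for the ablation), a 48-voxel working
#' crop, 2-level 16-filter reference models, and a handful of epochs.
#' The cohorts sample atrophy over 0 / 0.2 / 0.4 — mirroring a study
#' population covering a broad range of cerebellar atrophy — and carry a
#' random smooth multiplicative intensity drift per subject, which is
#' what makes bias-field augmentation meaningful.
#'
#' @name toy_experiments
NULL

# cohort conditions for the scaled-down experiments (fixed design)
TOY_ATROPHY_LEVELS <- c(0, 0.2, 0.4)
TOY_DRIFT <- 0.15
TOY_NOISE <- 0.1

# one prepared case: native phantom plus normalized working crop; the
# bounding box is jittered by a few voxels per subject, emulating the
# imprecision of a production localization step (a coarse whole-brain
# segmentation rather than ground truth) — the variation the affine
# translation augmentation is meant to absorb
toy_case <- function(seed, subject, grid = 64L, crop_side = 48L,
                     atrophy = 0, noise_sd = TOY_NOISE,
                     drift = TOY_DRIFT, box_jitter = 3L,
                     wm_branches = 6L) {
  spec <- phantom_spec(grid_shape = rep(grid, 3), atrophy = atrophy,
                       noise_sd = noise_sd, drift_amplitude = drift,
                       wm_branch_count = wm_branches,
                       seed = seed, subject = subject)
  ph <- generate_phantom(spec)
  box <- fit_bounding_box(cerebellum_mask(ph$labels), side = crop_side)
  if (box_jitter > 0) {
    jit <- with_seed(stream_seed(seed, subject, "cohort"),
                     sample(-box_jitter:box_jitter, 3, replace = TRUE))
    box$start <- pmax(0L, pmin(box$start + as.integer(jit),
                               box$native_shape - box$side))
  }
  list(volume = normalize_intensity(crop_volume(ph$volume, box)),
       labels = crop_volume(ph$labels, box),
       native_volume = ph$volume, native_labels = ph$labels,
       box = box, atrophy = atrophy, spec = spec)
}

#' Build train/validation/test phantom pools
#'
#' Subjects get independent anatomy streams; atrophy levels cycle
#' deterministically through the fixed design levels (0, 0.2, 0.4).
#'
#' @param n_train,n_val,n_test Pool sizes.
#' @param grid Phantom grid side (voxels).
#' @param crop_side Working crop side.
#' @param seed Base seed.
#' @return List with `train`, `val`, `test` lists of prepared cases.
#' @export
build_toy_sets <- function(n_train = 40L, n_val = 10L, n_test = 10L,
                           grid = 64L, crop_side = 48L, seed = 1L) {
  lv <- TOY_ATROPHY_LEVELS
  mk <- function(offset, n)
    lapply(seq_len(n), function(i)
      toy_case(seed, offset + i, grid, crop_side,
               atrophy = lv[(offset + i - 1) %% length(lv) + 1]))
  list(train = mk(0L, n_train), val = mk(n_train, n_val),
       test = mk(n_train + n_val, n_test))
}

#' Training configuration of the scaled-down runs
#' @param epochs Epochs (<= 10 in the toy experiments).
#' @param seed RNG seed.
#' @return A [train_config()].
#' @export
toy_train_config <- function(epochs = 10L, seed = 1L) {
  train_config(epochs = epochs, batch_size = 8L, lr0 = 2.5e-3,
               plateau_factor = 0.01, plateau_patience = 4L,
               max_grad_norm = 2, slices_per_epoch = 28L,
               val_subset = 3L, seed = seed)
}

#' Augmentation configuration of the scaled-down runs
#'
#' Ranges scaled to the 48-voxel crop (the printed production ranges
#' assume a 128-voxel crop of real anatomy).
#' @param flip,affine,bias Enable flags per family.
#' @return An [augmentation_config()].
#' @export
toy_augmentation_config <- function(flip = TRUE, affine = TRUE, bias = TRUE) {
  # ranges span the phantom population's variability (center jitter ~1.5 mm,
  # radii ~4%, drift ~0.15 relative == ~0.075 additive on the GM mean), the
  # same way the production ranges span human centroid/size variation
  augmentation_config(translation_mm = c(-3, 3), scale = c(0.96, 1.05),
                      rotation_deg = c(-5, 5),
                      flip_prob = if (flip) 0.5 else 0,
                      affine_prob = if (affine) 1 else 0,
                      bias_prob = if (bias) 0.3 else 0,
                      bias_range = c(-0.04, 0.04))
}

#' Train the three-view toy model ensemble
#'
#' One reference model per anatomical view on the given pools.
#'
#' @param sets A [build_toy_sets()] result (train/val used).
#' @param epochs Epochs per view.
#' @param filters Base filter count.
#' @param seed Seed for model init and batch sampling.
#' @param augmenters Augmentation config (`NULL` disables).
#' @param protocol A [build_protocol()].
#' @return List with `models` (axial/coronal/sagittal) and `histories`.
#' @export
train_toy_models <- function(sets, epochs = 8L, filters = 16L, seed = 1L,
                             augmenters = toy_augmentation_config(),
                             protocol = build_protocol()) {
  models <- list(); histories <- list()
  for (v in c("axial", "coronal", "sagittal")) {
    mc <- model_config(v, filters = filters, protocol = protocol)
    m <- build_reference_model(mc, seed)
    res <- train_view(m, sets$train, sets$val,
                      toy_train_config(epochs, seed), augmenters, protocol)
    models[[v]] <- res$model
    histories[[v]] <- res$history
  }
  list(models = models, histories = histories)
}

#' Evaluate the toy ensemble on test phantoms
#'
#' Runs the full native-space pipeline per test case and additionally
#' scores each single view on the working crop.
#'
#' @param models Three-view model list from [train_toy_models()].
#' @param test_cases Prepared test cases.
#' @param crop_side Working crop side used in training.
#' @param protocol A [build_protocol()].
#' @return data.frame with one row per case: aggregated and single-view
#'   macro Dice.
#' @export
evaluate_toy_models <- function(models, test_cases, crop_side = 48L,
                                protocol = build_protocol()) {
  ids <- protocol$structures$label_id
  rows <- lapply(seq_along(test_cases), function(i) {
    cs <- test_cases[[i]]
    seg <- segment_cerebellum(cs$native_volume, models, cs$native_labels,
                              protocol, crop_side = crop_side)
    agg <- macro_dice(cs$native_labels$data, seg$labels$data, ids)
    # single views on the crop
    crop_gt <- cs$labels$data
    sv <- vapply(c("axial", "coronal", "sagittal"), function(v) {
      p <- predict_view(models[[v]], extract_stacks(cs$volume, v))
      if (v == "sagittal") p <- expand_sagittal(p, protocol)
      macro_dice(crop_gt, probabilities_to_labels(p)$data, ids)
    }, numeric(1))
    data.frame(case = i, atrophy = cs$atrophy, dice_aggregated = agg,
               dice_axial = sv[["axial"]], dice_coronal = sv[["coronal"]],
               dice_sagittal = sv[["sagittal"]])
  })
  do.call(rbind, rows)
}

#' Run the scaled-down augmentation/pre-training ablation
#'
#' Single-view (axial) arms at reduced size: a no-augmentation baseline,
#' one arm per augmentation family (flip, bias field, in-slice affine,
#' static non-linear deformation), a pre-training arm, and the
#' combination of everything. Each arm is trained per seed and scored by
#' mean macro Dice on a held-out test pool.
#'
#' @param seeds Integer seeds (one training per arm and seed).
#' @param grid Phantom grid side.
#' @param crop_side Working crop side.
#' @param n_train,n_val,n_test Pool sizes per seed.
#' @param epochs Epochs per training stage.
#' @param filters Base filter count.
#' @param finetune_lr Learning rate of the fine-tuning stage in the staged
#'   arms (lower than the initial rate so pretrained features survive).
#' @param protocol A [build_protocol()].
#' @return data.frame `arm` x `seed` x `dice`.
#' @export
run_ablation <- function(seeds = 1:3, grid = 48L, crop_side = 36L,
                         n_train = 6L, n_val = 2L, n_test = 8L,
                         epochs = 8L, filters = 16L, finetune_lr = 1e-3,
                         protocol = build_protocol()) {
  arms <- c("baseline", "flip", "bias", "affine", "deformation",
            "pretrain", "all")
  out <- list()
  for (seed in seeds) {
    sets <- build_toy_sets(n_train, n_val, n_test, grid, crop_side,
                           seed = seed * 1000L)
    # pre-training pool: a larger cross-study stand-in with a domain
    # shift, like atlas-derived pre-training labels that miss fine
    # white-matter branch detail: coarser WM trees, no drift, less noise
    pre <- lapply(seq_len(2L * n_train), function(i)
      toy_case(seed * 1000L + 500L, i, grid, crop_side,
               atrophy = TOY_ATROPHY_LEVELS[(i - 1) %% 3 + 1],
               noise_sd = 0.05, drift = 0, wm_branches = 3L))
    pre_val <- pre[seq_len(n_val)]
    pre_train <- pre[-seq_len(n_val)]
    deformed <- local({
      set.seed(seed * 1000L + 7L)
      fields <- lapply(seq_len(n_train), function(k)
        generate_displacement_field(rep(crop_side, 3),
                                    max_disp_mm = 3, smoothness_mm = 6,
                                    seed = seed * 1000L + k))
      build_static_deformed_set(sets$train, fields)
    })
    for (arm in arms) {
      aug <- switch(arm,
        baseline = NULL,
        flip = toy_augmentation_config(TRUE, FALSE, FALSE),
        bias = toy_augmentation_config(FALSE, FALSE, TRUE),
        affine = toy_augmentation_config(FALSE, TRUE, FALSE),
        deformation = NULL,
        pretrain = NULL,
        all = toy_augmentation_config())
      train_pool <- sets$train
      if (arm %in% c("deformation", "all"))
        train_pool <- c(train_pool, deformed)
      mc <- model_config("axial", filters = filters, protocol = protocol)
      tc <- toy_train_config(epochs, seed)
      if (arm %in% c("pretrain", "all")) {
        ft <- tc; ft$lr0 <- finetune_lr
        # augmentation addresses the small fine-tuning set; the
        # pre-training pool is large enough to train clean
        res <- pretrain_then_finetune(mc, pre_train, pre_val, train_pool,
                                      sets$val, tc, ft, aug,
                                      pretrain_augmenters = NULL,
                                      protocol = protocol, seed = seed)
        model <- res$model
      } else {
        res <- train_view(build_reference_model(mc, seed), train_pool,
                          sets$val, tc, aug, protocol)
        model <- res$model
      }
      ds <- vapply(sets$test, function(cs) {
        p <- predict_view(model, extract_stacks(cs$volume, "axial"))
        macro_dice(cs$labels$data, probabilities_to_labels(p)$data,
                   protocol$structures$label_id)
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(arm = arm, seed = seed,
                                            dice = mean(ds))
    }
  }
  do.call(rbind, out)
}
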