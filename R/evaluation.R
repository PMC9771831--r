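#' Dice overlap of two binary masks
#'
#' `2 |G intersect P| / (|G| + |P|)`: 1 means exact agreement, 0 disjoint
#' segmentations. Two empty masks are defined to agree perfectly
#' (Dice = 1), since agreement on absence is still agreement.
#'
#' @param G,P Logical/0-1 arrays on the same grid.
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(G, P) {
  G <- as.array(G) != 0; P <- as.array(P) != 0
  if (!identical(dim(G), dim(P))) stop("masks must share one grid")
  sG <- sum(G); sP <- sum(P)
  if (sG + sP == 0) return(1.0)
  2 * sum(G & P) / (sG + sP)
}

#' Volume similarity of two segmentations
#'
#' `1 - |V_G - V_P| / (V_G + V_P)` with volumes in mm^3 (voxel count times
#' voxel volume), so masks on different grids are comparable. Undefined —
#' an error — when both volumes are zero.
#'
#' @param G,P Logical/0-1 arrays (any grids).
#' @param spacing_G,spacing_P Voxel spacings in mm.
#' @return Volume similarity in `[0, 1]`.
#' @export
volume_similarity <- function(G, P, spacing_G = c(1, 1, 1),
                              spacing_P = spacing_G) {
  vG <- sum(as.array(G) != 0) * prod(spacing_G)
  vP <- sum(as.array(P) != 0) * prod(spacing_P)
  if (vG + vP == 0) stop("volume similarity is undefined for two empty masks")
  1 - abs(vG - vP) / (vG + vP)
}

#' Boundary voxels of a binary mask
#'
#' Mask voxels with at least one face-adjacent (6-connectivity) non-mask
#' neighbor; grid-border voxels count as boundary. Coordinates are voxel
#' centers scaled to mm.
#'
#' @param mask Nonempty logical array.
#' @param spacing Voxel spacing in mm.
#' @return n x 3 matrix of boundary coordinates in mm.
#' @export
boundary_voxels <- function(mask, spacing = c(1, 1, 1)) {
  mask <- as.array(mask) != 0
  if (!any(mask)) stop("boundary of an empty mask is undefined")
  d <- dim(mask)
  interior <- array(TRUE, d)
  for (ax in 1:3) {
    # neighbor along +ax and -ax with the grid border treated as background
    shift_arr <- function(m, by) {
      out <- array(FALSE, d)
      src <- dst <- lapply(d, seq_len)
      if (by > 0) { src[[ax]] <- 1:(d[ax] - 1); dst[[ax]] <- 2:d[ax] }
      else { src[[ax]] <- 2:d[ax]; dst[[ax]] <- 1:(d[ax] - 1) }
      out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
      out
    }
    interior <- interior & shift_arr(mask, +1) & shift_arr(mask, -1)
  }
  b <- mask & !interior
  idx <- which(b, arr.ind = TRUE)
  idx * rep(spacing, each = nrow(idx))
}

#' Hausdorff distance between two masks
#'
#' Pools the two directed minimum boundary distances — for every boundary
#' voxel of each mask, the distance to the closest boundary voxel of the
#' other — and takes the maximum (`percentile = 100`, the standard HD) or
#' the 95th nearest-rank percentile (`percentile = 95`, the robust HD95).
#' HD95 <= HD always. Distances are voxel-center to voxel-center in mm.
#'
#' @param G,P Nonempty logical arrays on the same grid.
#' @param spacing Voxel spacing in mm.
#' @param percentile 100 (maximum) or 95 (robust).
#' @return Distance in mm, or `NA_real_` (with a warning) when either
#'   mask is empty — the missing-structure sentinel.
#' @export
hausdorff_distance <- function(G, P, spacing = c(1, 1, 1), percentile = 100) {
  stopifnot(percentile %in% c(95, 100))
  G <- as.array(G) != 0; P <- as.array(P) != 0
  if (!identical(dim(G), dim(P))) stop("masks must share one grid")
  if (!any(G) || !any(P)) {
    warning("empty mask: Hausdorff distance reported as missing")
    return(NA_real_)
  }
  BG <- boundary_voxels(G, spacing)
  BP <- boundary_voxels(P, spacing)
  D <- c(directed_min_dists_cpp(BP, BG), directed_min_dists_cpp(BG, BP))
  if (percentile == 100) return(max(D))
  sort(D)[ceiling(0.95 * length(D))]
}

#' Per-structure metric report
#'
#' One row per protocol structure with Dice, volume similarity, HD and
#' HD95, plus merged-region rows ([aggregate_regions()]) and macro means
#' over the structures present in the ground truth or prediction.
#' Structures absent from both maps are flagged (`present = FALSE`) and
#' excluded from macro means.
#'
#' @param gt,pred [cb_labels()] maps on the same grid.
#' @param protocol A [build_protocol()].
#' @return data.frame with attribute `"macro"` (named vector of macro
#'   means over present structure rows).
#' @export
per_structure_report <- function(gt, pred, protocol = build_protocol()) {
  if (!identical(dim(gt$data), dim(pred$data)))
    stop("ground-truth and prediction grids differ")
  if (!isTRUE(all.equal(gt$spacing, pred$spacing)))
    stop("ground-truth and prediction spacings differ")
  spacing <- gt$spacing
  rows <- function(ids, names, ga, pa) {
    out <- data.frame(label_id = ids, name = names, present = FALSE,
                      dice = NA_real_, volsim = NA_real_,
                      hd_mm = NA_real_, hd95_mm = NA_real_)
    for (i in seq_along(ids)) {
      Gm <- ga == ids[i]; Pm <- pa == ids[i]
      if (!any(Gm) && !any(Pm)) next
      out$present[i] <- TRUE
      out$dice[i] <- dice(Gm, Pm)
      out$volsim[i] <- volume_similarity(Gm, Pm, spacing)
      if (any(Gm) && any(Pm)) {
        out$hd_mm[i] <- hausdorff_distance(Gm, Pm, spacing, 100)
        out$hd95_mm[i] <- hausdorff_distance(Gm, Pm, spacing, 95)
      }
    }
    out
  }
  s <- protocol$structures
  main <- rows(s$label_id, s$name, gt$data, pred$data)
  mids <- merged_region_ids()
  gt_m <- aggregate_regions(gt, protocol)
  pred_m <- aggregate_regions(pred, protocol)
  merged <- rows(unname(mids), names(mids), gt_m$data, pred_m$data)
  merged$name <- paste0("Merged_", merged$name)
  rep <- rbind(main, merged)
  pres <- main$present
  attr(rep, "macro") <- c(
    dice = mean(main$dice[pres], na.rm = TRUE),
    volsim = mean(main$volsim[pres], na.rm = TRUE),
    hd_mm = mean(main$hd_mm[pres], na.rm = TRUE),
    hd95_mm = mean(main$hd95_mm[pres], na.rm = TRUE),
    n_present = sum(pres))
  rep
}

#' Test-retest intraclass correlation (two-way, consistency, single)
#'
#' Relative-agreement ICC for a single fixed rater — Shrout & Fleiss
#' ICC(3,1) — from the two-way ANOVA decomposition of paired per-subject
#' measurements:
#'   ICC = (MS_B - MS_E) / (MS_B + (k-1) MS_E)
#' with MS_B the between-subject and MS_E the residual mean square,
#' k = 2 repetitions. The 95% CI comes from the standard F bounds:
#' F = MS_B / MS_E with (n-1, (n-1)(k-1)) df; the interval endpoints are
#' (F/Fu - 1)/(F/Fu + k - 1) and (F*Fl - 1)/(F*Fl + k - 1) where
#' Fu = F(0.975; n-1, (n-1)(k-1)) and Fl = F(0.975; (n-1)(k-1), n-1).
#'
#' @param scan1_volumes,scan2_volumes Paired per-subject volumes for one
#'   structure (same length, n >= 3).
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `icc_result`: `icc`, `ci_low`, `ci_high`, `n`.
#' @export
icc_agreement <- function(scan1_volumes, scan2_volumes, conf_level = 0.95) {
  n <- length(scan1_volumes)
  if (length(scan2_volumes) != n) stop("paired vectors must have equal length")
  if (n < 3) stop("ICC requires at least 3 subjects")
  Y <- cbind(scan1_volumes, scan2_volumes)
  if (stats::var(rowMeans(Y)) < .Machine$double.eps)
    stop("zero between-subject variance: ICC is undefined for these data")
  k <- 2
  grand <- mean(Y)
  ss_b <- k * sum((rowMeans(Y) - grand)^2)
  ss_r <- n * sum((colMeans(Y) - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  df_e <- (n - 1) * (k - 1)
  ms_b <- ss_b / (n - 1)
  ms_e <- (ss_tot - ss_b - ss_r) / df_e
  # exact agreement leaves only floating-point dust in the residual;
  # snap it to zero so duplicated inputs give ICC = 1 exactly
  if (ms_e <= 1e-10 * ms_b) ms_e <- 0
  icc <- if (ms_b + (k - 1) * ms_e == 0) 1 else
    (ms_b - ms_e) / (ms_b + (k - 1) * ms_e)
  alpha <- 1 - conf_level
  if (ms_e == 0) {
    lo <- hi <- 1
  } else {
    Fobs <- ms_b / ms_e
    Fu <- stats::qf(1 - alpha / 2, n - 1, df_e)
    Fl <- stats::qf(1 - alpha / 2, df_e, n - 1)
    lo <- (Fobs / Fu - 1) / (Fobs / Fu + k - 1)
    hi <- (Fobs * Fl - 1) / (Fobs * Fl + k - 1)
  }
  structure(list(icc = icc, ci_low = min(lo, icc), ci_high = max(hi, icc),
                 n = n), class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(3,1) = %.4f  [%.4f, %.4f]  (n = %d)\n",
              x$icc, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Thin wrapper over [stats::wilcox.test()]: zero differences are
#' dropped (Wilcoxon's convention), the exact null distribution is used
#' for n <= 25 without ties, the normal approximation with continuity
#' correction beyond. Degenerate input (all differences zero) is
#' rejected.
#'
#' @param values_a,values_b Paired samples (n >= 5).
#' @return List with `statistic` (V, rank sum of positive differences)
#'   and `p_value` (two-sided).
#' @export
paired_wilcoxon <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("samples must be paired")
  if (length(values_a) < 5) stop("need at least 5 pairs")
  d <- values_a - values_b
  d <- d[d != 0]
  if (length(d) == 0) stop("degenerate input: all paired differences are zero")
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  ht <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Flag per-class metric outliers
#'
#' Flags values outside mean +/- `n_sd` standard deviations of their
#' class, mirroring the robustness scan of segmentation evaluations.
#'
#' @param values Numeric metric values.
#' @param classes Class labels (same length); a single class if omitted.
#' @param n_sd SD multiplier (default 2.5).
#' @return Logical vector of flags.
#' @export
outlier_scan <- function(values, classes = rep("all", length(values)),
                         n_sd = 2.5) {
  flags <- logical(length(values))
  for (cl in unique(classes)) {
    i <- classes == cl
    if (sum(i) < 3) next
    m <- mean(values[i]); s <- stats::sd(values[i])
    if (s == 0) next
    flags[i] <- abs(values[i] - m) > n_sd * s
  }
  flags
}

#' Write a per-structure report as TSV
#' @param report A [per_structure_report()] data.frame.
#' @param path Output path.
#' @export
write_report_tsv <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
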