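#' End-to-end cerebellum sub-segmentation
#'
#' Full inference path: robust intensity normalization, localization of
#' the working crop around the cerebellum, per-view 2.5D prediction,
#' sagittal lateral expansion, probability-space view aggregation,
#' argmax, and embedding back into the native grid. No bias-field
#' correction and no atlas registration anywhere in the path.
#'
#' @param t1 A [cb_volume()] with ~1 mm isotropic spacing.
#' @param models Named list with `axial`, `coronal`, `sagittal`
#'   `cb_model`s trained under one protocol.
#' @param localization_source A [cb_labels()] on the native grid whose
#'   cerebellar ids drive the bounding box (ground truth at desk scale;
#'   any coarse whole-brain segmentation in production).
#' @param protocol A [build_protocol()].
#' @param crop_side Working crop side in voxels (default 128).
#' @param weights View-aggregation weights (axial, coronal, sagittal).
#' @param spacing_tol Tolerated relative anisotropy before rejection.
#' @return List with `labels` (native-space [cb_labels()]), `report`
#'   ([volumes_from_labels()]), and `box` (the [fit_bounding_box()]).
#' @export
segment_cerebellum <- function(t1, models, localization_source,
                               protocol = build_protocol(),
                               crop_side = 128L, weights = c(1, 1, 0.5),
                               spacing_tol = 0.25) {
  for (v in c("axial", "coronal", "sagittal"))
    if (!inherits(models[[v]], "cb_model"))
      stop("missing checkpoint for the ", v, " view")
  hashes <- vapply(models, function(m) m$config$protocol_hash, character(1))
  if (length(unique(hashes)) != 1 ||
      hashes[[1]] != protocol_hash(protocol))
    stop("refusing to aggregate checkpoints trained under different protocols")
  if (max(abs(t1$spacing / mean(t1$spacing) - 1)) > spacing_tol)
    stop(sprintf("anisotropic spacing (%s mm) beyond tolerance",
                 paste(signif(t1$spacing, 3), collapse = "x")))
  t1 <- normalize_intensity(t1)
  mask <- cerebellum_mask(localization_source)
  box <- fit_bounding_box(mask, side = crop_side)
  crop <- crop_volume(t1, box)

  p_ax <- predict_view(models$axial, extract_stacks(crop, "axial"))
  p_co <- predict_view(models$coronal, extract_stacks(crop, "coronal"))
  p_sa <- expand_sagittal(
    predict_view(models$sagittal, extract_stacks(crop, "sagittal")), protocol)
  agg <- view_aggregate(p_ax, p_co, p_sa, weights)
  crop_labels <- probabilities_to_labels(agg, t1$spacing)
  native <- embed_labels(crop_labels, box)
  native$spacing <- t1$spacing
  list(labels = native, report = volumes_from_labels(native, protocol),
       box = box)
}

#' Tabulated per-structure volume report
#'
#' Exact voxel-count volumes (count times voxel volume in mm^3) for all
#' 27 structures plus the merged evaluation regions.
#'
#' @param labels A [cb_labels()] with spacing.
#' @param protocol A [build_protocol()].
#' @param subject_id Optional subject tag carried into the table.
#' @return data.frame with `label_id`, `name`, `volume_mm3` (27 + 5 rows).
#' @export
volumes_from_labels <- function(labels, protocol = build_protocol(),
                                subject_id = NA_character_) {
  vv <- prod(labels$spacing)
  arr <- labels$data
  s <- protocol$structures
  counts <- tabulate(arr[arr > 0L], nbins = max(s$label_id))
  main <- data.frame(subject = subject_id, label_id = s$label_id,
                     name = s$name,
                     volume_mm3 = counts[s$label_id] * vv)
  agg <- aggregate_regions(labels, protocol)
  mids <- merged_region_ids()
  mcounts <- vapply(mids, function(id) sum(agg$data == id), numeric(1))
  merged <- data.frame(subject = subject_id, label_id = unname(mids),
                       name = paste0("Merged_", names(mids)),
                       volume_mm3 = unname(mcounts) * vv)
  rbind(main, merged)
}

#' Write a volume report as TSV
#' @param report A [volumes_from_labels()] data.frame.
#' @param path Output path.
#' @export
write_volume_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
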