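#' Intensity volume container
#'
#' A 3D intensity grid with isotropic-ish voxel spacing in mm. Axes are
#' assumed to be in R-A-S order: axis 1 left-to-right, axis 2
#' posterior-to-anterior, axis 3 inferior-to-superior. [read_volume()]
#' reorients NIfTI input to this convention.
#'
#' @param data Numeric 3D array.
#' @param spacing Numeric length-3 voxel spacing in mm (default 1 mm iso).
#' @return An object of class `cb_volume`.
#' @export
cb_volume <- function(data, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(data)) == 3, length(spacing) == 3, all(spacing > 0))
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "cb_volume")
}

#' Label map container
#'
#' Integer label grid aligned with a [cb_volume()]. Value 0 is background.
#' @param data Integer 3D array.
#' @inheritParams cb_volume
#' @return An object of class `cb_labels`.
#' @export
cb_labels <- function(data, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(data)) == 3, length(spacing) == 3, all(spacing > 0))
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = as.numeric(spacing)),
            class = "cb_labels")
}

#' @export
print.cb_volume <- function(x, ...) {
  cat("cb_volume:", paste(dim(x$data), collapse = "x"),
      "voxels @", paste(signif(x$spacing, 3), collapse = "x"), "mm\n")
  invisible(x)
}

#' @export
print.cb_labels <- function(x, ...) {
  ids <- setdiff(unique(as.integer(x$data)), 0L)
  cat("cb_labels:", paste(dim(x$data), collapse = "x"),
      "voxels,", length(ids), "nonzero labels\n")
  invisible(x)
}

#' @export
dim.cb_volume <- function(x) dim(x$data)
#' @export
dim.cb_labels <- function(x) dim(x$data)

# internal accessors that tolerate raw arrays
label_data <- function(x) if (inherits(x, c("cb_labels", "cb_volume"))) x$data else as.array(x)
label_spacing <- function(x) if (inherits(x, c("cb_labels", "cb_volume"))) x$spacing else c(1, 1, 1)
replace_label_data <- function(x, arr) {
  if (inherits(x, "cb_labels")) { storage.mode(arr) <- "integer"; x$data <- arr; x }
  else if (inherits(x, "cb_volume")) { x$data <- arr; x }
  else arr
}

#' Robust intensity normalization to [0, 1]
#'
#' Linearly rescales intensities so the 0.1 and 99.9 percentiles map to 0
#' and 1, then clamps. This is the only intensity preprocessing in the
#' pipeline — no bias-field correction, no histogram matching.
#'
#' @param volume A [cb_volume()].
#' @param probs Lower/upper percentile pair.
#' @return Normalized [cb_volume()].
#' @export
normalize_intensity <- function(volume, probs = c(0.001, 0.999)) {
  q <- stats::quantile(volume$data, probs, names = FALSE)
  if (q[2] <= q[1]) q[2] <- q[1] + 1e-8
  volume$data <- pmin(pmax((volume$data - q[1]) / (q[2] - q[1]), 0), 1)
  volume
}

#' Read a NIfTI intensity volume
#'
#' Loads a NIfTI file, reorients to RAS axis order, and returns a
#' [cb_volume()]. The original orientation string is attached as attribute
#' `"orientation"` so outputs can be mapped back.
#' @param path NIfTI file path.
#' @return A [cb_volume()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  orient <- RNifti::orientation(img)
  if (!identical(orient, "RAS")) RNifti::orientation(img) <- "RAS"
  v <- cb_volume(array(as.numeric(img), dim = dim(img)[1:3]),
                 spacing = RNifti::pixdim(img)[1:3])
  attr(v, "orientation") <- orient
  v
}

#' Read a NIfTI label map
#' @inheritParams read_volume
#' @return A [cb_labels()].
#' @export
read_labels <- function(path) {
  img <- RNifti::readNifti(path)
  orient <- RNifti::orientation(img)
  if (!identical(orient, "RAS")) RNifti::orientation(img) <- "RAS"
  l <- cb_labels(array(as.integer(round(as.numeric(img))), dim = dim(img)[1:3]),
                 spacing = RNifti::pixdim(img)[1:3])
  attr(l, "orientation") <- orient
  l
}

#' Write a volume or label map as NIfTI
#'
#' Label maps are written with an integer datatype; an optional JSON
#' sidecar records provenance (spec, bounding box, seed).
#' @param x A [cb_volume()] or [cb_labels()].
#' @param path Output NIfTI path (`.nii` or `.nii.gz`).
#' @param sidecar Optional list serialized to `<path>.json`.
#' @export
write_volume <- function(x, path, sidecar = NULL) {
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing
  datatype <- if (inherits(x, "cb_labels")) "int16" else "float"
  RNifti::writeNifti(img, path, datatype = datatype)
  if (!is.null(sidecar)) {
    jsonlite::write_json(sidecar, paste0(sub("\\.nii(\\.gz)?$", "", path), ".json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}
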