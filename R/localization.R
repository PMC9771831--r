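#' Binary cerebellum mask from a label source
#'
#' Union of the listed structure ids in a label map. At desk scale the
#' source is a ground-truth phantom label map; in production any coarse
#' whole-brain segmentation carrying cerebellar ids works.
#'
#' @param source A [cb_labels()] map on the native grid.
#' @param cerebellar_ids Integer ids to union (default: all 27 protocol ids).
#' @return Logical array.
#' @export
cerebellum_mask <- function(source, cerebellar_ids = build_protocol()$structures$label_id) {
  if (length(cerebellar_ids) == 0) stop("cerebellar_ids must be nonempty")
  arr <- label_data(source)
  mask <- array(arr %in% cerebellar_ids, dim(arr))
  if (!any(mask)) stop("no cerebellum found: mask is empty")
  mask
}

#' Fit the fixed-side working bounding box
#'
#' Places a cube of side `side` symmetrically around the mask: per axis
#' the box is centered on the midpoint of the mask's extent (rounded
#' down), then clamped into the grid. If the grid is smaller than `side`
#' on an axis, the volume is zero-padded to `side` and the padding
#' recorded in the box. A containment warning is emitted when the mask is
#' wider than `side` on any axis; the side never changes.
#'
#' @param mask Nonempty logical array.
#' @param side Box side in voxels on every axis (default 128).
#' @return Object of class `cb_bbox`: list with `start` (0-based voxel
#'   indices into the native grid), `side`, `pad_lo`, `pad_hi`,
#'   `native_shape`.
#' @export
fit_bounding_box <- function(mask, side = 128L) {
  mask <- as.array(mask) != 0
  if (!any(mask)) stop("cannot fit a bounding box around an empty mask")
  d <- dim(mask)
  start <- integer(3); pad_lo <- integer(3); pad_hi <- integer(3)
  for (ax in 1:3) {
    pres <- apply(mask, ax, any)
    lo <- min(which(pres)) - 1L           # 0-based inclusive
    hi <- max(which(pres)) - 1L
    if (hi - lo + 1L > side)
      warning(sprintf("mask extent %d exceeds box side %d on axis %d",
                      hi - lo + 1L, side, ax))
    if (d[ax] >= side) {
      center <- (lo + hi + 1) / 2
      start[ax] <- max(0L, min(as.integer(floor(center - side / 2)),
                               d[ax] - side))
    } else {
      start[ax] <- 0L
      pad_lo[ax] <- as.integer(floor((side - d[ax]) / 2))
      pad_hi[ax] <- side - d[ax] - pad_lo[ax]
    }
  }
  structure(list(start = start, side = as.integer(side),
                 pad_lo = pad_lo, pad_hi = pad_hi,
                 native_shape = d),
            class = "cb_bbox")
}

#' @export
print.cb_bbox <- function(x, ...) {
  cat(sprintf("cb_bbox: side %d at start (%s) in grid (%s)\n", x$side,
              paste(x$start, collapse = ","),
              paste(x$native_shape, collapse = ",")))
  invisible(x)
}

#' Crop a volume or label map to a bounding box
#'
#' Returns a `side`^3 grid; regions outside the native grid are filled
#' with background (0).
#' @param x A [cb_volume()] or [cb_labels()].
#' @param box A [fit_bounding_box()] result.
#' @return Same class as `x`, cropped.
#' @export
crop_volume <- function(x, box) {
  arr <- label_data(x)
  if (!identical(dim(arr), box$native_shape))
    stop("grid shape does not match the bounding box")
  side <- box$side
  out <- array(if (inherits(x, "cb_labels")) 0L else 0, rep(side, 3))
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    s <- (box$start[ax] + 1L):(box$start[ax] + side)
    keep <- s >= 1 & s <= box$native_shape[ax]
    src[[ax]] <- s[keep]
    dst[[ax]] <- which(keep) + box$pad_lo[ax]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  if (inherits(x, "cb_labels")) cb_labels(out, label_spacing(x))
  else if (inherits(x, "cb_volume")) cb_volume(out, label_spacing(x))
  else out
}

#' Embed cropped labels back into the native grid
#'
#' Inverse of [crop_volume()] for label maps: voxels outside the box are
#' background.
#' @param cropped A [cb_labels()] (or integer array) of side `box$side`.
#' @param box The [fit_bounding_box()] used for cropping.
#' @param native_shape Target grid shape (defaults to the box's record).
#' @return A [cb_labels()] on the native grid.
#' @export
embed_labels <- function(cropped, box, native_shape = box$native_shape) {
  arr <- label_data(cropped)
  if (!all(dim(arr) == box$side)) stop("cropped grid does not match box side")
  out <- array(0L, native_shape)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    s <- (box$start[ax] + 1L):(box$start[ax] + box$side)
    keep <- s >= 1 & s <= native_shape[ax]
    dst[[ax]] <- s[keep]
    src[[ax]] <- which(keep) + box$pad_lo[ax]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  cb_labels(out, label_spacing(cropped))
}

#' Serialize a bounding box to a JSON sidecar
#' @param box A `cb_bbox`.
#' @param path Output path.
#' @export
write_bbox_json <- function(box, path) {
  jsonlite::write_json(unclass(box), path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
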