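#' Augmentation configuration
#'
#' Parameter ranges and probabilities for the four augmentation families:
#' in-slice affine (translation/scale/rotation), left-right flip with
#' label-id swapping, additive polynomial bias fields, and non-linear
#' deformation. Defaults are the published ranges: translation -12..12 mm,
#' scale 0.95..1.2, rotation -20..20 degrees, bias coefficients -0.5..0.5.
#'
#' @param translation_mm,scale,rotation_deg Closed sampling ranges.
#' @param flip_prob Probability of a left-right flip per volume.
#' @param affine_prob Probability of applying a sampled affine per slice.
#' @param bias_prob Probability of adding a sampled bias field per volume.
#' @param bias_range Coefficient range of the cubic polynomial basis.
#' @param normalize_before_bias Apply intensity normalization before the
#'   additive bias field (default) or after.
#' @return List of class `augment_config`.
#' @export
augmentation_config <- function(translation_mm = c(-12, 12),
                                scale = c(0.95, 1.2),
                                rotation_deg = c(-20, 20),
                                flip_prob = 0.5,
                                affine_prob = 0.5,
                                bias_prob = 0.5,
                                bias_range = c(-0.5, 0.5),
                                normalize_before_bias = TRUE) {
  structure(list(translation_mm = translation_mm, scale = scale,
                 rotation_deg = rotation_deg, flip_prob = flip_prob,
                 affine_prob = affine_prob, bias_prob = bias_prob,
                 bias_range = bias_range,
                 normalize_before_bias = normalize_before_bias),
            class = "augment_config")
}

#' Write/read an augmentation configuration as YAML
#' @param config An [augmentation_config()].
#' @param path File path.
#' @export
write_augmentation_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_augmentation_yaml
#' @export
read_augmentation_yaml <- function(path) {
  do.call(augmentation_config, yaml::read_yaml(path))
}

#' Sample in-slice affine parameters
#'
#' Each parameter is drawn uniformly from its closed range. Uses the
#' current R random stream (`set.seed()` for determinism).
#'
#' @param config An [augmentation_config()] carrying the ranges.
#' @return List of class `affine_params` with `translation_mm` (length 2),
#'   `scale`, `rotation_deg`.
#' @export
sample_affine <- function(config = augmentation_config()) {
  structure(list(translation_mm = stats::runif(2, config$translation_mm[1],
                                               config$translation_mm[2]),
                 scale = stats::runif(1, config$scale[1], config$scale[2]),
                 rotation_deg = stats::runif(1, config$rotation_deg[1],
                                             config$rotation_deg[2])),
            class = "affine_params")
}

#' Backward-warp matrix of in-slice affine parameters
#'
#' Composes translation, rotation and scaling about the slice center into
#' one 3x3 homogeneous matrix mapping output pixel coordinates (0-based)
#' to source pixel coordinates — the inverse of the forward transform, as
#' needed for backward warping.
#'
#' @param params An `affine_params` object.
#' @param shape Slice shape (rows, cols).
#' @param spacing In-plane pixel spacing in mm.
#' @return 3x3 numeric matrix.
#' @export
affine_matrix <- function(params, shape, spacing = c(1, 1)) {
  if (abs(params$scale) < 1e-12) stop("singular affine: zero scale")
  th <- params$rotation_deg * pi / 180
  R_inv <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)  # R(-th)
  A <- R_inv / params$scale
  ctr <- (shape - 1) / 2
  t_px <- params$translation_mm / spacing
  b <- ctr - A %*% (ctr + t_px)
  rbind(cbind(A, b), c(0, 0, 1))
}

#' Apply an in-slice affine to an image/label slice pair
#'
#' Backward warping: the image is resampled with bilinear interpolation,
#' labels with nearest-neighbor; out-of-field pixels become background.
#'
#' @param image_slice Numeric matrix.
#' @param label_slice Integer matrix of the same shape.
#' @param params An `affine_params` object.
#' @param spacing In-plane spacing in mm.
#' @return List with `image` and `labels`.
#' @export
apply_affine_inplane <- function(image_slice, label_slice, params,
                                 spacing = c(1, 1)) {
  stopifnot(identical(dim(image_slice), dim(label_slice)))
  M <- affine_matrix(params, dim(image_slice), spacing)
  res <- warp_slice_cpp(image_slice, label_slice, M)
  list(image = res$image, labels = res$labels)
}

#' Random left-right flip with label swapping
#'
#' With probability `p`, mirrors both grids across the mid-sagittal plane
#' (the first, left-right axis) and passes label ids through the
#' protocol's left-right bijection, so that mirrored left-hemisphere
#' voxels carry right-hemisphere ids. Midline ids are fixed points.
#'
#' @param volume A [cb_volume()].
#' @param labels A [cb_labels()] on the same grid.
#' @param protocol A [build_protocol()].
#' @param p Flip probability (`p = 1` forces the flip).
#' @return List with `volume`, `labels`, and `flipped` flag.
#' @export
random_lr_flip <- function(volume, labels, protocol = build_protocol(),
                           p = 0.5) {
  stopifnot(identical(dim(volume$data), dim(labels$data)))
  if (stats::runif(1) >= p)
    return(list(volume = volume, labels = labels, flipped = FALSE))
  rev1 <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
  volume$data <- rev1(volume$data)
  labels$data <- rev1(labels$data)
  labels <- swap_lateral_labels(labels, protocol)
  list(volume = volume, labels = labels, flipped = TRUE)
}

# monomial exponents of the cubic trivariate basis, graded lexicographic
bias_basis_exponents <- function() {
  ex <- expand.grid(a = 0:3, b = 0:3, c = 0:3)
  ex <- ex[ex$a + ex$b + ex$c <= 3, ]
  ex <- ex[order(ex$a + ex$b + ex$c, -ex$a, -ex$b, -ex$c), ]
  rownames(ex) <- NULL
  ex
}

#' Sample bias-field coefficients
#'
#' 20 coefficients — one per trivariate monomial `x^a y^b z^c` with
#' `a + b + c <= 3` in graded lexicographic order — drawn uniformly from
#' `range`.
#' @param range Coefficient range (default -0.5..0.5).
#' @return Numeric vector of length 20.
#' @export
sample_bias_coeffs <- function(range = c(-0.5, 0.5)) {
  stats::runif(20, range[1], range[2])
}

# evaluate the polynomial field on normalized [-1,1]^3 coordinates
bias_field_from_coeffs <- function(grid_shape, coeffs) {
  stopifnot(length(coeffs) == 20)
  ex <- bias_basis_exponents()
  u <- lapply(grid_shape, function(n)
    if (n > 1) 2 * (seq_len(n) - 1) / (n - 1) - 1 else 0)
  field <- array(0, grid_shape)
  for (k in seq_len(20)) {
    if (coeffs[k] == 0) next
    field <- field + coeffs[k] *
      outer(outer(u[[1]]^ex$a[k], u[[2]]^ex$b[k]), u[[3]]^ex$c[k])
  }
  field
}

#' Sample a polynomial bias field
#'
#' Linear combination of randomly weighted cubic polynomial basis
#' functions on coordinates normalized to `[-1, 1]^3`.
#' @param grid_shape Integer length-3.
#' @param coeffs Optional fixed coefficients (length 20); sampled from
#'   `range` when `NULL`.
#' @param range Coefficient range.
#' @return 3D array; attribute `"coeffs"` carries the coefficients.
#' @export
sample_bias_field <- function(grid_shape, coeffs = NULL,
                              range = c(-0.5, 0.5)) {
  if (is.null(coeffs)) coeffs <- sample_bias_coeffs(range)
  field <- bias_field_from_coeffs(grid_shape, coeffs)
  attr(field, "coeffs") <- coeffs
  field
}

#' Add a bias field to a volume
#'
#' The inhomogeneity field is linearly superimposed: output = input +
#' field, on the volume's normalized `[0, 1]` intensity scale.
#' @param volume A [cb_volume()].
#' @param field Array from [sample_bias_field()] (same grid).
#' @return Biased [cb_volume()].
#' @export
apply_bias <- function(volume, field) {
  stopifnot(identical(dim(volume$data), dim(field)))
  volume$data <- volume$data + as.numeric(field)
  dim(volume$data) <- dim(field)
  volume
}

#' Warp a volume/label pair with a displacement field
#'
#' Backward warping: each output voxel samples the input at its position
#' plus the field's displacement (mm). Image trilinear, labels
#' nearest-neighbor, out-of-field voxels become background — nearest-
#' neighbor resampling can never invent label ids.
#'
#' @param volume A [cb_volume()].
#' @param labels A [cb_labels()] on the same grid.
#' @param field A `cb_dispfield` from [generate_displacement_field()].
#' @return List with warped `volume` and `labels`.
#' @export
apply_displacement <- function(volume, labels, field) {
  stopifnot(inherits(field, "cb_dispfield"))
  d <- dim(volume$data)
  if (!identical(d, dim(labels$data)) || !identical(d, dim(field$field)[1:3]))
    stop("volume, labels and field grids must match")
  fv <- field$field
  for (c in 1:3) fv[, , , c] <- fv[, , , c] / volume$spacing[c]
  res <- warp_volume_cpp(volume$data, labels$data, fv)
  list(volume = cb_volume(res$volume, volume$spacing),
       labels = cb_labels(res$labels, labels$spacing))
}

#' Build a static non-linearly deformed training set
#'
#' Applies each displacement field to one training case such that every
#' case is used at least once; outputs carry provenance (case id, field
#' id). Pairing is drawn from the current R random stream.
#'
#' @param cases List of lists with `volume` and `labels`.
#' @param fields List of `cb_dispfield` objects (at least as many as cases).
#' @return List of lists `(volume, labels, case_id, field_id)`.
#' @export
build_static_deformed_set <- function(cases, fields) {
  n_c <- length(cases); n_f <- length(fields)
  if (n_c == 0 || n_f == 0) stop("cases and fields must be nonempty")
  if (n_f < n_c)
    stop("need at least as many fields as cases so every case is used once")
  assign <- c(sample.int(n_c), sample.int(n_c, n_f - n_c, replace = TRUE))
  out <- vector("list", n_f)
  for (f in seq_len(n_f)) {
    ci <- assign[f]
    wrp <- apply_displacement(cases[[ci]]$volume, cases[[ci]]$labels,
                              fields[[f]])
    out[[f]] <- list(volume = wrp$volume, labels = wrp$labels,
                     case_id = ci, field_id = f)
  }
  out
}
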