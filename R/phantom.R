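#' Phantom specification
#'
#' Describes a procedurally generated cerebellum-like phantom: two
#' ellipsoidal gray-matter hemispheres flanking a midline vermis slab, a
#' branching white-matter core per hemisphere, the 27-structure label
#' protocol, T1-like intensity contrast (WM > GM > background) with
#' additive Gaussian noise, optional smooth multiplicative intensity
#' drift, and a controllable degree of atrophy.
#'
#' Geometric defaults scale with the grid so the phantom stays inside a
#' crop of 3/4 of the grid extent. Atrophy `a` shrinks the outer radii by
#' factor `1 - 0.25 a`, thins the cortical clearance by `1 - a`, and
#' erodes the white-matter branch radius by `1 - 0.5 a`, so both gray and
#' white matter lose volume monotonically.
#'
#' @param grid_shape Integer length-3 (default `c(96, 96, 96)`).
#' @param spacing_mm Voxel spacing in mm (default 1 mm isotropic).
#' @param hemisphere_radii_mm Ellipsoid radii (LR, PA, IS) in mm; default
#'   `c(0.15, 0.21, 0.18) * min(extent)`.
#' @param cortical_thickness_mm Minimum gray clearance between white
#'   matter and the pial surface; default `0.10 * min(extent)`.
#' @param n_lobule_sectors Angular lobule sectors per hemisphere (10).
#' @param vermis_halfwidth_mm Half-width of the midline vermis slab;
#'   default `0.055 * min(extent)`.
#' @param wm_branch_count Primary white-matter branches per hemisphere.
#' @param wm_branch_radius_mm Dilation radius of branch strokes in mm.
#' @param noise_sd Additive Gaussian noise SD as a fraction of the GM mean.
#' @param drift_amplitude Amplitude of the optional smooth multiplicative
#'   intensity drift (0 disables it).
#' @param atrophy Degree of atrophy in `[0, 1]`.
#' @param subject_jitter Relative anatomical variability (radii/center)
#'   between subjects sharing a base seed.
#' @param intensity_means Named vector `c(background=, gm=, wm=)` on a
#'   `[0, 1]` scale.
#' @param seed Integer seed; all randomness flows through it via streams
#'   keyed by (seed, subject, purpose).
#' @param subject Subject index for the anatomy stream (default 1).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96),
                         spacing_mm = c(1, 1, 1),
                         hemisphere_radii_mm = NULL,
                         cortical_thickness_mm = NULL,
                         n_lobule_sectors = 10L,
                         vermis_halfwidth_mm = NULL,
                         wm_branch_count = 6L,
                         wm_branch_radius_mm = 1.8,
                         noise_sd = 0.1,
                         drift_amplitude = 0,
                         atrophy = 0,
                         subject_jitter = 0.04,
                         intensity_means = c(background = 0.1, gm = 0.5, wm = 0.8),
                         seed = 1L,
                         subject = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 16),
            all(spacing_mm > 0), atrophy >= 0, atrophy <= 1,
            noise_sd >= 0, n_lobule_sectors == 10L)
  ext <- min(grid_shape * spacing_mm)
  if (is.null(hemisphere_radii_mm)) hemisphere_radii_mm <- c(0.15, 0.21, 0.18) * ext
  if (is.null(cortical_thickness_mm)) cortical_thickness_mm <- 0.10 * ext
  if (is.null(vermis_halfwidth_mm)) vermis_halfwidth_mm <- 0.055 * ext
  if (cortical_thickness_mm * (1 - atrophy) < max(spacing_mm))
    stop("cortical_thickness_mm * (1 - atrophy) must cover at least one voxel")
  if (2 * (vermis_halfwidth_mm + 1.9 * hemisphere_radii_mm[1]) > grid_shape[1] * spacing_mm[1])
    stop("grid too small to contain both hemispheres at these radii")
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 hemisphere_radii_mm = hemisphere_radii_mm,
                 cortical_thickness_mm = cortical_thickness_mm,
                 n_lobule_sectors = as.integer(n_lobule_sectors),
                 vermis_halfwidth_mm = vermis_halfwidth_mm,
                 wm_branch_count = as.integer(wm_branch_count),
                 wm_branch_radius_mm = wm_branch_radius_mm,
                 noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude,
                 atrophy = atrophy,
                 subject_jitter = subject_jitter,
                 intensity_means = intensity_means,
                 seed = as.integer(seed),
                 subject = as.integer(subject)),
            class = "phantom_spec")
}

# deterministic RNG streams keyed by (seed, subject, purpose); adding new
# purposes never perturbs existing draws
stream_seed <- function(seed, subject, purpose) {
  pid <- switch(purpose, anatomy = 1, wm = 2, noise1 = 3, noise2 = 4,
                drift = 5, field = 6, cohort = 7, stop("unknown stream"))
  as.integer((as.numeric(seed) + subject * 1000003 + pid * 7777777) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# voxel-center coordinate grids in mm
coord_grids <- function(shape, spacing) {
  list(x = (seq_len(shape[1]) - 0.5) * spacing[1],
       y = (seq_len(shape[2]) - 0.5) * spacing[2],
       z = (seq_len(shape[3]) - 0.5) * spacing[3])
}

#' Generate a cerebellum phantom
#'
#' Builds the ground-truth label map (all 27 protocol structures for the
#' default spec) and a matching T1-like intensity volume. Bit-identical
#' for equal specs.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` ([cb_volume()]), `labels` ([cb_labels()]),
#'   and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- phantom_labels(spec)
  volume <- phantom_intensity(labels, spec, noise_stream = "noise1")
  list(volume = volume, labels = labels, spec = spec)
}

# anatomy (labels) only; deterministic in (seed, subject)
phantom_labels <- function(spec) {
  shape <- spec$grid_shape; sp <- spec$spacing_mm
  ctr <- shape * sp / 2
  a <- spec$atrophy
  # radii/center vary per subject (both are observable from the image);
  # sector boundary angles are deterministic in the hemisphere-local frame
  # because the phantom carries no fissure contrast that could signal them
  anat <- with_seed(stream_seed(spec$seed, spec$subject, "anatomy"), {
    j <- spec$subject_jitter
    list(radii_scale = 1 + stats::runif(3, -j, j),
         center_shift = stats::runif(3, -1.5, 1.5) * j / 0.04)
  })
  radii <- spec$hemisphere_radii_mm * anat$radii_scale * (1 - 0.25 * a)
  thick <- spec$cortical_thickness_mm * (1 - a)
  hw <- spec$vermis_halfwidth_mm
  ctr <- ctr + anat$center_shift

  g <- coord_grids(shape, sp)
  dx <- g$x - ctr[1]
  lab <- array(0L, shape)

  for (side in c("left", "right")) {
    sgn <- if (side == "left") -1 else 1
    hcx <- ctr[1] + sgn * (hw + 0.9 * radii[1])
    lx <- g$x - hcx; ly <- g$y - ctr[2]; lz <- g$z - ctr[3]
    # normalized squared radius of the outer ellipsoid
    r2 <- outer(outer((lx / radii[1])^2, (ly / radii[2])^2, "+"),
                (lz / radii[3])^2, "+")
    xside <- if (side == "left") dx < -hw else dx > hw
    inside <- r2 <= 1 & array(xside, shape)
    # angular lobule sectors about the left-right axis
    ang <- outer(outer(rep(0, shape[1]), ly, "+"), lz,
                 function(yv, zv) atan2(yv, zv))
    ang <- ang %% (2 * pi)
    sector <- pmin(floor(ang / (2 * pi / spec$n_lobule_sectors)) + 1L,
                   spec$n_lobule_sectors)
    base <- if (side == "left") 0L else 10L
    lab[inside] <- base + as.integer(sector[inside])
    # white-matter tree clipped inside the inner ellipsoid
    inner <- pmax(radii - thick, max(sp))
    wm <- wm_tree_mask(spec, side, c(hcx, ctr[2], ctr[3]), inner, g, shape, a)
    r2in <- outer(outer((lx / inner[1])^2, (ly / inner[2])^2, "+"),
                  (lz / inner[3])^2, "+")
    wm <- wm & r2in <= 1 & inside
    lab[wm] <- if (side == "left") 26L else 27L
  }

  # midline vermis slab, 5 angular sectors
  vr <- c(hw, 0.85 * radii[2], 0.85 * radii[3])
  vx <- dx; vy <- g$y - ctr[2]; vz <- g$z - ctr[3]
  r2v <- outer(outer((vx / vr[1])^2, (vy / vr[2])^2, "+"),
               (vz / vr[3])^2, "+")
  vin <- r2v <= 1 & array(abs(dx) <= hw, shape)
  angv <- outer(outer(rep(0, shape[1]), vy, "+"), vz,
                function(yv, zv) atan2(yv, zv))
  angv <- angv %% (2 * pi)
  sectv <- pmin(floor(angv / (2 * pi / 5)) + 1L, 5L)
  lab[vin] <- 20L + as.integer(sectv[vin])

  cb_labels(lab, sp)
}

# branching stroke tree: primary branches from the hemisphere center plus
# one child each, dilated by the (atrophy-eroded) branch radius
wm_tree_mask <- function(spec, side, center, inner, g, shape, atrophy) {
  sgn <- if (side == "left") -1 else 1
  dirs <- with_seed(stream_seed(spec$seed, spec$subject,  "wm"), {
    n <- spec$wm_branch_count
    th <- stats::runif(2 * n, 0, 2 * pi)
    u <- stats::runif(2 * n, -1, 1)
    keep <- if (side == "left") seq_len(n) else n + seq_len(n)
    cbind(sqrt(1 - u[keep]^2) * cos(th[keep]),
          sqrt(1 - u[keep]^2) * sin(th[keep]), u[keep])
  })
  rad <- spec$wm_branch_radius_mm * (1 - 0.5 * atrophy)
  pts <- matrix(numeric(0), ncol = 3)
  for (b in seq_len(nrow(dirs))) {
    d <- dirs[b, ]
    tip <- center + d * inner * 0.75
    s <- seq(0, 1, length.out = 24)
    pts <- rbind(pts, cbind(center[1] + s * (tip[1] - center[1]),
                            center[2] + s * (tip[2] - center[2]),
                            center[3] + s * (tip[3] - center[3])))
    # child branch from the midpoint, direction rotated toward another branch
    mid <- (center + tip) / 2
    d2 <- dirs[(b %% nrow(dirs)) + 1, ]
    child <- mid + (d + d2) / sqrt(sum((d + d2)^2) + 1e-9) * inner * 0.35
    s2 <- seq(0, 1, length.out = 12)
    pts <- rbind(pts, cbind(mid[1] + s2 * (child[1] - mid[1]),
                            mid[2] + s2 * (child[2] - mid[2]),
                            mid[3] + s2 * (child[3] - mid[3])))
  }
  sp <- spec$spacing_mm
  mask <- array(FALSE, shape)
  rv <- ceiling(rad / sp)
  off <- as.matrix(expand.grid(-rv[1]:rv[1], -rv[2]:rv[2], -rv[3]:rv[3]))
  off <- off[rowSums((off * rep(sp, each = nrow(off)))^2) <= rad^2, , drop = FALSE]
  vox <- cbind(round(pts[, 1] / sp[1] + 0.5), round(pts[, 2] / sp[2] + 0.5),
               round(pts[, 3] / sp[3] + 0.5))
  vox <- unique(vox)
  for (r in seq_len(nrow(vox))) {
    at <- sweep(off, 2, as.numeric(vox[r, ]), "+")
    ok <- at[, 1] >= 1 & at[, 1] <= shape[1] & at[, 2] >= 1 &
      at[, 2] <= shape[2] & at[, 3] >= 1 & at[, 3] <= shape[3]
    mask[at[ok, , drop = FALSE]] <- TRUE
  }
  mask
}

# intensity synthesis from a label map
phantom_intensity <- function(labels, spec, noise_stream = "noise1") {
  m <- spec$intensity_means
  arr <- labels$data
  img <- array(m[["background"]], dim(arr))
  img[arr >= 1 & arr <= 25] <- m[["gm"]]
  img[arr >= 26] <- m[["wm"]]
  if (spec$drift_amplitude > 0) {
    coeffs <- with_seed(stream_seed(spec$seed, spec$subject, "drift"),
                        stats::runif(20, -spec$drift_amplitude,
                                     spec$drift_amplitude))
    img <- img * (1 + bias_field_from_coeffs(dim(arr), coeffs))
  }
  noise <- with_seed(stream_seed(spec$seed, spec$subject, noise_stream),
                     stats::rnorm(length(img), 0, spec$noise_sd * m[["gm"]]))
  img <- img + array(noise, dim(arr))
  cb_volume(img, spec$spacing_mm)
}

#' Generate a test-retest phantom pair
#'
#' Two intensity volumes sharing one anatomy (one label map) with
#' independent noise draws; optionally the second scan is shifted by a
#' small rigid jitter applied consistently to image and labels.
#'
#' @param spec A [phantom_spec()].
#' @param jitter_mm Rigid translation applied to the second scan (length-3
#'   mm vector, default none).
#' @return List with `volume1`, `volume2`, `labels` (scan-1 anatomy) and
#'   `labels2` (scan-2 anatomy; identical to `labels` without jitter).
#' @export
generate_retest_pair <- function(spec, jitter_mm = c(0, 0, 0)) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- phantom_labels(spec)
  v1 <- phantom_intensity(labels, spec, noise_stream = "noise1")
  v2 <- phantom_intensity(labels, spec, noise_stream = "noise2")
  labels2 <- labels
  if (any(jitter_mm != 0)) {
    field <- constant_field(dim(labels$data), -jitter_mm, spec$spacing_mm)
    wrp <- apply_displacement(v2, labels, field)
    v2 <- wrp$volume; labels2 <- wrp$labels
  }
  list(volume1 = v1, volume2 = v2, labels = labels, labels2 = labels2,
       spec = spec)
}

#' Generate an atrophy cohort
#'
#' Independent subjects (seed streams keyed by subject index) at the
#' requested atrophy levels; group mean gray-matter volume decreases with
#' the level by construction.
#'
#' @param n_per_group Subjects per atrophy level (>= 1).
#' @param atrophy_levels Numeric vector of atrophy degrees in `[0, 1]`.
#' @param base_spec A [phantom_spec()] serving as template.
#' @return List of per-subject lists `(volume, labels, group, atrophy,
#'   subject)`.
#' @export
generate_cohort <- function(n_per_group, atrophy_levels, base_spec) {
  stopifnot(n_per_group >= 1)
  if (length(atrophy_levels) == 0) stop("atrophy_levels must be nonempty")
  out <- list()
  subj <- 0L
  for (lev in atrophy_levels) {
    for (i in seq_len(n_per_group)) {
      subj <- subj + 1L
      sp <- base_spec
      sp$atrophy <- lev
      sp$subject <- subj
      ph <- generate_phantom(sp)
      out[[subj]] <- list(volume = ph$volume, labels = ph$labels,
                          group = sprintf("atrophy_%g", lev),
                          atrophy = lev, subject = subj)
    }
  }
  out
}

#' Generate a synthetic smooth displacement field
#'
#' Smoothed white-noise vector field rescaled so the maximum displacement
#' magnitude equals `max_disp_mm` and tapered to zero on the grid
#' boundary. A synthetic stand-in for deformation fields obtained by
#' cross-subject registration of real scans.
#'
#' @param grid_shape Integer length-3.
#' @param spacing_mm Voxel spacing.
#' @param max_disp_mm Maximum displacement magnitude in mm (>= 0).
#' @param smoothness_mm Gaussian kernel scale in mm (> 0).
#' @param seed Integer seed.
#' @return Object of class `cb_dispfield`: list with `field`
#'   (X x Y x Z x 3 array, mm), `spacing_mm`, `max_disp_mm`,
#'   `smoothness_mm`.
#' @export
generate_displacement_field <- function(grid_shape, spacing_mm = c(1, 1, 1),
                                        max_disp_mm = 4, smoothness_mm = 8,
                                        seed = 1L) {
  if (max_disp_mm < 0) stop("max_disp_mm must be >= 0")
  if (smoothness_mm <= 0) stop("smoothness_mm must be positive")
  shape <- as.integer(grid_shape)
  field <- array(0, c(shape, 3))
  if (max_disp_mm > 0) {
    raw <- with_seed(stream_seed(seed, 0L, "field"),
                     array(stats::rnorm(prod(shape) * 3), c(shape, 3)))
    for (c in 1:3)
      raw[, , , c] <- gauss_smooth3(raw[, , , c], smoothness_mm / spacing_mm)
    taper <- boundary_taper(shape, ceiling(smoothness_mm / min(spacing_mm)))
    for (c in 1:3) raw[, , , c] <- raw[, , , c] * taper
    mag <- sqrt(raw[, , , 1]^2 + raw[, , , 2]^2 + raw[, , , 3]^2)
    mmax <- max(mag)
    if (mmax > 0) field <- raw * (max_disp_mm / mmax)
  }
  structure(list(field = field, spacing_mm = as.numeric(spacing_mm),
                 max_disp_mm = max_disp_mm, smoothness_mm = smoothness_mm),
            class = "cb_dispfield")
}

constant_field <- function(shape, disp_mm, spacing_mm) {
  field <- array(0, c(shape, 3))
  for (c in 1:3) field[, , , c] <- disp_mm[c]
  structure(list(field = field, spacing_mm = spacing_mm,
                 max_disp_mm = sqrt(sum(disp_mm^2)), smoothness_mm = Inf),
            class = "cb_dispfield")
}

# separable Gaussian smoothing; sigma in voxels per axis
gauss_smooth3 <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[min(ax, length(sigma_vox))]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-half:half, sd = s)
    k <- k / sum(k)
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(arr, perm)
    dm <- dim(m)
    mat <- matrix(m, nrow = dm[1])
    pad <- matrix(0, half, ncol(mat))
    fmat <- rbind(pad, mat, pad)
    sm <- stats::filter(fmat, k, sides = 2)
    sm <- sm[(half + 1):(half + dm[1]), , drop = FALSE]
    sm[is.na(sm)] <- 0
    arr <- aperm(array(sm, dm), order(perm))
  }
  arr
}

# per-voxel weight rising linearly from 0 at the boundary over `width` voxels
boundary_taper <- function(shape, width) {
  w1 <- function(n) pmin(1, pmin(seq_len(n) - 1, n - seq_len(n)) / width)
  tx <- w1(shape[1]); ty <- w1(shape[2]); tz <- w1(shape[3])
  outer(outer(tx, ty), tz)
}
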