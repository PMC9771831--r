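# Shared fixtures and independent oracles for the test suite.

# random binary mask with at least one voxel
random_mask <- function(shape, p = 0.2) {
  m <- array(stats::runif(prod(shape)) < p, shape)
  if (!any(m)) m[ceiling(shape / 2)[1], ceiling(shape / 2)[2],
                 ceiling(shape / 2)[3]] <- TRUE
  m
}

# --- brute-force oracles (independent of the package implementation) ------

oracle_boundary <- function(mask, spacing) {
  d <- dim(mask)
  pts <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    is_b <- FALSE
    for (r in 1:6) {
      q <- nb[r, ]
      if (any(q < 1) || any(q > d)) { is_b <- TRUE; break }
      if (!mask[q[1], q[2], q[3]]) { is_b <- TRUE; break }
    }
    if (is_b) pts <- rbind(pts, c(i, j, k) * spacing)
  }
  pts
}

oracle_hausdorff <- function(G, P, spacing, percentile) {
  BG <- oracle_boundary(G, spacing)
  BP <- oracle_boundary(P, spacing)
  dm <- function(A, B) {
    apply(A, 1, function(a) min(sqrt(colSums((t(B) - a)^2))))
  }
  D <- c(dm(BP, BG), dm(BG, BP))
  if (percentile == 100) max(D) else sort(D)[ceiling(0.95 * length(D))]
}

oracle_dice <- function(G, P) {
  inter <- 0; sg <- 0; sp <- 0
  for (i in seq_along(G)) {
    if (G[i]) sg <- sg + 1
    if (P[i]) sp <- sp + 1
    if (G[i] && P[i]) inter <- inter + 1
  }
  if (sg + sp == 0) 1 else 2 * inter / (sg + sp)
}

# exhaustive signed-rank null: two-sided p for observed V over all 2^n
# sign assignments of the ranked absolute differences
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  ev <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-12)
}

# small prepared phantom case for pipeline-level tests
small_case <- function(seed = 5, subject = 1, grid = 48, crop = 36,
                       atrophy = 0) {
  spec <- phantom_spec(grid_shape = rep(grid, 3), atrophy = atrophy,
                       seed = seed, subject = subject)
  ph <- generate_phantom(spec)
  box <- fit_bounding_box(cerebellum_mask(ph$labels), side = crop)
  list(volume = normalize_intensity(crop_volume(ph$volume, box)),
       labels = crop_volume(ph$labels, box),
       native_volume = ph$volume, native_labels = ph$labels, box = box)
}
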