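test_that("sampled affine parameters stay inside the printed ranges", {
  cfg <- augmentation_config()
  set.seed(1)
  draws <- replicate(10000, unlist(sample_affine(cfg)[c(
    "translation_mm", "scale", "rotation_deg")]))
  tr <- draws[1:2, ]; sc <- draws[3, ]; ro <- draws[4, ]
  expect_gte(min(tr), -12); expect_lte(max(tr), 12)
  expect_gte(min(sc), 0.95); expect_lte(max(sc), 1.2)
  expect_gte(min(ro), -20); expect_lte(max(ro), 20)
  expect_lt(abs(mean(tr)), 0.3)             # centered translation
  # fixed seed reproduces parameters
  set.seed(99); a <- sample_affine(cfg)
  set.seed(99); b <- sample_affine(cfg)
  expect_identical(a, b)
  # degenerate ranges collapse to a point
  cfg0 <- augmentation_config(translation_mm = c(3, 3), scale = c(1, 1),
                              rotation_deg = c(0, 0))
  p0 <- sample_affine(cfg0)
  expect_equal(p0$translation_mm, c(3, 3))
  expect_equal(p0$scale, 1)
})

test_that("identity affine is a bit-exact no-op", {
  par <- structure(list(translation_mm = c(0, 0), scale = 1,
                        rotation_deg = 0), class = "affine_params")
  img <- matrix(stats::runif(32 * 32), 32, 32)
  lab <- matrix(sample(0:5, 32 * 32, TRUE), 32, 32)
  res <- apply_affine_inplane(img, lab, par)
  expect_equal(res$image, img, tolerance = 1e-12)
  expect_identical(res$labels, lab)
  expect_error(affine_matrix(structure(list(translation_mm = c(0, 0),
                                            scale = 0, rotation_deg = 0),
                                       class = "affine_params"), c(32, 32)),
               "singular")
})

test_that("integer-voxel translations shift labels exactly", {
  par <- structure(list(translation_mm = c(3, -2), scale = 1,
                        rotation_deg = 0), class = "affine_params")
  lab <- matrix(0L, 24, 24); lab[8:12, 10:15] <- 7L
  img <- matrix(stats::runif(24 * 24), 24, 24)
  res <- apply_affine_inplane(img, lab, par)
  ref <- matrix(0L, 24, 24)
  ref[8:12 + 3, 10:15 - 2] <- 7L
  expect_identical(res$labels, ref)
  expect_true(all(unique(as.vector(res$labels)) %in% c(0L, 7L)))
})

test_that("four composed 90-degree rotations reproduce labels on a square", {
  rot90 <- structure(list(translation_mm = c(0, 0), scale = 1,
                          rotation_deg = 90), class = "affine_params")
  lab <- matrix(sample(0:3, 20 * 20, TRUE), 20, 20)
  img <- matrix(stats::runif(20 * 20), 20, 20)
  cur_i <- img; cur_l <- lab
  for (k in 1:4) {
    res <- apply_affine_inplane(cur_i, cur_l, rot90)
    cur_i <- res$image; cur_l <- res$labels
  }
  expect_identical(cur_l, lab)
})

test_that("left-right flip mirrors, swaps ids and is an involution", {
  p <- build_protocol()
  cs <- small_case()
  f1 <- random_lr_flip(cs$volume, cs$labels, p, p = 1)
  expect_true(f1$flipped)
  f2 <- random_lr_flip(f1$volume, f1$labels, p, p = 1)
  expect_identical(f2$volume$data, cs$volume$data)
  expect_identical(f2$labels$data, cs$labels$data)
  # a left-hemisphere voxel lands mirrored carrying the right id
  left_vox <- which(cs$labels$data == 4L, arr.ind = TRUE)[1, ]  # Left_Crus_I
  d1 <- dim(cs$labels$data)[1]
  expect_equal(f1$labels$data[d1 + 1 - left_vox[1], left_vox[2], left_vox[3]],
               14L)                                             # Right_Crus_I
  # vermis voxels keep their ids (positions mirrored)
  verm <- which(cs$labels$data == 23L, arr.ind = TRUE)[1, ]
  expect_equal(f1$labels$data[d1 + 1 - verm[1], verm[2], verm[3]], 23L)
  # p = 0 never flips
  f0 <- random_lr_flip(cs$volume, cs$labels, p, p = 0)
  expect_false(f0$flipped)
})

test_that("bias basis has 20 cubic monomials and the stated no-ops", {
  ex <- cerebseg:::bias_basis_exponents()
  expect_equal(nrow(ex), 20)
  expect_true(all(ex$a + ex$b + ex$c <= 3))
  expect_equal(ex[1, ], data.frame(a = 0, b = 0, c = 0), ignore_attr = TRUE)
  f0 <- sample_bias_field(c(8, 8, 8), coeffs = rep(0, 20))
  v <- cb_volume(array(stats::runif(8^3), c(8, 8, 8)))
  expect_equal(apply_bias(v, f0)$data, v$data, tolerance = 1e-15)
  # constant term only: every voxel shifted by the coefficient
  fc <- sample_bias_field(c(8, 8, 8), coeffs = c(0.3, rep(0, 19)))
  expect_equal(apply_bias(v, fc)$data, v$data + 0.3, tolerance = 1e-12)
})

test_that("bias fields obey the triangle-inequality bound", {
  set.seed(12)
  for (rep in 1:20) {
    co <- sample_bias_coeffs()
    expect_true(all(co >= -0.5 & co <= 0.5))
    f <- sample_bias_field(c(9, 7, 8), coeffs = co)
    expect_lte(max(abs(f)), sum(abs(co)) + 1e-12)
    expect_lte(sum(abs(co)), 10)
  }
})

test_that("displacement warping has exact no-op and shift behavior", {
  cs <- small_case()
  zero <- cerebseg:::constant_field(dim(cs$volume$data), c(0, 0, 0), c(1, 1, 1))
  res <- apply_displacement(cs$volume, cs$labels, zero)
  expect_equal(res$volume$data, cs$volume$data, tolerance = 1e-12)
  expect_identical(res$labels$data, cs$labels$data)
  # constant integer displacement equals a direct index shift
  sh <- cerebseg:::constant_field(dim(cs$volume$data), c(2, 0, -1), c(1, 1, 1))
  res2 <- apply_displacement(cs$volume, cs$labels, sh)
  d <- dim(cs$labels$data)
  ref <- array(0L, d)
  ref[1:(d[1] - 2), , 2:d[3]] <- cs$labels$data[3:d[1], , 1:(d[3] - 1)]
  expect_identical(res2$labels$data, ref)
  # warping never invents label ids
  f <- generate_displacement_field(dim(cs$volume$data), max_disp_mm = 4,
                                   smoothness_mm = 5, seed = 2)
  res3 <- apply_displacement(cs$volume, cs$labels, f)
  expect_true(all(unique(as.integer(res3$labels$data)) %in%
                    c(0L, unique(as.integer(cs$labels$data)))))
  expect_error(apply_displacement(cs$volume, cb_labels(array(0L, c(4, 4, 4))),
                                  f), "match")
})

test_that("static deformed sets use every case at least once", {
  cs <- small_case(grid = 32, crop = 24)
  cases <- list(list(volume = cs$volume, labels = cs$labels),
                list(volume = cs$volume, labels = cs$labels),
                list(volume = cs$volume, labels = cs$labels))
  fields <- lapply(1:7, function(k)
    generate_displacement_field(rep(24, 3), max_disp_mm = 2,
                                smoothness_mm = 4, seed = k))
  set.seed(5)
  aug <- build_static_deformed_set(cases, fields)
  expect_length(aug, 7)
  expect_setequal(unique(vapply(aug, `[[`, numeric(1), "case_id")), 1:3)
  expect_equal(vapply(aug, `[[`, numeric(1), "field_id"), 1:7)
  # single case, several fields
  aug1 <- build_static_deformed_set(cases[1], fields[1:3])
  expect_length(aug1, 3)
  expect_true(all(vapply(aug1, `[[`, numeric(1), "case_id") == 1))
  # deterministic pairing under a fixed seed
  set.seed(5); a <- build_static_deformed_set(cases, fields)
  set.seed(5); b <- build_static_deformed_set(cases, fields)
  expect_identical(vapply(a, `[[`, numeric(1), "case_id"),
                   vapply(b, `[[`, numeric(1), "case_id"))
  expect_error(build_static_deformed_set(list(), fields), "nonempty")
  expect_error(build_static_deformed_set(cases, fields[1:2]), "at least")
})
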