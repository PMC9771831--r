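test_that("slice stacks have 7 edge-replicated channels per slice", {
  v <- cb_volume(array(seq_len(16^3) / 16^3, c(16, 16, 16)))
  for (plane in c("axial", "coronal", "sagittal")) {
    st <- extract_stacks(v, plane)
    expect_equal(st$n, 16)
    expect_length(st$stacks, 16)
    expect_equal(dim(st$stacks[[1]]), c(16, 16, 7))
    # middle channel is the target slice
    expect_equal(st$stacks[[8]][, , 4],
                 cerebseg:::take_slice(v$data, plane, 8))
  }
  # a 7-slice volume: the middle stack holds slices 1..7 in order
  v7 <- cb_volume(array(stats::runif(8 * 8 * 7), c(8, 8, 7)))
  st7 <- extract_stacks(v7, "axial")
  for (ch in 1:7) expect_equal(st7$stacks[[4]][, , ch], v7$data[, , ch])
  # first slice replicates the edge into channels 1..3
  st1 <- extract_stacks(v7, "axial")$stacks[[1]]
  for (ch in 1:4) expect_equal(st1[, , ch], v7$data[, , max(ch - 3, 1)])
})

test_that("predict_view satisfies the softmax contract with stub models", {
  v <- cb_volume(array(stats::runif(12^3), c(12, 12, 12)))
  st <- extract_stacks(v, "axial")
  C <- 28
  uni <- stub_model(function(stack, pos)
    array(1 / C, c(dim(stack)[1:2], C)), "axial")
  p <- predict_view(uni, st)
  expect_equal(dim(p$data), c(12, 12, 12, C))
  expect_true(all(abs(p$data - 1 / C) < 1e-12))
  # one-hot stub: argmax reproduces the encoded labels exactly
  lab <- array(sample(0:27, 12^3, TRUE), c(12, 12, 12))
  hot <- stub_model(function(stack, pos) {
    i <- round(pos * 11) + 1
    out <- array(0, c(12, 12, C))
    sl <- lab[, , i]
    for (c in 0:27) out[, , c + 1][sl == c] <- 1
    out
  }, "axial")
  ph <- predict_view(hot, st)
  expect_identical(probabilities_to_labels(ph)$data, lab)
  # reassembly preserves slice order (index-encoding stub, coronal)
  idx <- stub_model(function(stack, pos) {
    out <- array(0, c(12, 12, C))
    out[, , 1] <- 1 - pos; out[, , 2] <- pos
    out
  }, "coronal")
  pi <- predict_view(idx, extract_stacks(v, "coronal"))
  expect_equal(pi$data[1, , 1, 2], (0:11) / 11)
  # view mismatch is rejected
  expect_error(predict_view(uni, extract_stacks(v, "coronal")), "match")
})

test_that("sagittal expansion copies merged classes to both sides", {
  p <- build_protocol()
  merged_ids <- c(0L, merged_lateral_ids(p))
  C <- length(merged_ids)
  d <- c(4, 4, 4)
  pm <- array(0, c(d, C))
  # put 0.6 on merged Crus I (id 4), 0.3 on vermis VIII (23), 0.1 background
  pm[, , , match(4L, merged_ids)] <- 0.6
  pm[, , , match(23L, merged_ids)] <- 0.3
  pm[, , , 1] <- 0.1
  probs <- structure(list(data = pm, class_ids = merged_ids,
                          view = "sagittal"), class = "cb_probs")
  ex <- expand_sagittal(probs, p)
  expect_equal(ex$class_ids, c(0L, 1:27))
  # left and right Crus I carry equal probability after renormalization
  lc <- ex$data[1, 1, 1, match(4L, ex$class_ids)]
  rc <- ex$data[1, 1, 1, match(14L, ex$class_ids)]
  expect_equal(lc, rc)
  expect_equal(lc / ex$data[1, 1, 1, match(23L, ex$class_ids)], 0.6 / 0.3,
               tolerance = 1e-12)
  # unit sum per voxel
  sums <- apply(ex$data, 1:3, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_error(expand_sagittal(ex, p), "merged-lateral")
})

test_that("view aggregation averages in probability space", {
  C <- 28
  d <- c(3, 3, 3)
  mk <- function(arr) structure(list(data = arr, class_ids = c(0L, 1:27),
                                     view = "x"), class = "cb_probs")
  one_hot <- function(cls) {
    a <- array(0, c(d, C)); a[, , , cls + 1] <- 1; mk(a)
  }
  pa <- one_hot(3); pc <- one_hot(3); ps <- one_hot(9)
  # three identical maps aggregate to themselves
  same <- view_aggregate(pa, pc, one_hot(3), weights = c(1, 1, 1))
  expect_equal(same$data, pa$data)
  # weights (1, 0, 0) reproduce the axial map
  ax <- view_aggregate(pa, ps, one_hot(17), weights = c(1, 0, 0))
  expect_equal(ax$data, pa$data)
  # equal weights: argmax follows the two agreeing one-hot maps
  maj <- view_aggregate(pa, pc, ps, weights = c(1, 1, 1))
  expect_true(all(probabilities_to_labels(maj)$data == 3L))
  expect_error(view_aggregate(pa, pc, mk(array(0.5, c(4, 4, 4, C)))),
               "grids differ")
})

test_that("argmax labeling breaks ties toward the lowest class id", {
  C <- 5
  d <- c(2, 2, 2)
  uni <- structure(list(data = array(1 / C, c(d, C)),
                        class_ids = c(0L, 1L, 2L, 3L, 4L), view = "x"),
                   class = "cb_probs")
  expect_true(all(probabilities_to_labels(uni)$data == 0L))
  a <- array(stats::runif(prod(d) * C), c(d, C))
  pr <- structure(list(data = a, class_ids = c(0L, 1L, 2L, 3L, 4L),
                       view = "x"), class = "cb_probs")
  expect_identical(probabilities_to_labels(pr)$data,
                   {p2 <- pr; p2$data <- 3.7 * p2$data
                    probabilities_to_labels(p2)$data})
})

test_that("reference models are deterministic and honor the shape contract", {
  cfg <- model_config("axial", filters = 4L)
  m1 <- build_reference_model(cfg, seed = 11)
  m2 <- build_reference_model(cfg, seed = 11)
  expect_equal(model_weights(m1), model_weights(m2))
  m3 <- build_reference_model(cfg, seed = 12)
  expect_false(isTRUE(all.equal(model_weights(m1), model_weights(m3))))
  # forward: 7 (+3 coord) channels in, per-pixel distribution over C out
  inp <- cerebseg:::prepare_input(array(stats::runif(64 * 64 * 7),
                                        c(64, 64, 7)), 0.5, TRUE)
  P <- cerebseg:::cnet_forward(m1$ptr, inp)
  expect_equal(dim(P), c(64, 64, 28))
  expect_true(all(abs(apply(P, 1:2, sum) - 1) < 1e-5))
  expect_true(all(P >= 0))
  # weight round-trip through checkpoints
  w <- model_weights(m1)
  restore_weights(m3, w)
  expect_equal(cerebseg:::cnet_forward(m3$ptr, inp), P, tolerance = 1e-7)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m1, ck)
  m4 <- load_checkpoint(ck)
  expect_equal(cerebseg:::cnet_forward(m4$ptr, inp), P, tolerance = 1e-7)
  expect_error(build_reference_model(model_config("axial", levels = 0L)),
               "invalid")
})

test_that("compiled loss agrees with the R reference and training reduces it", {
  cfg <- model_config("axial", filters = 4L, use_coords = TRUE)
  m <- build_reference_model(cfg, seed = 3)
  set.seed(3)
  stack <- array(stats::runif(16 * 16 * 7), c(16, 16, 7))
  inp <- cerebseg:::prepare_input(stack, 0.4, TRUE)
  target0 <- matrix(sample(0:27, 256, TRUE), 16, 16)   # 0-based ids = indices
  w <- rep(1, 28)
  P <- cerebseg:::cnet_forward(m$ptr, inp)
  ref <- composite_loss(P, target0 + 1L, w, dice_weight = 1, smooth = 1e-6)
  l1 <- cerebseg:::cnet_train_batch(m$ptr, list(inp), list(as.integer(target0)),
                                    w, 1e-3, 0, 1, 1e-6, 0)
  expect_equal(l1, ref, tolerance = 1e-4)
  # repeated steps on one batch drive the loss down
  ls <- replicate(30, cerebseg:::cnet_train_batch(
    m$ptr, list(inp), list(as.integer(target0)), w, 1e-3, 0, 1, 1e-6, 0))
  expect_lt(mean(tail(ls, 5)), mean(head(ls, 5)))
})
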