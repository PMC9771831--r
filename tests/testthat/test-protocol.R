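test_that("protocol contains the full 27-structure table", {
  p <- build_protocol()
  s <- p$structures
  expect_equal(nrow(s), 27)
  expect_equal(sum(s$group == "lobule"), 20)
  expect_equal(sum(s$group == "lobule" & s$laterality == "left"), 10)
  expect_equal(sum(s$group == "lobule" & s$laterality == "right"), 10)
  expect_equal(sum(s$group == "vermis"), 5)
  expect_equal(sum(s$group == "white_matter"), 2)
  expect_equal(anyDuplicated(s$name), 0)
  expect_equal(anyDuplicated(s$label_id), 0)
  expect_false(any(s$label_id == 0))
  expect_true(all(s$tissue[s$group == "white_matter"] == "white"))
  expect_true(all(s$laterality[s$group == "vermis"] == "midline"))
})

test_that("left-right swap is an involution fixing midline ids", {
  p <- build_protocol()
  sw <- p$lr_swap
  expect_equal(unname(sw[sw]), 1:27)          # involution
  mid <- p$structures$label_id[p$structures$laterality == "midline"]
  expect_equal(unname(sw[as.character(mid)]), mid)
  # each left id maps to the structure with the same name on the right
  s <- p$structures
  for (i in which(s$laterality == "left")) {
    hom <- s[s$label_id == sw[[as.character(s$label_id[i])]], ]
    expect_equal(sub("Right_", "", hom$name), sub("Left_", "", s$name[i]))
    expect_equal(hom$laterality, "right")
  }
})

test_that("swap_lateral_labels relabels voxels without touching geometry", {
  p <- build_protocol()
  arr <- array(0L, c(4, 4, 4))
  arr[1, 1, 1] <- 6L    # Left_VIIb
  arr[2, 2, 2] <- 23L   # Vermis_VIII (midline)
  lm <- cb_labels(arr)
  sw <- swap_lateral_labels(lm, p)
  expect_equal(sw$data[1, 1, 1], 16L)          # Right_VIIb
  expect_equal(sw$data[2, 2, 2], 23L)          # midline fixed point
  expect_identical(swap_lateral_labels(sw, p)$data, lm$data)  # involution
  arr[3, 3, 3] <- 99L
  expect_error(swap_lateral_labels(cb_labels(arr), p), "unknown label")
})

test_that("cortex/WM merge unions tissues and fills gaps with nearest gray", {
  p <- build_protocol()
  # disjoint cortex and WM, no gaps: simple union with side-dependent CWM ids
  arr <- array(0L, c(8, 8, 8))
  arr[2, 4, 4] <- 4L; arr[7, 4, 4] <- 14L
  wm <- array(FALSE, c(8, 8, 8)); wm[2, 6, 6] <- TRUE; wm[7, 6, 6] <- TRUE
  out <- merge_cortex_and_wm(cb_labels(arr), wm, p)
  expect_equal(out$data[2, 4, 4], 4L)
  expect_equal(out$data[2, 6, 6], 26L)   # left CWM
  expect_equal(out$data[7, 6, 6], 27L)   # right CWM
  # cortex wins over WM on overlap
  wm2 <- wm; wm2[2, 4, 4] <- TRUE
  out2 <- merge_cortex_and_wm(cb_labels(arr), wm2, p)
  expect_equal(out2$data[2, 4, 4], 4L)
  # errors
  expect_error(merge_cortex_and_wm(cb_labels(array(0L, c(8, 8, 8))), wm, p),
               "empty")
  expect_error(merge_cortex_and_wm(cb_labels(arr), wm[1:4, , ], p), "differ")
})

test_that("gap voxels get the gray id of the nearest gray voxel", {
  p <- build_protocol()
  arr <- array(0L, c(6, 6, 6))
  arr[2, 2, 2] <- 10L            # Left_X gray voxel
  wm <- array(FALSE, c(6, 6, 6))
  wm[2, 4, 2] <- TRUE
  # voxel (2,3,2) touches both gray (2,2,2) and wm (2,4,2): a gap
  out <- merge_cortex_and_wm(cb_labels(arr), wm, p)
  expect_equal(out$data[2, 3, 2], 10L)
  # equidistant tie broken toward the lowest label id
  arr2 <- array(0L, c(6, 6, 6))
  arr2[2, 2, 2] <- 9L; arr2[2, 4, 2] <- 3L    # both 1 voxel from (2,3,2)
  wm2 <- array(FALSE, c(6, 6, 6)); wm2[3, 3, 2] <- TRUE
  out2 <- merge_cortex_and_wm(cb_labels(arr2), wm2, p)
  expect_equal(out2$data[2, 3, 2], 3L)
})

test_that("merge agrees with a brute-force nearest-gray oracle", {
  p <- build_protocol()
  gray_ids <- p$structures$label_id[p$structures$tissue == "gray"]
  set.seed(42)
  for (rep in 1:20) {
    d <- c(10, 10, 10)
    arr <- array(0L, d)
    n_gray <- 15
    idx <- cbind(sample(d[1], n_gray, TRUE), sample(d[2], n_gray, TRUE),
                 sample(d[3], n_gray, TRUE))
    arr[idx] <- sample(gray_ids, n_gray, TRUE)
    wm <- array(stats::runif(prod(d)) < 0.08, d) & arr == 0L
    out <- merge_cortex_and_wm(cb_labels(arr), wm, p)
    # recompute gaps independently and check assignments by enumeration
    gray_pos <- which(arr != 0L, arr.ind = TRUE)
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      if (arr[i, j, k] != 0L || wm[i, j, k]) next
      nb <- as.matrix(expand.grid(i + (-1:1), j + (-1:1), k + (-1:1)))
      nb <- nb[!(nb[, 1] == i & nb[, 2] == j & nb[, 3] == k), , drop = FALSE]
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      has_gray <- any(apply(nb, 1, function(q) arr[q[1], q[2], q[3]] != 0L))
      has_wm <- any(apply(nb, 1, function(q) wm[q[1], q[2], q[3]]))
      if (has_gray && has_wm) {
        dd <- sqrt(colSums((t(gray_pos) - c(i, j, k))^2))
        cand <- arr[gray_pos[abs(dd - min(dd)) <= 1e-9, , drop = FALSE]]
        expect_equal(out$data[i, j, k], min(cand))
      } else {
        expect_equal(out$data[i, j, k], 0L)
      }
    }
  }
})

test_that("merge never changes nonzero cortex voxels and gaps stay gray", {
  p <- build_protocol()
  gray_ids <- p$structures$label_id[p$structures$tissue == "gray"]
  set.seed(7)
  for (rep in 1:10) {
    arr <- array(0L, c(12, 12, 12))
    n <- 30
    idx <- cbind(sample(12, n, TRUE), sample(12, n, TRUE), sample(12, n, TRUE))
    arr[idx] <- sample(gray_ids, n, TRUE)
    wm <- array(stats::runif(12^3) < 0.1, c(12, 12, 12))
    out <- merge_cortex_and_wm(cb_labels(arr), wm, p)
    nz <- arr != 0L
    expect_identical(out$data[nz], arr[nz])
    filled <- out$data != 0L & !nz & !wm
    expect_true(all(out$data[filled] %in% gray_ids))
  }
})

test_that("region aggregation produces the merged evaluation rows", {
  p <- build_protocol()
  arr <- array(0L, c(3, 3, 3))
  arr[1, , 1] <- c(1L, 5L, 10L)       # left lobules
  arr[2, , 1] <- c(11L, 15L, 20L)     # right lobules
  arr[3, , 1] <- c(21L, 25L, 26L)     # vermis, vermis, left CWM
  arr[1, 1, 2] <- 27L
  agg <- aggregate_regions(cb_labels(arr), p)
  mids <- merged_region_ids()
  expect_true(all(agg$data[1, , 1] == mids[["Left_CGM"]]))
  expect_true(all(agg$data[2, , 1] == mids[["Right_CGM"]]))
  expect_equal(unname(agg$data[3, 1:2, 1]), rep(mids[["Vermis"]], 2))
  expect_equal(agg$data[3, 3, 1], mids[["Left_CWM"]])
  expect_equal(agg$data[1, 1, 2], mids[["Right_CWM"]])
  expect_equal(agg$data[3, 3, 3], 0L)  # background stays background
  arr[2, 2, 2] <- 55L
  expect_error(aggregate_regions(cb_labels(arr), p), "unknown")
})

test_that("lateral merging maps pairs onto canonical side-free ids", {
  p <- build_protocol()
  arr <- array(0L, c(2, 2, 2))
  arr[1, 1, 1] <- 14L   # Right_Crus_I -> 4
  arr[2, 1, 1] <- 4L
  arr[1, 2, 1] <- 23L   # midline unchanged
  arr[2, 2, 1] <- 27L   # Right_CWM -> 26
  m <- merge_lateral_labels(cb_labels(arr), p)
  expect_equal(m$data[1, 1, 1], 4L)
  expect_equal(m$data[2, 1, 1], 4L)
  expect_equal(m$data[1, 2, 1], 23L)
  expect_equal(m$data[2, 2, 1], 26L)
  expect_equal(length(merged_lateral_ids(p)), 16)
})

test_that("protocol exports round-trip as TSV and LUT", {
  p <- build_protocol()
  tsv <- tempfile(fileext = ".tsv")
  write_protocol_tsv(p, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(back$label_id, p$structures$label_id)
  expect_equal(back$name, p$structures$name)
  lut <- tempfile(fileext = ".txt")
  write_protocol_lut(p, lut)
  ln <- utils::read.table(lut)
  expect_equal(nrow(ln), 28)            # background + 27
  expect_true(all(ln$V3 >= 0 & ln$V3 <= 255))
})
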