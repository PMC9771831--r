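#' The 27-structure cerebellar labeling protocol
#'
#' The cerebellum is sub-segmented into 27 disjoint macroscopic structures:
#' 10 hemispheric lobules per hemisphere (I-IV, V, VI, Crus I, Crus II, VIIb,
#' VIIIa, VIIIb, IX, X), five vermal sub-segments (VI-X, midline), and left
#' and right cerebellar white matter (CWM). Integer ids are assigned in a
#' fixed, documented order: left lobules 1-10 (superior to inferior), right
#' lobules 11-20 (same order), vermis 21-25, CWM 26 (left) and 27 (right).
#' Id 0 is reserved for background.
#'
#' @return An object of class `cereb_protocol`: a list with
#'   * `structures`: data.frame with columns `label_id`, `name`,
#'     `laterality` (`"left"`, `"right"`, `"midline"`), `tissue`
#'     (`"gray"`, `"white"`), `group` (`"lobule"`, `"vermis"`,
#'     `"white_matter"`);
#'   * `lr_swap`: named integer vector mapping each label id to its
#'     contralateral homolog (an involution; midline ids map to themselves);
#'   * `background_id`: 0.
#' @examples
#' p <- build_protocol()
#' nrow(p$structures)          # 27
#' p$lr_swap[["4"]]            # Left_Crus_I -> Right_Crus_I (14)
#' @export
build_protocol <- function() {
  lobules <- c("I_IV", "V", "VI", "Crus_I", "Crus_II",
               "VIIb", "VIIIa", "VIIIb", "IX", "X")
  vermis <- c("VI", "VII", "VIII", "IX", "X")
  structures <- rbind(
    data.frame(label_id = 1:10,
               name = paste0("Left_", lobules),
               laterality = "left", tissue = "gray", group = "lobule"),
    data.frame(label_id = 11:20,
               name = paste0("Right_", lobules),
               laterality = "right", tissue = "gray", group = "lobule"),
    data.frame(label_id = 21:25,
               name = paste0("Vermis_", vermis),
               laterality = "midline", tissue = "gray", group = "vermis"),
    data.frame(label_id = 26:27,
               name = c("Left_CWM", "Right_CWM"),
               laterality = c("left", "right"), tissue = "white",
               group = "white_matter")
  )
  rownames(structures) <- NULL
  swap <- c(11:20, 1:10, 21:25, 27L, 26L)
  names(swap) <- as.character(1:27)
  structure(list(structures = structures,
                 lr_swap = swap,
                 background_id = 0L),
            class = "cereb_protocol")
}

#' @export
print.cereb_protocol <- function(x, ...) {
  cat("Cerebellar labeling protocol:", nrow(x$structures), "structures\n")
  cat("  ", sum(x$structures$group == "lobule"), "hemispheric lobules,",
      sum(x$structures$group == "vermis"), "vermal sub-segments,",
      sum(x$structures$group == "white_matter"), "white-matter labels\n")
  invisible(x)
}

#' Swap left and right label ids
#'
#' Replaces every voxel value by its contralateral homolog under the
#' protocol's left-right bijection. Geometry is untouched; mirroring the
#' grid itself is part of the flip augmentation, not of this relabeling.
#'
#' @param labelmap A [cb_labels()] object or integer array.
#' @param protocol A [build_protocol()] object.
#' @return Same type as `labelmap` with ids swapped.
#' @export
swap_lateral_labels <- function(labelmap, protocol = build_protocol()) {
  arr <- label_data(labelmap)
  vals <- unique(as.integer(arr))
  bad <- setdiff(vals, c(protocol$background_id, protocol$structures$label_id))
  if (length(bad) > 0)
    stop("unknown label id(s): ", paste(sort(bad), collapse = ", "))
  lut <- c(0L, unname(protocol$lr_swap))   # index i+1 -> swap of id i
  out <- array(lut[as.integer(arr) + 1L], dim = dim(arr))
  replace_label_data(labelmap, out)
}

#' Merge a cortex parcellation with a white-matter mask
#'
#' Combines a cerebellar-cortex label map (gray-matter structures only)
#' with a binary cerebellar white-matter mask into a full protocol label
#' map. Cortex labels take precedence wherever both sources claim a voxel;
#' white matter fills cortex background, receiving the left or right CWM id
#' according to the voxel's side of the mid-sagittal plane (the center of
#' the first grid axis). Remaining gaps between the two tissue sources are
#' resolved by assigning each gap voxel the gray id of its nearest gray
#' voxel (Euclidean distance in mm; ties broken toward the lowest id).
#'
#' By default a gap is a background voxel whose 26-neighborhood intersects
#' both a gray label and the white-matter mask; callers may instead supply
#' an explicit `gap_mask`.
#'
#' @param cortex [cb_labels()] with gray-structure ids and background only.
#' @param wm_mask logical/0-1 array on the same grid.
#' @param protocol A [build_protocol()] object.
#' @param gap_mask Optional logical array marking gap voxels explicitly.
#' @return A [cb_labels()] map carrying gray, CWM and gap-filled labels.
#' @export
merge_cortex_and_wm <- function(cortex, wm_mask, protocol = build_protocol(),
                                gap_mask = NULL) {
  arr <- label_data(cortex)
  if (all(arr == protocol$background_id)) stop("cortex map is empty")
  wm <- as.array(wm_mask) != 0
  if (!identical(dim(arr), dim(wm))) stop("cortex and wm_mask grids differ")
  gray_ids <- protocol$structures$label_id[protocol$structures$tissue == "gray"]
  bad <- setdiff(unique(as.integer(arr)), c(0L, gray_ids))
  if (length(bad) > 0)
    stop("cortex map contains non-gray id(s): ", paste(sort(bad), collapse = ", "))

  dims <- dim(arr)
  out <- arr
  left_id <- protocol$structures$label_id[protocol$structures$name == "Left_CWM"]
  right_id <- protocol$structures$label_id[protocol$structures$name == "Right_CWM"]
  # mid-sagittal plane splits the first (left-right) axis
  xs <- slice.index(arr, 1)
  mid <- (dims[1] + 1) / 2
  fill <- wm & arr == 0L
  out[fill & xs < mid] <- left_id
  out[fill & xs >= mid] <- right_id

  if (is.null(gap_mask)) {
    gray_adj <- neighbor_any_26(arr != 0L)
    wm_adj <- neighbor_any_26(wm)
    gap <- (out == 0L) & gray_adj & wm_adj
  } else {
    gap <- as.array(gap_mask) & out == 0L
  }
  if (any(gap)) {
    spacing <- label_spacing(cortex)
    gray_idx <- which(arr != 0L, arr.ind = TRUE)
    gray_lab <- arr[arr != 0L]
    gap_idx <- which(gap, arr.ind = TRUE)
    assigned <- nearest_label_cpp(
      gap_idx * rep(spacing, each = nrow(gap_idx)),
      gray_idx * rep(spacing, each = nrow(gray_idx)),
      as.integer(gray_lab))
    out[gap] <- assigned
  }
  replace_label_data(cortex, out)
}

# TRUE where any of the 26 neighbors of a voxel is TRUE
neighbor_any_26 <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
    tx <- sx + dx; ty <- sy + dy; tz <- sz + dz
    ok_x <- tx >= 1 & tx <= d[1]; ok_y <- ty >= 1 & ty <= d[2]
    ok_z <- tz >= 1 & tz <= d[3]
    out[sx[ok_x], sy[ok_y], sz[ok_z]] <-
      out[sx[ok_x], sy[ok_y], sz[ok_z]] |
      mask[tx[ok_x], ty[ok_y], tz[ok_z]]
  }
  out
}

#' Merged evaluation-region ids
#'
#' Ids used by [aggregate_regions()] for the merged reporting rows:
#' left/right merged cerebellar gray matter, merged vermis, and left/right
#' cerebellar white matter.
#' @return Named integer vector.
#' @export
merged_region_ids <- function() {
  c(Left_CGM = 101L, Right_CGM = 102L, Vermis = 103L,
    Left_CWM = 104L, Right_CWM = 105L)
}

#' Aggregate protocol labels into merged evaluation regions
#'
#' Relabels the 27 structures into the merged rows used for evaluation:
#' left and right merged cerebellar gray matter (all lobules of a
#' hemisphere), one merged vermis region, and the two white-matter labels.
#'
#' @inheritParams swap_lateral_labels
#' @return Label map over [merged_region_ids()] plus background.
#' @export
aggregate_regions <- function(labelmap, protocol = build_protocol()) {
  arr <- label_data(labelmap)
  bad <- setdiff(unique(as.integer(arr)),
                 c(0L, protocol$structures$label_id))
  if (length(bad) > 0)
    stop("unknown label id(s): ", paste(sort(bad), collapse = ", "))
  mids <- merged_region_ids()
  s <- protocol$structures
  lut <- integer(28)          # index id+1
  lut[1] <- 0L
  for (i in seq_len(nrow(s))) {
    id <- s$label_id[i]
    lut[id + 1L] <-
      if (s$group[i] == "vermis") mids[["Vermis"]]
      else if (s$group[i] == "white_matter") {
        if (s$laterality[i] == "left") mids[["Left_CWM"]] else mids[["Right_CWM"]]
      } else if (s$laterality[i] == "left") mids[["Left_CGM"]]
      else mids[["Right_CGM"]]
  }
  out <- array(lut[as.integer(arr) + 1L], dim = dim(arr))
  replace_label_data(labelmap, out)
}

#' Map lateral label pairs onto merged (side-free) classes
#'
#' Sagittal slices carry no left/right information, so the sagittal-view
#' network is trained on a lateral-merged class set. Each left/right pair
#' is mapped to its left member's id (the canonical merged id,
#' `min(id, lr_swap(id))`); midline ids are unchanged.
#'
#' @inheritParams swap_lateral_labels
#' @return Label map over the merged-lateral id set.
#' @export
merge_lateral_labels <- function(labelmap, protocol = build_protocol()) {
  arr <- label_data(labelmap)
  lut <- c(0L, pmin(1:27, unname(protocol$lr_swap)))
  out <- array(lut[as.integer(arr) + 1L], dim = dim(arr))
  replace_label_data(labelmap, out)
}

#' Canonical merged-lateral id set (without background)
#' @param protocol A [build_protocol()] object.
#' @return Sorted integer vector of the 16 merged ids.
#' @export
merged_lateral_ids <- function(protocol = build_protocol()) {
  sort(unique(pmin(protocol$structures$label_id,
                   unname(protocol$lr_swap))))
}

#' Export the protocol as a tab-separated lookup table
#' @param protocol A [build_protocol()] object.
#' @param path Output file path.
#' @export
write_protocol_tsv <- function(protocol, path) {
  utils::write.table(protocol$structures, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a color lookup table for NIfTI viewers
#'
#' Writes `id name R G B A` rows (FreeSurfer-style LUT). Colors are
#' deterministic: hue spread over the gray structures, grays for CWM.
#' @inheritParams write_protocol_tsv
#' @export
write_protocol_lut <- function(protocol, path) {
  s <- protocol$structures
  n <- nrow(s)
  cols <- grDevices::col2rgb(grDevices::hcl(h = seq(0, 330, length.out = n),
                                            c = 70, l = 60))
  wm <- s$tissue == "white"
  cols[, wm] <- c(230, 230, 230)
  df <- data.frame(id = c(0L, s$label_id),
                   name = c("Background", s$name),
                   R = c(0L, cols[1, ]), G = c(0L, cols[2, ]),
                   B = c(0L, cols[3, ]), A = c(0L, rep(255L, n)))
  utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
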