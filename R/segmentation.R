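#' Slab scheme for z-stack averaging
#'
#' Parameters of the depth-sampling scheme used before cell extraction:
#' average every `group_size` adjacent z-slices into one slab, then skip the
#' next `skip` slices, so consecutive slabs contain (mostly) disjoint cells.
#' The default (average 3, skip 2, 3 um z-step) spans 6 um per slab.
#'
#' @param group_size Number of adjacent slices averaged per slab (>= 1).
#' @param skip Number of slices skipped between slabs (>= 0).
#' @param z_step Axial distance between adjacent slices in micrometres.
#' @return Object of class `campari_slab_scheme`.
#' @export
slab_scheme <- function(group_size = 3, skip = 2, z_step = 3) {
  stopifnot(group_size >= 1, skip >= 0, z_step > 0)
  structure(list(group_size = as.integer(group_size),
                 skip = as.integer(skip), z_step = z_step),
            class = "campari_slab_scheme")
}

#' Average a z-stack into depth slabs
#'
#' Slabs are consecutive groups of `group_size` slices starting at slice 1
#' with period `group_size + skip`; each slab is the pixelwise mean of its
#' slices. A trailing group with fewer than `group_size` slices is dropped
#' (averaging fewer slices would silently change the noise level). The depth
#' of a slab is the mean depth of its slices, with slice i at depth
#' `(i - 1) * z_step` (first slice at the surface).
#'
#' @param stack Numeric 3-D array (ny x nx x nz).
#' @param scheme A [slab_scheme()].
#' @return List with `slabs` (3-D array ny x nx x n_slabs), `depth` (numeric
#'   vector of slab depths, um), `slices` (list of slice indices per slab).
#' @export
slab_average <- function(stack, scheme = slab_scheme()) {
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  nz <- dim(stack)[3]
  gs <- scheme$group_size
  if (nz < gs) stop("stack has ", nz, " slices but group_size is ", gs)
  starts <- seq(1L, nz - gs + 1L, by = gs + scheme$skip)
  slabs <- array(0, c(dim(stack)[1], dim(stack)[2], length(starts)))
  depth <- numeric(length(starts))
  slices <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    idx <- starts[k]:(starts[k] + gs - 1L)
    slices[[k]] <- idx
    slabs[, , k] <- apply_slab_mean(stack, idx)
    depth[k] <- mean((idx - 1) * scheme$z_step)
  }
  list(slabs = slabs, depth = depth, slices = slices)
}

apply_slab_mean <- function(stack, idx) {
  if (length(idx) == 1) return(stack[, , idx])
  rowMeans(stack[, , idx, drop = FALSE], dims = 2)
}

#' Threshold-based fallback cell segmentation
#'
#' A deterministic built-in labeler for somata in a single 2-D image, for use
#' when no externally generated mask is available: Gaussian smoothing, global
#' thresholding at a quantile of the nonzero pixels, connected-component
#' labeling with 8-connectivity, then an area filter. External masks from
#' dedicated segmentation tools remain first-class inputs throughout the
#' package; only count-level agreement is expected from this fallback.
#'
#' @param image Numeric matrix.
#' @param min_area,max_area Component area bounds in pixels.
#' @param threshold_quantile Quantile (of nonzero pixel values) used as the
#'   global threshold.
#' @param smooth_sigma Gaussian smoothing sigma in pixels; 0 disables
#'   smoothing. The image is assumed background-free (background at 0, e.g.
#'   after dark/offset subtraction); the threshold quantile is taken over
#'   the remaining nonzero pixels.
#' @return Integer label matrix (0 = background, labels 1..n sequential).
#' @export
segment_cells <- function(image, min_area = 20, max_area = Inf,
                          threshold_quantile = 0.5, smooth_sigma = 1) {
  stopifnot(is.matrix(image), min_area >= 0, max_area >= min_area,
            threshold_quantile >= 0, threshold_quantile <= 1)
  img <- image
  if (smooth_sigma > 0) {
    img <- EBImage::imageData(EBImage::gblur(image, sigma = smooth_sigma))
  }
  # smoothing introduces tiny numerical ripples; treat them as background
  eps <- max(img) * 1e-6
  nz <- img[img > eps]
  if (length(nz) == 0) return(matrix(0L, nrow(image), ncol(image)))
  thr <- stats::quantile(nz, threshold_quantile, type = 7)
  fg <- img >= thr & img > eps
  if (!any(fg)) return(matrix(0L, nrow(image), ncol(image)))
  lab <- label_components8(fg)
  # area filter
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(areas >= min_area & areas <= max_area)
    relabel <- integer(max(lab))
    relabel[keep] <- seq_along(keep)
    lab[lab > 0] <- relabel[lab[lab > 0]]
  }
  matrix(as.integer(lab), nrow(image), ncol(image))
}

# 8-connected component labeling: 4-connected pass (EBImage), then merge
# labels that touch diagonally using union-find.
label_components8 <- function(fg) {
  lab <- EBImage::imageData(EBImage::bwlabel(fg))
  n <- max(lab)
  if (n < 2) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]   # down-right diagonal pairs
  sel <- a > 0 & b > 0 & a != b
  if (any(sel)) {
    pairs <- unique(cbind(a[sel], b[sel]))
    for (k in seq_len(nrow(pairs))) union(pairs[k, 1], pairs[k, 2])
  }
  a <- lab[-1, -nc]; b <- lab[-nr, -1]   # up-right diagonal pairs
  sel <- a > 0 & b > 0 & a != b
  if (any(sel)) {
    pairs <- unique(cbind(a[sel], b[sel]))
    for (k in seq_len(nrow(pairs))) union(pairs[k, 1], pairs[k, 2])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  compact <- match(roots, sort(unique(roots)))
  lab[lab > 0] <- compact[lab[lab > 0]]
  lab
}

#' Extract per-cell mean fluorescence under a label mask
#'
#' Computes, for every label in the mask, the mean green and red intensity
#' over the label's pixels together with the pixel count. Works on congruent
#' 2-D images or 3-D stacks. Labels listed in `expected_ids` but absent from
#' the mask are skipped with a warning.
#'
#' @param mask Integer label matrix/array (0 = background).
#' @param green,red Numeric matrix/array congruent with `mask`.
#' @param depth Depth (um) recorded for these cells (scalar, e.g. the slab
#'   depth), or NA.
#' @param min_area Minimum pixel count; smaller labels are excluded.
#' @param expected_ids Optional integer vector of labels that should be
#'   present.
#' @return data.frame with columns `cell_id`, `mean_green`, `mean_red`,
#'   `pixel_count`, `depth`.
#' @export
extract_cell_fluorescence <- function(mask, green, red, depth = NA_real_,
                                      min_area = 0, expected_ids = NULL) {
  if (!all(dim(mask) == dim(green)) || !all(dim(mask) == dim(red)))
    stop("mask and image dimensions differ")
  sel <- mask > 0
  if (!any(sel)) {
    out <- data.frame(cell_id = integer(0), mean_green = numeric(0),
                      mean_red = numeric(0), pixel_count = integer(0),
                      depth = numeric(0))
    return(out)
  }
  ids <- mask[sel]
  mg <- tapply(green[sel], ids, mean)
  mr <- tapply(red[sel], ids, mean)
  npx <- tapply(ids, ids, length)
  out <- data.frame(cell_id = as.integer(names(mg)),
                    mean_green = as.numeric(mg),
                    mean_red = as.numeric(mr),
                    pixel_count = as.integer(npx),
                    depth = depth)
  if (!is.null(expected_ids)) {
    missing <- setdiff(expected_ids, out$cell_id)
    if (length(missing))
      warning("labels absent from mask, skipped: ",
              paste(missing, collapse = ", "))
  }
  out <- out[out$pixel_count >= min_area, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$cell_id), , drop = FALSE]
}

#' Match cells between pre- and post-photoconversion masks
#'
#' Pairs labels of two masks of the same field of view by mutual nearest
#' neighbours of their centroids, subject to a maximum centroid distance.
#' Cells without a mutual nearest neighbour within the cap are reported as
#' unmatched.
#'
#' @param mask_pre,mask_post Integer label matrices/arrays (same geometry).
#' @param max_dist Maximum centroid distance in micrometres.
#' @param pixel_size Lateral pixel size (um/px) used to convert pixel
#'   distances to micrometres.
#' @param z_step Axial step (um/slice) for 3-D masks.
#' @return data.frame with columns `id_pre`, `id_post`, `distance` (um);
#'   attributes `unmatched_pre` and `unmatched_post` list leftover labels.
#' @export
match_cells_pre_post <- function(mask_pre, mask_post, max_dist = 5,
                                 pixel_size = 1, z_step = 1) {
  cp <- mask_centroids(mask_pre, pixel_size, z_step)
  cq <- mask_centroids(mask_post, pixel_size, z_step)
  empty <- data.frame(id_pre = integer(0), id_post = integer(0),
                      distance = numeric(0))
  if (nrow(cp) == 0 || nrow(cq) == 0) {
    attr(empty, "unmatched_pre") <- cp$id
    attr(empty, "unmatched_post") <- cq$id
    return(empty)
  }
  d <- outer(seq_len(nrow(cp)), seq_len(nrow(cq)), function(i, j) {
    sqrt((cp$x[i] - cq$x[j])^2 + (cp$y[i] - cq$y[j])^2 + (cp$z[i] - cq$z[j])^2)
  })
  nn_pq <- apply(d, 1, which.min)  # nearest post for each pre
  nn_qp <- apply(d, 2, which.min)  # nearest pre for each post
  keep <- which(nn_qp[nn_pq] == seq_len(nrow(cp)) &
                  d[cbind(seq_len(nrow(cp)), nn_pq)] <= max_dist)
  pairs <- data.frame(id_pre = cp$id[keep], id_post = cq$id[nn_pq[keep]],
                      distance = d[cbind(keep, nn_pq[keep])])
  attr(pairs, "unmatched_pre") <- setdiff(cp$id, pairs$id_pre)
  attr(pairs, "unmatched_post") <- setdiff(cq$id, pairs$id_post)
  pairs
}

mask_centroids <- function(mask, pixel_size = 1, z_step = 1) {
  sel <- which(mask > 0)
  if (!length(sel))
    return(data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0)))
  dm <- dim(mask)
  if (length(dm) == 2) dm <- c(dm, 1L)
  sub <- arrayInd(sel, dm)
  ids <- mask[sel]
  data.frame(
    id = as.integer(names(tapply(ids, ids, length))),
    y = as.numeric(tapply(sub[, 1], ids, mean)) * pixel_size,
    x = as.numeric(tapply(sub[, 2], ids, mean)) * pixel_size,
    z = as.numeric(tapply(sub[, 3], ids, mean)) * z_step
  )
}
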