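#' Construct a z-stack
#'
#' @param planes list of equally sized image matrices, ordered by z.
#' @param z_step_nm z spacing in nm.
#' @return An `image_stack` list.
#' @export
image_stack <- function(planes, z_step_nm = 300) {
  stopifnot(length(planes) >= 1)
  dims <- vapply(planes, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all planes of a stack must share the same shape")
  }
  structure(list(planes = planes, z_step_nm = z_step_nm),
            class = "image_stack")
}

#' Maximum-intensity projection of a z-stack
#'
#' @param stack an [image_stack()] (or a plain list of matrices).
#' @return A matrix: the per-pixel maximum across planes.
#' @export
max_project <- function(stack) {
  planes <- if (inherits(stack, "image_stack")) stack$planes else stack
  stopifnot(length(planes) >= 1)
  Reduce(pmax, planes)
}

#' Stitch overview tiles by stage coordinates
#'
#' Each tile is maximum-projected, placed at the integer pixel offset
#' nearest its stage coordinate, and overlapping pixels are fused by the
#' per-pixel mean. The output covers the bounding box of all tiles;
#' non-overlap pixels pass through unchanged.
#'
#' @param tileset a `tile_set` as produced by [generate_overview_scene()]:
#'   `tiles` (list of stacks), `stage_xy` (nm, columns x/y), and
#'   `pixel_size_nm`.
#' @return The fused 2D image matrix.
#' @export
stitch_tiles <- function(tileset) {
  stopifnot(length(tileset$tiles) == nrow(tileset$stage_xy))
  px <- tileset$pixel_size_nm
  if (length(px) != 1 || !is.finite(px) || px <= 0) {
    stop("tile set must carry a single positive pixel size")
  }
  projs <- lapply(tileset$tiles, max_project)
  r0 <- round(tileset$stage_xy[, 2] / px)
  c0 <- round(tileset$stage_xy[, 1] / px)
  r0 <- r0 - min(r0); c0 <- c0 - min(c0)
  h <- max(r0 + vapply(projs, nrow, 1L))
  w <- max(c0 + vapply(projs, ncol, 1L))
  acc <- matrix(0, h, w)
  cnt <- matrix(0L, h, w)
  for (k in seq_along(projs)) {
    ri <- r0[k] + seq_len(nrow(projs[[k]]))
    ci <- c0[k] + seq_len(ncol(projs[[k]]))
    acc[ri, ci] <- acc[ri, ci] + projs[[k]]
    cnt[ri, ci] <- cnt[ri, ci] + 1L
  }
  acc[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
  acc
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected, so
# labels that touch only diagonally are merged with a union-find pass.
label_components <- function(mask) {
  mask <- as_mat(mask) > 0
  L <- as_mat(EBImage::bwlabel(mask * 1))
  storage.mode(L) <- "integer"
  n <- max(L)
  if (n > 1L) {
    nr <- nrow(L); nc <- ncol(L)
    pairs <- rbind(
      cbind(as.vector(L[-nr, -nc]), as.vector(L[-1, -1])),   # \ diagonal
      cbind(as.vector(L[-nr, -1]), as.vector(L[-1, -nc]))    # / diagonal
    )
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      parent <- seq_len(n)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (k in seq_len(nrow(pairs))) {
        a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      root <- vapply(seq_len(n), find, 1L)
      relab <- match(root, sort(unique(root)))
      L[L > 0L] <- relab[L[L > 0L]]
      n <- max(L)
    }
  }
  structure(list(labels = L, n_objects = as.integer(n)), class = "label_mask")
}

# drop 8-connected foreground objects with strictly fewer than min_px pixels
remove_small_objects <- function(mask, min_px = 512) {
  m <- as_mat(mask) > 0
  lm <- label_components(m)
  if (lm$n_objects == 0L) return(m)
  areas <- tabulate(lm$labels[lm$labels > 0L], nbins = lm$n_objects)
  drop <- which(areas < min_px)
  if (length(drop)) m[lm$labels %in% drop] <- FALSE
  m
}

# fill enclosed background holes with strictly fewer than max_px pixels.
# Background components are 4-connected (the topological dual of
# 8-connected foreground), which is exactly what bwlabel provides.
fill_small_holes <- function(mask, max_px = 512) {
  mask <- as_mat(mask) > 0
  Lb <- as_mat(EBImage::bwlabel((!mask) * 1))
  storage.mode(Lb) <- "integer"
  nb <- max(Lb)
  if (nb == 0L) return(mask)
  border_labels <- unique(c(Lb[1, ], Lb[nrow(Lb), ], Lb[, 1], Lb[, ncol(Lb)]))
  areas <- tabulate(Lb[Lb > 0L], nbins = nb)
  fill <- setdiff(which(areas < max_px), border_labels)
  if (length(fill)) mask[Lb %in% fill] <- TRUE
  mask
}

#' Detection parameters for overview nucleus detection
#'
#' @param k_clusters number of k-means clusters (>= 2); the cluster with
#'   the highest mean raw intensity is taken as foreground.
#' @param gaussian_sigma_px width of the Gaussian filter response used as
#'   a per-pixel feature.
#' @param erosion_radius_px radius of the disk used for binary erosion of
#'   the foreground (removes small background detections).
#' @param seed k-means seed (10 restarts, best inertia kept).
#' @return A `detection_params` list.
#' @export
detection_params <- function(k_clusters = 2L, gaussian_sigma_px = 2,
                             erosion_radius_px = 3L, seed = 42L) {
  stopifnot(k_clusters >= 2, gaussian_sigma_px > 0, erosion_radius_px >= 1)
  structure(list(k_clusters = as.integer(k_clusters),
                 gaussian_sigma_px = gaussian_sigma_px,
                 erosion_radius_px = as.integer(erosion_radius_px),
                 seed = as.integer(seed)),
            class = "detection_params")
}

sobel_magnitude <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- as_mat(EBImage::filter2(img, kx, boundary = "replicate"))
  gy <- as_mat(EBImage::filter2(img, t(kx), boundary = "replicate"))
  sqrt(gx^2 + gy^2)
}

#' Detect candidate nuclei in an overview projection
#'
#' Clusters pixels by (raw intensity, Gaussian-filtered intensity, Sobel
#' gradient magnitude) with k-means, takes the cluster with the highest
#' mean raw intensity as foreground, erodes it with a disk to remove small
#' background detections, and labels the surviving 8-connected components.
#' Remnant components smaller than the erosion footprint itself are
#' dropped: the filter-response features dilate any bright object by a
#' pixel or two, so a sub-brush-sized detection can leave a few-pixel
#' core after erosion, which is exactly the class of detection the
#' erosion step exists to remove.
#'
#' @param img 2D image matrix.
#' @param p a [detection_params()] object.
#' @return A `label_mask`: `labels` (integer matrix, 0 = background) and
#'   `n_objects`.
#' @export
detect_nuclei_overview <- function(img, p = detection_params()) {
  assert_image(img)
  if (diff(range(img)) == 0) {
    return(structure(list(labels = matrix(0L, nrow(img), ncol(img)),
                          n_objects = 0L), class = "label_mask"))
  }
  feats <- cbind(as.vector(img),
                 as.vector(gaussian_blur(img, p$gaussian_sigma_px)),
                 as.vector(sobel_magnitude(img)))
  # z-scored so no single response dominates the Euclidean metric
  feats <- scale(feats)
  feats[, attr(feats, "scaled:scale") == 0] <- 0
  km <- with_seed(p$seed,
                  stats::kmeans(feats, centers = p$k_clusters,
                                nstart = 10, iter.max = 100))
  fg_cluster <- which.max(tapply(as.vector(img), km$cluster, mean))
  fg <- matrix(km$cluster == as.integer(names(fg_cluster)),
               nrow(img), ncol(img))
  brush <- EBImage::makeBrush(2L * p$erosion_radius_px + 1L, shape = "disc")
  eroded <- as_mat(EBImage::erode(fg * 1, brush)) > 0
  eroded <- remove_small_objects(eroded, min_px = sum(brush))
  label_components(eroded)
}

#' Object centroids and areas of a label mask
#'
#' @param lm a `label_mask`.
#' @return A data.frame with `label`, `centroid_row`, `centroid_col`,
#'   `area_px`.
#' @export
label_table <- function(lm) {
  if (lm$n_objects == 0L) {
    return(data.frame(label = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), area_px = integer(0)))
  }
  idx <- which(lm$labels > 0L)
  lab <- lm$labels[idx]
  r <- (idx - 1L) %% nrow(lm$labels) + 1L
  c <- (idx - 1L) %/% nrow(lm$labels) + 1L
  data.frame(label = sort(unique(lab)),
             centroid_row = as.numeric(tapply(r, lab, mean)),
             centroid_col = as.numeric(tapply(c, lab, mean)),
             area_px = as.integer(tapply(lab, lab, length)))
}

#' Li (minimum cross-entropy) threshold
#'
#' Fixed-point iteration for the minimum cross-entropy threshold of Li &
#' Tam: `t <- (mu_lo - mu_hi) / (log(mu_lo) - log(mu_hi))`, where `mu_lo`
#' and `mu_hi` are the means of the pixels below/above the current
#' threshold, iterated from the image mean until convergence. Intensities
#' are shifted to be positive before taking logs; the returned threshold
#' is on the original scale.
#'
#' @param x numeric vector or matrix of intensities.
#' @param tol convergence tolerance as a fraction of the intensity range.
#' @return The threshold (scalar).
#' @export
li_threshold <- function(x, tol = 1e-6) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  eps <- diff(rng) * 1e-9
  xs <- x - rng[1] + eps
  t_cur <- mean(xs)
  for (iter in 1:200) {
    lo <- xs[xs <= t_cur]; hi <- xs[xs > t_cur]
    if (!length(lo) || !length(hi)) break
    ml <- mean(lo); mh <- mean(hi)
    t_new <- (ml - mh) / (log(ml) - log(mh))
    if (abs(t_new - t_cur) < tol * diff(rng)) {
      t_cur <- t_new
      break
    }
    t_cur <- t_new
  }
  t_cur + rng[1] - eps
}

#' Parameters for detail-image foreground segmentation
#'
#' @param q_low,q_high normalization quantiles.
#' @param blur_sigma_px Gaussian blur width applied before thresholding.
#' @param min_object_px objects strictly smaller than this are removed.
#' @param max_hole_px holes strictly smaller than this are filled.
#' @param min_blur_contrast minimum range of the blurred normalized image
#'   for a frame to count as containing signal; below it the mask is empty
#'   and the result is flagged degenerate. Quantile normalization is
#'   gain-invariant, so without this guard an empty noise frame would
#'   segment spurious foreground: pure noise stretched to `[0, 1]` retains
#'   a residual range of roughly 0.1 after the strong blur, while a frame
#'   containing a nucleus spans more than 0.4; 0.2 sits between the two
#'   regimes.
#' @param fill_holes_first if `TRUE`, holes are filled before small-object
#'   removal instead of after.
#' @return A `sted_seg_params` list.
#' @export
sted_seg_params <- function(q_low = 0.025, q_high = 0.995, blur_sigma_px = 16,
                            min_object_px = 512, max_hole_px = 512,
                            min_blur_contrast = 0.2,
                            fill_holes_first = FALSE) {
  stopifnot(q_low >= 0, q_high <= 1, q_low < q_high, blur_sigma_px > 0)
  structure(list(q_low = q_low, q_high = q_high,
                 blur_sigma_px = blur_sigma_px,
                 min_object_px = min_object_px, max_hole_px = max_hole_px,
                 min_blur_contrast = min_blur_contrast,
                 fill_holes_first = fill_holes_first),
            class = "sted_seg_params")
}

#' Segment the nuclear foreground of a detail image
#'
#' Normalizes intensities to the (`q_low`, `q_high`) quantiles (clipped to
#' `[0, 1]`), thresholds a strongly blurred version of the normalized
#' image with the Li minimum-cross-entropy threshold, removes small
#' objects and fills small holes.
#'
#' @param img 2D image matrix (at least 128 x 128).
#' @param p a [sted_seg_params()] object.
#' @return A list with `mask` (logical matrix), `norm_img` (normalized
#'   image), `q_low_value`/`q_high_value` (raw-intensity quantiles used),
#'   `threshold`, and `degenerate` (TRUE when the frame had no usable
#'   signal).
#' @export
segment_sted_foreground <- function(img, p = sted_seg_params()) {
  assert_image(img)
  stopifnot(nrow(img) >= 128, ncol(img) >= 128)
  q <- quantile_pair(img, p$q_low, p$q_high)
  empty <- matrix(FALSE, nrow(img), ncol(img))
  if (q[2] <= q[1]) {
    return(list(mask = empty, norm_img = matrix(0, nrow(img), ncol(img)),
                q_low_value = q[1], q_high_value = q[2],
                threshold = NA_real_, degenerate = TRUE))
  }
  norm <- clip01((img - q[1]) / (q[2] - q[1]))
  blur <- gaussian_blur(norm, p$blur_sigma_px)
  if (diff(range(blur)) < p$min_blur_contrast) {
    return(list(mask = empty, norm_img = norm,
                q_low_value = q[1], q_high_value = q[2],
                threshold = NA_real_, degenerate = TRUE))
  }
  thr <- li_threshold(blur)
  mask <- blur > thr
  if (p$fill_holes_first) {
    mask <- fill_small_holes(mask, p$max_hole_px)
    mask <- remove_small_objects(mask, p$min_object_px)
  } else {
    mask <- remove_small_objects(mask, p$min_object_px)
    mask <- fill_small_holes(mask, p$max_hole_px)
  }
  list(mask = mask, norm_img = norm, q_low_value = q[1], q_high_value = q[2],
       threshold = thr, degenerate = !any(mask))
}

#' Crop the padded bounding box of one labelled object
#'
#' @param scene 2D image matrix.
#' @param label label id to crop.
#' @param mask a `label_mask` over the same scene.
#' @param pad_px padding added on every side, clipped at the scene bounds.
#' @return The cropped image matrix.
#' @export
crop_detail <- function(scene, label, mask, pad_px = 0L) {
  idx <- which(mask$labels == label)
  if (!length(idx)) stop("label ", label, " not present in mask")
  r <- (idx - 1L) %% nrow(mask$labels) + 1L
  c <- (idx - 1L) %/% nrow(mask$labels) + 1L
  r1 <- max(1L, min(r) - pad_px); r2 <- min(nrow(scene), max(r) + pad_px)
  c1 <- max(1L, min(c) - pad_px); c2 <- min(ncol(scene), max(c) + pad_px)
  scene[r1:r2, c1:c2, drop = FALSE]
}
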