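#' GLCM parameters for a feature-extraction profile
#'
#' The STED (detail-image) profile uses pair distances {2, 4, 7, 12, 16}
#' px and normalization quantiles (0.025, 0.995); the confocal profile
#' uses distances {2, 4, 8, 16} px and quantiles (0.025, 0.998). Both use
#' angles {0, pi/2} and a light pre-blur (sigma = 0.5 px) of the
#' normalized image before quantization.
#'
#' @param profile `"sted"` or `"confocal"`.
#' @param distances positive integer pair distances (px).
#' @param angles offset angles in radians; 0 means a horizontal offset of
#'   +d columns, pi/2 a vertical offset of +d rows.
#' @param levels number of grey levels after quantization.
#' @param symmetric if `TRUE`, each pair is counted in both orders.
#' @param normed if `TRUE`, each co-occurrence matrix is normalized to
#'   sum to 1.
#' @param pre_blur_sigma_px Gaussian blur applied to the normalized image
#'   before quantization.
#' @param q_low,q_high normalization quantiles for [extract_features()].
#' @return A `glcm_params` list.
#' @export
glcm_params <- function(profile = c("sted", "confocal"),
                        distances = NULL,
                        angles = c(0, pi / 2),
                        levels = 64L,
                        symmetric = TRUE,
                        normed = TRUE,
                        pre_blur_sigma_px = 0.5,
                        q_low = NULL, q_high = NULL) {
  profile <- match.arg(profile)
  if (is.null(distances)) {
    distances <- if (profile == "sted") c(2L, 4L, 7L, 12L, 16L)
                 else c(2L, 4L, 8L, 16L)
  }
  if (is.null(q_low)) q_low <- 0.025
  if (is.null(q_high)) q_high <- if (profile == "sted") 0.995 else 0.998
  stopifnot(all(distances >= 1), levels >= 2, q_low < q_high)
  structure(list(profile = profile, distances = as.integer(distances),
                 angles = angles, levels = as.integer(levels),
                 symmetric = symmetric, normed = normed,
                 pre_blur_sigma_px = pre_blur_sigma_px,
                 q_low = q_low, q_high = q_high),
            class = "glcm_params")
}

#' Quantize a normalized image to discrete grey levels
#'
#' `level = floor(value * levels)`, with the boundary value 1.0 mapped to
#' `levels - 1` so exactly `levels` levels are produced.
#'
#' @param norm_img matrix with values in `[0, 1]`.
#' @param levels number of levels.
#' @return An integer matrix of levels in `0 .. levels - 1`.
#' @export
quantize <- function(norm_img, levels) {
  if (any(norm_img < 0 | norm_img > 1, na.rm = TRUE)) {
    stop("quantize() expects values in [0, 1]")
  }
  q <- floor(norm_img * levels)
  q[q >= levels] <- levels - 1
  storage.mode(q) <- "integer"
  q
}

# (row, col) pixel offset for one (distance, angle); angle 0 => +d columns,
# pi/2 => +d rows
offset_for <- function(d, theta) {
  c(round(d * sin(theta)), round(d * cos(theta)))
}

#' Masked grey-level co-occurrence matrices
#'
#' Counts ordered pixel pairs `(a, b)` with `b` at the (distance, angle)
#' offset from `a`, keeping only pairs where both endpoints lie inside the
#' mask, for every combination of `p$distances` and `p$angles`. With
#' `symmetric = TRUE` the transposed counts are added; with `normed = TRUE`
#' each slice is divided by its total count.
#'
#' @param qimg integer matrix of quantized levels in `0 .. p$levels - 1`.
#' @param mask logical matrix, same shape.
#' @param p a [glcm_params()] object.
#' @return A `glcm_tensor`: `P` (array `levels x levels x n_dist x n_angle`),
#'   `valid_pairs` (matrix `n_dist x n_angle` of ordered-pair counts before
#'   symmetrization; 0 marks a degenerate slice), plus the parameters.
#' @export
compute_glcm <- function(qimg, mask, p = glcm_params("sted")) {
  stopifnot(is.matrix(qimg), all(dim(qimg) == dim(mask)))
  if (max(qimg) >= p$levels || min(qimg) < 0) {
    stop("quantized image has levels outside 0 .. levels-1")
  }
  mask <- mask > 0
  L <- p$levels
  nd <- length(p$distances); na <- length(p$angles)
  P <- array(0, dim = c(L, L, nd, na))
  valid <- matrix(0L, nd, na)
  nr <- nrow(qimg); nc <- ncol(qimg)
  for (ai in seq_len(na)) {
    for (di in seq_len(nd)) {
      off <- offset_for(p$distances[di], p$angles[ai])
      dr <- off[1]; dc <- off[2]
      if (abs(dr) >= nr || abs(dc) >= nc) next   # offset exceeds the image
      ra <- max(1, 1 - dr):min(nr, nr - dr)
      ca <- max(1, 1 - dc):min(nc, nc - dc)
      A <- qimg[ra, ca, drop = FALSE]
      B <- qimg[ra + dr, ca + dc, drop = FALSE]
      ok <- mask[ra, ca, drop = FALSE] & mask[ra + dr, ca + dc, drop = FALSE]
      n_pairs <- sum(ok)
      valid[di, ai] <- n_pairs
      if (n_pairs == 0L) next
      idx <- A[ok] + L * B[ok] + 1L      # column-major (a+1, b+1)
      M <- matrix(tabulate(idx, nbins = L * L), L, L)
      if (p$symmetric) M <- M + t(M)
      if (p$normed) M <- M / sum(M)
      P[, , di, ai] <- M
    }
  }
  structure(list(P = P, valid_pairs = valid, distances = p$distances,
                 angles = p$angles, levels = L, symmetric = p$symmetric,
                 normed = p$normed),
            class = "glcm_tensor")
}

#' Haralick summary statistics of a GLCM tensor
#'
#' For each (distance, angle) slice `P` computes: contrast
#' `sum P(i,j) (i-j)^2`; dissimilarity `sum P(i,j) |i-j|`; homogeneity
#' `sum P(i,j) / (1 + (i-j)^2)`; ASM `sum P(i,j)^2`; energy `sqrt(ASM)`;
#' and correlation `sum P(i,j)(i - mu_i)(j - mu_j) / (sd_i sd_j)` with
#' marginal means/sds, defined as 1 when either marginal sd is 0 (all mass
#' on one level). Degenerate slices (no valid pair) yield `NA` for all six
#' statistics.
#'
#' @param t a normed `glcm_tensor` from [compute_glcm()].
#' @return A data.frame with columns `stat`, `distance`, `angle`, `value`.
#' @export
glcm_props <- function(t) {
  if (!isTRUE(t$normed)) stop("glcm_props() requires a normed GLCM tensor")
  L <- t$levels
  lv <- 0:(L - 1)
  D <- outer(lv, lv, "-")
  w_contrast <- D^2
  w_dissim <- abs(D)
  w_homog <- 1 / (1 + D^2)
  stats_names <- c("contrast", "dissimilarity", "homogeneity",
                   "energy", "correlation", "ASM")
  out <- expand.grid(stat = stats_names,
                     distance = t$distances,
                     angle = t$angles,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$value <- NA_real_
  for (ai in seq_along(t$angles)) {
    for (di in seq_along(t$distances)) {
      sel <- out$distance == t$distances[di] & out$angle == t$angles[ai]
      if (t$valid_pairs[di, ai] == 0L) next
      P <- t$P[, , di, ai]
      asm <- sum(P^2)
      pi_m <- rowSums(P); pj_m <- colSums(P)
      mu_i <- sum(pi_m * lv); mu_j <- sum(pj_m * lv)
      sd_i <- sqrt(sum(pi_m * (lv - mu_i)^2))
      sd_j <- sqrt(sum(pj_m * (lv - mu_j)^2))
      corr <- if (sd_i * sd_j == 0) 1 else
        sum(P * outer(lv - mu_i, lv - mu_j)) / (sd_i * sd_j)
      vals <- c(contrast = sum(P * w_contrast),
                dissimilarity = sum(P * w_dissim),
                homogeneity = sum(P * w_homog),
                energy = sqrt(asm),
                correlation = corr,
                ASM = asm)
      out$value[sel] <- vals[out$stat[sel]]
    }
  }
  out
}

# stable column name for one GLCM statistic at one (distance, angle)
glcm_feature_name <- function(stat, distance, angle) {
  sprintf("glcm_%s_d%d_a%d", stat, distance, round(angle * 180 / pi))
}

# flatten glcm_props() output to a named vector in documented column order
glcm_feature_vector <- function(props) {
  stats::setNames(props$value,
                  glcm_feature_name(props$stat, props$distance, props$angle))
}
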