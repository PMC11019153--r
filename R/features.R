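#' Identify auxiliary (bookkeeping) features
#'
#' Auxiliary features — image size and the counts of blank rows/columns —
#' are used by the quality-control classifier but excluded from the t-SNE
#' embedding and the condition classifier.
#'
#' @param feature_names character vector of column names.
#' @return Logical vector, `TRUE` for auxiliary features.
#' @export
feature_is_auxiliary <- function(feature_names) {
  feature_names %in% c("img_width", "img_height",
                       "n_blank_rows", "n_blank_cols")
}

# provenance / label columns that are never model inputs
non_feature_columns <- function() {
  c("cell_id", "condition", "replicate", "qc_label", "bad_mode", "group")
}

# eccentricity of a binary mask from its second central moments,
# sqrt(1 - lambda_min / lambda_max) of the covariance eigenvalues
mask_eccentricity <- function(mask) {
  idx <- which(mask)
  if (length(idx) < 3) return(NA_real_)
  r <- (idx - 1) %% nrow(mask) + 1
  c <- (idx - 1) %/% nrow(mask) + 1
  cv <- stats::cov(cbind(r, c))
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) return(0)
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

#' Extract the feature vector of one nucleus image
#'
#' Normalizes the raw image to the profile's quantiles, applies a light
#' Gaussian pre-blur (sigma = 0.5 px), quantizes, and computes the six
#' GLCM statistics at every (distance, angle) of the profile within the
#' mask, plus profile-specific scalar features.
#'
#' The STED profile yields 70 values: 60 GLCM statistics (6 stats x 5
#' distances x 2 angles) plus mean foreground intensity in the raw and
#' normalized image, foreground intensity sd, segmented area, the two raw
#' quantile values used in normalization, image width/height, and the
#' number of rows and columns composed wholly of exact zeroes. The
#' confocal profile yields 51 values: 48 GLCM statistics (4 distances)
#' plus area, eccentricity and mean intensity.
#'
#' Blank rows/columns are counted on the raw image. If the mask is empty
#' or the image is constant, the texture block and mask-dependent scalars
#' are `NA` (a missing-feature sentinel, median-imputed before model
#' training) and the attribute `qc_hint` is set to `"degenerate"`.
#'
#' @param img raw 2D image matrix.
#' @param mask logical foreground mask, same shape.
#' @param profile `"sted"` or `"confocal"`.
#' @param p a [glcm_params()] object; defaults to the profile's parameters.
#' @param provenance optional named list (`cell_id`, `condition`,
#'   `replicate`, ...) prepended as columns.
#' @return A one-row data.frame.
#' @export
extract_features <- function(img, mask, profile = c("sted", "confocal"),
                             p = NULL, provenance = NULL) {
  profile <- match.arg(profile)
  if (is.null(p)) p <- glcm_params(profile)
  assert_image(img)
  stopifnot(all(dim(img) == dim(mask)))
  mask <- mask > 0

  n_blank_rows <- sum(rowSums(img != 0) == 0L)
  n_blank_cols <- sum(colSums(img != 0) == 0L)
  q <- quantile_pair(img, p$q_low, p$q_high)
  area <- sum(mask)

  degenerate <- area == 0L || q[2] <= q[1]
  glcm_template <- glcm_props(structure(
    list(P = array(0, c(2, 2, length(p$distances), length(p$angles))),
         valid_pairs = matrix(0L, length(p$distances), length(p$angles)),
         distances = p$distances, angles = p$angles, levels = 2L,
         normed = TRUE),
    class = "glcm_tensor"))
  glcm_vec <- glcm_feature_vector(glcm_template)   # all NA

  mean_fg_raw <- mean_fg_norm <- sd_fg <- NA_real_
  if (!degenerate) {
    norm <- clip01((img - q[1]) / (q[2] - q[1]))
    blurred <- clip01(gaussian_blur(norm, p$pre_blur_sigma_px))
    qimg <- quantize(blurred, p$levels)
    glcm_vec <- glcm_feature_vector(glcm_props(compute_glcm(qimg, mask, p)))
    mean_fg_raw <- mean(img[mask])
    mean_fg_norm <- mean(norm[mask])
    sd_fg <- stats::sd(img[mask])
  }

  scalars <- if (profile == "sted") {
    c(mean_fg_intensity_raw = mean_fg_raw,
      mean_fg_intensity_norm = mean_fg_norm,
      sd_fg_intensity = sd_fg,
      area_px = as.numeric(area),
      q_low_value = q[1], q_high_value = q[2],
      img_width = ncol(img), img_height = nrow(img),
      n_blank_rows = n_blank_rows, n_blank_cols = n_blank_cols)
  } else {
    c(area_px = as.numeric(area),
      eccentricity = mask_eccentricity(mask),
      mean_intensity = mean_fg_raw)
  }

  row <- as.data.frame(as.list(c(glcm_vec, scalars)), check.names = FALSE)
  if (!is.null(provenance)) {
    row <- cbind(as.data.frame(provenance, stringsAsFactors = FALSE), row)
  }
  attr(row, "qc_hint") <- if (degenerate) "degenerate" else "ok"
  row
}

#' Feature table for a population of detail-image records
#'
#' Runs foreground segmentation and feature extraction over every record
#' of a [generate_population()] output (or any list of records with
#' `image` plus provenance fields), producing one row per nucleus.
#'
#' @param records list of records with `image`, `cell_id`, `condition`,
#'   `replicate`, and optionally `qc_label`/`bad_mode`.
#' @param profile feature profile, `"sted"` or `"confocal"`.
#' @param p optional [glcm_params()] override.
#' @param seg optional [sted_seg_params()] override.
#' @return A data.frame with provenance columns followed by the feature
#'   columns.
#' @export
extract_features_table <- function(records, profile = "sted", p = NULL,
                                   seg = sted_seg_params()) {
  rows <- lapply(records, function(rec) {
    s <- segment_sted_foreground(rec$image, seg)
    prov <- list(cell_id = rec$cell_id %||% NA_character_,
                 condition = rec$condition %||% NA_character_,
                 replicate = rec$replicate %||% NA_integer_)
    if (!is.null(rec$qc_label)) prov$qc_label <- rec$qc_label
    if (!is.null(rec$bad_mode)) prov$bad_mode <- rec$bad_mode
    extract_features(rec$image, s$mask, profile = profile, p = p,
                     provenance = prov)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
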