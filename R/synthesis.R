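#' Condition-specific generator parameters
#'
#' Returns the default synthetic-nucleus parameters for one experimental
#' condition. Nuclei are modelled as ellipses whose interior chromatin
#' texture is a band-limited Gaussian random field (white noise smoothed
#' with a Gaussian of width `texture_corr_len_px`) plus hard-disk
#' heterochromatin-like foci. Senescent-like nuclei are larger with a
#' longer texture correlation length (smoother, more homogeneous texture)
#' and fewer/weaker foci than proliferating nuclei; the 3-day-treated
#' condition sits midway, and 6/9-day treatment matches senescence.
#'
#' @param condition one of `"proliferating"`, `"senescent"`, `"treated_d3"`,
#'   `"treated_d6"`, `"treated_d9"`.
#' @param ... named overrides for individual fields.
#' @return A `condition_params` list with fields `condition`,
#'   `area_mean_px`, `area_sd_px`, `texture_corr_len_px`, `foci_density`
#'   (per square micron), `foci_contrast`, `background_level`, `noise_sd`,
#'   `intensity_scale` and `pixel_size_nm`.
#' @export
condition_params <- function(condition = c("proliferating", "senescent",
                                           "treated_d3", "treated_d6",
                                           "treated_d9"),
                             ...) {
  condition <- match.arg(condition)
  base <- switch(condition,
    proliferating = list(area_mean_px = 7000, area_sd_px = 700,
                         texture_corr_len_px = 1.5, foci_density = 8,
                         foci_contrast = 0.25),
    treated_d3    = list(area_mean_px = 9500, area_sd_px = 900,
                         texture_corr_len_px = 2.25, foci_density = 6,
                         foci_contrast = 0.20),
    # treated_d6/d9 share the senescent morphology
    list(area_mean_px = 12000, area_sd_px = 1100,
         texture_corr_len_px = 3.0, foci_density = 4,
         foci_contrast = 0.15)
  )
  p <- c(list(condition = condition), base,
         list(background_level = 0.05, noise_sd = 0.02,
              intensity_scale = 1.0, pixel_size_nm = 25,
              aspect_range = c(0.72, 1)))
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) {
      stop("unknown condition parameter(s): ", paste(unknown, collapse = ", "))
    }
    p[names(dots)] <- dots
  }
  validate_condition_params(p)
  structure(p, class = "condition_params")
}

validate_condition_params <- function(p) {
  stopifnot(p$area_mean_px > 200, p$area_sd_px > 0,
            p$texture_corr_len_px > 0,
            p$foci_density >= 0, p$foci_contrast >= 0,
            p$background_level >= 0, p$noise_sd >= 0,
            p$intensity_scale > 0, p$pixel_size_nm > 0,
            length(p$aspect_range) == 2, all(p$aspect_range > 0),
            all(p$aspect_range <= 1))
  invisible(p)
}

# Draw one elliptical nucleus into a blank frame. Assumes the caller has
# already seeded the RNG. Returns the noiseless image and the exact mask.
render_nucleus <- function(params, shape, centre = NULL, allow_truncated = FALSE,
                           area_px = NULL) {
  h <- shape[1]; w <- shape[2]
  if (is.null(area_px)) {
    area_px <- max(500, stats::rnorm(1, params$area_mean_px, params$area_sd_px))
  }
  ar <- params$aspect_range %||% c(0.72, 1)
  aspect <- stats::runif(1, ar[1], ar[2])
  phi <- stats::runif(1, 0, pi)
  a <- sqrt(area_px / (pi * aspect))   # semi-major; pi*a*b = area
  b <- a * aspect
  if (is.null(centre)) centre <- c(h / 2, w / 2) + stats::runif(2, -2, 2)
  if (!allow_truncated && (a + 4 > min(centre[1], h - centre[1],
                                       centre[2], w - centre[2]))) {
    stop("nucleus of semi-axis ", round(a, 1),
         " px does not fit in a ", h, "x", w, " frame")
  }
  rr <- matrix(seq_len(h), h, w) - centre[1]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - centre[2]
  u <- rr * cos(phi) + cc * sin(phi)
  v <- -rr * sin(phi) + cc * cos(phi)
  mask <- (u / a)^2 + (v / b)^2 <= 1

  # band-limited random field; corr_len = Inf is the constant-texture limit
  if (is.finite(params$texture_corr_len_px)) {
    z <- matrix(stats::rnorm(h * w), h, w)
    z <- gaussian_blur(z, params$texture_corr_len_px)
    z <- (z - mean(z)) / max(stats::sd(z), 1e-12)
  } else {
    z <- matrix(0, h, w)
  }

  # hard-disk foci, Poisson-distributed over the nuclear area
  foci <- matrix(0, h, w)
  um2 <- sum(mask) * (params$pixel_size_nm / 1000)^2
  n_foci <- if (params$foci_density > 0) stats::rpois(1, params$foci_density * um2) else 0L
  if (n_foci > 0) {
    inside <- which(mask)
    pick <- inside[sample.int(length(inside), min(n_foci, length(inside)),
                              replace = TRUE)]
    fr <- (pick - 1) %% h + 1
    fc <- (pick - 1) %/% h + 1
    for (k in seq_along(pick)) {
      r0 <- max(1, fr[k] - 2):min(h, fr[k] + 2)
      c0 <- max(1, fc[k] - 2):min(w, fc[k] + 2)
      sub <- outer((r0 - fr[k])^2, (c0 - fc[k])^2, "+") <= 4
      foci[r0, c0][sub] <- 1
    }
  }

  img <- matrix(params$background_level, h, w)
  interior <- 0.55 + 0.15 * z + params$foci_contrast * foci
  img[mask] <- pmax(interior[mask], 0.02)
  list(image = img, mask = mask, area_px = sum(mask), centre = centre,
       semi_axes = c(a, b))
}

finish_image <- function(img, params) {
  if (params$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, params$noise_sd),
                        nrow(img), ncol(img))
  }
  pmax(img, 0) * params$intensity_scale
}

scene_truth <- function(masks, condition, qc_label, params, seed,
                        bad_mode = NA_character_) {
  structure(list(nucleus_masks = masks, condition = condition,
                 qc_label = qc_label, texture_params = params,
                 rng_seed = seed, bad_mode = bad_mode),
            class = "scene_truth")
}

#' Generate one single-nucleus detail image
#'
#' Produces a centred, complete, in-focus synthetic nucleus: an elliptical
#' foreground whose interior is a band-limited random texture field with
#' optional bright foci, over a dim background, with additive Gaussian
#' read-out noise. Output is a pure function of `(params, shape, seed)`.
#'
#' @param params a [condition_params()] object.
#' @param shape integer vector `c(rows, cols)`, at least 128 x 128.
#' @param seed integer seed.
#' @return A list with `image` (matrix) and `truth` (ground-truth
#'   `scene_truth`: exact nucleus mask, condition, `qc_label = "good"`).
#' @export
generate_nucleus_detail <- function(params, shape = c(192, 192), seed = 1) {
  stopifnot(length(shape) == 2, all(shape >= 128))
  with_seed(seed, {
    n <- render_nucleus(params, shape)
    img <- finish_image(n$image, params)
    list(image = img,
         truth = scene_truth(list(n$mask), params$condition, "good",
                             params, seed))
  })
}

#' Generate a labelled bad detail image
#'
#' Emulates the failure modes an automated microscope produces: out-of-focus
#' acquisitions, nuclei clipped at the frame border, blank-row scanner
#' artifacts (rows of exact zeroes, as when imaging outside the field of
#' view), empty frames, and frames containing two nuclei.
#'
#' @param mode one of `"out_of_focus"`, `"truncated"`, `"blank_rows"`,
#'   `"empty"`, `"doublet"`.
#' @param seed integer seed.
#' @param params a [condition_params()] object used for the underlying
#'   nucleus where one is drawn.
#' @param shape frame shape `c(rows, cols)`.
#' @return A list with `image` and `truth` (`qc_label = "bad"`,
#'   `bad_mode = mode`).
#' @export
generate_bad_detail <- function(mode = c("out_of_focus", "truncated",
                                         "blank_rows", "empty", "doublet"),
                                seed = 1,
                                params = condition_params("proliferating"),
                                shape = c(192, 192)) {
  mode <- match.arg(mode)
  stopifnot(length(shape) == 2, all(shape >= 128))
  h <- shape[1]; w <- shape[2]
  with_seed(seed, {
    out <- switch(mode,
      out_of_focus = {
        n <- render_nucleus(params, shape)
        img <- finish_image(gaussian_blur(n$image, 8), params)
        list(img, list(n$mask))
      },
      truncated = {
        # centre placed at the border so the mask is clipped by the frame
        side <- sample(4, 1)
        centre <- switch(side,
                         c(3, w / 2), c(h - 3, w / 2),
                         c(h / 2, 3), c(h / 2, w - 3))
        n <- render_nucleus(params, shape, centre = centre,
                            allow_truncated = TRUE)
        list(finish_image(n$image, params), list(n$mask))
      },
      blank_rows = {
        n <- render_nucleus(params, shape)
        img <- finish_image(n$image, params)
        n_blank <- ceiling(0.12 * h)
        start <- sample(h - n_blank + 1, 1)
        img[start:(start + n_blank - 1), ] <- 0
        list(img, list(n$mask))
      },
      empty = {
        img <- finish_image(matrix(params$background_level, h, w), params)
        list(img, list())
      },
      doublet = {
        p2 <- params
        p2$area_mean_px <- params$area_mean_px * 0.45
        p2$area_sd_px <- params$area_sd_px * 0.45
        n1 <- render_nucleus(p2, shape, centre = c(h / 2, w * 0.3),
                             allow_truncated = TRUE)
        n2 <- render_nucleus(p2, shape, centre = c(h / 2, w * 0.7),
                             allow_truncated = TRUE)
        img <- pmax(n1$image, n2$image)
        list(finish_image(img, params), list(n1$mask, n2$mask))
      }
    )
    list(image = out[[1]],
         truth = scene_truth(out[[2]], params$condition, "bad", params, seed,
                             bad_mode = mode))
  })
}

# clockwise spiral ordering of an nr x nc tile grid, mirroring a spiral
# acquisition path: start at the top-left, walk the rim inwards.
spiral_order <- function(nr, nc) {
  visited <- matrix(FALSE, nr, nc)
  ord <- matrix(0L, nr * nc, 2)
  dr <- c(0L, 1L, 0L, -1L); dc <- c(1L, 0L, -1L, 0L)
  r <- 1L; c <- 1L; d <- 1L
  for (k in seq_len(nr * nc)) {
    ord[k, ] <- c(r, c)
    visited[r, c] <- TRUE
    nr2 <- r + dr[d]; nc2 <- c + dc[d]
    if (nr2 < 1 || nr2 > nr || nc2 < 1 || nc2 > nc || visited[nr2, nc2]) {
      d <- d %% 4L + 1L
      nr2 <- r + dr[d]; nc2 <- c + dc[d]
    }
    r <- nr2; c <- nc2
  }
  ord
}

#' Generate a tiled confocal-like overview scene
#'
#' Places non-overlapping nuclei in a global scene, renders a 3-plane
#' z-stack (sharp mid-plane, defocused neighbours), and cuts it into a
#' spiral-ordered tile grid with the requested overlap, emitting per-tile
#' stage coordinates consistent with the cut. Stitching the tiles by stage
#' coordinate reconstructs the scene's maximum-intensity projection
#' exactly.
#'
#' @param n_nuclei number of nuclei to place (may be 0).
#' @param params a [condition_params()] object; areas are scaled from the
#'   detail-image (STED) pixel size to the overview pixel size.
#' @param tile_shape per-tile shape `c(rows, cols)`.
#' @param overlap_fraction nominal tile overlap in `[0, 0.5]`.
#' @param seed integer seed.
#' @param n_tiles tile grid `c(rows, cols)`.
#' @param pixel_size_nm overview pixel size (nm).
#' @return A list with `tiles` (a `tile_set`: list of 3-plane stacks,
#'   `stage_xy` in nm, `pixel_size_nm`, `overlap_fraction`), `truth`
#'   (masks and centroids in scene coordinates) and `scene` (the full
#'   scene stack, for reference).
#' @export
generate_overview_scene <- function(n_nuclei, params = condition_params(),
                                    tile_shape = c(160, 160),
                                    overlap_fraction = 0.2, seed = 1,
                                    n_tiles = c(2, 2),
                                    pixel_size_nm = 100) {
  stopifnot(n_nuclei >= 0, overlap_fraction >= 0, overlap_fraction <= 0.5)
  step_r <- round(tile_shape[1] * (1 - overlap_fraction))
  step_c <- round(tile_shape[2] * (1 - overlap_fraction))
  h <- step_r * (n_tiles[1] - 1) + tile_shape[1]
  w <- step_c * (n_tiles[2] - 1) + tile_shape[2]

  # overview nuclei are smaller in pixels than detail-image nuclei
  scale2 <- (params$pixel_size_nm / pixel_size_nm)^2
  p_ov <- params
  p_ov$area_mean_px <- params$area_mean_px * scale2
  p_ov$area_sd_px <- max(params$area_sd_px * scale2, 1)
  p_ov$pixel_size_nm <- pixel_size_nm

  with_seed(seed, {
    sharp <- matrix(p_ov$background_level, h, w)
    masks <- list()
    centres <- matrix(NA_real_, 0, 2)
    radii <- numeric(0)
    for (i in seq_len(n_nuclei)) {
      placed <- FALSE
      for (try in seq_len(500)) {
        area <- max(60, stats::rnorm(1, p_ov$area_mean_px, p_ov$area_sd_px))
        r_eff <- sqrt(area / pi) / sqrt(0.72)     # worst-case semi-major
        ctr <- c(stats::runif(1, r_eff + 5, h - r_eff - 5),
                 stats::runif(1, r_eff + 5, w - r_eff - 5))
        if (nrow(centres) == 0 ||
            all(sqrt(rowSums(sweep(centres, 2, ctr)^2)) >
                radii + r_eff + 4)) {
          n <- render_nucleus(p_ov, c(h, w), centre = ctr, area_px = area)
          sharp <- pmax(sharp, n$image)
          masks[[i]] <- n$mask
          centres <- rbind(centres, ctr)
          radii <- c(radii, r_eff)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place ", n_nuclei,
                        " non-overlapping nuclei after bounded retries")
    }
    sharp <- finish_image(sharp, p_ov)
    defocus <- gaussian_blur(sharp, 3) * 0.85
    planes <- list(defocus, sharp, defocus)

    ord <- spiral_order(n_tiles[1], n_tiles[2])
    tiles <- vector("list", nrow(ord))
    stage_xy <- matrix(0, nrow(ord), 2,
                       dimnames = list(NULL, c("x_nm", "y_nm")))
    for (k in seq_len(nrow(ord))) {
      r0 <- (ord[k, 1] - 1) * step_r
      c0 <- (ord[k, 2] - 1) * step_c
      tiles[[k]] <- image_stack(lapply(planes, function(p) {
        p[r0 + seq_len(tile_shape[1]), c0 + seq_len(tile_shape[2])]
      }))
      stage_xy[k, ] <- c(c0 * pixel_size_nm, r0 * pixel_size_nm)
    }
    tile_set <- structure(list(tiles = tiles, stage_xy = stage_xy,
                               pixel_size_nm = pixel_size_nm,
                               overlap_fraction = overlap_fraction),
                          class = "tile_set")
    truth <- scene_truth(masks, params$condition, "good", p_ov, seed)
    truth$centroids <- centres
    list(tiles = tile_set, truth = truth,
         scene = image_stack(planes))
  })
}

#' Generate a balanced labelled population of detail images
#'
#' Draws `n_cells_per_condition` good single-nucleus detail images for each
#' condition, and mixes in `round(bad_fraction * n_good)` labelled bad
#' images whose failure modes cycle through all five supported modes.
#'
#' @param n_cells_per_condition good images per condition (>= 1).
#' @param conditions character vector of condition names.
#' @param seed integer master seed; each image draws from its own
#'   deterministic sub-stream.
#' @param bad_fraction number of bad images as a fraction of the good count.
#' @param shape detail-image shape.
#' @param overrides optional named list of [condition_params()] overrides
#'   applied to every condition (e.g. to make two conditions identical).
#' @return A list of records, each with `image`, `mask`, `condition`,
#'   `qc_label`, `bad_mode`, `cell_id`, `replicate`.
#' @export
generate_population <- function(n_cells_per_condition,
                                conditions = c("proliferating", "senescent"),
                                seed = 1, bad_fraction = 0.2,
                                shape = c(192, 192), overrides = list()) {
  stopifnot(n_cells_per_condition >= 1, bad_fraction >= 0, bad_fraction <= 1)
  records <- list()
  id <- 0L
  for (ci in seq_along(conditions)) {
    pars <- do.call(condition_params, c(list(conditions[ci]), overrides))
    for (i in seq_len(n_cells_per_condition)) {
      id <- id + 1L
      g <- generate_nucleus_detail(pars, shape, seed = split_seed(seed, 1, id))
      records[[id]] <- list(image = g$image, mask = g$truth$nucleus_masks[[1]],
                            condition = conditions[ci], qc_label = "good",
                            bad_mode = NA_character_,
                            cell_id = sprintf("cell_%04d", id),
                            replicate = (i - 1L) %% 2L + 1L)
    }
  }
  n_good <- id
  n_bad <- round(bad_fraction * n_good)
  modes <- c("out_of_focus", "truncated", "blank_rows", "empty", "doublet")
  for (j in seq_len(n_bad)) {
    id <- id + 1L
    pars <- do.call(condition_params,
                    c(list(conditions[(j - 1L) %% length(conditions) + 1L]),
                      overrides))
    b <- generate_bad_detail(modes[(j - 1L) %% 5L + 1L],
                             seed = split_seed(seed, 2, j),
                             params = pars, shape = shape)
    records[[id]] <- list(image = b$image,
                          mask = if (length(b$truth$nucleus_masks))
                            b$truth$nucleus_masks[[1]] else
                              matrix(FALSE, shape[1], shape[2]),
                          condition = pars$condition, qc_label = "bad",
                          bad_mode = b$truth$bad_mode,
                          cell_id = sprintf("cell_%04d", id),
                          replicate = (j - 1L) %% 2L + 1L)
  }
  records
}
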