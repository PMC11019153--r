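test_that("quantization maps [0,1] onto the full level range", {
  expect_equal(quantize(matrix(0), 16)[1, 1], 0L)
  expect_equal(quantize(matrix(1), 16)[1, 1], 15L)
  expect_equal(quantize(matrix(0.49), 2)[1, 1], 0L)
  expect_equal(quantize(matrix(0.51), 2)[1, 1], 1L)
  expect_error(quantize(matrix(1.2), 16), "\\[0, 1\\]")
  expect_error(quantize(matrix(-0.1), 16), "\\[0, 1\\]")

  # level histogram of a uniform image matches the flat multinomial
  u <- matrix(with_seed(8, runif(128 * 128)), 128, 128)
  counts <- tabulate(quantize(u, 16) + 1L, 16)
  n <- length(u)
  expect_true(all(abs(counts - n / 16) < 5 * sqrt(n * (1 / 16) * (15 / 16))))
})

test_that("hand-enumerated 2x2 co-occurrence cases match exactly", {
  img <- matrix(c(0L, 1L, 0L, 1L), 2, 2)  # rows: (0,0) / (1,1)
  mask <- matrix(TRUE, 2, 2)
  p <- glcm_params("sted", distances = 1L, levels = 2L)

  tens <- compute_glcm(img, mask, p)
  # theta = 0 (horizontal): both pairs equal-valued
  P0 <- tens$P[, , 1, 1]
  expect_equal(P0, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  # theta = pi/2 (vertical): both pairs (0,1), symmetrized
  P90 <- tens$P[, , 1, 2]
  expect_equal(P90, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  props <- glcm_props(tens)
  v <- function(stat, ai) props$value[props$stat == stat &
                                        props$angle == p$angles[ai]]
  expect_equal(v("contrast", 1), 0)
  expect_equal(v("ASM", 1), 0.5)
  expect_equal(v("energy", 1), sqrt(0.5))
  expect_equal(v("correlation", 1), 1)
  expect_equal(v("contrast", 2), 1)
  expect_equal(v("dissimilarity", 2), 1)
  expect_equal(v("homogeneity", 2), 0.5)
  expect_equal(v("correlation", 2), -1)
})

test_that("constant images put all mass on one diagonal cell", {
  img <- matrix(3L, 8, 8)
  mask <- matrix(TRUE, 8, 8)
  p <- glcm_params("sted", distances = c(1L, 3L), levels = 8L)
  tens <- compute_glcm(img, mask, p)
  expect_equal(tens$P[4, 4, 1, 1], 1)
  expect_equal(sum(tens$P[, , 2, 2]), 1)
  props <- glcm_props(tens)
  expect_true(all(props$value[props$stat == "contrast"] == 0))
  expect_true(all(props$value[props$stat == "dissimilarity"] == 0))
  expect_true(all(props$value[props$stat == "homogeneity"] == 1))
  expect_true(all(props$value[props$stat == "ASM"] == 1))
  expect_true(all(props$value[props$stat == "energy"] == 1))
  expect_true(all(props$value[props$stat == "correlation"] == 1))
})

test_that("vectorized GLCM agrees with pair-enumeration oracle to 1e-12", {
  levels <- 8L
  p <- glcm_params("sted", distances = c(1L, 2L, 3L), levels = levels)
  stats_order <- c("contrast", "dissimilarity", "homogeneity",
                   "energy", "correlation", "ASM")
  with_seed(123, {
    for (rep in 1:100) {
      qimg <- matrix(sample(0:(levels - 1), 256, replace = TRUE), 16, 16)
      mask <- matrix(runif(256) < 0.7, 16, 16)
      tens <- compute_glcm(qimg, mask, p)
      props <- glcm_props(tens)
      for (di in 1:3) {
        for (ai in 1:2) {
          counts <- oracle_glcm(qimg, mask, p$distances[di], p$angles[ai],
                                levels)
          expected <- oracle_props(counts)
          got <- props$value[props$distance == p$distances[di] &
                               props$angle == p$angles[ai]]
          names(got) <- props$stat[props$distance == p$distances[di] &
                                     props$angle == p$angles[ai]]
          if (is.null(expected)) {
            expect_true(all(is.na(got)))
          } else {
            expect_equal(got[stats_order], expected[stats_order],
                         tolerance = 1e-12)
          }
        }
      }
    }
  })
})

test_that("normalization, bounds and Cauchy-Schwarz hold on random slices", {
  levels <- 16L
  p <- glcm_params("sted", distances = c(1L, 2L, 5L), levels = levels)
  with_seed(77, {
    for (rep in 1:25) {
      qimg <- matrix(sample(0:(levels - 1), 400, replace = TRUE), 20, 20)
      mask <- matrix(runif(400) < 0.8, 20, 20)
      tens <- compute_glcm(qimg, mask, p)
      props <- glcm_props(tens)
      for (di in seq_along(p$distances)) {
        for (ai in 1:2) {
          if (tens$valid_pairs[di, ai] > 0) {
            expect_equal(sum(tens$P[, , di, ai]), 1, tolerance = 1e-9)
          }
        }
      }
      sl <- split(props$value, interaction(props$distance, props$angle))
      nm <- split(props$stat, interaction(props$distance, props$angle))
      for (k in seq_along(sl)) {
        v <- setNames(sl[[k]], nm[[k]])
        if (any(is.na(v))) next
        expect_true(v["homogeneity"] > 0 && v["homogeneity"] <= 1)
        expect_true(v["ASM"] > 0 && v["ASM"] <= 1)
        expect_true(v["energy"] > 0 && v["energy"] <= 1)
        expect_gte(v[["contrast"]], 0)
        expect_gte(v[["dissimilarity"]], 0)
        expect_true(v["correlation"] >= -1 - 1e-12 &&
                      v["correlation"] <= 1 + 1e-12)
        expect_lte(v[["dissimilarity"]]^2, v[["contrast"]] + 1e-12)
      }
    }
  })
})

test_that("GLCM features ignore pixels outside the mask", {
  levels <- 16L
  p <- glcm_params("sted", distances = c(1L, 4L), levels = levels)
  qimg <- matrix(with_seed(5, sample(0:15, 900, replace = TRUE)), 30, 30)
  mask <- matrix(FALSE, 30, 30)
  mask[8:22, 8:22] <- TRUE
  scrambled <- qimg
  scrambled[!mask] <- with_seed(6, sample(0:15, sum(!mask), replace = TRUE))
  expect_identical(compute_glcm(qimg, mask, p)$P,
                   compute_glcm(scrambled, mask, p)$P)
})

test_that("degenerate slices carry NA sentinels, never silent zeros", {
  p <- glcm_params("sted", distances = c(1L, 20L), levels = 4L)
  qimg <- matrix(1L, 10, 10)
  empty <- matrix(FALSE, 10, 10)
  tens <- compute_glcm(qimg, empty, p)
  expect_true(all(tens$valid_pairs == 0))
  expect_true(all(is.na(glcm_props(tens)$value)))

  # distance 20 exceeds a 10 px image: only that slice is degenerate
  tens2 <- compute_glcm(qimg, matrix(TRUE, 10, 10), p)
  expect_gt(tens2$valid_pairs[1, 1], 0)
  expect_equal(tens2$valid_pairs[2, 1], 0)

  unnormed <- compute_glcm(qimg, matrix(TRUE, 10, 10),
                           glcm_params("sted", distances = 1L, levels = 4L,
                                       normed = FALSE))
  expect_error(glcm_props(unnormed), "normed")
})

test_that("feature records carry the documented profile schemas", {
  g <- generate_nucleus_detail(condition_params("proliferating"), seed = 12)
  mask <- g$truth$nucleus_masks[[1]]

  sted <- extract_features(g$image, mask, "sted")
  expect_equal(ncol(sted), 70)
  expect_equal(sum(grepl("^glcm_", names(sted))), 60)
  expect_true(all(c("mean_fg_intensity_raw", "mean_fg_intensity_norm",
                    "sd_fg_intensity", "area_px", "q_low_value",
                    "q_high_value", "img_width", "img_height",
                    "n_blank_rows", "n_blank_cols") %in% names(sted)))
  expect_equal(sted$area_px, sum(mask))
  expect_equal(sum(feature_is_auxiliary(names(sted))), 4)

  conf <- extract_features(g$image, mask, "confocal")
  expect_equal(ncol(conf), 51)
  expect_equal(sum(grepl("^glcm_", names(conf))), 48)
  expect_true(all(c("area_px", "eccentricity", "mean_intensity")
                  %in% names(conf)))
  expect_true(conf$eccentricity >= 0 && conf$eccentricity <= 1)

  # blank rows are counted on the raw image
  img <- g$image
  img[11:22, ] <- 0
  f <- extract_features(img, mask, "sted")
  expect_equal(f$n_blank_rows, 12)
  expect_equal(f$n_blank_cols, 0)

  # empty mask: NA texture block plus a QC hint
  f0 <- extract_features(g$image, matrix(FALSE, nrow(g$image), ncol(g$image)),
                         "sted")
  expect_true(all(is.na(unlist(f0[grepl("^glcm_", names(f0))]))))
  expect_equal(attr(f0, "qc_hint"), "degenerate")
  expect_equal(f0$area_px, 0)
})

test_that("homogeneity increases with the texture correlation length", {
  seeds <- 1:50
  mean_homog <- function(corr_len) {
    mean(vapply(seeds, function(s) {
      p <- condition_params("proliferating", area_mean_px = 4500,
                            area_sd_px = 200, foci_density = 0,
                            texture_corr_len_px = corr_len)
      g <- generate_nucleus_detail(p, c(128, 128), seed = s)
      mask <- g$truth$nucleus_masks[[1]]
      q <- quantile(g$image, c(0.025, 0.995), names = FALSE)
      norm <- pmin(pmax((g$image - q[1]) / (q[2] - q[1]), 0), 1)
      gp <- glcm_params("sted", distances = 2L)
      props <- glcm_props(compute_glcm(quantize(norm, gp$levels), mask, gp))
      mean(props$value[props$stat == "homogeneity"])
    }, 1))
  }
  h1 <- mean_homog(1)
  h2 <- mean_homog(2)
  h4 <- mean_homog(4)
  expect_lte(h1, h2)
  expect_lte(h2, h4)
})
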