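# Independent GLCM oracle: explicit pair enumeration plus direct
# formula sums, written without reference to the package's vectorized
# implementation.
oracle_glcm <- function(qimg, mask, d, theta, levels, symmetric = TRUE) {
  dr <- round(d * sin(theta))
  dc <- round(d * cos(theta))
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(qimg))) {
    for (cc in seq_len(ncol(qimg))) {
      r2 <- r + dr
      c2 <- cc + dc
      if (r2 >= 1 && r2 <= nrow(qimg) && c2 >= 1 && c2 <= ncol(qimg) &&
          mask[r, cc] && mask[r2, c2]) {
        i <- qimg[r, cc] + 1
        j <- qimg[r2, c2] + 1
        counts[i, j] <- counts[i, j] + 1
      }
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts
}

oracle_props <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) return(NULL)
  P <- counts / tot
  L <- nrow(P)
  contrast <- dissim <- homog <- asm <- 0
  mu_i <- mu_j <- 0
  for (i in 1:L) {
    for (j in 1:L) {
      p <- P[i, j]
      contrast <- contrast + p * (i - j)^2
      dissim <- dissim + p * abs(i - j)
      homog <- homog + p / (1 + (i - j)^2)
      asm <- asm + p^2
      mu_i <- mu_i + p * (i - 1)
      mu_j <- mu_j + p * (j - 1)
    }
  }
  var_i <- var_j <- cov_ij <- 0
  for (i in 1:L) {
    for (j in 1:L) {
      p <- P[i, j]
      var_i <- var_i + p * (i - 1 - mu_i)^2
      var_j <- var_j + p * (j - 1 - mu_j)^2
      cov_ij <- cov_ij + p * (i - 1 - mu_i) * (j - 1 - mu_j)
    }
  }
  corr <- if (var_i * var_j == 0) 1 else cov_ij / sqrt(var_i * var_j)
  c(contrast = contrast, dissimilarity = dissim, homogeneity = homog,
    energy = sqrt(asm), correlation = corr, ASM = asm)
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# mean silhouette coefficient for a 2-class labelling of 2D points
mean_silhouette <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  sil <- vapply(seq_len(nrow(coords)), function(i) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- mean(d[i, own])
    b <- mean(d[i, !own & seq_len(nrow(coords)) != i])
    (b - a) / max(a, b)
  }, 1)
  mean(sil)
}

# small feature table of two Gaussian blobs, for fast model tests
blob_features <- function(n_per_class, n_feat = 10, shift = 0, seed = 1) {
  with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * n_feat), n_per_class),
               matrix(rnorm(n_per_class * n_feat, mean = shift),
                      n_per_class))
    colnames(x) <- sprintf("f%02d", seq_len(n_feat))
    as.data.frame(x)
  })
}

glcm_contrast_of <- function(img, mask, d = 2, levels = 64) {
  q <- quantile(img, c(0.025, 0.995), names = FALSE)
  norm <- pmin(pmax((img - q[1]) / (q[2] - q[1]), 0), 1)
  p <- glcm_params("sted", distances = d, levels = levels)
  props <- glcm_props(compute_glcm(quantize(norm, levels), mask, p))
  props$value[props$stat == "contrast"]
}
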