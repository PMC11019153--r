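test_that("standardization fits on training data and reuses stored stats", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  s <- standardize(x)
  expect_equal(mean(s$x[, "a"]), 0)
  expect_equal(sd(s$x[, "a"]), 1)
  expect_equal(s$x[, "b"], c(0, 0, 0), ignore_attr = TRUE)
  expect_true(s$stats$zero_variance[["b"]])

  held <- cbind(a = c(10, 20), b = c(1, 2))
  z <- standardize(held, s$stats)
  # stored stats, not a refit: held-out columns need not be centred
  expect_equal(z$x[, "a"], (c(10, 20) - 2) / 1, ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(mean(z$x[, "a"]), 0)))
})

test_that("median imputation fills degenerate-feature sentinels", {
  x <- cbind(a = c(1, NA, 3), b = c(NA, NA, NA))
  imp <- senotex:::impute_median(x)
  expect_equal(imp$x[, "a"], c(1, 2, 3), ignore_attr = TRUE)
  expect_equal(imp$x[, "b"], c(0, 0, 0), ignore_attr = TRUE)
  reuse <- senotex:::impute_median(cbind(a = NA_real_, b = NA_real_),
                                   imp$medians)
  expect_equal(as.numeric(reuse$x), c(2, 0))
})

test_that("QC calibration reaches target precision on separable classes", {
  feats <- blob_features(100, shift = 4, seed = 21)
  labels <- rep(c("bad", "good"), each = 100)
  m <- train_qc(feats, labels, seed = 3)
  expect_lt(m$threshold, 1)
  oof_pred <- m$oof$p_good >= m$threshold
  tp <- sum(oof_pred & m$oof$label == "good")
  fp <- sum(oof_pred & m$oof$label == "bad")
  expect_gte(tp / (tp + fp), 0.95)

  d <- apply_qc(m, feats)
  expect_gte(mean(d$keep[labels == "good"]), 0.9)

  expect_error(train_qc(feats, rep("good", 200)), "both")
})

test_that("shuffled labels trigger the reject-all sentinel", {
  feats <- blob_features(100, shift = 4, seed = 22)
  sentinel <- 0L
  for (k in 1:20) {
    labels <- with_seed(1000 + k,
                        sample(rep(c("bad", "good"), each = 100)))
    m <- suppressWarnings(train_qc(feats, labels, n_trees = 100, seed = k))
    if (m$threshold > 1) sentinel <- sentinel + 1L
  }
  # a random scorer's precision is the 0.5 class prevalence at any
  # threshold with real support, so the target is essentially never met
  expect_gte(sentinel, 19L)

  m <- suppressWarnings(train_qc(feats,
                                 with_seed(5, sample(rep(c("bad", "good"),
                                                         each = 100))),
                                 n_trees = 100, seed = 1))
  if (m$threshold > 1) {
    expect_equal(sum(apply_qc(m, feats)$keep), 0)
  }
})

test_that("threshold zero keeps everything and schema mismatches error", {
  feats <- blob_features(50, shift = 4, seed = 23)
  labels <- rep(c("bad", "good"), each = 50)
  m <- train_qc(feats, labels, n_trees = 100, seed = 2)
  m$threshold <- 0
  expect_true(all(apply_qc(m, feats)$keep))
  wrong <- feats
  names(wrong)[1] <- "renamed"
  expect_error(apply_qc(m, wrong), "schema")
})

test_that("t-SNE embeds deterministically and separates disjoint clusters", {
  feats <- blob_features(50, shift = 6, seed = 31)
  labels <- rep(c("A", "B"), each = 50)
  e1 <- embed_features(feats, perplexity = 15, seed = 4)
  e2 <- embed_features(feats, perplexity = 15, seed = 4)
  expect_equal(dim(e1$coords), c(100, 2))
  expect_identical(e1$coords, e2$coords)
  expect_error(embed_features(feats[1:40, ], perplexity = 15), "perplexity")

  sil <- vapply(1:5, function(s) {
    mean_silhouette(embed_features(feats, perplexity = 15, seed = s)$coords,
                    labels)
  }, 1)
  expect_gte(mean(sil), 0.5)
})

test_that("condition SVM separates disjoint classes and not identical ones", {
  feats <- blob_features(60, shift = 5, seed = 41)
  labels <- rep(c("proliferating", "senescent"), each = 60)
  m <- train_condition(feats, labels, seed = 6)
  expect_gte(m$cv_accuracy, 0.95)

  null_feats <- blob_features(60, shift = 0, seed = 42)
  m0 <- train_condition(null_feats, labels, seed = 6)
  ci <- 1.96 * sqrt(0.25 / 120)
  expect_lt(abs(m0$cv_accuracy - 0.5), ci + 0.05)

  tiny <- train_condition(blob_features(10, shift = 5, seed = 43),
                          rep(c("proliferating", "senescent"), each = 10),
                          cross = 0, seed = 1)
  tmp <- tempfile(fileext = ".rds")
  saveRDS(tiny, tmp)
  back <- readRDS(tmp)
  probe <- blob_features(5, shift = 5, seed = 44)
  expect_identical(senotex:::predict_condition(back, probe),
                   senotex:::predict_condition(tiny, probe))
  unlink(tmp)

  expect_error(train_condition(feats, rep("senescent", 120)), "both")
})

test_that("treated-group fractions sum to one and respect mixtures", {
  feats <- blob_features(80, shift = 5, seed = 51)
  labels <- rep(c("proliferating", "senescent"), each = 80)
  m <- train_condition(feats, labels, seed = 7)

  sen_like <- blob_features(40, shift = 5, seed = 52)[41:80, ]
  cf <- classify_treated(m, sen_like, rep("treated_d6", 40))
  expect_equal(cf$fraction_proliferating + cf$fraction_senescent, 1,
               tolerance = 1e-12)
  expect_gte(cf$fraction_senescent, 0.9)
  expect_equal(cf$call, "senescent")

  mix <- blob_features(40, shift = 5, seed = 53)
  cfm <- classify_treated(m, mix, rep("treated_d3", 80))
  expect_equal(cfm$fraction_proliferating + cfm$fraction_senescent, 1,
               tolerance = 1e-12)
  expect_lt(abs(cfm$fraction_senescent - 0.5), 1.96 * sqrt(0.25 / 80) + 0.05)
  expect_equal(cfm$call, "ambiguous")

  grp <- factor(rep("treated_d6", 40), levels = c("treated_d3", "treated_d6"))
  expect_warning(classify_treated(m, sen_like, grp), "empty")
})

test_that("calibration and standardization use training data alone", {
  feats <- blob_features(60, shift = 4, seed = 61)
  labels <- rep(c("bad", "good"), each = 60)
  half <- c(1:30, 61:90)
  m_half <- train_qc(feats[half, ], labels[half], n_trees = 100, seed = 9)
  raw_half <- senotex:::feature_matrix(feats[half, ])
  expect_equal(m_half$std_stats$mean, colMeans(raw_half))
  expect_equal(unname(m_half$std_stats$sd), unname(apply(raw_half, 2, sd)))
  # out-of-fold probabilities exist for every training row, none elsewhere
  expect_equal(nrow(m_half$oof), 60)
  expect_false(any(is.na(m_half$oof$p_good)))
})

test_that("condition summaries produce box-plot-ready tables", {
  pop <- generate_population(6, c("proliferating", "senescent"),
                             seed = 19, bad_fraction = 0)
  feat <- extract_features_table(pop)
  sm <- condition_summaries(feat, feat$condition)
  expect_equal(nrow(sm), 6)
  expect_setequal(unique(sm$feature),
                  c("area_px", "glcm_energy_d4_a0",
                    "glcm_dissimilarity_d2_a90"))
  a <- sm[sm$feature == "area_px", ]
  expect_gt(a$median[a$condition == "senescent"],
            a$median[a$condition == "proliferating"])

  one <- condition_summaries(feat[feat$condition == "senescent", ],
                             rep("senescent", sum(feat$condition == "senescent")))
  expect_equal(nrow(one), 3)

  empty <- condition_summaries(feat[0, ], character(0))
  expect_equal(nrow(empty), 0)
})
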