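# Outlier exclusion, ANOVA channel ranking, LDA + jackknife, and the
# PCA + SVR mixture regression.

test_that("studentized exclusion removes gross outliers and keeps order", {
  set.seed(1)
  base <- 1 + rnorm(20, 0, 0.01)
  vals <- c(base[1:10], 2, 2, base[11:20], 2, 2)
  kept <- exclude_outliers(vals, 4)
  expect_length(kept, 20)
  expect_true(all(kept < 1.5))            # exactly the four 2.0s removed
  expect_identical(kept, vals[vals < 1.5])  # original order preserved
})

test_that("exclusion handles ties, zero counts, and bad requests", {
  same <- rep(3.3, 24)
  kept <- exclude_outliers(same, 4)
  expect_length(kept, 20)
  expect_equal(mean(kept), 3.3)
  expect_identical(exclude_outliers(same, 0), same)  # idempotent at n=0
  expect_error(exclude_outliers(same, 24), "smaller")
})

test_that("response matrix applies the 24-to-20 protocol per condition", {
  d <- array_design(seed = 5)     # defaults: 24 reps, 4 injected outliers
  pl <- generate_plate(d)
  rmx <- build_response_matrix(pl, n_exclude = 4)
  expect_equal(nrow(rmx$x), 8 * 20)
  expect_equal(ncol(rmx$x), 4)
  expect_equal(as.numeric(table(rmx$labels)), rep(20, 8))
  # the injected outlier wells are the ones removed
  truth <- unique(pl[pl$outlier, c("analyte", "replicate")])
  kept <- data.frame(analyte = as.character(rmx$labels),
                     replicate = rmx$replicate)
  overlap <- merge(truth, kept)
  expect_equal(nrow(overlap), 0)
})

test_that("ANOVA F matches hand-computed sums of squares", {
  # classes {0, 1e-6} vs {1, 1 + 1e-6}: SSB = 1, SSW = 1e-12, F = 2e12
  x <- matrix(c(0, 1e-6, 1, 1 + 1e-6), ncol = 1,
              dimnames = list(NULL, "ch"))
  res <- anova_contribution(x, c("a", "a", "b", "b"))
  expect_equal(res$F, 2e12, tolerance = 1e-6)
  # a channel identical across classes ranks at the bottom with F ~ 0
  x2 <- cbind(sig = c(0, 0.01, 1, 1.01), dead = c(0.5, 0.6, 0.5, 0.6))
  res2 <- anova_contribution(x2, c("a", "a", "b", "b"))
  expect_equal(res2$channel, c("sig", "dead"))
  expect_lt(res2$F[2], 1e-10)
  # zero within-class variance is flagged as infinite
  x3 <- cbind(exact = c(0, 0, 1, 1))
  res3 <- anova_contribution(x3, c("a", "a", "b", "b"))
  expect_true(res3$degenerate)
  expect_equal(res3$F, Inf)
})

test_that("BPR is the dominant channel on the default synthetic array", {
  d <- array_design(seed = 2)
  rmx <- build_response_matrix(generate_plate(d), 4)
  res <- anova_contribution(rmx)
  expect_equal(res$channel[1], "BPR")
})

test_that("LDA recovers the separating direction of two point clouds", {
  # exactly isotropic within-class scatter: the Fisher axis must then be
  # exactly parallel to the class-mean difference (up to sign)
  square <- 0.05 * rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  a <- square
  b <- sweep(square, 2, c(3, 3), "+")
  fit <- lda_fit(rbind(a, b), rep(c("a", "b"), each = 4))
  v <- fit$axes[, 1] / sqrt(sum(fit$axes[, 1]^2))
  d <- c(1, 1) / sqrt(2)                      # class-mean difference direction
  expect_equal(abs(sum(v * d)), 1, tolerance = 1e-8)
  expect_equal(unname(fit$assigned), rep(c("a", "b"), each = 4))
})

test_that("LDA works on noiseless classes where plain lda would be singular", {
  x <- rbind(matrix(c(0, 0), 5, 2, byrow = TRUE),
             matrix(c(1, 2), 5, 2, byrow = TRUE))
  fit <- lda_fit(x, rep(c("a", "b"), each = 5))
  expect_equal(unname(fit$assigned), rep(c("a", "b"), each = 5))
  rate <- jackknife_classification_rate(x, rep(c("a", "b"), each = 5))
  expect_equal(as.numeric(rate), 100)
})

test_that("classes with identical means classify at chance under jackknife", {
  set.seed(9)
  x <- matrix(rnorm(200), 100, 2)
  labs <- rep(c("a", "b"), 50)
  rate <- jackknife_classification_rate(x, labs)
  expect_lt(as.numeric(rate), 70)   # chance is 50 for two balanced classes
})

test_that("jackknife agrees with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  d <- array_design(noise_cv = 0.03, seed = 6)   # noisy enough to misclassify
  rmx <- build_response_matrix(generate_plate(d), 4)
  ours <- jackknife_classification_rate(rmx)
  preds <- vapply(seq_len(nrow(rmx$x)), function(i) {
    fit <- MASS::lda(rmx$x[-i, ], grouping = rmx$labels[-i])
    as.character(stats::predict(fit, rmx$x[i, , drop = FALSE])$class)
  }, character(1))
  mass_rate <- 100 * mean(preds == as.character(rmx$labels))
  # different classification rules (nearest centroid vs Gaussian posterior)
  # on the same discriminant subspace: rates must agree closely
  expect_lt(abs(as.numeric(ours) - mass_rate), 3)
})

test_that("classification rate is invariant to affine feature rescaling", {
  d <- array_design(noise_cv = 0.02, seed = 3)
  rmx <- build_response_matrix(generate_plate(d), 4)
  r1 <- as.numeric(jackknife_classification_rate(rmx$x, rmx$labels))
  x2 <- sweep(sweep(rmx$x, 2, c(10, 0.2, 3, 50), "*"), 2, c(1, -2, 0, 4), "+")
  r2 <- as.numeric(jackknife_classification_rate(x2, rmx$labels))
  expect_equal(r1, r2)
})

test_that("permuted labels classify at chance level", {
  d <- array_design(seed = 10)
  rmx <- build_response_matrix(generate_plate(d), 4)
  set.seed(123)
  rates <- replicate(20, {
    as.numeric(jackknife_classification_rate(rmx$x, sample(rmx$labels)))
  })
  # chance for 8 balanced classes is 12.5%
  expect_lt(mean(rates), 25)
  expect_gt(mean(rates), 4)
})

test_that("the full 8-class synthetic array is perfectly classified", {
  d <- array_design(seed = 17)
  rmx <- build_response_matrix(generate_plate(d), 4)
  rate <- jackknife_classification_rate(rmx)
  expect_equal(as.numeric(rate), 100)
  # Fru sits farthest from control in discriminant space
  fit <- lda_fit(rmx)
  cen <- sweep(fit$centroids, 2, fit$grand_mean) %*% fit$axes
  dist_to_ctrl <- sqrt(rowSums(sweep(cen, 2, cen["control", ])^2))
  expect_equal(names(which.max(dist_to_ctrl)), "Fru")
})

test_that("semi-quantitative series: perfect rate and monotone LD1 trend", {
  d <- concentration_series_design("Fru", c(0, 20, 40, 60, 80, 100) * 1e-3,
                                   seed = 21)
  rmx <- build_response_matrix(generate_plate(d), 4)
  sq <- semiquant_lda(rmx)
  expect_equal(sq$classification_rate, 100)
  expect_equal(abs(sq$trend_spearman), 1)
  # two far-apart levels at low noise are trivially separated
  d2 <- concentration_series_design("Glc", c(0, 100) * 1e-3, seed = 22)
  rmx2 <- build_response_matrix(generate_plate(d2), 4)
  expect_equal(semiquant_lda(rmx2)$classification_rate, 100)
})

test_that("identical concentration levels classify at chance", {
  d <- array_design(analytes = c("lvA", "lvB"),
                    analyte_conc_M = 10e-3,
                    kg = do.call(rbind, lapply(c("lvA", "lvB"), function(l) {
                      k <- kg_table()[kg_table()$analyte == "Fru", ]
                      k$analyte <- l
                      k
                    })),
                    include_control = FALSE, seed = 30)
  rmx <- build_response_matrix(generate_plate(d), 4)
  rate <- jackknife_classification_rate(rmx)
  expect_lt(as.numeric(rate), 75)   # chance is 50
})

test_that("PCA+SVR round-trips a noiseless linear encoding", {
  set.seed(2)
  t1 <- runif(80, 0, 100); t2 <- runif(80, 0, 100)
  x <- cbind(t1 + 0.2 * t2, t2, 0.5 * t1 - t2, t1 + t2)
  m <- fit_mixture_regression(x, cbind(Fru = t1, Glc = t2))
  expect_lt(max(m$training_rmse) / 100, 0.01)
  pred <- predict_mixture(m, x, truth = cbind(t1, t2))
  expect_lt(max(attr(pred, "rmse")) / 100, 0.01)
})

test_that("PCA+SVR recovers mixture concentrations from the forward model", {
  comp <- data.frame(Fru = seq(80, 10, by = -10) * 1e-3,
                     Glc = seq(10, 80, by = 10) * 1e-3)
  train0 <- generate_mixture_responses(comp, n_replicates = 20,
                                       noise_cv = 0, seed = 1)
  m0 <- fit_mixture_regression(train0$x, train0$targets)
  rng <- diff(range(train0$targets))
  expect_lt(max(m0$training_rmse) / rng, 0.01)   # noiseless round trip
  # calibrate on noisy replicates, predict held-out noisy mixtures
  train <- generate_mixture_responses(comp, n_replicates = 20,
                                      noise_cv = 0.01, seed = 2)
  m <- fit_mixture_regression(train$x, train$targets)
  test <- generate_mixture_responses(comp, n_replicates = 5,
                                     noise_cv = 0.01, seed = 99)
  pred <- predict_mixture(m, test$x, truth = test$targets)
  expect_lt(max(attr(pred, "rmse")) / rng, 0.10)
})

test_that("permuted targets give no predictive signal", {
  comp <- data.frame(Fru = seq(80, 10, by = -10) * 1e-3,
                     Glc = seq(10, 80, by = 10) * 1e-3)
  train <- generate_mixture_responses(comp, n_replicates = 10,
                                      noise_cv = 0.01, seed = 4)
  set.seed(5)
  shuffled <- train$targets[sample(nrow(train$targets)), ]
  m <- fit_mixture_regression(train$x, shuffled)
  # RMSE comparable to the spread of the targets themselves
  expect_gt(min(m$training_rmse / apply(shuffled, 2, sd)), 0.5)
})

test_that("mixture prediction validates dimensions and clips at zero", {
  set.seed(6)
  t1 <- runif(40, 0, 10)
  x <- cbind(t1, t1 * 2, t1 + 1, t1 - 0.5)
  m <- fit_mixture_regression(x, cbind(a = t1, b = 10 - t1))
  expect_error(predict_mixture(m, x[, 1:3]), "dimensionality")
  pred <- predict_mixture(m, x)
  expect_true(all(pred >= 0))
  expect_error(fit_mixture_regression(x[1:3, ], cbind(t1[1:3], t1[1:3])),
               "more observations")
})
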