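# Array chemometrics: replicate outlier exclusion, per-channel ANOVA
# contribution, linear discriminant analysis with leave-one-out jackknife
# validation, and PCA + support-vector regression for binary mixtures.

#' Exclude extreme replicates by iterative studentized deviation
#'
#' Implements the fixed-count outlier exclusion of the array protocol:
#' `n_exclude` times, the observation with the largest absolute studentized
#' deviation \eqn{|x_i - \bar x| / s} from the current mean is removed and
#' mean and standard deviation are recomputed. With the protocol defaults
#' (24 replicates, 4 excluded) 20 values remain. Ties are broken in favour
#' of the earliest observation, so the result is deterministic.
#'
#' @param values Numeric replicate values.
#' @param n_exclude How many observations to remove.
#' @return The retained values, in their original order.
#' @export
exclude_outliers <- function(values, n_exclude = 4) {
  if (!is.numeric(values)) stop("exclude_outliers: values must be numeric")
  if (n_exclude < 0) stop("exclude_outliers: n_exclude must be >= 0")
  if (n_exclude >= length(values))
    stop("exclude_outliers: n_exclude must be smaller than the number of values")
  keep <- rep(TRUE, length(values))
  for (k in seq_len(n_exclude)) {
    x <- values[keep]
    s <- stats::sd(x)
    dev <- abs(x - mean(x))
    if (!is.finite(s) || s == 0) {
      drop_rel <- 1L                      # all equal: remove the first
    } else {
      drop_rel <- which.max(dev / s)
    }
    keep[which(keep)[drop_rel]] <- FALSE
  }
  values[keep]
}

# well-level exclusion: per analyte, drop the n_exclude wells with the
# largest max-over-channels studentized deviation (a bad well corrupts all
# channels, so wells are scored jointly to keep the feature rows aligned)
exclude_outlier_wells <- function(mat, n_exclude) {
  keep <- rep(TRUE, nrow(mat))
  for (k in seq_len(n_exclude)) {
    x <- mat[keep, , drop = FALSE]
    mu <- colMeans(x)
    s <- apply(x, 2, stats::sd)
    s[!is.finite(s) | s == 0] <- Inf
    score <- apply(abs(sweep(x, 2, mu)) / rep(s, each = nrow(x)), 1, max)
    score[!is.finite(score)] <- 0
    keep[which(keep)[which.max(score)]] <- FALSE
  }
  which(keep)
}

#' Build the LDA response matrix from a plate table
#'
#' Pivots the long-format plate to one row per retained well with one
#' absorbance feature per dye channel, applying the fixed-count outlier
#' exclusion per analyte condition. Wells are scored by their largest
#' studentized deviation across channels, so the same wells are removed
#' from every channel and the feature rows stay aligned. With the protocol
#' defaults (8 conditions, 24 replicates, 4 excluded) the result has
#' 8 x 20 = 160 rows.
#'
#' @param plate A plate table (long format).
#' @param n_exclude Outlier wells to remove per analyte condition.
#' @return A list of class `response_matrix`: `x` (numeric matrix, one
#'   column per channel), `labels` (factor), `replicate` (original well
#'   indices).
#' @export
build_response_matrix <- function(plate, n_exclude = 4) {
  stopifnot(is.data.frame(plate))
  need <- c("analyte", "channel", "replicate", "absorbance")
  if (!all(need %in% names(plate)))
    stop("build_response_matrix: plate lacks columns ",
         paste(setdiff(need, names(plate)), collapse = ", "))
  channels <- sort(unique(plate$channel))
  analytes <- unique(plate$analyte)
  rows <- list(); labs <- character(0); reps <- integer(0)
  for (a in analytes) {
    sub <- plate[plate$analyte == a, ]
    wide <- stats::reshape(
      sub[, c("replicate", "channel", "absorbance")],
      direction = "wide", idvar = "replicate", timevar = "channel")
    wide <- wide[order(wide$replicate), ]
    mat <- as.matrix(wide[, paste0("absorbance.", channels), drop = FALSE])
    if (anyNA(mat))
      stop("build_response_matrix: incomplete channel data for analyte ", a)
    kept <- if (n_exclude > 0) exclude_outlier_wells(mat, n_exclude)
            else seq_len(nrow(mat))
    rows[[a]] <- mat[kept, , drop = FALSE]
    labs <- c(labs, rep(a, length(kept)))
    reps <- c(reps, wide$replicate[kept])
  }
  x <- do.call(rbind, rows)
  colnames(x) <- channels
  rownames(x) <- NULL
  structure(list(x = x, labels = factor(labs, levels = analytes),
                 replicate = reps),
            class = "response_matrix")
}

#' Per-channel ANOVA contribution to discrimination
#'
#' One-way ANOVA of each channel's absorbance against the class labels;
#' the F statistic (between-class over within-class mean square) ranks how
#' much each dye channel contributes to separating the analytes. A channel
#' with zero within-class variance is reported as infinite F and flagged.
#'
#' @param x Numeric feature matrix (one column per channel) or a
#'   `response_matrix`.
#' @param labels Class labels (ignored when `x` is a `response_matrix`).
#' @return A data.frame sorted by decreasing F: `channel`, `F`, `p_value`,
#'   `rank`, `degenerate`.
#' @export
anova_contribution <- function(x, labels = NULL) {
  if (inherits(x, "response_matrix")) { labels <- x$labels; x <- x$x }
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("anova_contribution: need >= 2 classes")
  if (any(table(labels) < 2)) stop("anova_contribution: need >= 2 observations per class")
  res <- lapply(seq_len(ncol(x)), function(j) {
    fit <- stats::aov(x[, j] ~ labels)
    tab <- summary(fit)[[1]]
    wss <- tab["Residuals", "Sum Sq"]
    scale <- sum(tab[, "Sum Sq"])
    if (wss <= 1e-14 * max(scale, 1e-300)) {
      data.frame(F = Inf, p_value = 0, degenerate = TRUE)
    } else {
      data.frame(F = tab[1, "F value"], p_value = tab[1, "Pr(>F)"],
                 degenerate = FALSE)
    }
  })
  out <- do.call(rbind, res)
  out$channel <- colnames(x)
  out <- out[order(-out$F), c("channel", "F", "p_value", "degenerate")]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# Fisher LDA on raw features: whiten the (ridge-regularised) within-class
# scatter, then eigendecompose the between-class scatter in whitened space.
# Axis signs are fixed so the largest-magnitude loading is positive.
lda_core <- function(x, labels, ridge = 1e-8) {
  x <- as.matrix(x)
  labels <- droplevels(factor(labels))
  k <- nlevels(labels)
  p <- ncol(x)
  if (k < 2) stop("lda_core: need >= 2 classes")
  grand <- colMeans(x)
  Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
  centroids <- matrix(0, k, p, dimnames = list(levels(labels), colnames(x)))
  for (g in levels(labels)) {
    xi <- x[labels == g, , drop = FALSE]
    mg <- colMeans(xi)
    centroids[g, ] <- mg
    cen <- sweep(xi, 2, mg)
    Sw <- Sw + crossprod(cen)
    Sb <- Sb + nrow(xi) * tcrossprod(mg - grand)
  }
  lam <- ridge * sum(diag(Sw)) / p
  if (lam <= 0) lam <- ridge * sum(diag(Sb)) / p
  if (lam <= 0)
    stop("lda_core: degenerate scatter (all observations identical); ",
         "increase the ridge or check the data")
  Swr <- Sw + diag(lam, p)
  ew <- eigen(Swr, symmetric = TRUE)
  Wi <- ew$vectors %*% diag(1 / sqrt(pmax(ew$values, lam * 1e-12)), p) %*%
    t(ew$vectors)
  eb <- eigen(Wi %*% Sb %*% Wi, symmetric = TRUE)
  r <- min(p, k - 1)
  axes <- Wi %*% eb$vectors[, seq_len(r), drop = FALSE]
  for (j in seq_len(r)) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  rownames(axes) <- colnames(x)
  colnames(axes) <- paste0("LD", seq_len(r))
  list(axes = axes, eigenvalues = eb$values[seq_len(r)], grand_mean = grand,
       centroids = centroids, labels_levels = levels(labels))
}

lda_scores <- function(core, x) {
  sweep(as.matrix(x), 2, core$grand_mean) %*% core$axes
}

lda_classify <- function(core, x) {
  sc <- lda_scores(core, x)
  cen <- lda_scores(core, core$centroids)
  d2 <- outer(rowSums(sc^2), rowSums(cen^2), "+") - 2 * sc %*% t(cen)
  core$labels_levels[max.col(-d2, ties.method = "first")]
}

#' Linear discriminant analysis of an array response matrix
#'
#' Fisher LDA: discriminant axes maximising between-class over within-class
#' scatter, computed by whitening the (lightly ridge-regularised)
#' within-class scatter and eigendecomposing the between-class scatter.
#' Observations are classified by the nearest class centroid in
#' discriminant space — Euclidean distance there is Mahalanobis distance in
#' feature space, since the space is whitened within-class. Results are
#' deterministic; axis signs are fixed by convention.
#'
#' @param x Feature matrix or `response_matrix`.
#' @param labels Class labels (ignored for a `response_matrix`).
#' @param ridge Within-class scatter ridge, as a fraction of its mean
#'   diagonal.
#' @return An object of class `discriminant_result`: `axes` (loadings),
#'   `scores`, `eigenvalues`, `centroids`, `assigned` (resubstitution
#'   labels), `labels`.
#' @export
lda_fit <- function(x, labels = NULL, ridge = 1e-8) {
  if (inherits(x, "response_matrix")) { labels <- x$labels; x <- x$x }
  labels <- droplevels(factor(labels))
  core <- lda_core(x, labels, ridge)
  structure(list(axes = core$axes,
                 scores = lda_scores(core, x),
                 eigenvalues = core$eigenvalues,
                 centroids = core$centroids,
                 grand_mean = core$grand_mean,
                 assigned = lda_classify(core, x),
                 labels = labels,
                 ridge = ridge),
            class = "discriminant_result")
}

#' Leave-one-out (jackknife) classification rate of LDA
#'
#' For every observation, LDA is refit on the remaining observations and
#' the held-out observation is classified by the nearest class centroid in
#' the refitted discriminant space. The rate is the percentage classified
#' correctly. Folds whose class would be left with fewer than one training
#' observation are flagged and excluded with a warning.
#'
#' @inheritParams lda_fit
#' @return Classification success rate in percent; attributes `predicted`
#'   and `confusion` carry the per-observation detail.
#' @export
jackknife_classification_rate <- function(x, labels = NULL, ridge = 1e-8) {
  if (inherits(x, "response_matrix")) { labels <- x$labels; x <- x$x }
  labels <- droplevels(factor(labels))
  n <- nrow(x)
  singletons <- names(which(table(labels) < 2))
  usable <- !(labels %in% singletons)
  if (length(singletons) > 0)
    warning("jackknife: classes with a single member excluded from the rate: ",
            paste(singletons, collapse = ", "))
  pred <- rep(NA_character_, n)
  for (i in which(usable)) {
    core <- lda_core(x[-i, , drop = FALSE], labels[-i], ridge)
    pred[i] <- lda_classify(core, x[i, , drop = FALSE])
  }
  ok <- usable & !is.na(pred)
  rate <- 100 * mean(pred[ok] == as.character(labels)[ok])
  attr(rate, "predicted") <- pred
  attr(rate, "confusion") <- table(truth = labels[ok],
                                   predicted = factor(pred[ok],
                                                      levels = levels(labels)))
  rate
}

#' Semi-quantitative LDA over a concentration series
#'
#' Runs LDA and the jackknife with ordered concentration levels of one
#' analyte as the classes, and additionally reports the Spearman rank
#' correlation between the level order and the per-level mean first
#' discriminant score — a monotone trend of the clusters along LD1 is what
#' makes the score plot readable as a semi-quantitative scale.
#'
#' @param x Feature matrix or `response_matrix` whose labels are
#'   concentration levels.
#' @param levels_conc Numeric concentration of each observation's level
#'   (ignored for a `response_matrix` with numeric-convertible labels).
#' @param ridge As in [lda_fit()].
#' @return A `discriminant_result` with extra fields
#'   `classification_rate` (percent, jackknifed) and `trend_spearman`.
#' @export
semiquant_lda <- function(x, levels_conc = NULL, ridge = 1e-8) {
  if (inherits(x, "response_matrix")) {
    if (is.null(levels_conc))
      levels_conc <- suppressWarnings(as.numeric(as.character(x$labels)))
    labels <- x$labels; x <- x$x
  } else {
    if (is.null(levels_conc))
      stop("semiquant_lda: levels_conc required")
    labels <- factor(levels_conc, levels = sort(unique(levels_conc)))
  }
  if (anyNA(levels_conc))
    stop("semiquant_lda: labels must be numeric concentration levels")
  fit <- lda_fit(x, labels, ridge)
  rate <- jackknife_classification_rate(x, labels, ridge)
  lev <- sort(unique(levels_conc))
  mean_ld1 <- vapply(lev, function(l) mean(fit$scores[levels_conc == l, 1]),
                     numeric(1))
  fit$classification_rate <- as.numeric(rate)
  fit$confusion <- attr(rate, "confusion")
  fit$trend_spearman <- stats::cor(lev, mean_ld1, method = "spearman")
  fit$level_means_LD1 <- stats::setNames(mean_ld1, lev)
  fit
}

#' Fit a PCA + support-vector regression model for binary mixtures
#'
#' Standardises the channel features, projects them on the leading
#' principal components (default 3), and trains one epsilon-SVR (radial
#' basis kernel) per target analyte on the component scores. Hyperparameters
#' are fixed: cost 10, gamma 1/(number of components), and an epsilon tube
#' of 0.2% of each target's range — narrow enough that a noiseless
#' calibration is recovered to well under 1% of the range (the tube acts
#' as an error floor: residuals inside it are not penalised).
#'
#' @param x Feature matrix (observations x channels).
#' @param targets Matrix or data.frame of known concentrations, one column
#'   per analyte (e.g. Fru and Glc).
#' @param n_components Number of principal components retained.
#' @param epsilon_frac Half-width of the SVR insensitivity tube as a
#'   fraction of each target's range.
#' @return An object of class `mixture_regression_model` with the scaling,
#'   rotation, per-target SVR models, and training RMSE per analyte.
#' @export
fit_mixture_regression <- function(x, targets, n_components = 3,
                                   epsilon_frac = 0.002) {
  x <- as.matrix(x)
  targets <- as.matrix(targets)
  if (nrow(targets) != nrow(x))
    stop("fit_mixture_regression: x and targets must have matching rows")
  if (nrow(x) <= n_components)
    stop("fit_mixture_regression: need more observations than components")
  if (length(unique(asplit(targets, 1))) < 8)
    warning("fit_mixture_regression: fewer than 8 distinct mixture compositions")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  n_components <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  scores <- xs %*% rot
  models <- list(); rmse <- numeric(0)
  for (j in seq_len(ncol(targets))) {
    y <- targets[, j]
    rng <- diff(range(y))
    ysd <- stats::sd(y)
    # epsilon_frac of the target range, expressed on the internally
    # standardised target scale the SVR actually fits
    eps <- if (rng > 0 && ysd > 0) epsilon_frac * rng / ysd else 0.01
    m <- e1071::svm(x = scores, y = y, type = "eps-regression",
                    kernel = "radial", cost = 10, epsilon = eps,
                    gamma = 1 / n_components, scale = TRUE)
    pr <- stats::predict(m, scores)
    models[[j]] <- m
    rmse[j] <- sqrt(mean((pr - targets[, j])^2))
  }
  nm <- colnames(targets)
  if (is.null(nm)) nm <- paste0("target", seq_len(ncol(targets)))
  names(models) <- nm; names(rmse) <- nm
  ev <- pc$sdev^2
  structure(list(center = ctr, scale = scl, rotation = rot,
                 n_components = n_components, models = models,
                 training_rmse = rmse,
                 explained_variance = sum(ev[seq_len(n_components)]) / sum(ev)),
            class = "mixture_regression_model")
}

#' Predict mixture concentrations from array responses
#'
#' Applies the stored standardisation and PCA projection, evaluates each
#' analyte's SVR, and clips negative concentration predictions at zero
#' (flagged via the `clipped` attribute). When the true concentrations are
#' supplied, the per-analyte RMSE of the predictions is attached.
#'
#' @param model A [fit_mixture_regression()] model.
#' @param x Feature matrix with the training dimensionality.
#' @param truth Optional matrix of known concentrations for RMSE.
#' @return Matrix of predicted concentrations (>= 0), with attributes
#'   `clipped` and, when `truth` is given, `rmse`.
#' @export
predict_mixture <- function(model, x, truth = NULL) {
  stopifnot(inherits(model, "mixture_regression_model"))
  x <- as.matrix(x)
  if (ncol(x) != length(model$center))
    stop("predict_mixture: feature dimensionality does not match training")
  xs <- scale(x, center = model$center, scale = model$scale)
  scores <- xs %*% model$rotation
  pred <- vapply(model$models, function(m) as.numeric(stats::predict(m, scores)),
                 numeric(nrow(x)))
  pred <- matrix(pred, nrow = nrow(x),
                 dimnames = list(NULL, names(model$models)))
  clipped <- pred < 0
  pred[clipped] <- 0
  attr(pred, "clipped") <- clipped
  if (!is.null(truth)) {
    truth <- as.matrix(truth)
    attr(pred, "rmse") <- sqrt(colMeans((pred - truth)^2))
  }
  pred
}
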