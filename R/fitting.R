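# Binding-constant estimation from UV-vis titration isotherms by nonlinear
# least squares against the IDA forward model. The two unknowns of an
# indicator titration (K_I, eps_HI) and the single unknown of a guest
# titration (K_G) are estimated by profiling: for any trial K the model is
# linear in the absorptivities, so the inner problem is solved exactly and
# the outer 1-D search over log10(K) is a deterministic multi-start grid
# followed by golden-section refinement.

#' Construct a titration curve
#'
#' An ordered series of (total titrant concentration, absorbance) points at
#' one observation wavelength. In an `indicator-titration` the host is
#' titrated into dye (the titrant totals are host totals, guest absent); in
#' a `guest-titration` the saccharide is titrated into the preformed
#' dye-host ensemble (the titrant totals are guest totals).
#'
#' @param titrant_totals Strictly increasing titrant totals (M); the first
#'   point may be 0.
#' @param absorbances Absorbance at each point (same length).
#' @param mode `"indicator-titration"` or `"guest-titration"`.
#' @param fixed_conditions An [assay_conditions()] template holding the
#'   non-varied totals and the path length.
#' @param observation_wavelength Observation wavelength in nm (metadata).
#'
#' @return An object of class `titration_curve`.
#' @export
titration_curve <- function(titrant_totals, absorbances,
                            mode = c("indicator-titration", "guest-titration"),
                            fixed_conditions,
                            observation_wavelength = NA_real_) {
  mode <- match.arg(mode)
  if (length(titrant_totals) != length(absorbances))
    stop("titration_curve: totals and absorbances must have equal length")
  if (any(!is.finite(titrant_totals)) || any(!is.finite(absorbances)))
    stop("titration_curve: non-finite values")
  if (any(diff(titrant_totals) <= 0))
    stop("titration_curve: titrant_totals must be strictly increasing")
  if (any(titrant_totals < 0))
    stop("titration_curve: titrant_totals must be >= 0")
  stopifnot(inherits(fixed_conditions, "assay_conditions"))
  structure(list(titrant_totals = as.numeric(titrant_totals),
                 absorbances = as.numeric(absorbances),
                 mode = mode,
                 fixed_conditions = fixed_conditions,
                 observation_wavelength = observation_wavelength),
            class = "titration_curve")
}

# forward model absorbances along a titration schedule
forward_curve <- function(totals, mode, fixed, params) {
  vapply(totals, function(tt) {
    cond <- if (mode == "indicator-titration") {
      assay_conditions(host_total = tt,
                       indicator_total = fixed$indicator_total,
                       guest_total = 0,
                       path_length = fixed$path_length)
    } else {
      assay_conditions(host_total = fixed$host_total,
                       indicator_total = fixed$indicator_total,
                       guest_total = tt,
                       path_length = fixed$path_length)
    }
    ida_absorbance(cond, params)
  }, numeric(1))
}

# golden-section minimisation of fn over [lo, hi] (log10 K axis)
golden_min <- function(fn, lo, hi, tol = 1e-10) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- fn(c1); f2 <- fn(c2)
  while (b - a > tol) {
    if (f1 < f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- fn(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- fn(c2)
    }
  }
  (a + b) / 2
}

# numeric central-difference Jacobian of model(theta) -> vector
num_jacobian <- function(model, theta, rel_h = 1e-6) {
  y0 <- model(theta)
  J <- matrix(0, length(y0), length(theta))
  for (j in seq_along(theta)) {
    h <- rel_h * max(abs(theta[j]), 1e-12)
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    J[, j] <- (model(tp) - model(tm)) / (2 * h)
  }
  J
}

se_from_jacobian <- function(J, rss, n) {
  p <- ncol(J)
  if (n <= p) return(rep(NA_real_, p))
  sigma2 <- rss / (n - p)
  JtJ <- crossprod(J)
  cv <- tryCatch(solve(JtJ), error = function(e) NULL)
  if (is.null(cv)) return(rep(NA_real_, p))
  sqrt(pmax(diag(cv) * sigma2, 0))
}

#' Fit the indicator binding constant from a dye-host titration
#'
#' Estimates \eqn{K_I} and \eqn{\epsilon_{HI}} from a titration of the dye
#' with host, by least squares against the 1:1 binding model (the IDA
#' forward model with no guest). \eqn{\epsilon_I} is anchored from the
#' zero-host point (\eqn{A_0 = \epsilon_I b [I]_t}) unless supplied; for a
#' trial \eqn{K_I} the remaining absorptivity enters linearly, so it is
#' profiled out exactly and only \eqn{\log_{10} K_I} is searched, from a
#' fixed multi-start grid (deterministic).
#'
#' @param curve A [titration_curve()] with `mode = "indicator-titration"`.
#' @param eps_I_fixed Molar absorptivity of the free dye; `NULL` anchors it
#'   from the first (zero-host) point.
#' @param K_grid Multi-start values of \eqn{K_I} (1/M).
#'
#' @return An object of class `fit_result`: list with `estimates`
#'   ([binding_parameters()]), `standard_errors`, `residual_sum_of_squares`,
#'   `converged`, `n_points`, `fitted`.
#' @export
fit_indicator_binding <- function(curve, eps_I_fixed = NULL,
                                  K_grid = 10^(1:5)) {
  stopifnot(inherits(curve, "titration_curve"))
  if (curve$mode != "indicator-titration")
    stop("fit_indicator_binding expects an indicator-titration curve")
  tt <- curve$titrant_totals
  A <- curve$absorbances
  n <- length(A)
  if (n < 5) stop("fit_indicator_binding: at least 5 points required")
  fixed <- curve$fixed_conditions
  It <- fixed$indicator_total
  b <- fixed$path_length
  if (It <= 0) stop("fit_indicator_binding: indicator_total must be > 0")

  if (diff(range(A)) <= 1e-12 * max(abs(A), 1))
    stop("fit_indicator_binding: flat curve, no binding signal to fit")

  if (is.null(eps_I_fixed)) {
    if (tt[1] != 0)
      stop("fit_indicator_binding: need a zero-host point to anchor eps_I, ",
           "or supply eps_I_fixed")
    eps_I <- A[1] / (b * It)
  } else {
    eps_I <- eps_I_fixed
  }

  # free host and bound-dye fraction along the schedule for a trial K_I
  spec_frac <- function(K) {
    vapply(tt, function(Ht) {
      sp <- solve_free_host(assay_conditions(Ht, It, 0, b),
                            binding_parameters(K_I = K))
      K * sp$free_host / (1 + K * sp$free_host)
    }, numeric(1))
  }
  # profile: with eps_I fixed, A = It*b*(eps_I*(1-fb) + eps_HI*fb)
  profile_rss <- function(log10K) {
    fb <- spec_frac(10^log10K)
    y <- A - It * b * eps_I * (1 - fb)
    x <- It * b * fb
    sxx <- sum(x * x)
    eps_HI <- if (sxx > 0) max(sum(x * y) / sxx, 0) else 0
    sum((y - eps_HI * x)^2)
  }

  grid <- log10(K_grid)
  rss_grid <- vapply(grid, profile_rss, numeric(1))
  i <- which.min(rss_grid)
  lo <- if (i == 1) grid[1] - 1 else grid[i - 1]
  hi <- if (i == length(grid)) grid[length(grid)] + 1 else grid[i + 1]
  log10K <- golden_min(profile_rss, lo, hi)
  K_I <- 10^log10K

  fb <- spec_frac(K_I)
  y <- A - It * b * eps_I * (1 - fb)
  x <- It * b * fb
  eps_HI <- if (sum(x * x) > 0) max(sum(x * y) / sum(x * x), 0) else 0
  fitted <- It * b * (eps_I * (1 - fb) + eps_HI * fb)
  rss <- sum((A - fitted)^2)

  at_bound <- log10K <= grid[1] - 1 + 1e-6 || log10K >= grid[length(grid)] + 1 - 1e-6
  model <- function(theta) {
    fbt <- spec_frac(theta[1])
    It * b * (eps_I * (1 - fbt) + theta[2] * fbt)
  }
  J <- num_jacobian(model, c(K_I, eps_HI))
  se <- se_from_jacobian(J, rss, n)

  structure(list(
    estimates = binding_parameters(K_I = K_I, K_G = 0,
                                   eps_I = eps_I, eps_HI = eps_HI),
    fitted_parameters = c("K_I", "eps_HI"),
    standard_errors = c(K_I = se[1], eps_HI = se[2]),
    residual_sum_of_squares = rss,
    converged = !at_bound,
    at_bound = at_bound,
    below_floor = FALSE,
    n_points = n,
    fitted = fitted
  ), class = "fit_result")
}

#' Fit the guest binding constant from an IDA displacement titration
#'
#' Estimates \eqn{K_G} from a titration of the preformed dye-host ensemble
#' with guest, by least squares against the full IDA forward model
#' (speciation solver + absorbance model) with \eqn{K_I} and the
#' absorptivities held fixed at the values obtained from the indicator
#' titration. The search is a deterministic multi-start over
#' \eqn{\log_{10} K_G} with golden-section refinement. Estimates below
#' `floor` (default 10 1/M) are reported as a below-floor bound — at such
#' small constants the guest barely perturbs the speciation and the value
#' is not identifiable, matching the "< 10" reporting convention.
#'
#' @param curve A [titration_curve()] with `mode = "guest-titration"`.
#' @param K_I_known Indicator binding constant (1/M), from
#'   [fit_indicator_binding()].
#' @param eps_I,eps_HI Fixed molar absorptivities.
#' @param floor Reporting floor for \eqn{K_G} (1/M).
#' @param K_grid Multi-start values of \eqn{K_G} (1/M).
#'
#' @return A `fit_result`; `below_floor = TRUE` flags bound-only estimates.
#' @export
fit_guest_binding <- function(curve, K_I_known, eps_I, eps_HI,
                              floor = 10, K_grid = 10^(1:5)) {
  stopifnot(inherits(curve, "titration_curve"))
  if (curve$mode != "guest-titration")
    stop("fit_guest_binding expects a guest-titration curve")
  tt <- curve$titrant_totals
  A <- curve$absorbances
  n <- length(A)
  if (n < 5) stop("fit_guest_binding: at least 5 points required")
  fixed <- curve$fixed_conditions
  if (fixed$indicator_total <= 0 || fixed$host_total <= 0)
    stop("fit_guest_binding: host_total and indicator_total must be > 0")

  rss_of <- function(log10K) {
    p <- binding_parameters(K_I = K_I_known, K_G = 10^log10K,
                            eps_I = eps_I, eps_HI = eps_HI)
    sum((A - forward_curve(tt, "guest-titration", fixed, p))^2)
  }

  grid <- log10(c(1, K_grid))
  rss_grid <- vapply(grid, rss_of, numeric(1))
  i <- which.min(rss_grid)
  lo <- if (i == 1) grid[1] - 2 else grid[i - 1]
  hi <- if (i == length(grid)) grid[length(grid)] + 1 else grid[i + 1]
  log10K <- golden_min(rss_of, lo, hi)
  K_G <- 10^log10K

  params <- binding_parameters(K_I = K_I_known, K_G = K_G,
                               eps_I = eps_I, eps_HI = eps_HI)
  fitted <- forward_curve(tt, "guest-titration", fixed, params)
  rss <- sum((A - fitted)^2)

  # identifiability: compare against the no-binding model
  rss0 <- sum((A - forward_curve(
    tt, "guest-titration", fixed,
    binding_parameters(K_I = K_I_known, K_G = 0,
                       eps_I = eps_I, eps_HI = eps_HI)))^2)
  signal_span <- diff(range(A))
  no_signal <- (rss0 - rss) <= 1e-10 * max(rss0, signal_span^2, 1e-30)
  below_floor <- K_G < floor || no_signal

  model <- function(theta) {
    forward_curve(tt, "guest-titration", fixed,
                  binding_parameters(K_I = K_I_known, K_G = theta[1],
                                     eps_I = eps_I, eps_HI = eps_HI))
  }
  se <- if (below_floor) NA_real_ else se_from_jacobian(
    num_jacobian(model, K_G), rss, n)

  structure(list(
    estimates = params,
    fitted_parameters = "K_G",
    standard_errors = c(K_G = se[1]),
    residual_sum_of_squares = rss,
    converged = !below_floor,
    at_bound = FALSE,
    below_floor = below_floor,
    floor = floor,
    n_points = n,
    fitted = fitted
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  est <- x$estimates
  cat("IDA fit (", paste(x$fitted_parameters, collapse = ", "), ")\n", sep = "")
  if (isTRUE(x$below_floor)) {
    cat(sprintf("  K_G below reporting floor: < %g 1/M\n", x$floor))
  } else {
    for (p in x$fitted_parameters)
      cat(sprintf("  %s = %.4g (se %.3g)\n", p, est[[p]],
                  unname(x$standard_errors[p])))
  }
  cat(sprintf("  RSS = %.3g over %d points; converged: %s\n",
              x$residual_sum_of_squares, x$n_points, x$converged))
  invisible(x)
}

#' Replicate-to-replicate relative error of a fitted constant
#'
#' The spread of a binding constant across repeated fits of independently
#' measured titrations, reported as a percent coefficient of variation:
#' \eqn{100 \cdot \mathrm{sd} / \mathrm{mean}} over the converged fits.
#'
#' @param fits A list of `fit_result` objects for the same system.
#' @param parameter Which fitted parameter to summarise.
#' @return Relative error in percent.
#' @export
replicate_error <- function(fits, parameter = "K_G") {
  ok <- vapply(fits, function(f) inherits(f, "fit_result") && isTRUE(f$converged),
               logical(1))
  if (sum(ok) < 2)
    stop("replicate_error: need at least 2 converged fits")
  est <- vapply(fits[ok], function(f) f$estimates[[parameter]], numeric(1))
  100 * stats::sd(est) / mean(est)
}
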