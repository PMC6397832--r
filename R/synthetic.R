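# Synthetic-data generator for the four-dye colorimetric array: titration
# curves from the IDA forward model, Gaussian-band dye spectra, and full
# 384-well plate tables with replicate noise and injected outliers.

# multiplicative noise, Normal on the relative scale, truncated at -0.5
# so absorbances stay positive
mult_noise <- function(n, cv) {
  if (cv == 0) return(rep(0, n))
  pmax(stats::rnorm(n, 0, cv), -0.5)
}

#' Generate a synthetic titration curve
#'
#' Evaluates the IDA forward model along a titrant schedule and applies
#' multiplicative measurement noise: \eqn{A_i (1 + \delta_i)} with
#' \eqn{\delta_i \sim N(0, \mathrm{cv})} truncated at \eqn{-0.5}. With
#' `noise_cv = 0` the curve is exactly the forward model.
#'
#' @param params [binding_parameters()] generating the curve.
#' @param schedule Increasing titrant totals (M).
#' @param conditions [assay_conditions()] template for the non-varied totals.
#' @param mode `"indicator-titration"` (schedule = host totals) or
#'   `"guest-titration"` (schedule = guest totals).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed; the same seed reproduces the curve exactly.
#' @param observation_wavelength Metadata, nm.
#'
#' @return A [titration_curve()].
#' @export
generate_titration <- function(params, schedule, conditions,
                               mode = c("guest-titration", "indicator-titration"),
                               noise_cv = 0, seed = NULL,
                               observation_wavelength = NA_real_) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "binding_parameters"),
            inherits(conditions, "assay_conditions"))
  if (length(schedule) == 0 || any(diff(schedule) <= 0) || any(schedule < 0))
    stop("generate_titration: schedule must be non-empty and strictly increasing")
  if (noise_cv < 0) stop("generate_titration: noise_cv must be >= 0")
  A <- forward_curve(schedule, mode, conditions, params)
  if (noise_cv > 0) {
    if (!is.null(seed)) set.seed(seed)
    A <- A * (1 + mult_noise(length(A), noise_cv))
  }
  titration_curve(schedule, A, mode = mode, fixed_conditions = conditions,
                  observation_wavelength = observation_wavelength)
}

#' Gaussian band model for dye spectra
#'
#' Describes the free dye and the host-bound dye as single Gaussian
#' absorption bands (centre, width, peak molar absorptivity). The default
#' is the ARS-like geometry: binding to the boronic acid blue-shifts the
#' apparent maximum by 46 nm.
#'
#' @param free_center,bound_center Band centres (nm).
#' @param free_width,bound_width Gaussian standard deviations (nm).
#' @param free_peak,bound_peak Peak molar absorptivities (1/M/cm).
#' @return An object of class `spectral_band_model`.
#' @export
spectral_band_model <- function(free_center = 501, bound_center = 455,
                                free_width = 55, bound_width = 55,
                                free_peak = 2.4e4, bound_peak = 2.0e4) {
  if (free_width <= 0 || bound_width <= 0)
    stop("spectral_band_model: widths must be > 0")
  if (free_center < 350 || free_center > 800 ||
      bound_center < 350 || bound_center > 800)
    stop("spectral_band_model: band centres must lie in 350-800 nm")
  structure(list(free_center = free_center, bound_center = bound_center,
                 free_width = free_width, bound_width = bound_width,
                 free_peak = free_peak, bound_peak = bound_peak),
            class = "spectral_band_model")
}

#' Synthesise a UV-vis spectrum from a speciation state
#'
#' Superimposes the Gaussian bands of the free and host-bound dye, weighted
#' by their concentrations (Beer-Lambert, path length `b`). Only the dye
#' species absorb; host and host-guest complex are transparent in the
#' visible range modelled here.
#'
#' @param speciation A `speciation` object from [solve_free_host()].
#' @param bands A [spectral_band_model()].
#' @param wavelengths Wavelength grid (nm).
#' @param path_length Path length (cm).
#' @return Numeric vector of absorbances on the grid.
#' @export
generate_spectrum <- function(speciation, bands, wavelengths, path_length = 1) {
  stopifnot(inherits(speciation, "speciation"),
            inherits(bands, "spectral_band_model"))
  if (length(wavelengths) == 0)
    stop("generate_spectrum: empty wavelength grid")
  gauss <- function(center, width, peak)
    peak * exp(-0.5 * ((wavelengths - center) / width)^2)
  path_length * (
    speciation$free_indicator * gauss(bands$free_center, bands$free_width,
                                      bands$free_peak) +
    speciation$host_indicator * gauss(bands$bound_center, bands$bound_width,
                                      bands$bound_peak))
}

#' Design of a synthetic 384-well array experiment
#'
#' Captures the array protocol: four dye channels read at their observation
#' wavelengths, an analyte panel (water control + seven saccharides), 24
#' replicate wells per (analyte, channel), 90 uL of dye/host ensemble plus
#' 10 uL of analyte stock per well, multiplicative replicate noise, and a
#' fixed number of gross outlier wells per analyte condition.
#'
#' `analyte_mode` sets how `analyte_conc_M` is interpreted: `"final"` as the
#' in-well concentration after dispensing (the concentration the figure
#' captions quote), `"stock"` as the dispensed stock, diluted by the
#' analyte volume fraction. The dye/host ensemble is always diluted by its
#' own volume fraction (0.9 with the default 90+10 uL).
#'
#' @param analytes Analyte labels; must be present in `kg` (plus "control").
#' @param analyte_conc_M Analyte concentration (M), one value or one per
#'   analyte; controls receive 0.
#' @param analyte_mode `"final"` or `"stock"` (see above).
#' @param channels Dye channel table, as [dye_channels()].
#' @param kg Host-guest constant table, as [kg_table()].
#' @param n_replicates Replicate wells per condition.
#' @param noise_cv Replicate coefficient of variation. The default 0.01 is
#'   the typical well-to-well reproducibility of a dispenser-filled
#'   microplate read in absorbance; the protocol-level quality ceiling for
#'   such arrays (6 percent) is a worst-case bound, and the methods
#'   vignette shows the discrimination margin as a function of this value.
#' @param n_outliers Outlier wells injected per analyte condition.
#' @param outlier_scale Range of the outlier shift in units of `noise_cv`.
#' @param dye_stock_M,host_stock_M Ensemble stock concentrations (M).
#' @param ensemble_volume_uL,analyte_volume_uL Dispensed volumes.
#' @param path_length Optical path (cm) of a filled well.
#' @param include_control Add the guest-free "control" condition.
#' @param seed Integer seed.
#' @return An object of class `array_design`.
#' @export
array_design <- function(analytes = c("Fru", "Gal", "Glc", "Xyl", "Man",
                                      "NAcGlc", "Rha"),
                         analyte_conc_M = 100e-3,
                         analyte_mode = c("final", "stock"),
                         channels = dye_channels(),
                         kg = kg_table(),
                         n_replicates = 24,
                         noise_cv = 0.01,
                         n_outliers = 4,
                         outlier_scale = c(5, 10),
                         dye_stock_M = assay_defaults()$dye_stock_M,
                         host_stock_M = assay_defaults()$host_stock_M,
                         ensemble_volume_uL = 90,
                         analyte_volume_uL = 10,
                         path_length = assay_defaults()$plate_path_cm,
                         include_control = TRUE,
                         seed = 1L) {
  analyte_mode <- match.arg(analyte_mode)
  if (noise_cv < 0) stop("array_design: noise_cv must be >= 0")
  if (n_outliers >= n_replicates)
    stop("array_design: n_outliers must be < n_replicates")
  analytes <- setdiff(analytes, "control")
  conc <- rep_len(analyte_conc_M, length(analytes))
  names(conc) <- analytes
  missing <- setdiff(
    paste(rep(channels$channel, each = length(analytes)), analytes),
    paste(kg$channel, kg$analyte))
  if (length(missing) > 0)
    stop("array_design: K_G table is missing pairs: ",
         paste(missing, collapse = ", "))
  structure(list(analytes = analytes, analyte_conc_M = conc,
                 analyte_mode = analyte_mode, channels = channels, kg = kg,
                 n_replicates = n_replicates, noise_cv = noise_cv,
                 n_outliers = n_outliers, outlier_scale = outlier_scale,
                 dye_stock_M = dye_stock_M, host_stock_M = host_stock_M,
                 ensemble_volume_uL = ensemble_volume_uL,
                 analyte_volume_uL = analyte_volume_uL,
                 path_length = path_length,
                 include_control = include_control, seed = as.integer(seed)),
            class = "array_design")
}

#' Design a concentration-series (semi-quantitative) array experiment
#'
#' Builds an [array_design()] whose conditions are increasing
#' concentration levels of a single analyte rather than different
#' analytes: every level shares the analyte's per-channel binding
#' constants, the zero level binds nothing, and level labels are the
#' concentrations in mM. Used for the semi-quantitative assay in which
#' LDA classifies concentration levels.
#'
#' @param analyte Analyte whose binding constants are used (must be in
#'   `kg`).
#' @param levels_M Increasing concentration levels (M); may start at 0.
#' @param kg Host-guest constant table, as [kg_table()].
#' @param analyte_mode Concentration convention for the levels; the series
#'   default is `"stock"` (levels are dispensed stocks, diluted 10x in the
#'   well), which keeps the whole grid on the rising part of the binding
#'   isotherm so consecutive levels stay resolvable — at in-well
#'   concentrations far above the host total the response saturates and
#'   the top levels collapse together.
#' @param ... Further arguments passed to [array_design()].
#' @return An `array_design` with one condition per level and no separate
#'   control condition (a zero level plays that role).
#' @export
concentration_series_design <- function(analyte = "Fru",
                                        levels_M = c(0, 20, 40, 60, 80, 100) * 1e-3,
                                        kg = kg_table(),
                                        analyte_mode = "stock", ...) {
  if (any(diff(levels_M) <= 0) || any(levels_M < 0))
    stop("concentration_series_design: levels_M must be increasing and >= 0")
  base <- kg[kg$analyte == analyte, ]
  if (nrow(base) == 0)
    stop("concentration_series_design: analyte '", analyte, "' not in kg table")
  labs <- format(levels_M * 1e3, trim = TRUE, drop0trailing = TRUE)
  kg2 <- do.call(rbind, lapply(seq_along(labs), function(i) {
    k <- base
    k$analyte <- labs[i]
    if (levels_M[i] == 0) { k$K_G <- 0; k$below_floor <- FALSE }
    k
  }))
  design <- array_design(analytes = labs, analyte_conc_M = levels_M,
                         kg = kg2, analyte_mode = analyte_mode,
                         include_control = FALSE, ...)
  design$series_analyte <- analyte
  design$levels_M <- stats::setNames(levels_M, labs)
  design
}

#' Simulate a full plate of array measurements
#'
#' For every (analyte, channel) condition the noise-free absorbance is the
#' IDA forward model at the post-dispense concentrations; each of the
#' `n_replicates` wells then receives independent multiplicative noise, and
#' `n_outliers` randomly chosen wells per analyte are additionally shifted
#' by a factor of \eqn{\pm U(5,10) \times} `noise_cv` across all four
#' channels (a gross dispensing error affects the whole well). The result
#' is reproducible bit-for-bit for a fixed design and seed.
#'
#' @param design An [array_design()].
#' @return A long-format data.frame (`plate_table`): columns `analyte`,
#'   `analyte_total_M`, `channel`, `replicate`, `absorbance`, plus a
#'   logical `outlier` marking injected outlier wells (ground truth the
#'   analysis does not use).
#' @export
generate_plate <- function(design) {
  stopifnot(inherits(design, "array_design"))
  set.seed(design$seed)
  vol_frac_ens <- design$ensemble_volume_uL /
    (design$ensemble_volume_uL + design$analyte_volume_uL)
  vol_frac_ana <- 1 - vol_frac_ens
  dye_well <- design$dye_stock_M * vol_frac_ens
  host_well <- design$host_stock_M * vol_frac_ens

  all_analytes <- if (isTRUE(design$include_control))
    c("control", design$analytes) else design$analytes
  ch <- design$channels
  kg <- design$kg
  n <- design$n_replicates
  rows <- vector("list", length(all_analytes))

  for (ai in seq_along(all_analytes)) {
    a <- all_analytes[ai]
    g_well <- if (a == "control") 0 else {
      if (design$analyte_mode == "final") design$analyte_conc_M[[a]]
      else design$analyte_conc_M[[a]] * vol_frac_ana
    }
    # well-level outliers: same wells across all channels
    out_idx <- if (design$n_outliers > 0)
      sample.int(n, design$n_outliers) else integer(0)
    shift <- rep(0, n)
    if (length(out_idx) > 0) {
      mag <- stats::runif(length(out_idx), design$outlier_scale[1],
                          design$outlier_scale[2])
      sgn <- sample(c(-1, 1), length(out_idx), replace = TRUE)
      shift[out_idx] <- sgn * mag * design$noise_cv
    }
    per_channel <- vector("list", nrow(ch))
    for (ci in seq_len(nrow(ch))) {
      kgi <- kg$K_G[kg$channel == ch$channel[ci] & kg$analyte == a]
      if (a != "control" && length(kgi) != 1)
        stop("generate_plate: missing K_G for ", ch$channel[ci], "/", a)
      if (a == "control") kgi <- 0
      p <- binding_parameters(K_I = ch$K_I[ci], K_G = kgi,
                              eps_I = ch$eps_I[ci], eps_HI = ch$eps_HI[ci])
      cond <- assay_conditions(host_total = host_well,
                               indicator_total = dye_well,
                               guest_total = g_well,
                               path_length = design$path_length)
      base <- ida_absorbance(cond, p)
      A <- base * (1 + mult_noise(n, design$noise_cv)) * (1 + shift)
      per_channel[[ci]] <- data.frame(
        analyte = a, analyte_total_M = g_well, channel = ch$channel[ci],
        replicate = seq_len(n), absorbance = pmax(A, 0),
        outlier = seq_len(n) %in% out_idx,
        stringsAsFactors = FALSE)
    }
    rows[[ai]] <- do.call(rbind, per_channel)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("plate_table", "data.frame")
  out
}

#' Simulate array responses to binary (or larger) analyte mixtures
#'
#' Generates replicate channel responses for wells containing several
#' saccharides at once, all competing for the host: the host mass balance
#' is extended to a sum over guest species, each with its per-channel
#' binding constant. Concentrations in `compositions` are in-well totals
#' (M). Used to train and test the mixture regression model.
#'
#' @param compositions data.frame of in-well analyte concentrations (M),
#'   one column per analyte (names must appear in `kg`), one row per
#'   mixture.
#' @param n_replicates Replicates per mixture.
#' @param noise_cv Multiplicative replicate noise.
#' @param channels Dye channel table, as [dye_channels()].
#' @param kg Host-guest constant table, as [kg_table()].
#' @param dye_stock_M,host_stock_M,ensemble_volume_uL,analyte_volume_uL,path_length
#'   As in [array_design()].
#' @param seed Integer seed.
#' @return A list: `x` (matrix, rows = mixtures x replicates, one column
#'   per channel), `targets` (matrix of the generating concentrations, M),
#'   `mixture` (row index into `compositions`).
#' @export
generate_mixture_responses <- function(compositions, n_replicates = 20,
                                       noise_cv = 0.01,
                                       channels = dye_channels(),
                                       kg = kg_table(),
                                       dye_stock_M = assay_defaults()$dye_stock_M,
                                       host_stock_M = assay_defaults()$host_stock_M,
                                       ensemble_volume_uL = 90,
                                       analyte_volume_uL = 10,
                                       path_length = assay_defaults()$plate_path_cm,
                                       seed = 1L) {
  compositions <- as.data.frame(compositions)
  analytes <- colnames(compositions)
  if (!all(analytes %in% kg$analyte))
    stop("generate_mixture_responses: unknown analyte(s): ",
         paste(setdiff(analytes, kg$analyte), collapse = ", "))
  set.seed(as.integer(seed))
  frac <- ensemble_volume_uL / (ensemble_volume_uL + analyte_volume_uL)
  It <- dye_stock_M * frac
  Ht <- host_stock_M * frac
  n_mix <- nrow(compositions)
  x <- matrix(NA_real_, n_mix * n_replicates, nrow(channels),
              dimnames = list(NULL, channels$channel))
  for (ci in seq_len(nrow(channels))) {
    KI <- channels$K_I[ci]
    KGs <- vapply(analytes, function(a)
      kg$K_G[kg$channel == channels$channel[ci] & kg$analyte == a], numeric(1))
    for (mi in seq_len(n_mix)) {
      g <- as.numeric(compositions[mi, ])
      h <- free_host_multi(Ht, It, KI, g, KGs)
      A <- It / (1 + KI * h) *
        (channels$eps_I[ci] * path_length +
         channels$eps_HI[ci] * path_length * KI * h)
      rows <- (mi - 1) * n_replicates + seq_len(n_replicates)
      x[rows, ci] <- A * (1 + mult_noise(n_replicates, noise_cv))
    }
  }
  targets <- as.matrix(compositions)[rep(seq_len(n_mix), each = n_replicates), ,
                                     drop = FALSE]
  rownames(targets) <- NULL
  list(x = x, targets = targets,
       mixture = rep(seq_len(n_mix), each = n_replicates))
}

#' Fingerprint response pattern of a plate
#'
#' Mean absorbance change of each analyte relative to the control, per dye
#' channel: the colorimetric "fingerprint" of the array. The control row is
#' identically zero.
#'
#' @param plate A plate table from [generate_plate()] or [read_plate_csv()].
#' @return A numeric matrix (analytes x channels) of mean \eqn{\Delta A}.
#' @export
fingerprint <- function(plate) {
  stopifnot(is.data.frame(plate))
  if (!"control" %in% plate$analyte)
    stop("fingerprint: plate has no control condition")
  means <- tapply(plate$absorbance, list(plate$analyte, plate$channel), mean)
  ctrl <- means["control", , drop = TRUE]
  delta <- sweep(means, 2, ctrl)
  ord <- c("control", setdiff(rownames(delta), "control"))
  delta[ord, , drop = FALSE]
}
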