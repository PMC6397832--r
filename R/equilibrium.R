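# Competitive three-component binding equilibrium (host H, indicator I,
# guest G; both complexes 1:1) and the absorbance observation model of an
# indicator displacement assay.

#' Assay conditions for an indicator displacement assay
#'
#' Bundles the known totals of a three-component competitive binding assay:
#' the receptor ("host", e.g. a phenylboronic acid), the reporter dye
#' ("indicator", e.g. a catechol dye) and the analyte ("guest", e.g. a
#' monosaccharide), together with the optical path length.
#'
#' @param host_total Total host concentration \eqn{[H]_t} (M).
#' @param indicator_total Total indicator concentration \eqn{[I]_t} (M).
#' @param guest_total Total guest concentration \eqn{[G]_t} (M).
#' @param path_length Optical path length \eqn{b} (cm).
#'
#' @return An object of class `assay_conditions` (a named list).
#' @examples
#' assay_conditions(host_total = 6e-3, indicator_total = 4e-5,
#'                  guest_total = 0, path_length = 1)
#' @export
assay_conditions <- function(host_total, indicator_total = 0,
                             guest_total = 0, path_length = 1) {
  vals <- c(host_total = host_total, indicator_total = indicator_total,
            guest_total = guest_total, path_length = path_length)
  if (!all(is.finite(vals)))
    stop("assay_conditions: all fields must be finite numbers")
  if (host_total < 0 || indicator_total < 0 || guest_total < 0)
    stop("assay_conditions: concentrations must be >= 0")
  if (path_length <= 0)
    stop("assay_conditions: path_length must be > 0")
  structure(list(host_total = host_total, indicator_total = indicator_total,
                 guest_total = guest_total, path_length = path_length),
            class = "assay_conditions")
}

#' Binding parameters of the 1:1 IDA model
#'
#' Association constants of the host-indicator (\eqn{K_I}) and host-guest
#' (\eqn{K_G}) complexes, and the molar absorptivities of the free indicator
#' (\eqn{\epsilon_I}) and the host-indicator complex (\eqn{\epsilon_{HI}})
#' at the observation wavelength. The host-guest complex is assumed not to
#' absorb at that wavelength.
#'
#' @param K_I Host-indicator association constant (1/M).
#' @param K_G Host-guest association constant (1/M).
#' @param eps_I Molar absorptivity of the free indicator (1/M/cm).
#' @param eps_HI Molar absorptivity of the host-indicator complex (1/M/cm).
#'
#' @return An object of class `binding_parameters`.
#' @export
binding_parameters <- function(K_I = 0, K_G = 0, eps_I = 0, eps_HI = 0) {
  vals <- c(K_I = K_I, K_G = K_G, eps_I = eps_I, eps_HI = eps_HI)
  if (!all(is.finite(vals)))
    stop("binding_parameters: all fields must be finite numbers")
  if (any(vals < 0))
    stop("binding_parameters: all fields must be >= 0")
  structure(as.list(vals), class = "binding_parameters")
}

#' Solve the competitive binding equilibrium for the free host concentration
#'
#' The mass balance of the host in the presence of an indicator and a guest,
#' each forming a 1:1 complex, is
#' \deqn{[H]_t = [H] + \frac{K_G [H]}{1 + K_G [H]} [G]_t
#'                   + \frac{K_I [H]}{1 + K_I [H]} [I]_t,}
#' a strictly increasing function of the free host concentration \eqn{[H]},
#' so the root in \eqn{[0, [H]_t]} is unique. It is located with Brent's
#' method on that bracket (\eqn{f(0) \le 0}, \eqn{f([H]_t) \ge 0} always).
#'
#' @param conditions An [assay_conditions()] object.
#' @param params A [binding_parameters()] object.
#' @param rel_tol,abs_tol Convergence tolerances on \eqn{[H]} (relative to
#'   \eqn{[H]_t}, and absolute in M).
#'
#' @return An object of class `speciation`: a list with components
#'   `free_host`, `free_indicator`, `free_guest`, `host_indicator`,
#'   `host_guest` (all M).
#' @examples
#' sp <- solve_free_host(
#'   assay_conditions(6e-3, 4e-5, 1e-2),
#'   binding_parameters(K_I = 480, K_G = 1900))
#' sp$free_host
#' @export
solve_free_host <- function(conditions, params,
                            rel_tol = 1e-12, abs_tol = 1e-18) {
  stopifnot(inherits(conditions, "assay_conditions"),
            inherits(params, "binding_parameters"))
  Ht <- conditions$host_total
  It <- conditions$indicator_total
  Gt <- conditions$guest_total
  KI <- params$K_I
  KG <- params$K_G

  if (Ht == 0) {
    h <- 0
  } else if (KI == 0 && KG == 0) {
    h <- Ht
  } else {
    f <- function(h) {
      h + KG * h * Gt / (1 + KG * h) + KI * h * It / (1 + KI * h) - Ht
    }
    tol <- max(abs_tol, rel_tol * Ht)
    r <- tryCatch(
      stats::uniroot(f, lower = 0, upper = Ht, f.lower = -Ht, f.upper = f(Ht),
                     tol = tol),
      error = function(e) stop(sprintf(
        "solve_free_host failed to converge for [H]t=%g, [I]t=%g, [G]t=%g, K_I=%g, K_G=%g: %s",
        Ht, It, Gt, KI, KG, conditionMessage(e)))
    )
    h <- r$root
    # one Newton polish: f' >= 1 everywhere, safe and sharpens the bracket root
    fp <- 1 + KG * Gt / (1 + KG * h)^2 + KI * It / (1 + KI * h)^2
    h2 <- h - f(h) / fp
    if (is.finite(h2) && h2 >= 0 && h2 <= Ht) h <- h2
  }

  HI <- KI * h * It / (1 + KI * h)
  HG <- KG * h * Gt / (1 + KG * h)
  structure(list(free_host = h,
                 free_indicator = It - HI,
                 free_guest = Gt - HG,
                 host_indicator = HI,
                 host_guest = HG),
            class = "speciation")
}

# free host with several competing guests (mass balance extended to a sum
# over guest species); used by the mixture simulator
free_host_multi <- function(Ht, It, KI, guest_totals, K_Gs,
                            rel_tol = 1e-12, abs_tol = 1e-18) {
  if (Ht == 0) return(0)
  f <- function(h) {
    h + sum(K_Gs * h * guest_totals / (1 + K_Gs * h)) +
      KI * h * It / (1 + KI * h) - Ht
  }
  if (f(Ht) <= 0) return(Ht)
  stats::uniroot(f, lower = 0, upper = Ht, f.lower = -Ht,
                 tol = max(abs_tol, rel_tol * Ht))$root
}

#' Absorbance of an IDA ensemble at the observation wavelength
#'
#' Evaluates the observation model
#' \deqn{A = \frac{[I]_t}{1 + K_I [H]}
#'           \left(\epsilon_I b + \epsilon_{HI} b K_I [H]\right),}
#' i.e. the Beer-Lambert absorbance of free indicator plus host-indicator
#' complex, with the free host concentration \eqn{[H]} obtained from
#' [solve_free_host()]. Displacement of the indicator by a competing guest
#' shifts the free/bound dye ratio and hence the absorbance.
#'
#' @inheritParams solve_free_host
#' @return A single non-negative absorbance value (dimensionless).
#' @examples
#' ida_absorbance(
#'   assay_conditions(6e-3, 4e-5, 1e-2),
#'   binding_parameters(K_I = 480, K_G = 1900, eps_I = 1e4, eps_HI = 5e3))
#' @export
ida_absorbance <- function(conditions, params) {
  sp <- solve_free_host(conditions, params)
  h <- sp$free_host
  It <- conditions$indicator_total
  b <- conditions$path_length
  It / (1 + params$K_I * h) * (params$eps_I * b + params$eps_HI * b * params$K_I * h)
}

#' Fraction of the indicator not bound to the host
#'
#' Summarises dye displacement: the free fraction equals the guest-free
#' baseline when no competing guest is present and increases monotonically
#' with the guest total as the guest sequesters host ("colour recovery").
#'
#' @inheritParams solve_free_host
#' @return Free indicator fraction in \[0, 1\].
#' @export
displacement_fraction <- function(conditions, params) {
  if (conditions$indicator_total <= 0)
    stop("displacement_fraction: indicator_total must be > 0")
  sp <- solve_free_host(conditions, params)
  sp$free_indicator / conditions$indicator_total
}
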