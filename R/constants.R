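# Reference constants of the four-dye / 3-NPBA saccharide sensing system:
# observation wavelengths, indicator binding constants, the host-guest
# binding-constant table, and the default assay concentrations.

#' Dye channel reference table
#'
#' The four catechol-dye channels of the colorimetric array: observation
#' wavelength, indicator binding constant \eqn{K_I} to the boronic acid
#' host, and default molar absorptivities of the free dye and the
#' dye-boronate complex at the observation wavelength. The \eqn{K_I} values
#' are the reported constants for ARS, BPR, PR and PV with 3-NPBA; the
#' absorptivities are generator defaults chosen to give a guest-free
#' ensemble absorbance of roughly 0.5-1 AU at 40 uM dye in a 1 cm cell
#' (typical of these dyes), with the complex absorbing less than the free
#' dye at the observation wavelength so that dye displacement increases the
#' signal. The free/complex contrast is strongest for BPR, which makes BPR
#' the dominant channel in the ANOVA contribution ranking, matching the
#' reported behaviour of the array.
#'
#' @return A data.frame with one row per channel: `channel`,
#'   `wavelength_nm`, `K_I` (1/M), `eps_I`, `eps_HI` (1/M/cm).
#' @export
dye_channels <- function() {
  data.frame(
    channel       = c("ARS", "BPR", "PR", "PV"),
    wavelength_nm = c(455, 540, 535, 497),
    K_I           = c(2100, 480, 670, 4600),
    eps_I         = c(2.2e4, 2.6e4, 2.0e4, 1.8e4),
    eps_HI        = c(9.0e3, 2.0e3, 8.0e3, 7.0e3),
    stringsAsFactors = FALSE
  )
}

#' Host-guest binding constants of the saccharide panel
#'
#' Association constants \eqn{K_G} (1/M) of 3-NPBA with each saccharide,
#' measured by IDA in the presence of each catechol dye. Entries reported
#' only as an upper bound ("< 10") are encoded with `floor_value`
#' (default 5, the midpoint of the undetectable range \[0, 10)); the
#' logical attribute `below_floor` marks them. The control (water) column
#' is 0 by definition.
#'
#' @param floor_value Value substituted for below-detection-floor entries.
#' @return A data.frame with columns `channel`, `analyte`, `K_G`,
#'   `below_floor`.
#' @export
kg_table <- function(floor_value = 5) {
  analytes <- c("Fru", "Gal", "Glc", "Xyl", "Man", "NAcGlc", "Rha")
  kg <- rbind(
    ARS = c(560, 110,  52,  41,  NA, NA, 17),
    BPR = c(1900, 230, 150, 110, 110, NA, 46),
    PR  = c(380,  NA,  NA,  NA,  NA, NA, NA),
    PV  = c(410,  33,  16,  12,  NA, NA, NA)
  )
  colnames(kg) <- analytes
  long <- expand.grid(channel = rownames(kg), analyte = analytes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$K_G <- kg[cbind(long$channel, long$analyte)]
  long$below_floor <- is.na(long$K_G)
  long$K_G[long$below_floor] <- floor_value
  ctrl <- data.frame(channel = rownames(kg), analyte = "control",
                     K_G = 0, below_floor = FALSE,
                     stringsAsFactors = FALSE)
  out <- rbind(ctrl, long)
  rownames(out) <- NULL
  out[order(match(out$analyte, c("control", analytes)),
            match(out$channel, rownames(kg))), , drop = FALSE]
}

#' Default assay concentrations and geometry
#'
#' Stock and in-well concentrations of the array protocol: 90 uL of buffer
#' containing dye (40 uM) and host (6 mM) per well, then 10 uL of analyte
#' solution, i.e. a 0.9 dilution factor for the premixed ensemble and 0.1
#' for the analyte stock. The cuvette titrations use the stated totals
#' directly with a 1 cm path; the plate path length defaults to 0.5 cm
#' (100 uL in a 384-well).
#'
#' @return A named list of defaults used by the generators.
#' @export
assay_defaults <- function() {
  list(
    dye_stock_M       = 40e-6,
    host_stock_M      = 6e-3,
    analyte_stock_M   = 100e-3,
    ensemble_volume_uL = 90,
    analyte_volume_uL  = 10,
    cuvette_path_cm   = 1,
    plate_path_cm     = 0.5
  )
}
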