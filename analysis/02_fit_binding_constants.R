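#!/usr/bin/env Rscript
# Step 2 — binding-constant estimation by nonlinear least squares.
#
# First the four indicator constants K_I are fitted from synthetic 1:1
# dye-host titrations; then, with K_I held fixed, every host-guest
# constant K_G is refit from a synthetic displacement titration of the
# preformed ensemble. Noiseless curves demonstrate exact recovery of the
# generating constants; five 2%-noise replicates of the strongest system
# (BPR/Fru) show the replicate-to-replicate spread of the estimate.

suppressMessages(library(idasense))
seed <- 1L
dir.create("results", showWarnings = FALSE)

ch <- dye_channels()
kg <- kg_table()
cuvette <- assay_conditions(6e-3, 40e-6, 0, path_length = 1)
host_schedule <- seq(0, 6e-3, length.out = 11)
guest_schedule <- c(0, 1, 2, 4, 6, 10, 15, 25, 40, 65, 100) * 1e-3

rows <- list()

cat("Indicator constants (noiseless round trip):\n")
for (i in seq_len(nrow(ch))) {
  curve <- generate_titration(
    binding_parameters(K_I = ch$K_I[i], eps_I = ch$eps_I[i],
                       eps_HI = ch$eps_HI[i]),
    host_schedule, assay_conditions(0, 40e-6, 0, 1),
    mode = "indicator-titration", noise_cv = 0)
  fit <- fit_indicator_binding(curve)
  cat(sprintf("  %-4s K_I generating %6.0f  recovered %9.2f 1/M\n",
              ch$channel[i], ch$K_I[i], fit$estimates$K_I))
  rows[[length(rows) + 1]] <- data.frame(
    channel = ch$channel[i], analyte = "(dye)", parameter = "K_I",
    generating = ch$K_I[i], recovered = fit$estimates$K_I,
    below_floor = FALSE)
}

cat("\nGuest constants (noiseless round trip, K_I fixed):\n")
quantified <- kg[kg$analyte != "control", ]
for (i in seq_len(nrow(quantified))) {
  row <- quantified[i, ]
  j <- match(row$channel, ch$channel)
  curve <- generate_titration(
    binding_parameters(K_I = ch$K_I[j], K_G = row$K_G,
                       eps_I = ch$eps_I[j], eps_HI = ch$eps_HI[j]),
    guest_schedule, cuvette, mode = "guest-titration", noise_cv = 0)
  fit <- fit_guest_binding(curve, K_I_known = ch$K_I[j],
                           eps_I = ch$eps_I[j], eps_HI = ch$eps_HI[j])
  shown <- if (fit$below_floor) "< 10 (bound)" else
    sprintf("%9.2f", fit$estimates$K_G)
  cat(sprintf("  %-4s %-7s K_G generating %6.0f  recovered %s 1/M\n",
              row$channel, row$analyte, row$K_G, shown))
  rows[[length(rows) + 1]] <- data.frame(
    channel = row$channel, analyte = row$analyte, parameter = "K_G",
    generating = row$K_G, recovered = fit$estimates$K_G,
    below_floor = fit$below_floor)
}
write.csv(do.call(rbind, rows), "results/binding_constants.csv",
          row.names = FALSE)

fits <- lapply(1:5, function(k) {
  j <- match("BPR", ch$channel)
  curve <- generate_titration(
    binding_parameters(K_I = ch$K_I[j], K_G = 1900,
                       eps_I = ch$eps_I[j], eps_HI = ch$eps_HI[j]),
    guest_schedule, cuvette, mode = "guest-titration",
    noise_cv = 0.02, seed = seed * 1000L + k)
  fit_guest_binding(curve, ch$K_I[j], ch$eps_I[j], ch$eps_HI[j])
})
re <- replicate_error(fits)
cat(sprintf("\nBPR/Fru, five 2%%-noise replicate fits: K_G spread %.1f%% (ceiling 19%%)\n", re))
cat("Entries generated below the 10 1/M floor are reported as bounds, not values.\n")
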