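# Synthetic titrations, spectra and plates: determinism, dilution
# bookkeeping, round-trip consistency, fingerprint structure.

test_that("noise-free titrations are the exact forward model and flat when inert", {
  cond <- assay_conditions(6e-3, 4e-5, 0, 1)
  p0 <- binding_parameters(K_I = 480, K_G = 0, eps_I = 2.6e4, eps_HI = 2e3)
  cv <- generate_titration(p0, seq(0, 0.1, length.out = 11), cond,
                           mode = "guest-titration", noise_cv = 0)
  expect_equal(diff(range(cv$absorbances)), 0)   # inert guest: flat curve
  # the flat level is the guest-free ensemble absorbance
  expect_equal(cv$absorbances[1], ida_absorbance(cond, p0))
})

test_that("titration generation is reproducible under a fixed seed", {
  cond <- assay_conditions(6e-3, 4e-5, 0, 1)
  p <- binding_parameters(K_I = 480, K_G = 1900, eps_I = 2.6e4, eps_HI = 2e3)
  a <- generate_titration(p, seq(0, 0.1, length.out = 11), cond,
                          noise_cv = 0.02, seed = 99)
  b <- generate_titration(p, seq(0, 0.1, length.out = 11), cond,
                          noise_cv = 0.02, seed = 99)
  expect_identical(a$absorbances, b$absorbances)
})

test_that("generated curves round-trip through the guest fit", {
  cond <- assay_conditions(6e-3, 4e-5, 0, 1)
  p <- binding_parameters(K_I = 480, K_G = 1900, eps_I = 2.6e4, eps_HI = 2e3)
  cv <- generate_titration(p, seq(0, 0.1, length.out = 11), cond,
                           mode = "guest-titration", noise_cv = 0)
  fit <- fit_guest_binding(cv, K_I_known = 480, eps_I = 2.6e4, eps_HI = 2e3)
  expect_equal(fit$estimates$K_G, 1900, tolerance = 1e-3)
})

test_that("spectra are concentration-weighted band superpositions", {
  grid <- seq(350, 800, by = 1)
  bands <- spectral_band_model()
  zero <- structure(list(free_host = 0, free_indicator = 0, free_guest = 0,
                         host_indicator = 0, host_guest = 0),
                    class = "speciation")
  expect_true(all(generate_spectrum(zero, bands, grid) == 0))
  pure_free <- zero; pure_free$free_indicator <- 4e-5
  pure_bound <- zero; pure_bound$host_indicator <- 4e-5
  sf <- generate_spectrum(pure_free, bands, grid)
  sb <- generate_spectrum(pure_bound, bands, grid)
  # apparent maxima of pure free vs pure complexed ARS differ by 46 nm
  expect_equal(grid[which.max(sf)] - grid[which.max(sb)], 46)
  mixed <- zero; mixed$free_indicator <- 3e-5; mixed$host_indicator <- 1e-5
  sm <- generate_spectrum(mixed, bands, grid)
  expect_equal(sm, 0.75 * sf + 0.25 * sb, tolerance = 1e-12)
  expect_error(generate_spectrum(zero, bands, numeric(0)), "empty")
})

test_that("plate dimensions and dilution bookkeeping follow the protocol", {
  d <- array_design(noise_cv = 0, n_outliers = 0, analyte_mode = "stock",
                    seed = 1)
  pl <- generate_plate(d)
  expect_equal(nrow(pl), 4 * 8 * 24)
  # 100 mM analyte stock diluted 10 uL into 100 uL -> 10 mM in-well
  expect_equal(unique(pl$analyte_total_M[pl$analyte == "Fru"]), 100e-3 * 0.1)
  expect_equal(unique(pl$analyte_total_M[pl$analyte == "control"]), 0)
  # noise-free, outlier-free: replicates within a condition are identical
  spread <- tapply(pl$absorbance, list(pl$analyte, pl$channel),
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))
})

test_that("plates are bit-identical under the same design and seed", {
  d1 <- array_design(seed = 7)
  d2 <- array_design(seed = 7)
  expect_identical(generate_plate(d1), generate_plate(d2))
  d3 <- array_design(seed = 8)
  expect_false(identical(generate_plate(d1)$absorbance,
                         generate_plate(d3)$absorbance))
})

test_that("control wells sit at the guest-free ensemble signal", {
  d <- array_design(noise_cv = 0, n_outliers = 0, seed = 1)
  pl <- generate_plate(d)
  ch <- dye_channels()
  for (i in seq_len(nrow(ch))) {
    expected <- ida_absorbance(
      assay_conditions(6e-3 * 0.9, 40e-6 * 0.9, 0, d$path_length),
      binding_parameters(K_I = ch$K_I[i], eps_I = ch$eps_I[i],
                         eps_HI = ch$eps_HI[i]))
    got <- unique(pl$absorbance[pl$analyte == "control" &
                                pl$channel == ch$channel[i]])
    expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("missing K_table entries are reported by pair", {
  kg <- kg_table()
  kg <- kg[!(kg$channel == "PR" & kg$analyte == "Man"), ]
  expect_error(array_design(kg = kg), "PR Man")
})

test_that("fingerprints have a zero control row and Fru dominates", {
  d <- array_design(noise_cv = 0.01, seed = 3)
  pl <- generate_plate(d)
  fp <- fingerprint(pl)
  expect_true(all(fp["control", ] == 0))
  for (ch in colnames(fp)) {
    strongest <- rownames(fp)[which.max(abs(fp[, ch]))]
    expect_equal(strongest, "Fru")
  }
  expect_error(fingerprint(pl[pl$analyte != "control", ]), "control")
})

test_that("fingerprints are all zero when nothing binds", {
  kg <- kg_table()
  kg$K_G <- 0
  d <- array_design(kg = kg, noise_cv = 0, n_outliers = 0, seed = 1)
  fp <- fingerprint(generate_plate(d))
  expect_true(all(fp == 0))
})

test_that("fingerprint magnitude follows K_G within each channel", {
  # noise-free plate: |dA| must increase with K_G channel by channel
  d <- array_design(noise_cv = 0, n_outliers = 0, seed = 1)
  pl <- generate_plate(d)
  fp <- fingerprint(pl)
  kg <- kg_table()
  for (ch in colnames(fp)) {
    k <- kg[kg$channel == ch & kg$analyte != "control", ]
    ord <- order(k$K_G)
    expect_true(all(diff(abs(fp[k$analyte[ord], ch])) >= -1e-12))
  }
})

test_that("a concentration-series design carries level labels and constants", {
  d <- concentration_series_design("Fru", c(0, 20, 40, 60, 80, 100) * 1e-3,
                                   noise_cv = 0, n_outliers = 0, seed = 1)
  pl <- generate_plate(d)
  expect_equal(sort(unique(pl$analyte)),
               sort(c("0", "20", "40", "60", "80", "100")))
  expect_false("control" %in% pl$analyte)
  # zero level binds nothing: equals the ensemble baseline of each channel
  m <- tapply(pl$absorbance, list(pl$analyte, pl$channel), mean)
  base <- m["0", ]
  mono <- m[c("0", "20", "40", "60", "80", "100"), "ARS"]
  expect_true(all(diff(mono) > 0))  # dye release grows with concentration
  expect_error(concentration_series_design("NotASugar"), "not in kg")
})
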