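test_that("a single noiseless Gaussian matching one model band is recovered exactly", {
  model <- band_model("ester")
  w <- default_grid()
  w <- w[w >= 1700 & w < 1780]
  s <- new_spectrum(w, gaussian_band(1740, 26, 0.2, w))
  fit <- fit_bands(s, model)
  expect_equal(fit$height, 0.2, tolerance = 1e-6)
  expect_equal(fit$center, 1740, tolerance = 1e-6)
  expect_equal(fit$fwhm, 26, tolerance = 1e-6)
  expect_true(attr(fit, "converged"))
  expect_lt(attr(fit, "residual_rms"), 1e-9)
})

test_that("two overlapping lipid Gaussians are separated within 0.5%", {
  model <- band_model("lipid")
  w <- default_grid()
  w <- w[w >= 2750 & w < 3100]
  y <- gaussian_band(2920, 28, 0.660, w) + gaussian_band(2960, 24, 0.400, w)
  fit <- fit_bands(new_spectrum(w, y), model)
  h <- setNames(fit$height, fit$name)
  expect_equal(h[["vas_ch2"]], 0.660, tolerance = 0.005)
  expect_equal(h[["vas_ch3"]], 0.400, tolerance = 0.005)
})

test_that("residual RMS of a correct model is noise-dominated", {
  noise_sd <- 0.004
  model <- band_model("lipid")
  w <- default_grid()
  w <- w[w >= 2750 & w < 3100]
  pre <- quiet_preset("steatotic")
  y <- numeric(length(w))
  for (nm in c("olefinic", "vas_ch3", "vas_ch2", "vs_ch3", "vs_ch2")) {
    b <- band_table()[band_table()$name == nm, ]
    y <- y + gaussian_band(b$center, b$fwhm, pre$band_heights[[nm]], w)
  }
  set.seed(123)
  fit <- fit_bands(new_spectrum(w, y + rnorm(length(w), 0, noise_sd)), model)
  expect_lt(attr(fit, "residual_rms"), 1.5 * noise_sd)
})

test_that("noiseless in-bounds Gaussian sums with separated centers are recovered within 1%", {
  # property over random draws: centers jittered inside bounds, FWHMs inside
  # bounds, random heights; pairwise center separation of the lipid table
  # already >= 10 cm-1
  model <- band_model("lipid")
  w <- default_grid()
  w <- w[w >= 2750 & w < 3100]
  set.seed(42)
  for (rep in 1:8) {
    centers <- model$center + runif(nrow(model), -3, 3)
    fwhms <- pmin(pmax(model$fwhm * runif(nrow(model), 0.8, 1.2), model$fwhm_lo), model$fwhm_hi)
    heights <- runif(nrow(model), 0.05, 0.7)
    y <- numeric(length(w))
    for (i in seq_len(nrow(model))) y <- y + gaussian_band(centers[i], fwhms[i], heights[i], w)
    fit <- fit_bands(new_spectrum(w, y), model)
    expect_equal(fit$height, heights, tolerance = 0.01)
    expect_equal(fit$center, centers, tolerance = 1e-3)
    expect_equal(fit$fwhm, fwhms, tolerance = 0.01)
  }
})

test_that("fit errors are informative", {
  model <- band_model("lipid")
  w <- toy_grid(1600, 1700, 100)
  expect_error(fit_bands(new_spectrum(w, rnorm(100)), model), "window")
})

test_that("integrated intensity is the closed-form Gaussian area", {
  model <- band_model("ester")
  w <- default_grid(); w <- w[w >= 1700 & w < 1780]
  fit <- fit_bands(new_spectrum(w, gaussian_band(1740, 26, 0.31, w)), model)
  # quadrature oracle on the reconstructed lone component
  wfine <- seq(1740 - 6 * fit$fwhm, 1740 + 6 * fit$fwhm, length.out = 20001)
  quad <- trapz_oracle(wfine, gaussian_band(fit$center, fit$fwhm, fit$height, wfine))
  expect_equal(integrated_intensity(fit, "ester_co"), quad, tolerance = 1e-4)
  # height 1, fwhm 1 -> 1.06447; zero height -> zero
  fake <- fit
  fake$height <- 1; fake$fwhm <- 1
  expect_equal(fake$height * fake$fwhm * sqrt(pi / (4 * log(2))), 1.06447, tolerance = 1e-5)
  fit0 <- fit; fit0$height <- 0
  expect_equal(integrated_intensity(fit0, "ester_co"), 0)
  expect_error(integrated_intensity(fit, "nonesuch"), "not present")
})

test_that("lipid metrics use fitted heights and reduce to the preset ratios without noise", {
  for (cond in c("untreated", "steatotic", "ex4")) {
    pre <- quiet_preset(cond)
    s <- generate_spectrum(pre, 1)
    m <- lipid_metrics(fit_window_of(s, "lipid"), fit_window_of(s, "ester"))
    expect_equal(m$vas_ratio, pre$band_heights[["vas_ch2"]] / pre$band_heights[["vas_ch3"]],
                 tolerance = 0.01)
    expect_equal(m$vs_ratio, pre$band_heights[["vs_ch2"]] / pre$band_heights[["vs_ch3"]],
                 tolerance = 0.01)
    expect_equal(m$unsat_ratio, pre$band_heights[["vas_ch2"]] / pre$band_heights[["olefinic"]],
                 tolerance = 0.02)
    expect_gt(m$ester_area, 0)
  }
  # all heights equal -> every ratio 1
  model <- band_model("lipid")
  w <- default_grid(); w <- w[w >= 2750 & w < 3100]
  y <- numeric(length(w))
  for (i in seq_len(nrow(model))) y <- y + gaussian_band(model$center[i], model$fwhm[i], 0.3, w)
  m_eq <- lipid_metrics(fit_bands(new_spectrum(w, y), model))
  expect_equal(m_eq$vas_ratio, 1, tolerance = 1e-4)
  expect_equal(m_eq$vs_ratio, 1, tolerance = 1e-4)
  expect_equal(m_eq$unsat_ratio, 1, tolerance = 1e-4)
})

test_that("amide deconvolution recovers generating secondary-structure fractions", {
  for (cond in c("untreated", "steatotic")) {
    pre <- quiet_preset(cond)
    s <- area_normalize(generate_spectrum(pre, 1))
    prof <- amide_deconvolution(prepare_window(s, band_model("amide_i")))
    expect_equal(sum(prof$fractions), 1, tolerance = 1e-6)
    for (nm in names(pre$amide_area_fractions)) {
      expect_lt(abs(prof$fractions[[nm]] - pre$amide_area_fractions[[nm]]), 0.02)
    }
    expect_lt(abs(prof$alpha_over_amide - pre$amide_area_fractions[["alpha_helix"]]), 0.02)
    expect_lt(abs(prof$sheet_over_alpha -
                    pre$amide_area_fractions[["beta_sheet"]] / pre$amide_area_fractions[["alpha_helix"]]),
              0.03)
  }
  # five equal-area components -> each fraction 0.20
  model <- band_model("amide_i")
  w <- default_grid(); w <- w[w >= 1600 & w < 1700]
  y <- numeric(length(w))
  for (i in seq_len(nrow(model))) {
    h <- 1 / (model$fwhm[i] * sqrt(pi / (4 * log(2))))  # unit area each
    y <- y + gaussian_band(model$center[i], model$fwhm[i], h, w)
  }
  prof_eq <- amide_deconvolution(new_spectrum(w, y))
  expect_equal(unname(prof_eq$fractions), rep(0.2, 5), tolerance = 0.01)
})
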