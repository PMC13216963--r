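test_that("noise-free mixtures built from the basis are recovered exactly", {
  set.seed(11)
  wl <- seq(300, 500, length.out = 150)
  eps <- cbind(HA1 = dnorm(wl, 340, 20), A1 = dnorm(wl, 420, 18),
               HA2 = dnorm(wl, 365, 15), A2 = dnorm(wl, 465, 22)) * 50
  basis <- pure_form_basis(wl, eps, ref_conc = 1)
  mix <- 0.3 * eps[, 1] + 0.7 * eps[, 2] + 0.5 * eps[, 3] + 0.5 * eps[, 4]
  sm <- spectrum_matrix(wl, cbind(m1 = mix))
  pts <- unmix_spectra(sm, basis)
  expect_equal(pts$alpha1, 0.7, tolerance = 1e-10)
  expect_equal(pts$alpha2, 0.5, tolerance = 1e-10)
  expect_true(pts$usable)
})

test_that("a pure single-form spectrum is flagged unusable, not guessed", {
  wl <- seq(300, 500, length.out = 150)
  eps <- cbind(dnorm(wl, 340, 20), dnorm(wl, 420, 18),
               dnorm(wl, 365, 15), dnorm(wl, 465, 22)) * 50
  basis <- pure_form_basis(wl, eps)
  sm <- spectrum_matrix(wl, cbind(only_ha1 = eps[, 1]))
  pts <- unmix_spectra(sm, basis)
  expect_false(pts$usable)
  expect_equal(pts$alpha1, 0, tolerance = 1e-10)
  expect_true(is.na(pts$alpha2))
  expect_match(pts$reason, "acid 2 absent")
})

test_that("unmixing tolerates realistic absorbance noise", {
  set.seed(42)
  wl <- seq(300, 500, length.out = 200)
  eps <- cbind(dnorm(wl, 335, 16), dnorm(wl, 425, 20),
               dnorm(wl, 370, 14), dnorm(wl, 462, 18)) * 60
  basis <- pure_form_basis(wl, eps)
  true_a <- c(0.6, 0.4)
  mix <- eps %*% c(1 - true_a[1], true_a[1], 1 - true_a[2], true_a[2]) +
    rnorm(length(wl), 0, 0.002)
  pts <- unmix_spectra(spectrum_matrix(wl, mix), basis)
  expect_lt(abs(pts$alpha1 - 0.6), 0.02)
  expect_lt(abs(pts$alpha2 - 0.4), 0.02)
})

test_that("an ill-conditioned basis is rejected with the pair named", {
  wl <- seq(300, 500, length.out = 100)
  s <- dnorm(wl, 400, 20)
  eps <- cbind(s, s * 1.000001, dnorm(wl, 350, 15), dnorm(wl, 450, 15))
  basis <- pure_form_basis(wl, eps, acids = c("HX", "HY"))
  sm <- spectrum_matrix(wl, cbind(rowSums(eps)))
  expect_error(unmix_spectra(sm, basis), "HX.*HY|ill-conditioned")
})

test_that("relative acidity from dissociation degrees follows the log-odds form", {
  expect_identical(delta_pkip_from_alphas(0.5, 0.5), 0)
  expect_equal(delta_pkip_from_alphas(0.9, 0.5), log10(9), tolerance = 1e-12)
  expect_equal(delta_pkip_from_alphas(0.5, 0.9), -log10(9), tolerance = 1e-12)
  expect_error(delta_pkip_from_alphas(1, 0.5), "strictly inside")
  expect_error(delta_pkip_from_alphas(0.5, 0), "strictly inside")
})

test_that("the log-odds form is antisymmetric and monotone over (0,1)^2", {
  set.seed(7)
  a1 <- runif(200, 0.01, 0.99); a2 <- runif(200, 0.01, 0.99)
  expect_equal(delta_pkip_from_alphas(a1, a2),
               -delta_pkip_from_alphas(a2, a1), tolerance = 1e-12)
  # strictly increasing in alpha1, strictly decreasing in alpha2
  grid <- seq(0.05, 0.95, by = 0.05)
  for (a in c(0.2, 0.5, 0.8)) {
    expect_true(all(diff(delta_pkip_from_alphas(grid, a)) > 0))
    expect_true(all(diff(delta_pkip_from_alphas(a, grid)) < 0))
  }
})

test_that("aggregation over usable points matches mean/median with spread", {
  pts <- data.frame(alpha1 = c(0.760, 0.7655, 0.755), alpha2 = 1 - c(0.760, 0.7655, 0.755),
                    usable = TRUE)
  vals <- delta_pkip_from_alphas(pts$alpha1, pts$alpha2)
  pr <- aggregate_pair(pts, acids = c("x", "y"))
  expect_equal(pr$delta_pkip, mean(vals), tolerance = 1e-12)
  expect_equal(pr$spread, sd(vals), tolerance = 1e-12)
  expect_equal(pr$n_points, 3L)
  prm <- aggregate_pair(pts, acids = c("x", "y"), method = "median")
  expect_equal(prm$delta_pkip, median(vals), tolerance = 1e-12)
  # single point: spread defined as 0
  one <- aggregate_pair(data.frame(alpha1 = 0.7, alpha2 = 0.5, usable = TRUE))
  expect_equal(one$spread, 0)
  expect_equal(one$n_points, 1L)
  # no usable points: error carries the reasons
  expect_error(aggregate_pair(data.frame(alpha1 = 0.99, alpha2 = 0.01,
                                         usable = FALSE, reason = "outside window")),
               "outside window")
})

test_that("scale invariance: a common positive factor leaves alphas unchanged", {
  tit <- gen_titration(delta_pk = 0.8, n_steps = 10, noise_sd = 0, seed = 5)
  p1 <- unmix_spectra(tit$mixtures, tit$basis)
  sc <- 3.7
  basis2 <- pure_form_basis(tit$basis$wavelengths, tit$basis$spectra * sc,
                            ref_conc = tit$basis$ref_conc)
  mix2 <- spectrum_matrix(tit$mixtures$wavelengths, tit$mixtures$absorbance * sc)
  p2 <- unmix_spectra(mix2, basis2)
  expect_equal(p1$alpha1, p2$alpha1, tolerance = 1e-10)
  expect_equal(p1$alpha2, p2$alpha2, tolerance = 1e-10)
})

test_that("swapping the two acids negates the aggregated relative acidity", {
  tit <- gen_titration(delta_pk = 1.1, n_steps = 14, noise_sd = 1e-4, seed = 9)
  pts <- unmix_spectra(tit$mixtures, tit$basis)
  pr <- aggregate_pair(pts)
  swapped <- data.frame(alpha1 = pts$alpha2, alpha2 = pts$alpha1,
                        usable = pts$usable)
  pr2 <- aggregate_pair(swapped, acids = c("acid2", "acid1"))
  expect_equal(pr2$delta_pkip, -pr$delta_pkip, tolerance = 1e-10)
})

test_that("nonnegative unmixing option recovers clean compositions", {
  tit <- gen_titration(delta_pk = 1.0, n_steps = 8, noise_sd = 0, seed = 13)
  p_free <- unmix_spectra(tit$mixtures, tit$basis)
  p_nn <- unmix_spectra(tit$mixtures, tit$basis, nonneg = TRUE)
  expect_equal(p_nn$alpha1, p_free$alpha1, tolerance = 1e-6)
  expect_equal(p_nn$alpha2, p_free$alpha2, tolerance = 1e-6)
})
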