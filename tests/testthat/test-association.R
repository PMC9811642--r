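# Free-energy-profile normalization, Boltzmann inversion, radial
# integration to the association constant, and minima classification.

flat_profile <- function(value = 0, r = seq(0.001, 1.6, by = 0.005), T = 300) {
  fes_profile(r, rep(value, length(r)), temperature = T)
}

test_that("plateau normalization zeroes the window mean and is idempotent", {
  p <- flat_profile(5)
  n1 <- normalize_profile(p)
  expect_true(n1$normalized)
  expect_equal(n1$E, rep(0, length(p$r)))
  # arbitrary profile: the shift is exactly the window mean
  r <- seq(0.2, 1.6, by = 0.002)
  E <- sin(3 * r) + 2.3
  p2 <- fes_profile(r, E)
  n2 <- normalize_profile(p2)
  sel <- r >= 1.0 & r <= 1.4
  expect_equal(mean(n2$E[sel]), 0, tolerance = 1e-12)
  expect_equal(n2$E, E - mean(E[sel]))
  # idempotence
  n3 <- normalize_profile(n2)
  expect_equal(n3$E, n2$E, tolerance = 1e-12)
  # window outside the grid is refused
  expect_error(normalize_profile(fes_profile(seq(0.2, 0.8, by = 0.01),
                                             rep(0, 61))), "window")
})

test_that("Boltzmann inversion gives the pointwise g(r) and demands normalization", {
  p <- normalize_profile(flat_profile(0))
  g <- profile_to_gid(p)
  expect_equal(g$g, rep(1, length(p$r)))
  # analytic inversion: E = -RT ln 2 gives g = 2
  RT <- 8.314462e-3 * 300
  r <- seq(0.2, 1.6, by = 0.002)
  E <- rep(0, length(r)); E[100] <- -RT * log(2)
  g2 <- profile_to_gid(fes_profile(r, E, normalized = TRUE))
  expect_equal(g2$g[100], 2, tolerance = 1e-12)
  # Gaussian well against element-wise exponentiation
  E3 <- -10 * exp(-(r - 0.3)^2 / (2 * 0.03^2))
  g3 <- profile_to_gid(fes_profile(r, E3, normalized = TRUE))
  expect_equal(g3$g, exp(-E3 / RT), tolerance = 1e-12)
  expect_true(all(g3$g > 0))
  expect_error(profile_to_gid(flat_profile(1)), "normalize")
})

test_that("dissociation boundary detection finds the first tail minimum", {
  r <- seq(0.2, 1.6, by = 0.002)
  # planted SIP maximum at 0.6 and minimum at 0.85
  gvals <- 1 + 2 * exp(-(r - 0.6)^2 / (2 * 0.05^2)) -
    0.5 * exp(-(r - 0.85)^2 / (2 * 0.05^2))
  g <- structure(list(r = r, g = gvals, temperature = 300),
                 class = "gid_table")
  ru <- detect_RU(g)
  expect_false(ru$fallback)
  expect_equal(ru$R_U, 0.85, tolerance = 2e-3)
  # two tail minima: the first is taken
  gv2 <- 1 + 2 * exp(-(r - 0.6)^2 / (2 * 0.05^2)) -
    0.5 * exp(-(r - 0.82)^2 / (2 * 0.04^2)) -
    0.8 * exp(-(r - 1.1)^2 / (2 * 0.04^2))
  g2 <- structure(list(r = r, g = gv2, temperature = 300),
                  class = "gid_table")
  expect_equal(detect_RU(g2)$R_U, 0.82, tolerance = 2e-3)
  # featureless g(r): no SIP structure at all
  gf <- structure(list(r = r, g = rep(1, length(r)), temperature = 300),
                  class = "gid_table")
  expect_error(detect_RU(gf), "no SIP structure")
  # maximum but monotone tail: flagged fallback
  gm <- structure(list(r = r, g = 1 + exp(-(r - 0.5)^2 / (2 * 0.05^2)),
                       temperature = 300), class = "gid_table")
  ru3 <- detect_RU(gm, fallback = 1.2)
  expect_true(ru3$fallback)
  expect_equal(ru3$R_U, 1.2)
})

test_that("radial integration reproduces sphere volume and a fine-grid oracle", {
  p <- normalize_profile(flat_profile(0))
  g <- profile_to_gid(p)
  ka <- association_constant(g, 1.0)
  expect_equal(ka$Ka_volume, 4 * pi / 3, tolerance = 1e-4)
  expect_equal(ka$Ka_molar, 4 * pi / 3 * 0.60221, tolerance = 1e-4)
  # square-well g on [0.2, 0.3]: compare to a high-resolution quadrature
  r <- seq(0.0001, 1.5, by = 0.0001)
  RT <- 8.314462e-3 * 300
  E <- ifelse(r >= 0.2 & r <= 0.3, -RT * log(100), 0)
  gsq <- structure(list(r = r, g = exp(-E / RT), temperature = 300),
                   class = "gid_table")
  got <- association_constant(gsq, 0.8)$Ka_volume
  oracle_fun <- function(x) ifelse(x >= 0.2 & x <= 0.3, -RT * log(100), 0)
  oracle <- ka_quadrature_oracle(oracle_fun, 0.8)
  expect_equal(got, oracle, tolerance = 1e-3)
  # additivity over disjoint segments
  y_all <- association_constant(gsq, 0.8)$Ka_volume
  y_a <- association_constant(gsq, 0.4)$Ka_volume
  r2 <- r[r >= 0.4]
  gsq_b <- structure(list(r = r2, g = gsq$g[r >= 0.4], temperature = 300),
                     class = "gid_table")
  y_b <- pracma::trapz(r2[r2 <= 0.8], 4 * pi * r2[r2 <= 0.8]^2 *
                         gsq_b$g[r2 <= 0.8])
  expect_equal(y_a + y_b, y_all, tolerance = 1e-12)
  expect_error(association_constant(gsq, 2.0), "outside")
})

test_that("dG bridges Ka at 300 K for every published pair", {
  expect_equal(delta_g(1, 300), 0)
  expect_equal(delta_g(1, 77), 0)
  # simulation and experimental (Ka, -dG) pairs, all consistent to the
  # printed decimal at 300 K
  ka <- c(7.07e10, 7.07, 1802.71, 548.22, 65.46, 25.87, 13.58,
          22.06, 10.98, 12.43, 7.40,
          91.20, 97.50, 13.64, 19.05, 133.10, 6.07, 11.54)
  minus_dg <- c(62.3, 4.9, 18.7, 15.7, 10.4, 8.1, 6.5,
                7.7, 6.0, 6.3, 5.0,
                11.3, 11.4, 6.5, 7.4, 12.2, 4.5, 6.1)
  expect_equal(round(-delta_g(ka, 300), 1), minus_dg)
  # round trip over nine decades
  for (k in 10^seq(-3, 12, by = 3)) {
    dg <- delta_g(k, 300)
    expect_equal(exp(-dg / (8.314462e-3 * 300)), k, tolerance = 1e-9)
  }
  expect_error(delta_g(0), "> 0")
  expect_error(delta_g(-3), "> 0")
})

test_that("minima classification labels the four ion-pair states", {
  p <- gen_fes_profile()  # four wells at the canonical positions
  m <- classify_minima(normalize_profile(p))
  expect_identical(m$state, c("biCIP", "monoCIP", "SIP", "SSIP"))
  expect_equal(m$position, c(0.290, 0.346, 0.513, 0.677), tolerance = 5e-3)
  # monotonic profile has no minima
  r <- seq(0.2, 1.6, by = 0.002)
  mono <- normalize_profile(fes_profile(r, -5 * (1.6 - r)))
  expect_equal(nrow(classify_minima(mono)), 0L)
  # two wells echo the published biCIP-monoCIP gap arithmetic
  p2 <- gen_fes_profile(wells = data.frame(center = c(0.29, 0.35),
                                           depth = c(-10, -5.2),
                                           width = c(0.02, 0.02)))
  m2 <- classify_minima(normalize_profile(p2))
  expect_equal(nrow(m2), 2L)
  expect_equal(diff(m2$depth), 4.8, tolerance = 0.05)
  # overlapping windows are refused
  expect_error(state_windows(biCIP = c(0, 0.35), monoCIP = c(0.31, 0.4)),
               "overlap")
})

test_that("the full pipeline is stable under grid refinement and well deepening", {
  RT <- 8.314462e-3 * 300
  well <- function(r) -20 * exp(-(r - 0.24)^2 / (2 * 0.02^2))
  r_fine <- seq(0.001, 1.6, by = 0.002)
  r_coarse <- r_fine[seq(1, length(r_fine), by = 2)]
  rep_f <- association_report(fes_profile(r_fine, well(r_fine)))
  rep_c <- association_report(fes_profile(r_coarse, well(r_coarse)))
  oracle <- ka_quadrature_oracle(well, rep_f$R_U)
  expect_equal(rep_f$Ka_volume, oracle, tolerance = 0.02)
  expect_equal(rep_c$dG, rep_f$dG, tolerance = 0.05)
  # flat profile falls back to the configured R_U and the sphere volume
  rep0 <- association_report(flat_profile(0), ru_fallback = 1.0)
  expect_true(rep0$R_U_fallback)
  expect_equal(rep0$Ka_volume, 4 * pi / 3, tolerance = 1e-4)
  # deepening any well never decreases Ka
  base <- gen_fes_profile()
  deeper <- gen_fes_profile(wells = data.frame(
    center = c(0.290, 0.346, 0.513, 0.677),
    depth = c(-12, -16, -6, -3), width = c(0.02, 0.02, 0.03, 0.03)))
  expect_gte(association_report(deeper)$Ka_molar,
             association_report(base)$Ka_molar)
})
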