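# RDF/ADF estimators, coordination numbers, local density and SASA.

test_that("rdf resolves fixed pairs and lattice shells", {
  fr <- traj_frame(rbind(c(1, 1, 1), c(1.3, 1, 1)), c("Ca", "Oc"), c(4, 4, 4))
  r <- rdf(fr, "Ca", "Oc", r_max = 1.0, n_bins = 100)
  expect_equal(r$r[which(r$g > 0)], 0.305)   # single occupied bin at 0.30
  expect_equal(tail(r$N, 1), 1)
  expect_equal(coordination_number(r, 0.5), 1)
  # simple-cubic lattice: first peak at the spacing, N jumps to 6
  a <- 0.5
  latt <- as.matrix(expand.grid(0:5, 0:5, 0:5)) * a
  fr2 <- traj_frame(latt, rep("Ca", 216), c(3, 3, 3))
  r2 <- rdf(fr2, "Ca", "Ca", r_max = 1.4, n_bins = 280)
  first_peak <- r2$r[which(r2$g > 0)[1]]
  expect_equal(first_peak, a, tolerance = 0.01)
  expect_equal(coordination_number(r2, 0.55), 6)
  expect_true(all(diff(r2$N) >= 0))
  expect_lte(tail(r2$N, 1), 215)
  expect_error(rdf(fr2, "Ca", "Ca", r_max = 2.0), "half")
})

test_that("rdf of an ideal gas is flat within Poisson error bars", {
  set.seed(101)
  box <- 4
  frames <- lapply(1:40, function(i) {
    traj_frame(matrix(runif(3 * 500, 0, box), ncol = 3),
               rep("Ca", 500), rep(box, 3))
  })
  r <- rdf(frames, "Ca", "Ca", r_max = 1.5, n_bins = 30)
  # expected pair count per bin under ideal-gas statistics
  shell <- 4 / 3 * pi * diff(r$edges^3)
  expected <- 500 * 40 * (499 / box^3) * shell
  sigma_g <- sqrt(expected) / expected
  expect_true(all(abs(r$g - 1) < 3.5 * sigma_g))
  expect_lt(mean(abs(r$g - 1)), 0.02)
  # coordination number matches the analytic sphere count
  rho <- 499 / box^3
  expect_equal(coordination_number(r, 1.0), 4 / 3 * pi * rho,
               tolerance = 0.02)
})

test_that("adf places planted geometries in the right angular bins", {
  # 90 degrees: Ow at +x, Hw at +y of the Oc vertex
  fr <- traj_frame(rbind(c(1, 1, 1), c(1.3, 1, 1), c(1, 1.1, 1)),
                   c("Oc", "Ow", "Hw"), c(5, 5, 5))
  h <- adf(fr, c("Ow", "Oc", "Hw"), 0.35, 0.12)
  expect_false(h$empty)
  expect_lt(abs(h$theta[which.max(h$count)] - 90), 2)
  expect_equal(sum(h$density) * (180 / length(h$theta)), 1, tolerance = 1e-12)
  # linear arrangement lands in the 180-degree bin
  fr2 <- traj_frame(rbind(c(1, 1, 1), c(1.3, 1, 1), c(0.9, 1, 1)),
                    c("Oc", "Ow", "Hw"), c(5, 5, 5))
  h2 <- adf(fr2, c("Ow", "Oc", "Hw"), 0.35, 0.12)
  expect_lt(abs(h2$theta[which.max(h2$count)] - 180), 2)
  # methane-like tetrahedron peaks at 109.47 degrees
  tet <- rbind(c(1, 1, 1), c(1, 1, 1) + 0.1 * c(1, 1, 1) / sqrt(3),
               c(1, 1, 1) + 0.1 * c(1, -1, -1) / sqrt(3),
               c(1, 1, 1) + 0.1 * c(-1, 1, -1) / sqrt(3),
               c(1, 1, 1) + 0.1 * c(-1, -1, 1) / sqrt(3))
  fr3 <- traj_frame(tet, c("Cc", rep("Hw", 4)), c(5, 5, 5))
  h3 <- adf(fr3, c("Hw", "Cc", "Hw"), 0.15, 0.15)
  expect_lt(abs(h3$theta[which.max(h3$count)] - 109.47), 2)
  # no qualifying triplets: flagged empty
  h4 <- adf(fr, c("Ow", "Oc", "Hw"), 0.05, 0.05)
  expect_true(h4$empty)
})

test_that("local density matches hand-computed mass over volume", {
  # single isolated Ca: one ion mass in the 0.9 nm sphere
  fr <- traj_frame(matrix(c(2, 2, 2), 1), "Ca", c(5, 5, 5))
  v_cm3 <- 4 / 3 * pi * 0.9^3 * 1e-21
  expect_equal(local_density(fr), (40.078 / 6.02214076e23) / v_cm3,
               tolerance = 1e-9)
  # planted pair: Ca + one carbonate unit within the radius
  co3 <- rbind(c(2.3, 2, 2), c(2.429, 2, 2), c(2.3 - 0.0645, 2.1117, 2),
               c(2.3 - 0.0645, 2 - 0.1117, 2))
  fr2 <- traj_frame(rbind(c(2, 2, 2), co3), c("Ca", "Cc", "Oc", "Oc", "Oc"),
                    c(5, 5, 5), mol = c(1, 2, 2, 2, 2))
  expect_equal(local_density(fr2),
               ((40.078 + 60.009) / 6.02214076e23) / v_cm3, tolerance = 1e-9)
  # uniform ion mixture approaches the bulk mass density
  sol <- gen_ion_solution(n_ca = 120, n_co3 = 120, box_edge = 6,
                          min_sep = 0.4, seed = 11)
  bulk <- (120 * (40.078 + 60.009) / 6.02214076e23) / (6^3 * 1e-21)
  expect_equal(local_density(sol), bulk, tolerance = 0.15)
  expect_error(local_density(fr, radius = 3), "half")
})

test_that("Shrake-Rupley SASA matches closed forms and symmetry", {
  fr <- traj_frame(matrix(c(1, 1, 1), 1), "Ca", c(5, 5, 5))
  s <- sasa(fr, radii = c(Ca = 0.2), probe = 0.14)
  expect_equal(s$total, 4 * pi * 0.34^2, tolerance = 1e-12)
  # atom fully enclosed inside a larger sphere exposes nothing
  fr2 <- traj_frame(rbind(c(1, 1, 1), c(1.01, 1, 1)), c("Hw", "Ca"),
                    c(5, 5, 5))
  s2 <- sasa(fr2, radii = c(Hw = 0.05, Ca = 0.4), probe = 0.14)
  expect_equal(s2$area[1], 0)
  # two equal spheres against the spherical-cap closed form within 1%
  R <- 0.34
  for (d in c(0.2, 0.3, 0.5)) {
    frd <- traj_frame(rbind(c(1, 1, 1), c(1 + d, 1, 1)), c("Ca", "Ca"),
                      c(5, 5, 5))
    sd <- sasa(frd, radii = c(Ca = 0.2), probe = 0.14)
    analytic <- 2 * (4 * pi * R^2 - 2 * pi * R * (R - d / 2))
    expect_equal(sd$total, analytic, tolerance = 0.01)
  }
  # rigid translation + rotation leave the total invariant (same point set)
  set.seed(7)
  cluster <- matrix(runif(3 * 8, 2, 2.6), ncol = 3)
  fra <- traj_frame(cluster, rep("Ca", 8), c(8, 8, 8))
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  frb <- traj_frame(sweep(cluster %*% rot, 2, c(1.2, 0.4, 2.0), "+"),
                    rep("Ca", 8), c(8, 8, 8))
  sa <- sasa(fra, radii = c(Ca = 0.2))
  sb <- sasa(frb, radii = c(Ca = 0.2))
  expect_equal(sb$total, sa$total, tolerance = 0.01)
  # bringing two atoms closer never increases the total
  d_seq <- c(0.6, 0.4, 0.25, 0.1)
  totals <- vapply(d_seq, function(d) {
    sasa(traj_frame(rbind(c(1, 1, 1), c(1 + d, 1, 1)), c("Ca", "Ca"),
                    c(5, 5, 5)), radii = c(Ca = 0.2))$total
  }, numeric(1))
  expect_true(all(diff(totals) <= 1e-9))
  expect_error(sasa(fr, radii = c(Oc = 0.15), subset = "Ca"), "Ca")
})
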