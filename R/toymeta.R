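#' Desk-scale well-tempered metadynamics on a radial coordinate
#'
#' A one-dimensional overdamped Langevin walker on a model potential,
#' biased with the well-tempered metadynamics protocol (Gaussian hills
#' whose heights decay with the accumulated bias, a quadratic upper wall),
#' plus the standard sum-of-hills free-energy reconstruction
#' `F(s) = -(gamma/(gamma-1)) V_bias(s)`. This is a surrogate for the full
#' molecular-dynamics engine: it exercises every downstream formula of the
#' profile-to-association-constant pipeline with known ground truth.
#'
#' @name toymeta
NULL

#' Well-tempered metadynamics protocol parameters
#'
#' Defaults follow the biasing protocol used for the Ca-carboxylate
#' profiles: 1.0 kJ/mol hills of width 0.02 nm every 10 ps, bias factor
#' 10, upper wall at 1.6 nm with force constant 2000 kJ/(mol nm^2),
#' 300 K.
#'
#' @param hill_height initial hill height w0 in kJ/mol.
#' @param hill_width Gaussian hill width in nm.
#' @param deposit_every deposition period in ps.
#' @param bias_factor well-tempering factor gamma (> 1).
#' @param wall_position upper-wall position in nm.
#' @param wall_kappa wall force constant in kJ/(mol nm^2).
#' @param temperature temperature in K.
#' @return An object of class `metad_protocol`.
#' @export
metad_protocol <- function(hill_height = 1.0, hill_width = 0.02,
                           deposit_every = 10, bias_factor = 10,
                           wall_position = 1.6, wall_kappa = 2000,
                           temperature = 300) {
  stopifnot(hill_height >= 0, hill_width > 0, deposit_every > 0,
            bias_factor > 1, wall_position > 0, wall_kappa >= 0,
            temperature > 0)
  structure(list(hill_height = hill_height, hill_width = hill_width,
                 deposit_every = deposit_every, bias_factor = bias_factor,
                 wall_position = wall_position, wall_kappa = wall_kappa,
                 temperature = temperature),
            class = "metad_protocol")
}

#' Analytic model potential of Gaussian wells
#'
#' `U(s) = sum_i depth_i exp(-(s - c_i)^2 / (2 w_i^2))`, optionally plus
#' the radial entropic term `-2 R T ln(s)` when the potential is meant as
#' a 3D pair potential rather than the free energy along s directly.
#'
#' @param wells data frame with columns `center` (nm), `depth` (kJ/mol,
#'   negative for wells) and `width` (nm); may have zero rows.
#' @param jacobian add the `-2 R T ln(s)` radial term (default `FALSE`).
#' @param temperature temperature in K for the Jacobian term.
#' @param domain_max wells must sit inside `(0, domain_max]`.
#' @return A vectorized function `U(s)` in kJ/mol.
#' @export
model_potential <- function(wells = data.frame(center = numeric(0),
                                               depth = numeric(0),
                                               width = numeric(0)),
                            jacobian = FALSE, temperature = 300,
                            domain_max = 1.6) {
  stopifnot(is.data.frame(wells))
  if (nrow(wells)) {
    stopifnot(all(c("center", "depth", "width") %in% names(wells)),
              all(wells$width > 0))
    if (any(wells$center <= 0 | wells$center > domain_max)) {
      stop("well centers must lie in (0, ", domain_max, "]")
    }
  }
  force(jacobian); force(temperature)
  function(s) {
    u <- numeric(length(s))
    for (i in seq_len(nrow(wells))) {
      u <- u + wells$depth[i] *
        exp(-(s - wells$center[i])^2 / (2 * wells$width[i]^2))
    }
    if (jacobian) u <- u - 2 * gas_constant_kj() * temperature * log(pmax(s, 1e-12))
    u
  }
}

#' Run a well-tempered metadynamics Langevin simulation
#'
#' Overdamped Langevin dynamics
#' `ds = D F(s) / (R T) dt + sqrt(2 D dt) xi` with
#' `F = -dU/ds - dV_bias/ds - dV_wall/ds`. Hills are deposited with the
#' well-tempered height `w0 exp(-V_bias(s) / ((gamma - 1) R T))`; the wall
#' is `kappa (s - s_wall)^2` beyond its position. The bias and its force
#' live on a fine grid (analytically accumulated Gaussians, linear
#' interpolation in between). A reflecting boundary at `s_min` keeps the
#' radial coordinate positive. Fully reproducible under a fixed seed.
#'
#' @param U model potential function (kJ/mol), e.g. [model_potential()].
#' @param protocol a `metad_protocol`.
#' @param steps number of integration steps.
#' @param dt time step in ps (default 0.02; stable when
#'   `D dt / (R T) * max|U''| << 1` for the stiffest feature).
#' @param seed integer RNG seed.
#' @param s0 initial position in nm.
#' @param diffusion walker diffusion coefficient in nm^2/ps.
#' @param s_min reflecting lower boundary in nm.
#' @param grid_spacing bias-grid spacing in nm.
#' @return A list with `s` (visited positions, one per step), `hills`
#'   (data frame `time`, `center`, `sigma`, `height`, `biasf`), `protocol`,
#'   `dt`.
#' @export
langevin_metad_run <- function(U, protocol = metad_protocol(), steps = 2e5,
                               dt = 0.02, seed = 1, s0 = 0.5,
                               diffusion = 0.1, s_min = 0.05,
                               grid_spacing = 0.002) {
  stopifnot(is.function(U), inherits(protocol, "metad_protocol"),
            steps >= 1, dt > 0, diffusion > 0)
  RT <- gas_constant_kj() * protocol$temperature
  s_max <- protocol$wall_position + 0.5
  grid <- seq(s_min, s_max, by = grid_spacing)
  ng <- length(grid)
  ## base force -dU/ds on the grid (central differences)
  u <- U(grid)
  if (any(!is.finite(u))) stop("model potential non-finite on the domain")
  f_base <- numeric(ng)
  f_base[2:(ng - 1)] <- -(u[3:ng] - u[1:(ng - 2)]) / (2 * grid_spacing)
  f_base[1] <- f_base[2]; f_base[ng] <- f_base[ng - 1]
  v_bias <- numeric(ng); f_bias <- numeric(ng)
  dep_stride <- max(1L, round(protocol$deposit_every / dt))
  n_hills_max <- floor(steps / dep_stride) + 1L
  hills <- list(time = numeric(n_hills_max), center = numeric(n_hills_max),
                height = numeric(n_hills_max))
  nh <- 0L
  set.seed(as.integer(seed))
  noise <- stats::rnorm(steps, sd = sqrt(2 * diffusion * dt))
  mob <- diffusion / RT * dt
  s <- s0
  traj <- numeric(steps)
  w2 <- protocol$hill_width^2
  for (k in seq_len(steps)) {
    ## linear interpolation of force on the grid
    x <- (s - s_min) / grid_spacing
    i0 <- min(max(floor(x), 0), ng - 2)
    frac <- x - i0
    f <- (f_base[i0 + 1] + f_bias[i0 + 1]) * (1 - frac) +
      (f_base[i0 + 2] + f_bias[i0 + 2]) * frac
    if (s > protocol$wall_position) {
      f <- f - 2 * protocol$wall_kappa * (s - protocol$wall_position)
    }
    if (!is.finite(f)) {
      stop(sprintf("non-finite force at step %d, s = %.4f", k, s))
    }
    s <- s + mob * f + noise[k]
    if (s < s_min) s <- 2 * s_min - s            # reflect
    if (s > s_max) s <- 2 * s_max - s
    traj[k] <- s
    if (protocol$hill_height > 0 && k %% dep_stride == 0L) {
      ib <- min(max(round((s - s_min) / grid_spacing) + 1, 1), ng)
      h <- protocol$hill_height *
        exp(-v_bias[ib] / ((protocol$bias_factor - 1) * RT))
      gaus <- exp(-(grid - s)^2 / (2 * w2))
      v_bias <- v_bias + h * gaus
      f_bias <- f_bias + h * gaus * (grid - s) / w2   # -d(h gaus)/ds
      nh <- nh + 1L
      hills$time[nh] <- k * dt; hills$center[nh] <- s; hills$height[nh] <- h
    }
  }
  hills_df <- data.frame(time = hills$time[seq_len(nh)],
                         center = hills$center[seq_len(nh)],
                         sigma = rep(protocol$hill_width, nh),
                         height = hills$height[seq_len(nh)],
                         biasf = rep(protocol$bias_factor, nh))
  list(s = traj, hills = hills_df, protocol = protocol, dt = dt)
}

#' Reconstruct the free-energy profile from deposited hills
#'
#' Standard well-tempered sum-of-hills estimator: the accumulated bias is
#' evaluated analytically on the grid and scaled,
#' `F(s) = -(gamma/(gamma-1)) V_bias(s)`. In the `gamma -> Inf` limit the
#' scaling factor tends to 1 (standard metadynamics).
#'
#' @param hills data frame with columns `center`, `sigma`, `height` (the
#'   `hills` component of [langevin_metad_run()], or read from a HILLS
#'   file).
#' @param grid distance grid in nm (>= 10 points).
#' @param bias_factor well-tempering factor gamma.
#' @param temperature temperature in K attached to the profile.
#' @param average_tail fraction of the deposition history over which the
#'   running estimate is time-averaged (default 0.5). The instantaneous
#'   sum-of-hills estimate oscillates around the converged profile by
#'   roughly a thermal energy; averaging the running estimate over the
#'   last part of the run damps that oscillation. `0` gives the
#'   final-bias (instantaneous) estimate.
#' @return An `fes_profile` (unnormalized).
#' @export
fes_from_hills <- function(hills, grid, bias_factor = 10, temperature = 300,
                           average_tail = 0.5) {
  stopifnot(is.data.frame(hills),
            all(c("center", "sigma", "height") %in% names(hills)))
  if (!nrow(hills)) stop("no hills to sum")
  stopifnot(bias_factor > 1, average_tail >= 0, average_tail < 1)
  nh <- nrow(hills)
  k0 <- max(1L, nh - floor(average_tail * nh) + 1L)
  v <- numeric(length(grid))
  vsum <- numeric(length(grid)); navg <- 0L
  for (i in seq_len(nh)) {
    v <- v + hills$height[i] *
      exp(-(grid - hills$center[i])^2 / (2 * hills$sigma[i]^2))
    if (i >= k0) { vsum <- vsum + v; navg <- navg + 1L }
  }
  vbar <- if (average_tail > 0) vsum / navg else v
  scale <- bias_factor / (bias_factor - 1)
  fes_profile(grid, -scale * vbar, temperature = temperature)
}

#' Write hills in the PLUMED HILLS dialect
#'
#' @param hills data frame with `time`, `center`, `sigma`, `height`,
#'   `biasf`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_hills <- function(hills, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("#! FIELDS time center sigma height biasf", con)
  writeLines(sprintf("%.4f %.8f %.8f %.8f %.1f", hills$time, hills$center,
                     hills$sigma, hills$height, hills$biasf), con)
  invisible(path)
}

#' Read a PLUMED-dialect HILLS file
#'
#' @param path file path.
#' @return A data frame with `time`, `center`, `sigma`, `height`, `biasf`.
#' @export
read_hills <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  toks <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  m <- do.call(rbind, toks)
  data.frame(time = m[, 1], center = m[, 2], sigma = m[, 3],
             height = m[, 4], biasf = m[, 5])
}
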