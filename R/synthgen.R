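#' Seeded generators for synthetic inputs
#'
#' Random ion solutions emulating supersaturated CaCO3 starting
#' configurations, trajectories with planted ion clusters of known sizes,
#' and synthetic free-energy profiles built from Gaussian wells. All
#' generators are bit-reproducible under a fixed seed and their outputs
#' satisfy the preconditions of the analysis modules that consume them.
#'
#' @name synthgen
NULL

#' Default simulation box edge (nm)
#'
#' Cube edge of the box holding 15831 water molecules at 1 g/cm^3
#' (volume about 473.6 nm^3, edge about 7.79 nm) — an estimate of the
#' production box, since only the water count is fixed.
#'
#' @return Edge length in nm.
#' @export
default_box_edge <- function() {
  vol_nm3 <- 15831 * 18.01528 / avogadro() * 1e21   # cm^3 -> nm^3
  vol_nm3^(1 / 3)
}

#' Molarity of n solute units in a cubic box
#'
#' @param n number of units.
#' @param box three box edges in nm (or one edge, recycled).
#' @return Concentration in mol/L.
#' @export
solution_molarity <- function(n, box) {
  box <- rep(as.numeric(box), length.out = 3)
  v_litre <- prod(box) * 1e-24
  (n / avogadro()) / v_litre
}

## uniform random rotation matrix (from a random quaternion)
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

## planar D3h carbonate: C at origin, 3 O at 0.129 nm
carbonate_template <- function() {
  ang <- c(0, 2, 4) * pi / 3
  rbind(c(0, 0, 0), cbind(0.129 * cos(ang), 0.129 * sin(ang), 0))
}

#' Generate a random ion solution
#'
#' Ca2+ ions and rigid planar carbonate units (C + 3 O, C-O 0.129 nm,
#' random orientation) placed uniformly at random in a periodic cubic box
#' with a minimum-image minimum-separation rejection between unit centers.
#' Defaults emulate the supersaturated starting solutions: 255 + 255 ions
#' in the [default_box_edge()] box, about 0.89 M in calcium.
#'
#' @param n_ca,n_co3 ion counts (defaults 255 each).
#' @param box_edge cubic box edge in nm; default [default_box_edge()].
#' @param min_sep minimum center-center separation in nm (default 0.45).
#' @param seed integer RNG seed.
#' @param max_tries placement attempts per unit before giving up.
#' @return A `traj_frame` with species `Ca`, `Cc`, `Oc` and molecule ids
#'   grouping carbonate atoms.
#' @export
gen_ion_solution <- function(n_ca = 255, n_co3 = 255,
                             box_edge = default_box_edge(),
                             min_sep = 0.45, seed = 1, max_tries = 2000L) {
  stopifnot(n_ca >= 0, n_co3 >= 0, box_edge > 0, min_sep >= 0)
  set.seed(as.integer(seed))
  box <- rep(box_edge, 3)
  n_units <- n_ca + n_co3
  if (n_units == 0L) {
    return(traj_frame(matrix(numeric(0), 0, 3), character(0), box))
  }
  centers <- matrix(NA_real_, n_units, 3)
  placed <- 0L
  for (u in seq_len(n_units)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- stats::runif(3, 0, box_edge)
      if (placed == 0L ||
          min(mic_distance(cand, centers[seq_len(placed), , drop = FALSE],
                           box)) >= min_sep) {
        ok <- TRUE; break
      }
    }
    if (!ok) {
      stop("packing failed after ", max_tries,
           " tries; use a larger box or smaller min_sep")
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
  }
  pos <- list(); species <- list(); mol <- list()
  tmpl <- carbonate_template()
  mol_id <- 0L
  for (i in seq_len(n_ca)) {
    mol_id <- mol_id + 1L
    pos[[mol_id]] <- centers[i, , drop = FALSE]
    species[[mol_id]] <- "Ca"
    mol[[mol_id]] <- mol_id
  }
  for (i in seq_len(n_co3)) {
    mol_id <- mol_id + 1L
    rot <- random_rotation()
    at <- sweep(tmpl %*% t(rot), 2, centers[n_ca + i, ], "+")
    pos[[mol_id]] <- at
    species[[mol_id]] <- c("Cc", "Oc", "Oc", "Oc")
    mol[[mol_id]] <- rep(mol_id, 4L)
  }
  p <- do.call(rbind, pos)
  p <- p - floor(p / box_edge) * box_edge      # wrap into the box
  traj_frame(p, unlist(species), box, mol = unlist(mol))
}

#' Generate a frame with planted ion clusters and known ground truth
#'
#' Each cluster is grown by random sequential attachment: every new
#' member is placed at `0.9 * contact` from a randomly chosen existing
#' member (so the contact graph is connected by construction), species
#' alternating between `Ca` and `Oc` stand-in ions. Cluster seeds and
#' background singletons are spaced more than `2 * contact + cluster
#' extent` apart so clusters can never merge.
#'
#' @param sizes integer vector of cluster sizes (each >= 2); may be
#'   empty.
#' @param n_singletons number of background single ions.
#' @param contact contact distance in nm (default 0.34); the returned
#'   cutoff table bonds all species pairs at this distance.
#' @param box_edge cubic box edge in nm; chosen automatically when `NULL`.
#' @param seed integer RNG seed.
#' @return A list with `frame` (a `traj_frame`), `truth` (integer vector
#'   of ground-truth cluster sizes, singletons included), `cutoffs` (the
#'   `cutoff_table` under which the truth holds).
#' @export
gen_planted_clusters <- function(sizes = integer(0), n_singletons = 0,
                                 contact = 0.34, box_edge = NULL, seed = 1) {
  sizes <- as.integer(sizes)
  stopifnot(all(sizes >= 2L), n_singletons >= 0, contact > 0)
  set.seed(as.integer(seed))
  n_groups <- length(sizes) + n_singletons
  ## cap each cluster inside a compact ball so groups can never touch
  r_cluster <- function(s) 0.9 * contact * (1 + ceiling(s^(1 / 3)))
  r_max <- if (length(sizes)) max(vapply(sizes, r_cluster, numeric(1))) else 0
  gap <- 2 * r_max + 2.5 * contact
  per_side <- max(1L, ceiling(n_groups^(1 / 3)))
  if (is.null(box_edge)) box_edge <- per_side * gap + gap
  box <- rep(box_edge, 3)
  if (box_edge / per_side <= gap && n_groups > 1L) {
    stop("box too small to keep planted groups separated")
  }
  grid1 <- (seq_len(per_side) - 0.5) * (box_edge / per_side)
  anchors <- as.matrix(expand.grid(grid1, grid1, grid1))
  if (nrow(anchors) < n_groups) stop("box too small for the requested groups")
  anchors <- anchors[sample(nrow(anchors), n_groups), , drop = FALSE]
  pos <- list(); species <- character(0)
  sp_cycle <- c("Ca", "Oc")
  gi <- 0L
  for (s in sizes) {
    gi <- gi + 1L
    rcap <- r_cluster(s)
    members <- matrix(NA_real_, s, 3)
    members[1, ] <- anchors[gi, ]
    for (k in 2:s) {
      repeat {
        base <- members[sample(k - 1L, 1L), ]
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        cand <- base + 0.9 * contact * dir
        if (sqrt(sum((cand - anchors[gi, ])^2)) <= rcap) break
      }
      members[k, ] <- cand
    }
    pos[[gi]] <- members
    species <- c(species, sp_cycle[(seq_len(s) - 1L) %% 2L + 1L])
  }
  for (k in seq_len(n_singletons)) {
    gi <- gi + 1L
    pos[[gi]] <- anchors[gi, , drop = FALSE]
    species <- c(species, sp_cycle[(k - 1L) %% 2L + 1L])
  }
  p <- if (length(pos)) do.call(rbind, pos) else matrix(numeric(0), 0, 3)
  if (nrow(p)) p <- p - floor(p / box_edge) * box_edge
  frame <- traj_frame(p, species, box)
  cutoffs <- cutoff_table("Ca-Oc" = contact, "Ca-Ca" = contact,
                          "Oc-Oc" = contact)
  list(frame = frame,
       truth = sort(c(sizes, rep(1L, n_singletons))),
       cutoffs = cutoffs)
}

#' Generate a synthetic free-energy profile from Gaussian wells
#'
#' Sum of Gaussian wells on a distance grid, optionally with additive
#' Gaussian noise. With the default well positions (the four ion-pair
#' minima near 0.29, 0.35, 0.51 and 0.68 nm) the profile asymptotes to
#' zero beyond 1 nm by construction.
#'
#' @param wells data frame with columns `center` (nm), `depth` (kJ/mol)
#'   and `width` (nm); defaults to four wells at the canonical ion-pair
#'   states.
#' @param grid distance grid in nm (default 0.2 to 1.6 nm, 2 pm spacing).
#' @param noise_sd standard deviation of additive noise in kJ/mol.
#' @param temperature temperature in K.
#' @param seed RNG seed (only used when `noise_sd > 0`).
#' @return An `fes_profile`.
#' @export
gen_fes_profile <- function(wells = data.frame(
                              center = c(0.290, 0.346, 0.513, 0.677),
                              depth = c(-12, -14, -6, -3),
                              width = c(0.02, 0.02, 0.03, 0.03)),
                            grid = seq(0.2, 1.6, by = 0.002),
                            noise_sd = 0, temperature = 300, seed = 1) {
  stopifnot(is.data.frame(wells), all(diff(grid) > 0))
  if (nrow(wells) &&
      any(wells$center < min(grid) | wells$center > max(grid))) {
    stop("well centers must lie inside the grid")
  }
  U <- model_potential(wells, domain_max = max(grid))
  E <- U(grid)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    E <- E + stats::rnorm(length(grid), sd = noise_sd)
  }
  fes_profile(grid, E, temperature = temperature)
}
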