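#' Structural observables on periodic trajectories
#'
#' Radial and angular distribution functions, running coordination
#' numbers, local mass density of mineral ions, and Shrake-Rupley
#' solvent-accessible surface area, all under the minimum-image convention
#' in orthorhombic boxes.
#'
#' @name trajstruct
NULL

## full minimum-image distance matrix between rows of A and rows of B
mic_dist_matrix <- function(A, B, box) {
  d2 <- matrix(0, nrow(A), nrow(B))
  for (k in 1:3) {
    dk <- outer(A[, k], B[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

as_frame_list <- function(traj) {
  if (inherits(traj, "traj_frame")) list(traj) else traj
}

#' Radial distribution function with running coordination integral
#'
#' Standard pair-correlation estimator: pair counts in spherical shells
#' under the minimum-image convention, normalized by the ideal-gas shell
#' expectation at the partner density. The running integral `N(r)` is the
#' average number of partners within r of a center, accumulated from the
#' raw (never smoothed) histogram.
#'
#' @param traj a `traj_frame` or list of frames.
#' @param species_a center species label.
#' @param species_b partner species label (may equal `species_a`).
#' @param r_max histogram range in nm; must not exceed half the smallest
#'   box edge.
#' @param n_bins number of bins (default `r_max / 0.002`).
#' @return An object of class `rdf_result` with fields `r` (bin centers),
#'   `g`, `N`, `pair`, `frames`.
#' @export
rdf <- function(traj, species_a, species_b, r_max, n_bins = NULL) {
  frames <- as_frame_list(traj)
  stopifnot(length(frames) >= 1L)
  box <- frames[[1]]$box
  if (r_max > min(box) / 2 + 1e-12) {
    stop("r_max = ", r_max, " nm exceeds half the smallest box edge (",
         min(box) / 2, " nm)")
  }
  if (is.null(n_bins)) n_bins <- max(10L, round(r_max / 0.002))
  edges <- seq(0, r_max, length.out = n_bins + 1L)
  counts <- numeric(n_bins)
  na_tot <- 0; rho_sum <- 0
  for (fr in frames) {
    ia <- which(fr$species == species_a)
    ib <- which(fr$species == species_b)
    if (!length(ia) || !length(ib)) {
      stop("species not present in frame: ",
           paste(setdiff(c(species_a, species_b), fr$species), collapse = ", "))
    }
    D <- mic_dist_matrix(fr$positions[ia, , drop = FALSE],
                         fr$positions[ib, , drop = FALSE], fr$box)
    if (species_a == species_b) diag(D) <- Inf
    d <- D[D <= r_max]
    if (length(d)) {
      counts <- counts + tabulate(pmin(pmax(ceiling(d / (r_max / n_bins)), 1L),
                                       n_bins), nbins = n_bins)
    }
    n_part <- if (species_a == species_b) length(ib) - 1L else length(ib)
    rho_sum <- rho_sum + n_part / prod(fr$box)
    na_tot <- na_tot + length(ia)
  }
  nf <- length(frames)
  rho <- rho_sum / nf                     # mean partner density per center
  shell <- 4 / 3 * pi * diff(edges^3)
  g <- counts / (na_tot * rho * shell)
  N <- cumsum(counts) / na_tot
  structure(list(r = (edges[-1] + edges[-length(edges)]) / 2, g = g, N = N,
                 edges = edges, pair = c(species_a, species_b), frames = nf,
                 rho_partner = rho),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  cat(sprintf("<rdf_result %s-%s> %d bins to %.3f nm over %d frame(s)\n",
              x$pair[1], x$pair[2], length(x$r), max(x$edges), x$frames))
  invisible(x)
}

#' Presentation-grade smoothed g(r)
#'
#' Cubic spline through the raw histogram bin centers, for display only;
#' all quantitative use (coordination numbers, cluster cutoffs) stays on
#' the raw histogram.
#'
#' @param x an `rdf_result`.
#' @param n number of interpolation points.
#' @return A data frame with columns `r` and `g`.
#' @export
smooth_rdf <- function(x, n = 10L * length(x$r)) {
  stopifnot(inherits(x, "rdf_result"))
  s <- stats::spline(x$r, x$g, n = n)
  data.frame(r = s$x, g = s$y)
}

#' Running coordination number at a cutoff
#'
#' Interpolates the running integral `N(r)` of an RDF at `r_cut`.
#'
#' @param x an `rdf_result`.
#' @param r_cut cutoff distance in nm, within the RDF range.
#' @return The coordination number (dimensionless).
#' @export
coordination_number <- function(x, r_cut) {
  stopifnot(inherits(x, "rdf_result"), is.numeric(r_cut), length(r_cut) == 1L)
  if (r_cut < 0 || r_cut > max(x$edges)) {
    stop("r_cut outside the RDF range [0, ", max(x$edges), "]")
  }
  ## N is cumulative at upper bin edges
  stats::approx(c(0, x$edges[-1]), c(0, x$N), xout = r_cut)$y
}

#' Angular distribution function at a vertex species
#'
#' Histogram of the A-B-C angle (vertex at B) over all triplets with
#' `|AB| <= r_cut_ab` and `|BC| <= r_cut_bc`, in degrees on [0, 180],
#' normalized to unit area. The defaults suit a hydrogen-bond geometry
#' (donor-acceptor 0.35 nm, covalent O-H 0.12 nm).
#'
#' @param traj a `traj_frame` or list of frames.
#' @param triplet character vector `c(A, B, C)` of species labels; the
#'   angle is measured at B.
#' @param r_cut_ab,r_cut_bc neighbor cutoffs in nm.
#' @param n_bins number of angular bins (default 90).
#' @return An object of class `adf_result` with `theta` (bin centers,
#'   degrees), `density` (1/degree), `count` and logical `empty`.
#' @export
adf <- function(traj, triplet, r_cut_ab = 0.35, r_cut_bc = 0.12,
                n_bins = 90L) {
  frames <- as_frame_list(traj)
  stopifnot(length(triplet) == 3L, r_cut_ab > 0, r_cut_bc > 0)
  edges <- seq(0, 180, length.out = n_bins + 1L)
  counts <- numeric(n_bins)
  for (fr in frames) {
    ib <- which(fr$species == triplet[2])
    ia_all <- which(fr$species == triplet[1])
    ic_all <- which(fr$species == triplet[3])
    for (b in ib) {
      pa <- fr$positions[ia_all, , drop = FALSE]
      pc <- fr$positions[ic_all, , drop = FALSE]
      da <- mic_displacement(fr$positions[b, ], pa, fr$box)
      dc <- mic_displacement(fr$positions[b, ], pc, fr$box)
      ra <- sqrt(rowSums(da * da)); rc <- sqrt(rowSums(dc * dc))
      sa <- which(ra > 1e-12 & ra <= r_cut_ab)
      sc <- which(rc > 1e-12 & rc <= r_cut_bc)
      for (i in sa) {
        for (j in sc) {
          if (ia_all[i] == ic_all[j] || ia_all[i] == b || ic_all[j] == b) next
          cosang <- sum(da[i, ] * dc[j, ]) / (ra[i] * rc[j])
          ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
          k <- min(max(ceiling(ang / (180 / n_bins)), 1L), n_bins)
          counts[k] <- counts[k] + 1
        }
      }
    }
  }
  tot <- sum(counts)
  dens <- if (tot > 0) counts / (tot * (180 / n_bins)) else counts
  structure(list(theta = (edges[-1] + edges[-length(edges)]) / 2,
                 density = dens, count = counts, empty = tot == 0,
                 triplet = triplet),
            class = "adf_result")
}

#' @export
print.adf_result <- function(x, ...) {
  cat(sprintf("<adf_result %s-%s-%s> %d triplets%s\n", x$triplet[1],
              x$triplet[2], x$triplet[3], sum(x$count),
              if (x$empty) " (empty)" else ""))
  invisible(x)
}

#' Local mass density of mineral ions around centers
#'
#' For every center ion the total unit mass (center included) within
#' `radius` is divided by the spherical volume, then averaged over centers
#' and frames. Ions are counted as whole units (a carbonate is one unit of
#' 60.009 g/mol located at its carbon), so a planted cluster of known
#' composition gives an exact hand-computable value.
#'
#' @param traj a `traj_frame` or list of frames.
#' @param center_species unit species whose surroundings are probed
#'   (default `"Ca"`).
#' @param included unit species counted inside the sphere (default
#'   `c("Ca", "CO3")`); the center unit itself is always counted.
#' @param radius probe radius in nm (default 0.9); must not exceed half
#'   the smallest box edge.
#' @param unit_masses named masses in g/mol per unit species.
#' @return Mean local density in g/cm^3.
#' @export
local_density <- function(traj, center_species = "Ca",
                          included = c("Ca", "CO3"), radius = 0.9,
                          unit_masses = c(Ca = 40.078, CO3 = 60.009)) {
  frames <- as_frame_list(traj)
  box <- frames[[1]]$box
  if (radius > min(box) / 2 + 1e-12) {
    stop("radius exceeds half the smallest box edge")
  }
  vol_cm3 <- 4 / 3 * pi * radius^3 * 1e-21     # nm^3 -> cm^3
  acc <- 0; n_centers <- 0
  for (fr in frames) {
    u <- ion_units(fr)
    if (!nrow(u$table)) next
    centers <- which(u$table$species == center_species)
    inc <- u$table$species %in% included
    for (ci in centers) {
      d <- mic_distance(u$pos[ci, ], u$pos, fr$box)
      within <- (d <= radius & inc) | seq_len(nrow(u$pos)) == ci
      mass_g <- sum(unit_masses[u$table$species[within]]) / avogadro()
      acc <- acc + mass_g / vol_cm3
      n_centers <- n_centers + 1
    }
  }
  if (n_centers == 0) stop("no centers of species ", center_species)
  acc / n_centers
}

#' Default Bondi-style van der Waals radii (nm)
#'
#' Used by [sasa()] unless overridden; publication-grade numbers should
#' pass an explicit table matched to the force field at hand.
#'
#' @return Named numeric vector of radii in nm.
#' @export
default_sasa_radii <- function() {
  c(Ca = 0.231, O = 0.152, Oc = 0.152, OD = 0.152, Ow = 0.152,
    C = 0.170, Cc = 0.170, N = 0.155, H = 0.120, Hw = 0.120)
}

## deterministic near-uniform points on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Each atom's sphere is expanded by the probe radius and covered with a
#' deterministic near-uniform point set; a point is exposed if it lies
#' outside every other expanded sphere. Neighbors are taken at their
#' minimum image relative to each atom, so a finite cluster in a periodic
#' box is treated as the compact object (no self-image occlusion).
#'
#' @param frame a `traj_frame`.
#' @param radii named van der Waals radii in nm per species; defaults to
#'   [default_sasa_radii()].
#' @param probe probe radius in nm (default 0.14, a water molecule).
#' @param n_points test points per sphere (default 960).
#' @param subset species labels to include (default: all species with a
#'   radius entry present in the frame).
#' @return An object of class `sasa_result` with `area` (per-atom, nm^2),
#'   `total` (nm^2), `probe`, `n_points`, `atoms` (indices used).
#' @export
sasa <- function(frame, radii = default_sasa_radii(), probe = 0.14,
                 n_points = 960L, subset = NULL) {
  stopifnot(inherits(frame, "traj_frame"), probe >= 0, n_points >= 12L)
  if (is.null(subset)) subset <- intersect(unique(frame$species), names(radii))
  idx <- which(frame$species %in% subset)
  missing <- setdiff(unique(frame$species[idx]), names(radii))
  if (length(missing)) {
    stop("no radius for species: ", paste(missing, collapse = ", "))
  }
  if (!length(idx)) {
    return(structure(list(area = numeric(0), total = 0, probe = probe,
                          n_points = n_points, atoms = integer(0)),
                     class = "sasa_result"))
  }
  pts <- fibonacci_sphere(n_points)
  R <- radii[frame$species[idx]] + probe
  pos <- frame$positions[idx, , drop = FALSE]
  area <- numeric(length(idx))
  for (a in seq_along(idx)) {
    disp <- mic_displacement(pos[a, ], pos, frame$box)
    dn <- sqrt(rowSums(disp * disp))
    nb <- which(dn > 1e-12 & dn < R[a] + R)
    sphere <- pts * R[a]
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dd <- sweep(sphere, 2, disp[j, ], "-")
      exposed <- exposed & rowSums(dd * dd) >= R[j]^2
      if (!any(exposed)) break
    }
    area[a] <- mean(exposed) * 4 * pi * R[a]^2
  }
  structure(list(area = area, total = sum(area), probe = probe,
                 n_points = n_points, atoms = idx),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> %d atoms, total = %.4f nm^2 (probe %.2f nm, %d points)\n",
              length(x$area), x$total, x$probe, x$n_points))
  invisible(x)
}
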