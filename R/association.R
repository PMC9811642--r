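#' Free-energy profiles and ion-pair association constants
#'
#' A one-dimensional free-energy profile along the cation-ligand distance
#' is normalized so its dissociated plateau sits at zero, converted into an
#' infinite-dilution radial distribution function
#' `g(r) = exp(-E(r) / (R T))`, and integrated to the association constant
#' `K_a = integral_0^R_U 4 pi r^2 g(r) dr`. The upper limit `R_U` is the
#' first local minimum of `g(r)` beyond the solvent-shared-ion-pair maximum,
#' i.e. the boundary of the dissociated state. `K_a` is reported both as a
#' volume (nm^3) and on a 1 M standard state, and converted to a free energy
#' of association via `dG = -R T ln(K_a)`.
#'
#' @name association
NULL

#' Construct a free-energy profile
#'
#' @param r strictly increasing distance grid in nm (>= 10 points).
#' @param E free energies in kJ/mol, one per grid point.
#' @param temperature temperature in K (default 300).
#' @param normalized whether the dissociated plateau has already been set
#'   to zero; set by [normalize_profile()].
#' @return An object of class `fes_profile`.
#' @export
fes_profile <- function(r, E, temperature = 300, normalized = FALSE) {
  r <- as.numeric(r); E <- as.numeric(E)
  if (length(r) < 10L) stop("profile needs >= 10 grid points")
  if (length(r) != length(E)) stop("`r` and `E` lengths differ")
  if (any(!is.finite(r)) || any(!is.finite(E))) stop("non-finite profile values")
  if (any(diff(r) <= 0)) stop("`r` must be strictly increasing")
  stopifnot(is.numeric(temperature), temperature > 0)
  structure(list(r = r, E = E, temperature = temperature,
                 normalized = isTRUE(normalized)),
            class = "fes_profile")
}

#' @export
print.fes_profile <- function(x, ...) {
  cat(sprintf("<fes_profile> %d points on [%.3f, %.3f] nm, T = %g K%s\n",
              length(x$r), min(x$r), max(x$r), x$temperature,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Zero a profile on its dissociated plateau
#'
#' The mean energy over the window (default 1.0-1.4 nm, the region where
#' the ion pair is fully dissolved) is subtracted from the whole profile,
#' so the dissociated plateau averages zero. Idempotent.
#'
#' @param p an `fes_profile`.
#' @param window two-element numeric, the averaging window in nm.
#' @return A normalized `fes_profile`.
#' @export
normalize_profile <- function(p, window = c(1.0, 1.4)) {
  stopifnot(inherits(p, "fes_profile"),
            is.numeric(window), length(window) == 2L, window[1] < window[2])
  sel <- p$r >= window[1] & p$r <= window[2]
  if (!any(sel)) {
    stop("normalization window [", window[1], ", ", window[2],
         "] nm lies outside the profile grid")
  }
  shift <- mean(p$E[sel])
  fes_profile(p$r, p$E - shift, temperature = p$temperature, normalized = TRUE)
}

#' Convert a normalized profile into an ideal-dilution g(r)
#'
#' `g(r) = exp(-E(r) / (R T))` pointwise, with R the molar gas constant in
#' kJ/(mol K). Requires an explicitly normalized profile: the Boltzmann
#' inversion is only meaningful once the dissociated plateau sits at zero.
#'
#' @param p a normalized `fes_profile`.
#' @return An object of class `gid_table` with fields `r` (nm), `g` and
#'   `temperature`.
#' @export
profile_to_gid <- function(p) {
  stopifnot(inherits(p, "fes_profile"))
  if (!p$normalized) {
    stop("profile must be normalized first (see normalize_profile())")
  }
  g <- exp(-p$E / (gas_constant_kj() * p$temperature))
  structure(list(r = p$r, g = g, temperature = p$temperature),
            class = "gid_table")
}

#' Locate the dissociation boundary R_U in g(r)
#'
#' The dissociated state begins at the first strict local minimum of
#' `g(r)` beyond the solvent-shared-ion-pair maximum (the last local
#' maximum at or below `sip_max_hint`). When the tail holds no minimum the
#' configured fallback is returned with `fallback = TRUE`.
#'
#' @param g a `gid_table`.
#' @param sip_max_hint position (nm) near which the SIP maximum is
#'   expected; default 0.8.
#' @param fallback distance (nm) returned when no tail minimum exists.
#' @return A list with `R_U` (nm) and logical `fallback`.
#' @export
detect_RU <- function(g, sip_max_hint = 0.8, fallback = 1.0) {
  stopifnot(inherits(g, "gid_table"))
  n <- length(g$r)
  if (n < 3L) stop("g(r) grid too short")
  interior <- 2:(n - 1)
  is_max <- g$g[interior] > g$g[interior - 1] & g$g[interior] > g$g[interior + 1]
  max_idx <- interior[is_max]
  max_idx <- max_idx[g$r[max_idx] <= sip_max_hint]
  if (!length(max_idx)) {
    stop("no SIP structure: no local maximum of g(r) at or below ",
         sip_max_hint, " nm")
  }
  sip <- max(max_idx)
  is_min <- g$g[interior] < g$g[interior - 1] & g$g[interior] < g$g[interior + 1]
  min_idx <- interior[is_min]
  min_idx <- min_idx[min_idx > sip]
  if (!length(min_idx)) {
    return(list(R_U = fallback, fallback = TRUE))
  }
  list(R_U = g$r[min(min_idx)], fallback = FALSE)
}

#' Association constant from g(r) by radial integration
#'
#' `K_a = integral_0^R_U 4 pi r^2 g(r) dr` with a composite trapezoid on
#' the native grid. Below the first grid point g is taken as zero (the
#' hard-core region), so integration effectively starts at `r[1]`; a
#' partial trapezoid handles `R_U` between grid points. The volume form
#' (nm^3) is converted to a 1 M standard state via `N_A / 10^24`.
#'
#' @param g a `gid_table`.
#' @param R_U upper integration limit in nm, inside the grid.
#' @return A list with `Ka_volume` (nm^3) and `Ka_molar` (dimensionless on
#'   the 1 M standard state; numerically 1/M).
#' @export
association_constant <- function(g, R_U) {
  stopifnot(inherits(g, "gid_table"),
            is.numeric(R_U), length(R_U) == 1L, is.finite(R_U))
  r <- g$r
  if (R_U > max(r) || R_U <= min(r)) {
    stop("R_U = ", R_U, " nm is outside the g(r) grid [",
         min(r), ", ", max(r), "]")
  }
  y <- 4 * pi * r^2 * g$g
  sel <- r <= R_U
  ka <- pracma::trapz(r[sel], y[sel])
  ## partial trapezoid between the last grid point inside and R_U
  i <- max(which(sel))
  if (r[i] < R_U) {
    yR <- y[i] + (y[i + 1] - y[i]) * (R_U - r[i]) / (r[i + 1] - r[i])
    ka <- ka + (R_U - r[i]) * (y[i] + yR) / 2
  }
  list(Ka_volume = ka, Ka_molar = ka * avogadro() / 1e24)
}

#' Free energy of association from a molar association constant
#'
#' `dG = -R T ln(K_a)` with R the molar gas constant.
#'
#' @param Ka_molar dimensionless association constant (1 M standard state).
#' @param T temperature in K.
#' @return Free energy of association in kJ/mol (negative for Ka > 1).
#' @examples
#' delta_g(65.46, 300)  # about -10.4 kJ/mol
#' @export
delta_g <- function(Ka_molar, T = 300) {
  stopifnot(is.numeric(Ka_molar), is.numeric(T), T > 0)
  if (any(Ka_molar <= 0)) stop("`Ka_molar` must be > 0")
  -gas_constant_kj() * T * log(Ka_molar)
}

#' Default ion-pair state windows
#'
#' Distance intervals (nm) assigning local minima of the free-energy
#' profile to ion-pair states: bidentate contact pair (biCIP), monodentate
#' contact pair (monoCIP), solvent-shared pair (SIP) and solvent-separated
#' pair (SSIP). Defaults are read off the reported minima positions
#' (0.290, 0.346, 0.513, 0.677 nm) and fully overridable.
#'
#' @param biCIP,monoCIP,SIP,SSIP two-element numeric intervals in nm.
#' @return An object of class `state_windows`.
#' @export
state_windows <- function(biCIP = c(0.0, 0.31), monoCIP = c(0.31, 0.40),
                          SIP = c(0.40, 0.65), SSIP = c(0.65, 0.85)) {
  w <- list(biCIP = biCIP, monoCIP = monoCIP, SIP = SIP, SSIP = SSIP)
  for (nm in names(w)) {
    iv <- w[[nm]]
    if (!is.numeric(iv) || length(iv) != 2L || iv[1] >= iv[2]) {
      stop("window `", nm, "` must be an increasing 2-vector")
    }
  }
  ord <- order(vapply(w, `[`, numeric(1), 1))
  w <- w[ord]
  lo <- vapply(w, `[`, numeric(1), 1)
  hi <- vapply(w, `[`, numeric(1), 2)
  if (any(lo[-1] < hi[-length(hi)])) stop("state windows overlap")
  structure(w, class = "state_windows")
}

#' Find and label local minima of a free-energy profile
#'
#' Strict three-point local minima at least `prominence` kJ/mol below the
#' normalized baseline (zero) are reported with their position, depth and
#' the state window they fall in. Ties and plateaus resolve toward
#' smaller r.
#'
#' @param p a normalized `fes_profile`.
#' @param windows a `state_windows` object.
#' @param prominence minimum depth below baseline in kJ/mol (default 0.5),
#'   suppressing sampling noise.
#' @return A data frame with columns `position` (nm), `depth` (kJ/mol,
#'   profile value at the minimum) and `state`.
#' @export
classify_minima <- function(p, windows = state_windows(), prominence = 0.5) {
  stopifnot(inherits(p, "fes_profile"), inherits(windows, "state_windows"))
  if (!p$normalized) stop("profile must be normalized first")
  E <- p$E; n <- length(E)
  idx <- which(E[2:(n - 1)] < E[1:(n - 2)] & E[2:(n - 1)] < E[3:n]) + 1L
  idx <- idx[E[idx] <= -prominence]
  if (!length(idx)) {
    return(data.frame(position = numeric(0), depth = numeric(0),
                      state = character(0), stringsAsFactors = FALSE))
  }
  pos <- p$r[idx]
  state <- vapply(pos, function(x) {
    for (nm in names(windows)) {
      iv <- windows[[nm]]
      if (x >= iv[1] && x < iv[2]) return(nm)
    }
    "unassigned"
  }, character(1))
  data.frame(position = pos, depth = E[idx], state = state,
             stringsAsFactors = FALSE)
}

#' Full free-energy-profile to association-constant pipeline
#'
#' Runs normalization, Boltzmann inversion to `g(r)`, dissociation-boundary
#' detection, radial integration to `K_a`, conversion to `dG`, and minima
#' classification. Deterministic for fixed input.
#'
#' @param p an `fes_profile` (raw or already normalized).
#' @param T temperature in K; defaults to the profile's.
#' @param windows a `state_windows` object.
#' @param sip_max_hint,ru_fallback passed to [detect_RU()]; when the g(r)
#'   tail is featureless (no SIP structure at all) `ru_fallback` is used
#'   and flagged.
#' @return An object of class `association_result`: a list with
#'   `Ka_volume` (nm^3), `Ka_molar`, `dG` (kJ/mol), `R_U` (nm),
#'   `R_U_fallback` (logical), `minima` (data frame) and `temperature`.
#' @export
association_report <- function(p, T = NULL, windows = state_windows(),
                               sip_max_hint = 0.8, ru_fallback = 1.0) {
  stopifnot(inherits(p, "fes_profile"))
  if (!is.null(T)) p <- fes_profile(p$r, p$E, temperature = T,
                                    normalized = p$normalized)
  if (!p$normalized) {
    p <- tryCatch(normalize_profile(p),
                  error = function(e) stop("normalize: ", conditionMessage(e)))
  }
  g <- profile_to_gid(p)
  ru <- tryCatch(detect_RU(g, sip_max_hint = sip_max_hint,
                           fallback = ru_fallback),
                 error = function(e) list(R_U = ru_fallback, fallback = TRUE))
  ka <- tryCatch(association_constant(g, ru$R_U),
                 error = function(e) stop("Ka: ", conditionMessage(e)))
  res <- list(Ka_volume = ka$Ka_volume, Ka_molar = ka$Ka_molar,
              dG = delta_g(ka$Ka_molar, p$temperature),
              R_U = ru$R_U, R_U_fallback = ru$fallback,
              minima = classify_minima(p, windows),
              temperature = p$temperature)
  class(res) <- "association_result"
  res
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result> T = %g K\n", x$temperature))
  cat(sprintf("  Ka = %.4g nm^3 = %.4g (1 M std state)\n",
              x$Ka_volume, x$Ka_molar))
  cat(sprintf("  dG_association = %.2f kJ/mol\n", x$dG))
  cat(sprintf("  R_U = %.3f nm%s\n", x$R_U,
              if (x$R_U_fallback) " (fallback)" else ""))
  if (nrow(x$minima)) {
    cat("  minima:\n")
    for (i in seq_len(nrow(x$minima))) {
      cat(sprintf("    %.3f nm  %7.2f kJ/mol  %s\n", x$minima$position[i],
                  x$minima$depth[i], x$minima$state[i]))
    }
  }
  invisible(x)
}
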