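#' Lennard-Jones parameter containers and mixing rules
#'
#' The functions in this file house, convert, mix and refine 12-6
#' Lennard-Jones parameter sets for Ca2+ and AMBER-style carboxylate
#' oxygens. Internal units are eV for well depths and Angstrom for
#' diameters; constructors accept kcal/mol with an explicit unit tag.
#'
#' @name forcefield
NULL

#' Construct a homoatomic Lennard-Jones parameter set
#'
#' @param epsilon well depth, `>= 0`.
#' @param sigma zero-crossing diameter in Angstrom, `> 0`.
#' @param label free-text label, e.g. `"Set_1"`.
#' @param epsilon_unit `"eV"` (default) or `"kcal/mol"`; kcal/mol input is
#'   converted on construction so that stored values are always eV.
#' @return An object of class `lj_params` with fields `epsilon` (eV),
#'   `sigma` (Angstrom) and `label`.
#' @examples
#' lj_params(0.019937830, 3.426200, label = "Set_1")
#' lj_params(0.2100, 2.9599219, label = "OD", epsilon_unit = "kcal/mol")
#' @export
lj_params <- function(epsilon, sigma, label = "",
                      epsilon_unit = c("eV", "kcal/mol")) {
  epsilon_unit <- match.arg(epsilon_unit)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, is.finite(epsilon),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (epsilon_unit == "kcal/mol") epsilon <- kcal_per_mol_to_ev(epsilon)
  if (epsilon < 0) stop("`epsilon` must be >= 0")
  if (sigma <= 0) stop("`sigma` must be > 0")
  structure(list(epsilon = epsilon, sigma = sigma, label = as.character(label)),
            class = "lj_params")
}

#' @export
print.lj_params <- function(x, ...) {
  cat(sprintf("<lj_params %s> epsilon = %.6f eV, sigma = %.6f A\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$epsilon, x$sigma))
  invisible(x)
}

#' Lorentz-Berthelot mixing of two Lennard-Jones parameter sets
#'
#' Arithmetic mean for sigma, geometric mean for epsilon — the combination
#' rule AMBER applies to heteroatomic pairs. Symmetric in its arguments.
#'
#' @param a,b `lj_params` objects (internal units).
#' @param label label for the mixed set; defaults to `"a-b"`.
#' @return An `lj_params` object with the mixed parameters.
#' @export
lorentz_berthelot_mix <- function(a, b, label = NULL) {
  stopifnot(inherits(a, "lj_params"), inherits(b, "lj_params"))
  if (a$epsilon < 0 || b$epsilon < 0) stop("negative epsilon is not mixable")
  if (is.null(label)) label <- paste0(a$label, "-", b$label)
  lj_params(sqrt(a$epsilon * b$epsilon), (a$sigma + b$sigma) / 2, label = label)
}

#' Repulsion and attraction coefficients of a 12-6 potential
#'
#' Converts (epsilon, sigma) into the A/B representation
#' `U(r) = A/r^12 - B/r^6` with `A = 4 eps sigma^12` and
#' `B = 4 eps sigma^6`, so that `A/B = sigma^6`. The A coefficient is the
#' intrinsic Pauli repulsion, B the dispersive attraction.
#'
#' @param p an `lj_params` object (eV, Angstrom).
#' @return An object of class `ab_coefficients` with fields `A`
#'   (eV Angstrom^12), `B` (eV Angstrom^6) and `ratio` (`A/B`, Angstrom^6;
#'   `NA` at zero well depth).
#' @export
ab_coefficients <- function(p) {
  stopifnot(inherits(p, "lj_params"))
  s6 <- p$sigma^6
  A <- 4 * p$epsilon * s6 * s6
  B <- 4 * p$epsilon * s6
  structure(list(A = A, B = B, ratio = if (B > 0) A / B else NA_real_,
                 label = p$label),
            class = "ab_coefficients")
}

#' @export
print.ab_coefficients <- function(x, ...) {
  cat(sprintf("<ab_coefficients %s> A = %.0f, B = %.0f, A/B = %s\n",
              x$label, round(x$A), round(x$B),
              if (is.na(x$ratio)) "NA" else sprintf("%.0f", round(x$ratio))))
  invisible(x)
}

#' Construct a heteroatomic pair interaction
#'
#' @param species_i,species_j species labels; stored in sorted order so the
#'   pair is symmetric under swapping.
#' @param params an `lj_params` object for the pair.
#' @param provenance `"mixed"`, `"override"` or `"scaled"`.
#' @param scale_percent the sigma-scaling percentage recorded when
#'   `provenance == "scaled"`.
#' @return An object of class `pair_interaction`.
#' @export
pair_interaction <- function(species_i, species_j, params,
                             provenance = c("mixed", "override", "scaled"),
                             scale_percent = NA_real_) {
  provenance <- match.arg(provenance)
  stopifnot(inherits(params, "lj_params"))
  if (provenance == "scaled" && !is.finite(scale_percent)) {
    stop("scaled provenance requires `scale_percent`")
  }
  sp <- sort(c(as.character(species_i), as.character(species_j)))
  structure(list(species_i = sp[1], species_j = sp[2], params = params,
                 provenance = provenance, scale_percent = scale_percent),
            class = "pair_interaction")
}

#' @export
print.pair_interaction <- function(x, ...) {
  prov <- x$provenance
  if (prov == "scaled") prov <- sprintf("scaled(%+.1f%%)", x$scale_percent)
  cat(sprintf("<pair_interaction %s-%s [%s]> epsilon = %.6f eV, sigma = %.14f A\n",
              x$species_i, x$species_j, prov, x$params$epsilon, x$params$sigma))
  invisible(x)
}

#' Scale the sigma of a pair interaction by a percentage
#'
#' The stepwise refinement applied to the Ca2+-carboxylate-oxygen pair:
#' `sigma' = sigma * (1 + percent/100)` with epsilon untouched. The applied
#' percentage is recorded in the provenance.
#'
#' @param p a `pair_interaction`.
#' @param percent scaling percentage, `>= -50` (guard against nonsense).
#' @return A new `pair_interaction` with scaled sigma and provenance
#'   `"scaled"`.
#' @examples
#' od <- lj_params(0.2100, 2.9599219, "OD", epsilon_unit = "kcal/mol")
#' ca <- lj_params(0.001104240, 3.247210, "Set_3")
#' pr <- pair_interaction("Ca", "OD", lorentz_berthelot_mix(ca, od))
#' scale_sigma(pr, 0.5)
#' @export
scale_sigma <- function(p, percent) {
  stopifnot(inherits(p, "pair_interaction"),
            is.numeric(percent), length(percent) == 1L, is.finite(percent))
  if (percent < -50) stop("`percent` must be >= -50")
  scaled <- lj_params(p$params$epsilon, p$params$sigma * (1 + percent / 100),
                      label = p$params$label)
  pair_interaction(p$species_i, p$species_j, scaled,
                   provenance = "scaled", scale_percent = percent)
}

#' Build the refined Set_3 calcium description
#'
#' Set_3 is built by averaging the Set_2 calcium parameters with the AMBER
#' carboxylate-oxygen parameters: arithmetic mean for sigma, geometric mean
#' for epsilon. This is the same combination as Lorentz-Berthelot mixing,
#' applied here to produce a *homoatomic* Ca description whose subsequent
#' mixing with the carboxylate oxygen lands the heteroatomic well at the
#' refined position.
#'
#' @param ca_set2 `lj_params` for the Set_2 calcium.
#' @param o_carboxylate `lj_params` for the carboxylate oxygen
#'   (see [amber_carboxylate_oxygen()]).
#' @return `lj_params` labelled `"Set_3"`.
#' @export
build_set3 <- function(ca_set2, o_carboxylate) {
  stopifnot(inherits(ca_set2, "lj_params"), inherits(o_carboxylate, "lj_params"))
  if (ca_set2$epsilon == 0 || o_carboxylate$epsilon == 0) {
    stop("geometric mean of epsilon is degenerate at zero well depth")
  }
  lj_params(sqrt(ca_set2$epsilon * o_carboxylate$epsilon),
            (ca_set2$sigma + o_carboxylate$sigma) / 2,
            label = "Set_3")
}

#' AMBER carboxylate-oxygen Lennard-Jones parameters
#'
#' The homoatomic parameters of the deprotonated carboxylate oxygen (OD)
#' in the AMBER description of aspartate/glutamate: well depth 0.2100
#' kcal/mol and sigma 2.9599219 Angstrom. These are the values consistent
#' with the published Set_3 construction (Set_3 sigma is the arithmetic
#' mean of the Set_2 and OD sigmas; Set_3 epsilon their geometric mean).
#'
#' @return `lj_params` labelled `"OD"` (epsilon stored in eV).
#' @export
amber_carboxylate_oxygen <- function() {
  lj_params(0.2100, 2.95992190164468, label = "OD", epsilon_unit = "kcal/mol")
}

#' Published calcium Lennard-Jones parameter sets
#'
#' The twelve literature descriptions of Ca2+ compared in this package,
#' as (epsilon, sigma) pairs in eV and Angstrom, including the CaCO3-derived
#' Set_2 and the refined Set_3.
#'
#' @return A data frame with columns `source`, `acronym`, `epsilon` (eV)
#'   and `sigma` (Angstrom).
#' @export
ca_parameter_table <- function() {
  data.frame(
    source = c("Hornak 2006", "Mamatkulov 2013 (AMBER)", "Aqvist 1990",
               "Wang 2008", "Mamatkulov 2013", "Martinek 2017",
               "Beglov 1994 (CHARMM)", "Dang 1995", "Shen",
               "Babu and Lim 2006", "CaCO3-derived", "Adjusted Set_2"),
    acronym = c("Set_1", "", "", "", "", "", "", "", "", "", "Set_2", "Set_3"),
    epsilon = c(0.019937830, 0.019899403, 0.019692117, 0.011457217,
                0.009742416, 0.005256800, 0.005182136, 0.004336300,
                0.003316575, 0.001243713, 0.000133902, 0.001104240),
    sigma = c(3.426200, 3.050000, 2.410000, 2.789015, 2.410000, 2.819600,
              2.430000, 2.895000, 2.450000, 3.250000, 3.534508, 3.247210),
    stringsAsFactors = FALSE
  )
}

#' Tabulate repulsion/attraction coefficients for a set of LJ parameters
#'
#' Presentation layer over [ab_coefficients()]: A, B and A/B rounded to
#' integers, epsilon/sigma at 6 decimals.
#'
#' @param tab a data frame with columns `epsilon` and `sigma` (and
#'   optionally `source`/`acronym`); defaults to [ca_parameter_table()].
#' @return A data frame adding integer-rounded columns `A`, `B`, `A_over_B`.
#' @export
lj_coefficient_table <- function(tab = ca_parameter_table()) {
  stopifnot(is.data.frame(tab), all(c("epsilon", "sigma") %in% names(tab)))
  ab <- lapply(seq_len(nrow(tab)), function(i) {
    ab_coefficients(lj_params(tab$epsilon[i], tab$sigma[i]))
  })
  tab$A <- round(vapply(ab, `[[`, numeric(1), "A"))
  tab$B <- round(vapply(ab, `[[`, numeric(1), "B"))
  tab$A_over_B <- round(vapply(ab, function(x) x$ratio, numeric(1)))
  tab
}

#' Assemble a force-field set of homoatomic species and pair overrides
#'
#' @param homoatomic named list of `lj_params`, one per species.
#' @param overrides list of `pair_interaction` objects; each may reference
#'   species absent from `homoatomic` only if listed in `external`.
#' @param external character vector of species declared external (parameters
#'   owned by another force field, e.g. the biomolecule side).
#' @return An object of class `forcefield_set`.
#' @export
forcefield_set <- function(homoatomic = list(), overrides = list(),
                           external = character()) {
  stopifnot(is.list(homoatomic), is.list(overrides))
  if (length(homoatomic)) {
    stopifnot(!is.null(names(homoatomic)), all(nzchar(names(homoatomic))))
    lapply(homoatomic, function(p) stopifnot(inherits(p, "lj_params")))
  }
  known <- c(names(homoatomic), external)
  for (ov in overrides) {
    stopifnot(inherits(ov, "pair_interaction"))
    missing <- setdiff(c(ov$species_i, ov$species_j), known)
    if (length(missing)) {
      stop("override references undeclared species: ",
           paste(missing, collapse = ", "))
    }
  }
  structure(list(homoatomic = homoatomic, overrides = overrides,
                 external = external),
            class = "forcefield_set")
}

#' Emit a deterministic engine-ready pair-coefficient listing
#'
#' All homoatomic pairs are mixed with Lorentz-Berthelot rules; overrides
#' (including sigma-scaled refinements) replace the mixed value for their
#' pair. Pairs are sorted canonically so the output is byte-identical
#' regardless of declaration order.
#'
#' @param ff a `forcefield_set`.
#' @return A character vector of lines: a header followed by one
#'   `pair_coeff` line per pair with epsilon (eV), sigma (Angstrom) and a
#'   provenance comment.
#' @export
emit_pair_table <- function(ff) {
  stopifnot(inherits(ff, "forcefield_set"))
  species <- sort(names(ff$homoatomic))
  pairs <- list()
  if (length(species)) {
    for (i in seq_along(species)) {
      for (j in i:length(species)) {
        key <- paste(species[i], species[j], sep = "-")
        mixed <- lorentz_berthelot_mix(ff$homoatomic[[species[i]]],
                                       ff$homoatomic[[species[j]]])
        pairs[[key]] <- list(eps = mixed$epsilon, sig = mixed$sigma,
                             prov = "mixed")
      }
    }
  }
  for (ov in ff$overrides) {
    key <- paste(ov$species_i, ov$species_j, sep = "-")
    prov <- ov$provenance
    if (prov == "scaled") prov <- sprintf("scaled(%+.2f%%)", ov$scale_percent)
    pairs[[key]] <- list(eps = ov$params$epsilon, sig = ov$params$sigma,
                         prov = prov)
  }
  keys <- sort(names(pairs))
  lines <- "# pair  epsilon(eV)  sigma(Angstrom)  provenance"
  for (k in keys) {
    p <- pairs[[k]]
    lines <- c(lines, sprintf("pair_coeff %-12s %.9e %.14f  # %s",
                              k, p$eps, p$sig, p$prov))
  }
  lines
}
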