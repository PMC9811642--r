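#' Ion-cluster detection by coordination-shell connectivity
#'
#' Two ions belong to the same cluster when any of their atoms lie closer
#' than the first-coordination-shell distance of the two species. A
#' carbonate counts as one ion regardless of how many of its atoms make
#' contacts; contacts are evaluated atom-wise. Connected components of the
#' resulting contact graph define the clusters.
#'
#' @name clusterscan
NULL

#' Contact-distance table for species pairs
#'
#' Symmetric lookup of first-coordination-shell distances. Keys are
#' `"A-B"` species pairs (order-insensitive). The default carries the
#' Ca-carbonate-oxygen contact of 0.34 nm (the first minimum of the
#' Ca-Oc RDF); species pairs without an entry are never bonded.
#'
#' @param ... named cutoffs in nm, e.g. `"Ca-Oc" = 0.34`; override or
#'   extend the default.
#' @return An object of class `cutoff_table` (named numeric, canonical
#'   sorted-pair keys).
#' @examples
#' cutoff_table()                         # Ca-Oc = 0.34 only
#' cutoff_table("Ca-Oc" = 0.34, "Ca-Cc" = 0.38)
#' @export
cutoff_table <- function(...) {
  vals <- c(...)
  if (is.null(vals)) vals <- numeric(0)
  defaults <- c("Ca-Oc" = 0.34)
  canon <- function(k) {
    parts <- sort(strsplit(k, "-", fixed = TRUE)[[1]])
    paste(parts, collapse = "-")
  }
  out <- defaults
  names(out) <- vapply(names(out), canon, character(1))
  if (length(vals)) {
    stopifnot(is.numeric(vals), !is.null(names(vals)), all(vals > 0))
    names(vals) <- vapply(names(vals), canon, character(1))
    out[names(vals)] <- vals
  }
  structure(out[sort(names(out))], class = "cutoff_table")
}

#' Look up a pair cutoff (NA when the pair is never bonded)
#' @param cutoffs a `cutoff_table`.
#' @param sp_a,sp_b species labels.
#' @return Cutoff in nm, or `NA` when absent.
#' @export
pair_cutoff <- function(cutoffs, sp_a, sp_b) {
  key <- paste(sort(c(sp_a, sp_b)), collapse = "-")
  if (key %in% names(cutoffs)) unname(cutoffs[[key]]) else NA_real_
}

#' Group the ion atoms of a frame into whole-ion units
#'
#' Atoms with species in `ion_species` are grouped by molecule id. A unit
#' containing a Ca atom is a `"Ca"` unit located at that atom; a unit
#' containing carbonate atoms (Cc/Oc) is a `"CO3"` unit located at its
#' carbon (or first atom when no carbon is present, as for single-atom
#' stand-ins).
#'
#' @param frame a `traj_frame`.
#' @param ion_species species labels regarded as mineral-ion atoms.
#' @return A list with `table` (data frame: `mol`, `species`) , `pos`
#'   (unit representative positions) and `atoms` (list of atom indices per
#'   unit).
#' @export
ion_units <- function(frame, ion_species = c("Ca", "Cc", "Oc")) {
  stopifnot(inherits(frame, "traj_frame"))
  idx <- which(frame$species %in% ion_species)
  if (!length(idx)) {
    return(list(table = data.frame(mol = integer(0), species = character(0)),
                pos = matrix(numeric(0), 0, 3), atoms = list()))
  }
  mols <- split(idx, frame$mol[idx])
  species <- character(length(mols)); rep_atom <- integer(length(mols))
  for (i in seq_along(mols)) {
    at <- mols[[i]]
    sp <- frame$species[at]
    if ("Ca" %in% sp) {
      species[i] <- "Ca"; rep_atom[i] <- at[match("Ca", sp)]
    } else {
      species[i] <- "CO3"
      rep_atom[i] <- if ("Cc" %in% sp) at[match("Cc", sp)] else at[1]
    }
  }
  ord <- order(vapply(mols, min, integer(1)))   # stable: by first atom index
  mols <- mols[ord]; species <- species[ord]; rep_atom <- rep_atom[ord]
  list(table = data.frame(mol = as.integer(names(mols)), species = species,
                          stringsAsFactors = FALSE),
       pos = frame$positions[rep_atom, , drop = FALSE],
       atoms = unname(mols))
}

#' Partition the ions of a frame into contact clusters
#'
#' Builds the atom-wise contact graph between ion units under the
#' minimum-image convention and returns its connected components. Cluster
#' labels are deterministic: each cluster is labelled by the smallest unit
#' index it contains.
#'
#' @param frame a `traj_frame`.
#' @param cutoffs a `cutoff_table`; pairs without an entry never bond.
#' @param ion_species species labels regarded as mineral-ion atoms.
#' @return An object of class `cluster_assignment`: list with `cluster`
#'   (per-unit cluster label), `sizes` (named table of cluster sizes in
#'   ions), `unit_species`, `n_ions` and `time`.
#' @export
find_clusters <- function(frame, cutoffs = cutoff_table(),
                          ion_species = c("Ca", "Cc", "Oc")) {
  stopifnot(inherits(frame, "traj_frame"))
  u <- ion_units(frame, ion_species)
  n <- nrow(u$table)
  if (n == 0L) {
    return(structure(list(cluster = integer(0), sizes = integer(0),
                          unit_species = character(0), n_ions = 0L,
                          time = frame$time),
                     class = "cluster_assignment"))
  }
  atom_idx <- unlist(u$atoms)
  unit_of <- rep(seq_len(n), lengths(u$atoms))
  sp <- frame$species[atom_idx]
  pos <- frame$positions[atom_idx, , drop = FALSE]
  max_cut <- if (length(cutoffs)) max(cutoffs) else 0
  edges <- integer(0)
  if (n > 1L && max_cut > 0) {
    D <- mic_dist_matrix(pos, pos, frame$box)
    usp <- sort(unique(sp))
    for (a in seq_along(usp)) {
      for (b in a:length(usp)) {
        cut <- pair_cutoff(cutoffs, usp[a], usp[b])
        if (is.na(cut)) next
        ia <- which(sp == usp[a]); ib <- which(sp == usp[b])
        hit <- which(D[ia, ib, drop = FALSE] < cut, arr.ind = TRUE)
        if (nrow(hit)) {
          ui <- unit_of[ia[hit[, 1]]]; uj <- unit_of[ib[hit[, 2]]]
          keep <- ui != uj
          edges <- c(edges, rbind(ui[keep], uj[keep]))
        }
      }
    }
  }
  gr <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) gr <- igraph::add_edges(gr, edges)
  comp <- igraph::components(gr)$membership
  label <- stats::ave(seq_len(n), comp, FUN = min)  # smallest unit index
  sizes <- table(label)
  structure(list(cluster = as.integer(label),
                 sizes = stats::setNames(as.integer(sizes), names(sizes)),
                 unit_species = u$table$species, n_ions = n,
                 time = frame$time),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d ions in %d cluster(s), largest = %d, t = %g ps\n",
              x$n_ions, length(x$sizes),
              if (length(x$sizes)) max(x$sizes) else 0L, x$time))
  invisible(x)
}

#' Cluster-size distribution over time
#'
#' Per frame, the ion-weighted distribution `P(s)` = (ions in clusters of
#' size s) / (total ions), or the cluster-count-weighted distribution
#' `P(s)` = (clusters of size s) / (total clusters). Each time slice sums
#' to one.
#'
#' @param assignments list of `cluster_assignment` objects (one per
#'   frame), consistent ion counts across frames.
#' @param weighting `"ion"` (default) or `"cluster"`.
#' @return An object of class `size_distribution_series`: list with
#'   `times`, `sizes` (1..n_ions), matrix `P` (time x size), `n_ions`,
#'   `weighting`, `replicates`.
#' @export
size_distribution <- function(assignments, weighting = c("ion", "cluster")) {
  weighting <- match.arg(weighting)
  stopifnot(length(assignments) >= 1L)
  n_ions <- unique(vapply(assignments, `[[`, integer(1), "n_ions"))
  if (length(n_ions) != 1L) stop("inconsistent ion counts across frames")
  P <- matrix(0, length(assignments), n_ions)
  times <- vapply(assignments, `[[`, numeric(1), "time")
  for (i in seq_along(assignments)) {
    sz <- assignments[[i]]$sizes
    w <- if (weighting == "ion") sz / n_ions else
      rep(1 / length(sz), length(sz))
    for (k in seq_along(sz)) P[i, sz[k]] <- P[i, sz[k]] + w[k]
  }
  structure(list(times = times, sizes = seq_len(n_ions), P = P,
                 n_ions = n_ions, weighting = weighting, replicates = 1L),
            class = "size_distribution_series")
}

#' @export
print.size_distribution_series <- function(x, ...) {
  cat(sprintf("<size_distribution_series> %d frames, %d ions, %s-weighted, %d replicate(s)\n",
              length(x$times), x$n_ions, x$weighting, x$replicates))
  invisible(x)
}

#' Average size-distribution series over replicate simulations
#'
#' Arithmetic pointwise average in time; all replicates must share the
#' same time grid, ion count and weighting.
#'
#' @param series_list list of `size_distribution_series`.
#' @return A `size_distribution_series` with `replicates` set.
#' @export
average_size_distributions <- function(series_list) {
  stopifnot(length(series_list) >= 1L)
  ref <- series_list[[1]]
  for (s in series_list[-1]) {
    if (!isTRUE(all.equal(s$times, ref$times)) || s$n_ions != ref$n_ions ||
        s$weighting != ref$weighting) {
      stop("replicate series have mismatched time grids, ion counts or weighting")
    }
  }
  P <- Reduce(`+`, lapply(series_list, `[[`, "P")) / length(series_list)
  structure(list(times = ref$times, sizes = ref$sizes, P = P,
                 n_ions = ref$n_ions, weighting = ref$weighting,
                 replicates = length(series_list)),
            class = "size_distribution_series")
}

#' Largest-cluster trajectory and first-passage time
#'
#' The largest cluster size per frame, and the earliest time it exceeds a
#' given fraction of all ions.
#'
#' @param series a `size_distribution_series` (ion-weighted or
#'   cluster-weighted; only support matters).
#' @param threshold fraction of total ions in (0, 1] for the
#'   first-passage read-out.
#' @return A list with `times`, `largest` (per-frame sizes),
#'   `first_passage` (time, or `NA` when never crossed) and `crossed`.
#' @export
largest_cluster_track <- function(series, threshold = 0.5) {
  stopifnot(inherits(series, "size_distribution_series"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("`threshold` must be in (0, 1]")
  }
  largest <- apply(series$P, 1, function(p) {
    occ <- which(p > 0)
    if (length(occ)) max(occ) else 0L
  })
  hit <- which(largest > threshold * series$n_ions)
  list(times = series$times, largest = as.integer(largest),
       first_passage = if (length(hit)) series$times[min(hit)] else NA_real_,
       crossed = length(hit) > 0)
}
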