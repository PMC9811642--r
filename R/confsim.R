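#' Configuration similarity via order-invariant distance vectors
#'
#' Starting configurations of random ion solutions are compared by first
#' flattening each configuration into an order-invariant distance vector
#' anchored at the biomolecule's center of mass, then measuring the
#' continuous Tanimoto distance between vectors. Used to certify that
#' replicate starting configurations differ.
#'
#' @name confsim
NULL

#' Build the order-invariant configuration vector of a frame
#'
#' A greedy chain over the ion atoms: the first anchor is the ion atom
#' nearest the biomolecule's center of mass; its minimum-image distances
#' to all not-yet-anchored atoms, sorted ascending, open the vector. The
#' next anchor is the unvisited atom nearest the current anchor, and so
#' on until all atoms are visited. Ties break toward the lowest atom
#' index, which together with the sorting makes the vector invariant to
#' input atom order.
#'
#' @param frame a `traj_frame`.
#' @param biomolecule_atoms indices of the biomolecule atoms (>= 1).
#' @param ion_atoms indices of the ion atoms entering the vector (>= 2).
#' @param masses named species masses for the center of mass; defaults to
#'   [species_masses()].
#' @return An object of class `config_vector`: list with `entries`
#'   (distances, nm) and `trace` (anchor order, original atom indices).
#' @export
config_vector <- function(frame, biomolecule_atoms, ion_atoms,
                          masses = species_masses()) {
  stopifnot(inherits(frame, "traj_frame"),
            length(biomolecule_atoms) >= 1L, length(ion_atoms) >= 2L)
  bio <- frame$positions[biomolecule_atoms, , drop = FALSE]
  m <- masses[frame$species[biomolecule_atoms]]
  if (any(is.na(m))) stop("missing mass for biomolecule species")
  ## unwrap the biomolecule about its first atom before the COM
  rel <- mic_displacement(bio[1, ], bio, frame$box)
  com <- bio[1, ] + colSums(rel * m) / sum(m)
  ions <- sort(as.integer(ion_atoms))          # canonical order for ties
  pos <- frame$positions[ions, , drop = FALSE]
  n <- length(ions)
  visited <- logical(n)
  d_com <- mic_distance(com, pos, frame$box)
  anchor <- which(d_com == min(d_com))[1]      # lowest index on ties
  entries <- numeric(0); trace <- integer(0)
  repeat {
    visited[anchor] <- TRUE
    trace <- c(trace, ions[anchor])
    rest <- which(!visited)
    if (!length(rest)) break
    d <- mic_distance(pos[anchor, ], pos[rest, , drop = FALSE], frame$box)
    entries <- c(entries, sort(d))
    anchor <- rest[which(d == min(d))[1]]
  }
  structure(list(entries = entries, trace = trace), class = "config_vector")
}

#' @export
print.config_vector <- function(x, ...) {
  cat(sprintf("<config_vector> %d entries over %d atoms\n",
              length(x$entries), length(x$trace)))
  invisible(x)
}

#' Continuous Tanimoto distance between two configuration vectors
#'
#' `d = 1 - a.b / (|a|^2 + |b|^2 - a.b)`, in [0, 1] for non-negative
#' vectors, zero for identical vectors, symmetric. Vectors must have equal
#' length (same ion counts); padding or truncation is refused.
#'
#' @param a,b `config_vector` objects or plain numeric vectors.
#' @return The Tanimoto distance.
#' @examples
#' tanimoto_distance(c(1, 0), c(1, 1))  # 0.5
#' @export
tanimoto_distance <- function(a, b) {
  if (inherits(a, "config_vector")) a <- a$entries
  if (inherits(b, "config_vector")) b <- b$entries
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) != length(b)) {
    stop("configuration vectors differ in length (", length(a), " vs ",
         length(b), "); same ion counts are required")
  }
  ab <- sum(a * b)
  den <- sum(a * a) + sum(b * b) - ab
  if (den == 0) stop("Tanimoto distance undefined for zero vectors")
  1 - ab / den
}

#' Pairwise acceptance of starting configurations
#'
#' Computes the full Tanimoto distance matrix and flags every pair under
#' the chosen criterion. Two conventions are supported because they pull
#' in opposite directions: `"similarity_below"` (default) accepts a pair
#' whose similarity `1 - d` is below the threshold — the reading under
#' which a threshold of 0.7 guarantees genuinely different
#' configurations — and `"distance_below"` accepts a pair whose distance
#' is below it. The report records which convention was applied.
#'
#' @param vectors list of `config_vector` objects (or numeric vectors),
#'   length >= 2.
#' @param threshold acceptance threshold (default 0.7).
#' @param mode `"similarity_below"` or `"distance_below"`.
#' @return A list with `distance` (matrix), `similarity` (matrix), `pass`
#'   (logical matrix over pairs), `verdict` (all off-diagonal pairs
#'   pass), `mode`, `threshold`.
#' @export
accept_pairwise <- function(vectors, threshold = 0.7,
                            mode = c("similarity_below", "distance_below")) {
  mode <- match.arg(mode)
  stopifnot(length(vectors) >= 2L)
  n <- length(vectors)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- tanimoto_distance(vectors[[i]], vectors[[j]])
    }
  }
  S <- 1 - D
  pass <- if (mode == "similarity_below") S < threshold else D < threshold
  diag(pass) <- NA
  off <- pass[upper.tri(pass)]
  list(distance = D, similarity = S, pass = pass,
       verdict = all(off), mode = mode, threshold = threshold)
}
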