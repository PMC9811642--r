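#' Labeled particle frames in periodic orthorhombic boxes
#'
#' A `traj_frame` carries positions in nm, species labels, an optional
#' molecule-id vector grouping atoms into rigid units (carbonate), the
#' orthorhombic box edges in nm and a time stamp in ps. A trajectory is a
#' plain list of frames.
#'
#' @name frame
NULL

#' Construct a trajectory frame
#'
#' @param positions n x 3 numeric matrix of coordinates in nm.
#' @param species character vector of n species labels (e.g. `"Ca"`,
#'   `"Cc"`, `"Oc"`, `"OD"`, `"N"`, `"Ow"`, `"Hw"`).
#' @param box three orthorhombic edge lengths in nm.
#' @param time frame time in ps.
#' @param mol optional integer molecule ids grouping atoms into units;
#'   defaults to one unit per atom.
#' @return An object of class `traj_frame`.
#' @export
traj_frame <- function(positions, species, box, time = 0, mol = NULL) {
  positions <- as.matrix(positions)
  if (length(positions) == 0L) positions <- matrix(numeric(0), 0, 3)
  if (ncol(positions) != 3L) stop("`positions` must be n x 3")
  n <- nrow(positions)
  species <- as.character(species)
  if (length(species) != n) stop("`species` length must match positions")
  box <- as.numeric(box)
  if (length(box) != 3L || any(box <= 0)) stop("`box` must be 3 positive edges")
  if (is.null(mol)) mol <- seq_len(n)
  mol <- as.integer(mol)
  if (length(mol) != n) stop("`mol` length must match positions")
  structure(list(positions = positions, species = species, box = box,
                 time = as.numeric(time), mol = mol),
            class = "traj_frame")
}

#' @export
print.traj_frame <- function(x, ...) {
  cat(sprintf("<traj_frame> %d atoms (%s), box %.3f x %.3f x %.3f nm, t = %g ps\n",
              nrow(x$positions),
              paste(names(sort(table(x$species), decreasing = TRUE)),
                    collapse = ","),
              x$box[1], x$box[2], x$box[3], x$time))
  invisible(x)
}

## minimum-image displacement of points `b` (matrix) relative to point `a`
mic_displacement <- function(a, b, box) {
  d <- sweep(b, 2, a, "-")
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

## minimum-image distances from point a to rows of b
mic_distance <- function(a, b, box) {
  d <- mic_displacement(a, b, box)
  sqrt(rowSums(d * d))
}

#' Default atomic masses by species label (g/mol)
#'
#' @return Named numeric vector of masses for the species vocabulary used
#'   throughout: Ca, carbonate carbon/oxygen (Cc/Oc), carboxylate oxygen
#'   (OD), N, water oxygen/hydrogen (Ow/Hw), C, O, H, Na.
#' @export
species_masses <- function() {
  c(Ca = 40.078, Cc = 12.011, Oc = 15.999, OD = 15.999, N = 14.007,
    Ow = 15.999, Hw = 1.008, C = 12.011, O = 15.999, H = 1.008,
    Na = 22.990)
}

#' Read an extended-XYZ trajectory
#'
#' Extended XYZ with a `Lattice="ax 0 0 0 by 0 0 0 cz"` comment line;
#' coordinates in nm. An optional `Time=<ps>` tag and a `mol` fourth data
#' column (molecule id) are honoured.
#'
#' @param path file path.
#' @return A list of `traj_frame` objects.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop("bad XYZ atom count at line ", i)
    comment <- lines[i + 1L]
    lat <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]]
    if (length(lat) < 2L) stop("XYZ frame missing Lattice tag at line ", i + 1L)
    lv <- as.numeric(strsplit(trimws(lat[2]), "\\s+")[[1]])
    box <- lv[c(1, 5, 9)]
    tm <- regmatches(comment, regexec("Time=([0-9eE.+-]+)", comment))[[1]]
    tm <- if (length(tm) >= 2L) as.numeric(tm[2]) else 0
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    species <- vapply(toks, `[`, character(1), 1)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    mol <- if (all(lengths(toks) >= 5L)) {
      as.integer(vapply(toks, `[`, character(1), 5))
    } else NULL
    frames[[length(frames) + 1L]] <-
      traj_frame(xyz, species, box, time = tm, mol = mol)
    i <- i + 2L + n
  }
  frames
}

#' Write an extended-XYZ trajectory
#'
#' @param frames a `traj_frame` or list of them.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(frames, path) {
  if (inherits(frames, "traj_frame")) frames <- list(frames)
  con <- file(path, "w"); on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$positions)
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Lattice="%.8f 0 0 0 %.8f 0 0 0 %.8f" Properties=species:S:1:pos:R:3:mol:I:1 Time=%g',
      fr$box[1], fr$box[2], fr$box[3], fr$time), con)
    if (n) {
      writeLines(sprintf("%s %.8f %.8f %.8f %d", fr$species,
                         fr$positions[, 1], fr$positions[, 2],
                         fr$positions[, 3], fr$mol), con)
    }
  }
  invisible(path)
}

#' Read a LAMMPS text dump trajectory
#'
#' Supports the `ITEM: ATOMS id type x y z` dialect (optionally with a
#' `mol` column) and orthorhombic `ITEM: BOX BOUNDS`. Coordinates are
#' interpreted in nm; numeric types are mapped to species via `type_map`.
#'
#' @param path file path.
#' @param type_map named character vector mapping type id (as character)
#'   to species label, e.g. `c("1" = "Ca", "2" = "Cc", "3" = "Oc")`.
#' @param timestep_ps physical time per dump timestep unit, in ps.
#' @return A list of `traj_frame` objects.
#' @export
read_lammps_dump <- function(path, type_map, timestep_ps = 1) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "ITEM: TIMESTEP")) { i <- i + 1L; next }
    step <- as.numeric(trimws(lines[i + 1L]))
    stopifnot(startsWith(lines[i + 2L], "ITEM: NUMBER OF ATOMS"))
    n <- as.integer(trimws(lines[i + 3L]))
    stopifnot(startsWith(lines[i + 4L], "ITEM: BOX BOUNDS"))
    box <- numeric(3)
    for (k in 1:3) {
      b <- as.numeric(strsplit(trimws(lines[i + 4L + k]), "\\s+")[[1]])
      box[k] <- b[2] - b[1]
    }
    hdr <- lines[i + 8L]
    stopifnot(startsWith(hdr, "ITEM: ATOMS"))
    cols <- strsplit(trimws(sub("ITEM: ATOMS", "", hdr)), "\\s+")[[1]]
    need <- c("id", "type", "x", "y", "z")
    if (!all(need %in% cols)) stop("dump must have columns id type x y z")
    body <- lines[(i + 9L):(i + 8L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    get <- function(nmcol) vapply(toks, `[`, character(1), match(nmcol, cols))
    ord <- order(as.integer(get("id")))
    type <- get("type")[ord]
    species <- unname(type_map[type])
    if (any(is.na(species))) {
      stop("type_map missing types: ",
           paste(unique(type[is.na(species)]), collapse = ", "))
    }
    xyz <- cbind(as.numeric(get("x")), as.numeric(get("y")),
                 as.numeric(get("z")))[ord, , drop = FALSE]
    mol <- if ("mol" %in% cols) as.integer(get("mol"))[ord] else NULL
    frames[[length(frames) + 1L]] <-
      traj_frame(xyz, species, box, time = step * timestep_ps, mol = mol)
    i <- i + 9L + n
  }
  frames
}

#' Write a LAMMPS text dump trajectory
#'
#' @param frames a `traj_frame` or list of them.
#' @param path output path.
#' @param type_map named character vector species -> type id; defaults to
#'   an alphabetical numbering of the species present.
#' @param timestep_ps physical time per timestep unit, in ps.
#' @return Invisibly, the `type_map` used (species -> type id).
#' @export
write_lammps_dump <- function(frames, path, type_map = NULL, timestep_ps = 1) {
  if (inherits(frames, "traj_frame")) frames <- list(frames)
  if (is.null(type_map)) {
    sp <- sort(unique(unlist(lapply(frames, `[[`, "species"))))
    type_map <- stats::setNames(as.character(seq_along(sp)), sp)
  }
  con <- file(path, "w"); on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$positions)
    writeLines(c("ITEM: TIMESTEP", format(fr$time / timestep_ps),
                 "ITEM: NUMBER OF ATOMS", as.character(n),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("0.0 %.8f", fr$box[1]),
                 sprintf("0.0 %.8f", fr$box[2]),
                 sprintf("0.0 %.8f", fr$box[3]),
                 "ITEM: ATOMS id type x y z mol"), con)
    if (n) {
      writeLines(sprintf("%d %s %.8f %.8f %.8f %d", seq_len(n),
                         type_map[fr$species], fr$positions[, 1],
                         fr$positions[, 2], fr$positions[, 3], fr$mol), con)
    }
  }
  invisible(type_map)
}

#' Read a two-column free-energy profile (PLUMED fes.dat dialect)
#'
#' Skips `#! FIELDS` headers and `#` comments; the first column is the
#' collective-variable distance in nm, the second the free energy in
#' kJ/mol.
#'
#' @param path file path.
#' @param temperature temperature in K attached to the profile.
#' @return An `fes_profile`.
#' @export
read_fes <- function(path, temperature = 300) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  toks <- strsplit(trimws(lines), "\\s+")
  r <- vapply(toks, function(t) as.numeric(t[1]), numeric(1))
  E <- vapply(toks, function(t) as.numeric(t[2]), numeric(1))
  fes_profile(r, E, temperature = temperature)
}

#' Write a free-energy profile as two-column text
#'
#' @param p an `fes_profile`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fes <- function(p, path) {
  stopifnot(inherits(p, "fes_profile"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("#! FIELDS dist file.free", con)
  writeLines(sprintf("%.6f %.10e", p$r, p$E), con)
  invisible(path)
}
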