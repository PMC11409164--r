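# Element-resolved 3D average atomic density maps.
#
# Environments are rigidly aligned on reference atoms of the central
# molecule; amplitude-1 Gaussians of width w (sd, 0.5 A by default) are
# placed at every atomic position and averaged over environments on a cubic
# grid with 12 A sides centered on the first aligned atom. With this
# normalization, an atom present at the same point in every environment
# gives a channel maximum of exactly one.

#' Alignment specification
#'
#' @param ref_atoms ordered central-molecule atom labels. `kabsch` mode
#'   needs at least 3 (non-collinear); `bond_axis` mode needs exactly 3:
#'   the origin atom, the atom defining the +z bond axis, and an
#'   orientation atom fixing the azimuth in the xz half-plane (x > 0).
#' @param mode `"kabsch"` or `"bond_axis"`.
#' @return object of class `alignment_spec`.
#' @export
alignment_spec <- function(ref_atoms, mode = c("kabsch", "bond_axis")) {
  mode <- match.arg(mode)
  if (mode == "kabsch" && length(ref_atoms) < 3)
    stop("kabsch alignment needs at least 3 reference atoms", call. = FALSE)
  if (mode == "bond_axis" && length(ref_atoms) != 3)
    stop("bond_axis alignment needs exactly 3 atoms: origin, axis, azimuth",
         call. = FALSE)
  structure(list(ref_atoms = ref_atoms, mode = mode),
            class = "alignment_spec")
}

#' Rigidly align an environment on reference atoms
#'
#' `kabsch` mode: proper-rotation least-squares superposition of the
#' environment's reference atoms onto `template` (rows in `ref_atoms`
#' order). `bond_axis` mode: the first reference atom is moved to the
#' template's first-atom position (origin by default), the bond to the
#' second atom is rotated onto +z, and the third atom fixes the azimuth in
#' the xz half-plane (x > 0).
#'
#' @param env a [mol_env()].
#' @param spec an [alignment_spec()].
#' @param template matrix of template coordinates for the reference atoms
#'   (one row per reference atom). Defaults to the origin-anchored frame in
#'   `bond_axis` mode; required for `kabsch`.
#' @return list `env` (aligned copy), `R` (rotation), `t` (translation),
#'   `rmsd` (reference-atom RMSD; kabsch mode).
#' @export
align_environment <- function(env, spec, template = NULL) {
  stopifnot(inherits(env, "mol_env"), inherits(spec, "alignment_spec"))
  P <- t(vapply(spec$ref_atoms, function(l) env_atom_coord(env, l),
                numeric(3)))
  X <- as.matrix(env$atoms[, c("x", "y", "z")])
  if (spec$mode == "kabsch") {
    if (is.null(template))
      stop("kabsch alignment needs template coordinates", call. = FALSE)
    template <- as.matrix(template)
    stopifnot(nrow(template) == length(spec$ref_atoms))
    # collinearity check on the environment's reference atoms
    P0 <- sweep(P, 2, colMeans(P))
    if (svd(P0)$d[2] < 1e-6)
      stop("reference atoms are collinear; use bond_axis mode", call. = FALSE)
    k <- kabsch(P, template)
    Xa <- apply_rigid(X, k$R, k$t)
    R <- k$R; tr <- k$t; rmsd <- k$rmsd
  } else {
    origin <- if (is.null(template)) c(0, 0, 0) else as.numeric(template[1, ])
    a <- P[1, ]; b <- P[2, ]; c_ <- P[3, ]
    R1 <- rotation_between(b - a, c(0, 0, 1))
    v <- as.numeric(R1 %*% (c_ - a))
    if (sqrt(v[1]^2 + v[2]^2) < 1e-8)
      stop("orientation atom is collinear with the bond axis; ",
           "choose an off-axis atom", call. = FALSE)
    phi <- atan2(v[2], v[1]) * 180 / pi
    R <- rotation_matrix(c(0, 0, 1), -phi) %*% R1
    tr <- origin - as.numeric(R %*% a)
    Xa <- apply_rigid(X, R, tr)
    rmsd <- 0
  }
  env2 <- env
  env2$atoms$x <- Xa[, 1]; env2$atoms$y <- Xa[, 2]; env2$atoms$z <- Xa[, 3]
  list(env = env2, R = R, t = tr, rmsd = rmsd)
}

#' Accumulate an element-resolved density map over aligned environments
#'
#' For every element channel e,
#' `channel_e(x) = mean_env sum_atoms exp(-|x - r|^2 / (2 w^2))`:
#' amplitude-1 Gaussians at each atom position, averaged over environments.
#' Atoms outside the grid contribute their in-grid tails; the evaluation is
#' exact (no cutoff). By default all hydrogens share one H channel.
#'
#' @param envs list of aligned [mol_env()] objects.
#' @param w Gaussian width (standard deviation), Angstrom.
#' @param L cube side length, Angstrom (grid spans \[-L/2, L/2\] about the
#'   origin, i.e. centered on the first aligned atom).
#' @param h grid spacing, Angstrom; must not exceed `w` so the grid
#'   resolves the Gaussian.
#' @param elements optional subset of element channels to accumulate.
#' @return object of class `density_map`: list with `axis` (grid
#'   coordinates per dimension), `h`, `L`, `w`, `n_env`, and `channels`
#'   (named list of 3D arrays, x-y-z indexed).
#' @export
accumulate_density <- function(envs, w = 0.5, L = 12, h = 0.2,
                               elements = NULL) {
  if (inherits(envs, "mol_env")) envs <- list(envs)
  if (length(envs) == 0) stop("no environments to accumulate", call. = FALSE)
  if (w <= 0) stop("gaussian width must be > 0", call. = FALSE)
  if (h > w) stop("grid spacing h must not exceed the Gaussian width w",
                  call. = FALSE)
  axis <- seq(-L / 2, L / 2, by = h)
  ng <- length(axis)
  all_at <- do.call(rbind, lapply(envs, function(e)
    e$atoms[, c("element", "x", "y", "z")]))
  if (is.null(elements)) elements <- sort(unique(all_at$element))
  channels <- list()
  for (el in elements) {
    sel <- all_at$element == el
    arr <- array(0, dim = c(ng, ng, ng))
    if (any(sel)) {
      R <- as.matrix(all_at[sel, c("x", "y", "z")])
      # separable Gaussians: channel[i,j,k] = sum_a X[i,a] Y[j,a] Z[k,a],
      # evaluated as ng matrix products (BLAS) over the z index
      Gx <- exp(-outer(axis, R[, 1], "-")^2 / (2 * w^2))
      Gy <- exp(-outer(axis, R[, 2], "-")^2 / (2 * w^2))
      Gz <- exp(-outer(axis, R[, 3], "-")^2 / (2 * w^2))
      for (k in seq_len(ng)) {
        Yk <- Gy * matrix(Gz[k, ], ng, ncol(Gz), byrow = TRUE)
        arr[, , k] <- Gx %*% t(Yk)
      }
    }
    channels[[el]] <- arr / length(envs)
  }
  structure(list(axis = axis, h = h, L = L, w = w, n_env = length(envs),
                 channels = channels),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d^3 grid (h = %g A, L = %g A, w = %g A), %d env(s), channels: %s\n",
              length(x$axis), x$h, x$L, x$w, x$n_env,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Density value at the grid point nearest a Cartesian position
#'
#' @param map a [density_map()].
#' @param element channel name.
#' @param point length-3 position, Angstrom.
#' @return list `value`, `index` (i, j, k).
#' @export
density_at <- function(map, element, point) {
  if (!element %in% names(map$channels))
    stop("no channel for element ", element, call. = FALSE)
  idx <- vapply(point, function(p) which.min(abs(map$axis - p)), integer(1))
  list(value = map$channels[[element]][idx[1], idx[2], idx[3]], index = idx)
}

BOHR_PER_ANGSTROM <- 1 / 0.52917721067

#' Export one element channel as a Gaussian cube file
#'
#' Standard cube layout: two comment lines; atom count and grid origin
#' (bohr); three axis lines (counts and spacings in bohr); values in
#' z-fastest order, six per line. The atom block is empty (count 0): the map
#' is an ensemble average, not a single structure.
#'
#' @param map a [density_map()].
#' @param element channel to export.
#' @param path output path.
#' @export
export_cube <- function(map, element, path) {
  if (!element %in% names(map$channels))
    stop("unknown element channel: ", element, call. = FALSE)
  arr <- map$channels[[element]]
  ng <- length(map$axis)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("nmrcryst density map, element %s", element),
               sprintf("averaged over %d environments, w = %g A",
                       map$n_env, map$w)), con)
  o <- min(map$axis) * BOHR_PER_ANGSTROM
  hb <- map$h * BOHR_PER_ANGSTROM
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", 0L, o, o, o), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", ng, hb, 0, 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", ng, 0, hb, 0), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", ng, 0, 0, hb), con)
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    v <- arr[i, j, ]
    lines <- split(v, ceiling(seq_along(v) / 6))
    writeLines(vapply(lines, function(z)
      paste(sprintf("%13.5E", z), collapse = ""), character(1)), con)
  }
  invisible(path)
}

#' Read a Gaussian cube file written by [export_cube()]
#'
#' @param path cube file path.
#' @return list `axis` (Angstrom), `values` (3D array, x-y-z indexed),
#'   `origin` (Angstrom).
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  natoms <- as.integer(hdr[1])
  origin <- as.numeric(hdr[2:4]) / BOHR_PER_ANGSTROM
  ax <- lapply(4:6, function(i) as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
  ng <- as.integer(ax[[1]][1])
  h <- ax[[1]][2] / BOHR_PER_ANGSTROM
  start <- 7 + abs(natoms)
  vals <- as.numeric(unlist(strsplit(trimws(lines[start:length(lines)]), "\\s+")))
  stopifnot(length(vals) == ng^3)
  arr <- array(0, dim = c(ng, ng, ng))
  # file order: x slowest, z fastest
  arr_perm <- array(vals, dim = c(ng, ng, ng))  # dims: z, y, x
  arr <- aperm(arr_perm, c(3, 2, 1))
  list(axis = origin[1] + h * (0:(ng - 1)), values = arr, origin = origin)
}

#' Export above-threshold density values as a CSV
#'
#' Light-weight inspection format: one row per grid point whose value in
#' the given channel exceeds `threshold`.
#'
#' @param map a [density_map()].
#' @param element channel name.
#' @param path output path.
#' @param threshold minimum value to report.
#' @export
export_density_csv <- function(map, element, path, threshold = 0.01) {
  arr <- map$channels[[element]]
  if (is.null(arr)) stop("unknown element channel: ", element, call. = FALSE)
  idx <- which(arr > threshold, arr.ind = TRUE)
  out <- data.frame(x = map$axis[idx[, 1]], y = map$axis[idx[, 2]],
                    z = map$axis[idx[, 3]], element = element,
                    value = arr[idx])
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
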