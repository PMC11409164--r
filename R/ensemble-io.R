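# Periodic snapshots and local molecular environments.
#
# A frame is a periodic box of whole-molecule coordinates; an environment is
# a central molecule plus every molecule with at least one atom within the
# distance cutoff (7 A in the reference protocol), unwrapped so that each
# molecule is whole and sits in the image nearest the central molecule.

#' Construct a periodic frame
#'
#' @param lattice 3x3 matrix of cell vectors (rows), Angstrom.
#' @param positions n x 3 Cartesian coordinates, Angstrom.
#' @param elements character vector of element symbols, length n.
#' @param mol_ids integer vector of molecule indices, length n.
#' @param frame_time time stamp in ps.
#' @return object of class `md_frame`.
#' @export
md_frame <- function(lattice, positions, elements, mol_ids, frame_time = 0) {
  lattice <- as.matrix(lattice)
  positions <- as.matrix(positions)
  stopifnot(all(dim(lattice) == c(3, 3)), ncol(positions) == 3)
  n <- nrow(positions)
  if (length(elements) != n || length(mol_ids) != n)
    stop("positions, elements and mol_ids must have the same length",
         call. = FALSE)
  if (abs(det(lattice)) < 1e-8) stop("lattice is singular", call. = FALSE)
  structure(list(lattice = lattice, positions = positions,
                 elements = as.character(elements),
                 mol_ids = as.integer(mol_ids),
                 frame_time = frame_time),
            class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("<md_frame> %d atoms, %d molecules, t = %g ps\n",
              nrow(x$positions), length(unique(x$mol_ids)), x$frame_time))
  invisible(x)
}

#' Evenly spaced frame times over a trajectory window
#'
#' Endpoint-inclusive sampling: a 100 ns window at 100 ps steps yields 1001
#' snapshot times. The window must be an exact multiple of the step; no
#' silent truncation is performed.
#'
#' @param window_start,window_end window bounds in ps.
#' @param step spacing in ps.
#' @return numeric vector of frame times (ps), both endpoints included.
#' @export
sample_frames <- function(window_start, window_end, step) {
  if (window_end < window_start)
    stop("window_end must be >= window_start", call. = FALSE)
  if (step <= 0) stop("step must be positive", call. = FALSE)
  if (window_end == window_start) return(window_start)
  span <- window_end - window_start
  k <- span / step
  if (abs(k - round(k)) > 1e-9 * max(1, k))
    stop(sprintf("window (%g ps) is not a multiple of step (%g ps)",
                 span, step), call. = FALSE)
  window_start + step * (0:round(k))
}

# --- minimum image machinery ------------------------------------------------

# Fractional coordinates of displacement rows D under lattice L (rows = cell
# vectors): solve f %*% L = D.
min_image_disp <- function(D, lattice) {
  f <- D %*% solve(lattice)
  f <- f - round(f)
  f %*% lattice
}

# Make every molecule whole via a BFS over a bonding-distance heuristic.
# Returns the positions matrix with each molecule internally unwrapped
# (anchored at its first atom's original position).
make_molecules_whole <- function(frame, bond_cut = 1.8) {
  pos <- frame$positions
  lat <- frame$lattice
  out <- pos
  for (m in unique(frame$mol_ids)) {
    idx <- which(frame$mol_ids == m)
    if (length(idx) == 1) next
    P <- pos[idx, , drop = FALSE]
    placed <- rep(FALSE, length(idx))
    new <- P
    placed[1] <- TRUE
    queue <- 1L
    while (length(queue) > 0) {
      i <- queue[1]; queue <- queue[-1]
      D <- sweep(P, 2, new[i, ])      # raw displacement atom i -> atom j
      Dmi <- min_image_disp(D, lat)   # nearest-image displacement
      dist <- sqrt(rowSums(Dmi^2))
      nb <- which(dist <= bond_cut & dist > 1e-9)
      for (j in nb) {
        cand <- new[i, ] + Dmi[j, ]
        if (placed[j]) {
          if (vec_norm(cand - new[j, ]) > 1e-6)
            stop(sprintf(paste0("molecule %d cannot be unwrapped consistently",
                                " (spans the box?)"), m), call. = FALSE)
        } else {
          new[j, ] <- cand
          placed[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
    if (!all(placed))
      stop(sprintf("molecule %d is not connected at bond cutoff %.2f A",
                   m, bond_cut), call. = FALSE)
    out[idx, ] <- new
  }
  out
}

#' Construct a molecular environment object
#'
#' @param atoms data.frame with columns `label` (NA allowed), `element`,
#'   `x`, `y`, `z`, `mol_id`, `central` (logical), `water` (logical).
#' @param env_id environment identifier.
#' @param cutoff neighbor cutoff in Angstrom.
#' @param run_id run identifier.
#' @return object of class `mol_env`.
#' @export
mol_env <- function(atoms, env_id, cutoff = NA_real_, run_id = NA_character_) {
  need <- c("label", "element", "x", "y", "z", "mol_id", "central", "water")
  stopifnot(all(need %in% names(atoms)))
  structure(list(env_id = env_id, run_id = run_id, cutoff = cutoff,
                 atoms = as.data.frame(atoms)[, need]),
            class = "mol_env")
}

#' @export
print.mol_env <- function(x, ...) {
  cat(sprintf("<mol_env> %s: %d atoms (%d central), %d neighbor molecule(s)\n",
              x$env_id, nrow(x$atoms), sum(x$atoms$central),
              length(unique(x$atoms$mol_id[!x$atoms$central]))))
  invisible(x)
}

env_central_coords <- function(env) {
  as.matrix(env$atoms[env$atoms$central, c("x", "y", "z")])
}

# Coordinates of one labeled atom of the central molecule.
env_atom_coord <- function(env, label) {
  i <- which(env$atoms$central & env$atoms$label == label)
  if (length(i) != 1)
    stop("central atom with label '", label, "' not found in ", env$env_id,
         call. = FALSE)
  as.numeric(env$atoms[i, c("x", "y", "z")])
}

#' Extract local molecular environments from a periodic frame
#'
#' Builds one environment per solute molecule: the central molecule plus
#' every other molecule with at least one atom within `cutoff` of any
#' central-molecule atom under the minimum-image convention. Included
#' molecules are made whole and translated to the image nearest the central
#' molecule. Water is identified as molecules of exactly three atoms.
#'
#' The minimum-image convention requires `cutoff` to be smaller than half
#' the shortest cell vector; this is asserted.
#'
#' @param frame an [md_frame()].
#' @param cutoff neighbor cutoff in Angstrom (default 7).
#' @param graph optional [molecule_graph()]; if given, solute molecules are
#'   labeled by matching atom order against the graph's atom order.
#' @param run_id run identifier used in `env_id` (`"<run>:<time>:<mol>"`).
#' @param bond_cut intramolecular bonding heuristic for unwrapping (A).
#' @return list of [mol_env()] objects.
#' @export
extract_environments <- function(frame, cutoff = 7, graph = NULL,
                                 run_id = "run", bond_cut = 1.8) {
  stopifnot(inherits(frame, "md_frame"))
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  min_cell <- min(sqrt(rowSums(frame$lattice^2)))
  if (cutoff >= min_cell / 2)
    stop(sprintf("cutoff %.2f A >= half the shortest cell vector (%.2f A)",
                 cutoff, min_cell / 2), call. = FALSE)

  pos <- make_molecules_whole(frame, bond_cut)
  ids <- sort(unique(frame$mol_ids))
  mol_idx <- lapply(ids, function(m) which(frame$mol_ids == m))
  names(mol_idx) <- as.character(ids)
  sizes <- vapply(mol_idx, length, integer(1))
  is_water <- vapply(mol_idx, function(ix)
    length(ix) == 3 &&
      identical(sort(frame$elements[ix]), c("H", "H", "O")), logical(1))
  solute <- ids[!is_water]
  if (length(solute) == 0) stop("frame contains no solute molecules",
                                call. = FALSE)

  label_for <- function(m) {
    n <- sizes[[as.character(m)]]
    if (is_water[[as.character(m)]] || is.null(graph)) return(rep(NA_character_, n))
    if (n != nrow(graph$atoms)) return(rep(NA_character_, n))
    graph$atoms$label
  }

  envs <- vector("list", length(solute))
  for (s in seq_along(solute)) {
    cm <- solute[s]
    ci <- mol_idx[[as.character(cm)]]
    C <- pos[ci, , drop = FALSE]
    rows <- list(data.frame(
      label = label_for(cm), element = frame$elements[ci],
      x = C[, 1], y = C[, 2], z = C[, 3], mol_id = cm,
      central = TRUE, water = FALSE, stringsAsFactors = FALSE))
    for (m in ids) {
      if (m == cm) next
      ni <- mol_idx[[as.character(m)]]
      P <- pos[ni, , drop = FALSE]
      # min-image distance per atom pair (central x neighbor)
      best <- Inf; best_shift <- c(0, 0, 0)
      for (i in seq_len(nrow(C))) {
        D <- sweep(P, 2, C[i, ])
        Dmi <- min_image_disp(D, frame$lattice)
        d <- sqrt(rowSums(Dmi^2))
        j <- which.min(d)
        if (d[j] < best) {
          best <- d[j]
          # lattice translation that brings atom j to its nearest image of C[i,]
          best_shift <- (C[i, ] + Dmi[j, ]) - P[j, ]
        }
      }
      if (best <= cutoff) {
        Pn <- sweep(P, 2, best_shift, "+")
        rows[[length(rows) + 1]] <- data.frame(
          label = label_for(m), element = frame$elements[ni],
          x = Pn[, 1], y = Pn[, 2], z = Pn[, 3], mol_id = m,
          central = FALSE, water = is_water[[as.character(m)]],
          stringsAsFactors = FALSE)
      }
    }
    envs[[s]] <- mol_env(do.call(rbind, rows),
                         env_id = sprintf("%s:%g:%d", run_id,
                                          frame$frame_time, cm),
                         cutoff = cutoff, run_id = run_id)
  }
  envs
}

# --- extended-XYZ -----------------------------------------------------------

#' Read extended-XYZ frames
#'
#' Reads one or more frames from an extended-XYZ file carrying a
#' `Lattice="..."` comment-line header, a `Properties=` specification with a
#' per-atom `mol_id` integer column, and optionally `Time=` (ps).
#'
#' @param path file path.
#' @return list of [md_frame()] objects.
#' @export
read_extxyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop("malformed extended-XYZ: expected atom count at line ",
                       i, call. = FALSE)
    header <- lines[i + 1]
    lat_m <- regmatches(header, regexpr('Lattice="[^"]*"', header))
    if (length(lat_m) == 0) stop("missing Lattice header in frame comment",
                                 call. = FALSE)
    lat_vals <- as.numeric(strsplit(gsub('Lattice="|"', "", lat_m), "\\s+")[[1]])
    lattice <- matrix(lat_vals, 3, 3, byrow = TRUE)
    time_m <- regmatches(header, regexpr("Time=[-0-9.eE+]+", header))
    frame_time <- if (length(time_m)) as.numeric(sub("Time=", "", time_m)) else 0
    body <- lines[(i + 2):(i + 1 + n)]
    toks <- strsplit(trimws(body), "\\s+")
    elements <- vapply(toks, `[`, character(1), 1)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    mol_ids <- vapply(toks, function(tk)
      if (length(tk) >= 5) as.integer(tk[5]) else 1L, integer(1))
    frames[[length(frames) + 1]] <-
      md_frame(lattice, xyz, elements, mol_ids, frame_time)
    i <- i + 2 + n
  }
  frames
}

#' Write frames to extended-XYZ
#'
#' @param frames a single [md_frame()] or a list of them.
#' @param path output path.
#' @param comment_extra optional string appended to each comment line.
#' @export
write_extxyz <- function(frames, path, comment_extra = NULL) {
  if (inherits(frames, "md_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$positions)
    lat <- paste(sprintf("%.8f", t(fr$lattice)), collapse = " ")
    header <- sprintf(
      'Lattice="%s" Properties=species:S:1:pos:R:3:mol_id:I:1 Time=%g',
      lat, fr$frame_time)
    if (!is.null(comment_extra)) header <- paste(header, comment_extra)
    writeLines(as.character(n), con)
    writeLines(header, con)
    writeLines(sprintf("%-3s %16.8f %16.8f %16.8f %6d",
                       fr$elements, fr$positions[, 1], fr$positions[, 2],
                       fr$positions[, 3], fr$mol_ids), con)
  }
  invisible(path)
}

#' Write molecular environments to extended-XYZ
#'
#' Environments are written concatenated, one XYZ block each, with the
#' `env_id` recorded in the comment line. The (non-periodic) bounding box is
#' written as a diagonal lattice for format compliance.
#'
#' @param envs list of [mol_env()] objects.
#' @param path output path.
#' @export
write_environments_xyz <- function(envs, path) {
  if (inherits(envs, "mol_env")) envs <- list(envs)
  con <- file(path, "w")
  on.exit(close(con))
  for (env in envs) {
    at <- env$atoms
    span <- max(apply(at[, c("x", "y", "z")], 2,
                      function(v) diff(range(v)))) + 20
    lat <- paste(sprintf("%.4f", diag(c(span, span, span))), collapse = " ")
    writeLines(as.character(nrow(at)), con)
    writeLines(sprintf(
      'Lattice="%s" Properties=species:S:1:pos:R:3:mol_id:I:1 env_id=%s',
      lat, env$env_id), con)
    writeLines(sprintf("%-3s %16.8f %16.8f %16.8f %6d",
                       at$element, at$x, at$y, at$z, at$mol_id), con)
  }
  invisible(path)
}
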