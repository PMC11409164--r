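# Synthetic amorphous ensembles with planted ground truth.
#
# The generator emits toy molecular environments around a fixed 14-atom
# model molecule carrying the structural roles the analysis cares about:
# one N-H donor (N1-H1), two distinct oxygen acceptors (O1 on the ring,
# O2 on a flexible tail), ring carbons C1-C6, and a two-torsion tail
# C4-C7-C8 providing conformational variability. Each environment carries
# truth flags (hydrogen-bond class, torsion mode) and its geometry realizes
# the flags: H-bonded environments get an acceptor placed inside the
# geometric criteria, all other neighbors stay well outside them.

#' The toy model molecule
#'
#' Returns the fixed model molecule used by the synthetic ensemble: its
#' bonded graph (labels C1-C8, N1, O1, O2, H1, H2, H8; all 1H/13C sites
#' assigned), base chemical shifts, and the atom roles (donor, acceptors,
#' torsion quads).
#'
#' @return list with `graph` ([molecule_graph()]), `base_shifts` (named ppm
#'   vector), `donor_H`, `donor_heavy`, `acceptors`, `torsion1`, `torsion2`
#'   (label quads), and `coords(theta1, theta2)` returning a 14 x 3 matrix
#'   in graph atom order.
#' @export
synth_molecule <- function() {
  labels <- c("C1", "C2", "C3", "C4", "C5", "C6", "C7", "C8",
              "N1", "O1", "O2", "H1", "H2", "H8")
  elements <- substr(labels, 1, 1)
  atoms <- data.frame(label = labels, element = elements,
                      assigned = elements %in% c("C", "H"),
                      stringsAsFactors = FALSE)
  bonds <- rbind(
    c("C1", "C2"), c("C2", "C3"), c("C3", "C4"), c("C4", "C5"),
    c("C5", "C6"), c("C6", "C1"),
    c("C1", "N1"), c("N1", "H1"), c("C2", "H2"), c("C3", "O1"),
    c("C4", "C7"), c("C7", "C8"), c("C8", "O2"), c("C8", "H8"))
  graph <- molecule_graph(atoms, data.frame(a = bonds[, 1], b = bonds[, 2],
                                            stringsAsFactors = FALSE))
  base_shifts <- c(C1 = 140, C2 = 128, C3 = 192, C4 = 136, C5 = 127,
                   C6 = 129, C7 = 38, C8 = 170,
                   H1 = 8.0, H2 = 7.3, H8 = 9.5)

  ring_r <- 1.4
  hexagon <- t(vapply(0:5, function(k) {
    th <- k * pi / 3
    ring_r * c(cos(th), sin(th), 0)
  }, numeric(3)))
  coords <- function(theta1 = 0, theta2 = 180) {
    P <- matrix(NA_real_, 14, 3, dimnames = list(labels, NULL))
    P[1:6, ] <- hexagon                                  # C1..C6
    P["N1", ] <- P["C1", ] * (1 + 1.40 / ring_r)
    P["H1", ] <- P["C1", ] * (1 + 2.41 / ring_r)
    P["H2", ] <- P["C2", ] * (1 + 1.09 / ring_r)
    P["O1", ] <- P["C3", ] * (1 + 1.23 / ring_r)
    P["C7", ] <- place_atom(P["C2", ], P["C3", ], P["C4", ], 1.50, 120, 180)
    P["C8", ] <- place_atom(P["C3", ], P["C4", ], P["C7", ], 1.52, 114, theta1)
    P["O2", ] <- place_atom(P["C4", ], P["C7", ], P["C8", ], 1.23, 120, theta2)
    P["H8", ] <- place_atom(P["C4", ], P["C7", ], P["C8", ], 1.09, 120,
                            theta2 + 180)
    P
  }
  list(graph = graph, base_shifts = base_shifts,
       donor_H = "H1", donor_heavy = "N1",
       acceptors = c("O1", "O2"),
       torsion1 = c("C3", "C4", "C7", "C8"),
       torsion2 = c("C4", "C7", "C8", "O2"),
       coords = coords)
}

water_coords <- function() {
  # O at origin, hydrogens below the xy-plane, HOH angle 104.5 deg
  a <- 104.5 / 2 * pi / 180
  rbind(O = c(0, 0, 0),
        H = 0.96 * c(sin(a), 0, -cos(a)),
        H = 0.96 * c(-sin(a), 0, -cos(a)))
}

#' Synthetic-ensemble configuration
#'
#' The defaults are the stated world every test runs in: 30% of
#' environments carry a planted hydrogen bond whose geometry satisfies the
#' default detection criteria; the donor proton moves 4 ppm downfield upon
#' hydrogen bonding; shift noise is 1.3 ppm (1H) / 2.0 ppm (13C), the scale
#' of amorphous MAS linewidths; the tail torsion has two modes at 0 and
#' 180 degrees. See the methods vignette for the reasoning behind each
#' value.
#'
#' @param n_runs number of simulated runs.
#' @param n_frames frames per run.
#' @param n_molecules solute molecules (environments) per frame.
#' @param box_length periodic box edge in Angstrom for frame assembly, or
#'   `NULL` to derive the smallest isolating box.
#' @param planted_hbond_fraction fraction of environments built H-bonded.
#' @param acceptor_weights normalized weights of the H-bond partner classes
#'   (`O1`, `O2`, `water`).
#' @param dihedral_modes list of `c(center_deg, sd_deg, weight)` rows for
#'   the primary tail torsion (about the C4-C7 bond).
#' @param delta_hb downfield increment of the donor proton upon H-bonding,
#'   ppm.
#' @param noise_sd named shift noise sd per nucleus, ppm.
#' @param dihedral_coupling amplitude (ppm) of the cos(theta1) dependence
#'   of the torsion-adjacent carbons C3, C4, C5, C7.
#' @param water_fraction probability that a non-bonded neighbor is water.
#' @param decoy_range integer range of non-bonded neighbor molecules per
#'   environment.
#' @param hb_distance,hb_distance_sd planted H...A distance mean/sd, A.
#' @param hb_angle_sd planted deviation of the D-H...A angle from 180, deg.
#' @param cutoff environment cutoff, A.
#' @param step_ps frame spacing, ps.
#' @param seed integer seed; the generator is byte-reproducible given it.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_runs = 2, n_frames = 10, n_molecules = 10,
                         box_length = NULL,
                         planted_hbond_fraction = 0.3,
                         acceptor_weights = c(O1 = 0.5, O2 = 0.3,
                                              water = 0.2),
                         dihedral_modes = list(c(0, 12, 0.5),
                                               c(180, 12, 0.5)),
                         delta_hb = 4,
                         noise_sd = c("1H" = 1.3, "13C" = 2.0),
                         dihedral_coupling = 0.8,
                         water_fraction = 0.1,
                         decoy_range = 1:2,
                         hb_distance = 1.85, hb_distance_sd = 0.05,
                         hb_angle_sd = 8,
                         cutoff = 7, step_ps = 100, seed = 1) {
  if (planted_hbond_fraction < 0 || planted_hbond_fraction > 1)
    stop("planted_hbond_fraction must be in [0, 1]", call. = FALSE)
  if (any(noise_sd <= 0)) stop("noise sd must be > 0", call. = FALSE)
  w <- vapply(dihedral_modes, `[`, numeric(1), 3)
  if (any(w < 0) || sum(w) <= 0)
    stop("dihedral mode weights must be non-negative and not all zero",
         call. = FALSE)
  aw <- acceptor_weights / sum(acceptor_weights)
  structure(list(n_runs = n_runs, n_frames = n_frames,
                 n_molecules = n_molecules, box_length = box_length,
                 planted_hbond_fraction = planted_hbond_fraction,
                 acceptor_weights = aw, dihedral_modes = dihedral_modes,
                 delta_hb = delta_hb, noise_sd = noise_sd,
                 dihedral_coupling = dihedral_coupling,
                 water_fraction = water_fraction,
                 decoy_range = decoy_range,
                 hb_distance = hb_distance, hb_distance_sd = hb_distance_sd,
                 hb_angle_sd = hb_angle_sd,
                 cutoff = cutoff, step_ps = step_ps, seed = seed),
            class = "synth_config")
}

# Rotate unit vector u by `ang` degrees about a random perpendicular axis.
tilt_vector <- function(u, ang) {
  perp <- cross3(u, if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
  perp <- unit_vec(perp)
  spin <- rotation_matrix(u, runif(1, 0, 360))
  axis <- as.numeric(spin %*% perp)
  as.numeric(rotation_matrix(axis, ang) %*% u)
}

# Build one environment's atoms; returns list of per-molecule pieces.
# Internal; runs inside the generator's seeded RNG stream.
build_env_geometry <- function(config, mol, hbond, hb_class, theta1, theta2) {
  coords <- mol$coords(theta1, theta2)
  Q <- random_rotation()
  C <- coords %*% t(Q)                      # central molecule, centroid ~ origin
  C <- sweep(C, 2, colMeans(C))
  rownames(C) <- rownames(coords)
  labels <- rownames(C)
  elements <- substr(labels, 1, 1)

  pieces <- list(list(xyz = C, element = elements, label = labels,
                      water = FALSE, central = TRUE))
  H <- C["H1", ]; N <- C["N1", ]
  u <- unit_vec(H - N)                      # donor axis, N -> H

  central_het <- C[elements %in% c("N", "O"), , drop = FALSE]

  add_partner <- function() {
    dev <- min(abs(rnorm(1, 0, config$hb_angle_sd)), 3 * config$hb_angle_sd)
    w <- tilt_vector(u, dev)                # H -> acceptor direction
    rHA <- max(min(rnorm(1, config$hb_distance, config$hb_distance_sd),
                   config$hb_distance + 3 * config$hb_distance_sd),
               config$hb_distance - 3 * config$hb_distance_sd)
    A_point <- H + rHA * w
    for (attempt in 1:25) {
      if (hb_class == "water") {
        W <- water_coords()
        # hydrogens point away from the donor: -z axis of the template -> +w
        R <- rotation_between(c(0, 0, -1), w)
        P <- W %*% t(R)
        P <- P %*% t(rotation_matrix(w, runif(1, 0, 360)))
        P <- sweep(P, 2, A_point - P[1, ], "+")
        lab <- rep(NA_character_, 3); el <- c("O", "H", "H"); wat <- TRUE
      } else {
        th1p <- sample_torsion(config)
        P0 <- mol$coords(th1p, rnorm(1, 180, 10))
        parent <- if (hb_class == "O1") "C3" else "C8"
        vpa <- unit_vec(P0[parent, ] - P0[hb_class, ])  # acceptor -> parent
        R <- rotation_between(vpa, w)                   # parent beyond acceptor
        P <- P0 %*% t(R)
        P <- P %*% t(rotation_matrix(w, runif(1, 0, 360)))
        P <- sweep(P, 2, A_point - P[hb_class, ], "+")
        lab <- rownames(P0); el <- substr(lab, 1, 1); wat <- FALSE
      }
      # reject orientations creating secondary H-bond contacts: partner
      # donor hydrogens near central N/O, or partner N/O (other than the
      # planted acceptor) near the central donor proton
      phet <- P[el %in% c("N", "O"), , drop = FALSE]
      keep <- TRUE
      if (!wat) {
        ph1 <- P[which(lab == "H1"), , drop = FALSE]
        if (min(cross_dist(ph1, central_het)) < 3.2) keep <- FALSE
        others <- phet[rownames(phet) != hb_class, , drop = FALSE]
        if (nrow(others) > 0 &&
            min(cross_dist(others, matrix(H, 1, 3))) < 3.2) keep <- FALSE
      }
      if (keep || attempt == 25)
        return(list(xyz = P, element = el, label = lab, water = wat,
                    central = FALSE))
    }
  }

  if (hbond) pieces[[length(pieces) + 1]] <- add_partner()

  # non-bonded neighbors: nearest-atom distance to the *central* molecule
  # in [4.5, 6.5] A (inside the cutoff, outside the H-bond criteria), and
  # kept clear of the other molecules in the cluster
  others <- do.call(rbind, lapply(pieces[-1], `[[`, "xyz"))
  n_decoys <- if (length(config$decoy_range) == 1) config$decoy_range
              else sample(config$decoy_range, 1)
  for (d in seq_len(n_decoys)) {
    is_w <- runif(1) < config$water_fraction
    if (is_w) {
      P0 <- water_coords()
      lab <- rep(NA_character_, 3); el <- c("O", "H", "H")
    } else {
      P0 <- mol$coords(sample_torsion(config), rnorm(1, 180, 10))
      lab <- rownames(P0); el <- substr(lab, 1, 1)
    }
    P0 <- P0 %*% t(random_rotation())
    P0 <- sweep(P0, 2, colMeans(P0))
    for (attempt in 1:20) {
      target <- runif(1, 4.5, 6.5)
      v <- unit_vec(rnorm(3))
      P <- sweep(P0, 2, (6 + target) * v, "+")
      for (it in 1:8) {
        m <- min(cross_dist(P, C))
        if (abs(m - target) < 0.02) break
        P <- sweep(P, 2, (m - target) * v * (-1), "+")
      }
      ok <- abs(min(cross_dist(P, C)) - target) < 0.05 &&
        (is.null(others) || min(cross_dist(P, others)) > 3.0)
      if (ok || attempt == 20) break
    }
    pieces[[length(pieces) + 1]] <- list(xyz = P, element = el, label = lab,
                                         water = is_w, central = FALSE)
    others <- rbind(others, P)
  }
  pieces
}

sample_torsion <- function(config) {
  w <- vapply(config$dihedral_modes, `[`, numeric(1), 3)
  k <- sample.int(length(w), 1, prob = w)
  m <- config$dihedral_modes[[k]]
  ang <- rnorm(1, m[1], m[2])
  ((ang + 180) %% 360) - 180
}

sample_torsion_mode <- function(config, n) {
  w <- vapply(config$dihedral_modes, `[`, numeric(1), 3)
  sample.int(length(w), n, replace = TRUE, prob = w)
}

#' Generate a synthetic environment set with ground truth
#'
#' Directly emits unwrapped molecular environments (the fast path used for
#' large ensembles): every environment is an isolated cluster of the
#' central model molecule, an optional planted H-bond partner, and 1-2
#' non-bonded neighbor molecules at 4.5-6.5 A. Ground-truth flags
#' (`hbond`, `hbond_class`, torsion angles and mode) are returned alongside.
#' Byte-reproducible for a fixed config seed.
#'
#' @param config a [synth_config()].
#' @return object of class `synth_ensemble`: list with `atoms` (one
#'   data.table over all environments), `truth` (data.frame, one row per
#'   environment), `graph`, `molecule`, `config`.
#' @export
generate_environments <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  mol <- synth_molecule()
  n_env <- config$n_runs * config$n_frames * config$n_molecules
  with_seed(config$seed, {
    run <- rep(seq_len(config$n_runs),
               each = config$n_frames * config$n_molecules)
    frame <- rep(rep(seq_len(config$n_frames), each = config$n_molecules),
                 times = config$n_runs)
    molec <- rep(seq_len(config$n_molecules),
                 times = config$n_runs * config$n_frames)
    env_id <- sprintf("r%d:%g:%d", run, (frame - 1) * config$step_ps, molec)
    hbond <- runif(n_env) < config$planted_hbond_fraction
    cls <- rep("none", n_env)
    cls[hbond] <- sample(names(config$acceptor_weights), sum(hbond),
                         replace = TRUE, prob = config$acceptor_weights)
    mode <- sample_torsion_mode(config, n_env)
    centers <- vapply(config$dihedral_modes, `[`, numeric(1), 1)
    sds <- vapply(config$dihedral_modes, `[`, numeric(1), 2)
    theta1 <- ((rnorm(n_env, centers[mode], sds[mode]) + 180) %% 360) - 180
    theta2 <- rnorm(n_env, 180, 10)

    acc <- vector("list", n_env)
    for (i in seq_len(n_env)) {
      pieces <- build_env_geometry(config, mol, hbond[i], cls[i],
                                   theta1[i], theta2[i])
      nat <- vapply(pieces, function(p) nrow(p$xyz), integer(1))
      xyz <- do.call(rbind, lapply(pieces, `[[`, "xyz"))
      acc[[i]] <- data.table(
        env_id = env_id[i],
        label = unlist(lapply(pieces, `[[`, "label")),
        element = unlist(lapply(pieces, `[[`, "element")),
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        mol_id = rep(seq_along(pieces), nat),
        central = rep(vapply(pieces, `[[`, logical(1), "central"), nat),
        water = rep(vapply(pieces, `[[`, logical(1), "water"), nat))
    }
    atoms <- rbindlist(acc)
    setkey(atoms, env_id)
    truth <- data.frame(env_id = env_id, run_id = sprintf("r%d", run),
                        hbond = hbond, hbond_class = cls,
                        theta1 = theta1, theta2 = theta2, mode = mode,
                        stringsAsFactors = FALSE)
    structure(list(atoms = atoms, truth = truth, graph = mol$graph,
                   molecule = mol, config = config),
              class = "synth_ensemble")
  })
}

#' @export
print.synth_ensemble <- function(x, ...) {
  cat(sprintf("<synth_ensemble> %d environments (%d H-bonded), %d atoms total\n",
              nrow(x$truth), sum(x$truth$hbond), nrow(x$atoms)))
  invisible(x)
}

#' Materialize environments from a synthetic ensemble
#'
#' @param ens a `synth_ensemble` from [generate_environments()].
#' @param ids environment ids to materialize (default: all).
#' @return list of [mol_env()] objects.
#' @export
get_environments <- function(ens, ids = NULL) {
  stopifnot(inherits(ens, "synth_ensemble"))
  if (is.null(ids)) ids <- ens$truth$env_id
  run_of <- setNames(ens$truth$run_id, ens$truth$env_id)
  sub <- ens$atoms[J(ids)]
  pieces <- split(as.data.frame(sub), factor(sub$env_id, levels = ids))
  lapply(ids, function(id)
    mol_env(pieces[[id]], env_id = id, cutoff = ens$config$cutoff,
            run_id = run_of[[id]]))
}

#' Generate periodic frames realizing the synthetic ensemble
#'
#' Assembles the environment clusters of [generate_environments()] into
#' periodic frames: clusters are placed on a cubic grid with enough spacing
#' that no atom of one cluster falls within the cutoff of another, so
#' environment extraction recovers exactly the generated clusters. Molecule
#' ids are unique within a frame, solutes first.
#'
#' @param config a [synth_config()].
#' @return list with `frames` (list of [md_frame()], `n_runs * n_frames`
#'   of them in run-major order), `ensemble` (the underlying
#'   `synth_ensemble`), `graph`, `truth`.
#' @export
generate_ensemble <- function(config) {
  ens <- generate_environments(config)
  atoms <- ens$atoms
  # cluster radius: max atom distance from cluster centroid
  radii <- atoms[, {
    cx <- mean(x); cy <- mean(y); cz <- mean(z)
    .(r = max(sqrt((x - cx)^2 + (y - cy)^2 + (z - cz)^2)))
  }, by = env_id]
  spacing_needed <- 2 * max(radii$r) + ens$config$cutoff + 0.5
  per_side <- ceiling(config$n_molecules^(1 / 3))
  box <- config$box_length
  if (is.null(box)) box <- per_side * spacing_needed
  if (box < per_side * spacing_needed)
    stop(sprintf(paste0("box too small for molecule count: need >= %.1f A",
                        " for %d molecules"), per_side * spacing_needed,
                 config$n_molecules), call. = FALSE)
  spacing <- box / per_side
  sites <- as.matrix(expand.grid(x = seq_len(per_side), y = seq_len(per_side),
                                 z = seq_len(per_side)))
  sites <- (sites - 0.5) * spacing

  frames <- list()
  truth <- ens$truth
  key <- sub(":[0-9]+$", "", truth$env_id)
  for (grp in unique(key)) {
    ids <- truth$env_id[key == grp]
    t_ps <- as.numeric(sub("^r[0-9]+:", "", grp))
    pos <- list(); el <- list(); mid <- list()
    next_id <- length(ids) + 1L
    for (s in seq_along(ids)) {
      sub_at <- atoms[J(ids[s])]
      ctr <- colMeans(as.matrix(sub_at[, .(x, y, z)]))
      X <- sweep(as.matrix(sub_at[, .(x, y, z)]), 2, ctr) +
        matrix(sites[s, ], nrow(sub_at), 3, byrow = TRUE)
      ml <- sub_at$mol_id
      new_ml <- integer(length(ml))
      new_ml[ml == 1] <- s                       # the solute keeps index s
      for (m in setdiff(unique(ml), 1L)) {
        new_ml[ml == m] <- next_id
        next_id <- next_id + 1L
      }
      pos[[s]] <- X; el[[s]] <- sub_at$element; mid[[s]] <- new_ml
    }
    frames[[length(frames) + 1]] <-
      md_frame(diag(c(box, box, box)) , do.call(rbind, pos),
               unlist(el), unlist(mid), frame_time = t_ps)
  }
  list(frames = frames, ensemble = ens, graph = ens$graph, truth = truth)
}

#' Forward shift model: predicted shifts from truth flags
#'
#' The donor proton's shift is its base value plus the planted downfield
#' increment when H-bonded; carbons adjacent to the primary torsion (C3,
#' C4, C5, C7) acquire a weak `cos(theta1)` dependence; every shift gets
#' independent Gaussian noise at the per-nucleus scale. All values are
#' emitted as shifts (not shieldings).
#'
#' @param truth truth table from [generate_environments()].
#' @param config the matching [synth_config()].
#' @param seed RNG seed for the shift noise; defaults to `config$seed + 1`.
#' @return data.frame `env_id`, `atom_label`, `value_ppm`, `kind`.
#' @export
forward_shifts <- function(truth, config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(seed)) seed <- config$seed + 1
  mol <- synth_molecule()
  labels <- names(mol$base_shifts)
  n <- nrow(truth)
  with_seed(seed, {
    out <- rbindlist(lapply(labels, function(l) {
      nuc <- if (substr(l, 1, 1) == "H") "1H" else "13C"
      v <- rep(mol$base_shifts[[l]], n)
      if (l == mol$donor_H) v <- v + config$delta_hb * truth$hbond
      if (l %in% c("C3", "C4", "C5", "C7"))
        v <- v + config$dihedral_coupling * cos(truth$theta1 * pi / 180)
      v <- v + rnorm(n, 0, config$noise_sd[[nuc]])
      data.table(env_id = truth$env_id, atom_label = l, value_ppm = v,
                 kind = "shift")
    }))
    as.data.frame(out)
  })
}

#' Empirical shift distributions from a subpopulation
#'
#' Builds a [shift_distributions()] table from the per-label mean and sd of
#' predicted shifts over a set of environments — the synthetic analogue of
#' fitting the experimental spectra of an ensemble.
#'
#' @param pred predicted-shift table (`env_id`, `atom_label`, `value_ppm`).
#' @param ids environment ids defining the subpopulation.
#' @return a [shift_distributions()] table.
#' @export
empirical_distributions <- function(pred, ids) {
  dt <- as.data.table(pred)[env_id %in% ids]
  ag <- dt[, .(mean_ppm = mean(value_ppm), sd_ppm = sd(value_ppm)),
           by = atom_label]
  nuc <- ifelse(substr(ag$atom_label, 1, 1) == "H", "1H", "13C")
  shift_distributions(ag$atom_label, nuc, ag$mean_ppm, ag$sd_ppm)
}

#' Write a ready-to-run synthetic workspace
#'
#' Emits the complete input set of a pipeline run into a directory:
#' the molecule description (JSON), frames (extended-XYZ), predicted
#' shifts and ground truth (CSV).
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_synth_workspace <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gen <- generate_ensemble(config)
  write_molecule(gen$graph, file.path(dir, "molecule.json"))
  write_extxyz(gen$frames, file.path(dir, "frames.extxyz"))
  pred <- forward_shifts(gen$truth, config)
  write.csv(pred, file.path(dir, "predicted_shifts.csv"), row.names = FALSE)
  write.csv(gen$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
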