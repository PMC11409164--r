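# Independent brute-force oracles. These deliberately re-derive each
# quantity by the most transparent route available (queues, image
# enumeration, scalar double loops) and share no code with the package
# implementations they check.

# Breadth-first bond-shell oracle: heavy-atom distances via an explicit
# queue over an adjacency list, hydrogens appended afterwards.
oracle_bond_shell <- function(atoms, bonds, center, n_bonds) {
  elem <- setNames(atoms$element, atoms$label)
  adj <- list()
  for (i in seq_len(nrow(bonds))) {
    a <- bonds$a[i]; b <- bonds$b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  start <- center
  if (elem[[center]] == "H") {
    hv <- Filter(function(l) elem[[l]] != "H", adj[[center]])
    start <- hv[1]
  }
  dist <- setNames(rep(Inf, nrow(atoms)), atoms$label)
  dist[start] <- 0
  queue <- start
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (elem[[w]] == "H") next
      if (dist[w] > dist[v] + 1) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  heavy <- names(dist)[is.finite(dist) & dist <= n_bonds & elem[names(dist)] != "H"]
  hydro <- unique(unlist(lapply(heavy, function(h)
    Filter(function(l) elem[[l]] == "H", adj[[h]]))))
  sort(unique(c(center, heavy, hydro)))
}

# Random connected molecule: a heavy-atom tree plus optional extra edges,
# with hydrogens hanging off random heavy atoms.
random_molecule <- function(n_heavy = 8, n_h = 4, extra_edges = 1) {
  heavy <- sprintf("C%d", seq_len(n_heavy))
  bonds <- data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n_heavy - 1)) {
    j <- sample(i, 1)
    bonds <- rbind(bonds, data.frame(a = heavy[i + 1], b = heavy[j]))
  }
  for (k in seq_len(extra_edges)) {
    ij <- sample(n_heavy, 2)
    pair <- sort(heavy[ij])
    dup <- any(bonds$a == pair[1] & bonds$b == pair[2] |
               bonds$a == pair[2] & bonds$b == pair[1])
    if (!dup) bonds <- rbind(bonds, data.frame(a = pair[1], b = pair[2]))
  }
  hs <- character(0)
  if (n_h > 0) {
    hs <- sprintf("H%d", seq_len(n_h))
    for (h in hs)
      bonds <- rbind(bonds, data.frame(a = h, b = sample(heavy, 1)))
  }
  atoms <- data.frame(label = c(heavy, hs),
                      element = c(rep("C", n_heavy), rep("H", length(hs))),
                      assigned = TRUE, stringsAsFactors = FALSE)
  list(atoms = atoms, bonds = bonds)
}

# 27-image neighbor oracle: which molecules have any atom within `cutoff`
# of the central molecule, enumerating every lattice image explicitly.
oracle_neighbor_set <- function(frame, central_mol, whole_positions, cutoff) {
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) %*% frame$lattice
  ci <- which(frame$mol_ids == central_mol)
  C <- whole_positions[ci, , drop = FALSE]
  found <- integer(0)
  for (m in setdiff(unique(frame$mol_ids), central_mol)) {
    P <- whole_positions[frame$mol_ids == m, , drop = FALSE]
    best <- Inf
    for (s in seq_len(nrow(shifts))) {
      Ps <- sweep(P, 2, shifts[s, ], "+")
      for (i in seq_len(nrow(C))) {
        d <- sqrt(rowSums(sweep(Ps, 2, C[i, ])^2))
        best <- min(best, min(d))
      }
    }
    if (best <= cutoff) found <- c(found, m)
  }
  sort(found)
}

# Scalar pair-sum oracle for the toy potential: a plain double loop over
# atom pairs, wells written out term by term.
oracle_toy_energy <- function(pos, el, eps_hb = 5, r_hb = 1.85, w_hb = 0.25) {
  eps <- c(C = 0.10, N = 0.15, O = 0.15, H = 0.05)
  contact <- c(C = 1.70, N = 1.55, O = 1.52, H = 1.20)
  n <- nrow(pos)
  # donor hydrogens: nearest N/O within 1.15 A
  donor_of <- rep(NA_integer_, n)
  for (i in which(el == "H")) {
    het <- which(el %in% c("N", "O"))
    if (length(het) == 0) next
    d <- sqrt(rowSums(sweep(pos[het, , drop = FALSE], 2, pos[i, ])^2))
    if (min(d) <= 1.15) donor_of[i] <- het[which.min(d)]
  }
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    e <- e - sqrt(eps[[el[i]]] * eps[[el[j]]]) *
      exp(-(r - contact[[el[i]]] - contact[[el[j]]])^2 / (2 * 0.5^2))
  }
  for (i in which(!is.na(donor_of))) {
    for (j in which(el %in% c("N", "O"))) {
      if (j == donor_of[i]) next
      vHA <- pos[j, ] - pos[i, ]
      vHD <- pos[donor_of[i], ] - pos[i, ]
      rHA <- sqrt(sum(vHA^2))
      cosang <- sum(vHA * vHD) / (rHA * sqrt(sum(vHD^2)))
      theta <- acos(min(max(cosang, -1), 1)) * 180 / pi
      if (theta >= 90)
        e <- e - eps_hb * exp(-(rHA - r_hb)^2 / (2 * w_hb^2)) * cosang^2
    }
  }
  e
}

# Build a tiny frame from per-molecule coordinate blocks (already whole).
frame_from_molecules <- function(mols, box, frame_time = 0) {
  pos <- do.call(rbind, lapply(mols, `[[`, "xyz"))
  md_frame(diag(rep(box, 3)), pos,
           unlist(lapply(mols, `[[`, "element")),
           rep(seq_along(mols), vapply(mols, function(m) nrow(m$xyz),
                                       integer(1))),
           frame_time)
}

# A rigid 3-atom chain "molecule" at a given anchor.
chain_molecule <- function(anchor, direction = c(1, 0, 0)) {
  u <- direction / sqrt(sum(direction^2))
  xyz <- rbind(anchor, anchor + 1.0 * u, anchor + 2.0 * u)
  list(xyz = xyz, element = c("C", "C", "C"))
}

# Minimal mol_env builder for constructed-geometry tests.
make_env <- function(coords, elements, labels = NULL, central = NULL,
                     water = NULL, mol_ids = NULL, env_id = "t:0:1") {
  n <- nrow(coords)
  if (is.null(labels)) labels <- rep(NA_character_, n)
  if (is.null(central)) central <- rep(TRUE, n)
  if (is.null(water)) water <- rep(FALSE, n)
  if (is.null(mol_ids)) mol_ids <- as.integer(!central) + 1L
  mol_env(data.frame(label = labels, element = elements,
                     x = coords[, 1], y = coords[, 2], z = coords[, 3],
                     mol_id = mol_ids, central = central, water = water,
                     stringsAsFactors = FALSE),
          env_id = env_id)
}
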