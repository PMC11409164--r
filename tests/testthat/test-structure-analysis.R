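# Constructed-geometry H-bond fixtures: central N-H donor along +x,
# acceptors placed at chosen distance/angle from the proton.
donor_env <- function(acceptors, acc_elements = NULL, acc_water = FALSE,
                      extra_central = NULL) {
  N <- c(0, 0, 0); H <- c(1.0, 0, 0)
  coords <- rbind(N, H)
  labels <- c("N1", "H1")
  elements <- c("N", "H")
  central <- c(TRUE, TRUE)
  if (!is.null(extra_central)) {
    coords <- rbind(coords, extra_central$coords)
    labels <- c(labels, extra_central$labels)
    elements <- c(elements, extra_central$elements)
    central <- c(central, rep(TRUE, length(extra_central$labels)))
  }
  if (!is.null(acceptors)) {
    acceptors <- matrix(acceptors, ncol = 3)
    if (is.null(acc_elements)) acc_elements <- rep("O", nrow(acceptors))
    coords <- rbind(coords, acceptors)
    labels <- c(labels, sprintf("O%d", 10 + seq_len(nrow(acceptors))))
    elements <- c(elements, acc_elements)
    central <- c(central, rep(FALSE, nrow(acceptors)))
  }
  make_env(coords, elements, labels, central,
           water = c(rep(FALSE, sum(central)),
                     rep(acc_water, sum(!central))))
}

# Acceptor position at distance r from H with D-H...A angle `ang` (deg).
acc_at <- function(r, ang) {
  th <- (180 - ang) * pi / 180
  c(1.0, 0, 0) + r * c(cos(th), sin(th), 0)
}

test_that("hydrogen bonds are detected by distance and angle criteria", {
  crit <- hbond_criteria(2.5, 120)
  env <- donor_env(acc_at(1.9, 165))
  rec <- detect_hbond(env, "H1", crit)
  expect_identical(rec$acceptor_class, "O11")
  expect_equal(rec$HA_distance, 1.9, tolerance = 1e-9)
  expect_equal(rec$DHA_angle, 165, tolerance = 1e-9)

  # no candidate acceptor at all
  expect_identical(detect_hbond(donor_env(NULL), "H1", crit)$acceptor_class,
                   "none")
  # distance criterion violated
  expect_identical(detect_hbond(donor_env(acc_at(2.6, 165)), "H1",
                                crit)$acceptor_class, "none")
  # angle criterion violated
  expect_identical(detect_hbond(donor_env(acc_at(1.9, 100)), "H1",
                                crit)$acceptor_class, "none")
  # nearest passing acceptor wins
  env2 <- donor_env(rbind(acc_at(2.2, 170), acc_at(1.9, 150)))
  expect_identical(detect_hbond(env2, "H1", crit)$acceptor_class, "O12")
  # water class
  env3 <- donor_env(acc_at(1.9, 165), acc_water = TRUE)
  expect_identical(detect_hbond(env3, "H1", crit)$acceptor_class, "water")
  expect_error(detect_hbond(env, "H9", crit), "not found")
})

test_that("intramolecular acceptors are excluded unless requested", {
  intra <- list(coords = matrix(acc_at(1.9, 160), 1),
                labels = "O5", elements = "O")
  env <- donor_env(NULL, extra_central = intra)
  expect_identical(detect_hbond(env, "H1")$acceptor_class, "none")
  # with the flag (no graph: no separation filter) the acceptor counts
  expect_identical(detect_hbond(env, "H1",
                                include_intramolecular = TRUE)$acceptor_class,
                   "O5")
})

test_that("H-bond detection is invariant under rigid motion", {
  set.seed(31)
  env <- donor_env(rbind(acc_at(2.0, 155), acc_at(2.3, 175)))
  rec <- detect_hbond(env, "H1")
  for (i in 1:5) {
    R <- rotation_matrix(rnorm(3), runif(1, 0, 360))
    tr <- rnorm(3, sd = 10)
    at <- env$atoms
    X <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
    at$x <- X[, 1] + tr[1]; at$y <- X[, 2] + tr[2]; at$z <- X[, 3] + tr[3]
    rec2 <- detect_hbond(mol_env(at, env$env_id), "H1")
    expect_identical(rec2$acceptor_class, rec$acceptor_class)
    expect_equal(rec2$HA_distance, rec$HA_distance, tolerance = 1e-9)
    expect_equal(rec2$DHA_angle, rec$DHA_angle, tolerance = 1e-6)
  }
})

test_that("dihedral angles follow the IUPAC convention", {
  p1 <- c(1, 1, 0); p2 <- c(1, 0, 0); p3 <- c(0, 0, 0)
  expect_equal(dihedral_angle(p1, p2, p3, c(0, 1, 0)), 0)     # cis
  expect_equal(dihedral_angle(p1, p2, p3, c(0, -1, 0)), 180)  # trans
  # gauche by explicit rotation of the cis position about the central bond
  for (ang in c(60, -60, 120, 175, -175)) {
    R <- rotation_matrix(p3 - p2, ang)  # right-handed about the 2->3 axis
    p4 <- as.numeric(R %*% c(0, 1, 0))
    expect_equal(dihedral_angle(p1, p2, p3, p4), ang, tolerance = 1e-9)
  }
  # reversal antisymmetry (180 identified with -180)
  set.seed(32)
  for (i in 1:10) {
    q <- matrix(rnorm(12, sd = 2), 4, 3)
    a <- try(dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ]), silent = TRUE)
    if (inherits(a, "try-error")) next
    # IUPAC torsions read the same from either end of the chain
    b <- dihedral_angle(q[4, ], q[3, ], q[2, ], q[1, ])
    d <- abs(a - b) %% 360
    expect_lt(min(d, 360 - d), 1e-8)
    # rigid-motion invariance
    R <- rotation_matrix(rnorm(3), runif(1, 0, 360))
    qt <- q %*% t(R) + matrix(rnorm(3), 4, 3, byrow = TRUE)
    expect_equal(dihedral_angle(qt[1, ], qt[2, ], qt[3, ], qt[4, ]), a,
                 tolerance = 1e-8)
  }
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("category comparison counts and percentages are consistent", {
  same <- rep(c("O13", "water", "none"), c(5, 3, 2))
  cc <- compare_categories(same, same)
  expect_equal(cc$percent_MD, cc$percent_NMR)
  expect_equal(sum(cc$percent_MD), 100)

  md <- rep(c("A", "B"), c(10, 90))
  nmr <- rep(c("A", "B"), c(25, 75))
  cc2 <- compare_categories(md, nmr, categories = c("A", "B", "C"))
  expect_equal(cc2$percent_MD, c(10, 90, 0))
  expect_equal(cc2$percent_NMR, c(25, 75, 0))
  expect_equal(cc2$delta, c(15, -15, 0))
  expect_equal(cc2$count_NMR, c(25, 75, 0))
  expect_error(compare_categories(character(0), "A"), "non-empty")
})

test_that("angle histograms bin periodically on (-180, 180]", {
  h <- angle_histogram(rep(0, 50), 10)
  expect_equal(sum(h$count > 0), 1)
  expect_equal(h$upper[h$count > 0], 0)  # right-closed: 0 is in (-10, 0]
  expect_equal(sum(h$frequency), 1)

  u <- angle_histogram(seq(-179, 180, by = 1), 10)
  expect_true(all(u$count == 10))
  expect_equal(nrow(u), 36)

  # 180 and -180 denote the same torsion
  hh <- angle_histogram(c(180, -180), 90)
  expect_equal(sum(hh$count > 0), 1)
  expect_equal(hh$count[hh$upper == 180], 2)
  expect_error(angle_histogram(1:5, 7), "divide")
})

test_that("labeled torsions are read off environments", {
  mol <- synth_molecule()
  P <- mol$coords(72, 180)
  env <- make_env(P, substr(rownames(P), 1, 1), rownames(P))
  rec <- env_dihedral(env, mol$torsion1)
  expect_equal(rec$angle_deg, 72, tolerance = 1e-9)
  expect_identical(rec$quad, "C3-C4-C7-C8")
})
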