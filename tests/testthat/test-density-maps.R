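test_that("kabsch alignment recovers constructed rigid motions", {
  mol <- synth_molecule()
  P <- mol$coords(30, 180)
  env <- make_env(P, substr(rownames(P), 1, 1), rownames(P))
  spec <- alignment_spec(c("N1", "C1", "C2", "C4"), "kabsch")
  template <- P[c("N1", "C1", "C2", "C4"), ]

  idfit <- align_environment(env, spec, template)
  expect_equal(idfit$rmsd, 0, tolerance = 1e-9)
  expect_equal(idfit$R, diag(3), tolerance = 1e-9)

  set.seed(41)
  for (i in 1:5) {
    R <- rotation_matrix(rnorm(3), runif(1, 0, 360))
    tr <- rnorm(3, sd = 8)
    at <- env$atoms
    X <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
    at$x <- X[, 1] + tr[1]; at$y <- X[, 2] + tr[2]; at$z <- X[, 3] + tr[3]
    moved <- mol_env(at, env$env_id)
    fit <- align_environment(moved, spec, template)
    expect_lt(fit$rmsd, 1e-8)
    Xb <- as.matrix(fit$env$atoms[, c("x", "y", "z")])
    expect_equal(Xb, unname(P), tolerance = 1e-7, ignore_attr = TRUE)
    expect_equal(det(fit$R), 1, tolerance = 1e-9)
  }
})

test_that("superposition never applies a reflection", {
  # near-planar reference: the improper solution would fit better by
  # mirroring, the proper-rotation constraint must refuse it
  P <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0), c(1.5, 1.5, 0.01))
  Q <- P; Q[, 3] <- -Q[, 3]  # mirrored target
  k <- kabsch(P, Q)
  expect_equal(det(k$R), 1, tolerance = 1e-9)
  expect_gt(k$rmsd, 0)
})

test_that("bond-axis alignment fixes origin, axis, and azimuth", {
  mol <- synth_molecule()
  P <- mol$coords(0, 180)
  env <- make_env(P, substr(rownames(P), 1, 1), rownames(P))
  spec <- alignment_spec(c("N1", "H1", "C2"), "bond_axis")
  fit <- align_environment(env, spec)
  A <- fit$env$atoms
  getl <- function(l) as.numeric(A[A$label == l, c("x", "y", "z")])
  expect_equal(getl("N1"), c(0, 0, 0), tolerance = 1e-9)
  h1 <- getl("H1")
  expect_equal(h1[1:2], c(0, 0), tolerance = 1e-9)
  expect_gt(h1[3], 0)                       # bond on +z
  c2 <- getl("C2")
  expect_equal(c2[2], 0, tolerance = 1e-9)  # azimuth atom in the xz plane
  expect_gt(c2[1], 0)                       # on the x > 0 side
  expect_error(alignment_spec(c("N1", "H1"), "bond_axis"), "exactly 3")
  # an azimuth atom on the bond axis cannot fix the frame
  expect_error(align_environment(env, alignment_spec(c("N1", "H1", "C1"),
                                                     "bond_axis")),
               "collinear")
  # collinear kabsch reference is refused with a pointer to bond_axis
  line <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  env_l <- make_env(line, c("C", "C", "C"), c("A1", "A2", "A3"))
  expect_error(align_environment(env_l, alignment_spec(c("A1", "A2", "A3")),
                                 template = line), "bond_axis")
})

test_that("density normalization gives max 1 for a persistent atom", {
  env1 <- make_env(matrix(c(0, 0, 0), 1), "C", "C1")
  m1 <- accumulate_density(list(env1), w = 0.5, L = 12, h = 0.2)
  expect_equal(max(m1$channels$C), 1, tolerance = 1e-6)
  expect_equal(density_at(m1, "C", c(0, 0, 0))$value, 1, tolerance = 1e-12)

  m10 <- accumulate_density(rep(list(env1), 10), w = 0.5, L = 12, h = 0.2)
  expect_equal(max(m10$channels$C), 1, tolerance = 1e-6)

  # atom present in one of two environments: averaged max 0.5
  env_far <- make_env(matrix(c(100, 100, 100), 1), "C", "C1")
  m2 <- accumulate_density(list(env1, env_far), w = 0.5, L = 12, h = 0.2)
  expect_equal(max(m2$channels$C), 0.5, tolerance = 1e-6)

  # closed-form value 0.5 A from a lone atom
  m3 <- accumulate_density(list(env1), w = 0.5, L = 12, h = 0.25)
  expect_equal(density_at(m3, "C", c(0.5, 0, 0))$value,
               exp(-0.5^2 / (2 * 0.5^2)), tolerance = 1e-9)
  expect_error(accumulate_density(list(), 0.5, 12, 0.2), "no environments")
  expect_error(accumulate_density(list(env1), w = 0.5, h = 0.6), "exceed")
})

test_that("grid accumulation equals the direct double sum", {
  set.seed(42)
  envs <- lapply(1:4, function(i) {
    n <- sample(3:8, 1)
    make_env(matrix(runif(3 * n, -4, 4), n),
             sample(c("C", "O", "H"), n, replace = TRUE))
  })
  map <- accumulate_density(envs, w = 0.5, L = 12, h = 0.5)
  at_all <- do.call(rbind, lapply(envs, function(e) e$atoms))
  for (rep in 1:20) {
    i <- sample(length(map$axis), 3)
    pt <- map$axis[i]
    for (el in names(map$channels)) {
      sel <- at_all$element == el
      direct <- if (!any(sel)) 0 else
        sum(exp(-((at_all$x[sel] - pt[1])^2 + (at_all$y[sel] - pt[2])^2 +
                    (at_all$z[sel] - pt[3])^2) / (2 * 0.5^2))) / length(envs)
      expect_equal(map$channels[[el]][i[1], i[2], i[3]], direct,
                   tolerance = 1e-12)
    }
  }
})

test_that("channel integrals scale with the atom count", {
  e1 <- make_env(matrix(c(0, 0, 0), 1), "C", "C1")
  e2 <- make_env(rbind(c(1, 0, 0), c(-1, 0, 0)), c("C", "C"))
  m1 <- accumulate_density(list(e1), w = 0.5, L = 12, h = 0.3)
  m2 <- accumulate_density(list(e2), w = 0.5, L = 12, h = 0.3)
  expect_equal(sum(m2$channels$C) / sum(m1$channels$C), 2, tolerance = 1e-6)
})

test_that("cube files round-trip", {
  set.seed(43)
  env <- make_env(matrix(runif(9, -2, 2), 3), c("C", "C", "O"))
  map <- accumulate_density(list(env), w = 0.5, L = 12, h = 0.2)
  expect_length(map$axis, 61)
  path <- tempfile(fileext = ".cube")
  export_cube(map, "C", path)
  cb <- read_cube(path)
  expect_equal(dim(cb$values), c(61, 61, 61))
  expect_equal(cb$axis, map$axis, tolerance = 1e-5)
  expect_equal(max(cb$values), max(map$channels$C), tolerance = 1e-5)
  expect_equal(which.max(cb$values), which.max(map$channels$C))
  expect_equal(cb$values, map$channels$C, tolerance = 1e-4)

  # an element absent from the environments gives an all-zero cube
  map_h <- accumulate_density(list(env), w = 0.5, L = 12, h = 0.2,
                              elements = c("C", "H"))
  export_cube(map_h, "H", path)
  expect_true(all(read_cube(path)$values == 0))
  expect_error(export_cube(map, "Xx", path), "unknown element")
})

test_that("maps are invariant to a common rigid motion before alignment", {
  mol <- synth_molecule()
  P <- mol$coords(45, 180)
  env <- make_env(P, substr(rownames(P), 1, 1), rownames(P))
  spec <- alignment_spec(c("N1", "H1", "C2"), "bond_axis")
  m_ref <- accumulate_density(list(align_environment(env, spec)$env),
                              w = 0.5, L = 12, h = 0.4)
  R <- rotation_matrix(c(1, 2, 3), 77)
  at <- env$atoms
  X <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at$x <- X[, 1] + 5; at$y <- X[, 2] - 3; at$z <- X[, 3] + 1
  m_mov <- accumulate_density(list(align_environment(mol_env(at, "m"),
                                                     spec)$env),
                              w = 0.5, L = 12, h = 0.4)
  expect_equal(m_mov$channels$C, m_ref$channels$C, tolerance = 1e-9)
  expect_equal(m_mov$channels$O, m_ref$channels$O, tolerance = 1e-9)
})
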