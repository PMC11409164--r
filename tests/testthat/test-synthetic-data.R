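test_that("generation is byte-reproducible from the seed", {
  cfg <- synth_config(n_runs = 1, n_frames = 2, n_molecules = 5, seed = 77)
  e1 <- generate_environments(cfg)
  e2 <- generate_environments(cfg)
  expect_identical(e1$atoms, e2$atoms)
  expect_identical(e1$truth, e2$truth)
  e3 <- generate_environments(synth_config(n_runs = 1, n_frames = 2,
                                           n_molecules = 5, seed = 78))
  expect_false(identical(e1$atoms, e3$atoms))
  # shift noise is reproducible too
  expect_identical(forward_shifts(e1$truth, cfg),
                   forward_shifts(e1$truth, cfg))
})

test_that("a zero planted fraction yields no detectable hydrogen bonds", {
  cfg <- synth_config(n_runs = 1, n_frames = 5, n_molecules = 20,
                      planted_hbond_fraction = 0, seed = 5)
  ens <- generate_environments(cfg)
  rec <- detect_hbonds(get_environments(ens), "H1")
  expect_true(all(rec$acceptor_class == "none"))
})

test_that("truth flags and geometric detection agree", {
  cfg <- synth_config(n_runs = 2, n_frames = 10, n_molecules = 25, seed = 21)
  ens <- generate_environments(cfg)
  rec <- detect_hbonds(get_environments(ens), "H1")
  stopifnot(identical(rec$env_id, ens$truth$env_id))
  agree <- mean((rec$acceptor_class != "none") == ens$truth$hbond)
  expect_gte(agree, 0.99)
  # detected class matches the planted class wherever both exist
  both <- ens$truth$hbond & rec$acceptor_class != "none"
  cls <- ifelse(ens$truth$hbond_class == "water", "water",
                ens$truth$hbond_class)
  expect_gte(mean(rec$acceptor_class[both] == cls[both]), 0.99)
  # planted torsions are the measured torsions
  mol <- synth_molecule()
  envs <- get_environments(ens, ens$truth$env_id[1:20])
  th <- vapply(envs, function(e) env_dihedral(e, mol$torsion1)$angle_deg,
               numeric(1))
  dd <- abs(th - ens$truth$theta1[1:20])
  expect_true(all(pmin(dd, 360 - dd) < 1e-6))
})

test_that("the detected H-bond fraction matches the planted rate", {
  cfg <- synth_config(n_runs = 2, n_frames = 50, n_molecules = 100,
                      planted_hbond_fraction = 0.3, seed = 33)
  ens <- generate_environments(cfg)           # 10,000 environments
  rec <- detect_hbonds(get_environments(ens), "H1")
  expect_lt(abs(mean(rec$acceptor_class != "none") - 0.3), 0.01)
})

test_that("the forward shift model plants the downfield donor signal", {
  cfg <- synth_config(n_runs = 1, n_frames = 20, n_molecules = 50, seed = 3)
  ens <- generate_environments(cfg)
  pred <- forward_shifts(ens$truth, cfg)
  h1 <- pred[pred$atom_label == "H1", ]
  stopifnot(identical(h1$env_id, ens$truth$env_id))
  expect_equal(mean(h1$value_ppm[ens$truth$hbond]), 12,
               tolerance = 0.2 / 12)
  expect_equal(mean(h1$value_ppm[!ens$truth$hbond]), 8, tolerance = 0.2 / 8)
  expect_true(all(pred$kind == "shift"))

  # null construction: with delta_hb = 0 the two populations coincide;
  # allow at most one spurious rejection at alpha = 0.01 over 20 repeats
  p_vals <- vapply(1:20, function(r) {
    cfg0 <- synth_config(n_runs = 1, n_frames = 5, n_molecules = 40,
                         delta_hb = 0, seed = 100 + r)
    ens0 <- generate_environments(cfg0)
    pr <- forward_shifts(ens0$truth, cfg0)
    v <- pr$value_ppm[pr$atom_label == "H1"]
    hb <- ens0$truth$hbond
    if (sum(hb) < 3 || sum(!hb) < 3) return(1)
    t.test(v[hb], v[!hb])$p.value
  }, numeric(1))
  expect_lte(sum(p_vals < 0.01), 1)
})

test_that("stronger planted signals select more H-bonded environments", {
  enrich <- vapply(c(0.5, 2, 4), function(delta) {
    cfg <- synth_config(n_runs = 1, n_frames = 40, n_molecules = 50,
                        delta_hb = delta, seed = 55)
    ens <- generate_environments(cfg)
    pred <- forward_shifts(ens$truth, cfg)
    dists <- empirical_distributions(pred, ens$truth$env_id[ens$truth$hbond])
    shell <- bond_shell(ens$graph, "N1", 3)
    sc <- local_probability(pred, dists, shell)
    sel <- select_environments(sc, "top_fraction", fraction = 0.05)
    mean(ens$truth$hbond[match(sel$env_id[sel$selected],
                               ens$truth$env_id)])
  }, numeric(1))
  expect_true(all(diff(enrich) > 0))
})

test_that("frames realize the same environments as the direct path", {
  cfg <- synth_config(n_runs = 1, n_frames = 2, n_molecules = 4, seed = 13)
  gen <- generate_ensemble(cfg)
  expect_length(gen$frames, 2)
  direct <- get_environments(gen$ensemble)
  for (fi in seq_along(gen$frames)) {
    envs <- extract_environments(gen$frames[[fi]], cutoff = cfg$cutoff,
                                 graph = gen$graph, run_id = "r1")
    # neighbor drug molecules legitimately become centrals of their own
    # extracted environments; only the generated solute environments have
    # a direct-path counterpart
    matched <- envs[vapply(envs, function(e)
      e$env_id %in% gen$truth$env_id, logical(1))]
    expect_length(matched, cfg$n_molecules)
    for (e in matched) {
      idx <- match(e$env_id, gen$truth$env_id)
      d <- direct[[idx]]
      # same molecules with identical internal geometry (clusters are
      # placed by translation only)
      expect_identical(nrow(e$atoms), nrow(d$atoms))
      expect_identical(e$atoms$element, d$atoms$element)
      Xe <- as.matrix(e$atoms[, c("x", "y", "z")])
      Xd <- as.matrix(d$atoms[, c("x", "y", "z")])
      expect_equal(sweep(Xe, 2, colMeans(Xe)), sweep(Xd, 2, colMeans(Xd)),
                   tolerance = 1e-7, ignore_attr = TRUE)
      # labels transferred onto the central molecule
      expect_identical(e$atoms$label[e$atoms$central],
                       d$atoms$label[d$atoms$central])
      expect_identical(e$atoms$water, d$atoms$water)
    }
  }
  expect_error(generate_ensemble(synth_config(n_runs = 1, n_frames = 1,
                                              n_molecules = 27,
                                              box_length = 30, seed = 1)),
               "box too small")
})

test_that("a synthetic workspace is written complete and readable", {
  dir <- tempfile("ws")
  cfg <- synth_config(n_runs = 1, n_frames = 2, n_molecules = 3, seed = 2)
  write_synth_workspace(cfg, dir)
  expect_true(all(file.exists(file.path(dir,
    c("molecule.json", "frames.extxyz", "predicted_shifts.csv",
      "truth.csv")))))
  g <- read_molecule(file.path(dir, "molecule.json"))
  expect_equal(nrow(g$atoms), 14)
  frames <- read_extxyz(file.path(dir, "frames.extxyz"))
  expect_length(frames, 2)
  pred <- read_predicted_shifts(file.path(dir, "predicted_shifts.csv"))
  expect_setequal(unique(pred$atom_label),
                  g$atoms$label[g$atoms$assigned])
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(planted_hbond_fraction = 1.2), "\\[0, 1\\]")
  expect_error(synth_config(noise_sd = c("1H" = -1, "13C" = 2)), "> 0")
  expect_error(synth_config(dihedral_modes = list(c(0, 10, 0))),
               "weights")
})
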