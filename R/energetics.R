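# Formation energies of local molecular environments.
#
# The formation energy is the difference between the energy of the full
# environment and the energy of the same environment with the central
# molecule removed: it captures the central molecule's conformational
# energy plus its intermolecular interactions. The quantum-chemical backend
# used in production work (semi-empirical tight binding) is external; the
# backend here is a pluggable contract with a shipped toy potential that is
# sufficient for every test, and an external-command adapter.

#' Energy backend contract
#'
#' @param name backend name.
#' @param evaluate function `(positions, elements) -> energy in kJ/mol`;
#'   must be deterministic and size-consistent (non-interacting fragments
#'   sum).
#' @return object of class `energy_backend`.
#' @export
energy_backend <- function(name, evaluate) {
  stopifnot(is.function(evaluate))
  structure(list(name = name, evaluate = evaluate), class = "energy_backend")
}

toy_default_params <- function() {
  list(eps = c(C = 0.10, N = 0.15, O = 0.15, H = 0.05),
       contact = c(C = 1.70, N = 1.55, O = 1.52, H = 1.20),
       pair_w = 0.5,       # width of the soft contact well, A
       eps_hb = 5,         # H-bond well depth, kJ/mol
       r_hb = 1.85,        # H-bond optimum H...A distance, A
       w_hb = 0.25)        # H-bond well width, A
}

# Index of the covalently bound heavy partner (N/O) for every hydrogen;
# NA for hydrogens not bound to a heteroatom.
donor_partners <- function(positions, elements, covalent_cut = 1.15) {
  partner <- rep(NA_integer_, length(elements))
  hs <- which(elements == "H")
  het <- which(elements %in% c("N", "O"))
  if (length(hs) == 0 || length(het) == 0) return(partner)
  D <- cross_dist(positions[hs, , drop = FALSE],
                  positions[het, , drop = FALSE])
  for (a in seq_along(hs)) {
    j <- which.min(D[a, ])
    if (D[a, j] <= covalent_cut) partner[hs[a]] <- het[j]
  }
  partner
}

#' Toy pairwise energy backend
#'
#' A transparent stand-in for a quantum-chemical backend: per element pair,
#' a soft Gaussian contact well (depth = geometric mean of per-element
#' depths `eps`, centered at the sum of contact radii); plus a directional
#' hydrogen-bond well between donor hydrogens (H covalently bound to N/O)
#' and N/O acceptors, with depth `eps_hb` at the optimum H...A distance
#' `r_hb`, Gaussian in distance and `cos^2`-modulated in the D-H...A angle
#' (zero below 90 degrees). Pairwise-additive given the donor assignment,
#' deterministic, rigid-motion invariant, and size-consistent: all terms
#' decay to zero at separation.
#'
#' @param eps_hb hydrogen-bond well depth, kJ/mol.
#' @param r_hb optimum H...A distance, Angstrom.
#' @param w_hb H-bond well width, Angstrom.
#' @param eps named per-element contact-well depths, kJ/mol (overrides the
#'   defaults C 0.10, N 0.15, O 0.15, H 0.05).
#' @return an [energy_backend()].
#' @export
toy_backend <- function(eps_hb = 5, r_hb = 1.85, w_hb = 0.25, eps = NULL) {
  par <- toy_default_params()
  par$eps_hb <- eps_hb; par$r_hb <- r_hb; par$w_hb <- w_hb
  if (!is.null(eps)) par$eps[names(eps)] <- eps
  evaluate <- function(positions, elements) {
    positions <- as.matrix(positions)
    n <- nrow(positions)
    if (n < 2) return(0)
    unknown <- setdiff(unique(elements), names(par$eps))
    if (length(unknown) > 0)
      stop("no toy parameters for element(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    D <- cross_dist(positions, positions)
    ci <- par$contact[elements]
    ei <- par$eps[elements]
    R0 <- outer(ci, ci, "+")
    EPS <- sqrt(outer(ei, ei))
    W <- -EPS * exp(-(D - R0)^2 / (2 * par$pair_w^2))
    e <- sum(W[upper.tri(W)])
    # directional H-bond wells
    partner <- donor_partners(positions, elements)
    donors <- which(!is.na(partner))
    acceptors <- which(elements %in% c("N", "O"))
    for (hi in donors) {
      acc <- setdiff(acceptors, partner[hi])
      if (length(acc) == 0) next
      H <- positions[hi, ]
      A <- positions[acc, , drop = FALSE]
      v2 <- sweep(A, 2, H)
      rHA <- sqrt(rowSums(v2^2))
      v1 <- positions[partner[hi], ] - H
      cosang <- (v2 %*% v1) / pmax(rHA * vec_norm(v1), 1e-12)
      cosang <- pmin(pmax(cosang, -1), 1)
      theta <- acos(cosang) * 180 / pi
      ok <- theta >= 90
      if (any(ok))
        e <- e - sum(par$eps_hb *
                       exp(-(rHA[ok] - par$r_hb)^2 / (2 * par$w_hb^2)) *
                       cosang[ok]^2)
    }
    e
  }
  energy_backend(sprintf("toy(eps_hb=%g)", eps_hb), evaluate)
}

#' External-command energy backend
#'
#' Adapter for plugging an external program (e.g. a tight-binding code):
#' the structure is written as XYZ to a temporary file, the command template
#' is run with `{xyz}` substituted, and the last whitespace-separated token
#' of its standard output is read as the energy and multiplied by
#' `unit_to_kj`.
#'
#' @param command_template shell command containing the placeholder `{xyz}`.
#' @param unit_to_kj conversion factor from the program's unit to kJ/mol.
#' @param name backend name.
#' @return an [energy_backend()].
#' @export
command_backend <- function(command_template, unit_to_kj = 1,
                            name = "command") {
  evaluate <- function(positions, elements) {
    xyz <- tempfile(fileext = ".xyz")
    on.exit(unlink(xyz))
    writeLines(c(as.character(length(elements)), "nmrcryst command backend",
                 sprintf("%-3s %16.8f %16.8f %16.8f", elements,
                         positions[, 1], positions[, 2], positions[, 3])),
               xyz)
    cmd <- gsub("{xyz}", xyz, command_template, fixed = TRUE)
    out <- system(cmd, intern = TRUE)
    toks <- strsplit(trimws(paste(out, collapse = " ")), "\\s+")[[1]]
    val <- suppressWarnings(as.numeric(toks[length(toks)]))
    if (!is.finite(val))
      stop("backend command produced no numeric energy: ", cmd, call. = FALSE)
    val * unit_to_kj
  }
  energy_backend(name, evaluate)
}

#' Formation energy of one environment
#'
#' Evaluates the backend on the full environment and on the environment
#' with the central molecule removed; the formation energy is the
#' difference. The identity `E_formation = E_full - E_minus_central` holds
#' exactly by construction.
#'
#' @param env a [mol_env()].
#' @param backend an [energy_backend()].
#' @return one-row data.frame `env_id`, `E_full`, `E_minus_central`,
#'   `E_formation` (kJ/mol).
#' @export
formation_energy <- function(env, backend) {
  stopifnot(inherits(env, "mol_env"), inherits(backend, "energy_backend"))
  at <- env$atoms
  ef <- tryCatch(
    backend$evaluate(as.matrix(at[, c("x", "y", "z")]), at$element),
    error = function(e) stop("backend '", backend$name, "' failed on ",
                             env$env_id, ": ", conditionMessage(e),
                             call. = FALSE))
  rest <- at[!at$central, , drop = FALSE]
  em <- if (nrow(rest) == 0) 0 else
    backend$evaluate(as.matrix(rest[, c("x", "y", "z")]), rest$element)
  data.frame(env_id = env$env_id, E_full = ef, E_minus_central = em,
             E_formation = ef - em, stringsAsFactors = FALSE)
}

#' Formation energies of many environments
#'
#' @param envs list of [mol_env()] objects.
#' @param backend an [energy_backend()].
#' @return data.frame of one [formation_energy()] record per environment.
#' @export
formation_energies <- function(envs, backend) {
  do.call(rbind, lapply(envs, formation_energy, backend = backend))
}

#' Compare energy distributions of two sets, optionally binned
#'
#' Per-bin mean/median formation energy and counts for a selected (NMR) set
#' and a baseline (random MD) set, plus their difference, binned on an
#' auxiliary variable (e.g. a torsion angle). Without `bin_var` a single
#' overall bin is used. Bins with fewer than `min_count` records in either
#' set are flagged.
#'
#' @param nmr_records,baseline_records data.frames with `E_formation` and,
#'   if binning, the column named by `bin_var`.
#' @param bin_var optional name of the binning column.
#' @param breaks bin breaks for `bin_var`.
#' @param min_count minimum per-bin record count before flagging.
#' @return data.frame with per-bin `mean`/`median`/`n` for both sets,
#'   `diff_mean`/`diff_median` (NMR minus baseline), and `flagged`.
#' @export
compare_energy_sets <- function(nmr_records, baseline_records,
                                bin_var = NULL, breaks = NULL,
                                min_count = 5) {
  a <- as.data.frame(nmr_records); b <- as.data.frame(baseline_records)
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("both record sets must be non-empty", call. = FALSE)
  if (is.null(bin_var)) {
    a$..bin <- "all"; b$..bin <- "all"
    levels_ <- "all"
  } else {
    stopifnot(bin_var %in% names(a), bin_var %in% names(b))
    if (is.null(breaks))
      breaks <- pretty(range(c(a[[bin_var]], b[[bin_var]])), 8)
    a$..bin <- as.character(cut(a[[bin_var]], breaks, include.lowest = TRUE))
    b$..bin <- as.character(cut(b[[bin_var]], breaks, include.lowest = TRUE))
    levels_ <- levels(cut(numeric(0), breaks, include.lowest = TRUE))
  }
  summ <- function(d) {
    s <- lapply(split(d$E_formation, factor(d$..bin, levels = levels_)),
                function(v) c(mean = mean(v), median = median(v),
                              n = length(v)))
    do.call(rbind, s)
  }
  sa <- summ(a); sb <- summ(b)
  occupied <- rownames(sa)[sa[, "n"] > 0 | sb[, "n"] > 0]
  if (!any(sa[, "n"] > 0 & sb[, "n"] > 0))
    stop("binning supports of the two sets are disjoint", call. = FALSE)
  out <- data.frame(bin = occupied,
                    mean_NMR = sa[occupied, "mean"],
                    median_NMR = sa[occupied, "median"],
                    n_NMR = sa[occupied, "n"],
                    mean_baseline = sb[occupied, "mean"],
                    median_baseline = sb[occupied, "median"],
                    n_baseline = sb[occupied, "n"],
                    stringsAsFactors = FALSE)
  out$diff_mean <- out$mean_NMR - out$mean_baseline
  out$diff_median <- out$median_NMR - out$median_baseline
  out$flagged <- out$n_NMR < min_count | out$n_baseline < min_count
  rownames(out) <- NULL
  out
}
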