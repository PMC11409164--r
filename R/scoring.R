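# Scoring candidate environments against experimental shift distributions.
#
# Each predicted shift delta is compared to its assigned experimental
# Gaussian (mu, s) through the two-sided tail probability
#   p_i = erfc(|delta - mu| / (s * sqrt(2)))
# (1 at the mean, decreasing with deviation), and per-environment agreement
# is the geometric mean of the p_i. Restricting the product to a bond-shell
# (W-n) subset gives the local probability used for partial assignments.

#' Default shielding-to-shift offsets
#'
#' Linear-regression offsets c_nuc mapping predicted isotropic shieldings to
#' shifts, delta = c_nuc - sigma_iso: 30.78 ppm for 1H and 170.04 ppm for 13C.
#'
#' @export
default_offsets <- c("1H" = 30.78, "13C" = 170.04)

#' Convert isotropic shielding to chemical shift
#'
#' @param sigma_iso predicted isotropic shielding(s), ppm.
#' @param nucleus `"1H"` or `"13C"` (recycled).
#' @param offsets named vector of per-nucleus offsets c_nuc.
#' @return chemical shift(s) delta = c_nuc - sigma_iso, ppm.
#' @export
shielding_to_shift <- function(sigma_iso, nucleus,
                               offsets = default_offsets) {
  if (!all(nucleus %in% names(offsets)))
    stop("no shielding-to-shift offset registered for nucleus: ",
         paste(setdiff(unique(nucleus), names(offsets)), collapse = ", "),
         call. = FALSE)
  unname(offsets[nucleus]) - sigma_iso
}

#' Per-shift match probability
#'
#' Two-sided Gaussian tail probability of observing a deviation at least as
#' large as |delta_pred - mu| under the experimental distribution:
#' `erfc(|delta - mu| / (s * sqrt(2)))`, i.e. `2 * pnorm(-|z|)`.
#'
#' @param delta_pred predicted shift(s), ppm.
#' @param mean_ppm experimental distribution mean(s), ppm.
#' @param sd_ppm experimental distribution width(s), ppm; must be > 0.
#' @return probabilities in \[0, 1\].
#' @export
shift_probability <- function(delta_pred, mean_ppm, sd_ppm) {
  if (any(sd_ppm <= 0)) stop("distribution width must be > 0", call. = FALSE)
  2 * pnorm(-abs(delta_pred - mean_ppm) / sd_ppm)
}

#' Global match probability of an environment
#'
#' Geometric mean of the per-shift probabilities; order-invariant and
#' bounded by `min(p) <= p_global <= max(p)`.
#'
#' @param p numeric vector of per-shift probabilities in \[0, 1\].
#' @return scalar p_global in \[0, 1\].
#' @export
global_probability <- function(p) {
  if (length(p) == 0) stop("empty probability list", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("probabilities must be finite and in [0, 1]", call. = FALSE)
  if (any(p == 0)) return(0)
  exp(mean(log(p)))
}

# Normalize a predicted-shift table: average chemically equivalent entries
# (multiple rows per env/label), convert shieldings, drop unassigned labels.
prepare_predictions <- function(pred, dists, offsets = default_offsets) {
  pred <- as.data.table(pred)
  need <- c("env_id", "atom_label", "value_ppm")
  if (!all(need %in% names(pred)))
    stop("predictions need columns env_id, atom_label, value_ppm",
         call. = FALSE)
  dd <- as.data.table(as.data.frame(dists))
  if ("kind" %in% names(pred) && any(pred$kind == "shielding")) {
    nuc <- dd$nucleus[match(pred$atom_label, dd$atom_label)]
    # shieldings for labels without a distribution can't be converted; they
    # are dropped below anyway
    sel <- pred$kind == "shielding" & !is.na(nuc)
    pred[sel, value_ppm := shielding_to_shift(value_ppm, nuc[sel],
                                              offsets = offsets)]
  }
  # equivalent-site averaging: one value per (env, label)
  pred <- pred[, .(value_ppm = mean(value_ppm)), by = .(env_id, atom_label)]
  merged <- merge(pred, dd[, .(atom_label, mean_ppm, sd_ppm)],
                  by = "atom_label")
  # a distribution with no prediction in some environment is a data defect
  n_lab <- length(unique(dd$atom_label))
  counts <- merged[, .N, by = env_id]
  if (any(counts$N != n_lab)) {
    bad <- counts[N != n_lab, env_id]
    stop("missing predicted shifts for assigned distribution(s) in ",
         "environment(s): ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  merged
}

#' Score environments against experimental distributions
#'
#' Computes the per-environment global (or bond-shell-restricted) match
#' probability from a long table of predicted shifts.
#'
#' Atoms with a prediction but no experimental distribution are ignored;
#' an assigned distribution missing its prediction in some environment is
#' an error. Multiple predictions for one (environment, label) pair —
#' chemically equivalent protons — are averaged before scoring.
#'
#' @param pred data.frame with columns `env_id`, `atom_label`, `value_ppm`
#'   and optionally `kind` (`"shift"` or `"shielding"`; shieldings are
#'   converted with `offsets`).
#' @param dists a [shift_distributions()] table.
#' @param shell optional [bond_shell()] selection: only distributions whose
#'   label is a shell member are used (W-n local probability).
#' @param offsets shielding-to-shift offsets.
#' @return data.frame `env_id`, `p_global`, ordered by decreasing
#'   probability (ties by `env_id`).
#' @export
score_environments <- function(pred, dists, shell = NULL,
                               offsets = default_offsets) {
  dd <- as.data.frame(dists)
  if (!is.null(shell)) {
    stopifnot(inherits(shell, "shell_selection"))
    keep <- dd$atom_label %in% shell$members
    if (!any(keep))
      stop("no assigned distribution lies inside the shell", call. = FALSE)
    dd <- dd[keep, , drop = FALSE]
  }
  m <- prepare_predictions(pred, dd, offsets)
  m[, log_p := log(shift_probability(value_ppm, mean_ppm, sd_ppm))]
  res <- m[, .(p_global = exp(mean(log_p))), by = env_id]
  res[!is.finite(p_global), p_global := 0]
  setorder(res, -p_global, env_id)
  as.data.frame(res)
}

#' Local (W-n) match probability
#'
#' Identical to [score_environments()] restricted to the distributions whose
#' atom label is a member of the bond shell.
#'
#' @inheritParams score_environments
#' @param shell a [bond_shell()] selection.
#' @return data.frame `env_id`, `p_global`.
#' @export
local_probability <- function(pred, dists, shell,
                              offsets = default_offsets) {
  score_environments(pred, dists, shell = shell, offsets = offsets)
}

#' Select the NMR set
#'
#' Keeps the environments in best agreement with the experimental
#' distributions, by fixed probability threshold, by count, or by fraction.
#' In `top_k`/`top_fraction` mode the implied threshold (the probability of
#' the last kept environment) is reported. Ties at the boundary are broken
#' by `env_id` lexicographic order after a stable sort.
#'
#' @param scores data.frame `env_id`, `p_global` (from
#'   [score_environments()]).
#' @param mode `"threshold"`, `"top_k"` or `"top_fraction"`.
#' @param p_star probability threshold (threshold mode): keep p > p_star.
#' @param k number of environments to keep (top_k mode).
#' @param fraction fraction of environments to keep (top_fraction mode).
#' @return data.frame `env_id`, `p_global`, `selected`, with attributes
#'   `threshold`, `n_selected` and `fraction_selected`.
#' @export
select_environments <- function(scores,
                                mode = c("threshold", "top_k", "top_fraction"),
                                p_star = NULL, k = NULL, fraction = NULL) {
  mode <- match.arg(mode)
  sc <- as.data.frame(scores)
  stopifnot(all(c("env_id", "p_global") %in% names(sc)))
  if (any(!is.finite(sc$p_global)))
    stop("non-finite probabilities", call. = FALSE)
  ord <- order(-sc$p_global, sc$env_id)
  sc <- sc[ord, , drop = FALSE]
  n <- nrow(sc)
  if (mode == "threshold") {
    if (is.null(p_star)) stop("threshold mode needs p_star", call. = FALSE)
    sc$selected <- sc$p_global > p_star
    thr <- p_star
  } else {
    if (mode == "top_fraction") {
      if (is.null(fraction)) stop("top_fraction mode needs fraction",
                                  call. = FALSE)
      k <- round(fraction * n)
    }
    if (is.null(k)) stop("top_k mode needs k", call. = FALSE)
    if (k > n) stop(sprintf("k = %d exceeds the number of environments (%d)",
                            k, n), call. = FALSE)
    sc$selected <- seq_len(n) <= k
    thr <- if (k > 0) sc$p_global[k] else Inf
  }
  rownames(sc) <- NULL
  attr(sc, "threshold") <- thr
  attr(sc, "n_selected") <- sum(sc$selected)
  attr(sc, "fraction_selected") <- sum(sc$selected) / n
  sc
}

#' Random per-run baseline sample of environments
#'
#' Uniform without-replacement sample of `n_per_run` environment ids from
#' each run, reproducible from `seed`. This is the random MD baseline that
#' energy and density comparisons are made against.
#'
#' @param env_ids character vector of environment ids.
#' @param run_ids run id per environment (same length).
#' @param n_per_run sample size per run.
#' @param seed integer seed.
#' @return character vector of sampled env_ids.
#' @export
sample_baseline <- function(env_ids, run_ids, n_per_run, seed = 1) {
  stopifnot(length(env_ids) == length(run_ids))
  split_ids <- split(env_ids, run_ids)
  small <- names(split_ids)[vapply(split_ids, length, integer(1)) < n_per_run]
  if (length(small) > 0)
    stop("run(s) with fewer than n_per_run environments: ",
         paste(small, collapse = ", "), call. = FALSE)
  with_seed(seed, {
    unlist(lapply(split_ids, function(ids) sample(ids, n_per_run)),
           use.names = FALSE)
  })
}

#' Read predicted shifts from CSV
#'
#' @param path CSV with columns `env_id`, `atom_label`, `value_ppm` and
#'   optionally `kind` (shift/shielding).
#' @return data.frame.
#' @export
read_predicted_shifts <- function(path) {
  tb <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("env_id", "atom_label", "value_ppm")
  if (!all(need %in% names(tb)))
    stop("predicted-shift CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  tb
}

#' Write a selection result to CSV
#'
#' @param selection result of [select_environments()].
#' @param path output path.
#' @export
write_selection <- function(selection, path) {
  write.csv(selection[, c("env_id", "p_global", "selected")], path,
            row.names = FALSE)
  invisible(path)
}
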