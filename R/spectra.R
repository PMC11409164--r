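# Experimental shift distributions: Gaussian deconvolution of 1D spectra
# seeded by a crystalline assignment, and proton distributions from picked
# HETCOR cross-peaks.
#
# Broad amorphous lines encode structural distributions: each assigned
# resonance is modeled as a Gaussian with mean mu_k and standard deviation
# s_k in ppm, and it is these (mu_k, s_k) that the scoring module compares
# predicted shifts against.

#' Construct a 1D spectrum
#'
#' @param ppm strictly monotone chemical-shift grid (ppm).
#' @param intensity non-negative intensity trace, same length.
#' @param nucleus `"1H"` or `"13C"`.
#' @return object of class `spectrum1d`.
#' @export
spectrum1d <- function(ppm, intensity, nucleus = "13C") {
  stopifnot(length(ppm) == length(intensity))
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0)))
    stop("ppm grid must be strictly monotone", call. = FALSE)
  if (any(!is.finite(intensity)))
    stop("intensities must be finite", call. = FALSE)
  if (d[1] < 0) { ppm <- rev(ppm); intensity <- rev(intensity) }
  structure(list(ppm = ppm, intensity = intensity,
                 nucleus = match.arg(nucleus, c("1H", "13C"))),
            class = "spectrum1d")
}

#' Build a shift-distribution table
#'
#' One row per assigned experimental resonance: atom label, nucleus,
#' Gaussian mean and width (ppm), amplitude (arbitrary units).
#'
#' @param atom_label,nucleus,mean_ppm,sd_ppm,amplitude vectors of equal length.
#' @return data.frame of class `shift_distributions`.
#' @export
shift_distributions <- function(atom_label, nucleus, mean_ppm, sd_ppm,
                                amplitude = 1) {
  if (any(sd_ppm <= 0)) stop("distribution widths must be > 0", call. = FALSE)
  out <- data.frame(atom_label = as.character(atom_label),
                    nucleus = as.character(nucleus),
                    mean_ppm = as.numeric(mean_ppm),
                    sd_ppm = as.numeric(sd_ppm),
                    amplitude = as.numeric(amplitude),
                    stringsAsFactors = FALSE)
  class(out) <- c("shift_distributions", "data.frame")
  out
}

gaussian_sum <- function(ppm, a, mu, s) {
  y <- numeric(length(ppm))
  for (k in seq_along(a)) y <- y + a[k] * exp(-(ppm - mu[k])^2 / (2 * s[k]^2))
  y
}

#' Simulate a 1D spectrum from Gaussian components
#'
#' Convenience generator used by tests and examples: a sum of Gaussians
#' plus optional white noise scaled to the maximum signal.
#'
#' @param components data.frame with `mean_ppm`, `sd_ppm`, `amplitude`.
#' @param ppm grid of shift values.
#' @param noise relative noise level (sd as a fraction of max intensity).
#' @param nucleus nucleus tag.
#' @return a [spectrum1d()].
#' @export
simulate_spectrum <- function(components, ppm, noise = 0, nucleus = "13C") {
  y <- gaussian_sum(ppm, components$amplitude, components$mean_ppm,
                    components$sd_ppm)
  if (noise > 0) y <- y + rnorm(length(ppm), sd = noise * max(y))
  spectrum1d(ppm, y, nucleus)
}

#' Fit a sum of Gaussians to a 1D spectrum
#'
#' Least-squares deconvolution of the trace into one Gaussian per seed,
#' initialized at the crystalline seed shifts. After fitting, each component
#' is assigned the label of the seed whose (crystalline) shift is closest to
#' the fitted mean — the assignment-transfer rule for amorphous forms whose
#' spectra overlap the crystalline ones.
#'
#' @param spectrum a [spectrum1d()].
#' @param seeds data.frame with columns `label` and `ppm` (crystalline
#'   seed shifts); at least one row, all within the spectral window.
#' @param init_width initial Gaussian sd in ppm.
#' @param baseline if `TRUE`, a linear baseline is fitted jointly.
#' @param maxit maximum optimizer iterations.
#' @return a [shift_distributions()] table with extra attributes
#'   `residual_norm` and column `width_flag` (TRUE when a fitted width
#'   collapsed below the grid spacing).
#' @export
fit_gaussian_mixture <- function(spectrum, seeds, init_width = 1,
                                 baseline = FALSE, maxit = 500) {
  stopifnot(inherits(spectrum, "spectrum1d"))
  seeds <- as.data.frame(seeds)
  stopifnot(all(c("label", "ppm") %in% names(seeds)), nrow(seeds) >= 1)
  x <- spectrum$ppm; y <- spectrum$intensity
  if (any(seeds$ppm < min(x) | seeds$ppm > max(x)))
    stop("seed mean(s) outside the spectral window", call. = FALSE)
  K <- nrow(seeds)
  dx <- min(abs(diff(x)))

  # parameters: a_k (amplitude), mu_k, log s_k [, b0, b1 baseline]
  a0 <- pmax(vapply(seeds$ppm, function(m) y[which.min(abs(x - m))],
                    numeric(1)), 1e-3 * max(y))
  par0 <- c(a0, seeds$ppm, rep(log(init_width), K))
  if (baseline) par0 <- c(par0, 0, 0)

  unpack <- function(p) list(a = p[1:K], mu = p[K + 1:K], s = exp(p[2 * K + 1:K]),
                             b = if (baseline) p[3 * K + 1:2] else c(0, 0))
  model <- function(p) {
    q <- unpack(p)
    gaussian_sum(x, q$a, q$mu, q$s) + q$b[1] + q$b[2] * (x - mean(x))
  }
  obj <- function(p) sum((y - model(p))^2)
  grad <- function(p) {
    q <- unpack(p)
    r <- model(p) - y
    g <- numeric(length(p))
    for (k in seq_len(K)) {
      e <- exp(-(x - q$mu[k])^2 / (2 * q$s[k]^2))
      g[k] <- 2 * sum(r * e)
      g[K + k] <- 2 * sum(r * q$a[k] * e * (x - q$mu[k]) / q$s[k]^2)
      # d/d(log s) = s * d/ds
      g[2 * K + k] <- 2 * sum(r * q$a[k] * e * (x - q$mu[k])^2 / q$s[k]^2)
    }
    if (baseline) {
      g[3 * K + 1] <- 2 * sum(r)
      g[3 * K + 2] <- 2 * sum(r * (x - mean(x)))
    }
    g
  }

  lower <- c(rep(0, K), rep(min(x), K), rep(log(dx / 10), K))
  upper <- c(rep(Inf, K), rep(max(x), K), rep(log(diff(range(x))), K))
  if (baseline) { lower <- c(lower, -Inf, -Inf); upper <- c(upper, Inf, Inf) }

  fit <- optim(par0, obj, grad, method = "L-BFGS-B", lower = lower,
               upper = upper, control = list(maxit = maxit))
  rn <- sqrt(fit$value)
  if (fit$convergence != 0 && fit$convergence != 52)
    stop(sprintf("Gaussian mixture fit did not converge (code %d, residual norm %.4g)",
                 fit$convergence, rn), call. = FALSE)
  q <- unpack(fit$par)

  # label each component by the nearest crystalline seed shift
  lab <- seeds$label[vapply(q$mu, function(m) which.min(abs(seeds$ppm - m)),
                            integer(1))]
  out <- shift_distributions(lab, spectrum$nucleus, q$mu, q$s, q$a)
  out$width_flag <- q$s < dx
  if (any(out$width_flag))
    warning("fitted width(s) collapsed below the grid spacing for: ",
            paste(out$atom_label[out$width_flag], collapse = ", "))
  attr(out, "residual_norm") <- rn
  attr(out, "baseline") <- if (baseline) q$b else NULL
  out
}

#' Proton distributions from HETCOR cross-peaks
#'
#' For each assigned carbon distribution, the picked 2D correlation peak
#' whose carbon coordinate is nearest the carbon's fitted mean (within
#' `window` ppm) defines the attached proton's Gaussian: mean from the
#' peak's proton coordinate, width from an optional `width_1H` column or
#' `default_width`. Ties on carbon distance are broken toward higher
#' intensity, then toward lower proton ppm. Carbons with no peak within the
#' window are left unassigned (reported, not fatal).
#'
#' @param hetcor_peaks data.frame with `ppm_13C`, `ppm_1H`, `intensity`,
#'   optional `width_1H`.
#' @param carbon_dists a [shift_distributions()] table of 13C components.
#' @param window maximum |carbon mean - peak 13C| in ppm.
#' @param default_width proton Gaussian sd (ppm) when no `width_1H` given.
#' @param proton_label function mapping a carbon label to its proton label;
#'   default turns `"C10"` into `"H10"`.
#' @return a [shift_distributions()] table of 1H components.
#' @export
assign_proton_distributions <- function(hetcor_peaks, carbon_dists,
                                        window = 2, default_width = 0.5,
                                        proton_label = function(l)
                                          sub("^C", "H", l)) {
  pk <- as.data.frame(hetcor_peaks)
  stopifnot(all(c("ppm_13C", "ppm_1H", "intensity") %in% names(pk)))
  cd <- as.data.frame(carbon_dists)
  rows <- list()
  unassigned <- character(0)
  for (i in seq_len(nrow(cd))) {
    d13 <- abs(pk$ppm_13C - cd$mean_ppm[i])
    cand <- which(d13 <= window)
    if (length(cand) == 0) { unassigned <- c(unassigned, cd$atom_label[i]); next }
    ord <- cand[order(d13[cand], -pk$intensity[cand], pk$ppm_1H[cand])]
    best <- ord[1]
    w <- if ("width_1H" %in% names(pk) && is.finite(pk$width_1H[best]))
      pk$width_1H[best] else default_width
    rows[[length(rows) + 1]] <- data.frame(
      atom_label = proton_label(cd$atom_label[i]), nucleus = "1H",
      mean_ppm = pk$ppm_1H[best], sd_ppm = w,
      amplitude = pk$intensity[best], stringsAsFactors = FALSE)
  }
  if (length(unassigned) > 0)
    message("no HETCOR peak within ", window, " ppm for: ",
            paste(unassigned, collapse = ", "))
  if (length(rows) == 0)
    return(shift_distributions(character(0), character(0), numeric(0),
                               numeric(0) + 1, numeric(0)))
  out <- do.call(rbind, rows)
  out <- shift_distributions(out$atom_label, out$nucleus, out$mean_ppm,
                             out$sd_ppm, out$amplitude)
  attr(out, "unassigned") <- unassigned
  out
}

#' Read a two-column (ppm, intensity) spectrum file
#'
#' @param path whitespace- or comma-separated two-column text file.
#' @param nucleus nucleus tag.
#' @return a [spectrum1d()].
#' @export
read_spectrum <- function(path, nucleus = "13C") {
  tb <- utils::read.table(path, header = FALSE, sep = "",
                          comment.char = "#",
                          col.names = c("ppm", "intensity"))
  spectrum1d(tb$ppm, tb$intensity, nucleus)
}

#' Write shift distributions to CSV
#'
#' @param dists a [shift_distributions()] table.
#' @param path output path.
#' @export
write_distributions <- function(dists, path) {
  write.csv(as.data.frame(dists)[, c("atom_label", "nucleus", "mean_ppm",
                                     "sd_ppm", "amplitude")],
            path, row.names = FALSE)
  invisible(path)
}

#' Read shift distributions from CSV
#'
#' @param path CSV with columns atom_label, nucleus, mean_ppm, sd_ppm,
#'   amplitude.
#' @return a [shift_distributions()] table.
#' @export
read_distributions <- function(path) {
  tb <- read.csv(path, stringsAsFactors = FALSE)
  shift_distributions(tb$atom_label, tb$nucleus, tb$mean_ppm, tb$sd_ppm,
                      if ("amplitude" %in% names(tb)) tb$amplitude else 1)
}
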