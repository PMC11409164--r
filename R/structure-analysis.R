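# Geometric characterization of selected vs background environments:
# hydrogen-bond partners of a chosen donor, torsion angles, and the
# promotion/demotion statistics between the NMR set and the MD set.

#' Hydrogen-bond geometric criteria
#'
#' The reference protocol states no geometric criteria; the defaults here
#' are common crystallographic practice: H...A distance at most 2.5 A and
#' D-H...A angle at least 120 degrees. All reported statistics should carry
#' the criteria used.
#'
#' @param max_HA_distance maximum H...acceptor distance, Angstrom.
#' @param min_DHA_angle minimum donor-H-acceptor angle, degrees.
#' @return object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_HA_distance = 2.5, min_DHA_angle = 120) {
  if (max_HA_distance <= 0) stop("distance criterion must be > 0", call. = FALSE)
  if (min_DHA_angle <= 0 || min_DHA_angle > 180)
    stop("angle criterion must be in (0, 180]", call. = FALSE)
  structure(list(max_HA_distance = max_HA_distance,
                 min_DHA_angle = min_DHA_angle),
            class = "hbond_criteria")
}

#' Detect the hydrogen bond of a donor proton in one environment
#'
#' Among all nitrogen/oxygen acceptor atoms satisfying the geometric
#' criteria — intermolecular drug atoms and water oxygens; the donor's own
#' molecule excluded by default — the acceptor with the smallest H...A
#' distance is returned. The acceptor class is the topology label of the
#' acceptor atom on the neighbor molecule, or `"water"`, or `"none"` when
#' no acceptor qualifies.
#'
#' @param env a [mol_env()].
#' @param donor_H label of the donor proton on the central molecule.
#' @param criteria an [hbond_criteria()].
#' @param include_intramolecular include acceptors on the central molecule
#'   itself, provided they are at least `min_bond_separation` bonds from the
#'   donor (requires `graph`).
#' @param graph optional [molecule_graph()], needed for the intramolecular
#'   bond-separation filter.
#' @param min_bond_separation minimum donor-acceptor bond count for
#'   intramolecular acceptors.
#' @return one-row data.frame: `env_id`, `donor_H`, `acceptor_class`,
#'   `HA_distance`, `DHA_angle`.
#' @export
detect_hbond <- function(env, donor_H, criteria = hbond_criteria(),
                         include_intramolecular = FALSE, graph = NULL,
                         min_bond_separation = 3) {
  stopifnot(inherits(env, "mol_env"), inherits(criteria, "hbond_criteria"))
  at <- env$atoms
  hi <- which(at$central & !is.na(at$label) & at$label == donor_H)
  if (length(hi) != 1)
    stop("donor proton '", donor_H, "' not found on the central molecule",
         call. = FALSE)
  H <- as.numeric(at[hi, c("x", "y", "z")])
  # bonded heavy donor atom: nearest central heavy atom within covalent range
  heavy <- which(at$central & at$element != "H")
  if (length(heavy) == 0) stop("central molecule has no heavy atoms", call. = FALSE)
  dH <- sqrt(rowSums(sweep(as.matrix(at[heavy, c("x", "y", "z")]), 2, H)^2))
  if (min(dH) > 1.3)
    stop("donor proton '", donor_H, "' has no bonded heavy atom", call. = FALSE)
  di <- heavy[which.min(dH)]
  D <- as.numeric(at[di, c("x", "y", "z")])

  cand <- which(at$element %in% c("N", "O"))
  cand <- setdiff(cand, di)
  if (!include_intramolecular) {
    cand <- cand[!at$central[cand]]
  } else if (!is.null(graph)) {
    intra <- cand[at$central[cand]]
    if (length(intra) > 0) {
      sep <- igraph::distances(graph$igraph, v = at$label[di],
                               to = at$label[intra])[1, ]
      drop <- intra[sep < min_bond_separation]
      cand <- setdiff(cand, drop)
    }
  }

  record <- data.frame(env_id = env$env_id, donor_H = donor_H,
                       acceptor_class = "none", HA_distance = NA_real_,
                       DHA_angle = NA_real_, stringsAsFactors = FALSE)
  if (length(cand) == 0) return(record)

  A <- as.matrix(at[cand, c("x", "y", "z")])
  rHA <- sqrt(rowSums(sweep(A, 2, H)^2))
  v1 <- matrix(D - H, length(cand), 3, byrow = TRUE)
  v2 <- sweep(A, 2, H)
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * pmax(sqrt(rowSums(v2^2)), 1e-12))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  ok <- rHA <= criteria$max_HA_distance & ang >= criteria$min_DHA_angle
  if (!any(ok)) return(record)
  best <- cand[ok][which.min(rHA[ok])]
  cls <- if (at$water[best]) "water"
         else if (!is.na(at$label[best])) at$label[best]
         else at$element[best]
  record$acceptor_class <- cls
  record$HA_distance <- min(rHA[ok])
  record$DHA_angle <- ang[ok][which.min(rHA[ok])]
  record
}

#' Detect hydrogen bonds across many environments
#'
#' @param envs list of [mol_env()] objects.
#' @inheritParams detect_hbond
#' @return data.frame of one record per environment.
#' @export
detect_hbonds <- function(envs, donor_H, criteria = hbond_criteria(), ...) {
  do.call(rbind, lapply(envs, detect_hbond, donor_H = donor_H,
                        criteria = criteria, ...))
}

#' Signed torsion angle of four points
#'
#' IUPAC sign convention: looking down the p2->p3 bond, the angle from the
#' p1-p2-p3 plane to the p2-p3-p4 plane, positive clockwise. Range
#' (-180, 180], invariant to rigid motion of all four points.
#'
#' @param p1,p2,p3,p4 length-3 Cartesian points.
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  if (vec_norm(p3 - p2) < 1e-10) stop("p2 and p3 coincide", call. = FALSE)
  if (vec_norm(cross3(p2 - p1, p3 - p2)) < 1e-10 ||
      vec_norm(cross3(p3 - p2, p4 - p3)) < 1e-10)
    stop("three consecutive points are collinear", call. = FALSE)
  b0 <- p1 - p2
  b1 <- unit_vec(p3 - p2)
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1     # projections orthogonal to the bond
  w <- b2 - sum(b2 * b1) * b1
  ang <- atan2(sum(cross3(b1, v) * w), sum(v * w)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  if (ang > 180) ang <- ang - 360
  ang
}

#' Torsion angle of a labeled quad in an environment
#'
#' @param env a [mol_env()].
#' @param quad character vector of four central-molecule atom labels,
#'   bonded in sequence (e.g. `c("C13","C14","C19","C20")` for the torsion
#'   about the C14-C19 bond).
#' @return one-row data.frame `env_id`, `quad`, `angle_deg`.
#' @export
env_dihedral <- function(env, quad) {
  stopifnot(length(quad) == 4)
  P <- lapply(quad, function(l) env_atom_coord(env, l))
  data.frame(env_id = env$env_id, quad = paste(quad, collapse = "-"),
             angle_deg = dihedral_angle(P[[1]], P[[2]], P[[3]], P[[4]]),
             stringsAsFactors = FALSE)
}

#' Category prevalence comparison between two sets
#'
#' Per-category counts and percentages for a background set (MD) and a
#' selected set (NMR); the promotion/demotion readout. Categories absent
#' from both sets are reported with zero counts. Percentages sum to 100
#' within each set.
#'
#' @param records_MD,records_NMR character vectors of category labels (one
#'   entry per environment), or data.frames with an `acceptor_class` column.
#' @param categories optional category ordering; defaults to the union of
#'   observed categories.
#' @return data.frame `category`, `count_MD`, `count_NMR`, `percent_MD`,
#'   `percent_NMR`, `delta` (NMR minus MD, percentage points).
#' @export
compare_categories <- function(records_MD, records_NMR, categories = NULL) {
  pull <- function(r) {
    if (is.data.frame(r)) r <- r$acceptor_class
    as.character(r)
  }
  md <- pull(records_MD); nmr <- pull(records_NMR)
  if (length(md) == 0 || length(nmr) == 0)
    stop("both record sets must be non-empty", call. = FALSE)
  if (is.null(categories)) categories <- sort(unique(c(md, nmr)))
  cm <- table(factor(md, levels = categories))
  cn <- table(factor(nmr, levels = categories))
  out <- data.frame(category = categories,
                    count_MD = as.integer(cm), count_NMR = as.integer(cn),
                    percent_MD = 100 * as.numeric(cm) / length(md),
                    percent_NMR = 100 * as.numeric(cn) / length(nmr),
                    stringsAsFactors = FALSE)
  out$delta <- out$percent_NMR - out$percent_MD
  out
}

#' Periodic histogram of torsion angles
#'
#' Bins angles on (-180, 180] with right-closed bins; -180 and 180 denote
#' the same torsion and land in the same bin. `bin_width` must divide 360.
#'
#' @param angles numeric vector of angles in degrees (any branch; reduced
#'   modulo 360 into (-180, 180]).
#' @param bin_width bin width in degrees.
#' @return data.frame `lower`, `upper`, `mid`, `count`, `frequency`
#'   (frequencies sum to 1).
#' @export
angle_histogram <- function(angles, bin_width = 10) {
  if (360 %% bin_width != 0)
    stop("bin_width must divide 360", call. = FALSE)
  a <- ((angles + 180) %% 360)
  a[a == 0] <- 360        # 180 and -180 share a bin
  a <- a - 180            # now in (-180, 180]
  breaks <- seq(-180, 180, by = bin_width)
  idx <- ceiling((a + 180) / bin_width)
  idx[idx < 1] <- 1
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  data.frame(lower = head(breaks, -1), upper = tail(breaks, -1),
             mid = head(breaks, -1) + bin_width / 2,
             count = counts,
             frequency = if (length(a) > 0) counts / length(a) else counts)
}
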