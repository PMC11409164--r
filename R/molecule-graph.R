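# Molecular topology: atom labels, the bonded graph, and bond-shell (W-n)
# subsets used for local (partial-assignment) selection.

nucleus_for_element <- function(element) {
  ifelse(element == "H", "1H", ifelse(element == "C", "13C", "other"))
}

#' Build a validated molecule graph
#'
#' A molecule is described at the label level: every atom carries a unique
#' label (e.g. `"N6"`, `"H6"`, `"C14"`), its element, and whether an
#' experimental shift distribution is assigned to it. Bonds are unordered
#' label pairs. The bonded graph is the topology over which bond-count
#' distances ("within n bonds") are measured.
#'
#' @param atoms data.frame with columns `label`, `element` and optionally
#'   `assigned` (logical, default `FALSE`).
#' @param bonds data.frame (or 2-column matrix) of bonded label pairs.
#' @return an object of class `molecule_graph` with elements `atoms`
#'   (data.frame with `label`, `element`, `nucleus`, `assigned`), `bonds`,
#'   and `igraph` (the bonded graph).
#' @examples
#' water <- molecule_graph(
#'   data.frame(label = c("O1", "H1", "H2"), element = c("O", "H", "H")),
#'   data.frame(a = c("O1", "O1"), b = c("H1", "H2")))
#' @export
molecule_graph <- function(atoms, bonds) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "element") %in% names(atoms)))
  if (!"assigned" %in% names(atoms)) atoms$assigned <- FALSE
  atoms$assigned <- as.logical(atoms$assigned)
  dup <- atoms$label[duplicated(atoms$label)]
  if (length(dup) > 0)
    stop("duplicate atom label(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  atoms$nucleus <- nucleus_for_element(atoms$element)

  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  if (ncol(bonds) < 2) stop("bonds must have two columns", call. = FALSE)
  names(bonds)[1:2] <- c("a", "b")
  bonds$a <- as.character(bonds$a); bonds$b <- as.character(bonds$b)
  missing_ep <- setdiff(unique(c(bonds$a, bonds$b)), atoms$label)
  if (length(missing_ep) > 0)
    stop("bond endpoint(s) not among atom labels: ",
         paste(missing_ep, collapse = ", "), call. = FALSE)
  if (any(bonds$a == bonds$b))
    stop("self-bond on atom: ", paste(bonds$a[bonds$a == bonds$b], collapse = ", "),
         call. = FALSE)

  g <- igraph::graph_from_data_frame(bonds[, c("a", "b")], directed = FALSE,
                                     vertices = atoms$label)
  if (nrow(atoms) > 1 && !igraph::is_connected(g))
    warning("molecule graph is not connected")
  structure(list(atoms = atoms, bonds = bonds[, c("a", "b")], igraph = g),
            class = "molecule_graph")
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat(sprintf("<molecule_graph> %d atoms, %d bonds; %d assigned 1H/13C shifts\n",
              nrow(x$atoms), nrow(x$bonds), sum(x$atoms$assigned &
                                                x$atoms$nucleus != "other")))
  invisible(x)
}

# Labels of hydrogens bonded to `label`.
attached_hydrogens <- function(graph, label) {
  nb <- igraph::neighbors(graph$igraph, label)$name
  nb[graph$atoms$element[match(nb, graph$atoms$label)] == "H"]
}

# Heavy-atom (non-H) induced subgraph.
heavy_subgraph <- function(graph) {
  heavy <- graph$atoms$label[graph$atoms$element != "H"]
  igraph::induced_subgraph(graph$igraph, heavy)
}

#' Bond-shell (W-n) atom subset around a center
#'
#' Returns the atoms whose heavy-atom graph distance from `center` is at
#' most `n_bonds`, plus every hydrogen bonded to an included heavy atom.
#' Distances are counted over heavy atoms only; hydrogens never relay a
#' path, they decorate included heavy atoms. This is the "W-n" subset used
#' for local selection: probabilities are then computed over the assigned
#' 1H/13C shifts of the shell only.
#'
#' @param graph a [molecule_graph()].
#' @param center atom label at the shell center. A hydrogen center is
#'   replaced by its bonded heavy atom for the distance computation (the
#'   hydrogen itself stays a member).
#' @param n_bonds non-negative integer shell radius in bonds.
#' @param assignment optional character vector of assigned labels; defaults
#'   to the graph's `assigned` flags. Used only for the shift-count fields.
#' @return an object of class `shell_selection`: list with `center`,
#'   `n_bonds`, `members` (character), `n_shifts_used`, `n_shifts_total`.
#' @export
bond_shell <- function(graph, center, n_bonds, assignment = NULL) {
  stopifnot(inherits(graph, "molecule_graph"))
  if (!center %in% graph$atoms$label)
    stop("unknown center label: ", center, call. = FALSE)
  if (n_bonds < 0) stop("n_bonds must be >= 0", call. = FALSE)
  if (is.null(assignment))
    assignment <- graph$atoms$label[graph$atoms$assigned]

  elem <- function(l) graph$atoms$element[match(l, graph$atoms$label)]
  heavy_center <- center
  if (elem(center) == "H") {
    nb <- igraph::neighbors(graph$igraph, center)$name
    nb <- nb[elem(nb) != "H"]
    if (length(nb) == 0) stop("hydrogen center has no bonded heavy atom",
                              call. = FALSE)
    heavy_center <- nb[1]
  }

  hg <- heavy_subgraph(graph)
  d <- igraph::distances(hg, v = heavy_center)[1, ]
  heavy_members <- names(d)[is.finite(d) & d <= n_bonds]
  hydro <- unique(unlist(lapply(heavy_members, attached_hydrogens,
                                graph = graph)))
  members <- union(heavy_members, hydro)
  if (!center %in% members) members <- c(center, members)

  scored <- graph$atoms$label[graph$atoms$nucleus %in% c("1H", "13C")]
  used <- intersect(intersect(members, assignment), scored)
  total <- intersect(assignment, scored)
  structure(list(center = center, n_bonds = as.integer(n_bonds),
                 members = sort(members),
                 n_shifts_used = length(used),
                 n_shifts_total = length(total)),
            class = "shell_selection")
}

#' @export
print.shell_selection <- function(x, ...) {
  cat(sprintf("<shell_selection> W%d around %s: %d atoms, %d of %d shifts used\n",
              x$n_bonds, x$center, length(x$members),
              x$n_shifts_used, x$n_shifts_total))
  invisible(x)
}

#' Read a molecule description from JSON or CSV
#'
#' JSON layout: `{"atoms": [{"label","element","assigned"}...],
#' "bonds": [["a","b"], ...]}`. CSV layout: pass two files via `bonds_file`,
#' atoms as (label, element, assigned) and bonds as (a, b).
#'
#' @param path path to the JSON molecule file, or the atoms CSV.
#' @param bonds_file optional path to a bonds CSV; if given, `path` is read
#'   as an atoms CSV.
#' @return a [molecule_graph()].
#' @export
read_molecule <- function(path, bonds_file = NULL) {
  if (!is.null(bonds_file)) {
    atoms <- read.csv(path, stringsAsFactors = FALSE)
    bonds <- read.csv(bonds_file, stringsAsFactors = FALSE)
    return(molecule_graph(atoms, bonds))
  }
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  bonds <- obj$bonds
  if (is.matrix(bonds)) bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  molecule_graph(obj$atoms, bonds)
}

#' Write a molecule description to JSON
#'
#' @param graph a [molecule_graph()].
#' @param path output path.
#' @export
write_molecule <- function(graph, path) {
  stopifnot(inherits(graph, "molecule_graph"))
  obj <- list(atoms = graph$atoms[, c("label", "element", "assigned")],
              bonds = as.matrix(graph$bonds))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
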