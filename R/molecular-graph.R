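#' Molecular graphs
#'
#' A light container for a covalent topology: atoms (element symbols), bonds
#' (unordered index pairs with an integer bond order) and, derived on demand,
#' the angle and dihedral enumerations that the bonded force-field terms need.
#'
#' @param elements character vector of element symbols, one per atom.
#' @param bonds two-column integer matrix of atom indices (1-based), one row
#'   per bond.
#' @param bond_orders integer vector, one per bond (1 = single, 2 = double).
#'   Defaults to all single.
#' @return An object of class `molecular_graph`.
#' @examples
#' g <- cyclohexene_graph()
#' g$elements
#' @export
molecular_graph <- function(elements, bonds, bond_orders = NULL) {
  stopifnot(is.character(elements), length(elements) >= 1)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (is.null(bond_orders)) bond_orders <- rep(1L, nrow(bonds))
  stopifnot(length(bond_orders) == nrow(bonds))
  if (nrow(bonds) > 0) {
    if (any(bonds < 1L) || any(bonds > length(elements)))
      stop("bond index out of range")
    key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
    if (anyDuplicated(key)) stop("duplicate bonds in graph")
    if (any(bonds[, 1] == bonds[, 2])) stop("self-bond in graph")
  }
  g <- structure(
    list(elements = elements, bonds = bonds,
         bond_orders = as.integer(bond_orders)),
    class = "molecular_graph"
  )
  g
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("molecular_graph:", length(x$elements), "atoms,",
      nrow(x$bonds), "bonds\n")
  cat("  composition:",
      paste(names(table(x$elements)), table(x$elements),
            sep = "", collapse = " "), "\n")
  invisible(x)
}

# adjacency list: integer neighbours per atom
graph_adjacency <- function(graph) {
  n <- length(graph$elements)
  adj <- vector("list", n)
  for (k in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds[k, 1]; j <- graph$bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

graph_is_connected <- function(graph) {
  n <- length(graph$elements)
  if (n == 0) return(FALSE)
  adj <- graph_adjacency(graph)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' Cyclohexene covalent graph
#'
#' The 16-atom cyclohexene topology: a six-carbon ring with one double bond
#' (C1=C2), four sp3 ring carbons, and ten hydrogens (one on each sp2 carbon,
#' two on each sp3 carbon). Atom order: C1..C6 then H7..H16.
#'
#' @return A `molecular_graph` with 6 C, 10 H, 16 bonds.
#' @export
cyclohexene_graph <- function() {
  elements <- c(rep("C", 6), rep("H", 10))
  ring <- cbind(1:6, c(2:6, 1))                 # C1-C2 ... C6-C1
  ring_orders <- c(2L, rep(1L, 5))              # C1=C2 double
  # H placement: C1,C2 get one H each; C3..C6 two H each
  hb <- rbind(
    c(1, 7), c(2, 8),
    c(3, 9), c(3, 10),
    c(4, 11), c(4, 12),
    c(5, 13), c(5, 14),
    c(6, 15), c(6, 16)
  )
  molecular_graph(elements, rbind(ring, hb),
                  c(ring_orders, rep(1L, nrow(hb))))
}

#' Enumerate angles and proper dihedrals from a bonded graph
#'
#' Angles are all paths i-j-k with i < k; dihedrals all paths i-j-k-l with the
#' canonical orientation (j < k, or j == k impossible) deduplicated.
#'
#' @param graph a `molecular_graph`.
#' @return list with integer matrices `angles` (3 cols) and `dihedrals` (4 cols).
#' @export
enumerate_angles_dihedrals <- function(graph) {
  adj <- graph_adjacency(graph)
  n <- length(graph$elements)
  angles <- list(); dihedrals <- list()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(sort(nb), 2)
      for (c1 in seq_len(ncol(cmb)))
        angles[[length(angles) + 1L]] <- c(cmb[1, c1], j, cmb[2, c1])
    }
  }
  for (bidx in seq_len(nrow(graph$bonds))) {
    j <- graph$bonds[bidx, 1]; k <- graph$bonds[bidx, 2]
    for (i in setdiff(adj[[j]], k)) {
      for (l in setdiff(adj[[k]], j)) {
        if (i == l) next  # 3-ring wrap
        quad <- c(i, j, k, l)
        # canonical direction: smaller outer-atom end first
        if (quad[4] < quad[1] || (quad[4] == quad[1] && quad[3] < quad[2]))
          quad <- rev(quad)
        dihedrals[[length(dihedrals) + 1L]] <- quad
      }
    }
  }
  ang <- if (length(angles)) do.call(rbind, angles) else
    matrix(integer(), ncol = 3)
  dih <- if (length(dihedrals)) unique(do.call(rbind, dihedrals)) else
    matrix(integer(), ncol = 4)
  list(angles = ang, dihedrals = dih)
}
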