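#' Atom-typing schemes for cyclohexene-class molecules
#'
#' Two typing schemes are supported for a hydrocarbon ring with one double
#' bond. The `neat` scheme distinguishes sp2 from sp3 carbons only (two carbon
#' types, two hydrogen types); the `hydrated` scheme additionally splits the
#' sp3 carbons into allylic (adjacent to an sp2 carbon) and homoallylic
#' (the rest), giving three carbon and three hydrogen types. Hydrogens always
#' inherit the class of the carbon they are bonded to, so typing is invariant
#' under every automorphism of the molecular graph.
#'
#' @param name `"neat"` or `"hydrated"`.
#' @return An object of class `atom_type_scheme`.
#' @export
atom_type_scheme <- function(name = c("neat", "hydrated")) {
  name <- match.arg(name)
  structure(list(name = name), class = "atom_type_scheme")
}

#' @export
print.atom_type_scheme <- function(x, ...) {
  cat("atom_type_scheme:", x$name,
      if (x$name == "neat") "(2 C types, 2 H types on cyclohexene)"
      else "(3 C types, 3 H types on cyclohexene)", "\n")
  invisible(x)
}

#' Assign atom types
#'
#' Classifies every atom of a cyclohexene-class graph under a typing scheme.
#' Carbons are classified structurally: `sp2` if they participate in a
#' double bond, `allylic` if sp3 and bonded to an sp2 carbon, `homoallylic`
#' otherwise. The neat scheme merges allylic and homoallylic into a single
#' sp3 class. Because the classification depends only on graph structure,
#' symmetric atoms always receive identical labels.
#'
#' @param graph a `molecular_graph` containing only C and H atoms.
#' @param scheme an `atom_type_scheme`.
#' @return character vector of type labels, one per atom.
#' @examples
#' table(assign_atom_types(cyclohexene_graph(), atom_type_scheme("neat")))
#' @export
assign_atom_types <- function(graph, scheme) {
  stopifnot(inherits(graph, "molecular_graph"),
            inherits(scheme, "atom_type_scheme"))
  el <- graph$elements
  bad <- setdiff(unique(el), c("C", "H"))
  if (length(bad))
    stop("unknown element(s) for this typing scheme: ",
         paste(bad, collapse = ", "))
  n <- length(el)
  adj <- graph_adjacency(graph)

  # carbons in a double bond are sp2
  sp2 <- logical(n)
  dbl <- graph$bonds[graph$bond_orders == 2L, , drop = FALSE]
  sp2[as.vector(dbl)] <- TRUE

  cclass <- rep(NA_character_, n)
  for (i in which(el == "C")) {
    if (length(adj[[i]]) == 0)
      stop("cannot classify atom ", i, ": carbon with no bonds")
    cclass[i] <- if (sp2[i]) "sp2"
      else if (any(sp2[adj[[i]]] & el[adj[[i]]] == "C")) "allylic"
      else "homoallylic"
  }
  if (scheme$name == "neat")
    cclass[cclass %in% c("allylic", "homoallylic")] <- "sp3"

  labels <- rep(NA_character_, n)
  cmap <- c(sp2 = "C2", sp3 = "C3", allylic = "CA", homoallylic = "CH")
  hmap <- c(sp2 = "H2", sp3 = "H3", allylic = "HA", homoallylic = "HH")
  labels[el == "C"] <- cmap[cclass[el == "C"]]
  for (i in which(el == "H")) {
    nb <- adj[[i]]
    if (length(nb) != 1 || el[nb] != "C")
      stop("cannot classify atom ", i,
           ": hydrogen must be bonded to exactly one carbon")
    labels[i] <- hmap[cclass[nb]]
  }
  labels
}

#' Count and list distinct bonded-term types
#'
#' Enumerates the distinct bond, angle and dihedral term types present in a
#' labelled graph. Bond types are unordered label pairs; angle types are
#' label triples with the ends in canonical (sorted) order; dihedral types
#' are label quadruples canonicalised by reversal.
#'
#' @param graph a `molecular_graph`.
#' @param labels per-atom type labels from [assign_atom_types()].
#' @return list with `bond_types`, `angle_types`, `dihedral_types` (character
#'   vectors of hyphen-joined label tuples) and the corresponding counts
#'   `n_bond_types`, `n_angle_types`, `n_dihedral_types`.
#' @examples
#' g <- cyclohexene_graph()
#' enumerate_bonded_terms(g, assign_atom_types(g, atom_type_scheme("neat")))$n_bond_types
#' @export
enumerate_bonded_terms <- function(graph, labels) {
  stopifnot(inherits(graph, "molecular_graph"))
  if (length(labels) != length(graph$elements) || anyNA(labels))
    stop("labels missing for some atoms")
  b <- graph$bonds
  bond_types <- unique(bond_type_key(labels[b[, 1]], labels[b[, 2]]))
  ad <- enumerate_angles_dihedrals(graph)
  a <- ad$angles
  angle_types <- if (nrow(a)) unique(angle_type_key(
    labels[a[, 1]], labels[a[, 2]], labels[a[, 3]])) else character()
  d <- ad$dihedrals
  dihedral_types <- if (nrow(d)) unique(dihedral_type_key(
    labels[d[, 1]], labels[d[, 2]], labels[d[, 3]], labels[d[, 4]]))
    else character()
  list(
    bond_types = sort(bond_types),
    angle_types = sort(angle_types),
    dihedral_types = sort(dihedral_types),
    n_bond_types = length(bond_types),
    n_angle_types = length(angle_types),
    n_dihedral_types = length(dihedral_types)
  )
}

# canonical type keys ---------------------------------------------------

bond_type_key <- function(l1, l2) {
  paste(pmin(l1, l2), pmax(l1, l2), sep = "-")
}

angle_type_key <- function(l1, l2, l3) {
  swap <- l1 > l3
  a <- ifelse(swap, l3, l1); c <- ifelse(swap, l1, l3)
  paste(a, l2, c, sep = "-")
}

dihedral_type_key <- function(l1, l2, l3, l4) {
  fwd <- paste(l1, l2, l3, l4, sep = "-")
  rev <- paste(l4, l3, l2, l1, sep = "-")
  ifelse(fwd <= rev, fwd, rev)
}
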