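#' Molecular configuration
#'
#' Coordinates plus the bookkeeping the evaluator needs: element symbols,
#' per-atom molecule ids, per-atom type labels, an orthorhombic box and a
#' periodicity flag. A `topology` attribute (list of `molecular_graph`s, one
#' per molecule, with atom indices local to the molecule) carries the bonded
#' structure.
#'
#' @param coords N x 3 numeric matrix of coordinates (Angstrom).
#' @param elements character vector of element symbols.
#' @param molecule_id integer vector assigning each atom to a molecule;
#'   each molecule's atoms must be contiguous.
#' @param types character vector of atom type labels.
#' @param box numeric length-3 orthorhombic box lengths (Angstrom).
#' @param periodic logical; apply the minimum-image convention when `TRUE`.
#' @param topology list of `molecular_graph`s, one per distinct molecule_id
#'   in order, or a single graph recycled for all molecules.
#' @return An object of class `md_configuration`.
#' @export
md_configuration <- function(coords, elements, molecule_id, types,
                             box = c(Inf, Inf, Inf), periodic = FALSE,
                             topology = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, is.numeric(coords))
  n <- nrow(coords)
  stopifnot(length(elements) == n, length(molecule_id) == n,
            length(types) == n, length(box) == 3)
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  molecule_id <- as.integer(molecule_id)
  # contiguity: molecule ids never re-appear after a different id intervenes
  r <- rle(molecule_id)
  if (anyDuplicated(r$values))
    stop("molecule_id blocks must be contiguous")
  if (periodic && any(!is.finite(box)))
    stop("periodic configuration requires finite box lengths")
  mol_ids <- unique(molecule_id)
  if (!is.null(topology)) {
    if (inherits(topology, "molecular_graph"))
      topology <- rep(list(topology), length(mol_ids))
    stopifnot(length(topology) == length(mol_ids))
    sizes <- tabulate(match(molecule_id, mol_ids))
    for (m in seq_along(topology))
      if (length(topology[[m]]$elements) != sizes[m])
        stop("topology/molecule size mismatch for molecule ", mol_ids[m])
  }
  structure(
    list(coords = coords, elements = elements, molecule_id = molecule_id,
         types = types, box = as.numeric(box), periodic = periodic,
         topology = topology),
    class = "md_configuration"
  )
}

#' @export
print.md_configuration <- function(x, ...) {
  cat("md_configuration:", nrow(x$coords), "atoms,",
      length(unique(x$molecule_id)), "molecules,",
      if (x$periodic) sprintf("periodic box %.2f x %.2f x %.2f A",
                              x$box[1], x$box[2], x$box[3])
      else "non-periodic", "\n")
  invisible(x)
}

n_atoms <- function(config) nrow(config$coords)

# first atom index of each molecule + sizes, in order of appearance
molecule_blocks <- function(config) {
  r <- rle(config$molecule_id)
  ends <- cumsum(r$lengths)
  data.frame(molecule = r$values, start = ends - r$lengths + 1L,
             end = ends, size = r$lengths)
}

#' Read and write configurations in the extended-XYZ dialect
#'
#' Line 1: atom count. Line 2: a key-value comment carrying
#' `box="lx ly lz"`, `periodic=T/F` and optionally `frame=<k>`. Body lines:
#' `element x y z molecule_id type`. Multiple frames may be concatenated in
#' one file; `read_xyz_frames` returns a list of `md_configuration`s.
#'
#' @param config an `md_configuration` (or list of them for
#'   `write_xyz_frames`).
#' @param path file path.
#' @return `read_xyz` returns one `md_configuration`; `read_xyz_frames` a
#'   list of them. Writers return `path` invisibly. Topology is not stored
#'   in the file; reattach it after reading if bonded evaluation is needed.
#' @export
write_xyz <- function(config, path) {
  write_xyz_frames(list(config), path)
}

#' @rdname write_xyz
#' @export
write_xyz_frames <- function(configs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(configs)) {
    config <- configs[[f]]
    writeLines(as.character(n_atoms(config)), con)
    writeLines(sprintf('box="%.17g %.17g %.17g" periodic=%s frame=%d',
                       config$box[1], config$box[2], config$box[3],
                       config$periodic, f), con)
    body <- sprintf("%s %.17g %.17g %.17g %d %s",
                    config$elements, config$coords[, 1], config$coords[, 2],
                    config$coords[, 3], config$molecule_id, config$types)
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  frames <- read_xyz_frames(path)
  if (length(frames) != 1) stop("expected a single frame in ", path)
  frames[[1]]
}

#' @rdname write_xyz
#' @export
read_xyz_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed frame header at line ", i)
    comment <- lines[i + 1L]
    boxm <- regmatches(comment,
                       regexec('box="([^"]+)"', comment))[[1]]
    if (length(boxm) < 2) stop("comment line missing box= field at line ",
                               i + 1L)
    box <- as.numeric(strsplit(trimws(boxm[2]), "\\s+")[[1]])
    perm <- regmatches(comment,
                       regexec("periodic=(\\w+)", comment))[[1]]
    periodic <- if (length(perm) >= 2) as.logical(perm[2]) else FALSE
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    if (any(lengths(parts) != 6))
      stop("malformed atom line in frame starting at line ", i)
    m <- do.call(rbind, parts)
    frames[[length(frames) + 1L]] <- md_configuration(
      coords = matrix(as.numeric(m[, 2:4]), ncol = 3),
      elements = m[, 1],
      molecule_id = as.integer(m[, 5]),
      types = m[, 6],
      box = box, periodic = periodic
    )
    i <- i + 2L + n
  }
  frames
}
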