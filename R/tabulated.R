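#' Write a GROMACS-style tabulated pair potential
#'
#' Buckingham pair interactions cannot use analytic Lennard-Jones kernels in
#' most MD engines and are supplied as user tables instead. The table has
#' seven whitespace-separated columns per the GROMACS user-table layout:
#' `r  f(r)  -f'(r)  g(r)  -g'(r)  h(r)  -h'(r)` with
#' \eqn{f(r) = 1/r} (Coulombic kernel), \eqn{g(r) = -1/r^6} (dispersion
#' kernel) and \eqn{h(r) = e^{-b r}} (repulsion kernel), so that the pair
#' energy is \eqn{k_e q_i q_j f + C_6 g + A h}. Derivative columns are
#' analytic.
#'
#' @param b repulsion decay (1/Angstrom) for the pair.
#' @param r_grid strictly increasing distance grid (Angstrom), starting above
#'   the overlap floor.
#' @param path output file path.
#' @param overlap_floor minimum allowed first grid point (Angstrom).
#' @return The table as a data.frame (columns `r, f, mfp, g, mgp, h, mhp`),
#'   invisibly, after writing it to `path`.
#' @export
write_tabulated_potential <- function(b, r_grid, path, overlap_floor = 0.1) {
  stopifnot(length(r_grid) >= 2)
  if (any(diff(r_grid) <= 0)) stop("r grid must be strictly increasing")
  if (r_grid[1] <= overlap_floor)
    stop("grid must start above the overlap floor (", overlap_floor, " A)")
  if (b <= 0) stop("b must be > 0")
  r <- r_grid
  tab <- data.frame(
    r = r,
    f = 1 / r,        mfp = 1 / r^2,        # -d(1/r)/dr
    g = -r^-6,        mgp = -6 * r^-7,      # -d(-r^-6)/dr
    h = exp(-b * r),  mhp = b * exp(-b * r) # -d(e^-br)/dr
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# tabulated pair potential: r f -f' g -g' h -h'", con)
  writeLines(sprintf("# b_repulsion_invA: %.17g", b), con)
  utils::write.table(format(tab, digits = 17, trim = TRUE), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(tab)
}

#' @rdname write_tabulated_potential
#' @param path file written by `write_tabulated_potential`.
#' @export
read_tabulated_potential <- function(path) {
  lines <- readLines(path)
  bline <- lines[startsWith(lines, "# b_repulsion_invA:")]
  b <- as.numeric(sub("# b_repulsion_invA:", "", bline))
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.table(text = body,
                           col.names = c("r", "f", "mfp", "g", "mgp",
                                         "h", "mhp"))
  attr(tab, "b") <- b
  tab
}

#' Pair energy from a tabulated potential
#'
#' Evaluates \eqn{k_e q_i q_j f + C_6 g + A h} from the table's function
#' columns at the tabulated grid points (no interpolation), for round-trip
#' checks against [evaluate_energy_forces()].
#'
#' @param tab table from [read_tabulated_potential()].
#' @param A,C6,qprod pair repulsion prefactor, dispersion coefficient and
#'   charge product.
#' @return numeric vector of pair energies at the grid distances.
#' @export
tabulated_pair_energy <- function(tab, A, C6, qprod = 0) {
  physical_constants$coulomb_kcal * qprod * tab$f + C6 * tab$g + A * tab$h
}
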