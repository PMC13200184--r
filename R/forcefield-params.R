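#' Buckingham-class force-field parameter set
#'
#' Holds pair-specific nonbonded parameters (no combining rules: every
#' type pair carries its own repulsion, decay and dispersion coefficients),
#' per-type partial charges, and bonded terms (harmonic bonds and angles,
#' cosine-series dihedrals).
#'
#' The nonbonded pair energy is
#' \deqn{U(r) = A e^{-b r} - C_6/r^6 - C_8/r^8 + k_e q_i q_j / r}
#' with `A` in kcal/mol, `b` in 1/Angstrom, `C6` in kcal A^6/mol, `C8` in
#' kcal A^8/mol and charges in elementary charge units
#' (`k_e` = 332.0637 kcal A/(mol e^2)). Bonded terms: bond
#' \eqn{U = k (r - r_0)^2}, angle \eqn{U = k (\theta - \theta_0)^2},
#' dihedral \eqn{U = \sum_n k_n (1 + \cos(n \phi))}.
#'
#' @param pairs data.frame with columns `type1`, `type2`, `A`, `b`, `C6` and
#'   optionally `C8` (defaults 0). One row per unordered type pair; the pair
#'   key is canonicalised, so (`t1`,`t2`) and (`t2`,`t1`) are the same entry.
#' @param charges named numeric vector of partial charges per type (e).
#' @param bonds data.frame with columns `type1`, `type2`, `r0` (A),
#'   `k` (kcal/(mol A^2)). Optional.
#' @param angles data.frame with columns `type1`, `type2`, `type3`,
#'   `theta0` (rad), `k` (kcal/(mol rad^2)). Optional.
#' @param dihedrals data.frame with columns `type1`..`type4`, `k1`, `k2`,
#'   `k3` (kcal/mol), the coefficients of \eqn{\sum_n k_n (1+\cos n\phi)}.
#'   Optional.
#' @param charges_enabled logical; if `FALSE` all charges are forced to zero
#'   (the neat-phase convention for a nonpolar molecule).
#' @param dispersion_frozen logical flag recording that C6/C8 come from an
#'   upstream dispersion fit and are never free parameters here.
#' @return An object of class `forcefield_params`.
#' @export
forcefield_params <- function(pairs, charges = numeric(),
                              bonds = NULL, angles = NULL, dihedrals = NULL,
                              charges_enabled = TRUE,
                              dispersion_frozen = TRUE) {
  stopifnot(is.data.frame(pairs),
            all(c("type1", "type2", "A", "b", "C6") %in% names(pairs)))
  if (!"C8" %in% names(pairs)) pairs$C8 <- 0
  pairs <- pairs[, c("type1", "type2", "A", "b", "C6", "C8")]
  # canonical unordered pair key
  t1 <- pmin(pairs$type1, pairs$type2)
  t2 <- pmax(pairs$type1, pairs$type2)
  pairs$type1 <- t1; pairs$type2 <- t2
  key <- paste(t1, t2, sep = "-")
  if (anyDuplicated(key))
    stop("duplicate pair entries: ", paste(key[duplicated(key)], collapse = ", "))
  if (any(pairs$b <= 0)) stop("decay parameter b must be > 0 for all pairs")
  rownames(pairs) <- key

  if (length(charges) && is.null(names(charges)))
    stop("charges must be a named vector (names = atom types)")
  if (!charges_enabled) charges[] <- 0

  empty_bonds <- data.frame(type1 = character(), type2 = character(),
                            r0 = numeric(), k = numeric())
  empty_angles <- data.frame(type1 = character(), type2 = character(),
                             type3 = character(), theta0 = numeric(),
                             k = numeric())
  empty_dih <- data.frame(type1 = character(), type2 = character(),
                          type3 = character(), type4 = character(),
                          k1 = numeric(), k2 = numeric(), k3 = numeric())
  bonds <- canonicalise_bonded(bonds %||% empty_bonds, "bond")
  angles <- canonicalise_bonded(angles %||% empty_angles, "angle")
  dihedrals <- canonicalise_bonded(dihedrals %||% empty_dih, "dihedral")

  structure(
    list(pairs = pairs, charges = charges, bonds = bonds, angles = angles,
         dihedrals = dihedrals, charges_enabled = charges_enabled,
         dispersion_frozen = dispersion_frozen),
    class = "forcefield_params"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

canonicalise_bonded <- function(df, kind) {
  if (kind == "bond") {
    stopifnot(all(c("type1", "type2", "r0", "k") %in% names(df)))
    key <- bond_type_key(df$type1, df$type2)
    swap <- df$type1 > df$type2
    tmp <- df$type1[swap]; df$type1[swap] <- df$type2[swap]
    df$type2[swap] <- tmp
  } else if (kind == "angle") {
    stopifnot(all(c("type1", "type2", "type3", "theta0", "k") %in% names(df)))
    key <- angle_type_key(df$type1, df$type2, df$type3)
    swap <- df$type1 > df$type3
    tmp <- df$type1[swap]; df$type1[swap] <- df$type3[swap]
    df$type3[swap] <- tmp
  } else {
    stopifnot(all(c("type1", "type2", "type3", "type4",
                    "k1", "k2", "k3") %in% names(df)))
    key <- dihedral_type_key(df$type1, df$type2, df$type3, df$type4)
    flip <- paste(df$type1, df$type2, df$type3, df$type4, sep = "-") != key
    for (cols in list(c("type1", "type4"), c("type2", "type3"))) {
      tmp <- df[[cols[1]]][flip]
      df[[cols[1]]][flip] <- df[[cols[2]]][flip]
      df[[cols[2]]][flip] <- tmp
    }
  }
  if (anyDuplicated(key))
    stop("duplicate ", kind, " entries: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  rownames(df) <- key
  df
}

#' @export
print.forcefield_params <- function(x, ...) {
  cat("forcefield_params:\n")
  cat("  nonbonded pairs:", nrow(x$pairs),
      if (any(x$pairs$C8 != 0)) "(with C8 terms)" else "(C6 only)", "\n")
  cat("  charges:", if (x$charges_enabled)
        paste0(length(x$charges), " types") else "disabled (all zero)", "\n")
  cat("  bonded terms:", nrow(x$bonds), "bond,", nrow(x$angles), "angle,",
      nrow(x$dihedrals), "dihedral\n")
  cat("  dispersion:", if (x$dispersion_frozen) "frozen (external fit)"
      else "free", "\n")
  invisible(x)
}

# look up pair rows for vectors of type labels; error on missing pairs
pair_rows <- function(params, l1, l2) {
  key <- paste(pmin(l1, l2), pmax(l1, l2), sep = "-")
  idx <- match(key, rownames(params$pairs))
  if (anyNA(idx))
    stop("missing pair parameters for: ",
         paste(unique(key[is.na(idx)]), collapse = ", "))
  idx
}

charge_of <- function(params, types) {
  if (!length(params$charges)) return(rep(0, length(types)))
  q <- params$charges[types]
  q[is.na(q)] <- 0
  unname(q)
}

#' Serialize / read force-field parameters
#'
#' Writes a human-readable parameter file (section-structured plain text)
#' and reads it back losslessly. A provenance header records free-form
#' key-value metadata such as the seed and fit stages.
#'
#' @param params a `forcefield_params` object.
#' @param path file path.
#' @param provenance named character vector written into the header.
#' @return `write_forcefield_params` returns `path` invisibly;
#'   `read_forcefield_params` returns a `forcefield_params`.
#' @export
write_forcefield_params <- function(params, path, provenance = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# forcefield_params v1", con)
  for (k in names(provenance))
    writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
  writeLines(sprintf("flags\tcharges_enabled=%s\tdispersion_frozen=%s",
                     params$charges_enabled, params$dispersion_frozen), con)
  wsec <- function(name, df) {
    writeLines(sprintf("[%s] %d", name, nrow(df)), con)
    if (nrow(df))
      utils::write.table(format(df, digits = 17, trim = TRUE), con,
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wsec("pairs", params$pairs)
  qdf <- data.frame(type = names(params$charges),
                    q = as.numeric(params$charges))
  wsec("charges", qdf)
  wsec("bonds", params$bonds)
  wsec("angles", params$angles)
  wsec("dihedrals", params$dihedrals)
  invisible(path)
}

#' @rdname write_forcefield_params
#' @export
read_forcefield_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  flagline <- lines[startsWith(lines, "flags")]
  flags <- strsplit(sub("^flags\t", "", flagline), "\t")[[1]]
  flagval <- function(name) {
    hit <- flags[startsWith(flags, paste0(name, "="))]
    as.logical(sub(".*=", "", hit))
  }
  sec_starts <- grep("^\\[", lines)
  read_sec <- function(name) {
    hdr <- grep(sprintf("^\\[%s\\] ", name), lines)
    n <- as.integer(sub(sprintf("^\\[%s\\] ", name), "", lines[hdr]))
    if (n == 0) return(NULL)
    block <- lines[(hdr + 1):(hdr + 1 + n)]  # header row + n rows
    utils::read.table(text = block, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  pairs <- read_sec("pairs")
  qdf <- read_sec("charges")
  charges <- if (is.null(qdf)) numeric() else
    stats::setNames(qdf$q, qdf$type)
  forcefield_params(
    pairs = pairs, charges = charges,
    bonds = read_sec("bonds"), angles = read_sec("angles"),
    dihedrals = read_sec("dihedrals"),
    charges_enabled = flagval("charges_enabled"),
    dispersion_frozen = flagval("dispersion_frozen")
  )
}
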