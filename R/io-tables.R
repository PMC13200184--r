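#' Tab-separated tables with unit headers
#'
#' All observable tables move through one dialect: a `#units` comment line
#' naming the unit of every column, then a tab-separated header and body.
#' Readers validate the unit line against the expectation of the object
#' being read and fail loudly on a missing or mismatched header, so a file
#' in the wrong unit system cannot slip through silently.
#'
#' @param df data.frame to write.
#' @param units character vector of unit strings, one per column.
#' @param path file path.
#' @return `write_units_table` returns `path` invisibly;
#'   `read_units_table` returns the data.frame with the units in the
#'   `"units"` attribute.
#' @export
write_units_table <- function(df, units, path) {
  stopifnot(length(units) == ncol(df))
  con <- file(path, "w")
  on.exit(close(con))
  u <- ifelse(nzchar(units), units, "-")   # "-" marks a unitless column
  writeLines(paste(c("#units", u), collapse = "\t"), con)
  utils::write.table(format(df, digits = 17, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_units_table
#' @param expected_units optional named character vector
#'   (column -> unit); mismatches raise an error.
#' @export
read_units_table <- function(path, expected_units = NULL) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#units"))
    stop("table ", path, " is missing the #units header line")
  units <- strsplit(first, "\t")[[1]][-1]
  units[units == "-"] <- ""

  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                          stringsAsFactors = FALSE)
  if (length(units) != ncol(df))
    stop("unit header names ", length(units), " columns but table has ",
         ncol(df))
  names(units) <- names(df)
  if (!is.null(expected_units)) {
    for (cn in names(expected_units)) {
      if (!cn %in% names(df))
        stop("expected column '", cn, "' missing from ", path)
      if (!identical(units[[cn]], expected_units[[cn]]))
        stop("unit mismatch for column '", cn, "': file says '",
             units[[cn]], "', expected '", expected_units[[cn]], "'")
    }
  }
  attr(df, "units") <- units
  df
}

#' Typed table readers and writers
#'
#' Round-trip the package's observable objects through the unit-headed
#' tab-separated dialect.
#'
#' @param x the object to write.
#' @param path file path.
#' @return readers return the typed object; writers return `path`
#'   invisibly.
#' @name typed_tables
NULL

#' @rdname typed_tables
#' @export
write_pressure_series <- function(x, path) {
  stopifnot(inherits(x, "pressure_tensor_series"))
  df <- data.frame(time = x$time, PX = x$PX, PY = x$PY, PZ = x$PZ,
                   L_Z = x$L_Z)
  write_units_table(df, c("ps", "bar", "bar", "bar", "nm"), path)
}

#' @rdname typed_tables
#' @export
read_pressure_series <- function(path) {
  df <- read_units_table(path, expected_units = c(time = "ps", PX = "bar",
                                                  PY = "bar", PZ = "bar",
                                                  L_Z = "nm"))
  pressure_tensor_series(df$time, df$PX, df$PY, df$PZ, df$L_Z[1])
}

#' @rdname typed_tables
#' @export
write_coexistence_curve <- function(x, path) {
  stopifnot(inherits(x, "coexistence_curve"))
  write_units_table(as.data.frame(x), c("K", "g/L", "g/L"), path)
}

#' @rdname typed_tables
#' @export
read_coexistence_curve <- function(path) {
  df <- read_units_table(path, expected_units = c(T = "K", rho_l = "g/L",
                                                  rho_g = "g/L"))
  coexistence_curve(df$T, df$rho_l, df$rho_g)
}

#' @rdname typed_tables
#' @export
write_vapor_pressure_curve <- function(x, path) {
  stopifnot(inherits(x, "vapor_pressure_curve"))
  write_units_table(as.data.frame(x), c("K", "bar"), path)
}

#' @rdname typed_tables
#' @export
read_vapor_pressure_curve <- function(path) {
  df <- read_units_table(path, expected_units = c(T = "K", P = "bar"))
  vapor_pressure_curve(df$T, df$P)
}

#' @rdname typed_tables
#' @export
write_density_profile <- function(x, path) {
  stopifnot(inherits(x, "density_profile"))
  df <- data.frame(z = x$z, density = x$density, n_frames = x$n_frames)
  write_units_table(df, c("nm", "g/L", ""), path)
}

#' @rdname typed_tables
#' @export
read_density_profile <- function(path) {
  df <- read_units_table(path, expected_units = c(z = "nm",
                                                  density = "g/L"))
  density_profile(df$z, df$density, df$n_frames[1])
}

#' @rdname typed_tables
#' @export
write_property_table <- function(x, path) {
  stopifnot(inherits(x, "property_table"))
  write_units_table(as.data.frame(x), c("", "", "", "", ""), path)
}

#' @rdname typed_tables
#' @export
read_property_table <- function(path) {
  df <- read_units_table(path)
  property_table(df)
}
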