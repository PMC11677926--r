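#' Construct an HDO spectrum
#'
#' A spectrum is a sampled band: intensity values on a strictly monotone
#' wavenumber grid, with a unit tag distinguishing raw absorbance from molar
#' absorption coefficients (dm^3 mol^-1 cm^-1). Spectra are stored with the
#' grid ascending; descending input is reordered.
#'
#' @param wavenumber Numeric vector of wavenumbers (cm^-1), strictly monotone,
#'   finite and positive, length >= 2.
#' @param value Numeric vector of intensities, same length as `wavenumber`.
#' @param unit One of `"absorbance"` or `"molar_absorption"`.
#' @param meta Optional named list of free-form provenance tags.
#' @return An object of class `hdo_spectrum` with components `wavenumber`
#'   (ascending), `value`, `unit` and `meta`.
#' @examples
#' s <- hdo_spectrum(c(2400, 2500, 2600), c(0.1, 0.9, 0.2))
#' s
#' @export
hdo_spectrum <- function(wavenumber, value,
                         unit = c("absorbance", "molar_absorption"),
                         meta = list()) {
  unit <- match.arg(unit)
  wavenumber <- as.numeric(wavenumber)
  value <- as.numeric(value)
  if (length(wavenumber) < 2L)
    stop("a spectrum needs at least 2 grid points", call. = FALSE)
  if (length(wavenumber) != length(value))
    stop("wavenumber and value lengths differ (", length(wavenumber),
         " vs ", length(value), ")", call. = FALSE)
  if (!all(is.finite(wavenumber)) || any(wavenumber <= 0))
    stop("wavenumber grid must be finite and positive", call. = FALSE)
  d <- diff(wavenumber)
  if (any(d == 0))
    stop("duplicate wavenumber in grid: ",
         wavenumber[which(d == 0)[1L]], call. = FALSE)
  if (any(d > 0) && any(d < 0))
    stop("wavenumber grid must be strictly monotone", call. = FALSE)
  if (d[1L] < 0) {          # normalise to ascending
    wavenumber <- rev(wavenumber)
    value <- rev(value)
  }
  structure(list(wavenumber = wavenumber, value = value,
                 unit = unit, meta = meta),
            class = "hdo_spectrum")
}

#' @export
print.hdo_spectrum <- function(x, ...) {
  cat("<hdo_spectrum> ", length(x$wavenumber), " points, ",
      format(min(x$wavenumber)), "-", format(max(x$wavenumber)),
      " cm-1, unit: ", x$unit, "\n", sep = "")
  if (length(x$meta))
    cat("  meta: ", paste(names(x$meta), unlist(lapply(x$meta, format)),
                          sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.hdo_spectrum <- function(x, ...) {
  data.frame(wavenumber = x$wavenumber, value = x$value)
}

#' @export
plot.hdo_spectrum <- function(x, ..., xlab = expression(tilde(nu) ~ (cm^-1)),
                              ylab = NULL, type = "l") {
  if (is.null(ylab))
    ylab <- if (x$unit == "molar_absorption")
      expression(epsilon ~ (dm^3 ~ mol^-1 ~ cm^-1)) else "absorbance"
  graphics::plot(x$wavenumber, x$value, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "hdo_spectrum")

stop_if_not_spectrum <- function(x, what = "argument") {
  if (!is_spectrum(x))
    stop(what, " must be an hdo_spectrum", call. = FALSE)
  invisible(x)
}

#' Check that spectra share a grid
#'
#' Grids must agree pointwise to a small absolute tolerance; use [resample()]
#' first when they do not.
#' @param ... `hdo_spectrum` objects.
#' @param tol Absolute tolerance on grid agreement, cm^-1.
#' @return `TRUE` invisibly; errors on mismatch.
#' @keywords internal
check_shared_grid <- function(..., tol = 1e-8) {
  ss <- list(...)
  g <- ss[[1L]]$wavenumber
  for (s in ss[-1L]) {
    if (length(s$wavenumber) != length(g) ||
        max(abs(s$wavenumber - g)) > tol)
      stop("spectra are not on a shared wavenumber grid; resample first",
           call. = FALSE)
  }
  invisible(TRUE)
}

check_same_unit <- function(...) {
  us <- vapply(list(...), function(s) s$unit, character(1L))
  if (length(unique(us)) > 1L)
    stop("refusing to mix units (", paste(unique(us), collapse = " vs "),
         "); convert explicitly first", call. = FALSE)
  invisible(us[1L])
}

#' Read a two-column spectrum from a text file
#'
#' Plain-text two-column format: wavenumber then intensity. Comment lines
#' start with `#`; the delimiter (comma, tab or whitespace) is sniffed unless
#' forced. The returned grid is ascending regardless of file order; duplicate
#' wavenumbers are rejected.
#'
#' @param path File path.
#' @param dialect `"auto"` (sniff), `"csv"`, or `"tsv"`.
#' @param unit Unit tag to attach, see [hdo_spectrum()].
#' @return An [hdo_spectrum()].
#' @export
read_spectrum <- function(path, dialect = c("auto", "csv", "tsv"),
                          unit = c("absorbance", "molar_absorption")) {
  dialect <- match.arg(dialect)
  unit <- match.arg(unit)
  if (!file.exists(path))
    stop("spectrum file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep))
    stop("no data rows in ", path, call. = FALSE)
  sep <- switch(dialect, csv = ",", tsv = "\t",
                auto = if (grepl(",", lines[keep[1L]])) "," else
                       if (grepl("\t", lines[keep[1L]])) "\t" else "")
  nu <- val <- numeric(length(keep))
  for (i in seq_along(keep)) {
    ln <- lines[keep[i]]
    parts <- if (sep == "") strsplit(trimws(ln), "\\s+")[[1L]] else
      trimws(strsplit(ln, sep, fixed = TRUE)[[1L]])
    parts <- parts[nzchar(parts)]
    xs <- suppressWarnings(as.numeric(parts))
    if (length(xs) < 2L || anyNA(xs[1:2]))
      stop("malformed spectrum row at line ", keep[i], " of ", path,
           ": '", ln, "'", call. = FALSE)
    nu[i] <- xs[1L]; val[i] <- xs[2L]
  }
  o <- order(nu)
  if (anyDuplicated(nu))
    stop("duplicate wavenumber ", nu[duplicated(nu)][1L], " in ", path,
         call. = FALSE)
  hdo_spectrum(nu[o], val[o], unit = unit, meta = list(source = path))
}

#' Write a spectrum as a two-column text file
#'
#' Round-trip companion of [read_spectrum()], same dialects.
#' @param s An [hdo_spectrum()].
#' @param path Output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, dialect = c("csv", "tsv")) {
  stop_if_not_spectrum(s)
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  lines <- c(paste0("# unit: ", s$unit),
             paste(format(s$wavenumber, digits = 12, trim = TRUE),
                   format(s$value, digits = 12, trim = TRUE), sep = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Resample a spectrum onto a new wavenumber grid
#'
#' Linear interpolation; no smoothing. The target grid must lie inside the
#' source grid's span (no extrapolation).
#'
#' @param s An [hdo_spectrum()].
#' @param grid Target wavenumber grid (strictly monotone).
#' @return An [hdo_spectrum()] on `grid` (ascending), same unit.
#' @export
resample <- function(s, grid) {
  stop_if_not_spectrum(s)
  grid <- sort(as.numeric(grid))
  eps <- 1e-9 * diff(range(s$wavenumber))
  if (min(grid) < min(s$wavenumber) - eps ||
      max(grid) > max(s$wavenumber) + eps)
    stop("target grid [", min(grid), ", ", max(grid),
         "] extends beyond the source span [", min(s$wavenumber), ", ",
         max(s$wavenumber), "]; refusing to extrapolate", call. = FALSE)
  v <- stats::approx(s$wavenumber, s$value, xout = grid, rule = 2)$y
  hdo_spectrum(grid, v, unit = s$unit, meta = s$meta)
}

#' Pointwise linear combination of spectra
#'
#' Computes sum_i c_i * s_i on the shared grid. All spectra must already share
#' one grid and one unit.
#'
#' @param spectra List of [hdo_spectrum()] objects on a common grid.
#' @param coefficients Numeric vector, one coefficient per spectrum.
#' @return An [hdo_spectrum()].
#' @export
linear_combination <- function(spectra, coefficients) {
  if (!length(spectra) || length(spectra) != length(coefficients))
    stop("need one coefficient per spectrum", call. = FALSE)
  lapply(spectra, stop_if_not_spectrum)
  do.call(check_shared_grid, spectra)
  unit <- do.call(check_same_unit, spectra)
  v <- rep(0, length(spectra[[1L]]$wavenumber))
  for (i in seq_along(spectra))
    v <- v + coefficients[i] * spectra[[i]]$value
  hdo_spectrum(spectra[[1L]]$wavenumber, v, unit = unit)
}

#' One point of a solution series
#'
#' Bundles a spectrum with the composition of the solution it was measured on.
#'
#' @param spectrum An [hdo_spectrum()].
#' @param molality Solute molality, mol kg^-1 (>= 0).
#' @param molarity Optional molar concentration, mol dm^-3.
#' @param density Optional solution density, g cm^-3.
#' @return An object of class `series_point`.
#' @export
series_point <- function(spectrum, molality, molarity = NULL, density = NULL) {
  stop_if_not_spectrum(spectrum)
  if (molality < 0) stop("molality must be >= 0", call. = FALSE)
  if (!is.null(molarity) && molarity < 0)
    stop("molarity must be >= 0", call. = FALSE)
  structure(list(spectrum = spectrum, molality = molality,
                 molarity = molarity, density = density),
            class = "series_point")
}

#' @export
print.series_point <- function(x, ...) {
  cat("<series_point> m =", x$molality, "mol/kg\n")
  print(x$spectrum)
  invisible(x)
}
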