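#' Remove water-vapor lines from an ATR spectrum
#'
#' Subtracts k times a vapor reference, choosing k (and, with several
#' references, the reference) that minimises the roughness of the result —
#' the sum of squared second differences — over the vapor-line region.
#' The quadratic in k is solved in closed form and clamped to `k_range`.
#'
#' @param s Sample spectrum.
#' @param vapor_refs A vapor reference spectrum or a list of them, on the
#'   same grid as `s`.
#' @param window Wavenumber interval of dense vapor lines used for the
#'   roughness measure; default 1300-2000 cm^-1.
#' @param k_range Search interval for the subtraction coefficient.
#' @return The corrected [hdo_spectrum()] with attributes `k` and
#'   `ref_index`.
#' @export
subtract_vapor <- function(s, vapor_refs, window = c(1300, 2000),
                           k_range = c(-2, 2)) {
  stop_if_not_spectrum(s)
  if (is_spectrum(vapor_refs)) vapor_refs <- list(vapor_refs)
  if (!length(vapor_refs))
    stop("need at least one vapor reference spectrum", call. = FALSE)
  lapply(vapor_refs, function(v) {
    stop_if_not_spectrum(v); check_shared_grid(s, v)
  })
  i <- which(s$wavenumber >= window[1L] & s$wavenumber <= window[2L])
  if (length(i) < 5L)
    stop("vapor window contains too few grid points", call. = FALSE)
  d2 <- function(x) diff(x, differences = 2L)
  ds <- d2(s$value[i])
  best <- NULL
  for (j in seq_along(vapor_refs)) {
    dv <- d2(vapor_refs[[j]]$value[i])
    denom <- sum(dv^2)
    k <- if (denom > 0) sum(ds * dv) / denom else 0
    k <- min(max(k, k_range[1L]), k_range[2L])
    rough <- sum((ds - k * dv)^2)
    if (is.null(best) || rough < best$rough)
      best <- list(k = k, j = j, rough = rough)
  }
  out <- hdo_spectrum(s$wavenumber,
                      s$value - best$k * vapor_refs[[best$j]]$value,
                      unit = s$unit, meta = s$meta)
  attr(out, "k") <- best$k
  attr(out, "ref_index") <- best$j
  out
}

#' Subtract the bulk-water background from a solution spectrum
#'
#' Pure water is removed with subtraction coefficient c_water / 55.33,
#' the ratio of the molar concentration of water in the sample to that of
#' pure water (55.33 mol dm^-3).
#'
#' @param sample Sample spectrum.
#' @param pure_water Pure-water spectrum on the same grid.
#' @param c_water Molar concentration of water in the sample, mol dm^-3,
#'   in (0, 55.33].
#' @param c_water_pure Molar concentration of pure water; 55.33 mol dm^-3.
#' @return The background-corrected [hdo_spectrum()].
#' @export
subtract_water_background <- function(sample, pure_water, c_water,
                                      c_water_pure = 55.33) {
  stop_if_not_spectrum(sample); stop_if_not_spectrum(pure_water)
  check_shared_grid(sample, pure_water)
  check_same_unit(sample, pure_water)
  if (c_water <= 0 || c_water > c_water_pure)
    stop("c_water must be in (0, ", c_water_pure, "] mol/dm^3",
         call. = FALSE)
  hdo_spectrum(sample$wavenumber,
               sample$value - (c_water / c_water_pure) * pure_water$value,
               unit = sample$unit, meta = sample$meta)
}

#' Convert an absorbance spectrum to a molar spectrum
#'
#' Divides by the solute molar concentration; the unit tag becomes
#' `molar_absorption`.
#'
#' @param s Absorbance spectrum.
#' @param c_solute Solute concentration, mol dm^-3 (> 0).
#' @return An [hdo_spectrum()] with unit `molar_absorption`.
#' @export
to_molar_spectrum <- function(s, c_solute) {
  stop_if_not_spectrum(s)
  if (c_solute <= 0) stop("c_solute must be > 0", call. = FALSE)
  hdo_spectrum(s$wavenumber, s$value / c_solute,
               unit = "molar_absorption", meta = s$meta)
}

#' Mean concentration-difference spectrum of a molar series
#'
#' From every molar spectrum except the first (lowest concentration), the
#' first is subtracted with coefficient 1; the differences are averaged with
#' equal weights. The result reports the average change of the solute bands
#' with concentration: flat when band positions are concentration-independent,
#' structured when solute-solute interactions shift them.
#'
#' @param molar_series List of molar spectra ordered by increasing
#'   concentration (>= 2, shared grid).
#' @return The averaged difference [hdo_spectrum()].
#' @export
mean_difference_spectrum <- function(molar_series) {
  if (length(molar_series) < 2L)
    stop("need at least 2 spectra in the series", call. = FALSE)
  lapply(molar_series, stop_if_not_spectrum)
  do.call(check_shared_grid, molar_series)
  ref <- molar_series[[1L]]$value
  diffs <- vapply(molar_series[-1L], function(s) s$value - ref,
                  numeric(length(ref)))
  hdo_spectrum(molar_series[[1L]]$wavenumber, rowMeans(diffs),
               unit = molar_series[[1L]]$unit)
}
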