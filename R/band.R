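#' Empirical OD wavenumber for an O...O distance
#'
#' The OD-stretch wavenumber of HDO correlates with the intermolecular
#' oxygen-oxygen distance of the donor-acceptor pair:
#' nu/cm^-1 = 2727 - exp(16.01 - 3.73 R/Angstrom). Strictly increasing in R.
#'
#' @param r O...O distance, Angstrom (> 0). Vectorised.
#' @return Wavenumber, cm^-1.
#' @export
distance_to_wavenumber <- function(r) {
  if (any(r <= 0)) stop("distance must be > 0", call. = FALSE)
  2727 - exp(16.01 - 3.73 * r)
}

#' O...O distance for an OD wavenumber
#'
#' Algebraic inverse of [distance_to_wavenumber()]:
#' R = (16.01 - ln(2727 - nu)) / 3.73, defined for nu < 2727 cm^-1.
#'
#' @param nu Wavenumber, cm^-1 (< 2727). Vectorised.
#' @return Distance, Angstrom.
#' @export
wavenumber_to_distance <- function(nu) {
  if (any(nu >= 2727))
    stop("the correlation is undefined at or above 2727 cm^-1",
         call. = FALSE)
  (16.01 - log(2727 - nu)) / 3.73
}

# dnu/dR of the correlation, Angstrom^-1 cm^-1
dnu_dr <- function(r) 3.73 * exp(16.01 - 3.73 * r)

# parabola through three points around a discrete extremum -> refined abscissa
quad_refine <- function(x, y, i) {
  if (i <= 1L || i >= length(x)) return(x[i])
  x0 <- x[(i - 1L):(i + 1L)]; y0 <- y[(i - 1L):(i + 1L)]
  d <- (y0[1L] - 2 * y0[2L] + y0[3L])
  if (d >= 0) return(x[i])
  # assumes symmetric local spacing; use exact parabola via polyfit otherwise
  h1 <- x0[2L] - x0[1L]; h2 <- x0[3L] - x0[2L]
  if (abs(h1 - h2) < 1e-9 * h1) {
    x0[2L] + 0.5 * h1 * (y0[1L] - y0[3L]) / d
  } else {
    a <- stats::lm(y0 ~ stats::poly(x0, 2, raw = TRUE))$coefficients
    -a[2L] / (2 * a[3L])
  }
}

default_band_window <- function(s) {
  c(max(2200, min(s$wavenumber)), min(2700, max(s$wavenumber)))
}

#' Band position at maximum
#'
#' Discrete maximum refined by a local quadratic through the three
#' surrounding points. A maximum on the window edge is returned with
#' attribute `boundary = TRUE`.
#'
#' @param s An [hdo_spectrum()].
#' @param window Wavenumber interval analysed; default the OD-stretch region
#'   2200-2700 cm^-1 clipped to the grid.
#' @return Wavenumber of the band maximum, cm^-1.
#' @export
band_maximum <- function(s, window = default_band_window(s)) {
  stop_if_not_spectrum(s)
  i <- which(s$wavenumber >= window[1L] & s$wavenumber <= window[2L])
  if (length(i) < 3L) stop("window too narrow", call. = FALSE)
  x <- s$wavenumber[i]; y <- s$value[i]
  if (diff(range(y)) <= 1e-12 * max(abs(y), 1e-300))
    stop("spectrum is flat in the window; maximum ill-defined",
         call. = FALSE)
  k <- which.max(y)
  if (k == 1L || k == length(y))
    return(structure(x[k], boundary = TRUE))
  quad_refine(x, y, k)
}

#' Band position at the gravity center
#'
#' Intensity-weighted mean wavenumber over the window (first moment,
#' trapezoidal integration) — a proxy for the mean hydrogen-bond energy of
#' the absorbing water population.
#'
#' @inheritParams band_maximum
#' @return Gravity-center wavenumber, cm^-1.
#' @export
gravity_center <- function(s, window = default_band_window(s)) {
  stop_if_not_spectrum(s)
  i <- which(s$wavenumber >= window[1L] & s$wavenumber <= window[2L])
  if (length(i) < 2L) stop("window too narrow", call. = FALSE)
  x <- s$wavenumber[i]; y <- s$value[i]
  denom <- pracma::trapz(x, y)
  if (abs(denom) <= 1e-300)
    stop("zero integrated intensity in window", call. = FALSE)
  pracma::trapz(x, x * y) / denom
}

#' O...O distance distribution from a band contour
#'
#' Maps a non-negative OD band onto the distance axis through the empirical
#' correlation: P(R) = C eps(nu(R)) (dnu/dR), with
#' dnu/dR = 3.73 exp(16.01 - 3.73 R) from differentiating the correlation,
#' and C normalising the integral to 1. Negative spectral values within
#' -1% of the peak are clipped to zero (with a warning); larger negative
#' excursions are an error.
#'
#' @param s An [hdo_spectrum()], non-negative over the mapped window.
#' @param r_range Distance interval, Angstrom. Default: the image of the
#'   band window (2200-2700 cm^-1 clipped to the grid).
#' @param n Number of points of the distance grid.
#' @return Object of class `oo_distribution`: `r_grid`, `p_values`, `r_max`
#'   (most probable distance), `r_gravity` (mean distance), `norm_constant`.
#' @export
distance_distribution <- function(s, r_range = NULL, n = 2001L) {
  stop_if_not_spectrum(s)
  win <- default_band_window(s)
  if (is.null(r_range)) r_range <- wavenumber_to_distance(win)
  r_range <- sort(as.numeric(r_range))
  nu_lo <- distance_to_wavenumber(r_range[1L])
  nu_hi <- distance_to_wavenumber(r_range[2L])
  eps <- 1e-9 * diff(range(s$wavenumber))
  if (nu_lo < min(s$wavenumber) - eps || nu_hi > max(s$wavenumber) + eps)
    stop("r_range maps to [", round(nu_lo, 1), ", ", round(nu_hi, 1),
         "] cm^-1, outside the spectrum span", call. = FALSE)
  r <- seq(r_range[1L], r_range[2L], length.out = n)
  nu <- distance_to_wavenumber(r)
  e <- stats::approx(s$wavenumber, s$value, xout = nu, rule = 2)$y
  pk <- max(e)
  if (min(e) < -0.01 * pk)
    stop("spectrum has negative values beyond 1% of the peak in the mapped ",
         "window; baseline-correct first", call. = FALSE)
  if (min(e) < 0) {
    warning("clipping small negative spectral values (>= -1% of peak) ",
            "to zero for the distance transform", call. = FALSE)
    e <- pmax(e, 0)
  }
  p <- e * dnu_dr(r)
  Z <- pracma::trapz(r, p)
  if (Z <= 0) stop("zero probability mass in r_range", call. = FALSE)
  p <- p / Z
  k <- which.max(p)
  structure(list(r_grid = r, p_values = p,
                 r_max = quad_refine(r, p, k),
                 r_gravity = pracma::trapz(r, r * p),
                 norm_constant = 1 / Z),
            class = "oo_distribution")
}

#' @export
print.oo_distribution <- function(x, ...) {
  cat("<oo_distribution> ", length(x$r_grid), " points on [",
      format(min(x$r_grid)), ", ", format(max(x$r_grid)), "] Angstrom\n",
      "  most probable R_OO: ", format(x$r_max, digits = 6),
      "   mean R_OO: ", format(x$r_gravity, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
plot.oo_distribution <- function(x, ...,
                                 xlab = expression(R[OO] ~ (ring(A))),
                                 ylab = expression(P(R[OO]))) {
  graphics::plot(x$r_grid, x$p_values, type = "l", xlab = xlab, ylab = ylab,
                 ...)
  graphics::abline(v = x$r_max, lty = 3)
  invisible(x)
}

#' Difference of two O...O distance distributions
#'
#' delta_P(R) = P1(R) - P2(R) on the overlap of the two distance grids
#' (linear resampling). Since both distributions integrate to 1, the
#' difference integrates to 0 when the grids fully overlap.
#'
#' @param p1,p2 `oo_distribution` objects with overlapping ranges.
#' @return List with `r_grid` and `dp` (signed density).
#' @export
distribution_difference <- function(p1, p2) {
  lo <- max(min(p1$r_grid), min(p2$r_grid))
  hi <- min(max(p1$r_grid), max(p2$r_grid))
  if (lo >= hi) stop("distance ranges do not overlap", call. = FALSE)
  r <- seq(lo, hi, length.out = max(length(p1$r_grid), length(p2$r_grid)))
  v1 <- stats::approx(p1$r_grid, p1$p_values, xout = r)$y
  v2 <- stats::approx(p2$r_grid, p2$p_values, xout = r)$y
  list(r_grid = r, dp = v1 - v2)
}
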