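#' Mean molar mass of the solvent in an HDO experiment
#'
#' Mass-weighted mean of the H2O (0.018015 kg/mol) and D2O (0.020027 kg/mol)
#' molar masses for a given D2O/H2O mass ratio: total mass over total moles.
#'
#' @param d2o_to_h2o_mass_ratio Mass of D2O added per unit mass of H2O,
#'   in `[0, 0.1]`. The transmission HDO experiments emulated here use 0.04.
#' @return Mean molar mass, kg/mol.
#' @examples
#' mean_molar_mass(0)      # pure H2O
#' mean_molar_mass(0.04)   # 4% D2O by weight
#' @export
mean_molar_mass <- function(d2o_to_h2o_mass_ratio) {
  r <- d2o_to_h2o_mass_ratio
  if (r < 0) stop("mass ratio must be >= 0", call. = FALSE)
  if (r > 0.1) stop("mass ratio above 0.1 is outside the model's range",
                    call. = FALSE)
  m_h2o <- 0.018015
  m_d2o <- 0.020027
  (1 + r) / (1 / m_h2o + r / m_d2o)
}

#' Affected-water spectrum from the two-state difference model
#'
#' The solution spectrum is modelled as a population mixture of bulk-like and
#' solute-affected water. Per mole of solute, N moles of water are affected,
#' giving eps_a = (eps - eps_b) / (N M m) + eps_b, where m is the molality
#' and M the mean molar mass of the solvent.
#'
#' @param solution Solution spectrum eps at molality `m` (molar absorption).
#' @param bulk Bulk-water spectrum eps_b on the same grid.
#' @param N Affected number (> 0).
#' @param M Mean molar mass of water, kg/mol (> 0); see [mean_molar_mass()].
#' @param m Molality, mol/kg (> 0).
#' @return The affected-water spectrum eps_a as an [hdo_spectrum()].
#' @export
affected_spectrum <- function(solution, bulk, N, M, m) {
  stop_if_not_spectrum(solution); stop_if_not_spectrum(bulk)
  check_shared_grid(solution, bulk)
  check_same_unit(solution, bulk)
  if (!all(c(N, M, m) > 0))
    stop("N, M and m must all be > 0", call. = FALSE)
  v <- (solution$value - bulk$value) / (N * M * m) + bulk$value
  hdo_spectrum(solution$wavenumber, v, unit = solution$unit)
}

#' Fit the affected-water model to a molality series
#'
#' Estimates the affected number N and the solute-affected water spectrum
#' eps_a from spectra of one solute at several molalities plus a bulk
#' reference. The two-state model implies that eps is linear in molality with
#' slope N*M*(eps_a - eps_b) at every wavenumber; the fit first computes that
#' slope spectrum by per-wavenumber regression, then fixes N by the bulk-free
#' criterion: eps_a must be non-negative and must vanish where only bulk-like
#' water absorbs. Because eps_a - eps_b is inversely proportional to N, the
#' criterion value is the smallest N for which eps_a stays non-negative;
#' it is attained where eps_a touches zero, i.e. on the blue flank of the OD
#' band for a redshifted affected spectrum. There the slope obeys
#' slope = -N*M*eps_b exactly, and N is estimated by weighted least squares
#' over an edge window of the analysis region (exact maximum-ratio shortcut
#' for noiseless input).
#'
#' @param series List of [series_point()]s (>= 3 molalities spanning at least
#'   a twofold range, unless `N` is supplied).
#' @param bulk Bulk-water reference spectrum.
#' @param N Optional fixed affected number; when given no estimation is done
#'   and eps_a is extracted directly (single-molality extraction allowed).
#' @param d2o_ratio D2O/H2O mass ratio defining M, default 0.04.
#' @param window_frac Analysis window: wavenumbers where the bulk spectrum
#'   exceeds this fraction of its peak. Default 0.02.
#' @param edge_width Width (cm^-1) of the blue-edge window assumed free of
#'   affected-water absorption. Default 60.
#' @param flank `"blue"` (redshifted affected spectrum, default) or `"red"`.
#' @return An object of class `affected_water` with components
#'   `epsilon_a` (averaged extraction), `N`, `M`, `m` (molalities),
#'   `slope` (slope spectrum), `bulk`, `diagnostics` (noise level, per-molality
#'   agreement, linearity check) and `estimated` (logical).
#' @seealso [affected_spectrum()], [make_binary_series()]
#' @export
affected_water <- function(series, bulk, N = NULL, d2o_ratio = 0.04,
                           window_frac = 0.02, edge_width = 60,
                           flank = c("blue", "red")) {
  flank <- match.arg(flank)
  stop_if_not_spectrum(bulk)
  if (inherits(series, "series_point")) series <- list(series)
  if (!length(series)) stop("empty series", call. = FALSE)
  lapply(series, function(p) {
    if (!inherits(p, "series_point"))
      stop("series must be a list of series_point objects", call. = FALSE)
  })
  mols <- vapply(series, function(p) p$molality, numeric(1L))
  specs <- lapply(series, function(p) resample(p$spectrum, bulk$wavenumber))
  M <- mean_molar_mass(d2o_ratio)
  nu <- bulk$wavenumber
  eb <- bulk$value
  E <- vapply(specs, function(s) s$value, numeric(length(nu)))

  if (is.null(N)) {
    if (length(unique(mols)) < 3L)
      stop("estimating N needs >= 3 distinct molalities; ",
           "supply N explicitly for single-point extraction", call. = FALSE)
    if (max(mols) / min(mols) < 2)
      stop("molalities must span at least a twofold range to estimate N",
           call. = FALSE)
    est <- estimate_N(nu, E, eb, mols, M, window_frac, edge_width, flank)
    N <- est$N
    estimated <- TRUE
  } else {
    if (N <= 0) stop("N must be > 0", call. = FALSE)
    est <- list(N = N, slope = NULL, sigma = NA_real_, window = NULL,
                edge = NULL, linear_ok = NA)
    estimated <- FALSE
  }

  # extract eps_a at each molality, then average
  ea_each <- vapply(seq_along(mols), function(i)
    (E[, i] - eb) / (N * M * mols[i]) + eb, numeric(length(nu)))
  ea <- rowMeans(ea_each)
  agree <- apply(ea_each, 2L, function(x) sqrt(mean((x - ea)^2)))

  out <- structure(list(
    epsilon_a = hdo_spectrum(nu, ea, unit = bulk$unit),
    N = N, M = M, m = mols,
    slope = if (!is.null(est$slope))
      hdo_spectrum(nu, est$slope, unit = bulk$unit) else NULL,
    bulk = bulk,
    diagnostics = list(sigma = est$sigma,
                       per_molality_rms = agree,
                       linear_ok = est$linear_ok,
                       window = est$window, edge = est$edge,
                       epsilon_a_by_molality = ea_each),
    estimated = estimated,
    call = match.call()),
    class = "affected_water")
  if (isFALSE(est$linear_ok))
    warning("solution spectra deviate from linearity in molality beyond ",
            "noise; the two-state model may be violated", call. = FALSE)
  out
}

# core N estimation; E is length(nu) x n_molalities
estimate_N <- function(nu, E, eb, mols, M, window_frac, edge_width, flank) {
  n_m <- length(mols)
  mb <- mean(mols)
  Sxx <- sum((mols - mb)^2)
  slope <- c(E %*% (mols - mb)) / Sxx
  fit <- outer(slope, mols - mb) + rowMeans(E)
  resid <- E - fit
  sig2 <- rowSums(resid^2) / max(n_m - 2L, 1L)
  # smooth the per-point residual variance; it only weights, never biases
  sig2s <- stats::filter(sig2, rep(1 / 21, 21), sides = 2)
  sig2s[is.na(sig2s)] <- sig2[is.na(sig2s)]
  se <- sqrt(pmax(c(sig2s), 0) / Sxx)

  W <- which(eb >= window_frac * max(eb))
  if (!length(W)) stop("empty analysis window", call. = FALSE)
  if (max(abs(slope[W])) <= 1e-12 * max(eb) ||
      max(abs(E - eb)) <= 1e-12 * max(eb))
    stop("no solute effect detected: solution spectra equal bulk; ",
         "the affected number is undetermined", call. = FALSE)

  ratio <- -slope / (M * eb)
  sigma <- sqrt(stats::median(sig2[W]))
  noiseless <- max(se[W]) <= 1e-10 * max(abs(slope))

  # linearity check: lack-of-fit of the per-wavenumber linear model against
  # an independent white-noise estimate from second differences along nu
  # (bands are smooth; white noise survives the high-pass)
  lin_ok <- TRUE
  if (n_m >= 4L) {
    hf2 <- stats::median(vapply(seq_len(n_m), function(i)
      (stats::mad(diff(E[W, i], differences = 2L)) / sqrt(6))^2,
      numeric(1L)))
    lin_ok <- stats::median(sig2[W]) <= 9 * hf2 +
      (1e-8 * max(abs(slope)))^2
  }

  if (noiseless) {
    N <- if (flank == "blue") max(ratio[W]) else max(ratio[W])
    return(list(N = N, slope = slope, sigma = 0, window = range(nu[W]),
                edge = NA, linear_ok = lin_ok))
  }

  # blue-edge (or red-edge) window assumed free of affected absorption
  step <- stats::median(diff(nu))
  k <- max(10L, round(edge_width / step))
  idx <- if (flank == "blue") {
    hi <- max(W); seq(max(min(W), hi - k + 1L), hi)
  } else {
    lo <- min(W); seq(lo, min(max(W), lo + k - 1L))
  }
  wls <- function(ii) {
    w <- 1 / pmax(se[ii]^2, 1e-300)
    -sum(w * slope[ii] * eb[ii]) / (M * sum(w * eb[ii]^2))
  }
  N <- wls(idx)
  u <- (slope[idx] + N * M * eb[idx]) / pmax(se[idx], 1e-300)
  keep <- abs(u) <= 4
  if (any(!keep) && sum(keep) >= 5L) N <- wls(idx[keep])
  if (!is.finite(N) || N <= 0)
    stop("affected-number estimate did not converge to a positive value; ",
         "check that the affected spectrum vanishes on the ", flank,
         " flank", call. = FALSE)
  list(N = N, slope = slope, sigma = sigma, window = range(nu[W]),
       edge = range(nu[idx]), linear_ok = lin_ok)
}

#' @export
print.affected_water <- function(x, ...) {
  cat("Affected-water fit (two-state HDO difference model)\n")
  cat("  N =", format(x$N, digits = 5),
      if (x$estimated) "(estimated, bulk-free criterion)" else "(fixed)",
      "\n")
  cat("  M =", format(x$M, digits = 6), "kg/mol;  molalities:",
      paste(format(x$m), collapse = ", "), "mol/kg\n")
  invisible(x)
}

#' @export
summary.affected_water <- function(object, ...) {
  d <- object$diagnostics
  cat("Affected-water fit\n")
  cat("  affected number N :", format(object$N, digits = 6),
      if (object$estimated) " (bulk-free criterion)" else " (user-fixed)", "\n")
  cat("  mean molar mass M :", format(object$M, digits = 6), "kg/mol\n")
  cat("  molalities        :", paste(format(object$m), collapse = ", "),
      "mol/kg\n")
  if (!is.na(d$sigma))
    cat("  noise sd (est.)   :", format(d$sigma, digits = 3), "\n")
  if (!is.null(d$edge) && !all(is.na(d$edge)))
    cat("  bulk-free window  :", paste(format(d$edge), collapse = " - "),
        "cm-1\n")
  cat("  per-molality eps_a rms deviation from mean:",
      paste(format(d$per_molality_rms, digits = 3), collapse = ", "), "\n")
  if (isFALSE(d$linear_ok))
    cat("  WARNING: linearity in molality violated beyond noise\n")
  invisible(object)
}

#' @export
coef.affected_water <- function(object, ...) {
  c(N = object$N, M = object$M)
}

#' Reconstruct solution spectra from an affected-water fit
#'
#' Inverts the two-state model at the requested molalities:
#' eps(m) = eps_b + N*M*m*(eps_a - eps_b).
#' @param object An `affected_water` fit.
#' @param molality Molalities to predict at; defaults to the fitted ones.
#' @param ... Unused.
#' @return A list of [hdo_spectrum()]s, one per molality.
#' @export
predict.affected_water <- function(object, molality = object$m, ...) {
  eb <- object$bulk$value
  ea <- object$epsilon_a$value
  lapply(molality, function(m)
    hdo_spectrum(object$bulk$wavenumber,
                 eb + object$N * object$M * m * (ea - eb),
                 unit = object$bulk$unit))
}

#' @export
residuals.affected_water <- function(object, ...) {
  d <- object$diagnostics
  sweep(d$epsilon_a_by_molality, 1L, object$epsilon_a$value)
}

#' @export
plot.affected_water <- function(x, ...) {
  nu <- x$bulk$wavenumber
  graphics::plot(nu, x$bulk$value, type = "l", lty = 2,
                 xlab = expression(tilde(nu) ~ (cm^-1)),
                 ylab = expression(epsilon), ...)
  graphics::lines(nu, x$epsilon_a$value, col = 2)
  graphics::legend("topright", c("bulk", "affected"), lty = c(2, 1),
                   col = c(1, 2), bty = "n")
  invisible(x)
}
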