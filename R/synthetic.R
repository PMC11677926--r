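#' @importFrom stats dnorm pnorm rnorm runif optimize uniroot approx
NULL

# Run code with a private RNG stream so generators never disturb (or depend
# on) the caller's global random state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# skew-normal density, location xi, scale omega, shape alpha
sn_density <- function(x, xi, omega, alpha) {
  z <- (x - xi) / omega
  2 / omega * stats::dnorm(z) * stats::pnorm(alpha * z)
}

sn_mean <- function(xi, omega, alpha) {
  xi + omega * alpha / sqrt(1 + alpha^2) * sqrt(2 / pi)
}

sn_mode <- function(xi, omega, alpha) {
  if (alpha == 0) return(xi)
  z <- stats::optimize(function(z) -sn_density(z, 0, 1, alpha),
                       c(-3, 3), tol = 1e-10)$minimum
  xi + omega * z
}

#' Default wavenumber grid for synthetic OD-stretch spectra
#'
#' 2000-2800 cm^-1 in 1 cm^-1 steps, covering the decoupled OD stretch of HDO
#' with margin on both flanks.
#' @return Numeric vector.
#' @export
default_grid <- function() seq(2000, 2800, by = 1)

#' Synthetic band presets emulating HDO OD-stretch contours
#'
#' Skew-normal parameter sets solved (once, numerically) so that each band
#' reproduces a characteristic pair of OD band positions — maximum and gravity
#' center — of bulk water and of water affected by small-peptide and DMSO
#' solutes, with full widths typical of HDO bands (150-230 cm^-1). `"binary_fixture"`
#' is the redshifted band used by the binary parameter-recovery fixtures; it
#' is floored to zero on its blue flank (see [make_band()]'s `floor_at`).
#'
#' @param name One of `"bulk"`, `"diglycine"`, `"nagma"`, `"dmso"`,
#'   `"changed"`, `"binary_fixture"`.
#' @return Named list with `xi`, `omega`, `alpha`, `amplitude`, `floor_at`
#'   (or `NULL`).
#' @export
band_preset <- function(name = c("bulk", "diglycine", "nagma", "dmso",
                                 "changed", "binary_fixture")) {
  name <- match.arg(name)
  # xi/omega/alpha solved from (nu_max, nu_gravity, fwhm) targets:
  # bulk 2509/2497/160, diglycine 2496/2449/200, nagma 2505/2488/170,
  # dmso 2514/2483/150, changed 2415/2355/180
  p <- switch(name,
    bulk      = list(xi = 2560.324, omega = 94.5699, alpha = -1.5433,
                     amplitude = 100, floor_at = NULL),
    diglycine = list(xi = 2561.502, omega = 146.7702, alpha = -3.4603,
                     amplitude = 105, floor_at = NULL),
    nagma     = list(xi = 2561.839, omega = 105.6548, alpha = -1.8154,
                     amplitude = 102, floor_at = NULL),
    dmso      = list(xi = 2564.395, omega = 107.3133, alpha = -3.0628,
                     amplitude = 100, floor_at = NULL),
    changed   = list(xi = 2465.630, omega = 141.1100, alpha = -5.2897,
                     amplitude = 95, floor_at = NULL),
    binary_fixture = list(xi = 2520, omega = 80, alpha = -2.2,
                          amplitude = 110, floor_at = 2615))
  p
}

#' Generate a synthetic skew-normal band
#'
#' Skew-normal contours keep analytic moments available to tests while
#' reproducing the asymmetry of experimental HDO bands (gravity center below
#' the maximum for negative skew). `floor_at` subtracts the band's value at
#' the given wavenumber and clips negatives, producing a band that touches
#' zero exactly there — the property the affected-number criterion keys on.
#'
#' @param center Band location parameter xi, cm^-1.
#' @param width Scale parameter omega, cm^-1 (> 0).
#' @param skew Shape parameter alpha (0 = symmetric Gaussian).
#' @param amplitude Peak height after scaling (0 allowed).
#' @param grid Wavenumber grid, default [default_grid()].
#' @param floor_at Optional wavenumber at which the band is floored to zero.
#' @return An [hdo_spectrum()] with unit `molar_absorption` and the analytic
#'   skew-normal moments attached in `meta$moments` (`mean`, `mode` of the
#'   unfloored density).
#' @export
make_band <- function(center, width, skew = 0, amplitude = 1,
                      grid = default_grid(), floor_at = NULL) {
  if (width <= 0) stop("width must be > 0", call. = FALSE)
  v <- sn_density(grid, center, width, skew)
  if (!is.null(floor_at)) {
    fl <- sn_density(floor_at, center, width, skew)
    v <- pmax(v - fl, 0)
  }
  pk <- max(v)
  v <- if (pk > 0) v / pk * amplitude else v * 0
  hdo_spectrum(grid, v, unit = "molar_absorption",
               meta = list(moments = list(
                 mean = sn_mean(center, width, skew),
                 mode = sn_mode(center, width, skew)),
                 params = list(xi = center, omega = width, alpha = skew,
                               amplitude = amplitude, floor_at = floor_at)))
}

#' Band from a named preset
#' @param name Preset name, see [band_preset()].
#' @param grid Wavenumber grid.
#' @return An [hdo_spectrum()].
#' @export
preset_band <- function(name, grid = default_grid()) {
  p <- band_preset(name)
  make_band(p$xi, p$omega, p$alpha, p$amplitude, grid = grid,
            floor_at = p$floor_at)
}

#' Generate a binary molality series from the two-state model
#'
#' Inverts the affected-spectrum relation: at molality m the solution spectrum
#' is eps(m) = eps_b + N*M*m*(eps_a - eps_b), optionally with seeded Gaussian
#' noise. The defaults are the study conditions of the accompanying analyses:
#' molalities 0.1-0.5 mol/kg and a 4% D2O/H2O mass ratio.
#'
#' @param bulk Bulk-water spectrum eps_b.
#' @param affected Affected-water spectrum eps_a (same grid).
#' @param N Affected number (moles of water per mole solute).
#' @param molalities Molalities, mol/kg.
#' @param d2o_ratio D2O/H2O mass ratio used for the mean molar mass.
#' @param noise_sd Noise level. For `noise_type = "additive"` this is a
#'   fraction of the bulk peak (default 0.003, i.e. 0.3%); for
#'   `"multiplicative"` it is the relative per-point standard deviation.
#' @param noise_type `"additive"` or `"multiplicative"`.
#' @param seed Integer seed; all randomness flows through it.
#' @return List of [series_point()]s, with the ground truth in
#'   `attr(, "truth")`.
#' @export
make_binary_series <- function(bulk, affected, N,
                               molalities = c(0.1, 0.2, 0.3, 0.4, 0.5),
                               d2o_ratio = 0.04,
                               noise_sd = 0.003,
                               noise_type = c("additive", "multiplicative"),
                               seed = 1L) {
  stop_if_not_spectrum(bulk); stop_if_not_spectrum(affected)
  check_shared_grid(bulk, affected)
  noise_type <- match.arg(noise_type)
  if (any(molalities <= 0)) stop("molalities must be > 0", call. = FALSE)
  M <- mean_molar_mass(d2o_ratio)
  scale0 <- max(bulk$value)
  pts <- with_seed(seed, lapply(molalities, function(m) {
    v <- bulk$value + N * M * m * (affected$value - bulk$value)
    if (noise_sd > 0) {
      v <- if (noise_type == "additive")
        v + stats::rnorm(length(v), 0, noise_sd * scale0)
      else v * (1 + stats::rnorm(length(v), 0, noise_sd))
    }
    series_point(hdo_spectrum(bulk$wavenumber, v, unit = bulk$unit),
                 molality = m)
  }))
  attr(pts, "truth") <- list(N = N, M = M, affected = affected, bulk = bulk,
                             noise_sd = noise_sd, noise_type = noise_type,
                             seed = seed)
  pts
}

#' Generate ternary (two-solute) affected spectra
#'
#' Composes the experimental affected spectrum of an A-B-water system as the
#' N-weighted mixture of pure-component affected spectra plus a
#' changed-affected contribution:
#' eps_exp = (N_A eps_A + N_B eps_B + N_changed eps_changed) / N_exp with
#' N_exp = N_A + N_B + N_changed. One fixture is produced per molar ratio;
#' the ratio scales N_B (the solute in excess).
#'
#' @param eps_A,eps_B Pure-component affected spectra (shared grid).
#' @param eps_changed Changed-affected spectrum (may be `NULL` when
#'   `N_changed = 0`).
#' @param N_A,N_B,N_changed Affected numbers (>= 0, not all zero).
#' @param molar_ratios Numeric vector of B:A molar ratios.
#' @param noise_sd Additive noise as a fraction of the A-band peak.
#' @param seed Integer seed.
#' @return List with one element per ratio: `ratio`, `spectrum` (eps_exp),
#'   `N_exp`, `N_theor` and the generating `truth`.
#' @export
make_ternary_series <- function(eps_A, eps_B, eps_changed = NULL,
                                N_A, N_B, N_changed = 0,
                                molar_ratios = 1,
                                noise_sd = 0, seed = 1L) {
  stop_if_not_spectrum(eps_A); stop_if_not_spectrum(eps_B)
  if (N_A < 0 || N_B < 0 || N_changed < 0)
    stop("affected numbers must be >= 0", call. = FALSE)
  if (N_A + N_B + N_changed == 0)
    stop("at least one affected number must be positive", call. = FALSE)
  check_shared_grid(eps_A, eps_B)
  if (N_changed > 0) {
    stop_if_not_spectrum(eps_changed)
    check_shared_grid(eps_A, eps_changed)
  }
  scale0 <- max(eps_A$value)
  with_seed(seed, lapply(molar_ratios, function(rho) {
    nb <- N_B * rho
    nexp <- N_A + nb + N_changed
    v <- (N_A * eps_A$value + nb * eps_B$value +
            if (N_changed > 0) N_changed * eps_changed$value else 0) / nexp
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd * scale0)
    list(ratio = rho,
         spectrum = hdo_spectrum(eps_A$wavenumber, v,
                                 unit = "molar_absorption"),
         N_exp = nexp,
         N_theor = N_A + nb,
         truth = list(N_A = N_A, N_B = nb, N_changed = N_changed))
  }))
}

#' Generate a toy hydration-shell geometry
#'
#' Builds coordinates whose water-oxygen O...O distance multiset is known by
#' construction. With `oo_target_distances` the oxygens form an extended chain
#' whose consecutive distances are the targets (non-consecutive pairs then
#' exceed the hydrogen-bond range, so the recoverable in-range multiset equals
#' the targets). Otherwise `n_waters` oxygens are placed at seeded random
#' positions within `radial_range` of a single solute atom.
#'
#' @param n_waters Number of water oxygens (>= 1); ignored when targets given.
#' @param radial_range Distance range (Angstrom) from the solute atom for
#'   random placement.
#' @param oo_target_distances Optional consecutive O-O distances (Angstrom).
#' @param seed Integer seed.
#' @return A [shell_model()] with one carbon solute atom at the origin.
#' @export
make_toy_shell <- function(n_waters = 10, radial_range = c(2.6, 3.4),
                           oo_target_distances = NULL, seed = 1L) {
  if (!is.null(oo_target_distances)) {
    d <- as.numeric(oo_target_distances)
    if (any(!is.finite(d)) || any(d <= 0))
      stop("infeasible target distances", call. = FALSE)
    # extended zig-zag chain: consecutive pairs at the target distances,
    # direction alternating slightly so non-consecutive pairs are longer
    n <- length(d) + 1L
    pos <- matrix(0, n, 3L)
    pos[1L, ] <- c(2.9, 0, 0)
    dir <- c(1, 0, 0)
    for (i in seq_along(d)) {
      bend <- if (i %% 2L == 0L) c(0, 0.15, 0) else c(0, -0.15, 0)
      v <- dir + bend; v <- v / sqrt(sum(v^2))
      pos[i + 1L, ] <- pos[i, ] + d[i] * v
    }
    atoms <- rbind(data.frame(element = "C", x = 0, y = 0, z = 0),
                   data.frame(element = "O", x = pos[, 1L], y = pos[, 2L],
                              z = pos[, 3L]))
    return(shell_model(atoms, solute_selection = 1L, label = "toy chain"))
  }
  if (n_waters < 1L) stop("n_waters must be >= 1", call. = FALSE)
  pos <- with_seed(seed, {
    r <- stats::runif(n_waters, radial_range[1L], radial_range[2L])
    u <- matrix(stats::rnorm(3L * n_waters), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    u * r
  })
  atoms <- rbind(data.frame(element = "C", x = 0, y = 0, z = 0),
                 data.frame(element = "O", x = pos[, 1L], y = pos[, 2L],
                            z = pos[, 3L]))
  shell_model(atoms, solute_selection = 1L, label = "toy cloud")
}
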