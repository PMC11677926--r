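# shared fixture builders; all randomness is seeded at the call site

tiny_spectrum <- function(values = c(0.1, 0.2, 0.3),
                          grid = c(2400, 2500, 2600),
                          unit = "absorbance") {
  hdo_spectrum(grid, values, unit = unit)
}

gaussian_band <- function(center, sigma, grid, amplitude = 1,
                          unit = "molar_absorption") {
  hdo_spectrum(grid, amplitude * exp(-(grid - center)^2 / (2 * sigma^2)),
               unit = unit)
}

# independent double-loop distance oracle
brute_force_oo <- function(xyz, r_range = c(2.55, 3.00)) {
  n <- nrow(xyz)
  out <- numeric(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d >= r_range[1L] && d <= r_range[2L]) out <- c(out, d)
  }
  sort(out)
}

# dense independent transform of a band onto the distance axis; oracle for
# distance_distribution (rectangle rule on a fine r grid)
brute_force_distribution <- function(s, r_lo, r_hi, n = 40001L) {
  r <- seq(r_lo, r_hi, length.out = n)
  nu <- 2727 - exp(16.01 - 3.73 * r)
  e <- approx(s$wavenumber, s$value, xout = nu, rule = 2)$y
  p <- pmax(e, 0) * 3.73 * exp(16.01 - 3.73 * r)
  dr <- r[2L] - r[1L]
  Z <- sum(p) * dr
  list(r = r, p = p / Z)
}

rigid_motion <- function(xyz, angles = c(0.3, -0.7, 1.1),
                         shift = c(5, -3, 2)) {
  rx <- function(a) matrix(c(1,0,0, 0,cos(a),-sin(a), 0,sin(a),cos(a)), 3, 3)
  ry <- function(a) matrix(c(cos(a),0,sin(a), 0,1,0, -sin(a),0,cos(a)), 3, 3)
  rz <- function(a) matrix(c(cos(a),-sin(a),0, sin(a),cos(a),0, 0,0,1), 3, 3)
  t(rx(angles[1]) %*% ry(angles[2]) %*% rz(angles[3]) %*% t(xyz)) +
    matrix(shift, nrow(xyz), 3, byrow = TRUE)
}
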