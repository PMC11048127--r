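#' One-port S-parameter sweep
#'
#' A tibble of class `s11_sweep` holding a uniform frequency grid (Hz)
#' and the complex reflection coefficient S11 at each point, with the
#' reference impedance kept as an attribute (default 50 ohm). Passivity
#' (`|S11| <= 1`) is enforced at construction.
#'
#' @param frequencies_hz Strictly increasing, uniform frequency grid (Hz).
#' @param s11 Complex S11 values, one per frequency.
#' @param z0 Reference impedance (ohm).
#' @return A tibble with columns `frequency_hz`, `s11`.
#' @examples
#' sw <- s11_sweep(seq(1e9, 2e9, by = 1e6), rep(complex(real = 0.9), 1001))
#' attr(sw, "z0")
#' @export
s11_sweep <- function(frequencies_hz, s11, z0 = 50) {
  if (length(frequencies_hz) < 2L) abort("a sweep needs at least 2 points.")
  if (length(s11) != length(frequencies_hz)) {
    abort("`s11` and `frequencies_hz` must have equal length.")
  }
  steps <- diff(frequencies_hz)
  if (any(steps <= 0)) abort("frequency grid must be strictly increasing.")
  if (max(steps) - min(steps) > 1e-6 * mean(steps)) {
    abort("frequency grid must be uniform.")
  }
  if (any(Mod(s11) > 1 + 1e-9)) {
    abort("passivity violated: |S11| must be <= 1 everywhere.")
  }
  out <- tibble(frequency_hz = as.numeric(frequencies_hz),
                s11 = as.complex(s11))
  attr(out, "z0") <- z0
  class(out) <- c("s11_sweep", class(out))
  out
}

#' Default VNA frequency grid
#'
#' The measurement grid used throughout: 0.0001 GHz to 3.0001 GHz in
#' steps of 0.0003 GHz, i.e. 10001 points.
#'
#' @return Numeric vector of frequencies in Hz.
#' @examples
#' length(vna_grid()) # 10001
#' @export
vna_grid <- function() {
  1e5 + (0:10000) * 3e5
}

#' Synthesise a one-port resonator reflection sweep
#'
#' Renders the S11 dip of a resonator seen through a single coupled
#' port, using the standard one-pole reflection model
#' `S11(f) = (G + 2i q d) / (1 + 2i q d)` with fractional detuning
#' `d = (f - f0) / f0` and on-resonance reflection
#' `G = (1 - g) / (1 + g)` set by the coupling factor `g`. Critical
#' coupling (`g = 1`) gives a perfect null at `f0`; `|S11| -> 1` far
#' from resonance; the grid minimum of `|S11|` falls on the grid point
#' nearest `f0`.
#'
#' @param grid Frequency grid (Hz), uniform and increasing.
#' @param f0 Resonant frequency (Hz); must lie inside the grid span.
#' @param q_loaded Loaded quality factor, > 0.
#' @param coupling Coupling factor `g > 0`; 1 is critical coupling.
#' @param z0 Reference impedance (ohm).
#' @return An [s11_sweep()].
#' @examples
#' sw <- synth_s11(vna_grid(), 1.28e9, q_loaded = 80, coupling = 0.9)
#' @export
synth_s11 <- function(grid, f0, q_loaded, coupling = 0.9, z0 = 50) {
  check_scalar(f0, "f0", positive = TRUE)
  check_scalar(q_loaded, "q_loaded", positive = TRUE)
  check_scalar(coupling, "coupling", positive = TRUE)
  if (f0 < min(grid) || f0 > max(grid)) {
    abort("`f0` must lie within the grid span.")
  }
  gam0 <- (1 - coupling) / (1 + coupling)
  detune <- (grid - f0) / f0
  s11 <- complex(real = gam0, imaginary = 2 * q_loaded * detune) /
    complex(real = 1, imaginary = 2 * q_loaded * detune)
  s11_sweep(grid, s11, z0 = z0)
}

#' Locate the resonance in an S11 sweep
#'
#' Finds the interior dip of `|S11|`, refines the resonant frequency by
#' parabolic interpolation of the log-magnitude through the three points
#' around the grid minimum (ties between equal adjacent minima break
#' toward lower frequency), and estimates the loaded Q from the
#' half-reflected-power bandwidth: the band edges are where `|S11|^2`
#' rises to halfway between its minimum and 1, which for the one-pole
#' model of [synth_s11()] occurs at `f0 * (1 +/- 1 / (2 Q))`.
#'
#' @param sweep An [s11_sweep()] or a data frame with columns
#'   `frequency_hz` and `s11`.
#' @return A one-row tibble: `f0_hz`, `q_loaded`, `depth_db` (the
#'   minimum of `|S11|` in dB, <= 0). `q_loaded` is `NA` when a 3 dB
#'   band edge falls outside the sweep.
#' @examples
#' extract_resonance(synth_s11(vna_grid(), 1.28e9, 80))
#' @export
extract_resonance <- function(sweep) {
  f <- sweep$frequency_hz
  mag <- Mod(sweep$s11)
  n <- length(f)
  i <- which.min(mag) # first minimum -> lower-frequency tie-break
  interior_dip <- i > 1L && i < n &&
    (mag[i] < mag[1L] - 1e-12 || mag[i] < mag[n] - 1e-12)
  if (!interior_dip) {
    abort("no resonance found: |S11| has no interior dip.")
  }
  db <- 20 * log10(pmax(mag, 1e-15))
  # parabolic vertex through (i-1, i, i+1) on the dB curve
  denom <- db[i - 1L] - 2 * db[i] + db[i + 1L]
  offset <- if (abs(denom) < 1e-12) 0 else {
    0.5 * (db[i - 1L] - db[i + 1L]) / denom
  }
  offset <- max(-0.5, min(0.5, offset))
  step <- f[2L] - f[1L]
  f0 <- f[i] + offset * step
  # half-reflected-power band edges: |S11|^2 = (1 + min^2) / 2
  p <- mag^2
  thr <- (1 + p[i]) / 2
  q_loaded <- NA_real_
  left <- which(p[seq_len(i)] >= thr)
  right_rel <- which(p[i:n] >= thr)
  if (length(left) > 0 && length(right_rel) > 0) {
    l <- max(left) # last point at/above thr left of dip
    r <- i + min(right_rel) - 1L
    f_lo <- f[l] + (thr - p[l]) / (p[l + 1L] - p[l]) * step
    f_hi <- f[r - 1L] + (thr - p[r - 1L]) / (p[r] - p[r - 1L]) * step
    if (f_hi > f_lo) q_loaded <- f0 / (f_hi - f_lo)
  }
  tibble(f0_hz = f0, q_loaded = q_loaded, depth_db = min(db))
}

#' Plot an S11 sweep
#'
#' @param object An [s11_sweep()].
#' @param ... Unused.
#' @return A ggplot of `|S11|` in dB against frequency in GHz.
#' @method autoplot s11_sweep
#' @export
autoplot.s11_sweep <- function(object, ...) {
  df <- tibble(
    frequency_ghz = hz_to_ghz(object$frequency_hz),
    s11_db = 20 * log10(pmax(Mod(object$s11), 1e-15))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency_ghz, .data$s11_db)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (GHz)", y = "|S11| (dB)")
}
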