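# Radial-frequency (RF) pattern geometry: radius profiles in polar
# coordinates, factorial stimulus designs, contour sampling and validation.

#' Specify a radial-frequency (RF) pattern
#'
#' An RF pattern is a closed contour obtained by modulating the radius of a
#' base circle sinusoidally as a function of polar angle. Spikiness adds
#' triangular-wave harmonics on top of the fundamental sinusoid, sharpening
#' each lobe toward a spike while the modulation depth stays fixed (the
#' modulator is rescaled to unit peak, see [triangular_modulator()]).
#'
#' @param frequency integer >= 1; modulation cycles per revolution (the
#'   number of lobes).
#' @param amplitude modulation depth in `[0, 1]`; the maximum fractional
#'   radial deviation from the base circle.
#' @param r_mean base-circle radius (> 0, arbitrary length units).
#' @param phase phase of the modulation, radians.
#' @param spikiness integer >= 0; number of triangular-wave harmonics added
#'   above the fundamental.
#' @return An object of class `"rf_spec"`.
#' @examples
#' spec <- rf_spec(frequency = 5, amplitude = 0.3)
#' range(radius_profile(spec, seq(0, 2 * pi, length.out = 1000)))
#' @export
rf_spec <- function(frequency, amplitude, r_mean = 1, phase = 0,
                    spikiness = 0) {
  if (length(frequency) != 1L || frequency < 1 || frequency != round(frequency))
    stop("`frequency` must be a single integer >= 1", call. = FALSE)
  if (length(amplitude) != 1L || amplitude < 0 || amplitude > 1)
    stop("`amplitude` must lie in [0, 1]", call. = FALSE)
  if (length(r_mean) != 1L || r_mean <= 0)
    stop("`r_mean` must be > 0", call. = FALSE)
  if (length(spikiness) != 1L || spikiness < 0 ||
      spikiness != round(spikiness))
    stop("`spikiness` must be a single integer >= 0", call. = FALSE)
  structure(
    list(r_mean = r_mean, amplitude = amplitude,
         frequency = as.integer(frequency), phase = phase,
         spikiness = as.integer(spikiness)),
    class = "rf_spec"
  )
}

#' @export
print.rf_spec <- function(x, ...) {
  cat(sprintf("RF pattern: frequency %d, amplitude %g, spikiness %d, phase %g, r_mean %g\n",
              x$frequency, x$amplitude, x$spikiness, x$phase, x$r_mean))
  invisible(x)
}

#' Triangular-wave modulator of an RF pattern
#'
#' Evaluates the angular modulation waveform: the fundamental sinusoid
#' `sin(frequency * theta + phase)` plus `spikiness` higher harmonics of the
#' Fourier series of a triangle wave (odd harmonics `n = 3, 5, ...`, amplitudes
#' proportional to `1/n^2` with alternating sign). With `normalize = TRUE`
#' (the default) the truncated series is rescaled to unit peak, so that the
#' amplitude factor of an RF pattern always equals the maximum fractional
#' radial deviation regardless of spikiness. The truncated series attains its
#' maximum where every term peaks simultaneously, so the peak equals
#' `sum(1/(2j+1)^2, j = 0..spikiness)` exactly.
#'
#' @param theta polar angle(s), radians.
#' @inheritParams rf_spec
#' @param normalize rescale the waveform to unit peak (default `TRUE`).
#' @return Numeric vector of modulation values, same length as `theta`;
#'   in `[-1, 1]` when normalized.
#' @examples
#' triangular_modulator(pi / 8, frequency = 4)        # fundamental peak: 1
#' triangular_modulator(0.1, frequency = 4, spikiness = 30)
#' @export
triangular_modulator <- function(theta, frequency, phase = 0, spikiness = 0,
                                 normalize = TRUE) {
  if (length(frequency) != 1L || frequency < 1 || frequency != round(frequency))
    stop("`frequency` must be a single integer >= 1", call. = FALSE)
  if (length(spikiness) != 1L || spikiness < 0 ||
      spikiness != round(spikiness))
    stop("`spikiness` must be a single integer >= 0", call. = FALSE)
  harm <- 2 * (0:spikiness) + 1               # odd harmonics 1, 3, 5, ...
  w <- (-1)^(0:spikiness) / harm^2            # triangle-wave Fourier weights
  x <- frequency * theta + phase
  val <- drop(sin(outer(x, harm)) %*% w)
  if (normalize) val <- val / sum(1 / harm^2)
  val
}

#' Radius profile of an RF pattern
#'
#' The radius as a function of polar angle:
#' `r(theta) = r_mean * (1 + amplitude * m(theta))` where `m` is the
#' unit-peak [triangular_modulator()]. The profile is bounded between
#' `r_mean * (1 - amplitude)` and `r_mean * (1 + amplitude)` and reduces to a
#' circle of radius `r_mean` at zero amplitude.
#'
#' @param spec an [rf_spec()] or [composite_spec()].
#' @param theta polar angle(s), radians.
#' @param ... passed on to methods.
#' @return Numeric vector of radii, same length as `theta`.
#' @export
radius_profile <- function(spec, theta, ...) UseMethod("radius_profile")

#' @rdname radius_profile
#' @export
radius_profile.rf_spec <- function(spec, theta, ...) {
  m <- triangular_modulator(theta, spec$frequency, spec$phase, spec$spikiness)
  spec$r_mean * (1 + spec$amplitude * m)
}

#' Specify a composite RF pattern
#'
#' A composite pattern superimposes several pure sinusoidal radius modulations
#' on one base circle:
#' `r(theta) = r_mean * (1 + sum_i A_i * sin(w_i * theta + phi_i))`.
#' Summed amplitudes must keep the radius strictly positive.
#'
#' @param frequency integer vector of component frequencies.
#' @param amplitude numeric vector of component amplitudes.
#' @param phase numeric vector of component phases, radians.
#' @param r_mean base-circle radius (> 0).
#' @return An object of class `"composite_spec"`.
#' @seealso [composite_preset()] for the rounded and angular five-component
#'   presets.
#' @export
composite_spec <- function(frequency, amplitude, phase, r_mean = 1) {
  k <- length(frequency)
  if (k < 1) stop("at least one component is required", call. = FALSE)
  if (length(amplitude) != k || length(phase) != k)
    stop("`frequency`, `amplitude` and `phase` must have equal length",
         call. = FALSE)
  if (any(frequency < 1) || any(frequency != round(frequency)))
    stop("component frequencies must be integers >= 1", call. = FALSE)
  if (any(amplitude < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (length(r_mean) != 1L || r_mean <= 0)
    stop("`r_mean` must be > 0", call. = FALSE)
  spec <- structure(
    list(r_mean = r_mean, frequency = as.integer(frequency),
         amplitude = amplitude, phase = phase),
    class = "composite_spec"
  )
  th <- seq(0, 2 * pi, length.out = 4096L)
  if (any(radius_profile(spec, th) <= 0))
    stop("summed modulation drives the radius non-positive", call. = FALSE)
  spec
}

#' @rdname radius_profile
#' @export
radius_profile.composite_spec <- function(spec, theta, ...) {
  dev <- rep(0, length(theta))
  for (i in seq_along(spec$frequency)) {
    dev <- dev + spec$amplitude[i] *
      sin(spec$frequency[i] * theta + spec$phase[i])
  }
  spec$r_mean * (1 + dev)
}

#' Radius profile of a composite RF pattern
#'
#' Convenience wrapper around [radius_profile()] for composite specs.
#'
#' @inheritParams radius_profile
#' @export
composite_radius <- function(spec, theta) {
  if (!inherits(spec, "composite_spec"))
    stop("`spec` must be a composite_spec", call. = FALSE)
  radius_profile(spec, theta)
}

#' Rounded and angular composite presets
#'
#' Two five-component composites built from frequencies 7, 14, 21, 28 and 35
#' with amplitudes 0.4, 0.2, 0.1, 0.05 and 0.025. In the `"angular"` preset
#' the peaks of all five components are aligned at `theta = 0`; in the
#' `"rounded"` preset the troughs of the 2nd and 4th components are aligned
#' with the peaks of the others, smoothing each lobe. These mimic the classic
#' rounded/angular outline pair used in Bouba/Kiki demonstrations.
#'
#' @param name `"angular"` or `"rounded"`.
#' @param r_mean base-circle radius.
#' @return A [composite_spec()].
#' @examples
#' radius_profile(composite_preset("angular"), 0)  # 1.775
#' radius_profile(composite_preset("rounded"), 0)  # 1.275
#' @export
composite_preset <- function(name = c("angular", "rounded"), r_mean = 1) {
  name <- match.arg(name)
  freq <- c(7L, 14L, 21L, 28L, 35L)
  amp <- c(0.4, 0.2, 0.1, 0.05, 0.025)
  # sin(w * 0 + pi/2) = 1: peak at theta = 0; -pi/2 puts a trough there
  phase <- if (name == "angular") rep(pi / 2, 5) else
    c(pi / 2, -pi / 2, pi / 2, -pi / 2, pi / 2)
  composite_spec(freq, amp, phase, r_mean = r_mean)
}

#' Sample an RF contour as a closed polyline
#'
#' Samples the radius profile on a uniform grid of `n_points` angles over the
#' half-open interval `[0, 2 * pi)` and converts to Cartesian coordinates
#' (mathematical convention, y up). The polyline is closed by duplicating the
#' first vertex, so `vertices` has `n_points + 1` rows.
#'
#' @param spec an [rf_spec()] or [composite_spec()].
#' @param n_points number of distinct sample angles (>= 16; default 4096).
#' @return An object of class `"rf_contour"`: a list with `vertices`
#'   (two-column matrix), `theta`, `radius` (length `n_points`, no duplicate)
#'   and `closed`.
#' @export
sample_contour <- function(spec, n_points = 4096L) {
  if (length(n_points) != 1L || n_points < 16)
    stop("`n_points` must be >= 16", call. = FALSE)
  n_points <- as.integer(n_points)
  theta <- seq(0, 2 * pi, length.out = n_points + 1L)[seq_len(n_points)]
  r <- radius_profile(spec, theta)
  v <- cbind(x = r * cos(theta), y = r * sin(theta))
  v <- rbind(v, v[1L, , drop = FALSE])
  structure(list(vertices = v, theta = theta, radius = r, closed = TRUE,
                 n_points = n_points),
            class = "rf_contour")
}

#' Count the lobes of a sampled contour
#'
#' A lobe is a strict local maximum of the radius-versus-angle sequence, with
#' circular wraparound and consecutive equal values collapsed to a single
#' plateau. A circle has no strict maxima and returns 0; an RF pattern of
#' frequency `w` returns `w`.
#'
#' @param contour an `"rf_contour"` from [sample_contour()].
#' @return Integer lobe count.
#' @export
count_lobes <- function(contour) {
  if (!inherits(contour, "rf_contour"))
    stop("`contour` must be an rf_contour", call. = FALSE)
  r <- contour$radius
  if (any(r <= 0))
    stop("contour does not enclose the origin", call. = FALSE)
  # winding number about the origin must be one full turn
  dth <- diff(c(contour$theta, contour$theta[1L] + 2 * pi))
  if (abs(sum(dth) - 2 * pi) > 1e-6)
    stop("contour does not enclose the origin", call. = FALSE)
  m <- length(r)
  same_next <- r == r[c(2:m, 1L)]
  if (all(same_next)) return(0L)   # constant radius: a circle
  rr <- r[!same_next]              # collapse plateaus (circular-safe)
  k <- length(rr)
  prv <- rr[c(k, seq_len(k - 1L))]
  nxt <- rr[c(2:k, 1L)]
  sum(rr > prv & rr > nxt)
}

#' Factorial stimulus design
#'
#' The crossing of frequency, amplitude and spikiness levels presented to each
#' respondent. The default levels (frequencies 4-9, amplitudes 0.1-0.4,
#' spikiness 0/1/30) give the 72-condition design.
#'
#' @param frequency ordered integer levels.
#' @param amplitude ordered amplitude levels.
#' @param spikiness ordered spikiness levels.
#' @param include_controls also include the two composite control shapes
#'   (`"rounded"`, `"angular"`) when rendering the design.
#' @return An object of class `"stimulus_design"`.
#' @examples
#' nrow(design_grid(stimulus_design()))  # 72
#' @export
stimulus_design <- function(frequency = 4:9,
                            amplitude = c(0.1, 0.2, 0.3, 0.4),
                            spikiness = c(0, 1, 30),
                            include_controls = FALSE) {
  if (anyDuplicated(frequency) || anyDuplicated(amplitude) ||
      anyDuplicated(spikiness))
    stop("design levels must be distinct", call. = FALSE)
  structure(
    list(frequency = as.integer(frequency), amplitude = amplitude,
         spikiness = as.integer(spikiness),
         include_controls = isTRUE(include_controls)),
    class = "stimulus_design"
  )
}

#' Enumerate the conditions of a stimulus design
#'
#' @param design a [stimulus_design()].
#' @return A data frame with one row per condition and columns `frequency`,
#'   `amplitude`, `spikiness`.
#' @export
design_grid <- function(design = stimulus_design()) {
  g <- expand.grid(frequency = design$frequency,
                   amplitude = design$amplitude,
                   spikiness = design$spikiness,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$frequency, g$amplitude, g$spikiness), , drop = FALSE]
  rownames(g) <- NULL
  g
}
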