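# Spectrum data model and rendering: ppm grids, dense 1D/2D spectra,
# instance-wise min-max normalization, Gaussian peak-list rendering and
# HSQC image reconstruction from cross-peak lists.

#' Construct a ppm grid
#'
#' An evenly spaced chemical-shift grid. The grid is stored in ascending ppm;
#' the NMR display convention (high ppm on the left) is a plotting concern
#' only. Grid value at index `j` (1-based) is
#' `start_ppm + (j-1) * (end_ppm - start_ppm) / (n_points - 1)`.
#'
#' @param start_ppm,end_ppm grid endpoints in ppm (inclusive).
#' @param n_points number of grid points (>= 2).
#' @return an object of class `ppm_grid`.
#' @export
ppm_grid <- function(start_ppm, end_ppm, n_points) {
  stopifnot(is.numeric(start_ppm), is.numeric(end_ppm),
            n_points >= 2, start_ppm != end_ppm)
  structure(list(start_ppm = as.numeric(start_ppm),
                 end_ppm = as.numeric(end_ppm),
                 n_points = as.integer(n_points)),
            class = "ppm_grid")
}

#' Grid point values of a ppm grid
#' @param grid a [ppm_grid()].
#' @return numeric vector of length `n_points`.
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "ppm_grid"))
  seq(grid$start_ppm, grid$end_ppm, length.out = grid$n_points)
}

# Default grids: chosen to cover common organic shift ranges at the dense-1D
# length convention (10 000 points); HSQC rendered at 256 x 256.
#' Default chemical-shift grids per modality
#' @param modality one of `"H1"`, `"C13"`, `"HSQC_H"`, `"HSQC_C"`.
#' @return a [ppm_grid()].
#' @export
default_grid <- function(modality = c("H1", "C13", "HSQC_H", "HSQC_C")) {
  switch(match.arg(modality),
    H1     = ppm_grid(-2, 12, 10000L),
    C13    = ppm_grid(-10, 230, 10000L),
    HSQC_H = ppm_grid(0, 12, 256L),
    HSQC_C = ppm_grid(0, 200, 256L))
}

#' Construct a 1D NMR spectrum
#'
#' @param nucleus `"H1"` or `"C13"`.
#' @param grid a [ppm_grid()].
#' @param intensities numeric vector, length `grid$n_points`, all finite.
#' @param normalized logical; whether intensities are already min-max scaled.
#' @return an object of class `spectrum_1d`.
#' @export
spectrum_1d <- function(nucleus = c("H1", "C13"), grid, intensities,
                        normalized = FALSE) {
  nucleus <- match.arg(nucleus)
  stopifnot(inherits(grid, "ppm_grid"),
            length(intensities) == grid$n_points,
            all(is.finite(intensities)))
  if (normalized) stopifnot(min(intensities) >= 0, max(intensities) <= 1 + 1e-12)
  structure(list(nucleus = nucleus, grid = grid,
                 intensities = as.numeric(intensities),
                 normalized = isTRUE(normalized)),
            class = "spectrum_1d")
}

#' Construct a 2D HSQC spectrum
#'
#' @param h_grid,c_grid [ppm_grid()]s for the 1H and 13C axes.
#' @param intensities numeric matrix `h_grid$n_points x c_grid$n_points`.
#' @param normalized logical.
#' @return an object of class `spectrum_hsqc`.
#' @export
spectrum_hsqc <- function(h_grid, c_grid, intensities, normalized = FALSE) {
  stopifnot(inherits(h_grid, "ppm_grid"), inherits(c_grid, "ppm_grid"),
            is.matrix(intensities),
            nrow(intensities) == h_grid$n_points,
            ncol(intensities) == c_grid$n_points,
            all(is.finite(intensities)))
  if (normalized) stopifnot(min(intensities) >= 0, max(intensities) <= 1 + 1e-12)
  structure(list(h_grid = h_grid, c_grid = c_grid,
                 intensities = intensities, normalized = isTRUE(normalized)),
            class = "spectrum_hsqc")
}

#' Construct a 1D peak list
#' @param nucleus `"H1"` or `"C13"`.
#' @param shift_ppm numeric vector of peak positions.
#' @param intensity non-negative numeric vector, same length.
#' @return an object of class `peaklist_1d`.
#' @export
peaklist_1d <- function(nucleus = c("H1", "C13"), shift_ppm = numeric(0),
                        intensity = numeric(0)) {
  nucleus <- match.arg(nucleus)
  stopifnot(length(shift_ppm) == length(intensity),
            all(is.finite(shift_ppm)), all(is.finite(intensity)),
            all(intensity >= 0))
  structure(list(nucleus = nucleus,
                 shift_ppm = as.numeric(shift_ppm),
                 intensity = as.numeric(intensity)),
            class = "peaklist_1d")
}

#' Construct an HSQC cross-peak list
#' @param h_ppm,c_ppm numeric vectors of cross-peak coordinates.
#' @param intensity non-negative numeric vector, same length.
#' @return an object of class `peaklist_hsqc`.
#' @export
peaklist_hsqc <- function(h_ppm = numeric(0), c_ppm = numeric(0),
                          intensity = numeric(0)) {
  stopifnot(length(h_ppm) == length(c_ppm),
            length(h_ppm) == length(intensity),
            all(is.finite(c(h_ppm, c_ppm, intensity))),
            all(intensity >= 0))
  structure(list(h_ppm = as.numeric(h_ppm), c_ppm = as.numeric(c_ppm),
                 intensity = as.numeric(intensity)),
            class = "peaklist_hsqc")
}

#' Instance-wise min-max normalization
#'
#' Rescales a spectrum independently of any other so that intensities lie in
#' `[0, 1]`: `(x - min) / (max - min)`. Removes dataset-specific scale factors
#' and baseline offsets. Idempotent on non-constant input. A constant
#' spectrum maps to all zeros with a warning (so batch pipelines survive
#' blank inputs).
#'
#' @param spectrum a [spectrum_1d()] or [spectrum_hsqc()].
#' @return spectrum of the same class with `normalized = TRUE`.
#' @export
normalize_instance <- function(spectrum) {
  UseMethod("normalize_instance")
}

.minmax <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) {
    warning("constant spectrum: normalizing to all zeros")
    return(x * 0)
  }
  (x - lo) / (hi - lo)
}

#' @export
normalize_instance.spectrum_1d <- function(spectrum) {
  spectrum$intensities <- .minmax(spectrum$intensities)
  spectrum$normalized <- TRUE
  spectrum
}

#' @export
normalize_instance.spectrum_hsqc <- function(spectrum) {
  spectrum$intensities <- .minmax(spectrum$intensities)
  spectrum$normalized <- TRUE
  spectrum
}

# Add Gaussian components at `shifts` with areas `weights` to a running
# intensity vector on `pts`. Support truncated at 8*sigma: the neglected tail
# mass is ~1e-14 of a peak, far below any tolerance used in this package.
.deposit_gaussians <- function(pts, shifts, weights, sigma, exact = FALSE) {
  y <- numeric(length(pts))
  for (k in seq_along(shifts)) {
    if (exact) {
      idx <- seq_along(pts)
    } else {
      idx <- which(pts >= shifts[k] - 8 * sigma & pts <= shifts[k] + 8 * sigma)
      if (!length(idx)) next
    }
    y[idx] <- y[idx] + weights[k] * exp(-(pts[idx] - shifts[k])^2 / (2 * sigma^2))
  }
  y
}

#' Render a 1D peak list to a dense spectrum
#'
#' Each peak contributes a Gaussian line of width `line_sigma` centred at its
#' shift, scaled by its intensity; the sum is then instance-normalized to
#' `[0, 1]`. An empty peak list yields an all-zero unnormalized spectrum with
#' a warning.
#'
#' @param peaks a [peaklist_1d()].
#' @param grid target [ppm_grid()] (default: the nucleus default grid).
#' @param line_sigma Gaussian line width in ppm (> 0).
#' @param exact evaluate Gaussians on the full grid instead of the truncated
#'   (8 sigma) support.
#' @return a normalized [spectrum_1d()].
#' @export
render_peaklist_1d <- function(peaks, grid = default_grid(peaks$nucleus),
                               line_sigma = if (peaks$nucleus == "H1") 0.01 else 0.1,
                               exact = FALSE) {
  stopifnot(inherits(peaks, "peaklist_1d"), line_sigma > 0)
  if (!length(peaks$shift_ppm)) {
    warning("empty peak list: returning all-zero spectrum")
    return(spectrum_1d(peaks$nucleus, grid, numeric(grid$n_points),
                       normalized = FALSE))
  }
  y <- .deposit_gaussians(grid_points(grid), peaks$shift_ppm, peaks$intensity,
                          line_sigma, exact = exact)
  normalize_instance(spectrum_1d(peaks$nucleus, grid, y, normalized = FALSE))
}

#' Reconstruct an HSQC intensity image from a cross-peak list
#'
#' Each cross-peak is deposited at its nearest 13C grid column and broadened
#' by a 1D Gaussian of width `h_sigma` along the 1H axis only. Negative raw
#' intensities (phase artifacts) are clipped to zero, a power-law rescale
#' `x^power` compresses the dynamic range BEFORE normalization, and the image
#' is instance-normalized to `[0, 1]`. Peaks outside both grid ranges are
#' dropped with a warning.
#'
#' @param peaks a [peaklist_hsqc()].
#' @param h_grid,c_grid target [ppm_grid()]s (defaults: 256-point HSQC grids).
#' @param h_sigma 1H Gaussian broadening in ppm (> 0).
#' @param power dynamic-range compression exponent (> 0); 0.3 by default.
#' @param exact full-support Gaussian evaluation (see [render_peaklist_1d()]).
#' @return a normalized [spectrum_hsqc()].
#' @export
reconstruct_hsqc <- function(peaks, h_grid = default_grid("HSQC_H"),
                             c_grid = default_grid("HSQC_C"),
                             h_sigma = 0.05, power = 0.3, exact = FALSE) {
  stopifnot(inherits(peaks, "peaklist_hsqc"), h_sigma > 0, power > 0)
  img <- matrix(0, h_grid$n_points, c_grid$n_points)
  if (!length(peaks$h_ppm)) {
    warning("empty HSQC peak list: returning zero matrix")
    return(spectrum_hsqc(h_grid, c_grid, img, normalized = FALSE))
  }
  hp <- grid_points(h_grid); cp <- grid_points(c_grid)
  h_rng <- range(hp); c_rng <- range(cp)
  dropped <- 0L
  for (k in seq_along(peaks$h_ppm)) {
    h <- peaks$h_ppm[k]; cc <- peaks$c_ppm[k]
    w <- max(peaks$intensity[k], 0)
    if (h < h_rng[1] || h > h_rng[2] || cc < c_rng[1] || cc > c_rng[2]) {
      dropped <- dropped + 1L
      next
    }
    jc <- which.min(abs(cp - cc))
    img[, jc] <- img[, jc] + .deposit_gaussians(hp, h, w, h_sigma, exact = exact)
  }
  if (dropped > 0L)
    warning(sprintf("%d HSQC peak(s) outside grid ranges dropped", dropped))
  img <- img^power
  normalize_instance(spectrum_hsqc(h_grid, c_grid, img, normalized = FALSE))
}

#' Zero out fixed chemical-shift windows (reference/solvent removal)
#'
#' Sets the intensity inside the given ppm windows to zero, emulating the
#' removal of reference and solvent peaks at fixed positions. Default windows
#' are this package's defaults for CDCl3/TMS conditions (1H: TMS around 0 and
#' residual CHCl3 7.24-7.28 ppm; 13C: CDCl3 triplet 76.5-77.5 ppm).
#'
#' @param spectrum a [spectrum_1d()].
#' @param windows list of `c(lo, hi)` ppm pairs; `NULL` selects the nucleus
#'   default.
#' @return the spectrum with windows zeroed (normalization flag untouched).
#' @export
zero_shift_windows <- function(spectrum, windows = NULL) {
  stopifnot(inherits(spectrum, "spectrum_1d"))
  if (is.null(windows)) {
    windows <- if (spectrum$nucleus == "H1") {
      list(c(-0.05, 0.05), c(7.24, 7.28))
    } else {
      list(c(76.5, 77.5))
    }
  }
  pts <- grid_points(spectrum$grid)
  for (w in windows) {
    stopifnot(length(w) == 2)
    spectrum$intensities[pts >= min(w) & pts <= max(w)] <- 0
  }
  spectrum
}

#' @export
print.ppm_grid <- function(x, ...) {
  cat(sprintf("<ppm_grid %g..%g ppm, %d points>\n",
              x$start_ppm, x$end_ppm, x$n_points))
  invisible(x)
}

#' @export
print.spectrum_1d <- function(x, ...) {
  cat(sprintf("<spectrum_1d %s, %d points, %g..%g ppm, %s>\n",
              x$nucleus, x$grid$n_points, x$grid$start_ppm, x$grid$end_ppm,
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' @export
print.spectrum_hsqc <- function(x, ...) {
  cat(sprintf("<spectrum_hsqc %d x %d, %s>\n",
              x$h_grid$n_points, x$c_grid$n_points,
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}
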