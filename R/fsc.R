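# Unmasked Fourier Shell Correlation and threshold-resolution estimation.

#' Fourier Shell Correlation between two volumes
#'
#' Computes the unmasked FSC: for each spherical shell of spatial frequency,
#' `FSC(s) = Re(sum F_A * conj(F_B)) / sqrt(sum |F_A|^2 * sum |F_B|^2)` with
#' the sums over all Fourier voxels in the shell. No mask is applied. Shells
#' are one reciprocal-grid step wide (`1/(N * voxel)` on a cubic grid; on
#' anisotropic boxes the finest reciprocal step across axes), binned by
#' rounding the physical frequency magnitude, and reported at the shell
#' center frequency up to Nyquist (`1/(2 * max voxel)`). The DC term is
#' excluded.
#'
#' @param map_a,map_b [voxel_grid()]s with identical shape and voxel size.
#' @return An `fsc_curve`: data frame with columns `shell_freq` (1/Å,
#'   strictly increasing), `correlation`, `n_voxels`, and a `voxel_size`
#'   attribute used for the Nyquist convention.
#' @export
fsc_curve <- function(map_a, map_b) {
  stopifnot(is.voxel_grid(map_a), is.voxel_grid(map_b))
  if (!identical(dim(map_a$data), dim(map_b$data)) ||
      any(abs(map_a$voxel_size - map_b$voxel_size) > 1e-6))
    stop("alignment error: maps must share shape and voxel size",
         call. = FALSE)
  if (all(map_a$data == 0) || all(map_b$data == 0))
    stop("undefined correlation: all-zero map", call. = FALSE)

  n <- dim(map_a$data)
  vox <- map_a$voxel_size
  fa <- stats::fft(map_a$data)
  fb <- stats::fft(map_b$data)

  # physical frequency along each axis (z, y, x), FFT ordering
  freq_axis <- function(na, va) {
    k <- 0:(na - 1)
    ifelse(k <= na %/% 2, k, k - na) / (na * va)
  }
  f2 <- lapply(1:3, function(a) freq_axis(n[a], vox[a])^2)
  s <- sqrt(outer(outer(f2[[1]], f2[[2]], "+"), f2[[3]], "+"))

  ds <- 1 / max(n * vox)                     # finest reciprocal step
  shell <- as.integer(round(s / ds))
  s_nyq <- 1 / (2 * max(vox))
  max_shell <- as.integer(floor(s_nyq / ds + 1e-9))
  keep <- shell >= 1L & shell <= max_shell

  idx <- shell[keep]
  num <- rowsum(Re(fa[keep] * Conj(fb[keep])), idx)
  da <- rowsum(abs(fa[keep])^2, idx)
  db <- rowsum(abs(fb[keep])^2, idx)
  nv <- rowsum(rep(1L, sum(keep)), idx)
  denom <- sqrt(da * db)
  ok <- denom > 0
  curve <- data.frame(
    shell_freq = as.integer(rownames(num))[ok] * ds,
    correlation = (num / denom)[ok],
    n_voxels = as.integer(nv)[ok]
  )
  curve <- curve[order(curve$shell_freq), , drop = FALSE]
  rownames(curve) <- NULL
  structure(curve, class = c("fsc_curve", "data.frame"),
            voxel_size = vox)
}

#' Resolution at an FSC threshold
#'
#' Finds the first frequency at which the FSC curve falls below the
#' threshold, by linear interpolation between adjacent shells, and reports
#' the corresponding resolution `1/s*` in Å. Conventions: if the very first
#' shell is already below the threshold, `s*` is the first shell's
#' frequency; if the curve never falls below the threshold, the estimate is
#' the Nyquist resolution (`2 * max voxel`) with `crossed = FALSE`.
#'
#' @param curve an `fsc_curve` from [fsc_curve()].
#' @param threshold correlation threshold; 0.143 is the standard map
#'   resolution criterion, 0.5 the more stringent map-model criterion.
#' @return A `resolution_estimate`: list with `threshold`, `resolution` (Å)
#'   and `crossed` (logical).
#' @export
resolution_at_threshold <- function(curve, threshold) {
  stopifnot(inherits(curve, "fsc_curve"), nrow(curve) > 0)
  f <- curve$shell_freq
  corr <- curve$correlation
  below <- which(corr < threshold)
  if (!length(below)) {
    vox <- attr(curve, "voxel_size")
    nyq_res <- if (!is.null(vox)) 2 * max(vox) else 1 / max(f)
    return(structure(list(threshold = threshold, resolution = nyq_res,
                          crossed = FALSE),
                     class = "resolution_estimate"))
  }
  i <- below[1L]
  s_star <- if (i == 1L) {
    f[1L]
  } else {
    f[i - 1L] + (corr[i - 1L] - threshold) / (corr[i - 1L] - corr[i]) *
      (f[i] - f[i - 1L])
  }
  structure(list(threshold = threshold, resolution = 1 / s_star,
                 crossed = TRUE),
            class = "resolution_estimate")
}

#' @export
print.resolution_estimate <- function(x, ...) {
  cat(sprintf("FSC %.3g resolution: %.3f Å%s\n", x$threshold, x$resolution,
              if (x$crossed) "" else " (threshold never crossed; Nyquist)"))
  invisible(x)
}

#' Map-model FSC
#'
#' Simulates an idealized density from the structure on the map's own grid
#' (see [simulate_on_map()]) and returns the unmasked FSC between the map
#' and that model map. Because the simulator uses a Gaussian kernel rather
#' than electron scattering factors, resolutions derived from this curve
#' agree with scattering-factor implementations only approximately.
#'
#' @param map a [voxel_grid()].
#' @param structure a `cryo_structure`.
#' @param params a [simulation_params()].
#' @return An `fsc_curve`.
#' @export
map_model_fsc <- function(map, structure, params) {
  simulated <- simulate_on_map(structure, map, params)
  fsc_curve(map, simulated)
}

#' Percent resolution improvement
#'
#' `100 * (before - after) / before`; positive when `after` is the better
#' (smaller) resolution.
#'
#' @param before,after resolutions in Å; `before` must be positive.
#' @return Percentage improvement.
#' @examples
#' percent_improvement(2.69, 1.95)   # ~27.5
#' @export
percent_improvement <- function(before, after) {
  if (any(!is.finite(before)) || any(before <= 0))
    stop("'before' must be positive", call. = FALSE)
  100 * (before - after) / before
}

#' Summarize a set of resolution estimates
#'
#' Box-plot style summary: mean, median, quartiles (type-7, linear
#' interpolation), IQR and the 1.5 x IQR whisker bounds.
#'
#' @param values numeric vector of resolutions (Å); must be non-empty.
#' @return List with `n`, `mean`, `median`, `q1`, `q3`, `iqr`,
#'   `whisker_low`, `whisker_high`.
#' @export
summarize_resolutions <- function(values) {
  values <- as.numeric(values)
  if (!length(values) || anyNA(values))
    stop("values must be a non-empty numeric vector without NA", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  list(n = length(values), mean = mean(values), median = q[2],
       q1 = q[1], q3 = q[3], iqr = iqr,
       whisker_low = q[1] - 1.5 * iqr, whisker_high = q[3] + 1.5 * iqr)
}
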