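#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities (shape 6 and 16, rate 1), giving a
#' response peaking near 5 s with an undershoot near 15 s and a
#' peak-to-undershoot ratio of 6. The kernel is scaled to unit integral so
#' that a sustained block regressor plateaus at 1 and block beta weights are
#' expressed in percent-signal-change units.
#'
#' @param t Numeric vector of times in seconds (non-negative).
#' @param peak_shape,undershoot_shape,rate Gamma parameters of the two lobes.
#' @param undershoot_ratio Peak-to-undershoot amplitude ratio.
#' @return Numeric vector, the HRF evaluated at `t`.
#' @export
#' @examples
#' h <- hrf_double_gamma(seq(0, 30, by = 0.1))
#' seq(0, 30, by = 0.1)[which.max(h)]  # ~5 s
hrf_double_gamma <- function(t, peak_shape = 6, undershoot_shape = 16,
                             rate = 1, undershoot_ratio = 6) {
  stopifnot(all(t >= 0))
  h <- stats::dgamma(t, shape = peak_shape, rate = rate) -
    stats::dgamma(t, shape = undershoot_shape, rate = rate) / undershoot_ratio
  h
}

#' HRF configuration
#'
#' @param peak_shape,undershoot_shape,rate,undershoot_ratio See
#'   [hrf_double_gamma()].
#' @param duration_s Kernel support length in seconds.
#' @param dt_s Temporal resolution used for convolution, in seconds.
#' @return A list of class `hrf_config`.
#' @export
hrf_config <- function(peak_shape = 6, undershoot_shape = 16, rate = 1,
                       undershoot_ratio = 6, duration_s = 32, dt_s = 0.1) {
  stopifnot(duration_s > 0, dt_s > 0)
  structure(list(peak_shape = peak_shape, undershoot_shape = undershoot_shape,
                 rate = rate, undershoot_ratio = undershoot_ratio,
                 duration_s = duration_s, dt_s = dt_s),
            class = "hrf_config")
}

# HRF kernel sampled on the fine grid, scaled to unit integral.
hrf_kernel <- function(hrf = hrf_config()) {
  tt <- seq(0, hrf$duration_s, by = hrf$dt_s)
  h <- hrf_double_gamma(tt, hrf$peak_shape, hrf$undershoot_shape,
                        hrf$rate, hrf$undershoot_ratio)
  h / (sum(h) * hrf$dt_s)
}

# Convolve a set of block onsets/durations with the HRF and sample at the
# volume acquisition times (0, TR, 2 TR, ...). Returns a length-n_volumes
# regressor. Shared by the simulator and the design-matrix builder so that a
# noise-free simulation is exactly reproduced by the GLM.
convolve_blocks <- function(onsets, durations, n_volumes, tr, hrf = hrf_config()) {
  dt <- hrf$dt_s
  total_s <- n_volumes * tr
  n_fine <- ceiling(total_s / dt) + 1L
  stim <- numeric(n_fine)
  for (i in seq_along(onsets)) {
    i0 <- floor(onsets[i] / dt) + 1L
    i1 <- min(n_fine, ceiling((onsets[i] + durations[i]) / dt))
    if (i1 >= i0) stim[i0:i1] <- 1
  }
  k <- hrf_kernel(hrf)
  conv <- stats::convolve(stim, rev(k), type = "open")[seq_len(n_fine)] * dt
  vol_idx <- round((0:(n_volumes - 1L)) * tr / dt) + 1L
  conv[vol_idx]
}

# Discrete cosine high-pass basis: columns k = 1..K with period 2*n*tr/k >=
# cutoff seconds. Returns an n x K matrix (possibly zero columns).
dct_highpass_basis <- function(n_volumes, tr, cutoff_s) {
  stopifnot(cutoff_s > 0)
  K <- floor(2 * n_volumes * tr / cutoff_s)
  if (K < 1L) return(matrix(numeric(0), nrow = n_volumes, ncol = 0))
  i <- seq_len(n_volumes)
  b <- vapply(seq_len(K), function(k) cos(pi * k * (i - 0.5) / n_volumes),
              numeric(n_volumes))
  colnames(b) <- paste0("cos", seq_len(K))
  b
}
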