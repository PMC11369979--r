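# Susceptibility-map-weighted imaging: channel combination, echo combination,
# paramagnetic masking of the QSM, and the final magnitude x mask product.

#' Combine receive channels
#'
#' Magnitude: voxelwise root sum of squares across channels. Phase: each
#' channel's constant phase offset relative to channel 1 is estimated as the
#' circular mean of the phase difference over a high-magnitude core region,
#' subtracted, and the offset-corrected phases averaged circularly with
#' magnitude weights. Output phase is wrapped to (-pi, pi].
#'
#' @param series an \code{echo_series} (see
#'   \code{\link{simulate_multiecho_gre}}).
#' @param core_quantile magnitude quantile defining the core region used for
#'   offset estimation (default 0.7).
#' @return list with \code{magnitude} and \code{phase}: lists of per-echo
#'   volumes.
#' @export
combine_channels <- function(series, core_quantile = 0.7) {
  nch <- length(series$magnitude)
  if (nch < 1) stop("at least one channel required")
  ne <- length(series$te_list)
  d0 <- dim(series$magnitude[[1]][[1]])
  for (ch in seq_len(nch)) for (e in seq_len(ne)) {
    if (!identical(dim(series$magnitude[[ch]][[e]]), d0) ||
        !identical(dim(series$phase[[ch]][[e]]), d0))
      stop("data error: channel/echo volume shape mismatch")
  }
  mag <- vector("list", ne)
  phs <- vector("list", ne)
  ref_mag <- Reduce(`+`, lapply(seq_len(nch), function(ch)
    Reduce(`+`, series$magnitude[[ch]])))
  core <- ref_mag > percentile_linear(ref_mag, core_quantile)

  offsets <- vapply(seq_len(nch), function(ch) {
    if (ch == 1) return(0)
    z <- 0 + 0i
    for (e in seq_len(ne)) {
      dphi <- series$phase[[ch]][[e]] - series$phase[[1]][[e]]
      z <- z + sum(exp(1i * dphi[core]))
    }
    Arg(z)
  }, 0)

  for (e in seq_len(ne)) {
    m2 <- Reduce(`+`, lapply(seq_len(nch), function(ch)
      series$magnitude[[ch]][[e]]^2))
    mag[[e]] <- sqrt(m2)
    z <- Reduce(`+`, lapply(seq_len(nch), function(ch)
      series$magnitude[[ch]][[e]] *
        exp(1i * (series$phase[[ch]][[e]] - offsets[ch]))))
    p <- Arg(z)
    # dead voxels (zero magnitude): fall back to offset-corrected mean phase
    dead <- Mod(z) == 0
    if (any(dead)) {
      pm <- Reduce(`+`, lapply(seq_len(nch), function(ch)
        series$phase[[ch]][[e]] - offsets[ch])) / nch
      p[dead] <- pm[dead]
    }
    phs[[e]] <- array(wrap_phase(p), d0)
  }
  list(magnitude = mag, phase = phs)
}

#' Combine echo magnitudes by root sum of squares
#'
#' @param magnitudes list of per-echo magnitude volumes.
#' @return volume, voxelwise RSS across echoes.
#' @export
combine_echo_magnitude <- function(magnitudes) {
  if (length(magnitudes) < 1) stop("at least one echo required")
  d0 <- dim(magnitudes[[1]])
  for (m in magnitudes) if (!identical(dim(m), d0)) stop("echo shape mismatch")
  sqrt(Reduce(`+`, lapply(magnitudes, function(m) m^2)))
}

#' Paramagnetic QSM weighting mask
#'
#' Linear ramp from 1 at \code{chi <= 0} to 0 at \code{chi >= chi_threshold},
#' raised to an integer power:
#' \code{w = clip((chi_threshold - chi) / chi_threshold, 0, 1)^power}.
#' Attenuates paramagnetic (iron-rich) voxels in the SMWI product.
#'
#' @param chi a \code{\link{susceptibility_map}} or plain ppb volume.
#' @param chi_threshold positive threshold in ppb (default 150).
#' @param power integer >= 1 (default 4).
#' @return weight volume in [0, 1].
#' @export
paramagnetic_mask <- function(chi, chi_threshold = 150, power = 4L) {
  if (chi_threshold <= 0) stop("parameter error: chi_threshold must be positive")
  if (power < 1) stop("parameter error: power must be >= 1")
  v <- if (inherits(chi, "susceptibility_map")) chi$values else chi
  pmin(pmax((chi_threshold - v) / chi_threshold, 0), 1)^power
}

#' Susceptibility-map-weighted image
#'
#' Voxelwise product of the combined magnitude and the paramagnetic weight.
#'
#' @param combined_magnitude echo-combined magnitude volume.
#' @param weight weight volume in [0, 1].
#' @param meta list recording the mask parameters.
#' @return object of class \code{smwi_volume}: list(values, meta).
#' @export
make_smwi <- function(combined_magnitude, weight, meta = list()) {
  if (!identical(dim(combined_magnitude), dim(weight)))
    stop("shape mismatch between magnitude and weight")
  if (any(weight < 0 | weight > 1)) stop("data error: weight outside [0, 1]")
  structure(list(values = combined_magnitude * weight, meta = meta),
            class = "smwi_volume")
}

#' Full SMWI reconstruction from a simulated acquisition
#'
#' The eight-step chain: channel combination (magnitude RSS, offset-corrected
#' circular phase mean), echo-magnitude RSS, Laplacian unwrapping + per-voxel
#' frequency, background removal, dipole inversion, paramagnetic threshold
#' mask, and the final product. Steps 4-6 reuse the QSM operations, so the
#' susceptibility map is identical to calling \code{\link{reconstruct_qsm}}
#' on the combined phase.
#'
#' @param series an \code{echo_series}.
#' @param mask logical brain mask; computed from the combined magnitude when
#'   NULL.
#' @param chi_threshold,power paramagnetic mask parameters.
#' @param delta,n_iter,smv_radius_mm QSM parameters.
#' @return list with \code{smwi} (\code{smwi_volume}), \code{qsm}
#'   (\code{susceptibility_map}), \code{combined_magnitude}, \code{mask}.
#' @export
reconstruct_smwi <- function(series, mask = NULL, chi_threshold = 150,
                             power = 4L, delta = 0.1, n_iter = 30L,
                             smv_radius_mm = 2) {
  comb <- combine_channels(series)
  cmag <- combine_echo_magnitude(comb$magnitude)
  if (is.null(mask)) mask <- compute_brain_mask(cmag, series$grid)
  qsm <- reconstruct_qsm(comb$phase, comb$magnitude, series$te_list, mask,
                         series$grid, b0 = series$b0, delta = delta,
                         n_iter = n_iter, smv_radius_mm = smv_radius_mm)
  w <- paramagnetic_mask(qsm, chi_threshold, power)
  smwi <- make_smwi(cmag, w, meta = list(chi_threshold = chi_threshold,
                                         power = power))
  list(smwi = smwi, qsm = qsm, combined_magnitude = cmag, mask = mask)
}
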