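# QSM reconstruction chain: brain masking, Laplacian phase unwrapping,
# per-voxel frequency fitting, spherical-mean-value (SMV) background-field
# removal, and truncated k-space dipole inversion with iterative refinement.
# All spectral solves use periodic FFTs with zero-padding factor 2 per axis.

#' Frequency map container
#' @param values field values in Hz.
#' @param mask logical brain mask.
#' @param grid a \code{\link{voxel_grid}}.
#' @return object of class \code{frequency_map}. Values outside the mask are
#'   set to 0.
#' @export
frequency_map <- function(values, mask, grid) {
  stopifnot(identical(dim(values), dim(mask)))
  if (any(!is.finite(values[mask]))) stop("non-finite field inside mask")
  values[!mask] <- 0
  structure(list(values = values, mask = mask, grid = grid),
            class = "frequency_map")
}

#' Susceptibility map container
#' @param values susceptibility in ppb.
#' @param mask logical brain mask.
#' @param grid a \code{\link{voxel_grid}}.
#' @param meta list of inversion parameters used.
#' @return object of class \code{susceptibility_map}.
#' @export
susceptibility_map <- function(values, mask, grid, meta = list()) {
  stopifnot(identical(dim(values), dim(mask)))
  values[!mask] <- 0
  structure(list(values = values, mask = mask, grid = grid, meta = meta),
            class = "susceptibility_map")
}

#' Brain mask from a magnitude image
#'
#' Thresholds at a configurable fraction of the robust maximum (99th
#' percentile), keeps the largest 6-connected component, and closes the
#' result morphologically.
#'
#' @param magnitude nonnegative magnitude volume.
#' @param grid a \code{\link{voxel_grid}} (for mm-scaled morphology).
#' @param frac threshold as a fraction of the robust maximum (default 0.2).
#' @param close_mm closing radius in mm (default 1).
#' @return logical mask array.
#' @export
compute_brain_mask <- function(magnitude, grid, frac = 0.2, close_mm = 1) {
  stopifnot(length(magnitude) > 0)
  rmax <- percentile_linear(magnitude, 0.99)
  if (rmax <= 0) stop("empty-mask error: magnitude has no signal")
  mask <- magnitude > frac * rmax
  mask <- largest_component(mask)
  if (close_mm > 0) mask <- close_mask(mask, close_mm, grid$voxel_size)
  mask
}

# Spectral Laplacian and inverse Laplacian with continuous -|2 pi k|^2 symbol.
spectral_k2 <- function(dims, voxel_size) {
  k <- kspace_coords(dims, voxel_size)
  (2 * pi)^2 * (k$kx^2 + k$ky^2 + k$kz^2)
}

#' Laplacian phase unwrapping
#'
#' Recovers unwrapped phase from wrapped phase psi by solving
#' \code{lap(phi) = cos(psi) lap(sin(psi)) - sin(psi) lap(cos(psi))}
#' spectrally (periodic FFT Poisson solve, k = 0 term zeroed, zero-padded by
#' factor 2). The output equals the true phase up to an additive constant
#' inside smooth regions.
#'
#' @param wrapped phase volume with values in (-pi, pi].
#' @param grid a \code{\link{voxel_grid}}.
#' @param pad zero-padding factor.
#' @return unwrapped phase volume (radians).
#' @export
laplacian_unwrap <- function(wrapped, grid, pad = 2L) {
  if (any(!is.finite(wrapped))) stop("data error: non-finite phase input")
  dims_p <- grid$dims * pad
  k2 <- spectral_k2(dims_p, grid$voxel_size)
  lap <- function(x) ifftn_real(-k2 * stats::fft(x))
  sp <- pad_volume(sin(wrapped), pad)
  # pad cos - 1 so the padded field is continuous at the pad boundary
  # (constants are in the Laplacian null space with the k = 0 term zeroed)
  cpm1 <- pad_volume(cos(wrapped) - 1, pad)
  rhs <- (cpm1 + 1) * lap(sp) - sp * lap(cpm1)
  Phi <- stats::fft(rhs) / (-k2)
  Phi[k2 == 0] <- 0
  unpad_volume(ifftn_real(Phi), grid$dims)
}

#' Per-voxel frequency from multi-echo unwrapped phase
#'
#' Weighted least-squares slope of phase against \code{2 * pi * TE} per voxel,
#' with an intercept absorbing TE-independent (receiver) phase offsets.
#' Default per-echo weights are proportional to the echo-mean squared
#' magnitude.
#'
#' @param phases list of unwrapped phase volumes, one per echo.
#' @param te_list echo times in ms, same length as \code{phases}.
#' @param mask logical brain mask.
#' @param grid a \code{\link{voxel_grid}}.
#' @param weights optional per-echo weights; default from \code{magnitudes}
#'   if given, else equal.
#' @param magnitudes optional list of per-echo magnitude volumes used for the
#'   default weights.
#' @param intercept_free single-echo mode: phase is taken as
#'   \code{2 pi f TE} with no offset (required when only one echo is given).
#' @return a \code{\link{frequency_map}} in Hz.
#' @export
estimate_frequency <- function(phases, te_list, mask, grid, weights = NULL,
                               magnitudes = NULL, intercept_free = FALSE) {
  ne <- length(phases)
  if (length(te_list) != ne) stop("te_list length must match echo count")
  if (ne < 2 && !intercept_free)
    stop("single echo requires intercept_free = TRUE")
  if (is.null(weights)) {
    weights <- if (!is.null(magnitudes)) {
      vapply(magnitudes, function(m) mean(m^2), 0)
    } else rep(1, ne)
  }
  w <- weights / sum(weights)
  x <- 2 * pi * te_list / 1000   # seconds
  if (intercept_free && ne == 1) {
    return(frequency_map(phases[[1]] / x, mask, grid))
  }
  xbar <- sum(w * x)
  sxx <- sum(w * (x - xbar)^2)
  num <- array(0, grid$dims)
  for (e in seq_len(ne)) num <- num + w[e] * (x[e] - xbar) * phases[[e]]
  frequency_map(num / sxx, mask, grid)
}

# Spherical-mean kernel (radius in mm), centred at the array origin with
# periodic wrap, on the padded grid; returns its FFT.
smv_kernel_fft <- function(dims, voxel_size, radius_mm) {
  off <- sphere_offsets(radius_mm, voxel_size)
  kern <- array(0, dims)
  idx <- cbind((off$di %% dims[1]) + 1L, (off$dj %% dims[2]) + 1L,
               (off$dk %% dims[3]) + 1L)
  kern[idx] <- 1
  stats::fft(kern / nrow(off))
}

#' Background-field removal by SMV filtering
#'
#' Applies the spherical-mean-value filter \code{(delta - S_r)} to the field,
#' deconvolves the filter inside the well-conditioned spectral region, and
#' restricts to the mask eroded by the kernel radius. Any field harmonic
#' inside the mask (i.e. generated by sources outside it) is annihilated up
#' to a boundary layer.
#'
#' @param freq a \code{\link{frequency_map}}.
#' @param radius_mm SMV kernel radius in mm (default 2).
#' @param deconv_tol spectral threshold below which the deconvolution is
#'   suppressed (default 0.05).
#' @param pad zero-padding factor.
#' @return a \code{\link{frequency_map}} of the local field, with the eroded
#'   mask.
#' @export
remove_background_field <- function(freq, radius_mm = 2, deconv_tol = 0.05,
                                    pad = 2L) {
  stopifnot(inherits(freq, "frequency_map"))
  grid <- freq$grid
  if (!any(freq$mask)) stop("mask nonempty required")
  eroded <- erode_mask(freq$mask, radius_mm, grid$voxel_size)
  if (!any(eroded)) stop("geometry error: SMV radius too large for mask")
  dims_p <- grid$dims * pad
  Sf <- smv_kernel_fft(dims_p, grid$voxel_size, radius_mm)
  H <- 1 - Sf
  # filter, restrict to the eroded mask (where the SMV sphere fits inside the
  # brain), then deconvolve the filter on the well-conditioned spectrum
  filt <- unpad_volume(ifftn_real(H * stats::fft(pad_volume(freq$values * freq$mask, pad))),
                       grid$dims)
  inv <- ifelse(Mod(H) > deconv_tol, 1 / H, 0)
  local <- unpad_volume(ifftn_real(inv * stats::fft(pad_volume(filt * eroded, pad))),
                        grid$dims)
  frequency_map(local * eroded, eroded, grid)
}

#' Dipole inversion by truncated k-space division with iterative refinement
#'
#' Initial estimate \code{chi = IFFT[FFT(f / (gamma_bar B0 1e-9)) * sign(D) /
#' max(|D|, delta)]}; then \code{n_iter} fixed-point refinements that enforce
#' exact data consistency on the well-conditioned k-space region
#' \code{|D| > delta} while constraining the image-space support to the mask
#' (the current estimate is kept on the ill-conditioned region). The output
#' is referenced to zero mean over the mask.
#'
#' @param local a \code{\link{frequency_map}} of the local field (Hz).
#' @param b0 tesla.
#' @param delta truncation threshold, in (0, 1/3) (default 0.1).
#' @param n_iter refinement iterations (default 30).
#' @param pad zero-padding factor.
#' @return a \code{\link{susceptibility_map}} in ppb.
#' @export
invert_dipole <- function(local, b0 = 3, delta = 0.1, n_iter = 30L, pad = 2L) {
  stopifnot(inherits(local, "frequency_map"))
  if (!(delta > 0 && delta < 1 / 3))
    stop("parameter error: delta must be in (0, 1/3)")
  if (n_iter < 0) stop("n_iter must be >= 0")
  grid <- local$grid
  dims_p <- grid$dims * pad
  D <- dipole_kernel(dims_p, grid$voxel_size, grid$slice_axis)
  scale <- GAMMA_BAR_HZ_PER_T * b0 * 1e-9
  f_norm <- pad_volume(local$values * local$mask / scale, pad)
  Fk <- stats::fft(f_norm)
  sgnD <- ifelse(D >= 0, 1, -1)
  Xk <- Fk * sgnD / pmax(abs(D), delta)
  well <- abs(D) > delta
  support <- pad_volume(local$mask * 1, pad) > 0
  chi <- ifftn_real(Xk)
  if (n_iter > 0) {
    for (it in seq_len(n_iter)) {
      chi[!support] <- 0
      Xk <- stats::fft(chi)
      Xk[well] <- Fk[well] / D[well]
      chi <- ifftn_real(Xk)
    }
  }
  chi <- unpad_volume(chi, grid$dims)
  chi <- chi - mean(chi[local$mask])
  susceptibility_map(chi, local$mask, grid,
                     meta = list(delta = delta, n_iter = n_iter, b0 = b0,
                                 pad = pad))
}

#' Reconstruct a susceptibility map from combined multi-echo phase
#'
#' Convenience chain: per-echo Laplacian unwrapping, frequency fit, SMV
#' background removal, dipole inversion. Phase outside the mask is zeroed
#' before unwrapping.
#'
#' @param phases list of combined (channel-averaged) wrapped phase volumes.
#' @param magnitudes list of per-echo combined magnitude volumes.
#' @param te_list echo times (ms).
#' @param mask logical brain mask.
#' @param grid a \code{\link{voxel_grid}}.
#' @param b0 tesla.
#' @param delta truncation threshold.
#' @param n_iter refinement iterations.
#' @param smv_radius_mm SMV kernel radius (mm).
#' @return a \code{\link{susceptibility_map}}.
#' @export
reconstruct_qsm <- function(phases, magnitudes, te_list, mask, grid, b0 = 3,
                            delta = 0.1, n_iter = 30L, smv_radius_mm = 2) {
  unwrapped <- lapply(phases, function(p) {
    p[!mask] <- 0
    laplacian_unwrap(p, grid)
  })
  freq <- estimate_frequency(unwrapped, te_list, mask, grid,
                             magnitudes = magnitudes)
  local <- remove_background_field(freq, radius_mm = smv_radius_mm)
  invert_dipole(local, b0 = b0, delta = delta, n_iter = n_iter)
}
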