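# Midbrain phantom rendering and multi-echo GRE simulation.
#
# Geometry (mm, relative to the field-of-view centre; slice axis = z, caudal =
# increasing slice index): paired substantia nigra (SN) ellipsoids with a
# dorsolateral nigrosome-1 (N1) subregion, red nucleus (RN) spheres cranial to
# the SN, all inside a large "head" ellipsoid that carries the MR signal.

phantom_geometry_defaults <- function() {
  list(
    sn_center = c(7.0, 2.0, 1.0),      # |x| lateral, y, z offsets (mm)
    sn_axes = c(4.5, 2.5, 4.5),        # semi-axes (mm)
    rn_center = c(4.5, -2.0, -4.0),
    rn_radius = 2.5,
    n1_offset = c(2.0, 0.8, -1.0),     # from SN centre, caudo-lateral; lateral sign follows side
    n1_axes = c(1.8, 1.4, 2.2),
    n1_shrink = 0.6,                   # fractional N1 shrinkage at full degeneration
    chi_sn_base = 90, chi_sn_gain = 60,      # ppb
    chi_n1_base = 10, chi_n1_gain = 120,     # ppb
    chi_rn = 100,                            # ppb
    chi_noise_sd = 3,                        # ppb texture
    nms_base = 1.0,
    nms_lo = 0.10, nms_hi = 0.25,      # SN neuromelanin contrast ramp (fraction)
    nms_noise_sd = 0.015,
    head_frac = 0.90                   # head ellipsoid semi-axes as FOV fraction
  )
}

# Physical coordinates (mm) of voxel centres, origin at the FOV centre.
grid_coords_mm <- function(grid) {
  d <- grid$dims; vs <- grid$voxel_size
  ax <- (seq_len(d[1]) - (d[1] + 1) / 2) * vs[1]
  ay <- (seq_len(d[2]) - (d[2] + 1) / 2) * vs[2]
  az <- (seq_len(d[3]) - (d[3] + 1) / 2) * vs[3]
  list(
    x = array(rep(ax, times = d[2] * d[3]), d),
    y = array(rep(rep(ay, each = d[1]), times = d[3]), d),
    z = array(rep(az, each = d[1] * d[2]), d)
  )
}

ellipsoid_mask <- function(co, center, axes) {
  ((co$x - center[1]) / axes[1])^2 + ((co$y - center[2]) / axes[2])^2 +
    ((co$z - center[3]) / axes[3])^2 <= 1
}

#' Render a midbrain susceptibility / neuromelanin phantom
#'
#' Builds ground-truth susceptibility (ppb) and neuromelanin-sensitive (NMS)
#' signal volumes for one subject from its per-hemisphere latent state, plus
#' the exact region masks (SN, RN, N1 per side) and the head support.
#' Degeneration raises N1 susceptibility toward the surrounding SN level,
#' shrinks the N1, and flattens the within-SN neuromelanin contrast ramp.
#'
#' @param latent list or one-row data.frame with \code{degeneration_L},
#'   \code{degeneration_R} in [0,1] (optionally \code{sn_scale}).
#' @param grid a \code{\link{voxel_grid}}; must contain both SN ellipsoids
#'   with a 2-voxel margin.
#' @param seed integer seed for the additive texture noise.
#' @param geom geometry/contrast constants, see
#'   \code{phantom_geometry_defaults()}.
#' @return list with \code{chi} (ppb), \code{nms}, \code{masks} (named list
#'   SN_L, SN_R, RN_L, RN_R, N1_L, N1_R), \code{head}, \code{grid}.
#' @export
render_phantom <- function(latent, grid, seed = 1L,
                           geom = phantom_geometry_defaults()) {
  stopifnot(inherits(grid, "voxel_grid"))
  latent <- as.list(latent)
  deg <- c(L = as.numeric(latent$degeneration_L),
           R = as.numeric(latent$degeneration_R))
  if (any(!is.finite(deg)) || any(deg < 0) || any(deg > 1))
    stop("degeneration must be finite in [0, 1] for both hemispheres")
  sn_scale <- if (!is.null(latent$sn_scale)) as.numeric(latent$sn_scale) else 1

  fov <- grid$dims * grid$voxel_size
  margin <- 2 * grid$voxel_size
  sn_reach <- abs(geom$sn_center) + geom$sn_axes * sn_scale
  if (any(sn_reach + margin > fov / 2))
    stop("geometry error: SN ellipsoids do not fit in the grid with a 2-voxel margin")

  co <- grid_coords_mm(grid)
  sgn <- c(L = -1, R = 1)
  masks <- list()
  chi <- array(0, grid$dims)
  nms <- array(geom$nms_base, grid$dims)

  head <- ellipsoid_mask(co, c(0, 0, 0), geom$head_frac * fov / 2)

  for (s in c("L", "R")) {
    d <- deg[[s]]
    sc <- c(sgn[[s]] * geom$sn_center[1], geom$sn_center[2], geom$sn_center[3])
    sn <- ellipsoid_mask(co, sc, geom$sn_axes * sn_scale)
    rn <- ellipsoid_mask(co, c(sgn[[s]] * geom$rn_center[1], geom$rn_center[2],
                               geom$rn_center[3]), rep(geom$rn_radius, 3))
    n1c <- sc + c(sgn[[s]] * geom$n1_offset[1], geom$n1_offset[2], geom$n1_offset[3])
    n1 <- ellipsoid_mask(co, n1c, geom$n1_axes * (1 - geom$n1_shrink * d)) & sn

    chi[sn] <- geom$chi_sn_base + geom$chi_sn_gain * d
    chi[n1] <- geom$chi_n1_base + geom$chi_n1_gain * d
    chi[rn] <- geom$chi_rn

    # neuromelanin: medial->lateral ramp inside the SN, scaled down by loss
    u <- pmin(1, pmax(0, (sgn[[s]] * (co$x[sn] - sc[1]) / (geom$sn_axes[1] * sn_scale) + 1) / 2))
    level <- 1 - 0.75 * d
    nms[sn] <- geom$nms_base + (geom$nms_lo + (geom$nms_hi - geom$nms_lo) * u) * level
    nms[n1] <- nms[n1] + 0.08 * (1 - d)

    masks[[paste0("SN_", s)]] <- sn
    masks[[paste0("RN_", s)]] <- rn
    masks[[paste0("N1_", s)]] <- n1
  }
  set.seed(seed)
  chi <- chi + array(stats::rnorm(prod(grid$dims), 0, geom$chi_noise_sd), grid$dims)
  nms <- nms + array(stats::rnorm(prod(grid$dims), 0, geom$nms_noise_sd), grid$dims)
  chi[!head] <- 0
  list(chi = chi, nms = nms, masks = masks, head = head, grid = grid)
}

#' Dipole kernel in k-space
#'
#' \code{D(k) = 1/3 - kz^2 / |k|^2} with \code{D(0) = 0}; the main field B0
#' lies along the grid's slice axis.
#'
#' @param dims (possibly padded) array dimensions.
#' @param voxel_size voxel size in mm.
#' @param slice_axis axis along B0 (1, 2 or 3).
#' @return numeric array of dipole kernel values.
#' @export
dipole_kernel <- function(dims, voxel_size, slice_axis = 3L) {
  k <- kspace_coords(dims, voxel_size)
  kb <- switch(slice_axis, k$kx, k$ky, k$kz)
  k2 <- k$kx^2 + k$ky^2 + k$kz^2
  D <- 1 / 3 - kb^2 / k2
  D[k2 == 0] <- 0
  D
}

#' Forward field of a susceptibility distribution
#'
#' Field shift in Hz from a susceptibility volume in ppb by dipole
#' convolution: \code{f = gamma_bar * B0 * 1e-9 * IFFT[D(k) FFT(chi)]},
#' computed on a zero-padded grid (factor 2 per axis) to suppress wrap-around.
#'
#' @param chi susceptibility volume (ppb).
#' @param grid a \code{\link{voxel_grid}}.
#' @param b0 field strength in tesla (default 3).
#' @param pad zero-padding factor.
#' @return field volume in Hz.
#' @export
forward_field <- function(chi, grid, b0 = 3, pad = 2L) {
  stopifnot(all(is.finite(chi)))
  dims_p <- grid$dims * pad
  D <- dipole_kernel(dims_p, grid$voxel_size, grid$slice_axis)
  Xk <- stats::fft(pad_volume(chi, pad))
  f <- ifftn_real(D * Xk)
  GAMMA_BAR_HZ_PER_T * b0 * 1e-9 * unpad_volume(f, grid$dims)
}

#' Proton gyromagnetic ratio over 2 pi, Hz per tesla
#' @export
GAMMA_BAR_HZ_PER_T <- 42.577e6

#' Simulate a multi-channel multi-echo GRE acquisition
#'
#' Computes the dipole-convolution field of \code{chi}, then per-echo phase
#' \code{2*pi*field*TE} plus a smooth quadratic background field and constant
#' per-channel phase offsets, wrapped to (-pi, pi]. Magnitude decays mildly
#' with TE; complex Gaussian noise is added per channel.
#'
#' @param chi susceptibility volume (ppb).
#' @param grid a \code{\link{voxel_grid}}.
#' @param te_list echo times in ms, strictly increasing
#'   (default 13.77, 26.39, 39).
#' @param b0 tesla (default 3).
#' @param n_channels receive channels (default 2).
#' @param noise_sd complex noise SD as a fraction of unit magnitude.
#' @param seed integer seed.
#' @param magnitude_support support of the MR-visible tissue (head mask);
#'   defaults to everywhere.
#' @param background_hz peak amplitude of the quadratic background field (Hz);
#'   0 disables it.
#' @param t2star_ms magnitude decay constant (ms).
#' @return object of class \code{echo_series}: list with \code{magnitude} and
#'   \code{phase} (4-D arrays indexed [x, y, z, channel * echo] as nested
#'   lists \code{[[channel]][[echo]]}), \code{te_list} (ms), \code{b0},
#'   \code{grid}, and the true \code{field} (Hz).
#' @export
simulate_multiecho_gre <- function(chi, grid, te_list = c(13.77, 26.39, 39),
                                   b0 = 3, n_channels = 2L, noise_sd = 0.01,
                                   seed = 1L, magnitude_support = NULL,
                                   background_hz = 2, t2star_ms = 50) {
  if (length(te_list) == 0) stop("config error: te_list must be nonempty")
  if (any(diff(te_list) <= 0)) stop("te_list must be strictly increasing")
  if (any(!is.finite(chi))) stop("chi must be finite")
  field <- forward_field(chi, grid, b0 = b0)
  if (is.null(magnitude_support)) magnitude_support <- array(TRUE, grid$dims)

  co <- grid_coords_mm(grid)
  fov <- grid$dims * grid$voxel_size
  bg <- background_hz * ((2 * co$x / fov[1])^2 + (2 * co$y / fov[2])^2 -
                           (2 * co$z / fov[3])^2)
  set.seed(seed)
  offsets <- stats::runif(n_channels, -pi, pi)
  gains <- stats::runif(n_channels, 0.8, 1.2)

  magnitude <- vector("list", n_channels)
  phase <- vector("list", n_channels)
  base_mag <- ifelse(magnitude_support, 1, 0)
  for (ch in seq_len(n_channels)) {
    magnitude[[ch]] <- vector("list", length(te_list))
    phase[[ch]] <- vector("list", length(te_list))
    for (e in seq_along(te_list)) {
      te_s <- te_list[e] / 1000
      true_phase <- 2 * pi * (field + bg) * te_s + offsets[ch]
      m <- gains[ch] * base_mag * exp(-te_list[e] / t2star_ms)
      sig <- m * exp(1i * true_phase)
      if (noise_sd > 0) {
        sig <- sig + complex(
          real = stats::rnorm(length(sig), 0, noise_sd),
          imaginary = stats::rnorm(length(sig), 0, noise_sd)
        )
      }
      magnitude[[ch]][[e]] <- array(Mod(sig), grid$dims)
      phase[[ch]][[e]] <- array(wrap_phase(Arg(sig)), grid$dims)
    }
  }
  structure(list(magnitude = magnitude, phase = phase,
                 te_list = te_list, b0 = b0, grid = grid, field = field),
            class = "echo_series")
}
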