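#' Voxel grid geometry
#'
#' Defines the sampling lattice shared by every volume in a run: matrix size,
#' voxel size in mm, and which array axis is the slice (through-plane) axis.
#' The internal slice convention is caudal = increasing slice index; loaders
#' normalising NIfTI orientation map onto this convention.
#'
#' @param dims integer vector of length 3, matrix size (nx, ny, nz).
#' @param voxel_size numeric vector of length 3, voxel edge lengths in mm.
#'   Default 0.5 x 0.5 x 1 mm.
#' @param slice_axis which axis indexes slices (1, 2 or 3). Default 3.
#' @return An object of class \code{voxel_grid}.
#' @examples
#' g <- voxel_grid(c(64, 64, 24))
#' voxel_volume(g)  # 0.25 mm^3
#' @export
voxel_grid <- function(dims, voxel_size = c(0.5, 0.5, 1.0), slice_axis = 3L) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L),
            length(voxel_size) == 3L, all(voxel_size > 0),
            slice_axis %in% 1:3)
  structure(list(dims = dims, voxel_size = as.numeric(voxel_size),
                 slice_axis = as.integer(slice_axis)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, %.3g x %.3g x %.3g mm, slice axis %d\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3], x$slice_axis))
  invisible(x)
}

#' @rdname voxel_grid
#' @param grid a \code{voxel_grid}.
#' @export
voxel_volume <- function(grid) prod(grid$voxel_size)

#' Number of slices along the grid's slice axis
#' @param grid a \code{voxel_grid}.
#' @return integer slice count.
#' @export
n_slices <- function(grid) grid$dims[grid$slice_axis]

# DFT sample frequencies (cycles per unit length), fftw/numpy ordering.
fft_freq <- function(n, d = 1) {
  if (n %% 2L == 0L) {
    c(0:(n / 2L - 1L), -(n / 2L):-1L) / (n * d)
  } else {
    c(0:((n - 1L) / 2L), -((n - 1L) / 2L):-1L) / (n * d)
  }
}

# k-space coordinate arrays for a (possibly padded) grid, in cycles/mm.
kspace_coords <- function(dims, voxel_size) {
  kx <- fft_freq(dims[1], voxel_size[1])
  ky <- fft_freq(dims[2], voxel_size[2])
  kz <- fft_freq(dims[3], voxel_size[3])
  list(
    kx = array(rep(kx, times = dims[2] * dims[3]), dims),
    ky = array(rep(rep(ky, each = dims[1]), times = dims[3]), dims),
    kz = array(rep(kz, each = dims[1] * dims[2]), dims)
  )
}

# Zero-pad an array by factor `pad` on each axis (array kept in the low corner).
pad_volume <- function(x, pad = 2L) {
  d <- dim(x)
  out <- array(0, d * pad)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x
  out
}

unpad_volume <- function(x, dims) {
  x[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])]
}

ifftn_real <- function(X) Re(stats::fft(X, inverse = TRUE)) / length(X)

#' Wrap phase into the principal interval
#'
#' Maps arbitrary phase values into (-pi, pi].
#'
#' @param phi numeric array of phase values (radians).
#' @return array of the same shape with values in (-pi, pi].
#' @export
wrap_phase <- function(phi) {
  w <- (phi + pi) %% (2 * pi) - pi
  # %% maps exact odd multiples of pi to -pi; the convention here is (-pi, pi]
  w[w == -pi] <- pi
  w
}

# Linear-interpolation percentile (order-statistic interpolation), the
# definition pinned for the NMS contrast range. Equivalent to quantile type 7.
percentile_linear <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
}

# Deterministic per-subject / per-stage seed derivation from a master seed.
# Counter-based so results do not depend on execution order.
derive_seed <- function(master, index, stage = 0L) {
  # double arithmetic: intermediate stays below 2^53, result below 2^31
  as.integer((as.numeric(master) * 7919 + as.numeric(index) * 104729 +
                as.numeric(stage) * 1299709) %% 2147483587)
}
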