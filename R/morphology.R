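# Small 3-D binary morphology toolkit used for brain masking and SMV erosion.
# Structuring elements are physical spheres specified in mm so anisotropic
# voxels are handled correctly.

# Logical array shifted by (di, dj, dk), zero-filled at the border.
shift_array <- function(x, di, dj, dk) {
  d <- dim(x)
  out <- array(FALSE, d)
  src_i <- max(1, 1 - di):min(d[1], d[1] - di)
  src_j <- max(1, 1 - dj):min(d[2], d[2] - dj)
  src_k <- max(1, 1 - dk):min(d[3], d[3] - dk)
  out[src_i + di, src_j + dj, src_k + dk] <- x[src_i, src_j, src_k]
  out
}

# Offsets of voxels whose centres lie within radius_mm of the origin.
sphere_offsets <- function(radius_mm, voxel_size) {
  r <- pmax(0L, floor(radius_mm / voxel_size))
  off <- expand.grid(di = -r[1]:r[1], dj = -r[2]:r[2], dk = -r[3]:r[3])
  d2 <- (off$di * voxel_size[1])^2 + (off$dj * voxel_size[2])^2 +
    (off$dk * voxel_size[3])^2
  off[d2 <= radius_mm^2, , drop = FALSE]
}

dilate_mask <- function(mask, radius_mm, voxel_size) {
  off <- sphere_offsets(radius_mm, voxel_size)
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(off)))
    out <- out | shift_array(mask, off$di[i], off$dj[i], off$dk[i])
  out
}

erode_mask <- function(mask, radius_mm, voxel_size) {
  !dilate_mask(!mask, radius_mm, voxel_size)
}

close_mask <- function(mask, radius_mm, voxel_size) {
  erode_mask(dilate_mask(mask, radius_mm, voxel_size), radius_mm, voxel_size)
}

# 6-connected components by iterative minimum-label propagation. Returns an
# integer array: 0 background, components numbered by decreasing size.
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0, d)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    nb <- lab
    for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      sh <- array(0, d)
      src_i <- max(1, 1 - s[1]):min(d[1], d[1] - s[1])
      src_j <- max(1, 1 - s[2]):min(d[2], d[2] - s[2])
      src_k <- max(1, 1 - s[3]):min(d[3], d[3] - s[3])
      sh[src_i + s[1], src_j + s[2], src_k + s[3]] <- lab[src_i, src_j, src_k]
      keep <- mask & sh > 0
      nb[keep] <- pmin(nb[keep], sh[keep])
    }
    if (identical(nb, lab)) break
    lab <- nb
  }
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids)) {
    sizes <- tabulate(match(lab[lab > 0], ids))
    remap <- integer(max(ids))
    remap[ids[order(sizes, decreasing = TRUE)]] <- seq_along(ids)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  lab
}

largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  label_components(mask) == 1L
}
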