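#' Apparent diffusion coefficient map
#'
#' Conventional ADC: a per-voxel Ball (mono-exponential) fit by Rician maximum
#' likelihood, reported in 1e-3 mm^2/s. By convention ADC uses the low-b
#' portion of the acquisition (default b <= 2000 s/mm^2, plus all b = 0).
#'
#' @param data_4d 4-D signal array.
#' @param scheme An `acq_scheme`.
#' @param noise A `noise_estimate` or scalar sigma.
#' @param mask 3-D logical array of voxels to fit.
#' @param b_max Largest b-value used in the ADC fit (Inf = all).
#' @param n_starts,seed Passed to [fit_voxel()].
#' @return A `parameter_maps` list containing the `adc` array (NaN outside
#'   the mask) and provenance.
#' @export
adc_map <- function(data_4d, scheme, noise, mask = NULL, b_max = 2000,
                    n_starts = 3L, seed = 1L) {
  sel <- scheme$b <= b_max
  sub <- scheme[sel, ]
  class(sub) <- class(scheme)
  attr(sub, "gamma") <- scheme_gamma(scheme)
  dm <- dim(data_4d)
  if (is.null(mask)) mask <- array(TRUE, dm[1:3])
  adc <- array(NaN, dm[1:3])
  vox <- which(mask != 0, arr.ind = TRUE)
  for (v in seq_len(nrow(vox))) {
    i <- vox[v, 1]; j <- vox[v, 2]; k3 <- vox[v, 3]
    fit <- fit_voxel(data_4d[i, j, k3, sel], sub, "Ball", noise,
                     n_starts = n_starts,
                     seed = if (is.null(seed)) NULL else seed + v)
    adc[i, j, k3] <- fit$params$D1
  }
  new_parameter_maps(list(adc = adc), model = "Ball",
                     note = sprintf("ADC fit restricted to b <= %g", b_max))
}

new_parameter_maps <- function(maps, voxdim = c(0.25, 0.25, 0.5), model = NA,
                               note = NULL) {
  structure(list(maps = maps, voxdim = voxdim, model = model, note = note),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat(sprintf("<parameter maps (%s): %s; voxel %s mm>\n",
              x$model, paste(names(x$maps), collapse = ", "),
              paste(x$voxdim, collapse = " x ")))
  invisible(x)
}

#' Fractional anisotropy of a cylindrically symmetric tensor
#'
#' Standard FA of the eigenvalue triple (D1, D2, D2) — the anisotropic
#' extracellular portion of a Zeppelin-containing fit, with any isotropic
#' restricted component removed from the calculation.
#'
#' @param D1 Principal diffusivity (vectorised).
#' @param D2 Perpendicular diffusivity.
#' @return FA in \[0, 1\]; NaN where D1 = D2 = 0 (undefined).
#' @examples
#' zeppelin_fa(2, 1)  # ~0.4082
#' @export
zeppelin_fa <- function(D1, D2) {
  if (any(D1 < D2 - 1e-12, na.rm = TRUE)) {
    stop("zeppelin_fa requires D1 >= D2", call. = FALSE)
  }
  md <- (D1 + 2 * D2) / 3
  num <- sqrt((D1 - md)^2 + 2 * (D2 - md)^2)
  den <- sqrt(D1^2 + 2 * D2^2)
  fa <- sqrt(3 / 2) * num / den
  fa[D1 == 0 & D2 == 0] <- NaN
  fa
}

#' Colour fractional anisotropy from per-voxel fits
#'
#' RGB encoding of the principal diffusion direction weighted by FA:
#' red = |n_x|, green = |n_y|, blue = |n_z|, each scaled by FA, so antipodal
#' directions map identically and channel values never exceed FA.
#'
#' @param fits Tidy fit table (from [fit_volume()]) for a Zeppelin-containing
#'   model, with columns `i, j, k_idx, D1, D2, theta, phi`.
#' @param dim 3-D grid dimensions.
#' @return A `colour_fa` list: `fa` (3-D array), `rgb` (4-D array x,y,z,3),
#'   both NaN/0 outside fitted voxels.
#' @export
colour_fa <- function(fits, dim) {
  need <- c("i", "j", "k_idx", "D1", "D2", "theta", "phi")
  miss <- setdiff(need, names(fits))
  if (length(miss)) stop("fits is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  fa_arr <- array(NaN, dim)
  rgb <- array(0, c(dim, 3))
  hiD <- pmax(fits$D1, fits$D2)
  loD <- pmin(fits$D1, fits$D2)
  fa <- zeppelin_fa(hiD, loD)
  nx <- abs(sin(fits$theta) * cos(fits$phi))
  ny <- abs(sin(fits$theta) * sin(fits$phi))
  nz <- abs(cos(fits$theta))
  ix <- cbind(fits$i, fits$j, fits$k_idx)
  fa_arr[ix] <- fa
  rgb[cbind(ix, 1)] <- nx * fa
  rgb[cbind(ix, 2)] <- ny * fa
  rgb[cbind(ix, 3)] <- nz * fa
  structure(list(fa = fa_arr, rgb = rgb), class = "colour_fa")
}

#' Block-average downsampling of a 4-D volume
#'
#' Averages the magnitude signal over in-plane (and optionally through-plane)
#' blocks before refitting, emulating acquisition at coarser resolution. When
#' the factors do not divide the grid, the volume is padded by edge
#' replication with a warning.
#'
#' @param volume_4d 4-D array (x, y, z, measurement).
#' @param factors Integer length-3 block size per spatial dimension.
#' @return Downsampled 4-D array.
#' @export
downsample <- function(volume_4d, factors) {
  factors <- as.integer(factors)
  if (length(factors) != 3 || any(factors < 1)) {
    stop("factors must be three positive integers", call. = FALSE)
  }
  dm <- dim(volume_4d)
  if (length(dm) != 4) stop("volume_4d must be 4-D", call. = FALSE)
  pad <- (factors - dm[1:3] %% factors) %% factors
  if (any(pad > 0)) {
    warning("factors do not divide grid dimensions; padding by edge replication")
    padded <- array(0, c(dm[1:3] + pad, dm[4]))
    padded[1:dm[1], 1:dm[2], 1:dm[3], ] <- volume_4d
    for (d in 1:3) if (pad[d] > 0) {
      idx_src <- rep(dm[d], pad[d])
      if (d == 1) padded[dm[1] + seq_len(pad[1]), , , ] <- padded[idx_src, , , , drop = FALSE]
      if (d == 2) padded[, dm[2] + seq_len(pad[2]), , ] <- padded[, idx_src, , , drop = FALSE]
      if (d == 3) padded[, , dm[3] + seq_len(pad[3]), ] <- padded[, , idx_src, , drop = FALSE]
    }
    volume_4d <- padded
    dm <- dim(volume_4d)
  }
  nd <- dm[1:3] %/% factors
  out <- array(0, c(nd, dm[4]))
  for (m in seq_len(dm[4])) {
    v <- volume_4d[, , , m]
    # block mean via successive dimension folding
    a <- array(v, c(factors[1], nd[1], dm[2], dm[3]))
    a <- colMeans(a)                                   # nd1 x d2 x d3
    a <- aperm(a, c(2, 1, 3))
    a <- array(a, c(factors[2], nd[2], nd[1], dm[3]))
    a <- colMeans(a)                                   # nd2 x nd1 x d3
    a <- aperm(a, c(3, 2, 1))                          # d3 x nd1 x nd2
    a <- array(a, c(factors[3], nd[3], nd[1], nd[2]))
    a <- colMeans(a)                                   # nd3 x nd1 x nd2
    out[, , , m] <- aperm(a, c(2, 3, 1))
  }
  out
}

#' Write parameter maps as NIfTI volumes
#'
#' One 3-D NIfTI per parameter, with the voxel dimensions recorded in the
#' header. Excluded voxels carry NaN.
#'
#' @param pm A `parameter_maps` object (or named list of 3-D arrays).
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @param voxdim Voxel dimensions in mm.
#' @return Invisibly, the written paths.
#' @export
write_parameter_maps <- function(pm, dir, prefix = "map",
                                 voxdim = NULL) {
  maps <- if (inherits(pm, "parameter_maps")) pm$maps else pm
  if (is.null(voxdim)) {
    voxdim <- if (inherits(pm, "parameter_maps")) pm$voxdim else c(1, 1, 1)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(maps)) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    img <- RNifti::asNifti(maps[[nm]])
    RNifti::pixdim(img) <- voxdim[seq_len(min(length(dim(maps[[nm]])), length(voxdim)))]
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a NIfTI volume as a plain array
#' @param path NIfTI file path.
#' @return Array with a `voxdim` attribute.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attr(arr, "voxdim") <- RNifti::pixdim(img)
  arr
}

#' Heatmap of one slice of a parameter map
#' @param map 3-D array.
#' @param slice Slice index (3rd dimension).
#' @param name Fill legend label.
#' @return A ggplot object.
#' @export
plot_map_slice <- function(map, slice = 1L, name = "value") {
  df <- expand.grid(x = seq_len(dim(map)[1]), y = seq_len(dim(map)[2]))
  df$value <- as.vector(map[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20", name = name) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
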