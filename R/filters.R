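# Filter bank: Laplacian-of-Gaussian band-pass images at several
# physical scales plus the eight sub-bands of a single-level
# undecimated separable 3-D wavelet transform. The default bank is
# 1 (original) + 3 (LoG) + 8 (wavelet) = 12 images, i.e. 11 derived
# ones.

# Coiflet-1 decomposition filters.
.COIF1_LO <- c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
               0.8525720202116004, 0.3378976624574818, -0.07273261951252645)
.COIF1_HI <- c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
               0.3848648468648578, 0.07273261951252645, -0.015655728135791993)

#' Build the derived-image filter bank
#'
#' Produces the named set of image variants features are computed on:
#' the original image, one scale-normalized Laplacian-of-Gaussian image
#' per sigma (in mm; band-pass, emphasizing structure at that physical
#' scale), and the 8 sub-bands (LLL..HHH) of a single-level undecimated
#' separable 3-D Coiflet-1 wavelet transform. All derived images live
#' on the original grid.
#'
#' @param img A `scalar_image`.
#' @param sigmas_mm LoG scales in mm (default 1, 2, 3).
#' @param wavelet Logical; include the 8 wavelet sub-bands.
#' @return Named list of `scalar_image`s; first element is `original`.
#' @export
apply_filter_bank <- function(img, sigmas_mm = c(1, 2, 3), wavelet = TRUE) {
  stopifnot(all(is.finite(img$data)))
  if (any(sigmas_mm <= 0)) stop("LoG sigma must be positive")
  bank <- list(original = img)
  for (s in sigmas_mm) {
    nm <- paste0("log.sigma.", gsub("\\.", "-", format(s)), "mm")
    bank[[nm]] <- scalar_image(.log_filter(img$data, img$voxel_size, s),
                               img$affine)
  }
  if (wavelet) {
    wb <- .wavelet_bank(img$data)
    for (nm in names(wb))
      bank[[paste0("wavelet.", nm)]] <- scalar_image(wb[[nm]], img$affine)
  }
  bank
}

# Scale-normalized LoG: separable Gaussian smoothing (sigma in mm,
# converted per-axis to voxels, replicate boundary) followed by the
# discrete Laplacian with physical spacing, times sigma^2.
.log_filter <- function(a, voxel_size, sigma_mm) {
  sm <- a
  for (ax in 1:3) {
    sv <- sigma_mm / voxel_size[ax]
    sm <- .gauss_axis(sm, sv, ax)
  }
  lap <- array(0, dim(a))
  for (ax in 1:3) {
    lap <- lap + (.shift_replicate(sm, 1L, ax) + .shift_replicate(sm, -1L, ax) -
                    2 * sm) / voxel_size[ax]^2
  }
  sigma_mm^2 * lap
}

.gauss_axis <- function(a, sigma_vox, axis) {
  if (sigma_vox <= 0) return(a)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  out <- array(0, dim(a))
  for (i in seq_along(k))
    out <- out + k[i] * .shift_replicate(a, i - r - 1L, axis)
  out
}

# Shift along an axis with replicate (nearest) boundary.
.shift_replicate <- function(a, by, axis) {
  n <- dim(a)[axis]
  src <- pmin(pmax(seq_len(n) + by, 1L), n)
  .index_axis(a, src, axis)
}

# Shift along an axis with periodic boundary.
.shift_periodic <- function(a, by, axis) {
  n <- dim(a)[axis]
  src <- ((seq_len(n) + by - 1L) %% n) + 1L
  .index_axis(a, src, axis)
}

.index_axis <- function(a, src, axis) {
  switch(axis,
         a[src, , , drop = FALSE],
         a[, src, , drop = FALSE],
         a[, , src, drop = FALSE])
}

# Single-level undecimated separable wavelet transform with periodic
# boundary. Along each axis: out[n] = sum_k h[k] * x[(n - k + 3) mod N]
# (0-based), matching the stationary-transform convention of standard
# wavelet libraries. Sub-band names: letter i refers to array dimension
# i, L = low-pass, H = high-pass.
.wavelet_bank <- function(a) {
  filt_axis <- function(x, h, axis) {
    out <- array(0, dim(x))
    for (k in seq_along(h))
      out <- out + h[k] * .shift_periodic(x, 3L - (k - 1L), axis)
    out
  }
  bands <- list(a)
  labels <- ""
  for (ax in 1:3) {
    nxt <- vector("list", 2L * length(bands))
    nlab <- character(2L * length(bands))
    for (b in seq_along(bands)) {
      nxt[[2L * b - 1L]] <- filt_axis(bands[[b]], .COIF1_LO, ax)
      nlab[2L * b - 1L] <- paste0(labels[b], "L")
      nxt[[2L * b]] <- filt_axis(bands[[b]], .COIF1_HI, ax)
      nlab[2L * b] <- paste0(labels[b], "H")
    }
    bands <- nxt
    labels <- nlab
  }
  names(bands) <- labels
  bands[order(labels)]
}
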