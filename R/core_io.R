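# Data model: streamlines, tractograms, voxel grids, and the coordinate
# conventions shared by every module. World frame is RAS millimetres;
# voxel indices are 0-based with voxel centers at integer indices.

#' Reference grid descriptor
#'
#' Describes the voxel grid a tractogram or image lives on: array shape,
#' voxel sizes in mm, and the 4x4 affine mapping 0-based voxel indices to
#' RAS world coordinates (mm).
#'
#' @param shape Integer vector of length 3 (array dimensions).
#' @param affine 4x4 numeric matrix, index -> world (RAS mm), 0-based indices.
#' @return An object of class `ref_grid`.
#' @export
ref_grid <- function(shape, affine = diag(4)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)), all(is.finite(affine)))
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 100)
    stop("affine must be invertible")
  structure(list(shape = shape, affine = affine,
                 voxel_size = sqrt(colSums(affine[1:3, 1:3]^2))),
            class = "ref_grid")
}

#' Voxel image constructors
#'
#' A `scalar_image` is a 3-D array of real intensities tied to an affine.
#' A `binary_mask` additionally requires all voxels in \{0, 1\}; a
#' `label_image` requires non-negative integer labels with 0 reserved
#' for background and labels 1..n denoting parcels.
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 index -> world affine (0-based indices, RAS mm).
#' @param n_parcels For `label_image`, the parcel count n; defaults to
#'   the maximum label present.
#' @return Object of class `scalar_image`, `binary_mask`, or `label_image`.
#' @export
scalar_image <- function(data, affine = diag(4)) {
  data <- as.array(data)
  stopifnot(length(dim(data)) == 3L)
  grid <- ref_grid(dim(data), affine)
  structure(list(data = data, affine = grid$affine,
                 voxel_size = grid$voxel_size),
            class = "scalar_image")
}

#' @rdname scalar_image
#' @export
binary_mask <- function(data, affine = diag(4)) {
  img <- scalar_image(data, affine)
  if (!all(img$data %in% c(0, 1)))
    stop("mask data must be binary (0/1)")
  class(img) <- c("binary_mask", "scalar_image")
  img
}

#' @rdname scalar_image
#' @export
label_image <- function(data, affine = diag(4), n_parcels = NULL) {
  img <- scalar_image(data, affine)
  v <- img$data
  if (any(v < 0) || any(v != round(v)))
    stop("label data must be non-negative integers")
  if (is.null(n_parcels)) n_parcels <- max(0L, max(v))
  if (max(v) > n_parcels) stop("labels exceed n_parcels")
  img$n_parcels <- as.integer(n_parcels)
  class(img) <- c("label_image", "scalar_image")
  img
}

#' Streamline and tractogram constructors
#'
#' A streamline is an ordered 3-D polyline in world millimetre
#' coordinates; a tractogram bundles streamlines with the reference grid
#' they are co-registered to.
#'
#' @param points Numeric matrix, one row per point, 3 columns (RAS mm).
#' @return `streamline`: validated n x 3 matrix.
#' @export
streamline <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("streamline points must be n x 3")
  if (nrow(points) < 2L) stop("streamline needs at least 2 points")
  if (!all(is.finite(points))) stop("streamline coordinates must be finite")
  seg <- diff(points)
  if (any(rowSums(seg^2) == 0)) stop("consecutive streamline points must be distinct")
  dimnames(points) <- NULL
  structure(points, class = "streamline")
}

#' @rdname streamline
#' @param streamlines List of streamlines (n x 3 matrices).
#' @param reference A `ref_grid` (or an image to borrow the grid from).
#' @export
tractogram <- function(streamlines, reference) {
  if (inherits(reference, "scalar_image"))
    reference <- ref_grid(dim(reference$data), reference$affine)
  stopifnot(inherits(reference, "ref_grid"))
  streamlines <- lapply(streamlines, function(s) {
    if (!inherits(s, "streamline")) s <- streamline(s)
    s
  })
  structure(list(streamlines = streamlines, reference = reference),
            class = "tractogram")
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' @export
print.tractogram <- function(x, ...) {
  np <- vapply(x$streamlines, nrow, integer(1))
  cat(sprintf("Tractogram: %d streamlines (%d-%d points) on %s grid\n",
              length(np), if (length(np)) min(np) else 0L,
              if (length(np)) max(np) else 0L,
              paste(x$reference$shape, collapse = "x")))
  invisible(x)
}

# ---- coordinate transforms -------------------------------------------------

#' Convert between world (mm) and continuous voxel-index coordinates
#'
#' Indices are 0-based with voxel centers at integer indices; conversion
#' goes through the image affine, so anisotropic and oblique grids are
#' handled. Out-of-grid points simply map to out-of-range indices.
#'
#' @param x A `scalar_image`, `ref_grid`, or 4x4 affine.
#' @param points n x 3 matrix of world coordinates (mm) or indices.
#' @return n x 3 matrix of continuous indices (or world coordinates).
#' @export
world_to_index <- function(x, points) {
  affine <- .as_affine(x)
  points <- .as_points(points)
  ph <- cbind(points, 1)
  out <- t(solve(affine) %*% t(ph))[, 1:3, drop = FALSE]
  dimnames(out) <- NULL
  out
}

#' @rdname world_to_index
#' @export
index_to_world <- function(x, points) {
  affine <- .as_affine(x)
  points <- .as_points(points)
  out <- t(affine %*% t(cbind(points, 1)))[, 1:3, drop = FALSE]
  dimnames(out) <- NULL
  out
}

.as_affine <- function(x) {
  if (is.matrix(x) && all(dim(x) == c(4, 4))) return(x)
  if (inherits(x, "ref_grid") || inherits(x, "scalar_image")) return(x$affine)
  stop("cannot extract an affine from this object")
}

.as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  as.matrix(points)
}

# Nearest-voxel membership: round half down so ties break toward the
# lower index (required for reproducible rasterization).
.round_index <- function(idx) ceiling(idx - 0.5)

#' World coordinates of all nonzero voxels in a mask
#'
#' Returns one world coordinate per nonzero voxel, at the voxel center,
#' in deterministic lexicographic index order (first axis fastest is NOT
#' used; ordering is lexicographic in (i, j, k)).
#'
#' @param mask A `binary_mask` (or any image; nonzero voxels are used).
#' @return n x 3 matrix of world coordinates (mm).
#' @export
voxel_centers <- function(mask) {
  idx <- which(mask$data != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty")
  idx0 <- idx - 1L                          # 0-based
  ord <- order(idx0[, 1], idx0[, 2], idx0[, 3])
  index_to_world(mask$affine, idx0[ord, , drop = FALSE])
}

# ---- NIfTI I/O -------------------------------------------------------------

#' Read and write volumetric neuroimaging files (NIfTI)
#'
#' Voxel data and the index->world affine are taken from the NIfTI
#' header (sform/qform). `type = "mask"` validates the volume as binary,
#' `type = "label"` as non-negative integer labels.
#'
#' @param path File path (.nii or .nii.gz).
#' @param type One of "scalar", "mask", "label".
#' @return A `scalar_image`, `binary_mask`, or `label_image`.
#' @export
read_image <- function(path, type = c("scalar", "mask", "label")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  nii <- RNifti::readNifti(path)
  aff <- RNifti::xform(nii)
  attributes(aff) <- list(dim = dim(aff))
  dat <- array(as.numeric(nii), dim = dim(nii))
  if (length(dim(dat)) == 2L) dim(dat) <- c(dim(dat), 1L)
  switch(type,
         scalar = scalar_image(dat, aff),
         mask = binary_mask(dat, aff),
         label = label_image(dat, aff))
}

#' @rdname read_image
#' @param img Image to write.
#' @export
write_image <- function(img, path) {
  nii <- RNifti::asNifti(img$data)
  # sform only: the quaternion qform cannot represent shear and would
  # take precedence over the exact matrix on re-read
  nii <- RNifti::`sform<-`(nii, structure(img$affine, code = 2L))
  RNifti::writeNifti(nii, path)
  invisible(path)
}

# ---- tractogram I/O --------------------------------------------------------

#' Read a tractogram (TRK or TCK)
#'
#' Streamlines are returned in RAS world millimetres regardless of the
#' on-disk convention: TRK stores corner-based voxel-mm coordinates that
#' are mapped through the header affine on load; TCK already stores
#' world mm. The reference grid comes from the TRK header; TCK files
#' carry no grid, so a `reference` (or image) must be supplied for
#' operations that need one.
#'
#' @param path File path ending in .trk or .tck.
#' @param reference Optional `ref_grid` or image; required to fully
#'   populate the reference for TCK files (defaults to a unit grid).
#' @return A `tractogram`.
#' @export
read_tractogram <- function(path, reference = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  tg <- switch(ext,
               trk = .read_trk(path),
               tck = .read_tck(path, reference),
               stop("unrecognized tractogram format: .", ext))
  if (length(tg$streamlines) == 0L) stop("tractogram contains no streamlines")
  tg
}

#' @rdname read_tractogram
#' @param t Tractogram to write; format chosen by the file extension.
#' @export
write_tractogram <- function(t, path) {
  stopifnot(inherits(t, "tractogram"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         trk = .write_trk(t, path),
         tck = .write_tck(t, path),
         stop("unrecognized tractogram format: .", ext))
  invisible(path)
}

# TrackVis .trk, header version 2 (1000-byte header, little endian).
# Points on disk are "voxmm": voxel indices scaled by voxel size, with
# the voxel *corner* at the origin; world = affine %*% (p / vs - 0.5).
.read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 6L))
  if (!startsWith(magic, "TRACK")) stop("not a TRK file (bad magic)")
  dim3 <- readBin(con, "integer", 3L, size = 2L, endian = "little")
  vs <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  readBin(con, "numeric", 3L, size = 4L, endian = "little")   # origin (unused)
  n_scalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)                                   # scalar names
  n_props <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)                                   # property names
  vox2ras <- matrix(readBin(con, "numeric", 16L, size = 4L, endian = "little"),
                    4, 4, byrow = TRUE)
  readBin(con, "raw", 444L + 4L + 4L + 24L + 2L + 6L)         # reserved..pads
  n_count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (hdr_size != 1000L) stop("unsupported TRK header size: ", hdr_size)
  if (all(vox2ras == 0)) {                                    # legacy header
    vox2ras <- diag(4)
    vox2ras[1:3, 1:3] <- diag(vs)
  }
  streamlines <- list()
  repeat {
    npts <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(npts) == 0L) break
    need <- npts * (3L + n_scalars)
    vals <- readBin(con, "numeric", need, size = 4L, endian = "little")
    if (length(vals) < need) stop("truncated TRK file")
    props <- readBin(con, "numeric", n_props, size = 4L, endian = "little")
    if (n_props > 0L && length(props) < n_props) stop("truncated TRK file")
    pts <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    idx <- sweep(sweep(pts, 2, vs, "/"), 2, 0.5, "-")
    streamlines[[length(streamlines) + 1L]] <- index_to_world(vox2ras, idx)
  }
  if (n_count > 0L && length(streamlines) != n_count)
    stop("truncated TRK file: expected ", n_count, " streamlines, read ",
         length(streamlines))
  tractogram(streamlines, ref_grid(dim3, vox2ras))
}

.write_trk <- function(t, path) {
  ref <- t$reference
  vs <- ref$voxel_size
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), raw(1L)), con)
  writeBin(as.integer(ref$shape), con, size = 2L, endian = "little")
  writeBin(as.numeric(vs), con, size = 4L, endian = "little")
  writeBin(numeric(3), con, size = 4L, endian = "little")       # origin
  writeBin(0L, con, size = 2L, endian = "little")               # n_scalars
  writeBin(raw(200L), con)
  writeBin(0L, con, size = 2L, endian = "little")               # n_properties
  writeBin(raw(200L), con)
  writeBin(as.numeric(t(ref$affine)), con, size = 4L, endian = "little")
  writeBin(raw(444L), con)                                      # reserved
  writeBin(c(charToRaw("RAS"), raw(1L)), con)                   # voxel_order
  writeBin(raw(4L + 24L + 2L + 6L), con)                        # pads/flags
  writeBin(length(t$streamlines), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")               # version
  writeBin(1000L, con, size = 4L, endian = "little")
  inv <- solve(ref$affine)
  for (s in t$streamlines) {
    idx <- index_to_world(inv, s)                               # world -> index
    voxmm <- sweep(sweep(idx, 2, 0.5, "+"), 2, vs, "*")
    writeBin(nrow(s), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

# MRtrix .tck: ASCII header terminated by END, then Float32LE triples,
# streamlines separated by NaN triples, stream terminated by Inf triple.
# Coordinates are already RAS world mm.
.read_tck <- function(path, reference = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- .read_line(con)
  if (!identical(first, "mrtrix tracks")) stop("not a TCK file (bad magic)")
  offset <- NA_integer_
  dtype <- "Float32LE"
  repeat {
    ln <- .read_line(con)
    if (is.null(ln)) stop("truncated TCK header")
    if (identical(ln, "END")) break
    kv <- regmatches(ln, regexpr(":", ln), invert = TRUE)[[1]]
    if (length(kv) == 2L) {
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (key == "file") offset <- as.integer(sub("^\\.\\s+", "", val))
      if (key == "datatype") dtype <- val
    }
  }
  if (is.na(offset)) stop("TCK header missing file offset")
  if (dtype != "Float32LE") stop("unsupported TCK datatype: ", dtype)
  seek(con, offset)
  raw_vals <- readBin(con, "numeric", file.size(path), size = 4L,
                      endian = "little")
  m <- matrix(raw_vals[seq_len(3L * (length(raw_vals) %/% 3L))],
              ncol = 3L, byrow = TRUE)
  fin <- which(!is.finite(m[, 1]) & !is.finite(m[, 2]) & !is.finite(m[, 3]))
  if (length(fin) == 0L || !any(is.infinite(m[fin[length(fin)], ])))
    stop("truncated TCK file: missing terminator")
  streamlines <- list(); start <- 1L
  for (i in fin) {
    if (i > start) {
      streamlines[[length(streamlines) + 1L]] <- m[start:(i - 1L), , drop = FALSE]
    }
    start <- i + 1L
    if (any(is.infinite(m[i, ]))) break
  }
  if (is.null(reference)) reference <- ref_grid(c(1L, 1L, 1L), diag(4))
  tractogram(streamlines, reference)
}

.read_line <- function(con) {
  chars <- character(0)
  repeat {
    b <- readBin(con, "raw", 1L)
    if (length(b) == 0L) return(NULL)
    if (b == as.raw(10L)) break
    chars <- c(chars, rawToChar(b))
  }
  paste(chars, collapse = "")
}

.write_tck <- function(t, path) {
  n <- length(t$streamlines)
  hdr_fmt <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ", n,
                    "\nfile: . %d\nEND\n")
  hdr <- sprintf(hdr_fmt, 0L)
  hdr <- sprintf(hdr_fmt, nchar(hdr, type = "bytes") +
                   (nchar(sprintf("%d", nchar(hdr, type = "bytes"))) - 1L))
  # stabilize: recompute until self-consistent (offset digits can grow)
  repeat {
    off <- nchar(hdr, type = "bytes")
    hdr2 <- sprintf(hdr_fmt, off)
    if (nchar(hdr2, type = "bytes") == off) { hdr <- hdr2; break }
    hdr <- hdr2
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  for (s in t$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}
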