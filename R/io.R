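# Volume and sinogram I/O (NIfTI via RNifti, or raw float32 with a YAML
# sidecar), and the dynamic frame-schedule parser.

.sidecarPath <- function(path) paste0(tools::file_path_sans_ext(path),
                                      ".yaml")

#' Read and write volumes
#'
#' Supported formats, chosen by extension: NIfTI (`.nii`, `.nii.gz`;
#' voxel size and origin stored in the qform) and raw little-endian
#' float32 (`.raw`) with a YAML sidecar carrying shape, voxel size,
#' origin and kind.  Raw round trips are bitwise lossless for float32
#' data; NIfTI does not record `kind` (pass it to `readVolume`).
#'
#' @param vol a [VoxelGrid-class].
#' @param path file path.
#' @param kind override the volume kind on read.
#' @return `writeVolume` returns `path` invisibly; `readVolume` a
#'   [VoxelGrid-class].
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "VoxelGrid"))
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::asNifti(vol@values)
    RNifti::pixdim(img) <- vol@voxelSize
    xf <- diag(c(vol@voxelSize, 1))
    xf[1:3, 4] <- vol@origin
    RNifti::qform(img) <- structure(xf, code = 2L)
    RNifti::writeNifti(img, path)
  } else if (ext == "raw") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.vector(vol@values), con, size = 4L, endian = "little")
    yaml::write_yaml(list(format = "raw-float32",
                          shape = as.integer(dim(vol)),
                          voxel_size = as.numeric(vol@voxelSize),
                          origin = as.numeric(vol@origin),
                          kind = vol@kind),
                     .sidecarPath(path), precision = 15L)
  } else stop(sprintf("writeVolume: unsupported format '%s'", ext))
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path, kind = NULL) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    img <- RNifti::readNifti(path)
    vox <- RNifti::pixdim(img)[1:3]
    xf <- RNifti::xform(img)
    origin <- xf[1:3, 4]
    VoxelGrid(array(as.numeric(img), dim = dim(img)[1:3]), vox, origin,
              kind %||% "activity")
  } else if (ext == "raw") {
    sc <- yaml::read_yaml(.sidecarPath(path))
    n <- prod(sc$shape)
    if (file.info(path)$size != 4 * n)
      stop(sprintf(
        "readVolume: raw file has %d bytes but sidecar shape needs %d",
        file.info(path)$size, 4 * n))
    con <- file(path, "rb")
    on.exit(close(con))
    v <- readBin(con, numeric(), n = n, size = 4L, endian = "little")
    VoxelGrid(array(v, dim = sc$shape), unlist(sc$voxel_size),
              unlist(sc$origin), kind %||% sc$kind)
  } else stop(sprintf("readVolume: unsupported format '%s'", ext))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write sinograms
#'
#' Raw little-endian float32 with a YAML sidecar (angles, radial binning,
#' subset partition, simulation seed).
#'
#' @param proj a [ProjectionData-class].
#' @param path `.raw` file path.
#' @return `writeProjection` returns `path` invisibly; `readProjection` a
#'   [ProjectionData-class].
#' @export
writeProjection <- function(proj, path) {
  stopifnot(is(proj, "ProjectionData"))
  g <- proj@geometry
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(proj@values), con, size = 4L, endian = "little")
  yaml::write_yaml(list(format = "raw-float32-sinogram",
                        n_radial = g@nRadial,
                        radial_spacing = g@radialSpacing,
                        angles = as.numeric(g@angles),
                        n_slices = g@nSlices,
                        subsets = lapply(proj@subsets, as.integer),
                        seed = proj@meta$seed),
                   .sidecarPath(path), precision = 15L)
  invisible(path)
}

#' @rdname writeProjection
#' @export
readProjection <- function(path) {
  sc <- yaml::read_yaml(.sidecarPath(path))
  nAngles <- length(sc$angles)
  n <- sc$n_radial * nAngles * sc$n_slices
  if (file.info(path)$size != 4 * n)
    stop("readProjection: raw file size disagrees with sidecar")
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = n, size = 4L, endian = "little")
  geom <- new("ProjectionGeometry", angles = unlist(sc$angles),
              nRadial = as.integer(sc$n_radial),
              radialSpacing = sc$radial_spacing,
              nSlices = as.integer(sc$n_slices))
  new("ProjectionData",
      values = array(v, dim = c(sc$n_radial, nAngles, sc$n_slices)),
      geometry = geom, subsets = lapply(sc$subsets, as.integer),
      meta = list(seed = sc$seed))
}

#' Parse a dynamic frame schedule
#'
#' Parses the compact `"NxS"` notation (`N` frames of `S` seconds,
#' comma-separated), e.g. `"1x6,6x2,2x5,1x10,1x20,3x30,1x452"`, into a
#' [FrameSchedule-class].  The schedule's own total duration and the
#' discarded start interval are reported separately and never
#' reconciled.
#'
#' @param text schedule string matching `Nxs(,Nxs)*`.
#' @param discard interval discarded at the start of the scan, seconds.
#' @return A [FrameSchedule-class].
#' @export
parseFrameSchedule <- function(text, discard = 0) {
  parts <- strsplit(text, ",", fixed = TRUE)[[1]]
  counts <- integer(length(parts))
  durations <- numeric(length(parts))
  for (i in seq_along(parts)) {
    m <- regmatches(parts[i],
                    regexec("^([0-9]+)x([0-9]*\\.?[0-9]+)$", parts[i]))[[1]]
    if (length(m) != 3L)
      stop(sprintf("parseFrameSchedule: malformed token '%s' at position %d",
                   parts[i], i))
    counts[i] <- as.integer(m[2])
    durations[i] <- as.numeric(m[3])
    if (counts[i] < 1L)
      stop(sprintf(
        "parseFrameSchedule: frame count must be >= 1 at position %d", i))
    if (durations[i] <= 0)
      stop(sprintf(
        "parseFrameSchedule: duration must be > 0 at position %d", i))
  }
  new("FrameSchedule", counts = counts, durations = durations,
      discard = as.numeric(discard))
}

#' Frame boundaries of a schedule
#'
#' @param schedule a [FrameSchedule-class].
#' @return data.frame with `start` and `end` seconds per expanded frame,
#'   starting after the discarded interval.
#' @export
frameTimes <- function(schedule) {
  stopifnot(is(schedule, "FrameSchedule"))
  durs <- rep(schedule@durations, schedule@counts)
  ends <- schedule@discard + cumsum(durs)
  data.frame(start = c(schedule@discard, head(ends, -1)), end = ends)
}
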