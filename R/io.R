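#' Read a 3D volume from NIfTI
#'
#' Reads a `.nii`/`.nii.gz` file into a [volume_grid()], taking voxel spacing
#' from the NIfTI header. The array axis order is kept as stored, interpreted
#' as `(depth, height, width)` under the package's axis convention.
#'
#' @param path file path.
#' @param kind volume kind; label volumes are rounded to integers.
#' @return a [volume_grid()].
#' @export
read_volume <- function(path, kind = c("intensity", "label", "probability")) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- array(as.vector(img), dim(img))  # plain array, header dropped
  if (kind == "label") {
    arr <- round(arr)
    storage.mode(arr) <- "integer"
  }
  volume_grid(arr, sp, kind)
}

#' Write a 3D volume to NIfTI
#'
#' Writes a [volume_grid()] to `.nii.gz`, preserving voxel spacing in the
#' header. Label maps are written as integers and round-trip losslessly.
#'
#' @param vol a [volume_grid()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot_volume(vol)
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing_mm
  RNifti::writeNifti(img, path,
                     datatype = if (vol$kind == "label") "int16" else "float")
  if (!file.exists(path)) stop("failed to write ", path)
  invisible(path)
}

#' Read / write a centroid table
#'
#' Centroid tables are JSON arrays of `{"label": k, "voxel": [d, h, w]}` with
#' 0-based (possibly fractional) voxel coordinates.
#'
#' @param centroids data.frame with columns `label`, `d`, `h`, `w`.
#' @param path file path.
#' @return `read_centroids` returns the data.frame; `write_centroids` returns
#'   `path` invisibly.
#' @export
write_centroids <- function(centroids, path) {
  recs <- lapply(seq_len(nrow(centroids)), function(i) {
    list(label = centroids$label[i],
         voxel = c(centroids$d[i], centroids$h[i], centroids$w[i]))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_centroids
#' @export
read_centroids <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  do.call(rbind, lapply(recs, function(r) {
    v <- unlist(r$voxel)
    data.frame(label = as.integer(r$label), d = v[1], h = v[2], w = v[3])
  }))
}
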