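#' 3D volume grid
#'
#' A minimal container for a 3D scalar grid with physical voxel spacing and a
#' declared kind. The fixed axis convention throughout the package is
#' `(depth, height, width)` with depth the cranio-caudal axis; voxel indexing
#' in all coordinate tables is 0-based.
#'
#' @param data 3D numeric array, dim `(depth, height, width)`.
#' @param spacing_mm positive numeric length 1 (isotropic) or 3, voxel size
#'   in millimetres per axis.
#' @param kind one of `"intensity"` (raw HU-like values), `"label"`
#'   (non-negative integer anatomical indices, 0 = background) or
#'   `"probability"` (values in \[0, 1\]).
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(data, spacing_mm = 1, kind = c("intensity", "label", "probability")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (depth, height, width)")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive finite values")
  if (kind == "label") {
    if (any(data < 0) || any(data != round(data)))
      stop("label volumes must hold non-negative integers")
    storage.mode(data) <- "integer"
  } else {
    storage.mode(data) <- "double"
    if (kind == "probability" && (min(data) < 0 || max(data) > 1))
      stop("probability volumes must lie in [0, 1]")
  }
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm), kind = kind),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %s> %s voxels @ %s mm\n", x$kind,
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x")))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

is_volume_grid <- function(x) inherits(x, "volume_grid")

stopifnot_volume <- function(x, kind = NULL) {
  if (!is_volume_grid(x)) stop("expected a `volume_grid`")
  if (!is.null(kind) && !(x$kind %in% kind))
    stop(sprintf("expected a volume of kind %s, got %s",
                 paste(kind, collapse = "/"), x$kind))
  invisible(x)
}
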