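#' Construct an intensity volume
#'
#' Wraps a 3D numeric array of grey-matter density values with grid metadata.
#' Values must be finite and non-negative; the axis convention declares which
#' positive grid direction means right, anterior and superior so that the
#' neighbour order used by the pattern encoding is well defined.
#'
#' @param values 3D numeric array, finite and >= 0.
#' @param voxel_size_mm length-3 positive numeric, edge lengths in mm.
#' @param axis_convention named character vector declaring the anatomical
#'   meaning of the positive x, y, z grid directions. Default RAS-style:
#'   \code{c(x = "right", y = "anterior", z = "superior")}.
#' @return An \code{intensity_volume}: the array with class and metadata
#'   attributes.
#' @export
intensity_volume <- function(values,
                             voxel_size_mm = c(1, 1, 1),
                             axis_convention = c(x = "right",
                                                 y = "anterior",
                                                 z = "superior")) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (any(!is.finite(values)))
    stop("intensity values must all be finite", call. = FALSE)
  if (any(values < 0))
    stop("intensity values must be non-negative", call. = FALSE)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be three positive numbers", call. = FALSE)
  stopifnot(all(c("x", "y", "z") %in% names(axis_convention)))
  structure(values,
            voxel_size_mm = as.numeric(voxel_size_mm),
            axis_convention = axis_convention[c("x", "y", "z")],
            class = c("intensity_volume", "array"))
}

#' @export
print.intensity_volume <- function(x, ...) {
  d <- dim(x)
  cat("<intensity_volume> ", paste(d, collapse = " x "),
      " voxels, ", paste(attr(x, "voxel_size_mm"), collapse = "x"),
      " mm\n", sep = "")
  ac <- attr(x, "axis_convention")
  cat("  axes: +x=", ac[["x"]], ", +y=", ac[["y"]], ", +z=", ac[["z"]], "\n",
      sep = "")
  cat("  range: [", format(min(x)), ", ", format(max(x)), "]\n", sep = "")
  invisible(x)
}

# Accept either an intensity_volume or a bare 3D array; return the array.
as_volume_array <- function(volume) {
  if (inherits(volume, "intensity_volume")) return(unclass(volume))
  if (is.array(volume) && length(dim(volume)) == 3L) {
    if (any(!is.finite(volume)))
      stop("intensity values must all be finite", call. = FALSE)
    return(volume)
  }
  stop("expected an intensity_volume or a 3D array", call. = FALSE)
}

# Validate a grey-matter mask against a volume's dimensions.
as_mask_array <- function(mask, dims) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D logical array", call. = FALSE)
  if (!identical(dim(mask), as.integer(dims)))
    stop(sprintf("mask shape (%s) does not match volume shape (%s)",
                 paste(dim(mask), collapse = "x"),
                 paste(dims, collapse = "x")), call. = FALSE)
  m <- array(as.logical(mask), dim(mask))
  if (any(is.na(m))) stop("mask contains missing values", call. = FALSE)
  m
}
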