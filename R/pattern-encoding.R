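# Neighbour order is fixed: right, left, anterior, posterior, superior,
# inferior. The first symbol (right) is the most significant bit of the
# 6-bit pattern code, so codes read in the same order the symbols are listed.
PATTERN_BIT_WEIGHTS <- c(32L, 16L, 8L, 4L, 2L, 1L)
NEIGHBOUR_ORDER <- c("right", "left", "anterior", "posterior",
                     "superior", "inferior")

#' Encode one voxel's structural pattern index
#'
#' Compares a centre intensity against its six neighbours in the fixed order
#' right, left, anterior, posterior, superior, inferior. Each comparison
#' yields symbol 1 when centre >= neighbour (ties count as 1) and 0
#' otherwise; the six symbols form a binary string read with the first
#' (right) symbol as the most significant bit, giving an integer in 0..63.
#'
#' @param center numeric scalar, the voxel's intensity.
#' @param neighbors numeric length-6, neighbour intensities in the order
#'   right, left, anterior, posterior, superior, inferior.
#' @return Integer pattern code in \code{[0, 63]}.
#' @examples
#' encode_pattern(1, rep(0, 6))        # 63: all comparisons hold
#' encode_pattern(5, c(3, 7, 5, 6, 1, 5))  # binary 101011 -> 43
#' @export
encode_pattern <- function(center, neighbors) {
  if (length(center) != 1L || length(neighbors) != 6L)
    stop("need one center value and exactly six neighbors", call. = FALSE)
  vals <- c(center, neighbors)
  if (!is.numeric(vals) || any(!is.finite(vals)))
    stop("all intensities must be finite numbers", call. = FALSE)
  bits <- as.integer(center >= neighbors)
  sum(bits * PATTERN_BIT_WEIGHTS)
}

#' Decode a pattern index into its six comparison symbols
#'
#' Inverse of \code{\link{encode_pattern}}: returns the binary relation
#' vector (S1..S6) for a code, named by neighbour direction.
#'
#' @param code integer vector of codes in \code{[0, 63]}.
#' @return Integer matrix, one row per code, columns named right..inferior.
#' @export
decode_pattern <- function(code) {
  code <- as.integer(code)
  if (any(is.na(code) | code < 0L | code > 63L))
    stop("codes must be integers in [0, 63]", call. = FALSE)
  bits <- vapply(PATTERN_BIT_WEIGHTS,
                 function(w) (code %/% w) %% 2L,
                 integer(length(code)))
  bits <- matrix(bits, nrow = length(code), ncol = 6L)
  colnames(bits) <- NEIGHBOUR_ORDER
  bits
}

#' Compute the voxel-wise structural pattern index map
#'
#' Encodes every mask voxel of a grey-matter density volume. The working
#' grid is the volume with out-of-mask voxels set to zero, zero-padded by
#' one layer on every face, so each mask voxel has six defined neighbour
#' values and boundary contrast against the zero background is preserved.
#' Voxels outside the mask carry no code (NA in the returned map).
#'
#' @param volume an \code{\link{intensity_volume}} or bare 3D array.
#' @param mask 3D logical array of the same shape, or NULL to derive the
#'   mask by thresholding the volume (\code{volume > mask_threshold}).
#' @param mask_threshold numeric, threshold used when \code{mask} is NULL.
#' @return A \code{pattern_map}: integer 3D array with values 0..63 at mask
#'   voxels and NA elsewhere, with \code{mask} and encoding metadata attached.
#' @examples
#' v <- array(runif(27), c(3, 3, 3))
#' pm <- compute_pattern_map(v)
#' table(pm[!is.na(pm)])
#' @export
compute_pattern_map <- function(volume, mask = NULL, mask_threshold = 0) {
  v <- as_volume_array(volume)
  d <- dim(v)
  if (is.null(mask)) {
    mask <- v > mask_threshold
  } else {
    mask <- as_mask_array(mask, d)
  }
  if (!any(mask)) stop("mask is empty: no voxels to encode", call. = FALSE)

  work <- v
  work[!mask] <- 0

  # one-layer zero pad on every face
  pad <- array(0, d + 2L)
  ix <- seq_len(d[1]) + 1L
  iy <- seq_len(d[2]) + 1L
  iz <- seq_len(d[3]) + 1L
  pad[ix, iy, iz] <- work

  ctr <- pad[ix, iy, iz]
  codes <- 32L * (ctr >= pad[ix + 1L, iy, iz]) +  # right  (+x)
           16L * (ctr >= pad[ix - 1L, iy, iz]) +  # left   (-x)
            8L * (ctr >= pad[ix, iy + 1L, iz]) +  # anterior (+y)
            4L * (ctr >= pad[ix, iy - 1L, iz]) +  # posterior (-y)
            2L * (ctr >= pad[ix, iy, iz + 1L]) +  # superior (+z)
            1L * (ctr >= pad[ix, iy, iz - 1L])    # inferior (-z)
  codes <- array(as.integer(codes), d)
  codes[!mask] <- NA_integer_

  structure(codes,
            mask = mask,
            bit_order = NEIGHBOUR_ORDER,
            msb = NEIGHBOUR_ORDER[1L],
            class = c("pattern_map", "array"))
}

#' @export
print.pattern_map <- function(x, ...) {
  n <- sum(!is.na(x))
  cat("<pattern_map> ", paste(dim(x), collapse = " x "),
      " grid, ", n, " coded voxels\n", sep = "")
  cat("  bit order (MSB first): ",
      paste(attr(x, "bit_order"), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Interior of a mask: voxels whose six neighbours are all in-mask
#'
#' The closed-form marginal law of the pattern codes under i.i.d.
#' intensities (P(code with k ones) = k!(6-k)!/7!) holds for voxels whose
#' seven values are all random draws, i.e. the mask interior; voxels
#' bordering the zero pad are biased toward 1-bits by construction.
#'
#' @param mask 3D logical array.
#' @return logical array flagging mask voxels with six in-mask neighbours.
#' @export
interior_mask <- function(mask) {
  m <- as_mask_array(mask, dim(mask))
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  ix <- seq_len(d[1]) + 1L; iy <- seq_len(d[2]) + 1L
  iz <- seq_len(d[3]) + 1L
  pad[ix, iy, iz] <- m
  m & pad[ix + 1L, iy, iz] & pad[ix - 1L, iy, iz] &
    pad[ix, iy + 1L, iz] & pad[ix, iy - 1L, iz] &
    pad[ix, iy, iz + 1L] & pad[ix, iy, iz - 1L]
}
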