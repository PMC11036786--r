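# Derive a per-(region, surrogate) RNG seed from the master seed so results
# do not depend on the order regions are processed. n_surrogates is assumed
# < 7919, keeping streams distinct per region.
derive_seed <- function(seed, region, surrogate) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(region) +
                as.numeric(surrogate)) %% 2147483647)
}

#' Spatially shuffled surrogate of a region
#'
#' Permutes the intensities at the region's voxels uniformly at random
#' among those voxels, leaving everything outside the region unchanged.
#' The multiset of region intensities is preserved exactly; only the
#' spatial arrangement is disrupted.
#'
#' @param volume an \code{\link{intensity_volume}} or 3D array.
#' @param region_mask 3D logical array flagging the region's voxels
#'   (at least 2).
#' @param seed optional integer; when given, the permutation is drawn from
#'   a locally seeded RNG without disturbing the global RNG state.
#' @return A volume of the same class and shape with region intensities
#'   permuted.
#' @export
shuffle_surrogate <- function(volume, region_mask, seed = NULL) {
  v <- as_volume_array(volume)
  m <- as_mask_array(region_mask, dim(v))
  idx <- which(m)
  if (length(idx) < 2L)
    stop("degenerate region: need at least 2 voxels to shuffle",
         call. = FALSE)
  perm <- if (is.null(seed)) {
    sample.int(length(idx))
  } else {
    local_rng(seed, sample.int(length(idx)))
  }
  out <- v
  out[idx] <- v[idx][perm]
  if (inherits(volume, "intensity_volume")) {
    attributes(out) <- attributes(volume)
  }
  out
}

# Evaluate expr under a temporary RNG seeded with `seed`, restoring the
# caller's RNG state afterwards.
local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Structural nonrandomness index of one region
#'
#' Quantifies how far a region's spatial pattern organisation departs from
#' what intensity shuffling alone would produce. The region's bounding box
#' is extracted with all non-region voxels set to zero and encoding done
#' under a one-voxel zero pad (the regional zero-padded mask), so boundary
#' treatment is identical for the original and every surrogate. The index
#' is the mean IBS distance between the original pattern-word distribution
#' and the distributions of \code{n_surrogates} spatially shuffled
#' surrogates. High values mean regular organisation; low values mean
#' random-like structure.
#'
#' @param volume an \code{\link{intensity_volume}} or 3D array.
#' @param mask 3D logical grey-matter mask (NULL: volume > 0).
#' @param atlas an \code{atlas_labels} (NULL when \code{region_mask} given).
#' @param region integer region label in \code{atlas}.
#' @param n_surrogates number of shuffled surrogates (default 10).
#' @param seed master integer seed; per-surrogate streams are derived from
#'   it deterministically.
#' @param region_mask alternative to \code{atlas}+\code{region}: a 3D
#'   logical array flagging the region voxels directly.
#' @param shuffle_scope \code{"region"} (default) permutes within the
#'   region's own voxels; \code{"mask"} permutes across the whole
#'   grey-matter mask before re-extracting the region.
#' @return numeric index in \code{[0, 1]}, with attribute
#'   \code{surrogate_distances} retaining the per-surrogate values.
#' @export
nonrandomness_index <- function(volume, mask = NULL, atlas = NULL,
                                region = NULL, n_surrogates = 10L,
                                seed = 1L, region_mask = NULL,
                                shuffle_scope = c("region", "mask")) {
  shuffle_scope <- match.arg(shuffle_scope)
  v <- as_volume_array(volume)
  d <- dim(v)
  if (is.null(mask)) mask <- v > 0 else mask <- as_mask_array(mask, d)
  if (is.null(region_mask)) {
    if (is.null(atlas) || is.null(region))
      stop("supply either region_mask or atlas + region", call. = FALSE)
    check_atlas_shape(atlas, d)
    region_mask <- atlas$labels == region & mask
  } else {
    region_mask <- as_mask_array(region_mask, d) & mask
  }
  if (!any(region_mask))
    stop("region is empty after masking", call. = FALSE)
  if (sum(region_mask) < 2L)
    stop("degenerate region: need at least 2 voxels", call. = FALSE)
  n_surrogates <- as.integer(n_surrogates)
  if (is.na(n_surrogates) || n_surrogates < 1L)
    stop("n_surrogates must be a positive integer", call. = FALSE)

  # regional zero-padded sub-volume: non-region voxels contribute 0
  bb <- apply(which(region_mask, arr.ind = TRUE), 2L, range)
  sx <- bb[1, 1]:bb[2, 1]; sy <- bb[1, 2]:bb[2, 2]; sz <- bb[1, 3]:bb[2, 3]
  sub_mask <- region_mask[sx, sy, sz, drop = FALSE]
  dim(sub_mask) <- c(length(sx), length(sy), length(sz))
  sub_v <- v[sx, sy, sz, drop = FALSE]
  dim(sub_v) <- dim(sub_mask)
  sub_v[!sub_mask] <- 0

  encode_region <- function(vol) {
    pm <- compute_pattern_map(vol, sub_mask)
    tally_distribution(pm)
  }
  orig <- encode_region(sub_v)

  region_id <- if (is.null(region)) 0L else as.integer(region)
  dists <- vapply(seq_len(n_surrogates), function(s) {
    s_seed <- derive_seed(seed, region_id, s)
    if (shuffle_scope == "region") {
      surr <- shuffle_surrogate(sub_v, sub_mask, seed = s_seed)
    } else {
      whole <- shuffle_surrogate(v, mask, seed = s_seed)
      surr <- whole[sx, sy, sz, drop = FALSE]
      dim(surr) <- dim(sub_mask)
      surr[!sub_mask] <- 0
    }
    sd <- encode_region(surr)
    ibs_value(orig$prob, orig$rank, sd$prob, sd$rank)[["value"]]
  }, numeric(1L))

  structure(mean(dists), surrogate_distances = dists)
}

#' Per-region nonrandomness profile
#'
#' Applies \code{\link{nonrandomness_index}} to every atlas region (or a
#' subset) of one subject.
#'
#' @inheritParams nonrandomness_index
#' @param regions integer labels to evaluate (default: all atlas regions).
#' @param subject_id optional identifier recorded in the output table.
#' @return A \code{nonrandomness_profile}: data.frame with columns
#'   subject, region, index, n_surrogates, seed; per-surrogate distances
#'   kept in attribute \code{surrogate_distances}.
#' @export
nonrandomness_profile <- function(volume, mask = NULL, atlas,
                                  regions = NULL, n_surrogates = 10L,
                                  seed = 1L,
                                  subject_id = NA_character_) {
  stopifnot(inherits(atlas, "atlas_labels"))
  if (is.null(regions)) regions <- atlas$regions
  vals <- lapply(regions, function(r)
    nonrandomness_index(volume, mask = mask, atlas = atlas, region = r,
                        n_surrogates = n_surrogates, seed = seed))
  out <- data.frame(subject = subject_id,
                    region = regions,
                    index = vapply(vals, as.numeric, numeric(1L)),
                    n_surrogates = as.integer(n_surrogates),
                    seed = as.integer(seed))
  attr(out, "surrogate_distances") <-
    lapply(vals, attr, "surrogate_distances")
  class(out) <- c("nonrandomness_profile", "data.frame")
  out
}

#' @export
print.nonrandomness_profile <- function(x, ...) {
  cat("<nonrandomness_profile> ", nrow(x), " regions, ",
      x$n_surrogates[1L], " surrogates, seed ", x$seed[1L], "\n", sep = "")
  print.data.frame(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}
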