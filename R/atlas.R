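#' Construct an atlas parcellation
#'
#' An integer label volume (0 = background, labels 1..R for regions) plus a
#' region lookup table. Shapes are checked against subject volumes when the
#' atlas is used.
#'
#' @param labels 3D integer array of region labels.
#' @param region_table data.frame with columns \code{label},
#'   \code{abbrev}, \code{name}; must cover every nonzero label present.
#' @return An \code{atlas_labels} object.
#' @export
atlas_labels <- function(labels, region_table = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("atlas labels must be a 3D array", call. = FALSE)
  labels <- array(as.integer(labels), dim(labels))
  if (any(is.na(labels) | labels < 0L))
    stop("atlas labels must be non-negative integers", call. = FALSE)
  present <- sort(unique(labels[labels > 0L]))
  if (is.null(region_table)) {
    region_table <- data.frame(label = present,
                               abbrev = sprintf("R%03d", present),
                               name = sprintf("region_%d", present))
  }
  need <- c("label", "abbrev", "name")
  if (!all(need %in% names(region_table)))
    stop("region_table needs columns label, abbrev, name", call. = FALSE)
  missing <- setdiff(present, region_table$label)
  if (length(missing) > 0L)
    stop(sprintf("atlas labels absent from region table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  structure(list(labels = labels,
                 region_table = region_table[order(region_table$label), ,
                                             drop = FALSE],
                 regions = present),
            class = "atlas_labels")
}

#' @export
print.atlas_labels <- function(x, ...) {
  cat("<atlas_labels> ", paste(dim(x$labels), collapse = " x "),
      " grid, ", length(x$regions), " regions\n", sep = "")
  invisible(x)
}

check_atlas_shape <- function(atlas, dims) {
  if (!identical(dim(atlas$labels), as.integer(dims)))
    stop(sprintf("atlas shape (%s) does not match volume shape (%s)",
                 paste(dim(atlas$labels), collapse = "x"),
                 paste(dims, collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

region_name <- function(atlas, region) {
  i <- match(region, atlas$region_table$label)
  if (is.na(i)) as.character(region) else atlas$region_table$abbrev[i]
}

#' Word distribution of one atlas region
#'
#' Tallies the pattern codes of all coded (non-undefined) voxels whose
#' atlas label equals \code{region}.
#'
#' @param map a \code{pattern_map}.
#' @param atlas an \code{atlas_labels} on the same grid.
#' @param region integer region label.
#' @return A \code{word_distribution}.
#' @export
region_distribution <- function(map, atlas, region) {
  stopifnot(inherits(map, "pattern_map"), inherits(atlas, "atlas_labels"))
  check_atlas_shape(atlas, dim(map))
  if (!region %in% atlas$regions)
    stop(sprintf("region %s not present in atlas", region), call. = FALSE)
  codes <- unclass(map)[atlas$labels == region]
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0L)
    stop(sprintf("region %s (%s) contains no coded voxels",
                 region, region_name(atlas, region)), call. = FALSE)
  tally_distribution(codes)
}

#' Per-subject inter-regional similarity matrix
#'
#' Computes the IBS distance between the pattern-word distributions of
#' every pair of atlas regions: the subject's individual morphological
#' network. For R regions the symmetric matrix carries R(R-1)/2
#' informative values (R = 90 gives 4005).
#'
#' @param map a \code{pattern_map}.
#' @param atlas an \code{atlas_labels} on the same grid.
#' @param subject_id optional subject identifier stored on the result.
#' @return A \code{similarity_matrix}: symmetric R x R matrix of IBS
#'   distances with zero diagonal, region labels as dimnames.
#' @export
interregional_matrix <- function(map, atlas, subject_id = NA_character_) {
  stopifnot(inherits(map, "pattern_map"), inherits(atlas, "atlas_labels"))
  regions <- atlas$regions
  if (length(regions) < 2L)
    stop("need at least two atlas regions", call. = FALSE)
  dists <- lapply(regions, function(r) region_distribution(map, atlas, r))
  R <- length(regions)
  m <- matrix(0, R, R, dimnames = list(regions, regions))
  for (i in seq_len(R - 1L)) {
    for (j in seq(i + 1L, R)) {
      v <- ibs_value(dists[[i]]$prob, dists[[i]]$rank,
                     dists[[j]]$prob, dists[[j]]$rank)
      m[i, j] <- m[j, i] <- v[["value"]]
    }
  }
  structure(m, subject_id = subject_id,
            region_order = regions,
            class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  R <- nrow(x)
  off <- x[upper.tri(x)]
  cat("<similarity_matrix> ", R, " regions, ", length(off),
      " region pairs", sep = "")
  sid <- attr(x, "subject_id")
  if (!is.na(sid)) cat(", subject ", sid, sep = "")
  cat(sprintf("\n  IBS distance: median %.4f, range [%.4f, %.4f]\n",
              stats::median(off), min(off), max(off)))
  invisible(x)
}

#' @export
plot.similarity_matrix <- function(x, main = "Inter-regional IBS distance",
                                   ...) {
  R <- nrow(x)
  image(seq_len(R), seq_len(R), unclass(x)[, R:1, drop = FALSE],
        xlab = "region", ylab = "region", main = main, ...)
  invisible(x)
}

#' Long-format view of a similarity matrix
#'
#' @param x a \code{similarity_matrix}.
#' @return data.frame with columns region_i, region_j, distance (i < j).
#' @export
similarity_long <- function(x) {
  stopifnot(inherits(x, "similarity_matrix"))
  regions <- attr(x, "region_order")
  idx <- which(upper.tri(x), arr.ind = TRUE)
  data.frame(region_i = regions[idx[, 1L]],
             region_j = regions[idx[, 2L]],
             distance = x[idx])
}

#' Regional dissimilarity between two groups
#'
#' For one atlas region, averages the per-subject word probability vectors
#' within each group (equal subject weight), re-ranks each group-average
#' distribution, and returns the IBS distance between the two. Small values
#' mean the region's pattern organisation is similar across groups.
#'
#' @param maps_A,maps_B lists of \code{pattern_map} for the two groups.
#' @param atlas an \code{atlas_labels}.
#' @param region integer region label.
#' @return numeric IBS distance in \code{[0, 1]}.
#' @export
group_region_dissimilarity <- function(maps_A, maps_B, atlas, region) {
  if (length(maps_A) == 0L || length(maps_B) == 0L)
    stop("both groups must contain at least one subject", call. = FALSE)
  avg <- function(maps) {
    probs <- vapply(maps,
                    function(m) region_distribution(m, atlas, region)$prob,
                    numeric(64L))
    word_distribution_from_prob(rowMeans(probs))
  }
  da <- avg(maps_A)
  db <- avg(maps_B)
  ibs_distance(da, db, warn_disjoint = FALSE)$value
}

#' Regional group dissimilarity profile over all atlas regions
#'
#' Applies \code{\link{group_region_dissimilarity}} to every region,
#' in ascending label order.
#'
#' @inheritParams group_region_dissimilarity
#' @return named numeric vector of per-region IBS distances.
#' @export
group_dissimilarity_profile <- function(maps_A, maps_B, atlas) {
  vapply(atlas$regions,
         function(r) group_region_dissimilarity(maps_A, maps_B, atlas, r),
         numeric(1L)) |> setNames(atlas$regions)
}
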