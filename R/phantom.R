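# Parse a structure descriptor: "iid", "gradient[:(+|-)(x|y|z)]",
# "smoothed[:width]". Defaults: gradient along +x, smoothing half-width 1.
parse_structure <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1L]]
  type <- parts[1L]
  if (!type %in% c("iid", "gradient", "smoothed"))
    stop(sprintf("unknown region structure '%s'", s), call. = FALSE)
  arg <- if (length(parts) > 1L) parts[2L] else NULL
  if (type == "gradient") {
    dir <- if (is.null(arg)) "+x" else arg
    if (!dir %in% c("+x", "-x", "+y", "-y", "+z", "-z"))
      stop(sprintf("bad gradient direction '%s'", dir), call. = FALSE)
    list(type = "gradient", direction = dir)
  } else if (type == "smoothed") {
    w <- if (is.null(arg)) 1L else as.integer(arg)
    if (is.na(w) || w < 1L)
      stop("smoothing width must be a positive integer", call. = FALSE)
    list(type = "smoothed", width = w)
  } else {
    list(type = "iid")
  }
}

# Separable box filter (window 2w+1 per axis). Borders within w of the edge
# become NA; callers generate on a padded grid and crop.
box_smooth3d <- function(a, w) {
  k <- rep(1 / (2 * w + 1), 2 * w + 1)
  f <- function(v) as.numeric(stats::filter(v, k, sides = 2))
  a <- apply(a, c(2, 3), f)                      # along dim 1
  a <- aperm(apply(a, c(1, 3), f), c(2, 1, 3))   # along dim 2
  a <- aperm(apply(a, c(1, 2), f), c(2, 3, 1))   # along dim 3
  a
}

# Factor n into three integers with product n, as cubic as possible.
block_factors <- function(n) {
  best <- NULL
  for (a in seq_len(n)) {
    if (n %% a != 0L) next
    m <- n %/% a
    for (b in seq_len(m)) {
      if (m %% b != 0L) next
      f <- sort(c(a, b, m %/% b))
      if (is.null(best) || f[3] / f[1] < best[3] / best[1]) best <- f
    }
  }
  best
}

#' Specify a synthetic labelled phantom
#'
#' Describes a 3D phantom: an ellipsoidal "brain" of non-negative
#' intensities tiled into box-shaped atlas regions, each carrying one of
#' three spatial structures — \code{"iid"} (uniform noise),
#' \code{"gradient[:dir]"} (linear ramp plus small noise) or
#' \code{"smoothed[:w]"} (iid noise box-filtered at half-width w, the
#' spatial-autocorrelation analogue of smoothed grey-matter density maps).
#'
#' @param shape grid dimensions (default 30^3).
#' @param n_regions number of atlas regions tiling the ellipsoid
#'   (default 12).
#' @param structure character, one descriptor per region (recycled).
#'   Default \code{"smoothed:1"} for every region.
#' @param noise_sd additive Gaussian noise sd applied to every structure
#'   (default 0.05); intensities are clipped to [0, 1].
#' @param seed integer RNG seed.
#' @param min_region_voxels smallest admissible region (default 64).
#' @return A \code{phantom_spec} list.
#' @export
phantom_spec <- function(shape = c(30, 30, 30), n_regions = 12L,
                         structure = "smoothed:1", noise_sd = 0.05,
                         seed = 1L, min_region_voxels = 64L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L), n_regions >= 1L,
            noise_sd >= 0)
  structure_v <- rep_len(structure, n_regions)
  parsed <- lapply(structure_v, parse_structure)
  out <- list(shape = shape, n_regions = as.integer(n_regions),
              structure = structure_v, parsed = parsed,
              noise_sd = noise_sd, seed = as.integer(seed),
              min_region_voxels = as.integer(min_region_voxels))
  class(out) <- "phantom_spec"
  out
}

# Deterministic atlas geometry for a spec (no RNG involved): ellipsoid
# interior split into a block grid.
phantom_atlas <- function(spec) {
  d <- spec$shape
  ctr <- (d + 1) / 2
  semi <- d / 2 - 1.5
  x <- (seq_len(d[1]) - ctr[1]) / semi[1]
  y <- (seq_len(d[2]) - ctr[2]) / semi[2]
  z <- (seq_len(d[3]) - ctr[3]) / semi[3]
  r2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
  inside <- r2 <= 1
  nb <- block_factors(spec$n_regions)
  cut_axis <- function(n, k) {
    br <- round(seq(0, n, length.out = k + 1L))
    findInterval(seq_len(n), br, rightmost.closed = TRUE,
                 all.inside = TRUE)
  }
  bx <- cut_axis(d[1], nb[1]); by <- cut_axis(d[2], nb[2])
  bz <- cut_axis(d[3], nb[3])
  block <- outer(outer((bx - 1L), (by - 1L) * nb[1], "+"),
                 (bz - 1L) * nb[1] * nb[2], "+") + 1L
  labels <- array(0L, d)
  labels[inside] <- block[inside]
  counts <- tabulate(labels[labels > 0L], nbins = spec$n_regions)
  if (any(counts < spec$min_region_voxels))
    stop(sprintf(
      "regions too small to tile: smallest has %d voxels (need >= %d); enlarge the grid or reduce n_regions",
      min(counts), spec$min_region_voxels), call. = FALSE)
  atlas_labels(labels)
}

# Realise one region's intensity field at the given voxel index set.
realize_region <- function(values, idx, coords, parsed, noise_sd) {
  n <- length(idx)
  base <- switch(parsed$type,
    iid = runif(n),
    gradient = {
      ax <- match(substr(parsed$direction, 2L, 2L), c("x", "y", "z"))
      sgn <- if (substr(parsed$direction, 1L, 1L) == "+") 1 else -1
      pos <- coords[, ax]
      rng <- range(pos)
      t <- if (rng[2] > rng[1]) (pos - rng[1]) / (rng[2] - rng[1]) else
        rep(0.5, n)
      if (sgn < 0) t <- 1 - t
      0.1 + 0.8 * t
    },
    smoothed = {
      w <- parsed$width
      lo <- apply(coords, 2L, min); hi <- apply(coords, 2L, max)
      ext <- hi - lo + 1L + 2L * w
      field <- array(runif(prod(ext)), ext)
      sm <- box_smooth3d(field, w)
      core <- sm[(w + 1):(w + hi[1] - lo[1] + 1),
                 (w + 1):(w + hi[2] - lo[2] + 1),
                 (w + 1):(w + hi[3] - lo[3] + 1), drop = FALSE]
      # restore part of the pre-filter spread so widths stay comparable in
      # level without heavy clipping at the [0,1] bounds
      core <- (core - 0.5) * 0.5 * sqrt((2 * w + 1)^3) + 0.5
      core[cbind(coords[, 1] - lo[1] + 1L,
                 coords[, 2] - lo[2] + 1L,
                 coords[, 3] - lo[3] + 1L)]
    })
  vals <- base + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
  values[idx] <- pmin(pmax(vals, 0), 1)
  values
}

#' Generate a labelled phantom volume
#'
#' Realises a \code{\link{phantom_spec}}: deterministic under its seed,
#' intensities in [0, 1], background zero, each region's spatial structure
#' as declared.
#'
#' @param spec a \code{phantom_spec}.
#' @param seed optional override of the spec's seed.
#' @return list with \code{volume} (an \code{\link{intensity_volume}}),
#'   \code{atlas} (an \code{\link{atlas_labels}}) and \code{mask}
#'   (logical array, the labelled ellipsoid).
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(20, 20, 20), n_regions = 4))
#' table(ph$atlas$labels[ph$mask])
#' @export
generate_phantom <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  atlas <- phantom_atlas(spec)
  labels <- atlas$labels
  values <- array(0, spec$shape)
  # each region draws from its own derived stream, so two specs sharing a
  # seed produce identical fields in every region whose structure matches
  for (r in seq_len(spec$n_regions)) {
    idx <- which(labels == r)
    if (length(idx) == 0L) next
    coords <- which(labels == r, arr.ind = TRUE)
    values <- local_rng(derive_seed(seed, r, 0L),
                        realize_region(values, idx, coords,
                                       spec$parsed[[r]], spec$noise_sd))
  }
  list(volume = intensity_volume(values),
       atlas = atlas,
       mask = labels > 0L)
}

#' Specify a synthetic two-group cohort
#'
#' Describes a two-group imaging cohort built from
#' \code{\link{phantom_spec}} geometry: control subjects carry the base
#' structure in every region; case subjects carry \code{effect_structure}
#' in \code{effect_regions} and the base structure elsewhere. Cognitive
#' scores follow \code{intercept + sum(coef * z(nonrandomness)) + noise},
#' clipped to \code{score_range}; age, sex and education are drawn
#' identically in both groups.
#'
#' @param n_per_group subjects per group (default 20).
#' @param shape,n_regions,base_structure,noise_sd phantom geometry and
#'   baseline structure (defaults 30^3, 12 regions, \code{"smoothed:1"}).
#' @param effect_regions integer labels receiving the case-group effect.
#' @param effect_structure structure descriptor replacing the base in
#'   effect regions for cases (default \code{"smoothed:3"}, a coarser
#'   spatial autocorrelation).
#' @param score_model list(intercept, coef (named numeric, per region, on
#'   the z-scored nonrandomness scale), noise_sd). Default: intercept 27,
#'   no structural coefficients, noise sd 1.
#' @param score_range admissible score interval (default MMSE-like 0..30).
#' @param n_surrogates surrogates used when scores depend on
#'   nonrandomness (default 10).
#' @param seed master seed.
#' @return A \code{cohort_spec} list.
#' @export
cohort_spec <- function(n_per_group = 20L, shape = c(30, 30, 30),
                        n_regions = 12L, base_structure = "smoothed:1",
                        effect_regions = integer(0),
                        effect_structure = "smoothed:3",
                        noise_sd = 0.05,
                        score_model = list(intercept = 27,
                                           coef = numeric(0),
                                           noise_sd = 1),
                        score_range = c(0, 30),
                        n_surrogates = 10L,
                        seed = 1L) {
  effect_regions <- as.integer(effect_regions)
  if (any(effect_regions < 1L | effect_regions > n_regions))
    stop("effect_regions must be atlas labels in 1..n_regions",
         call. = FALSE)
  if (length(score_model$coef) > 0) {
    if (is.null(names(score_model$coef)))
      stop("score_model$coef must be named by region label", call. = FALSE)
    if (any(!as.integer(names(score_model$coef)) %in% seq_len(n_regions)))
      stop("score_model$coef names must be atlas labels", call. = FALSE)
    if (any(!is.finite(score_model$coef)))
      stop("score coefficients must be finite", call. = FALSE)
  }
  out <- list(n_per_group = as.integer(n_per_group),
              shape = as.integer(shape), n_regions = as.integer(n_regions),
              base_structure = base_structure,
              effect_regions = effect_regions,
              effect_structure = effect_structure,
              noise_sd = noise_sd,
              score_model = score_model,
              score_range = score_range,
              n_surrogates = as.integer(n_surrogates),
              seed = as.integer(seed))
  class(out) <- "cohort_spec"
  out
}

#' Generate a synthetic two-group cohort
#'
#' Realises a \code{\link{cohort_spec}} deterministically under its seed.
#'
#' @param spec a \code{cohort_spec}.
#' @return list with \code{volumes} (named list of
#'   \code{intensity_volume}), \code{atlas}, \code{mask} and
#'   \code{subjects} (data.frame: id, group, age, sex, education,
#'   cognitive_score).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_per_group
  groups <- rep(c("control", "case"), each = n)
  ids <- sprintf("sub%03d", seq_len(2L * n))

  base <- rep_len(spec$base_structure, spec$n_regions)
  case_struct <- base
  case_struct[spec$effect_regions] <- spec$effect_structure

  ph_control <- phantom_spec(spec$shape, spec$n_regions, base,
                             noise_sd = spec$noise_sd, seed = spec$seed)
  ph_case <- phantom_spec(spec$shape, spec$n_regions, case_struct,
                          noise_sd = spec$noise_sd, seed = spec$seed)
  atlas <- phantom_atlas(ph_control)
  mask <- atlas$labels > 0L

  volumes <- vector("list", 2L * n)
  names(volumes) <- ids
  for (i in seq_len(2L * n)) {
    ph <- if (groups[i] == "control") ph_control else ph_case
    volumes[[i]] <- generate_phantom(ph,
                                     seed = derive_seed(spec$seed, 0L, i))$volume
  }

  covs <- local_rng(derive_seed(spec$seed, 1L, 0L), {
    data.frame(id = ids, group = groups,
               age = round(rnorm(2L * n, 72, 6), 1),
               sex = ifelse(rbinom(2L * n, 1L, 0.5) == 1L, "M", "F"),
               education = pmax(round(rnorm(2L * n, 14, 3)), 6))
  })

  coefs <- spec$score_model$coef
  structural <- 0
  if (length(coefs) > 0 && any(coefs != 0)) {
    reg <- as.integer(names(coefs))
    nr <- vapply(volumes, function(v) {
      vapply(reg, function(r)
        as.numeric(nonrandomness_index(v, mask = mask, atlas = atlas,
                                       region = r,
                                       n_surrogates = spec$n_surrogates,
                                       seed = spec$seed)),
        numeric(1L))
    }, numeric(length(reg)))
    nr <- matrix(nr, nrow = length(reg))
    zr <- t(apply(nr, 1L, function(x) (x - mean(x)) / sd(x)))
    structural <- as.numeric(coefs %*% zr)
  }
  scores <- local_rng(derive_seed(spec$seed, 2L, 0L), {
    spec$score_model$intercept + structural +
      rnorm(2L * n, 0, spec$score_model$noise_sd)
  })
  covs$cognitive_score <- pmin(pmax(scores, spec$score_range[1]),
                               spec$score_range[2])

  list(volumes = volumes, atlas = atlas, mask = mask, subjects = covs,
       spec = spec)
}
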