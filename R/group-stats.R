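#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of comparisons, >= 1.
#' @return \code{alpha / m} (0.05 over 90 regions gives 5.56e-4 to three
#'   significant figures).
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  m <- as.integer(m)
  if (is.na(m) || m < 1L)
    stop("m must be a positive integer", call. = FALSE)
  alpha / m
}

#' Flag regions with dissimilar group-level pattern structure
#'
#' Identifies atlas regions whose group dissimilarity D stands out as
#' significantly large among all regions. For each region a leave-one-out
#' one-sample t comparison is made: region i's D against the mean and
#' standard deviation of the remaining regions' values, right-tailed
#' (large D = dissimilar). Regions with p below \code{alpha} are flagged.
#'
#' @param regional_D named numeric vector of per-region group IBS
#'   distances (>= 3 regions).
#' @param alpha significance level (default 0.05, right-tailed).
#' @return A \code{comparison_table} data.frame: region, D, t, df, p, pass.
#' @export
flag_dissimilar_regions <- function(regional_D, alpha = 0.05) {
  n <- length(regional_D)
  if (n < 3L)
    stop("need at least 3 regions to flag outliers", call. = FALSE)
  regions <- names(regional_D)
  if (is.null(regions)) regions <- as.character(seq_len(n))
  regional_D <- unname(as.numeric(regional_D))
  res <- vapply(seq_len(n), function(i) {
    rest <- regional_D[-i]
    m <- mean(rest)
    s <- sd(rest)
    se <- s / sqrt(n - 1L)
    diff <- regional_D[i] - m
    t <- if (se == 0) {
      if (diff == 0) 0 else sign(diff) * Inf
    } else diff / se
    p <- pt(t, df = n - 2L, lower.tail = FALSE)
    c(t = t, p = p)
  }, numeric(2L))
  out <- data.frame(region = regions,
                    D = unname(regional_D),
                    t = res["t", ],
                    df = n - 2L,
                    p = res["p", ],
                    pass = res["p", ] < alpha,
                    row.names = NULL)
  structure(out, alpha = alpha, side = "right",
            class = c("comparison_table", "data.frame"))
}

# Vectorised two-sample t over rows of two matrices (items x subjects).
row_t_test <- function(xa, xb, var_equal = TRUE) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1L, stats::var); vb <- apply(xb, 1L, stats::var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (mb - ma) / se
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  list(t = t, df = df, p = p, mean_diff = mb - ma, se = se)
}

#' Screen inter-regional similarities for group differences
#'
#' Runs an independent two-sample t-test per region pair over the subjects'
#' inter-regional IBS distances (4005 pairs for a 90-region atlas) and
#' reports the pairs passing a fixed significance threshold, with the sign
#' of the effect in the case group. The default threshold of 1e-12 is a
#' configuration value suited to large cohorts; scale it to the study size.
#'
#' @param matrices_A,matrices_B lists of \code{similarity_matrix} for
#'   control and case groups (>= 2 subjects each).
#' @param threshold_p significance threshold.
#' @param var_equal pooled-variance t (default) or Welch.
#' @return A \code{comparison_table} data.frame: region_i, region_j, t, df,
#'   p, direction ("increase"/"decrease" in the case group), pass,
#'   testable. Pairs with zero variance in both groups are marked
#'   untestable and never pass.
#' @export
screen_interregional <- function(matrices_A, matrices_B,
                                 threshold_p = 1e-12, var_equal = TRUE) {
  if (length(matrices_A) < 2L || length(matrices_B) < 2L)
    stop("need at least 2 subjects per group", call. = FALSE)
  regions <- attr(matrices_A[[1L]], "region_order")
  pair_idx <- which(upper.tri(matrices_A[[1L]]), arr.ind = TRUE)
  vecs <- function(mats) vapply(mats, function(m) m[upper.tri(m)],
                                numeric(nrow(pair_idx)))
  xa <- vecs(matrices_A)
  xb <- vecs(matrices_B)
  tt <- row_t_test(xa, xb, var_equal = var_equal)
  testable <- is.finite(tt$se) & tt$se > 0
  p <- ifelse(testable, tt$p, NA_real_)
  out <- data.frame(region_i = regions[pair_idx[, 1L]],
                    region_j = regions[pair_idx[, 2L]],
                    t = ifelse(testable, tt$t, NA_real_),
                    df = tt$df,
                    p = p,
                    direction = ifelse(tt$mean_diff > 0, "increase",
                                       ifelse(tt$mean_diff < 0,
                                              "decrease", "none")),
                    pass = !is.na(p) & p < threshold_p,
                    testable = testable)
  structure(out, threshold_p = threshold_p,
            var_equal = var_equal,
            class = c("comparison_table", "data.frame"))
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("<comparison_table> ", nrow(x), " comparisons, ",
      sum(x$pass), " passing", sep = "")
  a <- attr(x, "alpha"); tp <- attr(x, "threshold_p")
  if (!is.null(a)) cat(" at alpha = ", format(a), sep = "")
  if (!is.null(tp)) cat(" at p < ", format(tp), sep = "")
  cat("\n")
  shown <- x[x$pass, , drop = FALSE]
  if (nrow(shown) > 0L) print.data.frame(head(shown, 12L), digits = 4)
  if (nrow(shown) > 12L) cat("  ...\n")
  invisible(x)
}

#' Group comparison of regional nonrandomness
#'
#' Independent two-sample t-test per region on the nonrandomness index,
#' Bonferroni-corrected over the number of regions
#' (\code{\link{bonferroni_threshold}}: 0.05 over 90 regions gives the
#' conventional 5.56e-4 cutoff).
#'
#' @param profiles_A,profiles_B lists of \code{nonrandomness_profile}
#'   (one per subject) for the two groups, over the same regions.
#' @param alpha family-wise error rate before correction (default 0.05).
#' @param var_equal pooled-variance t (default) or Welch.
#' @return A \code{comparison_table} data.frame: region, t, df, p,
#'   direction, pass at the Bonferroni-corrected threshold.
#' @export
compare_randomness <- function(profiles_A, profiles_B, alpha = 0.05,
                               var_equal = TRUE) {
  if (length(profiles_A) < 2L || length(profiles_B) < 2L)
    stop("need at least 2 subjects per group", call. = FALSE)
  regions <- profiles_A[[1L]]$region
  as_mat <- function(ps) vapply(ps, function(p) {
    if (!identical(p$region, regions))
      stop("profiles cover different region sets", call. = FALSE)
    p$index
  }, numeric(length(regions)))
  xa <- as_mat(profiles_A)
  xb <- as_mat(profiles_B)
  thr <- bonferroni_threshold(alpha, length(regions))
  tt <- row_t_test(xa, xb, var_equal = var_equal)
  testable <- is.finite(tt$se) & tt$se > 0
  p <- ifelse(testable, tt$p, NA_real_)
  out <- data.frame(region = regions,
                    t = ifelse(testable, tt$t, NA_real_),
                    df = tt$df,
                    p = p,
                    direction = ifelse(tt$mean_diff > 0, "increase",
                                       ifelse(tt$mean_diff < 0,
                                              "decrease", "none")),
                    pass = !is.na(p) & p < thr,
                    testable = testable)
  structure(out, alpha = alpha, threshold_p = thr,
            class = c("comparison_table", "data.frame"))
}
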