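test_that("bonferroni_threshold divides alpha and validates input", {
  expect_equal(signif(bonferroni_threshold(0.05, 90), 3), 5.56e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4), 0.0025)
  expect_error(bonferroni_threshold(0, 10), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "positive")
})

test_that("flag_dissimilar_regions isolates extreme regions and not flat profiles", {
  flat <- setNames(rep(0.2, 10), 1:10)
  tab <- flag_dissimilar_regions(flat)
  expect_false(any(tab$pass))
  spiked <- setNames(c(rep(0.01, 89), 0.5), 1:90)
  tab2 <- flag_dissimilar_regions(spiked, alpha = 0.05)
  expect_identical(tab2$region[tab2$pass], "90")
  # closed-form check of the leave-one-out t for the spiked region
  rest <- rep(0.01, 89)
  t_hand <- (0.5 - mean(rest)) / (sd(rest) / sqrt(89))
  expect_equal(tab2$t[90], t_hand, tolerance = 1e-12)
  expect_error(flag_dissimilar_regions(c(a = 1, b = 2)), "at least 3")
})

test_that("the inter-regional screen matches a textbook pooled t on toy data", {
  mk_sim <- function(vals) {
    m <- matrix(0, 3, 3, dimnames = list(1:3, 1:3))
    m[upper.tri(m)] <- vals
    m <- m + t(m)
    structure(m, subject_id = NA_character_, region_order = 1:3,
              class = c("similarity_matrix", "matrix", "array"))
  }
  A <- lapply(list(c(0.10, 0.20, 0.30), c(0.12, 0.22, 0.28),
                   c(0.08, 0.18, 0.33)), mk_sim)
  B <- lapply(list(c(0.30, 0.21, 0.29), c(0.35, 0.19, 0.31),
                   c(0.28, 0.23, 0.30)), mk_sim)
  tab <- screen_interregional(A, B, threshold_p = 0.01)
  # hand-computed pooled t for the first pair
  xa <- c(0.10, 0.12, 0.08); xb <- c(0.30, 0.35, 0.28)
  sp2 <- (2 * var(xa) + 2 * var(xb)) / 4
  t_hand <- (mean(xb) - mean(xa)) / sqrt(sp2 * (2 / 3))
  p_hand <- 2 * pt(abs(t_hand), 4, lower.tail = FALSE)
  expect_equal(tab$t[1], t_hand, tolerance = 1e-10)
  expect_equal(tab$p[1], p_hand, tolerance = 1e-10)
  expect_identical(tab$direction[1], "increase")
  expect_true(tab$pass[1])
  expect_false(any(tab$pass[-1]))
  # agreement with stats::t.test as an independent oracle
  ref <- t.test(xb, xa, var.equal = TRUE)
  expect_equal(tab$p[1], ref$p.value, tolerance = 1e-12)
  # duplicated groups produce no passes
  tab0 <- screen_interregional(A, A, threshold_p = 0.01)
  expect_false(any(tab0$pass))
})

test_that("degenerate-variance pairs are reported untestable, never passed", {
  mk_sim <- function(vals) {
    m <- matrix(0, 3, 3, dimnames = list(1:3, 1:3))
    m[upper.tri(m)] <- vals
    m <- m + t(m)
    structure(m, subject_id = NA_character_, region_order = 1:3,
              class = c("similarity_matrix", "matrix", "array"))
  }
  A <- lapply(list(c(0.2, 0.4, 0.1), c(0.2, 0.5, 0.2)), mk_sim)
  B <- lapply(list(c(0.2, 0.6, 0.3), c(0.2, 0.4, 0.4)), mk_sim)
  tab <- screen_interregional(A, B, threshold_p = 0.9)
  expect_false(tab$testable[1])
  expect_false(tab$pass[1])
  expect_true(all(tab$testable[-1]))
})

test_that("null screening pass-rates are compatible with the threshold", {
  # exchangeable groups: p-values uniform, so passes at p < thr are
  # Binomial(n_pairs * n_reps, thr)
  set.seed(51)
  thr <- 0.05
  n_pairs <- 45
  passes <- 0
  reps <- 40
  for (r in seq_len(reps)) {
    mk <- function() {
      m <- matrix(0, 10, 10, dimnames = list(1:10, 1:10))
      m[upper.tri(m)] <- runif(n_pairs, 0.1, 0.4)
      m <- m + t(m)
      structure(m, subject_id = NA_character_, region_order = 1:10,
                class = c("similarity_matrix", "matrix", "array"))
    }
    A <- replicate(6, mk(), simplify = FALSE)
    B <- replicate(6, mk(), simplify = FALSE)
    passes <- passes + sum(screen_interregional(A, B,
                                                threshold_p = thr)$pass)
  }
  bt <- binom.test(passes, n_pairs * reps, thr)
  expect_gt(bt$p.value, 1e-4)
})

test_that("randomness group comparison applies the Bonferroni cutoff per region", {
  mk_prof <- function(idx) {
    structure(data.frame(subject = NA_character_, region = seq_along(idx),
                         index = idx, n_surrogates = 10L, seed = 1L),
              class = c("nonrandomness_profile", "data.frame"))
  }
  set.seed(52)
  A <- replicate(8, mk_prof(c(rnorm(4, 0.3, 0.01), rnorm(1, 0.30, 0.01))),
                 simplify = FALSE)
  B <- replicate(8, mk_prof(c(rnorm(4, 0.3, 0.01), rnorm(1, 0.45, 0.01))),
                 simplify = FALSE)
  tab <- compare_randomness(A, B, alpha = 0.05)
  expect_equal(attr(tab, "threshold_p"), 0.01)
  expect_true(tab$pass[5])
  expect_identical(tab$direction[5], "increase")
  expect_false(any(tab$pass[1:4]))
})
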