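# small hand-buildable grids: labels over a 4x4x4 cube
toy_atlas <- function() {
  labels <- array(0L, c(4, 4, 4))
  labels[1:2, , ] <- 1L
  labels[3, , ] <- 2L
  labels[4, , ] <- 3L
  atlas_labels(labels)
}

# wrap an explicit code array as a pattern map (codes chosen by hand)
as_map <- function(codes) {
  structure(codes, mask = !is.na(codes),
            bit_order = c("right", "left", "anterior", "posterior",
                          "superior", "inferior"),
            msb = "right", class = c("pattern_map", "array"))
}

test_that("region_distribution tallies only coded voxels of the region", {
  atlas <- toy_atlas()
  codes <- array(NA_integer_, c(4, 4, 4))
  codes[atlas$labels == 1L] <- 63L
  codes[atlas$labels == 2L] <- rep(c(0L, 63L), each = 8)
  m <- as_map(codes)
  d1 <- region_distribution(m, atlas, 1)
  expect_equal(d1$prob[64], 1)
  d2 <- region_distribution(m, atlas, 2)
  expect_equal(d2$prob[c(1, 64)], c(0.5, 0.5))
  expect_error(region_distribution(m, atlas, 3), "no coded voxels")
  expect_error(region_distribution(m, atlas, 9), "not present")
})

test_that("interregional matrices are symmetric with zero diagonal and C(R,2) pairs", {
  set.seed(21)
  ph <- generate_phantom(phantom_spec(shape = c(20, 20, 20),
                                      n_regions = 4, structure = "iid"))
  pm <- compute_pattern_map(ph$volume, ph$mask)
  sm <- interregional_matrix(pm, ph$atlas, subject_id = "s1")
  expect_identical(dim(sm), c(4L, 4L))
  expect_identical(unname(diag(sm)), rep(0, 4))
  expect_equal(unclass(sm), t(unclass(sm)))
  expect_identical(sum(upper.tri(sm)), 6L)  # C(4,2)
  expect_true(all(sm >= 0 & sm <= 1))
  lg <- similarity_long(sm)
  expect_identical(nrow(lg), 6L)
  expect_equal(lg$distance,
               sm[cbind(match(lg$region_i, rownames(sm)),
                        match(lg$region_j, colnames(sm)))])
})

test_that("a 90-region parcellation yields exactly 4005 region pairs", {
  expect_identical(choose(90, 2), 4005)
  labels <- array(rep(1:90, each = 8), c(8, 90, 1))[, , 1, drop = FALSE]
  labels <- array(rep(1:90, each = 16), c(4, 4, 90))
  atlas <- atlas_labels(labels)
  set.seed(22)
  v <- array(runif(length(labels)), dim(labels))
  pm <- compute_pattern_map(v, array(TRUE, dim(labels)))
  sm <- interregional_matrix(pm, atlas)
  expect_identical(sum(upper.tri(sm)), 4005L)
})

test_that("matrix entries equal hand-computed oracle values on a toy grid", {
  atlas <- toy_atlas()
  codes <- array(NA_integer_, c(4, 4, 4))
  codes[atlas$labels == 1L] <- rep(c(1L, 2L, 3L, 5L), 8)
  codes[atlas$labels == 2L] <- rep(c(1L, 2L, 2L, 7L), 4)
  codes[atlas$labels == 3L] <- rep(c(3L, 5L, 5L, 5L), 4)
  m <- as_map(codes)
  sm <- interregional_matrix(m, atlas)
  prob_of <- function(region) {
    tally_distribution(codes[atlas$labels == region])$prob
  }
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(sm[i, j], brute_ibs(prob_of(i), prob_of(j)),
                 tolerance = 1e-12)
  }
  # identical code multisets give zero distance
  codes2 <- codes
  codes2[atlas$labels == 3L] <- rep(c(1L, 2L, 3L, 5L), 4)
  sm2 <- interregional_matrix(as_map(codes2), atlas)
  expect_identical(sm2[1, 3], 0)
})

test_that("group dissimilarity averages per-subject probabilities and is order-invariant", {
  atlas <- toy_atlas()
  mk <- function(region1_codes) {
    codes <- array(NA_integer_, c(4, 4, 4))
    codes[atlas$labels == 1L] <- region1_codes
    codes[atlas$labels == 2L] <- 5L
    codes[atlas$labels == 3L] <- 9L
    as_map(codes)
  }
  a1 <- mk(rep(c(0L, 63L), 16)); a2 <- mk(rep(c(0L, 0L, 63L, 63L), 8))
  b1 <- mk(rep(c(7L, 63L), 16)); b2 <- mk(rep(7L, 32))
  # identical groups -> 0
  expect_identical(group_region_dissimilarity(list(a1, a2), list(a1, a2),
                                              atlas, 1), 0)
  # subject order within groups is immaterial
  d12 <- group_region_dissimilarity(list(a1, a2), list(b1, b2), atlas, 1)
  d21 <- group_region_dissimilarity(list(a2, a1), list(b2, b1), atlas, 1)
  expect_identical(d12, d21)
  # equals the oracle on the averaged probability vectors
  pa <- (tally_distribution(a1[atlas$labels == 1])$prob +
           tally_distribution(a2[atlas$labels == 1])$prob) / 2
  pb <- (tally_distribution(b1[atlas$labels == 1])$prob +
           tally_distribution(b2[atlas$labels == 1])$prob) / 2
  expect_equal(d12, brute_ibs(pa, pb), tolerance = 1e-12)
  expect_equal(sum(pa), 1, tolerance = 1e-12)
})

test_that("rank reversal across a shared support gives the hand-computed maximum", {
  # group A: p = (0.5, 0.3, 0.2) on words 0,1,2; group B reverses the order
  mkmap <- function(p_counts) {
    codes <- array(NA_integer_, c(4, 4, 4))
    lab <- toy_atlas()$labels
    codes[lab == 1L] <- rep(c(0L, 1L, 2L), times = p_counts)[1:32]
    codes[lab == 2L] <- 5L
    codes[lab == 3L] <- 9L
    as_map(codes)
  }
  # 32 voxels: 16/10/6 vs 6/10/16
  a <- mkmap(c(16, 10, 6))
  b <- mkmap(c(6, 10, 16))
  d <- group_region_dissimilarity(list(a), list(b), toy_atlas(), 1)
  pa <- numeric(64); pa[1:3] <- c(16, 10, 6) / 32
  pb <- numeric(64); pb[1:3] <- c(6, 10, 16) / 32
  expect_equal(d, brute_ibs(pa, pb), tolerance = 1e-12)
  # hand evaluation: |dR| = (2, 0, 2), D = (2 F(w0) + 2 F(w2)) / 3
  f <- function(pa1, pb1) -pa1 * log(pa1) - pb1 * log(pb1)
  fw <- c(f(0.5, 6 / 32), f(10 / 32, 10 / 32), f(6 / 32, 0.5))
  expect_equal(d, (2 * fw[1] + 2 * fw[3]) / sum(fw) / 3,
               tolerance = 1e-12)
})
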