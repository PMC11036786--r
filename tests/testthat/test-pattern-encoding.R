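test_that("encode_pattern reproduces the worked examples and rejects bad input", {
  expect_identical(encode_pattern(1.0, rep(0, 6)), 63L)
  expect_identical(encode_pattern(0.0, rep(1, 6)), 0L)
  # ties count as 1 (centre >= neighbour)
  expect_identical(encode_pattern(0.5, rep(0.5, 6)), 63L)
  # binary 101011 with the first (right) symbol most significant
  expect_identical(encode_pattern(5, c(3, 7, 5, 6, 1, 5)), 43L)
  expect_error(encode_pattern(NA_real_, rep(0, 6)), "finite")
  expect_error(encode_pattern(1, c(Inf, 0, 0, 0, 0, 0)), "finite")
  expect_error(encode_pattern(1, rep(0, 5)), "six")
})

test_that("the 64 binary relation vectors map one-to-one onto codes 0..63", {
  grids <- as.matrix(expand.grid(rep(list(0:1), 6)))
  codes <- apply(grids, 1L, function(bits) {
    # centre 1 against neighbours 0 (bit 1) or 2 (bit 0)
    encode_pattern(1, ifelse(bits == 1, 0, 2))
  })
  expect_setequal(codes, 0:63)
  # decode inverts encode
  for (i in seq_len(64)) {
    expect_equal(unname(decode_pattern(codes[i])[1, ]),
                 unname(grids[i, ]))
  }
})

test_that("pattern map matches a brute-force re-encoder on random masked grids", {
  set.seed(42)
  for (rep in 1:3) {
    d <- c(sample(4:7, 1), sample(4:7, 1), sample(4:7, 1))
    v <- array(runif(prod(d)), d)
    mask <- array(runif(prod(d)) > 0.3, d)
    if (!any(mask)) mask[1] <- TRUE
    pm <- compute_pattern_map(v, mask)
    expect_identical(unclass(pm)[, , ], brute_pattern_map(v, mask))
  }
})

test_that("constant volumes code 63 everywhere and isolated voxels code 63", {
  v <- array(0.7, c(4, 4, 4))
  pm <- compute_pattern_map(v, array(TRUE, c(4, 4, 4)))
  expect_true(all(pm == 63L))
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  v2 <- array(0, c(5, 5, 5)); v2[3, 3, 3] <- 0.4
  pm2 <- compute_pattern_map(v2, m)
  expect_identical(pm2[3, 3, 3], 63L)
  expect_identical(sum(!is.na(pm2)), 1L)
})

test_that("encoding is invariant to intensity shift and positive scaling", {
  set.seed(7)
  v <- array(runif(6^3), c(6, 6, 6))
  mask <- array(TRUE, c(6, 6, 6))
  base <- compute_pattern_map(v, mask)
  expect_identical(unclass(compute_pattern_map(v + 2.5, mask)),
                   unclass(base))
  expect_identical(unclass(compute_pattern_map(v * 3.7, mask)),
                   unclass(base))
})

test_that("left-right reflection swaps the first two bits of interior codes", {
  set.seed(11)
  d <- c(6, 5, 5)
  v <- array(runif(prod(d)), d)
  mask <- array(TRUE, d)
  pm <- compute_pattern_map(v, mask)
  pm_ref <- compute_pattern_map(v[d[1]:1, , ], mask)
  interior <- interior_mask(mask)
  idx <- which(interior, arr.ind = TRUE)
  orig_bits <- decode_pattern(pm[idx])
  # voxel (i,j,k) lands at (d1+1-i, j, k) after reflection
  ridx <- cbind(d[1] + 1L - idx[, 1], idx[, 2], idx[, 3])
  refl_codes <- pm_ref[ridx]
  refl_bits <- decode_pattern(refl_codes)
  expect_identical(unname(refl_bits[, "right"]),
                   unname(orig_bits[, "left"]))
  expect_identical(unname(refl_bits[, "left"]),
                   unname(orig_bits[, "right"]))
  expect_identical(refl_bits[, 3:6], orig_bits[, 3:6])
})

test_that("shape mismatches and empty masks are rejected with clear errors", {
  v <- array(runif(27), c(3, 3, 3))
  expect_error(compute_pattern_map(v, array(TRUE, c(3, 3, 4))),
               "does not match")
  expect_error(compute_pattern_map(v, array(FALSE, c(3, 3, 3))),
               "empty")
})

test_that("interior code frequencies follow the k!(6-k)!/7! law on iid volumes", {
  set.seed(3)
  d <- c(32, 32, 32)
  v <- array(runif(prod(d)), d)
  mask <- array(TRUE, d)
  pm <- compute_pattern_map(v, mask)
  codes <- pm[interior_mask(mask)]
  n <- length(codes)
  phat <- tabulate(codes + 1L, 64L) / n
  pth <- code_law()
  z <- abs(phat - pth) / sqrt(pth * (1 - pth) / n)
  expect_lt(max(z), 4)
  expect_equal(phat[64], 1 / 7, tolerance = 0.02)
})
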