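test_that("phantoms are reproducible, bounded, and tile the ellipsoid", {
  spec <- phantom_spec(shape = c(24, 24, 24), n_regions = 6, seed = 41)
  ph1 <- generate_phantom(spec)
  ph2 <- generate_phantom(spec)
  expect_identical(unclass(ph1$volume), unclass(ph2$volume))
  expect_true(all(ph1$volume >= 0 & ph1$volume <= 1))
  expect_true(all(ph1$volume[!ph1$mask] == 0))
  counts <- table(ph1$atlas$labels[ph1$mask])
  expect_identical(length(counts), 6L)
  expect_true(all(counts >= 64))
  # a grid too small to give every region its minimum voxel count fails
  expect_error(generate_phantom(phantom_spec(shape = c(8, 8, 8),
                                             n_regions = 10)),
               "too small")
})

test_that("iid phantom regions follow the closed-form code law in their interior", {
  ph <- generate_phantom(phantom_spec(shape = c(26, 26, 26), n_regions = 1,
                                      structure = "iid", noise_sd = 0,
                                      seed = 42))
  pm <- compute_pattern_map(ph$volume, ph$mask)
  region <- ph$atlas$labels == 1L
  codes <- pm[interior_mask(region)]
  n <- length(codes)
  expect_gt(n, 2000)
  phat <- tabulate(codes + 1L, 64L) / n
  pth <- code_law()
  z <- abs(phat - pth) / sqrt(pth * (1 - pth) / n)
  expect_lt(max(z), 4)
})

test_that("a pure +x gradient region codes 31 throughout its interior", {
  # ramp along +x: right neighbour larger (bit 0), left smaller (bit 1),
  # y/z neighbours tie (bits 1): binary 011111 = 31
  ph <- generate_phantom(phantom_spec(shape = c(16, 16, 16), n_regions = 1,
                                      structure = "gradient:+x",
                                      noise_sd = 0, seed = 43))
  pm <- compute_pattern_map(ph$volume, ph$mask)
  interior <- interior_mask(ph$atlas$labels == 1L)
  expect_true(all(pm[interior] == 31L))
})

test_that("cohorts are seed-reproducible with group-specific structure only in effect regions", {
  spec <- cohort_spec(n_per_group = 2, shape = c(20, 20, 20), n_regions = 4,
                      effect_regions = 2L, effect_structure = "smoothed:3",
                      seed = 44)
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(lapply(co1$volumes, unclass),
                   lapply(co2$volumes, unclass))
  expect_identical(co1$subjects, co2$subjects)
  expect_identical(co1$subjects$group, rep(c("control", "case"), each = 2))
  expect_true(all(co1$subjects$cognitive_score >= 0 &
                    co1$subjects$cognitive_score <= 30))
  # matched seeds: case and control phantoms agree outside effect regions
  base <- rep("smoothed:1", 4)
  eff <- base; eff[2] <- "smoothed:3"
  p_ctrl <- generate_phantom(phantom_spec(c(20, 20, 20), 4, base,
                                          seed = 7))
  p_case <- generate_phantom(phantom_spec(c(20, 20, 20), 4, eff, seed = 7))
  lab <- p_ctrl$atlas$labels
  expect_identical(unclass(p_ctrl$volume)[lab != 2L],
                   unclass(p_case$volume)[lab != 2L])
  expect_false(identical(unclass(p_ctrl$volume)[lab == 2L],
                         unclass(p_case$volume)[lab == 2L]))
})

test_that("planted structural effects dominate the group dissimilarity profile", {
  spec <- cohort_spec(n_per_group = 4, shape = c(24, 24, 24),
                      n_regions = 6, effect_regions = c(3L, 5L),
                      effect_structure = "gradient:+x", seed = 45)
  co <- generate_cohort(spec)
  is_case <- co$subjects$group == "case"
  maps <- lapply(co$volumes, compute_pattern_map, mask = co$mask)
  prof <- group_dissimilarity_profile(maps[!is_case], maps[is_case],
                                      co$atlas)
  top2 <- as.integer(names(sort(prof, decreasing = TRUE)[1:2]))
  expect_setequal(top2, c(3L, 5L))
})

test_that("score coefficients propagate nonrandomness into cognitive scores", {
  spec <- cohort_spec(n_per_group = 4, shape = c(18, 18, 18), n_regions = 4,
                      score_model = list(intercept = 20,
                                         coef = c("2" = 3),
                                         noise_sd = 1e-6),
                      n_surrogates = 3, seed = 46)
  co <- generate_cohort(spec)
  nr <- vapply(co$volumes, function(v)
    as.numeric(nonrandomness_index(v, mask = co$mask, atlas = co$atlas,
                                   region = 2, n_surrogates = 3,
                                   seed = spec$seed)),
    numeric(1))
  z <- (nr - mean(nr)) / sd(nr)
  expect_equal(co$subjects$cognitive_score, unname(20 + 3 * z),
               tolerance = 1e-3)
})
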