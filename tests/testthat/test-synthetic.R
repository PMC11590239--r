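test_that("Spearman-to-latent map follows 2 sin(pi r / 6)", {
  m <- matrix(c(1, 0, .5, 0, 1, 1, .5, 1, 1), 3)
  lat <- spearman_to_latent_pearson(m)
  expect_equal(lat[1, 2], 0)
  expect_equal(lat[2, 3], 1)            # exact at r = 1
  expect_equal(lat[1, 3], 0.5176380902, tolerance = 1e-9)
  expect_equal(unname(diag(lat)), rep(1, 3))
})

test_that("correlation repair projects to PSD and fixes already-PSD input", {
  psd <- matrix(c(1, .3, .3, 1), 2)
  expect_equal(nearest_correlation_matrix(psd), psd, tolerance = 1e-8)

  bad <- matrix(c(1, .9, .9, .9, 1, -.9, .9, -.9, 1), 3)
  rep_ <- nearest_correlation_matrix(bad)
  ev <- eigen(rep_, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)
  expect_equal(unname(diag(rep_)), rep(1, 3), tolerance = 1e-8)
  expect_error(nearest_correlation_matrix(matrix(c(1, .2, .5, 1), 2)),
               "symmetric")
  # the transcribed study matrix itself is repairable and Cholesky-safe
  fixed <- nearest_correlation_matrix(
    spearman_to_latent_pearson(table3_fixture()))
  expect_no_error(chol(fixed))
})

test_that("copula recovers continuous-pair Spearman targets at n = 5000", {
  tgt <- matrix(c(1, .6, 0, -.6,
                  .6, 1, .3, -.3,
                  0, .3, 1, 0,
                  -.6, -.3, 0, 1), 4,
                dimnames = list(paste0("v", 1:4), paste0("v", 1:4)))
  expect_gte(min(eigen(tgt, only.values = TRUE)$values), 0)
  marg <- stats::setNames(
    list(marginal_numeric(0, 1), marginal_numeric(10, 2, 0, 20),
         marginal_numeric(-5, 3), marginal_numeric(1, 0.5)),
    rownames(tgt))
  ct <- generate_cohort(synthetic_spec(5000, tgt, marg, seed = 31))
  m <- correlation_matrix_of(ct)
  expect_lt(max(abs(unclass(m) - tgt)), 0.05)
})

test_that("identity target gives null off-diagonals within 3/sqrt(n)", {
  tgt <- diag(3)
  dimnames(tgt) <- list(paste0("v", 1:3), paste0("v", 1:3))
  marg <- stats::setNames(replicate(3, marginal_numeric(0, 1),
                                    simplify = FALSE), rownames(tgt))
  m <- correlation_matrix_of(
    generate_cohort(synthetic_spec(5000, tgt, marg, seed = 12)))
  off <- unclass(m)[upper.tri(m)]
  expect_lt(max(abs(off)), 0.05)
})

test_that("marginals respect their declared bounds, kinds and calibration", {
  spec <- survive_like_spec(n = 5000, missing_rate = 0, seed = 44)
  ct <- generate_cohort(spec)
  d <- ct$data
  expect_equal(dim(d), c(5000, 34))
  expect_true(all(d$Age >= 12 & d$Age <= 17))
  expect_true(all(d$PHQ >= 0 & d$PHQ <= 27))
  expect_true(all(d$NAt >= 1 & d$NAt == round(d$NAt)))
  expect_true(all(d$AcL %in% 1:5))
  expect_true(all(d$Sex %in% c(0, 1)))
  # binary calibration: female prevalence within 3 binomial SEs of 0.874
  se <- sqrt(0.874 * (1 - 0.874) / 5000)
  expect_lt(abs(mean(d$Sex) - 0.874), 3 * se)
  # count calibration: attempts mean within 3 SEs of 2.54 (SD 2.39)
  expect_lt(abs(mean(d$NAt) - 2.54), 3 * 2.39 / sqrt(5000))
})

test_that("generation is deterministic and discretisation only attenuates", {
  spec <- survive_like_spec(seed = 3)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$data, c2$data)
  expect_false(identical(c1$data, generate_cohort(spec, seed = 4)$data))

  tgt <- matrix(c(1, .6, .6, 1), 2, dimnames = list(c("b", "x"),
                                                    c("b", "x")))
  marg <- list(b = marginal_binary(0.3), x = marginal_numeric(0, 1))
  ct <- generate_cohort(synthetic_spec(4000, tgt, marg, seed = 9))
  r <- correlation_matrix_of(ct)["b", "x"]
  expect_lte(abs(r), 0.6 + 3 / sqrt(4000))
  expect_gt(r, 0.3)  # attenuated but clearly present
})

test_that("study-calibrated spec reproduces the cohort's shape", {
  ct <- generate_cohort(survive_like_spec(seed = 2))
  expect_equal(ct$n, 267)
  expect_equal(nrow(ct$meta), 34)
  expect_identical(ct$meta$name, rownames(table3_fixture()))
  expect_identical(ct$meta$group, fixture_variables()$group)
})

test_that("degenerate binary prevalence warns when dependence is demanded", {
  tgt <- matrix(c(1, .5, .5, 1), 2, dimnames = list(c("b", "x"),
                                                    c("b", "x")))
  marg <- list(b = marginal_binary(1), x = marginal_numeric(0, 1))
  expect_warning(generate_cohort(synthetic_spec(50, tgt, marg, seed = 1)),
                 "unattainable")
})

test_that("large-n study network puts SDQ total on top for strength", {
  spec <- survive_like_spec(n = 4000, missing_rate = 0, seed = 17)
  ct <- generate_cohort(spec)
  m <- suppressWarnings(correlation_matrix_of(ct))
  s <- node_strength(build_network(m, 0))
  expect_equal(names(which.max(s)), "SDQT")
})
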