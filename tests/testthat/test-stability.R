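# small complete cohort with genuine correlation structure
boot_cohort <- function(n = 60, seed = 5) {
  tgt <- matrix(c(1, .6, .2, .6, 1, 0, .2, 0, 1), 3,
                dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  marg <- list(x = marginal_numeric(0, 1), y = marginal_numeric(0, 1),
               z = marginal_numeric(0, 1))
  generate_cohort(synthetic_spec(n, tgt, marg, seed = seed))
}

test_that("edge bootstrap is reproducible and tracks the point estimates", {
  ct <- boot_cohort()
  b1 <- bootstrap_edge_weights(ct, threshold = 0, B = 50, seed = 9)
  b2 <- bootstrap_edge_weights(ct, threshold = 0, B = 50, seed = 9)
  expect_identical(b1$samples, b2$samples)
  expect_identical(b1$edges, b2$edges)
  b3 <- bootstrap_edge_weights(ct, threshold = 0, B = 50, seed = 10)
  expect_false(identical(b1$samples, b3$samples))
  expect_true(all(b1$edges$ci_low <= b1$edges$ci_high))
  full <- correlation_matrix_of(ct)
  expect_equal(b1$edges$estimate[1], full["x", "y"])
})

test_that("B = 1 collapses the percentile interval to the single draw", {
  ct <- boot_cohort()
  b <- bootstrap_edge_weights(ct, B = 1, seed = 3)
  expect_equal(b$edges$ci_low, b$edges$ci_high)
  expect_equal(b$edges$ci_low, b$samples[, 1])
})

test_that("a duplicated column's bootstrap distribution is degenerate at 1", {
  withr::with_seed(8, x <- stats::rnorm(40))
  ct <- small_cohort(list(a = x, b = x))
  b <- bootstrap_edge_weights(ct, B = 25, seed = 2)
  expect_equal(unname(b$samples[1, ]), rep(1, 25))
})

test_that("case-dropping: p = 0 reproduces the full sample exactly", {
  ct <- boot_cohort()
  cd <- case_dropping_bootstrap(ct, "strength", grid = c(0), m = 4, seed = 1)
  expect_equal(unname(as.vector(cd$correlations)), rep(1, 4))
})

test_that("case-dropping is seed-reproducible and validates its grid", {
  ct <- boot_cohort()
  c1 <- case_dropping_bootstrap(ct, "closeness", grid = c(.2, .5), m = 6,
                                seed = 4)
  c2 <- case_dropping_bootstrap(ct, "closeness", grid = c(.2, .5), m = 6,
                                seed = 4)
  expect_identical(c1$correlations, c2$correlations)
  expect_error(case_dropping_bootstrap(ct, "strength", grid = c(.5, .2)),
               "strictly increasing")
  expect_error(case_dropping_bootstrap(ct, "strength", grid = 0.99),
               "below 3")
})

test_that("CS-coefficient implements the monotone-enforcement definition", {
  fake <- structure(list(
    measure = "strength", grid = seq(0.1, 0.5, by = 0.1),
    correlations = rbind(matrix(0.9, 4, 20),
                         matrix(c(rep(0.9, 10), rep(0.1, 10)), 1, 20)),
    m = 20, seed = 1, threshold = 0, n = 100),
    class = "case_drop_result")
  # levels 0.1-0.4 pass at 95%, level 0.5 has only 50% >= 0.5
  expect_equal(cs_coefficient(fake, r_min = 0.5, confidence = 0.95), 0.4)

  allpass <- fake
  allpass$correlations <- matrix(1, 5, 20)
  expect_equal(cs_coefficient(allpass), 0.5)

  nopass <- fake
  nopass$correlations <- matrix(0.2, 5, 20)
  expect_equal(cs_coefficient(nopass), 0)

  # a failing early level blocks later passing levels
  gap <- fake
  gap$correlations <- rbind(matrix(0.1, 1, 20), matrix(0.9, 4, 20))
  expect_equal(cs_coefficient(gap), 0)
})

test_that("CS is non-increasing in r_min and in confidence", {
  ct <- boot_cohort(n = 120, seed = 21)
  cd <- case_dropping_bootstrap(ct, "strength", grid = seq(.1, .7, .2),
                                m = 20, seed = 6)
  expect_lte(cs_coefficient(cd, r_min = 0.7), cs_coefficient(cd, r_min = 0.5))
  expect_lte(cs_coefficient(cd, confidence = 0.99),
             cs_coefficient(cd, confidence = 0.8))
})

test_that("stronger subsampling degrades centrality correlations", {
  tgt <- matrix(0.05, 9, 9)
  tgt[1:3, 1:3] <- tgt[4:6, 4:6] <- tgt[7:9, 7:9] <- 0.6
  diag(tgt) <- 1
  dimnames(tgt) <- list(paste0("v", 1:9), paste0("v", 1:9))
  marg <- stats::setNames(replicate(9, marginal_numeric(0, 1),
                                    simplify = FALSE), rownames(tgt))
  ct <- generate_cohort(synthetic_spec(800, tgt, marg, seed = 2))
  cd <- case_dropping_bootstrap(ct, "strength", grid = c(0.1, 0.9),
                                m = 25, seed = 3)
  med <- apply(cd$correlations, 1, stats::median, na.rm = TRUE)
  expect_gt(med[1], med[2])
})

test_that("case-drop export carries one row per level and replicate", {
  ct <- boot_cohort()
  cd <- case_dropping_bootstrap(ct, "strength", grid = c(.1, .3), m = 5,
                                seed = 2)
  tf <- tempfile(fileext = ".csv")
  write_case_drop(cd, tf)
  out <- utils::read.csv(tf)
  expect_equal(nrow(out), 10)
  expect_setequal(unique(out$drop_proportion), c(0.1, 0.3))
  expect_equal(unique(out$cs), cs_coefficient(cd))
})
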