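test_that("centering is exact, idempotent, and flags constant columns", {
  cc <- cptboot:::center_cols(c(1, 2, 3), cbind(c(2, 4, 6), c(5, 5, 5)))
  expect_equal(cc$y, c(-1, 0, 1))
  expect_equal(cc$Z[, 1], c(-2, 0, 2))
  expect_identical(cc$usable, c(TRUE, FALSE))     # constant column flagged

  cc2 <- cptboot:::center_cols(cc$y, cc$Z)
  expect_equal(cc2$y, cc$y)
  expect_equal(cc2$Z, cc$Z)
})

test_that("every greedy pick matches an exhaustive scan", {
  # oracle: recompute the residual by least squares on the raw selected
  # columns, then scan all remaining columns for the normalised
  # correlation argmax -- independent of the Gram-Schmidt path
  for (seed in 1:6) {
    inst <- rand_instance(n = 20, p = sample(5:30, 1), seed = seed)
    D <- min(8L, ncol(inst$Z))
    path <- oga_path(inst$y, inst$Z, D, inst$usable)
    n <- length(inst$y)
    norms <- sqrt(colSums(inst$Z^2))
    for (d in seq_along(path$selected)) {
      S <- path$selected[seq_len(d - 1L)]
      r <- if (length(S)) stats::lm.fit(inst$Z[, S, drop = FALSE],
                                        inst$y)$residuals else inst$y
      score <- abs(as.vector(crossprod(inst$Z, r))) / (sqrt(n) * norms)
      score[S] <- -Inf
      expect_identical(path$selected[d], which.max(score))
    }
  }
})

test_that("path residual norms equal exact least squares on raw columns", {
  inst <- rand_instance(n = 30, p = 12, seed = 4)
  path <- oga_path(inst$y, inst$Z, 10L, inst$usable)
  for (d in seq_along(path$selected)) {
    S <- path$selected[seq_len(d)]
    expect_equal(path$rss[d], cptboot:::ls_rss(inst$y, inst$Z, S),
                 tolerance = 1e-8)
  }
  # monotone non-increasing
  expect_true(all(diff(path$rss) <= 1e-12))
})

test_that("the empty-set projection convention gives sigma^2 = mean(y^2)", {
  y <- c(1, -2, 3, 0.5)
  expect_equal(cptboot:::ls_rss(y, matrix(0, 4, 1), integer(0)) / 4,
               mean(y^2))
})

test_that("HDIC with zero penalty stops at the end of the path", {
  inst <- rand_instance(n = 40, p = 15, seed = 9)
  path <- oga_path(inst$y, inst$Z, 10L, inst$usable)
  fl <- cptboot:::sigma2_floor(inst$y)
  expect_identical(cptboot:::hdic_argmin(path, 0, fl),
                   length(path$selected))
})

test_that("HDIC stopping is monotone in the penalty multiplier", {
  for (seed in c(2, 8, 13)) {
    inst <- rand_instance(n = 50, p = 20, seed = seed)
    path <- oga_path(inst$y, inst$Z, 12L, inst$usable)
    fl <- cptboot:::sigma2_floor(inst$y)
    d <- vapply(c(0.5, 1, 2, 4, 8),
                function(cn) cptboot:::hdic_argmin(path, cn, fl),
                integer(1))
    expect_true(all(diff(d) <= 0L))
  }
})

test_that("trim keeps a single-column selection and recovers planted support", {
  set.seed(21)
  n <- 100
  Z <- matrix(rnorm(n * 20), n, 20)
  y <- 3 * Z[, 3] - 2 * Z[, 11] + rnorm(n, 0, 0.1)
  cc <- cptboot:::center_cols(y, Z)
  path <- oga_path(cc$y, cc$Z, 10L, cc$usable)
  fl <- cptboot:::sigma2_floor(cc$y)
  d_hat <- cptboot:::hdic_argmin(path, 2, fl)
  J <- cptboot:::trim_selection(cc$y, cc$Z, path, d_hat, 2, fl)
  expect_identical(J, c(3L, 11L))

  expect_identical(
    cptboot:::trim_selection(cc$y, cc$Z, path, 1L, 2, fl),
    path$selected[1L])
})

test_that("perfectly collinear relevant columns leave at most one survivor", {
  set.seed(5)
  n <- 60
  Z <- matrix(rnorm(n * 8), n, 8)
  Z[, 5] <- Z[, 3]                                  # exact duplicate
  y <- 2 * Z[, 3] + rnorm(n, 0, 0.2)
  cc <- cptboot:::center_cols(y, Z)
  path <- oga_path(cc$y, cc$Z, 6L, cc$usable)
  fl <- cptboot:::sigma2_floor(cc$y)
  d_hat <- cptboot:::hdic_argmin(path, 2, fl)
  J <- cptboot:::trim_selection(cc$y, cc$Z, path, d_hat, 2, fl)
  expect_lte(sum(J %in% c(3L, 5L)), 1L)
})

test_that("surviving columns map to change-point windows as specified", {
  plan <- cut_blocks(240, 24)                       # p = 10, q = 1
  cm <- data.frame(column = 1:10, block = 1:10, covariate = 1L)

  s0 <- cptboot:::select_segments(1L, cm, plan)     # only block 1 active
  expect_identical(s0$s, 0L)

  s1 <- cptboot:::select_segments(c(1L, 7L, 8L), cm, plan)
  expect_identical(s1$k, 7L)                        # run {7,8} -> k = 7
  expect_equal(unname(s1$windows[1, ]), c(145L, 192L))  # blocks 7-8

  s2 <- cptboot:::select_segments(c(1L, 5L), cm, plan)
  expect_identical(s2$k, 4L)                        # run {5} -> k = 4
  expect_equal(unname(s2$windows[1, ]), c(73L, 120L))   # blocks 4-5

  # windows are always 2m long and disjoint
  s3 <- cptboot:::select_segments(c(1L, 3L, 7L, 8L), cm, plan)
  expect_true(all(s3$windows[, 2] - s3$windows[, 1] + 1L == 48L))
  expect_true(all(diff(as.vector(t(s3$windows))) > 0))
})
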