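test_that("rank scores are ascending-in-importance mid-ranks", {
  expect_equal(unname(rank_scores(matrix(c(0.5, 0.3, 0.2), 1))),
               matrix(c(3, 2, 1), 1))
  expect_equal(unname(rank_scores(matrix(c(0.4, 0.4, 0.2), 1))),
               matrix(c(2.5, 2.5, 1), 1))
  set.seed(80)
  r <- rank_scores(matrix(runif(40), 5, 8))
  expect_equal(unname(rowSums(r)), rep(8 * 9 / 2, 5))
})

test_that("Kendall W hits its analytic endpoints", {
  # identical untied rankings -> perfect agreement
  r1 <- matrix(rep(1:7, each = 5), 5, 7)
  res1 <- kendall_w(r1)
  expect_equal(res1$w, 1, tolerance = 1e-12)
  expect_identical(res1$f_correction, 0)
  expect_true(res1$significant)

  # exactly reversed rankings -> all rank sums equal, W = 0
  r0 <- rbind(1:6, 6:1)
  res0 <- kendall_w(r0)
  expect_identical(res0$w, 0)
  expect_false(res0$significant)
})

test_that("tie-corrected W matches brute-force and vegan oracles", {
  # fixed m=3, n=4 table with one tied pair in one judge
  r <- rbind(c(1, 2, 3, 4),
             c(2, 1, 4, 3),
             c(1.5, 1.5, 3, 4))
  res <- kendall_w(r)
  expect_equal(res$w, brute_force_w(r), tolerance = 1e-12)
  expect_gt(res$f_correction, 0)

  skip_if_not_installed("vegan")
  set.seed(90)
  for (rep in 1:100) {
    m <- sample(2:6, 1); n <- sample(3:8, 1)
    rk <- random_rank_table(m, n, levels = sample(c(NA, 3, 4), 1))
    res <- kendall_w(rk)
    expect_equal(res$w, brute_force_w(rk), tolerance = 1e-12)
    vg <- vegan::kendall.global(t(rk))$Concordance_analysis
    expect_equal(res$w, unname(vg["W", 1]), tolerance = 1e-10)
    expect_equal(res$chi2, unname(vg["Chi2", 1]), tolerance = 1e-10)
  }
})

test_that("without ties the implementation reduces to the classic formula", {
  set.seed(91)
  for (rep in 1:20) {
    m <- sample(2:8, 1); n <- sample(3:9, 1)
    rk <- t(replicate(m, sample(n)))
    res <- kendall_w(rk)
    sums <- colSums(rk)
    ss <- sum((sums - mean(sums))^2)
    expect_lt(abs(res$w - 12 * ss / (m^2 * (n^3 - n))), 1e-12)
    expect_identical(res$f_correction, 0)
  }
})

test_that("W is invariant to relabeling judges/items and to duplicating the panel", {
  set.seed(92)
  for (rep in 1:100) {
    m <- sample(3:6, 1); n <- sample(4:7, 1)
    rk <- random_rank_table(m, n, levels = 5)
    w0 <- kendall_w(rk)$w
    expect_equal(kendall_w(rk[sample(m), sample(n)])$w, w0, tolerance = 1e-12)
    # doubling every judge of an untied panel leaves concordance unchanged
    rku <- t(replicate(m, sample(n)))
    expect_equal(kendall_w(rbind(rku, rku))$w, kendall_w(rku)$w,
                 tolerance = 1e-12)
  }
})

test_that("chi-square significance matches an independent tail computation", {
  set.seed(93)
  rk <- random_rank_table(19, 9)
  res <- kendall_w(rk)
  # independent tail via the gamma representation of the chi-square
  p_alt <- pgamma(res$chi2 / 2, shape = res$df / 2, lower.tail = FALSE)
  expect_equal(res$p_value, p_alt, tolerance = 1e-12)
  expect_identical(res$significant, res$p_value < 0.05)

  # permutation p-value agrees in verdict on a strongly concordant table
  rc <- matrix(rep(1:6, each = 4), 4, 6)
  resc <- kendall_w(rc, permutation = TRUE, n_perm = 199)
  expect_lt(resc$p_perm, 0.05)
})

test_that("under independent rankings mean W matches the Monte-Carlo null", {
  set.seed(94)
  m <- 19; n <- 9
  ws <- replicate(500, kendall_w(t(replicate(m, sample(n))))$w)
  # E[W] under the null is 1/m (E[chi2] = n-1); check within 3 standard errors
  se <- sd(ws) / sqrt(length(ws))
  expect_lt(abs(mean(ws) - 1 / m), 3 * se)
})

test_that("per-category concordance is 1 for a full-consensus survey", {
  gs <- generate_survey(generator_spec(protocol = small_protocol(),
                                       n_modelers = 5, seed = 6,
                                       judgment_noise_sigma = 0, agreement = 1))
  cc <- concordance_by_category(gs$bundle)
  expect_equal(cc$w, rep(1, nrow(cc)), tolerance = 1e-9)
  expect_identical(cc$matrix, c("A", "B", "categories"))
  expect_error(concordance_by_category(gs$bundle, retained = "M01"),
               "at least 2")
})

test_that("Wilks' lambda is 1 for identical group means and matches ANOVA when p = 1", {
  pts <- rbind(c(0, 0), c(1, 1), c(2, 0))
  x <- rbind(pts, pts)  # identical group means, full-rank within scatter
  g <- rep(c("a", "b"), each = 3)
  res <- wilks_manova(x, g)
  expect_equal(res$wilks_lambda, 1, tolerance = 1e-12)
  expect_false(res$significant)

  set.seed(95)
  y <- rnorm(12) + rep(c(0, 1, 3), each = 4)
  gg <- rep(c("a", "b", "c"), each = 4)
  res1 <- wilks_manova(matrix(y), gg)
  ssw <- sum(tapply(y, gg, function(v) sum((v - mean(v))^2)))
  sst <- sum((y - mean(y))^2)
  expect_equal(res1$wilks_lambda, ssw / sst, tolerance = 1e-12)
})

test_that("Wilks' lambda and Rao F match the reference MANOVA implementation", {
  set.seed(96)
  x <- matrix(rnorm(40), 20, 2)
  x[1:10, 1] <- x[1:10, 1] + 1.2
  g <- rep(c("u", "v"), each = 10)
  res <- wilks_manova(x, g)
  fit <- summary(stats::manova(x ~ g), test = "Wilks")$stats
  expect_equal(res$wilks_lambda, fit["g", "Wilks"], tolerance = 1e-8)
  expect_equal(res$statistic, fit["g", "approx F"], tolerance = 1e-8)
  expect_equal(res$p_value, fit["g", "Pr(>F)"], tolerance = 1e-8)

  # three groups, three features
  y <- matrix(rnorm(60), 20, 3)
  g3 <- rep(c("a", "b", "c"), length.out = 20)
  y[g3 == "c", 2] <- y[g3 == "c", 2] + 2
  res3 <- wilks_manova(y, g3)
  fit3 <- summary(stats::manova(y ~ g3), test = "Wilks")$stats
  expect_equal(res3$wilks_lambda, fit3["g3", "Wilks"], tolerance = 1e-8)
  expect_equal(res3$statistic, fit3["g3", "approx F"], tolerance = 1e-8)
  expect_equal(res3$p_value, fit3["g3", "Pr(>F)"], tolerance = 1e-8)
})

test_that("Wilks' lambda is invariant to common shifts and column scalings", {
  set.seed(97)
  x <- matrix(rnorm(45), 15, 3)
  g <- rep(c("a", "b", "c"), each = 5)
  l0 <- wilks_manova(x, g)$wilks_lambda
  shifted <- sweep(x, 2, c(10, -4, 0.5), "+")
  expect_equal(wilks_manova(shifted, g)$wilks_lambda, l0, tolerance = 1e-10)
  scaled <- sweep(x, 2, c(2, 0.1, 7), "*")
  expect_equal(wilks_manova(scaled, g)$wilks_lambda, l0, tolerance = 1e-10)
})

test_that("singular or under-determined feature sets are rejected with guidance", {
  set.seed(98)
  x <- matrix(rnorm(12), 4, 3)
  g <- c("a", "a", "b", "b")
  expect_error(wilks_manova(cbind(x, x[, 1]), g), "reduce the feature set")
  expect_error(wilks_manova(matrix(rnorm(8), 4, 2), c("a", "b", "a", "b")),
               NA)  # p = 2, n = 4 is the boundary but non-singular
  expect_error(wilks_manova(matrix(rnorm(20), 4, 5), g), "reduce the feature set")
  expect_error(wilks_manova(x, c("a", "a", "a", "b")), "at least 2 judges")
})

test_that("group_difference detects an injected model-type preference shift", {
  shift <- c(1.5, rep(0, 5))
  gs <- generate_survey(generator_spec(
    n_modelers = 20, seed = 123,
    judgment_noise_sigma = 0.2, agreement = 0.9,
    group_effects = list(list(factor = "model_type", level = "APSIM",
                              category = "CL", shift = shift))))
  suppressMessages(
    gd <- group_difference(gs$bundle, factor = "model_type", category = "CL",
                           retained = gs$bundle$profiles$modeler_id))
  expect_true(gd$manova$significant)
  # the shifted variable is flagged univariately too
  expect_true(gd$univariate$significant[1])
  # weights sum to 1, so one column is dropped from the MANOVA features
  expect_identical(gd$manova$p, 5L)
})
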