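test_that("priority vector handles identity and consistent matrices exactly", {
  pv <- priority_vector(pcm(matrix(1, 3, 3)))
  expect_equal(unname(pv$weights), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(pv$lambda_max, 3, tolerance = 1e-10)

  w <- c(0.6, 0.3, 0.1)
  pv <- priority_vector(consistent_pcm(w))
  expect_equal(unname(pv$weights), w, tolerance = 1e-10)
  expect_equal(pv$lambda_max, 3, tolerance = 1e-10)
})

test_that("priority vector matches a dense eigensolver oracle", {
  a <- pcm(matrix(c(1, 3, 1/2, 1/3, 1, 2, 2, 1/2, 1), 3, 3, byrow = TRUE))
  pv <- priority_vector(a)
  ev <- eigen(unclass(as.matrix(a)))
  k <- which.max(Re(ev$values))
  w_oracle <- Re(ev$vectors[, k]); w_oracle <- w_oracle / sum(w_oracle)
  expect_equal(unname(pv$weights), w_oracle, tolerance = 1e-8)
  expect_equal(pv$lambda_max, Re(ev$values[k]), tolerance = 1e-8)
})

test_that("Perron property and lambda_max >= n with equality iff consistent", {
  set.seed(101)
  for (r in 1:100) {
    n <- sample(3:8, 1)
    w <- danpsurvey:::rdirichlet1(3, n)
    pv_c <- priority_vector(consistent_pcm(w))
    expect_true(all(pv_c$weights > 0))
    expect_lt(abs(pv_c$lambda_max - n), 1e-8)

    p <- random_pcm(n)
    pv_p <- priority_vector(p)
    expect_true(all(pv_p$weights > 0))
    expect_gte(pv_p$lambda_max, n - 1e-8)
  }
})

test_that("eigenvector and row-geometric-mean weights agree near consistency", {
  set.seed(202)
  for (r in 1:20) {
    n <- sample(4:8, 1)
    w <- danpsurvey:::bound_ratio(danpsurvey:::rdirichlet1(5, n))
    p <- generate_pcm(w, sigma = 0.002)  # near-consistency limit, cr << 0.01
    expect_lt(consistency(p)$cr, 0.01)
    pv <- priority_vector(p)
    gm <- apply(unclass(as.matrix(p)), 1, function(row) exp(mean(log(row))))
    gm <- gm / sum(gm)
    expect_lt(max(abs(pv$weights - gm)), 1e-6)
  }
})

test_that("consistency index, ratio and flags follow the screening rules", {
  w <- c(0.5, 0.3, 0.2)
  cr <- consistency(consistent_pcm(w))
  expect_equal(cr$cr, 0, tolerance = 1e-10)
  expect_identical(cr$flag, "ok")

  # n = 2 is always perfectly consistent by convention
  expect_identical(consistency(pcm(matrix(c(1, 5, 1/5, 1), 2, 2, byrow = TRUE)))$cr, 0)

  # fixed perturbed 4x4: CR = (lambda - 4)/3 / RI(4) with oracle lambda
  a <- matrix(c(1, 2, 5, 1/2,
                1/2, 1, 3, 2,
                1/5, 1/3, 1, 1/4,
                2, 1/2, 4, 1), 4, 4, byrow = TRUE)
  p <- pcm(a)
  lam <- max(Re(eigen(a, only.values = TRUE)$values))
  rep4 <- consistency(p)
  expect_equal(rep4$cr, (lam - 4) / 3 / 0.90, tolerance = 1e-8)

  # flag bands: push noise until the ratio crosses the thresholds
  set.seed(33)
  w9 <- danpsurvey:::bound_ratio(danpsurvey:::rdirichlet1(5, 8))
  noisy <- generate_pcm(w9, sigma = 0.9)
  r <- consistency(noisy)
  expect_identical(r$flag,
                   if (r$cr > 0.30) "exclude" else if (r$cr > 0.10) "review" else "ok")
  expect_gt(r$cr, 0.10)  # sigma 0.9 is far past the review band for n = 8

  expect_error(consistency(random_pcm(16)), "unsupported")
})

test_that("consistency is invariant under simultaneous row/column permutation", {
  set.seed(44)
  p <- random_pcm(6, spread = 0.5)
  perm <- sample(6)
  pp <- pcm(unclass(as.matrix(p))[perm, perm])
  expect_equal(consistency(p)$cr, consistency(pp)$cr, tolerance = 1e-10)
})

test_that("geometric-mean aggregation is idempotent, symmetric and consistent-closed", {
  set.seed(55)
  p <- random_pcm(5)
  agg <- aggregate_pcms(list(p, p, p))
  expect_equal(unclass(as.matrix(agg)), unclass(as.matrix(p)), tolerance = 1e-12)

  inv <- pcm(1 / unclass(as.matrix(p)))
  ones <- aggregate_pcms(list(p, inv))
  expect_equal(unclass(as.matrix(ones)), matrix(1, 5, 5), tolerance = 1e-12,
               ignore_attr = TRUE)

  # aggregate of two consistent PCMs = consistent PCM of the normalized
  # element-wise geometric mean of the weight vectors
  w1 <- c(0.5, 0.3, 0.2); w2 <- c(0.2, 0.5, 0.3)
  agg2 <- aggregate_pcms(list(consistent_pcm(w1), consistent_pcm(w2)))
  wg <- sqrt(w1 * w2); wg <- wg / sum(wg)
  expect_equal(unclass(as.matrix(agg2)), outer(wg, wg, "/"), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(consistency(agg2)$cr, 0, tolerance = 1e-10)

  expect_error(aggregate_pcms(list()), "empty")
  q <- random_pcm(4)
  expect_error(aggregate_pcms(list(p, q)), "different item list")
})

test_that("screening retains exactly the modelers without an excluded matrix", {
  sig <- rep(0.3, 20); sig[7] <- 2.5  # one judge far past the exclusion band
  gs <- generate_survey(generator_spec(n_modelers = 20, seed = 99,
                                       judgment_noise_sigma = sig))
  scr <- screen_modelers(gs$bundle)
  # direct recount oracle over the same bundle
  ids <- gs$bundle$profiles$modeler_id
  bad <- vapply(ids, function(id) {
    mats <- c(gs$bundle$pcms[[id]], list(gs$bundle$category_pcm[[id]]))
    any(vapply(mats, function(m) consistency(m)$cr > 0.30, TRUE))
  }, TRUE)
  expect_identical(scr$retained, ids[!bad])
  expect_identical(scr$excluded, ids[bad])
  expect_true("M07" %in% scr$excluded)
  expect_length(scr$retained, 19)

  # fraction of judges above the review threshold per category, recounted
  tab <- scr$table
  for (code in c("SOI", "EDS")) {
    sub <- tab[tab$matrix == code, ]
    frac <- mean(sub$cr > 0.10)
    recount <- mean(vapply(ids, function(id)
      consistency(gs$bundle$pcms[[id]][[code]])$cr > 0.10, TRUE))
    expect_equal(frac, recount)
  }
})

test_that("fully consistent surveys are retained with no review flags", {
  gs <- generate_survey(generator_spec(protocol = small_protocol(),
                                       n_modelers = 4, seed = 1,
                                       judgment_noise_sigma = 0))
  scr <- screen_modelers(gs$bundle)
  expect_length(scr$retained, 4)
  expect_identical(nrow(scr$review), 0L)
  expect_true(all(scr$table$cr < 1e-8))
})
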