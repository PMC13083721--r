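test_that("equal-width partitions cover the observed range", {
  p <- build_partition(c(0, 0.3, 1), 4)
  expect_equal(p$breaks, c(0, 0.25, 0.5, 0.75, 1))
  expect_false(p$degenerate)
  p8 <- build_partition(c(-2, 2), 8)
  expect_equal(diff(p8$breaks), rep(0.5, 8))
  pd <- build_partition(rep(1.7, 5), 3)
  expect_true(pd$degenerate)
  expect_equal(pd$M, 1L)
  expect_error(build_partition(c(0, 1), 1), "M must be")
})

test_that("mass assignment reproduces singleton proportions and set evidence", {
  p <- build_partition(c(0, 1), 4)
  # four single-value sources hitting cells 1, 1, 3, 4
  m <- build_bpa(list(0.1, 0.15, 0.6, 0.9), p)
  key <- vapply(m$focal, paste, "", collapse = ",")
  expect_equal(m$mass[key == "1"], 0.5)
  expect_equal(m$mass[key == "3"], 0.25)
  expect_equal(m$mass[key == "4"], 0.25)
  expect_equal(sum(m$mass), 1, tolerance = 1e-12)
  # set-valued sources: one spans cells {1,2}, one {2,3}
  m2 <- build_bpa(list(c(0.1, 0.3), c(0.3, 0.6)), p)
  key2 <- vapply(m2$focal, paste, "", collapse = ",")
  expect_setequal(key2, c("1,2", "2,3"))
  expect_equal(m2$mass, c(0.5, 0.5))
  # out-of-range query values clamp with a warning
  expect_warning(m3 <- build_bpa(list(-0.5, 1.5), p), "clamped")
  expect_setequal(vapply(m3$focal, paste, "", collapse = ","), c("1", "4"))
})

test_that("belief and plausibility bracket ambiguous evidence", {
  p <- build_partition(c(0, 1), 4)
  m <- build_bpa(list(c(0.1, 0.3), c(0.3, 0.6)), p)  # m({1,2}) = m({2,3}) = .5
  expect_equal(belief(m, 1:4), 1)
  expect_equal(plausibility(m, 1:4), 1)
  expect_equal(belief(m, 2), 0)        # neither focal element is inside {2}
  expect_equal(plausibility(m, 2), 1)  # both intersect it
  # Bayesian (singleton) mass makes belief and plausibility coincide
  mb <- build_bpa(list(0.1, 0.15, 0.6, 0.9), p)
  expect_equal(belief(mb, 1), 0.5)
  expect_equal(plausibility(mb, 1), 0.5)
})

test_that("conflict measures the largest plausibility-belief gap", {
  p <- build_partition(c(0, 1), 4)
  expect_equal(conflict(build_bpa(list(0.1, 0.15, 0.6, 0.9), p), p), 0)
  m1 <- build_bpa(list(c(0.1, 0.3)), p)        # m({1,2}) = 1
  expect_equal(conflict(m1, p), 1)
  # m({1}) = 0.6, m({1,2}) = 0.4 -> gap 0.4 at both cells
  m2 <- build_bpa(list(0.1, 0.12, 0.2, c(0.1, 0.3), c(0.05, 0.4)), p)
  expect_equal(conflict(m2, p), 0.4)
})

test_that("belief duality and bounds hold on random mass functions", {
  set.seed(77)
  M <- 6
  for (r in 1:60) {
    nf <- sample(1:5, 1)
    focal <- lapply(seq_len(nf), function(i)
      sort(sample.int(M, sample(1:3, 1))))
    mass <- as.numeric(rmultinom(1, 20, rep(1, nf))) / 20
    keep <- mass > 0
    m <- structure(list(focal = focal[keep], mass = mass[keep], M = M),
                   class = "mass_function")
    A <- sort(sample.int(M, sample(1:5, 1)))
    expect_equal(sum(m$mass), 1, tolerance = 1e-12)
    expect_lte(belief(m, A), plausibility(m, A) + 1e-12)
    expect_equal(belief(m, A) + plausibility(m, setdiff(1:M, A)), 1,
                 tolerance = 1e-12)
    cf <- conflict(m)
    expect_true(cf >= 0 && cf <= 1)
  }
})

test_that("singleton belief converges to the cell probability with many sources", {
  p <- build_partition(c(0, 1), 5)
  errs <- vapply(c(50, 500, 5000), function(K) {
    set.seed(K)
    m <- build_bpa(as.list(runif(K, 0, 1)), p)
    max(abs(vapply(1:5, function(j) belief(m, j), 1) - 0.2))
  }, 1)
  expect_true(all(diff(errs) < 0))
})

test_that("the uncertainty distribution satisfies its boundary and median laws", {
  g <- uncertainty_cdf(c(1, 2, 3, 4))
  expect_equal(g$fun(0), 0)
  expect_equal(g$fun(4), 1)
  expect_equal(g$fun(2), 0.5)
  expect_equal(uncertainty_cdf(c(0, 0, 10))$fun(5), 2 / 3)
  set.seed(4)
  for (r in 1:10) {
    v <- rnorm(30)
    gg <- uncertainty_cdf(v)
    expect_equal(gg$fun(min(v) - 1), 0)
    expect_equal(gg$fun(max(v)), 1)
    grid <- seq(min(v) - 1, max(v) + 1, length.out = 50)
    expect_true(all(diff(gg$fun(grid)) >= 0))
    expect_gte(gg$fun(median(v)), 0.5)
  }
})

test_that("gamma entropy tracks dispersion and matches closed forms", {
  set.seed(15)
  wide <- uncertainty_cdf(runif(2000, 0, 3))
  narrow <- uncertainty_cdf(runif(2000, 0, 0.5))
  expect_gt(gamma_entropy(wide), gamma_entropy(narrow))
  expect_equal(gamma_entropy(uncertainty_cdf(runif(5000))), 0,
               tolerance = 0.05)
  expect_equal(gamma_entropy(uncertainty_cdf(rnorm(5000))),
               0.5 * log(2 * pi * exp(1)), tolerance = 0.05)
  expect_equal(gamma_entropy(uncertainty_cdf(rep(2, 5))), -Inf,
               ignore_attr = TRUE)
})

test_that("acquisition ranking sorts by variance with entropy tie-break", {
  expect_equal(unname(acquisition_ranking(c(4, 1))), c(1L, 2L))
  expect_equal(unname(acquisition_ranking(c(1, 1), c(0.3, 1.2))), c(2L, 1L))
  r <- acquisition_ranking(c(a = 0.2, b = 0.9, c = 0.5))
  expect_equal(unname(r), c(2L, 3L, 1L))
  expect_equal(names(r), c("b", "c", "a"))
})
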