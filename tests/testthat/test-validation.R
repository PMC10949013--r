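test_that("R2 reproduces hand-computed values", {
  y <- c(1, 2, 3)
  expect_equal(r2(y, y), 1)
  expect_equal(r2(y, rep(mean(y), 3)), 0)
  expect_equal(r2(y, c(1, 2, 4)), 0.5)  # 1 - 1/2
  expect_error(r2(c(2, 2, 2), c(1, 2, 3)), "variance")
})

test_that("external Q2F1/Q2F2 match hand arithmetic and their inequality", {
  expect_equal(q2_f1(c(1, 3), c(1, 3), 5), 1)
  expect_equal(q2_f2(c(1, 3), c(1, 3)), 1)
  expect_equal(q2_f1(c(1, 3), c(2, 2), 2), 0)  # 1 - 2/2
  # denominator inequality: Q2F1 >= Q2F2, strict when means differ
  for (seed in 1:20) {
    set.seed(seed)
    y <- rnorm(8); p <- y + rnorm(8, 0, 0.5); m_tr <- rnorm(1)
    f1 <- q2_f1(y, p, m_tr); f2 <- q2_f2(y, p)
    expect_gte(f1 + 1e-12, f2)
    expect_lte(f1, 1); expect_lte(f2, 1)
    if (abs(m_tr - mean(y)) > 1e-8) expect_gt(f1, f2)
  }
})

test_that("LOO Q2 is exact on noise-free data and matches a brute-force oracle", {
  inst <- random_linear_instance(10, 2, noise = 0, seed = 4)
  expect_equal(q2_loo(inst$table, "y", inst$features, "MLR"), 1,
               tolerance = 1e-10)

  # independent double loop with lm() on a noisy 10-point instance
  inst <- random_linear_instance(10, 2, noise = 2, seed = 8)
  press <- 0
  for (i in 1:10) {
    fit <- stats::lm(y ~ x1 + x2, inst$table[-i, ])
    press <- press + (inst$table$y[i] - predict(fit, inst$table[i, ]))^2
  }
  oracle <- 1 - press / sum((inst$table$y - mean(inst$table$y))^2)
  expect_equal(q2_loo(inst$table, "y", inst$features, "MLR"), unname(oracle),
               tolerance = 1e-10)
  # PLS path at full rank agrees with the same oracle
  expect_equal(q2_loo(inst$table, "y", inst$features, "PLS", 2),
               unname(oracle), tolerance = 1e-8)
})

test_that("LOO Q2 is negative for most pure-noise responses", {
  neg <- vapply(1:100, function(seed) {
    set.seed(seed)
    tab <- data.frame(x1 = rnorm(20), x2 = rnorm(20), y = rnorm(20))
    q2_loo(tab, "y", c("x1", "x2"), "MLR") < 0
  }, logical(1))
  expect_gt(mean(neg), 0.5)
})

test_that("rm2 metrics behave at the identities and match an algebraic oracle", {
  y <- c(0.1, 0.4, 0.5, 0.8, 1.0)
  ident <- rm2_metrics(y, y)
  expect_equal(ident$rm2_mean, 1)
  expect_equal(ident$rm2_delta, 0)
  # constant shift survives min-max scaling identically, so compare unscaled
  shifted <- rm2_metrics(y, y + 0.3, scale = FALSE)
  expect_gt(shifted$rm2_delta, 0)

  # algebraic oracle via lm() through-origin fits on the scaled values
  p <- c(0.15, 0.3, 0.6, 0.75, 0.95)
  mm <- function(v) (v - min(v)) / (max(v) - min(v))
  ys <- mm(y); ps <- mm(p)
  rm2_one <- function(a, b) {
    r2c <- cor(a, b)^2
    k <- coef(stats::lm(a ~ 0 + b))
    r02 <- 1 - sum((a - k * b)^2) / sum((a - mean(a))^2)
    r2c * (1 - sqrt(max(r2c - r02, 0)))
  }
  got <- rm2_metrics(y, p)
  expect_equal(got$rm2_mean, (rm2_one(ys, ps) + rm2_one(ps, ys)) / 2,
               tolerance = 1e-12)
  expect_equal(got$rm2_delta, abs(rm2_one(ys, ps) - rm2_one(ps, ys)),
               tolerance = 1e-12)
})

test_that("F statistic matches hand arithmetic and the published 1-LV value", {
  # R2 = 0.80, n = 13, p = 1 (one latent variable) -> 44.0, printed 44.20
  f1 <- f_statistic(0.80, 13, 1)
  expect_equal(f1$f, 44, tolerance = 1e-10)
  expect_lt(abs(f1$f - 44.20), 0.5)
  expect_lt(f1$p_value, 0.01)
  expect_equal(f_statistic(0, 20, 3)$f, 0)
  expect_equal(f_statistic(0.5, 12, 2)$f, 4.5)
  expect_equal(f_statistic(1, 10, 2)$f, Inf)
})

test_that("Y-randomization is seeded, deterministic, and separates signal from noise", {
  inst <- random_linear_instance(20, 2, noise = 0.01, seed = 12)
  yr <- y_randomization(inst$table, "y", inst$features, n_perm = 100, seed = 5)
  expect_equal(yr$exceedance, 0)  # noise-free strong model
  yr2 <- y_randomization(inst$table, "y", inst$features, n_perm = 100, seed = 5)
  expect_identical(yr$r2_perm, yr2$r2_perm)

  # pure-noise response: permuted R2 is exchangeable with the true one
  exc <- vapply(1:5, function(s) {
    set.seed(s + 100)
    tab <- data.frame(x1 = rnorm(25), x2 = rnorm(25), y = rnorm(25))
    y_randomization(tab, "y", c("x1", "x2"), n_perm = 100, seed = s)$exceedance
  }, numeric(1))
  expect_gte(mean(exc), 0.2)
})

test_that("Williams leverages satisfy the hat-matrix identities", {
  for (seed in 1:10) {
    inst <- random_linear_instance(sample(10:40, 1), sample(2:5, 1),
                                   noise = 1, seed = seed)
    fit <- fit_mlr(inst$table, "y", inst$features)
    rep <- williams(fit, inst$table, NULL, "y")
    tr <- rep$points[rep$points$set == "train", ]
    p <- length(inst$features) + 1
    n <- nrow(inst$table)
    expect_equal(sum(tr$h), p, tolerance = 1e-8)       # trace identity
    expect_true(all(tr$h >= 1 / n - 1e-12 & tr$h <= 1 + 1e-12))
    expect_equal(rep$h_star, 3 * p / n)
  }
})

test_that("Williams geometry of the damage model gives h* = 3*9/111", {
  # 8 descriptors + intercept on a 111-point training set
  set.seed(33)
  tab <- as.data.frame(matrix(rnorm(111 * 8), 111, 8,
                              dimnames = list(NULL, paste0("x", 1:8))))
  tab$y <- rnorm(111)
  fit <- fit_mlr(tab, "y", paste0("x", 1:8))
  rep <- williams(fit, tab, NULL, "y")
  expect_equal(rep$p, 9)
  expect_equal(rep$h_star, 3 * 9 / 111)
  expect_equal(round(rep$h_star, 4), 0.2432)
})

test_that("Williams flags extreme-x and extreme-y points", {
  set.seed(44)
  tab <- data.frame(x1 = c(rnorm(20), 8))  # one high-leverage point
  tab$y <- 2 * tab$x1 + rnorm(21, 0, 0.5)
  tab$y[5] <- tab$y[5] + 10                # one response outlier
  fit <- fit_mlr(tab, "y", "x1")
  rep <- williams(fit, tab, NULL, "y")
  tr <- rep$points
  # the most extreme x has the maximum leverage (monotone in |x - mean|)
  expect_equal(which.max(tr$h), 21L)
  expect_true(tr$x_outlier[21])
  expect_true(tr$y_outlier[5])
  # evaluation points get leverages from the training (X'X)^-1
  ev <- data.frame(x1 = c(0, 10), y = c(0, 20))
  rep2 <- williams(fit, tab, ev, "y")
  evp <- rep2$points[rep2$points$set == "eval", ]
  expect_gt(evp$h[2], rep2$h_star)
  expect_lt(evp$h[1], rep2$h_star)
})
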