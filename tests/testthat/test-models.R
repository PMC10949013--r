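test_that("MLR recovers generating coefficients exactly on noise-free data", {
  desc <- descriptor_table(study_formulas())
  m1 <- published_model("model1")
  desc$zeta_mv <- predict(m1, desc)
  fit <- fit_mlr(desc, "zeta_mv", names(m1$coefficients))
  expect_equal(fit$intercept, m1$intercept, tolerance = 1e-8)
  expect_equal(fit$coefficients, m1$coefficients, tolerance = 1e-8)
})

test_that("MLR matches the normal-equations oracle and the 2-point line", {
  inst <- random_linear_instance(10, 3, noise = 1, seed = 42)
  fit <- fit_mlr(inst$table, "y", inst$features)
  X <- as.matrix(inst$table[, inst$features])
  beta <- ols_oracle(X, inst$table$y)
  expect_equal(unname(c(fit$intercept, fit$coefficients)), unname(beta),
               tolerance = 1e-10)

  two <- data.frame(x1 = c(0, 2), x2 = c(1, 1), y = c(1, 5))
  fit2 <- fit_mlr(two[, c("x1", "y")], "y", "x1")
  expect_equal(unname(predict(fit2, two)), two$y, tolerance = 1e-12)
})

test_that("MLR errors name collinear columns and reject constants", {
  inst <- random_linear_instance(12, 2, seed = 7)
  inst$table$x3 <- inst$table$x1 + inst$table$x2
  expect_error(fit_mlr(inst$table, "y", c("x1", "x2", "x3")), "collinear")
  inst$table$x4 <- 5
  expect_error(fit_mlr(inst$table, "y", c("x1", "x4")), "constant")
})

test_that("PLS with full latent rank reproduces MLR on random instances", {
  for (seed in 1:25) {
    n <- sample(8:30, 1)
    p <- sample(2:5, 1)
    inst <- random_linear_instance(n, p, noise = 1, seed = seed)
    mlr <- fit_mlr(inst$table, "y", inst$features)
    pls <- fit_pls(inst$table, "y", inst$features, n_latent = p)
    expect_equal(predict(pls, inst$table), predict(mlr, inst$table),
                 tolerance = 1e-8)
  }
})

test_that("single-feature 1-LV PLS equals simple regression", {
  inst <- random_linear_instance(15, 1, noise = 0.5, seed = 3)
  pls <- fit_pls(inst$table, "y", "x1", 1)
  lmf <- stats::lm(y ~ x1, inst$table)
  expect_equal(unname(pls$intercept), unname(coef(lmf)[1]), tolerance = 1e-10)
  expect_equal(unname(pls$coefficients), unname(coef(lmf)[2]), tolerance = 1e-10)
})

test_that("PLS caps n_latent at the design rank with a warning", {
  inst <- random_linear_instance(20, 2, seed = 5)
  inst$table$x3 <- inst$table$x1 + inst$table$x2  # rank 2 in 3 columns
  expect_warning(fit <- fit_pls(inst$table, "y", c("x1", "x2", "x3"), 3),
                 "capped")
  expect_equal(fit$n_latent, 2L)
})

test_that("intermediate-LV PLS regression vector matches an independent NIPALS pass", {
  # independent implementation: textbook NIPALS recursion written directly
  # on the scaled matrices, without the packed helper-matrix algebra
  inst <- random_linear_instance(40, 8, noise = 1, seed = 11)
  X <- scale(as.matrix(inst$table[, inst$features]))
  y <- inst$table$y - mean(inst$table$y)
  E <- X; ws <- list(); ps <- list(); qs <- c()
  for (a in 1:7) {
    w <- drop(t(E) %*% y); w <- w / sqrt(sum(w^2))
    t_sc <- drop(E %*% w)
    p_l <- drop(t(E) %*% t_sc) / sum(t_sc^2)
    qs <- c(qs, sum(y * t_sc) / sum(t_sc^2))
    E <- E - outer(t_sc, p_l)
    y <- y - qs[a] * t_sc
    ws[[a]] <- w; ps[[a]] <- p_l
  }
  W <- do.call(cbind, ws); P <- do.call(cbind, ps)
  beta_sc <- drop(W %*% solve(t(P) %*% W) %*% qs)
  beta_raw <- beta_sc / attr(X, "scaled:scale")

  fit <- fit_pls(inst$table, "y", inst$features, 7)
  expect_equal(unname(fit$coefficients), unname(beta_raw), tolerance = 1e-8)
})

test_that("published models carry the printed coefficients verbatim", {
  m1 <- published_model("model1")
  expect_equal(m1$intercept, 35.9157)
  expect_equal(unname(m1$coefficients["chi_ox"]), -8.4317)
  expect_equal(unname(m1$coefficients["tot_metal_alpha"]), 2.0002)
  expect_equal(unname(m1$coefficients["vep"]), -0.1854)
  expect_equal(m1$n_latent, 1L)

  m2 <- published_model("model2")
  expect_equal(m2$intercept, -1.681)
  expect_equal(unname(m2$coefficients["time_h"]), 0.035)
  expect_equal(unname(m2$coefficients["zeta_mv"]), 0.00057)
  expect_equal(m2$n_latent, 7L)
  expect_error(published_model("model3"))

  # intercept-only predictions
  zero1 <- data.frame(chi_ox = 0, tot_metal_alpha = 0, vep = 0)
  expect_equal(predict(m1, zero1), 35.9157)
  zero2 <- as.data.frame(as.list(setNames(rep(0, 8), names(m2$coefficients))))
  expect_equal(predict(m2, zero2), -1.681)

  # WO3 through model 1 gives a finite mV value (experimental: -23 mV)
  wo3 <- descriptor_table("WO3")
  expect_true(is.finite(predict(m1, wo3)))
})

test_that("refit predictions are invariant under affine descriptor rescaling", {
  inst <- random_linear_instance(25, 3, noise = 1, seed = 9)
  base <- predict(fit_mlr(inst$table, "y", inst$features), inst$table)
  tab2 <- inst$table
  tab2$x1 <- 10 * tab2$x1 + 5
  tab2$x3 <- -0.2 * tab2$x3
  resc <- predict(fit_mlr(tab2, "y", inst$features), tab2)
  expect_equal(resc, base, tolerance = 1e-8)
})

test_that("stepwise selection finds dominant features and flags noise", {
  # only x1 determines y: nothing else can improve the fit
  set.seed(21)
  tab <- data.frame(x1 = rnorm(30), x2 = rnorm(30), x3 = rnorm(30))
  tab$y <- 3 * tab$x1
  expect_equal(stepwise_select(tab, "y", c("x1", "x2", "x3")), "x1")

  # noise-free zeta equation with distractor columns
  desc <- descriptor_table(study_formulas())
  m1 <- published_model("model1")
  desc$zeta_mv <- predict(m1, desc)
  sel <- stepwise_select(desc, "zeta_mv",
                         c("chi_ox", "tot_metal_alpha", "vep",
                           "electrons_active_m", "valence"))
  expect_setequal(intersect(sel, names(m1$coefficients)),
                  names(m1$coefficients))

  # all-noise features: empty or spurious single pick, with a warning
  set.seed(22)
  noise <- data.frame(x1 = rnorm(25), x2 = rnorm(25), y = rnorm(25))
  sel2 <- withCallingHandlers(
    stepwise_select(noise, "y", c("x1", "x2")),
    warning = function(w) invokeRestart("muffleWarning"))
  expect_lte(length(sel2), 1)
})

test_that("model JSON serialization round-trips the coefficients", {
  m <- published_model("model1")
  path <- tempfile(fileext = ".json")
  write_model_json(m, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$intercept, 35.9157)
  expect_equal(back$coefficients$chi_ox, -8.4317)
  expect_equal(back$kind, "PLS")
})
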