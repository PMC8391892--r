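test_that("PLSR and PCR reduce to OLS at full rank", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(40), 8, 5)
    y <- rnorm(8)
    b <- ols_oracle(X, y)
    for (m in c("plsr", "pcr"))
      expect_equal(coef(fit_mvr(X, y, method = m, ncomp = 5)), b,
                   tolerance = 1e-8, label = paste(m, "seed", seed))
  }
})

test_that("rank-one noiseless data is fit exactly with one factor", {
  y <- c(0, 2, 4, 8, 16, 32, 64, 100)
  X <- outer(y, c(0.2, -0.5, 1, 0.7)) / 100
  for (m in c("plsr", "pcr")) {
    fit <- fit_mvr(X, y, method = m, ncomp = 1)
    expect_equal(fitted(fit), y, tolerance = 1e-10)
    expect_equal(predict(fit, X), y, tolerance = 1e-10)
  }
})

test_that("the first PLS weight vector is the normalized covariance", {
  set.seed(3)
  X <- matrix(rnorm(48), 8, 6); y <- rnorm(8)
  fit <- fit_mvr(X, y, method = "plsr", ncomp = 2)
  Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  w1 <- drop(crossprod(Xc, yc)); w1 <- w1 / sqrt(sum(w1^2))
  expect_equal(unname(fit$weights[, 1]), unname(w1), tolerance = 1e-12)
})

test_that("PCR predictions are invariant to consistent column permutation", {
  set.seed(4)
  X <- matrix(rnorm(56), 8, 7); y <- rnorm(8)
  perm <- sample(7)
  p1 <- predict(fit_mvr(X, y, "pcr", ncomp = 3), X)
  p2 <- predict(fit_mvr(X[, perm], y, "pcr", ncomp = 3), X[, perm])
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("prediction respects the centering identity", {
  set.seed(5)
  X <- matrix(rnorm(45), 9, 5); y <- rnorm(9)
  fit <- fit_mvr(X, y, "plsr", ncomp = 2)
  expect_equal(predict(fit, colMeans(X)), mean(y), tolerance = 1e-12)
  expect_error(predict(fit, matrix(0, 1, 4)), "columns")
})

test_that("fits agree with an independent established PLS implementation", {
  skip_if_not_installed("mixOmics")
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(64), 8, 8); colnames(X) <- paste0("v", 1:8)
    y <- rnorm(8)
    k <- 3
    ref <- mixOmics::pls(X, matrix(y), ncomp = k, mode = "regression",
                         scale = FALSE)
    p_ref <- drop(predict(ref, X)$predict[, , k])
    fit <- fit_mvr(X, y, "plsr", ncomp = k)
    expect_equal(unname(predict(fit, X)), unname(p_ref), tolerance = 1e-6)
  }
})

test_that("cv_metrics reproduces the defining identities and printed pairs", {
  y <- c(0, 2, 4, 8, 16, 32, 64, 100)
  perfect <- cv_metrics(y, y)
  expect_equal(perfect$press, 0)
  expect_equal(perfect$secv, 0)
  expect_equal(perfect$bias, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$slope, 1)
  expect_equal(perfect$intercept, 0)
  # SECV = sqrt(PRESS/n) at n = 8 reproduces published-style pairs
  expect_equal(round(secv_from_press(34.57, 8), 2), 2.08)
  expect_equal(round(secv_from_press(1.49, 8), 2), 0.43)
  expect_equal(round(secv_from_press(52.06, 8), 2), 2.55)
  # bias is the absolute mean residual
  expect_equal(cv_metrics(c(0, 10, 20), c(1, 9, 20))$bias, 0)
  expect_equal(cv_metrics(c(0, 10, 20), c(2, 12, 22))$bias, 2)
  expect_error(cv_metrics(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("secv * sqrt(n) equals sqrt(press) across random inputs", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(3:20, 1)
    y <- rnorm(n); yh <- y + rnorm(n)
    m <- cv_metrics(y, yh)
    expect_equal(m$secv * sqrt(n), sqrt(m$press), tolerance = 1e-9)
    expect_true(m$r2 >= 0 && m$r2 <= 1)
  }
})

test_that("LOO cross-validation recovers noiseless low-rank systems", {
  y <- c(0, 2, 4, 8, 16, 32, 64, 100)
  X1 <- outer(y, c(1, 0.3, -0.7)) / 100
  for (m in c("plsr", "pcr")) {
    cv <- loo_cv(X1, y, method = m, ncomp = 1)
    expect_lt(cv$press, 1e-8)
    expect_equal(cv$n, 8)
    expect_equal(cv$secv, sqrt(cv$press / 8))
  }
  # hand-rolled per-fold OLS oracle on the single component score
  s <- c(1, 0.3, -0.7)
  t_score <- drop(X1 %*% s)
  oracle <- vapply(seq_along(y), function(i) {
    fit <- stats::lm.fit(cbind(1, t_score[-i]), y[-i])
    sum(fit$coefficients * c(1, t_score[i]))
  }, numeric(1))
  cv <- loo_cv(X1, y, method = "plsr", ncomp = 1)
  expect_equal(cv$y_predicted, oracle, tolerance = 1e-8)
})

test_that("LOO predictions are invariant to sample ordering", {
  tc <- two_component_set(p = 10, seed = 7)
  X <- tc$X + matrix(rnorm(80, sd = 1e-3), 8, 10)
  perm <- c(5, 1, 8, 3, 7, 2, 6, 4)
  cv1 <- loo_cv(X, tc$y, "plsr", ncomp = 2)
  cv2 <- loo_cv(X[perm, ], tc$y[perm], "plsr", ncomp = 2)
  expect_equal(cv1$y_predicted[perm], cv2$y_predicted, tolerance = 1e-10)
  expect_error(loo_cv(outer(c(1, 1, 1, 2), 1:3), c(5, 5, 5, 7), "plsr", 1),
               "fold error.*'4'")
})

test_that("PRESS is non-increasing in k on noiseless data up to the rank", {
  set.seed(12)
  y <- c(0, 2, 4, 8, 16, 32, 64, 100)
  X <- outer(y / 100, rnorm(9)) + outer(runif(8), rnorm(9)) # rank 2 + centering
  for (m in c("plsr", "pcr")) { # centered rank is 2, so sweep k = 1, 2
    press <- vapply(1:2, function(k) loo_cv(X, y, m, ncomp = k)$press,
                    numeric(1))
    expect_true(all(diff(press) <= 1e-8), label = m)
  }
})

test_that("factor selection minimizes LOO PRESS with ties toward smaller k", {
  # two-component noiseless mixtures select k = 2
  tc <- two_component_set(p = 8, seed = 2)
  expect_equal(select_factors(tc$X, tc$y, "plsr", k_max = 4), 2)
  # exhaustive sweep oracle
  press <- vapply(1:4, function(k) loo_cv(tc$X, tc$y, "plsr", ncomp = k)$press,
                  numeric(1))
  expect_equal(which.min(press), 2L)
})

test_that("noisy two-component series keep cross-validated R2 high", {
  # r2 >= 0.985 in at least 95% of 100 seeded replicates
  ok <- 0L
  for (seed in 1:100) {
    tc <- two_component_set(p = 12, seed = 1000 + seed)
    set.seed(seed)
    X <- tc$X + matrix(rnorm(length(tc$X), sd = 0.003), nrow = 8)
    if (loo_cv(X, tc$y, "plsr", ncomp = 2)$r2 >= 0.985) ok <- ok + 1L
  }
  expect_gte(ok, 95)
})
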