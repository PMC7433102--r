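# fixed 3-tip tree with hand-computed patristic distances:
# (A:1,(B:0.5,C:0.5):0.5);  d(A,B) = d(A,C) = 2, d(B,C) = 1
abc_tree <- ape::read.tree(text = "(A:1,(B:0.5,C:0.5):0.5);")

test_that("OU correlation matrix matches hand-computed patristic distances", {
  two <- ape::read.tree(text = "(A:0.7,B:0.7);")
  M <- ou_correlation_matrix(two, 1.3)
  expect_equal(M["A", "B"], exp(-1.3 * 2 * 0.7))
  expect_equal(diag(M), c(A = 1, B = 1))

  M3 <- ou_correlation_matrix(abc_tree, 1)
  expect_equal(M3["A", "B"], exp(-2))
  expect_equal(M3["A", "C"], exp(-2))
  expect_equal(M3["B", "C"], exp(-1))

  # numerically identity in the independence limit
  Mbig <- ou_correlation_matrix(abc_tree, 1e3)
  expect_lt(max(abs(Mbig - diag(3))), 1e-15)
  expect_error(ou_correlation_matrix(abc_tree, 0), "positive")
})

test_that("lambda correlation scales shared paths only", {
  tr <- simulate_tree(4, seed = 6)
  expect_equal(lambda_correlation_matrix(tr, 0), diag(4), ignore_attr = TRUE)
  Cbm <- stats::cov2cor(ape::vcv(tr))
  expect_equal(lambda_correlation_matrix(tr, 1), Cbm, tolerance = 1e-12)
  Chalf <- lambda_correlation_matrix(tr, 0.5)
  off <- upper.tri(Cbm)
  expect_equal(Chalf[off], 0.5 * Cbm[off], tolerance = 1e-12)
  expect_error(lambda_correlation_matrix(tr, -0.1), "nonnegative")
  expect_error(lambda_correlation_matrix(tr, 2), "cap")
})

test_that("area weights follow the inverse-smallest-log-area formula", {
  expect_equal(area_weights(c(50, 50, 50)), rep(1, 3))
  expect_equal(area_weights(c(1e2, 1e4)), c(1, 2))
  set.seed(3)
  areas <- 10^runif(20, 1, 6)
  a <- log10(areas)
  expect_equal(area_weights(areas), a / min(a), tolerance = 1e-12)
  expect_error(area_weights(c(10, -3)), "positive")
  expect_error(area_weights(c(0.5, 10)), "exceed 1")
})

test_that("PGLS reduces to OLS without phylogenetic correlation", {
  n <- 40
  star <- star_tree(n)
  set.seed(1)
  dat <- data.frame(y = rnorm(n), x = rnorm(n), row.names = star$tip.label)
  fit <- pgls_fit(y ~ x, dat, star, correlation = "OU")
  ols <- lm(y ~ x, dat)
  expect_lt(max(abs(fit$coefficients - coef(ols))), 1e-8)

  # three-way consistency on one non-star dataset
  tr <- simulate_tree(30, seed = 3)
  set.seed(2)
  dat2 <- data.frame(y = rnorm(30), x = rnorm(30), row.names = tr$tip.label)
  ols2 <- coef(lm(y ~ x, dat2))
  f_alpha <- pgls_fit(y ~ x, dat2, tr, alpha = 1e6 / max(ape::vcv(tr)))
  f_lam0 <- pgls_fit(y ~ x, dat2, tr, correlation = "lambda", lambda = 0)
  expect_lt(max(abs(f_alpha$coefficients - ols2)), 1e-6)
  expect_lt(max(abs(f_lam0$coefficients - ols2)), 1e-10)
  # lambda = 1 equals a Brownian-motion GLS computed directly
  f_lam1 <- pgls_fit(y ~ x, dat2, tr, correlation = "lambda", lambda = 1)
  C <- stats::cov2cor(ape::vcv(tr))[tr$tip.label, tr$tip.label]
  Ci <- solve(C)
  X <- cbind(1, dat2[tr$tip.label, "x"])
  yv <- dat2[tr$tip.label, "y"]
  beta_gls <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% yv)
  expect_lt(max(abs(f_lam1$coefficients - beta_gls)), 1e-10)
})

test_that("PGLS agrees with nlme::gls under the OU correlation", {
  skip_if_not_installed("nlme")
  tr <- simulate_tree(50, seed = 11)
  set.seed(42)
  x <- rnorm(50)
  y <- 2 + 1.5 * x + as.numeric(simulate_ou_trait(tr, 2, 1))
  dat <- data.frame(y = y, x = x, row.names = tr$tip.label)
  ref <- suppressWarnings(
    nlme::gls(y ~ x, dat, correlation = ape::corMartins(3, phy = tr,
                                                        fixed = TRUE),
              method = "ML"))
  mine <- pgls_fit(y ~ x, dat, tr, alpha = 3)
  expect_lt(max(abs(mine$coefficients - coef(ref))), 1e-10)
  expect_equal(mine$logLik, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_equal(unname(mine$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-6)

  ref_ml <- suppressWarnings(
    nlme::gls(y ~ x, dat, correlation = ape::corMartins(1, phy = tr),
              method = "ML"))
  mine_ml <- pgls_fit(y ~ x, dat, tr)
  a_ref <- as.numeric(coef(ref_ml$modelStruct$corStruct,
                           unconstrained = FALSE))
  expect_equal(mine_ml$alpha, a_ref, tolerance = 1e-3)
  expect_lt(max(abs(mine_ml$coefficients - coef(ref_ml))), 1e-6)
})

test_that("PGLS interpolates exact linear data and flags collinearity", {
  tr <- simulate_tree(12, seed = 8)
  set.seed(5)
  x <- rnorm(12)
  dat <- data.frame(y = 3 - 2 * x, x = x, row.names = tr$tip.label)
  fit <- pgls_fit(y ~ x, dat, tr, alpha = 0.5)
  expect_equal(unname(fit$coefficients), c(3, -2), tolerance = 1e-9)

  dat$z <- 2 * dat$x
  expect_error(pgls_fit(y ~ x + z, dat, tr, alpha = 0.5), "collinear")
})

test_that("PGLS is invariant to tip order and to constant weights", {
  tr <- simulate_tree(25, seed = 9)
  set.seed(10)
  dat <- data.frame(y = rnorm(25), x = rnorm(25), row.names = tr$tip.label)
  f1 <- pgls_fit(y ~ x, dat, tr)
  f2 <- pgls_fit(y ~ x, dat[sample(25), ], tr)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-12)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-10)

  f3 <- pgls_fit(y ~ x, dat, tr, weights = rep(1, 25))
  f4 <- pgls_fit(y ~ x, dat, tr,
                 weights = stats::setNames(rep(2.5, 25), tr$tip.label))
  expect_equal(f1$coefficients, f3$coefficients, tolerance = 1e-12)
  expect_equal(f3$coefficients, f4$coefficients, tolerance = 1e-10)
})

test_that("likelihood-ratio contrast is calibrated and bookkeeps df", {
  tr <- simulate_tree(20, seed = 2)
  set.seed(3)
  dat <- data.frame(y = rnorm(20), x = rnorm(20), row.names = tr$tip.label)
  f0 <- pgls_fit(y ~ 1, dat, tr, alpha = 1)
  expect_error(lr_anova(f0, f0), "not larger")
  f1 <- pgls_fit(y ~ x, dat, tr, alpha = 1)
  out <- lr_anova(f0, f1)
  expect_identical(out$df, 1L)
  expect_gte(out$statistic, 0)

  fother <- pgls_fit(y ~ 1, data.frame(y = rnorm(20), x = 0,
                                       row.names = tr$tip.label), tr,
                     alpha = 1)
  expect_error(lr_anova(fother, f1), "identical data")

  # null calibration of the nested contrast (chi-square reference)
  star <- star_tree(35)
  set.seed(6)
  rej <- mean(replicate(300, {
    d <- data.frame(y = rnorm(35), x = rnorm(35),
                    row.names = star$tip.label)
    lr_anova(pgls_fit(y ~ 1, d, star, alpha = 5),
             pgls_fit(y ~ x, d, star, alpha = 5))$p < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("variance-heterogeneity contrast detects and calibrates", {
  tr <- simulate_tree(60, seed = 12)
  grp <- rep(c("a", "b"), 30)
  names(grp) <- tr$tip.label
  D <- ape::cophenetic.phylo(tr)

  # power: group b has 4x residual variance
  set.seed(7)
  hits <- mean(replicate(25, {
    y <- as.numeric(simulate_ou_trait(tr, 3, 1)) +
      rnorm(60, 0, ifelse(grp == "b", 2, 0.5))
    names(y) <- tr$tip.label
    variance_heterogeneity_test(y, grp, tr, dist = D)$p < 0.05
  }))
  expect_gt(hits, 0.6)

  # type I under equal variances
  set.seed(8)
  fp <- mean(replicate(60, {
    y <- as.numeric(simulate_ou_trait(tr, 3, 1)) + rnorm(60, 0, 1)
    names(y) <- tr$tip.label
    variance_heterogeneity_test(y, grp, tr, dist = D)$p < 0.05
  }))
  expect_lt(fp, 0.17)

  # well-posedness on identical values across groups and a star tree
  star <- star_tree(20)
  yv <- stats::setNames(rep(c(1, 2, 3, 4), 5), star$tip.label)
  res <- variance_heterogeneity_test(yv, rep(c("a", "b"), 10), star)
  expect_gte(res$statistic, 0)
  expect_true(is.finite(res$statistic))
  expect_identical(res$df, 1L)

  expect_error(variance_heterogeneity_test(yv, rep("a", 20), star),
               "2 groups")
})

test_that("phylogenetic ANCOVA reports the interaction and rejects degeneracy", {
  tr <- simulate_tree(80, seed = 14)
  set.seed(15)
  f <- rbinom(80, 1, 0.5)
  x <- rnorm(80)
  # slopes differ by 1 between groups
  y <- 1 + 0.5 * x + 1 * f * x + as.numeric(simulate_ou_trait(tr, 3, 0.5))
  names(y) <- tr$tip.label
  fit <- ancova_interaction(y, f, x, tr)
  expect_lt(fit$interaction_p, 0.05)

  expect_error(ancova_interaction(y, f, f, tr), "collinear")
})

test_that("Pagel's lambda recovers signal and loses it under shuffling", {
  tr <- simulate_tree(120, seed = 16)
  set.seed(17)
  lams <- replicate(15, phylosig_lambda(simulate_ou_trait(tr, 0, 1), tr)$lambda)
  expect_gt(median(lams), 0.9)
  expect_lt(median(lams), 1.05)

  set.seed(18)
  shuf <- replicate(15, {
    y <- simulate_ou_trait(tr, 0, 1)
    names(y) <- sample(names(y))
    phylosig_lambda(y, tr)$lambda
  })
  expect_lte(median(shuf), 0.1)

  y <- simulate_ou_trait(tr, 0, 1, seed = 19)
  fit <- phylosig_lambda(y, tr)
  expect_gte(fit$logLik, fit$logLik0 - 1e-8)
  expect_gte(fit$logLik, fit$logLik1 - 1e-8)
  expect_error(phylosig_lambda(rep(1, 120), tr), "constant")
})

test_that("lambda estimates agree with phytools::phylosig", {
  skip_if_not_installed("phytools")
  tr <- simulate_tree(60, seed = 20)
  y <- simulate_ou_trait(tr, 0, 1, seed = 21)
  ref <- phytools::phylosig(tr, y, method = "lambda", test = TRUE)
  mine <- phylosig_lambda(y, tr)
  expect_equal(mine$lambda, ref$lambda, tolerance = 0.01)
  expect_equal(mine$p, ref$P, tolerance = 0.05)
})

test_that("phylogenetic logistic regression has the right limits and power", {
  n <- 80
  star <- star_tree(n)
  set.seed(22)
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.3 + 1.2 * x))
  dat <- data.frame(y = y, x = x, row.names = star$tip.label)
  fit <- phylo_logistic_fit(y ~ x, dat, star)
  oracle <- oracle_firth_logistic(y, cbind(1, x))
  expect_lt(max(abs(fit$coefficients - oracle)), 1e-4)

  # complete separation: finite estimates, warning, flag
  ysep <- as.integer(x > 0)
  dsep <- data.frame(y = ysep, x = x, row.names = star$tip.label)
  expect_warning(fsep <- phylo_logistic_fit(y ~ x, dsep, star), "separation")
  expect_true(fsep$separation)
  expect_true(all(is.finite(fsep$coefficients)))

  expect_error(phylo_logistic_fit(y ~ x, transform(dat, y = 1), star),
               "single class")

  # latent threshold model: sign of the slope recovered
  tr <- simulate_tree(200, seed = 23)
  D <- ape::cophenetic.phylo(tr)
  set.seed(24)
  signs <- replicate(100, {
    x2 <- rnorm(200)
    lat <- 1.5 * x2 + as.numeric(simulate_ou_trait(tr, 2, 1))
    y2 <- rbinom(200, 1, plogis(lat))
    d2 <- data.frame(y = y2, x = x2, row.names = tr$tip.label)
    f <- suppressWarnings(phylo_logistic_fit(y ~ x, d2, tr, dist = D))
    unname(f$coefficients["x"]) > 0
  })
  expect_gte(mean(signs), 0.9)
})
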