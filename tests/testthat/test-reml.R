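# independent restricted log-likelihood used as an oracle: builds the dense
# covariance V = sum_k s2_k Z_k K_k Z_k' + s2_e I from the ORIGINAL (not
# whitened) matrices and evaluates the standard REML expression
oracle_reml_ll <- function(y, X, terms, vc) {
  n <- length(y)
  V <- diag(vc[length(vc)], n)
  for (k in seq_along(terms)) {
    Z <- terms[[k]]$Z
    K <- if (is.null(terms[[k]]$K)) diag(ncol(Z)) else terms[[k]]$K
    V <- V + vc[k] * Z %*% K %*% t(Z)
  }
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       t(y) %*% P %*% y + (n - ncol(X)) * log(2 * pi)))
}

test_that("fit_reml with no random terms reproduces ordinary least squares", {
  set.seed(21)
  x <- rnorm(40)
  y <- 2 + 3 * x + rnorm(40)
  X <- model.matrix(~x)
  fit <- fit_reml(mixed_model_spec(y, X))
  ols <- lm(y ~ x)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(unname(fit$vc["residual"]), summary(ols)$sigma^2,
               tolerance = 1e-10)
  expect_equal(unname(fit$beta_cov), unname(vcov(ols)), tolerance = 1e-8)
})

test_that("fit_reml matches closed-form ANOVA estimators on a balanced one-way layout", {
  set.seed(22)
  g <- 12; r <- 6
  grp <- factor(rep(seq_len(g), each = r))
  u <- rnorm(g, 0, sqrt(2))
  y <- 5 + u[grp] + rnorm(g * r, 0, 1.5)
  X <- matrix(1, g * r, 1)
  Z <- indicator(grp)
  fit <- fit_reml(mixed_model_spec(y, X, list(grp = Z)))
  # closed-form REML = ANOVA estimators in the balanced case
  msb <- sum(r * (tapply(y, grp, mean) - mean(y))^2) / (g - 1)
  msw <- sum((y - ave(y, grp))^2) / (g * (r - 1))
  expect_equal(unname(fit$vc["grp"]), (msb - msw) / r, tolerance = 1e-6)
  expect_equal(unname(fit$vc["residual"]), msw, tolerance = 1e-6)
  expect_true(fit$converged)
  # the restricted log-likelihood at the estimate matches the dense oracle
  ll0 <- oracle_reml_ll(y, X, list(list(Z = Z, K = NULL)), fit$vc)
  expect_equal(fit$loglik_reml, ll0, tolerance = 1e-6)
  # BLUPs equal the closed-form shrunken group means
  lam <- fit$vc["residual"] / fit$vc["grp"]
  shrunk <- r * (tapply(y, grp, mean) - mean(y)) / (r + lam)
  expect_equal(unname(fit$blups$grp), as.vector(shrunk), tolerance = 1e-5)
})

test_that("fit_reml beats a brute-force likelihood grid on a tiny GCA/SCA instance", {
  sim <- sim_gca_sca(n_parents = 6, crosses = 9, n_years = 2, n_blocks = 1,
                     n_trt = 1, s2_G = 1.5, s2_H = 0.8, s2_e = 1, seed = 23)
  ph <- sim$phenotypes
  inc <- build_incidence(ph, sim$design)
  X <- cbind(`(Intercept)` = 1, yrY2 = as.numeric(ph$year == "Y2"))
  terms <- list(GCA = list(Z = inc$Z_G, K = sim$G),
                SCA = list(Z = inc$Z_H, K = NULL))
  fit <- fit_reml(mixed_model_spec(ph$value, X, terms))
  ll_hat <- oracle_reml_ll(ph$value, X, terms, fit$vc)
  # estimated components attain a likelihood no grid point can beat
  grid <- expand.grid(G = seq(0.1, 4, length.out = 12),
                      H = seq(0.1, 4, length.out = 12),
                      e = seq(0.2, 4, length.out = 12))
  ll_grid <- apply(grid, 1, function(th)
    oracle_reml_ll(ph$value, X, terms, th))
  expect_gte(ll_hat, max(ll_grid) - 1e-6)
  # and the internal loglik agrees with the dense oracle
  expect_equal(fit$loglik_reml, ll_hat, tolerance = 1e-6)
})

test_that("the EM trace is monotone and boundary components are flagged", {
  set.seed(24)
  g <- 8; r <- 4
  grp <- factor(rep(seq_len(g), each = r))
  # no group signal at all: group variance should hit the boundary
  y <- rnorm(g * r)
  fit <- fit_reml(mixed_model_spec(y, matrix(1, g * r, 1),
                                   list(grp = indicator(grp))),
                  max_iter = 2000)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  if (fit$vc["grp"] < 1e-6) expect_true(fit$boundary[["grp"]])
  expect_true(all(fit$vc >= 0))
})

test_that("unconstrained mode can go negative and never loses likelihood", {
  set.seed(25)
  g <- 10; r <- 3
  grp <- factor(rep(seq_len(g), each = r))
  y <- rnorm(g * r)  # true group variance 0: unconstrained REML may dip below
  spec <- mixed_model_spec(y, matrix(1, g * r, 1), list(grp = indicator(grp)))
  con <- fit_reml(spec, constrain = TRUE)
  unc <- fit_reml(spec, constrain = FALSE)
  expect_gte(unc$loglik_reml, con$loglik_reml - 1e-6)
})

test_that("wald_fixed detects a strong effect and validates terms", {
  set.seed(26)
  f <- factor(rep(c("a", "b"), each = 30))
  y <- 1 + 3 * (f == "b") + rnorm(60)
  X <- model.matrix(~f)
  attr(X, "term_labels") <- "group"
  fit <- fit_reml(mixed_model_spec(y, X))
  w <- wald_fixed(fit, "group")
  expect_equal(w$df, 1L)
  expect_lt(w$p_value, 1e-6)
  expect_error(wald_fixed(fit, "nope"), "unknown fixed term")
  # a null effect yields a large p most of the time; just check validity
  y0 <- rnorm(60)
  fit0 <- fit_reml(mixed_model_spec(y0, X))
  w0 <- wald_fixed(fit0, "group")
  expect_true(w0$p_value >= 0 && w0$p_value <= 1)
})

test_that("lrt_random applies the boundary mixture convention", {
  set.seed(27)
  g <- 10; r <- 4
  grp <- factor(rep(seq_len(g), each = r))
  u <- rnorm(g, 0, 2)
  y <- u[grp] + rnorm(g * r)
  X <- matrix(1, g * r, 1)
  full <- fit_reml(mixed_model_spec(y, X, list(grp = indicator(grp))))
  red <- fit_reml(mixed_model_spec(y, X))
  out <- lrt_random(full, red)
  expect_gt(out$statistic, 0)
  expect_equal(out$p_value, 0.5 * pchisq(out$statistic, 1, lower.tail = FALSE))
  expect_equal(out$dropped, "grp")
  # identical fits give statistic 0 and p exactly 1
  same <- lrt_random(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # non-nested models are rejected
  other <- fit_reml(mixed_model_spec(
    y, X, list(zz = indicator(factor(rep(1:4, length.out = g * r))))))
  expect_error(lrt_random(full, other), "not nested")
})

test_that("fit_reml input validation works", {
  y <- c(1, 2, NA, 4)
  X <- matrix(1, 4, 1)
  expect_error(fit_reml(mixed_model_spec(y, X)), "complete response")
  expect_error(mixed_model_spec(1:5, matrix(1, 4, 1)), "row count")
  expect_error(mixed_model_spec(rnorm(30000), matrix(1, 30000, 1)),
               "size guard")
})

test_that("gibbs_vc is seed-reproducible and agrees with REML on informative data", {
  sim <- sim_gca_sca(n_parents = 8, crosses = 16, n_years = 2, n_blocks = 3,
                     n_trt = 2, s2_G = 2, s2_H = 1, s2_e = 2, seed = 28)
  ph <- sim$phenotypes
  inc <- build_incidence(ph, sim$design)
  X <- cbind(`(Intercept)` = 1, yrY2 = as.numeric(ph$year == "Y2"))
  spec <- mixed_model_spec(ph$value, X,
                           list(GCA = list(Z = inc$Z_G, K = sim$G),
                                SCA = list(Z = inc$Z_H, K = NULL)))
  g1 <- gibbs_vc(spec, n_iter = 3000, burn_in = 500, seed = 99)
  g2 <- gibbs_vc(spec, n_iter = 3000, burn_in = 500, seed = 99)
  expect_identical(g1$vc_mean, g2$vc_mean)
  g3 <- gibbs_vc(spec, n_iter = 3000, burn_in = 500, seed = 100)
  expect_false(identical(g1$vc_mean, g3$vc_mean))
  rfit <- fit_reml(spec)
  for (nm in names(rfit$vc)) {
    expect_lt(abs(g1$vc_mean[[nm]] - rfit$vc[[nm]]), 3 * g1$vc_sd[[nm]])
  }
})

test_that("gibbs_vc imputes missing responses with the genomic prediction", {
  sim <- sim_gca_sca(n_parents = 8, crosses = 16, n_years = 2, n_blocks = 3,
                     n_trt = 1, s2_G = 4, s2_H = 0.5, s2_e = 1, seed = 29)
  ph <- sim$phenotypes
  inc <- build_incidence(ph, sim$design)
  X <- matrix(1, nrow(ph), 1)
  y <- ph$value
  hold <- which(ph$genotype_id %in% sim$design$hybrid_id[1:4])
  y_mask <- y
  y_mask[hold] <- NA
  spec <- mixed_model_spec(y_mask, X,
                           list(GCA = list(Z = inc$Z_G, K = sim$G),
                                SCA = list(Z = inc$Z_H, K = NULL)))
  fit <- gibbs_vc(spec, n_iter = 4000, burn_in = 1000, seed = 30)
  expect_equal(fit$missing, hold)
  expect_false(anyNA(fit$pred))
  # with strong genetic signal the held-out predictions track the truth
  expect_gt(cor(fit$pred[hold], y[hold]), 0.3)
})
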