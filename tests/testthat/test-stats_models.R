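test_that("Kendall tau matches a pair-counting oracle", {
  x <- c(1, 2, 3, 4); y <- c(10, 20, 30, 40)
  expect_equal(kendall_tau(x, y)$tau, 1)
  expect_equal(kendall_tau(x, -y)$tau, -1)
  # O(n^2) concordant/discordant oracle with tie correction (tau-b)
  tau_oracle <- function(x, y) {
    n <- length(x); C <- 0; D <- 0; tx <- 0; ty <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
      if (sx == 0 && sy == 0) next
      if (sx == 0) tx <- tx + 1
      else if (sy == 0) ty <- ty + 1
      else if (sx == sy) C <- C + 1 else D <- D + 1
    }
    (C - D) / sqrt((C + D + tx) * (C + D + ty))
  }
  set.seed(13)
  for (rep in 1:8) {
    x <- sample(1:5, 8, replace = TRUE)
    y <- sample(1:5, 8, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau(x, y)$tau, tau_oracle(x, y), tolerance = 1e-9)
    expect_equal(kendall_tau(x, y)$tau, kendall_tau(y, x)$tau)  # symmetry
    expect_equal(kendall_tau(exp(x), y)$tau, kendall_tau(x, y)$tau)
  }
  expect_warning(res <- kendall_tau(rep(1, 5), 1:5), "tied")
  expect_true(is.na(res$tau))
})

test_that("Welch's t-test handles degenerate and equal-variance limits", {
  x <- c(1, 2, 3, 4)
  expect_equal(welch_t(x, x)$t, 0)
  expect_equal(welch_t(x, x)$p, 1)
  expect_equal(welch_t(c(1, 1), c(1, 1))$t, 0)
  # equal sample variances: df equals n1 + n2 - 2
  w <- welch_t(c(1, 2, 3), c(7, 8, 9))
  expect_equal(w$df, 4, tolerance = 1e-9)
})

test_that("the Welch test holds its nominal type-I error", {
  set.seed(17)
  rej <- mean(replicate(2000, welch_t(rnorm(20), rnorm(20))$p < 0.05))
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
})

test_that("intercept-only logistic fit recovers the closed form", {
  set.seed(19)
  d <- data.frame(ars_present = rep(c(1, 0), c(25, 75)),
                  pct_sitting = runif(100, 0, 100),
                  n_dives = rpois(100, 2), trip_duration_h = runif(100, 1, 10))
  fit <- fit_ars_glmm(d, random_group = NULL, formula = ars_present ~ 1)
  expect_equal(unname(fit$coefficients[1]), qlogis(0.25), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("planted regression coefficients are recovered within 3 SE", {
  truth <- c(0.5, 1.214, 0.112, -0.261, -0.084)
  sim_sections <- function(n, seed) {
    set.seed(seed)
    ls <- rnorm(n); nd <- rpois(n, 3); td <- runif(n, 1, 12)
    eta <- truth[1] + truth[2] * ls + truth[3] * nd + truth[4] * td +
      truth[5] * ls * nd
    data.frame(ars_present = rbinom(n, 1, plogis(eta)),
               pct_sitting = 100 * plogis(ls), n_dives = nd,
               trip_duration_h = td)
  }
  fit <- fit_ars_glmm(sim_sections(2000, 101), random_group = NULL)
  co <- fit$coefficients[c("(Intercept)", "logit_sitting", "n_dives",
                           "trip_duration_h", "logit_sitting:n_dives")]
  expect_true(all(abs(co - truth) <= 3 * fit$se[names(co)]))
  # dropping the non-significant covariate keeps remaining signs
  fit2 <- fit_ars_glmm(sim_sections(2000, 102), random_group = NULL,
                       formula = ars_present ~ logit_sitting + n_dives)
  expect_gt(fit2$coefficients["logit_sitting"], 0)
  expect_gt(fit2$coefficients["n_dives"], 0)
})

test_that("a genuine random intercept is picked up, an absent one drops out", {
  set.seed(23)
  n_grp <- 40; per <- 12
  g <- rep(seq_len(n_grp), each = per)
  re <- rep(rnorm(n_grp, 0, 1.5), each = per)
  ls <- rnorm(n_grp * per)
  d <- data.frame(ars_present = rbinom(n_grp * per, 1, plogis(0.3 + ls + re)),
                  pct_sitting = 100 * plogis(ls),
                  n_dives = rpois(n_grp * per, 2),
                  trip_duration_h = runif(n_grp * per, 1, 10),
                  trip_id = sprintf("t%02d", g))
  fit <- fit_ars_glmm(d, formula = ars_present ~ logit_sitting)
  expect_equal(fit$model, "glmer")
  expect_gt(fit$re_var, 0.3)
  # no grouping column: reduces to plain logistic regression
  fit0 <- fit_ars_glmm(d[, -5], formula = ars_present ~ logit_sitting)
  expect_equal(fit0$model, "glm")
})

test_that("posterior simulation brackets the point prediction", {
  fit <- structure(list(coefficients = c(`(Intercept)` = 0, logit_sitting = 1),
                        se = c(0.1, 0.1),
                        vcov = diag(c(0.01, 0.01)),
                        re_var = NA_real_, converged = TRUE, model = "glm",
                        terms = terms(ars_present ~ logit_sitting)),
                   class = "ars_glmm")
  nd <- data.frame(logit_sitting = c(qlogis(0.3), qlogis(0.7)))
  pr <- predict_probability(fit, nd, n_draws = 2000, seed = 1)
  expect_true(all(pr$lo <= pr$prob & pr$prob <= pr$hi))
  # monotone in the planted coefficient: 70% sitting beats 30%
  expect_gt(pr$prob[2], pr$prob[1])
  # zero covariance collapses the interval
  fit0 <- fit; fit0$vcov <- diag(c(0, 0))
  pr0 <- predict_probability(fit0, nd, n_draws = 100, seed = 1)
  expect_equal(pr0$lo, pr0$prob, tolerance = 1e-12)
  expect_equal(pr0$hi, pr0$prob, tolerance = 1e-12)
  fitbad <- fit; fitbad$converged <- FALSE
  expect_error(predict_probability(fitbad, nd), "non-converged")
})

test_that("the deviance tree recovers a single-threshold rule", {
  set.seed(29)
  x <- data.frame(a = runif(200, 0, 6), b = runif(200, 0, 6))
  y <- factor(ifelse(x$a < 3, "false", "true"))
  tr <- fit_tree(x, y)
  expect_equal(tr$root$split_var, "a")
  grid <- sort(unique(x$a))
  expect_lt(abs(tr$root$threshold - 3), max(diff(grid)) + 0.05)
  expect_equal(as.character(predict_tree(tr, x)), as.character(y))
  # pure node: no split
  pure <- fit_tree(x, factor(rep("t", 200), levels = c("t", "f")))
  expect_equal(pure$root$type, "leaf")
  # identical feature vectors with balanced opposite labels: no split is
  # possible and the leaf sits at probability one half
  tie <- fit_tree(data.frame(a = rep(1, 10)), factor(rep(c("x", "y"), 5)))
  expect_equal(tie$root$type, "leaf")
  expect_equal(unname(tie$root$probs), c(0.5, 0.5))
})

test_that("tree predictions agree with an established deviance tree", {
  set.seed(31)
  n <- 150
  x <- data.frame(a = runif(n, 0, 10), b = runif(n, 0, 10))
  y <- factor(ifelse(x$a + rnorm(n, 0, 1.5) < 5, "false", "true"))
  mine <- fit_tree(x, y, min_leaf = 10, min_split_dev = 0.01)
  ref <- tree::tree(y ~ a + b, data = cbind(x, y = y),
                    control = tree::tree.control(n, mincut = 5, minsize = 10,
                                                 mindev = 0.01))
  agree <- mean(as.character(predict_tree(mine, x)) ==
                as.character(predict(ref, x, type = "class")))
  expect_gte(agree, 0.9)
})

test_that("jack-knife counts per-class successes and sums to n", {
  set.seed(37)
  x <- data.frame(a = c(runif(12, 0, 1), runif(12, 5, 6)))
  y <- factor(rep(c("false", "true"), each = 12))
  jk <- jackknife(x, y)
  expect_equal(jk$correct, c(12, 12))        # separable: all correct
  expect_equal(sum(jk$n), 24)
  expect_equal(attr(jk, "accuracy"), 1)
  # labels independent of features: with splitting suppressed the tree is a
  # majority stump, so accuracy settles at the majority-class frequency
  acc <- vapply(1:20, function(s) {
    set.seed(400 + s)
    xr <- data.frame(a = runif(24))
    yr <- factor(sample(rep(c("false", "true"), c(8, 16))))
    attr(jackknife(xr, yr, min_split_dev = 0.5), "accuracy")
  }, numeric(1))
  expect_equal(mean(acc), 2 / 3, tolerance = 0.05)
})
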