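# Causal estimators: Wald ratio, IVW, Egger, weighted median, modes

test_that("wald_ratio divides effects and propagates the first-order SE", {
  est <- wald_ratio(list(beta_exp = 0.5, beta_out = 0.25, se_out = 0.05))
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.1)
  est0 <- wald_ratio(list(beta_exp = 0.5, beta_out = 0, se_out = 0.05))
  expect_equal(est0$beta, 0)
  expect_equal(est0$or_, 1)
  estn <- wald_ratio(list(beta_exp = -0.2, beta_out = 0.1, se_out = 0.05))
  expect_equal(estn$beta, -0.5)
  expect_error(wald_ratio(list(beta_exp = 0, beta_out = 0.1, se_out = 0.05)),
               "beta_exp = 0")
})

test_that("ivw equals the inverse-variance weighted mean oracle", {
  # degenerate: identical ratios collapse to that ratio exactly
  h <- make_hset(beta_exp = c(0.1, 0.2, 0.4), beta_out = c(0.07, 0.14, 0.28))
  expect_equal(ivw(h)$beta, 0.7)
  # two SNPs, ratios {0, 1}, equal ratio SEs of 1 -> mean 0.5, fixed se 1/sqrt(2)
  h2 <- make_ratio_hset(c(0, 1), ratio_se = 1)
  est2 <- ivw(h2, variance_model = "fixed")
  expect_equal(est2$beta, 0.5)
  expect_equal(est2$se, 1 / sqrt(2))
  # random fixture vs brute-force weighted mean
  set.seed(61)
  h3 <- make_hset(beta_exp = rnorm(8, 0.2, 0.05), beta_out = rnorm(8, 0.1, 0.05),
                  se_exp = runif(8, 0.005, 0.02), se_out = runif(8, 0.02, 0.1))
  r <- ratio_estimates(h3)
  expect_equal(ivw(h3, "fixed")$beta, weighted.mean(r$ratio, r$w),
               tolerance = 1e-12)
  expect_equal(ivw(h3, "fixed")$se, sqrt(1 / sum(r$w)), tolerance = 1e-12)
  # multiplicative random effects only inflates
  expect_gte(ivw(h3, "multiplicative_random")$se, ivw(h3, "fixed")$se)
  expect_error(ivw(make_ratio_hset(1)), ">= 2")
})

test_that("ivw on one pair (forced via weights) equals the Wald ratio", {
  # duplicate a single SNP's statistics: weighted mean of identical ratios
  pair <- list(beta_exp = 0.3, beta_out = 0.12, se_out = 0.04)
  h <- make_hset(beta_exp = c(0.3, 0.3), beta_out = c(0.12, 0.12),
                 se_out = 0.04)
  expect_equal(ivw(h)$beta, wald_ratio(pair)$beta)
})

test_that("mr_egger recovers an exact line and matches the WLS oracle", {
  x <- c(0.05, 0.1, 0.15, 0.2, 0.3)
  h <- make_hset(beta_exp = x, beta_out = 0.1 + 0.7 * x,
                 se_out = c(0.04, 0.05, 0.06, 0.05, 0.04))
  est <- mr_egger(h)
  expect_equal(est$beta, 0.7, tolerance = 1e-12)
  expect_equal(est$extras$intercept, 0.1, tolerance = 1e-12)

  # noisy fixture vs stats::lm as an independent weighted-least-squares oracle
  set.seed(71)
  h2 <- make_hset(beta_exp = runif(10, 0.05, 0.3),
                  beta_out = rnorm(10, 0.05, 0.05),
                  se_out = runif(10, 0.02, 0.1))
  est2 <- mr_egger(h2)
  w <- 1 / h2$pairs$se_out^2
  fit <- lm(beta_out ~ beta_exp, data = h2$pairs, weights = w)
  expect_equal(est2$beta, unname(coef(fit)["beta_exp"]), tolerance = 1e-10)
  expect_equal(est2$extras$intercept, unname(coef(fit)["(Intercept)"]),
               tolerance = 1e-10)
  # SEs match lm's up to the multiplicative floor at 1
  s2_lm <- summary(fit)$sigma^2
  scale_floor <- sqrt(max(1, s2_lm) / s2_lm)
  expect_equal(est2$se,
               unname(summary(fit)$coefficients["beta_exp", "Std. Error"]) * scale_floor,
               tolerance = 1e-10)

  # orientation: recoding alleles of one SNP (negating both betas) changes nothing
  p3 <- h2$pairs
  p3$beta_exp[3] <- -p3$beta_exp[3]
  p3$beta_out[3] <- -p3$beta_out[3]
  est3 <- mr_egger(harmonized_set(p3))
  expect_equal(est3$beta, est2$beta, tolerance = 1e-12)

  expect_error(mr_egger(make_ratio_hset(c(1, 2))), ">= 3")
  expect_warning(mr_egger(make_ratio_hset(c(1, 2, 3))), "3 SNPs")
  expect_error(suppressWarnings(mr_egger(make_hset(beta_exp = c(0.1, 0.1, 0.1),
                                                   beta_out = c(0, 0.1, 0.2)))),
               "variation")
})

test_that("weighted_median interpolates the cumulative weights correctly", {
  expect_equal(weighted_median(make_ratio_hset(c(1, 2, 9)), n_boot = 0)$beta, 2)
  expect_equal(weighted_median(make_ratio_hset(c(3, 3, 3)), n_boot = 0)$beta, 3)
  expect_equal(weighted_median(make_ratio_hset(c(0, 1, 2, 3)), n_boot = 0)$beta, 1.5)
  # unequal weights vs a hand-computed interpolation oracle
  set.seed(81)
  ratios <- rnorm(7)
  ses <- runif(7, 0.5, 2)
  h <- make_hset(beta_exp = rep(1, 7), beta_out = ratios, se_out = ses)
  got <- weighted_median(h, n_boot = 0)$beta
  w <- 1 / ses^2
  ord <- order(ratios)
  r_s <- ratios[ord]; w_s <- w[ord] / sum(w)
  p <- cumsum(w_s) - w_s / 2
  want <- approx(p, r_s, xout = 0.5)$y
  expect_equal(got, want, tolerance = 1e-12)
  # bootstrap SE is reproducible under the same seed
  e1 <- weighted_median(h, n_boot = 50, seed = 9)
  e2 <- weighted_median(h, n_boot = 50, seed = 9)
  expect_identical(e1$se, e2$se)
  expect_error(weighted_median(make_ratio_hset(c(1, 2))), ">= 3")
})

test_that("mode estimators find the dominant cluster, not the mean", {
  # point mass
  expect_equal(mode_estimate(make_ratio_hset(rep(0.4, 5)), n_boot = 0)$beta, 0.4)
  # equal weights: weighted and simple modes coincide
  h <- make_ratio_hset(c(0.4, 0.45, 0.5, 0.55, 0.6, 3.0, 3.1))
  expect_equal(mode_estimate(h, weighted = TRUE, n_boot = 0)$beta,
               mode_estimate(h, weighted = FALSE, n_boot = 0)$beta)
  # 7 ratios near 0.5 plus 3 outliers at 3: estimate near 0.5
  h2 <- make_ratio_hset(c(0.45, 0.48, 0.5, 0.5, 0.52, 0.54, 0.55, 3, 3, 3))
  est <- mode_estimate(h2, n_boot = 0)
  expect_lt(abs(est$beta - 0.5), 0.2)
  r <- ratio_estimates(h2)$ratio
  expect_gt(mean(r) - est$beta, 0.5)  # far from the mean
  # grid-search density argmax oracle with the same bandwidth rule
  k <- length(r)
  hbw <- 0.9 * min(sd(r), mad(r)) * k^(-1 / 5)
  grid <- seq(min(r) - 3 * hbw, max(r) + 3 * hbw, length.out = 1000)
  dens <- sapply(grid, function(x) mean(dnorm((x - r) / hbw)))
  expect_equal(mode_estimate(h2, weighted = FALSE, n_boot = 0)$beta,
               grid[which.max(dens)], tolerance = 1e-12)
  expect_error(mode_estimate(make_ratio_hset(c(1, 2, 3))), ">= 4")
})

test_that("run_all_methods gates on instrument count as per the method table", {
  h1 <- make_ratio_hset(0.5)
  expect_equal(vapply(run_all_methods(h1), `[[`, "", "method"), "wald_ratio")
  h2 <- make_ratio_hset(c(0.4, 0.6))
  expect_equal(vapply(run_all_methods(h2), `[[`, "", "method"), "ivw")
  h3 <- make_ratio_hset(c(0.4, 0.5, 0.6))
  expect_setequal(vapply(run_all_methods(h3, n_boot = 10, seed = 1), `[[`, "", "method"),
                  c("ivw", "weighted_median", "mr_egger"))
  h5 <- make_ratio_hset(c(0.4, 0.45, 0.5, 0.55, 0.6))
  expect_setequal(vapply(run_all_methods(h5, n_boot = 10, seed = 1), `[[`, "", "method"),
                  c("ivw", "weighted_median", "mr_egger", "weighted_mode",
                    "simple_mode"))
  expect_error(run_all_methods(harmonized_set(NULL)), "empty")
})

test_that("odds-ratio conversion matches the exp transform and CI convention", {
  expect_equal(to_odds_ratio(0, 0.1)$or_, 1)
  expect_equal(to_odds_ratio(log(3.603), 0.2)$or_, 3.603)
  expect_equal(to_odds_ratio(log(0.489), 0.2)$or_, 0.489)
  o <- to_odds_ratio(0.3, 0.1)
  expect_equal(o$ci_low, exp(0.3 - 1.96 * 0.1))
  expect_equal(o$ci_high, exp(0.3 + 1.96 * 0.1))
})

test_that("all estimators are equivariant under outcome sign flip", {
  set.seed(91)
  h <- make_hset(beta_exp = runif(8, 0.1, 0.3), beta_out = rnorm(8, 0.1, 0.1),
                 se_out = runif(8, 0.02, 0.08))
  hneg <- harmonized_set(transform(h$pairs, beta_out = -beta_out))
  for (fn in list(function(x) ivw(x),
                  function(x) suppressWarnings(mr_egger(x)),
                  function(x) weighted_median(x, n_boot = 0),
                  function(x) mode_estimate(x, n_boot = 0),
                  function(x) mode_estimate(x, weighted = FALSE, n_boot = 0))) {
    a <- fn(h); b <- fn(hneg)
    expect_equal(b$beta, -a$beta, tolerance = 1e-10)
    expect_equal(b$or_, 1 / a$or_, tolerance = 1e-10)
  }
})
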