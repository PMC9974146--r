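#' Per-SNP ratio estimates
#'
#' For each harmonized pair, the Wald ratio `beta_out / beta_exp` with its
#' first-order standard error `se_out / |beta_exp|`, and the inverse-variance
#' weight `w = SE(ratio)^-2`. Defined only for `beta_exp != 0`.
#'
#' @param hset A `harmonized_set`.
#' @return data.frame with columns `snp_id`, `ratio`, `ratio_se`, `w`.
#' @export
ratio_estimates <- function(hset) {
  p <- hset$pairs
  if (any(p$beta_exp == 0)) stop("ratio estimate undefined for beta_exp = 0")
  data.frame(snp_id = p$snp_id,
             ratio = p$beta_out / p$beta_exp,
             ratio_se = p$se_out / abs(p$beta_exp),
             w = (p$beta_exp / p$se_out)^2,
             stringsAsFactors = FALSE)
}

# assemble an mr_estimate object; OR/CI via the 1.96-SE convention
.mr_estimate <- function(method, n_snp, beta, se, pvalue, extras = list()) {
  orci <- to_odds_ratio(beta, se)
  structure(list(method = method, n_snp = n_snp, beta = beta, se = se,
                 pvalue = pvalue, or_ = orci$or_, ci_low = orci$ci_low,
                 ci_high = orci$ci_high, extras = extras),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s (k=%d): beta=%.4g se=%.4g p=%.3g OR=%.3f [%.3f, %.3f]\n",
              x$method, x$n_snp, x$beta, x$se, x$pvalue,
              x$or_, x$ci_low, x$ci_high))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snp = x$n_snp, beta = x$beta, se = x$se,
             pvalue = x$pvalue, or_ = x$or_, ci_low = x$ci_low,
             ci_high = x$ci_high, stringsAsFactors = FALSE)
}

#' Convert a log-odds effect to an odds ratio with 95% interval
#'
#' @param beta Effect on the log-odds scale.
#' @param se Standard error of `beta` (>= 0; `NA` yields `NA` bounds).
#' @return List with `or_ = exp(beta)`, `ci_low = exp(beta - 1.96 se)`,
#'   `ci_high = exp(beta + 1.96 se)`.
#' @export
to_odds_ratio <- function(beta, se) {
  list(or_ = exp(beta), ci_low = exp(beta - 1.96 * se),
       ci_high = exp(beta + 1.96 * se))
}

#' Wald ratio causal estimate (single instrument)
#'
#' @param pair A one-row harmonized pair (data.frame row or list with
#'   `beta_exp`, `beta_out`, `se_out`), or a `harmonized_set` with exactly
#'   one pair.
#' @return An `mr_estimate` with method `wald_ratio`.
#' @export
wald_ratio <- function(pair) {
  if (inherits(pair, "harmonized_set")) {
    stopifnot(nrow(pair$pairs) == 1)
    pair <- pair$pairs[1, ]
  }
  if (pair$beta_exp == 0) stop("Wald ratio undefined: beta_exp = 0")
  beta <- pair$beta_out / pair$beta_exp
  se <- pair$se_out / abs(pair$beta_exp)
  p <- 2 * stats::pnorm(-abs(beta / se))
  .mr_estimate("wald_ratio", 1L, beta, se, p)
}

#' Inverse-variance-weighted causal estimate
#'
#' The weighted mean of the per-SNP ratio estimates with weights
#' `SE(ratio)^-2`, equivalent to a zero-intercept weighted regression of
#' outcome effects on exposure effects with weights `se_out^-2`. Under the
#' `fixed` variance model `se = (sum w)^-1/2`; under
#' `multiplicative_random` (the default) the SE is scaled by
#' `sqrt(max(1, Q / (k - 1)))`, inflating it when the instruments are
#' heterogeneous but never deflating it.
#'
#' @param hset A `harmonized_set` with at least two pairs.
#' @param variance_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_estimate` with method `ivw`.
#' @export
ivw <- function(hset, variance_model = c("multiplicative_random", "fixed")) {
  variance_model <- match.arg(variance_model)
  k <- nrow(hset$pairs)
  if (k < 2) stop("ivw requires >= 2 SNPs; use wald_ratio for a single instrument")
  r <- ratio_estimates(hset)
  beta <- sum(r$w * r$ratio) / sum(r$w)
  se <- sqrt(1 / sum(r$w))
  if (variance_model == "multiplicative_random") {
    q <- sum(r$w * (r$ratio - beta)^2)
    se <- se * sqrt(max(1, q / (k - 1)))
  }
  p <- 2 * stats::pnorm(-abs(beta / se))
  .mr_estimate("ivw", k, beta, se, p,
               extras = list(variance_model = variance_model))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' unconstrained intercept and weights `se_out^-2`, after orienting every
#' exposure effect to be non-negative (the outcome effect's sign flips with
#' it; Egger regression is not invariant to allele recoding without this).
#' The slope is the causal estimate; the intercept estimates the average
#' directional pleiotropic effect, and its test is reported in `extras`.
#' Standard errors use multiplicative residual scaling floored at 1, and
#' p-values come from the t distribution with `k - 2` degrees of freedom.
#'
#' @param hset A `harmonized_set` with at least three pairs.
#' @return An `mr_estimate` with method `mr_egger`; `extras` carries
#'   `intercept`, `intercept_se`, `intercept_pvalue`.
#' @export
mr_egger <- function(hset) {
  k <- nrow(hset$pairs)
  if (k < 3) stop("mr_egger requires >= 3 SNPs")
  if (k == 3) warning("mr_egger with exactly 3 SNPs has a single residual degree of freedom")
  s <- sign(hset$pairs$beta_exp)
  s[s == 0] <- 1
  x <- hset$pairs$beta_exp * s
  y <- hset$pairs$beta_out * s
  w <- 1 / hset$pairs$se_out^2
  if (stats::sd(x) == 0) stop("mr_egger: no variation in exposure effects")
  sw <- sum(w)
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  sxx <- sum(w * (x - xbar)^2)
  slope <- sum(w * (x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  resid <- y - intercept - slope * x
  # multiplicative residual scaling, floored at 1 (never deflates the SE)
  sigma2 <- max(1, sum(w * resid^2) / (k - 2))
  se_slope <- sqrt(sigma2 / sxx)
  se_int <- sqrt(sigma2 * (1 / sw + xbar^2 / sxx))
  p_slope <- 2 * stats::pt(-abs(slope / se_slope), df = k - 2)
  p_int <- 2 * stats::pt(-abs(intercept / se_int), df = k - 2)
  .mr_estimate("mr_egger", k, slope, se_slope, p_slope,
               extras = list(intercept = intercept, intercept_se = se_int,
                             intercept_pvalue = p_int))
}

# weighted median of ratio estimates by cumulative-weight interpolation
.weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  wn <- w[ord] / sum(w)
  p <- cumsum(wn) - wn / 2
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

# parametric bootstrap over both effect sides; returns the estimate spread
.parametric_boot <- function(hset, point_fun, n_boot, seed) {
  p <- hset$pairs
  k <- nrow(p)
  with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      be <- stats::rnorm(k, p$beta_exp, p$se_exp)
      bo <- stats::rnorm(k, p$beta_out, p$se_out)
      be[be == 0] <- .Machine$double.eps
      point_fun(bo / be, (be / p$se_out)^2)
    }, numeric(1))
  })
}

#' Weighted median causal estimate
#'
#' Median of the inverse-variance-weighted empirical distribution of per-SNP
#' ratio estimates, by linear interpolation of the ordered ratios at
#' cumulative weight 0.5. Consistent as long as at least half the weight
#' comes from valid instruments. The standard error comes from a parametric
#' bootstrap: both effect sides are resampled from normal distributions
#' centered on the observed effects with the observed SEs.
#'
#' @param hset A `harmonized_set` with at least three pairs.
#' @param n_boot Bootstrap replicates (default 1000; 0 skips the bootstrap,
#'   returning `NA` SE and p-value).
#' @param seed Seed for the bootstrap (optional; the caller's RNG state is
#'   preserved).
#' @return An `mr_estimate` with method `weighted_median`.
#' @export
weighted_median <- function(hset, n_boot = 1000, seed = NULL) {
  k <- nrow(hset$pairs)
  if (k < 3) stop("weighted_median requires >= 3 SNPs")
  r <- ratio_estimates(hset)
  beta <- .weighted_median_point(r$ratio, r$w)
  se <- p <- NA_real_
  if (n_boot > 0) {
    boots <- .parametric_boot(hset, .weighted_median_point, n_boot, seed)
    se <- stats::sd(boots)
    p <- 2 * stats::pnorm(-abs(beta / se))
  }
  .mr_estimate("weighted_median", k, beta, se, p,
               extras = list(n_boot = n_boot))
}

# mode of the kernel-smoothed ratio density on a fixed grid
.mode_point <- function(ratio, w, phi, grid_n = 1000) {
  k <- length(ratio)
  if (length(unique(ratio)) == 1) return(ratio[1])
  h <- phi * 0.9 * min(stats::sd(ratio), stats::mad(ratio)) * k^(-1 / 5)
  if (h == 0) h <- phi * 0.9 * stats::sd(ratio) * k^(-1 / 5)
  wn <- w / sum(w)
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = grid_n)
  dens <- vapply(grid, function(x) sum(wn * stats::dnorm(x, ratio, h)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Mode-based causal estimate (weighted or simple)
#'
#' Smooths the per-SNP ratio estimates with a normal kernel (bandwidth
#' `phi * 0.9 * min(sd, mad) * k^(-1/5)`, with `mad` on its consistency-scaled
#' default) and takes the argmax of the density over a 1000-point grid
#' spanning the ratio range plus three bandwidths. The weighted variant
#' multiplies each kernel contribution by the normalized inverse-variance
#' weight; the simple variant weights equally. Consistent when the largest
#' cluster of similar ratio estimates comes from valid instruments. SE by
#' parametric bootstrap as in [weighted_median()].
#'
#' @param hset A `harmonized_set` with at least four pairs.
#' @param weighted `TRUE` for the weighted mode, `FALSE` for the simple mode.
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot Bootstrap replicates (0 skips).
#' @param seed Bootstrap seed.
#' @return An `mr_estimate` with method `weighted_mode` or `simple_mode`.
#' @export
mode_estimate <- function(hset, weighted = TRUE, phi = 1,
                          n_boot = 1000, seed = NULL) {
  k <- nrow(hset$pairs)
  if (k < 4) stop("mode_estimate requires >= 4 SNPs")
  r <- ratio_estimates(hset)
  point_fun <- if (weighted) {
    function(ratio, w) .mode_point(ratio, w, phi)
  } else {
    function(ratio, w) .mode_point(ratio, rep(1, length(ratio)), phi)
  }
  beta <- point_fun(r$ratio, r$w)
  se <- p <- NA_real_
  if (n_boot > 0) {
    boots <- .parametric_boot(hset, point_fun, n_boot, seed)
    se <- stats::sd(boots)
    p <- 2 * stats::pnorm(-abs(beta / se))
  }
  .mr_estimate(if (weighted) "weighted_mode" else "simple_mode", k, beta, se, p,
               extras = list(phi = phi, n_boot = n_boot))
}

#' Run every causal estimator admissible for the instrument count
#'
#' Applies the minimum-instrument gating: one SNP yields the Wald ratio
#' alone; two add nothing but the IVW; three or more add the weighted median
#' and MR-Egger; four or more add the weighted and simple modes.
#'
#' @param hset A `harmonized_set` with at least one pair.
#' @param ivw_model IVW variance model (see [ivw()]).
#' @param n_boot Bootstrap replicates for median/mode SEs.
#' @param phi Mode bandwidth multiplier.
#' @param seed Seed for bootstrap SEs.
#' @return List of `mr_estimate` objects.
#' @export
run_all_methods <- function(hset, ivw_model = "multiplicative_random",
                            n_boot = 1000, phi = 1, seed = NULL) {
  k <- nrow(hset$pairs)
  if (k == 0) stop("harmonized set is empty")
  if (k == 1) return(list(wald_ratio(hset)))
  out <- list(ivw(hset, variance_model = ivw_model))
  if (k >= 3) {
    out <- c(out, list(weighted_median(hset, n_boot = n_boot, seed = seed)),
             list(suppressWarnings(mr_egger(hset))))
  }
  if (k >= 4) {
    out <- c(out,
             list(mode_estimate(hset, weighted = TRUE, phi = phi,
                                n_boot = n_boot, seed = seed)),
             list(mode_estimate(hset, weighted = FALSE, phi = phi,
                                n_boot = n_boot, seed = seed)))
  }
  out
}

#' Tabulate a list of estimates
#'
#' @param estimates List of `mr_estimate` objects.
#' @param exposure,outcome Optional trait labels prepended as columns.
#' @return data.frame with one row per estimate.
#' @export
estimates_table <- function(estimates, exposure = NULL, outcome = NULL) {
  tab <- do.call(rbind, lapply(estimates, as.data.frame))
  if (!is.null(outcome)) tab <- cbind(outcome = outcome, tab, stringsAsFactors = FALSE)
  if (!is.null(exposure)) tab <- cbind(exposure = exposure, tab, stringsAsFactors = FALSE)
  tab
}
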