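#' Cochran's Q heterogeneity test
#'
#' For the IVW form, `Q = sum_j w_j (ratio_j - ratio_bar)^2` where
#' `ratio_bar` is the inverse-variance-weighted mean of the per-SNP ratio
#' estimates and `w_j = SE(ratio_j)^-2`; degrees of freedom `k - 1`. For the
#' Egger form, Q is the weighted residual sum of squares about the Egger fit
#' (weights `se_out^-2` on orientation-adjusted effects) with `k - 2`
#' degrees of freedom. The p-value is the upper tail of the chi-square
#' distribution; excess heterogeneity (p < 0.05) suggests invalid
#' instruments.
#'
#' @param hset A `harmonized_set` (k >= 2 for `ivw`, k >= 3 for `mr_egger`).
#' @param method `"ivw"` (default) or `"mr_egger"`.
#' @return A `q_result`: list with `method`, `Q`, `df`, `pvalue`.
#' @export
cochran_q <- function(hset, method = c("ivw", "mr_egger")) {
  method <- match.arg(method)
  k <- nrow(hset$pairs)
  if (method == "ivw") {
    if (k < 2) stop("cochran_q (ivw) requires >= 2 SNPs")
    r <- ratio_estimates(hset)
    bbar <- sum(r$w * r$ratio) / sum(r$w)
    q <- sum(r$w * (r$ratio - bbar)^2)
    df <- k - 1
  } else {
    if (k < 3) stop("cochran_q (mr_egger) requires >= 3 SNPs")
    s <- sign(hset$pairs$beta_exp)
    s[s == 0] <- 1
    x <- hset$pairs$beta_exp * s
    y <- hset$pairs$beta_out * s
    w <- 1 / hset$pairs$se_out^2
    fit <- suppressWarnings(mr_egger(hset))
    resid <- y - fit$extras$intercept - fit$beta * x
    q <- sum(w * resid^2)
    df <- k - 2
  }
  structure(list(method = method, Q = q, df = df,
                 pvalue = stats::pchisq(q, df, lower.tail = FALSE)),
            class = "q_result")
}

#' @export
print.q_result <- function(x, ...) {
  cat(sprintf("<q_result> %s: Q = %.4g on %d df, p = %.3g\n",
              x$method, x$Q, x$df, x$pvalue))
  invisible(x)
}

#' MR-PRESSO global and outlier tests for horizontal pleiotropy
#'
#' The observed residual sum of squares (RSS) accumulates, over SNPs, the
#' squared residual of each SNP's outcome effect from the IVW fit computed
#' with that SNP left out, standardized by the outcome SE. The null
#' distribution is built by simulation: in each replicate both effect sides
#' are redrawn from normal distributions centered on the leave-one-out-fitted
#' expectations with the observed SEs, and the RSS recomputed the same way.
#' The global p-value is the +1-corrected empirical tail proportion. Each
#' SNP's outlier p-value is the empirical tail of its own residual
#' contribution, Bonferroni-corrected across the k instruments; flagged
#' outliers are removed and the IVW estimate recomputed.
#'
#' Requires at least four instruments; with fewer, a not-applicable result is
#' returned (`applicable = FALSE`) rather than an error, so pipelines can
#' report it as such.
#'
#' @param hset A `harmonized_set`.
#' @param n_sim Null-simulation replicates (default 1000).
#' @param seed Simulation seed; results are bit-for-bit reproducible given
#'   the same seed.
#' @param alpha_outlier Significance level for the Bonferroni-corrected
#'   per-SNP outlier flags (default 0.05).
#' @return A `presso_result`: list with `applicable`, `global_rss_observed`,
#'   `global_pvalue`, `outlier_pvalues` (adjusted, named by SNP),
#'   `outlier_snps`, `corrected_estimate` (IVW after outlier removal, or
#'   `NULL` when no outliers were flagged or too few SNPs remain).
#' @export
mr_presso <- function(hset, n_sim = 1000, seed = NULL, alpha_outlier = 0.05) {
  k <- nrow(hset$pairs)
  if (k < 4) {
    return(structure(list(applicable = FALSE, n_snp = k,
                          global_rss_observed = NA_real_,
                          global_pvalue = NA_real_,
                          outlier_pvalues = NULL, outlier_snps = character(),
                          corrected_estimate = NULL),
                     class = "presso_result"))
  }
  p <- hset$pairs
  r <- ratio_estimates(hset)

  loo_beta <- function(ratio, w) {
    (sum(w * ratio) - w * ratio) / (sum(w) - w)
  }
  b_loo <- loo_beta(r$ratio, r$w)
  resid_obs <- p$beta_out - b_loo * p$beta_exp
  contrib_obs <- (resid_obs / p$se_out)^2
  rss_obs <- sum(contrib_obs)

  e_out <- b_loo * p$beta_exp
  sims <- with_seed(seed, {
    exp_star <- matrix(stats::rnorm(n_sim * k, rep(p$beta_exp, each = n_sim),
                                    rep(p$se_exp, each = n_sim)), n_sim, k)
    out_star <- matrix(stats::rnorm(n_sim * k, rep(e_out, each = n_sim),
                                    rep(p$se_out, each = n_sim)), n_sim, k)
    list(exp_star = exp_star, out_star = out_star)
  })
  se_out_m <- matrix(p$se_out, n_sim, k, byrow = TRUE)
  w_star <- (sims$exp_star / se_out_m)^2
  rw_star <- sims$out_star * sims$exp_star / se_out_m^2  # w* x ratio*
  tw <- rowSums(w_star)
  twr <- rowSums(rw_star)
  b_loo_star <- (twr - rw_star) / (tw - w_star)
  resid_star <- sims$out_star - b_loo_star * sims$exp_star
  contrib_star <- (resid_star / se_out_m)^2
  rss_star <- rowSums(contrib_star)

  global_p <- (1 + sum(rss_star >= rss_obs)) / (n_sim + 1)
  outlier_p_raw <- (1 + colSums(contrib_star >= rep(contrib_obs, each = n_sim))) /
    (n_sim + 1)
  outlier_p <- pmin(1, outlier_p_raw * k)
  names(outlier_p) <- p$snp_id
  outliers <- p$snp_id[outlier_p < alpha_outlier]

  corrected <- NULL
  if (length(outliers) > 0 && k - length(outliers) >= 2) {
    reduced <- harmonized_set(p[!p$snp_id %in% outliers, , drop = FALSE],
                              exposure_name = hset$exposure_name,
                              outcome_name = hset$outcome_name)
    corrected <- ivw(reduced)
  }
  structure(list(applicable = TRUE, n_snp = k,
                 global_rss_observed = rss_obs, global_pvalue = global_p,
                 outlier_pvalues = outlier_p, outlier_snps = outliers,
                 corrected_estimate = corrected),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  if (!x$applicable) {
    cat(sprintf("<presso_result> not applicable (k = %d < 4)\n", x$n_snp))
  } else {
    cat(sprintf("<presso_result> RSS = %.4g, global p = %.4g, %d outlier(s)%s\n",
                x$global_rss_observed, x$global_pvalue,
                length(x$outlier_snps),
                if (length(x$outlier_snps) > 0)
                  paste0(": ", paste(x$outlier_snps, collapse = ", ")) else ""))
  }
  invisible(x)
}

#' Leave-one-out influence analysis
#'
#' Refits the IVW estimator with each SNP excluded in turn. A SNP is flagged
#' influential when its exclusion moves the estimate outside the full fit's
#' 95% confidence interval or changes its sign. The influence flag is judged
#' against the fixed-effect (homogeneous) interval: an outlier inflates the
#' multiplicative-random-effects interval in proportion to its own
#' displacement, which would mask exactly the influence being probed.
#'
#' @param hset A `harmonized_set` with at least three pairs.
#' @param variance_model IVW variance model.
#' @return A `loo_table`: data.frame with one row per left-out SNP plus a
#'   final `(all)` row, columns `snp_left_out`, `beta`, `se`, `ci_low`,
#'   `ci_high` (on the effect scale), `or_`, and `influential`.
#' @export
leave_one_out <- function(hset, variance_model = "multiplicative_random") {
  k <- nrow(hset$pairs)
  if (k < 3) stop("leave_one_out requires >= 3 SNPs")
  full <- ivw(hset, variance_model = variance_model)
  rows <- lapply(seq_len(k), function(j) {
    reduced <- harmonized_set(hset$pairs[-j, , drop = FALSE],
                              exposure_name = hset$exposure_name,
                              outcome_name = hset$outcome_name)
    fit <- ivw(reduced, variance_model = variance_model)
    data.frame(snp_left_out = hset$pairs$snp_id[j], beta = fit$beta,
               se = fit$se, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, data.frame(snp_left_out = "(all)", beta = full$beta,
                               se = full$se, stringsAsFactors = FALSE))
  tab$ci_low <- tab$beta - 1.96 * tab$se
  tab$ci_high <- tab$beta + 1.96 * tab$se
  tab$or_ <- exp(tab$beta)
  full_fixed <- ivw(hset, variance_model = "fixed")
  full_lo <- full_fixed$beta - 1.96 * full_fixed$se
  full_hi <- full_fixed$beta + 1.96 * full_fixed$se
  tab$influential <- c(
    tab$beta[seq_len(k)] < full_lo | tab$beta[seq_len(k)] > full_hi |
      (sign(tab$beta[seq_len(k)]) != sign(full$beta) & full$beta != 0),
    FALSE
  )
  class(tab) <- c("loo_table", "data.frame")
  tab
}

#' Combined sensitivity report for one exposure-outcome analysis
#'
#' Runs the heterogeneity, pleiotropy, and influence diagnostics admissible
#' for the instrument count and summarizes them in one row. Heterogeneity is
#' flagged at p < 0.05; no estimator switching is performed.
#'
#' @param hset A `harmonized_set`.
#' @param presso_n_sim,seed,alpha_outlier Passed to [mr_presso()].
#' @return A `sensitivity_report`: list with `q_ivw`, `q_egger` (or `NULL`
#'   when gated out), `egger_intercept` fields, `presso`, `loo`, and a
#'   one-row `summary` data.frame.
#' @export
sensitivity_report <- function(hset, presso_n_sim = 1000, seed = NULL,
                               alpha_outlier = 0.05) {
  k <- nrow(hset$pairs)
  q_ivw <- if (k >= 2) cochran_q(hset, "ivw") else NULL
  q_egger <- if (k >= 3) cochran_q(hset, "mr_egger") else NULL
  egger <- if (k >= 3) suppressWarnings(mr_egger(hset)) else NULL
  presso <- mr_presso(hset, n_sim = presso_n_sim, seed = seed,
                      alpha_outlier = alpha_outlier)
  loo <- if (k >= 3) leave_one_out(hset) else NULL
  summary <- data.frame(
    exposure = hset$exposure_name, outcome = hset$outcome_name, n_snp = k,
    q_ivw = if (is.null(q_ivw)) NA_real_ else q_ivw$Q,
    q_ivw_df = if (is.null(q_ivw)) NA_integer_ else q_ivw$df,
    q_ivw_pvalue = if (is.null(q_ivw)) NA_real_ else q_ivw$pvalue,
    q_egger = if (is.null(q_egger)) NA_real_ else q_egger$Q,
    q_egger_df = if (is.null(q_egger)) NA_integer_ else q_egger$df,
    q_egger_pvalue = if (is.null(q_egger)) NA_real_ else q_egger$pvalue,
    heterogeneity = if (is.null(q_ivw)) NA else q_ivw$pvalue < 0.05,
    egger_intercept = if (is.null(egger)) NA_real_ else egger$extras$intercept,
    egger_intercept_pvalue = if (is.null(egger)) NA_real_ else egger$extras$intercept_pvalue,
    presso_global_pvalue = presso$global_pvalue,
    n_outliers = if (presso$applicable) length(presso$outlier_snps) else NA_integer_,
    loo_influential_count = if (is.null(loo)) NA_integer_ else sum(loo$influential),
    stringsAsFactors = FALSE
  )
  structure(list(q_ivw = q_ivw, q_egger = q_egger, egger = egger,
                 presso = presso, loo = loo, summary = summary),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}
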