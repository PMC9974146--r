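#' Instrument-selection parameters
#'
#' Thresholds controlling instrument selection. Two presets mirror the two
#' regimes used when screening a microbiome panel against a disease trait:
#'
#' * `microbiome_exposure`: p < 1e-5, MAF >= 0.01, clump r2 0.01 within
#'   500 kb, proxy r2 > 0.8, F >= 10 — the relaxed threshold conventional for
#'   taxa with few genome-wide-significant hits;
#' * `disease_exposure`: genome-wide significance p < 1e-8, clump r2 0.001
#'   within 10,000 kb, otherwise identical.
#'
#' @param p_threshold Association p-value cut-off (exclusive).
#' @param maf_min Minimum minor-allele frequency.
#' @param clump_r2 Maximum pairwise r2 between retained instruments.
#' @param clump_window_kb Clumping window in kilobases, measured from the
#'   index SNP in both directions.
#' @param proxy_r2_min Minimum r2 (exclusive) for a proxy substitute.
#' @param f_min Minimum aggregate F-statistic; a weaker set is excluded.
#' @return A `selection_params` list.
#' @export
selection_params <- function(p_threshold = 1e-5, maf_min = 0.01,
                             clump_r2 = 0.01, clump_window_kb = 500,
                             proxy_r2_min = 0.8, f_min = 10) {
  stopifnot(p_threshold > 0, p_threshold <= 1,
            maf_min >= 0, maf_min <= 0.5,
            clump_r2 >= 0, clump_r2 <= 1,
            clump_window_kb > 0,
            proxy_r2_min >= 0, proxy_r2_min <= 1,
            f_min >= 0)
  structure(list(p_threshold = p_threshold, maf_min = maf_min,
                 clump_r2 = clump_r2, clump_window_kb = clump_window_kb,
                 proxy_r2_min = proxy_r2_min, f_min = f_min),
            class = "selection_params")
}

#' @rdname selection_params
#' @param preset `"microbiome_exposure"` or `"disease_exposure"`.
#' @export
selection_preset <- function(preset = c("microbiome_exposure", "disease_exposure")) {
  preset <- match.arg(preset)
  switch(preset,
         microbiome_exposure = selection_params(),
         disease_exposure = selection_params(p_threshold = 1e-8,
                                             clump_r2 = 0.001,
                                             clump_window_kb = 10000))
}

#' Filter candidate instruments by significance and minor-allele frequency
#'
#' @param dataset A `summary_dataset`.
#' @param p_threshold Keep records with `pvalue < p_threshold`.
#' @param maf_min Keep records with `min(eaf, 1 - eaf) >= maf_min`; records
#'   with missing `eaf` pass the MAF filter (frequency unknown).
#' @return data.frame of candidate records sorted by ascending p-value.
#' @export
filter_candidates <- function(dataset, p_threshold = 1e-5, maf_min = 0.01) {
  stopifnot(inherits(dataset, "summary_dataset"))
  rec <- dataset$records
  if (nrow(rec) == 0) stop("dataset has no records")
  maf <- pmin(rec$eaf, 1 - rec$eaf)
  keep <- rec$pvalue < p_threshold & (is.na(maf) | maf >= maf_min)
  out <- rec[keep, , drop = FALSE]
  out <- out[order(out$pvalue, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping
#'
#' Repeatedly takes the lowest-p remaining record as an index SNP and removes
#' all remaining records on the same chromosome within `window_kb` of it that
#' have `r2 > clump_r2` with it. SNPs absent from the LD reference behave as
#' uncorrelated (r2 = 0).
#'
#' @param candidates data.frame of records sorted by ascending p-value
#'   (as produced by [filter_candidates()]).
#' @param ld An `ld_reference` or `NULL`.
#' @param clump_r2 r2 threshold above which a SNP is removed.
#' @param window_kb Window in kilobases around the index SNP.
#' @return data.frame of index SNPs in selection order.
#' @export
clump <- function(candidates, ld = NULL, clump_r2 = 0.01, window_kb = 500) {
  stopifnot(is.data.frame(candidates))
  if (nrow(candidates) == 0) return(candidates)
  if (is.unsorted(candidates$pvalue)) {
    stop("candidates must be sorted by ascending p-value")
  }
  remaining <- candidates
  kept <- list()
  while (nrow(remaining) > 0) {
    index <- remaining[1, , drop = FALSE]
    kept[[length(kept) + 1]] <- index
    remaining <- remaining[-1, , drop = FALSE]
    if (nrow(remaining) == 0) break
    in_window <- remaining$chrom == index$chrom &
      abs(remaining$pos - index$pos) <= window_kb * 1000
    if (any(in_window)) {
      r2 <- ld_r2(ld, index$snp_id, remaining$snp_id[in_window])
      drop <- in_window
      drop[in_window] <- r2 > clump_r2
      remaining <- remaining[!drop, , drop = FALSE]
    }
  }
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  out
}

#' Find proxy SNPs for instruments absent from the outcome dataset
#'
#' For each missing instrument, picks the outcome SNP on the same chromosome
#' within the reference window that maximizes r2 with it, provided
#' `r2 > proxy_r2_min`. Instruments with no eligible neighbor are reported as
#' unresolved. With no LD reference, everything is unresolved.
#'
#' @param missing data.frame of instrument records absent from the outcome.
#' @param outcome `summary_dataset` for the outcome.
#' @param ld An `ld_reference` or `NULL`.
#' @param proxy_r2_min Minimum r2 (exclusive).
#' @return data.frame with columns `snp_id`, `proxy_snp_id` (`NA` when
#'   unresolved) and `r2`.
#' @export
find_proxies <- function(missing, outcome, ld = NULL, proxy_r2_min = 0.8) {
  stopifnot(is.data.frame(missing), inherits(outcome, "summary_dataset"))
  res <- data.frame(snp_id = missing$snp_id,
                    proxy_snp_id = NA_character_,
                    r2 = NA_real_, stringsAsFactors = FALSE)
  if (nrow(missing) == 0 || is.null(ld)) return(res)
  out_rec <- outcome$records
  window_bp <- ld$window_kb * 1000
  for (i in seq_len(nrow(missing))) {
    m <- missing[i, ]
    nearby <- out_rec$chrom == m$chrom & abs(out_rec$pos - m$pos) <= window_bp &
      out_rec$snp_id != m$snp_id
    if (!any(nearby)) next
    ids <- out_rec$snp_id[nearby]
    r2 <- ld_r2(ld, m$snp_id, ids)
    best <- which.max(r2)
    if (r2[best] > proxy_r2_min) {
      res$proxy_snp_id[i] <- ids[best]
      res$r2[i] <- r2[best]
    }
  }
  res
}

#' Variance in the exposure explained by one SNP
#'
#' Computes `2 * eaf * (1 - eaf) * beta^2`, the variance explained assuming a
#' unit-variance trait. When `eaf` is missing, falls back to the
#' approximation `z^2 / (z^2 + n - 2)` with `z = beta / se`.
#'
#' @param record One summary-statistic record (data.frame row or list with
#'   `eaf`, `beta`, and for the fallback `se`, `n`).
#' @return Scalar r2 contribution.
#' @export
per_snp_r2 <- function(record) {
  if (!is.na(record$eaf)) {
    2 * record$eaf * (1 - record$eaf) * record$beta^2
  } else {
    z2 <- (record$beta / record$se)^2
    z2 / (z2 + record$n - 2)
  }
}

#' Instrument-strength F-statistic
#'
#' `F = R2 * (n - k - 1) / (k * (1 - R2))` where `R2` is the exposure
#' variance explained by the `k` instruments and `n` the exposure GWAS sample
#' size. Instrument sets with F below 10 carry weak-instrument bias and are
#' conventionally excluded.
#'
#' @param r2_total Aggregate variance explained, in \[0, 1).
#' @param n Sample size (`n > k + 1`).
#' @param k Number of instruments (>= 1).
#' @return The F-statistic.
#' @export
f_statistic <- function(r2_total, n, k) {
  if (r2_total < 0 || r2_total >= 1) stop("r2_total must be in [0, 1)")
  if (k < 1) stop("k must be >= 1")
  if (n <= k + 1) stop("n must exceed k + 1")
  r2_total * (n - k - 1) / (k * (1 - r2_total))
}

#' Select instrumental variables from an exposure dataset
#'
#' Composition of the selection funnel: significance/MAF filter, greedy LD
#' clumping, per-SNP variance-explained aggregation, and the F-statistic
#' screen. A set whose aggregate F falls below `params$f_min` is flagged weak
#' (and excluded from analysis by the pipeline).
#'
#' @param dataset Exposure `summary_dataset`.
#' @param ld `ld_reference` or `NULL`.
#' @param params A `selection_params` object.
#' @param prune_per_snp_f If `TRUE`, individual SNPs with single-SNP F below
#'   `params$f_min` are pruned before the aggregate screen (off by default;
#'   the default action on weakness is exclusion of the whole set).
#' @return An `instrument_set`: list with `exposure_name`, `snps` (records
#'   plus `r2_snp` and `f_snp` columns), `r2_total`, `f_stat`, `weak`,
#'   `params`.
#' @export
select_instruments <- function(dataset, ld = NULL,
                               params = selection_preset("microbiome_exposure"),
                               prune_per_snp_f = FALSE) {
  stopifnot(inherits(dataset, "summary_dataset"),
            inherits(params, "selection_params"))
  n <- if (!is.null(dataset$n_total)) dataset$n_total else
    stats::median(dataset$records$n)
  cand <- filter_candidates(dataset, params$p_threshold, params$maf_min)
  snps <- clump(cand, ld, params$clump_r2, params$clump_window_kb)
  if (nrow(snps) > 0) {
    snps$r2_snp <- vapply(seq_len(nrow(snps)),
                          function(i) per_snp_r2(snps[i, ]), numeric(1))
    snps$f_snp <- vapply(snps$r2_snp, function(r2) {
      if (r2 >= 1) Inf else f_statistic(min(r2, 1 - 1e-12), n, 1)
    }, numeric(1))
    if (prune_per_snp_f) {
      snps <- snps[snps$f_snp >= params$f_min, , drop = FALSE]
    }
  }
  k <- nrow(snps)
  if (k == 0) {
    return(structure(list(exposure_name = dataset$trait_name, snps = snps,
                          r2_total = 0, f_stat = NA_real_, weak = NA,
                          n = n, params = params),
                     class = "instrument_set"))
  }
  # retained instruments are approximately independent post-clumping
  r2_total <- sum(snps$r2_snp)
  f_stat <- f_statistic(min(r2_total, 1 - 1e-12), n, k)
  structure(list(exposure_name = dataset$trait_name, snps = snps,
                 r2_total = r2_total, f_stat = f_stat,
                 weak = f_stat < params$f_min, n = n, params = params),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s: %d SNPs, R2 = %.4g, F = %.3g%s\n",
              x$exposure_name, nrow(x$snps), x$r2_total,
              if (is.na(x$f_stat)) NA else x$f_stat,
              if (isTRUE(x$weak)) " (weak, excluded)" else ""))
  invisible(x)
}

#' Restrict a summary dataset to an instrument set
#'
#' @param dataset The exposure `summary_dataset` the instruments came from.
#' @param iv_set An `instrument_set`.
#' @return A `summary_dataset` containing only the instrument records.
#' @export
instrument_dataset <- function(dataset, iv_set) {
  stopifnot(inherits(iv_set, "instrument_set"))
  keep <- dataset$records$snp_id %in% iv_set$snps$snp_id
  summary_dataset(dataset$records[keep, , drop = FALSE],
                  trait_name = dataset$trait_name,
                  trait_type = dataset$trait_type,
                  n_total = dataset$n_total, n_case = dataset$n_case,
                  n_control = dataset$n_control, level = dataset$level)
}
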