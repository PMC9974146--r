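#' Configuration for one direction of the bidirectional analysis
#'
#' @param direction `"exposure_to_outcome"` (step 1, e.g. taxa -> disease) or
#'   `"outcome_to_exposure"` (step 2, disease -> taxa).
#' @param selection A `selection_params`; defaults to the microbiome preset
#'   for step 1 and the genome-wide disease preset for step 2.
#' @param alpha Reporting significance level (default 0.05).
#' @param ivw_model IVW variance model.
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param phi Mode bandwidth multiplier.
#' @param presso_n_sim MR-PRESSO null-simulation replicates.
#' @param alpha_outlier MR-PRESSO outlier significance level.
#' @param palindrome_policy,eaf_window Harmonization controls, see
#'   [harmonize()].
#' @param prune_per_snp_f See [select_instruments()].
#' @return A `direction_config` list.
#' @export
direction_config <- function(direction = c("exposure_to_outcome", "outcome_to_exposure"),
                             selection = NULL, alpha = 0.05,
                             ivw_model = "multiplicative_random",
                             n_boot = 1000, phi = 1,
                             presso_n_sim = 1000, alpha_outlier = 0.05,
                             palindrome_policy = "infer_by_eaf",
                             eaf_window = 0.08, prune_per_snp_f = FALSE) {
  direction <- match.arg(direction)
  if (is.null(selection)) {
    selection <- selection_preset(
      if (direction == "exposure_to_outcome") "microbiome_exposure"
      else "disease_exposure")
  }
  stopifnot(inherits(selection, "selection_params"), alpha > 0, alpha <= 1)
  structure(list(direction = direction, selection = selection, alpha = alpha,
                 ivw_model = ivw_model, n_boot = n_boot, phi = phi,
                 presso_n_sim = presso_n_sim, alpha_outlier = alpha_outlier,
                 palindrome_policy = palindrome_policy, eaf_window = eaf_window,
                 prune_per_snp_f = prune_per_snp_f),
            class = "direction_config")
}

# substitute proxies: missing instruments adopt the proxy's outcome effect
# under the instrument's alleles (orientation assumed aligned; the r2-only
# reference cannot resolve phase)
.apply_proxies <- function(iv_records, outcome, ld, proxy_r2_min) {
  missing <- iv_records[!iv_records$snp_id %in% outcome$records$snp_id, ,
                        drop = FALSE]
  if (nrow(missing) == 0) return(list(outcome = outcome, proxies = NULL))
  proxies <- find_proxies(missing, outcome, ld, proxy_r2_min)
  resolved <- proxies[!is.na(proxies$proxy_snp_id), , drop = FALSE]
  if (nrow(resolved) == 0) return(list(outcome = outcome, proxies = proxies))
  add <- outcome$records[match(resolved$proxy_snp_id, outcome$records$snp_id), ,
                         drop = FALSE]
  miss_rec <- missing[match(resolved$snp_id, missing$snp_id), , drop = FALSE]
  add$snp_id <- resolved$snp_id
  add$effect_allele <- miss_rec$effect_allele
  add$other_allele <- miss_rec$other_allele
  add$chrom <- miss_rec$chrom
  add$pos <- miss_rec$pos
  out2 <- summary_dataset(rbind(outcome$records, add),
                          trait_name = outcome$trait_name,
                          trait_type = outcome$trait_type,
                          n_total = outcome$n_total, n_case = outcome$n_case,
                          n_control = outcome$n_control, level = outcome$level)
  list(outcome = out2, proxies = proxies)
}

#' Run one direction of the MR screen over many exposures
#'
#' For each exposure: instrument selection, proxy substitution for
#' instruments absent from the outcome, harmonization, all admissible causal
#' estimators, and the sensitivity suite. Exposures yielding no instruments,
#' a weak instrument set (aggregate F below the threshold), or no harmonized
#' pairs are recorded as skipped with a reason rather than silently dropped.
#' Deterministic given `seed`.
#'
#' @param exposures List of exposure `summary_dataset`s (or a single one).
#' @param outcome Outcome `summary_dataset`.
#' @param ld `ld_reference` or `NULL`.
#' @param config A `direction_config`.
#' @param seed Integer seed driving all stochastic components.
#' @return An `mr_result_table`: list with `results` (one row per
#'   exposure x method, including odds ratios and a supplementary
#'   Benjamini-Hochberg column computed within method across exposures),
#'   `sensitivity` (one row per analyzed exposure), `skipped`
#'   (exposure/reason), `plotdata` (named list of [make_plot_data()]
#'   outputs), `provenance`.
#' @export
run_direction <- function(exposures, outcome, ld = NULL,
                          config = direction_config(), seed = NULL) {
  if (inherits(exposures, "summary_dataset")) exposures <- list(exposures)
  stopifnot(length(exposures) >= 1, inherits(outcome, "summary_dataset"))
  if (nrow(outcome$records) == 0) stop("outcome dataset is empty")
  seeds <- derive_seeds(seed, length(exposures))

  results <- list(); sens <- list(); skipped <- list(); plotdata <- list()
  for (i in seq_along(exposures)) {
    exp_ds <- exposures[[i]]
    skip <- function(reason) {
      skipped[[length(skipped) + 1]] <<- data.frame(
        exposure = exp_ds$trait_name, reason = reason, stringsAsFactors = FALSE)
    }
    iv <- select_instruments(exp_ds, ld, config$selection,
                             prune_per_snp_f = config$prune_per_snp_f)
    if (nrow(iv$snps) == 0) { skip("no_instruments"); next }
    if (isTRUE(iv$weak)) { skip("weak_instruments"); next }
    sub <- .apply_proxies(iv$snps, outcome, ld, config$selection$proxy_r2_min)
    hset <- harmonize(instrument_dataset(exp_ds, iv), sub$outcome,
                      palindrome_policy = config$palindrome_policy,
                      eaf_window = config$eaf_window)
    if (nrow(hset$pairs) == 0) { skip("all_dropped_harmonization"); next }
    est_seeds <- derive_seeds(seeds[[i]], 2)
    ests <- run_all_methods(hset, ivw_model = config$ivw_model,
                            n_boot = config$n_boot, phi = config$phi,
                            seed = est_seeds[[1]])
    sr <- sensitivity_report(hset, presso_n_sim = config$presso_n_sim,
                             seed = est_seeds[[2]],
                             alpha_outlier = config$alpha_outlier)
    tab <- estimates_table(ests, exposure = exp_ds$trait_name,
                           outcome = outcome$trait_name)
    tab$level <- if (is.null(exp_ds$level)) NA_character_ else exp_ds$level
    results[[length(results) + 1]] <- tab
    sens[[length(sens) + 1]] <- sr$summary
    loo <- if (nrow(hset$pairs) >= 3) leave_one_out(hset, config$ivw_model) else NULL
    plotdata[[exp_ds$trait_name]] <- make_plot_data(hset, ests, loo)
  }

  results <- if (length(results) > 0) do.call(rbind, results) else
    data.frame(exposure = character(), outcome = character(), method = character(),
               n_snp = integer(), beta = numeric(), se = numeric(),
               pvalue = numeric(), or_ = numeric(), ci_low = numeric(),
               ci_high = numeric(), level = character(), stringsAsFactors = FALSE)
  if (nrow(results) > 0) {
    # supplementary BH correction within method across exposures
    results$pvalue_bh <- NA_real_
    for (m in unique(results$method)) {
      idx <- results$method == m
      results$pvalue_bh[idx] <- stats::p.adjust(results$pvalue[idx], method = "BH")
    }
  } else results$pvalue_bh <- numeric(0)
  structure(list(
    results = results,
    sensitivity = if (length(sens) > 0) do.call(rbind, sens) else NULL,
    skipped = if (length(skipped) > 0) do.call(rbind, skipped) else
      data.frame(exposure = character(), reason = character(),
                 stringsAsFactors = FALSE),
    plotdata = plotdata,
    provenance = list(direction = config$direction, config = config, seed = seed)),
    class = "mr_result_table")
}

#' @export
print.mr_result_table <- function(x, ...) {
  cat(sprintf("<mr_result_table> %s: %d result row(s), %d exposure(s) skipped\n",
              x$provenance$direction, nrow(x$results), nrow(x$skipped)))
  invisible(x)
}

#' Run the full bidirectional two-step analysis
#'
#' Step 1 treats each taxon as the exposure and the disease as the outcome
#' (microbiome selection preset); step 2 treats the disease as the exposure
#' and each taxon as the outcome (genome-wide preset). Returns both result
#' tables.
#'
#' @param taxa Non-empty list of taxon `summary_dataset`s.
#' @param disease Disease `summary_dataset`.
#' @param ld `ld_reference` or `NULL`.
#' @param config_step1,config_step2 `direction_config`s for the two steps.
#' @param seed Integer seed.
#' @return List with elements `step1` and `step2`, each an `mr_result_table`.
#' @export
run_bidirectional <- function(taxa, disease, ld = NULL,
                              config_step1 = direction_config("exposure_to_outcome"),
                              config_step2 = direction_config("outcome_to_exposure"),
                              seed = NULL) {
  if (inherits(taxa, "summary_dataset")) taxa <- list(taxa)
  if (length(taxa) == 0) stop("taxa list is empty")
  seeds <- derive_seeds(seed, 1 + length(taxa))
  step1 <- run_direction(taxa, disease, ld, config_step1, seed = seeds[[1]])

  # step 2: the disease is the (single) exposure against each taxon outcome
  parts <- lapply(seq_along(taxa), function(t) {
    run_direction(list(disease), taxa[[t]], ld, config_step2,
                  seed = seeds[[1 + t]])
  })
  results2 <- do.call(rbind, lapply(parts, function(p) {
    r <- p$results
    if (nrow(r) > 0) r$level <- NA_character_  # exposure (disease) has no level
    r
  }))
  # in step 2 taxonomic level belongs to the outcome
  lvl <- vapply(taxa, function(d) if (is.null(d$level)) NA_character_ else d$level,
                character(1))
  names(lvl) <- vapply(taxa, function(d) d$trait_name, character(1))
  if (nrow(results2) > 0) results2$level <- unname(lvl[results2$outcome])
  if (nrow(results2) > 0) {
    results2$pvalue_bh <- NA_real_
    for (m in unique(results2$method)) {
      idx <- results2$method == m
      results2$pvalue_bh[idx] <- stats::p.adjust(results2$pvalue[idx], method = "BH")
    }
  }
  sens2 <- do.call(rbind, lapply(parts, function(p) p$sensitivity))
  skipped2 <- do.call(rbind, lapply(seq_along(parts), function(t) {
    s <- parts[[t]]$skipped
    if (nrow(s) > 0) s$outcome <- taxa[[t]]$trait_name
    s
  }))
  plot2 <- do.call(c, lapply(seq_along(parts), function(t) {
    pd <- parts[[t]]$plotdata
    if (length(pd) > 0) names(pd) <- paste0(names(pd), "->", taxa[[t]]$trait_name)
    pd
  }))
  step2 <- structure(list(results = results2, sensitivity = sens2,
                          skipped = if (is.null(skipped2))
                            data.frame(exposure = character(), reason = character(),
                                       stringsAsFactors = FALSE) else skipped2,
                          plotdata = plot2,
                          provenance = list(direction = config_step2$direction,
                                            config = config_step2, seed = seed)),
                     class = "mr_result_table")
  list(step1 = step1, step2 = step2)
}

#' Filter a result table to nominally significant rows
#'
#' Keeps rows with `pvalue < alpha`, sorted by taxonomic level
#' (phylum, class, order, family, genus, then unlabeled) and ascending
#' p-value within level.
#'
#' @param table An `mr_result_table`.
#' @param alpha Significance level (default 0.05).
#' @return The filtered, sorted `results` data.frame.
#' @export
significant_results <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "mr_result_table"))
  keep <- !is.na(table$results$pvalue) & table$results$pvalue < alpha
  res <- table$results[keep, , drop = FALSE]
  if (nrow(res) > 0) {
    lvl_order <- match(res$level, c("phylum", "class", "order", "family", "genus"))
    lvl_order[is.na(lvl_order)] <- 6L
    res <- res[order(lvl_order, res$pvalue), , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Assemble scatter and leave-one-out plot data
#'
#' Scatter points are oriented so the exposure effect is non-negative (the
#' outcome effect's sign follows), making every estimator's fitted line
#' drawable as `y = intercept + slope * x` with `slope` the causal estimate;
#' only the Egger line has a non-zero intercept. The orientation makes the
#' plot invariant to allele recoding of any SNP.
#'
#' @param hset A `harmonized_set`.
#' @param estimates Non-empty list of `mr_estimate`s.
#' @param loo Optional `loo_table`.
#' @return A `plot_data`: list with `scatter` (snp_id, beta_exp, se_exp,
#'   beta_out, se_out), `lines` (method, slope, intercept) and `loo`
#'   (ordered by SNP id; `NULL` when not supplied).
#' @export
make_plot_data <- function(hset, estimates, loo = NULL) {
  stopifnot(length(estimates) >= 1)
  s <- sign(hset$pairs$beta_exp)
  s[s == 0] <- 1
  scatter <- data.frame(snp_id = hset$pairs$snp_id,
                        beta_exp = hset$pairs$beta_exp * s,
                        se_exp = hset$pairs$se_exp,
                        beta_out = hset$pairs$beta_out * s,
                        se_out = hset$pairs$se_out,
                        stringsAsFactors = FALSE)
  scatter <- scatter[order(scatter$snp_id), , drop = FALSE]
  rownames(scatter) <- NULL
  lines <- do.call(rbind, lapply(estimates, function(e) {
    data.frame(method = e$method, slope = e$beta,
               intercept = if (e$method == "mr_egger") e$extras$intercept else 0,
               stringsAsFactors = FALSE)
  }))
  loo_out <- NULL
  if (!is.null(loo)) {
    k <- nrow(loo) - 1
    body <- loo[seq_len(k), , drop = FALSE]
    body <- body[order(body$snp_left_out), , drop = FALSE]
    loo_out <- rbind(body, loo[k + 1, , drop = FALSE])
    rownames(loo_out) <- NULL
  }
  structure(list(scatter = scatter, lines = lines, loo = loo_out),
            class = "plot_data")
}

#' Write a result table's artifacts as tab-delimited files
#'
#' Writes `results.tsv`, `sensitivity.tsv`, `skipped.tsv` and one
#' `plotdata/<exposure>.{scatter,lines,loo}.tsv` trio per analyzed exposure.
#'
#' @param table An `mr_result_table`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result_table <- function(table, dir) {
  stopifnot(inherits(table, "mr_result_table"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (!is.null(df)) utils::write.table(df, file.path(dir, name), sep = "\t",
                                         quote = FALSE, row.names = FALSE)
  }
  wt(table$results, "results.tsv")
  wt(table$sensitivity, "sensitivity.tsv")
  wt(table$skipped, "skipped.tsv")
  if (length(table$plotdata) > 0) {
    pd_dir <- file.path(dir, "plotdata")
    dir.create(pd_dir, showWarnings = FALSE)
    for (nm in names(table$plotdata)) {
      safe <- gsub("[^A-Za-z0-9_.-]", "_", nm)
      pd <- table$plotdata[[nm]]
      utils::write.table(pd$scatter, file.path(pd_dir, paste0(safe, ".scatter.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(pd$lines, file.path(pd_dir, paste0(safe, ".lines.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(pd$loo)) {
        utils::write.table(pd$loo, file.path(pd_dir, paste0(safe, ".loo.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  invisible(dir)
}
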