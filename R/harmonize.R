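#' Harmonize exposure and outcome summary statistics
#'
#' Aligns per-SNP outcome effects to the exposure's effect allele so that both
#' betas refer to the same allele. Matching is by `snp_id`. For each exposure
#' SNP present in the outcome:
#'
#' * alleles identical: kept as-is (`aligned`);
#' * effect/other alleles swapped: outcome beta negated and `eaf_out`
#'   replaced by `1 - eaf_out` (`flipped`);
#' * alleles match only after strand complementation (A<->T, C<->G): the
#'   outcome alleles are complemented and the above rules applied
#'   (`strand_complemented`);
#' * palindromic SNPs (A/T or G/C allele pairs): strand cannot be resolved
#'   from alleles, so under `infer_by_eaf` alignment uses allele frequency
#'   only — kept when both frequencies lie outside `0.5 +/- eaf_window`
#'   (`palindromic_kept`; outcome beta negated when the frequencies fall on
#'   opposite sides of 0.5), dropped otherwise; under `drop`, always dropped.
#'
#' Exposure SNPs absent from the outcome are dropped with reason
#' `missing_in_outcome` (proxy substitution happens upstream, see
#' [find_proxies()]). Allele codes outside A/C/G/T drop the record with
#' reason `bad_alleles`.
#'
#' @param exposure_snps `summary_dataset` restricted to the instruments.
#' @param outcome `summary_dataset` for the outcome trait.
#' @param palindrome_policy `"infer_by_eaf"` (default) or `"drop"`.
#' @param eaf_window Half-width of the ambiguous frequency band around 0.5
#'   (default 0.08: frequencies in \[0.42, 0.58\] are treated as unresolvable).
#'
#' @return A `harmonized_set` with elements `exposure_name`, `outcome_name`,
#'   `pairs` (data.frame: `snp_id`, `beta_exp`, `se_exp`, `beta_out`,
#'   `se_out`, `eaf_exp`, `eaf_out`, `flag`, `beta_flipped`) and `dropped`
#'   (data.frame: `snp_id`, `reason`).
#' @export
harmonize <- function(exposure_snps, outcome,
                      palindrome_policy = c("infer_by_eaf", "drop"),
                      eaf_window = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(inherits(exposure_snps, "summary_dataset"),
            inherits(outcome, "summary_dataset"))
  exp_rec <- exposure_snps$records
  if (nrow(exp_rec) == 0) stop("exposure instrument set is empty")
  out_rec <- outcome$records
  out_idx <- match(exp_rec$snp_id, out_rec$snp_id)

  comp <- c(A = "T", T = "A", C = "G", G = "C")
  valid_allele <- function(a) a %in% names(comp)

  pairs <- vector("list", nrow(exp_rec))
  dropped <- vector("list", nrow(exp_rec))
  for (i in seq_len(nrow(exp_rec))) {
    e <- exp_rec[i, ]
    drop_with <- function(reason) {
      dropped[[i]] <<- data.frame(snp_id = e$snp_id, reason = reason,
                                  stringsAsFactors = FALSE)
    }
    if (!valid_allele(e$effect_allele) || !valid_allele(e$other_allele)) {
      drop_with("bad_alleles"); next
    }
    if (is.na(out_idx[i])) {
      drop_with("missing_in_outcome"); next
    }
    o <- out_rec[out_idx[i], ]
    if (!valid_allele(o$effect_allele) || !valid_allele(o$other_allele)) {
      drop_with("bad_alleles"); next
    }

    palindromic <- comp[[e$effect_allele]] == e$other_allele
    beta_out <- o$beta
    eaf_out <- o$eaf
    flag <- NA_character_
    flipped <- FALSE

    if (palindromic) {
      # outcome must carry the same unordered base pair
      if (!setequal(c(o$effect_allele, o$other_allele),
                    c(e$effect_allele, e$other_allele))) {
        drop_with("allele_mismatch"); next
      }
      if (palindrome_policy == "drop") {
        drop_with("palindromic"); next
      }
      if (is.na(e$eaf) || is.na(eaf_out) ||
          abs(e$eaf - 0.5) <= eaf_window || abs(eaf_out - 0.5) <= eaf_window) {
        drop_with("palindromic_ambiguous"); next
      }
      # strand unresolvable: frequency is the only arbiter of orientation
      if ((e$eaf < 0.5) != (eaf_out < 0.5)) {
        beta_out <- -beta_out
        eaf_out <- 1 - eaf_out
        flipped <- TRUE
      }
      flag <- "palindromic_kept"
    } else {
      oe <- o$effect_allele; oo <- o$other_allele
      if (oe == e$effect_allele && oo == e$other_allele) {
        flag <- "aligned"
      } else if (oe == e$other_allele && oo == e$effect_allele) {
        flag <- "flipped"; flipped <- TRUE
      } else if (comp[[oe]] == e$effect_allele && comp[[oo]] == e$other_allele) {
        flag <- "strand_complemented"
      } else if (comp[[oe]] == e$other_allele && comp[[oo]] == e$effect_allele) {
        flag <- "strand_complemented"; flipped <- TRUE
      } else {
        drop_with("allele_mismatch"); next
      }
      if (flipped) {
        beta_out <- -beta_out
        eaf_out <- 1 - eaf_out
      }
    }

    pairs[[i]] <- data.frame(
      snp_id = e$snp_id, beta_exp = e$beta, se_exp = e$se,
      beta_out = beta_out, se_out = o$se,
      eaf_exp = e$eaf, eaf_out = eaf_out,
      flag = flag, beta_flipped = flipped,
      stringsAsFactors = FALSE
    )
  }

  harmonized_set(
    pairs = do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))]),
    dropped = do.call(rbind, dropped[!vapply(dropped, is.null, logical(1))]),
    exposure_name = exposure_snps$trait_name,
    outcome_name = outcome$trait_name
  )
}

#' Construct a harmonized set
#'
#' Low-level constructor used by [harmonize()] and by simulations/tests that
#' build aligned effect pairs directly.
#'
#' @param pairs data.frame with at least `snp_id`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out` (optionally `eaf_exp`, `eaf_out`, `flag`,
#'   `beta_flipped`); may be `NULL`/empty.
#' @param dropped data.frame with `snp_id`, `reason`; may be `NULL`.
#' @param exposure_name,outcome_name Trait labels.
#' @return A `harmonized_set`.
#' @export
harmonized_set <- function(pairs, dropped = NULL,
                           exposure_name = "exposure", outcome_name = "outcome") {
  if (is.null(pairs)) {
    pairs <- data.frame(snp_id = character(), beta_exp = numeric(),
                        se_exp = numeric(), beta_out = numeric(),
                        se_out = numeric(), eaf_exp = numeric(),
                        eaf_out = numeric(), flag = character(),
                        beta_flipped = logical(), stringsAsFactors = FALSE)
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  for (col in c("eaf_exp", "eaf_out")) if (!col %in% names(pairs)) pairs[[col]] <- NA_real_
  if (!"flag" %in% names(pairs)) pairs$flag <- "aligned"
  if (!"beta_flipped" %in% names(pairs)) pairs$beta_flipped <- FALSE
  if (nrow(pairs) > 0) {
    stopifnot(all(pairs$se_exp > 0), all(pairs$se_out > 0))
    if (anyDuplicated(pairs$snp_id)) stop("duplicate snp_id in harmonized pairs")
  }
  if (is.null(dropped)) {
    dropped <- data.frame(snp_id = character(), reason = character(),
                          stringsAsFactors = FALSE)
  }
  rownames(pairs) <- NULL
  structure(list(exposure_name = exposure_name, outcome_name = outcome_name,
                 pairs = pairs, dropped = dropped),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s: %d pairs, %d dropped\n",
              x$exposure_name, x$outcome_name, nrow(x$pairs), nrow(x$dropped)))
  invisible(x)
}

#' Number of harmonized SNP pairs
#' @param hset A `harmonized_set`.
#' @export
n_pairs <- function(hset) nrow(hset$pairs)
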