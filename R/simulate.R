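#' Ground-truth configuration for a synthetic exposure-outcome pair
#'
#' Describes the generating model for one synthetic two-sample MR dataset:
#' a continuous exposure (unit variance) with `m_instruments` genuine
#' instruments among `m_null` null SNPs, and a binary outcome on the
#' log-odds scale. Per-instrument exposure effects `gamma_j` are drawn from
#' `N(gamma_mean, gamma_sd)`; a fraction `invalid_fraction` of instruments
#' additionally carries a direct (pleiotropic) outcome effect `alpha_j`:
#' `none` sets all alpha to 0, `balanced` draws `N(0, sd_alpha)` centered to
#' exact zero mean, `directional` draws `N(mu_alpha, sd_alpha)` (independent
#' of gamma, so the InSIDE condition holds), and `directional_inside_violated`
#' correlates alpha with gamma for Egger stress tests.
#'
#' Default sample sizes match a multi-ethnic 16S microbiome GWAS
#' (n = 18,340) and a large biobank disease GWAS (n = 212,453 with 2,176
#' cases), the study conditions this generator emulates. Instruments sit at
#' the head of LD blocks of `ld_block_size` SNPs with AR(1)-decaying r2
#' (`rho^(2|i-j|)`); tag SNPs carry correlation-attenuated copies of the
#' index effect, so clumping has real work to do.
#'
#' @param beta_causal True causal effect of the exposure on the outcome
#'   (log-odds per SD of exposure).
#' @param m_instruments Number of genuine instruments.
#' @param m_null Number of null SNPs.
#' @param n_exp,n_out Exposure and outcome GWAS sample sizes.
#' @param n_case,n_control Outcome case/control split (must sum to `n_out`).
#'   When both are given, outcome SEs use the binomial effective sample size
#'   `n_case * n_control / n_out` — the information content of a log-odds
#'   GWAS effect; set both to `NULL` to treat the outcome SE like a
#'   continuous trait's at `n_out`.
#' @param gamma_mean,gamma_sd Normal parameters for instrument effects.
#' @param invalid_fraction Fraction of instruments with pleiotropic effects.
#' @param pleiotropy_mode One of `"none"`, `"balanced"`, `"directional"`,
#'   `"directional_inside_violated"`.
#' @param mu_alpha,sd_alpha Pleiotropy distribution parameters.
#' @param maf_min Allele frequencies are drawn uniformly on
#'   `[maf_min, 1 - maf_min]`.
#' @param ld_block_size SNPs per LD block (1 = no LD).
#' @param ld_rho AR(1) correlation parameter within a block, in \[0, 1).
#' @return A `simulation_truth` configuration list.
#' @export
simulation_truth <- function(beta_causal = 0, m_instruments = 10, m_null = 490,
                             n_exp = 18340, n_out = 212453,
                             n_case = 2176, n_control = 210277,
                             gamma_mean = 0.15, gamma_sd = 0.03,
                             invalid_fraction = 0,
                             pleiotropy_mode = c("none", "balanced", "directional",
                                                 "directional_inside_violated"),
                             mu_alpha = 0.1, sd_alpha = 0.05,
                             maf_min = 0.05, ld_block_size = 1, ld_rho = 0.9) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(m_instruments >= 0, m_null >= 0, m_instruments + m_null > 0,
            n_exp > 2, n_out > 2,
            invalid_fraction >= 0, invalid_fraction <= 1,
            maf_min > 0, maf_min < 0.5,
            ld_block_size >= 1, ld_rho >= 0, ld_rho < 1)
  if (pleiotropy_mode == "none" && invalid_fraction > 0) {
    stop("invalid_fraction > 0 requires a pleiotropy mode other than 'none'")
  }
  if (xor(is.null(n_case), is.null(n_control))) {
    stop("supply both n_case and n_control, or neither")
  }
  if (!is.null(n_case) && n_case + n_control != n_out) {
    stop("n_case + n_control must equal n_out")
  }
  structure(list(beta_causal = beta_causal, m_instruments = m_instruments,
                 m_null = m_null, n_exp = n_exp, n_out = n_out,
                 n_case = n_case, n_control = n_control,
                 gamma_mean = gamma_mean, gamma_sd = gamma_sd,
                 invalid_fraction = invalid_fraction,
                 pleiotropy_mode = pleiotropy_mode,
                 mu_alpha = mu_alpha, sd_alpha = sd_alpha,
                 maf_min = maf_min, ld_block_size = as.integer(ld_block_size),
                 ld_rho = ld_rho),
            class = "simulation_truth")
}

# information-bearing sample size of the outcome GWAS: the binomial
# effective n for a case-control trait, the full n otherwise
.n_out_eff <- function(truth) {
  if (!is.null(truth$n_case) && !is.null(truth$n_control)) {
    truth$n_case * truth$n_control / truth$n_out
  } else {
    truth$n_out
  }
}

# non-palindromic allele pairs, sampled per SNP
.allele_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                          "G", "A", "C", "A", "G", "T", "C", "T"),
                        ncol = 2, byrow = TRUE)

# lay out blocks of SNPs: within-block spacing 10 kb, blocks 1,000 kb apart
# (beyond the default 500 kb clumping window), chromosomes cycling 1..22
.block_layout <- function(block_sizes) {
  n_blocks <- length(block_sizes)
  chrom <- as.character(rep_len(1:22, n_blocks))
  block_start <- integer(n_blocks)
  offset_by_chrom <- stats::setNames(rep(1e6, 22), as.character(1:22))
  for (b in seq_len(n_blocks)) {
    block_start[b] <- offset_by_chrom[[chrom[b]]]
    offset_by_chrom[[chrom[b]]] <- offset_by_chrom[[chrom[b]]] +
      1e6 + (block_sizes[b] - 1) * 1e4
  }
  data.frame(
    block = rep(seq_len(n_blocks), block_sizes),
    idx_in_block = unlist(lapply(block_sizes, seq_len)),
    chrom = rep(chrom, block_sizes),
    pos = unlist(lapply(seq_len(n_blocks), function(b)
      block_start[b] + (seq_len(block_sizes[b]) - 1) * 1e4)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a block-diagonal LD reference
#'
#' Builds an `ld_reference` whose r2 decays as `rho^(2|i-j|)` between the
#' i-th and j-th SNP of a block and is 0 across blocks.
#'
#' @param block_sizes Integer vector of SNPs per block.
#' @param rho AR(1) correlation parameter in \[0, 1).
#' @param snp_ids Optional character vector of SNP ids (length
#'   `sum(block_sizes)`); defaults to `blk<b>_snp<i>`.
#' @param window_kb Window metadata for the reference.
#' @return An `ld_reference`.
#' @export
simulate_ld <- function(block_sizes, rho, snp_ids = NULL, window_kb = 500) {
  stopifnot(rho >= 0, rho < 1, all(block_sizes >= 1))
  layout <- .block_layout(block_sizes)
  if (is.null(snp_ids)) {
    snp_ids <- paste0("blk", layout$block, "_snp", layout$idx_in_block)
  }
  stopifnot(length(snp_ids) == nrow(layout))
  pairs <- list()
  for (b in unique(layout$block)) {
    members <- which(layout$block == b)
    if (length(members) < 2 || rho == 0) next
    combs <- utils::combn(members, 2)
    d <- abs(layout$idx_in_block[combs[1, ]] - layout$idx_in_block[combs[2, ]])
    pairs[[length(pairs) + 1]] <- data.frame(
      snp_a = snp_ids[combs[1, ]], snp_b = snp_ids[combs[2, ]],
      r2 = rho^(2 * d), stringsAsFactors = FALSE)
  }
  ld_reference(if (length(pairs) > 0) do.call(rbind, pairs) else NULL,
               window_kb = window_kb)
}

# draw pleiotropic direct effects for the invalid instruments
.draw_alpha <- function(truth, gamma) {
  m <- truth$m_instruments
  alpha <- numeric(m)
  n_invalid <- round(truth$invalid_fraction * m)
  if (n_invalid == 0 || truth$pleiotropy_mode == "none") return(alpha)
  invalid <- seq_len(n_invalid)  # first instruments are the invalid ones
  a <- switch(truth$pleiotropy_mode,
    balanced = {
      raw <- stats::rnorm(n_invalid, 0, truth$sd_alpha)
      raw - mean(raw)
    },
    directional = stats::rnorm(n_invalid, truth$mu_alpha, truth$sd_alpha),
    directional_inside_violated =
      truth$mu_alpha + 0.5 * (gamma[invalid] - truth$gamma_mean) +
        stats::rnorm(n_invalid, 0, truth$sd_alpha)
  )
  alpha[invalid] <- a
  alpha
}

#' Simulate one exposure-outcome pair of GWAS summary datasets
#'
#' Draws summary statistics directly from the asymptotic model: with
#' effect-allele frequency `f` and sample size `n`, the per-allele SE on a
#' unit-variance trait is `(2 f (1 - f) n)^(-1/2)`; observed effects are
#' `beta_exp ~ N(gamma, se_exp)` and
#' `beta_out ~ N(beta_causal * gamma + alpha, se_out)`, with independent
#' noise on the two sides (non-overlapping samples). Null SNPs have
#' `gamma = alpha = 0`. Two-sided normal p-values. Tag SNPs within an LD
#' block carry `rho^d`-attenuated copies of the index SNP's effects.
#'
#' @param truth A `simulation_truth` configuration.
#' @param seed Integer seed (required for reproducibility; `NULL` uses the
#'   current RNG stream).
#' @param exposure_name,outcome_name,level Trait metadata.
#' @return A `synthetic_bundle`: list with `exposure` and `outcome`
#'   (`summary_dataset`s), `ld` (`ld_reference`), and `truth` (the
#'   configuration plus realized `gamma`, `alpha`, `instrument_ids`).
#' @export
simulate_pair <- function(truth = simulation_truth(), seed = NULL,
                          exposure_name = "exposure", outcome_name = "outcome",
                          level = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  with_seed(seed, {
    bs <- truth$ld_block_size
    m_i <- truth$m_instruments
    # instruments head their own blocks; null SNPs form same-sized blocks
    null_blocks <- if (truth$m_null > 0) {
      c(rep(bs, truth$m_null %/% bs), if (truth$m_null %% bs > 0) truth$m_null %% bs)
    } else integer(0)
    block_sizes <- c(rep(bs, m_i), null_blocks)
    layout <- .block_layout(block_sizes)
    m <- nrow(layout)
    snp_id <- sprintf("rs%06d", seq_len(m))

    gamma_idx <- stats::rnorm(m_i, truth$gamma_mean, truth$gamma_sd)
    alpha_idx <- .draw_alpha(truth, gamma_idx)
    # per-SNP true effects: index effects attenuated by rho^d on tags
    g <- numeric(m)
    a <- numeric(m)
    in_instrument_block <- layout$block <= m_i
    if (m_i > 0) {
      atten <- truth$ld_rho^(layout$idx_in_block[in_instrument_block] - 1)
      g[in_instrument_block] <- gamma_idx[layout$block[in_instrument_block]] * atten
      a[in_instrument_block] <- alpha_idx[layout$block[in_instrument_block]] * atten
    }

    eaf <- stats::runif(m, truth$maf_min, 1 - truth$maf_min)
    se_exp <- 1 / sqrt(2 * eaf * (1 - eaf) * truth$n_exp)
    se_out <- 1 / sqrt(2 * eaf * (1 - eaf) * .n_out_eff(truth))
    beta_exp <- stats::rnorm(m, g, se_exp)
    beta_out <- stats::rnorm(m, truth$beta_causal * g + a, se_out)
    alleles <- .allele_pairs[sample.int(nrow(.allele_pairs), m, replace = TRUE), ,
                             drop = FALSE]

    base <- data.frame(snp_id = snp_id, chrom = layout$chrom, pos = layout$pos,
                       effect_allele = alleles[, 1], other_allele = alleles[, 2],
                       eaf = eaf, stringsAsFactors = FALSE)
    exposure <- summary_dataset(
      cbind(base, beta = beta_exp, se = se_exp,
            pvalue = .norm_pvalue(beta_exp / se_exp), n = truth$n_exp),
      trait_name = exposure_name, trait_type = "continuous",
      n_total = truth$n_exp, level = level)
    outcome <- summary_dataset(
      cbind(base, beta = beta_out, se = se_out,
            pvalue = .norm_pvalue(beta_out / se_out), n = truth$n_out),
      trait_name = outcome_name, trait_type = "binary",
      n_total = truth$n_out, n_case = truth$n_case, n_control = truth$n_control)
    ld <- simulate_ld(block_sizes, truth$ld_rho, snp_ids = snp_id)

    truth_out <- truth
    truth_out$gamma <- gamma_idx
    truth_out$alpha <- alpha_idx
    truth_out$instrument_ids <- snp_id[in_instrument_block & layout$idx_in_block == 1]
    structure(list(exposure = exposure, outcome = outcome, ld = ld,
                   truth = truth_out, seed = seed),
              class = "synthetic_bundle")
  })
}

#' Build a harmonized set directly from a bundle's true instruments
#'
#' Convenience for estimator studies: restricts the exposure to the planted
#' instrument SNPs and harmonizes against the outcome, bypassing instrument
#' selection.
#'
#' @param bundle A `synthetic_bundle`.
#' @return A `harmonized_set` over the true instruments.
#' @export
truth_harmonized <- function(bundle) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  rec <- bundle$exposure$records
  keep <- rec$snp_id %in% bundle$truth$instrument_ids
  exp_iv <- summary_dataset(rec[keep, , drop = FALSE],
                            trait_name = bundle$exposure$trait_name,
                            trait_type = bundle$exposure$trait_type,
                            n_total = bundle$exposure$n_total)
  harmonize(exp_iv, bundle$outcome)
}

#' Simulate a taxa panel sharing one disease outcome
#'
#' Generates a panel of per-taxon exposure datasets plus one shared binary
#' disease dataset over a common SNP universe, with causal structure in both
#' directions: `effect_map[t]` is taxon t's causal effect on the disease
#' (its instruments' disease effects are `effect * gamma`), and
#' `reverse_effect_map[t]` is the disease's causal effect on taxon t (the
#' disease instruments' taxon effects are `reverse_effect * gamma_disease`).
#' Disease instruments are drawn strong enough to pass genome-wide
#' significance. Taxon metadata cycles through the five taxonomic levels.
#'
#' @param n_taxa Number of taxa (default 20).
#' @param effect_map Numeric vector (recycled) of per-taxon causal effects on
#'   the disease; default all 0.
#' @param reverse_effect_map Numeric vector (recycled) of disease effects on
#'   each taxon; default all 0.
#' @param seed Integer seed.
#' @param m_instruments Instruments per taxon (default 8).
#' @param m_disease_instruments Disease instruments (default 13).
#' @param m_null Shared null SNPs (default sized so each dataset holds 2,000
#'   SNPs).
#' @param truth Base `simulation_truth` supplying sample sizes, effect and
#'   frequency distributions (its SNP counts are overridden by the panel
#'   arguments).
#' @param gamma_disease_mean,gamma_disease_sd Disease-instrument effect
#'   distribution (log-odds scale).
#' @return A `taxa_panel`: list with `taxa` (list of exposure
#'   `summary_dataset`s), `disease` (shared `summary_dataset`), `ld`, and
#'   `truth` (per-taxon instrument ids/effects and the disease instruments).
#' @export
make_taxa_panel <- function(n_taxa = 20, effect_map = 0, reverse_effect_map = 0,
                            seed = NULL, m_instruments = 8,
                            m_disease_instruments = 13, m_null = NULL,
                            truth = simulation_truth(),
                            gamma_disease_mean = 0.25, gamma_disease_sd = 0.03) {
  stopifnot(n_taxa >= 1)
  effect_map <- rep_len(effect_map, n_taxa)
  reverse_effect_map <- rep_len(reverse_effect_map, n_taxa)
  if (is.null(m_null)) {
    m_null <- max(0, 2000 - n_taxa * m_instruments - m_disease_instruments)
  }
  levels5 <- c("phylum", "class", "order", "family", "genus")
  with_seed(seed, {
    m <- n_taxa * m_instruments + m_disease_instruments + m_null
    block_sizes <- rep(1L, m)  # panel SNPs are mutually independent
    layout <- .block_layout(block_sizes)
    snp_id <- sprintf("rs%06d", seq_len(m))
    eaf <- stats::runif(m, truth$maf_min, 1 - truth$maf_min)
    se_taxon <- 1 / sqrt(2 * eaf * (1 - eaf) * truth$n_exp)
    se_dis <- 1 / sqrt(2 * eaf * (1 - eaf) * .n_out_eff(truth))
    alleles <- .allele_pairs[sample.int(nrow(.allele_pairs), m, replace = TRUE), ,
                             drop = FALSE]
    base <- data.frame(snp_id = snp_id, chrom = layout$chrom, pos = layout$pos,
                       effect_allele = alleles[, 1], other_allele = alleles[, 2],
                       eaf = eaf, stringsAsFactors = FALSE)

    taxon_iv_idx <- lapply(seq_len(n_taxa), function(t)
      (t - 1) * m_instruments + seq_len(m_instruments))
    dis_iv_idx <- n_taxa * m_instruments + seq_len(m_disease_instruments)
    gamma_taxa <- lapply(seq_len(n_taxa), function(t)
      stats::rnorm(m_instruments, truth$gamma_mean, truth$gamma_sd))
    gamma_dis <- stats::rnorm(m_disease_instruments,
                              gamma_disease_mean, gamma_disease_sd)

    # disease dataset: own instruments + causal propagation from taxa
    mu_dis <- numeric(m)
    mu_dis[dis_iv_idx] <- gamma_dis
    for (t in seq_len(n_taxa)) {
      mu_dis[taxon_iv_idx[[t]]] <- effect_map[t] * gamma_taxa[[t]]
    }
    beta_dis <- stats::rnorm(m, mu_dis, se_dis)
    disease <- summary_dataset(
      cbind(base, beta = beta_dis, se = se_dis,
            pvalue = .norm_pvalue(beta_dis / se_dis), n = truth$n_out),
      trait_name = "disease", trait_type = "binary",
      n_total = truth$n_out, n_case = truth$n_case, n_control = truth$n_control)

    taxa <- vector("list", n_taxa)
    for (t in seq_len(n_taxa)) {
      mu_t <- numeric(m)
      mu_t[taxon_iv_idx[[t]]] <- gamma_taxa[[t]]
      mu_t[dis_iv_idx] <- reverse_effect_map[t] * gamma_dis
      beta_t <- stats::rnorm(m, mu_t, se_taxon)
      lvl <- levels5[((t - 1) %% 5) + 1]
      taxa[[t]] <- summary_dataset(
        cbind(base, beta = beta_t, se = se_taxon,
              pvalue = .norm_pvalue(beta_t / se_taxon), n = truth$n_exp),
        trait_name = sprintf("%s_taxon_%02d", lvl, t),
        trait_type = "continuous", n_total = truth$n_exp, level = lvl)
    }
    names(taxa) <- vapply(taxa, function(d) d$trait_name, character(1))

    structure(list(
      taxa = taxa, disease = disease,
      ld = ld_reference(window_kb = 500),
      truth = list(effect_map = stats::setNames(effect_map, names(taxa)),
                   reverse_effect_map = stats::setNames(reverse_effect_map, names(taxa)),
                   taxon_instrument_ids = stats::setNames(
                     lapply(taxon_iv_idx, function(i) snp_id[i]), names(taxa)),
                   disease_instrument_ids = snp_id[dis_iv_idx],
                   gamma_taxa = gamma_taxa, gamma_disease = gamma_dis)),
      class = "taxa_panel")
  })
}
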