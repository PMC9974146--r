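# Shared fixture builders. Everything is constructed in code; no files.

# a valid records data.frame; override any column (incl. `n`) via ...
make_records <- function(len = 3, ...) {
  rec <- data.frame(
    snp_id = sprintf("rs%03d", seq_len(len)),
    chrom = rep("1", len),
    pos = seq(1e6, by = 5e4, length.out = len),
    effect_allele = rep("A", len),
    other_allele = rep("G", len),
    eaf = rep(0.3, len),
    beta = seq(0.1, by = 0.05, length.out = len),
    se = rep(0.02, len),
    pvalue = rep(1e-6, len),
    n = rep(10000, len),
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

make_dataset <- function(len = 3, trait_name = "trait",
                         trait_type = "continuous", ...) {
  summary_dataset(make_records(len, ...), trait_name = trait_name,
                  trait_type = trait_type, n_total = 10000)
}

# harmonized set straight from effect vectors (already aligned)
make_hset <- function(beta_exp, beta_out, se_exp = 0.01, se_out = 0.05,
                      snp_id = NULL) {
  k <- length(beta_exp)
  if (is.null(snp_id)) snp_id <- sprintf("rs%03d", seq_len(k))
  harmonized_set(data.frame(
    snp_id = snp_id, beta_exp = beta_exp, se_exp = rep_len(se_exp, k),
    beta_out = beta_out, se_out = rep_len(se_out, k),
    stringsAsFactors = FALSE
  ))
}

# hset with prescribed ratio estimates and ratio SEs; exposure effects vary
# (so Egger is estimable) but weights w = 1/ratio_se^2 are unaffected
make_ratio_hset <- function(ratios, ratio_se = 1) {
  k <- length(ratios)
  x <- seq(1, 1.5, length.out = max(k, 2))[seq_len(k)]
  rse <- rep_len(ratio_se, k)
  make_hset(beta_exp = x, beta_out = ratios * x, se_exp = 1e-8,
            se_out = rse * x)
}
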