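# Reading, writing, and harmonizing summary statistics

test_that("read_summary_stats parses a well-formed table and honors a column map", {
  rec <- make_records(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ds <- read_summary_stats(path, trait_name = "t")
  expect_s3_class(ds, "summary_dataset")
  expect_equal(n_snps(ds), 3)
  expect_equal(ds$records$beta, rec$beta)

  # shuffled column order + renamed columns with a map gives the same dataset
  shuffled <- rec[, rev(seq_along(rec))]
  names(shuffled)[names(shuffled) == "snp_id"] <- "rsid"
  names(shuffled)[names(shuffled) == "beta"] <- "effect"
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(shuffled, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  ds2 <- read_summary_stats(path2, column_map = c(snp_id = "rsid", beta = "effect"),
                            trait_name = "t")
  expect_equal(ds2$records, ds$records)
})

test_that("invalid rows are dropped and counted; missing mapped column errors", {
  rec <- make_records(4)
  rec$se[2] <- 0            # invariant violation
  rec$effect_allele[3] <- "N"  # bad allele
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(ds <- read_summary_stats(path, trait_name = "t"), "2 invalid")
  expect_equal(n_snps(ds), 2)
  expect_equal(attr(ds, "n_invalid_dropped"), 2)

  expect_error(read_summary_stats(path, column_map = c(beta = "nonexistent")),
               "not present")
  expect_error(read_summary_stats(path, column_map = c(nonsense = "x")),
               "canonical")
})

test_that("write/read round trip preserves all fields exactly, incl. absent eaf", {
  set.seed(11)
  rec <- make_records(5, beta = rnorm(5), se = runif(5, 0.001, 0.1),
                      eaf = runif(5), pvalue = runif(5))
  ds <- summary_dataset(rec, "t", n_total = 10000)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ds, path)
  back <- read_summary_stats(path, trait_name = "t", n_total = 10000)
  expect_identical(back$records, ds$records)

  # absent eaf: column omitted, absence survives
  ds_na <- summary_dataset(make_records(3, eaf = NA_real_), "t")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ds_na, path2)
  header <- strsplit(readLines(path2, n = 1), "\t")[[1]]
  expect_false("eaf" %in% header)
  back2 <- read_summary_stats(path2, trait_name = "t")
  expect_true(all(is.na(back2$records$eaf)))

  expect_error(write_summary_stats(summary_dataset(make_records(0), "t"), path),
               "empty")
})

test_that("harmonize aligns, flips, and strand-complements correctly", {
  exp_ds <- summary_dataset(make_records(4,
    snp_id = c("rs1", "rs2", "rs3", "rs4"),
    effect_allele = c("A", "A", "A", "A"),
    other_allele = c("G", "G", "G", "G"),
    beta = c(0.1, 0.1, 0.1, 0.1), eaf = c(0.3, 0.3, 0.3, 0.3)), "exp")
  out_ds <- summary_dataset(make_records(4,
    snp_id = c("rs1", "rs2", "rs3", "rs4"),
    effect_allele = c("A", "G", "T", "C"),
    other_allele = c("G", "A", "C", "T"),
    beta = c(0.3, 0.3, 0.3, 0.3), eaf = c(0.3, 0.7, 0.3, 0.7)), "out")
  h <- harmonize(exp_ds, out_ds)
  expect_equal(nrow(h$pairs), 4)
  expect_equal(h$pairs$flag,
               c("aligned", "flipped", "strand_complemented", "strand_complemented"))
  # rs1 kept as-is; rs2 swapped alleles: negated; rs3 complement (T/C ~ A/G):
  # as-is; rs4 complement-swapped: negated
  expect_equal(h$pairs$beta_out, c(0.3, -0.3, 0.3, -0.3))
  expect_equal(h$pairs$eaf_out, c(0.3, 0.3, 0.3, 0.3))
  expect_equal(h$pairs$beta_flipped, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("palindromic SNPs follow the frequency rule across all cases", {
  # enumerate: (exposure eaf side, outcome eaf side, either in window) x policy
  mk <- function(eaf_exp, eaf_out) {
    e <- summary_dataset(make_records(1, snp_id = "rs1", effect_allele = "A",
                                      other_allele = "T", eaf = eaf_exp,
                                      beta = 0.1), "e")
    o <- summary_dataset(make_records(1, snp_id = "rs1", effect_allele = "A",
                                      other_allele = "T", eaf = eaf_out,
                                      beta = 0.3), "o")
    list(e = e, o = o)
  }
  # same side, both clear of the window: kept unflipped
  d <- mk(0.30, 0.28)
  h <- harmonize(d$e, d$o, eaf_window = 0.08)
  expect_equal(h$pairs$flag, "palindromic_kept")
  expect_equal(h$pairs$beta_out, 0.3)
  # opposite sides: frequencies indicate opposite effect alleles -> negated
  d <- mk(0.30, 0.72)
  h <- harmonize(d$e, d$o, eaf_window = 0.08)
  expect_equal(h$pairs$beta_out, -0.3)
  expect_equal(h$pairs$eaf_out, 0.28)
  # either frequency inside [0.42, 0.58]: dropped as ambiguous
  for (pair in list(c(0.5, 0.3), c(0.3, 0.55), c(0.45, 0.45))) {
    d <- mk(pair[1], pair[2])
    h <- harmonize(d$e, d$o, eaf_window = 0.08)
    expect_equal(nrow(h$pairs), 0)
    expect_equal(h$dropped$reason, "palindromic_ambiguous")
  }
  # missing eaf: dropped (cannot infer strand)
  d <- mk(NA_real_, 0.3)
  h <- harmonize(d$e, d$o)
  expect_equal(h$dropped$reason, "palindromic_ambiguous")
  # drop policy: always dropped
  d <- mk(0.30, 0.28)
  h <- harmonize(d$e, d$o, palindrome_policy = "drop")
  expect_equal(h$dropped$reason, "palindromic")
})

test_that("missing and mismatching SNPs are dropped with reasons; conservation holds", {
  exp_ds <- summary_dataset(make_records(3, snp_id = c("rs1", "rs2", "rs3")), "e")
  out_ds <- summary_dataset(make_records(2, snp_id = c("rs1", "rs3"),
                                         effect_allele = c("A", "C"),
                                         other_allele = c("G", "G")), "o")
  h <- harmonize(exp_ds, out_ds)
  expect_equal(nrow(h$pairs) + nrow(h$dropped), 3)  # conservation
  expect_equal(h$dropped$reason[h$dropped$snp_id == "rs2"], "missing_in_outcome")
  expect_equal(h$dropped$reason[h$dropped$snp_id == "rs3"], "allele_mismatch")
})

test_that("harmonization is idempotent and sign-consistent", {
  set.seed(21)
  n <- 30
  alleles <- matrix(c("A", "G", "T", "C", "A", "T", "C", "G"), ncol = 2, byrow = TRUE)
  pick <- sample.int(4, n, replace = TRUE)
  exp_ds <- summary_dataset(make_records(
    n, snp_id = sprintf("rs%02d", 1:n),
    effect_allele = alleles[pick, 1], other_allele = alleles[pick, 2],
    beta = rnorm(n), eaf = runif(n, 0.05, 0.40)), "e")
  # outcome: random swaps of effect/other with matching beta/eaf adjustment
  out_rec <- exp_ds$records
  out_rec$beta <- rnorm(n)
  swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
  tmp <- out_rec$effect_allele[swap]
  out_rec$effect_allele[swap] <- out_rec$other_allele[swap]
  out_rec$other_allele[swap] <- tmp
  out_rec$eaf[swap] <- 1 - out_rec$eaf[swap]
  out_ds <- summary_dataset(out_rec, "o")
  h1 <- harmonize(exp_ds, out_ds)

  # idempotence: re-harmonizing the harmonized output changes nothing
  exp2 <- exp_ds$records[exp_ds$records$snp_id %in% h1$pairs$snp_id, ]
  out2 <- exp2
  out2$beta <- h1$pairs$beta_out[match(out2$snp_id, h1$pairs$snp_id)]
  out2$eaf <- h1$pairs$eaf_out[match(out2$snp_id, h1$pairs$snp_id)]
  h2 <- harmonize(summary_dataset(exp2, "e"), summary_dataset(out2, "o"))
  expect_equal(h2$pairs$beta_out, h1$pairs$beta_out)
  expect_equal(nrow(h2$dropped), 0)

  # sign consistency: globally swapping outcome alleles + negating beta
  # yields identical harmonized effect pairs
  out_rec2 <- out_ds$records
  tmp <- out_rec2$effect_allele
  out_rec2$effect_allele <- out_rec2$other_allele
  out_rec2$other_allele <- tmp
  out_rec2$beta <- -out_rec2$beta
  out_rec2$eaf <- 1 - out_rec2$eaf
  h3 <- harmonize(exp_ds, summary_dataset(out_rec2, "o"))
  expect_equal(h3$pairs$beta_exp, h1$pairs$beta_exp)
  expect_equal(h3$pairs$beta_out, h1$pairs$beta_out)
})
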