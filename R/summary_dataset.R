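#' GWAS summary-statistics datasets
#'
#' A `summary_dataset` bundles one trait's GWAS summary statistics with trait
#' metadata. Records are held in a data frame with the canonical columns
#' `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#' `se`, `pvalue`, `n`. Effects for binary traits are on the log-odds scale.
#'
#' @param records data.frame with the canonical columns (`eaf` may be `NA`).
#' @param trait_name Trait label, e.g. a taxon name or a disease name.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param n_total Total sample size of the GWAS.
#' @param n_case,n_control Case/control counts for binary traits (optional).
#' @param level Optional taxonomic-level label (phylum/class/order/family/genus)
#'   carried as free-text metadata.
#' @param drop_invalid If `TRUE`, rows violating the record invariants are
#'   dropped (and counted in the load report attribute) instead of raising an
#'   error.
#'
#' @return An object of class `summary_dataset`.
#' @export
summary_dataset <- function(records, trait_name, trait_type = c("continuous", "binary"),
                            n_total = NULL, n_case = NULL, n_control = NULL,
                            level = NULL, drop_invalid = FALSE) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  required <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "se", "pvalue", "n")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("records is missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"eaf" %in% names(records)) records$eaf <- NA_real_
  records <- records[, c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                         "eaf", "beta", "se", "pvalue", "n")]
  records$snp_id <- as.character(records$snp_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    records[[col]] <- as.numeric(records[[col]])
  }

  bad <- .invalid_record_mask(records)
  n_invalid <- sum(bad)
  if (n_invalid > 0) {
    if (!drop_invalid) {
      stop(sprintf("%d record(s) violate summary-statistic invariants (e.g. %s)",
                   n_invalid, records$snp_id[which(bad)[1]]))
    }
    records <- records[!bad, , drop = FALSE]
  }
  if (anyDuplicated(records$snp_id)) {
    stop("duplicate snp_id in dataset: ", records$snp_id[duplicated(records$snp_id)][1])
  }
  if (!is.null(n_case) && !is.null(n_control) && !is.null(n_total) &&
      n_case + n_control != n_total) {
    stop("n_case + n_control must equal n_total")
  }
  rownames(records) <- NULL
  structure(
    list(trait_name = as.character(trait_name), trait_type = trait_type,
         records = records,
         n_total = if (is.null(n_total)) NULL else as.integer(n_total),
         n_case = if (is.null(n_case)) NULL else as.integer(n_case),
         n_control = if (is.null(n_control)) NULL else as.integer(n_control),
         level = level),
    class = "summary_dataset",
    n_invalid_dropped = n_invalid
  )
}

# rows violating SummaryStatRecord invariants
.invalid_record_mask <- function(records) {
  alleles_ok <- records$effect_allele %in% c("A", "C", "G", "T") &
    records$other_allele %in% c("A", "C", "G", "T") &
    records$effect_allele != records$other_allele
  eaf_ok <- is.na(records$eaf) | (records$eaf >= 0 & records$eaf <= 1)
  !(
    !is.na(records$snp_id) & nzchar(records$snp_id) &
      alleles_ok & eaf_ok &
      is.finite(records$pos) & records$pos >= 1 &
      is.finite(records$beta) &
      is.finite(records$se) & records$se > 0 &
      is.finite(records$pvalue) & records$pvalue > 0 & records$pvalue <= 1 &
      is.finite(records$n) & records$n > 0
  )
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("<summary_dataset> %s (%s%s): %d SNPs\n",
              x$trait_name, x$trait_type,
              if (!is.null(x$level)) paste0(", ", x$level) else "",
              nrow(x$records)))
  invisible(x)
}

#' Number of records in a summary dataset
#' @param x A `summary_dataset`.
#' @export
n_snps <- function(x) nrow(x$records)

#' Read GWAS summary statistics from a tab-delimited file
#'
#' Reads a tab-delimited table with a header row and maps its columns onto the
#' canonical fields. Rows violating the record invariants (non-positive SE,
#' alleles outside A/C/G/T, out-of-range frequency or p-value, ...) are
#' dropped; the count of dropped rows is reported via message and available as
#' `attr(x, "n_invalid_dropped")`.
#'
#' @param path Path to the file.
#' @param column_map Named character vector mapping canonical field names to
#'   source column names, e.g. `c(snp_id = "rsid", beta = "effect")`. Fields
#'   not named keep their canonical name. `eaf` is optional; a missing source
#'   column for it yields `NA`.
#' @param trait_name,trait_type,n_total,n_case,n_control,level Passed to
#'   [summary_dataset()]; `trait_name` defaults to the file name.
#'
#' @return A `summary_dataset`.
#' @export
read_summary_stats <- function(path, column_map = NULL, trait_name = NULL,
                               trait_type = "continuous", n_total = NULL,
                               n_case = NULL, n_control = NULL, level = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  canonical <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pvalue", "n")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), canonical)
    if (length(unknown) > 0) {
      stop("column_map names must be canonical fields; unknown: ",
           paste(unknown, collapse = ", "))
    }
    map[names(column_map)] <- column_map
  }
  required <- setdiff(canonical, "eaf")
  absent <- map[required][!map[required] %in% names(raw)]
  if (length(absent) > 0) {
    stop("mapped column(s) not present in file: ", paste(absent, collapse = ", "))
  }
  records <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                        lapply(map[required], function(src) raw[[src]]))
  names(records) <- required
  records$eaf <- if (map[["eaf"]] %in% names(raw)) raw[[map[["eaf"]]]] else NA_real_
  if (nrow(records) == 0) stop("zero parseable rows in ", path)
  if (is.null(trait_name)) trait_name <- sub("\\.[^.]*$", "", basename(path))
  ds <- summary_dataset(records, trait_name = trait_name, trait_type = trait_type,
                        n_total = n_total, n_case = n_case, n_control = n_control,
                        level = level, drop_invalid = TRUE)
  if (nrow(ds$records) == 0) stop("zero valid rows in ", path)
  n_bad <- attr(ds, "n_invalid_dropped")
  if (n_bad > 0) {
    message(sprintf("read_summary_stats: dropped %d invalid row(s) from %s", n_bad, path))
  }
  ds
}

#' Write GWAS summary statistics to a tab-delimited file
#'
#' Writes the canonical columns with full double precision so that
#' `read_summary_stats(write_summary_stats(d))` reproduces every field
#' exactly. If `eaf` is absent (all `NA`) the column is omitted and the
#' absence survives the round trip.
#'
#' @param dataset A `summary_dataset` with at least one record.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(dataset, path) {
  stopifnot(inherits(dataset, "summary_dataset"))
  rec <- dataset$records
  if (nrow(rec) == 0) stop("refusing to write an empty dataset")
  if (all(is.na(rec$eaf))) rec$eaf <- NULL
  out <- rec
  for (col in intersect(c("pos", "eaf", "beta", "se", "pvalue", "n"), names(out))) {
    out[[col]] <- sprintf("%.17g", out[[col]])
    out[[col]][is.na(rec[[col]])] <- "NA"
  }
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
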