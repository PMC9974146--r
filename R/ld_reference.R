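#' Pairwise-r2 LD reference
#'
#' A pluggable lookup of pairwise squared correlations between variants,
#' backed by a table of `(snp_a, snp_b, r2)` triples. r2 is symmetric,
#' `r2(x, x) = 1`, and any pair absent from the table — including pairs
#' farther apart than the window the table was built with — is treated as 0.
#'
#' @param table data.frame with columns `snp_a`, `snp_b`, `r2` (may have zero
#'   rows for a reference with no correlated pairs).
#' @param window_kb Window (kilobases) the table's r2 values cover; carried as
#'   metadata.
#' @return An object of class `ld_reference`.
#' @export
ld_reference <- function(table = NULL, window_kb = 500) {
  if (is.null(table)) {
    table <- data.frame(snp_a = character(), snp_b = character(),
                        r2 = numeric(), stringsAsFactors = FALSE)
  }
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(table)))
  table$snp_a <- as.character(table$snp_a)
  table$snp_b <- as.character(table$snp_b)
  table$r2 <- as.numeric(table$r2)
  stopifnot(all(table$r2 >= 0 & table$r2 <= 1))
  lookup <- new.env(parent = emptyenv())
  if (nrow(table) > 0) {
    keys <- ifelse(table$snp_a <= table$snp_b,
                   paste0(table$snp_a, "\r", table$snp_b),
                   paste0(table$snp_b, "\r", table$snp_a))
    for (i in seq_along(keys)) assign(keys[i], table$r2[i], envir = lookup)
  }
  structure(list(table = table, lookup = lookup, window_kb = window_kb),
            class = "ld_reference")
}

#' Look up pairwise r2
#'
#' @param ld An `ld_reference` (or `NULL`, in which case 0 is returned for
#'   any non-identical pair).
#' @param snp_a,snp_b Variant identifiers (vectorized; recycled).
#' @return Numeric vector of r2 values; 1 on the diagonal, 0 for pairs not in
#'   the reference.
#' @export
ld_r2 <- function(ld, snp_a, snp_b) {
  nmax <- max(length(snp_a), length(snp_b))
  snp_a <- rep_len(as.character(snp_a), nmax)
  snp_b <- rep_len(as.character(snp_b), nmax)
  out <- ifelse(snp_a == snp_b, 1, 0)
  if (is.null(ld)) return(out)
  stopifnot(inherits(ld, "ld_reference"))
  for (i in which(snp_a != snp_b)) {
    key <- if (snp_a[i] <= snp_b[i]) paste0(snp_a[i], "\r", snp_b[i])
           else paste0(snp_b[i], "\r", snp_a[i])
    out[i] <- mget(key, envir = ld$lookup, ifnotfound = 0)[[1]]
  }
  out
}

#' Read an LD reference from a tab-delimited triple file
#'
#' @param path File with header `snp_a  snp_b  r2`.
#' @param window_kb Window metadata, see [ld_reference()].
#' @export
read_ld_reference <- function(path, window_kb = 500) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  ld_reference(tab, window_kb = window_kb)
}

#' Write an LD reference to a tab-delimited triple file
#'
#' @param ld An `ld_reference`.
#' @param path Output path.
#' @export
write_ld_reference <- function(ld, path) {
  stopifnot(inherits(ld, "ld_reference"))
  out <- ld$table
  out$r2 <- sprintf("%.17g", out$r2)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
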