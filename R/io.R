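#' GWAS summary-statistics tables
#'
#' A `summary_stats` object is a validated data frame of per-variant
#' association statistics for one trait, the unit of input for the whole
#' pipeline.  Canonical columns: `variant_id`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' `beta` is the additive effect per copy of the effect allele (SD units
#' for continuous traits, log-odds for binary traits).
#'
#' Rows violating the record invariants (alleles outside A/C/G/T,
#' `effect_allele == other_allele`, `se <= 0`, `pval` outside (0, 1],
#' duplicated `variant_id`) are dropped at construction and counted in the
#' load report stored in `attr(x, "load_report")`.  A missing `eaf` is
#' permitted but makes the record ambiguous-ineligible during
#' harmonization.
#'
#' @param x data frame holding at least `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval`; `chrom`, `pos`, `eaf` and `n`
#'   are optional and filled with `NA` when absent.
#' @param trait_id character scalar naming the trait.
#' @param trait_type `"continuous"` or `"binary"`.
#' @return A `summary_stats` data frame with attributes `trait_id`,
#'   `trait_type` and `load_report`.
#' @export
summary_stats <- function(x, trait_id, trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(x), is.character(trait_id), length(trait_id) == 1L)
  mandatory <- c("variant_id", "effect_allele", "other_allele", "beta", "se", "pval")
  missing_cols <- setdiff(mandatory, names(x))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(x) == 0L) stop("empty summary-statistics table")

  for (col in c("chrom", "pos", "eaf", "n"))
    if (is.null(x[[col]])) x[[col]] <- NA
  x <- x[c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
           "eaf", "beta", "se", "pval", "n")]
  x$variant_id <- as.character(x$variant_id)
  x$chrom <- as.character(x$chrom)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n"))
    x[[col]] <- as.numeric(x[[col]])

  n_read <- nrow(x)
  bases <- c("A", "C", "G", "T")
  bad_allele <- !(x$effect_allele %in% bases) | !(x$other_allele %in% bases) |
    x$effect_allele == x$other_allele
  bad_se <- is.na(x$se) | x$se <= 0
  bad_pval <- is.na(x$pval) | x$pval <= 0 | x$pval > 1
  bad_beta <- is.na(x$beta)
  dup <- duplicated(x$variant_id)
  bad_eaf <- !is.na(x$eaf) & (x$eaf <= 0 | x$eaf >= 1)
  drop <- bad_allele | bad_se | bad_pval | bad_beta | dup | bad_eaf
  report <- list(
    n_read = n_read,
    n_kept = sum(!drop),
    n_dropped = sum(drop),
    reasons = c(invalid_allele = sum(bad_allele), invalid_se = sum(bad_se),
                invalid_pval = sum(bad_pval), missing_beta = sum(bad_beta),
                duplicate_id = sum(dup), invalid_eaf = sum(bad_eaf))
  )
  x <- x[!drop, , drop = FALSE]
  rownames(x) <- NULL
  structure(x,
            trait_id = trait_id, trait_type = trait_type, load_report = report,
            class = c("summary_stats", "data.frame"))
}

#' Read a delimited GWAS summary-statistics file
#'
#' Reads a tab- (or otherwise-) delimited text file with a header row and
#' validates it into a [summary_stats] table.  Source files with
#' non-canonical column names are handled through a dialect: a named
#' character vector mapping canonical field names to the source's column
#' names, e.g. `c(variant_id = "SNP", beta = "Effect")`.
#'
#' @param path file path.
#' @param trait_id,trait_type forwarded to [summary_stats()].
#' @param dialect named character vector (canonical = source) or `NULL`
#'   when the file already uses canonical names.
#' @param sep field separator, tab by default.
#' @return A `summary_stats` table; invalid rows are dropped and counted
#'   in `attr(, "load_report")`.
#' @export
read_summary_stats <- function(path, trait_id, trait_type = "continuous",
                               dialect = NULL, sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty file: ", path)
  if (!is.null(dialect)) {
    missing_src <- setdiff(unname(dialect), names(raw))
    if (length(missing_src))
      stop("dialect names absent from file: ", paste(missing_src, collapse = ", "))
    for (canon in names(dialect)) names(raw)[names(raw) == dialect[[canon]]] <- canon
  }
  summary_stats(raw, trait_id = trait_id, trait_type = trait_type)
}

#' Write a result table as lossless TSV
#'
#' Writes any of the pipeline's tabular objects (summary statistics,
#' harmonized sets, estimate tables, ledgers coerced via
#' `as.data.frame`) as a tab-separated file with one header row.  Numeric
#' columns are written with 17 significant digits so that
#' `read` of `write` round-trips doubles exactly.
#'
#' @param x a data frame (or object coercible with `as.data.frame`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  x <- as.data.frame(x)
  out <- x
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- NA
      out[[col]] <- v
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a generic pipeline result table
#'
#' Companion to [write_table()]; reads a TSV written by it back into a
#' data frame.  Column types are inferred; use [read_summary_stats()] for
#' summary-statistics files so that validation is applied.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_table <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("summary_stats: %s (%s), %d variants\n",
              attr(x, "trait_id"), attr(x, "trait_type"), nrow(x)))
  rep <- attr(x, "load_report")
  if (!is.null(rep) && rep$n_dropped > 0)
    cat(sprintf("  %d of %d rows dropped at load\n", rep$n_dropped, rep$n_read))
  print.data.frame(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

# keep class + attributes through row subsetting
#' @export
`[.summary_stats` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && identical(names(out), names(x))) {
    attr(out, "trait_id") <- attr(x, "trait_id")
    attr(out, "trait_type") <- attr(x, "trait_type")
    class(out) <- class(x)
  }
  out
}
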