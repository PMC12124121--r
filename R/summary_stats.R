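#' GWAS summary-statistics tables
#'
#' A `summary_stats` object is a validated data frame holding one GWAS
#' association record per SNP for a single trait on a single scale
#' (linear beta for continuous traits, log-odds for binary traits).
#' Mandatory columns are `snp`, `chr`, `pos` (1-based), `ea` (effect
#' allele), `oa` (other allele), `eaf` (effect-allele frequency), `beta`,
#' `se`, `pval` and `n` (GWAS sample size).
#'
#' @param data data frame (or coercible) containing the mandatory columns.
#' @param trait_id label for the trait, e.g. a lipid species name or a
#'   cohort accession.
#' @param trait_type `"continuous"` (betas in SD units) or `"binary"`
#'   (betas on the log-odds scale).
#'
#' @details Rows with a non-finite or non-positive `se`, a non-finite
#'   `beta`, an allele frequency outside (0, 1) or a p-value outside
#'   (0, 1] are rejected with a warning reporting the row numbers.
#'   Duplicated SNP identifiers are an error.
#'
#' @return A data frame of class `summary_stats` with attributes
#'   `trait_id` and `trait_type`.
#' @export
summary_stats <- function(data, trait_id, trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SUMMARY_COLS, names(data))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  data <- data[SUMMARY_COLS]
  for (col in c("pos", "eaf", "beta", "se", "pval", "n"))
    data[[col]] <- as.numeric(data[[col]])
  data$snp <- as.character(data$snp)
  data$chr <- as.character(data$chr)
  data$ea <- toupper(as.character(data$ea))
  data$oa <- toupper(as.character(data$oa))

  bad <- !is.finite(data$beta) | !is.finite(data$se) | data$se <= 0 |
    !is.finite(data$eaf) | data$eaf <= 0 | data$eaf >= 1 |
    !is.finite(data$pval) | data$pval <= 0 | data$pval > 1 |
    !is.finite(data$n) | data$n < 2 | data$ea == data$oa
  if (any(bad)) {
    shown <- utils::head(which(bad), 10L)
    warning(sprintf("rejected %d malformed row(s) (rows %s%s)", sum(bad),
                    paste(shown, collapse = ", "),
                    if (sum(bad) > 10L) ", ..." else ""), call. = FALSE)
    data <- data[!bad, , drop = FALSE]
  }
  if (anyDuplicated(data$snp))
    stop("duplicated snp identifiers: ",
         paste(unique(data$snp[duplicated(data$snp)]), collapse = ", "),
         call. = FALSE)
  rownames(data) <- NULL
  structure(data,
            trait_id = as.character(trait_id),
            trait_type = trait_type,
            class = c("summary_stats", "data.frame"))
}

SUMMARY_COLS <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "pval", "n")

#' @export
`[.summary_stats` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(SUMMARY_COLS %in% names(out))) {
    attr(out, "trait_id") <- attr(x, "trait_id")
    attr(out, "trait_type") <- attr(x, "trait_type")
    class(out) <- c("summary_stats", "data.frame")
    rownames(out) <- NULL
  }
  out
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d SNPs\n",
              attr(x, "trait_id"), attr(x, "trait_type"), nrow(x)))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Read a GWAS summary-statistics table from TSV
#'
#' Reads a tab-separated summary-statistics file (plain or gzipped, UTF-8,
#' `.` decimal) into a validated [summary_stats()] object. The default
#' header dialect is `snp, chr, pos, ea, oa, eaf, beta, se, pval, n`;
#' other headers are supported through `column_map`.
#'
#' @param path file path; `.gz` files are read transparently.
#' @param trait_id trait label; defaults to the file name without extension.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param column_map optional named character vector mapping canonical
#'   column names to the file's header names, e.g.
#'   `c(snp = "SNP", pval = "p")`. Unmapped canonical names are assumed to
#'   match the file header directly.
#'
#' @return A [summary_stats()] object.
#' @export
read_summary_stats <- function(path, trait_id = NULL,
                               trait_type = c("continuous", "binary"),
                               column_map = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (!is.null(column_map)) {
    if (is.null(names(column_map)) || any(names(column_map) == ""))
      stop("'column_map' must be a named character vector", call. = FALSE)
    for (canonical in names(column_map)) {
      src <- column_map[[canonical]]
      if (!src %in% names(raw))
        stop(sprintf("mapped column '%s' (for '%s') absent from %s",
                     src, canonical, path), call. = FALSE)
      names(raw)[names(raw) == src] <- canonical
    }
  }
  if (is.null(trait_id))
    trait_id <- sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path))
  summary_stats(raw, trait_id = trait_id, trait_type = trait_type)
}

#' Write a GWAS summary-statistics table to TSV
#'
#' @param stats a [summary_stats()] object.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  stopifnot(inherits(stats, "summary_stats"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(as.data.frame(stats), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
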