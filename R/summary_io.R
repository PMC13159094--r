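# Canonical column set for a GWAS summary-statistics table.
.SUMSTAT_REQUIRED <- c("snp_id", "chrom", "pos", "effect_allele",
                       "other_allele", "beta", "se", "pval")
.SUMSTAT_OPTIONAL <- c("eaf", "n")
.NUCLEOTIDES <- c("A", "C", "G", "T")

#' Construct a validated GWAS summary-statistics table
#'
#' Builds a `summary_stats` object (a data frame with one row per SNP) from a
#' raw data frame, dropping rows that violate the invariants of per-SNP
#' association records and recording every drop in an audit log.
#'
#' Invariants enforced row-wise: `se > 0`; `pval` in (0, 1]; alleles are
#' single nucleotides (A/C/G/T) and differ within a row; `snp_id` unique
#' (first occurrence kept); `eaf`, when present, strictly inside (0, 1)
#' (out-of-range values are set to missing rather than dropping the row,
#' since allele frequency only matters for palindromic-SNP resolution).
#'
#' @param x data frame with at least the canonical columns `snp_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `beta`, `se`, `pval`; optionally
#'   `eaf` and `n`.
#' @param trait_id character label for the trait this table describes.
#' @return A `summary_stats` object: the cleaned data frame with attributes
#'   `trait_id` and `audit` (named integer vector of drop counts).
#' @seealso [read_summary_stats()], [audit_log()]
#' @export
summary_stats <- function(x, trait_id = "trait") {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(.SUMSTAT_REQUIRED, names(x))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (col in setdiff(.SUMSTAT_OPTIONAL, names(x))) x[[col]] <- NA_real_
  x <- x[, c(.SUMSTAT_REQUIRED, .SUMSTAT_OPTIONAL)]
  x$snp_id <- as.character(x$snp_id)
  x$chrom <- as.character(x$chrom)
  x$pos <- as.integer(x$pos)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("beta", "se", "pval", "eaf", "n")) {
    x[[col]] <- as.numeric(x[[col]])
  }

  audit <- c(nonpositive_se = 0L, bad_pval = 0L, bad_alleles = 0L,
             missing_beta = 0L, duplicate_snp_id = 0L, bad_eaf = 0L)

  drop_rows <- function(x, bad, reason) {
    bad[is.na(bad)] <- TRUE
    audit[[reason]] <<- audit[[reason]] + sum(bad)
    x[!bad, , drop = FALSE]
  }
  x <- drop_rows(x, is.na(x$beta), "missing_beta")
  x <- drop_rows(x, !(x$se > 0), "nonpositive_se")
  x <- drop_rows(x, !(x$pval > 0 & x$pval <= 1), "bad_pval")
  x <- drop_rows(x,
                 !(x$effect_allele %in% .NUCLEOTIDES) |
                   !(x$other_allele %in% .NUCLEOTIDES) |
                   x$effect_allele == x$other_allele,
                 "bad_alleles")
  x <- drop_rows(x, duplicated(x$snp_id), "duplicate_snp_id")

  bad_eaf <- !is.na(x$eaf) & !(x$eaf > 0 & x$eaf < 1)
  audit[["bad_eaf"]] <- sum(bad_eaf)
  x$eaf[bad_eaf] <- NA_real_

  rownames(x) <- NULL
  structure(x,
            trait_id = as.character(trait_id),
            audit = audit,
            class = c("summary_stats", "data.frame"))
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab- or whitespace-delimited text file (gzip-transparent) and
#' validates it into a [summary_stats()] object. Column names in the source
#' file are mapped to the canonical names through `column_map`, so both
#' FinnGen-style and GWAS-Catalog-style headers can be ingested.
#'
#' @param path path to a delimited text file, optionally gzip-compressed.
#' @param column_map named character vector mapping canonical names to source
#'   column names, e.g. `c(snp_id = "rsids", beta = "beta", se = "sebeta")`.
#'   Canonical columns absent from the map are looked up under their
#'   canonical name directly. `NULL` means the header is already canonical.
#' @param trait_id trait label; defaults to the file name without extension.
#' @param sep field separator, default tab.
#' @return A `summary_stats` object; drop counts are in `audit_log()`.
#' @export
read_summary_stats <- function(path, column_map = NULL, trait_id = NULL,
                               sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           check.names = FALSE)
  if (!is.null(column_map)) {
    if (is.null(names(column_map)) || any(names(column_map) == "")) {
      stop("column_map must be a fully named character vector")
    }
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw)) {
        stop("missing mandatory column: '", src, "' (mapped to ", canon, ")")
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  if (is.null(trait_id)) {
    trait_id <- sub("\\.(tsv|txt|gz|tsv\\.gz|txt\\.gz)$", "",
                    basename(path))
  }
  out <- summary_stats(raw, trait_id = trait_id)
  if (nrow(out) == 0L) stop("no rows survive validation in ", path)
  out
}

#' Retrieve the audit log of a validated object
#'
#' @param x an object created by this package carrying an `audit` attribute
#'   (e.g. `summary_stats`, `harmonized_set`).
#' @return Named integer vector of counts of rows dropped or modified, by
#'   reason.
#' @export
audit_log <- function(x) {
  a <- attr(x, "audit")
  if (is.null(a)) stop("object carries no audit log")
  a
}

#' Trait identifier of a summary-statistics table
#' @param x a `summary_stats` object.
#' @return Character trait label.
#' @export
trait_id <- function(x) attr(x, "trait_id")

#' @export
print.summary_stats <- function(x, ...) {
  cat("GWAS summary statistics for '", trait_id(x), "': ",
      nrow(x), " SNPs\n", sep = "")
  a <- audit_log(x)
  if (any(a > 0)) {
    cat("rows dropped/modified at validation:",
        paste(sprintf("%s=%d", names(a)[a > 0], a[a > 0]), collapse = ", "),
        "\n")
  }
  NextMethod()
}

#' Write a summary-statistics table in the canonical on-disk format
#'
#' Tab-separated with header, canonical column order, floats at 6 significant
#' digits (enough to round-trip betas and standard errors at GWAS precision).
#' A `.gz` suffix on `path` triggers gzip compression.
#'
#' @param stats a `summary_stats` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  stopifnot(inherits(stats, "summary_stats"))
  write_results(as.data.frame(stats), path)
}

#' Write a result table as deterministic TSV
#'
#' All result tables downstream (estimates, sensitivity, mediation rows, and
#' the canonical summary-stat format itself) are written through this one
#' function: tab-separated, header, column order as given, numeric columns
#' serialized at a fixed number of significant digits so that
#' read-after-write reproduces the values to that precision.
#'
#' @param tab nonempty data frame.
#' @param path output path; `.gz` suffix writes gzip.
#' @param digits significant digits for numeric columns (default 6).
#' @return `path`, invisibly.
#' @export
write_results <- function(tab, path, digits = 6) {
  tab <- as.data.frame(tab)
  if (nrow(tab) == 0L) stop("refusing to write an empty table")
  for (col in names(tab)) {
    if (is.double(tab[[col]])) {
      tab[[col]] <- formatC(signif(tab[[col]], digits), digits = digits,
                            format = "g")
      tab[[col]][tab[[col]] %in% c("NA", " NA")] <- NA
    }
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  ok <- tryCatch({
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) {
    close(con)
    stop("cannot write results to ", path, ": ", conditionMessage(e))
  })
  close(con)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records thresholds, seeds and package version for one pipeline invocation
#' so every emitted number is re-derivable.
#'
#' @param config named list of run parameters (thresholds, seeds, inputs).
#' @param path output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path) {
  config$package <- "mrmediate"
  config$package_version <- as.character(utils::packageVersion("mrmediate"))
  config$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
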