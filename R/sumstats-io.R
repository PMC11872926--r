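# Reading, writing and validating GWAS summary-statistics tables.
#
# A summary-statistics table is a plain data.frame with one row per SNP and
# the mandatory columns below (extra columns are carried along untouched).
# Files are tab-separated UTF-8 with a header, "." decimal point, scientific
# notation accepted for p-values.

sumstats_columns <- c("snp_id", "chrom", "pos", "effect_allele",
                      "other_allele", "eaf", "beta", "se", "pvalue", "n")

# pos is stored as double (whole-valued): base-pair coordinates can exceed
# the 32-bit integer range on large synthetic panels
.sumstats_numeric <- c("pos", "eaf", "beta", "se", "pvalue")
.sumstats_integer <- c("n")

#' Validate a summary-statistics table
#'
#' Checks the mandatory columns and the per-record invariants: `se > 0`,
#' `0 < eaf < 1`, `pvalue` in (0, 1], alleles single distinct letters.
#'
#' @param table data.frame of per-SNP association records.
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_sumstats <- function(table) {
  missing <- setdiff(sumstats_columns, names(table))
  if (length(missing))
    stop("summary-statistics format error: missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(table) == 0L) return(invisible(table))
  bad <- function(cond, what) {
    if (any(cond, na.rm = TRUE) || anyNA(cond))
      stop("summary-statistics invariant violated: ", what, " (rows ",
           paste(utils::head(which(cond | is.na(cond)), 5), collapse = ", "),
           ")", call. = FALSE)
  }
  bad(table$se <= 0, "se must be > 0")
  bad(table$eaf <= 0 | table$eaf >= 1, "eaf must be in (0, 1)")
  bad(table$pvalue <= 0 | table$pvalue > 1, "pvalue must be in (0, 1]")
  bad(table$effect_allele == table$other_allele,
      "effect_allele must differ from other_allele")
  bad(table$n <= 0, "n must be positive")
  invisible(table)
}

#' Write a summary-statistics table to a tab-separated file
#'
#' Reals are written with 15 significant digits so a round trip preserves at
#' least 12 significant digits; strings and integers round-trip exactly.
#' Extra (non-mandatory) columns are preserved.
#'
#' @param table data.frame with the mandatory summary-statistics columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(table, path) {
  missing <- setdiff(sumstats_columns, names(table))
  if (length(missing))
    stop("summary-statistics format error: missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- table[, c(sumstats_columns, setdiff(names(table), sumstats_columns)),
               drop = FALSE]
  for (col in names(out)) {
    if (is.double(out[[col]]))
      out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a summary-statistics table from a tab-separated file
#'
#' @param path input file path.
#' @param validate check record invariants after reading (default `TRUE`).
#' @return data.frame with the mandatory columns typed (`pos`/`n` integer,
#'   `eaf`/`beta`/`se`/`pvalue` double, the rest character) plus any extra
#'   columns found in the file.
#' @export
read_summary_stats <- function(path, validate = TRUE) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(sumstats_columns, names(raw))
  if (length(missing))
    stop("summary-statistics format error: missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in .sumstats_numeric) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(val) & !is.na(raw[[col]]) & raw[[col]] != "NA")
    if (length(bad))
      stop("summary-statistics format error: non-numeric `", col,
           "` at line ", bad[1] + 1L, " (\"", raw[[col]][bad[1]], "\")",
           call. = FALSE)
    raw[[col]] <- val
  }
  for (col in .sumstats_integer) {
    val <- suppressWarnings(as.integer(as.numeric(raw[[col]])))
    bad <- which(is.na(val) & !is.na(raw[[col]]) & raw[[col]] != "NA")
    if (length(bad))
      stop("summary-statistics format error: non-integer `", col,
           "` at line ", bad[1] + 1L, call. = FALSE)
    raw[[col]] <- val
  }
  if (validate) validate_sumstats(raw)
  raw
}

#' Write / read a pairwise LD (r-squared) matrix
#'
#' The file is a tab-separated square matrix with SNP identifiers as the
#' first row and first column.
#'
#' @param ld symmetric numeric matrix of r-squared values with unit diagonal
#'   and SNP identifiers as dimnames.
#' @param path file path.
#' @return `write_ld_matrix`: `path` invisibly; `read_ld_matrix`: the matrix.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(is.matrix(ld), nrow(ld) == ncol(ld),
            !is.null(rownames(ld)), !is.null(colnames(ld)))
  out <- as.data.frame(formatC(ld, digits = 15, format = "g"),
                       stringsAsFactors = FALSE)
  out <- cbind(snp_id = rownames(ld), out)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_ld_matrix
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE, row.names = 1L,
                           check.names = FALSE, fileEncoding = "UTF-8")
  ld <- as.matrix(raw)
  storage.mode(ld) <- "double"
  validate_ld_matrix(ld)
  ld
}

#' Validate an LD matrix
#'
#' Checks symmetry, a unit diagonal and entries in \[0, 1\].
#'
#' @param ld square numeric matrix with SNP identifier dimnames.
#' @return `ld`, invisibly, if valid.
#' @export
validate_ld_matrix <- function(ld) {
  if (!is.matrix(ld) || nrow(ld) != ncol(ld))
    stop("LD matrix must be square", call. = FALSE)
  if (!isTRUE(all.equal(ld, t(ld), tolerance = 1e-8)))
    stop("LD matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(ld) - 1) > 1e-8))
    stop("LD matrix diagonal must be exactly 1", call. = FALSE)
  if (any(ld < -1e-12 | ld > 1 + 1e-12))
    stop("LD matrix entries must lie in [0, 1]", call. = FALSE)
  invisible(ld)
}
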