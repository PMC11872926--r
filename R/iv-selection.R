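# Instrument selection and allele harmonization.
#
# Pipeline order follows standard two-sample MR practice: genome-wide
# significance filter -> greedy LD clumping -> instrument-strength (F) filter
# -> exposure/outcome allele harmonization. Every SNP dropped at any stage is
# recorded in an exclusion log (snp_id, reason, stage) so that
# |retained| + |excluded| always equals the number of input SNPs.

#' Instrument-selection configuration
#'
#' @param p_threshold genome-wide significance threshold; a SNP is retained
#'   when `pvalue < p_threshold` (strict). Default `5e-8`.
#' @param clump_r2 LD clumping r-squared threshold; SNPs correlated with a
#'   retained index SNP above this (strict) are removed. Default `0.001`.
#' @param clump_window_kb physical clumping window in kilobases; only SNPs
#'   on the same chromosome within this distance are clumped. Default
#'   `10000` (10,000 kb).
#' @param f_min instrument-strength threshold; SNPs with
#'   `F = (beta/se)^2 > f_min` (strict) are retained. Default `10`.
#' @param palindrome_policy `"drop_all_palindromic"` (default) excludes every
#'   A/T and C/G SNP; `"drop_ambiguous_only"` keeps palindromic SNPs whose
#'   effect-allele frequency is informative (outside the ambiguity window in
#'   both studies) and orients them by frequency.
#' @param ambiguity_window frequency window around 0.5 inside which a
#'   palindromic SNP is considered unresolvable under
#'   `"drop_ambiguous_only"`.
#' @return A `selection_config` object.
#' @export
selection_config <- function(p_threshold = 5e-8,
                             clump_r2 = 0.001,
                             clump_window_kb = 10000L,
                             f_min = 10,
                             palindrome_policy = c("drop_all_palindromic",
                                                   "drop_ambiguous_only"),
                             ambiguity_window = c(0.42, 0.58)) {
  check_scalar(p_threshold, "p_threshold", lo = 0, hi = 1,
               strict_lo = TRUE)
  check_scalar(clump_r2, "clump_r2", lo = 0, hi = 1)
  check_scalar(clump_window_kb, "clump_window_kb", lo = 1, integer = TRUE)
  check_scalar(f_min, "f_min", lo = 0, strict_lo = TRUE)
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(length(ambiguity_window) == 2L, ambiguity_window[1] < 0.5,
            ambiguity_window[2] > 0.5)
  structure(list(p_threshold = as.numeric(p_threshold),
                 clump_r2 = as.numeric(clump_r2),
                 clump_window_kb = as.integer(clump_window_kb),
                 f_min = as.numeric(f_min),
                 palindrome_policy = palindrome_policy,
                 ambiguity_window = as.numeric(ambiguity_window)),
            class = "selection_config")
}

#' Filter SNPs by association p-value
#'
#' Retains rows with `pvalue < p_threshold` (strict inequality), preserving
#' the original row order. An empty result is returned, not an error.
#'
#' @param table summary-statistics data.frame.
#' @param p_threshold significance threshold.
#' @return The filtered table.
#' @export
select_significant <- function(table, p_threshold = 5e-8) {
  if (!"pvalue" %in% names(table))
    stop("summary-statistics format error: missing mandatory column(s): pvalue",
         call. = FALSE)
  table[table$pvalue < p_threshold, , drop = FALSE]
}

#' Per-SNP instrument-strength F-statistic
#'
#' `F = (beta / se)^2`, the square of the per-SNP Wald z-statistic, computed
#' from the reported effect and standard error (the only quantities
#' guaranteed in summary files).
#'
#' @param beta,se numeric vectors; `se` must be positive.
#' @return Non-negative numeric vector of F-statistics.
#' @export
f_statistic <- function(beta, se) {
  if (any(se <= 0)) stop("se must be positive", call. = FALSE)
  (beta / se)^2
}

#' Filter SNPs by instrument strength
#'
#' Retains rows with `f_statistic(beta, se) > f_min` (strict inequality).
#'
#' @param table summary-statistics data.frame.
#' @param f_min strength threshold (conventionally 10).
#' @return The filtered table.
#' @export
filter_strong <- function(table, f_min = 10) {
  table[f_statistic(table$beta, table$se) > f_min, , drop = FALSE]
}

#' Greedy LD clumping
#'
#' Repeatedly takes the remaining SNP with the smallest p-value (ties broken
#' lexicographically by `snp_id`), keeps it, and removes all remaining SNPs
#' on the same chromosome within `clump_window_kb` kilobases whose r-squared
#' with it exceeds `clump_r2` (strict). The result is the kept SNPs in kept
#' (selection) order.
#'
#' @param table summary-statistics data.frame.
#' @param ld square r-squared matrix with SNP identifiers as dimnames; every
#'   SNP in `table` must be present.
#' @param clump_r2 r-squared threshold.
#' @param clump_window_kb window in kilobases; distance is
#'   `|pos_i - pos_j| <= clump_window_kb * 1000` on the same chromosome.
#' @return The clumped table, rows in kept order.
#' @export
ld_clump <- function(table, ld, clump_r2 = 0.001, clump_window_kb = 10000) {
  if (nrow(table) == 0L) return(table)
  absent <- setdiff(table$snp_id, rownames(ld))
  if (length(absent))
    stop("SNP(s) absent from LD matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  remaining <- table[order(table$pvalue, table$snp_id), , drop = FALSE]
  kept <- character(0)
  while (nrow(remaining) > 0L) {
    idx <- remaining[1L, ]
    kept <- c(kept, idx$snp_id)
    r2 <- ld[idx$snp_id, remaining$snp_id]
    drop <- (remaining$chrom == idx$chrom &
               abs(remaining$pos - idx$pos) <= clump_window_kb * 1000 &
               r2 > clump_r2) | remaining$snp_id == idx$snp_id
    remaining <- remaining[!drop, , drop = FALSE]
  }
  out <- table[match(kept, table$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

is_palindromic <- function(a1, a2) {
  p <- paste0(a1, a2)
  p %in% c("AT", "TA", "CG", "GC")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Pairs SNPs present in both tables on a common effect-allele orientation.
#' Outcome rows reported on swapped alleles have their beta negated and eaf
#' complemented; SNPs whose allele sets differ are excluded as
#' `allele_mismatch`; palindromic SNPs (A/T, C/G) are excluded under
#' `"drop_all_palindromic"`, or, under `"drop_ambiguous_only"`, oriented by
#' effect-allele frequency when the frequency is outside the ambiguity
#' window in both studies and excluded otherwise. Every exposure SNP lands
#' either in the retained set or in the exclusion log.
#'
#' @param exposure,outcome summary-statistics data.frames keyed by `snp_id`
#'   (duplicates are an error).
#' @param palindrome_policy see [selection_config()].
#' @param ambiguity_window see [selection_config()].
#' @param prior_exclusions optional data.frame (`snp_id`, `reason`, `stage`)
#'   from earlier selection stages, carried into the exclusion log.
#' @return A data.frame of class `harmonized_set` with columns `snp_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `beta_exposure`,
#'   `se_exposure`, `eaf_exposure`, `pvalue_exposure`, `beta_outcome`,
#'   `se_outcome`, `eaf_outcome`, `pvalue_outcome`; the exclusion log is in
#'   `attr(, "exclusions")` (see [exclusion_log()]).
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop_all_palindromic",
                                            "drop_ambiguous_only"),
                      ambiguity_window = c(0.42, 0.58),
                      prior_exclusions = NULL) {
  palindrome_policy <- match.arg(palindrome_policy)
  for (tbl in list(exposure = exposure, outcome = outcome)) {
    dup <- tbl$snp_id[duplicated(tbl$snp_id)]
    if (length(dup))
      stop("duplicate snp_id in table: ", paste(unique(dup), collapse = ", "),
           call. = FALSE)
  }
  m <- match(exposure$snp_id, outcome$snp_id)
  excl <- list()
  note <- function(ids, reason) {
    if (length(ids))
      excl[[length(excl) + 1L]] <<- data.frame(
        snp_id = ids, reason = reason, stage = "harmonize",
        stringsAsFactors = FALSE)
  }

  present <- !is.na(m)
  note(exposure$snp_id[!present], "missing_in_outcome")

  ex <- exposure[present, , drop = FALSE]
  ou <- outcome[m[present], , drop = FALSE]

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  same <- ou$effect_allele == ex$effect_allele &
    ou$other_allele == ex$other_allele
  swapped <- ou$effect_allele == ex$other_allele &
    ou$other_allele == ex$effect_allele
  mismatch <- !(same | swapped)

  keep <- rep(FALSE, nrow(ex))
  flip <- rep(FALSE, nrow(ex))

  # non-palindromic SNPs: orientation read off the allele labels
  np <- !pal
  keep[np & same] <- TRUE
  keep[np & swapped] <- TRUE
  flip[np & swapped] <- TRUE
  note(ex$snp_id[np & mismatch], "allele_mismatch")

  # palindromic SNPs: labels cannot distinguish a swap from a strand flip
  if (any(pal)) {
    pal_mismatch <- pal & mismatch
    note(ex$snp_id[pal_mismatch], "allele_mismatch")
    pal_ok <- pal & !mismatch
    if (palindrome_policy == "drop_all_palindromic") {
      note(ex$snp_id[pal_ok], "palindromic")
    } else {
      informative <- pmin(ex$eaf, 1 - ex$eaf) < ambiguity_window[1] &
        pmin(ou$eaf, 1 - ou$eaf) < ambiguity_window[1]
      rescue <- pal_ok & informative
      keep[rescue] <- TRUE
      # discordant frequency sides imply the outcome row is on the other
      # orientation
      flip[rescue] <- (ex$eaf[rescue] - 0.5) * (ou$eaf[rescue] - 0.5) < 0
      note(ex$snp_id[pal_ok & !informative], "palindromic")
    }
  }

  beta_out <- ifelse(flip, -ou$beta, ou$beta)
  eaf_out <- ifelse(flip, 1 - ou$eaf, ou$eaf)

  h <- data.frame(
    snp_id = ex$snp_id, chrom = ex$chrom, pos = ex$pos,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    beta_exposure = ex$beta, se_exposure = ex$se, eaf_exposure = ex$eaf,
    pvalue_exposure = ex$pvalue,
    beta_outcome = beta_out, se_outcome = ou$se, eaf_outcome = eaf_out,
    pvalue_outcome = ou$pvalue,
    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(h) <- NULL

  exclusions <- do.call(rbind, c(list(empty_exclusions(), prior_exclusions),
                                 excl))
  structure(h, class = c("harmonized_set", "data.frame"),
            exclusions = exclusions)
}

empty_exclusions <- function() {
  data.frame(snp_id = character(0), reason = character(0),
             stage = character(0), stringsAsFactors = FALSE)
}

#' Exclusion log of a harmonized set
#'
#' @param h a `harmonized_set`.
#' @return data.frame with columns `snp_id`, `reason`
#'   (`not_significant`, `clumped`, `weak_instrument`, `palindromic`,
#'   `allele_mismatch`, `missing_in_outcome`) and `stage`.
#' @export
exclusion_log <- function(h) {
  ex <- attr(h, "exclusions")
  if (is.null(ex)) empty_exclusions() else ex
}

# subset rows of a harmonized set, preserving class and exclusion log
hset_rows <- function(h, idx) {
  out <- as.data.frame(h)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("harmonized_set", "data.frame"),
            exclusions = attr(h, "exclusions"))
}

# build a harmonized set directly from aligned vectors (used by tests and
# by callers that already have instrument-level associations)
harmonized_set <- function(snp_id, beta_exposure, se_exposure,
                           beta_outcome, se_outcome) {
  stopifnot(all(se_exposure > 0), all(se_outcome > 0))
  k <- length(snp_id)
  structure(data.frame(
    snp_id = as.character(snp_id), chrom = rep("1", k), pos = seq_len(k),
    effect_allele = rep("A", k), other_allele = rep("G", k),
    beta_exposure = beta_exposure, se_exposure = se_exposure,
    eaf_exposure = rep(0.3, k), pvalue_exposure =
      two_sided_p(beta_exposure / se_exposure),
    beta_outcome = beta_outcome, se_outcome = se_outcome,
    eaf_outcome = rep(0.3, k), pvalue_outcome =
      two_sided_p(beta_outcome / se_outcome),
    stringsAsFactors = FALSE),
    class = c("harmonized_set", "data.frame"),
    exclusions = empty_exclusions())
}

#' Full instrument-selection pipeline
#'
#' Runs significance filtering, LD clumping, F-statistic filtering and
#' harmonization in that order, accumulating the exclusion log across
#' stages.
#'
#' @param exposure,outcome summary-statistics data.frames.
#' @param ld r-squared matrix covering the exposure SNPs that reach the
#'   clumping stage.
#' @param sel a [selection_config()].
#' @return A `harmonized_set`; its exclusion log partitions the exposure
#'   SNPs: `nrow(h) + nrow(exclusion_log(h)) == nrow(exposure)`.
#' @export
select_instruments <- function(exposure, outcome, ld,
                               sel = selection_config()) {
  stopifnot(inherits(sel, "selection_config"))
  log <- empty_exclusions()
  add <- function(ids, reason, stage) {
    if (length(ids))
      rbind(log, data.frame(snp_id = ids, reason = reason, stage = stage,
                            stringsAsFactors = FALSE))
    else log
  }
  sig <- select_significant(exposure, sel$p_threshold)
  log <- add(setdiff(exposure$snp_id, sig$snp_id), "not_significant",
             "significance")
  clumped <- ld_clump(sig, ld, sel$clump_r2, sel$clump_window_kb)
  log <- add(setdiff(sig$snp_id, clumped$snp_id), "clumped", "clump")
  strong <- filter_strong(clumped, sel$f_min)
  log <- add(setdiff(clumped$snp_id, strong$snp_id), "weak_instrument",
             "f_filter")
  harmonize(strong, outcome, sel$palindrome_policy, sel$ambiguity_window,
            prior_exclusions = log)
}
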