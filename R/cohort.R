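# Reference cohort handling: a table of previously scored plans with optional
# QA outcomes, used to place a new plan in context (histogram, percentile)
# and to build site-stratified summary tables.

COHORT_COLUMNS <- c("plan_id", "site", "fractionation", "complexity_mm_inv",
                    "qa_pass")

#' Load a reference cohort CSV
#'
#' Expected header: `plan_id,site,fractionation,complexity_mm_inv,qa_pass`.
#' `fractionation` is `standard`, `SBRT` or `unknown` (blank -> unknown);
#' `qa_pass` is `TRUE`/`FALSE` or blank for unlabeled reference plans.
#' Malformed rows are reported with their line number.
#'
#' @param path CSV file path
#' @return data.frame of cohort records (one row per plan)
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) abort("cohort file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols)) {
    abort("cohort CSV missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  if (n == 0L) abort("cohort CSV has no records")
  line <- seq_len(n) + 1L                       # +1 for the header line

  complexity <- suppressWarnings(as.numeric(raw$complexity_mm_inv))
  bad <- which(is.na(complexity) | complexity <= 0)
  if (length(bad)) {
    abort("cohort CSV line ", line[bad[1]], ": complexity_mm_inv must be a positive ",
          "number, got '", raw$complexity_mm_inv[bad[1]], "'")
  }
  frac <- trimws(raw$fractionation)
  frac[!nzchar(frac)] <- "unknown"
  ok_frac <- frac %in% c("standard", "SBRT", "unknown")
  if (any(!ok_frac)) {
    abort("cohort CSV line ", line[which(!ok_frac)[1]],
          ": fractionation must be standard, SBRT or unknown")
  }
  qa <- trimws(toupper(raw$qa_pass))
  qa_pass <- rep(NA, n)
  qa_pass[qa %in% c("TRUE", "T", "1", "PASS")] <- TRUE
  qa_pass[qa %in% c("FALSE", "F", "0", "FAIL")] <- FALSE
  unparsed <- nzchar(qa) & is.na(qa_pass)
  if (any(unparsed)) {
    abort("cohort CSV line ", line[which(unparsed)[1]],
          ": qa_pass must be TRUE, FALSE or blank, got '",
          raw$qa_pass[which(unparsed)[1]], "'")
  }
  data.frame(plan_id = raw$plan_id, site = trimws(raw$site),
             fractionation = frac, complexity_mm_inv = complexity,
             qa_pass = qa_pass, stringsAsFactors = FALSE)
}

#' Save a cohort table as CSV
#'
#' Round-trip stable with [load_cohort()].
#'
#' @param records cohort data.frame (as from [load_cohort()] or
#'   [simulate_cohort()])
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
save_cohort <- function(records, path) {
  stopifnot(all(COHORT_COLUMNS %in% names(records)))
  out <- records[COHORT_COLUMNS]
  out$qa_pass <- ifelse(is.na(out$qa_pass), "", as.character(out$qa_pass))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a labeled cohort from contingency counts
#'
#' Reconstructs a minimal labeled cohort that reproduces given
#' above/below-threshold counts for the passing and failing classes --
#' useful for confusion-rate arithmetic when only a published summary table
#' is available, not the underlying per-plan scores.  Records are placed at
#' `threshold * (1 +/- 0.1)`.
#'
#' @param threshold the complexity threshold the counts refer to, 1/mm
#' @param fail_above,fail_below,pass_above,pass_below record counts
#' @param site site label for all records (default "all")
#' @return cohort data.frame
#' @export
cohort_from_counts <- function(threshold, fail_above, fail_below,
                               pass_above, pass_below, site = "all") {
  n <- fail_above + fail_below + pass_above + pass_below
  if (n < 1L) abort("cohort_from_counts: empty cohort")
  hi <- threshold * 1.1
  lo <- threshold * 0.9
  data.frame(
    plan_id = sprintf("plan%05d", seq_len(n)),
    site = site,
    fractionation = "unknown",
    complexity_mm_inv = c(rep(hi, fail_above), rep(lo, fail_below),
                          rep(hi, pass_above), rep(lo, pass_below)),
    qa_pass = c(rep(FALSE, fail_above + fail_below),
                rep(TRUE, pass_above + pass_below)),
    stringsAsFactors = FALSE
  )
}

cohort_group_label <- function(records) {
  ifelse(records$fractionation == "SBRT",
         paste(records$site, "SBRT"), records$site)
}

summarise_group <- function(rec, threshold) {
  above <- rec$complexity_mm_inv > threshold
  failing <- !is.na(rec$qa_pass) & !rec$qa_pass
  passing <- !is.na(rec$qa_pass) & rec$qa_pass
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  # sample SD needs n >= 2; a single plan reports its mean with no SD
  sd_or_na <- function(x) if (length(x) >= 2L) sd(x) else NA_real_
  data.frame(
    total = nrow(rec),
    failing = sum(failing),
    above = sum(above),
    failing_above = sum(failing & above),
    mean_pass = mean_or_na(rec$complexity_mm_inv[passing]),
    sd_pass = sd_or_na(rec$complexity_mm_inv[passing]),
    mean_fail = mean_or_na(rec$complexity_mm_inv[failing]),
    sd_fail = sd_or_na(rec$complexity_mm_inv[failing])
  )
}

#' Site-stratified cohort summary
#'
#' Per site-by-fractionation group (SBRT split out as "<site> SBRT") plus an
#' "All" row: total plans, failing plans, plans above the threshold, failing
#' plans above the threshold, and mean +/- sample SD of the complexity of
#' passing and failing plans.  "Above" is strict (`M > threshold`); a plan
#' exactly at the threshold is not flagged.  Groups with a single
#' failing/passing plan report the mean with `NA` SD; groups with none
#' report `NA` means (rendered as a dash by [format_cohort_summary()]).
#'
#' @param records cohort data.frame
#' @param threshold complexity threshold in 1/mm (default 0.18)
#' @return data.frame with one row per group ("All" first), columns `group`,
#'   `total`, `failing`, `above`, `failing_above`, `mean_pass`, `sd_pass`,
#'   `mean_fail`, `sd_fail`
#' @export
cohort_summary <- function(records, threshold = 0.18) {
  if (nrow(records) < 1L) abort("cohort_summary: need >= 1 record")
  groups <- cohort_group_label(records)
  order_keys <- unique(groups)
  rows <- lapply(c(list(records),
                   lapply(order_keys, function(g) records[groups == g, ])),
                 summarise_group, threshold = threshold)
  out <- do.call(rbind, rows)
  out <- cbind(group = c("All", order_keys), out)
  rownames(out) <- NULL
  out
}

#' Format a cohort summary the way clinical tables print it
#'
#' Means +/- SD to three decimals; a lone plan prints its mean alone; an
#' empty class prints a dash.
#'
#' @param summary result of [cohort_summary()]
#' @return data.frame with character `passing` / `failing` columns
#' @export
format_cohort_summary <- function(summary) {
  fmt <- function(m, s) {
    ifelse(is.na(m), "-",
           ifelse(is.na(s), formatC(m, format = "f", digits = 3),
                  paste0(formatC(m, format = "f", digits = 3), "±",
                         formatC(s, format = "f", digits = 3))))
  }
  data.frame(
    group = summary$group, total = summary$total, failing = summary$failing,
    above = summary$above, failing_above = summary$failing_above,
    passing_complexity = fmt(summary$mean_pass, summary$sd_pass),
    failing_complexity = fmt(summary$mean_fail, summary$sd_fail),
    stringsAsFactors = FALSE
  )
}

#' Histogram of cohort complexities
#'
#' Fixed-width bins anchored at 0: bin k covers `[k w, (k+1) w)`.  Counts
#' always sum to the number of records after filtering.
#'
#' @param records cohort data.frame
#' @param site_filter site label, or "all" to keep everything
#' @param bin_width bin width in 1/mm (default 0.01)
#' @return data.frame with `bin_lo`, `bin_hi`, `count`
#' @export
cohort_histogram <- function(records, site_filter = "all", bin_width = 0.01) {
  if (!is.finite(bin_width) || bin_width <= 0) abort("bin_width must be > 0")
  rec <- filter_site(records, site_filter)
  idx <- floor(rec$complexity_mm_inv / bin_width)
  counts <- table(factor(idx, levels = 0:max(idx)))
  data.frame(
    bin_lo = as.numeric(names(counts)) * bin_width,
    bin_hi = (as.numeric(names(counts)) + 1) * bin_width,
    count = as.integer(counts)
  )
}

filter_site <- function(records, site_filter) {
  rec <- if (identical(site_filter, "all")) records
         else records[records$site == site_filter, , drop = FALSE]
  if (nrow(rec) == 0L) {
    abort("no cohort records left after site filter '", site_filter, "'")
  }
  rec
}

#' Empirical percentile of a complexity value in a cohort
#'
#' Mid-rank percentile: `100 * (count(< m) + 0.5 * count(= m)) / n`, so a
#' value equal to the single record sits at the 50th percentile and the
#' function is non-decreasing in `m`.
#'
#' @param m complexity value in 1/mm
#' @param records cohort data.frame
#' @param site_filter site label or "all"
#' @return percentile in `[0, 100]`
#' @export
percentile_of <- function(m, records, site_filter = "all") {
  rec <- filter_site(records, site_filter)
  x <- rec$complexity_mm_inv
  100 * (sum(x < m) + 0.5 * sum(x == m)) / length(x)
}
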