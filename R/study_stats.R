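#' @title Outcome classification and evaluation statistics
#'
#' @description
#' The evaluation of a paired crossover accuracy study (each case scanned by
#' each operator in both assisted and nonassisted mode) rests on a small
#' statistical battery: per-scan outcome classification, proportions with
#' rounded percentages, paired t tests for continuous variables, exact
#' McNemar tests for paired binary outcomes, Cohen's weighted kappa for
#' scoring reproducibility, and Wald confidence intervals for proportion
#' differences.
#'
#' @name study_stats
NULL

# round half away from zero (so 29.5 -> 30 and -26.5 -> -27); base round()
# rounds half to even, which does not reproduce conventional table rounding
.round_half_out <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Classify one scan against the gold-standard diagnosis
#'
#' Computes the four outcome flags used in the study tables:
#' * `correct_location`: the report states the gold location class
#'   definitively (intrauterine for a nonectopic gold, ectopic for an
#'   ectopic gold). A conclusion of pregnancy of unknown location commits to
#'   no location and is never a correct location diagnosis.
#' * `exact_diagnosis`: correct location and, for an ectopic gold, the
#'   precise implantation site explicitly stated and matching.
#' * `fn_ep`: gold ectopic but the conclusion is not ectopic (the clinically
#'   dangerous error).
#' * `fp_ep`: gold nonectopic but the conclusion is ectopic.
#'
#' @param gold,conclusion [diagnosis()] statements; `gold` must be
#'   intrauterine or ectopic (study cases have a confirmed final diagnosis).
#' @return Named logical vector with elements `correct_location`,
#'   `exact_diagnosis`, `fn_ep`, `fp_ep`.
#' @export
#' @examples
#' classify_outcome(diagnosis("ectopic", "tubal"), diagnosis("intrauterine"))
classify_outcome <- function(gold, conclusion) {
  stopifnot(inherits(gold, "diagnosis"), inherits(conclusion, "diagnosis"))
  if (gold$location_class == "pregnancy_of_unknown_location")
    stop("gold standard must be a definite location (intrauterine or ectopic)",
         call. = FALSE)
  gold_ep <- gold$location_class == "ectopic"
  concl_ep <- conclusion$location_class == "ectopic"
  correct <- conclusion$location_class == gold$location_class
  if (gold_ep) {
    site <- conclusion$ectopic_site
    exact <- correct && !is.null(site) && site != "unspecified" &&
      !is.null(gold$ectopic_site) && site == gold$ectopic_site
  } else {
    exact <- correct
  }
  c(correct_location = correct,
    exact_diagnosis = exact,
    fn_ep = gold_ep && !concl_ep,
    fp_ep = !gold_ep && concl_ep)
}

#' Integer percentage, rounded half away from zero
#'
#' @param count Numerator, `0 <= count <= n`.
#' @param n Positive denominator.
#' @return `100 * count / n` rounded half away from zero to an integer.
#' @export
#' @examples
#' proportion_pct(52, 64) # 81
proportion_pct <- function(count, n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n <= 0)
    stop("n must be a positive number", call. = FALSE)
  if (!is.numeric(count) || length(count) != 1L || is.na(count) ||
      count < 0 || count > n)
    stop("count must satisfy 0 <= count <= n", call. = FALSE)
  as.integer(.round_half_out(100 * count / n))
}

#' Percent change, rounded half away from zero
#'
#' @param new,old Values to compare; `old` must be nonzero.
#' @return `100 * (new - old) / old` rounded half away from zero to an
#'   integer (e.g. `pct_change(12.5, 10.2)` is `23`).
#' @export
pct_change <- function(new, old) {
  if (!is.numeric(old) || length(old) != 1L || is.na(old) || old == 0)
    stop("old must be a nonzero number", call. = FALSE)
  as.integer(.round_half_out(100 * (new - old) / old))
}

#' Paired t test for a continuous scan variable
#'
#' Classical paired t statistic on the within-pair differences
#' `assisted - nonassisted`, with a two-sided p value from the t
#' distribution on `n - 1` degrees of freedom.
#'
#' @param assisted,nonassisted Equal-length numeric vectors (n >= 2), paired
#'   elementwise.
#' @return List of class `paired_comparison` with elements `mean_assisted`,
#'   `mean_nonassisted`, `difference`, `pct_difference`, `t_statistic`,
#'   `degrees_freedom`, `p_value`, `n_pairs`.
#' @export
#' @examples
#' paired_t(c(1, 2, 3), c(2, 4, 6))
paired_t <- function(assisted, nonassisted) {
  if (length(assisted) != length(nonassisted))
    stop("paired vectors must have equal length", call. = FALSE)
  n <- length(assisted)
  if (n < 2L)
    stop("at least 2 pairs are required", call. = FALSE)
  if (anyNA(assisted) || anyNA(nonassisted))
    stop("missing values are not allowed", call. = FALSE)
  d <- assisted - nonassisted
  sd_d <- stats::sd(d)
  if (sd_d == 0)
    stop("differences have zero variance; the paired t statistic is undefined",
         call. = FALSE)
  t_stat <- mean(d) / (sd_d / sqrt(n))
  df <- n - 1L
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  ma <- mean(assisted); mn <- mean(nonassisted)
  structure(list(
    mean_assisted = ma,
    mean_nonassisted = mn,
    difference = ma - mn,
    pct_difference = if (mn != 0) 100 * (ma - mn) / mn else NA_real_,
    t_statistic = t_stat,
    degrees_freedom = df,
    p_value = p,
    n_pairs = n
  ), class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("paired t: mean %.3f vs %.3f, diff %+.3f (%s), t = %.4f, df = %d, p = %.4g\n",
              x$mean_assisted, x$mean_nonassisted, x$difference,
              if (is.na(x$pct_difference)) "NA" else sprintf("%+.0f%%", x$pct_difference),
              x$t_statistic, x$degrees_freedom, x$p_value))
  invisible(x)
}

#' Exact McNemar test on discordant pairs
#'
#' For paired binary outcomes with `b` pairs succeeding only under the first
#' condition and `c` only under the second, the two-sided exact p value is
#' `min(1, 2 * P(X <= min(b, c)))` with `X ~ Binomial(b + c, 1/2)`.
#'
#' @param b,c Nonnegative discordant-pair counts with `b + c >= 1`.
#' @return The exact two-sided p value.
#' @export
#' @examples
#' mcnemar_exact(13, 0) # 2 * 0.5^13
mcnemar_exact <- function(b, c) {
  for (v in list(b = b, c = c))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v != as.integer(v))
      stop("b and c must be nonnegative integers", call. = FALSE)
  n <- b + c
  if (n == 0L)
    stop("no discordant pairs: the McNemar test is undefined", call. = FALSE)
  min(1, 2 * stats::pbinom(min(b, c), size = n, prob = 0.5))
}

#' Cohen's weighted kappa for ordinal agreement
#'
#' Chance-corrected agreement between two raters on an ordered categorical
#' scale, with distance-based disagreement weights:
#' `kappa = 1 - sum(w * O) / sum(w * E)` where `O` is the observed and `E`
#' the chance-expected contingency proportion matrix, and `w[i, j]` is
#' `|i - j| / (k - 1)` (linear) or its square (quadratic).
#'
#' @param r1,r2 Equal-length rating vectors.
#' @param categories Ordered vector of all valid categories; defaults to the
#'   sorted union of observed ratings.
#' @param weights `"quadratic"` (default) or `"linear"`.
#' @return The weighted kappa coefficient (1 for perfect agreement).
#' @export
#' @examples
#' weighted_kappa(c(1, 2, 3), c(1, 2, 3)) # 1
weighted_kappa <- function(r1, r2, categories = NULL,
                           weights = c("quadratic", "linear")) {
  weights <- match.arg(weights)
  if (length(r1) != length(r2))
    stop("rating vectors must have equal length", call. = FALSE)
  if (length(r1) < 1L)
    stop("at least one rating pair is required", call. = FALSE)
  if (is.null(categories)) categories <- sort(unique(c(r1, r2)))
  i1 <- match(r1, categories)
  i2 <- match(r2, categories)
  if (anyNA(i1) || anyNA(i2))
    stop("ratings outside the declared categories", call. = FALSE)
  k <- length(categories)
  if (k == 1L) return(1)
  obs <- matrix(0, k, k)
  for (idx in seq_along(i1))
    obs[i1[idx], i2[idx]] <- obs[i1[idx], i2[idx]] + 1
  obs <- obs / length(r1)
  exp_ <- outer(rowSums(obs), colSums(obs))
  d <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  w <- if (weights == "linear") d else d^2
  denom <- sum(w * exp_)
  if (denom == 0) return(1) # both raters constant on one category
  1 - sum(w * obs) / denom
}

#' Wald confidence interval for a difference of proportions
#'
#' Unpaired 95% Wald interval
#' `(p1 - p2) +/- 1.96 * sqrt(p1 (1 - p1) / n + p2 (1 - p2) / n)`,
#' reported in percentage points. Note this deliberately simple method does
#' not account for the pairing of the study design; pair-level intervals
#' require the per-pair discordance table.
#'
#' @param p1,p2 Proportions in \[0, 1\].
#' @param n Per-group sample size.
#' @return Named numeric vector `c(lower, upper)` in percentage points.
#' @export
#' @examples
#' wald_ci_diff(52 / 64, 39 / 64, 64)
wald_ci_diff <- function(p1, p2, n) {
  for (p in list(p1 = p1, p2 = p2))
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
      stop("proportions must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n <= 0)
    stop("n must be positive", call. = FALSE)
  se <- sqrt(p1 * (1 - p1) / n + p2 * (1 - p2) / n)
  diff <- p1 - p2
  c(lower = 100 * (diff - 1.96 * se), upper = 100 * (diff + 1.96 * se))
}

## Scan-record tables --------------------------------------------------------

.record_columns <- function() {
  c("case_id", "operator_id", "mode", "gold_location", "gold_site",
    "concl_location", "concl_site", "image_count", "duration_min",
    "quality_score", "trust_level")
}

.check_records <- function(records) {
  if (!is.data.frame(records))
    stop("records must be a data frame", call. = FALSE)
  missing_cols <- setdiff(.record_columns(), names(records))
  if (length(missing_cols) > 0L)
    stop(sprintf("records are missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (!all(records$mode %in% c("assisted", "nonassisted")))
    stop("mode must be 'assisted' or 'nonassisted'", call. = FALSE)
  invisible(records)
}

#' Classify every scan record
#'
#' Vectorized [classify_outcome()] over a record table.
#'
#' @param records Scan-record data frame (see [read_scan_records()] for the
#'   column contract).
#' @return The records with four logical columns appended:
#'   `correct_location`, `exact_diagnosis`, `fn_ep`, `fp_ep`.
#' @export
classify_records <- function(records) {
  .check_records(records)
  flags <- t(vapply(seq_len(nrow(records)), function(i) {
    gold <- diagnosis(records$gold_location[i],
                      if (records$gold_location[i] == "ectopic")
                        .site_or_null(records$gold_site[i]))
    concl <- diagnosis(records$concl_location[i],
                       if (records$concl_location[i] == "ectopic")
                         .site_or_null(records$concl_site[i]))
    classify_outcome(gold, concl)
  }, logical(4)))
  cbind(records, as.data.frame(flags))
}

.site_or_null <- function(x) {
  if (is.na(x) || !nzchar(x)) NULL else x
}

#' Summarize a crossover study
#'
#' Produces the two standard result tables from a full record set:
#' * `table1`: per-mode mean (SD) of image count, scan duration, quality
#'   score and trust score, with the paired t test on each.
#' * `table2`: per-mode counts and integer percentages of correct pregnancy
#'   location, exact diagnosis, false negatives and false positives of
#'   ectopic pregnancy, with discordant-pair counts and the exact McNemar p
#'   value for the two diagnosis outcomes.
#'
#' Records must pair exactly: one assisted and one nonassisted scan per
#' (case, operator).
#'
#' @param records Scan-record data frame.
#' @return List of class `study_summary` with elements `table1`, `table2`,
#'   `n_per_mode`.
#' @export
#' @examples
#' summarize_study(table2_records())$table2
summarize_study <- function(records) {
  recs <- classify_records(records)
  recs$pair_id <- paste(recs$case_id, recs$operator_id, sep = "\r")
  a <- recs[recs$mode == "assisted", , drop = FALSE]
  b <- recs[recs$mode == "nonassisted", , drop = FALSE]
  if (nrow(a) != nrow(b) || anyDuplicated(a$pair_id) || anyDuplicated(b$pair_id) ||
      !setequal(a$pair_id, b$pair_id))
    stop("records do not pair: each (case_id, operator_id) needs exactly one assisted and one nonassisted scan",
         call. = FALSE)
  ord <- order(a$pair_id, method = "radix")
  a <- a[ord, , drop = FALSE]
  b <- b[order(b$pair_id, method = "radix"), , drop = FALSE]
  n <- nrow(a)

  cont <- c(image_count = "Image count in report",
            duration_min = "Scan duration (minutes)",
            quality_score = "Quality score of image sets",
            trust_level = "Trust score of report")
  t1 <- do.call(rbind, lapply(names(cont), function(col) {
    ma <- mean(a[[col]]); mb <- mean(b[[col]])
    # degenerate inputs (a single pair, or identical differences) leave the
    # t statistic undefined; the summary reports NA rather than failing
    pt <- tryCatch(paired_t(a[[col]], b[[col]]), error = function(e) NULL)
    data.frame(parameter = cont[[col]],
               mean_assisted = ma,
               sd_assisted = stats::sd(a[[col]]),
               mean_nonassisted = mb,
               sd_nonassisted = stats::sd(b[[col]]),
               difference = ma - mb,
               pct_difference = if (mb != 0) pct_change(ma, mb) else NA_integer_,
               t_statistic = if (is.null(pt)) NA_real_ else pt$t_statistic,
               degrees_freedom = length(a[[col]]) - 1L,
               p_value = if (is.null(pt)) NA_real_ else pt$p_value,
               stringsAsFactors = FALSE)
  }))
  rownames(t1) <- NULL

  outs <- c(correct_location = "Correct pregnancy location (ectopic/nonectopic)",
            exact_diagnosis = "Exact diagnosis (with precise ectopic location)",
            fn_ep = "False-negative of ectopic pregnancy",
            fp_ep = "False-positive of ectopic pregnancy")
  t2 <- do.call(rbind, lapply(names(outs), function(col) {
    na <- sum(a[[col]]); nb <- sum(b[[col]])
    disc_b <- sum(a[[col]] & !b[[col]])
    disc_c <- sum(!a[[col]] & b[[col]])
    p <- if (disc_b + disc_c > 0) mcnemar_exact(disc_b, disc_c) else NA_real_
    data.frame(outcome = outs[[col]],
               n_assisted = na,
               pct_assisted = proportion_pct(na, n),
               n_nonassisted = nb,
               pct_nonassisted = proportion_pct(nb, n),
               difference_n = na - nb,
               difference_pct = as.integer(.round_half_out(100 * (na - nb) / n)),
               discordant_b = disc_b,
               discordant_c = disc_c,
               p_value = p,
               stringsAsFactors = FALSE)
  }))
  rownames(t2) <- NULL

  structure(list(table1 = t1, table2 = t2, n_per_mode = n),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("Study summary (%d scans per mode)\n\n", x$n_per_mode))
  cat("Scan quality (assisted vs nonassisted, paired t):\n")
  t1 <- x$table1
  for (i in seq_len(nrow(t1)))
    cat(sprintf("  %-28s %6.2f (%.2f) vs %6.2f (%.2f)  %+0.2f (%+d%%)  p = %.3g\n",
                t1$parameter[i], t1$mean_assisted[i], t1$sd_assisted[i],
                t1$mean_nonassisted[i], t1$sd_nonassisted[i], t1$difference[i],
                t1$pct_difference[i], t1$p_value[i]))
  cat("\nDiagnostic performance (exact McNemar):\n")
  t2 <- x$table2
  for (i in seq_len(nrow(t2)))
    cat(sprintf("  %-48s %2d (%d%%) vs %2d (%d%%)%s\n",
                t2$outcome[i], t2$n_assisted[i], t2$pct_assisted[i],
                t2$n_nonassisted[i], t2$pct_nonassisted[i],
                if (is.na(t2$p_value[i])) "" else sprintf("  p = %.3g", t2$p_value[i])))
  invisible(x)
}

#' Write scan records to CSV
#'
#' @param records Scan-record data frame.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_scan_records <- function(records, file) {
  .check_records(records)
  utils::write.csv(records[, .record_columns()], file, row.names = FALSE,
                   na = "")
  invisible(file)
}

#' Read scan records from CSV
#'
#' The documented header is: `case_id, operator_id, mode, gold_location,
#' gold_site, concl_location, concl_site, image_count, duration_min,
#' quality_score, trust_level`. Site columns are empty for non-ectopic
#' diagnoses.
#'
#' @param file CSV path.
#' @return Scan-record data frame.
#' @export
read_scan_records <- function(file) {
  recs <- utils::read.csv(file, stringsAsFactors = FALSE,
                          colClasses = c(case_id = "character",
                                         operator_id = "character",
                                         gold_site = "character",
                                         concl_site = "character"))
  recs$gold_site[is.na(recs$gold_site)] <- ""
  recs$concl_site[is.na(recs$concl_site)] <- ""
  .check_records(recs)
  recs
}
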