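# Operating-characteristic estimation: confusion counts, sensitivity /
# specificity / AUC (mean of the two, since adjudicators are binary),
# exact binomial confidence intervals, majority-vote gold standards with
# leave-one-out, and PPV/sensitivity of phenotype algorithms against a
# silver standard.

# Normalizes labels to data.table(person_id, label). Accepts
# (person_id, label), truth labels (person_id, true_case), or
# adjudication results (person_id, effective_label).
as_label_set <- function(x) {
  x <- as.data.frame(x)
  col <- intersect(c("label", "true_case", "effective_label"), names(x))
  if (!"person_id" %in% names(x) || !length(col))
    stop("labels need a person_id column and one of: label, true_case, ",
         "effective_label")
  out <- data.table::data.table(person_id = as.integer(x$person_id),
                                label = as.logical(x[[col[1L]]]))
  if (anyNA(out$label)) stop("labels contain NA")
  if (anyDuplicated(out$person_id)) stop("duplicate person_id in labels")
  data.table::setorder(out, person_id)
  out[]
}

#' Confusion counts of predictions against a reference
#'
#' @param reference,predictions label sets over identical rosters: any
#'   data.frame with `person_id` and one of `label` / `true_case` /
#'   `effective_label`.
#' @return object of class `confusion_counts`: `tp, fp, tn, fn`.
#' @export
confusion <- function(reference, predictions) {
  ref <- as_label_set(reference)
  prd <- as_label_set(predictions)
  only_ref <- setdiff(ref$person_id, prd$person_id)
  only_prd <- setdiff(prd$person_id, ref$person_id)
  if (length(only_ref) || length(only_prd))
    stop("rosters differ; only in reference: ",
         paste(head(only_ref, 10), collapse = ", "),
         "; only in predictions: ",
         paste(head(only_prd, 10), collapse = ", "))
  m <- merge(ref, prd, by = "person_id", suffixes = c("_ref", "_prd"))
  structure(list(tp = sum(m$label_ref & m$label_prd),
                 fp = sum(!m$label_ref & m$label_prd),
                 tn = sum(!m$label_ref & !m$label_prd),
                 fn = sum(m$label_ref & !m$label_prd)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fp=%d tn=%d fn=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Exact and approximate binomial confidence intervals
#'
#' Clopper-Pearson (default) uses beta quantiles:
#' lower = qbeta(alpha/2; x, n-x+1), upper = qbeta(1-alpha/2; x+1, n-x),
#' with the boundary conventions lower = 0 at x = 0 and upper = 1 at x = n.
#' Wilson is the score interval.
#'
#' @param successes,n non-negative counts, `0 <= successes <= n`, `n >= 1`.
#' @param method `"clopper_pearson"` or `"wilson"`.
#' @param level two-sided confidence level.
#' @return named numeric `c(lower, upper)`.
#' @export
binomial_interval <- function(successes, n,
                              method = c("clopper_pearson", "wilson"),
                              level = 0.95) {
  method <- match.arg(method)
  if (n < 1 || successes < 0 || successes > n)
    stop("need 0 <= successes <= n and n >= 1")
  alpha <- 1 - level
  if (method == "clopper_pearson") {
    lower <- if (successes == 0) 0 else
      qbeta(alpha / 2, successes, n - successes + 1)
    upper <- if (successes == n) 1 else
      qbeta(1 - alpha / 2, successes + 1, n - successes)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    p <- successes / n
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lower <- max(0, centre - half)
    upper <- min(1, centre + half)
  }
  c(lower = lower, upper = upper)
}

#' Sensitivity, specificity and AUC from confusion counts
#'
#' For binary adjudicators the AUC equals the mean of sensitivity and
#' specificity. A metric whose denominator is empty (no positives, or no
#' negatives, in the reference) is returned as `NA` with its name listed in
#' `undefined` rather than silently reported as 0.
#'
#' @param counts a [confusion()] result.
#' @param ci_method passed to [binomial_interval()].
#' @param level confidence level.
#' @return object of class `metrics_result`: `sensitivity, specificity,
#'   auc, ci_sensitivity, ci_specificity, n_pos, n_neg, undefined`.
#' @export
metrics <- function(counts, ci_method = "clopper_pearson", level = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  n_pos <- counts$tp + counts$fn
  n_neg <- counts$tn + counts$fp
  undefined <- character(0)
  if (n_pos >= 1) {
    sens <- counts$tp / n_pos
    ci_sens <- binomial_interval(counts$tp, n_pos, ci_method, level)
  } else {
    sens <- NA_real_; ci_sens <- c(lower = NA_real_, upper = NA_real_)
    undefined <- c(undefined, "sensitivity")
  }
  if (n_neg >= 1) {
    spec <- counts$tn / n_neg
    ci_spec <- binomial_interval(counts$tn, n_neg, ci_method, level)
  } else {
    spec <- NA_real_; ci_spec <- c(lower = NA_real_, upper = NA_real_)
    undefined <- c(undefined, "specificity")
  }
  auc <- if (length(undefined)) NA_real_ else (sens + spec) / 2
  structure(list(sensitivity = sens, specificity = spec, auc = auc,
                 ci_sensitivity = ci_sens, ci_specificity = ci_spec,
                 n_pos = n_pos, n_neg = n_neg, undefined = undefined),
            class = "metrics_result")
}

#' @export
print.metrics_result <- function(x, ...) {
  fmt <- function(v, ci) if (is.na(v)) "undefined" else
    sprintf("%.1f%% (%.1f-%.1f%%)", 100 * v, 100 * ci[1], 100 * ci[2])
  cat("<metrics_result>\n")
  cat("  sensitivity: ", fmt(x$sensitivity, x$ci_sensitivity),
      "  [n_pos=", x$n_pos, "]\n", sep = "")
  cat("  specificity: ", fmt(x$specificity, x$ci_specificity),
      "  [n_neg=", x$n_neg, "]\n", sep = "")
  cat("  AUC:         ",
      if (is.na(x$auc)) "undefined" else sprintf("%.2f", x$auc), "\n",
      sep = "")
  invisible(x)
}

#' Majority-vote gold standard with leave-one-out
#'
#' Votes are a complete person-by-reviewer logical matrix. When evaluating
#' a reviewer, that reviewer's column is left out of the vote so their own
#' labels never enter their gold standard. A person is positive when
#' strictly more than half of the remaining reviewers vote positive; an
#' exact tie (possible with an even remaining count) resolves to negative
#' and is flagged — the conservative convention also used for unresolved
#' adjudications.
#'
#' @param reviews logical matrix, rownames = person ids, colnames =
#'   reviewer ids; no missing cells.
#' @param leave_out reviewer id (column name) to exclude, or `NULL`.
#' @return data.table `(person_id, label, tie)`.
#' @export
majority_vote_gold <- function(reviews, leave_out = NULL) {
  if (!is.matrix(reviews) || !is.logical(reviews))
    stop("reviews must be a logical matrix (persons x reviewers)")
  if (anyNA(reviews))
    stop("review matrix has missing cells; complete-block designs required")
  if (is.null(rownames(reviews)) || is.null(colnames(reviews)))
    stop("reviews needs person rownames and reviewer colnames")
  if (ncol(reviews) < 3)
    stop("majority vote needs >= 3 reviewers before leave-out")
  if (!is.null(leave_out)) {
    if (!leave_out %in% colnames(reviews))
      stop("unknown reviewer: ", leave_out)
    reviews <- reviews[, setdiff(colnames(reviews), leave_out),
                       drop = FALSE]
  }
  k <- ncol(reviews)
  votes <- rowSums(reviews)
  data.table::data.table(person_id = as.integer(rownames(reviews)),
                         label = votes > k / 2,
                         tie = votes == k / 2)
}

#' PPV and sensitivity of a phenotype algorithm against a silver standard
#'
#' With every person in a (high-sensitivity) roster labelled by the silver
#' standard, both operating characteristics are estimable:
#' PPV = tp / n_flagged over the algorithm-flagged persons and
#' sensitivity = tp / n_silver_pos over the silver positives, each with a
#' binomial confidence interval.
#'
#' @param silver silver-standard label set over the full roster.
#' @param algorithm_flags label set of algorithm-flagged persons (same
#'   roster).
#' @param ci_method passed to [binomial_interval()].
#' @param level confidence level.
#' @return object of class `operating_characteristics`: `ppv, ci_ppv,
#'   sensitivity, ci_sensitivity, counts(n_flagged, n_silver_pos, tp)`.
#' @export
operating_characteristics <- function(silver, algorithm_flags,
                                      ci_method = "clopper_pearson",
                                      level = 0.95) {
  cc <- confusion(silver, algorithm_flags)
  n_flagged <- cc$tp + cc$fp
  n_silver_pos <- cc$tp + cc$fn
  if (n_flagged < 1)
    stop("undefined PPV: the algorithm flagged no one")
  if (n_silver_pos < 1)
    stop("undefined sensitivity: the silver standard has no positives")
  structure(list(
    ppv = cc$tp / n_flagged,
    ci_ppv = binomial_interval(cc$tp, n_flagged, ci_method, level),
    sensitivity = cc$tp / n_silver_pos,
    ci_sensitivity = binomial_interval(cc$tp, n_silver_pos, ci_method,
                                       level),
    counts = list(n_flagged = n_flagged, n_silver_pos = n_silver_pos,
                  tp = cc$tp)),
    class = "operating_characteristics")
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat("<operating_characteristics>\n")
  cat(sprintf("  PPV:         %.1f%% (95%% CI %.1f-%.1f%%)  [tp=%d / flagged=%d]\n",
              100 * x$ppv, 100 * x$ci_ppv[1], 100 * x$ci_ppv[2],
              x$counts$tp, x$counts$n_flagged))
  cat(sprintf("  sensitivity: %.1f%% (95%% CI %.1f-%.1f%%)  [tp=%d / silver+=%d]\n",
              100 * x$sensitivity, 100 * x$ci_sensitivity[1],
              100 * x$ci_sensitivity[2], x$counts$tp,
              x$counts$n_silver_pos))
  invisible(x)
}

#' Metrics for adjudication results against a reference standard
#'
#' Indeterminate verdicts enter the confusion matrix as negative
#' predictions (their effective label) but are also counted separately.
#'
#' @param results an `adjudication_results` table.
#' @param reference reference label set.
#' @param ci_method,level passed to [metrics()].
#' @return a `metrics_result` with an extra `n_indeterminate` field.
#' @export
adjudication_metrics <- function(results, reference,
                                 ci_method = "clopper_pearson",
                                 level = 0.95) {
  m <- metrics(confusion(reference, results), ci_method, level)
  m$n_indeterminate <- sum(results$decision == "indeterminate")
  m
}

#' Long-format evaluation report across strategies / models / reviewers
#'
#' One row per labelled `metrics_result`, with display columns rounded
#' half-away-from-zero at the customary printed precision (percentages to
#' one decimal, AUC to two) alongside the full-precision values.
#' Re-rendering the same results is byte-stable.
#'
#' @param results named list of `metrics_result` objects (names label the
#'   rows, e.g. prompt variant or model).
#' @param path optional CSV output path.
#' @return data.table report.
#' @export
evaluation_report <- function(results, path = NULL) {
  if (!length(results)) stop("need >= 1 result")
  stopifnot(all(vapply(results, inherits, logical(1), "metrics_result")))
  rows <- lapply(names(results), function(nm) {
    m <- results[[nm]]
    data.table::data.table(
      strategy = nm,
      sensitivity = m$sensitivity, specificity = m$specificity,
      auc = m$auc,
      sensitivity_pct = round_half_up(100 * m$sensitivity, 1),
      specificity_pct = round_half_up(100 * m$specificity, 1),
      auc_2dp = round_half_up(m$auc, 2),
      ci_sens_lower = m$ci_sensitivity[["lower"]],
      ci_sens_upper = m$ci_sensitivity[["upper"]],
      ci_spec_lower = m$ci_specificity[["lower"]],
      ci_spec_upper = m$ci_specificity[["upper"]],
      n_pos = m$n_pos, n_neg = m$n_neg,
      n_indeterminate = m$n_indeterminate %||% NA_integer_)
  })
  report <- data.table::rbindlist(rows)
  if (!is.null(path)) data.table::fwrite(report, path)
  report[]
}

#' Manual-review effort accounting
#'
#' Tallies the human reviews a validation design consumes: a development
#' set reviewed once, plus complete-block test sets of
#' reviewers x diseases x cases-per-disease.
#'
#' @param dev_reviews reviews spent on the development set.
#' @param sets list of numeric triples `c(reviewers, diseases,
#'   cases_per_disease)`.
#' @return list with `per_set` (integer vector) and `total`.
#' @export
review_effort <- function(dev_reviews, sets) {
  per_set <- vapply(sets, function(s) {
    if (length(s) != 3) stop("each set is c(reviewers, diseases, cases)")
    as.integer(prod(s))
  }, integer(1))
  list(dev_reviews = as.integer(dev_reviews), per_set = per_set,
       total = as.integer(dev_reviews + sum(per_set)))
}
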