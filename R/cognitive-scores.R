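#' Default cognitive test batteries
#'
#' The four cognitive components and their constituent neuropsychological
#' tests: long-term memory (CVLT long-delay free recall and its contrasts
#' with trial 5 and short-delay recall), short-term memory (CVLT short-delay
#' free recall, first recall of list A, total recall), semantic retrieval
#' (Boston Naming Test, category fluency), and manipulation (Alpha Span,
#' Digit Span Backwards). Column names are lower-snake-case versions of the
#' test names. All tests are taken to be oriented so that higher raw scores
#' indicate better performance; an inverted raw test must be negated by the
#' caller before composite construction.
#'
#' @return Named list: domain -> character vector of test column names.
#' @export
defaultBatteries <- function() {
  list(
    LTM = c("cvlt_long_free_recall",
            "cvlt_long_free_vs_list5",
            "cvlt_long_free_vs_short_free"),
    STM = c("cvlt_short_free_recall",
            "cvlt_list_a1",
            "cvlt_total_recall"),
    SemanticRetrieval = c("boston_naming",
                          "category_fluency_total"),
    Manipulation = c("alpha_span",
                     "digit_backwards")
  )
}

#' z-normalize one raw test column
#'
#' Centers and scales to sample mean 0 and sample SD 1 (n - 1 denominator)
#' over the non-missing subjects; missing entries stay missing.
#'
#' @param raw numeric vector of raw scores (may contain `NA`).
#' @return Numeric vector of z-scores, same length and missingness as `raw`.
#' @examples
#' normalizeTest(c(1, 2, 3))  # -1 0 1
#' @export
normalizeTest <- function(raw) {
  ok <- !is.na(raw)
  if (sum(ok) < 2L) stop("need at least 2 non-missing scores")
  if (any(!is.finite(raw[ok]))) stop("raw scores must be finite")
  s <- stats::sd(raw[ok])
  if (s == 0) stop("zero variance: test scores are all equal")
  out <- raw
  out[ok] <- (raw[ok] - mean(raw[ok])) / s
  out
}

#' Composite cognitive score for one domain
#'
#' The composite is the mean of the z-normalized scores of the domain's
#' tests, per subject. Subjects missing any of the domain's tests are
#' excluded listwise (no imputation), which is why the analyzed sample size
#' differs between domains. Normalization uses the analyzed sample itself.
#'
#' @param table data.frame with a `subject_id` column and one column per raw
#'   test (plus any covariates).
#' @param battery character vector of test column names for the domain.
#' @param domain optional domain label attached to the result.
#' @return data.frame with columns `subject_id` and `composite` (z-units),
#'   one row per complete subject, with attributes `domain` and `n`.
#' @export
compositeScore <- function(table, battery, domain = NULL) {
  missing <- setdiff(battery, colnames(table))
  if (length(missing))
    stop("battery tests absent from table: ", paste(missing, collapse = ", "))
  complete <- stats::complete.cases(table[, battery, drop = FALSE])
  if (!any(complete)) stop("no subjects with complete test data")
  sub <- table[complete, , drop = FALSE]
  z <- vapply(battery, function(t) normalizeTest(sub[[t]]), numeric(nrow(sub)))
  out <- data.frame(subject_id = sub$subject_id,
                    composite = rowMeans(matrix(z, nrow = nrow(sub))),
                    stringsAsFactors = FALSE)
  attr(out, "domain") <- domain
  attr(out, "n") <- nrow(out)
  out
}

# composite scores aligned to a cohort's subjects; subjects missing any test
# of the domain are dropped (domain-specific N_c)
.cohortComposite <- function(cohort, domain) {
  battery <- cohort@batteries[[domain]]
  if (is.null(battery)) stop("unknown domain: ", domain)
  compositeScore(cohort@scores, battery, domain = domain)
}
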