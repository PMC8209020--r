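#' Summarize one morphometric parameter within a group
#'
#' Mean and standard error of the mean (sample s.d. with the n - 1
#' denominator divided by sqrt(n)) over the per-image (or per-sample)
#' values of one parameter. Missing values — e.g., undefined thickness on
#' empty images — are excluded with a message reporting how many were
#' dropped.
#'
#' @param values numeric vector of per-unit parameter values.
#' @param parameterName label of the parameter.
#' @param units unit string (\code{"\%"}, \code{"/mm2"}, \code{"mm"},
#'   \code{"um"}, ...).
#' @return a \code{\linkS4class{GroupStats}}.
#' @examples
#' groupSummary(c(1, 2, 3))  # mean 2, sem 1/sqrt(3)
#' @export
groupSummary <- function(values, parameterName = "", units = "") {
  miss <- sum(is.na(values))
  if (miss > 0) {
    message(sprintf("groupSummary: excluded %d missing value(s)%s", miss,
                    if (nzchar(parameterName))
                      paste0(" for ", parameterName) else ""))
    values <- values[!is.na(values)]
  }
  if (length(values) < 2L)
    stop("at least 2 non-missing values are required")
  new("GroupStats", n = length(values), mean = mean(values),
      sem = stats::sd(values) / sqrt(length(values)),
      parameterName = parameterName, units = units)
}

asGroupStats <- function(x, what) {
  if (is(x, "GroupStats")) return(x)
  if (is.numeric(x)) return(groupSummary(x))
  stop(sprintf("'%s' must be a GroupStats object or a numeric vector", what))
}

#' Two-sample t-test from raw values or printed summaries
#'
#' Two-tailed two-sample t-test operating either on raw per-unit values or
#' directly on published summaries (n, mean, SEM) — the latter makes it
#' possible to reproduce significance calls from printed group statistics
#' alone. In both modes the statistic is
#' \eqn{t = (\bar x_a - \bar x_b) / \sqrt{sem_a^2 + sem_b^2}}; the
#' \code{"student"} variant uses pooled degrees of freedom
#' \eqn{n_a + n_b - 2} (identical to the classic pooled-variance test when
#' group sizes are equal), the \code{"welch"} variant uses the
#' Welch-Satterthwaite approximation. Degenerate zero-variance input follows
#' the conventions p = 1 for equal means and p = 0 (with a warning) for
#' unequal means.
#'
#' @param a,b each either a \code{\linkS4class{GroupStats}} or a numeric
#'   vector of raw values (n >= 2).
#' @param variant \code{"student"} (default) or \code{"welch"}.
#' @return a \code{\linkS4class{TTestResult}}.
#' @examples
#' bpTlf <- new("GroupStats", n = 6L, mean = 500.9, sem = 43.1)
#' bpGlu <- new("GroupStats", n = 6L, mean = 140.3, sem = 31.6)
#' tTestGroups(bpTlf, bpGlu)
#' @export
tTestGroups <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  src <- if (is(a, "GroupStats") && is(b, "GroupStats"))
    "summary-stats" else "raw-values"
  a <- asGroupStats(a, "a"); b <- asGroupStats(b, "b")
  se2 <- a@sem^2 + b@sem^2
  diff <- a@mean - b@mean
  df <- if (variant == "student") {
    a@n + b@n - 2
  } else {
    if (se2 > 0)
      se2^2 / (a@sem^4 / (a@n - 1) + b@sem^4 / (b@n - 1))
    else a@n + b@n - 2
  }
  if (se2 == 0) {
    if (diff == 0) {
      tstat <- 0; p <- 1
    } else {
      warning("zero variance with unequal means; p = 0 by convention")
      tstat <- sign(diff) * Inf; p <- 0
    }
  } else {
    tstat <- diff / sqrt(se2)
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  new("TTestResult", tStatistic = tstat, df = df, pValue = p,
      variant = variant, source = src)
}

#' Ratio of a dense to a sparse marker's positive-area fraction
#'
#' Ratio of the group-mean positive areas of two stains (e.g., a pan-nerve
#' marker over a sympathetic-fiber marker), with a first-order propagated
#' standard error
#' \eqn{\sqrt{(sem_a / \bar x_b)^2 + (\bar x_a\, sem_b / \bar x_b^2)^2}}.
#'
#' @param denseMarker,sparseMarker \code{\linkS4class{GroupStats}} of
#'   positive-area percentages; the sparse marker's mean must be positive.
#' @return a list with elements \code{ratio} and \code{se}.
#' @examples
#' s100 <- new("GroupStats", n = 6L, mean = 9.0, sem = 1.0)
#' th <- new("GroupStats", n = 6L, mean = 0.08, sem = 0.01)
#' markerRatio(s100, th)$ratio  # 112.5
#' @export
markerRatio <- function(denseMarker, sparseMarker) {
  stopifnot(is(denseMarker, "GroupStats"), is(sparseMarker, "GroupStats"))
  if (sparseMarker@mean <= 0)
    stop("undefined ratio: the sparse marker's mean must be > 0")
  ratio <- denseMarker@mean / sparseMarker@mean
  se <- sqrt((denseMarker@sem / sparseMarker@mean)^2 +
             (denseMarker@mean * sparseMarker@sem / sparseMarker@mean^2)^2)
  list(ratio = ratio, se = se)
}

#' Compare two groups across all morphometric parameters
#'
#' Builds the machine-readable twin of a grouped morphometry figure: one row
#' per parameter with both groups' n, mean and SEM, and the two-sample
#' t-test. Missing values (e.g., undefined thickness) are excluded per
#' parameter. A note is emitted when more than four comparisons are run,
#' since no multiple-testing correction is applied.
#'
#' @param perImage data.frame with a \code{group} column and one column per
#'   parameter.
#' @param parameters character vector of parameter column names.
#' @param variant t-test variant, see \code{\link{tTestGroups}}.
#' @return a data.frame with columns parameter, group_a, n_a, mean_a, sem_a,
#'   group_b, n_b, mean_b, sem_b, t, df, p, variant.
#' @export
compareGroups <- function(perImage,
                          parameters = c("positive_area_pct",
                                         "bp_density_per_mm2",
                                         "total_length_mm",
                                         "mean_thickness_um"),
                          variant = c("student", "welch")) {
  variant <- match.arg(variant)
  grps <- unique(perImage$group)
  if (length(grps) != 2L)
    stop("exactly two groups are required")
  if (length(parameters) > 4L)
    message("note: more than 4 comparisons without multiple-testing ",
            "correction")
  rows <- lapply(parameters, function(p) {
    va <- perImage[[p]][perImage$group == grps[1L]]
    vb <- perImage[[p]][perImage$group == grps[2L]]
    ga <- suppressMessages(groupSummary(va, p))
    gb <- suppressMessages(groupSummary(vb, p))
    tt <- tTestGroups(ga, gb, variant)
    data.frame(parameter = p,
               group_a = grps[1L], n_a = ga@n, mean_a = ga@mean,
               sem_a = ga@sem,
               group_b = grps[2L], n_b = gb@n, mean_b = gb@mean,
               sem_b = gb@sem,
               t = tt@tStatistic, df = tt@df, p = tt@pValue,
               variant = variant, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
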