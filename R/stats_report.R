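#' Unpaired two-tailed Student's t test
#'
#' The parametric group comparison applied to most assay readouts: the
#' pooled-variance (Student's, not Welch's) unpaired t statistic with
#' `n1 + n2 - 2` degrees of freedom and a two-sided p value. Welch's
#' unequal-variance variant is available behind `welch = TRUE`.
#'
#' Degenerate inputs are resolved explicitly: zero pooled variance with
#' equal means gives p = 1; zero pooled variance with unequal means gives
#' p = 0 and a `degenerate` flag.
#'
#' @param x,y Numeric samples (each n >= 2, finite).
#' @param welch Use Welch's unequal-variance t instead. Default `FALSE`.
#' @return Object of class `group_comparison`: `test`, `statistic`,
#'   `p_value`, `n1`, `n2`, `group_summary` (means), `degenerate`.
#' @export
students_t_two_tailed <- function(x, y, welch = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples need n >= 2", call. = FALSE)
  if (any(!is.finite(c(x, y))))
    stop("samples must be finite", call. = FALSE)
  degenerate <- FALSE
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      stat <- 0; p <- 1
    } else {
      stat <- Inf * sign(mean(x) - mean(y)); p <- 0; degenerate <- TRUE
    }
  } else {
    ht <- stats::t.test(x, y, var.equal = !welch)
    stat <- unname(ht$statistic); p <- ht$p.value
  }
  structure(list(test = if (welch) "welch_t" else "students_t",
                 statistic = stat, p_value = p,
                 n1 = length(x), n2 = length(y),
                 group_summary = c(mean1 = mean(x), mean2 = mean(y)),
                 degenerate = degenerate),
            class = "group_comparison")
}

#' Two-sided Mann-Whitney U test
#'
#' The nonparametric group comparison: the U statistic computed from
#' midranks, with an exact two-sided p value (full null enumeration of
#' rank assignments) when `n1 + n2 <= 16` and the data carry no ties, and
#' a normal approximation with tie correction and continuity correction
#' otherwise. `mode` forces either branch.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param mode `"auto"` (default), `"exact"` or `"approx"`.
#' @return Object of class `group_comparison`: `test`, `statistic` (U of
#'   the first sample), `p_value`, `n1`, `n2`, `group_summary` (medians),
#'   `mode` (branch used).
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples need n >= 2", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  ties <- any(duplicated(c(x, y)))
  exact <- switch(mode,
                  exact = TRUE,
                  approx = FALSE,
                  auto = (n1 + n2 <= 16L) && !ties)
  if (exact && ties)
    stop("exact mode is defined only for tie-free data", call. = FALSE)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(c(x, y))) == 1L) {
    p <- 1
  } else if (exact) {
    # exact two-sided p: 2 * min tail of the null U distribution
    # (stats::[pd]wilcox enumerate the rank-sum combinatorics)
    p_lo <- stats::pwilcox(U, n1, n2)
    p_hi <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    p <- ht$p.value
  }
  structure(list(test = "mann_whitney", statistic = unname(U),
                 p_value = p, n1 = n1, n2 = n2,
                 group_summary = c(median1 = stats::median(x),
                                   median2 = stats::median(y)),
                 mode = if (exact) "exact" else "approx"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic %.4g, p = %.4g %s (n = %d, %d)\n",
              x$test, x$statistic, x$p_value,
              significance_stars(x$p_value), x$n1, x$n2))
  invisible(x)
}

#' Significance stars at the 0.05 / 0.01 / 0.001 thresholds
#'
#' @param p Numeric vector of p values.
#' @return Character vector: `"***"` for p < 0.001, `"**"` for p < 0.01,
#'   `"*"` for p < 0.05, `"ns"` otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Per-group summary with pairwise tests against a control
#'
#' The per-genotype summary behind the bar-and-stars figures: per-group n,
#' mean, sd and median, plus a pairwise comparison of every group against
#' the designated control group using the configured test. No
#' multiple-testing correction is applied -- each contrast is reported with
#' its raw p value, matching how these assays are conventionally reported;
#' apply a correction downstream if your design needs one.
#'
#' @param values Numeric vector of per-animal results.
#' @param groups Group labels, same length.
#' @param control Label of the control group; default the first level.
#' @param test `"students_t"` (default) or `"mann_whitney"`; may be a
#'   named character vector giving a per-group test choice.
#' @return Data frame (class `report_table`) with one row per group:
#'   `group`, `n`, `mean`, `sd`, `median`, `test`, `p_value`, `stars`
#'   (control row has NA test columns).
#' @export
summarize_groups <- function(values, groups, control = NULL,
                             test = "students_t") {
  values <- as.numeric(values)
  groups <- as.character(groups)
  if (length(values) != length(groups))
    stop("`values` and `groups` must have equal length", call. = FALSE)
  lv <- unique(groups)
  if (length(lv) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (is.null(control)) control <- lv[1L]
  if (!control %in% lv) stop("control group '", control, "' not found",
                             call. = FALSE)
  ns <- table(groups)[lv]
  small <- names(ns)[ns < 2L]
  if (length(small)) {
    warning("excluding group(s) with n < 2: ",
            paste(small, collapse = ", "))
    if (control %in% small)
      stop("control group has n < 2", call. = FALSE)
    keep <- !groups %in% small
    values <- values[keep]; groups <- groups[keep]
    lv <- setdiff(lv, small)
    if (length(lv) < 2L) stop("fewer than 2 usable groups", call. = FALSE)
  }
  ctrl_vals <- values[groups == control]
  rows <- lapply(lv, function(g) {
    v <- values[groups == g]
    row <- data.frame(group = g, n = length(v), mean = mean(v),
                      sd = stats::sd(v), median = stats::median(v),
                      test = NA_character_, p_value = NA_real_,
                      stars = NA_character_,
                      stringsAsFactors = FALSE)
    if (g != control) {
      tg <- if (length(test) > 1L && g %in% names(test)) test[[g]]
            else test[[1L]]
      cmp <- switch(tg,
                    students_t = students_t_two_tailed(v, ctrl_vals),
                    mann_whitney = mann_whitney(v, ctrl_vals),
                    stop("unknown test '", tg, "'", call. = FALSE))
      row$test <- tg
      row$p_value <- cmp$p_value
      row$stars <- significance_stars(cmp$p_value)
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("report_table", class(out))
  out
}
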