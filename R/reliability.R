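## Internal-consistency and test-retest reliability from two-way mean
## squares (rows = subjects, columns = items/raters), following the
## McGraw & Wong taxonomy of intraclass correlations.

## Two-way mean squares for an n x k complete matrix.
two_way_ms <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 items")
  if (anyNA(m)) stop("missing cells: apply listwise deletion upstream")
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  list(
    n = n, k = k,
    msr = ss_rows / (n - 1),
    msc = ss_cols / (k - 1),
    mse = ss_err / ((n - 1) * (k - 1))
  )
}

new_reliability_result <- function(estimate, ci_low, ci_high, form, n, k,
                                   degenerate = FALSE) {
  structure(
    list(
      estimate = estimate, ci_low = ci_low, ci_high = ci_high,
      form = form, n_subjects = n, n_items = k, degenerate = degenerate
    ),
    class = "reliability_result"
  )
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf(
    "%s = %.4f, 95%% CI [%.4f, %.4f] (%d subjects x %d items)%s\n",
    x$form, x$estimate, x$ci_low, x$ci_high, x$n_subjects, x$n_items,
    if (isTRUE(x$degenerate)) " [degenerate]" else ""
  ))
  invisible(x)
}

#' Intraclass correlation coefficients (McGraw-Wong)
#'
#' Two-way ICCs from a complete subjects x items matrix. Consistency forms
#' treat item (column) offsets as irrelevant; agreement forms count them as
#' error. Single-measure forms (`*_1`) describe one item, average-measure
#' forms (`*_k`) the mean of all k items. ICC(C,k) is numerically identical
#' to Cronbach's alpha. Confidence intervals use the exact F intervals for
#' the consistency forms and the Satterthwaite approximation for the
#' agreement forms.
#'
#' @param m numeric matrix or data.frame, subjects in rows, items in columns;
#'   no missing cells.
#' @param form one of "ICC_C1", "ICC_Ck", "ICC_A1", "ICC_Ak".
#' @param conf confidence level (default 0.95).
#' @return a `reliability_result` with `estimate`, `ci_low`, `ci_high`.
#' @export
icc <- function(m, form = c("ICC_Ck", "ICC_C1", "ICC_A1", "ICC_Ak"),
                conf = 0.95) {
  form <- match.arg(form)
  ms <- two_way_ms(m)
  n <- ms$n; k <- ms$k
  msr <- ms$msr; msc <- ms$msc; mse <- ms$mse
  if (stats::var(as.vector(as.matrix(m))) < 1e-300) {
    stop("constant matrix: variance undefined")
  }
  a2 <- (1 - conf) / 2
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)

  if (msr < 1e-12 * max(msc, mse, 1)) {
    ## no between-subject variance at all
    return(new_reliability_result(0, NA_real_, NA_real_, form, n, k,
                                  degenerate = TRUE))
  }

  if (form %in% c("ICC_C1", "ICC_Ck")) {
    fobs <- msr / mse
    fl <- fobs / stats::qf(1 - a2, df1, df2)
    fu <- fobs * stats::qf(1 - a2, df2, df1)
    if (form == "ICC_C1") {
      est <- (msr - mse) / (msr + (k - 1) * mse)
      lo <- (fl - 1) / (fl + k - 1)
      hi <- (fu - 1) / (fu + k - 1)
    } else {
      est <- (msr - mse) / msr
      lo <- 1 - 1 / fl
      hi <- 1 - 1 / fu
    }
    return(new_reliability_result(est, lo, hi, form, n, k))
  }

  ## agreement forms
  est1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  a <- (k * est1) / (n * (1 - est1))
  b <- 1 + (k * est1 * (n - 1)) / (n * (1 - est1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_up <- stats::qf(1 - a2, df1, v)
  f_lo <- stats::qf(1 - a2, v, df1)
  lo1 <- n * (msr - f_up * mse) /
    (f_up * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi1 <- n * (f_lo * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_lo * msr)
  if (form == "ICC_A1") {
    return(new_reliability_result(est1, lo1, hi1, "ICC_A1", n, k))
  }
  sb <- function(r1) k * r1 / (1 + (k - 1) * r1)
  estk <- (msr - mse) / (msr + (msc - mse) / n)
  new_reliability_result(estk, sb(lo1), sb(hi1), "ICC_Ak", n, k)
}

#' Cronbach's alpha
#'
#' alpha = k/(k-1) (1 - sum of item variances / variance of item sums);
#' numerically identical to ICC(C,k) on the same complete matrix. The
#' confidence interval is the Feldt F interval (the same interval as
#' ICC(C,k)).
#'
#' @inheritParams icc
#' @return a `reliability_result` with form "alpha".
#' @export
cronbach_alpha <- function(m, conf = 0.95) {
  m <- as.matrix(m)
  ms <- two_way_ms(m) # validates input
  k <- ncol(m)
  item_var <- apply(m, 2, stats::var)
  total_var <- stats::var(rowSums(m))
  if (total_var < 1e-300) stop("constant matrix: variance undefined")
  est <- k / (k - 1) * (1 - sum(item_var) / total_var)
  ci <- icc(m, "ICC_Ck", conf)
  new_reliability_result(est, ci$ci_low, ci$ci_high, "alpha", ms$n, k,
                         degenerate = ci$degenerate)
}

#' Test-retest reliability between two days
#'
#' Treats the two days as two "items" over matched measurement units
#' (typically participant x target mean angles) and reports ICC(C,k) over
#' the n x 2 matrix. With `circular = TRUE` the angles are first unwrapped
#' about the pooled circular mean (each value replaced by its signed
#' circular distance from that mean) so the linear mean-square machinery
#' applies to directions near the wrap point.
#'
#' @param day1,day2 numeric vectors of matched measurements (same length,
#'   same unit order).
#' @param circular treat values as angles in degrees (default FALSE).
#' @param form ICC form, as in [icc()].
#' @return a `reliability_result`.
#' @export
test_retest <- function(day1, day2, circular = FALSE, form = "ICC_Ck") {
  stopifnot(length(day1) == length(day2))
  keep <- stats::complete.cases(day1, day2)
  day1 <- day1[keep]; day2 <- day2[keep]
  if (length(day1) < 3) stop("need at least 3 matched units")
  if (circular) {
    pooled <- circ_mean(c(day1, day2))$mean_deg
    day1 <- circ_distance(day1, pooled)
    day2 <- circ_distance(day2, pooled)
  }
  icc(cbind(day1 = day1, day2 = day2), form)
}
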