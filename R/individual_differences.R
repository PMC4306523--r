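# Individual differences: relate the winning model's rivalry-minus-replay
# modulation differences to each subject's mean dominance duration by
# multiple regression, after excluding influential subjects by Cook's
# distance.

#' Rivalry-minus-replay modulation differences per subject
#'
#' @param fits List (one per subject) of winning-model `posterior_fit`
#'   objects holding both conditions' B estimates.
#' @param mean_durations Numeric vector of per-subject mean dominance
#'   durations (s), same order as `fits`.
#' @return A `delta_b_table` data.frame: `subject`, one `delta_b.<conn>`
#'   column per modulated connection, `mean_duration_s`.
#' @export
compute_delta_b <- function(fits, mean_durations) {
  stopifnot(length(fits) == length(mean_durations))
  rows <- lapply(seq_along(fits), function(i) {
    riv <- b_estimates(fits[[i]], "rivalry")
    rep_ <- b_estimates(fits[[i]], "replay")
    if (!length(riv) || !length(rep_))
      stop("subject ", i, " lacks B estimates for one condition")
    stopifnot(identical(names(riv), names(rep_)))
    d <- riv - rep_
    row <- data.frame(subject = i)
    for (nm in names(d)) row[[paste0("delta_b.", nm)]] <- unname(d[[nm]])
    row$mean_duration_s <- mean_durations[i]
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("delta_b_table", "data.frame")
  out
}

#' Cook's distance for ordinary least squares
#'
#' `D_i = r_i^2 / p * h_i / (1 - h_i)` with studentized residual
#' `r_i = e_i / (s * sqrt(1 - h_i))`, hat leverage `h_i` and `p` fitted
#' coefficients; equivalently the scaled shift of all fitted values when
#' observation `i` is deleted.
#'
#' @param y Outcome vector.
#' @param X Predictor matrix including the intercept column.
#' @return Numeric vector of distances, one per observation.
#' @export
cooks_distance <- function(y, X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than coefficients")
  qrX <- qr(X)
  if (qrX$rank < p) stop("singular predictor matrix")
  e <- y - X %*% qr.coef(qrX, y)
  h <- rowSums(qr.Q(qrX)^2)
  s2 <- sum(e^2) / (n - p)
  drop(e^2 / (p * s2) * h / (1 - h)^2)
}

#' Regression of mean dominance duration on modulation differences
#'
#' Fits `mean_duration ~ delta_b` on all subjects, excludes subjects whose
#' Cook's distance exceeds the threshold (one pass by default), refits on
#' the retained subjects and reports coefficients (unstandardized and
#' standardized on the retained sample), R-squared, adjusted R-squared, the
#' F statistic with its degrees of freedom, and the full- and
#' retained-sample distances.
#'
#' @param table A [compute_delta_b()] table (or any data.frame with
#'   `delta_b.*` predictor columns and `mean_duration_s`).
#' @param cooks_threshold Exclusion threshold (strict inequality, default
#'   1).
#' @param iterate If TRUE, repeat the exclusion pass on the retained sample
#'   until no distance exceeds the threshold (off by default; the single
#'   pass is the primary rule).
#' @return A `regression_report`.
#' @export
fit_dominance_regression <- function(table, cooks_threshold = 1.0,
                                     iterate = FALSE) {
  pred_cols <- grep("^delta_b\\.", names(table), value = TRUE)
  if (!length(pred_cols)) stop("no delta_b predictor columns")
  y <- table$mean_duration_s
  X <- cbind(intercept = 1, as.matrix(table[pred_cols]))
  n <- nrow(X); p <- ncol(X)
  if (n - p < 1) stop("not enough subjects for ", length(pred_cols),
                      " predictors")
  D_full <- cooks_distance(y, X)
  keep <- D_full <= cooks_threshold
  if (iterate) {
    repeat {
      Dk <- cooks_distance(y[keep], X[keep, , drop = FALSE])
      if (all(Dk <= cooks_threshold)) break
      idx <- which(keep)
      keep[idx[Dk > cooks_threshold]] <- FALSE
      if (sum(keep) - p < 1) stop("exclusion left no residual df")
    }
  }
  excluded <- table$subject[!keep]
  n_ret <- sum(keep)
  if (n_ret - p < 1)
    stop("residual degrees of freedom exhausted after exclusion")

  dat <- data.frame(y = y[keep], table[keep, pred_cols, drop = FALSE],
                    check.names = FALSE)
  fml <- stats::as.formula(paste("y ~", paste(sprintf("`%s`", pred_cols),
                                              collapse = " + ")))
  fit <- lm(fml, data = dat)
  sm <- summary(fit)
  zdat <- as.data.frame(scale(dat))
  zfit <- lm(fml, data = zdat)
  std_beta <- coef(zfit)[-1]

  r2 <- sm$r.squared
  adj <- 1 - (1 - r2) * (n_ret - 1) / (n_ret - p)
  stopifnot(abs(adj - sm$adj.r.squared) < 1e-10)  # bookkeeping self-check

  coefs <- data.frame(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, 1],
    se = sm$coefficients[, 2],
    t = sm$coefficients[, 3],
    p = sm$coefficients[, 4],
    std_beta = c(NA_real_, unname(std_beta)),
    row.names = NULL)

  structure(list(
    coefficients = coefs,
    r_squared = r2, adj_r_squared = adj,
    f_statistic = unname(sm$fstatistic["value"]),
    df1 = as.integer(sm$fstatistic["numdf"]),
    df2 = as.integer(sm$fstatistic["dendf"]),
    p_value = unname(stats::pf(sm$fstatistic["value"],
                               sm$fstatistic["numdf"],
                               sm$fstatistic["dendf"], lower.tail = FALSE)),
    cooks_full = setNames(D_full, table$subject),
    cooks_retained = setNames(
      cooks_distance(y[keep], X[keep, , drop = FALSE]),
      table$subject[keep]),
    excluded = excluded, n_retained = n_ret,
    threshold = cooks_threshold),
    class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf(
    "Dominance-duration regression: R^2 = %.3f (adjusted %.3f), F(%d, %d) = %.2f, p = %.4g\n",
    x$r_squared, x$adj_r_squared, x$df1, x$df2, x$f_statistic, x$p_value))
  if (length(x$excluded))
    cat("excluded subjects (Cook's D > ", x$threshold, "): ",
        paste(x$excluded, collapse = ", "), "\n", sep = "")
  print(x$coefficients, digits = 3)
  invisible(x)
}
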