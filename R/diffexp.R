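#' @name diffexp
#' @title Moderated differential expression for miRNA counts
#' @description
#' The two-group differential-expression model: counts are transformed to
#' log2 counts-per-million, per-observation precision weights are derived
#' from a smoothed mean-variance trend (voom-style), each miRNA is fit by
#' weighted least squares against a two-column design (intercept, group),
#' residual variances are shrunk toward a scaled-F prior estimated by
#' method of moments on log variances (empirical Bayes), and two-sided
#' moderated-t p-values are adjusted by Benjamini-Hochberg. A miRNA is
#' called differentially expressed when the adjusted p-value is below 0.05
#' and the linear fold change is at least 1.5.
NULL

#' Log2 counts-per-million transform
#'
#' `log2((count + 0.5) / (libsize + 1) * 1e6)`, with library sizes taken as
#' column sums.
#'
#' @param counts A [count_matrix()] or a plain counts matrix.
#' @return Real matrix of log2-CPM values, same dimnames as the input.
#' @export
log_cpm <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  libsize <- colSums(m)
  if (any(libsize == 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(m)[libsize == 0], collapse = ", "))
  }
  t(log2(t(m + 0.5) / (libsize + 1) * 1e6))
}

#' Two-column design matrix (intercept, frozen indicator)
#'
#' @param groups Factor or character of `control`/`frozen` labels.
#' @return Numeric matrix with columns `intercept` and `groupfrozen`.
#' @export
group_design <- function(groups) {
  g <- factor(as.character(groups), levels = c("control", "frozen"))
  stopifnot(!anyNA(g), nlevels(droplevels(g)) == 2L)
  cbind(intercept = 1, groupfrozen = as.numeric(g == "frozen"))
}

#' Voom-style precision weights from the mean-variance trend
#'
#' Fits each row by ordinary least squares, smooths the square root of the
#' residual standard deviations against the row mean log2-CPM with a
#' locally weighted linear smoother (span 0.5), interpolates the trend at
#' each observation's fitted value (clamped to the trend's range at the
#' extremes), and returns weights equal to the interpolated trend value to
#' the power -4. With fewer than `min_rows` rows the trend cannot be
#' estimated and unit weights are returned with a warning.
#'
#' @param logcpm Log2-CPM matrix.
#' @param design Design matrix from [group_design()].
#' @param span Smoother span.
#' @param min_rows Minimum number of rows required for trend fitting.
#' @return Positive weight matrix, same shape as `logcpm`.
#' @export
voom_weights <- function(logcpm, design, span = 0.5, min_rows = 10L) {
  n <- ncol(logcpm)
  p <- ncol(design)
  stopifnot(n > p)
  if (nrow(logcpm) < min_rows) {
    warning("fewer than ", min_rows,
            " rows: mean-variance trend not estimable, using unit weights")
    return(matrix(1, nrow(logcpm), ncol(logcpm),
                  dimnames = dimnames(logcpm)))
  }
  fit <- stats::lm.fit(design, t(logcpm))
  res <- t(fit$residuals)
  fitted_vals <- t(fit$fitted.values)
  s <- sqrt(rowSums(res^2) / (n - p))
  sx <- rowMeans(logcpm)
  sy <- sqrt(s)
  lo <- stats::lowess(sx, sy, f = span)
  # guard against a degenerate (zero) trend before the ^-4 blow-up
  trend <- stats::approx(lo$x, lo$y, xout = as.vector(fitted_vals),
                         rule = 2, ties = mean)$y
  trend <- pmax(trend, 1e-4)
  w <- matrix(trend^(-4), nrow(logcpm), ncol(logcpm),
              dimnames = dimnames(logcpm))
  w
}

#' Per-miRNA weighted least squares for the group effect
#'
#' Fits each row of the normalized matrix by weighted least squares with
#' the given precision weights and extracts the group (frozen - control)
#' coefficient in log2 units.
#'
#' @param logcpm Log2-CPM matrix.
#' @param weights Positive weight matrix of the same shape.
#' @param design Design matrix from [group_design()].
#' @return Data frame per miRNA: `mirna_id`, `coef` (log2FC),
#'   `stdev_unscaled` (unscaled standard error of the coefficient), `s_sq`
#'   (residual variance), `df_residual`, `avg_logcpm`.
#' @export
fit_group_model <- function(logcpm, weights, design) {
  stopifnot(all(dim(logcpm) == dim(weights)), all(weights > 0),
            nrow(design) == ncol(logcpm), ncol(design) == 2L)
  if (qr(design)$rank < ncol(design)) stop("design matrix is not full rank")
  n <- ncol(logcpm)
  df <- n - ncol(design)
  stopifnot(df >= 1L)
  ids <- rownames(logcpm)
  out <- data.frame(mirna_id = ids, coef = NA_real_,
                    stdev_unscaled = NA_real_, s_sq = NA_real_,
                    df_residual = df, avg_logcpm = rowMeans(logcpm),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_len(nrow(logcpm))) {
    w <- weights[i, ]
    y <- logcpm[i, ]
    xtwx <- crossprod(design * w, design)
    xi <- tryCatch(solve(xtwx), error = function(e) {
      stop("singular weighted design for miRNA '", ids[i], "'")
    })
    beta <- xi %*% crossprod(design * w, y)
    r <- y - design %*% beta
    out$coef[i] <- beta[2L]
    out$stdev_unscaled[i] <- sqrt(xi[2L, 2L])
    out$s_sq[i] <- sum(w * r^2) / df
  }
  out
}

#' Estimate the empirical-Bayes variance prior
#'
#' Method of moments on log residual variances under a scaled-F prior
#' (`s^2 ~ s0^2 * F(df, d0)`): the excess spread of `log(s^2)` beyond
#' `trigamma(df/2)` determines the prior degrees of freedom `d0` via a
#' monotone trigamma equation solved by bisection on [0.1, 500]; no excess
#' spread gives an infinite `d0` with `s0^2` recovered from the geometric
#' mean. Non-positive variances are excluded from moment estimation.
#'
#' @param s_sq Vector of residual variances.
#' @param df_residual Residual degrees of freedom of each fit.
#' @return List of class `moderation_params`: `d0`, `s0_sq`, `df_residual`.
#' @export
estimate_prior <- function(s_sq, df_residual) {
  df <- df_residual[1]
  z <- log(s_sq[is.finite(s_sq) & s_sq > 0])
  if (length(z) < 2L) {
    stop("degenerate data: need at least two positive finite variances")
  }
  evar <- stats::var(z)
  bias <- digamma(df / 2) - log(df / 2)
  excess <- evar - trigamma(df / 2)
  if (excess <= trigamma(250)) {
    # spread fully explained by chi-square sampling noise (or beyond the
    # solvable range): infinite prior df
    d0 <- Inf
    s0_sq <- exp(mean(z) - bias)
  } else {
    f <- function(d0) trigamma(d0 / 2) - excess
    lo <- 0.1
    hi <- 500
    d0 <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
    s0_sq <- exp(mean(z) - bias + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq, df_residual = df),
            class = "moderation_params")
}

#' Moderated t-test for one or more coefficients
#'
#' Shrinks each residual variance toward the prior,
#' `s_tilde^2 = (d0 * s0^2 + df * s^2) / (d0 + df)`, forms
#' `t = coef / (stdev_unscaled * s_tilde)`, and computes two-sided p-values
#' on `df + d0` degrees of freedom (capped at 1e6 when `d0` is infinite,
#' numerically the normal limit).
#'
#' @param coef,stdev_unscaled,s_sq,df_residual Vectors from
#'   [fit_group_model()].
#' @param prior A `moderation_params` from [estimate_prior()]; `d0 = 0`
#'   reduces to the ordinary t-test.
#' @return Data frame with `t_mod` and `p_raw`.
#' @export
moderated_test <- function(coef, stdev_unscaled, s_sq, df_residual, prior) {
  d0 <- prior$d0
  s0 <- prior$s0_sq
  s_tilde_sq <- if (is.infinite(d0)) {
    rep(s0, length(s_sq))
  } else {
    (d0 * s0 + df_residual * s_sq) / (d0 + df_residual)
  }
  df_total <- pmin(df_residual + d0, 1e6)
  t_mod <- coef / (stdev_unscaled * sqrt(s_tilde_sq))
  p_raw <- 2 * stats::pt(-abs(t_mod), df = df_total)
  data.frame(t_mod = t_mod, p_raw = p_raw)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adj_i = min over j >= i of (m * p_(j) / j)`, capped at 1, mapped back
#' to the input order.
#'
#' @param p_raw Vector of p-values in [0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_raw) {
  stopifnot(all(p_raw >= 0 & p_raw <= 1))
  m <- length(p_raw)
  if (m == 0L) return(numeric(0))
  o <- order(p_raw, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p_raw[o]))[ro]
}

#' Flag differentially expressed miRNAs
#'
#' Significant iff the FDR-adjusted p-value is strictly below `alpha` and
#' the absolute linear fold change is at least `fc_threshold` (inclusive).
#'
#' @param records Data frame with `log2fc` and `p_adj`.
#' @param alpha Adjusted-p cutoff (strict).
#' @param fc_threshold Linear fold-change cutoff (inclusive).
#' @return The data frame with a logical `significant` column.
#' @export
call_de <- function(records, alpha = 0.05, fc_threshold = 1.5) {
  stopifnot(all(c("log2fc", "p_adj") %in% names(records)))
  records$significant <- records$p_adj < alpha &
    abs(records$log2fc) >= log2(fc_threshold)
  records
}

#' Run the full differential-expression stage on a count matrix
#'
#' log2-CPM, voom-style weights (optional), per-miRNA weighted least
#' squares, empirical-Bayes moderation, BH adjustment and DE calling.
#'
#' @param cm A [count_matrix()] (already low-count filtered).
#' @param weighted Use voom-style precision weights inside the linear model
#'   (`TRUE`) or unit weights (`FALSE`).
#' @param alpha,fc_threshold DE-calling thresholds, see [call_de()].
#' @return Data frame per miRNA: `mirna_id`, `log2fc`, `fc`, `avg_logcpm`,
#'   `t_mod`, `p_raw`, `p_adj`, `significant`, sorted as the input rows.
#' @export
run_diffexp <- function(cm, weighted = TRUE, alpha = 0.05,
                        fc_threshold = 1.5) {
  stopifnot(inherits(cm, "count_matrix"))
  design <- group_design(cm$groups)
  lc <- log_cpm(cm)
  w <- if (weighted) {
    voom_weights(lc, design)
  } else {
    matrix(1, nrow(lc), ncol(lc), dimnames = dimnames(lc))
  }
  fit <- fit_group_model(lc, w, design)
  prior <- estimate_prior(fit$s_sq, fit$df_residual)
  mt <- moderated_test(fit$coef, fit$stdev_unscaled, fit$s_sq,
                       fit$df_residual, prior)
  de <- data.frame(
    mirna_id = fit$mirna_id,
    log2fc = fit$coef,
    fc = 2^fit$coef,
    avg_logcpm = fit$avg_logcpm,
    t_mod = mt$t_mod,
    p_raw = mt$p_raw,
    p_adj = bh_adjust(mt$p_raw),
    stringsAsFactors = FALSE
  )
  de <- call_de(de, alpha = alpha, fc_threshold = fc_threshold)
  attr(de, "prior") <- prior
  de
}
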