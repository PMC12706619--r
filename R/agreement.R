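#' Bland-Altman agreement between automated and manual measurements
#'
#' Differences are oriented automated minus manual, so a positive bias
#' means the automated method overestimates. Limits of agreement are
#' bias +/- 1.96 times the sample SD of the differences (n - 1 denominator).
#'
#' @param auto,manual Equal-length numeric vectors of paired measurements
#'   (pairing is positional), n >= 2, all finite.
#' @return An object of class `agreement_stats`: `n`, `bias`, `sd`,
#'   `loa_low`, `loa_high`, `mae` and `pearson_r` (NA when n < 3 or either
#'   input is constant).
#' @export
bland_altman <- function(auto, manual) {
  auto <- as.numeric(auto); manual <- as.numeric(manual)
  if (length(auto) != length(manual)) stop("length mismatch")
  n <- length(auto)
  if (n < 2) stop("need at least 2 pairs")
  if (!all(is.finite(auto)) || !all(is.finite(manual)))
    stop("non-finite values")
  d <- auto - manual
  bias <- mean(d)
  s <- stats::sd(d)
  r <- if (n >= 3 && stats::sd(auto) > 0 && stats::sd(manual) > 0)
    stats::cor(auto, manual) else NA_real_
  structure(list(n = n, bias = bias, sd = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 mae = mean(abs(d)), pearson_r = r),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat("<agreement_stats> n = ", x$n,
      "\n  bias (auto - manual): ", sprintf("%.4f", x$bias),
      "\n  SD of differences:    ", sprintf("%.4f", x$sd),
      "\n  95% LoA:              [", sprintf("%.4f", x$loa_low), ", ",
      sprintf("%.4f", x$loa_high), "]",
      "\n  MAE:                  ", sprintf("%.4f", x$mae),
      "\n  Pearson r:            ", sprintf("%.4f", x$pearson_r), "\n",
      sep = "")
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()]: constant input is an error
#' (the coefficient is undefined), never a silent 0.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, both nonconstant.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  stats::cor(x, y)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; absolute differences are ranked with
#' mid-ranks for ties; the statistic W is the sum of ranks of positive
#' differences. For `n_eff <= exact_limit` the two-sided p-value is exact,
#' computed from the full null distribution of W over all 2^n sign
#' assignments (evaluated by dynamic programming over the ranks, which
#' enumerates the same distribution without materialising 2^n terms);
#' otherwise a normal approximation with tie correction and a 0.5 continuity
#' correction is used. The two-sided p is the symmetric tail probability
#' P(W >= max(w, S - w)) + P(W <= min(w, S - w)) with S the total rank sum.
#'
#' @param a,b Equal-length numeric vectors; differences `a - b`.
#' @param exact_limit Largest n_eff for the exact distribution (default 25).
#' @return An object of class `wilcoxon_result`: `statistic` (W),
#'   `p_two_sided`, `n_effective` and `method` (`"exact"` or
#'   `"normal_approx"`).
#' @export
wilcoxon_signed_rank <- function(a, b, exact_limit = 25) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("length mismatch")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero")
  r <- rank(abs(d))               # mid-ranks for ties
  W <- sum(r[d > 0])
  S <- n * (n + 1) / 2
  if (n <= exact_limit) {
    # null distribution of 2W (integer-valued since mid-ranks are halves)
    r2 <- as.integer(round(2 * r))
    maxs <- sum(r2)
    p_w <- numeric(maxs + 1)      # p_w[s + 1] = #assignments with 2W = s
    p_w[1] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), p_w[seq_len(maxs + 1 - rk)])
      p_w <- p_w + shifted
    }
    p_w <- p_w / 2^n
    w2 <- as.integer(round(2 * W))
    hi <- max(w2, 2 * S - w2); lo <- min(w2, 2 * S - w2)
    p <- sum(p_w[(hi + 1):(maxs + 1)]) + sum(p_w[seq_len(lo + 1)])
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- S / 2
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  structure(list(statistic = W, p_two_sided = p, n_effective = n,
                 method = method),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat("<wilcoxon_result> W = ", x$statistic, ", n_eff = ", x$n_effective,
      ", p = ", format.pval(x$p_two_sided), " (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Screen measurement error against covariates
#'
#' Checks for systematic bias in absolute measurement errors: continuous
#' covariates are tested with the Pearson correlation and its t-based
#' two-sided p-value; binary covariates with a Welch two-sample t-test on
#' the absolute errors.
#'
#' @param abs_err Numeric vector of absolute errors.
#' @param covariates Data frame; columns with exactly two distinct values
#'   are treated as binary, other numeric columns as continuous.
#' @return A data frame with one row per covariate: `covariate`, `type`,
#'   `stat` (r or t), `p` and `n`.
#' @export
covariate_bias_screen <- function(abs_err, covariates) {
  abs_err <- as.numeric(abs_err)
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(abs_err))
  rows <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    lv <- unique(v[!is.na(v)])
    if (length(lv) == 2L) {
      groups <- split(abs_err, v)
      if (any(vapply(groups, length, 1L) < 3L))
        stop("covariate '", nm, "': fewer than 3 observations in a group")
      if (all(vapply(groups, stats::sd, 1) == 0) &&
          abs(diff(vapply(groups, mean, 1))) == 0) {
        tt <- list(statistic = c(t = 0), p.value = 1)
      } else {
        tt <- stats::t.test(groups[[1]], groups[[2]])
      }
      data.frame(covariate = nm, type = "binary",
                 stat = unname(tt$statistic), p = tt$p.value,
                 n = length(abs_err))
    } else {
      if (!is.numeric(v)) stop("covariate '", nm, "' is neither numeric nor binary")
      if (length(abs_err) < 3) stop("need n >= 3")
      r <- pearson_r(abs_err, v)
      n <- length(abs_err)
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p <- if (is.finite(tstat)) 2 * stats::pt(-abs(tstat), n - 2) else 0
      data.frame(covariate = nm, type = "continuous", stat = r, p = p, n = n)
    }
  })
  do.call(rbind, rows)
}

#' Summarise rotational-perturbation errors
#'
#' Takes a long table of Evans Index measurements under controlled
#' rotations (one row per case x axis x angle x mode) and, per
#' (axis, angle) cell, reports the median and IQR of the blind-mode
#' absolute error |EI_perturbed - EI_baseline|, a Wilcoxon signed-rank test
#' of the blind-mode errors against the corrected-mode residuals at the
#' same cell (the corrected-mode residual plays the role of the neutral
#' condition: with a deterministic pipeline the neutral error against
#' itself is identically zero, so the residual discretization noise of the
#' corrected pipeline is the synthetic analogue), and a per-axis
#' monotonicity flag of the median error across increasing |angle|.
#'
#' @param study Data frame with columns `case_id`, `axis`, `angle_deg`,
#'   `mode` (`"blind"` and/or `"corrected"`), `ei` and `ei_baseline`.
#' @return A data frame with columns `axis`, `angle_deg`, `median_abs_err`,
#'   `iqr`, `W`, `p` and `monotone_axis`.
#' @export
perturbation_report <- function(study) {
  need <- c("case_id", "axis", "angle_deg", "mode", "ei", "ei_baseline")
  if (!all(need %in% names(study)))
    stop("study table must have columns: ", paste(need, collapse = ", "))
  study$abs_err <- abs(study$ei - study$ei_baseline)
  blind <- study[study$mode == "blind", ]
  corr <- study[study$mode == "corrected", ]
  if (nrow(blind) == 0) stop("no blind-mode rows in study table")
  cells <- unique(blind[, c("axis", "angle_deg")])
  cells <- cells[order(cells$axis, cells$angle_deg), ]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    ax <- cells$axis[i]; ang <- cells$angle_deg[i]
    bcell <- blind[blind$axis == ax & blind$angle_deg == ang, ]
    bcell <- bcell[order(bcell$case_id), ]
    W <- NA_real_; p <- NA_real_
    ccell <- corr[corr$axis == ax & corr$angle_deg == ang, ]
    if (nrow(ccell) == nrow(bcell) && nrow(ccell) > 0) {
      ccell <- ccell[order(ccell$case_id), ]
      if (any(bcell$abs_err != ccell$abs_err)) {
        wt <- wilcoxon_signed_rank(bcell$abs_err, ccell$abs_err)
        W <- wt$statistic; p <- wt$p_two_sided
      }
    }
    data.frame(axis = ax, angle_deg = ang,
               median_abs_err = stats::median(bcell$abs_err),
               iqr = stats::IQR(bcell$abs_err), W = W, p = p)
  }))
  # monotonicity of median error in |angle|, pooling the two signs
  out$monotone_axis <- NA
  for (ax in unique(out$axis)) {
    sub <- blind[blind$axis == ax, ]
    med <- tapply(sub$abs_err, abs(sub$angle_deg), stats::median)
    med <- med[order(as.numeric(names(med)))]
    out$monotone_axis[out$axis == ax] <- all(diff(med) >= 0)
  }
  rownames(out) <- NULL
  out
}
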