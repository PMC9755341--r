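# Inter- and intra-rater agreement statistics, implemented from their
# defining formulas: two-way ANOVA intraclass correlation with F-based
# confidence limits, Fleiss' kappa with a subject-resampling bootstrap CI,
# pairwise Cohen's kappa, Spearman rank correlation with the t
# approximation, Pearson chi-square on 2x2 proportion tables, and the
# interpretive band systems used in the nuclear-cardiology literature.

check_ratings <- function(mat, min_rows = 2L) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (nrow(mat) < min_rows || ncol(mat) < 2L) {
    stop_mibg("mibg_argument",
              "ratings must have >= %d subjects and >= 2 raters", min_rows)
  }
  if (anyNA(mat)) {
    stop_mibg("mibg_argument", "ratings must not contain missing cells")
  }
  mat
}

#' Intraclass correlation coefficient (two-way random effects, single rater)
#'
#' Computes the ICC from the two-way ANOVA mean squares.  The default form
#' is absolute agreement, ICC(A,1); `type = "consistency"` gives ICC(C,1).
#' 95% confidence limits use the F-distribution method (Satterthwaite
#' degrees of freedom for the absolute-agreement form).
#'
#' @param mat Numeric subjects x raters matrix (no missing cells).
#' @param type `"agreement"` (default) or `"consistency"`.
#' @param conf Confidence level (default 0.95).
#' @return List with `estimate`, `ci_low`, `ci_high`, `label`, `type`,
#'   and the mean squares `ms`.
#' @export
icc <- function(mat, type = c("agreement", "consistency"), conf = 0.95) {
  type <- match.arg(type)
  mat <- check_ratings(mat)
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  rm_ <- rowMeans(mat); cm_ <- colMeans(mat)
  ss_total <- sum((mat - grand)^2)
  ss_rows <- k * sum((rm_ - grand)^2)
  ss_cols <- n * sum((cm_ - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (ss_total <= .Machine$double.eps * max(1, abs(grand))) {
    stop_mibg("mibg_degenerate", "zero total variance: ICC undefined")
  }
  alpha <- 1 - conf
  if (type == "consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    f_obs <- msr / mse
    fl <- f_obs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f_obs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    if (mse <= 0 && msc <= 0) {
      lo <- hi <- est # perfect-agreement degenerate case
    } else {
      a <- (k * est) / (n * (1 - est))
      b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
      if (!is.finite(a) || !is.finite(b)) {
        lo <- hi <- est
      } else {
        v <- (a * msc + b * mse)^2 /
          ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
        fstar <- stats::qf(1 - alpha / 2, n - 1, v)
        fstar2 <- stats::qf(1 - alpha / 2, v, n - 1)
        lo <- n * (msr - fstar * mse) /
          (fstar * (k * msc + (k * n - k - n) * mse) + n * msr)
        hi <- n * (fstar2 * msr - mse) /
          (k * msc + (k * n - k - n) * mse + n * fstar2 * msr)
      }
    }
  }
  est <- min(1, max(-1, est))
  lo <- min(est, max(-1, lo))
  hi <- max(est, min(1, hi))
  list(estimate = est, ci_low = lo, ci_high = hi,
       label = interpret_agreement("icc", est), type = type,
       ms = c(msr = msr, msc = msc, mse = mse))
}

fleiss_point <- function(mat, levels) {
  n <- nrow(mat); k <- ncol(mat)
  counts <- vapply(levels, function(l) rowSums(mat == l), numeric(n))
  if (n == 1L) counts <- matrix(counts, nrow = 1L)
  p_i <- (rowSums(counts^2) - k) / (k * (k - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(counts) / (n * k)
  pe <- sum(p_j^2)
  list(p_bar = p_bar, pe = pe,
       kappa = if (pe >= 1 - 1e-12) NA_real_ else (p_bar - pe) / (1 - pe))
}

#' Fleiss' kappa with a bootstrap confidence interval
#'
#' Chance-corrected agreement for `n` subjects each rated by the same `k`
#' raters into mutually exclusive categories:
#' `kappa = (P_bar - Pe_bar) / (1 - Pe_bar)`.  The 95% CI resamples
#' subjects with replacement (the asymptotic variance is valid only under
#' the null hypothesis, so a bootstrap is used instead).
#'
#' @param mat Subjects x raters matrix of category labels (any atomic type).
#' @param B Number of bootstrap resamples (default 2000; `0` skips the CI).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for the bootstrap resampling (default 1).
#' @return List with `estimate`, `ci_low`, `ci_high`, `label`, and
#'   `degenerate` (`TRUE` when every rating falls in one category, so the
#'   expected agreement is 1 and kappa is undefined).
#' @export
fleiss_kappa <- function(mat, B = 2000L, conf = 0.95, seed = 1L) {
  mat <- check_ratings(mat)
  levels <- sort(unique(as.vector(mat)))
  pt <- fleiss_point(mat, levels)
  if (is.na(pt$kappa)) {
    return(list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                label = NA_character_, degenerate = TRUE,
                p_bar = pt$p_bar, pe = pt$pe))
  }
  est <- min(1, max(-1, pt$kappa))
  lo <- hi <- NA_real_
  if (B > 0L) {
    n <- nrow(mat)
    boots <- with_seed(derive_seed(seed, 17L), {
      vapply(seq_len(B), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        fleiss_point(mat[idx, , drop = FALSE], levels)$kappa
      }, numeric(1))
    })
    boots <- boots[!is.na(boots)]
    if (length(boots) >= 10L) {
      alpha <- 1 - conf
      qs <- stats::quantile(boots, c(alpha / 2, 1 - alpha / 2),
                            names = FALSE, type = 7)
      lo <- min(est, max(-1, qs[1L]))
      hi <- max(est, min(1, qs[2L]))
    }
  }
  list(estimate = est, ci_low = lo, ci_high = hi,
       label = interpret_agreement("fleiss", est), degenerate = FALSE,
       p_bar = pt$p_bar, pe = pt$pe)
}

#' Cohen's kappa for two raters
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` from the cross-table of the two
#' raters' categorical ratings.
#'
#' @param r1,r2 Equal-length rating vectors (>= 2 subjects), or `r1` may be
#'   a square cross-table with `r2` missing.
#' @return List with `estimate`, `label`, `p_o`, `p_e`, and `degenerate`.
#' @export
cohens_kappa <- function(r1, r2 = NULL) {
  if (is.null(r2)) {
    tab <- as.matrix(r1)
    if (nrow(tab) != ncol(tab)) {
      stop_mibg("mibg_argument", "cross-table must be square")
    }
  } else {
    if (length(r1) != length(r2) || length(r1) < 2L) {
      stop_mibg("mibg_argument",
                "rating vectors must have equal length >= 2")
    }
    lev <- sort(unique(c(as.vector(r1), as.vector(r2))))
    tab <- table(factor(r1, levels = lev), factor(r2, levels = lev))
  }
  n <- sum(tab)
  if (n == 0) stop_mibg("mibg_argument", "empty cross-table")
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1 - 1e-12) {
    return(list(estimate = NA_real_, label = NA_character_,
                p_o = p_o, p_e = p_e, degenerate = TRUE))
  }
  est <- min(1, max(-1, (p_o - p_e) / (1 - p_e)))
  list(estimate = est, label = interpret_agreement("cohen", est),
       p_o = p_o, p_e = p_e, degenerate = FALSE)
}

#' Interpretive bands for agreement statistics
#'
#' Band systems: ICC reliability (< 0.5 poor, 0.5-0.75 moderate, 0.75-0.9
#' good, > 0.9 excellent); Fleiss kappa strength of agreement (<= 0.20
#' poor, 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80 good, 0.81-1.00
#' very good); Cohen kappa (<= 0 none, 0.01-0.20 slight, 0.21-0.40 fair,
#' 0.41-0.60 moderate, 0.61-0.80 substantial, 0.81-1.00 perfect).
#'
#' @param kind `"icc"`, `"fleiss"` or `"cohen"`.
#' @param value Statistic value in `[-1, 1]`.
#' @return A character label.
#' @export
interpret_agreement <- function(kind = c("icc", "fleiss", "cohen"), value) {
  kind <- match.arg(kind)
  if (is.na(value)) return(NA_character_)
  if (value < -1 - 1e-9 || value > 1 + 1e-9) {
    stop_mibg("mibg_argument", "value must lie in [-1, 1]")
  }
  switch(kind,
    icc = {
      if (value < 0.5) "poor"
      else if (value < 0.75) "moderate"
      else if (value <= 0.9) "good"
      else "excellent"
    },
    fleiss = {
      if (value <= 0.20) "poor"
      else if (value <= 0.40) "fair"
      else if (value <= 0.60) "moderate"
      else if (value <= 0.80) "good"
      else "very good"
    },
    cohen = {
      if (value <= 0) "none"
      else if (value <= 0.20) "slight"
      else if (value <= 0.40) "fair"
      else if (value <= 0.60) "moderate"
      else if (value <= 0.80) "substantial"
      else "perfect"
    }
  )
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average ranks (ties averaged); the p-value uses
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom,
#' two-sided.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p`, `n`, and `degenerate` (constant input).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop_mibg("mibg_argument", "need equal-length vectors with n >= 3")
  }
  if (anyNA(x) || anyNA(y)) {
    stop_mibg("mibg_argument", "inputs must not contain NA")
  }
  n <- length(x)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  rho <- sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  rho <- min(1, max(-1, rho))
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n, degenerate = FALSE)
}

#' Pearson chi-square test on a 2x2 proportion table
#'
#' No continuity correction by default (Yates available by flag); the
#' p-value comes from the chi-square distribution with 1 degree of freedom.
#'
#' @param tab 2x2 nonnegative integer matrix (rows = groups/raters,
#'   columns = categories); all margins must be positive.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return List with `statistic`, `p`, `df`.
#' @export
chi_square_2x2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) || any(tab != floor(tab))) {
    stop_mibg("mibg_argument", "need a 2x2 nonnegative integer table")
  }
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop_mibg("mibg_degenerate", "table has a zero margin")
  }
  expected <- outer(rs, cs) / n
  dev <- abs(tab - expected)
  if (correct) dev <- pmax(0, dev - 0.5)
  stat <- sum(dev^2 / expected)
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
       df = 1L)
}

#' McNemar test on paired 2x2 classifications
#'
#' Paired-design alternative to [chi_square_2x2()] for two raters
#' classifying the same subjects; provided for completeness and not used in
#' the replication pipeline, which follows the unpaired chi-square design.
#'
#' @param tab 2x2 cross-table of paired classifications.
#' @param correct Continuity correction (default `TRUE`).
#' @return List with `statistic`, `p`, `df`.
#' @export
mcnemar_2x2 <- function(tab, correct = TRUE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0)) {
    stop_mibg("mibg_argument", "need a 2x2 nonnegative table")
  }
  b <- tab[1L, 2L]; c <- tab[2L, 1L]
  if (b + c == 0) {
    stop_mibg("mibg_degenerate", "no discordant pairs")
  }
  num <- if (correct) (abs(b - c) - 1)^2 else (b - c)^2
  stat <- max(0, num) / (b + c)
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
       df = 1L)
}
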