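# Agreement statistics: exact Wilcoxon signed-rank (midranks under ties,
# exact null by convolution), Spearman's rho, and ICC(A,1) -- the two-way
# model, single-measurement, absolute-agreement intraclass correlation.

.signed_rank_dist <- function(ranks2) {
  # exact null pmf of 2*W+ by convolution over sign assignments
  S2 <- sum(ranks2)
  p <- numeric(S2 + 1)
  p[1] <- 1
  for (g in ranks2) {
    shifted <- c(numeric(g), p[seq_len(S2 + 1 - g)])
    p <- (p + shifted) / 2
  }
  p
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test of symmetric paired differences. For `n <= exact_cutoff`
#' nonzero differences the null distribution of the rank sum is computed
#' exactly by convolution over all sign assignments, with midranks for tied
#' magnitudes (unlike the classical exact tables, this stays exact under
#' ties). Larger samples use the normal approximation with tie correction
#' and continuity correction.
#'
#' @param a First measurement per subject, or precomputed differences when
#'   `b` is `NULL`.
#' @param b Second measurement per subject (paired with `a`).
#' @param exact_cutoff Largest n for which the exact distribution is used.
#' @param zero_handling `"wilcoxon"` drops zero differences before ranking;
#'   `"pratt"` ranks them jointly and then discards their ranks.
#' @return A `frac_htest`: `statistic` (W+, sum of positive ranks),
#'   `w_minus`, `p.value`, `n` (nonzero differences), `exact`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(a, b = NULL, exact_cutoff = 25,
                                 zero_handling = c("wilcoxon", "pratt")) {
  zero_handling <- match.arg(zero_handling)
  d <- if (is.null(b)) as.numeric(a) else as.numeric(a) - as.numeric(b)
  if (length(d) < 1 || any(!is.finite(d))) .stop_invalid("differences must be finite")
  if (all(d == 0)) {
    warn("all paired differences are zero; test is degenerate")
    return(structure(list(statistic = 0, w_minus = 0, p.value = NA_real_,
                          n = 0L, exact = NA, degenerate = TRUE,
                          method = "Wilcoxon signed-rank"),
                     class = "frac_htest"))
  }
  if (zero_handling == "wilcoxon") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    keep <- d != 0
    r <- r_all[keep]
    d <- d[keep]
  }
  n <- length(d)
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  S <- sum(r)
  exact <- n <= exact_cutoff
  if (exact) {
    ranks2 <- as.integer(round(2 * r))
    pmf <- .signed_rank_dist(ranks2)
    w2 <- as.integer(round(2 * w_plus))
    S2 <- sum(ranks2)
    lo <- min(w2, S2 - w2); hi <- max(w2, S2 - w2)
    p <- sum(pmf[seq_len(lo + 1)]) + sum(pmf[(hi + 1):(S2 + 1)]) -
      if (lo == hi) pmf[lo + 1] else 0
    p <- min(1, p)
  } else {
    mu <- S / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sigma
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(statistic = w_plus, w_minus = w_minus, p.value = p, n = n,
                 exact = exact, degenerate = FALSE,
                 method = paste0("Wilcoxon signed-rank (",
                                 if (exact) "exact" else "normal approximation",
                                 ", zeros: ", zero_handling, ")")),
            class = "frac_htest")
}

#' Spearman's rank correlation
#'
#' Pearson correlation of midranks (tie-safe).
#'
#' @param a,b Paired numeric vectors.
#' @return A `frac_htest` with `statistic` = rho.
#' @export
spearman_rho <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 2)
    .stop_invalid("need two paired vectors of length >= 2")
  ra <- rank(a); rb <- rank(b)
  if (var(ra) == 0 || var(rb) == 0) {
    warn("constant ranks: correlation undefined")
    rho <- NA_real_
  } else rho <- sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  structure(list(statistic = rho, p.value = NA_real_, n = length(a),
                 exact = NA, degenerate = is.na(rho),
                 method = "Spearman rank correlation"),
            class = "frac_htest")
}

#' @export
print.frac_htest <- function(x, ...) {
  cat("<", x$method, "> statistic = ", format(x$statistic),
      if (!is.na(x$p.value)) paste0(", p = ", format(x$p.value)) else "",
      ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.frac_htest <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value, n = x$n,
         method = x$method)
}

#' Intraclass correlation ICC(A,1)
#'
#' Two-way model, single measurements, absolute agreement (McGraw-Wong
#' ICC(A,1)), from the two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` for n subjects and k
#' raters. Also reports the mean absolute between-rater difference.
#'
#' @param table n x k numeric matrix or data frame: subjects in rows, raters
#'   in columns, no missing cells.
#' @return A `frac_icc`: `icc`, `abs_mean_diff`, mean squares, `n`, `k`.
#' @export
icc_a1 <- function(table) {
  m <- as.matrix(table)
  if (any(!is.finite(m))) .stop_invalid("rater table has missing cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) .stop_invalid("need at least 2 subjects and 2 raters")
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  sst <- sum((m - grand)^2)
  mse <- (sst - msr * (n - 1) - msc * (k - 1)) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  icc <- if (abs(denom) < 1e-300) {
    warn("zero between-subject variance: ICC undefined")
    NA_real_
  } else (msr - mse) / denom
  pairs <- utils::combn(k, 2)
  amd <- mean(vapply(seq_len(ncol(pairs)), function(j)
    mean(abs(m[, pairs[1, j]] - m[, pairs[2, j]])), 0))
  structure(list(icc = icc, abs_mean_diff = amd, msr = msr, msc = msc,
                 mse = mse, n = n, k = k), class = "frac_icc")
}

#' @export
print.frac_icc <- function(x, ...) {
  cat(sprintf("<ICC(A,1)> %.4f, absolute mean difference %.3f (n = %d, k = %d)\n",
              x$icc, x$abs_mean_diff, x$n, x$k))
  invisible(x)
}

#' @export
tidy.frac_icc <- function(x, ...) {
  tibble(icc = x$icc, abs_mean_diff = x$abs_mean_diff, n = x$n, k = x$k)
}

#' @export
glance.frac_icc <- function(x, ...) {
  tibble(icc = x$icc, abs_mean_diff = x$abs_mean_diff,
         msr = x$msr, msc = x$msc, mse = x$mse, n = x$n, k = x$k)
}
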