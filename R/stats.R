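#' Coefficient of determination of an ordinary least-squares line
#'
#' R-squared of `y` regressed on `x`. Cohorts with a large mass of
#' zero-difference pairs routinely produce degenerate strata, so a constant
#' response (or constant predictor) is defined to have R-squared 0 rather
#' than NaN, and fewer than 3 points returns NA with a message.
#'
#' @param x numeric predictor (a geometric metric).
#' @param y numeric response (absolute dose differences).
#' @return R-squared in \[0, 1\], or NA for < 3 complete pairs.
#' @export
linear_r2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    message("linear_r2: fewer than 3 points; returning NA")
    return(NA_real_)
  }
  if (stats::var(y) == 0 || stats::var(x) == 0) return(0)
  stats::cor(x, y)^2
}

## Exact null distribution of the positive-rank sum W+ for given ranks:
## dynamic-programming convolution over sign assignments. Ranks may be
## half-integers under midranks, so sums are tracked on a doubled integer
## lattice. Returns P(W+ <= w) and P(W+ >= w).
wplus_exact_tails <- function(ranks, w) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1L)  # counts[s+1] = number of assignments with 2*W+ = s
  counts[1L] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  probs <- counts / sum(counts)
  w2 <- 2 * w
  # tolerate float w on the doubled lattice
  le <- sum(probs[seq_len(total + 1L) - 1L <= w2 + 1e-9])
  ge <- sum(probs[seq_len(total + 1L) - 1L >= w2 - 1e-9])
  c(le = le, ge = ge)
}

#' Two-sided Wilcoxon signed-rank test with zeros retained in ranking
#'
#' Tests whether signed paired differences are centered at zero. Contour-QA
#' cohorts put a large point mass exactly at zero (auto-contours used as-is),
#' so zeros are handled by the Pratt method: all absolute differences —
#' zeros included — are midranked together, then zero differences are dropped
#' from the rank sum. Classic zero-dropping would discard most of the sample
#' and overstate significance.
#'
#' With at most `exact_max_n` nonzero differences the null distribution of
#' the positive-rank sum is enumerated exactly over all sign assignments
#' (two-sided p = `min(1, 2 * min(P(W+ <= w), P(W+ >= w)))`); above that, a
#' normal approximation with Pratt zero correction and tie correction is
#' used.
#'
#' @param deltas signed differences (cGy in this package; any unit works).
#' @param exact_max_n largest nonzero count for the exact path (default 15).
#' @return list of class `wilcoxon_signed_result`: `p` (two-sided),
#'   `statistic` (positive-rank sum W+), `n` (total), `n_nonzero`, `method`
#'   (`"exact"`, `"normal"`, or `"all-zero"`).
#' @export
wilcoxon_signed <- function(deltas, exact_max_n = 15) {
  d <- deltas[is.finite(deltas)]
  if (length(d) == 0L) stop("no finite differences supplied")
  nz <- d != 0
  m <- sum(nz)
  if (m == 0L) {
    message("wilcoxon_signed: all differences are zero; p = 1")
    return(structure(list(p = 1, statistic = 0, n = length(d), n_nonzero = 0L,
                          method = "all-zero"),
                     class = "wilcoxon_signed_result"))
  }
  r <- rank(abs(d))           # zeros participate in the ranking (Pratt)
  rnz <- r[nz]
  w <- sum(rnz[d[nz] > 0])
  if (m <= exact_max_n) {
    tails <- wplus_exact_tails(rnz, w)
    p <- min(1, 2 * min(tails))
    method <- "exact"
  } else {
    n_all <- length(d)
    z0 <- n_all - m
    mu <- (n_all * (n_all + 1) - z0 * (z0 + 1)) / 4
    tie_tab <- table(abs(d[nz]))
    sigma2 <- (n_all * (n_all + 1) * (2 * n_all + 1) -
                 z0 * (z0 + 1) * (2 * z0 + 1)) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    zstat <- (w - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(zstat)))
    method <- "normal"
  }
  structure(list(p = p, statistic = w, n = length(d), n_nonzero = m,
                 method = method),
            class = "wilcoxon_signed_result")
}

#' @export
print.wilcoxon_signed_result <- function(x, ...) {
  cat(sprintf("<wilcoxon_signed> W+ = %g, n = %d (%d nonzero), p = %.4g [%s]\n",
              x$statistic, x$n, x$n_nonzero, x$p, x$method))
  invisible(x)
}

#' Express a dose difference as a percentage of the prescription
#'
#' `100 * delta / prescription`; e.g. 200 cGy against a 6996 cGy
#' prescription is about 3 percent (one conventional 212 cGy fraction).
#'
#' @param delta_cgy dose difference in cGy.
#' @param prescription_cgy plan prescription in cGy (> 0).
#' @return percentage.
#' @export
pct_of_prescription <- function(delta_cgy, prescription_cgy) {
  if (any(!is.finite(prescription_cgy)) || any(prescription_cgy <= 0))
    stop("prescription must be a positive dose in cGy")
  100 * delta_cgy / prescription_cgy
}
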