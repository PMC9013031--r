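# Statistical tests used by the concordance analysis: exact Fisher tests on
# 2xk tables (Freeman-Halton enumeration for k = 3), Wilcoxon rank tests
# (exact by dynamic programming for small untied samples, normal
# approximation with tie correction otherwise), and Spearman correlation.
# All p values are two-sided and no multiplicity adjustment is applied.

stat_result <- function(method, statistic, p_value, n, exact, estimate = NULL, notes = NULL) {
  structure(
    list(
      method = method, statistic = statistic, p_value = p_value,
      n = n, exact = exact, estimate = estimate, notes = notes
    ),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf(
    "<stat_result> %s: statistic %s, p = %.4g (%s, n = %s)\n",
    x$method,
    if (is.null(x$statistic)) "-" else format(x$statistic, digits = 4),
    x$p_value,
    if (x$exact) "exact" else "approximate",
    paste(x$n, collapse = "/")
  ))
  invisible(x)
}

#' Exact Fisher test for a 2 x k contingency table (k = 2 or 3)
#'
#' Enumerates every table with the observed margins (the Freeman-Halton
#' extension for 2 x 3) and sums the probabilities of tables no more likely
#' than the observed one — the "sum of probabilities <= observed" two-sided
#' convention, with the usual `1 + 1e-7` relative tolerance on the
#' comparison. Used to compare concordant/discordant counts across sample
#' groups.
#'
#' @param table a 2 x k integer matrix of non-negative counts.
#' @return a `stat_result` with the exact two-sided p value.
#' @examples
#' fisher_exact_rxc(matrix(c(2, 0, 0, 2), nrow = 2))$p_value # 1/3
#' @export
fisher_exact_rxc <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2L || !ncol(table) %in% c(2L, 3L)) {
    stop("table must be 2x2 or 2x3", call. = FALSE)
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    stop("degenerate table: a row or column margin is zero", call. = FALSE)
  }
  N <- sum(table)
  k <- ncol(table)
  # log probability of a table given margins (multivariate hypergeometric)
  log_p <- function(x1) {
    sum(lchoose(cs, x1)) - lchoose(N, rs[1L])
  }
  obs <- log_p(table[1L, ])
  total <- 0
  if (k == 2L) {
    lo <- max(0L, rs[1L] - cs[2L])
    hi <- min(rs[1L], cs[1L])
    for (x11 in lo:hi) {
      lp <- log_p(c(x11, rs[1L] - x11))
      if (lp <= obs + log(1 + 1e-7)) total <- total + exp(lp)
    }
  } else {
    for (x11 in 0:min(rs[1L], cs[1L])) {
      for (x12 in 0:min(rs[1L] - x11, cs[2L])) {
        x13 <- rs[1L] - x11 - x12
        if (x13 > cs[3L]) next
        lp <- log_p(c(x11, x12, x13))
        if (lp <= obs + log(1 + 1e-7)) total <- total + exp(lp)
      }
    }
  }
  stat_result(
    method = if (k == 2L) "Fisher exact 2x2" else "Fisher exact 2x3 (Freeman-Halton)",
    statistic = NULL, p_value = min(total, 1), n = cs, exact = TRUE
  )
}

# Number of subsets S of {1..n} with sum(S) = v, for the signed-rank null.
signrank_counts <- function(n) {
  maxv <- n * (n + 1) / 2
  f <- numeric(maxv + 1L)
  f[1L] <- 1
  for (i in seq_len(n)) {
    for (v in maxv:i) f[v + 1L] <- f[v + 1L] + f[v - i + 1L]
  }
  f
}

# P(U <= u) under the exact Mann-Whitney null. Counts of tables come from
# the standard recurrence c(u; i, j) = c(u - j; i - 1, j) + c(u; i, j - 1)
# (add the largest x-observation or drop the largest y-observation).
mann_whitney_cdf <- function(u, m, n) {
  if (u < 0) return(0)
  u <- min(floor(u), m * n)
  g <- array(0, dim = c(m + 1L, n + 1L, m * n + 1L))
  g[1L, , 1L] <- 1
  for (i in 1:m) {
    for (j in 0:n) {
      for (uu in 0:(i * j)) {
        val <- 0
        if (j >= 1) val <- val + g[i + 1L, j, uu + 1L]
        if (uu - j >= 0) val <- val + g[i, j + 1L, uu - j + 1L]
        g[i + 1L, j + 1L, uu + 1L] <- val
      }
    }
  }
  dist <- g[m + 1L, n + 1L, ]
  sum(dist[seq_len(u + 1L)]) / choose(m + n, m)
}

#' Wilcoxon rank test (rank-sum or signed-rank), two-sided
#'
#' With `paired = FALSE` (the default) runs the Mann-Whitney rank-sum form:
#' exact enumeration of the U null distribution when both samples have at
#' most 25 untied observations, otherwise the normal approximation with
#' continuity and tie corrections. With `paired = TRUE` runs the Wilcoxon
#' signed-rank form (zero differences dropped; exact for n <= 25 without
#' ties). Mirrors the conventional two-sided doubling of the smaller tail.
#'
#' @param x,y numeric samples.
#' @param paired logical.
#' @return a `stat_result`; `statistic` is U (unpaired) or V (paired), and
#'   `estimate` carries the two sample medians.
#' @export
rank_test <- function(x, y, paired = FALSE) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("empty input", call. = FALSE)
  medians <- c(median_x = stats::median(x), median_y = stats::median(y))
  if (paired) {
    if (length(x) != length(y)) stop("paired test requires equal lengths", call. = FALSE)
    d <- x - y
    d <- d[d != 0]
    n <- length(d)
    if (n == 0L) {
      return(stat_result("Wilcoxon signed-rank", statistic = 0, p_value = 1,
        n = length(x), exact = FALSE, estimate = medians,
        notes = "all differences zero"))
    }
    r <- rank(abs(d))
    V <- sum(r[d > 0])
    ties <- any(duplicated(abs(d)))
    if (n <= 25L && !ties) {
      f <- signrank_counts(n)
      tot <- 2^n
      cdf <- function(v) if (v < 0) 0 else sum(f[seq_len(min(v, n * (n + 1) / 2) + 1L)]) / tot
      p <- if (V > n * (n + 1) / 4) 1 - cdf(V - 1) else cdf(V)
      return(stat_result("Wilcoxon signed-rank", V, min(2 * p, 1), n, exact = TRUE, estimate = medians))
    }
    nt <- table(r)
    z <- V - n * (n + 1) / 4
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(nt^3 - nt) / 48)
    z <- (z - sign(z) * 0.5) / sigma
    p <- 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE))
    return(stat_result("Wilcoxon signed-rank (normal approx.)", V, min(p, 1), n,
      exact = FALSE, estimate = medians,
      notes = if (ties) "tie correction applied" else NULL))
  }
  m <- length(x)
  n <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (m <= 25L && n <= 25L && !ties) {
    p <- if (U > m * n / 2) 1 - mann_whitney_cdf(U - 1, m, n) else mann_whitney_cdf(U, m, n)
    return(stat_result("Wilcoxon rank-sum", U, min(2 * p, 1), c(m, n), exact = TRUE, estimate = medians))
  }
  nt <- table(r)
  N <- m + n
  z <- U - m * n / 2
  sigma <- sqrt((m * n / 12) * ((N + 1) - sum(nt^3 - nt) / (N * (N - 1))))
  z <- (z - sign(z) * 0.5) / sigma
  p <- 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE))
  stat_result("Wilcoxon rank-sum (normal approx.)", U, min(p, 1), c(m, n),
    exact = FALSE, estimate = medians,
    notes = if (ties) "tie correction applied" else NULL)
}

#' Spearman rank correlation with a t-distribution p value
#'
#' Average ranks for ties, Pearson correlation of the ranks, and a
#' two-sided p value from `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2
#' degrees of freedom. Constant input is an error (the correlation is
#' undefined).
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return a `stat_result` with `estimate` = rho.
#' @export
spearman_correlation <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input vector", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  stat_result("Spearman rank correlation (t approx.)",
    statistic = rho, p_value = p, n = n, exact = FALSE, estimate = rho)
}
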