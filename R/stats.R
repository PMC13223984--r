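#' Modified z-score outlier detection on paired score differences
#'
#' For two aligned score vectors, computes per-participant absolute
#' differences `diff = |a - b|` and the modified z-score
#' `Zdiff = 0.6745 * (diff - median(diff)) / MAD`, where
#' `MAD = median(|diff - median(diff)|)`. Pairs with `Zdiff > 3` are marked
#' outliers. When the MAD is zero (all differences equal) nothing is
#' excluded and a warning is raised.
#'
#' @param a,b Paired numeric score vectors (pairwise-complete entries only;
#'   pairs with a missing value are never flagged).
#' @return Tibble with `diff`, `zdiff` and logical `outlier` per pair.
#' @examples
#' zdiff_outliers(c(1, 2, 3, 4), c(1.1, 2, 3.2, 9))
#' @export
zdiff_outliers <- function(a, b) {
  if (length(a) != length(b)) stop("score vectors must be aligned")
  d <- abs(a - b)
  ok <- !is.na(d)
  med <- stats::median(d[ok])
  mad_ <- stats::median(abs(d[ok] - med))
  z <- rep(NA_real_, length(d))
  if (isTRUE(mad_ == 0)) {
    warning("zero MAD of score differences; no outliers excluded")
    z[ok] <- 0
  } else {
    z[ok] <- 0.6745 * (d[ok] - med) / mad_
  }
  tibble::tibble(diff = d, zdiff = z, outlier = !is.na(z) & z > 3)
}

#' Intraclass correlation ICC(3,1)
#'
#' Two-way mixed-effects, consistency, single-measure intraclass
#' correlation between paired measurements, computed from the two-way
#' ANOVA decomposition: with n subjects and k = 2 measurements,
#' `r = (MSR - MSE) / (MSR + (k - 1) * MSE)` where MSR is the between-
#' subject mean square and MSE the residual mean square after removing the
#' measurement (column) effect. The p value comes from `F = MSR / MSE`
#' with (n - 1, (n - 1)(k - 1)) degrees of freedom.
#'
#' @param x,y Paired measurement vectors (repetition 1 and 2). Incomplete
#'   pairs are dropped.
#' @return Tibble with `r`, `p`, `n`, `df1`, `df2`.
#' @export
icc31 <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("ICC needs at least 3 complete pairs")
  k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr <= 0 && mse <= 0) stop("zero variance; ICC undefined")
  r <- (msr - mse) / (msr + (k - 1) * mse)
  f <- msr / mse
  p <- stats::pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  tibble::tibble(r = r, p = p, n = n, df1 = n - 1, df2 = (n - 1) * (k - 1))
}

#' Spearman rank correlation with p value
#'
#' Pearson correlation of mid-ranks (ties averaged). For n <= 9 the p value
#' is exact, from full enumeration of rank permutations; otherwise it uses
#' the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2
#' degrees of freedom (two-sided).
#'
#' @param x,y Paired vectors; incomplete pairs dropped.
#' @return Tibble with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("Spearman correlation needs at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("constant vector; Spearman correlation undefined")
  }
  rho <- stats::cor(rx, ry)
  p <- if (n <= 9) {
    spearman_exact_p(rx, ry)
  } else if (abs(rho) >= 1) {
    0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
  }
  tibble::tibble(rho = rho, p = min(p, 1), n = n)
}

# exact two-sided permutation p for |rho| via full enumeration (n <= 9)
spearman_exact_p <- function(rx, ry) {
  n <- length(rx)
  perms <- permutations_of(n)
  obs <- abs(stats::cor(rx, ry))
  ry_c <- ry - mean(ry)
  rx_c <- rx - mean(rx)
  denom <- (n - 1) * stats::sd(rx) * stats::sd(ry)
  vals <- as.numeric(matrix(ry_c[perms], nrow(perms)) %*% rx_c) / denom
  mean(abs(vals) >= obs - 1e-12)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * nrow(sub) + 1L):(i * nrow(sub))
    out[rows, 1L] <- i
    rest <- setdiff(seq_len(n), i)
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Cohen interpretation of a correlation coefficient
#'
#' Magnitude bands 0.1 / 0.3 / 0.5 for small / medium / large.
#'
#' @param r Correlation coefficient(s).
#' @return Character: `"small"`, `"medium"` or `"large"`.
#' @export
cohen_label <- function(r) {
  a <- abs(r)
  dplyr::case_when(a >= 0.5 ~ "large", a >= 0.3 ~ "medium", TRUE ~ "small")
}
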