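u_statistic <- function(x, y) {
  # U for x: number of (x_i, y_j) pairs with x_i > y_j, ties counting 1/2
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

#' Mann-Whitney U test
#'
#' For combined sample sizes up to \code{exact_limit} the null distribution of
#' U is obtained by exact enumeration of all ways to assign the pooled values
#' to the two groups, which handles ties correctly; above that, the normal
#' approximation with the standard tie correction is used. The two-sided
#' p-value is the doubled smaller exact tail, capped at 1.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_limit switch to the normal approximation when
#'   \code{length(x) + length(y)} exceeds this; default 12.
#' @return list with \code{U} (for \code{x}) and two-sided \code{p}.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 12) {
  if (!is.numeric(x) || !is.numeric(y)) stop("x and y must be numeric")
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  u <- u_statistic(x, y)
  if (n <= exact_limit) {
    pooled <- c(x, y)
    idx <- utils::combn(n, n1)
    us <- apply(idx, 2, function(ii) u_statistic(pooled[ii], pooled[-ii]))
    eps <- 1e-9
    p_lo <- mean(us <= u + eps)
    p_hi <- mean(us >= u - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    ties <- table(c(x, y))
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(list(U = u, p = 1))
    z <- (u - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = u, p = p)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the standard rule: the sum of hypergeometric
#' probabilities (margins fixed) of all tables at most as probable as the
#' observed one. The reported odds ratio is the sample odds ratio
#' \eqn{ad/bc} (not the conditional MLE).
#'
#' @param tab 2x2 matrix of non-negative integers with positive row and
#'   column margins.
#' @return list with \code{odds_ratio} and two-sided \code{p}.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) stop("entries must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all row and column margins must be positive")
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  orr <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = orr, p = min(1, p))
}

sem <- function(x) stats::sd(x) / sqrt(length(x))
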