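# Nonparametric multi-group tests, implemented from the rank formulas so
# they can be checked against independent references: tie-corrected
# Kruskal-Wallis, two-tailed Dunn's test with Bonferroni correction, and the
# Mann-Whitney test with an exact branch for small tie-free samples.

rank_ties <- function(x) {
  r <- rank(x)
  t <- table(x)
  list(ranks = r, tie_term = sum(t^3 - t))
}

#' Kruskal-Wallis rank sum test
#'
#' Tie-corrected H statistic with a chi-squared reference distribution on
#' k - 1 degrees of freedom. H is defined as 0 (p = 1) when all pooled values
#' are equal.
#'
#' @param groups list of k >= 2 nonempty numeric vectors, or a numeric vector
#'   with `g` giving group labels.
#' @param g optional group labels when `groups` is a vector.
#' @return list(statistic, df, p.value, n) of class `smith_test`.
#' @export
kruskal_wallis <- function(groups, g = NULL) {
  if (!is.list(groups)) groups <- split(groups, g)
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  if (any(lengths(groups) == 0)) stop("empty group")
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  rt <- rank_ties(x)
  tie_corr <- 1 - rt$tie_term / (N^3 - N)
  if (!is.finite(tie_corr) || tie_corr <= 0) {
    out <- list(statistic = 0, df = k - 1, p.value = 1, n = N)
    class(out) <- "smith_test"
    return(out)
  }
  idx <- rep(seq_len(k), lengths(groups))
  Ri <- tapply(rt$ranks, idx, sum)
  ni <- lengths(groups)
  H <- (12 / (N * (N + 1)) * sum(Ri^2 / ni) - 3 * (N + 1)) / tie_corr
  out <- list(statistic = as.numeric(H), df = k - 1,
              p.value = pchisq(H, df = k - 1, lower.tail = FALSE), n = N)
  class(out) <- "smith_test"
  out
}

#' @export
print.smith_test <- function(x, ...) {
  cat(sprintf("statistic = %.6g, df = %s, p = %.6g (n = %d)\n",
              x$statistic, if (is.null(x$df)) "-" else x$df, x$p.value, x$n))
  invisible(x)
}

#' Dunn's post-hoc test
#'
#' Pairwise z statistics on pooled mean ranks with the tie-corrected standard
#' error, two-tailed normal p-values, and Bonferroni correction over all
#' k(k-1)/2 pairs (capped at 1).
#'
#' @param groups list of named numeric vectors (or vector + `g` labels).
#' @param g optional group labels.
#' @return data.frame(group1, group2, z, p.value, p.adjusted).
#' @export
dunn_test <- function(groups, g = NULL) {
  if (!is.list(groups)) groups <- split(groups, g)
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  rt <- rank_ties(x)
  idx <- rep(seq_len(k), lengths(groups))
  mean_rank <- tapply(rt$ranks, idx, mean)
  ni <- lengths(groups)
  var_term <- N * (N + 1) / 12 - rt$tie_term / (12 * (N - 1))
  m <- k * (k - 1) / 2
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(var_term * (1 / ni[i] + 1 / ni[j]))
      z <- if (se > 0) (mean_rank[i] - mean_rank[j]) / se else 0
      p <- 2 * pnorm(-abs(z))
      rows[[length(rows) + 1]] <- data.frame(
        group1 = names(groups)[i], group2 = names(groups)[j],
        z = as.numeric(z), p.value = p, p.adjusted = min(1, m * p),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Reports W = number of (x, y) pairs with x > y (+ 1/2 per tie), the
#' convention of the standard rank-sum W for the first sample. The p-value is
#' exact (distribution of W under permutation) for tie-free data with
#' n_x * n_y <= 400, otherwise a normal approximation with tie and continuity
#' corrections.
#'
#' @param x,y numeric samples.
#' @param alternative "two.sided", "less" (x shifted below y) or "greater".
#' @param exact force (TRUE) or forbid (FALSE) the exact branch; NULL (the
#'   default) applies the n_x * n_y <= 400, tie-free rule.
#' @return list(statistic = W, p.value, n) of class `smith_test`.
#' @export
mann_whitney <- function(x, y,
                         alternative = c("two.sided", "less", "greater"),
                         exact = NULL) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(pooled))
  use_exact <- if (is.null(exact)) (nx * ny <= 400 && !ties) else isTRUE(exact)
  if (use_exact && !ties) {
    p <- switch(alternative,
      less = pwilcox(W, nx, ny),
      greater = pwilcox(W - 1, nx, ny, lower.tail = FALSE),
      two.sided = {
        if (W > nx * ny / 2) {
          min(1, 2 * pwilcox(W - 1, nx, ny, lower.tail = FALSE))
        } else {
          min(1, 2 * pwilcox(W, nx, ny))
        }
      })
  } else {
    N <- nx + ny
    t <- table(pooled)
    sigma2 <- (nx * ny / 12) * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
    mu <- nx * ny / 2
    if (sigma2 <= 0) {
      p <- 1
    } else {
      cc <- 0.5  # continuity correction
      p <- switch(alternative,
        less = pnorm((W - mu + cc) / sqrt(sigma2)),
        greater = pnorm((W - mu - cc) / sqrt(sigma2), lower.tail = FALSE),
        two.sided = {
          z <- (W - mu - sign(W - mu) * cc) / sqrt(sigma2)
          min(1, 2 * pnorm(-abs(z)))
        })
    }
  }
  out <- list(statistic = as.numeric(W), df = NULL, p.value = as.numeric(p),
              n = nx + ny)
  class(out) <- "smith_test"
  out
}
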