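# Independent oracles used to cross-check the implementation.

# Exact two-sided Mann-Whitney p by full enumeration of all
# choose(n1+n2, n1) assignments of the pooled values to group 1.
# Valid for untied data.
enum_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  idx <- utils::combn(n1 + n2, n1)
  u_of <- function(sel) {
    r <- rank(pooled)
    u1 <- sum(r[sel]) - n1 * (n1 + 1) / 2
    min(u1, n1 * n2 - u1)
  }
  u_obs <- u_of(seq_len(n1))
  u_all <- apply(idx, 2L, u_of)
  # two-sided: P(min-U at least as extreme) already covers both tails
  min(1, mean(u_all <= u_obs))
}

# Closed-form Pearson chi-square for a 2x2 table (no correction):
# N (ad - bc)^2 / (r1 r2 c1 c2)
chisq_closed_form <- function(tab) {
  tab <- matrix(as.numeric(tab), 2)  # avoid integer overflow
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c_ + d
  n * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
}

# Naive O(n^3) average-linkage agglomeration over a distance matrix.
# Returns the sorted merge heights.
naive_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  sort(heights)
}

# Equal-variance two-sample t-test p from the textbook formula.
t_test_closed_form <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(t), df = n1 + n2 - 2)
}
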