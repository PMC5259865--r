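# Independent oracles used across tests: deliberately naive implementations
# that never share code with the package internals.

# Pearson correlation straight from the textbook sum formula
pearson_bf <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# maximum nested base-pair count by explicit interval recursion (plain R,
# structure rules: AU/UA/GC/CG/GU/UG, hairpin >= 3 unpaired)
max_pairs_bf <- function(seq) {
  s <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  ok <- function(a, b) paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  n <- length(s)
  memo <- array(NA_integer_, dim = c(n, n))
  f <- function(i, j) {
    if (j - i < 4) return(0L)
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- f(i + 1, j)
    for (k in seq(i + 4, j)) {
      if (ok(s[i], s[k])) {
        inner <- if (k - 1 >= i + 1) f(i + 1, k - 1) else 0L
        right <- if (k + 1 <= j) f(k + 1, j) else 0L
        best <- max(best, 1L + inner + right)
      }
    }
    memo[i, j] <<- best
    best
  }
  if (n < 5) 0L else f(1L, n)
}

# upper-tail hypergeometric by exhaustive enumeration of all C(N, n) draws
hyper_upper_bf <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are the annotated ones
  mean(hits >= k)
}

# BH step-up computed by hand: q_(i) = min_{j>=i} p_(j) * m / j
bh_bf <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(1, q_sorted)
  q
}

# adjusted Rand index from the contingency table (direct formula)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# random RNA string under given base probabilities
random_rna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "U"), n, TRUE, prob = prob), collapse = "")
}

# a small noiseless chase dataset with the given kinetic classes
toy_classes_4 <- function() {
  list(
    kinetic_class(1, half_life = 0.25),
    kinetic_class(2, half_life = 1),
    kinetic_class(3, half_life = 4),
    kinetic_class(4, half_life = 24, long_lived = TRUE)
  )
}
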