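## independent oracles used across tests; deliberately naive implementations

## plug-in mutual information by explicit double loop over a 4 x 4 table
oracle_mi_plugin <- function(b, f) {
  N <- length(b)
  mi <- 0
  for (bb in 1:4) {
    for (ff in 1:4) {
      pj <- sum(b == bb & f == ff) / N
      if (pj == 0) next
      mi <- mi + pj * log2(pj / ((sum(b == bb) / N) * (sum(f == ff) / N)))
    }
  }
  mi
}

oracle_mi_corrected <- function(b, f) {
  oracle_mi_plugin(b, f) - 9 * log2(exp(1)) / (2 * length(b))
}

## exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mwu_exact <- function(x, y) {
  ux <- sum(rank(c(x, y))[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  pooled <- c(x, y)
  n <- length(pooled)
  combos <- combn(n, length(x))
  us <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - length(x) * (length(x) + 1) / 2
  })
  mu <- length(x) * length(y) / 2
  min(1, mean(abs(us - mu) >= abs(ux - mu) - 1e-12))
}

## reference Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

## type-7 percentile by hand (linear interpolation between order statistics)
oracle_percentile <- function(x, prob) {
  s <- sort(x)
  h <- (length(x) - 1) * prob + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(x))] - s[lo])
}

## naive Hamming distance
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

random_dna <- function(n, L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}
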