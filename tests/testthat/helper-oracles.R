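# Naive string-based oracles for every summary statistic, independent of the
# packed-sequence implementation: all arithmetic on plain character matrices.

random_dna <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                                collapse = "")

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# strings: character vector of equal-length sequences
oracle_stats <- function(strings) {
  n <- length(strings)
  mat <- do.call(rbind, strsplit(strings, ""))
  L <- ncol(mat)
  seg <- vapply(seq_len(L), function(j) length(unique(mat[, j])) > 1, TRUE)
  S <- sum(seg)
  an <- sum(1 / seq_len(n - 1))
  pairs <- utils::combn(n, 2)
  pi <- mean(apply(pairs, 2, function(p) sum(mat[p[1], ] != mat[p[2], ])))
  haps <- table(strings)
  h <- length(haps)
  p <- as.numeric(haps) / n
  HA <- (n / (n - 1)) * (1 - sum(p^2))
  HN <- mean(vapply(seq_len(L), function(j) {
    q <- as.numeric(table(mat[, j])) / n
    1 - sum(q^2)
  }, 1))
  list(S = S, theta_w = S / an, pi = pi, h = h, H_A = HA, H_N = HN)
}

# decoded sequences of a panel
panel_strings <- function(panel) {
  vapply(seq_len(panel$n),
         function(j) as.character(matesim:::.packed_from_raw(panel$seq[, j],
                                                             panel$length)),
         "")
}

# decoded copies of one locus for the whole population, engine layout order
pop_locus_strings <- function(pop, class, index = 1) {
  panel_strings(collect_panel(pop, class, index))
}
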