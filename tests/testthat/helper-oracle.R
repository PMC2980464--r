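# Independent naive affine-gap local-alignment oracle: full three-matrix
# DP in plain R, written without reference to the package's engine.  A
# gap of length k costs gap_open + (k - 1) * gap_extend.
sw_oracle <- function(a, b, score_fun, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    E[i + 1, j + 1] <- max(H[i + 1, j] - gap_open, E[i + 1, j] - gap_extend)
    F[i + 1, j + 1] <- max(H[i, j + 1] - gap_open, F[i, j + 1] - gap_extend)
    H[i + 1, j + 1] <- max(0, H[i, j] + score_fun(av[i], bv[j]),
                           E[i + 1, j + 1], F[i + 1, j + 1])
    best <- max(best, H[i + 1, j + 1])
  }
  best
}

rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")
rand_aa <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                    n, replace = TRUE), collapse = "")

# package score of a single pair (0 when no alignment is reported)
pkg_score <- function(a, b, scheme) {
  al <- smith_waterman(seq_set("a", a, alphabet = scheme$mode),
                       seq_set("b", b, alphabet = scheme$mode), scheme)
  if (nrow(al)) al$score else 0L
}

# sprinkle exactly k length-1 indels at random positions
add_indels <- function(s, k) {
  for (i in seq_len(k)) {
    pos <- sample(nchar(s), 1)
    s <- if (stats::runif(1) < 0.5)
      paste0(substr(s, 1, pos), sample(c("A", "C", "G", "T"), 1),
             substr(s, pos + 1, nchar(s)))
    else
      paste0(substr(s, 1, pos - 1), substr(s, pos + 1, nchar(s)))
  }
  s
}
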