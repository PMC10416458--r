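# Independent quadratic-space Smith-Waterman oracle (pure R), used to check
# the package's aligner. Same scoring convention: BLOSUM62, gap of length k
# costs gap_open + k * gap_extend.

sw_oracle_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  B <- env$BLOSUM62
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      d <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1], 0)
      M[i, j] <- d + B[av[i - 1], bv[j - 1]]
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

random_aa <- function(len) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], len,
               replace = TRUE), collapse = "")
}
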