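# Independent brute-force PseTNC: nested loops over every trinucleotide
# pair, sharing no code with pse_tnc(). w fixed at the 0.05 default.
psetnc_oracle <- function(seq, lambda, props) {
  tri <- rownames(props)
  m <- nchar(seq) - 2L
  words <- substring(seq, 1:m, 3:(m + 2L))
  ok <- !grepl("N", words)
  f <- sapply(tri, function(t) sum(words[ok] == t))
  f <- f / sum(f)
  theta <- numeric(lambda)
  for (j in 1:lambda) {
    vals <- c()
    for (i in 1:(m - j)) {
      if (ok[i] && ok[i + j]) {
        d <- props[words[i], ] - props[words[i + j], ]
        vals <- c(vals, mean(d^2))
      }
    }
    theta[j] <- if (length(vals)) mean(vals) else 0
  }
  c(f, 0.05 * theta) / (1 + 0.05 * sum(theta))
}
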