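# Independent brute-force oracles for the signal path: direct double-loop
# evaluation of the causal FIR convolution and the O(N^2) DFT sum.

fir_oracle <- function(b, x) {
  n <- length(x); M <- length(b)
  y <- numeric(n)
  for (i in seq_len(n)) {
    for (k in seq_len(M)) {
      j <- i - (k - 1)
      if (j >= 1) y[i] <- y[i] + b[k] * x[j]
    }
  }
  y
}

dft_oracle <- function(y) {
  n <- length(y)
  vapply(0:(n - 1), function(k) {
    sum(y * exp(-1i * k * (0:(n - 1)) * 2 * pi / n))
  }, complex(1))
}
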