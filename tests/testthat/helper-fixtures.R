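# Small fixtures shared across tests; everything is generated in code.

tiny_connectome <- function(n = 10, seed = 42) {
  generate_synthetic_connectome(n_regions = n, seed = seed,
                                n_modules = 2, length_scale = 20)
}

# deterministic 3-node connectome with hand-set weights/lengths
toy3 <- function() {
  w <- matrix(c(0, 1, 2,
                1, 0, 4,
                2, 4, 0), 3, 3)
  l <- matrix(c(0, 10, 20,
                10, 0, 40,
                20, 40, 0), 3, 3)
  connectome(w, l)
}

single_mass <- function() connectome(matrix(0, 1, 1), matrix(0, 1, 1))

# brute-force LZ76 oracle: literal exhaustive-history definition, O(n^3)
lz76_oracle <- function(bits) {
  n <- length(bits)
  if (n == 0) return(0)
  c <- 0L; pos <- 1L
  while (pos <= n) {
    lmax <- 0L
    q <- 1L
    while (q < pos) {
      k <- 0L
      while (pos + k <= n && bits[q + k] == bits[pos + k]) k <- k + 1L
      if (k > lmax) lmax <- k
      q <- q + 1L
    }
    pos <- pos + lmax + 1L
    c <- c + 1L
  }
  c
}

# all binary vectors of a given length
all_bitstrings <- function(len) {
  if (len == 0) return(list(integer(0)))
  m <- as.matrix(expand.grid(rep(list(0:1), len)))
  lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ]))
}

expect_connectome_valid <- function(c) {
  expect_true(validate_connectome(c))
}
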