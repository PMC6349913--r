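# Shared fixtures, all generated in code.

random_peptides <- function(n, seed = 1) {
  withr::with_seed(seed, {
    apply(matrix(sample(aa_alphabet(), 9 * n, replace = TRUE), n, 9),
          1, paste, collapse = "")
  })
}

# a tiny deterministic study: 3 alleles, a handful of ic50 samples
toy_alleles <- function() {
  m <- planted_binding_model(seed = 11)
  generate_alleles(m, 3, seed = 12)
}

toy_samples <- function(alleles = toy_alleles(), n_per_allele = 20, seed = 13) {
  m <- planted_binding_model(seed = 11)
  generate_samples(alleles, n_per_allele, m, seed = seed)$samples
}

# brute-force AUC over all positive-negative pairs (ties count 1/2)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# classical Spearman d^2 formula (tie-free inputs only)
srcc_d2 <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# plain shared-weight valid convolution, direct triple loop (oracle)
conv_valid_bruteforce <- function(x, kernel, bias = NULL) {
  # x: N x W x C_in, kernel: k x C_in x C_out
  n <- dim(x)[1]; w <- dim(x)[2]; c_in <- dim(x)[3]
  k <- dim(kernel)[1]; c_out <- dim(kernel)[3]
  wp <- w - k + 1
  y <- array(0, c(n, wp, c_out))
  for (i in seq_len(wp)) {
    for (o in seq_len(c_out)) {
      acc <- numeric(n)
      for (t in seq_len(k)) {
        for (c in seq_len(c_in)) {
          acc <- acc + x[, i + t - 1, c] * kernel[t, c, o]
        }
      }
      y[, i, o] <- acc + if (is.null(bias)) 0 else bias[o]
    }
  }
  y
}
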