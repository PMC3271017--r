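# Shared fixtures and independent oracles.

# One model for the whole suite; construction is cheap but there is no point
# rebuilding it per test.
test_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- blosum62_rate_matrix()
    m
  }
})

# Independent matrix-exponential oracle: scaling-and-squaring free Taylor
# series summed to machine convergence. Never uses the eigendecomposition.
expm_series <- function(q, t) {
  a <- diag(nrow(q))
  acc <- a
  k <- 0
  repeat {
    k <- k + 1
    a <- a %*% (q * t) / k
    acc <- acc + a
    if (max(abs(a)) < 1e-18 || k > 500) break
  }
  acc
}

# Independent dyad-count oracle: explicit position-by-position scan with
# substr, no vector tricks.
count_naive <- function(seq, dyad) {
  n <- nchar(seq)
  if (n < 2) return(0L)
  hits <- 0L
  for (i in seq_len(n - 1))
    if (substr(seq, i, i + 1) == dyad) hits <- hits + 1L
  hits
}

random_aa_string <- function(len) paste(sample(aa_alphabet(), len, replace = TRUE), collapse = "")

# Small shared trees
cherry <- function() parse_newick("(A:0.1,B:0.2);")
three_leaf <- function() parse_newick("(A:0.1,(B:0.2,C:0.3):0.05);")

star_tree <- function(n, len) {
  parse_newick(paste0("(", paste(sprintf("t%d:%g", seq_len(n), len), collapse = ","), ");"))
}
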