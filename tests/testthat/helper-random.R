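# random fixtures built in code

random_tt <- function(k, nonconstant = FALSE) {
  repeat {
    out <- sample(0:1, 2^k, replace = TRUE)
    if (!nonconstant || length(unique(out)) > 1L) return(truth_table(out))
  }
}

# a fully random Boolean network: random structure, unconstrained tables
random_network <- function(N, k_max = 3L) {
  nodes <- paste0("g", seq_len(N))
  regs <- stats::setNames(lapply(seq_len(N), function(i) {
    nodes[sample.int(N, sample.int(min(k_max, N), 1L))]
  }), nodes)
  fns <- stats::setNames(lapply(nodes, function(nd) {
    truth_table(sample(0:1, 2^length(regs[[nd]]), replace = TRUE),
                regs[[nd]])
  }), nodes)
  boolean_network(nodes, regs, fns)
}

# naive double-loop sensitivity oracle: per state, count output-changing flips
naive_sensitivity <- function(tt) {
  k <- tt$k
  m <- input_matrix_oracle(k)
  total <- 0
  for (r in seq_len(2^k)) {
    x <- m[r, ]
    for (j in seq_len(k)) {
      y <- x; y[j] <- 1L - y[j]
      if (tt_eval(tt, y) != tt_eval(tt, x)) total <- total + 1
    }
  }
  total / 2^k
}

# independent row-order oracle (expand.grid, not the package helper)
input_matrix_oracle <- function(k) {
  g <- as.matrix(expand.grid(rep(list(0:1), k)))[, k:1, drop = FALSE]
  ord <- order(g %*% 2^((k - 1):0))
  unname(g[ord, , drop = FALSE])
}

# brute-force AUROC: concordant positive-negative pairs (ties count 1/2)
auroc_pairs <- function(score, positive) {
  ps <- score[positive]; ns <- score[!positive]
  tot <- 0
  for (p in ps) for (n in ns)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(ps) * length(ns))
}
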