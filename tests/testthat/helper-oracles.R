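# Independent oracle implementations used to cross-check the package.
# These are deliberately scalar/loop-based re-derivations, not calls into
# the code paths they verify.

# Benjamini-Hochberg step-up, computed from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  q <- numeric(m)
  q[o] <- pmin(adj, 1)
  q
}

# Upper-tail hypergeometric P(X >= O) by direct summation of the pmf
hyper_tail_oracle <- function(O, T_, D, N) {
  if (O > min(D, T_)) stop("invalid configuration")
  sum(stats::dhyper(O:min(D, T_), m = D, n = N - D, k = T_))
}

# CLR scores by a plain double loop over the definition
clr_oracle <- function(mi) {
  g <- nrow(mi)
  z <- matrix(0, g, g)
  for (i in seq_len(g)) {
    row <- mi[i, -i]
    mu <- mean(row)
    s <- sqrt(sum((row - mu)^2) / (length(row) - 1))
    if (s > 0) {
      for (j in seq_len(g)) {
        if (j != i) z[i, j] <- max(0, (mi[i, j] - mu) / s)
      }
    }
  }
  out <- matrix(0, g, g)
  for (i in seq_len(g)) for (j in seq_len(g)) {
    out[i, j] <- sqrt(z[i, j]^2 + z[j, i]^2)
  }
  out
}

# Small balanced two-batch fixture with planted additive/multiplicative
# batch effects and an optional treatment effect
make_batch_fixture <- function(n_probes, n_per_cell, additive = 0,
                               scale = 1, treatment = 0, noise_sd = 0.5,
                               seed = 1) {
  set.seed(seed)
  ns <- 4 * n_per_cell
  batch <- rep(c("A", "B"), each = 2 * n_per_cell)
  grp <- rep(rep(c("day0_control", "diff_control"), each = n_per_cell), 2)
  m <- matrix(stats::rnorm(n_probes * ns, 7, noise_sd), n_probes, ns,
              dimnames = list(sprintf("P%04d", seq_len(n_probes)),
                              sprintf("S%03d", seq_len(ns))))
  m[, grp == "diff_control"] <- m[, grp == "diff_control"] + treatment
  for (g in unique(grp)) {
    idx <- grp == g & batch == "B"
    mu <- rowMeans(m[, idx, drop = FALSE])
    m[, idx] <- mu + (m[, idx] - mu) * scale + additive
  }
  design <- data.frame(sample_id = colnames(m), role = grp, batch = batch,
                       replicate = seq_len(ns), stringsAsFactors = FALSE)
  list(matrix = m, design = design, batch = batch, grp = grp)
}

# Pooled within-cell residual SD of one batch
pooled_residual_sd <- function(m, batch, grp, which_batch) {
  v <- c()
  for (g in unique(grp)) {
    idx <- grp == g & batch == which_batch
    v <- c(v, as.vector(m[, idx, drop = FALSE] -
                          rowMeans(m[, idx, drop = FALSE])))
  }
  stats::sd(v)
}
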