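# Independent oracles used across tests. These deliberately avoid lm(),
# cor() and the package's own fitting code paths.

# brute-force simple OLS by iterative grid refinement of the SSE surface;
# the grid searches in centered coordinates (y = a' + b (x - xbar)) where
# the two parameters are orthogonal, so zooming cannot get trapped in the
# diagonal SSE valley of the raw parametrization
brute_ols <- function(x, y, levels = 60, grid = 21) {
  xbar <- mean(x)
  xc <- x - xbar
  ry <- diff(range(y)); rx <- diff(range(x))
  a_lo <- min(y) - 2 * ry - 1; a_hi <- max(y) + 2 * ry + 1
  smax <- 4 * (ry + 1) / max(rx, 1e-9)
  b_lo <- -smax; b_hi <- smax
  for (lev in seq_len(levels)) {
    a_grid <- seq(a_lo, a_hi, length.out = grid)
    b_grid <- seq(b_lo, b_hi, length.out = grid)
    sse <- outer(a_grid, b_grid, Vectorize(function(a, b) {
      sum((y - a - b * xc)^2)
    }))
    idx <- which(sse == min(sse), arr.ind = TRUE)[1, ]
    a_best <- a_grid[idx[1]]; b_best <- b_grid[idx[2]]
    a_step <- a_grid[2] - a_grid[1]; b_step <- b_grid[2] - b_grid[1]
    a_lo <- a_best - 2 * a_step; a_hi <- a_best + 2 * a_step
    b_lo <- b_best - 2 * b_step; b_hi <- b_best + 2 * b_step
  }
  list(intercept = a_best - b_best * xbar, slope = b_best)
}

# cophenetic distances implied by a linkage_tree: height at which each
# pair of leaves first shares a cluster
tree_cophenetic <- function(tree) {
  labs <- sort(tree$labels)
  n <- length(labs)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (k in seq_along(tree$height)) {
    for (a in tree$members[[k]]$a) {
      for (b in tree$members[[k]]$b) {
        d[a, b] <- d[b, a] <- tree$height[k]
      }
    }
  }
  d
}

# published lipophilicity matrices assembled once for reuse
paper_logp_table <- function() {
  t3 <- tlclipo::load_fixture("table3_retention")
  cbind(tlclipo::load_fixture("table4_theoretical_logp"),
        logP_TLC = t3$logp_tlc)
}

paper_full_table <- function() {
  cbind(paper_logp_table()[, c(11, 1:10)],
        tlclipo::load_fixture("table6_properties"))
}
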