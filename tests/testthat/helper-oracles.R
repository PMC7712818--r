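# Shared fixtures and independent oracles used across the suite.

# canonical type order used by all length-4 vectors
type_tbl <- dilemma_types()

make_counts <- function(n_action, n_total, group = NULL) {
  out <- dilemma_types()
  out$n_action <- n_action
  out$n_total <- n_total
  if (!is.null(group)) out <- tibble::add_column(out, group = group, .before = 1)
  out
}

# reference aggregates (per-type mean action scores out of 6)
high_means <- c(3.00, 2.18, 3.91, 3.21)
low_means <- c(2.46, 1.56, 4.51, 3.60)
both_counts <- function() {
  dplyr::bind_rows(
    counts_from_means(high_means, 174, group = "high"),
    counts_from_means(low_means, 188, group = "low")
  )
}

# independent direct-formula evaluation of G^2: 2 * sum obs*ln(obs/exp)
# over the 8 cells, with 0*ln(0/e) = 0. Deliberately written cell by cell,
# not via the package's likelihood path.
g2_oracle <- function(n_action, n_total, p_action) {
  total <- 0
  for (t in 1:4) {
    if (n_total[t] == 0) next
    obs <- c(n_action[t], n_total[t] - n_action[t])
    expd <- n_total[t] * c(p_action[t], 1 - p_action[t])
    for (cell in 1:2) {
      if (obs[cell] > 0) total <- total + obs[cell] * log(obs[cell] / expd[cell])
    }
  }
  2 * total
}

# independent tree-probability evaluation (hand-transcribed branch sums)
p_action_oracle <- function(C, N, I) {
  c(
    C + (1 - C) * (1 - N) * (1 - I),           # proscriptive / greater
    (1 - C) * (1 - N) * (1 - I),               # proscriptive / smaller
    C + (1 - C) * N + (1 - C) * (1 - N) * (1 - I), # prescriptive / greater
    (1 - C) * N + (1 - C) * (1 - N) * (1 - I)  # prescriptive / smaller
  )
}

# Exhaustive grid-search minimizer of G^2 at 0.001 resolution: a vectorized
# exhaustive 0.01-step pass over the whole cube, then an exhaustive
# 0.001-step pass in a box around the coarse optimum.
grid_g2_min <- function(n_action, n_total) {
  eval_grid <- function(Cs, Ns, Is) {
    g <- expand.grid(C = Cs, N = Ns, I = Is)
    p1 <- g$C + (1 - g$C) * (1 - g$N) * (1 - g$I)
    p2 <- (1 - g$C) * (1 - g$N) * (1 - g$I)
    p3 <- g$C + (1 - g$C) * g$N + p2
    p4 <- (1 - g$C) * g$N + p2
    g2 <- rep(0, nrow(g))
    ps <- list(p1, p2, p3, p4)
    for (t in 1:4) {
      if (n_total[t] == 0) next
      for (cell in 1:2) {
        obs <- if (cell == 1) n_action[t] else n_total[t] - n_action[t]
        if (obs == 0) next
        p <- if (cell == 1) ps[[t]] else 1 - ps[[t]]
        g2 <- g2 + 2 * obs * log(obs / pmax(n_total[t] * p, 1e-300))
      }
    }
    i <- which.min(g2)
    list(par = unlist(g[i, ]), g2 = g2[i])
  }
  s <- seq(0, 1, by = 0.01)
  coarse <- eval_grid(s, s, s)
  box <- function(x) {
    seq(max(x - 0.012, 0), min(x + 0.012, 1), by = 0.001)
  }
  fine <- eval_grid(box(coarse$par[1]), box(coarse$par[2]), box(coarse$par[3]))
  if (fine$g2 <= coarse$g2) fine else coarse
}

# aggregate binomial draw from the tree (fast cohort-free simulation)
simulate_counts <- function(params, n_total) {
  p <- p_action_oracle(params[1], params[2], params[3])
  make_counts(rbinom(4, n_total, p), rep(n_total, 4))
}

expect_silent_tibble <- function(x, n_rows) {
  expect_s3_class(x, "tbl_df")
  expect_equal(nrow(x), n_rows)
}
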