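# Independent oracles used across the suite.

# Brute-force ladder solve: numeric minimisation of the sum of squares with
# general-purpose optimisation, independent of the incidence-matrix solver.
brute_force_ladder <- function(meas, pinned) {
  nodes <- sort(unique(c(meas$node_a, meas$node_b, names(pinned))))
  free <- setdiff(nodes, names(pinned))
  ss <- function(v) {
    val <- setNames(numeric(length(nodes)), nodes)
    val[names(pinned)] <- pinned
    val[free] <- v
    sum((meas$delta - (val[meas$node_b] - val[meas$node_a]))^2)
  }
  fit <- optim(rep(0, length(free)), ss, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  val <- setNames(numeric(length(nodes)), nodes)
  val[names(pinned)] <- pinned
  val[free] <- fit$par
  val
}

# Random connected measurement graph on n nodes (spanning tree + extras).
random_connected_graph <- function(n, extra = 2) {
  ids <- letters[seq_len(n)]
  a <- character(0); b <- character(0)
  for (i in seq_len(n)[-1]) {
    a <- c(a, ids[sample(i - 1, 1)]); b <- c(b, ids[i])
  }
  for (k in seq_len(extra)) {
    p <- sample(ids, 2); a <- c(a, p[1]); b <- c(b, p[2])
  }
  data.frame(node_a = a, node_b = b, delta = rnorm(length(a)),
             stringsAsFactors = FALSE)
}

# Bisection oracle for the two-acid equilibrium on the mass-balance residual.
bisect_equilibrium <- function(delta_pk, c1, c2, base_added, iter = 200) {
  K <- 10^delta_pk
  f <- function(t) {
    a1 <- K * t / (1 + K * t); a2 <- t / (1 + t)
    c1 * a1 + c2 * a2 - base_added
  }
  lo <- 1e-300; hi <- 1e300
  for (i in seq_len(iter)) {
    mid <- sqrt(lo * hi)
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  t <- sqrt(lo * hi)
  c(alpha1 = K * t / (1 + K * t), alpha2 = t / (1 + t))
}
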