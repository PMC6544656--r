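# Independent oracles and small fixture builders used across the suite.

# Brute-force stress centrality: enumerate every shortest path explicitly
# (recursive backtracking over predecessors), count unordered pairs once.
stress_oracle <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0; q <- s
    while (length(q) > 0) {
      v <- q[1]; q <- q[-1]
      for (w in which(adj[v, ] > 0)) if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1; q <- c(q, w)
      }
    }
    D[s, ] <- dist
  }
  all_paths <- function(s, t) {
    if (s == t) return(list(s))
    out <- list()
    for (w in which(adj[, t] > 0))
      if (is.finite(D[s, w]) && D[s, w] + 1 == D[s, t])
        for (pp in all_paths(s, w)) out[[length(out) + 1L]] <- c(pp, t)
    out
  }
  stress <- numeric(n)
  if (n < 3) return(stress)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t])) next
    for (pp in all_paths(s, t)) {
      inner <- setdiff(pp, c(s, t))
      stress[inner] <- stress[inner] + 1
    }
  }
  stress
}

random_graph <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  adj[up] <- as.integer(stats::runif(length(up)) < p)
  adj <- adj + t(adj)
  dimnames(adj) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  adj
}

igraph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

# Exact Mann-Whitney p by enumerating every assignment of ranks to group x
# (no ties assumed), using the standard two-sided doubling convention.
mw_enumeration_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  ux_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) sum(seq_len(nx + ny)[idx]) - nx * (nx + 1) / 2)
  if (ux_obs > nx * ny / 2) p <- 2 * mean(us >= ux_obs) else p <- 2 * mean(us <= ux_obs)
  min(p, 1)
}

# first principal direction of a samples x genes matrix by plain power
# iteration on the sample-sample crossproduct
power_iteration_pc1 <- function(x, iters = 500) {
  m <- x %*% t(x)
  u <- stats::rnorm(nrow(m))
  for (i in seq_len(iters)) {
    u <- m %*% u
    u <- u / sqrt(sum(u^2))
  }
  as.numeric(u)
}

# tiny two-group expression fixture with known structure
toy_expression <- function(seed = 42, n_genes = 12, n_control = 4, n_case = 4) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * (n_control + n_case)) + 8, n_genes,
              dimnames = list(sprintf("g%02d", 1:n_genes),
                              c(sprintf("C%d", 1:n_control),
                                sprintf("T%d", 1:n_case))))
  traits <- data.frame(sample_id = colnames(m),
                       group = rep(c("control", "case"), c(n_control, n_case)),
                       stringsAsFactors = FALSE)
  list(expr = m, traits = traits)
}

# Ct-table fixture builder
make_ct <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(sample_id = r[[1]], target = r[[2]], ct = as.numeric(r[[3]]),
               plate_id = r[[4]], role = r[[5]],
               group = if (length(r) > 5) r[[6]] else NA_character_,
               stringsAsFactors = FALSE)))
}
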