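make_module_fixture <- function(seed = 3) {
  sim <- simulate_expression(expr_sim_config(
    n_genes = 60, n_control = 6, n_case = 6, module_sizes = c(15, 15),
    case_shift_per_module = c(-2, 0), seed = seed))
  a <- adjacency(correlation_matrix(sim$expr), 6)
  me <- module_eigengenes(sim$expr, sim$truth$modules)
  list(sim = sim, adj = a, me = me)
}

test_that("gene module statistics: MM, GS, kIM and normalization", {
  fx <- make_module_fixture()
  st <- gene_module_statistics(fx$sim$expr, fx$sim$truth$modules, fx$me,
                               fx$sim$traits, fx$adj)
  expect_equal(nrow(st), 60)
  expect_true(all(abs(st$MM) <= 1, na.rm = TRUE))
  expect_true(all(abs(st$GS) <= 1))
  expect_true(all(st$kIM_norm >= 0 & st$kIM_norm <= 1, na.rm = TRUE))
  # per module exactly one gene attains kIM_norm = 1
  for (l in 1:2)
    expect_equal(sum(st$kIM_norm[st$module == l] == 1), 1)
  # background genes carry no module stats
  expect_true(all(is.na(st$MM[st$module == 0])))

  # gene identical to its eigengene: MM = 1
  expr <- fx$sim$expr
  expr["gene_0001", ] <- fx$me[, "ME1"]
  st2 <- gene_module_statistics(expr, fx$sim$truth$modules, fx$me,
                                fx$sim$traits, fx$adj)
  expect_equal(st2$MM[st2$gene == "gene_0001"], 1, tolerance = 1e-10)

  # 3-gene module with pairwise adjacency 0.5: each kIM = 1
  a3 <- matrix(0.5, 3, 3); diag(a3) <- 1
  dimnames(a3) <- list(paste0("g", 1:3), paste0("g", 1:3))
  m3 <- matrix(stats::rnorm(3 * 6), 3, dimnames = list(paste0("g", 1:3),
                                                       paste0("s", 1:6)))
  mods3 <- stats::setNames(rep(1L, 3), paste0("g", 1:3))
  me3 <- module_eigengenes(m3, mods3)
  tr3 <- data.frame(sample_id = paste0("s", 1:6),
                    group = rep(c("control", "case"), 3))
  st3 <- gene_module_statistics(m3, mods3, me3, tr3, a3)
  expect_equal(st3$kIM, rep(1, 3))
})

test_that("hub selection uses strict AND thresholds and signed subsets", {
  st <- data.frame(
    gene = c("exact", "neg_hub", "pos_hub", "weak"),
    module = 1L,
    MM = c(0.8, 0.9, 0.95, 0.6),
    GS = c(0.9, -0.7, 0.8, 0.2),
    kIM = 1,
    kIM_norm = c(0.9, 0.6, 0.7, 0.4),
    stringsAsFactors = FALSE)
  sel <- select_hub_genes(st)
  expect_false("exact" %in% sel$hubs$gene)    # MM = 0.8 exactly: excluded
  expect_false("weak" %in% sel$hubs$gene)
  expect_true("neg_hub" %in% sel$down$gene)
  expect_true("pos_hub" %in% sel$up$gene)

  # all below thresholds: both subsets empty
  none <- select_hub_genes(within(st, MM <- 0.1))
  expect_equal(nrow(none$down), 0)
  expect_equal(nrow(none$up), 0)

  # hub set shrinks weakly as any threshold rises
  fx <- make_module_fixture()
  stats_tab <- gene_module_statistics(fx$sim$expr, fx$sim$truth$modules, fx$me,
                                      fx$sim$traits, fx$adj)
  base <- select_hub_genes(stats_tab, 0.5, 0.3, 0.3)$hubs$gene
  for (arg in list(c(0.7, 0.3, 0.3), c(0.5, 0.5, 0.3), c(0.5, 0.3, 0.5))) {
    sub <- select_hub_genes(stats_tab, arg[1], arg[2], arg[3])$hubs$gene
    expect_true(all(sub %in% base))
  }
})

test_that("threshold graph keeps strict super-cutoff edges and isolated nodes", {
  a <- matrix(c(1, 0.3, 0.1, 0.3, 1, 0.25, 0.1, 0.25, 1), 3,
              dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  g <- threshold_graph(a, paste0("g", 1:3), edge_cutoff = 0.2)
  el <- igraph::as_edgelist(g)
  expect_equal(nrow(el), 2)           # edges 1-2 and 2-3 only
  expect_setequal(paste(el[, 1], el[, 2]),
                  c("g1 g2", "g2 g3"))

  # adjacency exactly at the cutoff: no edge; isolated node retained
  a2 <- matrix(c(1, 0.2, 0.2, 1), 2, dimnames = list(c("x", "y"), c("x", "y")))
  g2 <- threshold_graph(a2, c("x", "y"))
  expect_equal(igraph::ecount(g2), 0)
  expect_equal(igraph::vcount(g2), 2)

  # saturated adjacency on 4 nodes: complete graph K4
  a4 <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(igraph::ecount(threshold_graph(a4, letters[1:4])), 6)
})

test_that("stress centrality: path, star and cycle examples", {
  path <- igraph::make_graph(~ A - B, B - C)
  st <- stress_centrality(path)
  expect_equal(st$stress[st$node == "B"], 1)
  expect_equal(st$stress[st$node %in% c("A", "C")], c(0, 0))

  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("n", 1:5)
  st2 <- stress_centrality(star)
  expect_equal(st2$stress[1], 6)      # C(4,2) leaf pairs
  expect_true(all(st2$stress[-1] == 0))

  ring <- igraph::make_ring(4)
  igraph::V(ring)$name <- paste0("r", 1:4)
  st3 <- stress_centrality(ring)
  expect_equal(st3$stress, rep(1, 4))
})

test_that("stress centrality equals the brute-force path-enumeration oracle", {
  set.seed(77)
  for (i in 1:120) {
    n <- sample(3:8, 1)
    adj <- random_graph(n, stats::runif(1, 0.2, 0.8))
    g <- igraph_from_adj(adj)
    st <- stress_centrality(g)
    expect_equal(st$stress, stress_oracle(adj))
    # isomorphism invariance: relabeling permutes stress identically
    perm <- sample(n)
    st_p <- stress_centrality(igraph_from_adj(adj[perm, perm]))
    expect_equal(st_p$stress, st$stress[perm])
  }
})

test_that("network export writes SIF and round-trips GraphML", {
  # empty graph: valid (empty) files
  g0 <- igraph::make_empty_graph(0, directed = FALSE)
  ce0 <- stress_centrality(g0)
  sif0 <- tempfile(fileext = ".sif"); gml0 <- tempfile(fileext = ".graphml")
  export_network(g0, ce0, NULL, sif0, gml0)
  expect_equal(length(readLines(sif0)), 0)
  expect_equal(igraph::vcount(read_network_graphml(gml0)), 0)

  # 3-node toy: SIF holds each unordered edge exactly once
  a <- matrix(c(1, 0.3, 0.1, 0.3, 1, 0.25, 0.1, 0.25, 1), 3,
              dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  g <- threshold_graph(a, paste0("g", 1:3))
  ce <- stress_centrality(g)
  sif <- tempfile(fileext = ".sif"); gml <- tempfile(fileext = ".graphml")
  export_network(g, ce, NULL, sif, gml)
  expect_setequal(readLines(sif), c("g1\tco\tg2", "g2\tco\tg3"))

  # random 30-node graph: GraphML round trip preserves topology and
  # attributes
  set.seed(12)
  adj <- random_graph(30, 0.15) * stats::runif(900, 0.3, 0.9)
  adj <- (adj + t(adj)) / 2; diag(adj) <- 1
  g30 <- threshold_graph(adj, rownames(adj), 0.2)
  ce30 <- stress_centrality(g30)
  export_network(g30, ce30, NULL, sif, gml)
  back <- read_network_graphml(gml)
  expect_equal(igraph::vcount(back), 30)
  expect_equal(igraph::ecount(back), igraph::ecount(g30))
  ord <- match(igraph::V(g30)$name, igraph::V(back)$name)
  expect_equal(igraph::V(back)$stress[ord], ce30$stress)
  expect_equal(igraph::V(back)$degree[ord], ce30$degree)
  m_orig <- igraph::as_adjacency_matrix(g30, attr = "weight", sparse = FALSE)
  m_back <- igraph::as_adjacency_matrix(back, attr = "adjacency", sparse = FALSE)
  expect_equal(m_back[rownames(m_orig), colnames(m_orig)], m_orig,
               tolerance = 1e-6)
})
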