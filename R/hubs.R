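# Per-gene module statistics, hub selection, thresholded module graphs,
# stress centrality, and Cytoscape-compatible export.

#' Per-gene module statistics
#'
#' For every assigned gene: MM (signed Pearson correlation with its module
#' eigengene), GS (signed Pearson correlation with the binary trait
#' indicator), kIM (intramodule connectivity, the sum of adjacency to the
#' other genes of its module) and kIM_norm (kIM divided by the module
#' maximum; defined as 0 in singleton or fully disconnected modules).
#'
#' @param expr genes x samples matrix.
#' @param modules named integer vector gene -> module label (0 = unassigned;
#'   unassigned genes get `NA` MM/kIM).
#' @param eigengenes samples x modules matrix from [module_eigengenes()].
#' @param traits sample traits.
#' @param adjacency adjacency matrix over the same genes.
#' @return data.frame: gene, module, MM, GS, kIM, kIM_norm.
#' @export
gene_module_statistics <- function(expr, modules, eigengenes, traits, adjacency) {
  check_expression_matrix(expr)
  check_traits(traits)
  assert_that(all(names(modules) == rownames(expr)),
              "modules must be named by the expression genes, same order")
  y <- trait_indicator(traits, colnames(expr))
  gs <- as.numeric(stats::cor(t(expr), y))

  mm <- rep(NA_real_, nrow(expr))
  kim <- rep(NA_real_, nrow(expr))
  kim_norm <- rep(NA_real_, nrow(expr))
  for (l in sort(unique(modules[modules > 0]))) {
    genes <- which(modules == l)
    me <- eigengenes[, paste0("ME", l)]
    mm[genes] <- as.numeric(stats::cor(t(expr[genes, , drop = FALSE]), me))
    sub <- adjacency[genes, genes, drop = FALSE]
    diag(sub) <- 0
    k <- rowSums(sub)
    kim[genes] <- k
    kmax <- max(k)
    kim_norm[genes] <- if (kmax > 0) k / kmax else 0
  }
  data.frame(gene = rownames(expr), module = unname(modules),
             MM = mm, GS = gs, kIM = kim, kIM_norm = kim_norm,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select hub genes
#'
#' Hubs satisfy `|MM| > mm_min`, `|GS| > gs_min` and `kIM_norm > kim_min`
#' (all strict). They are split by the sign of GS into a down-in-case
#' (negative) and an up-in-case (positive) subset; within each subset genes
#' are ranked by the mean of `|MM|` and `|GS|`, then by `kIM_norm`, and the
#' top 10 are reported.
#'
#' @param stats a [gene_module_statistics()] table.
#' @param mm_min,gs_min,kim_min strict lower thresholds (defaults 0.8, 0.5,
#'   0.5).
#' @param top_n hubs reported per subset (default 10).
#' @return list with `hubs` (all hubs, ranked, with `subset` column),
#'   `down` and `up` (top-`top_n` per subset).
#' @export
select_hub_genes <- function(stats, mm_min = 0.8, gs_min = 0.5, kim_min = 0.5,
                             top_n = 10) {
  need <- c("gene", "MM", "GS", "kIM_norm")
  assert_that(all(need %in% names(stats)), "stats must come from gene_module_statistics()")
  ok <- !is.na(stats$MM) & !is.na(stats$GS) & !is.na(stats$kIM_norm) &
    abs(stats$MM) > mm_min & abs(stats$GS) > gs_min & stats$kIM_norm > kim_min
  hubs <- stats[ok, , drop = FALSE]
  hubs$subset <- ifelse(hubs$GS < 0, "down", "up")
  hubs$mean_cor <- (abs(hubs$MM) + abs(hubs$GS)) / 2
  hubs <- hubs[order(-hubs$mean_cor, -hubs$kIM_norm), , drop = FALSE]
  rownames(hubs) <- NULL
  list(hubs = hubs,
       down = utils::head(hubs[hubs$subset == "down", , drop = FALSE], top_n),
       up = utils::head(hubs[hubs$subset == "up", , drop = FALSE], top_n))
}

#' Thresholded module graph
#'
#' Undirected simple graph over `module_genes` with an edge wherever
#' adjacency strictly exceeds `edge_cutoff`; isolated nodes are retained and
#' adjacency values are stored as edge weights for export only (shortest
#' paths are hop counts).
#'
#' @param adjacency adjacency matrix.
#' @param module_genes gene IDs to include (subset of the matrix genes).
#' @param edge_cutoff strict adjacency cutoff (default 0.2).
#' @return igraph object with graph attribute `edge_cutoff`.
#' @export
threshold_graph <- function(adjacency, module_genes, edge_cutoff = 0.2) {
  assert_that(all(module_genes %in% rownames(adjacency)),
              "module_genes must be rows of the adjacency matrix")
  a <- adjacency[module_genes, module_genes, drop = FALSE]
  a[a <= edge_cutoff] <- 0
  diag(a) <- 0
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::graph_attr(g, "edge_cutoff") <- edge_cutoff
  g
}

#' Stress centrality
#'
#' For every node v, the number of shortest paths between unordered pairs of
#' other nodes that pass through v (Shimbel's stress). Computed from
#' all-pairs BFS distances and shortest-path counts on the unweighted
#' graph: `sigma_st(v) = sigma_sv * sigma_vt` whenever
#' `d(s,t) = d(s,v) + d(v,t)`. Disconnected pairs contribute nothing;
#' leaves and isolated nodes score 0.
#'
#' @param g igraph object (simple, undirected; weights ignored).
#' @return data.frame: node, stress, degree.
#' @export
stress_centrality <- function(g) {
  assert_that(igraph::is_igraph(g), "g must be an igraph object")
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  deg <- igraph::degree(g)
  if (n == 0)
    return(data.frame(node = character(), stress = numeric(),
                      degree = numeric(), stringsAsFactors = FALSE))
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, as.integer)

  D <- matrix(Inf, n, n)
  S <- matrix(0, n, n)   # shortest-path counts
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); sigma <- rep(0, n)
    dist[s] <- 0; sigma[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.infinite(dist[w])) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
    S[s, ] <- sigma
  }

  stress <- numeric(n)
  for (v in seq_len(n)) {
    on_path <- is.finite(D) & (outer(D[, v], D[v, ], "+") == D)
    cnt <- (S[, v] %o% S[v, ]) * on_path
    cnt[v, ] <- 0; cnt[, v] <- 0
    diag(cnt) <- 0
    stress[v] <- sum(cnt) / 2   # each unordered {s,t} counted once
  }
  data.frame(node = nodes, stress = stress, degree = as.numeric(deg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export a module graph
#'
#' Writes a SIF file (`node TAB "co" TAB node`, one line per unordered
#' edge, isolated nodes as single-field lines) and a GraphML file carrying
#' node attributes `stress`, `degree`, `MM`, `GS` and the adjacency edge
#' weights; [read_network_graphml()] round-trips the GraphML.
#'
#' @param g igraph from [threshold_graph()].
#' @param centrality a [stress_centrality()] table.
#' @param stats a [gene_module_statistics()] table (for MM/GS), or `NULL`.
#' @param sif_path,graphml_path output paths.
#' @return invisibly, the two paths.
#' @export
export_network <- function(g, centrality, stats = NULL,
                           sif_path, graphml_path) {
  nodes <- igraph::V(g)$name
  ce <- centrality[match(nodes, centrality$node), , drop = FALSE]
  igraph::V(g)$stress <- ce$stress
  igraph::V(g)$degree <- ce$degree
  if (!is.null(stats)) {
    st <- stats[match(nodes, stats$gene), , drop = FALSE]
    igraph::V(g)$MM <- st$MM
    igraph::V(g)$GS <- st$GS
  }
  if (is.null(igraph::E(g)$weight)) igraph::E(g)$weight <- rep(1, igraph::ecount(g))
  igraph::E(g)$adjacency <- igraph::E(g)$weight

  el <- igraph::as_edgelist(g)
  sif_lines <- if (nrow(el) > 0) sprintf("%s\tco\t%s", el[, 1], el[, 2]) else character(0)
  isolated <- setdiff(nodes, unique(c(el)))
  sif_lines <- c(sif_lines, isolated)
  tryCatch(writeLines(sif_lines, sif_path),
           error = function(e) stopf("failed writing SIF '%s': %s", sif_path,
                                     conditionMessage(e)))
  tryCatch(igraph::write_graph(g, graphml_path, format = "graphml"),
           error = function(e) stopf("failed writing GraphML '%s': %s",
                                     graphml_path, conditionMessage(e)))
  invisible(c(sif = sif_path, graphml = graphml_path))
}

#' Read back an exported GraphML network
#'
#' @param path GraphML file written by [export_network()].
#' @return igraph object.
#' @export
read_network_graphml <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path)
  igraph::read_graph(path, format = "graphml")
}
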