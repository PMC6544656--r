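test_that("correlation matrix matches hand computation and flags degeneracy", {
  m <- rbind(x = c(1, 2, 3), y = c(1, 2, 4), z = c(3, 2, 1))
  colnames(m) <- paste0("s", 1:3)
  cc <- correlation_matrix(m)
  expect_equal(cc["x", "y"], 0.9820, tolerance = 5e-5)
  expect_equal(cc["x", "z"], -1)
  expect_equal(diag(cc), c(x = 1, y = 1, z = 1))

  dup <- rbind(a = c(1, 5, 2, 8), b = c(1, 5, 2, 8))
  colnames(dup) <- paste0("s", 1:4)
  expect_equal(correlation_matrix(dup)["a", "b"], 1)

  bad <- rbind(flat = rep(1, 4), ok = 1:4)
  colnames(bad) <- paste0("s", 1:4)
  expect_error(correlation_matrix(bad), "flat")
})

test_that("adjacency is the elementwise soft power with unit diagonal", {
  cc <- matrix(c(1, 0.5, -1, 0.5, 1, 0, -1, 0, 1), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  a <- adjacency(cc, beta = 6)
  expect_equal(a["a", "b"], 0.5^6)
  expect_equal(a["a", "c"], 1)       # |cor| = 1 for any beta
  expect_equal(diag(a), c(a = 1, b = 1, c = 1))
  expect_equal(unname(adjacency(cc, 1)), unname(abs(cc)), ignore_attr = TRUE)
  expect_error(adjacency(cc, 0), "beta")
  # monotone: larger |cor| gives larger adjacency at fixed beta
  r <- seq(-1, 1, by = 0.05)
  ord <- order(abs(r))
  for (beta in c(1, 4, 6))
    expect_true(all(diff(abs(r[ord])^beta) >= 0))
})

test_that("TOM identities: pair reduction, 3-clique value, saturation", {
  # isolated pair: TOM equals the adjacency
  a2 <- matrix(c(1, 0.37, 0.37, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(topological_overlap(a2)["a", "b"], 0.37)

  # 3-node clique, all adjacency 0.5: (0.25 + 0.5) / (1 + 1 - 0.5) = 0.5
  a3 <- matrix(0.5, 3, 3); diag(a3) <- 1
  dimnames(a3) <- list(letters[1:3], letters[1:3])
  tom3 <- topological_overlap(a3)
  expect_equal(tom3["a", "b"], 0.5)

  # complete graph with all adjacency 1: TOM all 1
  a1 <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(abs(topological_overlap(a1) - 1) < 1e-12))
})

test_that("TOM is symmetric, bounded and permutation-equivariant", {
  set.seed(5)
  for (i in 1:5) {
    fx <- toy_expression(seed = i, n_genes = 15, n_control = 5, n_case = 5)
    a <- adjacency(correlation_matrix(fx$expr), 6)
    tom <- topological_overlap(a)
    expect_equal(tom, t(tom), tolerance = 1e-12)
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
    perm <- sample(nrow(a))
    expect_equal(topological_overlap(a[perm, perm]), tom[perm, perm],
                 tolerance = 1e-12)
  }
})

test_that("soft-threshold picker recognizes a power-law degree sequence", {
  # degrees from a preferential-attachment-style law give a high fit index
  set.seed(8)
  k <- as.numeric(round(1 / stats::runif(3000)^(1 / 1.8)))  # Pareto tail
  k <- k[k <= 500]
  fit <- revtranslate:::scale_free_fit(k)
  expect_gte(fit$fit, 0.8)
  expect_lt(fit$slope, 0)

  # fallback: pure noise never reaches the target; argmax beta returned
  # with a warning and the full fit table
  fx <- toy_expression(seed = 13, n_genes = 60, n_control = 5, n_case = 5)
  expect_warning(res <- pick_soft_threshold(fx$expr, candidates = c(1, 2),
                                            r2_target = 0.999), "no candidate")
  expect_true(res$beta %in% c(1, 2))
  expect_equal(nrow(res$fit_table), 2)
  expect_true(all(c("beta", "fit", "slope", "mean_k") %in% names(res$fit_table)))
  expect_true(all(diff(res$fit_table$mean_k) <= 0))  # mean k falls with beta
})

test_that("eigengenes are zero-mean, unit-norm, oriented, and PC1-optimal", {
  sim <- simulate_expression(expr_sim_config(
    n_genes = 30, n_control = 6, n_case = 6, module_sizes = c(8, 7),
    case_shift_per_module = c(0, 0), seed = 2))
  me <- module_eigengenes(sim$expr, sim$truth$modules)
  expect_equal(colnames(me), c("ME1", "ME2"))
  for (j in 1:2) {
    expect_lt(abs(mean(me[, j])), 1e-10)
    expect_equal(sum(me[, j]^2), 1, tolerance = 1e-10)
  }
  # orientation: mean correlation with module genes is non-negative
  for (l in 1:2) {
    x <- t(sim$expr[sim$truth$modules == l, ])
    expect_gte(mean(stats::cor(me[, l], x)), 0)
  }
  # maximality against a power-iteration oracle on the standardized
  # submatrix, and against random unit sample-weight vectors
  set.seed(99)
  for (l in 1:2) {
    x <- scale(t(sim$expr[sim$truth$modules == l, ]))
    u_or <- power_iteration_pc1(x)
    expect_gt(abs(stats::cor(me[, l], u_or)), 1 - 1e-6)
    v_me <- sum((t(x) %*% me[, l])^2)
    for (i in 1:50) {
      w <- stats::rnorm(nrow(x)); w <- w / sqrt(sum(w^2))
      expect_gte(v_me + 1e-8, sum((t(x) %*% w)^2))
    }
  }
})

test_that("module detection separates planted blocks (ARI = 1)", {
  skip_if_not_installed("mclust")
  # two factor-driven blocks, enough samples that background TOM is far
  # from the blocks' similarity
  sim <- simulate_expression(expr_sim_config(
    n_genes = 60, n_control = 20, n_case = 20, module_sizes = c(30, 30),
    module_gene_loading_range = c(0.85, 0.95),
    case_shift_per_module = c(0, 0), seed = 4))
  tom <- topological_overlap(adjacency(correlation_matrix(sim$expr), 6))
  det <- detect_modules(tom, min_module_size = 10, cut_height = 0.99,
                        merge_cut_height = 0.25, expr = sim$expr)
  expect_equal(length(unique(det$modules[det$modules > 0])), 2)
  expect_equal(mclust::adjustedRandIndex(det$modules, sim$truth$modules), 1)
})

test_that("independent genes end up unassigned", {
  set.seed(17)
  m <- matrix(stats::rnorm(100 * 30), 100,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:30)))
  tom <- topological_overlap(adjacency(correlation_matrix(m), 6))
  expect_warning(
    det <- detect_modules(tom, min_module_size = 10, cut_height = 0.9,
                          merge_cut_height = 0.25, expr = m),
    "unassigned")
  expect_true(all(det$modules == 0))
})

test_that("blocks sharing a latent factor merge by eigengene similarity", {
  set.seed(23)
  n_s <- 30
  e1 <- stats::rnorm(n_s)
  e2 <- (e1 + 0.5 * stats::rnorm(n_s)) / sqrt(1.25)  # cor ~ 0.89
  gene <- function(f) 0.95 * f + sqrt(1 - 0.95^2) * stats::rnorm(n_s)
  m <- rbind(t(replicate(15, gene(e1))), t(replicate(15, gene(e2))))
  dimnames(m) <- list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:n_s))
  tom <- topological_overlap(adjacency(correlation_matrix(m), 6))
  # pick a cut height at which the two blocks are still separate clusters
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cut_h <- mean(rev(hc$height)[1:2])   # between the top two merge heights
  det <- detect_modules(tom, min_module_size = 10, cut_height = cut_h,
                        merge_cut_height = 0.25, expr = m)
  expect_equal(length(unique(det$modules[det$modules > 0])), 1)
  expect_gte(det$n_merged, 1)
})

test_that("correlation p-values follow the Student-t formula", {
  expect_equal(cor_pvalue_student(0, 10), 1)
  expect_equal(round(cor_pvalue_student(0.7429, 12), 4), 0.0056)
  expect_equal(cor_pvalue_student(0.6, 15), cor_pvalue_student(-0.6, 15))
  expect_equal(cor_pvalue_student(1, 5), 0)
  # cross-check against cor.test on actual data
  set.seed(6)
  x <- stats::rnorm(20); y <- x + stats::rnorm(20)
  expect_equal(cor_pvalue_student(stats::cor(x, y), 20),
               stats::cor.test(x, y)$p.value, tolerance = 1e-12)
})

test_that("module-trait table scores eigengenes against the trait", {
  fx <- toy_expression(seed = 55, n_genes = 10, n_control = 5, n_case = 5)
  y <- as.numeric(fx$traits$group == "case")
  # an eigengene equal to the standardized trait indicator: |r| = 1, top
  me <- cbind(ME1 = scale(y)[, 1] / sqrt(sum(scale(y)[, 1]^2)),
              ME2 = scale(stats::rnorm(10))[, 1])
  rownames(me) <- fx$traits$sample_id
  mt <- module_trait_table(me, fx$traits)
  expect_equal(abs(mt$table$r[1]), 1, tolerance = 1e-10)
  expect_equal(mt$top_module, "ME1")
  expect_equal(mt$n_modules, 2)
  expect_error(module_trait_table(me, within(fx$traits, group <- "case")),
               "both groups")
})

test_that("a strongly shifted planted module is recovered as top module", {
  # strong-signal sanity recovery: with a 3-SD latent shift the eigengene
  # test has near-unit power, so the planted module must surface as the
  # significant top module in almost every seed
  hits <- vapply(1:10, function(s) {
    sim <- simulate_expression(expr_sim_config(
      n_genes = 400, module_sizes = c(40, 40),
      case_shift_per_module = c(-3, 0), seed = s))
    m <- baseline_transform(quantile_normalize(sim$expr))
    tom <- topological_overlap(adjacency(correlation_matrix(m), 6))
    det <- detect_modules(tom, min_module_size = 15, cut_height = 0.99,
                          merge_cut_height = 0.25, expr = m)
    if (is.null(det$eigengenes)) return(0)
    mt <- module_trait_table(det$eigengenes, sim$traits)
    if (is.na(mt$top_module)) return(0)
    lab <- as.integer(sub("ME", "", mt$top_module))
    planted <- names(sim$truth$modules)[sim$truth$modules == 1]
    as.numeric(mean(planted %in% names(det$modules)[det$modules == lab]) > 0.8)
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})
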