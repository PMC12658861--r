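test_that("pathway TSV dialect loads typed nodes and signed edges", {
  path <- system.file("extdata", "example_pathways.tsv", package = "lcmstats")
  pw <- load_pathways(path)
  expect_length(pw, 2L)
  g1 <- pw[[1]]
  expect_equal(sum(g1$nodes$kind == "gene"), 2L)
  expect_equal(sum(g1$nodes$kind == "compound"), 2L)
  expect_equal(nrow(g1$edges), 3L)
  expect_equal(g1$edges$sign, c(1, 1, -1))  # activation, +1, inhibition
  # minimal 2-node graph built inline
  g <- pathway_graph("p1", nodes = data.frame(id = c("g", "c"),
                                              kind = c("gene", "compound")),
                     edges = data.frame(src = "g", dst = "c", sign = 1))
  expect_equal(nrow(g$edges), 1L)
  # dangling endpoint is an error
  expect_error(pathway_graph("p2",
                             nodes = data.frame(id = "g", kind = "gene"),
                             edges = data.frame(src = "g", dst = "ghost",
                                                sign = 1)),
               "endpoint")
})

test_that("KGML parsing extracts entries and signed relations, dropping unsigned", {
  path <- write_kgml_fixture(file.path(tempdir(), "fixture.kgml"))
  pw <- load_pathways(path)
  g <- pw[[1]]
  expect_equal(sum(g$nodes$kind == "gene"), 3L)
  expect_equal(sum(g$nodes$kind == "compound"), 1L)
  expect_equal(nrow(g$edges), 2L)
  expect_equal(sort(g$edges$sign), c(-1, 1))
  expect_equal(attr(pw, "n_dropped_relations"), 1L)
})

test_that("ORA matches exhaustive enumeration and its closed forms", {
  mk_universe <- function(N, K) {
    data.frame(feature_id = paste0("f", 1:N), kind = "gene",
               significant = c(rep(TRUE, K), rep(FALSE, N - K)))
  }
  # N=10, K=4, n=3, k=2 (members chosen so exactly 2 are significant)
  u <- mk_universe(10, 4)
  g <- pathway_graph("p", nodes = data.frame(id = c("f1", "f2", "f5"),
                                             kind = "gene"))
  res <- ora(g, u, "gene")
  expect_equal(res$p, 40 / 120, tolerance = 1e-12)
  # exhaustive enumeration oracle for several configurations, N <= 12
  for (cfg in list(c(8, 3, 4), c(12, 5, 4), c(9, 2, 3), c(11, 6, 5))) {
    N <- cfg[1]; K <- cfg[2]; n <- cfg[3]
    u <- mk_universe(N, K)
    memb <- paste0("f", c(seq_len(min(2, K)), seq(K + 1, length.out = n - min(2, K))))
    g <- pathway_graph("p", nodes = data.frame(id = memb, kind = "gene"))
    res <- ora(g, u, "gene")
    expect_equal(res$p, ora_enumerate(N, K, res$n, res$k), tolerance = 1e-12)
  }
  # k == 0 boundary: upper tail at 0 is 1
  u <- mk_universe(10, 3)
  g0 <- pathway_graph("p", nodes = data.frame(id = c("f8", "f9"), kind = "gene"))
  expect_equal(ora(g0, u, "gene")$p, 1)
  # k == n == K closed form
  u <- mk_universe(10, 2)
  gk <- pathway_graph("p", nodes = data.frame(id = c("f1", "f2"), kind = "gene"))
  expect_equal(ora(gk, u, "gene")$p,
               choose(8, 0) * choose(2, 2) / choose(10, 2), tolerance = 1e-12)
  # unmapped pathway -> p = 1 with flag
  gx <- pathway_graph("p", nodes = data.frame(id = "zz", kind = "gene"))
  resx <- ora(gx, u, "gene")
  expect_true(resx$empty); expect_equal(resx$p, 1)
})

test_that("perturbation statistic solves the hand-worked chain and is linear in signs", {
  g <- make_chain_pathway(sign = 1)
  es <- espia(g, c(a = 2), n_boot = 200, seed = 1)
  # PF(b) = 2, Acc(b) = 2, t_A = 2
  expect_equal(es$t_a, 2, tolerance = 1e-12)
  gneg <- make_chain_pathway(sign = -1)
  esn <- espia(gneg, c(a = 2), n_boot = 200, seed = 1)
  expect_equal(esn$t_a, -2, tolerance = 1e-12)
  # edgeless pathway: no propagation
  g0 <- pathway_graph("p0", nodes = data.frame(id = c("x", "y"),
                                               kind = "gene"))
  es0 <- espia(g0, c(x = 1), n_boot = 200, seed = 2)
  expect_equal(es0$t_a, 0, tolerance = 1e-12)
  expect_gt(es0$p, 0.5)
  # no significant nodes at all
  expect_equal(espia(g0, c(other = 3), n_boot = 200, seed = 1)$p, 1)
  expect_error(espia(g0, c(x = 1), n_boot = 10), "at least 100")
})

test_that("linear-solve propagation equals iterative propagation on acyclic graphs", {
  nodes <- data.frame(id = letters[1:5],
                      kind = c("gene", "gene", "gene", "compound", "compound"))
  edges <- data.frame(src = c("a", "a", "b", "c"),
                      dst = c("b", "c", "d", "e"),
                      sign = c(1, -1, 1, 1))
  g <- pathway_graph("acyc", nodes = nodes, edges = edges)
  de <- c(a = 1.5, c = -0.5)
  sys <- lcmstats:::espia_system(g)
  de_full <- setNames(numeric(5), letters[1:5]); de_full[names(de)] <- de
  pf_solve <- drop(sys$inv %*% de_full)
  # fixed-point iteration oracle
  pf <- de_full
  for (i in 1:200) pf <- de_full + drop(sys$M %*% pf)
  expect_equal(pf_solve, pf, tolerance = 1e-10)
  expect_equal(espia(g, de, n_boot = 200, seed = 1)$t_a,
               sum(pf_solve - de_full), tolerance = 1e-10)
})

test_that("Fisher combination matches its closed form and is conservative vs p", {
  x <- -2 * (log(0.1) + log(0.1))
  expect_equal(x, 9.2103, tolerance = 1e-4)
  expect_equal(combine_p(0.1, 0.1, "fisher"), (1 + x / 2) * exp(-x / 2),
               tolerance = 1e-12)
  expect_equal(combine_p(0.1, 0.1, "fisher"), 0.05605, tolerance = 1e-4)
  expect_equal(combine_p(1, 1, "fisher"), 1)
  for (p in c(0.001, 0.01, 0.2, 0.7, 0.99))
    expect_gte(combine_p(p, 1, "fisher"), p)
  expect_warning(combine_p(0, 0.5, "fisher"), "clamped")
  # pbine strategy: empirical tail under a supplied joint null
  null_pairs <- cbind(runif(500), runif(500))
  pb <- combine_p(0.01, 0.01, "pbine", null_pairs = null_pairs)
  expect_true(pb > 0 && pb <= 1)
  expect_error(combine_p(0.1, 0.1, "pbine"), "null_pairs")
})

test_that("Fisher combination of independent uniforms is uniform", {
  set.seed(11)
  p <- combine_p(runif(1e4), runif(1e4), "fisher")
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("multiplicity adjustment equals the independent step-up oracle", {
  expect_equal(adjust_p(c(0.01, 0.02, 0.03), "fdr_bh"), rep(0.03, 3))
  expect_equal(adjust_p(0.2, "fdr_bh"), 0.2)
  expect_equal(adjust_p(0.2, "bonferroni"), 0.2)
  expect_equal(adjust_p(rep(0.4, 3), "bonferroni"), rep(1, 3))
  set.seed(13)
  for (r in 1:25) {
    p <- runif(sample(3:40, 1))
    expect_equal(adjust_p(p, "fdr_bh"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("iopa_run recovers a planted enriched pathway deterministically", {
  sim <- simulate_pathways(n_pathways = 6, seed = 21)
  res <- iopa_run(sim$pathways, sim$gene_summary, sim$compound_summary,
                  beta_threshold = 0.5, n_boot = 200, seed = 5)
  expect_equal(res$results$pathway_id[1], sim$truth$enriched)
  # determinism
  res2 <- iopa_run(sim$pathways, sim$gene_summary, sim$compound_summary,
                   beta_threshold = 0.5, n_boot = 200, seed = 5)
  expect_identical(res$results, res2$results)
  # count invariants
  with(res$results, {
    expect_true(all(deG_n <= G_n & deC_n <= C_n & deP_n <= P_n))
    expect_equal(P_n, G_n + C_n)
    expect_equal(deP_n, deG_n + deC_n)
  })
  # infinite beta threshold -> nothing significant, joint ORA p all 1
  res_inf <- iopa_run(sim$pathways, sim$gene_summary, sim$compound_summary,
                      beta_threshold = Inf, n_boot = 200, seed = 5)
  expect_true(all(res_inf$results$p_ora_joint == 1))
  expect_true(all(res_inf$results$deP_n == 0))
  # plot-ready tables align with results
  expect_equal(res$manhattan$neg_log10_p_fdr, -log10(res$results$p_fdr))
  expect_equal(nrow(res$volcano), 6L)
})

test_that("pbine combination is a valid p-value and finds the planted pathway", {
  sim <- simulate_pathways(n_pathways = 5, seed = 33)
  res <- iopa_run(sim$pathways, sim$gene_summary, sim$compound_summary,
                  beta_threshold = 0.5, combine_method = "pbine",
                  n_boot = 200, n_perm = 100, seed = 9)
  expect_true(all(res$results$p_combined > 0 & res$results$p_combined <= 1))
  expect_equal(res$results$pathway_id[1], sim$truth$enriched)
})
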