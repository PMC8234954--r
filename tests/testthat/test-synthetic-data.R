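test_that("simulation_config enforces its invariants", {
  expect_error(simulation_config(n_genes = 10, module_sizes = c(6, 6), n_modules = 2,
                                 hub_leaf_counts = c(0, 0), seed = 1),
               "exceeds n_genes")
  expect_error(simulation_config(n_samples = 2, seed = 1), "n_samples")
  expect_error(simulation_config(within_module_corr = 1, seed = 1), "strictly")
  expect_error(simulation_config(within_module_corr = 0, seed = 1), "strictly")
  expect_error(simulation_config(noise_sd = 0, seed = 1), "noise_sd")
  expect_warning(simulation_config(seed = NULL), "generated seed")
})

test_that("identical seeds give byte-identical expression output", {
  cfg <- simulation_config(n_genes = 50, n_modules = 2, module_sizes = c(6, 6),
                           hub_leaf_counts = c(3, 3), seed = 99)
  a <- generate_modular_expression(cfg)
  b <- generate_modular_expression(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$truth$radiation_labels, b$truth$radiation_labels)
  fa <- tempfile(); fb <- tempfile()
  write_expression(a$expression, fa); write_expression(b$expression, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("degenerate limits behave: near-unit correlation, zero radiation fraction", {
  cfg <- simulation_config(n_genes = 12, n_samples = 8, n_modules = 1,
                           module_sizes = 10, hub_leaf_counts = 0,
                           within_module_corr = 0.999, noise_sd = 1e-3,
                           frac_radiation_induced = 0, seed = 5)
  sim <- generate_modular_expression(cfg)
  C <- cor(t(sim$expression[1:10, ]))
  expect_true(all(C[upper.tri(C)] > 0.99))
  expect_false(any(sim$truth$radiation_labels))
})

test_that("mean within-module correlation tracks the configured rho", {
  # Monte-Carlo oracle: average sample correlation over replicate simulations
  rs <- vapply(1:50, function(s) {
    cfg <- simulation_config(n_genes = 30, n_samples = 8, n_modules = 1,
                             module_sizes = 20, hub_leaf_counts = 0,
                             within_module_corr = 0.9, seed = 1000 + s)
    sim <- generate_modular_expression(cfg)
    C <- cor(t(sim$expression[1:20, ]))
    mean(C[upper.tri(C)])
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.9), 0.1)

  # convergence at large replicate count
  cfg <- simulation_config(n_genes = 30, n_samples = 200, n_modules = 1,
                           module_sizes = 20, hub_leaf_counts = 0,
                           within_module_corr = 0.6, seed = 7)
  sim <- generate_modular_expression(cfg)
  C <- cor(t(sim$expression[1:20, ]))
  expect_lt(abs(mean(C[upper.tri(C)]) - 0.6), 0.02)
})

test_that("background correlations follow the null t-distribution", {
  cfg <- simulation_config(n_genes = 160, n_samples = 5, n_modules = 1,
                           module_sizes = 2, hub_leaf_counts = 0,
                           within_module_corr = 0.5, seed = 21)
  sim <- generate_modular_expression(cfg)
  bg <- sim$expression[names(which(sim$truth$module_assignment == 0L)), ]
  C <- cor(t(bg))
  r <- C[upper.tri(C)]
  p <- correlation_test(r, ncol(bg))$p_value
  expect_gt(length(p), 10000)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("star leaves correlate with their hub", {
  cfg <- simulation_config(n_genes = 40, n_samples = 200, n_modules = 1,
                           module_sizes = 5, hub_leaf_counts = 12,
                           within_module_corr = 0.81, seed = 3)
  sim <- generate_modular_expression(cfg)
  hub <- sim$truth$hubs[1]
  leaves <- sim$truth$hub_leaves[[1]]
  expect_length(leaves, 12)
  r_hl <- cor(sim$expression[hub, ], t(sim$expression[leaves, ]))
  # hub-leaf expected correlation is sqrt(rho) = 0.9
  expect_lt(abs(mean(r_hl) - 0.9), 0.05)
})

test_that("bn_dag rejects cycles and generate_bn_data respects the structure", {
  expect_error(bn_dag(data.frame(from = c("A", "B"), to = c("B", "A"))), "acyclic")

  # no edges: all pairwise correlations near zero
  dag0 <- bn_dag(NULL, nodes = c("A", "B", "C"))
  d0 <- generate_bn_data(dag0, 1000, seed = 1)
  C <- cor(d0)
  expect_true(all(abs(C[upper.tri(C)]) < 0.1))

  # chain X -> Y -> Z: X and Z independent given Y
  chain <- bn_dag(data.frame(from = c("X", "Y"), to = c("Y", "Z"), coef = 1))
  dc <- generate_bn_data(chain, 2000, seed = 2)
  expect_gt(abs(cor(dc[, "X"], dc[, "Z"])), 0.2)
  expect_lt(abs(partial_correlation("X", "Z", "Y", dc)), 0.08)

  # collider X -> Z <- Y: marginally independent, dependent given Z
  col <- bn_dag(data.frame(from = c("X", "Y"), to = c("Z", "Z"), coef = 1))
  dk <- generate_bn_data(col, 2000, seed = 3)
  expect_lt(abs(cor(dk[, "X"], dk[, "Y"])), 0.08)
  expect_gt(abs(partial_correlation("X", "Y", "Z", dk)), 0.3)

  # determinism
  expect_identical(generate_bn_data(chain, 50, seed = 9),
                   generate_bn_data(chain, 50, seed = 9))
})

test_that("true_markov_blanket reads parents, children and spouses off the DAG", {
  dag <- bn_dag(data.frame(from = c("A", "B", "T", "S"), to = c("T", "T", "C", "C")))
  expect_setequal(true_markov_blanket(dag, "T"), c("A", "B", "C", "S"))
  expect_setequal(true_markov_blanket(dag, "A"), c("T", "B"))
  expect_setequal(true_markov_blanket(dag, "S"), c("C", "T"))
})

test_that("generate_gene_sets plants one positive per module plus decoys", {
  cfg <- simulation_config(n_genes = 60, n_modules = 2, module_sizes = c(8, 6),
                           hub_leaf_counts = c(3, 3), seed = 4)
  sim <- generate_modular_expression(cfg)
  sets <- generate_gene_sets(sim$truth, n_sets = 7, overlap_frac = 0, seed = 5)
  expect_length(sets, 7)
  genes <- names(sim$truth$module_assignment)
  expect_setequal(sets[["module_process_1"]],
                  genes[sim$truth$module_assignment == 1L])
  expect_setequal(sets[["module_process_2"]],
                  genes[sim$truth$module_assignment == 2L])
  background <- genes[sim$truth$module_assignment == 0L]
  for (d in sprintf("decoy_process_%d", 1:5))
    expect_true(all(sets[[d]] %in% background))

  with_leaves <- generate_gene_sets(sim$truth, n_sets = 2, include_leaves = TRUE,
                                    seed = 5)
  expect_true(all(sim$truth$hub_leaves[[1]] %in% with_leaves[["module_process_1"]]))
  expect_error(generate_gene_sets(sim$truth, n_sets = 1, seed = 5), "at least")
})
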