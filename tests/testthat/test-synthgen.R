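test_that("circuit generation is deterministic per seed", {
  g1 <- generate_circuit(small_circuit_config(seed = 3))
  g2 <- generate_circuit(small_circuit_config(seed = 3))
  expect_identical(g1$connectors, g2$connectors)
  expect_identical(g1$neurons, g2$neurons)
  expect_identical(lapply(g1$skeletons, `[[`, "nodes"),
                   lapply(g2$skeletons, `[[`, "nodes"))
  g3 <- generate_circuit(small_circuit_config(seed = 4))
  expect_false(identical(g1$connectors, g3$connectors))
})

test_that("zero connection probability yields no synaptic pairs", {
  cfg <- small_circuit_config(seed = 1, p = 0)
  cfg$peripheral_zone_rate <- 0
  gen <- generate_circuit(cfg)
  expect_equal(nrow(gen$connectors), 0L)
})

test_that("config invariants are validated before generation", {
  expect_error(small_circuit_config(p = 1.5),
               class = "vagusnet_validation_error")
  expect_error(circuit_config(asymmetry_eps = 2),
               class = "vagusnet_validation_error")
  expect_error(circuit_config(polyadicity = 0.5),
               class = "vagusnet_validation_error")
  expect_error(circuit_config(tissue_probs = c(a = 0.5, b = 0.2)),
               class = "vagusnet_validation_error")
  bad_edges <- default_edges()
  bad_edges$to[1] <- "nonexistent"
  expect_error(circuit_config(edges = bad_edges),
               class = "vagusnet_validation_error")
})

test_that("planted ground truth matches the analysis modules", {
  gen <- generate_circuit(circuit_config(seed = 17))
  m <- build_counts(gen$connectors, gen$neurons)
  expect_identical(m, gen$truth$counts)

  f <- suppressMessages(input_fractions(m))
  expect_equal(f, gen$truth$fractions)

  for (k in sample(nrow(gen$truth$hemisphere_budgets), 6L)) {
    row <- gen$truth$hemisphere_budgets[k, ]
    b <- hemisphere_budgets(gen$connectors, gen$neurons, row$cluster,
                            row$direction)
    expect_equal(c(b$LL, b$RR, b$LR, b$RL),
                 c(row$LL, row$RR, row$LR, row$RL))
  }

  nr <- gen$neurons
  sens <- nr$neuron_id[nr$cell_class == "sensory"]
  int <- nr$neuron_id[nr$cell_class == "interneuron"]
  tg <- nr$neuron_id[nr$cell_class == "modulatory"]
  ds <- suppressMessages(direct_scores(f, sens, tg))
  is_ <- suppressMessages(indirect_scores(f, sens, int, tg, 2L))
  mine <- pathway_sums_from_records(ds, is_)
  truth <- gen$truth$pathway_sums
  mrg <- merge(mine, truth, by = c("source", "target"), all = TRUE)
  expect_false(anyNA(mrg$score))
  expect_false(anyNA(mrg$pathway_sum))
  expect_lt(max(abs(mrg$score - mrg$pathway_sum)), 1e-12)
})

test_that("generated pair totals stay near expectation across seeds", {
  # edge S->T: 2x2 neurons per hemisphere pair grid, p=0.8, mean 3
  exp_pairs_edge <- function(n, p, mean_pairs) (2 * n)^2 * p * mean_pairs
  totals <- vapply(1:20, function(seed) {
    gen <- generate_circuit(small_circuit_config(seed = seed, n = 2L))
    sum(gen$truth$counts)
  }, numeric(1))
  mu <- 3 * exp_pairs_edge(2, 0.8, 3)  # three identical edge specs
  # per ordered pair: count = Bernoulli(p) * Poisson(m)
  v_pair <- 0.8 * 3 + 0.8 * (1 - 0.8) * 3^2
  v <- 3 * (2 * 2)^2 * v_pair
  expect_lt(abs(mean(totals) - mu), 4 * sqrt(v / 20))
})

test_that("generated files parse back without warnings", {
  gen <- generate_circuit(small_circuit_config(seed = 8))
  dir <- withr::local_tempdir()
  paths <- write_circuit(gen, dir)
  expect_no_warning({
    skels <- read_skeleton_manifest(paths$manifest)
    conn <- read_connectors(paths$connectors)
    ann <- read_neuron_annotations(paths$annotations)
  })
  expect_equal(length(skels), nrow(gen$neurons))
  expect_equal(nrow(conn), nrow(gen$connectors))
  # connector nodes all exist in the skeletons (validated via placement)
  for (id in utils::head(ann$neuron_id, 3L))
    expect_no_error(synapse_distances(skels[[id]], conn))
})

test_that("trace generation plants clean events deterministically", {
  g1 <- generate_trace(trace_config(seed = 2, duration_s = 60))
  g2 <- generate_trace(trace_config(seed = 2, duration_s = 60))
  expect_identical(g1$trace$roi1, g2$trace$roi1)
  expect_identical(g1$trigger_times, g2$trigger_times)

  # noise-free, always-completed triggers: bumps offset by the latency
  g <- generate_trace(trace_config(seed = 1, duration_s = 60,
                                   trigger_rate = 4, completion_prob = 1,
                                   noise_sd = 0))
  expect_equal(g$wave_times, g$trigger_times + 0.5)
  i1 <- which.max(g$trace$roi1)
  i2 <- which.max(g$trace$roi2)
  expect_equal(g$trace$t[i2] - g$trace$t[i1], 0.5, tolerance = 0.051)

  # completion_prob 0 leaves ROI2 flat (noise only)
  g0 <- generate_trace(trace_config(seed = 3, duration_s = 60,
                                    completion_prob = 0, noise_sd = 0))
  expect_equal(max(abs(g0$trace$roi2)), 0)
})

test_that("planted events are recovered at default detector settings", {
  sens <- prec <- numeric(6)
  for (seed in 1:6) {
    gen <- generate_trace(trace_config(seed = seed, duration_s = 300))
    ev <- detect_events(gen$trace$roi1, gen$trace$t)
    rec <- event_recovery(ev, gen$trigger_times)
    sens[seed] <- rec$sensitivity
    prec[seed] <- rec$precision
  }
  expect_gte(min(sens), 0.95)
  expect_gte(min(prec), 0.95)
})
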