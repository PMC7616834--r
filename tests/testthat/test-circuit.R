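test_that("build_counts applies the polyadic pair convention", {
  neurons <- toy_neurons()
  # one connector, pre s1, post [i1, i2] -> two pairs
  conn <- make_pairs(c("s1", "s1"), c("i1", "i2"))
  conn$connector_id <- "c001"
  m <- build_counts(conn, neurons)
  expect_equal(m["s1", "i1"], 1L)
  expect_equal(m["s1", "i2"], 1L)
  expect_equal(sum(m), 2L)

  empty <- make_pairs(character(0), character(0))
  expect_true(all(build_counts(empty, neurons) == 0L))
})

test_that("build_counts drops and reports unknown neurons", {
  neurons <- toy_neurons()
  conn <- make_pairs(c("s1", "ghost"), c("i1", "i1"))
  expect_warning(m <- build_counts(conn, neurons), "ghost")
  expect_equal(sum(m), 1L)
})

test_that("count totals always equal the number of synaptic pairs", {
  for (seed in 1:3) {
    gen <- generate_circuit(small_circuit_config(seed = seed))
    m <- build_counts(gen$connectors, gen$neurons)
    expect_equal(sum(m), sum(!is.na(gen$connectors$post_neuron)))
    expect_identical(m, gen$truth$counts)
  }
})

test_that("input fractions invert exactly and flag undefined columns", {
  neurons <- toy_neurons()
  conn <- make_pairs(c("s1", "s1", "s2", "s2", "s2", "i1", "i1", "i1", "i1",
                       "i1"),
                     c("t1", "t1", "t1", "t1", "t1", "t1", "t1", "t1", "t1",
                       "t1"))
  m <- build_counts(conn, neurons)
  expect_message(f <- input_fractions(m), "zero inputs")
  expect_equal(f["s1", "t1"], 0.2)
  expect_equal(f["s2", "t1"], 0.3)
  expect_equal(f["i1", "t1"], 0.5)
  expect_true(all(is.na(f[, "s1"])))  # never silently zero

  # algebraic inversion: fractions x column totals reproduce counts
  set.seed(9)
  mm <- matrix(rpois(36, 3), 6, 6,
               dimnames = list(letters[1:6], letters[1:6]))
  ff <- suppressMessages(input_fractions(mm))
  tot <- colSums(mm)
  back <- sweep(ff, 2L, tot, "*")
  back[is.na(back)] <- 0
  mm0 <- mm; mm0[, tot == 0] <- 0
  expect_equal(back, mm0 + 0, tolerance = 1e-12)
})

test_that("cluster aggregation sums blocks and computes outgoing percent", {
  neurons <- toy_neurons()
  conn <- make_pairs(c("s1", "s1", "s2", "i1", "i1"),
                     c("i1", "i2", "i1", "t1", "t1"))
  m <- build_counts(conn, neurons)
  agg <- aggregate_by_cluster(m, neurons)
  expect_equal(agg["S", "I"], 3L)
  expect_equal(agg["I", "T"], 2L)
  pct <- aggregate_by_cluster(m, neurons, percent_out = TRUE)
  expect_equal(pct["S", "I"], 100)
  expect_equal(sum(pct["I", ]), 100)

  # singleton clusters reproduce the neuron-level matrix
  n2 <- neurons
  n2$cluster <- n2$neuron_id
  agg2 <- aggregate_by_cluster(m, n2)
  expect_equal(unname(agg2[rownames(m), colnames(m)]), unname(m + 0))
})

test_that("io_balance computes input share with region filtering", {
  conn <- rbind(make_pairs(rep("a", 10), rep("b", 10)),
                within(make_pairs(rep("b", 10), rep("a", 10)), {
                  connector_id <- sprintf("d%03d", 1:10)
                }))
  bal <- io_balance("a", conn)
  expect_equal(bal$input_share, 0.5)  # hybrid input/output pattern
  expect_equal(io_balance("b", conn)$input_share, 0.5)

  out_only <- io_balance("a", make_pairs(rep("a", 5), rep("b", 5)))
  expect_equal(out_only$input_share, 0)

  none <- io_balance("a", make_pairs("a", "b", region = "periphery"),
                     region = "CNS")
  expect_true(is.na(none$input_share))
})

test_that("hemisphere budgets respect mirror symmetry and totals", {
  neurons <- data.frame(
    neuron_id = c("aL", "aR", "bL", "bR", "u1"),
    cell_class = "interneuron",
    cluster = c("A", "A", "B", "B", "U"),
    hemisphere = c("L", "R", "L", "R", "unpaired"),
    modality = NA_character_)
  # perfectly mirrored: aL->bL twice, aR->bR twice, aL->bR once, aR->bL once
  conn <- make_pairs(c("aL", "aL", "aR", "aR", "aL", "aR"),
                     c("bL", "bL", "bR", "bR", "bR", "bL"))
  b <- hemisphere_budgets(conn, neurons, "A", "out")
  expect_equal(b$LL, b$RR)
  expect_equal(b$LR, b$RL)
  expect_equal(b$LL + b$RR + b$LR + b$RL, 6L)

  b_in <- hemisphere_budgets(conn, neurons, "B", "in")
  expect_equal(b_in$LL + b_in$RR + b_in$LR + b_in$RL, 6L)

  # all ipsilateral-left
  conn2 <- make_pairs(c("aL", "aL"), c("bL", "bL"))
  b2 <- hemisphere_budgets(conn2, neurons, "A", "out")
  expect_equal(c(b2$RR, b2$LR, b2$RL), c(0L, 0L, 0L))

  # unpaired partners are excluded and reported
  conn3 <- make_pairs(c("aL", "aL"), c("bL", "u1"))
  b3 <- hemisphere_budgets(conn3, neurons, "A", "out")
  expect_equal(b3$excluded, 1L)
  expect_equal(b3$LL, 1L)

  expect_error(hemisphere_budgets(conn, neurons, "nope", "out"),
               class = "vagusnet_lookup_error")
})

test_that("L/R relabeling swaps LL with RR and LR with RL", {
  gen <- generate_circuit(small_circuit_config(seed = 5, eps = 0.4))
  mirror <- function(id)
    sub("_X", "_R", sub("_R", "_L", sub("_L", "_X", id)))
  conn_m <- gen$connectors
  conn_m$pre_neuron <- mirror(conn_m$pre_neuron)
  conn_m$post_neuron <- ifelse(is.na(conn_m$post_neuron), NA,
                               mirror(conn_m$post_neuron))
  b <- hemisphere_budgets(gen$connectors, gen$neurons, "S", "out")
  bm <- hemisphere_budgets(conn_m, gen$neurons, "S", "out")
  expect_equal(bm$LL, b$RR)
  expect_equal(bm$RR, b$LL)
  expect_equal(bm$LR, b$RL)
  expect_equal(bm$RL, b$LR)
})

test_that("peripheral zone tallies are exact and validated", {
  expect_equal(nrow(peripheral_zone_tally(make_pairs("a", "b"))), 0L)

  pz <- data.frame(connector_id = sprintf("p%d", 1:5),
                   pre_neuron = "se0", pre_node = 1L,
                   post_neuron = NA_character_, post_node = NA_integer_,
                   region = "periphery",
                   tissue_tag = c("HCG", "HCG", "HCG", "PVG", "PVG"))
  tal <- peripheral_zone_tally(pz)
  expect_equal(tal$n[tal$tissue_tag == "HCG"], 3L)
  expect_equal(tal$n[tal$tissue_tag == "PVG"], 2L)
  expect_equal(sum(tal$n), 5L)

  bad <- pz
  bad$tissue_tag[1] <- NA
  expect_error(peripheral_zone_tally(bad),
               class = "vagusnet_validation_error")
  expect_error(peripheral_zone_tally(pz, taxonomy = c("HCG")),
               class = "vagusnet_validation_error")

  gen <- generate_circuit(small_circuit_config(seed = 2))
  expect_identical(peripheral_zone_tally(gen$connectors),
                   gen$truth$peripheral_tally)
})
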