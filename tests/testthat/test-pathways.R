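make_f <- function() {
  ids <- c("s1", "s2", "i1", "i2", "t1")
  f <- matrix(0, 5, 5, dimnames = list(ids, ids))
  f["s1", "i1"] <- 0.5
  f["i1", "t1"] <- 0.3
  f["s1", "t1"] <- 0.2
  f["s2", "i2"] <- 0.5
  f["i1", "i2"] <- 0.4
  f["i2", "t1"] <- 0.3
  f
}

test_that("direct scores are the input fractions, element by element", {
  f <- make_f()
  ds <- direct_scores(f, c("s1", "s2"), "t1")
  expect_equal(nrow(ds), 1L)  # s2 has no synapse onto t1: no record
  expect_equal(ds$score, 0.2)
  expect_equal(ds$n_layers, 0L)

  # random circuit: scores equal matrix entries elementwise
  rc <- random_fraction_matrix(5, 4, 3, seed = 11)
  ds <- direct_scores(rc$f, rc$sensory, rc$targets)
  for (k in seq_len(nrow(ds)))
    expect_identical(ds$score[k], rc$f[ds$source[k], ds$target[k]])

  # undefined target column is reported
  f2 <- f
  f2[, "t1"] <- NA
  expect_message(ds2 <- direct_scores(f2, c("s1", "s2"), "t1"), "undefined")
  expect_equal(attr(ds2, "undefined_targets"), "t1")
})

test_that("indirect scores multiply hop fractions along simple paths", {
  f <- make_f()
  one <- indirect_scores(f, c("s1", "s2"), c("i1", "i2"), "t1",
                         max_layers = 1L)
  expect_equal(one$score[one$source == "s1" & one$via == "i1"], 0.5 * 0.3)
  expect_equal(one$score[one$source == "s2" & one$via == "i2"], 0.5 * 0.3)
  expect_true(all(one$n_layers == 1L))

  two <- indirect_scores(f, c("s1", "s2"), c("i1", "i2"), "t1",
                         max_layers = 2L)
  deep <- two[two$n_layers == 2L, ]
  expect_equal(deep$via, "i1;i2")
  expect_equal(deep$score, 0.5 * 0.4 * 0.3)

  expect_error(indirect_scores(f, "s1", "s1", "t1"),
               class = "vagusnet_validation_error")
  expect_error(indirect_scores(f, "s1", "i1", "t1", max_layers = 3L),
               class = "vagusnet_validation_error")
})

test_that("pathway sums equal exhaustive simple-path enumeration", {
  for (seed in 1:8) {
    rc <- random_fraction_matrix(6, 5, 3, seed = seed)
    ds <- direct_scores(rc$f, rc$sensory, rc$targets)
    is_ <- indirect_scores(rc$f, rc$sensory, rc$interneurons, rc$targets,
                           max_layers = 2L)
    mine <- pathway_sums_from_records(ds, is_)
    oracle <- enumerate_pathway_sums(rc$f, rc$sensory, rc$interneurons,
                                     rc$targets, max_layers = 2L)
    expect_equal(nrow(mine), nrow(oracle))
    m <- merge(mine, oracle, by = c("source", "target"))
    expect_equal(nrow(m), nrow(oracle))
    expect_lt(max(abs(m$score - m$pathway_sum)), 1e-12)
  }
})

test_that("path scores are monotone in a hop weight at fixed denominators", {
  f <- make_f()
  base <- indirect_scores(f, "s1", c("i1", "i2"), "t1", max_layers = 2L)
  f_up <- f
  f_up["s1", "i1"] <- f_up["s1", "i1"] + 0.1  # extra synapse, denominators frozen
  up <- indirect_scores(f_up, "s1", c("i1", "i2"), "t1", max_layers = 2L)
  m <- merge(base, up, by = c("source", "target", "via"))
  expect_true(all(m$score.y >= m$score.x))
})

test_that("sensory fingerprints group input fractions by modality", {
  f <- make_f()
  mods <- c(s1 = "mechano", s2 = "chemo")
  fp <- sensory_fingerprint(f, "i1", c("s1", "s2"), mods)
  expect_equal(fp[["mechano"]], 0.5)
  expect_equal(fp[["chemo"]], 0)
  expect_error(sensory_fingerprint(f, "i1", c("s1", "s2"), mods["s1"]),
               class = "vagusnet_validation_error")

  # two mechano neurons at 0.1 each -> mechano 0.2
  ids <- c("a", "b", "i")
  f2 <- matrix(0, 3, 3, dimnames = list(ids, ids))
  f2["a", "i"] <- 0.1; f2["b", "i"] <- 0.1
  fp2 <- sensory_fingerprint(f2, "i", c("a", "b"),
                             c(a = "mechano", b = "mechano"))
  expect_equal(fp2[["mechano"]], 0.2)
})

test_that("modality rollup sums paths and normalizes to 100 percent", {
  f <- make_f()
  mods <- c(s1 = "mechano", s2 = "chemo")
  ds <- direct_scores(f, c("s1", "s2"), "t1")
  is_ <- indirect_scores(f, c("s1", "s2"), c("i1", "i2"), "t1",
                         max_layers = 2L)
  ro <- modality_rollup(ds, is_, mods)
  expect_equal(ro$total, ro$direct + ro$indirect)
  expect_equal(sum(ro$normalized_percent), 100, tolerance = 1e-9)
  mech <- ro[ro$modality == "mechano", ]
  expect_equal(mech$direct, 0.2)
  expect_equal(mech$indirect, 0.5 * 0.3 + 0.5 * 0.4 * 0.3)

  # single modality present -> 100%
  ro1 <- modality_rollup(ds[ds$source == "s1", ],
                         is_[is_$source == "s1", ], mods)
  expect_equal(ro1$normalized_percent, 100)

  # forced 75/25 split
  d2 <- data.frame(source = c("s1", "s2"), target = "t1", via = "",
                   n_layers = 0L, score = c(0.3, 0.1))
  ro2 <- modality_rollup(d2, d2[0, ], mods)
  expect_equal(sort(ro2$normalized_percent), c(25, 75))
})

test_that("direct-only circuits degenerate to total = direct", {
  rc <- random_fraction_matrix(5, 0, 2, seed = 3)
  ds <- direct_scores(rc$f, rc$sensory, rc$targets)
  empty <- ds[0, ]
  mods <- stats::setNames(rep("mechano", 5), rc$sensory)
  ro <- modality_rollup(ds, empty, mods)
  expect_equal(ro$total, ro$direct)
  expect_equal(ro$indirect, rep(0, nrow(ro)))
})

test_that("planted dominant modality is recovered from the generator", {
  gen <- generate_circuit(circuit_config(seed = 21))
  f <- suppressMessages(input_fractions(gen$truth$counts))
  nr <- gen$neurons
  sens <- nr$neuron_id[nr$cell_class == "sensory"]
  int <- nr$neuron_id[nr$cell_class == "interneuron"]
  tg <- nr$neuron_id[nr$cell_class == "modulatory"]
  ds <- suppressMessages(direct_scores(f, sens, tg))
  is_ <- suppressMessages(indirect_scores(f, sens, int, tg, 2L))
  mods <- stats::setNames(nr$modality, nr$neuron_id)[sens]
  ro <- suppressMessages(modality_rollup(ds, is_, mods))
  dom <- dominant_modality(ro)
  # the default cast is mechanosensory-dominated (3 of 4 sensory clusters)
  expect_true(all(dom$modality == "ENS_mechano"))
})
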