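# Fixtures and independent oracles shared across the suite. Everything is
# generated in code; no binary fixtures.

# A 3-node chain with Pythagorean edge lengths 3 and 5 (total arc 8).
chain_skeleton <- function() {
  skeleton("chain", data.frame(
    node_id = 1:3, type = 0L,
    x = c(0, 3, 6), y = c(0, 0, 4), z = 0,
    radius = NA_real_, parent_id = c(NA, 1L, 2L)))
}

# Unbranched chain along x with given segment lengths.
line_skeleton <- function(seg_lengths, neuron_id = "line") {
  n <- length(seg_lengths) + 1L
  skeleton(neuron_id, data.frame(
    node_id = seq_len(n), type = 0L,
    x = cumsum(c(0, seg_lengths)), y = 0, z = 0,
    radius = NA_real_, parent_id = c(NA, seq_len(n - 1L))))
}

# Random tree with integer coordinates; each node attaches to a uniformly
# chosen earlier node (independent of the package's own generator).
random_test_tree <- function(n, seed, scale = 10L) {
  set.seed(seed)
  parent <- c(NA_integer_,
              vapply(seq_len(n - 1L) + 1L,
                     function(i) sample.int(i - 1L, 1L), integer(1)))
  skeleton(paste0("t", seed), data.frame(
    node_id = seq_len(n), type = 0L,
    x = sample.int(scale * n, n, replace = TRUE),
    y = sample.int(scale * n, n, replace = TRUE),
    z = sample.int(scale * n, n, replace = TRUE),
    radius = NA_real_, parent_id = parent))
}

# Generic graph-search oracle: geodesic distances via igraph's Dijkstra on
# the same weighted edges.
igraph_distances <- function(s, from) {
  nd <- s$nodes
  has_p <- !is.na(nd$parent_id)
  pidx <- match(nd$parent_id[has_p], nd$node_id)
  w <- sqrt((nd$x[has_p] - nd$x[pidx])^2 +
            (nd$y[has_p] - nd$y[pidx])^2 +
            (nd$z[has_p] - nd$z[pidx])^2)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(nd$node_id[has_p]),
               to = as.character(nd$parent_id[has_p])),
    directed = FALSE,
    vertices = data.frame(name = as.character(nd$node_id)))
  d <- igraph::distances(g, v = as.character(from), weights = w)
  stats::setNames(as.numeric(d), colnames(d))
}

# Tiny hand-built circuit: sensory s1/s2, interneurons i1/i2, target t1.
toy_neurons <- function() {
  data.frame(
    neuron_id = c("s1", "s2", "i1", "i2", "t1"),
    cell_class = c("sensory", "sensory", "interneuron", "interneuron",
                   "modulatory"),
    cluster = c("S", "S", "I", "I", "T"),
    hemisphere = c("L", "R", "L", "R", "L"),
    modality = c("mechano", "chemo", NA, NA, NA))
}

# Connector rows built from a pair list; one row per (pre, post) pair.
make_pairs <- function(pre, post, region = "CNS") {
  n <- length(pre)
  data.frame(connector_id = sprintf("c%03d", seq_len(n)),
             pre_neuron = pre, pre_node = rep(1L, n),
             post_neuron = post, post_node = rep(1L, n),
             region = rep(region, length.out = n),
             tissue_tag = rep(NA_character_, n))
}

# Random sparse layered fraction matrix over disjoint sensory/interneuron/
# target sets; rows/cols indexed by all neurons. Column sums <= 1.
random_fraction_matrix <- function(n_s, n_i, n_t, seed, density = 0.5) {
  set.seed(seed)
  ids <- c(paste0("s", seq_len(n_s)), paste0("i", seq_len(n_i)),
           paste0("t", seq_len(n_t)))
  f <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  fill <- function(from, to) {
    for (b in to) {
      w <- stats::runif(length(from)) * (stats::runif(length(from)) < density)
      if (sum(w) > 0) f[from, b] <<- f[from, b] + w / sum(w) * stats::runif(1)
    }
  }
  s <- ids[seq_len(n_s)]
  i <- ids[n_s + seq_len(n_i)]
  t <- ids[n_s + n_i + seq_len(n_t)]
  fill(s, i); fill(c(s, i), t); fill(i, i)
  diag(f) <- 0
  list(f = f, sensory = s, interneurons = i, targets = t)
}

# Sum the per-path records of direct_scores + indirect_scores per
# (source, target).
pathway_sums_from_records <- function(ds, is_) {
  all_ <- rbind(ds, is_)
  if (!nrow(all_))
    return(data.frame(source = character(0), target = character(0),
                      score = numeric(0)))
  agg <- stats::aggregate(list(score = all_$score),
                          by = list(source = all_$source,
                                    target = all_$target), FUN = sum)
  agg[order(agg$source, agg$target), ]
}

# All permutations of a vector (recursive; only used for tiny n).
combinat_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (k in seq_along(v))
    out <- c(out, lapply(combinat_perms(v[-k]), function(p) c(v[k], p)))
  out
}

# Event matching against planted ground truth within a tolerance.
event_recovery <- function(detected, truth, tol = 0.25) {
  tp <- sum(vapply(truth, function(e) any(abs(detected - e) <= tol),
                   logical(1)))
  fp <- sum(vapply(detected, function(e) min(abs(truth - e)) > tol,
                   logical(1)))
  list(sensitivity = if (length(truth)) tp / length(truth) else NA_real_,
       precision = if (length(detected))
         (length(detected) - fp) / length(detected) else NA_real_)
}

# Small circuit config for fast generator-based tests.
small_circuit_config <- function(seed = 1L, eps = 0, n = 2L,
                                 p = 0.8, mean_pairs = 3) {
  circuit_config(
    seed = seed,
    clusters = data.frame(
      label = c("S", "I", "T"),
      cell_class = c("sensory", "interneuron", "modulatory"),
      modality = c("mechano", NA, NA),
      n_per_hemisphere = n, unpaired = FALSE),
    edges = data.frame(
      from = c("S", "S", "I"), to = c("I", "T", "T"),
      p_connect = p, mean_pairs = mean_pairs),
    asymmetry_eps = eps,
    skeleton_nodes = 8L,
    peripheral_zone_rate = 2)
}
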