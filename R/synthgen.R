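#' Configuration for a synthetic bilateral clustered connectome
#'
#' Describes the circuit to emulate: bilaterally mirrored neuron clusters
#' in feed-forward layers (sensory -> interneuron L1/L2 -> modulatory and
#' motor outputs), polyadic connectors, random-walk tree skeletons with a
#' designated entry-node origin, and peripheral active zones on modulatory
#' neurons. The default cast mirrors the enteric/vagus circuit at reduced
#' scale: sensory clusters EG_ant (chemosensory), EG_med/EG_post
#' (mechanosensory), PVG_sens, interneuron layers L1/L2, motor cluster
#' ERM_motor and the serotonergic modulatory cluster Se0_ens whose
#' peripheral active zones are tagged HCG / PVG / ring_gland / midgut.
#'
#' @param seed Integer seed; every stochastic draw flows from it.
#' @param clusters `data.frame` with columns `label`, `cell_class`,
#'   `modality` (`NA` for non-sensory), `n_per_hemisphere`, `unpaired`.
#' @param edges `data.frame` with columns `from`, `to` (cluster labels),
#'   `p_connect` (connection probability per ordered neuron pair, in
#'   \[0, 1\]) and `mean_pairs` (mean synaptic pairs per connected pair).
#' @param asymmetry_eps Excess left-ipsilateral drive in \[-1, 1\]:
#'   expected left-left pair counts are scaled by `1 + eps` and
#'   right-right by `1 - eps`, so the expected ipsilateral asymmetry
#'   index is `100 * eps` percent.
#' @param polyadicity Mean postsynaptic partners per connector (>= 1).
#' @param skeleton_nodes Nodes per neuron skeleton.
#' @param skeleton_step_nm Segment length of the skeleton random walk, nm.
#' @param branch_prob Probability that a new skeleton node starts a branch
#'   from a random earlier node instead of extending the current tip.
#' @param peripheral_zone_rate Mean peripheral active zones per modulatory
#'   or secretory neuron.
#' @param tissue_probs Named probability vector over tissue tags for
#'   peripheral active zones.
#' @return List of class `circuit_config`.
#' @export
circuit_config <- function(seed = 1L,
                           clusters = default_clusters(),
                           edges = default_edges(),
                           asymmetry_eps = 0,
                           polyadicity = 2,
                           skeleton_nodes = 40L,
                           skeleton_step_nm = 1000,
                           branch_prob = 0.1,
                           peripheral_zone_rate = 6,
                           tissue_probs = c(HCG = 0.4, PVG = 0.3,
                                            ring_gland = 0.2, midgut = 0.1)) {
  cfg <- list(seed = as.integer(seed), clusters = clusters, edges = edges,
              asymmetry_eps = asymmetry_eps, polyadicity = polyadicity,
              skeleton_nodes = as.integer(skeleton_nodes),
              skeleton_step_nm = skeleton_step_nm,
              branch_prob = branch_prob,
              peripheral_zone_rate = peripheral_zone_rate,
              tissue_probs = tissue_probs)
  class(cfg) <- "circuit_config"
  validate_circuit_config(cfg)
  cfg
}

#' Default synthetic cluster and edge specifications
#'
#' The reduced-scale cast used by [circuit_config]: four sensory clusters,
#' two interneuron layers, a motor and a modulatory output cluster, wired
#' sensory -> L1 -> L2 -> Se0_ens with direct sensory shortcuts, an
#' EG_med -> ERM_motor motor drive and the recurrent ERM_motor -> EG_post
#' axo-axonic connection.
#'
#' @return A `data.frame` (see the `clusters`/`edges` arguments of
#'   [circuit_config]).
#' @export
default_clusters <- function() {
  data.frame(
    label = c("EG_ant", "EG_med", "EG_post", "PVG_sens",
              "L1", "L2", "ERM_motor", "Se0_ens"),
    cell_class = c("sensory", "sensory", "sensory", "sensory",
                   "interneuron", "interneuron", "motor", "modulatory"),
    modality = c("ENS_chemo", "ENS_mechano", "ENS_mechano", "ENS_mechano",
                 NA, NA, NA, NA),
    n_per_hemisphere = c(3L, 3L, 3L, 2L, 4L, 3L, 3L, 2L),
    unpaired = FALSE
  )
}

#' @rdname default_clusters
#' @export
default_edges <- function() {
  data.frame(
    from = c("EG_ant", "EG_med", "EG_post", "PVG_sens",
             "EG_post", "PVG_sens",
             "L1", "L1", "L2",
             "EG_med", "ERM_motor"),
    to = c("L1", "L1", "L1", "L1",
           "Se0_ens", "Se0_ens",
           "L2", "Se0_ens", "Se0_ens",
           "ERM_motor", "EG_post"),
    p_connect = c(0.5, 0.5, 0.5, 0.5,
                  0.8, 0.4,
                  0.5, 0.5, 0.6,
                  0.6, 0.6),
    mean_pairs = c(3, 3, 3, 3,
                   4, 2,
                   3, 3, 3,
                   3, 3)
  )
}

validate_circuit_config <- function(cfg) {
  cl <- cfg$clusters
  need_cl <- c("label", "cell_class", "modality", "n_per_hemisphere",
               "unpaired")
  if (!all(need_cl %in% names(cl)))
    abort_validation(paste0("clusters needs columns: ",
                            paste(need_cl, collapse = ", ")))
  if (anyDuplicated(cl$label))
    abort_validation("cluster labels must be unique")
  if (any(cl$n_per_hemisphere <= 0))
    abort_validation("cluster sizes must be positive")
  ed <- cfg$edges
  need_ed <- c("from", "to", "p_connect", "mean_pairs")
  if (!all(need_ed %in% names(ed)))
    abort_validation(paste0("edges needs columns: ",
                            paste(need_ed, collapse = ", ")))
  bad <- setdiff(unique(c(ed$from, ed$to)), cl$label)
  if (length(bad))
    abort_validation(paste0("edges reference unknown cluster(s): ",
                            paste(bad, collapse = ", ")))
  if (any(ed$p_connect < 0 | ed$p_connect > 1))
    abort_validation("connection probabilities must lie in [0, 1]")
  if (any(ed$mean_pairs < 0))
    abort_validation("mean_pairs must be non-negative")
  if (abs(cfg$asymmetry_eps) > 1)
    abort_validation("asymmetry_eps must lie in [-1, 1]")
  if (cfg$polyadicity < 1)
    abort_validation("polyadicity must be at least 1")
  if (abs(sum(cfg$tissue_probs) - 1) > 1e-9 || any(cfg$tissue_probs < 0))
    abort_validation("tissue_probs must be a probability vector")
  if (cfg$skeleton_nodes < 1 || cfg$skeleton_step_nm <= 0 ||
      cfg$peripheral_zone_rate < 0)
    abort_validation("skeleton and peripheral-zone parameters must be positive")
  invisible(cfg)
}

random_skeleton <- function(neuron_id, n_nodes, step_nm, branch_prob) {
  x <- y <- z <- numeric(n_nodes)
  parent <- rep(NA_integer_, n_nodes)
  tip <- 1L
  for (i in seq_len(n_nodes)[-1L]) {
    from <- if (stats::runif(1) < branch_prob) sample.int(i - 1L, 1L) else tip
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    x[i] <- x[from] + round(step_nm * dir[1L])
    y[i] <- y[from] + round(step_nm * dir[2L])
    z[i] <- z[from] + round(step_nm * dir[3L])
    parent[i] <- from
    tip <- i
  }
  skeleton(neuron_id,
           data.frame(node_id = seq_len(n_nodes), type = 0L,
                      x = x, y = y, z = z, radius = NA_real_,
                      parent_id = parent),
           origin_node = 1L)
}

#' Generate a synthetic connectome with planted ground truth
#'
#' Deterministic for a given seed. Neurons are instantiated per cluster
#' and hemisphere; every neuron gets a random-walk tree skeleton with node
#' 1 as its designated entry origin. For each edge specification and each
#' ordered neuron pair (pre, post) across those clusters, a connection is
#' drawn with probability `p_connect` and its synaptic pair count from a
#' Poisson with mean `mean_pairs`, scaled by `1 + eps` for left-left and
#' `1 - eps` for right-right pairs. Pairs are then grouped into polyadic
#' connectors, synapse nodes are sampled from the skeletons, and
#' peripheral active zones are planted on modulatory/secretory neurons
#' with the configured tissue-tag distribution.
#'
#' The returned ground-truth bundle holds the exact planted tallies
#' (count matrix, hemisphere budgets, peripheral-zone tallies) and the
#' exhaustively enumerated sensory pathway sums onto the modulatory
#' targets, so recovery can be asserted without re-deriving anything from
#' the generated files.
#'
#' @param cfg A [circuit_config].
#' @return List with `skeletons` (named list), `connectors`, `neurons`
#'   (the two tables), and `truth`.
#' @export
generate_circuit <- function(cfg) {
  validate_circuit_config(cfg)
  with_seed(cfg$seed, {
    cl <- cfg$clusters
    neurons <- do.call(rbind, lapply(seq_len(nrow(cl)), function(i) {
      if (isTRUE(cl$unpaired[i])) {
        data.frame(neuron_id = sprintf("%s_U%d", cl$label[i],
                                       seq_len(cl$n_per_hemisphere[i])),
                   cell_class = cl$cell_class[i], cluster = cl$label[i],
                   hemisphere = "unpaired", modality = cl$modality[i])
      } else {
        data.frame(
          neuron_id = c(sprintf("%s_L%d", cl$label[i],
                                seq_len(cl$n_per_hemisphere[i])),
                        sprintf("%s_R%d", cl$label[i],
                                seq_len(cl$n_per_hemisphere[i]))),
          cell_class = cl$cell_class[i], cluster = cl$label[i],
          hemisphere = rep(c("L", "R"), each = cl$n_per_hemisphere[i]),
          modality = cl$modality[i])
      }
    }))
    rownames(neurons) <- NULL

    skeletons <- lapply(neurons$neuron_id, function(id)
      random_skeleton(id, cfg$skeleton_nodes, cfg$skeleton_step_nm,
                      cfg$branch_prob))
    names(skeletons) <- neurons$neuron_id

    hemi <- stats::setNames(neurons$hemisphere, neurons$neuron_id)
    members <- split(neurons$neuron_id, neurons$cluster)

    # draw synaptic pair counts per ordered neuron pair
    pre_v <- character(0); post_v <- character(0); k_v <- integer(0)
    for (e in seq_len(nrow(cfg$edges))) {
      pres <- members[[cfg$edges$from[e]]]
      posts <- members[[cfg$edges$to[e]]]
      for (a in pres) for (b in posts) {
        if (a == b) next
        scale <- if (hemi[a] == "L" && hemi[b] == "L")
          1 + cfg$asymmetry_eps
        else if (hemi[a] == "R" && hemi[b] == "R")
          1 - cfg$asymmetry_eps
        else 1
        if (stats::runif(1) < cfg$edges$p_connect[e]) {
          k <- stats::rpois(1, cfg$edges$mean_pairs[e] * scale)
          if (k > 0) {
            pre_v <- c(pre_v, a); post_v <- c(post_v, b)
            k_v <- c(k_v, k)
          }
        }
      }
    }
    pair_pre <- rep(pre_v, k_v)
    pair_post <- rep(post_v, k_v)

    # group each presynaptic neuron's pairs into polyadic connectors
    conn_rows <- list()
    cid <- 0L
    for (a in unique(pair_pre)) {
      idx <- which(pair_pre == a)
      idx <- idx[sample.int(length(idx))]
      while (length(idx)) {
        k <- 1L + stats::rpois(1, cfg$polyadicity - 1)
        take <- idx[seq_len(min(k, length(idx)))]
        idx <- idx[-seq_len(min(k, length(idx)))]
        cid <- cid + 1L
        pre_node <- sample(skeletons[[a]]$nodes$node_id, 1L)
        post_nodes <- vapply(pair_post[take], function(b)
          sample(skeletons[[b]]$nodes$node_id, 1L), integer(1))
        conn_rows[[length(conn_rows) + 1L]] <- data.frame(
          connector_id = sprintf("cn%06d", cid),
          pre_neuron = a, pre_node = pre_node,
          post_neuron = pair_post[take], post_node = post_nodes,
          region = "CNS", tissue_tag = NA_character_)
      }
    }

    # peripheral active zones on modulatory / secretory neurons
    periph_targets <- neurons$neuron_id[
      neurons$cell_class %in% c("modulatory", "secretory")]
    planted_pz <- list()
    for (a in periph_targets) {
      nz <- stats::rpois(1, cfg$peripheral_zone_rate)
      if (nz == 0) next
      tags <- sample(names(cfg$tissue_probs), nz, replace = TRUE,
                     prob = cfg$tissue_probs)
      nodes <- sample(skeletons[[a]]$nodes$node_id, nz, replace = TRUE)
      cid_seq <- cid + seq_len(nz)
      cid <- cid + nz
      planted_pz[[a]] <- data.frame(
        connector_id = sprintf("cn%06d", cid_seq),
        pre_neuron = a, pre_node = nodes,
        post_neuron = NA_character_, post_node = NA_integer_,
        region = "periphery", tissue_tag = tags)
    }
    connectors <- do.call(rbind, c(conn_rows, unname(planted_pz)))
    if (is.null(connectors))
      connectors <- data.frame(connector_id = character(0),
                               pre_neuron = character(0),
                               pre_node = integer(0),
                               post_neuron = character(0),
                               post_node = integer(0),
                               region = character(0),
                               tissue_tag = character(0))
    rownames(connectors) <- NULL

    truth <- plant_truth(cfg, neurons, connectors, pair_pre, pair_post)
    list(config = cfg, skeletons = skeletons, connectors = connectors,
         neurons = neurons, truth = truth)
  })
}

plant_truth <- function(cfg, neurons, connectors, pair_pre, pair_post) {
  ids <- neurons$neuron_id
  counts <- table(factor(pair_pre, levels = ids),
                  factor(pair_post, levels = ids))
  counts <- matrix(as.integer(counts), nrow = length(ids),
                   dimnames = list(pre = ids, post = ids))
  fractions <- suppressMessages(input_fractions(counts))

  hemi <- stats::setNames(neurons$hemisphere, ids)
  budgets <- do.call(rbind, lapply(unique(neurons$cluster), function(clu) {
    memb <- ids[neurons$cluster == clu]
    do.call(rbind, lapply(c("in", "out"), function(dir) {
      sel <- if (dir == "out") pair_pre %in% memb else pair_post %in% memb
      oh <- hemi[pair_pre[sel]]
      th <- hemi[pair_post[sel]]
      ok <- oh %in% c("L", "R") & th %in% c("L", "R")
      tab <- table(factor(oh[ok], c("L", "R")), factor(th[ok], c("L", "R")))
      data.frame(cluster = clu, direction = dir,
                 LL = tab["L", "L"], RR = tab["R", "R"],
                 LR = tab["L", "R"], RL = tab["R", "L"])
    }))
  }))
  rownames(budgets) <- NULL

  pz <- peripheral_zones(connectors)
  pz_tally <- if (nrow(pz)) peripheral_zone_tally(connectors) else
    data.frame(neuron_id = character(0), tissue_tag = character(0),
               n = integer(0))

  sensory <- ids[neurons$cell_class == "sensory"]
  inter <- ids[neurons$cell_class == "interneuron"]
  targets <- ids[neurons$cell_class == "modulatory"]
  pathway_sums <- if (length(sensory) && length(targets))
    enumerate_pathway_sums(fractions, sensory, inter, targets,
                           max_layers = 2L)
  else data.frame(source = character(0), target = character(0),
                  pathway_sum = numeric(0))

  list(counts = counts, fractions = fractions, hemisphere_budgets = budgets,
       peripheral_tally = pz_tally, pathway_sums = pathway_sums)
}

#' Write a generated circuit to disk
#'
#' Emits one SWC per neuron plus a skeleton manifest, the connector TSV
#' and the annotation TSV, in the exact formats the readers consume.
#'
#' @param gen Output of [generate_circuit].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths.
#' @export
write_circuit <- function(gen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  skel_dir <- file.path(dir, "skeletons")
  dir.create(skel_dir, showWarnings = FALSE)
  swc_paths <- vapply(gen$skeletons, function(s) {
    p <- file.path(skel_dir, paste0(s$neuron_id, ".swc"))
    write_swc(s, p)
    p
  }, character(1))
  manifest <- data.frame(neuron_id = names(gen$skeletons),
                         swc_path = file.path("skeletons",
                                              basename(swc_paths)),
                         origin_node = vapply(gen$skeletons,
                                              function(s) s$origin_node,
                                              numeric(1)))
  man_path <- file.path(dir, "skeletons.tsv")
  utils::write.table(manifest, man_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  conn_path <- file.path(dir, "connectors.tsv")
  write_connectors(gen$connectors, conn_path)
  ann_path <- file.path(dir, "neurons.tsv")
  write_neuron_annotations(gen$neurons, ann_path)
  list(manifest = man_path, connectors = conn_path, annotations = ann_path,
       swc = unname(swc_paths))
}

#' Configuration for a synthetic two-ROI peristalsis trace
#'
#' Emulates a paired neurogenic/myogenic calcium recording: triggers occur
#' as a Poisson process with a hard refractory period (a contraction wave
#' occupies the esophagus for over a second, so triggers cannot overlap),
#' each trigger completes into a myogenic wave with probability
#' `completion_prob` after `latency` seconds, bumps are unit-amplitude
#' instant-rise exponential-decay kernels, and Gaussian noise is added at
#' `noise_sd` times the bump amplitude.
#'
#' @param seed Integer seed.
#' @param duration_s Recording duration, seconds.
#' @param sampling_rate Hz.
#' @param trigger_rate Triggers per minute.
#' @param completion_prob Probability a trigger completes, in \[0, 1\].
#' @param latency_s Trigger-to-wave latency, seconds.
#' @param kernel_tau_s Exponential decay constant of a bump, seconds.
#' @param noise_sd Noise standard deviation as a fraction of amplitude.
#' @param refractory_s Minimum inter-trigger gap, seconds.
#' @return List of class `trace_config`.
#' @export
trace_config <- function(seed = 1L, duration_s = 1200, sampling_rate = 20,
                         trigger_rate = 10, completion_prob = 0.6,
                         latency_s = 0.5, kernel_tau_s = 0.8,
                         noise_sd = 0.05, refractory_s = 2) {
  cfg <- list(seed = as.integer(seed), duration_s = duration_s,
              sampling_rate = sampling_rate, trigger_rate = trigger_rate,
              completion_prob = completion_prob, latency_s = latency_s,
              kernel_tau_s = kernel_tau_s, noise_sd = noise_sd,
              refractory_s = refractory_s)
  class(cfg) <- "trace_config"
  if (any(unlist(cfg[c("duration_s", "sampling_rate", "trigger_rate",
                       "latency_s", "kernel_tau_s")]) <= 0))
    abort_validation("durations, rates and time constants must be positive")
  if (cfg$completion_prob < 0 || cfg$completion_prob > 1)
    abort_validation("completion_prob must lie in [0, 1]")
  if (cfg$noise_sd < 0 || cfg$refractory_s < 0)
    abort_validation("noise_sd and refractory_s must be non-negative")
  mean_gap <- 60 / cfg$trigger_rate
  if (cfg$latency_s >= mean_gap)
    warning("latency is at least the mean inter-trigger interval: trigger/wave pairing will be ambiguous")
  if (cfg$refractory_s >= mean_gap)
    abort_validation("refractory_s must be below the mean inter-trigger gap")
  cfg
}

#' Generate a synthetic two-ROI trace with planted events
#'
#' @param cfg A [trace_config].
#' @return List with `trace` (a `two_roi_trace`), `trigger_times`,
#'   `completed_flags` and `wave_times` — the planted ground truth.
#' @export
generate_trace <- function(cfg) {
  with_seed(cfg$seed, {
    mean_gap <- 60 / cfg$trigger_rate
    exp_rate <- 1 / (mean_gap - cfg$refractory_s)
    # Poisson-with-refractory trigger times; draw enough gaps to cover
    n_guess <- ceiling(cfg$duration_s / mean_gap * 2) + 20L
    gaps <- cfg$refractory_s + stats::rexp(n_guess, exp_rate)
    trig <- cumsum(gaps)
    trig <- trig[trig < cfg$duration_s - cfg$latency_s - 1]
    completed <- stats::runif(length(trig)) < cfg$completion_prob
    wave <- trig[completed] + cfg$latency_s

    t <- seq(0, cfg$duration_s, by = 1 / cfg$sampling_rate)
    bump_sum <- function(times) {
      sig <- numeric(length(t))
      for (t0 in times) {
        i0 <- which(t >= t0)[1L]
        if (is.na(i0)) next
        idx <- i0:length(t)
        sig[idx] <- sig[idx] + exp(-(t[idx] - t[i0]) / cfg$kernel_tau_s)
      }
      sig
    }
    roi1 <- bump_sum(trig) + stats::rnorm(length(t), 0, cfg$noise_sd)
    roi2 <- bump_sum(wave) + stats::rnorm(length(t), 0, cfg$noise_sd)
    list(trace = two_roi_trace(t, roi1, roi2),
         trigger_times = trig, completed_flags = completed,
         wave_times = wave)
  })
}

#' Write a generated trace as CSV
#' @param gen Output of [generate_trace].
#' @param path Output CSV path.
#' @export
write_trace <- function(gen, path) {
  utils::write.csv(data.frame(t = gen$trace$t, roi1 = gen$trace$roi1,
                              roi2 = gen$trace$roi2),
                   path, row.names = FALSE)
  invisible(path)
}
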