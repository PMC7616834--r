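#' Read a connector (synapse) table
#'
#' One row per synaptic pair: a polyadic connector contacting k postsynaptic
#' partners occupies k rows sharing a `connector_id`. A row with an empty
#' `post_neuron` is a peripheral active zone — a presynaptic-like release
#' site with no identifiable postsynaptic partner — and must carry a
#' `tissue_tag` (the tissue it abuts, e.g. HCG, PVG, ring_gland, midgut).
#' The `region` column (for example `CNS` vs `periphery`) is an input
#' annotation, never inferred from geometry.
#'
#' @param path TSV with columns `connector_id`, `pre_neuron`, `pre_node`,
#'   `post_neuron` (empty for peripheral zones), `post_node`, `region`,
#'   `tissue_tag`.
#' @return `data.frame` of synaptic pairs and peripheral zones.
#' @export
read_connectors <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("connector_id", "pre_neuron", "pre_node", "post_neuron",
            "post_node", "region", "tissue_tag")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_parse(paste0("connector table missing column(s): ",
                       paste(miss, collapse = ", ")))
  validate_connectors(df)
  df
}

validate_connectors <- function(connectors) {
  periph <- is.na(connectors$post_neuron)
  untagged <- periph & is.na(connectors$tissue_tag)
  if (any(untagged))
    abort_validation(paste0(
      "peripheral active zone(s) without tissue_tag: connector ",
      paste(utils::head(connectors$connector_id[untagged], 10L),
            collapse = ", ")))
  invisible(connectors)
}

#' Write a connector table
#' @param connectors Connector `data.frame` (see [read_connectors]).
#' @param path Output TSV path.
#' @export
write_connectors <- function(connectors, path) {
  utils::write.table(connectors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a neuron annotation table
#'
#' @param path TSV with columns `neuron_id`, `cell_class` (one of sensory,
#'   interneuron, motor, modulatory, secretory, tissue), `cluster`,
#'   `hemisphere` (`L`, `R` or `unpaired`) and `modality` (required exactly
#'   for sensory neurons, e.g. `ENS_mechano`, `gustatory`).
#' @return `data.frame` of neuron records.
#' @export
read_neuron_annotations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("neuron_id", "cell_class", "cluster", "hemisphere", "modality")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_parse(paste0("annotation table missing column(s): ",
                       paste(miss, collapse = ", ")))
  validate_neurons(df)
  df
}

validate_neurons <- function(neurons) {
  classes <- c("sensory", "interneuron", "motor", "modulatory",
               "secretory", "tissue")
  bad <- setdiff(unique(neurons$cell_class), classes)
  if (length(bad))
    abort_validation(paste0("unknown cell_class: ", paste(bad, collapse = ", ")))
  if (anyDuplicated(neurons$neuron_id))
    abort_validation("duplicate neuron_id in annotation table")
  if (any(is.na(neurons$cluster)) || any(is.na(neurons$hemisphere)))
    abort_validation("cluster and hemisphere must be non-empty")
  sens <- neurons$cell_class == "sensory"
  if (any(sens & is.na(neurons$modality)))
    abort_validation(paste0("sensory neuron(s) lacking modality: ",
      paste(neurons$neuron_id[sens & is.na(neurons$modality)], collapse = ", ")))
  if (any(!sens & !is.na(neurons$modality)))
    abort_validation("modality must be present exactly for sensory neurons")
  invisible(neurons)
}

#' Write a neuron annotation table
#' @param neurons Annotation `data.frame` (see [read_neuron_annotations]).
#' @param path Output TSV path.
#' @export
write_neuron_annotations <- function(neurons, path) {
  utils::write.table(neurons, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

synaptic_pairs <- function(connectors) {
  connectors[!is.na(connectors$post_neuron), , drop = FALSE]
}

peripheral_zones <- function(connectors) {
  connectors[is.na(connectors$post_neuron), , drop = FALSE]
}

#' Build the synapse-pair count matrix
#'
#' Entry (i, j) is the number of synaptic pairs with presynaptic neuron i
#' and postsynaptic neuron j across all connectors; a polyadic connector
#' with k postsynaptic partners contributes k pairs. Pairs referencing
#' neurons absent from the annotation table are reported in a warning and
#' dropped.
#'
#' @param connectors Connector `data.frame` (see [read_connectors]).
#' @param neurons Annotation `data.frame` (see [read_neuron_annotations]).
#' @return Integer matrix with one row and column per annotated neuron, in
#'   annotation-table order.
#' @export
build_counts <- function(connectors, neurons) {
  ids <- neurons$neuron_id
  pairs <- synaptic_pairs(connectors)
  known <- pairs$pre_neuron %in% ids & pairs$post_neuron %in% ids
  if (any(!known)) {
    bad <- unique(c(setdiff(pairs$pre_neuron, ids),
                    setdiff(pairs$post_neuron, ids)))
    warning(sprintf("dropping %d pair(s) referencing unannotated neuron(s): %s",
                    sum(!known), paste(bad, collapse = ", ")))
    pairs <- pairs[known, , drop = FALSE]
  }
  m <- table(factor(pairs$pre_neuron, levels = ids),
             factor(pairs$post_neuron, levels = ids))
  m <- matrix(as.integer(m), nrow = length(ids),
              dimnames = list(pre = ids, post = ids))
  m
}

#' Convert a count matrix to input fractions
#'
#' Each column j is divided by the total number of synaptic inputs onto
#' neuron j (the column sum — the neuron's full input budget as present in
#' the count matrix). Columns with zero inputs are undefined and returned
#' as `NA`, never silently zero; their names are reported in a message.
#'
#' @param m Count matrix from [build_counts] (or any non-negative matrix).
#' @return Numeric matrix of input fractions in `[0, 1]`; undefined columns
#'   are all-`NA`.
#' @export
input_fractions <- function(m) {
  totals <- colSums(m)
  f <- sweep(m, 2L, totals, "/")
  if (any(totals == 0)) {
    f[, totals == 0] <- NA_real_
    message(sprintf("input fractions undefined for %d neuron(s) with zero inputs: %s",
                    sum(totals == 0),
                    paste(colnames(m)[totals == 0], collapse = ", ")))
  }
  f
}

#' Aggregate a neuron-level matrix to cluster level
#'
#' Counts are summed within cluster blocks. With `percent_out = TRUE` each
#' source cluster's row is expressed as the percent of that cluster's total
#' outgoing budget (the convention used for monosynaptic output budgets).
#'
#' @param m Matrix with neuron ids as dimnames (counts or fractions).
#' @param neurons Annotation table mapping `neuron_id` to `cluster`.
#' @param percent_out If `TRUE`, scale each row to percent of its row total.
#' @return Cluster-by-cluster matrix.
#' @export
aggregate_by_cluster <- function(m, neurons, percent_out = FALSE) {
  cl_row <- neurons$cluster[match(rownames(m), neurons$neuron_id)]
  cl_col <- neurons$cluster[match(colnames(m), neurons$neuron_id)]
  if (anyNA(cl_row) || anyNA(cl_col))
    abort_validation("every indexed neuron needs a cluster annotation")
  levels_row <- unique(neurons$cluster[neurons$neuron_id %in% rownames(m)])
  levels_col <- unique(neurons$cluster[neurons$neuron_id %in% colnames(m)])
  agg <- rowsum(t(rowsum(m, cl_row)), cl_col)
  agg <- t(agg)[levels_row, levels_col, drop = FALSE]
  if (percent_out) {
    tot <- rowSums(agg)
    agg <- sweep(agg, 1L, tot, "/") * 100
    agg[tot == 0, ] <- NA_real_
  }
  agg
}

#' Input/output synaptic balance of one neuron
#'
#' Counts this neuron's synaptic inputs and outputs (peripheral active
#' zones count as outputs), optionally restricted to connectors in one
#' region (for example only synapses in the CNS), and reports the input
#' share in/(in+out) — 0 for a pure output neuron, 1 for pure input, near
#' 0.5 for the hybrid pattern.
#'
#' @param neuron_id Neuron to profile.
#' @param connectors Connector table.
#' @param region Optional region label filter (matched against the
#'   connector `region` column).
#' @return List with `inputs`, `outputs`, `input_share` (`NA` when the
#'   neuron has no synapses in the selection).
#' @export
io_balance <- function(neuron_id, connectors, region = NULL) {
  sel <- connectors
  if (!is.null(region)) sel <- sel[sel$region %in% region, , drop = FALSE]
  pairs <- synaptic_pairs(sel)
  n_in <- sum(pairs$post_neuron == neuron_id)
  n_out <- sum(sel$pre_neuron == neuron_id)
  share <- if (n_in + n_out == 0) NA_real_ else n_in / (n_in + n_out)
  list(inputs = n_in, outputs = n_out, input_share = share)
}

#' Hemisphere budget of a neuron cluster
#'
#' Tallies a cluster's incoming or outgoing synaptic pairs by origin and
#' target hemisphere (LL, RR, LR, RL). For `direction = "out"` the origin
#' is the cluster neuron and the target the partner; for `"in"` the origin
#' is the presynaptic partner and the target the cluster neuron. Pairs
#' whose endpoints include an unpaired or unannotated neuron are excluded
#' and their count reported, because they have no hemisphere homologue.
#'
#' @param connectors Connector table.
#' @param neurons Annotation table.
#' @param cluster Cluster label.
#' @param direction `"in"` or `"out"`.
#' @return List with `cluster`, `direction`, `LL`, `RR`, `LR`, `RL`,
#'   `excluded` (pairs dropped), and `percent` (the four tallies as percent
#'   of their total, `NA` when the total is zero).
#' @export
hemisphere_budgets <- function(connectors, neurons, cluster,
                               direction = c("out", "in")) {
  direction <- match.arg(direction)
  if (!cluster %in% neurons$cluster)
    abort_lookup(sprintf("cluster '%s' not present in annotations", cluster))
  members <- neurons$neuron_id[neurons$cluster == cluster]
  hemi <- stats::setNames(neurons$hemisphere, neurons$neuron_id)
  pairs <- synaptic_pairs(connectors)
  pairs <- if (direction == "out")
    pairs[pairs$pre_neuron %in% members, , drop = FALSE]
  else
    pairs[pairs$post_neuron %in% members, , drop = FALSE]
  origin <- if (direction == "out") pairs$pre_neuron else pairs$pre_neuron
  target <- pairs$post_neuron
  # origin hemisphere x target hemisphere; origin is always the presynaptic
  # side of the pair, target the postsynaptic side
  oh <- unname(hemi[pairs$pre_neuron])
  th <- unname(hemi[pairs$post_neuron])
  ok <- !is.na(oh) & !is.na(th) & oh %in% c("L", "R") & th %in% c("L", "R")
  excluded <- sum(!ok)
  oh <- oh[ok]; th <- th[ok]
  tab <- table(factor(oh, c("L", "R")), factor(th, c("L", "R")))
  counts <- c(LL = tab["L", "L"], RR = tab["R", "R"],
              LR = tab["L", "R"], RL = tab["R", "L"])
  total <- sum(counts)
  pct <- if (total > 0) 100 * counts / total else rep(NA_real_, 4L)
  c(list(cluster = cluster, direction = direction),
    as.list(as.integer(counts)) |> stats::setNames(names(counts)),
    list(excluded = excluded, percent = pct))
}

#' Tally peripheral active zones by tissue
#'
#' Counts per-neuron, per-tissue peripheral active zones (connectors with
#' no postsynaptic partner). The grand total always equals the number of
#' empty-post connectors. An untagged peripheral zone is a validation
#' error, as is a tag outside the supplied taxonomy.
#'
#' @param connectors Connector table.
#' @param taxonomy Optional character vector of allowed tissue tags.
#' @return `data.frame` with columns `neuron_id`, `tissue_tag`, `n`.
#' @export
peripheral_zone_tally <- function(connectors, taxonomy = NULL) {
  pz <- peripheral_zones(connectors)
  if (!nrow(pz))
    return(data.frame(neuron_id = character(0), tissue_tag = character(0),
                      n = integer(0)))
  if (any(is.na(pz$tissue_tag)))
    abort_validation(paste0("untagged peripheral active zone(s): connector ",
      paste(pz$connector_id[is.na(pz$tissue_tag)], collapse = ", ")))
  if (!is.null(taxonomy)) {
    bad <- setdiff(unique(pz$tissue_tag), taxonomy)
    if (length(bad))
      abort_validation(paste0("tissue tag(s) outside taxonomy: ",
                              paste(bad, collapse = ", ")))
  }
  agg <- stats::aggregate(list(n = pz$connector_id),
                          by = list(neuron_id = pz$pre_neuron,
                                    tissue_tag = pz$tissue_tag),
                          FUN = length)
  agg <- agg[order(agg$neuron_id, agg$tissue_tag), ]
  rownames(agg) <- NULL
  agg
}

#' Write a labeled matrix as CSV
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
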