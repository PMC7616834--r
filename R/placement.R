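#' Geodesic placement of every synapse on a neuron's arbor
#'
#' For each synaptic pair involving the analyzed neuron, reports the
#' geodesic distance (in nm, along the arbor) between the designated
#' origin node — typically the annotated CNS-entry / vagus-nerve-junction
#' node — and the synapse's node on this neuron: the presynaptic node for
#' outputs (including peripheral active zones), the postsynaptic node for
#' inputs. Partners are grouped by the supplied mapping (for example their
#' cluster); peripheral active zones are grouped by their tissue tag.
#' When several neurons share an anatomical origin, each neuron's distances
#' are measured on its own tree from its own annotated entry node —
#' cross-neuron distances are never mixed.
#'
#' @param s A [skeleton] for the analyzed neuron.
#' @param connectors Connector table (see [read_connectors]).
#' @param origin Origin node id; defaults to the skeleton's `origin_node`.
#' @param partner_group Named character vector mapping partner neuron ids
#'   to group labels; unmapped partners fall into `"other"`.
#' @return `data.frame` with columns `neuron`, `connector`, `polarity`
#'   (`input`/`output`), `partner`, `partner_group`, `node_id`,
#'   `geodesic_nm`.
#' @export
synapse_distances <- function(s, connectors, origin = s$origin_node,
                              partner_group = NULL) {
  if (is.null(origin))
    abort_validation("no origin node: set origin or the skeleton's origin_node")
  nid <- s$neuron_id
  pairs <- synaptic_pairs(connectors)
  outs <- pairs[pairs$pre_neuron == nid, , drop = FALSE]
  ins <- pairs[pairs$post_neuron == nid, , drop = FALSE]
  pz <- peripheral_zones(connectors)
  pz <- pz[pz$pre_neuron == nid, , drop = FALSE]
  rec <- data.frame(
    neuron = rep(nid, nrow(outs) + nrow(ins) + nrow(pz)),
    connector = c(outs$connector_id, ins$connector_id, pz$connector_id),
    polarity = c(rep("output", nrow(outs)), rep("input", nrow(ins)),
                 rep("output", nrow(pz))),
    partner = c(outs$post_neuron, ins$pre_neuron, rep(NA, nrow(pz))),
    node_id = c(outs$pre_node, ins$post_node, pz$pre_node)
  )
  absent <- setdiff(unique(rec$node_id), s$nodes$node_id)
  if (length(absent))
    abort_validation(paste0("connector node(s) absent from skeleton '", nid,
                            "': ", paste(absent, collapse = ", ")))
  grp <- rep("other", nrow(rec))
  if (!is.null(partner_group)) {
    hit <- !is.na(rec$partner) & rec$partner %in% names(partner_group)
    grp[hit] <- unname(partner_group[rec$partner[hit]])
  }
  grp[is.na(rec$partner)] <- pz$tissue_tag
  rec$partner_group <- grp
  d <- geodesic_all(s, origin)
  rec$geodesic_nm <- unname(d[as.character(rec$node_id)])
  rec <- rec[, c("neuron", "connector", "polarity", "partner",
                 "partner_group", "node_id", "geodesic_nm")]
  rownames(rec) <- NULL
  rec
}

#' One-way group comparison of synapse placement
#'
#' Classical one-way fixed-effects analysis of variance of geodesic
#' distance by partner group: between- and within-group sums of squares,
#' the F statistic and its upper-tail p value, plus per-group summaries
#' ordered by mean distance. When every group has zero within-group
#' variance but the means differ, F diverges and is reported as `Inf` with
#' p = 0 and a warning.
#'
#' @param records `data.frame` from [synapse_distances] (needs columns
#'   `partner_group`, `geodesic_nm`), or any data with those columns.
#' @param min_n Minimum group size; groups smaller than this are dropped
#'   with a message.
#' @return List with `groups` (n, mean, median per group, ordered by
#'   mean), `F`, `df` (numerator, denominator), `p_value`.
#' @export
group_order_test <- function(records, min_n = 2L) {
  g <- factor(records$partner_group)
  y <- records$geodesic_nm
  sizes <- table(g)
  small <- names(sizes)[sizes < min_n]
  if (length(small)) {
    message(sprintf("dropping group(s) with n < %d: %s", min_n,
                    paste(small, collapse = ", ")))
    keep <- !(as.character(g) %in% small)
    g <- droplevels(g[keep]); y <- y[keep]
  }
  k <- nlevels(g)
  n <- length(y)
  if (k < 2L || n < k + 1L)
    abort_insufficient(
      "need at least 2 groups with at least 2 observations each")
  means <- tapply(y, g, mean)
  grand <- mean(y)
  ssb <- sum(table(g) * (means - grand)^2)
  ssw <- sum((y - means[g])^2)
  df1 <- k - 1L
  df2 <- n - k
  if (ssw == 0) {
    if (ssb == 0) {
      Fstat <- 0
      p <- 1
    } else {
      warning("zero within-group variance with distinct means: F reported as Inf, p = 0")
      Fstat <- Inf
      p <- 0
    }
  } else {
    Fstat <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  }
  summ <- data.frame(
    partner_group = names(means),
    n = as.integer(table(g)),
    mean_nm = as.numeric(means),
    median_nm = as.numeric(tapply(y, g, stats::median))
  )
  summ <- summ[order(summ$mean_nm), ]
  rownames(summ) <- NULL
  list(groups = summ, F = Fstat, df = c(df1, df2), p_value = p)
}
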