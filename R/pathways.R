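#' Direct sensory pathway scores
#'
#' The direct pathway score of sensory neuron s onto target t is simply
#' the normalized synaptic input fraction f\[s, t\]: the share of t's total
#' synaptic input budget contributed by s. One record is emitted per
#' (source, target) pair with a nonzero fraction.
#'
#' @param f Input-fraction matrix from [input_fractions].
#' @param sensory Character vector of sensory neuron ids (rows of `f`).
#' @param targets Character vector of target neuron ids (columns of `f`).
#' @return `data.frame` with columns `source`, `target`, `via` (empty for
#'   direct paths), `n_layers` (0) and `score`. Targets whose input
#'   fractions are undefined (zero total input) are skipped and listed in
#'   the `undefined_targets` attribute.
#' @export
direct_scores <- function(f, sensory, targets) {
  check_index(f, sensory, targets)
  sub <- f[sensory, targets, drop = FALSE]
  undef <- targets[colSums(is.na(sub)) == length(sensory)]
  recs <- which(!is.na(sub) & sub > 0, arr.ind = TRUE)
  out <- data.frame(
    source = sensory[recs[, 1L]],
    target = targets[recs[, 2L]],
    via = rep("", nrow(recs)),
    n_layers = rep(0L, nrow(recs)),
    score = sub[recs]
  )
  out <- out[order(out$source, out$target), ]
  rownames(out) <- NULL
  if (length(undef)) {
    message(sprintf("direct scores undefined for target(s): %s",
                    paste(undef, collapse = ", ")))
    attr(out, "undefined_targets") <- undef
  }
  out
}

check_index <- function(f, ...) {
  wanted <- unique(unlist(list(...)))
  miss <- setdiff(wanted, intersect(rownames(f), colnames(f)))
  if (length(miss))
    abort_lookup(paste0("neuron(s) not indexed in fraction matrix: ",
                        paste(miss, collapse = ", ")))
}

#' Indirect sensory pathway scores through one or two interneuron layers
#'
#' For every simple path s -> i1 \[-> i2\] -> t, with s sensory, i1/i2
#' interneurons and t a target, the path score is the product of the input
#' fractions along its hops — each hop's fraction being normalized to the
#' total input budget of the hop's postsynaptic neuron. Paths revisiting a
#' neuron are excluded, each distinct path is a separate record, and hops
#' whose fraction is undefined (postsynaptic neuron with zero recorded
#' inputs) skip the path with a log message.
#'
#' @param f Input-fraction matrix from [input_fractions].
#' @param sensory,interneurons,targets Disjoint neuron id sets.
#' @param max_layers Interneuron layer depth, 1 or 2.
#' @return `data.frame` with columns `source`, `target`, `via`
#'   (semicolon-joined interneuron ids), `n_layers` and `score`.
#' @export
indirect_scores <- function(f, sensory, interneurons, targets,
                            max_layers = 2L) {
  if (!max_layers %in% c(1L, 2L))
    abort_validation("max_layers must be 1 or 2")
  if (length(intersect(sensory, interneurons)) ||
      length(intersect(sensory, targets)) ||
      length(intersect(interneurons, targets)))
    abort_validation("sensory, interneuron and target sets must be disjoint")
  check_index(f, sensory, interneurons, targets)

  edges <- function(from, to) {
    sub <- f[from, to, drop = FALSE]
    idx <- which(!is.na(sub) & sub > 0, arr.ind = TRUE)
    data.frame(from = from[idx[, 1L]], to = to[idx[, 2L]], w = sub[idx])
  }
  si <- edges(sensory, interneurons)     # sensory -> L1
  names(si) <- c("source", "i1", "w1")
  it <- edges(interneurons, targets)     # L1/L2 -> target
  names(it) <- c("ilast", "target", "wt")
  n_skipped <- sum(is.na(f[sensory, interneurons])) +
    sum(is.na(f[interneurons, targets]))

  one <- merge(si, it, by.x = "i1", by.y = "ilast")
  recs <- data.frame(source = one$source, target = one$target, via = one$i1,
                     n_layers = rep(1L, nrow(one)), score = one$w1 * one$wt)

  if (max_layers == 2L && nrow(si)) {
    ii <- edges(interneurons, interneurons)  # L1 -> L2
    names(ii) <- c("i1", "i2", "w2")
    ii <- ii[ii$i1 != ii$i2, , drop = FALSE]
    if (nrow(ii)) {
      two <- merge(merge(si, ii, by = "i1"), it,
                   by.x = "i2", by.y = "ilast")
      if (nrow(two)) {
        recs2 <- data.frame(
          source = two$source, target = two$target,
          via = paste(two$i1, two$i2, sep = ";"),
          n_layers = rep(2L, nrow(two)), score = two$w1 * two$w2 * two$wt
        )
        recs <- rbind(recs, recs2)
      }
    }
  }
  if (n_skipped > 0)
    message(sprintf(
      "%d hop(s) with undefined input fractions excluded from path search",
      n_skipped))
  recs <- recs[order(recs$source, recs$target, recs$n_layers, recs$via), ]
  rownames(recs) <- NULL
  recs
}

#' Sensory fingerprint (sensory composition) of an interneuron
#'
#' The complete sensory input of one interneuron grouped by sensory
#' modality: for each modality, the sum of input fractions f\[s, i\] over
#' the sensory neurons s of that modality.
#'
#' @param f Input-fraction matrix.
#' @param interneuron Interneuron id (column of `f`).
#' @param sensory Sensory neuron ids.
#' @param modality_map Named character vector mapping sensory neuron id to
#'   modality label.
#' @return Named numeric vector of per-modality input fractions (all
#'   modalities occurring in `modality_map` for `sensory`, zero-filled).
#' @export
sensory_fingerprint <- function(f, interneuron, sensory, modality_map) {
  check_index(f, sensory, interneuron)
  miss <- setdiff(sensory, names(modality_map))
  if (length(miss))
    abort_validation(paste0("sensory neuron(s) lacking modality: ",
                            paste(miss, collapse = ", ")))
  mods <- sort(unique(unname(modality_map[sensory])))
  vals <- f[sensory, interneuron]
  vals[is.na(vals)] <- 0
  out <- vapply(mods, function(m)
    sum(vals[modality_map[sensory] == m]), numeric(1))
  out
}

#' Roll pathway scores up to modality-level pathway weights
#'
#' For each target (or target group) and sensory modality, sums all direct
#' and all indirect pathway scores whose source belongs to that modality.
#' The full pathway weight is `total = direct + indirect`, and
#' `normalized_percent` expresses each modality's total as a percent of the
#' summed totals for that target (summing to 100 per target).
#'
#' @param direct `data.frame` from [direct_scores].
#' @param indirect `data.frame` from [indirect_scores] (may have 0 rows).
#' @param modality_map Named character vector: sensory neuron id -> modality.
#' @param target_group Optional named character vector mapping target
#'   neuron id to a group label (e.g. its cluster); unmapped targets keep
#'   their own id.
#' @return `data.frame` with columns `target`, `modality`, `direct`,
#'   `indirect`, `total`, `normalized_percent`. Targets with all-zero
#'   totals have `NA` percentages, reported in a message.
#' @export
modality_rollup <- function(direct, indirect, modality_map,
                            target_group = NULL) {
  paths <- rbind(direct[, c("source", "target", "n_layers", "score")],
                 indirect[, c("source", "target", "n_layers", "score")])
  if (!nrow(paths))
    return(data.frame(target = character(0), modality = character(0),
                      direct = numeric(0), indirect = numeric(0),
                      total = numeric(0), normalized_percent = numeric(0)))
  miss <- setdiff(unique(paths$source), names(modality_map))
  if (length(miss))
    abort_validation(paste0("source(s) lacking modality: ",
                            paste(miss, collapse = ", ")))
  paths$modality <- unname(modality_map[paths$source])
  if (!is.null(target_group)) {
    grp <- target_group[paths$target]
    paths$target <- ifelse(is.na(grp), paths$target, unname(grp))
  }
  key <- interaction(paths$target, paths$modality, drop = TRUE, sep = "\r")
  d <- tapply(ifelse(paths$n_layers == 0L, paths$score, 0), key, sum)
  i <- tapply(ifelse(paths$n_layers > 0L, paths$score, 0), key, sum)
  parts <- do.call(rbind, strsplit(names(d), "\r", fixed = TRUE))
  out <- data.frame(target = parts[, 1L], modality = parts[, 2L],
                    direct = as.numeric(d), indirect = as.numeric(i))
  out$total <- out$direct + out$indirect
  tsum <- tapply(out$total, out$target, sum)
  out$normalized_percent <- 100 * out$total / as.numeric(tsum[out$target])
  zero <- names(tsum)[tsum == 0]
  if (length(zero)) {
    out$normalized_percent[out$target %in% zero] <- NA_real_
    message(sprintf("all-zero pathway totals for target(s): %s",
                    paste(zero, collapse = ", ")))
  }
  out <- out[order(out$target, out$modality), ]
  rownames(out) <- NULL
  out
}

#' Dominant sensory modality per target
#'
#' @param rollup Output of [modality_rollup].
#' @return `data.frame` with columns `target`, `modality` (ties broken
#'   lexicographically and flagged in the `tie` column).
#' @export
dominant_modality <- function(rollup) {
  split_tabs <- split(rollup, rollup$target)
  recs <- lapply(split_tabs, function(tab) {
    best <- max(tab$total)
    winners <- sort(tab$modality[tab$total == best])
    data.frame(target = tab$target[1L], modality = winners[1L],
               tie = length(winners) > 1L)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Exhaustive pathway-sum enumeration (reference route)
#'
#' Depth-limited exhaustive enumeration of simple sensory -> interneuron
#' -> target paths by recursive depth-first search over the nonzero
#' entries of the fraction matrix, summing hop products per
#' (source, target). This is a deliberately independent, unoptimized code
#' path used to cross-check the vectorized [direct_scores] /
#' [indirect_scores] tables and to stamp ground truth into synthetic
#' circuits.
#'
#' @inheritParams indirect_scores
#' @param include_direct Include the zero-interneuron (direct) hop.
#' @return `data.frame` with columns `source`, `target`, `pathway_sum`.
#' @export
enumerate_pathway_sums <- function(f, sensory, interneurons, targets,
                                   max_layers = 2L, include_direct = TRUE) {
  acc <- new.env(parent = emptyenv())
  add <- function(s, t, w) {
    key <- paste(s, t, sep = "\r")
    acc[[key]] <- (acc[[key]] %||% 0) + w
  }
  hop <- function(from, to) {
    w <- f[from, to]
    if (is.na(w)) 0 else w
  }
  walk <- function(s, node, w, depth, visited, at_target) {
    if (at_target) { add(s, node, w); return(invisible()) }
    for (t in targets) {
      wt <- hop(node, t)
      if (wt > 0) walk(s, t, w * wt, depth, visited, TRUE)
    }
    if (depth < max_layers)
      for (i in interneurons) {
        if (i %in% visited) next
        wi <- hop(node, i)
        if (wi > 0) walk(s, i, w * wi, depth + 1L, c(visited, i), FALSE)
      }
  }
  for (s in sensory) {
    if (include_direct)
      for (t in targets) {
        wt <- hop(s, t)
        if (wt > 0) add(s, t, wt)
      }
    for (i in interneurons) {
      wi <- hop(s, i)
      if (wi > 0) walk(s, i, wi, 1L, i, FALSE)
    }
  }
  keys <- ls(acc)
  if (!length(keys))
    return(data.frame(source = character(0), target = character(0),
                      pathway_sum = numeric(0)))
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- data.frame(source = parts[, 1L], target = parts[, 2L],
                    pathway_sum = vapply(keys, function(k) acc[[k]],
                                         numeric(1)))
  out <- out[order(out$source, out$target), ]
  rownames(out) <- NULL
  out
}
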