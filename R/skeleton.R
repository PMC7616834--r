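#' Construct a neuronal skeleton
#'
#' A skeleton is the rooted tree of 3D nodes tracing one neuron's arbor, the
#' substrate for geodesic distances, dendrogram linearization and synapse
#' placement analysis. Coordinates are in nanometres throughout; no unit
#' conversion happens inside the package.
#'
#' @param neuron_id Identifier of the neuron the skeleton belongs to.
#' @param nodes `data.frame` with columns `node_id` (positive integer, unique),
#'   `type` (integer, preserved but not interpreted), `x`, `y`, `z`
#'   (nanometres), `radius` (nanometres, may be `NA`) and `parent_id`
#'   (integer; `NA` for the single root).
#' @param origin_node Optional node id used as measurement origin (for
#'   example the CNS-entry/vagus-nerve-junction node). Never inferred from
#'   geometry: it is an anatomical annotation that must be supplied.
#' @return An object of class `skeleton`.
#' @export
skeleton <- function(neuron_id, nodes, origin_node = NULL) {
  required <- c("node_id", "x", "y", "z", "parent_id")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols))
    abort_validation(paste0("nodes is missing column(s): ",
                            paste(missing_cols, collapse = ", ")))
  if (is.null(nodes$type)) nodes$type <- 0L
  if (is.null(nodes$radius)) nodes$radius <- NA_real_
  nodes <- nodes[order(nodes$node_id),
                 c("node_id", "type", "x", "y", "z", "radius", "parent_id")]
  rownames(nodes) <- NULL
  s <- structure(list(neuron_id = neuron_id, nodes = nodes,
                      origin_node = origin_node),
                 class = "skeleton")
  validate_skeleton(s)
  s
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("skeleton '%s': %d nodes, cable %.0f nm, root %d%s\n",
              x$neuron_id, nrow(x$nodes), cable_length(x), skeleton_root(x),
              if (!is.null(x$origin_node))
                sprintf(", origin %d", x$origin_node) else ""))
  invisible(x)
}

validate_skeleton <- function(s) {
  nd <- s$nodes
  if (anyDuplicated(nd$node_id))
    abort_validation(paste0("duplicate node ids: ",
      paste(unique(nd$node_id[duplicated(nd$node_id)]), collapse = ", ")))
  if (any(nd$node_id <= 0, na.rm = TRUE) || anyNA(nd$node_id))
    abort_validation("node ids must be positive integers")
  roots <- which(is.na(nd$parent_id))
  if (length(roots) != 1L)
    abort_validation(sprintf("skeleton must have exactly one root, found %d",
                             length(roots)))
  dangling <- setdiff(nd$parent_id[!is.na(nd$parent_id)], nd$node_id)
  if (length(dangling))
    abort_validation(paste0("dangling parent id(s): ",
                            paste(dangling, collapse = ", ")))
  # A connected tree on n nodes has n-1 child->parent edges and no cycles;
  # detect cycles/disconnection by walking each node to the root.
  idx <- match(nd$parent_id, nd$node_id)
  n <- nrow(nd)
  reach <- logical(n)
  reach[roots] <- TRUE
  for (i in seq_len(n)) {
    path <- integer(0)
    j <- i
    while (!reach[j]) {
      if (j %in% path)
        abort_validation(paste0("cycle detected involving node ",
                                nd$node_id[j]))
      path <- c(path, j)
      j <- idx[j]
    }
    reach[path] <- TRUE
  }
  if (!is.null(s$origin_node) && !(s$origin_node %in% nd$node_id))
    abort_validation(sprintf("origin_node %s not present in skeleton",
                             s$origin_node))
  invisible(s)
}

skeleton_root <- function(s) s$nodes$node_id[is.na(s$nodes$parent_id)]

# Undirected weighted adjacency of the tree; edge weights are Euclidean
# parent-child segment lengths in nm. Returns list(ids, adj) where adj[[i]]
# is a matrix with columns (neighbour index, edge length).
skeleton_adjacency <- function(s) {
  nd <- s$nodes
  ids <- nd$node_id
  pidx <- match(nd$parent_id, ids)
  has_parent <- !is.na(pidx)
  dx <- nd$x - nd$x[pidx]
  dy <- nd$y - nd$y[pidx]
  dz <- nd$z - nd$z[pidx]
  elen <- sqrt(dx^2 + dy^2 + dz^2)
  n <- length(ids)
  adj <- vector("list", n)
  for (i in which(has_parent)) {
    p <- pidx[i]
    adj[[i]] <- rbind(adj[[i]], c(p, elen[i]))
    adj[[p]] <- rbind(adj[[p]], c(i, elen[i]))
  }
  list(ids = ids, adj = adj, edge_len = elen, parent_idx = pidx)
}

# Distances (nm) from `from` (node id) to every node, by depth-first
# accumulation over the undirected tree. Returns a vector named by node id.
geodesic_all <- function(s, from) {
  g <- skeleton_adjacency(s)
  start <- match(from, g$ids)
  if (is.na(start))
    abort_lookup(sprintf("node %s not in skeleton '%s'", from, s$neuron_id))
  n <- length(g$ids)
  dist <- rep(NA_real_, n)
  dist[start] <- 0
  stack <- start
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- g$adj[[v]]
    if (is.null(nb)) next
    for (k in seq_len(nrow(nb))) {
      w <- nb[k, 1L]
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + nb[k, 2L]
        stack <- c(stack, w)
      }
    }
  }
  names(dist) <- g$ids
  dist
}

#' Geodesic distance between two nodes of a skeleton
#'
#' Path length along the arbor (sum of Euclidean parent-child segment
#' lengths over the unique tree path), not the straight-line distance.
#'
#' @param s A [skeleton].
#' @param a,b Node ids.
#' @return Distance in nanometres; zero iff `a == b`.
#' @export
geodesic_distance <- function(s, a, b) {
  if (!(b %in% s$nodes$node_id))
    abort_lookup(sprintf("node %s not in skeleton '%s'", b, s$neuron_id))
  unname(geodesic_all(s, a)[as.character(b)])
}

#' Total cable length of a skeleton
#'
#' @param s A [skeleton].
#' @return Sum of all segment lengths, in nanometres.
#' @export
cable_length <- function(s) {
  g <- skeleton_adjacency(s)
  sum(g$edge_len, na.rm = TRUE)
}

#' Linearize a skeleton into a 2D dendrogram layout
#'
#' Each node is placed at (arc position, lane): the arc position is its
#' geodesic distance from the root, and lanes separate sibling subtrees so
#' the drawing never overlaps. Leaves occupy consecutive integer lanes in
#' depth-first order (children visited by ascending node id, so the layout
#' is deterministic); an internal node sits in the lane of its first child.
#'
#' @param s A [skeleton].
#' @return `data.frame` with columns `node_id`, `arc_nm`, `lane`.
#' @export
dendrogram <- function(s) {
  nd <- s$nodes
  ids <- nd$node_id
  root <- skeleton_root(s)
  arc <- geodesic_all(s, root)[as.character(ids)]
  children <- split(ids[!is.na(nd$parent_id)],
                    factor(nd$parent_id[!is.na(nd$parent_id)], levels = ids))
  lane <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  next_lane <- 0L
  # iterative post-order: assign leaf lanes in DFS order, then propagate up
  stack <- list(list(id = root, stage = 1L))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    kids <- sort(children[[as.character(fr$id)]])
    if (fr$stage == 1L) {
      if (!length(kids)) {
        lane[as.character(fr$id)] <- next_lane
        next_lane <- next_lane + 1L
      } else {
        stack <- c(stack, list(list(id = fr$id, stage = 2L)))
        for (k in rev(kids)) stack <- c(stack, list(list(id = k, stage = 1L)))
      }
    } else {
      lane[as.character(fr$id)] <- lane[as.character(kids[1L])]
    }
  }
  data.frame(node_id = ids, arc_nm = unname(arc), lane = unname(lane[as.character(ids)]))
}

#' Read a skeleton from an SWC file
#'
#' Accepts the common SWC dialect: whitespace-separated columns
#' `id type x y z radius parent`, `#` comment lines, parent `-1` marking the
#' root. Node ids need not be contiguous; the `type` column is preserved but
#' carries no meaning here. Structural violations (duplicate ids, several
#' roots, a parent that does not exist, a cycle) raise a parse error naming
#' the offending line.
#'
#' @param path Path to an SWC file.
#' @param neuron_id Neuron identifier; defaults to the file name without
#'   extension.
#' @param origin_node Optional origin node id (see [skeleton]).
#' @return A [skeleton].
#' @export
read_swc <- function(path, neuron_id = NULL,
                     origin_node = NULL) {
  if (!file.exists(path)) abort_parse(sprintf("SWC file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (!length(rows)) abort_parse(sprintf("no node records in %s", path))
  fields <- strsplit(trimws(lines[rows]), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad))
    abort_parse(sprintf("line %d of %s: expected 7 columns, found %d",
                        rows[bad[1L]], path, lengths(fields)[bad[1L]]))
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7L, byrow = TRUE)
  if (anyNA(m))
    abort_parse(sprintf("line %d of %s: non-numeric field",
                        rows[which(rowSums(is.na(m)) > 0)[1L]], path))
  nodes <- data.frame(node_id = as.integer(m[, 1L]), type = as.integer(m[, 2L]),
                      x = m[, 3L], y = m[, 4L], z = m[, 5L], radius = m[, 6L],
                      parent_id = as.integer(m[, 7L]))
  nodes$parent_id[nodes$parent_id == -1L] <- NA_integer_
  dup <- which(duplicated(nodes$node_id))
  if (length(dup))
    abort_parse(sprintf("line %d of %s: duplicate node id %d",
                        rows[dup[1L]], path, nodes$node_id[dup[1L]]))
  dang <- which(!is.na(nodes$parent_id) &
                  !(nodes$parent_id %in% nodes$node_id))
  if (length(dang))
    abort_parse(sprintf("line %d of %s: node %d lists absent parent %d",
                        rows[dang[1L]], path, nodes$node_id[dang[1L]],
                        nodes$parent_id[dang[1L]]))
  if (is.null(neuron_id))
    neuron_id <- sub("\\.[^.]*$", "", basename(path))
  tryCatch(
    skeleton(neuron_id, nodes, origin_node = origin_node),
    vagusnet_validation_error = function(e)
      abort_parse(sprintf("%s: %s", path, conditionMessage(e)))
  )
}

#' Write a skeleton to an SWC file
#'
#' Canonical form: nodes sorted by ascending id, single-space separated
#' columns `id type x y z radius parent`, root parent written as `-1`,
#' plain decimal coordinates. Reading a canonical file and writing it again
#' reproduces the node records byte for byte.
#'
#' @param s A [skeleton].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(s, path) {
  nd <- s$nodes[order(s$nodes$node_id), ]
  radius <- ifelse(is.na(nd$radius), "1", format_num(nd$radius))
  parent <- ifelse(is.na(nd$parent_id), "-1", as.character(nd$parent_id))
  rec <- paste(nd$node_id, nd$type, format_num(nd$x), format_num(nd$y),
               format_num(nd$z), radius, parent)
  writeLines(rec, path)
  invisible(path)
}

#' Read a skeleton manifest
#'
#' A manifest is a TSV with columns `neuron_id`, `swc_path`, `origin_node`
#' listing one SWC file per neuron plus its annotated measurement origin.
#' Relative `swc_path`s are resolved against the manifest's directory.
#'
#' @param path Path to the manifest TSV.
#' @return Named list of [skeleton] objects, keyed by `neuron_id`.
#' @export
read_skeleton_manifest <- function(path) {
  man <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("neuron_id", "swc_path", "origin_node")
  if (!all(need %in% names(man)))
    abort_parse(paste0("manifest must have columns: ",
                       paste(need, collapse = ", ")))
  base <- dirname(path)
  out <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$swc_path[i]
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    read_swc(p, neuron_id = man$neuron_id[i],
             origin_node = if (is.na(man$origin_node[i])) NULL
                           else man$origin_node[i])
  })
  names(out) <- man$neuron_id
  out
}
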