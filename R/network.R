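# Per-frame residue-water hydrogen-bond graphs and water-mediated
# connection probabilities between key residues (shortest-path search).

#' Build a per-frame hydrogen-bond graph
#'
#' Nodes are residue labels (and water ids); an undirected, unweighted edge
#' joins two nodes when at least one hydrogen bond between them exists in
#' the frame (duplicate bonds collapse to one edge).
#'
#' @param events data.frame of \code{\link{detect_hbonds}} events from one
#'   frame; the \code{donor_res}/\code{acceptor_res} columns (or explicit
#'   \code{node_a}/\code{node_b}) name the endpoints.
#' @param node_universe character vector of all node names (isolated nodes
#'   are kept).
#' @return An \pkg{igraph} graph.
#' @export
build_frame_graph <- function(events, node_universe) {
  if (nrow(events) > 0) {
    a <- if ("node_a" %in% names(events)) events$node_a else events$donor_res
    b <- if ("node_b" %in% names(events)) events$node_b else events$acceptor_res
    unknown <- setdiff(unique(c(a, b)), node_universe)
    if (length(unknown))
      stop("event references node outside the universe: ",
           paste(unknown, collapse = ", "))
    keep <- a != b
    ed <- unique(data.frame(a = pmin(a[keep], b[keep]),
                            b = pmax(a[keep], b[keep]),
                            stringsAsFactors = FALSE))
  } else ed <- data.frame(a = character(0), b = character(0))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(node_universe), name = node_universe)
  if (nrow(ed) > 0)
    g <- igraph::add_edges(g, rbind(ed$a, ed$b))
  g
}

#' Are two residues connected (directly or water-mediated)?
#'
#' Shortest-path search (Dijkstra on unit weights, equivalent to BFS) from
#' \code{res_a} to \code{res_b}; any path -- a direct hydrogen bond or a
#' chain through waters and/or other residues -- counts as a connection.
#'
#' @param graph an \pkg{igraph} graph from \code{\link{build_frame_graph}}.
#' @param res_a,res_b node names.
#' @return List: \code{connected} (logical), \code{path} (node names of a
#'   shortest path, or \code{NULL}), \code{length} (edges, or \code{Inf}).
#' @export
residues_connected <- function(graph, res_a, res_b) {
  vn <- igraph::V(graph)$name
  if (!res_a %in% vn) stop("unknown residue label: ", res_a)
  if (!res_b %in% vn) stop("unknown residue label: ", res_b)
  sp <- suppressWarnings(
    igraph::shortest_paths(graph, from = res_a, to = res_b,
                           weights = rep(1, igraph::ecount(graph)),
                           algorithm = "dijkstra"))
  path <- sp$vpath[[1]]
  if (length(path) == 0 && res_a != res_b)
    return(list(connected = FALSE, path = NULL, length = Inf))
  list(connected = TRUE, path = igraph::V(graph)$name[path],
       length = max(length(path) - 1, 0))
}

#' Per-frame hydrogen-bond events for a channel's node universe
#'
#' Detects all hydrogen bonds among the channel's key residues, its
#' assigned waters and (when present) the hydronium ion, and returns one
#' event table per frame with node labels attached.
#'
#' @param traj a \code{cf_trajectory}.
#' @param key_residues data.frame (\code{chain}, \code{resid},
#'   \code{label}).
#' @param water_scope per-frame list of water keys assigned to the channel
#'   (e.g. \code{cf_hydration$inside_ids} for polyhedron scope), or
#'   \code{NULL} to use all waters every frame.
#' @param criterion a \code{\link{hbond_criterion}}.
#' @param table donor/acceptor table.
#' @param include_hydronium add the hydronium ion (resname H3O) as a node
#'   when present.
#' @return List of per-frame data.frames with columns \code{node_a},
#'   \code{node_b}.
#' @export
channel_frame_events <- function(traj, key_residues, water_scope = NULL,
                                 criterion = hbond_criterion(),
                                 table = hbond_atom_table(),
                                 include_hydronium = TRUE) {
  top <- traj$topology
  groups <- lapply(seq_len(nrow(key_residues)), function(i)
    resolve_hbond_group(top, key_residues[i, c("chain", "resid")], table))
  labels <- key_residues$label
  if (include_hydronium && any(top$resname == "H3O")) {
    groups <- c(groups, list(resolve_hbond_group(top, "hydronium", table)))
    labels <- c(labels, "H3O+")
  }
  wg <- resolve_hbond_group(top, "water", table)
  # atom -> node label map
  node_of <- rep(NA_character_, nrow(top))
  for (i in seq_along(groups)) {
    at <- groups[[i]]$atoms
    node_of[at] <- labels[i]
  }
  wat_atoms <- wg$atoms
  node_of[wat_atoms] <- water_key(top, wat_atoms)
  donors <- do.call(rbind, c(lapply(groups, `[[`, "donors"),
                             list(wg$donors)))
  acceptors <- unique(c(unlist(lapply(groups, `[[`, "acceptors")),
                        wg$acceptors))
  lapply(seq_len(n_frames(traj)), function(i) {
    ev <- detect_hbonds(frame_coords(traj, i), top, donors, acceptors,
                        criterion)
    if (nrow(ev) == 0)
      return(data.frame(node_a = character(0), node_b = character(0)))
    na_ <- node_of[ev$donor]
    nb <- node_of[ev$acceptor]
    keep <- !is.na(na_) & !is.na(nb) & na_ != nb
    if (!is.null(water_scope)) {
      wk <- water_scope[[i]]
      in_scope <- function(nd) !grepl(":", nd) | nd %in% wk
      keep <- keep & in_scope(na_) & in_scope(nb)
    }
    data.frame(node_a = na_[keep], node_b = nb[keep],
               stringsAsFactors = FALSE)
  })
}

#' Water-mediated connection probabilities between residue pairs
#'
#' For every frame, builds the channel graph and tests connectivity of each
#' residue pair; the probability is the connected-frame fraction.  The
#' full matrix is always returned; the 1\% display threshold used in the
#' network figures is applied only by downstream reporting.
#'
#' @param frame_events list of per-frame event tables
#'   (\code{\link{channel_frame_events}}).
#' @param residue_labels character vector of the key-residue node labels.
#' @param pairs optional 2-column character matrix of label pairs (default:
#'   all unordered pairs of \code{residue_labels}).
#' @return data.frame: \code{res_a}, \code{res_b}, \code{probability},
#'   \code{n_frames}.
#' @export
connection_probability <- function(frame_events, residue_labels,
                                   pairs = NULL) {
  if (is.null(pairs)) {
    cmb <- utils::combn(residue_labels, 2)
    pairs <- t(cmb)
  }
  nf <- length(frame_events)
  hits <- matrix(0L, nrow(pairs), 1)
  for (i in seq_len(nf)) {
    ev <- frame_events[[i]]
    nodes <- unique(c(residue_labels, ev$node_a, ev$node_b))
    g <- build_frame_graph(ev, nodes)
    comp <- igraph::components(g)$membership
    m <- comp[pairs[, 1]] == comp[pairs[, 2]]
    hits <- hits + as.integer(m)
  }
  data.frame(res_a = pairs[, 1], res_b = pairs[, 2],
             probability = as.vector(hits) / nf, n_frames = nf,
             stringsAsFactors = FALSE)
}

#' Replica-averaged connection probabilities
#'
#' @param per_replica list of data.frames from
#'   \code{\link{connection_probability}} (one per replica, same pair
#'   order).
#' @param threshold reporting filter on the mean probability (default 0:
#'   keep all; the network figures use 0.01).
#' @return data.frame with \code{res_a}, \code{res_b}, \code{mean},
#'   \code{se}.
#' @export
connection_probability_summary <- function(per_replica, threshold = 0) {
  p <- vapply(per_replica, function(d) d$probability,
              numeric(nrow(per_replica[[1]])))
  p <- matrix(p, ncol = length(per_replica))
  st <- t(apply(p, 1, function(v) {
    s <- replica_average(v); c(s$mean, s$se)
  }))
  out <- data.frame(res_a = per_replica[[1]]$res_a,
                    res_b = per_replica[[1]]$res_b,
                    mean = st[, 1], se = st[, 2],
                    stringsAsFactors = FALSE)
  out[out$mean >= threshold, , drop = FALSE]
}
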