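# Minimal simple-undirected-graph structure for incremental growth.
# Nodes are 1-based consecutive integers in insertion order; the node
# count t doubles as "time".  Written edge lists use 0-based ids.

new_growing_network <- function(adj, deg, L) {
  structure(list(t = length(adj), L = as.integer(L),
                 adj = adj, deg = as.integer(deg)),
            class = "growing_network")
}

#' Initial network for growth simulations
#'
#' All growth models in this package start from a small seed network.
#' The default (and currently only) seed is a pair: two nodes joined by
#' a single link.
#'
#' @param kind Seed kind; only `"pair"` is supported.
#' @return A `growing_network` object with `t = 2`, `L = 1`.
#' @examples
#' net <- initial_network()
#' degrees(net)
#' @export
initial_network <- function(kind = "pair") {
  if (!identical(kind, "pair")) {
    stop("unknown initial network kind: ", kind)
  }
  new_growing_network(adj = list(2L, 1L), deg = c(1L, 1L), L = 1L)
}

#' Add a new node linked to a set of existing nodes
#'
#' Appends node `t + 1` and connects it to every node in `targets`.
#' This is the elementary growth move shared by all models.
#'
#' @param net A `growing_network`.
#' @param targets Integer vector of distinct existing node ids (1-based).
#' @return The grown `growing_network`.
#' @export
add_node_with_links <- function(net, targets) {
  targets <- as.integer(targets)
  if (length(targets) == 0L) stop("targets must be nonempty")
  if (anyDuplicated(targets)) stop("targets must be distinct")
  if (any(targets < 1L) | any(targets > net$t)) {
    stop("target ids must be existing nodes (1..t)")
  }
  .add_node(net, targets)
}

# Internal variant that tolerates an empty target set (the copying
# baseline can produce isolated new nodes).
.add_node <- function(net, targets) {
  x <- net$t + 1L
  adj <- net$adj
  adj[[x]] <- targets
  for (u in targets) adj[[u]] <- c(adj[[u]], x)
  deg <- c(net$deg, length(targets))
  deg[targets] <- deg[targets] + 1L
  new_growing_network(adj, deg, net$L + length(targets))
}

#' Closed neighborhood of a node
#'
#' Returns the neighbors of `z` together with `z` itself.  This set is
#' the target pool of the neighborhood-OPA link rule.
#'
#' @param net A `growing_network`.
#' @param z Node id (1-based).
#' @return Integer vector of node ids, of length `degree(z) + 1`.
#' @export
closed_neighborhood <- function(net, z) {
  z <- as.integer(z)
  if (length(z) != 1L || is.na(z) || z < 1L || z > net$t) {
    stop("node id out of range")
  }
  c(net$adj[[z]], z)
}

#' Degree sequence
#'
#' @param net A `growing_network`.
#' @return Integer vector of node degrees, in node-id order.
#' @export
degrees <- function(net) net$deg

#' Edge matrix of a growing network
#'
#' @param net A `growing_network`.
#' @return A two-column integer matrix of 1-based node ids with
#'   `u < v`, one row per undirected edge, ordered by `u` then `v`.
#' @export
network_edges <- function(net) {
  adj <- net$adj
  u <- rep.int(seq_len(net$t), net$deg)
  v <- unlist(adj, use.names = FALSE)
  keep <- u < v
  m <- cbind(u = u[keep], v = v[keep])
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' Convert to an igraph object
#'
#' @param net A `growing_network`.
#' @return An undirected `igraph` graph with `t` vertices.
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = net$t, directed = FALSE)
  e <- network_edges(net)
  igraph::add_edges(g, as.vector(t(e)))
}

#' @export
print.growing_network <- function(x, ...) {
  cat(sprintf("growing_network: t = %d nodes, L = %d links, max degree = %d\n",
              x$t, x$L, max(x$deg)))
  invisible(x)
}

# Structural invariants; used by tests and after file round trips.
validate_growing_network <- function(net) {
  stopifnot(inherits(net, "growing_network"))
  t <- net$t
  stopifnot(length(net$adj) == t, length(net$deg) == t)
  stopifnot(identical(lengths(net$adj, use.names = FALSE), net$deg))
  stopifnot(sum(net$deg) == 2L * net$L)
  for (v in seq_len(t)) {
    nb <- net$adj[[v]]
    if (anyDuplicated(nb)) stop("parallel edge at node ", v)
    if (v %in% nb) stop("self-loop at node ", v)
    for (u in nb) {
      if (!(v %in% net$adj[[u]])) stop("asymmetric adjacency ", u, "-", v)
    }
  }
  invisible(TRUE)
}

#' Write an edge list to a TSV file
#'
#' Writes one undirected edge per line as two tab-separated 0-based
#' integer ids with `u < v` (no header).  Optionally writes a JSON
#' sidecar `<file>.json` with run metadata; the sidecar records `t`,
#' so isolated nodes survive a round trip.
#'
#' @param net A `growing_network`.
#' @param file Output path.
#' @param meta Optional named list of metadata (model, delta or p, seed,
#'   trial, ...); `t` and `L` are added automatically.
#' @return `file`, invisibly.
#' @export
write_edgelist <- function(net, file, meta = NULL) {
  e <- network_edges(net) - 1L
  utils::write.table(e, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(meta)) {
    meta$t <- net$t
    meta$L <- net$L
    jsonlite::write_json(meta, paste0(file, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

#' Read an edge list written by [write_edgelist()]
#'
#' @param file Path to a two-column TSV of 0-based node ids.
#' @param t Node count; defaults to the JSON sidecar's value if present,
#'   else to the largest id + 1.
#' @return A `growing_network`.
#' @export
read_edgelist <- function(file, t = NULL) {
  e <- utils::read.table(file, sep = "\t",
                         col.names = c("u", "v"),
                         colClasses = "integer")
  if (is.null(t)) {
    sidecar <- paste0(file, ".json")
    t <- if (file.exists(sidecar)) {
      as.integer(jsonlite::read_json(sidecar)$t)
    } else {
      max(e$u, e$v) + 1L
    }
  }
  u <- e$u + 1L
  v <- e$v + 1L
  if (any(u >= v)) stop("edge list must have u < v")
  if (max(v) > t) stop("edge id exceeds declared node count")
  adj <- vector("list", t)
  for (i in seq_len(t)) adj[[i]] <- integer(0)
  both_from <- c(u, v)
  both_to <- c(v, u)
  o <- order(both_from)
  sp <- split(both_to[o], both_from[o])
  for (nm in names(sp)) adj[[as.integer(nm)]] <- sp[[nm]]
  net <- new_growing_network(adj, lengths(adj), nrow(e))
  validate_growing_network(net)
  net
}
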