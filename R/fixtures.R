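# Named small graphs with canonical node numbering, used throughout
# the examples and tests.

#' Small named fixture networks
#'
#' @param name One of `"pair"` (2 nodes, 1 link), `"path3"` (center is
#'   node 1, degrees 2,1,1), `"star4"` (center node 1 with 3 leaves),
#'   `"triangle"`, `"k4"` (complete graph on 4 nodes).
#' @return A `growing_network`.
#' @export
fixture_network <- function(name = c("pair", "path3", "star4",
                                     "triangle", "k4")) {
  name <- match.arg(name)
  edges <- switch(name,
    pair     = cbind(1L, 2L),
    path3    = cbind(1L, 2:3),
    star4    = cbind(1L, 2:4),
    triangle = rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)),
    k4       = t(utils::combn(4L, 2L)))
  t <- max(edges)
  adj <- lapply(seq_len(t), function(v) {
    sort(c(edges[edges[, 1L] == v, 2L], edges[edges[, 2L] == v, 1L]))
  })
  net <- new_growing_network(adj, lengths(adj), nrow(edges))
  validate_growing_network(net)
  net
}
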