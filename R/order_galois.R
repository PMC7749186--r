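# The degree preorder on nodes (x <= y iff d_x <= d_y), the ability map
# G(x) = ceiling(delta * d_x), and an executable check of the Galois
# connection between the two.

#' Link-forming ability of a node
#'
#' Converts a realized degree into a link-forming ability via the
#' conversion coefficient `delta`: `ability(d, delta) = ceiling(delta * d)`.
#' The ability is the evaluation value against which a new node's
#' virtual degree is compared in all OPA link rules.
#'
#' The ceiling is taken with ordinary floating arithmetic and no epsilon
#' guard; for irrational `delta` (e.g. `sqrt(2)`) the product is never
#' exactly integral, so the simple rule is bit-reproducible.
#'
#' @param d Positive integer degree(s).
#' @param delta Positive conversion coefficient.
#' @return Integer ability value(s), `>= 1`; nondecreasing in `d`.
#' @examples
#' ability(2, sqrt(2))   # ceiling(2.828...) = 3
#' @export
ability <- function(d, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0) {
    stop("delta must be a positive number")
  }
  if (any(d < 1)) stop("ability is defined for degrees >= 1")
  as.integer(ceiling(delta * d))
}

#' Candidate set of an OPA step
#'
#' Nodes whose ability is at least the virtual degree `k`, i.e.
#' `{z : k <= ceiling(delta * d_z)}`.  Antitone in `k`; may be empty
#' for `k` above the maximum ability.
#'
#' @param net A `growing_network`.
#' @param delta Positive conversion coefficient.
#' @param k Positive integer virtual degree.
#' @return Integer vector of node ids (possibly empty).
#' @export
candidate_set <- function(net, delta, k) {
  stopifnot(k >= 1)
  which(ability(net$deg, delta) >= k)
}

#' Minimum elements of the candidate set
#'
#' Under the degree preorder the minimum elements of the candidate set
#' are exactly the candidates of minimal degree.  This is the value set
#' of the lower adjoint F(k), and the target pool of the adjunction
#' link rule.
#'
#' @inheritParams candidate_set
#' @return Integer vector of node ids; error if the candidate set is
#'   empty (no minimum exists).
#' @export
minimum_elements <- function(net, delta, k) {
  cand <- candidate_set(net, delta, k)
  if (length(cand) == 0L) {
    stop("empty candidate set: no minimum elements for k = ", k)
  }
  cand[net$deg[cand] == min(net$deg[cand])]
}

#' Verify the Galois-connection laws on a network
#'
#' Checks, by brute-force enumeration over every virtual degree
#' `k in [1, max G(X)]` and every node `x`, the adjunction law
#' `F(k) <=_X x  <=>  k <= G(x)`, where `G(x) = ceiling(delta * d_x)`,
#' `<=_X` compares degrees, and `F(k)` is a choice of minimum element of
#' the candidate set of `k`.  For `delta >= 1` it additionally checks
#' the unit law: `F(G(x))` is equivalent to `x` (equal degrees) for
#' every node.
#'
#' Any choice from the minimum elements defines a valid `F`; the law
#' cannot depend on the choice because all minimum elements are mutually
#' equivalent.  `choice` exposes this: `"first"` is deterministic,
#' `"random"` draws an arbitrary minimum element per `k`.
#'
#' @param net A `growing_network` with all degrees `>= 1`.
#' @param delta Positive conversion coefficient.
#' @param choice How F picks among minimum elements.
#' @return An object of class `galois_verdict`: a list with `holds`,
#'   `unit_equivalent` (NA when `delta < 1`), `n_checks`, and a
#'   `counterexamples` data frame (columns `k`, `x`) of violations.
#' @export
verify_galois <- function(net, delta, choice = c("first", "random")) {
  choice <- match.arg(choice)
  deg <- net$deg
  if (any(deg < 1L)) stop("degree preorder requires all degrees >= 1")
  ab <- ability(deg, delta)
  kmax <- max(ab)
  bad_k <- integer(0)
  bad_x <- integer(0)
  for (k in seq_len(kmax)) {
    cand <- which(ab >= k)
    mind <- min(deg[cand])
    M <- cand[deg[cand] == mind]
    Fk <- if (choice == "first") M[1L] else M[sample.int(length(M), 1L)]
    # F(k) <=_X x  <=>  k <= G(x), for every node x
    viol <- which((deg[Fk] <= deg) != (k <= ab))
    bad_k <- c(bad_k, rep.int(k, length(viol)))
    bad_x <- c(bad_x, viol)
  }
  unit <- NA
  if (delta >= 1) {
    unit <- TRUE
    for (x in seq_len(net$t)) {
      k <- ab[x]
      cand <- which(ab >= k)
      mind <- min(deg[cand])
      M <- cand[deg[cand] == mind]
      Fk <- if (choice == "first") M[1L] else M[sample.int(length(M), 1L)]
      if (deg[Fk] != deg[x]) { unit <- FALSE; break }
    }
  }
  structure(list(holds = length(bad_k) == 0L,
                 unit_equivalent = unit,
                 n_checks = kmax * net$t,
                 counterexamples = data.frame(k = bad_k, x = bad_x)),
            class = "galois_verdict")
}

#' @export
print.galois_verdict <- function(x, ...) {
  cat(sprintf("Galois connection check: %s (%d (k, x) pairs checked)\n",
              if (x$holds) "holds" else "VIOLATED", x$n_checks))
  if (!is.na(x$unit_equivalent)) {
    cat(sprintf("unit law F(G(x)) ~ x: %s\n",
                if (x$unit_equivalent) "holds" else "VIOLATED"))
  }
  if (!x$holds) {
    cat(sprintf("%d counterexamples, first few:\n",
                nrow(x$counterexamples)))
    print(utils::head(x$counterexamples))
  }
  invisible(x)
}
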