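# Growth dynamics.  All models share the degree-copying step (a random
# node's degree, scaled by delta, bounds the new node's virtual degree);
# they differ in the link-formation rule:
#   previous_opa     - connect to random candidates (pre-adjunction rule)
#   adjunction       - connect to random minimum elements only
#   neighborhood_opa - connect within the closed neighborhood of a
#                      random candidate hub
# plus the duplication-divergence copying baseline.

MODEL_KINDS <- c("previous_opa", "adjunction", "neighborhood_opa", "copying")

#' Configuration for a growth simulation
#'
#' @param model One of `"previous_opa"`, `"adjunction"`,
#'   `"neighborhood_opa"`, `"copying"`.
#' @param delta Positive conversion coefficient (OPA-family models).
#'   The dense scale-free regime of the theory is `1 <= delta < e`;
#'   values outside it are simulated but theory predictions are
#'   out-of-regime.
#' @param p Link-deletion probability in (0, 1) (copying model only).
#' @param t_max Target node count (> 2).
#' @param n_trials Number of independent trials; trial `i` uses seed
#'   `seed + i`.
#' @param seed Base RNG seed.
#' @param checkpoints Node counts at which snapshots are recorded;
#'   defaults to powers of two up to `t_max` (plus `t_max` itself).
#' @return A `model_config` list.
#' @export
model_config <- function(model, delta = NULL, p = NULL, t_max = 1000L,
                         n_trials = 1L, seed = 1L,
                         checkpoints = NULL) {
  model <- match.arg(model, MODEL_KINDS)
  if (model == "copying") {
    if (is.null(p) || p <= 0 || p >= 1) {
      stop("copying model requires deletion probability p in (0, 1)")
    }
  } else {
    if (is.null(delta) || delta <= 0) {
      stop("OPA-family models require delta > 0")
    }
  }
  t_max <- as.integer(t_max)
  if (t_max <= 2L) stop("t_max must exceed the 2-node initial network")
  if (n_trials < 1L) stop("n_trials must be >= 1")
  if (is.null(checkpoints)) checkpoints <- default_checkpoints(t_max)
  checkpoints <- sort(unique(as.integer(checkpoints)))
  if (any(checkpoints < 3L) || any(checkpoints > t_max)) {
    stop("checkpoints must lie in [3, t_max]")
  }
  structure(list(model = model, delta = delta, p = p, t_max = t_max,
                 n_trials = as.integer(n_trials), seed = as.integer(seed),
                 checkpoints = checkpoints),
            class = "model_config")
}

#' Default checkpoint schedule: powers of 2 up to t_max
#' @param t_max Target node count.
#' @return Sorted integer vector of node counts including `t_max`.
#' @export
default_checkpoints <- function(t_max) {
  ck <- 2L^(2:floor(log2(t_max)))
  sort(unique(c(ck[ck <= t_max], as.integer(t_max))))
}

#' Degree-copying step: draw a virtual degree
#'
#' Picks an existing node `y` uniformly at random and draws the new
#' node's virtual degree uniformly from `{1, ..., ceiling(delta * d_y)}`.
#'
#' @param net A `growing_network` with all degrees `>= 1`.
#' @param delta Positive conversion coefficient.
#' @return A list with `y` (copied node id) and `d_star` (virtual degree).
#' @export
draw_virtual_degree <- function(net, delta) {
  y <- sample.int(net$t, 1L)
  if (net$deg[y] < 1L) stop("copied node is isolated (degree 0)")
  list(y = y, d_star = sample.int(ability(net$deg[y], delta), 1L))
}

# Shared internal rule kernels operating on raw vectors so the growth
# loop and the public one-step operations use identical logic.

.targets_pre <- function(deg, ab, d_star) {
  cand <- which(ab >= d_star)
  if (length(cand) >= d_star) cand[sample.int(length(cand), d_star)] else cand
}

.targets_adj <- function(deg, ab, d_star) {
  cand <- which(ab >= d_star)
  M <- cand[deg[cand] == min(deg[cand])]
  if (length(M) >= d_star) M[sample.int(length(M), d_star)] else M
}

.targets_nbr <- function(adj, deg, ab, d_star) {
  cand <- which(ab >= d_star)
  z <- cand[sample.int(length(cand), 1L)]
  Nz <- c(adj[[z]], z)
  targets <- if (d_star < length(Nz)) Nz[sample.int(length(Nz), d_star)] else Nz
  list(z = z, targets = targets)
}

#' One-step link targets under the pre-adjunction (classical OPA) rule
#'
#' Samples `d_star` nodes uniformly without replacement from the
#' candidate set `{z : d_star <= ability(d_z)}`; if fewer candidates
#' exist, all of them are taken.
#'
#' @param net A `growing_network`.
#' @param delta Positive conversion coefficient.
#' @param d_star Virtual degree of the incoming node.
#' @return Integer vector of target node ids.
#' @export
targets_pre_adjunction <- function(net, delta, d_star) {
  stopifnot(d_star >= 1)
  .targets_pre(net$deg, ability(net$deg, delta), d_star)
}

#' One-step link targets under the adjunction rule
#'
#' As [targets_pre_adjunction()], but sampling is restricted to the
#' minimum elements of the candidate set (the literal value set of the
#' lower adjoint F).  This rule does not produce dense scale-free
#' networks; it is included for the structural comparison.
#'
#' @inheritParams targets_pre_adjunction
#' @return Integer vector of target node ids.
#' @export
targets_adjunction <- function(net, delta, d_star) {
  stopifnot(d_star >= 1)
  .targets_adj(net$deg, ability(net$deg, delta), d_star)
}

#' One-step link targets under the neighborhood-OPA rule
#'
#' Chooses a hub `z` uniformly from the candidate set, then samples
#' `d_star` targets uniformly without replacement from the closed
#' neighborhood of `z` (all of it when `d_star >=` its size).
#'
#' @inheritParams targets_pre_adjunction
#' @return A list with `z` (the chosen hub) and `targets`.
#' @export
targets_neighborhood <- function(net, delta, d_star) {
  stopifnot(d_star >= 1)
  .targets_nbr(net$adj, net$deg, ability(net$deg, delta), d_star)
}

#' One growth step of the duplication-divergence copying model
#'
#' A new node copies the neighbor set of a uniformly chosen existing
#' node; each copied link is then deleted independently with
#' probability `p`.  The new node may end up isolated; such nodes are
#' kept.  No extra link to the parent is added.
#'
#' @param net A `growing_network`.
#' @param p Deletion probability in (0, 1).
#' @return The grown `growing_network`.
#' @export
copying_step <- function(net, p) {
  stopifnot(p > 0, p < 1)
  y <- sample.int(net$t, 1L)
  nb <- net$adj[[y]]
  keep <- stats::runif(length(nb)) >= p
  .add_node(net, nb[keep])
}

#' Run one growth trial
#'
#' Grows a network from the two-node seed to `config$t_max` nodes under
#' the configured model, recording snapshots at the checkpoints.  The
#' run is deterministic given the seed: identical seeds give identical
#' edge lists.
#'
#' @param config A [model_config()].
#' @param trial Trial index (`>= 1`); the RNG is seeded with
#'   `config$seed + trial`.
#' @param snapshots If `FALSE`, only the summary table and final network
#'   are kept (saves memory on large runs).
#' @return A list with `summary` (data frame of `t`, `L`, `max_degree`
#'   per checkpoint), `network` (final `growing_network`), and
#'   `snapshots` (named list of `growing_network`s keyed by checkpoint
#'   `t`, when requested).
#' @export
grow <- function(config, trial = 1L, snapshots = TRUE) {
  stopifnot(inherits(config, "model_config"), trial >= 1L)
  set.seed(config$seed + as.integer(trial))
  model <- config$model
  delta <- config$delta
  p <- config$p
  t_max <- config$t_max
  cps <- config$checkpoints

  adj <- vector("list", t_max)
  adj[[1L]] <- 2L; adj[[2L]] <- 1L
  deg <- integer(t_max); deg[1:2] <- 1L
  ab <- integer(t_max)
  opa <- model != "copying"
  if (opa) ab[1:2] <- ability(1L, delta)
  t <- 2L; L <- 1L

  snap <- if (snapshots) vector("list", length(cps)) else NULL
  sum_t <- integer(length(cps)); sum_L <- integer(length(cps))
  sum_md <- integer(length(cps)); ci <- 1L

  while (t < t_max) {
    if (opa) {
      y <- sample.int(t, 1L)
      d_star <- sample.int(ab[y], 1L)
      targets <- switch(model,
        previous_opa = .targets_pre(deg[1:t], ab[1:t], d_star),
        adjunction = .targets_adj(deg[1:t], ab[1:t], d_star),
        neighborhood_opa = .targets_nbr(adj, deg, ab[1:t], d_star)$targets)
    } else {
      y <- sample.int(t, 1L)
      nb <- adj[[y]]
      targets <- nb[stats::runif(length(nb)) >= p]
    }
    x <- t + 1L
    adj[[x]] <- targets
    deg[x] <- length(targets)
    if (length(targets)) {
      for (u in targets) adj[[u]] <- c(adj[[u]], x)
      deg[targets] <- deg[targets] + 1L
    }
    if (opa) {
      # OPA steps always attach >= 1 link (the copied node qualifies)
      ab[x] <- ability(deg[x], delta)
      ab[targets] <- ability(deg[targets], delta)
    }
    L <- L + length(targets)
    t <- x
    while (ci <= length(cps) && cps[ci] == t) {
      sum_t[ci] <- t; sum_L[ci] <- L; sum_md[ci] <- max(deg[1:t])
      if (snapshots) {
        snap[[ci]] <- new_growing_network(adj[1:t], deg[1:t], L)
      }
      ci <- ci + 1L
    }
  }
  out <- list(summary = data.frame(t = sum_t, L = sum_L,
                                   max_degree = sum_md),
              network = new_growing_network(adj[1:t], deg[1:t], L))
  if (snapshots) {
    names(snap) <- as.character(cps)
    out$snapshots <- snap
  }
  out
}

#' Run all trials of a configuration
#'
#' @param config A [model_config()].
#' @param snapshots Keep per-checkpoint snapshots for every trial
#'   (memory-heavy at large `t_max`; default `FALSE`).
#' @return A list of per-trial results as returned by [grow()], of
#'   length `config$n_trials`.
#' @export
grow_ensemble <- function(config, snapshots = FALSE) {
  lapply(seq_len(config$n_trials), function(i) {
    grow(config, trial = i, snapshots = snapshots)
  })
}
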