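test_that("virtual degrees are copied uniformly within the scaled degree bound", {
  pair <- initial_network()
  set.seed(1)
  expect_true(all(replicate(50, draw_virtual_degree(pair, 1)$d_star) == 1L))

  # from the path fixture, d* = 2 requires copying the center then the
  # upper value: probability 1/3 * 1/2 = 1/6
  p3 <- fixture_network("path3")
  set.seed(2)
  n <- 30000L
  ds <- replicate(n, draw_virtual_degree(p3, 1)$d_star)
  expect_true(within_3sigma(sum(ds == 2L), n, 1 / 6))

  # conditional on copying a degree-5 node, d* is uniform on 1..5
  star6 <- add_node_with_links(fixture_network("star4"), 1L)
  star6 <- add_node_with_links(star6, 1L)      # center degree 5
  set.seed(3)
  draws <- replicate(20000L, {
    d <- draw_virtual_degree(star6, 1)
    if (d$y == 1L) d$d_star else NA_integer_
  })
  draws <- draws[!is.na(draws)]
  expect_gt(stats::chisq.test(tabulate(draws, 5L))$p.value, 1e-3)
})

test_that("pre-adjunction targets come uniformly from the candidate set, capped at its size", {
  p3 <- fixture_network("path3")
  # leaves have ability 1 < 2: the center is the only candidate
  set.seed(4)
  for (i in 1:20) expect_identical(targets_pre_adjunction(p3, 1, 2L), 1L)

  star <- fixture_network("star4")
  set.seed(5)
  n <- 20000L
  picks <- replicate(n, targets_pre_adjunction(star, 1, 1L))
  for (v in 1:4) expect_true(within_3sigma(sum(picks == v), n, 1 / 4))
})

test_that("adjunction targets are restricted to the minimum elements", {
  p3 <- fixture_network("path3")
  set.seed(6)
  n <- 20000L
  picks <- replicate(n, targets_adjunction(p3, 1, 1L))
  expect_setequal(unique(picks), c(2L, 3L))          # center excluded
  expect_true(within_3sigma(sum(picks == 2L), n, 1 / 2))
  for (i in 1:20) expect_identical(targets_adjunction(p3, 1, 2L), 1L)
})

test_that("neighborhood targets are drawn inside the chosen hub's closed neighborhood", {
  p3 <- fixture_network("path3")
  set.seed(7)
  n <- 20000L
  tri <- replicate(n, {
    s <- targets_neighborhood(p3, 1, 2L)
    stopifnot(s$z == 1L)                             # only candidate
    1L %in% s$targets                                # closes a triangle
  })
  expect_true(within_3sigma(sum(tri), n, 2 / 3))

  # star center forced as hub when d* exceeds leaf abilities
  star <- fixture_network("star4")
  set.seed(8)
  for (i in 1:20) {
    s <- targets_neighborhood(star, 1, 3L)
    expect_identical(s$z, 1L)
    expect_length(s$targets, 3L)
    expect_true(all(s$targets %in% closed_neighborhood(star, 1L)))
  }
})

test_that("copying steps thin the parent's neighborhood and may isolate the new node", {
  pair <- initial_network()
  set.seed(9)
  n <- 20000L
  iso <- replicate(n, degrees(copying_step(pair, 0.3))[3L] == 0L)
  expect_true(within_3sigma(sum(iso), n, 0.3))

  tri <- fixture_network("triangle")
  set.seed(10)
  degs <- replicate(n, degrees(copying_step(tri, 0.5))[4L])
  expect_lt(abs(mean(degs) - 1.0), 3 * stats::sd(degs) / sqrt(n))
})

test_that("one-step outcome distributions match exact enumeration", {
  p3 <- fixture_network("path3")
  n <- 20000L
  draw <- list(
    pre = function() targets_pre_adjunction(p3, 1,
                       draw_virtual_degree(p3, 1)$d_star),
    adjunction = function() targets_adjunction(p3, 1,
                       draw_virtual_degree(p3, 1)$d_star),
    neighborhood = function() targets_neighborhood(p3, 1,
                       draw_virtual_degree(p3, 1)$d_star)$targets)
  for (rule in names(draw)) {
    expected <- enum_onestep_p3(rule)
    expect_equal(sum(expected), 1, tolerance = 1e-12)
    set.seed(11)
    keys <- replicate(n, paste(sort(draw[[rule]]()), collapse = ","))
    counts <- table(keys)
    expect_true(all(names(counts) %in% names(expected)))
    obs <- vapply(names(expected),
                  function(key) if (key %in% names(counts))
                    counts[[key]] else 0L, numeric(1))
    gof <- stats::chisq.test(obs, p = unname(expected), rescale.p = TRUE)
    expect_gt(gof$p.value, 1e-3, label = sprintf("%s rule GoF", rule))
  }
})

test_that("growth is reproducible and emits consistent checkpoints", {
  cfg <- model_config("previous_opa", delta = 1, t_max = 100L, seed = 42L)
  e1 <- network_edges(grow(cfg, snapshots = FALSE)$network)
  e2 <- network_edges(grow(cfg, snapshots = FALSE)$network)
  expect_identical(e1, e2)

  run <- grow(model_config("neighborhood_opa", delta = sqrt(2),
                           t_max = 256L, seed = 1L), snapshots = TRUE)
  expect_equal(run$summary$t, default_checkpoints(256L))
  for (j in seq_along(run$snapshots)) {
    snap <- run$snapshots[[j]]
    expect_equal(snap$t, run$summary$t[j])
    expect_equal(snap$L, run$summary$L[j])
    expect_equal(max(degrees(snap)), run$summary$max_degree[j])
  }
  # trials are seeded independently and differ
  cfg2 <- model_config("neighborhood_opa", delta = 1, t_max = 100L,
                       n_trials = 2L, seed = 7L)
  runs <- grow_ensemble(cfg2)
  expect_false(identical(network_edges(runs[[1]]$network),
                         network_edges(runs[[2]]$network)))
})

test_that("every step links to at least one and at most d_star distinct existing nodes", {
  set.seed(13)
  net <- initial_network()
  delta <- sqrt(3 / 2)
  for (i in 1:150) {
    d <- draw_virtual_degree(net, delta)
    expect_true(length(candidate_set(net, delta, d$d_star)) >= 1L)
    s <- targets_neighborhood(net, delta, d$d_star)
    expect_true(length(s$targets) >= 1L)
    expect_lte(length(s$targets),
               min(d$d_star, length(closed_neighborhood(net, s$z))))
    expect_false(anyDuplicated(s$targets) > 0)
    net <- add_node_with_links(net, s$targets)
  }
  expect_true(validate_growing_network(net))
})

test_that("model configuration rejects invalid parameters", {
  expect_error(model_config("copying", p = 1.2, t_max = 10L), "p in")
  expect_error(model_config("previous_opa", t_max = 10L), "delta")
  expect_error(model_config("previous_opa", delta = 1, t_max = 2L), "t_max")
  expect_error(model_config("previous_opa", delta = 1, t_max = 10L,
                            checkpoints = c(2L, 5L)), "checkpoints")
})
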