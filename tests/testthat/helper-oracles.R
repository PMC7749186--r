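# Brute-force oracles, independent of the package internals they check.

# Exact one-step outcome distribution for the 3-node path fixture
# (node 1 = center, degrees 2,1,1) at delta = 1.  Enumerates the copied
# node y, the virtual degree d*, and every equally likely choice of the
# link rule; returns probabilities keyed by the sorted target set
# ("1", "2", "1,2", ...).
enum_onestep_p3 <- function(rule) {
  deg <- c(2L, 1L, 1L)
  adj <- list(c(2L, 3L), 1L, 1L)
  ab <- ceiling(deg)            # delta = 1
  out <- new.env()
  addp <- function(targets, p) {
    key <- paste(sort(targets), collapse = ",")
    out[[key]] <- (if (is.null(out[[key]])) 0 else out[[key]]) + p
  }
  subsets <- function(pool, m) utils::combn(pool, m, simplify = FALSE)
  for (y in 1:3) {
    for (ds in seq_len(ab[y])) {
      p_yd <- (1 / 3) * (1 / ab[y])
      cand <- which(ab >= ds)
      if (rule == "pre") {
        if (length(cand) >= ds) {
          ch <- subsets(cand, ds)
          for (s in ch) addp(s, p_yd / length(ch))
        } else addp(cand, p_yd)
      } else if (rule == "adjunction") {
        M <- cand[deg[cand] == min(deg[cand])]
        if (length(M) >= ds) {
          ch <- subsets(M, ds)
          for (s in ch) addp(s, p_yd / length(ch))
        } else addp(M, p_yd)
      } else if (rule == "neighborhood") {
        for (z in cand) {
          Nz <- c(adj[[z]], z)
          p_z <- p_yd / length(cand)
          if (ds < length(Nz)) {
            ch <- subsets(Nz, ds)
            for (s in ch) addp(s, p_z / length(ch))
          } else addp(Nz, p_z)
        }
      }
    }
  }
  unlist(as.list(out))
}

# Per-degree mean neighbor degree by direct double loop.
bf_knn <- function(net) {
  deg <- degrees(net)
  mnd <- vapply(seq_len(net$t), function(v) {
    nb <- net$adj[[v]]
    if (length(nb) == 0L) NA_real_ else mean(deg[nb])
  }, numeric(1))
  ks <- sort(unique(deg[deg > 0L]))
  vapply(ks, function(k) mean(mnd[deg == k]), numeric(1)) |>
    stats::setNames(ks)
}

# Per-degree local clustering by counting linked neighbor pairs.
bf_ck <- function(net) {
  deg <- degrees(net)
  lc <- vapply(seq_len(net$t), function(v) {
    nb <- net$adj[[v]]
    d <- length(nb)
    if (d < 2L) return(NA_real_)
    pairs <- utils::combn(nb, 2L)
    linked <- sum(vapply(seq_len(ncol(pairs)), function(j) {
      pairs[2L, j] %in% net$adj[[pairs[1L, j]]]
    }, logical(1)))
    linked / (d * (d - 1) / 2)
  }, numeric(1))
  ks <- sort(unique(deg[deg >= 2L]))
  vapply(ks, function(k) mean(lc[deg == k]), numeric(1)) |>
    stats::setNames(ks)
}

# Galois adjunction law by full (k, x) enumeration with an arbitrary
# (here: last, to differ from the implementation's first) choice of
# minimum element.
bf_galois_holds <- function(deg, delta) {
  ab <- ceiling(delta * deg)
  for (k in seq_len(max(ab))) {
    cand <- which(ab >= k)
    if (length(cand) == 0L) return(FALSE)
    M <- cand[deg[cand] == min(deg[cand])]
    Fk <- M[length(M)]
    if (any((deg[Fk] <= deg) != (k <= ab))) return(FALSE)
  }
  TRUE
}

# Multinomial three-sigma bound for an observed count at probability p.
within_3sigma <- function(observed, n, p) {
  abs(observed - n * p) <= 3 * sqrt(n * p * (1 - p)) + 1e-9
}

# A small grown network for property tests.
grown_fixture <- function(model = "neighborhood_opa", delta = sqrt(2),
                          t_max = 200L, seed = 5L) {
  cfg <- model_config(model, delta = delta, t_max = t_max, seed = seed)
  grow(cfg, snapshots = FALSE)$network
}
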