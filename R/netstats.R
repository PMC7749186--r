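# Ensemble statistics: degree distribution p_k, degree correlation
# k_nn(k), degree-dependent local clustering C(k), power-law exponent
# fits on log-binned data, and link-count scaling fits.

new_stat_curve <- function(k, value, count, stat) {
  structure(data.frame(k = as.integer(k), value = value,
                       count = as.integer(count)),
            stat = stat, class = c("stat_curve", "data.frame"))
}

stat_type <- function(curve) attr(curve, "stat")

#' Degree distribution of a network
#'
#' @param net A `growing_network`.
#' @return A `stat_curve` data frame (`k`, `value`, `count`) with
#'   `value = count / t`, restricted to populated degrees; fractions sum
#'   to 1 and the mean equals `2 L / t`.
#' @export
degree_distribution <- function(net) {
  deg <- net$deg
  if (any(deg == 0L)) {
    # tabulate() drops zeros; count isolated nodes explicitly
    cnt0 <- sum(deg == 0L)
  } else cnt0 <- 0L
  cnt <- tabulate(deg)
  k <- which(cnt > 0L)
  kk <- c(if (cnt0 > 0L) 0L, k)
  cc <- c(if (cnt0 > 0L) cnt0, cnt[k])
  new_stat_curve(kk, cc / net$t, cc, "pk")
}

#' Degree correlation function k_nn(k)
#'
#' Average degree of the neighbors of degree-k nodes: for each populated
#' degree `k`, the mean over all degree-k nodes of their mean neighbor
#' degree.  Flat k_nn(k) indicates neutral degree-degree mixing;
#' an increasing curve indicates assortativity.
#'
#' @param net A `growing_network`.
#' @return A `stat_curve` (`k`, `value`, `count`); isolated nodes are
#'   excluded with a warning.
#' @export
knn_curve <- function(net) {
  deg <- net$deg
  keep <- deg > 0L
  if (!all(keep)) warning("excluding ", sum(!keep), " isolated node(s)")
  g <- as_igraph(net)
  mnd <- suppressWarnings(igraph::knn(g)$knn)  # per-vertex mean neighbor degree
  agg <- rowsum(mnd[keep], deg[keep])
  cnt <- tabulate(deg[keep])
  k <- sort(unique(deg[keep]))
  new_stat_curve(k, agg[, 1L] / cnt[k], cnt[k], "knn")
}

#' Degree-dependent local clustering C(k)
#'
#' For each node of degree `d >= 2`, the fraction of its neighbor pairs
#' that are linked; averaged over all degree-k nodes.  A decreasing
#' C(k) is the hallmark of hierarchical/modular structure.  Nodes of
#' degree < 2 have no neighbor pair and contribute no value.
#'
#' @param net A `growing_network`.
#' @return A `stat_curve` (`k`, `value`, `count`) over degrees `>= 2`.
#' @export
clustering_curve <- function(net) {
  deg <- net$deg
  g <- as_igraph(net)
  lc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  keep <- deg >= 2L
  agg <- rowsum(lc[keep], deg[keep])
  cnt <- tabulate(deg[keep])
  k <- sort(unique(deg[keep]))
  new_stat_curve(k, agg[, 1L] / cnt[k], cnt[k], "ck")
}

#' Average statistic curves over trials
#'
#' Degree distributions are averaged unweighted (mean of per-trial
#' fractions at each degree, absent degrees counting as 0), matching
#' the convention of averaging an ensemble of equal-`t` snapshots.
#' k_nn and C(k) curves are averaged weighted by the per-degree node
#' counts, so the result equals the pooled per-node mean.
#'
#' @param curves A nonempty list of `stat_curve`s of a common type.
#' @return A single averaged `stat_curve`.
#' @export
average_curves <- function(curves) {
  if (length(curves) == 0L) stop("no curves to average")
  types <- unique(vapply(curves, stat_type, character(1)))
  if (length(types) != 1L) stop("curves have mixed statistic types")
  all_k <- sort(unique(unlist(lapply(curves, `[[`, "k"))))
  val <- matrix(0, nrow = length(all_k), ncol = length(curves))
  cnt <- matrix(0L, nrow = length(all_k), ncol = length(curves))
  for (j in seq_along(curves)) {
    i <- match(curves[[j]]$k, all_k)
    val[i, j] <- curves[[j]]$value
    cnt[i, j] <- curves[[j]]$count
  }
  tot <- rowSums(cnt)
  if (types == "pk") {
    v <- rowMeans(val)
  } else {
    # count-weighted; degrees absent from a trial carry zero weight
    v <- rowSums(val * cnt) / tot
  }
  new_stat_curve(all_k, v, tot, types)
}

# Geometric (log-spaced) binning of a p_k curve: bins [b, 2b) starting
# at k_min.  Returns bin centers and the probability density (summed
# fraction / bin width).  A bin over integers lo..hi-1 approximates the
# integral over [lo - 1/2, hi - 1/2) (midpoint rule), so the center is
# the geometric mean of the half-integer edges; without this shift the
# discreteness biases the fitted slope by O(1/k_min).
.log_bin <- function(pk, k_min, k_max, ratio = 2) {
  edges <- k_min
  while (edges[length(edges)] < k_max) {
    edges <- c(edges, edges[length(edges)] * ratio)
  }
  if (length(edges) < 2L) stop("degenerate fit window")
  lo <- edges[-length(edges)]
  hi <- edges[-1L]
  x <- sqrt((lo - 0.5) * (hi - 0.5))
  dens <- numeric(length(lo))
  for (j in seq_along(lo)) {
    sel <- pk$k >= lo[j] & pk$k < hi[j]
    dens[j] <- sum(pk$value[sel]) / (hi[j] - lo[j])
  }
  list(x = x, dens = dens, lo = lo, hi = hi)
}

#' Fit a power-law exponent to a degree distribution
#'
#' Estimates the exponent `gamma` of `p_k ~ k^-gamma` as minus the
#' least-squares slope of log density against log degree on
#' geometrically binned (ratio-2) data within a fit window.  The window
#' defaults implement the scale-free regime `1 << k < cutoff`:
#' `k_min = 8` and `k_max =` (max populated degree) / 2.
#'
#' A curvature diagnostic refits the two halves of the window; a
#' half-window slope difference above 0.3 flags the distribution as not
#' power-law-like (`power_law_ok = FALSE`).
#'
#' @param pk A `stat_curve` degree distribution.
#' @param k_min,k_max Fit window bounds on the degree axis.
#' @return An `exponent_fit` list: `gamma_hat`, `stderr`, `k_min`,
#'   `k_max`, `n_bins`, `curvature`, `power_law_ok`.
#' @export
fit_power_exponent <- function(pk, k_min = 8L,
                               k_max = max(pk$k[pk$value > 0]) / 2) {
  if (k_min >= k_max) stop("invalid fit window: k_min >= k_max")
  b <- .log_bin(pk, k_min, k_max)
  ok <- b$dens > 0
  if (sum(ok) < 5L) {
    stop("too few populated bins (", sum(ok), ") in fit window [",
         k_min, ", ", round(k_max), "] for a power-law fit")
  }
  lx <- log(b$x[ok]); ly <- log(b$dens[ok])
  fit <- stats::lm(ly ~ lx)
  n <- length(lx)
  h1 <- seq_len(ceiling(n / 2))
  h2 <- seq.int(floor(n / 2) + 1L, n)
  s1 <- stats::coef(stats::lm(ly[h1] ~ lx[h1]))[2L]
  s2 <- stats::coef(stats::lm(ly[h2] ~ lx[h2]))[2L]
  curv <- abs(s1 - s2)
  structure(list(gamma_hat = -unname(stats::coef(fit)[2L]),
                 stderr = unname(summary(fit)$coefficients[2L, 2L]),
                 k_min = k_min, k_max = k_max, n_bins = n,
                 curvature = unname(curv),
                 power_law_ok = unname(curv) <= 0.3),
            class = "exponent_fit")
}

#' @export
print.exponent_fit <- function(x, ...) {
  cat(sprintf(
    "power-law fit: gamma_hat = %.4f (se %.4f), window [%g, %g], %d bins\n",
    x$gamma_hat, x$stderr, x$k_min, x$k_max, x$n_bins))
  cat(sprintf("curvature diagnostic: %.3f (%s)\n", x$curvature,
              if (x$power_law_ok) "consistent with a power law"
              else "NOT power-law-like"))
  invisible(x)
}

#' Curvature check usable on distributions that may not support a fit
#'
#' Wraps [fit_power_exponent()]: a distribution whose populated range
#' cannot even fill the fit window fails the power-law diagnostic by
#' construction.
#'
#' @inheritParams fit_power_exponent
#' @return A list with `ok` (logical) and `fit` (the `exponent_fit`, or
#'   `NULL` when the window is unpopulated) and `reason`.
#' @export
power_law_check <- function(pk, k_min = 8L,
                            k_max = max(pk$k[pk$value > 0]) / 2) {
  fit <- tryCatch(fit_power_exponent(pk, k_min, k_max),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(ok = FALSE, fit = NULL, reason = conditionMessage(fit)))
  }
  list(ok = fit$power_law_ok, fit = fit,
       reason = if (fit$power_law_ok) "curvature within tolerance"
                else "half-window slopes differ beyond tolerance")
}

#' Log-log slope of a statistic curve over a degree window
#'
#' Weighted least-squares slope of `log(value)` on `log(k)` over
#' geometric ratio-2 bins (bin values are count-weighted means), used
#' to summarize the trend of k_nn(k) or C(k) in the mid-degree range.
#'
#' @param curve A `stat_curve`.
#' @param k_min,k_max Window bounds; defaults as in
#'   [fit_power_exponent()].
#' @return The fitted slope (a number).
#' @export
curve_loglog_slope <- function(curve, k_min = 8L,
                               k_max = max(curve$k[curve$count > 0]) / 2) {
  sel <- curve$k >= k_min & curve$k < k_max &
    curve$count > 0 & curve$value > 0
  if (sum(sel) < 3L) stop("too few populated degrees in window")
  k <- curve$k[sel]; v <- curve$value[sel]; w <- curve$count[sel]
  bin <- floor(log2(k / k_min))
  bx <- rowsum(w * log(k), bin)[, 1L] / rowsum(w, bin)[, 1L]
  by <- rowsum(w * log(v), bin)[, 1L] / rowsum(w, bin)[, 1L]
  if (length(bx) < 3L) stop("too few populated bins in window")
  unname(stats::coef(stats::lm(by ~ bx))[2L])
}

#' Fit the predicted link-count scaling to an L(t) series
#'
#' For `gamma = 2` fits `L = a t ln t` (through the origin); for
#' `1 < gamma < 2` fits the free-slope power law
#' `log L = log a + s log t`, whose slope should approach `2 / gamma`.
#'
#' @param series Data frame with columns `t` and `L` (>= 5 checkpoints).
#' @param gamma Predicted degree exponent in (1, 2].
#' @return A list with `form` (`"t_ln_t"` or `"t_pow"`), `prefactor`,
#'   `slope` (`NA` for the `t ln t` form), and `r_squared`.
#' @export
fit_link_scaling <- function(series, gamma) {
  stopifnot(gamma > 1, gamma <= 2)
  if (nrow(series) < 5L) stop("need >= 5 checkpoints to fit link scaling")
  if (length(unique(series$t)) < 5L) stop("degenerate t series")
  if (gamma == 2) {
    x <- series$t * log(series$t)
    fit <- stats::lm(L ~ 0 + x, data = cbind(series, x = x))
    ss_res <- sum(stats::resid(fit)^2)
    ss_tot <- sum((series$L - mean(series$L))^2)
    list(form = "t_ln_t",
         prefactor = unname(stats::coef(fit)[1L]),
         slope = NA_real_,
         r_squared = 1 - ss_res / ss_tot)
  } else {
    fit <- stats::lm(log(L) ~ log(t), data = series)
    list(form = "t_pow",
         prefactor = exp(unname(stats::coef(fit)[1L])),
         slope = unname(stats::coef(fit)[2L]),
         r_squared = summary(fit)$r.squared)
  }
}
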