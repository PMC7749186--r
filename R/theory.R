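# Rate-equation theory for the OPA-family growth models: closed-form
# degree exponent of the neighborhood-OPA model, the implicit exponent
# equation of the classical OPA model, the per-degree rate quantities
# and their large-k asymptotics, and the self-consistency residual
# whose root recovers the closed form.

#' Predicted degree exponent of the neighborhood-OPA model
#'
#' Closed form `gamma = 1 + (1 - ln delta) / (1 + ln delta)`, valid in
#' the dense scale-free regime `1 <= delta < e` where it decreases
#' strictly from 2 (at `delta = 1`) towards 1 (as `delta -> e`).
#' Outside the regime the formula is evaluated anyway and a warning is
#' issued.
#'
#' @param delta Positive conversion coefficient.
#' @return The predicted exponent (a number).
#' @examples
#' gamma_new(1)        # 2
#' gamma_new(sqrt(2))  # 1.4852...
#' @export
gamma_new <- function(delta) {
  if (!is.numeric(delta) || any(delta <= 0)) stop("delta must be > 0")
  if (any(delta < 1 | delta >= exp(1))) {
    warning("delta outside the dense scale-free regime [1, e); ",
            "prediction is out of theory's validity range")
  }
  1 + (1 - log(delta)) / (1 + log(delta))
}

#' Predicted degree exponent of the classical OPA model
#'
#' The exponent of the degree-copying + pre-adjunction (classical OPA)
#' model is the nontrivial root `gamma > 1` of the implicit equation
#' `gamma = delta * (gamma - 1)^2 + delta^(gamma - 1)`.  `gamma = 1` is
#' always a root and is rejected.  The root is located by bracketing
#' and bisection to 1e-10: with `f(gamma) = delta*(gamma-1)^2 +
#' delta^(gamma-1) - gamma`, `f(1) = 0` and `f'(1) = ln delta - 1 < 0`
#' for `delta < e`, so `f` is negative just above 1 and positive at
#' large gamma, bracketing the nontrivial root.
#'
#' @param delta Conversion coefficient in `[1, e)`.
#' @param tol Bisection tolerance.
#' @return The root `gamma > 1`.
#' @export
gamma_previous <- function(delta, tol = 1e-10) {
  if (!is.numeric(delta) || delta <= 0) stop("delta must be > 0")
  # delta^(g-1) - g  written as  expm1((g-1) log delta) + 1 - g  to avoid
  # catastrophic cancellation when the root sits just above 1
  f <- function(g) delta * (g - 1)^2 + expm1((g - 1) * log(delta)) + 1 - g
  lo <- 1 + 1e-6
  hi <- 4
  if (f(lo) >= 0) {
    stop("no exponent root gamma > 1 at delta = ", delta,
         " (outside the dense scale-free regime delta < e)")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Critical conversion coefficient of the dense scale-free regime
#'
#' The supremum of `delta` for which the model's predicted exponent
#' exceeds 1.  For the neighborhood-OPA model this is analytic
#' (`ln delta = 1`, i.e. `delta = e`); for the classical OPA model it is
#' located numerically as the largest `delta` at which the implicit
#' equation still has a root `gamma > 1 + eps`.  Both equal `e`.
#'
#' The existence probe evaluates `f(1 + eps)` with the `expm1` form of
#' the implicit equation; `eps` shifts the located boundary by about
#' `3.2 * eps * e`, so the default `1e-9` resolves `e` to ~1e-8.
#'
#' @param model `"new"` (neighborhood-OPA) or `"previous"`
#'   (classical OPA).
#' @param tol Bisection tolerance on delta (numeric branch).
#' @param eps Margin above 1 defining a nontrivial root.
#' @return The critical delta.
#' @export
delta_critical <- function(model = c("new", "previous"), tol = 1e-10,
                           eps = 1e-9) {
  model <- match.arg(model)
  if (model == "new") return(exp(1))
  has_root <- function(delta) {
    delta * eps^2 + expm1(eps * log(delta)) - eps < 0
  }
  lo <- 1; hi <- 3.5
  stopifnot(has_root(lo), !has_root(hi))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (has_root(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Rate-equation quantities for a given degree distribution
#'
#' Evaluates, literally as finite sums over the supported degrees of
#' `p`, the per-step probabilities of the neighborhood-OPA model when
#' the network has `t` nodes and degree distribution `p`:
#' \describe{
#'   \item{q_k}{probability that the new node's virtual degree is k:
#'     `sum over l with k <= ceiling(delta l) < t of p_l /
#'     ceiling(delta l)`;}
#'   \item{N_k}{expected number of candidates of an incoming virtual
#'     degree k: `t * sum over the same l of p_l`;}
#'   \item{b_k}{probability that the new node ends with degree k;}
#'   \item{d_k}{probability that a specific degree-k node's closed
#'     neighborhood is chosen and a specific member of it becomes a
#'     target;}
#'   \item{a_k}{probability that an existing degree-k node gains a
#'     link, assuming neighbor degrees independent of the node's own
#'     degree (`p(k'|k) = k' p_k' / <k>`).}
#' }
#'
#' @param p A `stat_curve` degree distribution (or data frame with
#'   columns `k`, `value`), normalized.
#' @param delta Conversion coefficient (`>= 1` for the theory's regime).
#' @param t Node count entering the `ceiling(delta l) < t` cutoffs and
#'   the candidate counts.
#' @param exact_k_plus_1 Use the exact `k + 1` factor in `d_k` (the
#'   asymptotic forms replace it by `k`); default `TRUE`.
#' @return An object of class `rate_quantities`: list with `k`
#'   (1..k_max grid), `q`, `b`, `d`, `a`, `N`, `delta`, `t`.
#' @export
rate_quantities <- function(p, delta, t, exact_k_plus_1 = TRUE) {
  stopifnot(delta > 0, t >= 2)
  supp <- p$k[p$value > 0]
  pv <- p$value[p$value > 0]
  if (any(supp < 1)) stop("rate equations require degrees >= 1")
  if (abs(sum(pv) - 1) > 1e-8) stop("input distribution is not normalized")
  A <- ability(supp, delta)            # ceiling(delta * l) per degree class
  in_t <- A < t
  kmax <- max(max(A[in_t]), max(supp))
  kk <- seq_len(kmax)

  q <- vapply(kk, function(k) sum(pv[in_t & A >= k] / A[in_t & A >= k]),
              numeric(1))
  N <- t * vapply(kk, function(k) sum(pv[in_t & A >= k]), numeric(1))
  if (any(q > 0 & N == 0)) {
    stop("distribution inconsistent with delta: q_k > 0 where N_k = 0")
  }

  mean_deg <- sum(supp * pv)
  pfull <- numeric(kmax)               # p on the dense 1..kmax grid
  pfull[supp[supp <= kmax]] <- pv[supp <= kmax]

  b <- vapply(kk, function(k) {
    s_deg <- sum(pv[supp >= k & supp < t])
    s_ab <- sum(pv[in_t & A >= k])
    first <- if (s_ab > 0) q[k] * s_deg / s_ab else 0
    ak <- ability(k, delta)
    ls <- kk[kk > k & kk <= ak]
    second <- 0
    if (length(ls) && pfull[k] > 0) {
      denom <- vapply(ls, function(l) sum(pv[in_t & A >= l]), numeric(1))
      second <- sum(q[ls] * pfull[k] / denom)
    }
    first + second
  }, numeric(1))

  d <- vapply(kk, function(k) {
    ls1 <- kk[kk <= k & q[kk] > 0]
    term1 <- if (length(ls1)) {
      sum(q[ls1] / N[ls1] * ls1 / (if (exact_k_plus_1) k + 1 else k))
    } else 0
    ak <- ability(k, delta)
    ls2 <- kk[kk > k & kk <= ak & q[kk] > 0]
    term2 <- if (length(ls2)) sum(q[ls2] / N[ls2]) else 0
    term1 + term2
  }, numeric(1))

  # a_k = d_k + k * sum_k' p(k'|k) d_k', with p(k'|k) = k' p_k' / <k>
  neighbor_term <- sum(supp * pv * d[supp]) / mean_deg
  a <- d + kk * neighbor_term

  structure(list(k = kk, q = q, b = b, d = d, a = a, N = N,
                 delta = delta, t = t),
            class = "rate_quantities")
}

#' Large-k asymptotic forms of the rate quantities
#'
#' Closed-form asymptotics under the power-law ansatz
#' `p_k = c k^-gamma` within the scale-free window:
#' `q_k ~ (c delta^(gamma-1) / gamma) k^-gamma`,
#' `b_k ~ (c (1 + (gamma-1) ln delta) / gamma) k^-gamma`,
#' `d_k ~ (gamma-1)(1 + ln delta) / (gamma t)`, and
#' `a_k ~ (gamma-1)(1 + ln delta) k / (gamma t)`.
#'
#' @param gamma Degree exponent in (1, 2].
#' @param delta Conversion coefficient.
#' @param c Power-law normalization constant of the input ansatz.
#' @param t Node count.
#' @param k Degree(s) at which to evaluate.
#' @param exact_k_plus_1 Use `k + 1` instead of `k` in `a_k` (the form
#'   before the final large-k simplification).
#' @return A list of vectors `q`, `b`, `d`, `a`.
#' @export
asymptotics <- function(gamma, delta, c, t, k, exact_k_plus_1 = FALSE) {
  stopifnot(gamma > 1, gamma <= 2, k >= 1)
  ld <- log(delta)
  kf <- if (exact_k_plus_1) k + 1 else k
  list(q = c * delta^(gamma - 1) / gamma * k^(-gamma),
       b = c * (1 + (gamma - 1) * ld) / gamma * k^(-gamma),
       d = rep((gamma - 1) * (1 + ld) / (gamma * t), length(k)),
       a = (gamma - 1) * (1 + ld) * kf / (gamma * t))
}

#' Self-consistency residual of the rate-equation derivation
#'
#' Substituting the power-law ansatz and the asymptotic forms of `a_k`
#' and `b_k` into the continuum degree-balance equation
#' `d/dk (a_k t p_k) = b_k - p_k` and comparing the coefficients of
#' `k^-gamma` leaves the mismatch
#' `(gamma - 1)(1 + ln delta) + (ln delta - 1)`, which vanishes exactly
#' when `gamma` equals the closed-form prediction of [gamma_new()].
#'
#' @param gamma Candidate exponent (> 1).
#' @param delta Conversion coefficient (> 0).
#' @return The coefficient mismatch (0 iff self-consistent).
#' @export
consistency_residual <- function(gamma, delta) {
  stopifnot(gamma > 1, delta > 0)
  (gamma - 1) * (1 + log(delta)) + (log(delta) - 1)
}

#' Predicted growth of the link count
#'
#' The scaling form (up to a prefactor) of the number of links at node
#' count `t`: `t ln t` when `gamma = 2` (i.e. `delta = 1`) and
#' `t^(2/gamma)` for `1 < gamma < 2`.  The average degree therefore
#' diverges as `ln t` or `t^(2/gamma - 1)`: the networks are dense.
#'
#' @param t Node count(s), `>= 2`.
#' @param gamma Degree exponent in (1, 2].
#' @return Numeric vector of scaling values.
#' @export
predicted_link_growth <- function(t, gamma) {
  stopifnot(gamma > 1, gamma <= 2, t >= 2)
  if (gamma == 2) t * log(t) else t^(2 / gamma)
}
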