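# Maximization and root solving over the shared early-event colonization
# probability, with the final event fixed (default 1: all niches present
# today were filled by the last event).

sweep_objective <- function(census, model, events, pool_size, q, final_prob,
                            objective = c("pairs_plus_triplets", "pairs")) {
  objective <- match.arg(objective)
  census <- as_census(census)
  force(pool_size); force(q); force(final_prob); force(events)
  function(p) {
    vapply(p, function(pi) {
      scen <- if (model == "repeated") {
        colonization_scenario("repeated", c(rep(pi, events - 1L), final_prob),
                              pool_size = pool_size)
      } else {
        colonization_scenario("single", pi, diversification_prob = q)
      }
      pred <- expected_sister_fractions(census, scen)
      if (objective == "pairs") pred$expected_pair_fraction
      else pred$expected_sister_fraction
    }, numeric(1))
  }
}

#' Maximize the expected sister fraction over the colonization probability
#'
#' Finds the shared early-event niche colonization probability p (p1 for two
#' events, p1 = p2 = p for three; the final event probability stays fixed)
#' that maximizes the expected fraction of sister-containing aquifers. A grid
#' scan at step `step` brackets the optimum, then a golden-section refinement
#' polishes it to tolerance `tol`. Grid ties break toward the smaller p.
#'
#' @param census An [aquifer_census()].
#' @param model `"repeated"` or `"single"`.
#' @param events Number of colonization events (repeated model; 2 or 3).
#' @param pool_size Ancestral pool size n (repeated model).
#' @param q Diversification probability (single model).
#' @param objective `"pairs_plus_triplets"` (default; the combined sister
#'   fraction) or `"pairs"`. With two events the triplet contribution is
#'   identically zero, so the objectives coincide.
#' @param final_prob Colonization probability of the last event (default 1).
#' @param step Grid step of the initial scan (default 1e-3).
#' @param tol Tolerance of the bracketed refinement (default 1e-6).
#' @return A list with `p_star` (the argmax), `value` (the maximized expected
#'   fraction) and `objective`.
#' @examples
#' maximize_probability(yilgarn_census(), "repeated", events = 2, pool_size = 10)
#' @export
maximize_probability <- function(census, model = c("repeated", "single"),
                                 events = 2L, pool_size = NULL, q = 1,
                                 objective = c("pairs_plus_triplets", "pairs"),
                                 final_prob = 1, step = 1e-3, tol = 1e-6) {
  model <- match.arg(model)
  objective <- match.arg(objective)
  f <- sweep_objective(census, model, events, pool_size, q, final_prob, objective)
  grid <- seq(0, 1, by = step)
  vals <- f(grid)
  i <- which.max(vals) # first (smallest p) on ties
  lo <- max(0, grid[i] - step)
  hi <- min(1, grid[i] + step)
  opt <- stats::optimize(f, interval = c(lo, hi), maximum = TRUE, tol = tol)
  if (opt$objective < vals[i]) { # degenerate flat objective: keep the grid point
    opt <- list(maximum = grid[i], objective = vals[i])
  }
  list(p_star = opt$maximum, value = opt$objective, objective = objective)
}

#' Solve the colonization probability for an observed sister fraction
#'
#' Finds every p in [0, 1] at which the expected combined sister fraction
#' (pairs plus triplets) equals `observed_fraction`. Roots are located by
#' sign-change bisection on a grid of step `step` ([stats::uniroot()] to
#' tolerance `tol`); exact grid hits are kept as-is. Returns the roots in
#' increasing order, or an empty vector when the target exceeds the model
#' maximum.
#'
#' @inheritParams maximize_probability
#' @param observed_fraction Target fraction in [0, 1].
#' @return Numeric vector of roots (possibly empty), increasing.
#' @examples
#' solve_probability_for_fraction(yilgarn_census(), "single", q = 1,
#'                                observed_fraction = 11 / 45)
#' @export
solve_probability_for_fraction <- function(census, model = c("repeated", "single"),
                                           events = 2L, pool_size = NULL, q = 1,
                                           observed_fraction,
                                           final_prob = 1, step = 1e-3, tol = 1e-9) {
  model <- match.arg(model)
  check_prob(observed_fraction, "observed_fraction")
  f <- sweep_objective(census, model, events, pool_size, q, final_prob,
                       "pairs_plus_triplets")
  g <- function(p) f(p) - observed_fraction
  grid <- seq(0, 1, by = step)
  gv <- g(grid)
  roots <- grid[gv == 0]
  sgn <- sign(gv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in flips) {
    r <- stats::uniroot(g, lower = grid[i], upper = grid[i + 1L], tol = tol)
    roots <- c(roots, r$root)
  }
  roots <- sort(roots)
  if (length(roots) > 1L)
    roots <- roots[c(TRUE, diff(roots) > 1e-8)]
  roots
}
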