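# Closed-form sister-species probabilities for both colonization models.
#
# Repeated model bookkeeping: a given niche is first filled at event j with
# probability q_j = p_j * prod_{i<j} (1 - p_i), and stays empty with
# probability q_0 = prod_i (1 - p_i). Niches are independent until species
# identities are drawn; within one event the colonists are distinct species,
# across events draws are independent uniform picks from the pool of n.
# Sisters require the SAME ancestral species in DIFFERENT events, so all
# probabilities below marginalize over niche fill-times and species matches.

fill_time_weights <- function(event_probs) {
  stay <- cumprod(1 - event_probs)
  q <- event_probs * c(1, utils::head(stay, -1L))
  list(q = q, q0 = stay[length(stay)])
}

# elementary symmetric polynomials e1..e3 of a short vector
esym <- function(q) {
  e1 <- sum(q)
  e2 <- 0
  e3 <- 0
  k <- length(q)
  if (k >= 2) e2 <- sum(q * rev(cumsum(rev(q)) - rev(q))) # sum_{a<b} qa qb
  if (k >= 3) e3 <- prod(q[1:3])
  c(e1 = e1, e2 = e2, e3 = e3)
}

check_repeated_args <- function(niches, event_probs, pool_size) {
  if (!niches %in% 2:3) stop("niches must be 2 or 3", call. = FALSE)
  if (!length(event_probs) %in% 2:3)
    stop("repeated model takes 2 or 3 colonization events", call. = FALSE)
  check_prob(event_probs, "event_probs")
  if (length(pool_size) != 1L || is.na(pool_size) || pool_size != round(pool_size))
    stop("pool_size must be a single integer", call. = FALSE)
  if (pool_size < niches)
    stop("pool_size must be at least the niche count (distinct within-event colonists)",
         call. = FALSE)
}

#' Sister-pair probability under the repeated-colonization model
#'
#' Probability that an aquifer with `niches` niches ends up with a sympatric
#' sister pair as its largest same-ancestor group: the same ancestral species
#' colonized the aquifer in exactly two distinct events.
#'
#' With \eqn{q_j} the probability that a niche is first filled at event j and
#' \eqn{e_k} the elementary symmetric polynomials of the \eqn{q_j}, the closed
#' forms are \eqn{2 e_2 / n} for two niches and
#' \eqn{(6/n)(e_2 - 3 e_3) + 18 (n-1) e_3 / n^2} for three niches.
#'
#' @param niches Number of niches in the aquifer, 2 or 3.
#' @param event_probs Per-event niche colonization probabilities (length 2
#'   or 3); the field convention fixes the last one at 1.
#' @param pool_size Ancestral species pool size n (>= `niches`).
#' @return A single probability.
#' @examples
#' pair_probability_repeated(2, c(0.5, 1), pool_size = 10) # 2 p (1-p) / n = 0.05
#' @export
pair_probability_repeated <- function(niches, event_probs, pool_size) {
  check_repeated_args(niches, event_probs, pool_size)
  w <- fill_time_weights(event_probs)
  e <- esym(w$q)
  n <- pool_size
  if (niches == 2L) {
    2 * e[["e2"]] / n
  } else {
    (6 / n) * (e[["e2"]] - 3 * e[["e3"]]) + 18 * (n - 1) * e[["e3"]] / n^2
  }
}

#' Sister-triplet probability under the repeated-colonization model
#'
#' Probability that one ancestral species colonizes a three-niche aquifer in
#' three distinct events (largest same-ancestor group of size 3). Triplets
#' require at least three colonization events, so the probability is
#' identically zero with two events. Closed form: \eqn{6 q_1 q_2 q_3 / n^2}.
#'
#' @inheritParams pair_probability_repeated
#' @return A single probability.
#' @export
triplet_probability_repeated <- function(event_probs, pool_size) {
  check_repeated_args(3L, event_probs, pool_size)
  if (length(event_probs) < 3L) return(0)
  w <- fill_time_weights(event_probs)
  6 * prod(w$q) / pool_size^2
}

#' Sister-pair probability under the single-colonization model
#'
#' Probability that a largest within-aquifer sister clade of exactly two
#' species forms: for two niches, one founder whose empty neighbour niche is
#' filled in situ (\eqn{2 p (1-p) q}); for three niches, either two founders
#' with the third niche filled in situ, or one founder with exactly one of
#' the two empty niches filled (\eqn{3 p^2 (1-p) q + 6 p (1-p)^2 q (1-q)}).
#' Independent of the ancestral pool size.
#'
#' @param niches Number of niches, 2 or 3.
#' @param p Initial per-niche colonization probability.
#' @param q Probability an empty niche is filled by within-aquifer speciation.
#' @return A single probability.
#' @export
pair_probability_single <- function(niches, p, q) {
  if (!niches %in% 2:3) stop("niches must be 2 or 3", call. = FALSE)
  check_prob(p, "p"); check_prob(q, "q")
  if (niches == 2L) {
    2 * p * (1 - p) * q
  } else {
    3 * p^2 * (1 - p) * q + 6 * p * (1 - p)^2 * q * (1 - q)
  }
}

#' Sister-triplet probability under the single-colonization model
#'
#' Probability that a three-niche aquifer is filled by a single founder plus
#' two in-situ descendant species: \eqn{3 p (1-p)^2 q^2}.
#'
#' @inheritParams pair_probability_single
#' @return A single probability.
#' @export
triplet_probability_single <- function(p, q) {
  check_prob(p, "p"); check_prob(q, "q")
  3 * p * (1 - p)^2 * q^2
}

#' Expected region-wide fractions of sister-containing aquifers
#'
#' Weights the per-niche-class sister probabilities by the census counts
#' a1..a3 and divides by the total number of aquifers A. One-niche aquifers
#' contribute probability 0. Aquifers that end partly or fully empty (possible
#' under the single model with p < 1) still count in the denominator A.
#'
#' @param census An [aquifer_census()].
#' @param scenario A [colonization_scenario()].
#' @return An object of class `sister_prediction`: per-niche pair
#'   probabilities, the triplet probability (3-niche aquifers), and the
#'   expected pair / triplet / combined sister fractions of aquifers.
#' @examples
#' expected_sister_fractions(
#'   yilgarn_census(),
#'   colonization_scenario("single", 0.784, diversification_prob = 1)
#' )
#' @export
expected_sister_fractions <- function(census, scenario) {
  census <- as_census(census)
  scenario <- as_scenario(scenario)
  if (census$total == 0L) stop("census has zero aquifers", call. = FALSE)
  if (scenario$model == "repeated") {
    n_needed <- max(which(census$by_niche > 0L))
    if (!is.null(scenario$pool_size) && scenario$pool_size < n_needed)
      stop("pool_size smaller than the largest niche count in the census", call. = FALSE)
    p2 <- pair_probability_repeated(2L, scenario$event_probs, scenario$pool_size)
    p3 <- pair_probability_repeated(3L, scenario$event_probs, scenario$pool_size)
    t3 <- triplet_probability_repeated(scenario$event_probs, scenario$pool_size)
  } else {
    p <- scenario$event_probs[1L]
    q <- scenario$diversification_prob
    p2 <- pair_probability_single(2L, p, q)
    p3 <- pair_probability_single(3L, p, q)
    t3 <- triplet_probability_single(p, q)
  }
  a <- census$by_niche
  A <- census$total
  pair_frac <- (a[["2"]] * p2 + a[["3"]] * p3) / A
  trip_frac <- a[["3"]] * t3 / A
  structure(
    list(pair_prob_by_niche = c(`2` = p2, `3` = p3),
         triplet_prob = t3,
         expected_pair_fraction = pair_frac,
         expected_triplet_fraction = trip_frac,
         expected_sister_fraction = pair_frac + trip_frac,
         census = census, scenario = scenario),
    class = "sister_prediction"
  )
}

#' @export
print.sister_prediction <- function(x, ...) {
  cat("Sister-species prediction (", x$scenario$model, " model)\n", sep = "")
  cat(sprintf("  P(pair | 2 niches) = %.6f\n", x$pair_prob_by_niche[["2"]]))
  cat(sprintf("  P(pair | 3 niches) = %.6f\n", x$pair_prob_by_niche[["3"]]))
  cat(sprintf("  P(triplet | 3 niches) = %.6f\n", x$triplet_prob))
  cat(sprintf("  expected fraction of aquifers: pairs %.4f, triplets %.4f, combined %.4f\n",
              x$expected_pair_fraction, x$expected_triplet_fraction,
              x$expected_sister_fraction))
  invisible(x)
}
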