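# Tabular front ends tying the modules together: probability sweeps,
# randomization-band tables, detection reports and probability fits.

#' Expected-fraction sweep over the colonization probability
#'
#' Evaluates the closed-form expected pair, triplet and combined sister
#' fractions over a grid of the early-event colonization probability
#' (crossed with pool sizes for the repeated model), the table behind the
#' model curves.
#'
#' @param census An [aquifer_census()].
#' @param model `"repeated"` or `"single"`.
#' @param p Grid of early-event colonization probabilities.
#' @param events Number of events (repeated model).
#' @param pool_size Pool size(s) n; may be a vector (repeated model).
#' @param q Diversification probability (single model).
#' @param final_prob Final event probability (default 1).
#' @return A data frame with columns `model`, `p`, `pool_size` (NA for the
#'   single model), `pair_fraction`, `triplet_fraction`, `sister_fraction`.
#' @examples
#' head(predict_table(yilgarn_census(), "single", p = seq(0, 1, 0.25)))
#' @export
predict_table <- function(census, model = c("repeated", "single"),
                          p = seq(0, 1, by = 0.01), events = 2L,
                          pool_size = 10L, q = 1, final_prob = 1) {
  model <- match.arg(model)
  census <- as_census(census)
  grid <- if (model == "repeated") {
    expand.grid(p = p, pool_size = pool_size)
  } else {
    data.frame(p = p, pool_size = NA_integer_)
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    scen <- if (model == "repeated") {
      colonization_scenario("repeated", c(rep(grid$p[i], events - 1L), final_prob),
                            pool_size = grid$pool_size[i])
    } else {
      colonization_scenario("single", grid$p[i], diversification_prob = q)
    }
    pred <- expected_sister_fractions(census, scen)
    data.frame(model = model, p = grid$p[i], pool_size = grid$pool_size[i],
               pair_fraction = pred$expected_pair_fraction,
               triplet_fraction = pred$expected_triplet_fraction,
               sister_fraction = pred$expected_sister_fraction)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Randomization-band table against an observed tally
#'
#' Runs the seeded randomization at each parameter point and reports the
#' 5/95-percentile band of the chosen statistic next to the observed value,
#' with a verdict: is the observation inside or outside (above) the band?
#'
#' @param census An [aquifer_census()].
#' @param observed A [sister_tally()].
#' @param model `"repeated"` or `"single"`.
#' @param p Early-event colonization probability (single value for the
#'   repeated model; may be a vector for the single model).
#' @param pool_size Pool size(s) to scan (repeated model).
#' @param events,q,final_prob As in [predict_table()].
#' @param replicates,seed Randomization size and seed.
#' @param statistic Band statistic, default combined `"sister_fraction"`.
#' @return A data frame with one row per parameter point: `model`, `p`,
#'   `pool_size`, `lower`, `upper`, `mean`, `observed`, `verdict`.
#' @export
band_table <- function(census, observed, model = c("repeated", "single"),
                       p = 0.5, pool_size = 3:10, events = 2L, q = 1,
                       final_prob = 1, replicates = 10000L, seed = 1L,
                       statistic = c("sister_fraction", "pair_fraction",
                                     "triplet_fraction")) {
  model <- match.arg(model)
  statistic <- match.arg(statistic)
  census <- as_census(census)
  if (!inherits(observed, "sister_tally"))
    stop("observed must be a sister_tally", call. = FALSE)
  grid <- if (model == "repeated") {
    expand.grid(p = p, pool_size = pool_size)
  } else {
    data.frame(p = p, pool_size = NA_integer_)
  }
  obs <- observed[[statistic]]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    scen <- if (model == "repeated") {
      colonization_scenario("repeated", c(rep(grid$p[i], events - 1L), final_prob),
                            pool_size = grid$pool_size[i])
    } else {
      colonization_scenario("single", grid$p[i], diversification_prob = q)
    }
    band <- percentile_band(simulate_region(census, scen, replicates, seed),
                            statistic = statistic)
    data.frame(model = model, p = grid$p[i], pool_size = grid$pool_size[i],
               lower = band$lower, upper = band$upper, mean = band$mean,
               observed = obs,
               verdict = if (obs > band$upper) "outside_above"
                         else if (obs < band$lower) "outside_below"
                         else "inside")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  attr(out, "replicates") <- replicates
  out
}

#' Detection report for an annotated tree
#'
#' Runs sister-clade detection and tallies the result against a census.
#'
#' @param atree An [read_annotated_tree()] object.
#' @param census An [aquifer_census()].
#' @param min_support Support threshold passed to
#'   [find_sympatric_sister_clades()].
#' @return A list with `clades` (the detected clades) and `tally`
#'   (a [sister_tally()]).
#' @export
detect_report <- function(atree, census, min_support = 0) {
  clades <- find_sympatric_sister_clades(atree, min_support = min_support)
  list(clades = clades, tally = tally_observed(clades, census))
}

#' Fit the colonization probability to an observed tally
#'
#' Convenience wrapper around [solve_probability_for_fraction()] starting
#' from a [sister_tally()] rather than a bare fraction.
#'
#' @inheritParams solve_probability_for_fraction
#' @param observed A [sister_tally()].
#' @return A list with `roots` and `estimate` (the larger root, `NA` if none).
#' @export
fit_report <- function(census, observed, model = c("repeated", "single"),
                       events = 2L, pool_size = NULL, q = 1, final_prob = 1) {
  if (!inherits(observed, "sister_tally"))
    stop("observed must be a sister_tally", call. = FALSE)
  roots <- solve_probability_for_fraction(census, model, events = events,
                                          pool_size = pool_size, q = q,
                                          observed_fraction = observed$sister_fraction,
                                          final_prob = final_prob)
  list(roots = roots,
       estimate = if (length(roots)) max(roots) else NA_real_,
       observed = observed)
}
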