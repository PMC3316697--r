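# Seeded Monte Carlo implementation of both colonization processes and the
# 5/95-percentile randomization bands.

# Per-replicate L'Ecuyer-CMRG substreams derived from one seed, so replicate r
# is reproducible independently of evaluation order. The caller's RNG state is
# saved and restored around any use.

make_streams <- function(seed, n) {
  if (length(seed) != 1L || is.na(seed)) stop("seed must be a single integer", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
  set.seed(as.integer(seed %% .Machine$integer.max))
  s <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

use_stream <- function(s) assign(".Random.seed", s, envir = globalenv())

#' Sister tally
#'
#' Counts of aquifers whose largest sympatric sister group is a pair or a
#' triplet (disjoint classifications), with the corresponding fractions of
#' the regional total.
#'
#' @param pair_aquifers,triplet_aquifers,total_aquifers Non-negative counts.
#' @return An object of class `sister_tally`.
#' @examples
#' sister_tally(9, 2, 45) # the observed Yilgarn tally
#' @export
sister_tally <- function(pair_aquifers, triplet_aquifers, total_aquifers) {
  k <- c(pair_aquifers, triplet_aquifers, total_aquifers)
  if (anyNA(k) || any(k < 0) || any(k != round(k)))
    stop("tally counts must be non-negative integers", call. = FALSE)
  if (pair_aquifers + triplet_aquifers > total_aquifers)
    stop("pair + triplet aquifers exceed the total", call. = FALSE)
  if (total_aquifers == 0L) stop("total_aquifers must be positive", call. = FALSE)
  structure(
    list(pair_aquifers = as.integer(pair_aquifers),
         triplet_aquifers = as.integer(triplet_aquifers),
         total_aquifers = as.integer(total_aquifers),
         pair_fraction = pair_aquifers / total_aquifers,
         triplet_fraction = triplet_aquifers / total_aquifers,
         sister_fraction = (pair_aquifers + triplet_aquifers) / total_aquifers),
    class = "sister_tally"
  )
}

#' @export
print.sister_tally <- function(x, ...) {
  cat(sprintf("Sister tally: %d pairs + %d triplets of %d aquifers (fraction %.4f)\n",
              x$pair_aquifers, x$triplet_aquifers, x$total_aquifers, x$sister_fraction))
  invisible(x)
}

# fast classification-only kernels (niches exchangeable, so only counts drawn)

sim_class_repeated <- function(m, probs, n) {
  empty <- m
  sp <- integer(0)
  for (pj in probs) {
    if (empty == 0L) break
    k <- stats::rbinom(1L, empty, pj)
    if (k > 0L) {
      sp <- c(sp, sample.int(n, k))
      empty <- empty - k
    }
  }
  if (length(sp) < 2L) return(0L)
  mx <- max(tabulate(match(sp, sp)))
  if (mx >= 3L) 3L else if (mx == 2L) 2L else 0L
}

sim_class_single <- function(m, p, q) {
  k <- stats::rbinom(1L, m, p)
  if (k == 0L || k == m) return(0L)
  e <- m - k
  filled <- stats::rbinom(1L, e, q)
  if (filled == 0L) return(0L)
  if (k == 1L) {
    # all in-situ species descend from the single founder
    if (filled + 1L >= 3L) 3L else 2L
  } else {
    # k = 2, e = 1: the in-situ species pairs with one of the two founders
    2L
  }
}

#' Simulate one aquifer under a colonization scenario
#'
#' Draws a single aquifer history from the current R random number stream.
#' Under the repeated model, each still-empty niche opens independently with
#' the event's probability and opened niches receive distinct species drawn
#' uniformly from the ancestral pool; under the single model one event founds
#' niches independently with probability p, then each remaining empty niche is
#' filled with probability q by a descendant of a uniformly chosen current
#' resident (empty niches processed in index order).
#'
#' @param niches Number of niches, 1, 2 or 3.
#' @param scenario A [colonization_scenario()].
#' @return An object of class `aquifer_outcome`: `niches`, a data frame
#'   `occupants` with columns `niche`, `species` (ancestral species id),
#'   `event` (founding event index; `NA` for in-situ species), `origin`
#'   (`"colonization"` or `"in_situ_split"`), and `classification`
#'   (`"none"`, `"pair"` or `"triplet"` by the largest same-ancestor group).
#' @examples
#' set.seed(1)
#' simulate_aquifer(3, colonization_scenario("single", 0.78, diversification_prob = 1))
#' @export
simulate_aquifer <- function(niches, scenario) {
  scenario <- as_scenario(scenario)
  if (!niches %in% 1:3) stop("niches must be 1, 2 or 3", call. = FALSE)
  if (scenario$model == "repeated" && scenario$pool_size < niches)
    stop("pool_size must be at least the niche count", call. = FALSE)
  occ <- data.frame(niche = integer(0), species = integer(0), event = integer(0),
                    origin = character(0), stringsAsFactors = FALSE)
  if (scenario$model == "repeated") {
    filled <- rep(FALSE, niches)
    for (j in seq_along(scenario$event_probs)) {
      open <- which(!filled)
      if (!length(open)) break
      colonized <- open[stats::runif(length(open)) < scenario$event_probs[j]]
      if (length(colonized)) {
        sp <- sample.int(scenario$pool_size, length(colonized))
        occ <- rbind(occ, data.frame(niche = colonized, species = sp,
                                     event = j, origin = "colonization",
                                     stringsAsFactors = FALSE))
        filled[colonized] <- TRUE
      }
    }
  } else {
    p <- scenario$event_probs[1L]
    q <- scenario$diversification_prob
    founded <- which(stats::runif(niches) < p)
    if (length(founded))
      occ <- data.frame(niche = founded, species = seq_along(founded),
                        event = 1L, origin = "colonization",
                        stringsAsFactors = FALSE)
    for (i in setdiff(seq_len(niches), founded)) {
      if (nrow(occ) == 0L) break
      if (stats::runif(1) < q) {
        parent <- occ[sample.int(nrow(occ), 1L), ]
        occ <- rbind(occ, data.frame(niche = i, species = parent$species,
                                     event = NA_integer_, origin = "in_situ_split",
                                     stringsAsFactors = FALSE))
      }
    }
  }
  mx <- if (nrow(occ)) max(tabulate(match(occ$species, occ$species))) else 0L
  classification <- if (mx >= 3L) "triplet" else if (mx == 2L) "pair" else "none"
  structure(list(niches = niches, occupants = occ, classification = classification),
            class = "aquifer_outcome")
}

#' Simulate replicate regions and tally sister aquifers
#'
#' Simulates the whole aquifer census independently `replicates` times under
#' one scenario and tallies pair- and triplet-aquifers per replicate. Each
#' replicate draws from its own RNG substream derived deterministically from
#' `seed`, so results are reproducible and independent of evaluation order.
#'
#' @param census An [aquifer_census()].
#' @param scenario A [colonization_scenario()].
#' @param replicates Number of replicate regions (>= 1).
#' @param seed Integer seed.
#' @return A data frame (class `region_tallies`) with one row per replicate:
#'   `replicate`, `pair_aquifers`, `triplet_aquifers`, `total_aquifers`,
#'   `pair_fraction`, `triplet_fraction`, `sister_fraction`. The seed is
#'   stored in `attr(, "seed")`.
#' @export
simulate_region <- function(census, scenario, replicates = 10000L, seed = 1L) {
  census <- as_census(census)
  scenario <- as_scenario(scenario)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  max_niche <- max(which(census$by_niche > 0L))
  if (scenario$model == "repeated" && scenario$pool_size < max_niche)
    stop("pool_size smaller than the largest niche count in the census", call. = FALSE)
  niches_vec <- rep.int(1:3, census$by_niche)
  niches_vec <- niches_vec[niches_vec >= 2L] # one-niche aquifers never hold sisters
  streams <- make_streams(seed, replicates)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  pairs <- integer(replicates)
  trips <- integer(replicates)
  repeated <- scenario$model == "repeated"
  for (r in seq_len(replicates)) {
    use_stream(streams[[r]])
    np <- 0L; nt <- 0L
    for (m in niches_vec) {
      cl <- if (repeated) {
        sim_class_repeated(m, scenario$event_probs, scenario$pool_size)
      } else {
        sim_class_single(m, scenario$event_probs[1L], scenario$diversification_prob)
      }
      if (cl == 2L) np <- np + 1L else if (cl == 3L) nt <- nt + 1L
    }
    pairs[r] <- np; trips[r] <- nt
  }
  A <- census$total
  out <- data.frame(replicate = seq_len(replicates),
                    pair_aquifers = pairs, triplet_aquifers = trips,
                    total_aquifers = A,
                    pair_fraction = pairs / A, triplet_fraction = trips / A,
                    sister_fraction = (pairs + trips) / A)
  attr(out, "seed") <- seed
  attr(out, "scenario") <- scenario
  class(out) <- c("region_tallies", "data.frame")
  out
}

#' Empirical percentile band of a replicate statistic
#'
#' Randomization confidence limits: empirical percentiles (default 5th and
#' 95th) of a tally statistic over randomization replicates, estimated with
#' linear interpolation between order statistics ([stats::quantile()] type 7).
#'
#' @param tallies A `region_tallies` data frame from [simulate_region()].
#' @param statistic One of `"sister_fraction"`, `"pair_fraction"`,
#'   `"triplet_fraction"`.
#' @param levels Two percentile levels in (0, 100), default `c(5, 95)`.
#' @return An object of class `percentile_band`: `statistic`, `lower`,
#'   `upper`, `mean`, `sd`, `replicates`, `seed`.
#' @export
percentile_band <- function(tallies,
                            statistic = c("sister_fraction", "pair_fraction",
                                          "triplet_fraction"),
                            levels = c(5, 95)) {
  statistic <- match.arg(statistic)
  if (!is.data.frame(tallies) || !statistic %in% names(tallies))
    stop("tallies must be a region_tallies data frame", call. = FALSE)
  x <- tallies[[statistic]]
  if (!length(x)) stop("empty replicate set", call. = FALSE)
  qs <- stats::quantile(x, probs = sort(levels) / 100, type = 7, names = FALSE)
  structure(
    list(statistic = statistic, lower = qs[1L], upper = qs[2L],
         mean = mean(x), sd = stats::sd(x), replicates = length(x),
         seed = attr(tallies, "seed")),
    class = "percentile_band"
  )
}

#' @export
print.percentile_band <- function(x, ...) {
  cat(sprintf("Percentile band for %s: [%.4f, %.4f] (mean %.4f, sd %.4f, %d replicates)\n",
              x$statistic, x$lower, x$upper, x$mean,
              ifelse(is.na(x$sd), NA, x$sd), x$replicates))
  invisible(x)
}

#' Smallest ancestral pool incompatible with the observed tally
#'
#' Scans pool sizes upward under the two-event repeated-colonization model and
#' reports the smallest n at which the observed sister fraction exceeds the
#' 95th percentile of the randomized sister fraction, i.e. the point where the
#' repeated-colonization null is rejected by the percentile band.
#'
#' @param census An [aquifer_census()].
#' @param observed A [sister_tally()] of the observed region.
#' @param p1 First-event colonization probability (default 0.5, the
#'   pair-maximizing value).
#' @param final_prob Last-event colonization probability (default 1).
#' @param n_range Ascending pool sizes to scan; every value must be at least
#'   the largest niche count in the census.
#' @param replicates Randomization replicates per pool size (default 10000).
#' @param seed Integer seed (reused for each pool size, giving common random
#'   numbers across the scan).
#' @param statistic Band statistic, default `"sister_fraction"`.
#' @return The smallest qualifying pool size as an integer, or `NA` if none in
#'   range. The per-n band table is attached as `attr(, "scan")`.
#' @export
min_pool_size_outside_band <- function(census, observed, p1 = 0.5, final_prob = 1,
                                       n_range = 3:30, replicates = 10000L,
                                       seed = 1L,
                                       statistic = c("sister_fraction",
                                                     "pair_fraction",
                                                     "triplet_fraction")) {
  census <- as_census(census)
  statistic <- match.arg(statistic)
  if (!inherits(observed, "sister_tally"))
    stop("observed must be a sister_tally", call. = FALSE)
  if (is.unsorted(n_range)) stop("n_range must be ascending", call. = FALSE)
  max_niche <- max(which(census$by_niche > 0L))
  if (any(n_range < max_niche))
    stop(sprintf("pool sizes below the largest niche count (%d) are infeasible",
                 max_niche), call. = FALSE)
  obs <- observed[[statistic]]
  scan <- data.frame(pool_size = integer(0), lower = numeric(0), upper = numeric(0),
                     mean = numeric(0), observed = numeric(0), outside = logical(0))
  found <- NA_integer_
  for (n in n_range) {
    scen <- colonization_scenario("repeated", c(p1, final_prob), pool_size = n)
    band <- percentile_band(simulate_region(census, scen, replicates, seed),
                            statistic = statistic)
    outside <- obs > band$upper
    scan <- rbind(scan, data.frame(pool_size = n, lower = band$lower,
                                   upper = band$upper, mean = band$mean,
                                   observed = obs, outside = outside))
    if (outside) { found <- as.integer(n); break }
  }
  attr(found, "scan") <- scan
  found
}
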