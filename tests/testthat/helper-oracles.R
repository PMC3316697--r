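# Independent brute-force oracles for the colonization models. These
# enumerate the full outcome space (niche fill times x ordered
# without-replacement species draws) and never reuse the package's closed
# forms, so agreement is a real cross-check.

# all ordered k-tuples of distinct values from 1..n, as a matrix (rows)
ordered_draws <- function(n, k) {
  if (k == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), k)))
  grid[apply(grid, 1L, function(r) !anyDuplicated(r)), , drop = FALSE]
}

# exact P(pair), P(triplet) under the repeated model by exhaustive enumeration
oracle_repeated <- function(niches, probs, n) {
  E <- length(probs)
  fill_prob <- function(e) {
    if (e == 0L) prod(1 - probs) else probs[e] * prod(1 - probs[seq_len(e - 1L)])
  }
  assignments <- as.matrix(expand.grid(rep(list(0:E), niches)))
  pair <- 0; triplet <- 0
  for (r in seq_len(nrow(assignments))) {
    a <- assignments[r, ]
    pa <- prod(vapply(a, fill_prob, numeric(1)))
    if (pa == 0) next
    evs <- sort(unique(a[a > 0L]))
    ks <- vapply(evs, function(e) sum(a == e), integer(1))
    if (sum(ks) < 2L) next
    draw_sets <- lapply(ks, function(k) ordered_draws(n, k))
    idx <- expand.grid(lapply(draw_sets, function(m) seq_len(nrow(m))))
    w <- 1 / prod(vapply(draw_sets, nrow, numeric(1)))
    for (j in seq_len(nrow(idx))) {
      sp <- unlist(lapply(seq_along(draw_sets), function(e) {
        draw_sets[[e]][idx[j, e], ]
      }))
      mx <- max(tabulate(factor(sp)))
      if (mx == 2L) pair <- pair + pa * w
      if (mx >= 3L) triplet <- triplet + pa * w
    }
  }
  c(pair = pair, triplet = triplet)
}

# exact P(pair), P(triplet) under the single-colonization model: enumerate
# founder sets, then the per-empty-niche fill/parent choices in order
oracle_single <- function(niches, p, q) {
  pair <- 0; triplet <- 0
  for (founders in 0:niches) {
    pf <- choose(niches, founders) * p^founders * (1 - p)^(niches - founders)
    if (founders == 0L || pf == 0) next
    states <- list(list(prob = 1, clades = rep(1L, founders)))
    for (i in seq_len(niches - founders)) {
      nxt <- list()
      for (s in states) {
        nxt <- c(nxt, list(list(prob = s$prob * (1 - q), clades = s$clades)))
        total <- sum(s$clades)
        for (ci in seq_along(s$clades)) {
          cl <- s$clades
          cl[ci] <- cl[ci] + 1L
          nxt <- c(nxt, list(list(prob = s$prob * q * s$clades[ci] / total,
                                  clades = cl)))
        }
      }
      states <- nxt
    }
    for (s in states) {
      mx <- max(s$clades)
      if (mx == 2L) pair <- pair + pf * s$prob
      if (mx >= 3L) triplet <- triplet + pf * s$prob
    }
  }
  c(pair = pair, triplet = triplet)
}

# Monte Carlo frequency of pair/triplet outcomes from repeated simulate_aquifer
mc_aquifer_freq <- function(niches, scenario, reps, seed = 1) {
  set.seed(seed)
  cls <- vapply(seq_len(reps), function(i) {
    simulate_aquifer(niches, scenario)$classification
  }, character(1))
  c(pair = mean(cls == "pair"), triplet = mean(cls == "triplet"))
}

# small annotated fixture used across detection tests
toy_annotated_tree <- function() {
  nwk <- "(((a1x:1,a1y:1)0.95:1,a2z:2):1,(s1:2.5,(a3u:0.5,(a3v:0.2,a3w:0.2):0.3):2):0.5);"
  md <- data.frame(
    tip_id = c("a1x", "a1y", "a2z", "s1", "a3u", "a3v", "a3w"),
    aquifer_id = c("aq1", "aq1", "aq2", NA, "aq3", "aq3", "aq3"),
    habitat = c("subterranean", "subterranean", "subterranean", "surface",
                "subterranean", "subterranean", "subterranean"),
    stringsAsFactors = FALSE
  )
  read_annotated_tree(nwk, md)
}
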