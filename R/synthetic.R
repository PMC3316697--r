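# Synthetic annotated phylogenies with known colonization ground truth:
# a Yule surface radiation onto which subterranean clades are grafted
# according to simulated aquifer histories.

# --- internal mutable tree store -------------------------------------------
# nodes indexed 1..N; parent NA marks the root; age = time before present;
# label non-NA marks a tip; habitat only meaningful for tips.

new_store <- function() {
  env <- new.env(parent = emptyenv())
  env$parent <- integer(0)
  env$age <- numeric(0)
  env$label <- character(0)
  env$habitat <- character(0)
  env
}

store_add <- function(st, parent, age, label = NA_character_,
                      habitat = NA_character_) {
  i <- length(st$parent) + 1L
  st$parent[i] <- parent
  st$age[i] <- age
  st$label[i] <- label
  st$habitat[i] <- habitat
  i
}

store_to_phylo <- function(st) {
  n <- length(st$parent)
  is_tip <- !is.na(st$label)
  ntip <- sum(is_tip)
  root <- which(is.na(st$parent))
  stopifnot(length(root) == 1L)
  kids <- split(seq_len(n), factor(st$parent, levels = seq_len(n)))
  num <- integer(n)
  num[is_tip] <- seq_len(ntip)
  # preorder numbering of internal nodes, root first (ape convention)
  stack <- root
  next_internal <- ntip + 1L
  order_visit <- integer(0)
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    if (!is_tip[nd]) {
      num[nd] <- next_internal
      next_internal <- next_internal + 1L
      stack <- c(kids[[nd]], stack)
      order_visit <- c(order_visit, nd)
    }
  }
  nonroot <- setdiff(seq_len(n), root)
  edge <- cbind(num[st$parent[nonroot]], num[nonroot])
  len <- st$age[st$parent[nonroot]] - st$age[nonroot]
  tip.label <- character(ntip)
  tip.label[num[is_tip]] <- st$label[is_tip]
  phy <- list(edge = edge, edge.length = len, tip.label = tip.label,
              Nnode = n - ntip)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

yule_store <- function(n_tips, birth_rate, tip_prefix = "S") {
  st <- new_store()
  root <- store_add(st, NA_integer_, NA_real_)
  active <- c(root, root) # pending parent of each live lineage
  times <- c(0)           # forward time of the root
  t <- 0
  k <- 2L
  node_time <- c(0)       # forward time per created node (root = 0)
  while (k < n_tips) {
    t <- t + stats::rexp(1L, k * birth_rate)
    i <- sample.int(k, 1L)
    nd <- store_add(st, active[i], NA_real_)
    node_time[nd] <- t
    active <- c(active[-i], nd, nd)
    k <- k + 1L
  }
  t_end <- t + stats::rexp(1L, n_tips * birth_rate)
  for (j in seq_along(active)) {
    nd <- store_add(st, active[j], NA_real_,
                    label = sprintf("%s%03d", tip_prefix, j),
                    habitat = "surface")
    node_time[nd] <- t_end
  }
  st$age <- t_end - node_time
  st
}

#' Simulate an ultrametric surface radiation
#'
#' Pure-birth (Yule) tree: starting from the root's two daughter lineages,
#' each of k live lineages splits at total rate k times `birth_rate`, until
#' `n_tips` lineages exist; the clock then runs one final exponential waiting
#' time before the present. Expected depth is \eqn{\sum_{k=2}^{n} 1/(k \lambda)}.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate per lineage per million years (> 0).
#' @param seed Optional integer seed; `NULL` draws from the current RNG state.
#' @return An ultrametric `phylo` with tip labels `S001`, `S002`, ...
#' @examples
#' tr <- generate_surface_tree(10, 0.5, seed = 1)
#' @export
generate_surface_tree <- function(n_tips, birth_rate, seed = NULL) {
  if (length(n_tips) != 1L || n_tips < 2L || n_tips != round(n_tips))
    stop("n_tips must be an integer >= 2", call. = FALSE)
  if (length(birth_rate) != 1L || !is.finite(birth_rate) || birth_rate <= 0)
    stop("birth_rate must be positive", call. = FALSE)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  store_to_phylo(yule_store(n_tips, birth_rate))
}

# eligible original surface edges spanning a given age (strictly inside)
edges_spanning <- function(st, surface_nodes, a) {
  v <- surface_nodes[!is.na(st$parent[surface_nodes])]
  v[st$age[st$parent[v]] > a & st$age[v] < a]
}

# attach a clade of `k` tips for one same-ancestor group onto edge above `v`
# at stem age `ages[1]`; internal split ages ages[-1] (decreasing, < ages[1])
graft_group <- function(st, v, ages, labels) {
  k <- length(labels)
  w <- store_add(st, st$parent[v], ages[1L])
  st$parent[v] <- w
  hang <- w
  if (k > 1L) {
    for (j in 2:k) {
      x <- store_add(st, hang, ages[j])
      if (j < k) {
        store_add(st, x, 0, label = labels[j - 1L], habitat = "subterranean")
        hang <- x
      } else {
        store_add(st, x, 0, label = labels[j - 1L], habitat = "subterranean")
        store_add(st, x, 0, label = labels[j], habitat = "subterranean")
      }
    }
  } else {
    store_add(st, w, 0, label = labels[1L], habitat = "subterranean")
  }
  invisible(st)
}

#' Generate a synthetic annotated dataset with known ground truth
#'
#' Simulates every aquifer of the census under one colonization scenario,
#' then builds a time-calibrated phylogeny realizing those histories: a Yule
#' surface radiation onto which each same-ancestor group of subterranean
#' species is grafted as a clade on its own donor surface lineage. Repeated
#' colonizations of one ancestral species become successive splits at the
#' event ages; within-aquifer diversification becomes splits at ages drawn
#' uniformly between the colonization age and the present. Donor lineages are
#' distinct across all groups, so the planted pairs and triplets are exactly
#' the maximal sympatric sister clades of the resulting tree.
#'
#' @param census An [aquifer_census()].
#' @param scenario A [colonization_scenario()].
#' @param event_ages Ages (My) of the colonization events, strictly
#'   decreasing, one per event. Defaults: 7 and 3.5 for two events,
#'   7/5/3.5 for three, 7 for the single model.
#' @param n_surface_tips,birth_rate Surface radiation size and speciation
#'   rate; the defaults (600 tips, 0.2/My) give a deep tree with ample
#'   lineages alive at the oldest event age.
#' @param seed Integer seed.
#' @return An object of class `synthetic_dataset`: `tree` (an
#'   `annotated_tree`), `metadata`, `census`, `scenario`, `event_ages`,
#'   `outcomes` (per-aquifer `aquifer_outcome` ground truth), `tally` (the
#'   planted [sister_tally()]) and `seed`.
#' @examples
#' ds <- generate_colonization_dataset(
#'   aquifer_census(3, 3, 2),
#'   colonization_scenario("single", 0.8, diversification_prob = 1),
#'   n_surface_tips = 60, birth_rate = 0.2, seed = 7)
#' ds$tally
#' @export
generate_colonization_dataset <- function(census, scenario, event_ages = NULL,
                                          n_surface_tips = 600L,
                                          birth_rate = 0.2, seed = 1L) {
  census <- as_census(census)
  scenario <- as_scenario(scenario)
  n_events <- length(scenario$event_probs)
  if (is.null(event_ages)) {
    event_ages <- switch(as.character(n_events),
                         "1" = 7, "2" = c(7, 3.5), "3" = c(7, 5, 3.5))
  }
  if (length(event_ages) != n_events || any(diff(event_ages) >= 0) && n_events > 1L)
    stop("event_ages must be strictly decreasing, one age per event", call. = FALSE)
  if (any(event_ages <= 0)) stop("event_ages must be positive", call. = FALSE)

  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)

  # aquifer histories
  niches_vec <- rep.int(1:3, census$by_niche)
  aq_ids <- sprintf("A%03d", seq_along(niches_vec))
  outcomes <- lapply(niches_vec, simulate_aquifer, scenario = scenario)
  names(outcomes) <- aq_ids
  cls <- vapply(outcomes, function(o) o$classification, character(1))
  planted <- sister_tally(sum(cls == "pair"), sum(cls == "triplet"), census$total)

  # surface backbone
  st <- yule_store(n_surface_tips, birth_rate)
  root_age <- max(st$age, na.rm = TRUE)
  if (max(event_ages) >= root_age)
    stop(sprintf("oldest event age (%.2f) exceeds the surface tree depth (%.2f)",
                 max(event_ages), root_age), call. = FALSE)
  surface_nodes <- seq_along(st$parent)
  used_edges <- integer(0)

  for (i in seq_along(outcomes)) {
    occ <- outcomes[[i]]$occupants
    if (!nrow(occ)) next
    for (sp in unique(occ$species)) {
      grp <- occ[occ$species == sp, , drop = FALSE]
      col_rows <- grp$origin == "colonization"
      if (scenario$model == "repeated") {
        ages <- sort(event_ages[grp$event], decreasing = TRUE)
      } else {
        stem <- event_ages[1L]
        n_insitu <- sum(!col_rows)
        ages <- c(stem, sort(stats::runif(n_insitu, 0, stem), decreasing = TRUE))
      }
      labels <- sprintf("%s_sp%d_%d", aq_ids[i], sp, seq_len(nrow(grp)))
      eligible <- setdiff(edges_spanning(st, surface_nodes, ages[1L]), used_edges)
      if (!length(eligible))
        stop(sprintf("no unused surface lineage alive at %.2f My for aquifer %s; ",
                     ages[1L], aq_ids[i]),
             "increase n_surface_tips or lower birth_rate", call. = FALSE)
      donor <- eligible[sample.int(length(eligible), 1L)]
      used_edges <- c(used_edges, donor)
      graft_group(st, donor, ages, labels)
    }
  }

  phy <- store_to_phylo(st)
  tips <- !is.na(st$label)
  metadata <- data.frame(
    tip_id = st$label[tips],
    aquifer_id = ifelse(st$habitat[tips] == "subterranean",
                        sub("_sp.*$", "", st$label[tips]), NA_character_),
    habitat = st$habitat[tips],
    stringsAsFactors = FALSE
  )
  atree <- read_annotated_tree(phy, metadata)
  structure(
    list(tree = atree, metadata = metadata, census = census,
         scenario = scenario, event_ages = event_ages,
         outcomes = outcomes, tally = planted, seed = seed),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic colonization dataset (", x$scenario$model, " model, seed ",
      x$seed, ")\n", sep = "")
  print(x$tree)
  cat("Planted ")
  print(x$tally)
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits `tree.nwk` (newick), `metadata.tsv` (tip_id, aquifer_id, habitat) and
#' `ground_truth.json` (scenario, event ages, planted tally and per-aquifer
#' histories) into `dir`.
#'
#' @param dataset A [generate_colonization_dataset()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("tree.nwk", "metadata.tsv", "ground_truth.json"))
  ape::write.tree(dataset$tree$phylo, paths[1L])
  utils::write.table(dataset$metadata, paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(
    scenario = unclass(dataset$scenario),
    event_ages = dataset$event_ages,
    seed = dataset$seed,
    tally = unclass(dataset$tally),
    aquifers = lapply(dataset$outcomes, function(o) {
      list(niches = o$niches, classification = o$classification,
           occupants = o$occupants)
    })
  )
  jsonlite::write_json(truth, paths[3L], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(paths)
}

#' Recover the colonization probability from a synthetic dataset
#'
#' Closes the inference loop: detects sympatric sister clades on the dataset's
#' tree, tallies them against the census, and solves the closed-form expected
#' sister fraction for the colonization probability (q = 1 and final event
#' probability 1 assumed, as in the generator).
#'
#' @param dataset A [generate_colonization_dataset()] result.
#' @param model Model family to invert (defaults to the generating one).
#' @return A list with `roots` (all solutions in [0, 1], possibly empty when
#'   the observed fraction exceeds the model maximum), `estimate` (the larger
#'   root, `NA` if none) and `tally` (the detected [sister_tally()]).
#' @export
recover_parameters <- function(dataset, model = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (is.null(model)) model <- dataset$scenario$model
  clades <- find_sympatric_sister_clades(dataset$tree)
  tally <- tally_observed(clades, dataset$census)
  roots <- solve_probability_for_fraction(
    dataset$census, model,
    events = max(2L, length(dataset$scenario$event_probs)),
    pool_size = dataset$scenario$pool_size,
    q = 1, observed_fraction = tally$sister_fraction
  )
  list(roots = roots,
       estimate = if (length(roots)) max(roots) else NA_real_,
       tally = tally)
}
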