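# Surface vs subterranean lineage-through-time curves.

#' Lineage-through-time counts by habitat class
#'
#' Counts lineages alive at each queried age, split into surface and
#' subterranean classes. Every maximal all-subterranean clade (of any size,
#' including lone subterranean tips) is assumed to have colonized the
#' subterranean environment somewhere on its stem branch; the colonization
#' point sits at `colonization_fraction` of the way from the older (rootward)
#' end of that branch. A lineage is counted as subterranean for ages younger
#' than its colonization point and surface otherwise.
#'
#' A branch is alive at age t when its child end is at age <= t and its
#' parent end at age > t, so the two class counts always sum to the total
#' number of branches crossing t (ages must lie below the root age).
#'
#' @param atree An [read_annotated_tree()] object; must be ultrametric
#'   (tip ages equal to within 1e-6 of the tree depth).
#' @param ages Ages (million years before present) at which to count;
#'   default: 101 evenly spaced points from the present to just below the
#'   root.
#' @param colonization_fraction Position of the colonization point along the
#'   stem branch, measured from the rootward end (default 0.5, the midpoint).
#' @return A data frame with columns `age`, `surface_count`,
#'   `subterranean_count`, `total_count`.
#' @export
ltt_counts <- function(atree, ages = NULL, colonization_fraction = 0.5) {
  stopifnot(inherits(atree, "annotated_tree"))
  check_prob(colonization_fraction, "colonization_fraction")
  if (!tree_is_ultrametric(atree$phylo))
    stop("LTT requires an ultrametric tree", call. = FALSE)
  s <- node_aquifer_summary(atree)
  phy <- s$phy
  ntip <- length(phy$tip.label)
  node_age <- node_ages(phy)
  if (is.null(ages)) {
    root_age <- node_age[ntip + 1L]
    ages <- seq(0, root_age * (1 - 1e-9), length.out = 101L)
  }
  if (any(ages < 0)) stop("ages must be non-negative", call. = FALSE)

  # maximal all-subterranean nodes (any size, tips included)
  parent <- integer(ntip + phy$Nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  maximal_sub <- s$all_sub
  has_parent <- parent > 0L
  maximal_sub[has_parent] <- s$all_sub[has_parent] & !s$all_sub[parent[has_parent]]

  par_age <- node_age[phy$edge[, 1L]]
  ch_age <- node_age[phy$edge[, 2L]]
  ch_node <- phy$edge[, 2L]
  inside_sub <- s$all_sub[phy$edge[, 1L]] # parent fully subterranean => interior edge
  is_stem <- maximal_sub[ch_node] & !inside_sub
  # colonization age on each stem branch, measured from the rootward end
  col_age <- rep(NA_real_, nrow(phy$edge))
  col_age[is_stem] <- par_age[is_stem] -
    colonization_fraction * (par_age[is_stem] - ch_age[is_stem])

  # absolute tolerance absorbs floating error in reconstructed node ages
  tol <- 1e-8 * max(node_age, 1e-12)
  counts <- vapply(ages, function(t) {
    alive <- ch_age <= t + tol & par_age > t + tol
    sub <- alive & (inside_sub | (is_stem & t < col_age))
    c(surface = sum(alive & !sub), subterranean = sum(sub))
  }, numeric(2))
  data.frame(age = ages,
             surface_count = counts["surface", ],
             subterranean_count = counts["subterranean", ],
             total_count = colSums(counts))
}
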