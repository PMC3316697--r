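# Detection of sympatric sister clades: maximal monophyletic groups of 2-3
# subterranean tips sharing one aquifer.

# Per-node aggregation over a postorder edge traversal. For each node:
# tip count, whether all descendant tips are subterranean, and their shared
# aquifer id ("" marks mixed/invalid).
node_aquifer_summary <- function(atree) {
  phy <- ape::reorder.phylo(atree$phylo, "postorder")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  size <- integer(nnode)
  all_sub <- logical(nnode)
  aq <- character(nnode) # "" = invalid/mixed
  sub_tip <- atree$tips$habitat == "subterranean"
  size[seq_len(ntip)] <- 1L
  all_sub[seq_len(ntip)] <- sub_tip
  aq[seq_len(ntip)] <- ifelse(sub_tip, atree$tips$aquifer_id, "")
  started <- logical(nnode)
  for (i in seq_len(nrow(phy$edge))) {
    par <- phy$edge[i, 1L]; ch <- phy$edge[i, 2L]
    if (!started[par]) {
      started[par] <- TRUE
      size[par] <- size[ch]
      all_sub[par] <- all_sub[ch]
      aq[par] <- aq[ch]
    } else {
      size[par] <- size[par] + size[ch]
      all_sub[par] <- all_sub[par] && all_sub[ch]
      if (aq[par] != aq[ch]) aq[par] <- ""
    }
  }
  list(phy = phy, size = size, all_sub = all_sub, aq = aq)
}

#' Find sympatric sister clades
#'
#' Scans the tree for maximal monophyletic clades of two or three
#' subterranean tips that share a single aquifer: the phylogenetic signature
#' of sympatric sister pairs and triplets. A clade is kept only if its parent
#' clade violates the condition (maximality), so a triplet is never also
#' reported as a nested pair.
#'
#' @param atree An [read_annotated_tree()] object.
#' @param min_support Drop clades whose own node support is present and below
#'   this value (default 0 keeps everything; 0.7 mirrors the usual posterior
#'   cut-off).
#' @return A data frame (class `sister_clades`) with one row per clade:
#'   `aquifer_id`, `size`, `tips` (comma-separated tip ids), `crown_age`,
#'   `support` (`NA` when absent) and `node` (ape node number).
#' @export
find_sympatric_sister_clades <- function(atree, min_support = 0) {
  stopifnot(inherits(atree, "annotated_tree"))
  check_prob(min_support, "min_support")
  s <- node_aquifer_summary(atree)
  phy <- s$phy
  ntip <- length(phy$tip.label)
  qualifies <- s$all_sub & s$aq != "" & s$size %in% 2:3
  qualifies[seq_len(ntip)] <- FALSE # a single tip is not a sister clade
  parent <- integer(ntip + phy$Nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  parent_qualifies <- rep(FALSE, length(qualifies))
  has_parent <- parent > 0L
  parent_qualifies[has_parent] <- qualifies[parent[has_parent]]
  keep <- sort(which(qualifies & !parent_qualifies))
  ages <- node_ages(phy)
  clades <- lapply(keep, function(nd) {
    tips <- tip_descendants(phy, nd)
    supp <- atree$supports[nd - ntip]
    data.frame(aquifer_id = s$aq[nd], size = s$size[nd],
               tips = paste(phy$tip.label[tips], collapse = ","),
               crown_age = ages[nd], support = supp, node = nd,
               stringsAsFactors = FALSE)
  })
  out <- if (length(clades)) do.call(rbind, clades) else {
    data.frame(aquifer_id = character(0), size = integer(0), tips = character(0),
               crown_age = numeric(0), support = numeric(0), node = integer(0),
               stringsAsFactors = FALSE)
  }
  if (nrow(out) && min_support > 0) {
    out <- out[is.na(out$support) | out$support >= min_support, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("sister_clades", "data.frame")
  out
}

tip_descendants <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  stack <- node
  tips <- integer(0)
  children <- split(phy$edge[, 2L], phy$edge[, 1L])
  while (length(stack)) {
    nd <- stack[[1L]]
    stack <- stack[-1L]
    ch <- children[[as.character(nd)]]
    is_tip <- ch <= ntip
    tips <- c(tips, ch[is_tip])
    stack <- c(stack, ch[!is_tip])
  }
  sort(tips)
}

#' Tally observed sister clades against a census
#'
#' Counts aquifers whose largest detected sister clade is a pair or a triplet
#' and expresses them as fractions of the census total. An aquifer carrying
#' more than three sister tips violates the three-niche model and raises an
#' error rather than being truncated.
#'
#' @param clades A `sister_clades` data frame from
#'   [find_sympatric_sister_clades()].
#' @param census An [aquifer_census()].
#' @return A [sister_tally()].
#' @export
tally_observed <- function(clades, census) {
  census <- as_census(census)
  if (!nrow(clades)) return(sister_tally(0L, 0L, census$total))
  tips_per_aquifer <- tapply(clades$size, clades$aquifer_id, sum)
  if (any(tips_per_aquifer > 3L))
    stop("aquifer(s) with more than three sister tips violate the niche model: ",
         paste(names(tips_per_aquifer)[tips_per_aquifer > 3L], collapse = ", "),
         call. = FALSE)
  largest <- tapply(clades$size, clades$aquifer_id, max)
  pairs <- sum(largest == 2L)
  trips <- sum(largest == 3L)
  if (trips > census$by_niche[["3"]] ||
      pairs + trips > census$by_niche[["2"]] + census$by_niche[["3"]])
    stop("tally inconsistent with the census niche structure", call. = FALSE)
  sister_tally(pairs, trips, census$total)
}
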