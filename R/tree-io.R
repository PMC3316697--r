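# Annotated time-calibrated trees: an ape "phylo" plus per-tip habitat and
# aquifer labels and optional internal-node posterior supports.

#' Read an annotated phylogeny
#'
#' Combines a rooted tree with branch lengths (in million years) and a tip
#' metadata table into an `annotated_tree`. Internal node labels that parse
#' as numbers in [0, 1] are kept as posterior supports.
#'
#' @param tree A path to a newick file, a newick string, or an
#'   [ape::read.tree()] `phylo` object.
#' @param metadata A data frame, or path to a TSV, with columns `tip_id`,
#'   `aquifer_id`, `habitat`. `habitat` must be `"surface"` or
#'   `"subterranean"`; every subterranean tip needs a non-missing
#'   `aquifer_id` (surface tips may have `NA`).
#' @return An object of class `annotated_tree`: list with `phylo` (the tree),
#'   `tips` (metadata aligned to `phylo$tip.label`) and `supports` (numeric
#'   per internal node, `NA` where absent or non-numeric).
#' @examples
#' md <- data.frame(tip_id = c("A", "B"), aquifer_id = c(NA, "aq1"),
#'                  habitat = c("surface", "subterranean"))
#' read_annotated_tree("(A:1,B:1);", md)
#' @export
read_annotated_tree <- function(tree, metadata) {
  phy <- as_phylo_input(tree)
  if (is.null(phy$edge.length))
    stop("tree must have branch lengths", call. = FALSE)
  if (any(phy$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  if (!ape::is.rooted(phy)) stop("tree must be rooted", call. = FALSE)
  md <- as_metadata_input(metadata)
  missing_md <- setdiff(phy$tip.label, md$tip_id)
  if (length(missing_md))
    stop("tips missing from metadata: ", paste(missing_md, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(md$tip_id, phy$tip.label)
  if (length(unknown))
    stop("metadata rows for unknown tips: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  md <- md[match(phy$tip.label, md$tip_id), , drop = FALSE]
  rownames(md) <- NULL
  supports <- rep(NA_real_, phy$Nnode)
  if (!is.null(phy$node.label)) {
    sv <- suppressWarnings(as.numeric(phy$node.label))
    sv[!is.na(sv) & (sv < 0 | sv > 1)] <- NA_real_
    supports <- sv
  }
  structure(list(phylo = phy, tips = md, supports = supports),
            class = "annotated_tree")
}

as_phylo_input <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    phy <- if (file.exists(tree)) ape::read.tree(tree)
           else ape::read.tree(text = tree)
    if (is.null(phy)) stop("could not parse newick input", call. = FALSE)
    return(phy)
  }
  stop("tree must be a phylo object, a newick string or a file path", call. = FALSE)
}

as_metadata_input <- function(metadata) {
  md <- if (is.character(metadata) && length(metadata) == 1L) {
    utils::read.delim(metadata, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  } else if (is.data.frame(metadata)) {
    metadata
  } else {
    stop("metadata must be a data frame or a TSV path", call. = FALSE)
  }
  need <- c("tip_id", "aquifer_id", "habitat")
  if (!all(need %in% names(md)))
    stop("metadata needs columns tip_id, aquifer_id, habitat", call. = FALSE)
  if (anyDuplicated(md$tip_id))
    stop("duplicated tip_id in metadata", call. = FALSE)
  if (!all(md$habitat %in% c("surface", "subterranean")))
    stop("habitat must be 'surface' or 'subterranean'", call. = FALSE)
  md$aquifer_id <- as.character(md$aquifer_id)
  if (any(md$habitat == "subterranean" & (is.na(md$aquifer_id) | md$aquifer_id == "")))
    stop("every subterranean tip needs an aquifer_id", call. = FALSE)
  md[, need]
}

#' @export
print.annotated_tree <- function(x, ...) {
  n_sub <- sum(x$tips$habitat == "subterranean")
  cat(sprintf("Annotated tree: %d tips (%d subterranean across %d aquifers), %d internal nodes\n",
              length(x$phylo$tip.label), n_sub,
              length(unique(stats::na.omit(x$tips$aquifer_id[x$tips$habitat == "subterranean"]))),
              x$phylo$Nnode))
  invisible(x)
}

# node ages (time before present); for non-ultrametric trees ages are measured
# from the deepest tip
node_ages <- function(phy) {
  depth <- ape::node.depth.edgelength(phy)
  max(depth[seq_along(phy$tip.label)]) - depth
}

tree_is_ultrametric <- function(phy, rel_tol = 1e-6) {
  depth <- ape::node.depth.edgelength(phy)
  tipd <- depth[seq_along(phy$tip.label)]
  diff(range(tipd)) <= rel_tol * max(tipd)
}
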