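#' Minimal Dollo-parsimony loss placement for one family
#'
#' Under the Dollo model (a single origin at the root, irreversible losses),
#' the minimal set of loss branches reproducing a leaf presence/absence
#' profile is the set of stems of maximal all-absent clades; this set is
#' unique, so no tie-breaking between co-optimal placements is needed — the
#' placements returned are the root-most (deepest) ones. An all-absent
#' profile is explained by absence at the root: zero losses with attribute
#' `flag = "family-absent-from-root"`.
#'
#' @param profile Named logical vector over every leaf of `tree`.
#' @param tree Rooted tree (`ape::phylo`) with node labels; polytomies are
#'   allowed (each child branch is treated independently).
#' @param family Optional family label carried into the result.
#' @return Tibble of loss events (`family`, `branch`, `n_leaves`, and a
#'   `clade` list-column of the leaves below each loss), with attribute
#'   `flag` (`NA` or `"family-absent-from-root"`).
#' @export
dollo_map <- function(profile, tree, family = NA_character_) {
  if (is.null(tree$node.label)) {
    tree$node.label <- c("root", paste0("N", seq_len(tree$Nnode - 1)))
  }
  missing <- setdiff(tree$tip.label, names(profile))
  if (length(missing) > 0) {
    abort(paste0("profile is missing leaves: ",
                 paste(missing, collapse = ", ")))
  }
  profile <- profile[tree$tip.label]
  nn <- node_names(tree)
  n_tip <- length(tree$tip.label)
  any_present <- c(profile, rep(FALSE, tree$Nnode))
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    any_present[p] <- any_present[p] || any_present[ch]
  }
  empty <- tibble(family = character(), branch = character(),
                  n_leaves = integer(), clade = list())
  if (!any_present[n_tip + 1L]) {
    attr(empty, "flag") <- "family-absent-from-root"
    return(empty)
  }
  # losses: children that are all-absent while their parent clade has a
  # present leaf (i.e. stems of maximal all-absent clades)
  below <- clade_leaves(tree)
  loss_nodes <- integer(0)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    if (!any_present[ch] && any_present[p]) loss_nodes <- c(loss_nodes, ch)
  }
  branch <- nn[loss_nodes]
  out <- tibble(
    family = rep(family, length(branch)), branch = branch,
    n_leaves = vapply(branch, function(b) length(below[[b]]), integer(1)),
    clade = unname(below[branch])
  ) |>
    arrange(.data$branch)
  attr(out, "flag") <- NA_character_
  out
}

#' Map losses of every family onto a species tree
#'
#' Runs [dollo_map()] per family of a presence/absence matrix and annotates
#' the tree: the label of each loss branch's child node gains a
#' `|loss:<family>` suffix in the returned Newick string.
#'
#' @param matrix A `pa_matrix` from [build_matrix()].
#' @param tree Rooted species tree covering at least the matrix species;
#'   extra leaves are pruned with a warning, matrix species missing from the
#'   tree are an error.
#' @return List with `events` (tibble of all loss events), `flags` (named
#'   character, per family) and `annotated_newick` (string).
#' @export
map_losses <- function(matrix, tree) {
  fams <- setdiff(names(matrix), c("species", "group"))
  missing <- setdiff(matrix$species, tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("matrix species not in tree: ",
                 paste(missing, collapse = ", ")))
  }
  extra <- setdiff(tree$tip.label, matrix$species)
  if (length(extra) > 0) {
    warn(paste0("pruning tree leaves absent from matrix: ",
                paste(extra, collapse = ", ")))
    tree <- ape::drop.tip(tree, extra)
    if (is.null(tree$node.label)) {
      tree$node.label <- c("root", paste0("N", seq_len(tree$Nnode - 1)))
    }
  }
  events <- list()
  flags <- character(0)
  for (f in fams) {
    profile <- setNames(matrix[[f]], matrix$species)
    ev <- dollo_map(profile, tree, family = f)
    flags[f] <- attr(ev, "flag")
    events[[f]] <- ev
  }
  events <- bind_rows(events)
  ann <- tree
  labels <- node_names(ann)
  if (nrow(events) > 0) {
    # "=" survives ape's Newick label sanitisation (":" would not)
    suffix <- tapply(events$family, events$branch, function(f) {
      paste0("|loss=", f, collapse = "")
    })
    for (b in names(suffix)) {
      k <- match(b, node_names(tree))
      labels[k] <- paste0(labels[k], suffix[[b]])
    }
  }
  n_tip <- length(ann$tip.label)
  ann$tip.label <- labels[seq_len(n_tip)]
  ann$node.label <- labels[(n_tip + 1):length(labels)]
  list(events = events, flags = flags,
       annotated_newick = ape::write.tree(ann))
}
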