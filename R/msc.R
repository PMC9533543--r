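#' Simulate gene trees under the multispecies coalescent
#'
#' Branch lengths of the species tree are in coalescent units (2N
#' generations), so within a population any two lineages coalesce at
#' rate 1 per unit time; with k lineages the total rate is k(k-1)/2.
#' Lineages that fail to coalesce on a branch are passed to the parent
#' population; coalescence is completed above the root.
#'
#' With `introgression = list(donor=, recipient=, gamma=)`, each sampled
#' lineage of the recipient species independently follows the donor's
#' path through the species tree with probability `gamma` (massive
#' recent gene flow: the lineage behaves as if sampled in the donor,
#' while keeping its recipient tip label). This asymmetric rerouting is
#' what makes the two minor triplet topologies unequal at affected
#' nodes.
#'
#' @param species_tree rooted `ape::phylo` or newick string, branch
#'   lengths in coalescent units (>= 0).
#' @param n_trees number of gene trees.
#' @param seed integer seed.
#' @param introgression optional list with `donor`, `recipient` (tip
#'   labels) and `gamma` in \[0,1\].
#' @param samples copies sampled per species: scalar or named vector.
#'   With more than one copy per species, tips are labelled
#'   `"species|i"`.
#' @return a `multiPhylo` of rooted gene trees with coalescent-unit
#'   branch lengths.
#' @examples
#' trs <- simulate_gene_trees_msc("((A:1,B:1):1,C:2);", 10, seed = 1)
#' @export
simulate_gene_trees_msc <- function(species_tree, n_trees, seed = 1,
                                    introgression = NULL, samples = 1) {
  tree <- as_phylo(species_tree)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("species tree must have nonnegative coalescent-unit branch lengths")
  if (!is.null(introgression)) {
    g <- introgression$gamma
    if (is.null(g) || g < 0 || g > 1) stop("gamma must be in [0,1]")
    if (!all(c(introgression$donor, introgression$recipient) %in%
             tree$tip.label))
      stop("introgression donor/recipient must be tip labels")
  }
  set.seed(seed)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  # node times measured backwards from the tips: depth below root, flipped
  depth <- ape::node.depth.edgelength(tree)
  tmax <- max(depth[seq_len(ntip)])
  node_time <- tmax - depth             # tips at (possibly) 0, root at tmax
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  if (is.null(names(samples)))
    samples <- stats::setNames(rep_len(samples, ntip), tree$tip.label)
  trees <- vector("list", n_trees)
  for (tr in seq_len(n_trees)) {
    # active lineages: newick fragment + node height + current sp node
    lab <- list(); hgt <- numeric(0); loc <- integer(0)
    for (i in seq_len(ntip)) {
      sp <- tree$tip.label[i]
      k <- samples[[sp]]
      for (s in seq_len(k)) {
        lab[[length(lab) + 1L]] <- if (k == 1L) sp else paste0(sp, "|", s)
        hgt <- c(hgt, node_time[i])
        start <- i
        if (!is.null(introgression) && sp == introgression$recipient &&
            stats::runif(1) < introgression$gamma)
          start <- match(introgression$donor, tree$tip.label)
        loc <- c(loc, start)
      }
    }
    # process species-tree nodes from the tips up
    ord <- order(node_time[(ntip + 1L):(ntip + tree$Nnode)]) + ntip
    for (v in c(ord)) {
      # coalesce lineages inside each child branch of v up to node_time[v]
      for (child in tree$edge[tree$edge[, 1] == v, 2]) {
        idx <- which(loc == child)
        t_now <- if (length(idx)) max(hgt[idx], node_time[child]) else 0
        while (length(idx) >= 2L) {
          k <- length(idx)
          t_now <- t_now + stats::rexp(1, rate = k * (k - 1) / 2)
          if (t_now > node_time[v]) break
          pair <- sample(idx, 2L)
          merged <- sprintf("(%s:%.8f,%s:%.8f)",
                            lab[[pair[1]]], t_now - hgt[pair[1]],
                            lab[[pair[2]]], t_now - hgt[pair[2]])
          lab[[pair[1]]] <- merged
          hgt[pair[1]] <- t_now
          lab <- lab[-pair[2]]; hgt <- hgt[-pair[2]]; loc <- loc[-pair[2]]
          idx <- which(loc == child)
        }
        loc[loc == child] <- v
      }
    }
    # above the root: coalesce everything
    idx <- seq_along(lab)
    t_now <- max(c(hgt, node_time[root]))
    while (length(idx) >= 2L) {
      k <- length(idx)
      t_now <- t_now + stats::rexp(1, rate = k * (k - 1) / 2)
      pair <- sample(idx, 2L)
      merged <- sprintf("(%s:%.8f,%s:%.8f)",
                        lab[[pair[1]]], t_now - hgt[pair[1]],
                        lab[[pair[2]]], t_now - hgt[pair[2]])
      lab[[pair[1]]] <- merged
      hgt[pair[1]] <- t_now
      lab <- lab[-pair[2]]; hgt <- hgt[-pair[2]]
      idx <- seq_along(lab)
    }
    trees[[tr]] <- ape::read.tree(text = paste0(lab[[1]], ";"))
  }
  class(trees) <- "multiPhylo"
  trees
}

#' Probability that a gene tree matches the species tree at a 3-taxon node
#'
#' Under the multispecies coalescent with internal branch length `t`
#' (coalescent units), the gene tree is concordant with probability
#' `1 - (2/3) exp(-t)`; each discordant topology has probability
#' `(1/3) exp(-t)`.
#'
#' @param t internal branch length in coalescent units.
#' @return concordance probability.
#' @export
msc_concordance_prob <- function(t) 1 - (2 / 3) * exp(-t)

#' Graft a duplicate copy next to a tip
#'
#' Adds a sister leaf to `tip`, modelling a gene duplication on the
#' terminal branch (i.e. after all speciations involving that species).
#' Used to build gene trees whose duplicates arose after a species
#' split, the signature of independent polyploidy.
#'
#' @param tree an `ape::phylo`.
#' @param tip tip label to duplicate.
#' @param label new leaf's label (default `"tip|2"`).
#' @param at fraction of the terminal branch (from the tip) at which
#'   the duplication attaches (default 0.5).
#' @return the augmented `phylo`.
#' @export
add_tip_duplicate <- function(tree, tip, label = paste0(tip, "|2"),
                              at = 0.5) {
  i <- match(tip, tree$tip.label)
  if (is.na(i)) stop("unknown tip: ", tip)
  edge <- which(tree$edge[, 2] == i)
  len <- if (is.null(tree$edge.length)) 1 else tree$edge.length[edge]
  pos <- len * at
  ape::bind.tree(tree, structure(list(
    edge = matrix(c(2L, 1L), 1, 2), tip.label = label,
    edge.length = pos, Nnode = 1L), class = "phylo"),
    where = i, position = pos)
}

#' Write / read newick tree sets
#' @param trees `multiPhylo` or list of `phylo`.
#' @param path file path (one newick per line).
#' @return `read_tree_set` returns a `multiPhylo`.
#' @export
write_tree_set <- function(trees, path) {
  ape::write.tree(trees, path)
  invisible(path)
}

#' @rdname write_tree_set
#' @export
read_tree_set <- function(path) {
  ape::read.tree(path)
}
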