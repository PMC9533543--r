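#' Simulate a clade of genomes along a species tree
#'
#' Evolves an ancestral genome root-to-tip along a species tree, applying
#' the structural events listed in `scenario` on each branch, and returns
#' the tip genomes together with a fully concrete event log whose replay
#' reproduces every tip exactly.
#'
#' `scenario` is a named list keyed by branch (the label of the child
#' node the branch leads to; internal nodes are auto-labelled `n1`,
#' `n2`, ... in `ape::makeNodeLabel` order when the tree has none). Each
#' entry is an ordered list of event specifications, a list with element
#' `kind` (`"WGD"`, `"WGT"`, `"EEJ"`, `"RTA"`, `"NCF"`, `"INVERSION"`,
#' `"FISSION"`) plus the parameters of the corresponding `apply_*`
#' operator (unset parameters are drawn at random). Event `age`s must be
#' nondecreasing along a branch.
#'
#' @param species_tree an `ape::phylo` object or newick string (rooted).
#' @param scenario per-branch event specification (see Details).
#' @param seed integer seed governing all random choices.
#' @param ancestor root `genome`; default `simulate_ancestor(n_chrom,
#'   genes_per_chrom)`.
#' @param n_chrom,genes_per_chrom ancestor shape when `ancestor` is NULL.
#' @return a `sim_dataset`: list with `ancestor`, `tips` (named list of
#'   genomes), `event_log` (named list of concrete events per branch),
#'   `tree` (`phylo` with node labels), and `node_ages` (time depth of
#'   each node, tips at their distance below the root).
#' @examples
#' ds <- simulate_clade("((A:1,B:1)n1:1,C:2)n2;",
#'   scenario = list(A = list(list(kind = "WGD", retention = 0.8, age = 1.5))),
#'   seed = 1)
#' names(ds$tips)
#' @export
simulate_clade <- function(species_tree, scenario = list(), seed = 1,
                           ancestor = NULL, n_chrom = 7,
                           genes_per_chrom = 100) {
  tree <- as_phylo(species_tree)
  if (is.null(tree$node.label) || any(tree$node.label == ""))
    tree <- ape::makeNodeLabel(tree, prefix = "n")
  labels <- c(tree$tip.label, tree$node.label)
  bad <- setdiff(names(scenario), labels)
  if (length(bad))
    stop("scenario references unknown branch labels: ",
         paste(bad, collapse = ", "))
  set.seed(seed)
  if (is.null(ancestor))
    ancestor <- simulate_ancestor(n_chrom, genes_per_chrom)
  root <- ape::Ntip(tree) + 1L
  event_log <- list()
  tips <- list()
  recurse <- function(node, genome) {
    children <- tree$edge[tree$edge[, 1] == node, 2]
    for (child in children) {
      lab <- labels[child]
      g <- genome
      specs <- scenario[[lab]]
      events <- list()
      if (length(specs)) {
        ages <- vapply(specs, function(s) if (is.null(s$age)) 0 else s$age,
                       numeric(1))
        if (is.unsorted(ages))
          stop("event ages must be nondecreasing along branch '", lab, "'")
        for (s in specs) {
          res <- apply_spec(g, s)
          g <- res$genome
          events[[length(events) + 1L]] <- res$event
        }
      }
      event_log[[lab]] <<- events
      if (child <= ape::Ntip(tree)) {
        g$species_id <- lab
        tips[[lab]] <<- g
      } else recurse(child, g)
    }
  }
  recurse(root, ancestor)
  structure(list(ancestor = ancestor, tips = tips, event_log = event_log,
                 tree = tree, node_ages = node_depths(tree)),
            class = "sim_dataset")
}

as_phylo <- function(x) {
  if (inherits(x, "phylo")) return(x)
  if (is.character(x) && length(x) == 1L) return(ape::read.tree(text = x))
  stop("expected an ape::phylo object or a newick string")
}

# time of every node measured from the root (root = 0)
node_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  names(d) <- c(tree$tip.label, tree$node.label)
  d
}

apply_spec <- function(genome, s) {
  kind <- s$kind
  age <- if (is.null(s$age)) 0 else s$age
  switch(kind,
    WGD = apply_polyploidy(genome, 2L, s$retention %||% 1, age),
    WGT = apply_polyploidy(genome, 3L, s$retention %||% 1, age),
    EEJ = , RTA = , NCF =
      apply_fusion(genome, kind, chroms = s$chroms,
                   breakpoints = s$breakpoints,
                   x_end = s$x_end %||% "tail", y_end = s$y_end %||% "head",
                   age = age),
    INVERSION = apply_inversion(genome, s$chrom, s$i, s$j, age),
    FISSION = apply_fission(genome, s$chrom, s$p, age),
    stop("unknown event kind: ", kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Replay an event log
#'
#' Re-derives every tip genome deterministically from the ancestor and a
#' concrete event log; the result is identical to the simulated tips.
#'
#' @param dataset a `sim_dataset` (or a list with `ancestor`, `tree`,
#'   `event_log`).
#' @return named list of tip genomes.
#' @export
replay_event_log <- function(dataset) {
  tree <- dataset$tree
  labels <- c(tree$tip.label, tree$node.label)
  root <- ape::Ntip(tree) + 1L
  tips <- list()
  recurse <- function(node, genome) {
    children <- tree$edge[tree$edge[, 1] == node, 2]
    for (child in children) {
      lab <- labels[child]
      g <- genome
      for (ev in dataset$event_log[[lab]]) g <- apply_event(g, ev)
      if (child <= ape::Ntip(tree)) {
        g$species_id <- lab
        tips[[lab]] <<- g
      } else recurse(child, g)
    }
  }
  recurse(root, dataset$ancestor)
  tips
}

#' Events on the root-to-tip path of a species
#' @param dataset a `sim_dataset`.
#' @param species tip label.
#' @return list of `evo_event` in root-to-tip order.
#' @export
path_events <- function(dataset, species) {
  tree <- dataset$tree
  labels <- c(tree$tip.label, tree$node.label)
  tip <- match(species, tree$tip.label)
  if (is.na(tip)) stop("unknown species: ", species)
  path <- character(0)
  node <- tip
  root <- ape::Ntip(tree) + 1L
  while (node != root) {
    path <- c(labels[node], path)
    node <- tree$edge[tree$edge[, 2] == node, 1]
  }
  do.call(c, lapply(path, function(lab) dataset$event_log[[lab]]))
}

#' A standard six-genome test scenario
#'
#' The canonical simulation used throughout the package's tests and
#' documentation: six species descend from a 7-chromosome, 100-gene
#' ancestor; every lineage undergoes one polyploidization (two
#' triplications, four duplications) with the given duplicate retention,
#' and lineages carry 0-2 fusions (all three kinds represented) plus a
#' few inversions. This emulates a clade in which each genome is a
#' shuffled, fractionated multiple of the same ancestral karyotype.
#'
#' @param retention duplicate retention after polyploidy (default 0.7).
#' @param genes_per_chrom genes per ancestral chromosome.
#' @param seed integer seed.
#' @return a `sim_dataset` with six tips S1..S6.
#' @export
moderate_scenario <- function(retention = 0.7, genes_per_chrom = 100,
                              seed = 1) {
  tree <- "((((S1:1,S2:1)n1:1,(S3:1,S4:1)n2:1)n3:1,S5:3)n4:1,S6:4)n5;"
  sc <- list(
    S1 = list(list(kind = "WGD", retention = retention, age = 1.0),
              list(kind = "EEJ", age = 1.2),
              list(kind = "INVERSION", age = 1.4)),
    S2 = list(list(kind = "WGD", retention = retention, age = 1.0),
              list(kind = "NCF", age = 1.3)),
    S3 = list(list(kind = "WGT", retention = retention, age = 1.1),
              list(kind = "RTA", age = 1.5)),
    S4 = list(list(kind = "WGD", retention = retention, age = 0.9),
              list(kind = "INVERSION", age = 1.2)),
    S5 = list(list(kind = "WGD", retention = retention, age = 1.6),
              list(kind = "EEJ", age = 2.0),
              list(kind = "INVERSION", age = 2.2)),
    S6 = list(list(kind = "WGT", retention = retention, age = 2.0),
              list(kind = "INVERSION", age = 2.5)))
  simulate_clade(tree, sc, seed = seed, n_chrom = 7,
                 genes_per_chrom = genes_per_chrom)
}

#' Write an event log as JSON
#' @param dataset a `sim_dataset`.
#' @param path output file.
#' @export
write_event_log <- function(dataset, path) {
  log <- lapply(dataset$event_log, function(events)
    lapply(events, function(ev) unclass(ev)))
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
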