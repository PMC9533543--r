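#' Gene-tree support for each species-tree bipartition
#'
#' For every internal bipartition of the species tree, the percentage of
#' gene trees whose unrooted splits include that bipartition restricted
#' to the taxa the gene tree contains. Gene trees missing taxa are
#' pruned, not discarded; trees for which the restricted bipartition is
#' trivial (fewer than two taxa on either side) are uninformative and
#' excluded from that bipartition's denominator. High support means low
#' gene-tree variation at the node.
#'
#' @param species_tree `ape::phylo` or newick (rooted or unrooted).
#' @param gene_trees `multiPhylo`/list; leaf sets must be subsets of the
#'   species-tree leaves.
#' @return data frame `node` (internal node id in the species tree),
#'   `clade` (semicolon-joined tip labels), `support` (percent),
#'   `n_informative`.
#' @export
bipartition_support <- function(species_tree, gene_trees) {
  sp <- as_phylo(species_tree)
  sp_tips <- sp$tip.label
  for (g in gene_trees)
    if (!all(g$tip.label %in% sp_tips))
      stop("gene tree contains leaves absent from the species tree")
  clades <- internal_clades(sp)
  gt_splits <- lapply(gene_trees, function(g)
    list(tips = g$tip.label, splits = internal_clades(g)))
  res <- lapply(names(clades), function(nd) {
    A <- clades[[nd]]
    hits <- 0L; inform <- 0L
    for (g in gt_splits) {
      shared <- g$tips
      a <- intersect(A, shared)
      b <- setdiff(shared, a)
      if (length(a) < 2L || length(b) < 2L) next
      inform <- inform + 1L
      key_a <- paste(sort(a), collapse = ";")
      key_b <- paste(sort(b), collapse = ";")
      found <- FALSE
      for (cl in g$splits) {
        k <- paste(sort(cl), collapse = ";")
        kc <- paste(sort(setdiff(shared, cl)), collapse = ";")
        if (k == key_a || k == key_b || kc == key_a) { found <- TRUE; break }
      }
      if (found) hits <- hits + 1L
    }
    data.frame(node = as.integer(nd),
               clade = paste(sort(A), collapse = ";"),
               support = if (inform) 100 * hits / inform else NA_real_,
               n_informative = inform, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# tip sets of non-trivial internal edges (named by internal node id)
internal_clades <- function(tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- list()
  for (i in seq_along(pp)) {
    node <- ntip + i
    if (node == root) next  # the root clade is the full tip set
    tips <- labs[pp[[i]]]
    if (length(tips) >= 2L && length(tips) <= ntip - 2L)
      out[[as.character(node)]] <- tips
  }
  out
}

#' Per-node coalescent parameter theta from branch lengths
#'
#' Combines the mutation-unit length `m` (substitutions/site, e.g. from
#' a concatenated ML re-estimate on the fixed species topology) and the
#' coalescent-unit length `d` of the same branch (e.g. from a summary
#' coalescent method): with `d = t/(2N)` generations and `m = mu t`,
#' `theta = 2 m / d = 4 N mu`. Large theta marks nodes with high
#' expected incomplete lineage sorting.
#'
#' @param m mutation-unit branch length (>= 0).
#' @param d coalescent-unit branch length (> 0).
#' @return theta estimate(s); vectorized.
#' @export
estimate_theta <- function(m, d) {
  if (any(d <= 0)) stop("coalescent branch length must be > 0")
  if (any(m < 0)) stop("mutation branch length must be >= 0")
  2 * m / d
}

#' Rooted triplet topology counts over gene trees
#'
#' For taxa (A, B, C) the three rooted triplets are ((A,B),C),
#' ((A,C),B), ((B,C),A). Counts are tallied over gene trees containing
#' all required taxa; trees are rooted on `outgroup` when given,
#' otherwise they must already be rooted. Trees missing a taxon (or the
#' outgroup) are skipped and tallied.
#'
#' @param gene_trees `multiPhylo`/list.
#' @param taxa character(3): A, B, C.
#' @param outgroup optional taxon used to root each tree.
#' @return list with `taxa`, `counts` (named: `ab`, `ac`, `bc` — the
#'   pair that is sister), `n_trees`, `n_skipped`.
#' @export
triplet_counts <- function(gene_trees, taxa, outgroup = NULL) {
  stopifnot(length(taxa) == 3L)
  D <- triplet_depth_array(gene_trees, c(taxa, outgroup), outgroup)
  cnt <- count_triplet(D, taxa)
  list(taxa = taxa, counts = cnt$counts, n_trees = cnt$n,
       n_skipped = length(gene_trees) - cnt$n)
}

# For each tree, the topological depth (root = 0, larger = closer to
# the tips) of the MRCA of every taxon pair; NA plane when a taxon is
# missing. Returns taxa x taxa x trees array.
triplet_depth_array <- function(gene_trees, taxa, outgroup = NULL) {
  taxa <- unique(taxa[!is.null(taxa)])
  nt <- length(taxa)
  D <- array(NA_real_, c(nt, nt, length(gene_trees)),
             dimnames = list(taxa, taxa, NULL))
  for (i in seq_along(gene_trees)) {
    tr <- gene_trees[[i]]
    if (!is.null(outgroup)) {
      if (!outgroup %in% tr$tip.label) next
      tr <- tryCatch(ape::root(tr, outgroup = outgroup,
                               resolve.root = TRUE),
                     error = function(e) NULL)
      if (is.null(tr)) next
    }
    present <- intersect(taxa, tr$tip.label)
    if (length(present) < 2L) next
    # topological node depths (edge counts from the root)
    tr2 <- tr
    tr2$edge.length <- rep(1, nrow(tr2$edge))
    dep <- ape::node.depth.edgelength(tr2)
    m <- ape::mrca(tr)
    idx <- match(present, tr$tip.label)
    D[present, present, i] <- dep[m[idx, idx, drop = FALSE]]
  }
  D
}

count_triplet <- function(D, taxa) {
  a <- taxa[1]; b <- taxa[2]; c_ <- taxa[3]
  dab <- D[a, b, ]; dac <- D[a, c_, ]; dbc <- D[b, c_, ]
  ok <- is.finite(dab) & is.finite(dac) & is.finite(dbc)
  # the sister pair has the deepest (most tipward) MRCA; ties = unresolved
  ab <- ok & dab > dac & dab > dbc
  ac <- ok & dac > dab & dac > dbc
  bc <- ok & dbc > dab & dbc > dac
  resolved <- ab | ac | bc
  list(counts = c(ab = sum(ab), ac = sum(ac), bc = sum(bc)),
       n = sum(resolved))
}

#' Chi-squared test of minor-triplet asymmetry
#'
#' Under pure incomplete lineage sorting the two minor (discordant)
#' triplet topologies are equally frequent; gene flow makes them
#' unequal. Without null counts the observed minors are tested against
#' exact equality (goodness of fit, df = 1). With counts from ILS-only
#' simulated trees, the observed and simulated minor frequencies are
#' compared by a 2x2 contingency chi-squared test, so that sampling
#' noise in the null calibration is accounted for.
#'
#' @param minor observed counts of the two minor topologies (length 2).
#' @param null_minor optional counts from ILS-only simulated trees.
#' @return list `statistic`, `p_value`, `expected`.
#' @export
minor_triplet_chisq <- function(minor, null_minor = NULL) {
  stopifnot(length(minor) == 2L)
  n <- sum(minor)
  if (n == 0) return(list(statistic = 0, p_value = 1, expected = c(0, 0)))
  if (is.null(null_minor) || sum(null_minor) == 0) {
    e <- n * c(0.5, 0.5)
    stat <- sum((minor - e)^2 / e)
  } else {
    tab <- rbind(obs = minor, null = null_minor)
    e_full <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - e_full)^2 / e_full)
    e <- e_full[1, ]
  }
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       expected = e)
}

#' Per-node reticulation index
#'
#' For each internal node of a rooted species tree, taxon triplets are
#' formed by sampling one taxon from each of the three taxon sets
#' meeting at the node (its two child subtrees and the rest of the
#' tree; the root is skipped). For each sampled combination the two
#' minor triplet topologies are counted in the observed gene trees and
#' tested for asymmetry against ILS-only null trees with
#' [minor_triplet_chisq()]; p-values are Benjamini-Hochberg corrected
#' across a node's combinations. The reticulation index of the node is
#' the fraction of combinations rejected at `alpha` — near zero under
#' pure ILS, elevated at nodes involved in gene flow. The mean raw
#' asymmetry `|m1 - m2| / (m1 + m2)` is also reported.
#'
#' @param species_tree rooted `ape::phylo` or newick.
#' @param gene_trees observed rooted gene trees.
#' @param null_trees ILS-only trees simulated on the same species tree
#'   (e.g. [simulate_gene_trees_msc()]); `NULL` uses exact-equality
#'   nulls.
#' @param alpha significance level after BH correction (default 0.05).
#' @param max_comb maximum triplet combinations sampled per node.
#' @param seed integer seed for combination sampling.
#' @return data frame `node`, `n_comb`, `reticulation_index`,
#'   `mean_asymmetry`; nodes without a valid combination get `NA`.
#' @export
reticulation_index <- function(species_tree, gene_trees,
                               null_trees = NULL, alpha = 0.05,
                               max_comb = 200, seed = 1) {
  sp <- as_phylo(species_tree)
  set.seed(seed)
  ntip <- ape::Ntip(sp)
  root <- ntip + 1L
  taxa <- sp$tip.label
  D_obs <- triplet_depth_array(gene_trees, taxa)
  D_null <- if (!is.null(null_trees)) triplet_depth_array(null_trees, taxa)
  out <- list()
  for (node in (ntip + 1L):(ntip + sp$Nnode)) {
    if (node == root) next
    children <- sp$edge[sp$edge[, 1] == node, 2]
    if (length(children) != 2L) next
    s1 <- tips_under(sp, children[1])
    s2 <- tips_under(sp, children[2])
    under <- c(s1, s2)
    s3 <- setdiff(taxa, under)
    if (!length(s3)) next
    combos <- expand.grid(a = s1, b = s2, c = s3,
                          stringsAsFactors = FALSE)
    if (nrow(combos) > max_comb)
      combos <- combos[sample.int(nrow(combos), max_comb), , drop = FALSE]
    pvals <- numeric(0); asym <- numeric(0)
    for (r in seq_len(nrow(combos))) {
      tri <- c(combos$a[r], combos$b[r], combos$c[r])
      cnt <- count_triplet(D_obs, tri)$counts
      minor <- cnt[c("ac", "bc")]  # major is the species-tree pair (a,b)
      null_minor <- if (!is.null(D_null))
        count_triplet(D_null, tri)$counts[c("ac", "bc")] else NULL
      tst <- minor_triplet_chisq(minor, null_minor)
      pvals <- c(pvals, tst$p_value)
      asym <- c(asym, if (sum(minor) > 0)
        abs(minor[1] - minor[2]) / sum(minor) else NA_real_)
    }
    idx <- if (length(pvals))
      mean(stats::p.adjust(pvals, "BH") < alpha) else NA_real_
    out[[length(out) + 1L]] <- data.frame(
      node = node, n_comb = nrow(combos), reticulation_index = idx,
      mean_asymmetry = mean(asym, na.rm = TRUE))
  }
  do.call(rbind, out)
}

tips_under <- function(tree, node) {
  if (node <= ape::Ntip(tree)) tree$tip.label[node]
  else ape::extract.clade(tree, node)$tip.label
}

#' Jukes-Cantor distance between two aligned sequences
#'
#' `d = -(3/4) log(1 - (4/3) p)` for mismatch fraction `p`, computed
#' after pairwise deletion of gap/ambiguity sites. A mismatch fraction
#' at or beyond 3/4 is saturated: an error of class
#' `"jc_saturation_error"` is signalled rather than truncating.
#'
#' @param seq_a,seq_b equal-length character vectors of "A"/"C"/"G"/"T"
#'   (case-insensitive; anything else is treated as a gap).
#' @return substitutions per site.
#' @examples
#' jc_distance(c("A","C","G","T"), c("A","C","G","T"))  # 0
#' @export
jc_distance <- function(seq_a, seq_b) {
  if (length(seq_a) != length(seq_b))
    stop("sequences must have equal length")
  a <- toupper(seq_a); b <- toupper(seq_b)
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(keep)) stop("no comparable sites")
  p <- mean(a[keep] != b[keep])
  if (p >= 3 / 4)
    stop(structure(class = c("jc_saturation_error", "error", "condition"),
                   list(message = sprintf(
                     "saturated distance (mismatch fraction %.3f >= 0.75)", p),
                     call = sys.call(-1))))
  -3 / 4 * log(1 - 4 / 3 * p)
}

#' Jukes-Cantor distance matrix of an alignment
#' @param aln character matrix (tips x sites).
#' @return symmetric distance matrix.
#' @export
jc_dist_matrix <- function(aln) {
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- jc_distance(aln[i, ], aln[j, ])
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (exact recovery for additive
#' distances), with input validation.
#'
#' @param distances square symmetric nonnegative matrix with zero
#'   diagonal and row names.
#' @return unrooted `phylo`.
#' @export
nj_tree <- function(distances) {
  d <- as.matrix(distances)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be square and symmetric")
  if (any(d < 0) || any(abs(diag(d)) > 1e-12))
    stop("distances must be nonnegative with zero diagonal")
  ape::nj(d)
}

#' Gene-tree estimation error by simulation on the species tree
#'
#' Isolates estimation error from biological discordance: `n_sim`
#' alignments are simulated on the fixed species tree (gene tree equal
#' to species tree) under GTR, each tree is rebuilt by neighbor-joining
#' on Jukes-Cantor distances, and per-node support is the percentage of
#' rebuilt trees containing the node's bipartition. Saturated
#' replicates (undefined distances) are skipped and tallied.
#'
#' @param species_tree rooted `ape::phylo`/newick with
#'   substitutions/site branch lengths.
#' @param n_sim number of simulated alignments (default 200).
#' @param length alignment length in bp (default 1500).
#' @param rates,base_freqs,gamma_shape GTR parameters.
#' @param seed integer seed.
#' @return data frame as [bipartition_support()] plus attribute
#'   `n_skipped`.
#' @export
estimation_error_support <- function(species_tree, n_sim = 200,
                                     length = 1500, rates = rep(1, 6),
                                     base_freqs = rep(0.25, 4),
                                     gamma_shape = NULL, seed = 1) {
  sp <- as_phylo(species_tree)
  rebuilt <- list()
  n_skip <- 0L
  for (i in seq_len(n_sim)) {
    aln <- simulate_sequences_gtr(sp, length, rates, base_freqs,
                                  gamma_shape, seed = seed + i)
    d <- tryCatch(jc_dist_matrix(aln),
                  jc_saturation_error = function(e) NULL,
                  error = function(e) NULL)
    if (is.null(d)) { n_skip <- n_skip + 1L; next }
    rebuilt[[length(rebuilt) + 1L]] <- nj_tree(d)
  }
  if (!length(rebuilt)) stop("all replicates saturated")
  out <- bipartition_support(sp, rebuilt)
  attr(out, "n_skipped") <- n_skip
  out
}

#' Relative-importance (lmg) decomposition of a regression
#'
#' Decomposes the R-squared of a linear regression over its predictors
#' by averaging, over all orderings of the predictors, the increment in
#' R-squared each predictor contributes when added after those before
#' it. Shares sum exactly to the full-model R-squared; for mutually
#' orthogonal predictors each share equals the predictor's marginal
#' R-squared.
#'
#' @param response numeric vector.
#' @param predictors numeric matrix or data frame (>= 5 rows, full rank
#'   after centering).
#' @return list with `shares` (named, one per predictor), `r_squared`.
#' @export
lmg_decomposition <- function(response, predictors) {
  X <- as.matrix(predictors)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  if (n < 5) stop("need at least 5 observations")
  if (qr(scale(X, scale = FALSE))$rank < p)
    stop("rank-deficient design: predictors are collinear")
  r2 <- function(cols) {
    if (!length(cols)) return(0)
    fit <- stats::lm(response ~ X[, cols, drop = FALSE])
    summary(fit)$r.squared
  }
  # average over orderings via the subset-weight identity:
  # share_k = sum over subsets S not containing k of
  #   |S|! (p-|S|-1)! / p!  *  (R2(S+k) - R2(S))
  subsets <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  r2_cache <- vapply(subsets, r2, numeric(1))
  key <- vapply(subsets, function(s) paste(s, collapse = ","), character(1))
  shares <- stats::setNames(numeric(p), colnames(X))
  for (k in seq_len(p)) {
    for (si in seq_along(subsets)) {
      S <- subsets[[si]]
      if (k %in% S) next
      s_plus <- sort(c(S, k))
      wgt <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
      r2_plus <- r2_cache[match(paste(s_plus, collapse = ","), key)]
      shares[k] <- shares[k] + wgt * (r2_plus - r2_cache[si])
    }
  }
  list(shares = shares, r_squared = r2(seq_len(p)))
}

#' Full per-node discordance diagnostics
#'
#' Convenience wrapper assembling, for each internal node of the
#' species tree: observed gene-tree support, estimation-error support
#' from GTR simulation, and the reticulation index; theta must be
#' supplied per node (it needs externally estimated branch lengths).
#'
#' @param species_tree rooted `phylo`/newick (coalescent-unit branch
#'   lengths used for the ILS null simulation).
#' @param gene_trees observed rooted gene trees.
#' @param mut_tree optional tree with mutation-unit lengths (same
#'   topology) used for estimation-error simulation and theta.
#' @param n_null ILS-only null trees to simulate.
#' @param n_sim,length,rates,base_freqs GTR settings for estimation
#'   error.
#' @param alpha,max_comb reticulation-index settings.
#' @param seed integer seed.
#' @return data frame of per-node diagnostics.
#' @export
node_diagnostics <- function(species_tree, gene_trees, mut_tree = NULL,
                             n_null = 1000, n_sim = 100, length = 1500,
                             rates = rep(1, 6), base_freqs = rep(0.25, 4),
                             alpha = 0.05, max_comb = 100, seed = 1) {
  sp <- as_phylo(species_tree)
  supp <- bipartition_support(sp, gene_trees)
  nulls <- simulate_gene_trees_msc(sp, n_null, seed = seed + 1)
  ret <- reticulation_index(sp, gene_trees, nulls, alpha = alpha,
                            max_comb = max_comb, seed = seed + 2)
  out <- merge(supp, ret, by = "node", all.x = TRUE)
  if (!is.null(mut_tree)) {
    mt <- as_phylo(mut_tree)
    est <- estimation_error_support(mt, n_sim = n_sim, length = length,
                                    rates = rates, base_freqs = base_freqs,
                                    seed = seed + 3)
    names(est)[names(est) == "support"] <- "est_error_support"
    out <- merge(out, est[, c("node", "est_error_support")],
                 by = "node", all.x = TRUE)
    # per-node theta from matching branch lengths (mutation vs coalescent)
    mlen <- stats::setNames(mt$edge.length, mt$edge[, 2])
    clen <- stats::setNames(sp$edge.length, sp$edge[, 2])
    th <- vapply(as.character(out$node), function(nd) {
      m <- mlen[nd]; d <- clen[nd]
      if (is.na(m) || is.na(d) || d <= 0) NA_real_ else estimate_theta(m, d)
    }, numeric(1))
    out$theta <- unname(th)
  }
  out
}

#' Write node diagnostics as TSV
#' @param diag data frame from [node_diagnostics()].
#' @param path file path.
#' @export
write_diagnostics <- function(diag, path) {
  utils::write.table(diag, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
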