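#' GTR rate matrix
#'
#' Builds the general time-reversible rate matrix from six
#' exchangeabilities (order AC, AG, AT, CG, CT, GT) and stationary base
#' frequencies (A, C, G, T), normalized so that one unit of branch
#' length equals one expected substitution per site.
#'
#' @param rates six nonnegative exchangeabilities.
#' @param base_freqs four frequencies summing to 1.
#' @return 4x4 rate matrix with rownames/colnames ACGT.
#' @export
gtr_rate_matrix <- function(rates = rep(1, 6),
                            base_freqs = rep(0.25, 4)) {
  if (length(rates) != 6 || any(rates < 0))
    stop("need six nonnegative exchangeabilities")
  if (length(base_freqs) != 4 || any(base_freqs < 0) ||
      abs(sum(base_freqs) - 1) > 1e-8)
    stop("base_freqs must be a 4-simplex")
  nt <- c("A", "C", "G", "T")
  R <- matrix(0, 4, 4, dimnames = list(nt, nt))
  R[lower.tri(R)] <- rates[c(1, 2, 3, 4, 5, 6)]
  # fill symmetric exchangeabilities: order AC, AG, AT, CG, CT, GT
  R <- matrix(0, 4, 4, dimnames = list(nt, nt))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    R[pairs[k, 1], pairs[k, 2]] <- rates[k]
    R[pairs[k, 2], pairs[k, 1]] <- rates[k]
  }
  Q <- R %*% diag(base_freqs)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(base_freqs * diag(Q))
  Q <- Q / scale
  dimnames(Q) <- list(nt, nt)
  Q
}

# transition probability matrix exp(Q t) via the symmetrized
# eigendecomposition (Q is reversible)
gtr_pmatrix <- function(Q, base_freqs, t) {
  sp <- sqrt(base_freqs)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  P <- diag(1 / sp) %*% e$vectors %*% diag(exp(e$values * t)) %*%
    t(e$vectors) %*% diag(sp)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate a multiple alignment under the GTR model
#'
#' Evolves sequences site-independently down a tree whose branch lengths
#' are expected substitutions per site. The root sequence is drawn from
#' the stationary distribution; each branch applies `exp(Q t)`.
#' Optional discrete-gamma rate heterogeneity (4 categories) multiplies
#' per-site branch lengths.
#'
#' @param tree `ape::phylo` or newick string with substitutions/site
#'   branch lengths.
#' @param length alignment length in sites (>= 1).
#' @param rates,base_freqs GTR parameters, see [gtr_rate_matrix()].
#' @param gamma_shape optional shape for gamma rate heterogeneity.
#' @param seed integer seed.
#' @return character matrix (tips x sites) of "A"/"C"/"G"/"T", rownames
#'   = tip labels.
#' @export
simulate_sequences_gtr <- function(tree, length, rates = rep(1, 6),
                                   base_freqs = rep(0.25, 4),
                                   gamma_shape = NULL, seed = 1) {
  tree <- as_phylo(tree)
  if (length < 1) stop("alignment length must be >= 1")
  Q <- gtr_rate_matrix(rates, base_freqs)
  set.seed(seed)
  length <- as.integer(length)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  # site rate categories (discrete gamma, equal-probability quantile means)
  if (is.null(gamma_shape)) {
    site_rate_cat <- rep(1L, length); cat_rates <- 1
  } else {
    ncat <- 4L
    q <- stats::qgamma((seq_len(ncat) - 0.5) / ncat, shape = gamma_shape,
                       rate = gamma_shape)
    cat_rates <- q / mean(q)
    site_rate_cat <- sample.int(ncat, length, replace = TRUE)
  }
  states <- matrix(0L, nnode, length)
  root <- ntip + 1L
  states[root, ] <- sample.int(4L, length, replace = TRUE, prob = base_freqs)
  ord <- order(ape::node.depth.edgelength(tree)[tree$edge[, 2]])
  for (e in seq_len(nrow(tree$edge))[order(
    ape::node.depth.edgelength(tree)[tree$edge[, 2]])]) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    t_e <- tree$edge.length[e]
    for (rc in seq_along(cat_rates)) {
      cols <- which(site_rate_cat == rc)
      if (!length(cols)) next
      P <- gtr_pmatrix(Q, base_freqs, t_e * cat_rates[rc])
      ps <- states[par, cols]
      cs <- integer(length(cols))
      for (s in 1:4) {
        w <- which(ps == s)
        if (length(w))
          cs[w] <- sample.int(4L, length(w), replace = TRUE, prob = P[s, ])
      }
      states[child, cols] <- cs
    }
  }
  nt <- c("A", "C", "G", "T")
  out <- matrix(nt[states[seq_len(ntip), , drop = FALSE]], ntip, length)
  rownames(out) <- tree$tip.label
  out
}

#' Write an alignment as FASTA
#' @param aln character matrix (tips x sites).
#' @param path file path.
#' @export
write_alignment <- function(aln, path) {
  low <- aln
  low[] <- tolower(low)  # DNAbin encodes lower-case nucleotides
  bin <- ape::as.DNAbin(low)
  ape::write.FASTA(bin, path)
  invisible(path)
}
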