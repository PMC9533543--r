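#' Collinearity ratio between two chromosomes
#'
#' The fraction of two chromosomes' genes that sit in shared collinear
#' blocks: `x_ij = 2 * CN_ij / (N_i + N_j)`, where `CN_ij` is the number
#' of anchor pairs in all retained blocks between chromosomes i and j
#' and `N_i`, `N_j` are their gene counts. Identical chromosomes give
#' exactly 1.
#'
#' @param cn anchor-pair count between the chromosomes.
#' @param n_i,n_j gene counts of the two chromosomes (>= 1).
#' @return numeric in \[0, 1\].
#' @examples
#' collinearity_ratio(50, 80, 120)  # 0.5
#' @export
collinearity_ratio <- function(cn, n_i, n_j) {
  if (n_i < 1 || n_j < 1) stop("chromosome gene counts must be >= 1")
  if (cn < 0 || cn > min(n_i, n_j))
    stop("anchor count cannot exceed the smaller chromosome")
  2 * cn / (n_i + n_j)
}

#' Build the collinearity-ratio matrix over all chromosomes
#'
#' Chromosomes of all species are indexed as `"species:chrom"`. For every
#' pair, `CN_ij` sums anchors over all blocks between them (both
#' orientations); `x_ij = 2 CN_ij / (N_i + N_j)`. Blocks of a chromosome
#' against itself (intra-chromosomal duplications) are excluded from CN
#' counting, and the diagonal is `NA` by construction.
#'
#' @param genomes named list of `genome` objects or gene-order tables.
#' @param blocks optional precomputed [all_blocks()] result.
#' @param ... passed to [all_blocks()] when `blocks` is NULL.
#' @return a `collinearity_matrix`: list with `x` (symmetric matrix,
#'   `NA` diagonal), `cn` (anchor counts), `n` (per-chromosome gene
#'   counts), and after [z_normalize()] also `mu`, `sigma`, `z`.
#' @export
collinearity_matrix <- function(genomes, blocks = NULL, ...) {
  tabs <- lapply(genomes, function(g)
    if (inherits(g, "genome")) gene_order_table(g) else g)
  if (is.null(blocks)) blocks <- all_blocks(tabs, ...)
  keys <- unlist(lapply(tabs, function(t)
    paste(t$species[1], unique(t$chrom), sep = ":")), use.names = FALSE)
  n <- unlist(lapply(tabs, function(t) as.vector(table(t$chrom)[unique(t$chrom)])),
              use.names = FALSE)
  names(n) <- keys
  cn <- matrix(0, length(keys), length(keys), dimnames = list(keys, keys))
  for (b in blocks) {
    ki <- paste(b$species_a, b$chrom_a, sep = ":")
    kj <- paste(b$species_b, b$chrom_b, sep = ":")
    if (ki == kj) next  # self-diagonal blocks excluded from CN
    cn[ki, kj] <- cn[ki, kj] + b$n_anchors
    cn[kj, ki] <- cn[kj, ki] + b$n_anchors
  }
  x <- 2 * cn / outer(n, n, `+`)
  diag(x) <- NA_real_
  structure(list(x = x, cn = cn, n = n), class = "collinearity_matrix")
}

#' @export
print.collinearity_matrix <- function(x, ...) {
  cat("collinearity_matrix over", length(x$n), "chromosomes",
      if (!is.null(x$z)) "(Z-normalized)" else "", "\n")
  invisible(x)
}

#' Z-transform a collinearity matrix
#'
#' Row-wise standardization: `Zx_ij = (x_ij - mu_i) / sigma_i`, where
#' `mu_i` and `sigma_i` are the mean and sample (n-1) standard deviation
#' of row i's off-diagonal entries. A row with zero spread is an error
#' (that chromosome cannot be placed relative to the others).
#'
#' @param cm a `collinearity_matrix`.
#' @return the matrix with `mu`, `sigma`, `z` filled; `z` is row-wise
#'   and therefore not symmetric.
#' @export
z_normalize <- function(cm) {
  stopifnot(inherits(cm, "collinearity_matrix"))
  x <- cm$x
  mu <- rowMeans(x, na.rm = TRUE)
  sigma <- apply(x, 1, stats::sd, na.rm = TRUE)
  bad <- which(!is.finite(sigma) | sigma == 0)
  if (length(bad))
    stop("degenerate collinearity row(s) with zero spread: ",
         paste(rownames(x)[bad], collapse = ", "))
  cm$mu <- mu
  cm$sigma <- sigma
  cm$z <- (x - mu) / sigma
  cm
}

#' Cluster chromosomes into ancestral groups
#'
#' Symmetrizes the Z-matrix as `S = (Z + t(Z)) / 2`, converts similarity
#' to distance `d = max(S) - S`, and cuts an average-linkage hierarchical
#' clustering at `k` groups. With `k = "auto"` the number of groups is
#' chosen to maximize the mean silhouette width over `2..k_max`.
#'
#' @param cm a Z-normalized `collinearity_matrix` (or a plain matrix to
#'   use directly as Z).
#' @param k number of clusters, or `"auto"`.
#' @param k_max largest k tried when `k = "auto"`.
#' @return list with `labels` (named integer cluster per chromosome),
#'   `k`, `silhouette` (mean width per candidate k when auto), and the
#'   `hclust` object.
#' @export
cluster_chromosomes <- function(cm, k = "auto",
                                k_max = min(15L, nrow(z_of(cm)) - 1L)) {
  z <- z_of(cm)
  n <- nrow(z)
  if (is.numeric(k) && k > n) stop("fewer chromosomes than clusters")
  s <- (z + t(z)) / 2
  d <- max(s, na.rm = TRUE) - s
  diag(d) <- 0
  d[d < 0] <- 0
  dd <- stats::as.dist(d)
  hc <- stats::hclust(dd, method = "average")
  sil <- NULL
  if (identical(k, "auto")) {
    ks <- 2:k_max
    sil <- vapply(ks, function(kk) {
      lab <- stats::cutree(hc, kk)
      mean(cluster::silhouette(lab, dd)[, "sil_width"])
    }, numeric(1))
    names(sil) <- ks
    k <- ks[which.max(sil)]
  }
  labels <- stats::cutree(hc, k)
  list(labels = labels, k = as.integer(k), silhouette = sil, hclust = hc)
}

z_of <- function(cm) {
  if (inherits(cm, "collinearity_matrix")) {
    if (is.null(cm$z)) cm <- z_normalize(cm)
    cm$z
  } else as.matrix(cm)
}

#' Write a matrix as TSV
#' @param m matrix (or `collinearity_matrix`, whose `x` is written).
#' @param path file path.
#' @export
write_matrix <- function(m, path) {
  if (inherits(m, "collinearity_matrix")) m <- m$x
  utils::write.table(m, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Syntenic depth of two genomes over each other
#'
#' Tiles each genome into non-overlapping windows of `window` consecutive
#' genes and counts, per window, the number of distinct collinear blocks
#' from the other genome whose span covers the window midpoint. The depth
#' of A over B is the modal count over covered windows of B (e.g. 2:1
#' after one unshared whole-genome duplication in A). The two modal
#' depths are the syntenic depth ratio used to read off ploidy levels.
#'
#' @param blocks `collinear_blocks` between the two species.
#' @param table_a,table_b gene-order tables of species A and B.
#' @param window window size in genes (default 20).
#' @return named numeric: `depth_a_over_b`, `depth_b_over_a`.
#' @export
syntenic_depth <- function(blocks, table_a, table_b, window = 20) {
  if (!length(blocks)) stop("no blocks: syntenic depth undefined")
  sp_a <- unique(table_a$species); sp_b <- unique(table_b$species)
  depth_over <- function(target_tab, target_is_b) {
    counts <- integer(0)
    for (ch in unique(target_tab$chrom)) {
      L <- sum(target_tab$chrom == ch)
      mids <- seq(window / 2, L - window / 2, by = window)
      if (!length(mids)) next
      cnt <- integer(length(mids))
      for (b in blocks) {
        if (target_is_b) {
          if (!(identical(b$species_b, sp_b[1]) && b$chrom_b == ch)) next
          rng <- range(b$anchors$index_b)
        } else {
          if (!(identical(b$species_a, sp_a[1]) && b$chrom_a == ch)) next
          rng <- range(b$anchors$index_a)
        }
        cnt <- cnt + as.integer(mids >= rng[1] & mids <= rng[2])
      }
      counts <- c(counts, cnt)
    }
    counts <- counts[counts >= 1]
    if (!length(counts)) stop("no covered windows: syntenic depth undefined")
    as.integer(names(which.max(table(counts))))
  }
  c(depth_a_over_b = depth_over(table_b, TRUE),
    depth_b_over_a = depth_over(table_a, FALSE))
}
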