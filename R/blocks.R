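#' Detect collinear blocks between two gene orders
#'
#' Anchors are pairs of same-family genes, one from each chromosome;
#' every copy combination of a multi-copy family is a candidate anchor.
#' Blocks are chains of anchors strictly monotonic in both genomes
#' (jointly ascending, orientation `+1`, or with the second coordinate
#' descending, orientation `-1`), with at most `max_gap` intervening
#' genes between consecutive anchors on either chromosome, and at least
#' `min_anchors` anchors. Chains are extracted greedily: the longest
#' remaining chain is emitted and its anchors removed, until no chain of
#' `min_anchors` is left, so overlapping blocks from polyploid
#' multi-copy regions are all retained. Within one block each gene
#' participates in at most one anchor (monotonicity enforces this).
#'
#' Self-comparison of a chromosome against itself excludes the trivial
#' diagonal (and, to avoid mirrored duplicates, only the upper triangle
#' of anchor pairs is considered).
#'
#' @param table_a,table_b gene-order data frames (see
#'   [gene_order_table()]); may be the same species.
#' @param min_anchors minimum anchors per block (default 5).
#' @param max_gap maximum number of intervening genes between adjacent
#'   anchors in either genome (default 25).
#' @return an object of class `collinear_blocks`: a list of blocks, each
#'   `list(species_a, species_b, chrom_a, chrom_b, orientation,
#'   n_anchors, score, anchors)` with `anchors` a data frame of
#'   `index_a`, `index_b` (0-based), `gene_a`, `gene_b`, `family_id`.
#' @export
detect_blocks <- function(table_a, table_b, min_anchors = 5, max_gap = 25) {
  if (!nrow(table_a) || !nrow(table_b)) stop("empty gene-order table")
  sp_a <- unique(table_a$species); sp_b <- unique(table_b$species)
  stopifnot(length(sp_a) == 1L, length(sp_b) == 1L)
  same_species <- identical(sp_a, sp_b)
  blocks <- list()
  chroms_a <- unique(table_a$chrom)
  chroms_b <- unique(table_b$chrom)
  # index rows by family for fast per-pair anchor construction
  split_a <- split(table_a, table_a$chrom)
  split_b <- split(table_b, table_b$chrom)
  for (ca in chroms_a) {
    A <- split_a[[ca]]
    A <- A[order(A$order_index), ]
    for (cb in chroms_b) {
      if (same_species && match(cb, chroms_b) < match(ca, chroms_a)) next
      B <- split_b[[cb]]
      B <- B[order(B$order_index), ]
      shared <- intersect(A$family_id, B$family_id)
      if (length(shared) < min_anchors) next
      ia <- which(A$family_id %in% shared)
      # all copy combinations
      m <- merge(data.frame(family_id = A$family_id[ia],
                            index_a = A$order_index[ia], gene_a = A$gene_id[ia],
                            stringsAsFactors = FALSE),
                 data.frame(family_id = B$family_id, index_b = B$order_index,
                            gene_b = B$gene_id, stringsAsFactors = FALSE),
                 by = "family_id")
      if (same_species && ca == cb)
        m <- m[m$index_a < m$index_b, , drop = FALSE]
      if (nrow(m) < min_anchors) next
      chains <- extract_chains(m$index_a, m$index_b, min_anchors, max_gap)
      for (ch in chains) {
        anc <- m[ch$idx, c("index_a", "index_b", "gene_a", "gene_b",
                           "family_id")]
        anc <- anc[order(anc$index_a), ]
        rownames(anc) <- NULL
        blocks[[length(blocks) + 1L]] <- list(
          species_a = sp_a, species_b = sp_b, chrom_a = ca, chrom_b = cb,
          orientation = ch$orientation, n_anchors = nrow(anc),
          score = nrow(anc), anchors = anc)
      }
    }
  }
  structure(blocks, class = "collinear_blocks",
            species = c(sp_a, sp_b))
}

#' @export
print.collinear_blocks <- function(x, ...) {
  cat("collinear_blocks: ", length(x), " blocks between '",
      attr(x, "species")[1], "' and '", attr(x, "species")[2], "'\n",
      sep = "")
  invisible(x)
}

# Greedy repeated extraction of longest gap-bounded monotone chains.
# Returns list of list(idx = anchor row indices, orientation = +-1).
extract_chains <- function(ia, ib, min_anchors, max_gap) {
  active <- rep(TRUE, length(ia))
  out <- list()
  repeat {
    idx <- which(active)
    if (length(idx) < min_anchors) break
    fwd <- best_chain(ia[idx], ib[idx], max_gap)
    rev_ <- best_chain(ia[idx], -ib[idx], max_gap)
    if (length(fwd) >= length(rev_)) {
      chain <- idx[fwd]; orient <- 1L
    } else {
      chain <- idx[rev_]; orient <- -1L
    }
    if (length(chain) < min_anchors) break
    out[[length(out) + 1L]] <- list(idx = chain, orientation = orient)
    active[chain] <- FALSE
  }
  out
}

# Longest chain with both coordinates strictly increasing and index
# difference <= max_gap + 1 between consecutive anchors. O(n^2) dynamic
# program with the inner maximization vectorized; n per chromosome pair
# is at most the shared-family count, which keeps this fast.
best_chain <- function(ia, ib, max_gap) {
  n <- length(ia)
  ord <- order(ia, ib)
  a <- ia[ord]; b <- ib[ord]
  dp <- rep(1L, n); parent <- rep(0L, n)
  g <- max_gap + 1L
  lo <- 1L
  for (k in seq_len(n)) {
    while (a[lo] < a[k] - g) lo <- lo + 1L
    if (lo < k) {
      j <- lo:(k - 1L)
      ok <- a[j] < a[k] & b[j] < b[k] & (b[k] - b[j]) <= g
      if (any(ok)) {
        jj <- j[ok]
        best <- jj[which.max(dp[jj])]
        dp[k] <- dp[best] + 1L
        parent[k] <- best
      }
    }
  }
  end <- which.max(dp)
  chain <- integer(dp[end])
  i <- dp[end]
  while (end != 0L) { chain[i] <- end; i <- i - 1L; end <- parent[end] }
  ord[chain]
}

#' Compute collinear blocks among all chromosome pairs of a set of genomes
#'
#' Runs [detect_blocks()] over every ordered species pair (including each
#' species against itself, where duplicated regions from polyploidy
#' produce intra-genomic blocks).
#'
#' @param genomes named list of `genome` objects (or gene-order tables).
#' @inheritParams detect_blocks
#' @return a single `collinear_blocks` list covering all pairs.
#' @export
all_blocks <- function(genomes, min_anchors = 5, max_gap = 25) {
  tabs <- lapply(genomes, function(g)
    if (inherits(g, "genome")) gene_order_table(g) else g)
  out <- list()
  nm <- names(tabs)
  for (i in seq_along(tabs)) for (j in i:length(tabs)) {
    bl <- detect_blocks(tabs[[i]], tabs[[j]], min_anchors, max_gap)
    out <- c(out, unclass(bl))
  }
  structure(out, class = "collinear_blocks", species = nm)
}

#' Write / read collinearity blocks (MCScanX/WGDI-style TSV)
#'
#' Each block is written as a header line
#' `## block <id>: <spA>:<chromA> <spB>:<chromB> orient=<+1/-1> score=<s>`
#' followed by one anchor line per gene pair
#' (`gene_a  gene_b  index_a  index_b  family_id`).
#'
#' @param blocks a `collinear_blocks` object.
#' @param path file path.
#' @return `read_blocks` returns a `collinear_blocks` object.
#' @export
write_blocks <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    cat(sprintf("## block %d: %s:%s %s:%s orient=%d score=%g\n", i,
                b$species_a, b$chrom_a, b$species_b, b$chrom_b,
                b$orientation, b$score), file = con)
    utils::write.table(b$anchors[, c("gene_a", "gene_b", "index_a",
                                     "index_b", "family_id")],
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_blocks
#' @export
read_blocks <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^## block ", lines)
  ends <- c(hdr[-1] - 1L, length(lines))
  blocks <- vector("list", length(hdr))
  for (k in seq_along(hdr)) {
    h <- lines[hdr[k]]
    m <- regmatches(h, regexec(
      "^## block \\d+: ([^:]+):(\\S+) ([^:]+):(\\S+) orient=(-?1) score=(\\S+)$",
      h))[[1]]
    body <- lines[seq(hdr[k] + 1L, ends[k])]
    anc <- utils::read.table(text = body, sep = "\t",
                             col.names = c("gene_a", "gene_b", "index_a",
                                           "index_b", "family_id"),
                             stringsAsFactors = FALSE)
    anc <- anc[, c("index_a", "index_b", "gene_a", "gene_b", "family_id")]
    blocks[[k]] <- list(species_a = m[2], chrom_a = m[3], species_b = m[4],
                        chrom_b = m[5], orientation = as.integer(m[6]),
                        n_anchors = nrow(anc), score = as.numeric(m[7]),
                        anchors = anc)
  }
  sp <- unique(unlist(lapply(blocks, function(b) c(b$species_a, b$species_b))))
  structure(blocks, class = "collinear_blocks", species = sp)
}
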