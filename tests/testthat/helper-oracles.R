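# Independent oracles and small fixtures used across test files.

# exhaustive longest-chain enumeration (independent of the package's
# dynamic program): recursive search over anchors, both orientations
brute_longest_chain <- function(ia, ib, max_gap) {
  g <- max_gap + 1
  n <- length(ia)
  best <- 0
  extend <- function(last, used_len, sign_) {
    cand <- which(ia > ia[last] & ia - ia[last] <= g &
                    sign_ * ib > sign_ * ib[last] &
                    sign_ * (ib - ib[last]) <= g)
    if (!length(cand)) {
      best <<- max(best, used_len)
      return(invisible())
    }
    for (k in cand) extend(k, used_len + 1, sign_)
    best <<- max(best, used_len)
  }
  for (sgn in c(1, -1)) for (s in seq_len(n)) extend(s, 1, sgn)
  best
}

# independent validator of an emitted block
validate_block_oracle <- function(b, min_anchors, max_gap) {
  a <- b$anchors
  if (nrow(a) < min_anchors) return(FALSE)
  if (is.unsorted(a$index_a, strictly = TRUE)) return(FALSE)
  ib <- if (b$orientation > 0) a$index_b else -a$index_b
  if (is.unsorted(ib, strictly = TRUE)) return(FALSE)
  if (any(diff(a$index_a) > max_gap + 1)) return(FALSE)
  if (any(abs(diff(a$index_b)) > max_gap + 1)) return(FALSE)
  TRUE
}

# lmg by direct enumeration of all orderings (independent of the
# subset-weight implementation)
lmg_enumeration_oracle <- function(y, X) {
  X <- as.matrix(X)
  p <- ncol(X)
  r2 <- function(cols) {
    if (!length(cols)) return(0)
    summary(stats::lm(y ~ X[, cols, drop = FALSE]))$r.squared
  }
  perms <- gtools_permutations(p)
  shares <- numeric(p)
  for (r in seq_len(nrow(perms))) {
    pi_ <- perms[r, ]
    for (pos in seq_len(p)) {
      before <- pi_[seq_len(pos - 1)]
      k <- pi_[pos]
      shares[k] <- shares[k] + r2(c(before, k)) - r2(before)
    }
  }
  shares / nrow(perms)
}

gtools_permutations <- function(p) {
  if (p == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(p - 1)
  out <- NULL
  for (k in seq_len(p)) {
    rest <- setdiff(seq_len(p), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# the true ancestral karyotype of a simulated ancestor, as an `aek`
# object usable for projection (ground-truth painting reference)
true_aek <- function(ancestor) {
  got <- gene_order_table(ancestor)
  structure(data.frame(aek_chrom = got$anc_chrom, aek_index = got$anc_index,
                       family_id = got$family_id, stringsAsFactors = FALSE),
            class = c("aek", "data.frame"))
}

# map a reconstructed AEK's chromosome numbering onto the true ancestral
# numbering by majority vote of member families
aek_chrom_map <- function(aek, ancestor) {
  anc <- gene_order_table(ancestor)
  truth <- stats::setNames(anc$anc_chrom, anc$family_id)
  tab <- table(aek$aek_chrom, truth[aek$family_id])
  apply(tab, 1, function(r) as.integer(colnames(tab)[which.max(r)]))
}
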