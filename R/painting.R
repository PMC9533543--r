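#' Project an ancestral karyotype onto a genome
#'
#' Every gene anchored in a collinear block between the ancestral
#' karyotype (treated as a pseudo-genome) and the target receives the
#' ancestral chromosome and index of its anchor; when a gene is anchored
#' in several blocks the highest-scoring block wins (score tie: lower
#' ancestral index). Unanchored genes flanked on both sides, within
#' `gap_tol` genes, by anchors of the same ancestral chromosome inherit
#' that chromosome with a linearly interpolated (fractional) index;
#' everything else is unassigned.
#'
#' @param aek an `aek` object.
#' @param genome target `genome` or gene-order table.
#' @param blocks optional `collinear_blocks` between [aek_as_genome()]
#'   and the target (computed when NULL).
#' @param gap_tol flank search distance for in-fill assignment.
#' @param min_anchors,max_gap block thresholds when `blocks` is NULL.
#' @return a `painting`: gene-order data frame with added columns
#'   `aek_chrom` (NA = unassigned), `aek_index`, `copy` (filled by
#'   [label_copies()]).
#' @export
project <- function(aek, genome, blocks = NULL, gap_tol = 10,
                    min_anchors = 5, max_gap = 25) {
  tab <- if (inherits(genome, "genome")) gene_order_table(genome) else genome
  # a target that shares the karyotype's species id (e.g. self-projection)
  # must not trigger the intra-species diagonal exclusion
  if (identical(tab$species[1], "AEK")) tab$species <- "AEK_target"
  aekg <- aek_as_genome(aek)
  if (is.null(blocks))
    blocks <- detect_blocks(gene_order_table(aekg), tab, min_anchors, max_gap)
  tab <- tab[order(tab$chrom, tab$order_index), ]
  tab$aek_chrom <- NA_integer_
  tab$aek_index <- NA_real_
  tab$copy <- NA_character_
  if (!length(blocks)) {
    warning("no blocks between karyotype and target: painting is empty")
    return(structure(tab, class = c("painting", "data.frame")))
  }
  best_score <- rep(-Inf, nrow(tab))
  key <- paste(tab$chrom, tab$order_index)
  for (b in blocks) {
    aekc <- as.integer(sub("^aek", "", b$chrom_a))
    rows <- match(paste(b$chrom_b, b$anchors$index_b), key)
    ok <- which(b$score > best_score[rows] |
                  (b$score == best_score[rows] &
                     aekc < tab$aek_chrom[rows] & !is.na(tab$aek_chrom[rows])))
    if (!length(ok)) next
    r <- rows[ok]
    tab$aek_chrom[r] <- aekc
    tab$aek_index[r] <- b$anchors$index_a[ok]
    best_score[r] <- b$score
  }
  # in-fill: interpolate unanchored genes between same-chromosome anchors
  for (ch in unique(tab$chrom)) {
    rows <- which(tab$chrom == ch)
    assigned <- rows[!is.na(tab$aek_chrom[rows])]
    if (length(assigned) < 2L) next
    un <- rows[is.na(tab$aek_chrom[rows])]
    for (u in un) {
      left <- assigned[assigned < u]
      right <- assigned[assigned > u]
      if (!length(left) || !length(right)) next
      l <- max(left); r <- min(right)
      if (u - l > gap_tol || r - u > gap_tol) next
      if (tab$aek_chrom[l] != tab$aek_chrom[r]) next
      tab$aek_chrom[u] <- tab$aek_chrom[l]
      tab$aek_index[u] <- tab$aek_index[l] +
        (tab$aek_index[r] - tab$aek_index[l]) * (u - l) / (r - l)
    }
  }
  structure(tab, class = c("painting", "data.frame"))
}

#' Segment a painting into ancestral-origin runs
#'
#' Per target chromosome, maximal runs of consecutive assigned genes
#' sharing one ancestral chromosome (unassigned genes are transparent:
#' they neither break nor join runs). Runs shorter than `min_seg` genes
#' are dropped to unassigned; adjacent same-origin runs then merge, so a
#' short alien insert inside a long segment is absorbed.
#'
#' @param painting a `painting` (copy column may be empty).
#' @param min_seg minimum run length in genes (default 10).
#' @return data frame of segments: `chrom`, `target_start`, `target_end`
#'   (0-based half-open gene interval), `aek_chrom`, `aek_start`,
#'   `aek_end` (closed interval of anchored ancestral indices),
#'   `orientation`, `n_genes`, `copy` (NA until [label_copies()]).
#' @export
segment_painting <- function(painting, min_seg = 10) {
  p <- painting
  repeat {
    segs <- raw_runs(p)
    short <- segs$n_genes < min_seg
    if (!any(short)) break
    # drop genes of short runs to unassigned, then recompute
    for (i in which(short)) {
      rows <- which(p$chrom == segs$chrom[i] &
                      p$order_index >= segs$target_start[i] &
                      p$order_index < segs$target_end[i] &
                      !is.na(p$aek_chrom) & p$aek_chrom == segs$aek_chrom[i])
      p$aek_chrom[rows] <- NA_integer_
      p$aek_index[rows] <- NA_real_
    }
  }
  segs <- raw_runs(p)
  rownames(segs) <- NULL
  segs$copy <- NA_character_
  segs
}

raw_runs <- function(p) {
  out <- list()
  for (ch in unique(p$chrom)) {
    d <- p[p$chrom == ch, ]
    d <- d[order(d$order_index), ]
    a <- d[!is.na(d$aek_chrom), ]
    if (!nrow(a)) next
    run <- cumsum(c(TRUE, diff(a$aek_chrom) != 0))
    for (r in split(a, run)) {
      ori <- if (nrow(r) >= 2) {
        s <- stats::coef(stats::lm(r$aek_index ~ r$order_index))[2]
        if (is.na(s) || s >= 0) 1L else -1L
      } else 1L
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, target_start = min(r$order_index),
        target_end = max(r$order_index) + 1L,
        aek_chrom = r$aek_chrom[1],
        aek_start = min(r$aek_index), aek_end = max(r$aek_index),
        orientation = ori, n_genes = nrow(r), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), target_start = integer(0),
                      target_end = integer(0), aek_chrom = integer(0),
                      aek_start = numeric(0), aek_end = numeric(0),
                      orientation = integer(0), n_genes = integer(0)))
  do.call(rbind, out)
}

#' Group painted segments into ancestral-chromosome copies and label them
#'
#' After a polyploidization a genome carries several copies of each
#' ancestral chromosome. Segments of one ancestral chromosome are
#' grouped greedily into copies: repeatedly start a new copy from the
#' largest unused segment and add unused segments whose ancestral
#' interval overlaps the copy's covered intervals by less than
#' `overlap_tau` of their own span. Copies are ranked by completeness
#' (fraction of the ancestral chromosome's families covered by the
#' copy's genes) and labelled A, B, C, ... (best first); ties are broken
#' by target chromosome id.
#'
#' @param painting a `painting`.
#' @param aek_sizes named integer: families per ancestral chromosome
#'   (names = ancestral chromosome ids), e.g.
#'   `table(aek$aek_chrom)`.
#' @param min_seg passed to [segment_painting()].
#' @param overlap_tau interval-overlap threshold for joining a segment
#'   to an existing copy (default 0.2).
#' @return list with `copies` (data frame: `aek_chrom`, `copy`,
#'   `completeness`, `n_segments`, `n_genes`), `segments` (segment table
#'   with `copy` filled), and `painting` (gene-level `copy` filled).
#' @export
label_copies <- function(painting, aek_sizes, min_seg = 10,
                         overlap_tau = 0.2) {
  segs <- segment_painting(painting, min_seg)
  copies_out <- list()
  for (ac in sort(unique(segs$aek_chrom))) {
    idx <- which(segs$aek_chrom == ac)
    idx <- idx[order(-segs$n_genes[idx], segs$chrom[idx],
                     segs$target_start[idx])]
    used <- logical(length(idx))
    copy_no <- 0L
    while (any(!used)) {
      copy_no <- copy_no + 1L
      seed_i <- idx[which(!used)[1]]
      used[which(!used)[1]] <- TRUE
      cover <- matrix(c(segs$aek_start[seed_i], segs$aek_end[seed_i]),
                      ncol = 2)
      members <- seed_i
      for (t in seq_along(idx)) {
        if (used[t]) next
        i <- idx[t]
        ov <- interval_overlap(segs$aek_start[i], segs$aek_end[i], cover)
        span <- max(segs$aek_end[i] - segs$aek_start[i], 1)
        if (ov / span < overlap_tau) {
          members <- c(members, i)
          used[t] <- TRUE
          cover <- rbind(cover, c(segs$aek_start[i], segs$aek_end[i]))
        }
      }
      segs$copy[members] <- as.character(copy_no)
      copies_out[[length(copies_out) + 1L]] <- data.frame(
        aek_chrom = ac, group = as.character(copy_no),
        n_segments = length(members), n_genes = sum(segs$n_genes[members]),
        chrom_min = min(segs$chrom[members]), stringsAsFactors = FALSE)
    }
  }
  cp <- do.call(rbind, copies_out)
  # completeness: distinct families covered by the copy's genes
  p <- painting
  p$copy <- NA_character_
  for (i in seq_len(nrow(segs))) {
    rows <- which(p$chrom == segs$chrom[i] &
                    p$order_index >= segs$target_start[i] &
                    p$order_index < segs$target_end[i] &
                    !is.na(p$aek_chrom) & p$aek_chrom == segs$aek_chrom[i])
    p$copy[rows] <- segs$copy[i]
  }
  cp$completeness <- vapply(seq_len(nrow(cp)), function(i) {
    fams <- unique(p$family_id[!is.na(p$aek_chrom) &
                                 p$aek_chrom == cp$aek_chrom[i] &
                                 p$copy == cp$group[i]])
    min(1, length(fams) / as.integer(aek_sizes[as.character(cp$aek_chrom[i])]))
  }, numeric(1))
  # rank copies per ancestral chromosome and assign letters
  cp$copy <- NA_character_
  for (ac in unique(cp$aek_chrom)) {
    rows <- which(cp$aek_chrom == ac)
    ord <- rows[order(-cp$completeness[rows], cp$chrom_min[rows])]
    cp$copy[ord] <- LETTERS[seq_along(ord)]
  }
  # propagate labels to segments and genes
  relab <- stats::setNames(cp$copy, paste(cp$aek_chrom, cp$group))
  segs$copy <- relab[paste(segs$aek_chrom, segs$copy)]
  pk <- paste(p$aek_chrom, p$copy)
  p$copy <- ifelse(is.na(p$aek_chrom), NA_character_, relab[pk])
  cp <- cp[order(cp$aek_chrom, cp$copy),
           c("aek_chrom", "copy", "completeness", "n_segments", "n_genes")]
  rownames(cp) <- NULL
  list(copies = cp, segments = segs,
       painting = structure(p, class = c("painting", "data.frame")))
}

interval_overlap <- function(s, e, cover) {
  sum(pmax(0, pmin(e, cover[, 2]) - pmax(s, cover[, 1])))
}

#' Project, segment and label in one call
#'
#' @inheritParams project
#' @param min_seg,overlap_tau passed to [label_copies()].
#' @return the [label_copies()] list, with the blocks used attached as
#'   attribute `blocks`.
#' @export
paint_genome <- function(aek, genome, blocks = NULL, gap_tol = 10,
                         min_anchors = 5, max_gap = 25, min_seg = 10,
                         overlap_tau = 0.2) {
  p <- project(aek, genome, blocks = blocks, gap_tol = gap_tol,
               min_anchors = min_anchors, max_gap = max_gap)
  sizes <- table(aek$aek_chrom)
  out <- label_copies(p, sizes, min_seg = min_seg, overlap_tau = overlap_tau)
  attr(out, "blocks") <- blocks
  out
}

#' Write a painting as TSV
#' @param painting a `painting` (or the list from [paint_genome()]).
#' @param path file path.
#' @export
write_painting <- function(painting, path) {
  if (is.list(painting) && !is.data.frame(painting) &&
      !is.null(painting$painting))
    painting <- painting$painting
  utils::write.table(painting, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
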