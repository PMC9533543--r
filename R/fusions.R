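#' Classify chromosome fusions from a segmented painting
#'
#' Reads fusion events off the ancestral-origin segment pattern of each
#' derived chromosome:
#' * **NCF** (nested fusion): pattern X-Y-X, the two X pieces jointly
#'   covering at least `coverage_tau` of ancestral chromosome X and Y
#'   covering at least `coverage_tau` of Y.
#' * **EEJ** (end-end joining): pattern X-Y with each side covering at
#'   least `coverage_tau` of its ancestral chromosome and the joined
#'   extremities mapping within `end_eps` genes of the respective
#'   ancestral termini.
#' * **RTA** (reciprocally translocated arms): two derived chromosomes
#'   carrying complementary pieces of X and of Y (per-chromosome piece
#'   overlap at most `end_eps` genes, joint coverage at least
#'   `coverage_tau`).
#' * **FISSION**: one ancestral chromosome copy split across several
#'   single-segment derived chromosomes with no partner segments.
#' Multi-segment chromosomes matching none of these yield an
#' `UNCLASSIFIED` call. Intact single-segment chromosomes yield no call.
#'
#' Participants are (ancestral chromosome, copy) pairs; every call
#' carries its junction(s): the inter-gene position on the derived
#' chromosome between the last assigned gene of one segment and the
#' first of the next, with the flanking genes' ancestral coordinates.
#'
#' @param segments segment table from [segment_painting()] or
#'   [label_copies()] (a `copy` column of NAs is treated as one copy).
#' @param aek_sizes named integer, families per ancestral chromosome.
#' @param coverage_tau minimum coverage fraction (default 0.8).
#' @param end_eps tolerance in genes for terminus/complementarity checks
#'   (default 10).
#' @return a `fusion_calls` list; each call is
#'   `list(kind, participants, chroms, junctions, coverage)` with
#'   `junctions` a data frame (`chrom`, `pos`, `left_aek_chrom`,
#'   `left_aek_index`, `right_aek_chrom`, `right_aek_index`).
#' @export
classify_fusion <- function(segments, aek_sizes, coverage_tau = 0.8,
                            end_eps = 10) {
  segs <- segments
  if (is.null(segs$copy)) segs$copy <- NA_character_
  segs$copy[is.na(segs$copy)] <- "A"
  segs$unit <- paste0(segs$aek_chrom, segs$copy)
  calls <- list()
  sizes <- function(ac) as.integer(aek_sizes[as.character(ac)])
  cov_of <- function(rows) {
    ac <- segs$aek_chrom[rows[1]]
    iv <- cbind(segs$aek_start[rows], segs$aek_end[rows])
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    tot <- 0; hi <- -Inf
    for (i in seq_len(nrow(iv))) {
      s <- max(iv[i, 1], hi); e <- iv[i, 2]
      if (e > s) tot <- tot + (e - s)
      hi <- max(hi, e)
    }
    tot / sizes(ac)
  }
  junction_between <- function(i, j) {
    data.frame(chrom = segs$chrom[i], pos = segs$target_end[i],
               left_aek_chrom = segs$aek_chrom[i],
               left_aek_index = if (segs$orientation[i] > 0)
                 segs$aek_end[i] else segs$aek_start[i],
               right_aek_chrom = segs$aek_chrom[j],
               right_aek_index = if (segs$orientation[j] > 0)
                 segs$aek_start[j] else segs$aek_end[j],
               stringsAsFactors = FALSE)
  }
  near_terminus <- function(idx, side) {
    # aek coordinate of the segment end facing `side` ("left"/"right" on target)
    ac <- segs$aek_chrom[idx]
    coord <- if ((side == "right") == (segs$orientation[idx] > 0))
      segs$aek_end[idx] else segs$aek_start[idx]
    coord <= end_eps || coord >= sizes(ac) - 1 - end_eps
  }
  by_chrom <- split(seq_len(nrow(segs)), segs$chrom)
  two_seg_chroms <- list()  # RTA candidates
  for (ch in names(by_chrom)) {
    rows <- by_chrom[[ch]]
    rows <- rows[order(segs$target_start[rows])]
    units <- segs$unit[rows]
    if (length(rows) == 1L) next
    if (length(rows) == 3L && units[1] == units[3] && units[1] != units[2]) {
      xr <- rows[c(1, 3)]; yr <- rows[2]
      cx <- cov_of(xr); cy <- cov_of(yr)
      if (cx >= coverage_tau && cy >= coverage_tau) {
        calls[[length(calls) + 1L]] <- list(
          kind = "NCF",
          participants = data.frame(
            aek_chrom = segs$aek_chrom[c(xr[1], yr)],
            copy = segs$copy[c(xr[1], yr)],
            coverage = c(cx, cy), stringsAsFactors = FALSE),
          chroms = ch,
          junctions = rbind(junction_between(rows[1], rows[2]),
                            junction_between(rows[2], rows[3])))
        next
      }
    }
    if (length(rows) == 2L && units[1] != units[2]) {
      cx <- cov_of(rows[1]); cy <- cov_of(rows[2])
      if (cx >= coverage_tau && cy >= coverage_tau &&
          near_terminus(rows[1], "right") && near_terminus(rows[2], "left") &&
          near_terminus(rows[1], "left") && near_terminus(rows[2], "right")) {
        calls[[length(calls) + 1L]] <- list(
          kind = "EEJ",
          participants = data.frame(
            aek_chrom = segs$aek_chrom[rows], copy = segs$copy[rows],
            coverage = c(cx, cy), stringsAsFactors = FALSE),
          chroms = ch,
          junctions = junction_between(rows[1], rows[2]))
        next
      }
      two_seg_chroms[[ch]] <- rows
    } else if (length(rows) >= 2L) {
      calls[[length(calls) + 1L]] <- list(
        kind = "UNCLASSIFIED",
        participants = data.frame(aek_chrom = segs$aek_chrom[rows],
                                  copy = segs$copy[rows],
                                  coverage = NA_real_,
                                  stringsAsFactors = FALSE),
        chroms = ch,
        junctions = do.call(rbind, lapply(seq_len(length(rows) - 1L),
          function(t) junction_between(rows[t], rows[t + 1L]))))
    }
  }
  # RTA pairing over two-segment chromosomes (exhaustive; genomes small)
  cand <- names(two_seg_chroms)
  used <- character(0)
  if (length(cand) >= 2L) for (i in seq_along(cand)) for (j in seq_along(cand)) {
    if (i == j) next
    c1 <- cand[i]; c2 <- cand[j]
    if (c1 %in% used || c2 %in% used) next
    r1 <- two_seg_chroms[[c1]]; r2 <- two_seg_chroms[[c2]]
    u1 <- segs$unit[r1]; u2 <- segs$unit[r2]
    # chromosome 1 = [X., Y.], chromosome 2 must hold the complements
    if (!setequal(u1, u2)) next
    m1 <- r1[match(u1, segs$unit[r1])]
    x1 <- r1[1]; y1 <- r1[2]
    x2 <- r2[match(u1[1], segs$unit[r2])]
    y2 <- r2[match(u1[2], segs$unit[r2])]
    comp <- function(a, b) {
      ov <- min(segs$aek_end[a], segs$aek_end[b]) -
        max(segs$aek_start[a], segs$aek_start[b])
      ov <= end_eps && cov_of(c(a, b)) >= coverage_tau
    }
    if (comp(x1, x2) && comp(y1, y2)) {
      calls[[length(calls) + 1L]] <- list(
        kind = "RTA",
        participants = data.frame(
          aek_chrom = segs$aek_chrom[c(x1, y1)],
          copy = segs$copy[c(x1, y1)],
          coverage = c(cov_of(c(x1, x2)), cov_of(c(y1, y2))),
          stringsAsFactors = FALSE),
        chroms = c(c1, c2),
        junctions = rbind(junction_between(r1[1], r1[2]),
                          junction_between(r2[1], r2[2])))
      used <- c(used, c1, c2)
    }
  }
  for (ch in setdiff(cand, used)) {
    rows <- two_seg_chroms[[ch]]
    calls[[length(calls) + 1L]] <- list(
      kind = "UNCLASSIFIED",
      participants = data.frame(aek_chrom = segs$aek_chrom[rows],
                                copy = segs$copy[rows],
                                coverage = NA_real_, stringsAsFactors = FALSE),
      chroms = ch,
      junctions = junction_between(rows[1], rows[2]))
  }
  # fissions: a copy split across single-segment chromosomes
  singles <- vapply(by_chrom, length, integer(1)) == 1L
  single_rows <- unlist(by_chrom[singles], use.names = FALSE)
  if (length(single_rows) >= 2L) {
    for (u in unique(segs$unit[single_rows])) {
      rows <- single_rows[segs$unit[single_rows] == u]
      if (length(rows) >= 2L && cov_of(rows) >= coverage_tau) {
        calls[[length(calls) + 1L]] <- list(
          kind = "FISSION",
          participants = data.frame(aek_chrom = segs$aek_chrom[rows[1]],
                                    copy = segs$copy[rows[1]],
                                    coverage = cov_of(rows),
                                    stringsAsFactors = FALSE),
          chroms = segs$chrom[rows], junctions = NULL)
      }
    }
  }
  structure(calls, class = "fusion_calls")
}

#' @export
print.fusion_calls <- function(x, ...) {
  cat("fusion_calls:", length(x), "call(s)\n")
  for (c_ in x)
    cat("  ", c_$kind, " on ", paste(c_$chroms, collapse = "+"),
        " [", paste0(c_$participants$aek_chrom, c_$participants$copy,
                     collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Test whether two species share a fusion or acquired it independently
#'
#' A fusion inherited from a common ancestor leaves the junction inside
#' continuous collinear gene blocks between the two species: some block
#' must span the junction of species 1 (anchors strictly on both sides)
#' and span the corresponding junction of species 2, and the two
#' junctions must sit within `window` anchored genes of each other
#' inside that block. Fusions of the same ancestral chromosome pair that
#' fail this are called independent (parallel) events. The test is
#' symmetrized over its two arguments.
#'
#' @param fusion_a,fusion_b single calls from [classify_fusion()] for
#'   species 1 and 2; must involve the same unordered ancestral
#'   chromosome pair.
#' @param blocks `collinear_blocks` between the two species (species 1
#'   as side a or b).
#' @param window junction co-location tolerance in anchored genes.
#' @return `"shared"` or `"independent"`.
#' @export
shared_fusion_test <- function(fusion_a, fusion_b, blocks, window = 10) {
  pa <- sort(unique(as.integer(fusion_a$participants$aek_chrom)))
  pb <- sort(unique(as.integer(fusion_b$participants$aek_chrom)))
  if (!identical(pa, pb))
    stop("fusions involve different ancestral chromosome pairs; ",
         "shared-fusion test undefined")
  # a fusion compared with itself is shared by definition (the trivial
  # self-diagonal is excluded from block detection, so test it directly)
  if (identical(fusion_a$junctions, fusion_b$junctions) &&
      identical(fusion_a$chroms, fusion_b$chroms))
    return("shared")
  ok_ab <- junctions_colocated(fusion_a, fusion_b, blocks, window)
  ok_ba <- junctions_colocated(fusion_b, fusion_a, blocks, window)
  if (ok_ab && ok_ba) "shared" else "independent"
}

# every junction of fa must lie inside a block that also spans a
# junction of fb, within `window` anchored genes
junctions_colocated <- function(fa, fb, blocks, window) {
  ja <- fa$junctions; jb <- fb$junctions
  if (is.null(ja) || is.null(jb)) return(FALSE)
  for (i in seq_len(nrow(ja))) {
    found <- FALSE
    for (b in blocks) {
      # orient the block so side "1" is fa's genome
      sides <- list(c(ch = b$chrom_a, idx = "index_a", other = "index_b",
                      och = b$chrom_b),
                    c(ch = b$chrom_b, idx = "index_b", other = "index_a",
                      och = b$chrom_a))
      for (s in sides) {
        if (s[["ch"]] != ja$chrom[i]) next
        i1 <- b$anchors[[s[["idx"]]]]
        i2 <- b$anchors[[s[["other"]]]]
        pos <- ja$pos[i]
        if (!(any(i1 < pos) && any(i1 >= pos))) next
        # matching junction of fb on the block's other chromosome
        jj <- which(jb$chrom == s[["och"]])
        for (j in jj) {
          pos2 <- jb$pos[j]
          if (!(any(i2 < pos2) && any(i2 >= pos2))) next
          # rank distance between mapped junction positions
          left_anchor <- max(i1[i1 < pos])
          mapped <- i2[which(i1 == left_anchor)[1]]
          rank_dist <- sum(i2 > min(mapped, pos2) & i2 <= max(mapped, pos2))
          if (rank_dist <= window) { found <- TRUE; break }
        }
        if (found) break
      }
      if (found) break
    }
    if (!found) return(FALSE)
  }
  TRUE
}

#' Write fusion calls as TSV
#' @param calls a `fusion_calls` object.
#' @param path file path.
#' @export
write_fusion_calls <- function(calls, path) {
  rows <- lapply(calls, function(c_) data.frame(
    kind = c_$kind,
    chroms = paste(c_$chroms, collapse = "+"),
    participants = paste0(c_$participants$aek_chrom, c_$participants$copy,
                          collapse = ","),
    coverage = paste(round(c_$participants$coverage, 3), collapse = ","),
    junctions = if (is.null(c_$junctions)) "" else
      paste(c_$junctions$chrom, c_$junctions$pos, sep = ":", collapse = ","),
    stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
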