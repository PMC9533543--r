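#' Select the reference chromosome of a cluster
#'
#' The most complete chromosome of an ancestral cluster: the member with
#' the highest mean collinearity ratio to the other members. Ties are
#' broken by larger gene count, then lexicographically by id. A
#' singleton cluster returns its only member.
#'
#' @param members character vector of chromosome keys (`species:chrom`).
#' @param cm a `collinearity_matrix`.
#' @return a single chromosome key.
#' @export
select_reference <- function(members, cm) {
  if (!length(members)) stop("empty cluster")
  if (length(members) == 1L) return(members)
  x <- cm$x[members, members, drop = FALSE]
  means <- rowMeans(x, na.rm = TRUE)
  n <- cm$n[members]
  ord <- order(-means, -n, members)
  members[ord[1]]
}

#' Augment a reference chromosome into an ancestral chromosome
#'
#' Starting from the reference chromosome's family order, donor
#' chromosomes of the same cluster are processed in decreasing mean
#' collinearity ratio to the reference. For each pair of adjacent
#' anchors inside a single collinear block between reference and donor,
#' if the donor carries 1..`max_intervening` genes between the two
#' anchors, the families among them not yet present are inserted between
#' the two reference anchors (immediately before the right anchor),
#' preserving donor order (reversed for orientation -1 blocks). Anchor
#' pairs whose reference positions are out of order (crossing inserts,
#' e.g. from an inversion inside the block) are skipped and counted.
#'
#' @param ref reference chromosome key (`species:chrom`).
#' @param donors other chromosome keys of the cluster.
#' @param blocks a `collinear_blocks` list covering ref-donor pairs.
#' @param tables named (by species) list of gene-order tables.
#' @param cm `collinearity_matrix` used to order donors.
#' @param max_intervening largest donor insert accepted (default 5).
#' @return data frame with columns `family_id`, `src_species`,
#'   `src_chrom`, `src_index` in ancestral order, plus an attribute
#'   `skipped` counting crossing anchor pairs.
#' @export
augment_reference <- function(ref, donors, blocks, tables, cm,
                              max_intervening = 5) {
  parse_key <- function(k) {
    p <- regmatches(k, regexpr(":", k), invert = TRUE)[[1]]
    c(species = p[1], chrom = p[2])
  }
  rk <- parse_key(ref)
  rt <- tables[[rk["species"]]]
  rt <- rt[rt$chrom == rk["chrom"], ]
  rt <- rt[order(rt$order_index), ]
  keep <- !duplicated(rt$family_id)  # uniqueness within an ancestral chromosome
  aek <- data.frame(family_id = rt$family_id[keep],
                    src_species = rk[["species"]],
                    src_chrom = rk[["chrom"]], src_index = rt$order_index[keep],
                    stringsAsFactors = FALSE)
  skipped <- 0L
  if (length(donors)) {
    ord <- order(-cm$x[ref, donors])
    donors <- donors[ord]
  }
  for (don in donors) {
    dk <- parse_key(don)
    dt <- tables[[dk["species"]]]
    dt <- dt[dt$chrom == dk["chrom"], ]
    dt <- dt[order(dt$order_index), ]
    for (b in blocks) {
      ka <- paste(b$species_a, b$chrom_a, sep = ":")
      kb <- paste(b$species_b, b$chrom_b, sep = ":")
      if (ka == ref && kb == don) {
        anc <- b$anchors; ref_gene <- "gene_a"; don_idx <- "index_b"
        ref_idx <- "index_a"
      } else if (kb == ref && ka == don) {
        anc <- b$anchors; ref_gene <- "gene_b"; don_idx <- "index_a"
        ref_idx <- "index_b"
      } else next
      anc <- anc[order(anc[[ref_idx]]), ]
      if (nrow(anc) < 2L) next
      for (t in seq_len(nrow(anc) - 1L)) {
        f1 <- rt$family_id[match(anc[[ref_gene]][t], rt$gene_id)]
        f2 <- rt$family_id[match(anc[[ref_gene]][t + 1L], rt$gene_id)]
        p1 <- match(f1, aek$family_id)
        p2 <- match(f2, aek$family_id)
        if (is.na(p1) || is.na(p2) || p2 <= p1) { skipped <- skipped + 1L; next }
        d1 <- anc[[don_idx]][t]; d2 <- anc[[don_idx]][t + 1L]
        lo <- min(d1, d2); hi <- max(d1, d2)
        if (hi - lo - 1L < 1L || hi - lo - 1L > max_intervening) next
        seg <- dt[dt$order_index > lo & dt$order_index < hi, , drop = FALSE]
        seg <- seg[order(seg$order_index), ]
        if (d2 < d1) seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
        seg <- seg[!(seg$family_id %in% aek$family_id), , drop = FALSE]
        if (!nrow(seg)) next
        ins <- data.frame(family_id = seg$family_id,
                          src_species = dk[["species"]],
                          src_chrom = dk[["chrom"]],
                          src_index = seg$order_index,
                          stringsAsFactors = FALSE)
        aek <- rbind(aek[seq_len(p2 - 1L), ], ins,
                     aek[seq(p2, nrow(aek)), ])
        rownames(aek) <- NULL
      }
    }
  }
  attr(aek, "skipped") <- skipped
  aek
}

#' Build an ancestral karyotype from a set of genomes
#'
#' The full reconstruction pipeline: detect collinear blocks among all
#' chromosomes, build and Z-normalize the collinearity-ratio matrix,
#' cluster chromosomes into ancestral groups, pick each cluster's most
#' complete chromosome as reference, and augment it with the cluster's
#' other chromosomes' specific genes. Ancestral chromosomes are numbered
#' 1..k by descending family count.
#'
#' @param genomes named list of `genome` objects or gene-order tables
#'   (>= 2 genomes).
#' @param blocks optional precomputed [all_blocks()] result.
#' @param k number of ancestral chromosomes, or `"auto"` (silhouette).
#' @param min_anchors,max_gap block-detection thresholds.
#' @param max_intervening augmentation insert limit.
#' @return an object of class `aek`: data frame with columns
#'   `aek_chrom`, `aek_index` (0-based), `family_id`, `src_species`,
#'   `src_chrom`, `src_index`; attributes `clusters` (the clustering
#'   result) and `references` (per-cluster reference keys).
#' @export
build_aek <- function(genomes, blocks = NULL, k = "auto",
                      min_anchors = 5, max_gap = 25, max_intervening = 5) {
  if (length(genomes) < 2L) stop("need at least two genomes")
  tabs <- lapply(genomes, function(g)
    if (inherits(g, "genome")) gene_order_table(g) else g)
  names(tabs) <- vapply(tabs, function(t) t$species[1], character(1))
  if (is.null(blocks)) blocks <- all_blocks(tabs, min_anchors, max_gap)
  cm <- z_normalize(collinearity_matrix(tabs, blocks = blocks))
  cl <- cluster_chromosomes(cm, k = k)
  chroms <- lapply(seq_len(cl$k), function(g) names(cl$labels)[cl$labels == g])
  refs <- vapply(chroms, select_reference, character(1), cm = cm)
  built <- lapply(seq_along(chroms), function(g)
    augment_reference(refs[g], setdiff(chroms[[g]], refs[g]), blocks,
                      tabs, cm, max_intervening))
  ord <- order(-vapply(built, nrow, integer(1)))
  out <- do.call(rbind, lapply(seq_along(ord), function(i) {
    d <- built[[ord[i]]]
    data.frame(aek_chrom = i, aek_index = seq_len(nrow(d)) - 1L, d,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("aek", "data.frame"),
            clusters = cl, references = refs[ord])
}

#' Represent an ancestral karyotype as a pseudo-genome
#'
#' One chromosome per ancestral chromosome, gene ids equal to family
#' ids, so that block detection and projection can treat the karyotype
#' like any other genome.
#'
#' @param aek an `aek` object (or data frame with `aek_chrom`,
#'   `aek_index`, `family_id`).
#' @return a `genome` with species id `"AEK"`.
#' @export
aek_as_genome <- function(aek) {
  chroms <- lapply(split(aek, aek$aek_chrom), function(d) {
    d <- d[order(d$aek_index), ]
    data.frame(gene_id = d$family_id, family_id = d$family_id,
               strand = 1L, anc_chrom = NA, anc_index = NA,
               stringsAsFactors = FALSE)
  })
  names(chroms) <- paste0("aek", names(chroms))
  new_genome("AEK", chroms)
}

#' Write an ancestral karyotype as TSV
#' @param aek an `aek` object.
#' @param path file path.
#' @export
write_aek <- function(aek, path) {
  utils::write.table(aek, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
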