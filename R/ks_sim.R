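#' Emit synonymous-divergence (Ks) values for a simulated dataset
#'
#' Gene pairs born at an event of age `a` receive Ks values drawn from a
#' lognormal distribution with median `a * ks_per_age` and coefficient
#' of variation `cv` (cv = 0 gives the exact median). Paralog pairs come
#' from the duplicate maps of polyploidy events on each tip's root-to-tip
#' path (pairs whose copies were since lost are skipped); ortholog pairs
#' between two tips share the age of the species-tree divergence node.
#' Ks peaks in the resulting tables sit near `age * ks_per_age` for each
#' event, which is what downstream mixture fitting recovers.
#'
#' @param dataset a `sim_dataset` from [simulate_clade()].
#' @param ks_per_age Ks units per unit event age (default 0.3).
#' @param cv lognormal coefficient of variation (>= 0, default 0.2).
#' @param seed integer seed.
#' @param include_orthologs also emit cross-species ortholog pairs
#'   (single-copy families only; default FALSE).
#' @return data frame `gene_a`, `gene_b`, `species_a`, `species_b`,
#'   `family_id`, `event_age`, `ks`.
#' @export
emit_ks <- function(dataset, ks_per_age = 0.3, cv = 0.2, seed = 1,
                    include_orthologs = FALSE) {
  if (cv < 0) stop("cv must be >= 0")
  set.seed(seed)
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  rows <- list()
  for (sp in names(dataset$tips)) {
    tab <- gene_order_table(dataset$tips[[sp]])
    present <- tab$gene_id
    fam <- stats::setNames(tab$family_id, tab$gene_id)
    for (ev in path_events(dataset, sp)) {
      if (!ev$kind %in% c("WGD", "WGT")) next
      cp <- ev$copies[ev$copies$kept, , drop = FALSE]
      cp <- cp[cp$src_gene %in% present & cp$new_gene %in% present, ,
               drop = FALSE]
      if (!nrow(cp)) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = cp$src_gene, gene_b = cp$new_gene,
        species_a = sp, species_b = sp,
        family_id = fam[cp$src_gene], event_age = ev$age,
        stringsAsFactors = FALSE)
    }
  }
  if (include_orthologs) {
    tips <- names(dataset$tips)
    ages <- dataset$node_ages
    tree <- dataset$tree
    labels <- c(tree$tip.label, tree$node.label)
    for (i in seq_along(tips)) for (j in seq_along(tips)) {
      if (j <= i) next
      mrca <- ape::getMRCA(tree, c(tips[i], tips[j]))
      # divergence age: time from the mrca down to the tips
      div <- max(ages[tips[c(i, j)]]) - ages[labels[mrca]]
      ta <- gene_order_table(dataset$tips[[tips[i]]])
      tb <- gene_order_table(dataset$tips[[tips[j]]])
      sa <- ta[!duplicated(ta$family_id) & !(ta$family_id %in%
               ta$family_id[duplicated(ta$family_id)]), ]
      sb <- tb[!duplicated(tb$family_id) & !(tb$family_id %in%
               tb$family_id[duplicated(tb$family_id)]), ]
      m <- merge(sa[, c("gene_id", "family_id")],
                 sb[, c("gene_id", "family_id")], by = "family_id")
      if (!nrow(m)) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = m$gene_id.x, gene_b = m$gene_id.y,
        species_a = tips[i], species_b = tips[j],
        family_id = m$family_id, event_age = div,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      species_a = character(0), species_b = character(0),
                      family_id = character(0), event_age = numeric(0),
                      ks = numeric(0)))
  out <- do.call(rbind, rows)
  med <- out$event_age * ks_per_age
  out$ks <- if (sdlog > 0)
    stats::rlnorm(nrow(out), meanlog = log(pmax(med, .Machine$double.eps)),
                  sdlog = sdlog) * (med > 0)
  else med
  rownames(out) <- NULL
  out
}

#' Write / read Ks tables as TSV
#' @param ks a Ks data frame.
#' @param path file path.
#' @export
write_ks_table <- function(ks, path) {
  utils::write.table(ks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ks_table
#' @export
read_ks_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
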