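#' Genome objects
#'
#' A `genome` is an ordered collection of chromosomes, each an ordered
#' data frame of genes. Gene order, not base-pair coordinates, is the
#' substrate of all synteny computation in this package: every gene has a
#' 0-based position on its chromosome given implicitly by row order.
#'
#' Columns of each chromosome data frame:
#' \describe{
#'   \item{gene_id}{unique within the genome}
#'   \item{family_id}{gene-family label shared across genomes and copies}
#'   \item{strand}{+1 or -1 reading orientation}
#'   \item{anc_chrom, anc_index}{provenance: ancestral chromosome and
#'     position this gene descends from (`NA` when unknown); maintained by
#'     every simulator operation so that downstream reconstructions can be
#'     scored against the truth}
#' }
#'
#' @param species_id character scalar naming the genome.
#' @param chromosomes named list of chromosome data frames.
#' @return an object of class `genome`.
#' @keywords internal
new_genome <- function(species_id, chromosomes) {
  stopifnot(is.character(species_id), length(species_id) == 1L,
            is.list(chromosomes), length(chromosomes) >= 1L,
            !is.null(names(chromosomes)))
  g <- structure(list(species_id = species_id, chromosomes = chromosomes),
                 class = "genome")
  validate_genome(g)
}

validate_genome <- function(g) {
  stopifnot(inherits(g, "genome"))
  for (nm in names(g$chromosomes)) {
    chr <- g$chromosomes[[nm]]
    if (nrow(chr) == 0L)
      stop("chromosome '", nm, "' of genome '", g$species_id, "' is empty")
    stopifnot(all(c("gene_id", "family_id", "strand") %in% names(chr)))
  }
  ids <- unlist(lapply(g$chromosomes, `[[`, "gene_id"), use.names = FALSE)
  if (anyDuplicated(ids))
    stop("duplicated gene_ids in genome '", g$species_id, "'")
  if (anyDuplicated(names(g$chromosomes)))
    stop("duplicated chromosome names in genome '", g$species_id, "'")
  g
}

#' @export
print.genome <- function(x, ...) {
  n <- vapply(x$chromosomes, nrow, integer(1))
  cat("genome '", x$species_id, "': ", length(n), " chromosomes, ",
      sum(n), " genes\n", sep = "")
  print(n)
  invisible(x)
}

#' Number of genes in a genome
#' @param genome a `genome`.
#' @return integer gene count.
#' @export
n_genes <- function(genome) {
  sum(vapply(genome$chromosomes, nrow, integer(1)))
}

#' Simulate an ancestral genome
#'
#' Creates the root karyotype of a simulation: `n_chrom` chromosomes of
#' `genes_per_chrom` single-copy genes each, every gene its own family,
#' all on the + strand. Provenance labels (`anc_chrom`, `anc_index`) are
#' set to each gene's own location so descendants can be scored against
#' the ancestral coordinate system. The default shape (7 chromosomes)
#' mirrors the seven-chromosome ancestral eudicot karyotype.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param genes_per_chrom genes per chromosome (>= 1).
#' @param seed optional integer seed (the operation is deterministic; the
#'   seed is accepted for interface uniformity).
#' @param species_id genome name.
#' @return a `genome`.
#' @examples
#' anc <- simulate_ancestor(7, 100)
#' n_genes(anc)
#' @export
simulate_ancestor <- function(n_chrom = 7, genes_per_chrom = 100,
                              seed = NULL, species_id = "ancestor") {
  if (!is.numeric(n_chrom) || n_chrom < 1 ||
      !is.numeric(genes_per_chrom) || genes_per_chrom < 1)
    stop("n_chrom and genes_per_chrom must be >= 1")
  n_chrom <- as.integer(n_chrom); genes_per_chrom <- as.integer(genes_per_chrom)
  chroms <- list()
  k <- 0L
  for (i in seq_len(n_chrom)) {
    fam <- sprintf("F%05d", k + seq_len(genes_per_chrom))
    chroms[[paste0("c", i)]] <- data.frame(
      gene_id = sprintf("g%06d", k + seq_len(genes_per_chrom)),
      family_id = fam,
      strand = 1L,
      anc_chrom = i,
      anc_index = seq_len(genes_per_chrom) - 1L,
      stringsAsFactors = FALSE)
    k <- k + genes_per_chrom
  }
  g <- new_genome(species_id, chroms)
  attr(g, "gene_counter") <- k
  g
}

next_gene_ids <- function(genome, n) {
  k <- attr(genome, "gene_counter")
  if (is.null(k)) {
    # derive a safe counter from existing ids
    ids <- unlist(lapply(genome$chromosomes, `[[`, "gene_id"), use.names = FALSE)
    num <- suppressWarnings(as.integer(sub("^g", "", ids)))
    k <- max(0L, num, na.rm = TRUE)
  }
  list(ids = sprintf("g%06d", k + seq_len(n)), counter = k + n)
}

#' Flatten a genome into a gene-order table
#'
#' @param genome a `genome`.
#' @return data frame with columns `species`, `chrom`, `order_index`
#'   (0-based, consecutive within chromosome), `gene_id`, `family_id`,
#'   `strand`, plus provenance columns `anc_chrom`, `anc_index` when the
#'   genome carries them.
#' @export
gene_order_table <- function(genome) {
  stopifnot(inherits(genome, "genome"))
  out <- lapply(names(genome$chromosomes), function(nm) {
    chr <- genome$chromosomes[[nm]]
    data.frame(species = genome$species_id, chrom = nm,
               order_index = seq_len(nrow(chr)) - 1L,
               gene_id = chr$gene_id, family_id = chr$family_id,
               strand = chr$strand,
               anc_chrom = if ("anc_chrom" %in% names(chr)) chr$anc_chrom else NA,
               anc_index = if ("anc_index" %in% names(chr)) chr$anc_index else NA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write / read gene-order tables as TSV
#'
#' The on-disk format has columns species, chrom, order_index, gene_id,
#' family_id, strand (provenance columns are carried along when present).
#'
#' @param x a `genome` or a gene-order data frame.
#' @param path file path.
#' @return `read_gene_order` returns a gene-order data frame.
#' @export
write_gene_order <- function(x, path) {
  tab <- if (inherits(x, "genome")) gene_order_table(x) else x
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_order
#' @export
read_gene_order <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Rebuild a `genome` from a gene-order table
#' @param tab a gene-order data frame (one species).
#' @return a `genome`.
#' @export
genome_from_table <- function(tab) {
  sp <- unique(tab$species)
  if (length(sp) != 1L) stop("table must contain exactly one species")
  tab <- tab[order(match(tab$chrom, unique(tab$chrom)), tab$order_index), ,
             drop = FALSE]
  chroms <- split(tab, factor(tab$chrom, levels = unique(tab$chrom)))
  chroms <- lapply(chroms, function(d) {
    data.frame(gene_id = d$gene_id, family_id = d$family_id,
               strand = d$strand,
               anc_chrom = if ("anc_chrom" %in% names(d)) d$anc_chrom else NA,
               anc_index = if ("anc_index" %in% names(d)) d$anc_index else NA,
               stringsAsFactors = FALSE)
  })
  new_genome(sp, chroms)
}
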