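#' Genome evolution events
#'
#' Each operator takes a `genome`, applies one structural event, and
#' returns `list(genome=, event=)`. The event record is fully concrete
#' (all random outcomes realized and stored), so that replaying an event
#' log from the ancestor reproduces every descendant genome exactly.
#'
#' Coordinates are 0-based; all intervals are half-open `[i, j)`. A
#' breakpoint `b` on a chromosome of length `L` denotes the inter-gene
#' position between genes `b-1` and `b` (so `0 < b < L` is interior).
#'
#' @name evolution-events
NULL

new_event <- function(kind, age, params) {
  structure(c(list(kind = kind, age = age), params), class = "evo_event")
}

#' @export
print.evo_event <- function(x, ...) {
  cat("<", x$kind, " event, age ", x$age, ">\n", sep = "")
  invisible(x)
}

rev_segment <- function(seg) {
  seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
  seg$strand <- -seg$strand
  rownames(seg) <- NULL
  seg
}

#' Whole-genome duplication or triplication with fractionation
#'
#' Every chromosome gains `multiplicity - 1` extra copies. The progenitor
#' copy of each gene is always kept; each extra copy is retained
#' independently with probability `retention` (fractionation as
#' per-family Bernoulli loss of the duplicate, never of the last copy).
#' `retention` may be one value per extra copy to model biased subgenome
#' fractionation. Entirely emptied duplicate chromosomes are dropped.
#'
#' @param genome a `genome`.
#' @param multiplicity 2 (WGD) or 3 (WGT).
#' @param retention duplicate retention probability in \[0,1\]; scalar or
#'   vector of length `multiplicity - 1`.
#' @param age event age in arbitrary time units (drives Ks emission).
#' @param seed optional integer seed.
#' @param event a previously recorded event to replay (internal use).
#' @return `list(genome, event)`; the event stores the duplicate gene map
#'   (`copies`: src_gene, new_gene, copy, kept) used for replay and for
#'   paralog-pair Ks emission.
#' @export
apply_polyploidy <- function(genome, multiplicity = 2, retention = 1,
                             age = 0, seed = NULL, event = NULL) {
  validate_genome(genome)
  if (is.null(event)) {
    if (!multiplicity %in% c(2L, 3L)) stop("multiplicity must be 2 or 3")
    if (any(retention < 0 | retention > 1)) stop("retention must be in [0,1]")
    retention <- rep_len(retention, multiplicity - 1L)
    if (!is.null(seed)) set.seed(seed)
    maps <- list()
    counter <- next_gene_ids(genome, 0L)$counter
    for (cp in seq_len(multiplicity - 1L)) {
      for (nm in names(genome$chromosomes)) {
        chr <- genome$chromosomes[[nm]]
        n <- nrow(chr)
        kept <- stats::runif(n) < retention[cp]
        new_ids <- sprintf("g%06d", counter + seq_len(n)); counter <- counter + n
        maps[[length(maps) + 1L]] <- data.frame(
          src_chrom = nm, src_gene = chr$gene_id, new_gene = new_ids,
          copy = cp + 1L, kept = kept, stringsAsFactors = FALSE)
      }
    }
    map <- do.call(rbind, maps)
    event <- new_event(if (multiplicity == 2L) "WGD" else "WGT", age,
                       list(multiplicity = multiplicity,
                            retention = retention, copies = map))
  } else {
    map <- event$copies
    multiplicity <- event$multiplicity
  }
  chroms <- genome$chromosomes
  gene_chr <- rep(names(chroms), vapply(chroms, nrow, integer(1)))
  names(gene_chr) <- unlist(lapply(chroms, `[[`, "gene_id"), use.names = FALSE)
  for (cp in 2:multiplicity) {
    for (nm in names(genome$chromosomes)) {
      sub <- map[map$copy == cp & map$src_chrom == nm, , drop = FALSE]
      chr <- genome$chromosomes[[nm]]
      keep <- sub$kept[match(chr$gene_id, sub$src_gene)]
      new_chr <- chr[keep, , drop = FALSE]
      if (nrow(new_chr) == 0L) next
      new_chr$gene_id <- sub$new_gene[match(new_chr$gene_id, sub$src_gene)]
      rownames(new_chr) <- NULL
      # repeated rounds of polyploidy must not collide on copy names
      new_nm <- paste0(nm, "x", cp)
      while (new_nm %in% names(chroms)) new_nm <- paste0(new_nm, "x", cp)
      chroms[[new_nm]] <- new_chr
    }
  }
  out <- new_genome(genome$species_id, chroms)
  attr(out, "gene_counter") <- max(next_gene_ids(genome, 0L)$counter,
                                   suppressWarnings(max(as.integer(
                                     sub("^g", "", map$new_gene)))))
  list(genome = out, event = event)
}

#' Chromosome fusion: end-end joining, reciprocal arm translocation,
#' or nested fusion
#'
#' * `EEJ` concatenates two whole chromosomes (`chromosome count - 1`).
#'   By default the tail of X joins the head of Y; `x_end`/`y_end` select
#'   other end combinations, reversing (with strand flip) the segment
#'   whose joined end is not the default one.
#' * `RTA` exchanges arms at interior breakpoints `bx`, `by`: the derived
#'   chromosomes are `X[0,bx) + Y[by,L_Y)` and `Y[0,by) + X[bx,L_X)`
#'   (chromosome count unchanged).
#' * `NCF` inserts the whole of Y into X at interior point `p`:
#'   `X[0,p) + Y + X[p,L_X)` (chromosome count - 1).
#'
#' Gene content is always preserved.
#'
#' @param genome a `genome`.
#' @param kind `"EEJ"`, `"RTA"` or `"NCF"`.
#' @param chroms length-2 character vector of distinct chromosome names
#'   (X then Y); `NULL` to pick a random pair.
#' @param breakpoints `RTA`: `c(bx, by)`; `NCF`: insertion point `p`;
#'   ignored for `EEJ`. `NULL` draws interior points at random.
#' @param x_end,y_end for `EEJ`: which end of each chromosome is joined
#'   (`"tail"`/`"head"` for X, `"head"`/`"tail"` for Y).
#' @param margin when breakpoints are drawn at random, keep them at
#'   least `margin` genes away from both termini (default 0). Fusion
#'   arms shorter than a collinear block cannot be resolved by synteny,
#'   so simulations meant to test junction detection should use a
#'   margin of at least the block size.
#' @inheritParams apply_polyploidy
#' @return `list(genome, event)`.
#' @export
apply_fusion <- function(genome, kind = c("EEJ", "RTA", "NCF"),
                         chroms = NULL, breakpoints = NULL,
                         x_end = "tail", y_end = "head", margin = 0,
                         age = 0, seed = NULL, event = NULL) {
  validate_genome(genome)
  if (is.null(event)) {
    kind <- match.arg(kind)
    if (!is.null(seed)) set.seed(seed)
    if (is.null(chroms)) {
      if (length(genome$chromosomes) < 2L) stop("need >= 2 chromosomes")
      chroms <- sample(names(genome$chromosomes), 2L)
    }
    if (length(chroms) != 2L || chroms[1] == chroms[2] ||
        !all(chroms %in% names(genome$chromosomes)))
      stop("chroms must name two distinct chromosomes of the genome")
    lx <- nrow(genome$chromosomes[[chroms[1]]])
    ly <- nrow(genome$chromosomes[[chroms[2]]])
    draw_bp <- function(L) {
      lo <- max(1L, as.integer(margin)); hi <- min(L - 1L, L - as.integer(margin))
      if (lo > hi) stop("chromosome too short for requested breakpoint margin")
      sample(lo:hi, 1L)
    }
    if (kind == "RTA") {
      if (is.null(breakpoints)) breakpoints <- c(draw_bp(lx), draw_bp(ly))
      if (breakpoints[1] <= 0 || breakpoints[1] >= lx ||
          breakpoints[2] <= 0 || breakpoints[2] >= ly)
        stop("RTA breakpoints must be interior")
    } else if (kind == "NCF") {
      if (is.null(breakpoints)) breakpoints <- draw_bp(lx)
      if (breakpoints[1] <= 0 || breakpoints[1] >= lx)
        stop("NCF insertion point must be interior")
    } else breakpoints <- integer(0)
    event <- new_event(kind, age,
                       list(chroms = chroms, breakpoints = breakpoints,
                            x_end = x_end, y_end = y_end))
  } else {
    kind <- event$kind; chroms <- event$chroms
    breakpoints <- event$breakpoints
    x_end <- event$x_end; y_end <- event$y_end
  }
  X <- genome$chromosomes[[chroms[1]]]
  Y <- genome$chromosomes[[chroms[2]]]
  chrs <- genome$chromosomes
  chrs[[chroms[1]]] <- NULL; chrs[[chroms[2]]] <- NULL
  if (kind == "EEJ") {
    if (identical(x_end, "head")) X <- rev_segment(X)
    if (identical(y_end, "tail")) Y <- rev_segment(Y)
    chrs[[paste(chroms, collapse = "_")]] <- rbind(X, Y)
  } else if (kind == "NCF") {
    p <- breakpoints[1]
    chrs[[paste(chroms, collapse = "_")]] <-
      rbind(X[seq_len(p), , drop = FALSE], Y,
            X[setdiff(seq_len(nrow(X)), seq_len(p)), , drop = FALSE])
  } else { # RTA
    bx <- breakpoints[1]; by <- breakpoints[2]
    chrs[[paste0(chroms[1], "r")]] <-
      rbind(X[seq_len(bx), , drop = FALSE],
            Y[setdiff(seq_len(nrow(Y)), seq_len(by)), , drop = FALSE])
    chrs[[paste0(chroms[2], "r")]] <-
      rbind(Y[seq_len(by), , drop = FALSE],
            X[setdiff(seq_len(nrow(X)), seq_len(bx)), , drop = FALSE])
  }
  chrs <- lapply(chrs, function(d) { rownames(d) <- NULL; d })
  out <- new_genome(genome$species_id, chrs)
  attr(out, "gene_counter") <- next_gene_ids(genome, 0L)$counter
  list(genome = out, event = event)
}

#' Intra-chromosomal inversion
#'
#' Reverses the gene segment `[i, j)` of a chromosome and flips the
#' strand of every gene inside it. Applying the same inversion twice
#' restores the original genome.
#'
#' @param genome a `genome`.
#' @param chrom chromosome name (`NULL`: random).
#' @param i,j 0-based half-open interval bounds, `0 <= i < j <= length`
#'   (`NULL`: random interval).
#' @inheritParams apply_polyploidy
#' @return `list(genome, event)`.
#' @export
apply_inversion <- function(genome, chrom = NULL, i = NULL, j = NULL,
                            age = 0, seed = NULL, event = NULL) {
  validate_genome(genome)
  if (is.null(event)) {
    if (!is.null(seed)) set.seed(seed)
    if (is.null(chrom)) chrom <- sample(names(genome$chromosomes), 1L)
    L <- nrow(genome$chromosomes[[chrom]])
    if (is.null(i) || is.null(j)) {
      b <- sort(sample(0:L, 2L)); i <- b[1]; j <- b[2]
      if (i == j) { i <- 0L; j <- L }
    }
    if (!(i >= 0 && i < j && j <= L)) stop("invalid inversion interval")
    event <- new_event("INVERSION", age, list(chrom = chrom, i = i, j = j))
  } else { chrom <- event$chrom; i <- event$i; j <- event$j }
  chr <- genome$chromosomes[[chrom]]
  idx <- (i + 1L):j
  chr[idx, ] <- rev_segment(chr[idx, , drop = FALSE])
  rownames(chr) <- NULL
  genome$chromosomes[[chrom]] <- chr
  list(genome = validate_genome(genome), event = event)
}

#' Chromosome fission
#'
#' Splits a chromosome at interior breakpoint `p` into `[0, p)` and
#' `[p, L)` (chromosome count + 1; content preserved).
#'
#' @param genome a `genome`.
#' @param chrom chromosome name (`NULL`: random).
#' @param p interior breakpoint (`NULL`: random).
#' @inheritParams apply_polyploidy
#' @return `list(genome, event)`.
#' @export
apply_fission <- function(genome, chrom = NULL, p = NULL,
                          age = 0, seed = NULL, event = NULL) {
  validate_genome(genome)
  if (is.null(event)) {
    if (!is.null(seed)) set.seed(seed)
    if (is.null(chrom)) chrom <- sample(names(genome$chromosomes), 1L)
    L <- nrow(genome$chromosomes[[chrom]])
    if (is.null(p)) p <- sample(L - 1L, 1L)
    if (p <= 0 || p >= L) stop("fission breakpoint must be interior")
    event <- new_event("FISSION", age, list(chrom = chrom, p = p))
  } else { chrom <- event$chrom; p <- event$p }
  chr <- genome$chromosomes[[chrom]]
  chrs <- genome$chromosomes
  chrs[[chrom]] <- NULL
  a <- chr[seq_len(p), , drop = FALSE]
  b <- chr[setdiff(seq_len(nrow(chr)), seq_len(p)), , drop = FALSE]
  rownames(a) <- rownames(b) <- NULL
  chrs[[paste0(chrom, "a")]] <- a
  chrs[[paste0(chrom, "b")]] <- b
  out <- new_genome(genome$species_id, chrs)
  attr(out, "gene_counter") <- next_gene_ids(genome, 0L)$counter
  list(genome = out, event = event)
}

#' Replay one recorded event
#' @param genome a `genome`.
#' @param event an `evo_event` produced by an `apply_*` operator.
#' @return the derived `genome`.
#' @export
apply_event <- function(genome, event) {
  stopifnot(inherits(event, "evo_event"))
  switch(event$kind,
    WGD = , WGT = apply_polyploidy(genome, event = event)$genome,
    EEJ = , RTA = , NCF = apply_fusion(genome, event = event)$genome,
    INVERSION = apply_inversion(genome, event = event)$genome,
    FISSION = apply_fission(genome, event = event)$genome,
    stop("unknown event kind: ", event$kind))
}
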