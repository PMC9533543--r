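test_that("ancestor simulation produces the requested karyotype", {
  g <- simulate_ancestor(7, 100)
  expect_length(g$chromosomes, 7)
  expect_equal(n_genes(g), 700)
  tab <- gene_order_table(g)
  expect_equal(length(unique(tab$family_id)), 700)
  expect_true(all(tab$strand == 1))
  # degenerate single-gene genome
  g1 <- simulate_ancestor(1, 1)
  expect_equal(n_genes(g1), 1)
  expect_error(simulate_ancestor(0, 10), "must be >= 1")
  # deterministic
  expect_identical(unclass(simulate_ancestor(3, 5)),
                   unclass(simulate_ancestor(3, 5)))
})

test_that("polyploidy duplicates chromosomes and fractionates at the stated rate", {
  anc <- simulate_ancestor(7, 100)
  full <- apply_polyploidy(anc, 2, retention = 1, seed = 1)
  expect_equal(n_genes(full$genome), 1400)
  expect_length(full$genome$chromosomes, 14)
  wgt <- apply_polyploidy(anc, 3, retention = 1, seed = 1)
  expect_equal(n_genes(wgt$genome), 2100)
  expect_error(apply_polyploidy(anc, 4), "multiplicity")

  # retained-duplicate fraction within binomial 99% bounds (n = 700)
  r <- apply_polyploidy(anc, 2, retention = 0.6, seed = 42)
  kept <- sum(r$event$copies$kept)
  bounds <- qbinom(c(0.005, 0.995), 700, 0.6)
  expect_gte(kept, bounds[1])
  expect_lte(kept, bounds[2])
  expect_equal(n_genes(r$genome), 700 + kept)
})

test_that("fusion operators rearrange without changing gene content", {
  anc <- simulate_ancestor(7, 20)
  genes <- sort(gene_order_table(anc)$gene_id)

  eej <- apply_fusion(anc, "EEJ", chroms = c("c1", "c2"))
  expect_length(eej$genome$chromosomes, 6)
  expect_equal(sort(gene_order_table(eej$genome)$gene_id), genes)
  fused <- eej$genome$chromosomes[["c1_c2"]]
  expect_equal(fused$gene_id,
               c(anc$chromosomes$c1$gene_id, anc$chromosomes$c2$gene_id))

  rta <- apply_fusion(anc, "RTA", chroms = c("c1", "c2"),
                      breakpoints = c(5L, 12L))
  expect_length(rta$genome$chromosomes, 7)
  expect_equal(sort(gene_order_table(rta$genome)$gene_id), genes)
  d1 <- rta$genome$chromosomes[["c1r"]]
  d2 <- rta$genome$chromosomes[["c2r"]]
  expect_equal(d1$gene_id,
               c(anc$chromosomes$c1$gene_id[1:5],
                 anc$chromosomes$c2$gene_id[13:20]))
  expect_equal(d2$gene_id,
               c(anc$chromosomes$c2$gene_id[1:12],
                 anc$chromosomes$c1$gene_id[6:20]))

  ncf <- apply_fusion(anc, "NCF", chroms = c("c1", "c2"), breakpoints = 8L)
  expect_length(ncf$genome$chromosomes, 6)
  nested <- ncf$genome$chromosomes[["c1_c2"]]
  expect_equal(nested$gene_id,
               c(anc$chromosomes$c1$gene_id[1:8],
                 anc$chromosomes$c2$gene_id,
                 anc$chromosomes$c1$gene_id[9:20]))
  expect_error(apply_fusion(anc, "NCF", chroms = c("c1", "c2"),
                            breakpoints = 0L), "interior")
  expect_error(apply_fusion(anc, "RTA", chroms = c("c1", "c1")), "distinct")
})

test_that("inversion is an involution and flips orientations", {
  anc <- simulate_ancestor(2, 30)
  inv <- apply_inversion(anc, "c1", 5, 15)
  seg <- inv$genome$chromosomes$c1[6:15, ]
  expect_equal(seg$gene_id, rev(anc$chromosomes$c1$gene_id[6:15]))
  expect_true(all(seg$strand == -1))
  back <- apply_inversion(inv$genome, "c1", 5, 15)
  expect_identical(back$genome$chromosomes, anc$chromosomes)
  # full-chromosome and single-gene inversions
  full <- apply_inversion(anc, "c2", 0, 30)
  expect_equal(full$genome$chromosomes$c2$gene_id,
               rev(anc$chromosomes$c2$gene_id))
  one <- apply_inversion(anc, "c1", 3, 4)
  expect_equal(one$genome$chromosomes$c1$gene_id,
               anc$chromosomes$c1$gene_id)
  expect_equal(one$genome$chromosomes$c1$strand[4], -1)
  expect_error(apply_inversion(anc, "c1", 10, 5), "invalid")
})

test_that("fission splits and EEJ re-joining restores the original order", {
  anc <- simulate_ancestor(3, 100)
  fis <- apply_fission(anc, "c1", 40)
  expect_length(fis$genome$chromosomes, 4)
  expect_equal(nrow(fis$genome$chromosomes$c1a), 40)
  expect_equal(nrow(fis$genome$chromosomes$c1b), 60)
  rejoined <- apply_fusion(fis$genome, "EEJ", chroms = c("c1a", "c1b"))
  expect_equal(rejoined$genome$chromosomes$c1a_c1b$gene_id,
               anc$chromosomes$c1$gene_id)
  expect_error(apply_fission(anc, "c1", 0), "interior")
})

test_that("clade simulation is deterministic and its event log replays exactly", {
  ds1 <- moderate_scenario(seed = 11, genes_per_chrom = 40)
  ds2 <- moderate_scenario(seed = 11, genes_per_chrom = 40)
  expect_identical(lapply(ds1$tips, unclass), lapply(ds2$tips, unclass))
  # empty scenario: tips identical to the ancestor (up to species id)
  ds0 <- simulate_clade("((A:1,B:1):1,C:2);", seed = 1, n_chrom = 2,
                        genes_per_chrom = 10)
  for (tp in ds0$tips)
    expect_identical(tp$chromosomes, ds0$ancestor$chromosomes)
  # one WGD on one branch only doubles that tip
  ds <- simulate_clade("((A:1,B:1):1,C:2);",
                       scenario = list(A = list(list(kind = "WGD"))),
                       seed = 2, n_chrom = 3, genes_per_chrom = 10)
  expect_length(ds$tips$A$chromosomes, 6)
  expect_length(ds$tips$B$chromosomes, 3)
  expect_error(simulate_clade("((A:1,B:1):1,C:2);",
                              scenario = list(Z = list())),
               "unknown branch")
})

test_that("event-log replay reproduces tip genomes over random scenarios", {
  kinds <- c("WGD", "EEJ", "RTA", "NCF", "INVERSION", "FISSION")
  for (s in 1:20) {
    set.seed(s)
    n_ev <- sample(0:3, 3, replace = TRUE)
    sc <- list()
    for (tip in c("A", "B", "C")) {
      k <- n_ev[match(tip, c("A", "B", "C"))]
      if (k > 0)
        sc[[tip]] <- lapply(seq_len(k), function(i)
          list(kind = sample(kinds, 1),
               retention = runif(1, 0.5, 1), age = i))
    }
    ds <- simulate_clade("((A:1,B:1):1,C:2);", scenario = sc, seed = s,
                         n_chrom = 4, genes_per_chrom = 30)
    replayed <- replay_event_log(ds)
    expect_identical(lapply(replayed, unclass), lapply(ds$tips, unclass))
  }
})

test_that("gene-order and event-log round trips preserve the data", {
  ds <- simulate_clade("((A:1,B:1):1,C:2);",
                       scenario = list(A = list(list(kind = "WGD",
                                                     retention = 0.8))),
                       seed = 3, n_chrom = 2, genes_per_chrom = 15)
  tmp <- tempfile(fileext = ".tsv")
  write_gene_order(ds$tips$A, tmp)
  back <- genome_from_table(read_gene_order(tmp))
  expect_equal(gene_order_table(back)[, 1:6],
               gene_order_table(ds$tips$A)[, 1:6])
  tmp2 <- tempfile(fileext = ".json")
  write_event_log(ds, tmp2)
  expect_true(jsonlite::validate(paste(readLines(tmp2), collapse = "")))
})
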