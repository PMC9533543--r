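test_that("reference selection maximizes mean collinearity with declared ties", {
  x <- matrix(NA, 3, 3, dimnames = list(c("S:a", "S:b", "S:c"),
                                        c("S:a", "S:b", "S:c")))
  x["S:a", c("S:b", "S:c")] <- c(0.8, 0.8)   # mean 0.8
  x["S:b", c("S:a", "S:c")] <- c(0.8, 0.4)   # mean 0.6
  x["S:c", c("S:a", "S:b")] <- c(0.8, 0.4)   # mean 0.6
  cm <- structure(list(x = x, n = c("S:a" = 100, "S:b" = 120, "S:c" = 100)),
                  class = "collinearity_matrix")
  expect_equal(select_reference(rownames(x), cm), "S:a")
  # tie on mean ratio -> larger gene count wins
  x2 <- x; x2["S:b", c("S:a", "S:c")] <- c(0.8, 0.8)
  x2["S:a", c("S:b", "S:c")] <- c(0.8, 0.8)
  cm2 <- cm; cm2$x <- x2
  expect_equal(select_reference(c("S:a", "S:b"), cm2), "S:b")
  expect_equal(select_reference("S:c", cm), "S:c")
  expect_error(select_reference(character(0), cm), "empty")
})

test_that("augmentation inserts short donor runs and respects the threshold", {
  # reference lost families F6..F7; donor retains them between anchors
  ref_t <- data.frame(species = "R", chrom = "c1", order_index = 0:7,
                      gene_id = paste0("r", 1:8),
                      family_id = paste0("F", c(1:5, 8:10)),
                      strand = 1L, stringsAsFactors = FALSE)
  don_t <- data.frame(species = "D", chrom = "c1", order_index = 0:9,
                      gene_id = paste0("d", 1:10),
                      family_id = paste0("F", 1:10),
                      strand = 1L, stringsAsFactors = FALSE)
  bl <- detect_blocks(ref_t, don_t, min_anchors = 3, max_gap = 25)
  cm <- collinearity_matrix(list(R = ref_t, D = don_t), blocks = bl)
  aek <- augment_reference("R:c1", "D:c1", bl, list(R = ref_t, D = don_t),
                           cm, max_intervening = 5)
  expect_equal(aek$family_id, paste0("F", 1:10))
  expect_equal(aek$src_species[aek$family_id %in% c("F6", "F7")],
               c("D", "D"))
  # more than five intervening genes: no insertion
  don_big <- data.frame(species = "D", chrom = "c1", order_index = 0:13,
                        gene_id = paste0("d", 1:14),
                        family_id = paste0("F", c(1:5, 11:16, 8:10)),
                        strand = 1L, stringsAsFactors = FALSE)
  bl2 <- detect_blocks(ref_t, don_big, min_anchors = 3, max_gap = 25)
  cm2 <- collinearity_matrix(list(R = ref_t, D = don_big), blocks = bl2)
  aek2 <- augment_reference("R:c1", "D:c1", bl2,
                            list(R = ref_t, D = don_big), cm2)
  expect_false(any(paste0("F", 11:16) %in% aek2$family_id))
})

test_that("duplicate families arriving from later donors are suppressed", {
  ref_t <- data.frame(species = "R", chrom = "c1", order_index = 0:5,
                      gene_id = paste0("r", 1:6),
                      family_id = paste0("F", c(1:3, 7:9)),
                      strand = 1L, stringsAsFactors = FALSE)
  don1 <- data.frame(species = "D", chrom = "c1", order_index = 0:8,
                     gene_id = paste0("d", 1:9),
                     family_id = paste0("F", 1:9),
                     strand = 1L, stringsAsFactors = FALSE)
  don2 <- data.frame(species = "E", chrom = "c1", order_index = 0:8,
                     gene_id = paste0("e", 1:9),
                     family_id = paste0("F", 1:9),
                     strand = 1L, stringsAsFactors = FALSE)
  tabs <- list(R = ref_t, D = don1, E = don2)
  bl <- all_blocks(tabs, min_anchors = 3, max_gap = 25)
  cm <- collinearity_matrix(tabs, blocks = bl)
  aek <- augment_reference("R:c1", c("D:c1", "E:c1"), bl, tabs, cm)
  expect_equal(anyDuplicated(aek$family_id), 0L)
  expect_equal(sort(aek$family_id), paste0("F", 1:9))
})

test_that("two identical event-free genomes rebuild the ancestor exactly", {
  anc <- simulate_ancestor(3, 40)
  a <- anc; a$species_id <- "A"
  b <- anc; b$species_id <- "B"
  aek <- build_aek(list(A = a, B = b), k = 3)
  got <- gene_order_table(anc)
  for (i in unique(aek$aek_chrom)) {
    fams <- aek$family_id[aek$aek_chrom == i]
    anc_ch <- got$family_id[got$anc_chrom == got$anc_chrom[
      match(fams[1], got$family_id)]]
    expect_equal(fams, anc_ch)
  }
})

test_that("AEK recovery on the standard scenario meets recall and accuracy", {
  ds <- moderate_scenario(retention = 0.7, genes_per_chrom = 100, seed = 4)
  bl <- all_blocks(ds$tips)
  aek <- build_aek(ds$tips, blocks = bl, k = "auto")
  expect_equal(length(unique(aek$aek_chrom)), 7L)
  anc_f <- gene_order_table(ds$ancestor)$family_id
  recall <- mean(anc_f %in% aek$family_id)
  expect_gte(recall, 0.90)
  # order agreement: Kendall concordance between reconstructed and true
  # order on shared families, per ancestral chromosome
  got <- gene_order_table(ds$ancestor)
  truth_idx <- stats::setNames(got$anc_index, got$family_id)
  truth_ch <- stats::setNames(got$anc_chrom, got$family_id)
  taus <- vapply(split(aek, aek$aek_chrom), function(d) {
    d <- d[truth_ch[d$family_id] ==
             as.integer(names(which.max(table(truth_ch[d$family_id])))), ]
    abs(stats::cor(d$aek_index, truth_idx[d$family_id],
                   method = "kendall"))
  }, numeric(1))
  expect_gte(mean(taus), 0.95)
  # painting ancestry accuracy over all six tips
  cmap <- aek_chrom_map(aek, ds$ancestor)
  accs <- vapply(names(ds$tips), function(sp) {
    p <- project(aek, ds$tips[[sp]])
    ok <- !is.na(p$aek_chrom)
    mean(cmap[as.character(p$aek_chrom[ok])] == p$anc_chrom[ok])
  }, numeric(1))
  expect_gte(min(accs), 0.95)
})

test_that("recovery degrades gracefully as duplicate retention falls", {
  metric <- vapply(c(0.9, 0.7, 0.5), function(ret) {
    ds <- moderate_scenario(retention = ret, genes_per_chrom = 60, seed = 8)
    aek <- build_aek(ds$tips, k = 7)
    cmap <- aek_chrom_map(aek, ds$ancestor)
    p <- project(aek, ds$tips$S2)
    ok <- !is.na(p$aek_chrom)
    recall <- mean(gene_order_table(ds$ancestor)$family_id %in%
                     aek$family_id)
    acc <- mean(cmap[as.character(p$aek_chrom[ok])] == p$anc_chrom[ok])
    min(recall, acc)
  }, numeric(1))
  expect_true(all(diff(metric) <= 0.02))  # monotone up to noise
  expect_gte(metric[1], 0.95)
})

test_that("projection of the karyotype onto the true ancestor is the identity", {
  anc <- simulate_ancestor(4, 50)
  aek <- true_aek(anc)
  p <- project(aek, anc)
  expect_true(all(!is.na(p$aek_chrom)))
  expect_equal(p$aek_chrom, p$anc_chrom)
  expect_equal(p$aek_index, as.numeric(p$anc_index))
  # self-projection (karyotype onto its own pseudo-genome)
  selfp <- project(aek, aek_as_genome(aek))
  expect_equal(selfp$aek_chrom,
               as.integer(sub("^aek", "", selfp$chrom)))
})

test_that("copy labels rank subgenomes by completeness", {
  anc <- simulate_ancestor(3, 60)
  aek <- true_aek(anc)
  # loss-free triplication: three copies, each complete, labels A, B, C
  wgt <- apply_polyploidy(anc, 3, retention = 1, seed = 1)$genome
  wgt$species_id <- "W"
  pg <- paint_genome(aek, wgt)
  for (ac in 1:3) {
    cp <- pg$copies[pg$copies$aek_chrom == ac, ]
    expect_equal(sort(cp$copy), c("A", "B", "C"))
    expect_true(all(cp$completeness > 0.9))
  }
  # asymmetric fractionation: the well-retained subgenome must be A
  asym <- apply_polyploidy(anc, 3, retention = c(0.9, 0.5),
                           seed = 3)$genome
  asym$species_id <- "Y"
  pg2 <- paint_genome(aek, asym)
  for (ac in 1:3) {
    cp <- pg2$copies[pg2$copies$aek_chrom == ac, ]
    cp <- cp[order(cp$copy), ]
    expect_true(all(diff(cp$completeness) <= 0))
    expect_gt(cp$completeness[1], 0.9)
  }
})
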