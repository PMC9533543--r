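test_that("bipartition support is 100 for the species tree against itself", {
  sp <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,(D:1,E:1):2);")
  trees <- rep(c(sp), 25); class(trees) <- "multiPhylo"
  res <- bipartition_support(sp, trees)
  expect_true(all(res$support == 100))
  expect_error(bipartition_support(sp, c(ape::read.tree(text = "(A:1,(Z:1,B:1):1);"))),
               "absent")
})

test_that("equal quartet resolutions give one-third support", {
  sp <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  trees <- c(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"),
             ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);"),
             ape::read.tree(text = "((A:1,D:1):1,(B:1,C:1):1);"))
  trees <- rep(trees, 10)
  res <- bipartition_support(sp, trees)
  expect_equal(res$support[res$clade == "A;B"], 100 / 3, tolerance = 1e-9)
})

test_that("MSC-simulated support matches the coalescent closed form", {
  # distant outgroup makes the A-B split informative as an unrooted
  # bipartition while leaving its probability at 1 - (2/3) exp(-T)
  T_ <- 1
  sp <- ape::read.tree(text = sprintf("(((A:1,B:1):%g,C:%g):3,O:%g);",
                                      T_, 1 + T_, 4 + T_))
  trees <- simulate_gene_trees_msc(sp, 2000, seed = 23)
  res <- bipartition_support(sp, trees)
  p <- msc_concordance_prob(T_)
  se <- 100 * sqrt(p * (1 - p) / 2000)
  expect_lt(abs(res$support[res$clade == "A;B"] - 100 * p), 3 * se)
  # gene trees reduced below a quartet become uninformative, not errors
  pruned <- lapply(trees[1:100], function(t) ape::drop.tip(t, "O"))
  res2 <- bipartition_support(sp, pruned)
  expect_equal(res2$n_informative[res2$clade == "A;B"], 0L)
})

test_that("theta follows 2m/d and is recovered end to end within 25%", {
  expect_equal(estimate_theta(0.01, 1.0), 0.02)
  expect_equal(estimate_theta(0, 2), 0)
  expect_error(estimate_theta(0.1, 0), "> 0")
  skip_if_not_installed("phangorn")
  theta <- 0.02
  sp_coal <- ape::read.tree(text = "(((A:2,B:2):1,C:3):2,O:5);")
  gts <- simulate_gene_trees_msc(sp_coal, 500, seed = 31)
  taxa <- c("A", "B", "C", "O")
  Dsum <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  conc <- 0; nn <- 0
  for (i in seq_along(gts)) {
    gt <- gts[[i]]
    gt$edge.length <- gt$edge.length * theta / 2
    aln <- simulate_sequences_gtr(gt, 300, seed = 5000 + i)
    d <- tryCatch(jc_dist_matrix(aln), error = function(e) NULL)
    if (is.null(d)) next
    nn <- nn + 1
    Dsum <- Dsum + d[taxa, taxa]
    tr <- ape::root(nj_tree(d), "O", resolve.root = TRUE)
    if (ape::is.monophyletic(tr, c("A", "B"))) conc <- conc + 1
  }
  d_hat <- -log(1.5 * (1 - conc / nn))       # coalescent units from discordance
  mt <- phangorn::nnls.tree(stats::as.dist(Dsum / nn),
                            ape::read.tree(text = "(((A,B),C),O);"),
                            method = "unrooted")
  ut <- ape::unroot(mt)
  m_hat <- ut$edge.length[ut$edge[, 2] > ape::Ntip(ut)][1]
  theta_hat <- estimate_theta(m_hat, d_hat)
  expect_lt(abs(theta_hat - theta) / theta, 0.25)
})

test_that("triplet counts follow topology and symmetry", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,O:3);")
  res <- triplet_counts(rep(c(tr), 100), c("A", "B", "C"), outgroup = "O")
  expect_equal(unname(res$counts), c(100, 0, 0))
  # taxa relabeling consistent with symmetry: swapping A and B swaps
  # the two minor counts
  trees <- simulate_gene_trees_msc("((A:1,B:1):0.5,C:1.5);", 1000, seed = 3)
  r1 <- triplet_counts(trees, c("A", "B", "C"))
  r2 <- triplet_counts(trees, c("B", "A", "C"))
  expect_equal(r1$counts[["ab"]], r2$counts[["ab"]])
  expect_equal(r1$counts[["ac"]], r2$counts[["bc"]])
  # T = 0: all three topologies near n/3
  t0 <- simulate_gene_trees_msc("((A:1,B:1):0,C:1);", 1500, seed = 4)
  r0 <- triplet_counts(t0, c("A", "B", "C"))
  expect_gt(stats::chisq.test(r0$counts)$p.value, 0.001)
})

test_that("minor-triplet chi-square matches its closed form", {
  r <- minor_triplet_chisq(c(80, 20))
  expect_equal(r$statistic, 36)
  expect_lt(r$p_value, 1e-8)
  expect_equal(minor_triplet_chisq(c(50, 50))$statistic, 0)
})

test_that("introgression skews one minor triplet with decisive significance", {
  trees <- simulate_gene_trees_msc(
    "((A:1,B:1):1,C:2);", 2000, seed = 6,
    introgression = list(donor = "C", recipient = "B", gamma = 0.3))
  cnt <- triplet_counts(trees, c("A", "B", "C"))$counts
  r <- minor_triplet_chisq(cnt[c("ac", "bc")])
  expect_lt(r$p_value, 0.001)
  expect_gt(cnt[["bc"]], cnt[["ac"]])
})

test_that("reticulation index is controlled under ILS and localizes gene flow", {
  sp9 <- ape::read.tree(
    text = "(((((A:1,B:1):1,C:2):1,D:3):1,E:4):1,O:5);")
  # false-positive control over seeds
  fp <- numeric(0)
  for (s in 1:4) {
    obs <- simulate_gene_trees_msc(sp9, 800, seed = 100 + s)
    nul <- simulate_gene_trees_msc(sp9, 800, seed = 200 + s)
    ri <- reticulation_index(sp9, obs, nul, max_comb = 25, seed = s)
    fp <- c(fp, ri$reticulation_index)
  }
  expect_lte(mean(fp, na.rm = TRUE), 0.05 + 3 * sqrt(0.05 * 0.95 / length(fp)))
  # introgression E -> C: the node joining C must carry the top index
  obs <- simulate_gene_trees_msc(sp9, 1500, seed = 7,
    introgression = list(donor = "E", recipient = "C", gamma = 0.3))
  nul <- simulate_gene_trees_msc(sp9, 1500, seed = 8)
  ri <- reticulation_index(sp9, obs, nul, max_comb = 25, seed = 5)
  node_c <- ape::getMRCA(sp9, c("A", "B", "C"))
  expect_equal(ri$node[which.max(ri$reticulation_index)], node_c)
})

test_that("Jukes-Cantor distance matches its closed form and signals saturation", {
  expect_equal(jc_distance(c("A", "C", "G", "T"), c("A", "C", "G", "T")), 0)
  a <- c(rep("A", 90), rep("C", 10)); b <- rep("A", 100)
  expect_lt(abs(jc_distance(a, b) - 0.10732), 1e-5)
  sat <- c(rep("C", 75), rep("A", 25))
  expect_error(jc_distance(sat, rep("A", 100)), class = "jc_saturation_error")
  expect_error(jc_distance("A", c("A", "C")), "equal length")
  # cross-check against the reference implementation in ape
  set.seed(2)
  aln <- simulate_sequences_gtr("(A:0.2,B:0.3);", 2000, seed = 10)
  d_ape <- ape::dist.dna(ape::as.DNAbin(aln), model = "JC69")
  expect_equal(jc_distance(aln["A", ], aln["B", ]), as.numeric(d_ape),
               tolerance = 1e-9)
})

test_that("neighbor joining recovers additive trees and validates input", {
  true <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):1);")
  d <- ape::cophenetic.phylo(true)
  got <- nj_tree(d)
  # enumeration over the three quartet topologies: the recovered one
  # must be the only one consistent with the distances
  expect_equal(ape::dist.topo(ape::unroot(true), got), 0,
               ignore_attr = TRUE)
  expect_equal(sort(ape::cophenetic.phylo(got)[rownames(d), colnames(d)]),
               sort(d), tolerance = 1e-9)
  # three taxa: closed-form branch lengths solve the three-point equations
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(d3)
  expect_equal(sort(t3$edge.length), sort(c(1, 2, 3)), tolerance = 1e-9)
  # permutation invariance
  perm <- c("D", "A", "C", "B")
  got2 <- nj_tree(d[perm, perm])
  expect_equal(ape::dist.topo(got, got2), 0, ignore_attr = TRUE)
  bad <- d; bad[1, 2] <- 9
  expect_error(nj_tree(bad), "symmetric")
})

test_that("estimation-error support is high with signal, random without, deterministic", {
  sp <- ape::read.tree(text = "(((A:0.05,B:0.05):0.5,C:0.1):0.5,D:0.2);")
  strong <- estimation_error_support(sp, n_sim = 40, length = 2000, seed = 3)
  expect_true(all(strong$support > 95))
  sp0 <- ape::read.tree(text = "(((A:0.05,B:0.05):0.0,C:0.1):0.5,D:0.2);")
  weak <- estimation_error_support(sp0, n_sim = 150, length = 1000, seed = 3)
  expect_lt(abs(weak$support[weak$clade == "A;B"] - 100 / 3), 12)
  again <- estimation_error_support(sp, n_sim = 40, length = 2000, seed = 3)
  expect_identical(strong, again)
})

test_that("lmg shares sum to R2, respect orthogonality, and match enumeration", {
  set.seed(14)
  n <- 120
  # exactly orthogonal, centered predictors: QR of a centered matrix
  X0 <- scale(matrix(stats::rnorm(n * 3), n, 3), center = TRUE,
              scale = FALSE)
  Xr <- qr.Q(qr(X0))
  y <- Xr %*% c(2, 1, 0.5) + stats::rnorm(n, sd = 0.5)
  r <- lmg_decomposition(y, Xr)
  marg <- vapply(1:3, function(k)
    summary(stats::lm(y ~ Xr[, k]))$r.squared, numeric(1))
  expect_equal(unname(r$shares), marg, tolerance = 1e-8)
  expect_equal(sum(r$shares), r$r_squared, tolerance = 1e-10)
  # correlated designs against the all-orderings enumeration oracle
  for (s in 1:10) {
    set.seed(s)
    X <- matrix(stats::rnorm(50 * 3), 50, 3)
    X[, 2] <- X[, 2] + 0.7 * X[, 1]
    y <- X %*% stats::rnorm(3) + stats::rnorm(50)
    r <- lmg_decomposition(y, X)
    oracle <- lmg_enumeration_oracle(y, X)
    expect_equal(unname(r$shares), oracle, tolerance = 1e-10)
    expect_equal(sum(r$shares), r$r_squared, tolerance = 1e-10)
  }
  expect_error(lmg_decomposition(y[1:3], X[1:3, ]), "at least 5")
  Xd <- cbind(X[, 1], X[, 1], X[, 2])
  expect_error(lmg_decomposition(y, Xd), "rank")
})

test_that("the pipeline attributes gene flow and ILS to the right nodes", {
  # one introgression edge (E -> C) and one short high-ILS branch (A,B)
  sp9 <- ape::read.tree(
    text = "(((((A:0.2,B:0.2):0.2,C:0.4):2,D:2.4):2,E:4.4):1,O:5.4);")
  hits_ret <- 0L; hits_theta <- 0L
  n_seed <- 3
  for (s in seq_len(n_seed)) {
    obs <- simulate_gene_trees_msc(sp9, 1000, seed = 400 + s,
      introgression = list(donor = "E", recipient = "C", gamma = 0.3))
    nul <- simulate_gene_trees_msc(sp9, 1000, seed = 500 + s)
    ri <- reticulation_index(sp9, obs, nul, max_comb = 25, seed = s)
    node_c <- ape::getMRCA(sp9, c("A", "B", "C"))
    if (ri$node[which.max(ri$reticulation_index)] == node_c)
      hits_ret <- hits_ret + 1L
    # theta per node: identical mutation rate, so the shortest
    # coalescent branch carries the largest theta
    supp <- bipartition_support(sp9, obs)
    clen <- stats::setNames(sp9$edge.length, sp9$edge[, 2])
    theta <- estimate_theta(0.01, clen[as.character(supp$node)])
    node_ab <- ape::getMRCA(sp9, c("A", "B"))
    if (supp$node[which.max(theta)] == node_ab) hits_theta <- hits_theta + 1L
  }
  expect_equal(hits_ret, n_seed)
  expect_equal(hits_theta, n_seed)
})
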