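test_that("allele-sharing distance follows the multiset-intersection rule", {
  p <- c(M1 = "AA"); q <- c(M1 = "AT"); r <- c(M1 = "TT")
  expect_equal(allele_sharing_distance(p, p), 0)
  expect_equal(allele_sharing_distance(p, r), 1)
  expect_equal(allele_sharing_distance(p, q), 0.5)  # {A,A} n {A,T} = {A}
  expect_equal(allele_sharing_distance(q, q), 0)
  # chimeric tokens contribute their union allele set as a heterozygote
  expect_equal(allele_sharing_distance(c(M1 = "CC~CT"), c(M1 = "CT")), 0)
  expect_equal(allele_sharing_distance(c(M1 = "CC~CT"), c(M1 = "CC")), 0.5)
  # multi-locus mean
  a <- c(M1 = "AA", M2 = "CC"); b <- c(M1 = "AT", M2 = "CC")
  expect_equal(allele_sharing_distance(a, b), 0.25)
  expect_error(allele_sharing_distance(p, c(M2 = "AA")), "different marker")
})

test_that("distance matrices are bounded symmetric premetrics", {
  sim <- generate_panel(panel_sim_config(seed = 7))
  cls <- group_profiles(sim$panel)
  dm <- class_distance_matrix(cls, reference = default_reference_profile())
  expect_true(all(dm >= 0 & dm <= 1))
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  expect_true("REF" %in% rownames(dm))
  # off-diagonal distances positive for distinct profiles
  expect_true(all(dm[upper.tri(dm)] > 0))
})

test_that("UPGMA reproduces the hand-computed three-taxon dendrogram", {
  dm <- matrix(c(0, 0.2, 0.6, 0.2, 0, 0.6, 0.6, 0.6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  phy <- upgma_tree(dm)
  clades <- attr(phy, "clades")
  expect_equal(clades[[1]]$labels, c("A", "B"))
  expect_equal(clades[[1]]$height, 0.1)
  expect_equal(clades[[2]]$height, 0.3)
  expect_true(ape::is.ultrametric(phy))
})

test_that("equal distances resolve by the lexicographic tie-break, staying ultrametric", {
  dm <- matrix(0.4, 4, 4, dimnames = list(c("D", "B", "C", "A"),
                                          c("D", "B", "C", "A")))
  diag(dm) <- 0
  phy <- upgma_tree(dm)
  clades <- attr(phy, "clades")
  expect_equal(clades[[1]]$labels, c("A", "B"))   # smallest label pair first
  expect_true(ape::is.ultrametric(phy))
  expect_equal(max(vapply(clades, `[[`, 0, "height")), 0.2)
})

test_that("UPGMA recovers the generating hierarchy of ultrametric matrices", {
  set.seed(12)
  for (rep in 1:10) {
    # random ultrametric via a random tree with accumulated heights
    n <- 6
    labs <- paste0("t", 1:n)
    merge_h <- sort(runif(n - 1, 0.05, 0.5))
    groups <- as.list(labs)
    dm <- matrix(0, n, n, dimnames = list(labs, labs))
    for (h in merge_h) {
      i <- sample(length(groups), 2)
      for (x in groups[[i[1]]]) for (y in groups[[i[2]]]) {
        dm[x, y] <- dm[y, x] <- 2 * h
      }
      groups <- c(groups[-i], list(c(groups[[i[1]]], groups[[i[2]]])))
    }
    phy <- upgma_tree(dm)
    # cophenetic distances of the rebuilt tree reproduce the input matrix
    coph <- ape::cophenetic.phylo(phy)[labs, labs]
    expect_equal(coph, dm, tolerance = 1e-8)
  }
})

test_that("UPGMA topology matches the reference average-linkage implementation", {
  skip_if_not_installed("phangorn")
  set.seed(5)
  for (rep in 1:5) {
    p <- matrix(runif(49), 7)
    p <- (p + t(p)) / 2
    diag(p) <- 0
    dimnames(p) <- list(letters[1:7], letters[1:7])
    t1 <- upgma_tree(p)
    t2 <- phangorn::upgma(stats::as.dist(p))
    expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap supports match analytic resampling probabilities", {
  # two classes differing at every locus: the split is certain
  prof2 <- rbind(X = rep("AA", 10), Y = rep("TT", 10))
  colnames(prof2) <- paste0("L", 1:10)
  prof3 <- rbind(prof2, Z = rep("GG", 10))
  b3 <- bootstrap_support(prof3, n_reps = 200, seed = 2)
  expect_equal(unname(b3$support[["X,Y,Z"]]), 1)

  # a cherry supported by exactly one locus in ten: recovered iff the
  # locus is resampled, P = 1 - 0.9^10 ~ 0.651; ties without the locus
  # fall to the lexicographic pair (C1, C2), not the cherry (C2, C3)
  prof <- rbind(C1 = c("TT", "AA", "TT", "GG", "AA", "TT", "GG", "AA", "TT", "GG"),
                C2 = c("AA", "CC", "AA", "CC", "TT", "AA", "CC", "TT", "AA", "CC"),
                C3 = c("AA", "GG", "CC", "TT", "GG", "CC", "TT", "GG", "CC", "TT"))
  colnames(prof) <- paste0("L", 1:10)
  b <- bootstrap_support(prof, n_reps = 1000, seed = 9)
  expect_lt(abs(b$support[["C2,C3"]] - (1 - 0.9^10)), 0.05)

  # determinism under a fixed seed
  b2 <- bootstrap_support(prof, n_reps = 200, seed = 4)
  b2b <- bootstrap_support(prof, n_reps = 200, seed = 4)
  expect_identical(b2$support, b2b$support)
})

test_that("the NJ alternative runs on the same distances", {
  sim <- generate_panel(panel_sim_config(seed = 7))
  cls <- group_profiles(sim$panel)
  nj <- genotype_tree(cls, method = "nj")
  expect_s3_class(nj, "phylo")
  expect_equal(sort(nj$tip.label), sort(vapply(cls$classes, `[[`, "", "label")))
})

test_that("median-joining networks cover the textbook cases", {
  # two profiles one step apart: a single edge, no medians
  p2 <- rbind(A = c("AA", "CC"), B = c("AT", "CC"))
  colnames(p2) <- c("m1", "m2")
  net2 <- median_joining_network(p2)
  expect_equal(nrow(net2$nodes), 2)
  expect_equal(nrow(net2$edges), 1)
  expect_equal(net2$edges$loci, "m1")

  # three profiles around an unobserved centre: one median of degree 3
  p3 <- rbind(X = c("T", "A", "A"), Y = c("A", "T", "A"), Z = c("A", "A", "T"))
  colnames(p3) <- paste0("m", 1:3)
  net3 <- median_joining_network(p3)
  expect_equal(sum(!net3$nodes$observed), 1)
  med <- net3$nodes$name[!net3$nodes$observed]
  expect_equal(sum(net3$edges$from == med | net3$edges$to == med), 3)
  expect_equal(unname(unlist(net3$nodes[!net3$nodes$observed,
                                        paste0("m", 1:3)])),
               c("A", "A", "A"))
})

test_that("the default-panel network is connected, complete and MST-bearing", {
  sim <- generate_panel(panel_sim_config(seed = 7))
  cls <- group_profiles(sim$panel)
  net <- median_joining_network(cls)
  g <- net$graph
  expect_true(igraph::is_connected(g))
  labels <- vapply(cls$classes, `[[`, "", "label")
  expect_true(all(labels %in% net$nodes$name))
  expect_gte(nrow(net$edges), 6)
  # observed node frequencies carry class sizes
  expect_equal(net$nodes$frequency[match(labels, net$nodes$name)],
               unname(class_counts(cls)))
  # the network embeds a minimum spanning tree of the observed profiles:
  # every MST edge is realised as a shortest path of equal total length
  prof <- clonotyper:::class_profile_matrix(cls)
  D <- clonotyper:::hamming_matrix(prof)
  cg <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                            weighted = TRUE)
  mst <- igraph::mst(cg)
  dd <- igraph::distances(g, weights = igraph::E(g)$weight)
  for (e in seq_len(igraph::ecount(mst))) {
    ends <- igraph::ends(mst, e)
    expect_lte(dd[ends[1], ends[2]], D[ends[1], ends[2]])
  }
})
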