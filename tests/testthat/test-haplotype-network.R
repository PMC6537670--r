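# Haplotype collapsing, the median-joining construction, the exhaustive
# oracle and haplogroup partitioning.

test_that("collapsing merges identical rows and drops constant sites", {
  sim <- simulateHaplotypes(twoHaplogroupTree(), seed = 4)
  ht <- collapseHaplotypes(sim$gm)
  expect_equal(nrow(haploMatrix(ht)), 7L)   # 8 samples, one shared pair
  expect_equal(sum(haploMultiplicity(ht)), 8L)
  shared <- haploMembers(ht)[[which(haploMultiplicity(ht) == 2L)]]
  expect_setequal(shared, c("WC214", "WC218"))

  m <- rbind(A = c(0L, 1L, 1L), B = c(0L, 1L, 1L), C = c(0L, 1L, 1L))
  ht1 <- collapseHaplotypes(m)
  expect_equal(nrow(haploMatrix(ht1)), 1L)
  expect_equal(length(droppedConstantSites(ht1)), 3L)  # all constant

  m3 <- rbind(A = c(1L, 0L, 0L), B = c(0L, 1L, 0L), C = c(0L, 0L, 1L))
  expect_equal(nrow(haploMatrix(collapseHaplotypes(m3))), 3L)

  expect_error(collapseHaplotypes(m[0, ]), "empty")
  m[1, 1] <- NA
  expect_error(collapseHaplotypes(m), "missing")
})

test_that("two haplotypes give a single edge and no medians", {
  m <- rbind(A = c(1L, 1L, 1L, 1L, 1L), B = c(0L, 0L, 0L, 0L, 0L))
  net <- medianJoining(collapseHaplotypes(m))
  expect_equal(networkLength(net), 5)
  ed <- networkEdges(net)
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$length, 5)
  expect_equal(sum(networkNodes(net)$isMedian), 0L)
  # trivially identical to the oracle
  orc <- networkOracle(collapseHaplotypes(m))
  expect_equal(networkLength(orc), networkLength(net))
})

test_that("a three-tip star resolves to the Steiner median", {
  sim <- simulateHaplotypes(starTree(c(A = 13, B = 14, C = 15)), seed = 2)
  ht <- collapseHaplotypes(sim$gm)
  net <- medianJoining(ht)
  nd <- networkNodes(net)
  expect_equal(sum(nd$isMedian), 1L)
  expect_equal(networkLength(net), 42)
  ed <- networkEdges(net)
  expect_setequal(ed$length, c(13, 14, 15))
  # exhaustive check: no intermediate vector does better
  expect_equal(networkLength(networkOracle(ht)), 42)
})

test_that("the demonstration network reproduces the published topology scale", {
  sim <- simulateHaplotypes(twoHaplogroupTree(), seed = 6)
  ht <- collapseHaplotypes(sim$gm)
  net <- medianJoining(ht)
  expect_equal(networkLength(net), 590)
  # the introgressed wild sample sits 12 mutations from the domestic-side
  # median node
  hap <- names(Filter(function(v) "WC305" %in% v, haploMembers(ht)))
  ed <- networkEdges(net)
  touch <- ed[ed$from == hap | ed$to == hap, ]
  expect_equal(nrow(touch), 1L)
  expect_equal(touch$length, 12)
  other <- setdiff(unlist(touch[, c("from", "to")]), hap)
  expect_true(networkNodes(net)$isMedian[networkNodes(net)$node == other])
})

test_that("path lengths equal Hamming distances on infinite-sites data", {
  for (seed in 1:8) {
    tree <- randomTipTree(nTips = sample(4:7, 1), seed = seed)
    sim <- simulateHaplotypes(tree, seed = seed + 50)
    ht <- collapseHaplotypes(sim$gm)
    net <- medianJoining(ht)
    g <- networkGraph(net)
    obs <- rownames(haploMatrix(ht))
    d <- igraph::distances(g, v = obs, to = obs, weights = igraph::E(g)$weight)
    hm <- as.matrix(dist(haploMatrix(ht), method = "manhattan"))
    expect_equal(unname(d[obs, obs]), unname(hm[obs, obs]))
    # tree-like data: medians never exceed observed count minus 2
    expect_lte(sum(networkNodes(net)$isMedian), nrow(haploMatrix(ht)) - 2L)
    # network length never exceeds a spanning tree over observed haplotypes
    expect_lte(networkLength(net), msynet:::.primLength(hm))
  }
})

test_that("oracle length equals the generating tree total on sampled-tip trees", {
  for (seed in 1:10) {
    tree <- randomTipTree(nTips = 5, seed = seed + 300)
    sim <- simulateHaplotypes(tree, seed = seed + 400)
    ht <- collapseHaplotypes(sim$gm)
    orc <- networkOracle(ht)
    mj <- medianJoining(ht)
    # every simulated mutation lies on the path to some tip, so the Steiner
    # minimum equals the sum of tree edges above sampled tips
    expect_equal(networkLength(orc), networkLength(mj))
    expect_lte(networkLength(orc), treeTotal(tree))
  }
})

test_that("oracle enforces its size limits", {
  big <- setNames(rep(2L, 13), paste0("T", 1:13))
  ht13 <- collapseHaplotypes(simulateHaplotypes(starTree(big), seed = 1)$gm)
  expect_error(networkOracle(ht13), "12 haplotypes")
  wide <- setNames(rep(13L, 5), paste0("T", 1:5))
  htWide <- collapseHaplotypes(simulateHaplotypes(starTree(wide), seed = 1)$gm)
  expect_error(networkOracle(htWide), "64 sites")
})

test_that("relabeling haplotypes yields an isomorphic network", {
  sim <- simulateHaplotypes(twoHaplogroupTree(), seed = 8)
  m <- t(assay(sim$gm, "gt"))
  net1 <- medianJoining(collapseHaplotypes(m))
  set.seed(1)
  net2 <- medianJoining(collapseHaplotypes(m[sample(nrow(m)), ]))
  expect_equal(networkLength(net1), networkLength(net2))
  expect_equal(sort(networkEdges(net1)$length), sort(networkEdges(net2)$length))
  expect_equal(sort(igraph::degree(networkGraph(net1))),
               sort(igraph::degree(networkGraph(net2))),
               ignore_attr = TRUE)
})

test_that("haplogroup assignment cuts the longest edge between seeds", {
  # two-node network: the only edge is the split
  m <- rbind(A = c(1L, 1L, 0L), B = c(0L, 0L, 1L))
  net <- medianJoining(collapseHaplotypes(m))
  hg <- assignHaplogroups(net, c(H1 = "X", H2 = "Y"))
  expect_equal(sort(unlist(hg$splitEdge[, c("from", "to")]), method = "radix"),
               c("H1", "H2"), ignore_attr = TRUE)
  expect_equal(unname(hg$labels[c("H1", "H2")]), c("X", "Y"))

  # demonstration fixture: the introgressed wild sample lands in the
  # domestic haplogroup
  sim <- simulateHaplotypes(twoHaplogroupTree(), seed = 10)
  ht <- collapseHaplotypes(sim$gm)
  netd <- medianJoining(ht)
  hapOf <- function(s) names(Filter(function(v) s %in% v, haploMembers(ht)))
  hg2 <- assignHaplogroups(netd, setNames(c("D", "W"),
                                          c(hapOf("DC116"), hapOf("WC101"))))
  expect_equal(unname(hg2$labels[hapOf("WC305")]), "D")
  expect_equal(hg2$splitEdge$length, 530)
  nd <- networkNodes(hg2$network)
  expect_equal(length(unique(na.omit(nd$haplogroup))), 2L)
})

test_that("equal candidate cut edges raise a tie error", {
  sim <- simulateHaplotypes(starTree(c(A = 5, B = 5, C = 5)), seed = 3)
  net <- medianJoining(collapseHaplotypes(sim$gm))
  expect_error(assignHaplogroups(net, c(H1 = "X", H2 = "Y")), "tie")
})
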