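# Depth normalization, the Poisson window classifier, contig cleanup and
# assembly statistics.

test_that("normalization scales each sample to mean 1 and honours exclusions", {
  depth <- cbind(S1 = c(10, 30), S2 = c(1, 3), S3 = c(5, 5), DC269 = c(8, 2))
  wdt <- rawTable(depth, sex = c("male", "male", "female", "male"))
  norm <- normalizeDepths(wdt, exclude = "DC269")
  nm <- assay(norm, "depth")
  expect_false("DC269" %in% colnames(nm))
  # constant-depth sample: exactly 1 everywhere
  expect_equal(unname(nm[, "S3"]), c(1, 1))
  # scale invariance: (10,30) and (1,3) normalize identically
  expect_equal(unname(nm[, "S1"]), c(0.5, 1.5))
  expect_equal(unname(nm[, "S1"]), unname(nm[, "S2"]))
  expect_equal(unname(norm$meanDepth), c(20, 2, 5))
})

test_that("zero-total samples are rejected by name", {
  depth <- cbind(S1 = c(1, 2), DEAD = c(0, 0), F1 = c(1, 1))
  wdt <- rawTable(depth, sex = c("male", "male", "female"))
  expect_error(normalizeDepths(wdt), "DEAD")
})

test_that("classifier matches direct evaluation of the three class likelihoods", {
  # normalized male/female depths per window; sample means fixed at 20
  norm <- rbind(c(1.0, 1.0), c(0.5, 0.02), c(1.5, 0.02), c(2.0, 0.02))
  colnames(norm) <- c("M1", "F1")
  nt <- normTable(norm, sex = c("male", "female"), meanDepth = 20)
  cls <- classifyWindows(nt, epsilon = 0.02)
  expect_equal(as.character(cls$class), c("nonMSY", "scY", "mcY", "mcY"))
  expect_equal(cls$copyNumber[3], 3L)  # 0.5k closest at k = 3
  expect_equal(cls$copyNumber[4], 4L)
  # independent likelihood oracle for the scY window: ll(class) =
  # sum_s d log(r) - r on normalized depths
  d <- norm[2, ]
  ll <- function(rm, rf) {
    lam <- c(rm, rf)
    sum(d * log(lam) - lam)
  }
  expect_equal(unname(cls$llScY[2]), ll(0.5, 0.02))
  expect_equal(unname(cls$llNonMSY[2]), ll(1, 1))
  expect_gt(cls$llScY[2], max(cls$llMcY[2], cls$llNonMSY[2]))
})

test_that("all-zero windows get the no-call sentinel", {
  norm <- rbind(c(1, 1), c(0, 0))
  colnames(norm) <- c("M1", "F1")
  nt <- normTable(norm, sex = c("male", "female"))
  cls <- suppressMessages(classifyWindows(nt))
  expect_equal(as.character(cls$class), c("nonMSY", "nocall"))
})

test_that("assignments are invariant to rescaling one sample's raw depths", {
  tpl <- simulateTemplate(nContigs = 10, seed = 21)
  ch <- demoCohort(10)
  wdt <- simulateDepths(tpl, ch, seed = 21)
  cls1 <- classifyWindows(normalizeDepths(wdt))
  wdt2 <- wdt
  assays(wdt2)$depth[, "WC101"] <- assay(wdt, "depth")[, "WC101"] * 7.3
  cls2 <- classifyWindows(normalizeDepths(wdt2))
  expect_identical(as.character(cls1$class), as.character(cls2$class))
})

test_that("window class recovery exceeds 95% on a sexed 10x cohort", {
  tpl <- simulateTemplate(nContigs = 30, meanLength = 3000, seed = 31)
  ch <- demoCohort(10)  # 8 males, 6 females
  wdt <- simulateDepths(tpl, ch, femaleLeak = 0.02, seed = 31)
  cls <- classifyWindows(normalizeDepths(wdt, exclude = "DC269"))
  acc <- mean(as.character(cls$class) == rowData(wdt)$trueClass)
  expect_gte(acc, 0.95)
})

test_that("contig cleanup applies both thresholds and merges intervals", {
  mk <- function(contig, starts, classes, width = 50) {
    GRanges(contig, IRanges(starts, width = width),
            class = factor(classes, c("scY", "mcY", "nonMSY", "nocall")))
  }
  # 150-bp contig, 100% scY -> discarded (too short)
  # 300-bp contig, 40% Y -> discarded (content below 50%)
  # 1000-bp contig, windows sc,sc,non,sc -> kept; scY rows [0,100) and [150,200)
  cls <- suppressWarnings(
    c(mk("short", c(1, 51, 101), rep("scY", 3)),
      mk("lowY", c(1, 51, 101, 151, 201), c("scY", "scY", rep("nonMSY", 3))),
      mk("good", c(1, 51, 101, 151), c("scY", "scY", "nonMSY", "scY"))))
  lens <- c(short = 150, lowY = 300, good = 1000)
  res <- cleanContigs(cls, lens, minLength = 200, minFraction = 0.5)
  rep <- res$report
  expect_equal(rep$kept[match(c("short", "lowY", "good"), rep$contig)],
               c(FALSE, FALSE, TRUE))
  expect_equal(rep$yFraction[match("lowY", rep$contig)], 0.4)
  scy <- res$scY
  expect_equal(as.character(seqnames(scy)), c("good", "good"))
  expect_equal(start(scy) - 1L, c(0L, 150L))   # BED coordinates
  expect_equal(end(scy), c(100L, 200L))
  # intervals disjoint, sorted, within bounds; total bp = 50 * kept scY windows
  expect_true(all(diff(start(scy)) > 0))
  expect_equal(sum(width(scy)), 50 * 3)
  # unknown contig -> error
  expect_error(cleanContigs(mk("ghost", 1, "scY"), lens), "ghost")
})

test_that("no-call windows count against Y-specific content", {
  gr <- GRanges("c1", IRanges(c(1, 51, 101, 151), width = 50),
                class = factor(c("scY", "scY", "nocall", "nocall"),
                               c("scY", "mcY", "nonMSY", "nocall")))
  res <- cleanContigs(gr, c(c1 = 500), minFraction = 0.6)
  expect_false(res$report$kept)  # 2/4 = 50% < 60%
})

test_that("assembly statistics match hand-computed answers", {
  expect_equal(unlist(assemblyStats(1000)), c(totalBp = 1000, nContigs = 1, n50 = 1000))
  expect_equal(assemblyStats(c(500, 300, 200))$n50, 500)
  expect_equal(assemblyStats(c(400, 300, 300))$n50, 300)
  expect_error(assemblyStats(numeric()), "empty")
  expect_error(assemblyStats(c(10, -1)), "positive")
})
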