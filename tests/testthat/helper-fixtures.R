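# Shared fixture builders. Everything is generated in code; no data files.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

# hand-built template: one contig, segments with known classes
toyTemplate <- function() {
  gr <- GRanges(
    c("c1", "c1", "c1", "c2"),
    IRanges(c(1, 501, 801, 1), c(500, 800, 1200, 600)),
    copyClass = factor(c("scY", "mcY", "nonMSY", "nonMSY"),
                       c("scY", "mcY", "nonMSY")),
    copyNumber = c(1L, 4L, 1L, 1L),
    seqinfo = Seqinfo(c("c1", "c2"), c(1200L, 600L)))
  genomeTemplate(gr)
}

# a normalized WindowDepthTable built directly from a matrix of
# normalized depths (rows = windows, cols = samples)
normTable <- function(norm, sex, meanDepth = 20) {
  windows <- GRanges("c1", IRanges(seq_len(nrow(norm)) * 50 - 49, width = 50),
                     seqinfo = Seqinfo("c1", nrow(norm) * 50L))
  se <- SummarizedExperiment(
    assays = list(depth = norm), rowRanges = windows,
    colData = DataFrame(sex = sex,
                        meanDepth = rep(meanDepth, length.out = ncol(norm)),
                        row.names = colnames(norm)))
  metadata(se)$normalized <- TRUE
  new("WindowDepthTable", se)
}

# raw table from a depth matrix over 50-bp windows
rawTable <- function(depth, sex) {
  windows <- GRanges("c1", IRanges(seq_len(nrow(depth)) * 50 - 49, width = 50),
                     seqinfo = Seqinfo("c1", nrow(depth) * 50L))
  se <- SummarizedExperiment(
    assays = list(depth = depth), rowRanges = windows,
    colData = DataFrame(sex = sex, row.names = colnames(depth)))
  metadata(se)$normalized <- FALSE
  new("WindowDepthTable", se)
}

# in-memory VCF record structure (what readVcfGeno returns)
makeRecords <- function(pos, ref, alt, gt, dp = NULL, gq = NULL, chrom = "c1") {
  n <- length(pos)
  if (is.null(dp)) dp <- matrix(30, n, ncol(gt), dimnames = dimnames(gt))
  if (is.null(gq)) gq <- matrix(99, n, ncol(gt), dimnames = dimnames(gt))
  list(sites = data.frame(chrom = rep(chrom, n), pos = pos, ref = ref, alt = alt,
                          stringsAsFactors = FALSE),
       gt = gt, dp = dp, gq = gq, samples = colnames(gt))
}

# an scY BED covering a whole contig
fullScy <- function(chrom = "c1", len = 1e6) {
  GRanges(chrom, IRanges(1, len), seqinfo = Seqinfo(chrom, as.integer(len)))
}

# random tree-like instance: random topology, every edge >= 1 mutation,
# samples only on tips (internal nodes are unobserved Steiner points)
randomTipTree <- function(nTips, seed, maxEdge = 6, nInternalMax = 2) {
  set.seed(seed)
  nodes <- "root"
  parent <- c(root = NA_character_)
  for (i in seq_len(sample(0:nInternalMax, 1L))) {
    id <- paste0("I", i)
    parent[id] <- sample(nodes, 1L)
    nodes <- c(nodes, id)
  }
  tips <- paste0("T", seq_len(nTips))
  for (tp in tips) parent[tp] <- sample(nodes, 1L)
  muts <- setNames(sample.int(maxEdge, length(parent) - 1L, replace = TRUE),
                   setdiff(names(parent), "root"))
  treeSpec(parent, mutations = muts,
           tipSamples = setNames(as.list(tips), tips))
}

# path-sum distance between two nodes of a TreeSpec (additivity oracle)
treeDist <- function(tree, a, b) {
  lineage <- function(n) {
    path <- n
    while (!is.na(tree@parent[[n]])) { n <- tree@parent[[n]]; path <- c(path, n) }
    path
  }
  pa <- lineage(a); pb <- lineage(b)
  mrca <- intersect(pa, pb)[1L]
  up <- function(p) {
    keep <- seq_len(match(mrca, p) - 1L)
    sum(tree@mutations[p[keep]])
  }
  up(pa) + up(pb)
}

# GenotypeMatrix from a samples x sites 0/1/NA matrix
gmFromMatrix <- function(m) {
  gt <- t(m)
  mode(gt) <- "integer"
  sites <- GRanges("c1", IRanges(seq_len(ncol(m)), width = 1L),
                   ref = "A", alt = "G")
  names(sites) <- paste0("c1:", seq_len(ncol(m)))
  rownames(gt) <- names(sites)
  se <- SummarizedExperiment(
    assays = list(gt = gt), rowRanges = sites,
    colData = DataFrame(outgroup = rep(FALSE, nrow(m)),
                        row.names = rownames(m)))
  new("GenotypeMatrix", se)
}

# total mutation count of a TreeSpec
treeTotal <- function(tree) sum(tree@mutations, na.rm = TRUE)
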