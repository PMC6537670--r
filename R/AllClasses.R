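#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges findOverlaps pintersect reduce seqnames start end width tileGenome
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlevels seqnames<- Seqinfo
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assays<- rowRanges colData rowData rowData<-
#' @importFrom BiocGenerics sort
#' @importFrom stats rpois rexp dist hclust cutree as.dist setNames
#' @importFrom utils read.table write.table head tail
NULL

#' GenomeTemplate: a labeled MSY genome template
#'
#' Holds contigs and a tiling of each contig into segments labeled with a
#' copy class: `scY` (single-copy Y), `mcY` (multi-copy Y, with an integer
#' copy number >= 2) or `nonMSY` (not Y-specific, i.e. autosome/X-like).
#' The template is the ground truth behind depth simulation and window
#' classification recovery tests.
#'
#' @slot segments A [GenomicRanges::GRanges] with complete seqlengths whose
#'   ranges tile every contig without gap or overlap, carrying metadata
#'   columns `copyClass` (factor: scY/mcY/nonMSY) and `copyNumber` (integer;
#'   1 for scY, >= 2 for mcY, NA allowed for nonMSY).
#' @exportClass GenomeTemplate
setClass("GenomeTemplate", representation(segments = "GRanges"))

.validGenomeTemplate <- function(object) {
  gr <- object@segments
  msg <- character()
  if (length(gr) == 0L) msg <- c(msg, "template has no segments")
  if (!all(c("copyClass", "copyNumber") %in% names(mcols(gr))))
    msg <- c(msg, "segments need 'copyClass' and 'copyNumber' metadata columns")
  else {
    cc <- as.character(gr$copyClass)
    if (!all(cc %in% c("scY", "mcY", "nonMSY")))
      msg <- c(msg, "copyClass must be one of scY, mcY, nonMSY")
    if (any(cc == "scY" & gr$copyNumber != 1L))
      msg <- c(msg, "scY segments must have copyNumber 1")
    if (any(cc == "mcY" & (is.na(gr$copyNumber) | gr$copyNumber < 2L)))
      msg <- c(msg, "mcY segments must have copyNumber >= 2")
  }
  sl <- seqlengths(gr)
  if (any(is.na(sl))) msg <- c(msg, "all contigs must have known lengths")
  else {
    for (ctg in seqlevels(gr)) {
      seg <- gr[as.character(seqnames(gr)) == ctg]
      seg <- seg[order(start(seg))]
      if (length(seg) == 0L) { msg <- c(msg, paste0("contig ", ctg, " has no segments")); next }
      ok <- start(seg)[1L] == 1L && end(seg)[length(seg)] == sl[[ctg]] &&
        (length(seg) == 1L || all(start(seg)[-1L] == end(seg)[-length(seg)] + 1L))
      if (!ok) msg <- c(msg, paste0("segments do not tile contig ", ctg))
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("GenomeTemplate", .validGenomeTemplate)

#' WindowDepthTable: per-sample mean read depth on fixed-width windows
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] with one assay,
#' `depth` (windows x samples, nonnegative), `colData` columns `sex`
#' ("male"/"female") and, after [normalizeDepths()], `meanDepth` (the
#' genome-wide mean raw window depth used as the normalizer).
#' `metadata()$normalized` records whether the assay holds raw or
#' per-sample-normalized values. Simulated tables carry the true copy class
#' per window in `rowData()$trueClass`.
#'
#' @exportClass WindowDepthTable
setClass("WindowDepthTable", contains = "RangedSummarizedExperiment")

.validWindowDepthTable <- function(object) {
  msg <- character()
  if (!"depth" %in% names(assays(object))) msg <- c(msg, "assay 'depth' required")
  else if (any(assay(object, "depth") < 0)) msg <- c(msg, "depths must be nonnegative")
  if (!"sex" %in% names(colData(object))) msg <- c(msg, "colData column 'sex' required")
  else if (!all(object$sex %in% c("male", "female")))
    msg <- c(msg, "sex must be 'male' or 'female'")
  if (length(msg)) msg else TRUE
}
setValidity("WindowDepthTable", .validWindowDepthTable)

#' GenotypeMatrix: haploid biallelic genotypes with per-cell DP and GQ
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] over single-base
#' sites (rowRanges width 1, with `ref` and `alt` metadata columns) and
#' samples. Assays: `gt` (integer; 0 = REF, 1 = ALT, NA = missing), and
#' optionally `dp` (read depth) and `gq` (genotype quality) retained for
#' audit. `colData()$outgroup` flags outgroup samples whose genotypes are
#' carried but excluded from ingroup-only determinations.
#'
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

.validGenotypeMatrix <- function(object) {
  msg <- character()
  if (!"gt" %in% names(assays(object))) msg <- c(msg, "assay 'gt' required")
  else {
    gt <- assay(object, "gt")
    if (!all(gt %in% c(0L, 1L, NA))) msg <- c(msg, "gt cells must be 0, 1 or NA")
  }
  rr <- rowRanges(object)
  if (length(rr) && !all(width(rr) == 1L)) msg <- c(msg, "sites must be single-base")
  if (length(rr) && !all(c("ref", "alt") %in% names(mcols(rr))))
    msg <- c(msg, "rowRanges need 'ref' and 'alt' metadata columns")
  if (length(msg)) msg else TRUE
}
setValidity("GenotypeMatrix", .validGenotypeMatrix)

#' TreeSpec: a rooted tree with per-edge mutation counts
#'
#' Encodes the simulation tree as parent links. Each non-root node has a
#' parent and a nonnegative integer mutation count on the edge to its
#' parent (either given directly, or derived as Poisson draws from per-edge
#' durations in generations together with `mu` and `nSites`). Tips may carry
#' one or more sample ids (two samples on one tip share a haplotype).
#'
#' @slot nodes Character vector of node ids (root first is not required).
#' @slot parent Named character; `parent[node]` is the parent id, NA for the root.
#' @slot mutations Named integer; mutations on the edge above each non-root node.
#' @slot durations Named numeric or empty; edge durations in generations.
#' @slot tipSamples Named list; `tipSamples[[tip]]` is a character vector of sample ids.
#' @exportClass TreeSpec
setClass("TreeSpec", representation(
  nodes = "character", parent = "character", mutations = "integer",
  durations = "numeric", tipSamples = "list"))

.validTreeSpec <- function(object) {
  msg <- character()
  nodes <- object@nodes
  if (anyDuplicated(nodes)) msg <- c(msg, "duplicate node ids")
  p <- object@parent[nodes]
  root <- nodes[is.na(p)]
  if (length(root) != 1L) msg <- c(msg, "tree must have exactly one root")
  if (!all(p[!is.na(p)] %in% nodes)) msg <- c(msg, "parent links point outside the node set")
  if (any(object@mutations < 0L, na.rm = TRUE)) msg <- c(msg, "negative mutation count")
  # acyclicity / connectivity: every node must reach the root
  if (length(root) == 1L) {
    for (nd in nodes) {
      seen <- character(); cur <- nd
      while (!is.na(p[cur])) {
        if (cur %in% seen) { msg <- c(msg, "cycle in parent links"); break }
        seen <- c(seen, cur); cur <- p[[cur]]
      }
    }
  }
  samp <- unlist(object@tipSamples, use.names = FALSE)
  if (anyDuplicated(samp)) msg <- c(msg, "a sample id is mapped to two tips")
  if (length(msg)) unique(msg) else TRUE
}
setValidity("TreeSpec", .validTreeSpec)

#' HaplotypeTable: distinct haplotypes with multiplicities
#'
#' @slot haplo Integer matrix (haplotypes x segregating sites; 0/1), rows
#'   named by haplotype id, columns by site id.
#' @slot multiplicity Named integer; samples carrying each haplotype.
#' @slot members Named list; sample ids per haplotype.
#' @slot droppedConstant Character; site ids dropped as constant across all
#'   samples (they cannot separate haplotypes; the count is kept so diversity
#'   denominators remain the full sequence length).
#' @exportClass HaplotypeTable
setClass("HaplotypeTable", representation(
  haplo = "matrix", multiplicity = "integer", members = "list",
  droppedConstant = "character"))

.validHaplotypeTable <- function(object) {
  msg <- character()
  h <- object@haplo
  if (anyDuplicated(apply(h, 1L, paste, collapse = ""))) msg <- c(msg, "haplotype rows must be distinct")
  if (length(object@multiplicity) != nrow(h)) msg <- c(msg, "multiplicity length mismatch")
  if (any(is.na(h))) msg <- c(msg, "haplotypes must not contain missing calls")
  if (length(msg)) msg else TRUE
}
setValidity("HaplotypeTable", .validHaplotypeTable)

#' HaploNetwork: a haplotype network with mutation-labeled edges
#'
#' Nodes are observed haplotypes plus inferred median vectors (multiplicity
#' 0); each edge carries the set of sites that mutate on it, so edge length
#' equals the size of that set. For homoplasy-free data the network is a
#' tree and path lengths equal Hamming distances.
#'
#' @slot graph An [igraph::graph] with vertex attributes `name`, `isMedian`,
#'   `multiplicity`, `haplogroup` and edge attributes `weight` and `sites`
#'   (list of site-id vectors).
#' @slot vectors Integer matrix of node allele vectors (nodes x sites).
#' @slot members Named list of sample ids per observed node.
#' @slot totalLength Numeric; minimum spanning length over the node set.
#' @exportClass HaploNetwork
setClass("HaploNetwork", representation(
  graph = "ANY", vectors = "matrix", members = "list", totalLength = "numeric"))

.validHaploNetwork <- function(object) {
  msg <- character()
  g <- object@graph
  if (!igraph::is_igraph(g)) msg <- c(msg, "graph slot must be an igraph object")
  else {
    if (igraph::vcount(g) > 1L && !igraph::is_connected(g)) msg <- c(msg, "network must be connected")
    if (igraph::ecount(g) > 0L && any(igraph::E(g)$weight < 1)) msg <- c(msg, "edges must mutate at least one site")
    if (!setequal(igraph::V(g)$name, rownames(object@vectors))) msg <- c(msg, "vectors/graph node mismatch")
  }
  if (length(msg)) msg else TRUE
}
setValidity("HaploNetwork", .validHaploNetwork)

setMethod("show", "GenomeTemplate", function(object) {
  gr <- object@segments
  cc <- table(factor(gr$copyClass, c("scY", "mcY", "nonMSY")))
  bp <- tapply(width(gr), factor(gr$copyClass, c("scY", "mcY", "nonMSY")), sum)
  bp[is.na(bp)] <- 0
  cat("GenomeTemplate:", length(seqlevels(gr)), "contigs,",
      sum(seqlengths(gr)), "bp\n")
  for (k in names(cc))
    cat(sprintf("  %-6s %3d segments, %d bp\n", k, cc[[k]], bp[[k]]))
})

setMethod("show", "WindowDepthTable", function(object) {
  cat("WindowDepthTable:", nrow(object), "windows x", ncol(object), "samples",
      if (isTRUE(metadata(object)$normalized)) "(normalized)" else "(raw)", "\n")
  cat("  sexes:", paste(sprintf("%s=%d", names(table(object$sex)), table(object$sex)),
                        collapse = ", "), "\n")
})

setMethod("show", "GenotypeMatrix", function(object) {
  gt <- assay(object, "gt")
  cat("GenotypeMatrix:", nrow(object), "sites x", ncol(object), "samples;",
      sum(is.na(gt)), "missing cells\n")
})

setMethod("show", "TreeSpec", function(object) {
  cat("TreeSpec:", length(object@nodes), "nodes,",
      sum(object@mutations, na.rm = TRUE), "mutations,",
      length(unlist(object@tipSamples)), "samples\n")
})

setMethod("show", "HaplotypeTable", function(object) {
  cat("HaplotypeTable:", nrow(object@haplo), "haplotypes over",
      ncol(object@haplo), "segregating sites (",
      length(object@droppedConstant), "constant sites dropped )\n")
})

setMethod("show", "HaploNetwork", function(object) {
  g <- object@graph
  cat("HaploNetwork:", igraph::vcount(g), "nodes (",
      sum(igraph::V(g)$isMedian), "median vectors ),",
      igraph::ecount(g), "edges, total length", object@totalLength, "\n")
  hg <- igraph::V(g)$haplogroup
  if (!all(is.na(hg)))
    cat("  haplogroups:", paste(unique(hg[!is.na(hg)]), collapse = ", "), "\n")
})
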