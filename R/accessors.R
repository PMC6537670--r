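#' Accessors for msynet classes
#'
#' Small accessor layer so user code never touches slots directly.
#'
#' @param x An msynet object.
#' @name accessors
NULL

#' @describeIn accessors Template segments as a GRanges (copyClass, copyNumber).
#' @export
templateSegments <- function(x) {
  stopifnot(is(x, "GenomeTemplate"))
  x@segments
}

#' @describeIn accessors Named contig lengths of a template.
#' @export
contigLengths <- function(x) {
  stopifnot(is(x, "GenomeTemplate"))
  seqlengths(x@segments)
}

#' @describeIn accessors Haplotype allele matrix (haplotypes x sites, 0/1).
#' @export
haploMatrix <- function(x) {
  stopifnot(is(x, "HaplotypeTable"))
  x@haplo
}

#' @describeIn accessors Named multiplicities (samples per haplotype).
#' @export
haploMultiplicity <- function(x) {
  stopifnot(is(x, "HaplotypeTable"))
  x@multiplicity
}

#' @describeIn accessors Sample membership list per haplotype.
#' @export
haploMembers <- function(x) {
  stopifnot(is(x, "HaplotypeTable"))
  x@members
}

#' @describeIn accessors Site ids dropped as constant during collapsing.
#' @export
droppedConstantSites <- function(x) {
  stopifnot(is(x, "HaplotypeTable"))
  x@droppedConstant
}

#' @describeIn accessors The underlying igraph of a network.
#' @export
networkGraph <- function(x) {
  stopifnot(is(x, "HaploNetwork"))
  x@graph
}

#' @describeIn accessors Node allele vectors of a network (nodes x sites).
#' @export
networkVectors <- function(x) {
  stopifnot(is(x, "HaploNetwork"))
  x@vectors
}

#' @describeIn accessors Minimum spanning length over the network's node set.
#' @export
networkLength <- function(x) {
  stopifnot(is(x, "HaploNetwork"))
  x@totalLength
}

#' @describeIn accessors Node table: id, isMedian, multiplicity, haplogroup.
#' @export
networkNodes <- function(x) {
  stopifnot(is(x, "HaploNetwork"))
  g <- x@graph
  data.frame(
    node = igraph::V(g)$name,
    isMedian = igraph::V(g)$isMedian,
    multiplicity = igraph::V(g)$multiplicity,
    haplogroup = igraph::V(g)$haplogroup,
    stringsAsFactors = FALSE)
}

#' @describeIn accessors Edge table: endpoints, length, mutating sites.
#' @export
networkEdges <- function(x) {
  stopifnot(is(x, "HaploNetwork"))
  g <- x@graph
  if (igraph::ecount(g) == 0L)
    return(data.frame(from = character(), to = character(),
                      length = integer(), sites = character()))
  ends <- igraph::ends(g, igraph::E(g))
  data.frame(
    from = ends[, 1L], to = ends[, 2L],
    length = igraph::E(g)$weight,
    sites = vapply(igraph::E(g)$sites, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
}

#' @describeIn accessors Sample members per observed network node.
#' @export
networkMembers <- function(x) {
  stopifnot(is(x, "HaploNetwork"))
  x@members
}
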