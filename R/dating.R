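# Rho-statistic dating of network nodes. Rho is the multiplicity-weighted
# mean number of mutations from a set of tip haplotypes to a designated
# ancestral node; dividing by (mutation rate x surveyed sites) converts it
# to generations, and multiplying by the generation time to calendar
# years. The standard error follows the per-edge tip-count estimator used
# with haplotype networks (Saillard-type): sigma^2 = sum over edges of the
# spanning subtree of (tips descending through the edge)^2 x edge length,
# divided by n^2.

# geodesic edge path tip -> node; errors if the geodesic is ambiguous
.geodesicEdges <- function(g, tip, node) {
  all <- igraph::all_shortest_paths(g, tip, node, weights = igraph::E(g)$weight)
  paths <- if (!is.null(all$vpaths)) all$vpaths else all$res
  if (length(paths) > 1L)
    stop("ambiguous geodesic between ", tip, " and ", node,
         " (reticulation on the path)")
  vp <- paths[[1L]]
  if (length(vp) < 2L) return(integer())
  as.integer(igraph::get_edge_ids(g, rep(as.integer(vp), each = 2L)[-c(1L,
    2L * length(vp))]))
}

.tipWeights <- function(net, tips) {
  g <- networkGraph(net)
  mult <- setNames(igraph::V(g)$multiplicity, igraph::V(g)$name)
  w <- mult[tips]
  if (any(is.na(w))) stop("tip(s) not in network: ",
                          paste(tips[is.na(w)], collapse = ", "))
  w[w == 0L] <- 1L  # a median used as a tip counts once
  w
}

#' Rho statistic: mean mutational distance from tips to a node
#'
#' @param net A [HaploNetwork-class] (tree-like on the relevant paths).
#' @param tips Node ids of the tip haplotypes; each is weighted by its
#'   sample multiplicity.
#' @param node The ancestral node id.
#' @return Rho (mutations).
#' @export
rhoStatistic <- function(net, tips, node) {
  g <- networkGraph(net)
  w <- .tipWeights(net, tips)
  d <- vapply(tips, function(tp) {
    eids <- .geodesicEdges(g, tp, node)
    sum(igraph::E(g)$weight[eids])
  }, numeric(1L))
  sum(w * d) / sum(w)
}

#' Standard error of rho
#'
#' @inheritParams rhoStatistic
#' @return sigma(rho).
#' @export
sigmaRho <- function(net, tips, node) {
  g <- networkGraph(net)
  w <- .tipWeights(net, tips)
  n <- sum(w)
  edgeTips <- numeric(igraph::ecount(g))
  for (i in seq_along(tips)) {
    eids <- .geodesicEdges(g, tips[i], node)
    edgeTips[eids] <- edgeTips[eids] + w[i]
  }
  used <- edgeTips > 0
  sqrt(sum(edgeTips[used]^2 * igraph::E(g)$weight[used]) / n^2)
}

#' Convert rho (and its error) to calendar years
#'
#' `T = rho / (mu * L) * g`; the standard deviation scales identically.
#'
#' @param rho,sigma Rho statistic and its standard error (mutations).
#' @param mu Mutations per site per generation.
#' @param L Sites surveyed (bp).
#' @param generationYears Years per generation.
#' @param node Optional node id recorded in the result.
#' @param n Optional tip count recorded in the result.
#' @return data.frame: node, n, rho, sigma, T_years, T_sd_years, mu, L,
#'   generation_years.
#' @export
rhoToYears <- function(rho, sigma, mu, L, generationYears,
                       node = NA_character_, n = NA_integer_) {
  stopifnot(mu > 0, L > 0, generationYears > 0, rho >= 0, sigma >= 0)
  scale <- generationYears / (mu * L)
  data.frame(node = node, n = n, rho = rho, sigma = sigma,
             T_years = rho * scale, T_sd_years = sigma * scale,
             mu = mu, L = L, generation_years = generationYears,
             stringsAsFactors = FALSE)
}

#' Date a network node from tips in one call
#'
#' @inheritParams rhoStatistic
#' @inheritParams rhoToYears
#' @return One-row data.frame as in [rhoToYears()].
#' @export
dateNode <- function(net, tips, node, mu, L, generationYears) {
  rho <- rhoStatistic(net, tips, node)
  sig <- sigmaRho(net, tips, node)
  rhoToYears(rho, sig, mu, L, generationYears, node = node,
             n = sum(.tipWeights(net, tips)))
}
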