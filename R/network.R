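# Haplotype collapsing and the median-joining network, with an exhaustive
# Steiner-tree oracle for tests. All vectors are binary (0/1) over the
# retained segregating sites; distances are Hamming distances.

.hamming <- function(m) as.matrix(dist(m, method = "manhattan"))

# Prim's algorithm: minimum spanning tree length over a distance matrix.
# Ties resolve to the lowest index, so results are deterministic in the
# (lexicographically ordered) input.
.primLength <- function(D) {
  n <- nrow(D)
  if (n <= 1L) return(0)
  inT <- logical(n); inT[1L] <- TRUE
  mind <- D[1L, ]
  tot <- 0
  for (t in seq_len(n - 1L)) {
    mind[inT] <- Inf
    j <- which.min(mind)
    tot <- tot + mind[j]
    inT[j] <- TRUE
    mind <- pmin(mind, D[j, ])
  }
  unname(tot)
}

.primEdges <- function(D) {
  n <- nrow(D)
  if (n <= 1L) return(matrix(integer(), 0L, 2L))
  inT <- logical(n); inT[1L] <- TRUE
  mind <- D[1L, ]; from <- rep(1L, n)
  res <- matrix(0L, n - 1L, 2L)
  for (t in seq_len(n - 1L)) {
    mind[inT] <- Inf
    j <- which.min(mind)
    res[t, ] <- c(from[j], j)
    inT[j] <- TRUE
    upd <- !inT & D[j, ] < mind
    from[upd] <- j
    mind <- pmin(mind, D[j, ])
  }
  res
}

# epsilon-relaxed minimum spanning network: all edges whose length is
# within eps of the minimax (bottleneck) path distance between their
# endpoints; eps = 0 gives the union of all minimum spanning trees.
.msnEdges <- function(D, eps = 0) {
  n <- nrow(D)
  if (n <= 1L) return(matrix(integer(), 0L, 2L))
  mstE <- .primEdges(D)
  adj <- vector("list", n)
  for (r in seq_len(nrow(mstE))) {
    i <- mstE[r, 1L]; j <- mstE[r, 2L]
    adj[[i]] <- rbind(adj[[i]], c(j, D[i, j]))
    adj[[j]] <- rbind(adj[[j]], c(i, D[i, j]))
  }
  minimax <- matrix(0, n, n)
  for (s in seq_len(n)) {       # DFS over the tree from s
    stack <- list(c(s, 0)); seen <- logical(n); seen[s] <- TRUE
    while (length(stack)) {
      top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      v <- top[1L]; mx <- top[2L]
      minimax[s, v] <- mx
      for (r in seq_len(NROW(adj[[v]]))) {
        w <- adj[[v]][r, 1L]
        if (!seen[w]) { seen[w] <- TRUE; stack[[length(stack) + 1L]] <- c(w, max(mx, adj[[v]][r, 2L])) }
      }
    }
  }
  keep <- which(upper.tri(D) & D <= minimax + eps, arr.ind = TRUE)
  keep
}

.medianVector <- function(a, b, c) as.integer(a + b + c >= 2L)

.vecKey <- function(v) paste(v, collapse = "")

# assemble a HaploNetwork from a set of vectors (observed + medians)
.buildNetwork <- function(vecs, multiplicity, members, eps = 0) {
  n <- nrow(vecs)
  isMedian <- !(rownames(vecs) %in% names(multiplicity))
  mult <- setNames(integer(n), rownames(vecs))
  mult[names(multiplicity)] <- multiplicity
  D <- .hamming(vecs)
  E <- .msnEdges(D, eps)
  siteIds <- colnames(vecs)
  edges <- data.frame(from = rownames(vecs)[E[, 1L]], to = rownames(vecs)[E[, 2L]],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = rownames(vecs), isMedian = isMedian,
                          multiplicity = unname(mult),
                          haplogroup = NA_character_, stringsAsFactors = FALSE))
  if (nrow(edges)) {
    igraph::E(g)$weight <- D[E]
    igraph::E(g)$sites <- lapply(seq_len(nrow(E)), function(r)
      siteIds[vecs[E[r, 1L], ] != vecs[E[r, 2L], ]])
  } else {
    g <- igraph::set_edge_attr(g, "weight", value = numeric())
    g <- igraph::set_edge_attr(g, "sites", value = list())
  }
  new("HaploNetwork", graph = g, vectors = vecs, members = members,
      totalLength = .primLength(D))
}

#' Collapse a genotype matrix into distinct haplotypes
#'
#' Identical sample rows merge into one haplotype; sites constant across
#' all samples are dropped (they cannot separate haplotypes) and their ids
#' are kept in the result so diversity denominators can remain the full
#' sequence length.
#'
#' @param gm A [GenotypeMatrix-class] with no missing cells (run
#'   [imputeMissing()] first), or a plain samples x sites 0/1 matrix.
#' @return A [HaplotypeTable-class]; haplotypes are named H1, H2, ... in
#'   order of first appearance in the sample order.
#' @export
collapseHaplotypes <- function(gm) {
  m <- if (is(gm, "GenotypeMatrix")) t(assay(gm, "gt")) else gm
  if (!nrow(m)) stop("empty genotype matrix")
  if (anyNA(m)) stop("matrix has missing cells; run imputeMissing() first")
  if (is.null(colnames(m)) && ncol(m))
    colnames(m) <- paste0("site", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("sample", seq_len(nrow(m)))
  constant <- colSums(m) %in% c(0L, nrow(m))
  dropped <- colnames(m)[constant]
  m2 <- m[, !constant, drop = FALSE]
  keys <- apply(m2, 1L, .vecKey)
  first <- !duplicated(keys)
  haplo <- m2[first, , drop = FALSE]
  hapIds <- paste0("H", seq_len(nrow(haplo)))
  rownames(haplo) <- hapIds
  members <- lapply(keys[first], function(k) rownames(m)[keys == k])
  names(members) <- hapIds
  mode(haplo) <- "integer"
  new("HaplotypeTable", haplo = haplo,
      multiplicity = setNames(vapply(members, length, 1L), hapIds),
      members = members, droppedConstant = dropped)
}

#' Build a median-joining network
#'
#' Iterates the median-joining construction on binary haplotype vectors:
#' build the epsilon-relaxed minimum spanning network over the current
#' vector set; for every connected triple, form the per-site majority
#' (median) vector and add it if doing so strictly shortens the minimum
#' spanning length; repeat to a fixed point; finally prune obsolete median
#' vectors (unsampled nodes of degree <= 2 that lie on geodesics and
#' contribute no length saving). The final network spans all observed
#' haplotypes and its total length never exceeds that of a spanning tree
#' over the observed haplotypes alone.
#'
#' @param ht A [HaplotypeTable-class].
#' @param epsilon Relaxation of the spanning network (default 0, the
#'   standard choice for SNP data).
#' @return A [HaploNetwork-class]; inferred nodes are named MV1, MV2, ...
#' @export
medianJoining <- function(ht, epsilon = 0) {
  stopifnot(is(ht, "HaplotypeTable"))
  obs <- haploMatrix(ht)
  cur <- obs
  medN <- 0L
  repeat {
    D <- .hamming(cur)
    base <- .primLength(D)
    E <- .msnEdges(D, epsilon)
    # connected triples: two MSN edges sharing a node
    adj <- vector("list", nrow(cur))
    for (r in seq_len(nrow(E))) {
      adj[[E[r, 1L]]] <- c(adj[[E[r, 1L]]], E[r, 2L])
      adj[[E[r, 2L]]] <- c(adj[[E[r, 2L]]], E[r, 1L])
    }
    have <- vapply(seq_len(nrow(cur)), function(i) .vecKey(cur[i, ]), "")
    newMeds <- list()
    for (v in seq_len(nrow(cur))) {
      nb <- adj[[v]]
      if (length(nb) < 2L) next
      prs <- utils::combn(sort(unique(nb)), 2L)
      for (p in seq_len(ncol(prs))) {
        med <- .medianVector(cur[prs[1L, p], ], cur[prs[2L, p], ], cur[v, ])
        k <- .vecKey(med)
        if (!(k %in% have) && is.null(newMeds[[k]])) newMeds[[k]] <- med
      }
    }
    accepted <- list()
    for (k in names(newMeds)) {
      D2 <- .hamming(rbind(cur, newMeds[[k]]))
      if (.primLength(D2) < base) accepted[[k]] <- newMeds[[k]]
    }
    if (!length(accepted)) break
    for (k in sort(names(accepted))) {
      medN <- medN + 1L
      cur <- rbind(cur, accepted[[k]])
      rownames(cur)[nrow(cur)] <- paste0("MV", medN)
    }
  }
  # prune obsolete medians
  repeat {
    D <- .hamming(cur)
    base <- .primLength(D)
    E <- .msnEdges(D, epsilon)
    deg <- tabulate(c(E), nbins = nrow(cur))
    removed <- FALSE
    for (i in rev(seq_len(nrow(cur)))) {
      if (rownames(cur)[i] %in% rownames(obs)) next
      if (deg[i] > 2L) next
      rest <- cur[-i, , drop = FALSE]
      if (.primLength(.hamming(rest)) <= base) { cur <- rest; removed <- TRUE; break }
    }
    if (!removed) break
  }
  # renumber medians deterministically
  medRows <- !(rownames(cur) %in% rownames(obs))
  if (any(medRows)) {
    keys <- vapply(which(medRows), function(i) .vecKey(cur[i, ]), "")
    rownames(cur)[medRows][order(keys)] <- paste0("MV", seq_len(sum(medRows)))
  }
  .buildNetwork(cur, haploMultiplicity(ht), haploMembers(ht), epsilon)
}

#' Exhaustive Steiner-network oracle (tests only)
#'
#' Enumerates candidate median vectors (majority vectors of all node
#' triples, closed under iteration), then searches every subset of
#' candidates for the minimum spanning length over observed haplotypes
#' plus that subset. Exponential; intended as an independent check of
#' [medianJoining()] on small instances.
#'
#' @param ht A [HaplotypeTable-class] with at most 12 haplotypes and 64
#'   sites; at most 16 distinct candidate medians are allowed.
#' @return A [HaploNetwork-class] of minimum total length.
#' @export
networkOracle <- function(ht) {
  stopifnot(is(ht, "HaplotypeTable"))
  obs <- haploMatrix(ht)
  if (nrow(obs) > 12L) stop("oracle size limit: > 12 haplotypes")
  if (ncol(obs) > 64L) stop("oracle size limit: > 64 sites")
  pool <- obs
  have <- vapply(seq_len(nrow(pool)), function(i) .vecKey(pool[i, ]), "")
  repeat {
    added <- FALSE
    if (nrow(pool) < 3L) break
    idx <- utils::combn(nrow(pool), 3L)
    for (c1 in seq_len(ncol(idx))) {
      med <- .medianVector(pool[idx[1L, c1], ], pool[idx[2L, c1], ], pool[idx[3L, c1], ])
      k <- .vecKey(med)
      if (!(k %in% have)) {
        pool <- rbind(pool, med)
        rownames(pool)[nrow(pool)] <- paste0("C", nrow(pool) - nrow(obs))
        have <- c(have, k)
        added <- TRUE
        if (nrow(pool) - nrow(obs) > 16L)
          stop("oracle size limit: median closure exceeds 16 candidates")
      }
    }
    if (!added) break
  }
  nObs <- nrow(obs)
  nCand <- nrow(pool) - nObs
  D <- .hamming(pool)
  best <- .primLength(D[seq_len(nObs), seq_len(nObs), drop = FALSE])
  bestSet <- integer()
  if (nCand > 0L) {
    for (mask in seq_len(2^nCand) - 1L) {
      sel <- which(bitwAnd(mask, 2^(seq_len(nCand) - 1L)) > 0L)
      idx <- c(seq_len(nObs), nObs + sel)
      len <- .primLength(D[idx, idx, drop = FALSE])
      if (len < best || (len == best && length(sel) < length(bestSet))) {
        best <- len; bestSet <- sel
      }
    }
  }
  vecs <- pool[c(seq_len(nObs), nObs + bestSet), , drop = FALSE]
  medRows <- !(rownames(vecs) %in% rownames(obs))
  if (any(medRows)) {
    keys <- vapply(which(medRows), function(i) .vecKey(vecs[i, ]), "")
    rownames(vecs)[medRows][order(keys)] <- paste0("MV", seq_len(sum(medRows)))
  }
  .buildNetwork(vecs, haploMultiplicity(ht), haploMembers(ht))
}

#' Partition a network into haplogroups
#'
#' Cuts the single longest edge on the path between differently-labeled
#' seed nodes and propagates seed labels within the resulting components.
#' Ambiguity (a tie among longest edges on a seed path, or disagreeing
#' candidate cut edges across seed pairs) raises an error listing the
#' candidates, since resolution is a judgment call.
#'
#' @param net A [HaploNetwork-class].
#' @param seeds Named character: `seeds[nodeId] = label`, at least two
#'   nodes carrying at least two labels.
#' @return list with `network` (haplogroup labels set on the nodes),
#'   `splitEdge` (data.frame from/to/length) and `labels` (named character
#'   per node).
#' @export
assignHaplogroups <- function(net, seeds) {
  stopifnot(is(net, "HaploNetwork"), length(seeds) >= 2L)
  g <- networkGraph(net)
  if (!all(names(seeds) %in% igraph::V(g)$name))
    stop("seed node(s) not in network: ",
         paste(setdiff(names(seeds), igraph::V(g)$name), collapse = ", "))
  if (length(unique(seeds)) < 2L) stop("need at least two distinct labels")
  prs <- utils::combn(names(seeds), 2L)
  cutEdges <- character()
  for (p in seq_len(ncol(prs))) {
    a <- prs[1L, p]; b <- prs[2L, p]
    if (seeds[[a]] == seeds[[b]]) next
    sp <- igraph::shortest_paths(g, a, b, weights = igraph::E(g)$weight,
                                 output = "epath")$epath[[1L]]
    w <- igraph::E(g)$weight[as.integer(sp)]
    mx <- which(w == max(w))
    if (length(mx) > 1L) {
      ends <- igraph::ends(g, sp[mx])
      stop("tie among longest edges on the ", a, "-", b, " path: ",
           paste(apply(ends, 1L, paste, collapse = "--"), collapse = ", "))
    }
    e <- sp[mx]
    cutEdges <- union(cutEdges, paste(sort(igraph::ends(g, e)[1L, ]), collapse = "|"))
  }
  if (length(cutEdges) != 1L)
    stop("seed pairs disagree on the split edge; candidates: ",
         paste(cutEdges, collapse = "; "))
  uv <- strsplit(cutEdges, "|", fixed = TRUE)[[1L]]
  eid <- igraph::get_edge_ids(g, uv)
  len <- igraph::E(g)$weight[eid]
  g2 <- igraph::delete_edges(g, eid)
  comp <- igraph::components(g2)$membership
  labels <- setNames(rep(NA_character_, igraph::vcount(g)), igraph::V(g)$name)
  for (cm in unique(comp)) {
    inComp <- names(comp)[comp == cm]
    sl <- unique(seeds[names(seeds) %in% inComp])
    if (length(sl) > 1L)
      stop("seeds with labels ", paste(sl, collapse = ", "),
           " fall in one component after the cut")
    if (length(sl) == 1L) labels[inComp] <- sl
  }
  igraph::V(g)$haplogroup <- unname(labels[igraph::V(g)$name])
  out <- net
  out@graph <- g
  list(network = out,
       splitEdge = data.frame(from = uv[1L], to = uv[2L], length = len,
                              stringsAsFactors = FALSE),
       labels = labels)
}
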