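# Synthetic-data generators: sexed coverage over a labeled genome template,
# and haplotypes evolved on a known tree under the infinite-sites model.
# Everything the pipeline consumes can be generated here with full ground
# truth, so recovery tests never need the original sequencing data.

# All randomness flows from one top-level seed through named substreams:
# each operation re-seeds from (seed, operation-name) so adding a draw in
# one operation never perturbs another.
.substream <- function(seed, name) {
  h <- 0
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% 2147480009
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

.withSubstream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.substream(seed, name))
  expr
}

#' Construct a genome template from labeled segments
#'
#' @param segments A `GRanges` tiling each contig, with metadata columns
#'   `copyClass` ("scY"/"mcY"/"nonMSY") and `copyNumber`; seqlengths must be set.
#' @return A [GenomeTemplate-class] object.
#' @export
genomeTemplate <- function(segments) {
  if (is.null(segments$copyNumber))
    segments$copyNumber <- ifelse(as.character(segments$copyClass) == "mcY", 2L, 1L)
  segments$copyNumber <- as.integer(segments$copyNumber)
  new("GenomeTemplate", segments = segments)
}

#' Simulate a random labeled genome template
#'
#' Draws contigs with geometric-ish length variation and tiles each with
#' segments whose classes follow `classProbs`; mcY segments get a copy
#' number uniform in 2..maxCopy.
#'
#' @param nContigs Number of contigs.
#' @param meanLength Mean contig length in bp.
#' @param meanSegment Mean segment length in bp.
#' @param classProbs Named probabilities for scY, mcY, nonMSY.
#' @param maxCopy Largest mcY copy number drawn.
#' @param seed Integer seed.
#' @return A [GenomeTemplate-class].
#' @export
simulateTemplate <- function(nContigs = 20, meanLength = 5000, meanSegment = 1000,
                             classProbs = c(scY = 0.45, mcY = 0.15, nonMSY = 0.40),
                             maxCopy = 4, seed = 1) {
  stopifnot(nContigs >= 1, meanLength >= 100)
  .withSubstream(seed, "template", {
    lens <- pmax(200L, as.integer(round(meanLength * rexp(nContigs) + 200)))
    names(lens) <- sprintf("ctg%03d", seq_len(nContigs))
    segs <- list()
    for (ctg in names(lens)) {
      pos <- 1L
      while (pos <= lens[[ctg]]) {
        w <- max(50L, as.integer(round(rexp(1, 1 / meanSegment))))
        endp <- min(lens[[ctg]], pos + w - 1L)
        cls <- sample(names(classProbs), 1L, prob = classProbs)
        segs[[length(segs) + 1L]] <- data.frame(
          ctg = ctg, start = pos, end = endp, cls = cls,
          k = if (cls == "mcY") sample(2:maxCopy, 1L) else 1L)
        pos <- endp + 1L
      }
    }
    segs <- do.call(rbind, segs)
    gr <- GRanges(segs$ctg, IRanges(segs$start, segs$end),
                  copyClass = factor(segs$cls, c("scY", "mcY", "nonMSY")),
                  copyNumber = as.integer(segs$k),
                  seqinfo = Seqinfo(names(lens), lens))
    genomeTemplate(gr)
  })
}

#' A demonstration cohort sheet: eight males and six females
#'
#' Mirrors the study design this package targets: three domestic and five
#' wild male Bactrian-camel-like samples (one of them, DC269, the individual
#' the reference derives from), plus six females used only for window
#' classification.
#'
#' @param meanDepth Mean autosomal depth (reads/bp) given to every sample.
#' @return data.frame with `sample_id`, `sex`, `mean_depth`.
#' @export
demoCohort <- function(meanDepth = 10) {
  data.frame(
    sample_id = c("DC269", "DC116", "DC184", "WC305", "WC101", "WC102",
                  "WC214", "WC218", "DF1", "DF2", "WF1", "WF2", "WF3", "WF4"),
    sex = c(rep("male", 8L), rep("female", 6L)),
    mean_depth = meanDepth,
    stringsAsFactors = FALSE)
}

# majority copy class (and its copy number) per window; ties go to the
# segment covering the window start, which is deterministic under the fixed
# tiling.
.windowTruth <- function(windows, segments) {
  ov <- findOverlaps(windows, segments)
  w <- width(pintersect(windows[S4Vectors::queryHits(ov)],
                        segments[S4Vectors::subjectHits(ov)]))
  ord <- order(S4Vectors::queryHits(ov), -w, start(segments)[S4Vectors::subjectHits(ov)])
  ov <- ov[ord]
  keep <- !duplicated(S4Vectors::queryHits(ov))
  sel <- S4Vectors::subjectHits(ov)[keep]
  qh <- S4Vectors::queryHits(ov)[keep]
  cls <- rep(NA_character_, length(windows)); k <- rep(NA_integer_, length(windows))
  cls[qh] <- as.character(segments$copyClass[sel])
  k[qh] <- segments$copyNumber[sel]
  list(class = cls, copyNumber = k)
}

#' Simulate per-window sexed read depths over a genome template
#'
#' Depth for sample s on window w is Poisson with mean
#' `mean_depth[s] * factor`, where the factor is 0.5 * copyNumber for males
#' on Y windows (the Y is haploid), `femaleLeak` for females on Y windows
#' (mismapping leak), and 1 for both sexes on nonMSY windows. Windows that
#' straddle a segment boundary take the class covering the majority of
#' their bases.
#'
#' @param template A [GenomeTemplate-class].
#' @param cohort data.frame with `sample_id`, `sex`, `mean_depth`.
#' @param windowSize Window width in bp (default 50).
#' @param femaleLeak Expected fraction of spurious female depth on true Y
#'   windows (default 0.02).
#' @param seed Integer seed; fixed seed gives identical tables.
#' @return A [WindowDepthTable-class] with `rowData()$trueClass` and
#'   `rowData()$trueCopyNumber` ground truth.
#' @export
simulateDepths <- function(template, cohort, windowSize = 50, femaleLeak = 0.02,
                           seed = 1) {
  stopifnot(is(template, "GenomeTemplate"), windowSize >= 1)
  stopifnot(all(c("sample_id", "sex", "mean_depth") %in% names(cohort)))
  if (!any(cohort$sex == "male") || !any(cohort$sex == "female"))
    stop("cohort needs at least one male and one female")
  if (any(cohort$mean_depth <= 0)) stop("mean_depth must be positive")
  sl <- contigLengths(template)
  if (windowSize > min(sl))
    stop("windowSize (", windowSize, ") exceeds the shortest contig (", min(sl), " bp)")
  windows <- tileGenome(sl, tilewidth = windowSize, cut.last.tile.in.chrom = TRUE)
  truth <- .windowTruth(windows, templateSegments(template))
  isY <- truth$class %in% c("scY", "mcY")
  depth <- .withSubstream(seed, "depths", {
    m <- matrix(0, nrow = length(windows), ncol = nrow(cohort),
                dimnames = list(NULL, cohort$sample_id))
    for (j in seq_len(nrow(cohort))) {
      fac <- ifelse(isY,
                    if (cohort$sex[j] == "male") 0.5 * truth$copyNumber else femaleLeak,
                    1)
      m[, j] <- rpois(length(windows), cohort$mean_depth[j] * fac)
    }
    m
  })
  se <- SummarizedExperiment(
    assays = list(depth = depth),
    rowRanges = windows,
    colData = DataFrame(sex = cohort$sex, row.names = cohort$sample_id))
  rowData(se)$trueClass <- truth$class
  rowData(se)$trueCopyNumber <- truth$copyNumber
  metadata(se)$normalized <- FALSE
  metadata(se)$windowSize <- windowSize
  new("WindowDepthTable", se)
}

#' Construct a tree specification
#'
#' @param parent Named character: `parent[node]` is the parent node id; the
#'   root has NA. All node ids are taken from `names(parent)`.
#' @param mutations Named integer: mutation count on the edge above each
#'   non-root node. Omit (give `durations`) to draw counts as
#'   Poisson(mu * nSites * duration) in [simulateHaplotypes()].
#' @param tipSamples Named list mapping node ids to sample id vectors; two
#'   samples on one node share a haplotype.
#' @param durations Named numeric edge durations in generations (optional).
#' @return A [TreeSpec-class].
#' @export
treeSpec <- function(parent, mutations = integer(), tipSamples = list(),
                     durations = numeric()) {
  nodes <- names(parent)
  new("TreeSpec", nodes = nodes, parent = parent,
      mutations = as.integer(mutations)[seq_along(mutations)] |> setNames(names(mutations)),
      durations = durations, tipSamples = tipSamples)
}

#' A star tree: one ancestral node, one tip per branch
#'
#' @param branches Named integer vector of branch mutation counts; names
#'   become tip and sample ids.
#' @return A [TreeSpec-class] rooted at `"anc"`.
#' @export
starTree <- function(branches) {
  tips <- names(branches)
  parent <- c(anc = NA_character_, setNames(rep("anc", length(tips)), tips))
  treeSpec(parent,
           mutations = setNames(as.integer(branches), tips),
           tipSamples = setNames(as.list(tips), tips))
}

#' The two-haplogroup demonstration tree
#'
#' A star-like topology mimicking the wild/domestic Bactrian camel MSY
#' network: a wild basal haplotype carrying one sample, two short wild
#' lineages (one shared by a father-sharing sample pair), a long
#' inter-haplogroup edge, three domestic lineages of 13-16 mutations and
#' one wild-in-domestic lineage of 12.
#'
#' @param interEdge Mutations on the inter-haplogroup edge.
#' @param domestic Three domestic branch lengths.
#' @param introgressed Branch length of the wild sample inside the domestic
#'   haplogroup.
#' @param wildLineages Two wild branch lengths from the wild basal node.
#' @return A [TreeSpec-class]; 8 samples, 7 distinct haplotypes,
#'   `sum(c(interEdge, domestic, introgressed, wildLineages))` mutations.
#' @export
twoHaplogroupTree <- function(interEdge = 530, domestic = c(13, 14, 15),
                              introgressed = 12, wildLineages = c(2, 4)) {
  stopifnot(length(domestic) == 3L, length(wildLineages) == 2L)
  parent <- c(W_basal = NA_character_,
              W_shared = "W_basal", W_tip2 = "W_basal", D_basal = "W_basal",
              D_tip1 = "D_basal", D_tip2 = "D_basal", D_tip3 = "D_basal",
              D_intro = "D_basal")
  mutations <- c(W_shared = wildLineages[1L], W_tip2 = wildLineages[2L],
                 D_basal = interEdge,
                 D_tip1 = domestic[1L], D_tip2 = domestic[2L], D_tip3 = domestic[3L],
                 D_intro = introgressed)
  tipSamples <- list(W_basal = "WC102", W_shared = c("WC214", "WC218"),
                     W_tip2 = "WC101",
                     D_tip1 = "DC116", D_tip2 = "DC184", D_tip3 = "DC269",
                     D_intro = "WC305")
  treeSpec(parent, mutations = mutations, tipSamples = tipSamples)
}

.treeRoot <- function(tree) tree@nodes[is.na(tree@parent[tree@nodes])]

# nodes in parent-before-child order
.topoOrder <- function(tree) {
  ord <- .treeRoot(tree)
  repeat {
    nxt <- tree@nodes[tree@parent[tree@nodes] %in% ord & !tree@nodes %in% ord]
    if (!length(nxt)) break
    ord <- c(ord, nxt)
  }
  ord
}

#' Simulate haplotypes on a tree under the infinite-sites model
#'
#' The root carries the all-REF state; each edge toggles as many fresh
#' sites as its mutation count (no site is ever hit twice), and sampled
#' nodes inherit the cumulative state. Site positions are placed uniformly
#' without replacement inside the template's scY regions when a template is
#' given, otherwise on a single synthetic contig.
#'
#' @param tree A [TreeSpec-class]. If it has durations instead of mutation
#'   counts, counts are drawn Poisson(`mu * nSites * duration`) per edge.
#' @param seed Integer seed.
#' @param template Optional [GenomeTemplate-class] to place sites in.
#' @param mu Per-site per-generation mutation rate (used with durations).
#' @param nSites Available site pool (used with durations; also the pool
#'   cap when no template is given; default 1e6).
#' @return list with `gm` (a [GenotypeMatrix-class], all cells called),
#'   `edgeSites` (named list: child node -> site ids mutated on its edge)
#'   and `tree`.
#' @export
simulateHaplotypes <- function(tree, seed = 1, template = NULL,
                               mu = NULL, nSites = 1e6) {
  stopifnot(is(tree, "TreeSpec"))
  ord <- .topoOrder(tree)
  mut <- tree@mutations
  if (length(tree@durations)) {
    stopifnot(!is.null(mu), is.finite(mu * nSites * max(tree@durations)))
    mut <- .withSubstream(seed, "edge-counts", {
      setNames(rpois(length(tree@durations), mu * nSites * tree@durations),
               names(tree@durations))
    })
  }
  nonroot <- setdiff(ord, .treeRoot(tree))
  mut <- mut[nonroot]
  if (anyNA(mut)) stop("every non-root edge needs a mutation count or duration")
  S <- sum(mut)
  pool <- if (is.null(template)) nSites else sum(width(templateSegments(template)[
    templateSegments(template)$copyClass == "scY"]))
  if (S > pool) stop("requested ", S, " mutations but only ", pool, " sites available")
  # positions for the S segregating sites
  .withSubstream(seed, "sites", {
    if (is.null(template)) {
      pos <- sort(sample.int(max(S, 1L) * 10L + 100L, S))
      sites <- GRanges(rep("scY_1", S), IRanges(pos, width = 1L))
    } else {
      scy <- templateSegments(template)[templateSegments(template)$copyClass == "scY"]
      all_pos <- unlist(lapply(seq_along(scy), function(i)
        paste(as.character(seqnames(scy))[i], start(scy)[i]:end(scy)[i])))
      pick <- sort(sample(length(all_pos), S))
      parts <- strsplit(all_pos[pick], " ", fixed = TRUE)
      sites <- GRanges(vapply(parts, `[`, "", 1L),
                       IRanges(as.integer(vapply(parts, `[`, "", 2L)), width = 1L))
      sites <- sort(sites)
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, S, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    sites$ref <- ref; sites$alt <- unname(alt)
    # assign fresh sites to edges in topological order
    edgeSites <- list(); nxt <- 1L
    siteIds <- if (S == 0L) character() else
      paste0(as.character(seqnames(sites)), ":", start(sites))
    names(sites) <- siteIds
    for (nd in nonroot) {
      m <- mut[[nd]]
      edgeSites[[nd]] <- if (m > 0L) siteIds[nxt:(nxt + m - 1L)] else character()
      nxt <- nxt + m
    }
    # cumulative states
    states <- list()
    states[[.treeRoot(tree)]] <- integer(S)
    for (nd in nonroot) {
      st <- states[[tree@parent[[nd]]]]
      idx <- match(edgeSites[[nd]], siteIds)
      st[idx] <- 1L - st[idx]
      states[[nd]] <- st
    }
    samples <- unlist(tree@tipSamples, use.names = FALSE)
    if (!length(samples)) stop("tree maps no samples")
    gt <- matrix(NA_integer_, nrow = S, ncol = length(samples),
                 dimnames = list(siteIds, samples))
    for (nd in names(tree@tipSamples))
      for (sm in tree@tipSamples[[nd]]) gt[, sm] <- states[[nd]]
    se <- SummarizedExperiment(
      assays = list(gt = gt), rowRanges = sites,
      colData = DataFrame(outgroup = rep(FALSE, length(samples)),
                          row.names = samples))
    list(gm = new("GenotypeMatrix", se), edgeSites = edgeSites, tree = tree)
  })
}

#' Write a complete on-disk fixture
#'
#' Emits, under `dir`: `regions_truth.bed` (template classes), `depths.tsv`,
#' `samples.tsv`, and `variants.vcf` (haploid GT with per-cell DP and GQ
#' drawn Poisson around configurable means, so threshold behaviour can be
#' exercised). Optionally blanks exactly `floor(missingFrac * cells)`
#' genotype cells to missing. Files round-trip losslessly through the
#' package readers; a fixed seed gives byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param template A [GenomeTemplate-class].
#' @param depths A [WindowDepthTable-class] (raw).
#' @param sim Result of [simulateHaplotypes()].
#' @param cohort The sample sheet used for `depths`.
#' @param dpMean,gqMean Poisson means for simulated per-cell DP and GQ.
#' @param missingFrac Fraction of genotype cells blanked to missing.
#' @param seed Integer seed.
#' @param overwrite Refuse to clobber an existing fixture unless TRUE.
#' @return Named character vector of file paths, invisibly.
#' @export
writeFixture <- function(dir, template, depths, sim, cohort,
                         dpMean = 20, gqMean = 60, missingFrac = 0,
                         seed = 1, overwrite = FALSE) {
  if (nrow(cohort) == 0L) stop("empty cohort")
  gm <- sim$gm
  if (!all(colnames(gm) %in% cohort$sample_id))
    stop("genotype samples missing from the sample sheet: ",
         paste(setdiff(colnames(gm), cohort$sample_id), collapse = ", "))
  paths <- c(bed = file.path(dir, "regions_truth.bed"),
             depths = file.path(dir, "depths.tsv"),
             samples = file.path(dir, "samples.tsv"),
             vcf = file.path(dir, "variants.vcf"))
  if (!overwrite && any(file.exists(paths)))
    stop("fixture files exist in ", dir, "; use overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seg <- templateSegments(template)
  seg2 <- seg; names(seg2) <- NULL; seg2$name <- as.character(seg2$copyClass)
  writeBed(seg2, paths[["bed"]], name = "name")
  writeDepthTable(depths, paths[["depths"]])
  writeSampleSheet(cohort, paths[["samples"]])
  gt <- assay(gm, "gt")
  ncell <- length(gt)
  .withSubstream(seed, "fixture-vcf", {
    dp <- matrix(rpois(ncell, dpMean), nrow(gt), dimnames = dimnames(gt))
    gq <- matrix(rpois(ncell, gqMean), nrow(gt), dimnames = dimnames(gt))
    if (missingFrac > 0) {
      nmiss <- floor(missingFrac * ncell)
      gt[sample.int(ncell, nmiss)] <- NA_integer_
    }
    writeVcfGeno(rowRanges(gm), gt, dp, gq, paths[["vcf"]])
  })
  invisible(paths)
}
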