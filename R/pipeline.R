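# End-to-end pipeline: classify -> filter -> impute -> collapse -> network
# -> haplogroups -> diversity -> dating, with on-disk intermediates so any
# suffix of the pipeline can be resumed from a previous run. Every output
# file carries a header comment naming its producing stage and the config
# hash; reruns under the same config are byte-identical.

.PIPE_STAGES <- c("classify", "filter", "impute", "network", "diversity", "dating")

#' Assemble a pipeline configuration
#'
#' Defaults mirror the analysis this package implements: 50-bp windows,
#' contig cleanup at 200 bp / 50% Y content, DP >= 3 and GQ > 9 variant
#' thresholds, a 0.02 mismapping floor, and dating with
#' mu = 1.68e-8 mutations/site/generation and a 6-year generation time.
#'
#' @param depths,samples,vcf Input file paths (depth TSV, sample sheet, VCF).
#' @param outdir Output directory.
#' @param exclude Samples dropped before depth normalization (e.g. the
#'   reference individual).
#' @param epsilon Mismapping floor for classification.
#' @param maxCopy mcY copy-number grid cap.
#' @param minLength,minFraction Contig cleanup thresholds.
#' @param dpMin,gqMin Variant thresholds (GQ strict).
#' @param outgroup Outgroup sample ids.
#' @param epsilonMj Median-joining relaxation.
#' @param hgSeeds Named character: sample id -> haplogroup label (>= 2 labels).
#' @param subsets Named list of sample subsets for diversity; defaults to
#'   all ingroup samples as one subset named "all".
#' @param L Diversity denominator in bp, or "auto" to use the classified
#'   scY total.
#' @param datingL Dating denominator in bp (default: same as `L`).
#' @param mu Mutations/site/generation.
#' @param generationYears Years per generation.
#' @param seed Integer seed recorded in the manifest.
#' @return A list with class `msynetConfig`.
#' @export
pipelineConfig <- function(depths, samples, vcf, outdir,
                           exclude = character(), epsilon = 0.02, maxCopy = 20,
                           minLength = 200, minFraction = 0.5,
                           dpMin = 3, gqMin = 9, outgroup = character(),
                           epsilonMj = 0, hgSeeds = character(),
                           subsets = NULL, L = "auto", datingL = NULL,
                           mu = 1.68e-8, generationYears = 6, seed = 1) {
  stopifnot(epsilon > 0, minLength >= 0, minFraction >= 0, minFraction <= 1,
            dpMin >= 0, gqMin >= 0, mu > 0, generationYears > 0)
  cfg <- list(depths = depths, samples = samples, vcf = vcf, outdir = outdir,
              exclude = exclude, epsilon = epsilon, maxCopy = maxCopy,
              minLength = minLength, minFraction = minFraction,
              dpMin = dpMin, gqMin = gqMin, outgroup = outgroup,
              epsilonMj = epsilonMj, hgSeeds = hgSeeds, subsets = subsets,
              L = L, datingL = datingL, mu = mu,
              generationYears = generationYears, seed = seed)
  class(cfg) <- "msynetConfig"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror [pipelineConfig()] arguments; `overrides` (e.g. parsed CLI
#' flags) take precedence over the file, which takes precedence over the
#' defaults.
#'
#' @param path YAML file.
#' @param overrides Named list of overriding values.
#' @return A `msynetConfig`.
#' @export
readPipelineConfig <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  if (!is.null(vals$hgSeeds)) vals$hgSeeds <- unlist(vals$hgSeeds)
  do.call(pipelineConfig, vals)
}

.configHash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg[order(names(unclass(cfg)))], tmp, version = 2L)
  unname(tools::md5sum(tmp))
}

#' Export a network as GraphViz DOT
#'
#' Observed nodes are boxes labeled with their members; medians are small
#' points. Edge labels are mutation counts.
#'
#' @param net A [HaploNetwork-class].
#' @param path Output path.
#' @param header Optional comment lines.
#' @export
exportDot <- function(net, path, header = NULL) {
  nd <- networkNodes(net)
  ed <- networkEdges(net)
  members <- networkMembers(net)
  lines <- c(paste0("// ", header), "graph haplonet {")
  for (i in seq_len(nrow(nd))) {
    lbl <- if (nd$isMedian[i]) "" else
      paste0(nd$node[i], "\\n", paste(members[[nd$node[i]]], collapse = ","))
    shape <- if (nd$isMedian[i]) "point" else "ellipse"
    grp <- if (is.na(nd$haplogroup[i])) "" else
      paste0(", color=", c("blue", "darkgreen", "red", "orange")[
        match(nd$haplogroup[i], sort(unique(nd$haplogroup)))])
    lines <- c(lines, sprintf('  "%s" [shape=%s, label="%s"%s];',
                              nd$node[i], shape, lbl, grp))
  }
  for (i in seq_len(nrow(ed)))
    lines <- c(lines, sprintf('  "%s" -- "%s" [label="%d"];',
                              ed$from[i], ed$to[i], as.integer(ed$length[i])))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

.writeNetworkTables <- function(net, outdir, header) {
  nd <- networkNodes(net)
  members <- networkMembers(net)
  nd$members <- vapply(nd$node, function(x)
    paste(if (is.null(members[[x]])) character() else members[[x]], collapse = ","), "")
  con <- file(file.path(outdir, "nodes.tsv"), "w")
  .writeHeader(con, header)
  write.table(nd, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  con <- file(file.path(outdir, "edges.tsv"), "w")
  .writeHeader(con, header)
  write.table(networkEdges(net), con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  exportDot(net, file.path(outdir, "network.dot"), header = header)
}

.stageMsg <- function(stage, ...) message("[", stage, "] ", ...)

# dating requires unique geodesics; a reticulated path is reported as an
# NA row rather than aborting the whole run
.dateNodeOrNA <- function(net, tips, node, mu, L, g) {
  tryCatch(dateNode(net, tips, node, mu, L, g), error = function(e) {
    message("[dating] ", conditionMessage(e))
    data.frame(node = node, n = NA_integer_, rho = NA_real_, sigma = NA_real_,
               T_years = NA_real_, T_sd_years = NA_real_, mu = mu, L = L,
               generation_years = g, stringsAsFactors = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes classify -> filter -> impute -> collapse/network -> haplogroups
#' -> diversity -> dating, writing per-stage outputs and a JSON manifest
#' (parameters, config hash, per-stage record counts) under
#' `cfg$outdir`. With `resume = TRUE`, stages whose outputs already exist
#' are reloaded instead of recomputed.
#'
#' @param cfg A `msynetConfig` from [pipelineConfig()].
#' @param resume Reuse existing on-disk intermediates.
#' @return The manifest, invisibly.
#' @export
runPipeline <- function(cfg, resume = FALSE) {
  stopifnot(inherits(cfg, "msynetConfig"))
  for (f in c(cfg$depths, cfg$samples, cfg$vcf))
    if (!file.exists(f)) stop("input file not found: ", f)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- .configHash(cfg)
  hdr <- function(stage) c(paste0("msynet stage=", stage), paste0("config=", hash))
  manifest <- list(package = "msynet",
                   version = as.character(utils::packageVersion("msynet")),
                   config = unclass(cfg)[!vapply(unclass(cfg), is.null, TRUE)],
                   configHash = unname(hash), counts = list())
  out <- function(...) file.path(cfg$outdir, ...)

  withStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # -- classify ---------------------------------------------------------
  cohort <- readSampleSheet(cfg$samples)
  scyPath <- out("scY.bed")
  if (resume && file.exists(scyPath)) {
    .stageMsg("classify", "resumed from ", scyPath)
    scy <- readBed(scyPath)
    scyBp <- sum(width(scy))
    rpt <- read.table(out("contig_report.tsv"), header = TRUE, sep = "\t",
                      comment.char = "#")
    manifest$counts$classify <- list(
      windows = sum(rpt$scY + rpt$mcY + rpt$nonMSY + rpt$nocall),
      contigsKept = sum(rpt$kept), scY_bp = scyBp,
      mcY_bp = sum(width(readBed(out("mcY.bed")))))
  } else {
    withStage("classify", {
      wdt <- readDepthTable(cfg$depths, cohort)
      norm <- normalizeDepths(wdt, exclude = cfg$exclude)
      cls <- classifyWindows(norm, epsilon = cfg$epsilon, maxCopy = cfg$maxCopy)
      lens <- seqlengths(rowRanges(wdt))
      clean <- cleanContigs(cls, lens, cfg$minLength, cfg$minFraction)
      scy <- clean$scY
      scyBp <- sum(width(scy))
      writeBed(clean$scY, scyPath, header = hdr("classify"))
      writeBed(clean$mcY, out("mcY.bed"), header = hdr("classify"))
      con <- file(out("contig_report.tsv"), "w")
      .writeHeader(con, hdr("classify"))
      write.table(clean$report, con, sep = "\t", quote = FALSE, row.names = FALSE)
      close(con)
      kept <- clean$report$contig[clean$report$kept]
      st <- if (length(kept)) assemblyStats(lens[kept]) else
        list(totalBp = 0, nContigs = 0L, n50 = NA)
      jsonlite::write_json(c(list(stage = "classify", config = unname(hash)), st),
                           out("assembly_stats.json"), auto_unbox = TRUE)
      manifest$counts$classify <- list(
        windows = length(cls), contigsKept = sum(clean$report$kept),
        scY_bp = scyBp, mcY_bp = sum(width(clean$mcY)))
      .stageMsg("classify", length(cls), " windows; ",
                sum(clean$report$kept), " contigs kept; scY ", scyBp, " bp")
    })
  }

  # -- filter -----------------------------------------------------------
  withStage("filter", {
    fl <- filterVariants(cfg$vcf, scy, dpMin = cfg$dpMin, gqMin = cfg$gqMin,
                         outgroup = cfg$outgroup)
    if (nrow(fl$gm) == 0L) stop("no variants retained (empty scY set?)")
    gm <- fl$gm
    writeGenotypeMatrix(fl$gm, out("genotypes_raw.tsv"), header = hdr("filter"))
    con <- file(out("filter_log.tsv"), "w")
    .writeHeader(con, hdr("filter"))
    write.table(fl$log, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    manifest$counts$filter <- list(retained = nrow(fl$gm), dropped = nrow(fl$log))
    .stageMsg("filter", nrow(fl$gm), " sites retained, ", nrow(fl$log), " dropped")
  })

  # -- impute -----------------------------------------------------------
  withStage("impute", {
    ingroupGm <- gm[, !gm$outgroup]
    imp <- imputeMissing(ingroupGm)
    gmi <- imp$gm
    writeGenotypeMatrix(imp$gm, out("genotypes.tsv"), header = hdr("impute"))
    con <- file(out("imputation_log.tsv"), "w")
    .writeHeader(con, hdr("impute"))
    write.table(imp$log, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    manifest$counts$impute <- list(imputed = nrow(imp$log))
    .stageMsg("impute", nrow(imp$log), " cells imputed")
  })

  # -- network ----------------------------------------------------------
  withStage("network", {
    ht <- collapseHaplotypes(gmi)
    net <- medianJoining(ht, epsilon = cfg$epsilonMj)
    split <- NULL
    if (length(cfg$hgSeeds) >= 2L && length(unique(cfg$hgSeeds)) >= 2L) {
      nodeOf <- function(sm) {
        hit <- names(Filter(function(v) sm %in% v, haploMembers(ht)))
        if (!length(hit)) stop("seed sample not in matrix: ", sm)
        hit
      }
      seeds <- setNames(cfg$hgSeeds, vapply(names(cfg$hgSeeds), nodeOf, ""))
      seeds <- seeds[!duplicated(names(seeds))]
      hg <- assignHaplogroups(net, seeds)
      net <- hg$network
      split <- hg$splitEdge
    }
    net <- net; split <- split
    .writeNetworkTables(net, cfg$outdir, hdr("network"))
    manifest$counts$network <- list(
      haplotypes = nrow(haploMatrix(ht)),
      medians = sum(networkNodes(net)$isMedian),
      haplogroups = length(unique(stats::na.omit(networkNodes(net)$haplogroup))),
      totalLength = networkLength(net),
      splitEdge = if (is.null(split)) NULL else as.list(split))
    .stageMsg("network", nrow(haploMatrix(ht)), " haplotypes, ",
              manifest$counts$network$haplogroups, " haplogroups")
  })

  # -- diversity --------------------------------------------------------
  withStage("diversity", {
    L <- if (identical(cfg$L, "auto")) scyBp else cfg$L
    subs <- cfg$subsets
    if (is.null(subs)) subs <- list(all = colnames(gmi))
    div <- diversityTable(gmi, L, subs)
    con <- file(out("diversity.tsv"), "w")
    .writeHeader(con, hdr("diversity"))
    write.table(div, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    manifest$counts$diversity <- list(subsets = nrow(div), L = L)
    .stageMsg("diversity", nrow(div), " subsets over L=", L, " bp")
  })

  # -- dating -----------------------------------------------------------
  withStage("dating", {
    L <- if (!is.null(cfg$datingL)) cfg$datingL else
      if (identical(cfg$L, "auto")) scyBp else cfg$L
    nd <- networkNodes(net)
    rows <- list()
    if (!is.null(split)) {
      for (lab in unique(stats::na.omit(nd$haplogroup))) {
        tips <- nd$node[!nd$isMedian & !is.na(nd$haplogroup) & nd$haplogroup == lab]
        base <- intersect(c(split$from, split$to),
                          nd$node[!is.na(nd$haplogroup) & nd$haplogroup == lab])
        if (length(base) == 1L && length(tips))
          rows[[paste0("HG_", lab)]] <- cbind(
            label = paste0("HG_", lab),
            .dateNodeOrNA(net, tips, base, cfg$mu, L, cfg$generationYears))
      }
      allTips <- nd$node[!nd$isMedian]
      for (endp in c(split$from, split$to))
        rows[[paste0("MRCA_at_", endp)]] <- cbind(
          label = paste0("MRCA_at_", endp),
          .dateNodeOrNA(net, allTips, endp, cfg$mu, L, cfg$generationYears))
    }
    dating <- if (length(rows)) do.call(rbind, rows) else
      data.frame(label = character())
    rownames(dating) <- NULL
    con <- file(out("dating.tsv"), "w")
    .writeHeader(con, hdr("dating"))
    write.table(dating, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    manifest$counts$dating <- list(nodes = nrow(dating))
    .stageMsg("dating", nrow(dating), " node(s) dated over L=", L, " bp")
  })

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
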