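# Window classification: scY / mcY / nonMSY from sexed read depth.
#
# Model: on a true Y window a male carries one Y per diploid genome, so his
# expected depth is 0.5 x copyNumber x his autosomal depth, while a female's
# is only a small mismapping leak (epsilon x autosomal). On a nonMSY window
# both sexes sit at their autosomal depth. Each window is scored by a
# Poisson log-likelihood of the observed per-sample depths under the three
# class hypotheses (mcY maximized over an integer copy-number grid) and
# assigned the argmax.

#' Normalize a depth table to per-sample mean 1
#'
#' Divides each sample's window depths by that sample's genome-wide mean
#' window depth, so samples of different sequencing depth become
#' comparable. Samples listed in `exclude` (typically the individual the
#' reference assembly derives from, whose self-mapping is uninformative)
#' are dropped from the output.
#'
#' @param wdt A raw [WindowDepthTable-class].
#' @param exclude Sample ids to drop before normalization.
#' @return A normalized [WindowDepthTable-class]; `colData()$meanDepth`
#'   records each sample's normalizer.
#' @export
normalizeDepths <- function(wdt, exclude = character()) {
  stopifnot(is(wdt, "WindowDepthTable"))
  if (isTRUE(metadata(wdt)$normalized)) stop("table is already normalized")
  keep <- setdiff(colnames(wdt), exclude)
  if (!length(keep)) stop("no samples left after exclusions")
  wdt <- wdt[, keep]
  depth <- assay(wdt, "depth")
  mns <- colMeans(depth)
  if (any(mns <= 0))
    stop("sample(s) with zero total depth: ",
         paste(colnames(depth)[mns <= 0], collapse = ", "))
  out <- SummarizedExperiment(
    assays = list(depth = sweep(depth, 2L, mns, "/")),
    rowRanges = rowRanges(wdt),
    colData = colData(wdt))
  out$meanDepth <- mns
  metadata(out) <- metadata(wdt)
  metadata(out)$normalized <- TRUE
  new("WindowDepthTable", out)
}

#' Classify windows into scY / mcY / nonMSY
#'
#' Scores each window under three hypotheses by a Poisson likelihood of
#' the per-sample normalized depths against class-expected rates `r`: 1
#' for both sexes (nonMSY); 0.5 for males and `epsilon` for females (scY,
#' the Y being haploid); `0.5 * k` for males (k on an integer grid
#' 2..maxCopy, best k reported) and `epsilon` for females (mcY). Samples
#' are weighted equally, so assignments depend only on normalized values
#' and are exactly invariant to rescaling any one sample's raw depths.
#' All-zero windows get the sentinel class `"nocall"` (no information).
#'
#' Because the table is normalized by the genome-wide mean of a
#' Y-enriched assembly (not by true autosomal depth), a second pass
#' recalibrates each sample against the windows initially classed nonMSY
#' (autosome-like) and rescores; this removes the composition bias of the
#' normalizer. The pass is skipped when fewer than `minRecal` windows are
#' available to calibrate on.
#'
#' @param norm A normalized [WindowDepthTable-class] (see [normalizeDepths()]).
#' @param epsilon Mismapping floor: expected female depth on true Y windows
#'   as a fraction of her autosomal depth (default 0.02).
#' @param maxCopy Upper bound of the mcY copy-number grid (default 20).
#' @param recalibrate Run the nonMSY recalibration pass (default TRUE).
#' @param minRecal Minimum nonMSY windows needed to recalibrate (default 20).
#' @return A `GRanges` of the windows with metadata columns `class`
#'   (factor scY/mcY/nonMSY/nocall), `copyNumber` (best k; 1 for scY, NA
#'   otherwise), per-class log-likelihood columns `llScY`, `llMcY`,
#'   `llNonMSY`, and any `trueClass` ground truth carried through.
#' @export
classifyWindows <- function(norm, epsilon = 0.02, maxCopy = 20,
                            recalibrate = TRUE, minRecal = 20) {
  stopifnot(is(norm, "WindowDepthTable"))
  if (!isTRUE(metadata(norm)$normalized))
    stop("classifyWindows needs a normalized table; run normalizeDepths() first")
  stopifnot(epsilon > 0, maxCopy >= 2)
  sex <- norm$sex
  if (!any(sex == "male") || !any(sex == "female"))
    stop("need at least one male and one female after exclusions")
  nd0 <- assay(norm, "depth")
  male <- sex == "male"
  ks <- 2:maxCopy
  # Poisson log-likelihood on normalized depths, per sample:
  # sum_s d_s log(r_s) - r_s with r_s the class-expected normalized rate.
  # Any common count scale multiplies all between-class score differences
  # equally, so assignments depend on the normalized values alone -- which
  # makes them exactly invariant to rescaling any one sample's raw depths.
  score <- function(nd) {
    llRatio <- function(rMale, rFemale) {
      r <- ifelse(male, rMale, rFemale)
      drop(nd %*% log(r)) - sum(r)
    }
    llNon <- llRatio(1, 1)
    llSc <- llRatio(0.5, epsilon)
    llMcK <- vapply(ks, function(k) llRatio(0.5 * k, epsilon), numeric(nrow(nd)))
    bestK <- ks[max.col(llMcK, ties.method = "first")]
    llMc <- llMcK[cbind(seq_len(nrow(nd)), match(bestK, ks))]
    scores <- cbind(scY = llSc, mcY = llMc, nonMSY = llNon)
    cls <- colnames(scores)[max.col(scores, ties.method = "last")]
    list(cls = cls, bestK = bestK, llSc = llSc, llMc = llMc, llNon = llNon)
  }
  fit <- score(nd0)
  if (recalibrate && sum(fit$cls == "nonMSY") >= minRecal) {
    f <- colMeans(nd0[fit$cls == "nonMSY", , drop = FALSE])
    if (all(f > 0)) fit <- score(sweep(nd0, 2L, f, "/"))
  }
  if (any(fit$bestK == maxCopy & fit$cls == "mcY"))
    message(sum(fit$bestK == maxCopy & fit$cls == "mcY"),
            " window(s) hit the copy-number grid cap k=", maxCopy)
  cls <- fit$cls
  nocall <- rowSums(nd0) == 0
  cls[nocall] <- "nocall"
  if (any(nocall)) message(sum(nocall), " all-zero window(s) assigned 'nocall'")
  out <- rowRanges(norm)
  out$class <- factor(cls, c("scY", "mcY", "nonMSY", "nocall"))
  out$copyNumber <- ifelse(cls == "mcY", fit$bestK,
                           ifelse(cls == "scY", 1L, NA_integer_))
  out$llScY <- fit$llSc; out$llMcY <- fit$llMc; out$llNonMSY <- fit$llNon
  out
}

#' Clean contigs by length and Y-specific content
#'
#' A contig is kept iff its length is at least `minLength` bp AND the
#' fraction of its windows classified scY or mcY is at least `minFraction`
#' (no-call windows count against the fraction). Per-class intervals on
#' kept contigs are merged into maximal runs.
#'
#' @param cls Classified windows (output of [classifyWindows()]).
#' @param lengths Named contig lengths in bp.
#' @param minLength Minimum contig length (default 200).
#' @param minFraction Minimum scY+mcY window fraction (default 0.5).
#' @return list with `report` (per-contig data.frame: length, per-class
#'   window counts, yFraction, kept), `scY` and `mcY` (merged `GRanges`
#'   restricted to kept contigs).
#' @export
cleanContigs <- function(cls, lengths, minLength = 200, minFraction = 0.5) {
  ctg <- as.character(seqnames(cls))
  unknown <- setdiff(unique(ctg), names(lengths))
  if (length(unknown))
    stop("no length entry for contig(s): ", paste(unknown, collapse = ", "))
  tab <- table(ctg, factor(cls$class, c("scY", "mcY", "nonMSY", "nocall")))
  counts <- as.data.frame.matrix(tab)
  contigs <- rownames(counts)
  total <- rowSums(counts)
  yFrac <- (counts$scY + counts$mcY) / total
  len <- as.numeric(lengths[contigs])
  kept <- len >= minLength & yFrac >= minFraction
  report <- data.frame(contig = contigs, length = len,
                       scY = counts$scY, mcY = counts$mcY,
                       nonMSY = counts$nonMSY, nocall = counts$nocall,
                       yFraction = yFrac, kept = kept,
                       row.names = NULL, stringsAsFactors = FALSE)
  keptSet <- contigs[kept]
  classBed <- function(k) {
    gr <- cls[as.character(cls$class) == k & ctg %in% keptSet]
    mcols(gr) <- NULL
    reduce(sort(gr))
  }
  list(report = report, scY = classBed("scY"), mcY = classBed("mcY"))
}

#' Assembly summary statistics
#'
#' N50 is the length of the contig at which the cumulative sum of
#' descending-sorted lengths first reaches half the total.
#'
#' @param lengths Positive contig lengths.
#' @return list with `totalBp`, `nContigs`, `n50`.
#' @export
assemblyStats <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (!length(lengths)) stop("empty length set")
  if (any(lengths <= 0)) stop("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  n50 <- s[which(cumsum(s) >= sum(s) / 2)[1L]]
  list(totalBp = sum(s), nContigs = length(s), n50 = n50)
}
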