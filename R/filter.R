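# Variant filter cascade and missing-call imputation. The cascade reduces
# a raw haploid VCF to biallelic SNVs inside single-copy Y regions; each
# dropped site gets exactly one primary reason, the first matching rule.

.FILTER_REASONS <- c("not_scY", "indel", "multiallelic", "heterozygous",
                     "phased", "reference_error", "empty", "below_thresholds")

# parse a GT string into called allele (0/1), NA if missing;
# attributes: het (two differing alleles), phased ("|" separator)
.parseGt <- function(g) {
  miss <- is.na(g) | g %in% c(".", "./.", ".|.")
  phased <- !miss & grepl("|", g, fixed = TRUE)
  parts <- strsplit(ifelse(miss, "0", g), "[/|]")
  het <- mapply(function(p) length(unique(p[p != "."])) > 1L, parts)
  allele <- vapply(parts, function(p) {
    p <- p[p != "."]
    if (!length(p)) NA_integer_ else suppressWarnings(as.integer(p[1L]))
  }, integer(1L))
  allele[miss] <- NA_integer_
  list(allele = allele, het = het & !miss, phased = phased, missing = miss)
}

#' Apply the single-copy-Y variant filter cascade
#'
#' Rules, in order (first failure recorded as the site's reason):
#' 1. inside an scY region; 2. SNV (REF and ALT both length 1);
#' 3. exactly one ALT; 4. no heterozygous genotype in any sample;
#' 5. no phase-annotated genotype; 6. not a reference error, i.e. not every
#' called ingroup sample carrying ALT (the reference is one individual's
#' consensus, so unanimity flags a wrong reference base, not a
#' polymorphism); 7. not all-missing; 8. at least one sample with
#' DP >= `dpMin` AND GQ > `gqMin`. Cells failing the per-sample thresholds
#' are demoted to missing rather than dropping the site.
#'
#' @param vcf Path to a VCF, or the record list from [readVcfGeno()].
#' @param scyBed scY regions: a `GRanges` or a BED path.
#' @param dpMin Minimum read depth (site kept if any sample reaches it;
#'   default 3).
#' @param gqMin Exclusive genotype-quality threshold (kept if any sample
#'   exceeds it; default 9).
#' @param outgroup Sample ids carried through but excluded from the
#'   reference-error unanimity test (and flagged in the output).
#' @param refErrorIncludeOutgroup Include outgroup samples in the
#'   unanimity test (default FALSE).
#' @return list with `gm` (a [GenotypeMatrix-class] of retained sites, DP
#'   and GQ kept as audit assays) and `log` (data.frame site/reason for
#'   dropped sites).
#' @export
filterVariants <- function(vcf, scyBed, dpMin = 3, gqMin = 9,
                           outgroup = character(),
                           refErrorIncludeOutgroup = FALSE) {
  rec <- if (is.character(vcf)) readVcfGeno(vcf) else vcf
  scy <- if (is.character(scyBed)) readBed(scyBed) else scyBed
  sites <- rec$sites
  if (!any(unique(sites$chrom) %in% seqlevels(scy)))
    stop("no VCF contig matches the scY BED (contig naming mismatch?)")
  samples <- rec$samples
  ingroup <- setdiff(samples, outgroup)
  if (!length(ingroup)) stop("no ingroup samples")
  n <- nrow(sites)
  siteGr <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L))
  inScy <- IRanges::overlapsAny(siteGr, scy)

  parsed <- apply(rec$gt, 2L, .parseGt, simplify = FALSE)
  allele <- vapply(parsed, `[[`, integer(n), "allele")
  het <- vapply(parsed, `[[`, logical(n), "het")
  phased <- vapply(parsed, `[[`, logical(n), "phased")
  if (n == 1L) { allele <- rbind(allele); het <- rbind(het); phased <- rbind(phased) }
  dimnames(allele) <- dimnames(het) <- dimnames(phased) <- dimnames(rec$gt)

  isSnv <- nchar(sites$ref) == 1L & nchar(sites$alt) == 1L & !grepl(",", sites$alt)
  oneAlt <- !grepl(",", sites$alt)
  refErrCols <- if (refErrorIncludeOutgroup) samples else ingroup
  called <- !is.na(allele[, refErrCols, drop = FALSE])
  refError <- rowSums(called) > 0L &
    rowSums(allele[, refErrCols, drop = FALSE] == 1L, na.rm = TRUE) == rowSums(called)
  allEmpty <- rowSums(!is.na(allele)) == 0L
  passCell <- !is.na(allele) & !is.na(rec$dp) & !is.na(rec$gq) &
    rec$dp >= dpMin & rec$gq > gqMin
  anyPass <- rowSums(passCell) > 0L

  reason <- rep(NA_character_, n)
  firstFail <- function(cond, why) {
    hit <- is.na(reason) & cond
    reason[hit] <<- why
  }
  firstFail(!inScy, "not_scY")
  firstFail(nchar(sites$ref) != 1L | (oneAlt & nchar(sites$alt) != 1L), "indel")
  firstFail(!oneAlt, "multiallelic")
  firstFail(rowSums(het) > 0L, "heterozygous")
  firstFail(rowSums(phased) > 0L, "phased")
  firstFail(refError, "reference_error")
  firstFail(allEmpty, "empty")
  firstFail(!anyPass, "below_thresholds")

  keep <- is.na(reason)
  log <- data.frame(site = paste0(sites$chrom, ":", sites$pos)[!keep],
                    reason = reason[!keep], stringsAsFactors = FALSE)
  gt <- allele
  gt[!passCell] <- NA_integer_   # demote sub-threshold cells
  gt <- gt[keep, , drop = FALSE]
  rr <- GRanges(sites$chrom[keep], IRanges(sites$pos[keep], width = 1L),
                ref = sites$ref[keep], alt = sites$alt[keep])
  names(rr) <- paste0(sites$chrom, ":", sites$pos)[keep]
  rownames(gt) <- names(rr)
  se <- SummarizedExperiment(
    assays = list(gt = gt,
                  dp = rec$dp[keep, , drop = FALSE],
                  gq = rec$gq[keep, , drop = FALSE]),
    rowRanges = rr,
    colData = DataFrame(outgroup = samples %in% outgroup, row.names = samples))
  list(gm = new("GenotypeMatrix", se), log = log)
}

# cluster samples on complete sites; cut the average-linkage tree at its
# largest merge-height gap (single cluster when no clear gap exists)
.provisionalClusters <- function(m) {
  ns <- nrow(m)
  if (ns < 3L) return(setNames(rep(1L, ns), rownames(m)))
  d <- dist(m, method = "manhattan")
  hc <- hclust(d, method = "average")
  h <- hc$height
  if (length(h) < 2L || max(diff(h)) <= 0) return(setNames(rep(1L, ns), rownames(m)))
  k <- length(h) - which.max(diff(h)) + 1L
  cutree(hc, k = k)
}

#' Impute missing genotype calls from the samples' clustering
#'
#' Builds a provisional clustering on complete sites (no missing call in
#' any sample), then fills each missing cell with the allele of the
#' nearest sample called at that site (Hamming distance on complete
#' sites). Ties are broken toward the majority allele among the tied
#' donors within the recipient's cluster, then toward the overall donor
#' majority, then toward REF. Every imputation is logged with its donor
#' set and distance.
#'
#' @param gm A [GenotypeMatrix-class].
#' @return list with `gm` (no missing cells) and `log` (data.frame:
#'   sample, site, allele, donors, distance, tie).
#' @export
imputeMissing <- function(gm) {
  stopifnot(is(gm, "GenotypeMatrix"))
  gt <- assay(gm, "gt")
  m <- t(gt)  # samples x sites
  allMissing <- rownames(m)[rowSums(!is.na(m)) == 0L]
  if (length(allMissing))
    stop("sample(s) with 100% missing calls cannot be placed: ",
         paste(allMissing, collapse = ", "))
  complete <- colSums(is.na(m)) == 0L
  if (!any(complete)) stop("no complete site to cluster on")
  mc <- m[, complete, drop = FALSE]
  clus <- .provisionalClusters(mc)
  d <- as.matrix(dist(mc, method = "manhattan"))
  log <- list()
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx)) {
    ord <- order(idx[, 2L], idx[, 1L])
    idx <- idx[ord, , drop = FALSE]
  }
  for (r in seq_len(nrow(idx))) {
    s <- idx[r, 1L]; j <- idx[r, 2L]
    donors <- which(!is.na(m[, j]) & seq_len(nrow(m)) != s)
    dd <- d[s, donors]
    nearest <- donors[dd == min(dd)]
    alleles <- m[nearest, j]
    tie <- length(unique(alleles)) > 1L
    if (!tie) a <- alleles[1L]
    else {
      inClus <- nearest[clus[nearest] == clus[s]]
      a <- .majorityAllele(m[inClus, j])
      if (is.na(a)) a <- .majorityAllele(alleles)
      if (is.na(a)) a <- 0L
    }
    m[s, j] <- a
    log[[length(log) + 1L]] <- data.frame(
      sample = rownames(m)[s], site = colnames(m)[j], allele = a,
      donors = paste(rownames(m)[nearest], collapse = ","),
      distance = min(dd), tie = tie, stringsAsFactors = FALSE)
  }
  out <- gm
  assays(out)$gt <- t(m)
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(sample = character(), site = character(), allele = integer(),
               donors = character(), distance = numeric(), tie = logical())
  list(gm = out, log = log)
}

# strict-majority allele; NA on tie or empty
.majorityAllele <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_integer_)
  n1 <- sum(x == 1L); n0 <- length(x) - n1
  if (n1 > n0) 1L else if (n0 > n1) 0L else NA_integer_
}
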