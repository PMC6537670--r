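# Readers and writers for the pipeline's on-disk formats. Coordinate
# conventions: BED is 0-based half-open on disk, VCF is 1-based; in memory
# everything is a 1-based GRanges. The two conversions live only here.

.writeHeader <- function(con, header) {
  if (length(header)) writeLines(paste0("# ", header), con)
}

#' Read a BED file into a GRanges
#'
#' 0-based half-open intervals on disk become 1-based closed GRanges.
#' Comment lines (leading `#`) are ignored. With `merge = TRUE` the result
#' is sorted and overlap-merged; otherwise overlapping intervals raise an
#' error (class region files must be disjoint).
#'
#' @param path BED file path.
#' @param merge Sort and merge overlapping intervals instead of erroring.
#' @return A `GRanges`; a `name` metadata column is kept when present.
#' @export
readBed <- function(path, merge = FALSE) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  tmp <- tempfile(fileext = ".bed")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  gr <- rtracklayer::import(tmp, format = "BED")
  if (any(start(gr) < 1L)) stop("negative coordinate in ", path)
  if (merge) return(reduce(sort(gr)))
  if (length(gr) > 1L) {
    hits <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
    if (length(hits)) stop("overlapping intervals in ", path)
  }
  gr
}

#' Write a GRanges as BED (0-based half-open)
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param name Optional metadata column to write as the BED name field.
#' @param header Optional comment lines (written with a leading `#`).
#' @export
writeBed <- function(gr, path, name = NULL, header = NULL) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  if (!is.null(name)) df$name <- as.character(mcols(gr)[[name]])
  con <- file(path, "w"); on.exit(close(con))
  .writeHeader(con, header)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write the per-window depth table
#'
#' TSV with header `contig`, `start` (0-based), `end`, then one column per
#' sample. Sex labels come from the sample sheet.
#'
#' @param path Depth TSV path.
#' @param cohort Sample sheet data.frame (`sample_id`, `sex`) or path to one.
#' @return A [WindowDepthTable-class] (raw).
#' @export
readDepthTable <- function(path, cohort) {
  if (is.character(cohort)) cohort <- readSampleSheet(cohort)
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
  sampleCols <- setdiff(names(tab), c("contig", "start", "end"))
  missing <- setdiff(sampleCols, cohort$sample_id)
  if (length(missing)) stop("samples absent from sheet: ", paste(missing, collapse = ", "))
  cohort <- cohort[match(sampleCols, cohort$sample_id), ]
  depth <- as.matrix(tab[, sampleCols, drop = FALSE])
  sl <- tapply(tab$end, tab$contig, max)
  gr <- GRanges(tab$contig, IRanges(tab$start + 1L, tab$end),
                seqinfo = Seqinfo(names(sl), as.integer(sl)))
  se <- SummarizedExperiment(
    assays = list(depth = depth), rowRanges = gr,
    colData = DataFrame(sex = cohort$sex, row.names = cohort$sample_id))
  metadata(se)$normalized <- FALSE
  new("WindowDepthTable", se)
}

#' @rdname readDepthTable
#' @param wdt A [WindowDepthTable-class].
#' @param header Optional comment lines.
#' @export
writeDepthTable <- function(wdt, path, header = NULL) {
  gr <- rowRanges(wdt)
  df <- data.frame(contig = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(assay(wdt, "depth"), check.names = FALSE))
  con <- file(path, "w"); on.exit(close(con))
  .writeHeader(con, header)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sample sheet (sample_id, sex[, mean_depth])
#' @param path TSV path.
#' @export
readSampleSheet <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "sex") %in% names(tab)))
  if (!all(tab$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  tab
}

#' @rdname readSampleSheet
#' @param cohort Sample sheet data.frame.
#' @param header Optional comment lines.
#' @export
writeSampleSheet <- function(cohort, path, header = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  .writeHeader(con, header)
  write.table(cohort, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# GT integer -> VCF string
.gtString <- function(g) ifelse(is.na(g), ".", as.character(g))

#' Write haploid genotypes as a VCF 4.2 file
#'
#' One record per site with FORMAT `GT:DP:GQ`; genotypes are haploid
#' (`0`, `1` or `.`).
#'
#' @param sites GRanges with `ref`/`alt` metadata columns (width-1 ranges).
#' @param gt Integer matrix sites x samples (0/1/NA).
#' @param dp,gq Numeric matrices, same shape as `gt`.
#' @param path Output path.
#' @param header Extra `##`-style meta lines to include.
#' @export
writeVcfGeno <- function(sites, gt, dp, gq, path, header = NULL) {
  stopifnot(nrow(gt) == length(sites))
  samples <- colnames(gt)
  meta <- c("##fileformat=VCFv4.2",
            paste0("##contig=<ID=", seqlevels(sites), ">"),
            '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
            '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
            '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
            header,
            paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", samples), collapse = "\t"))
  body <- character(length(sites))
  for (i in seq_along(sites)) {
    cells <- paste(.gtString(gt[i, ]), dp[i, ], gq[i, ], sep = ":")
    body[i] <- paste(c(as.character(seqnames(sites))[i], start(sites)[i], ".",
                       sites$ref[i], sites$alt[i], ".", "PASS", ".",
                       "GT:DP:GQ", cells), collapse = "\t")
  }
  writeLines(c(meta, body), path)
  invisible(path)
}

#' Read a VCF into the record structure the filter consumes
#'
#' Parses with `vcfR` and extracts per-sample GT (verbatim string), DP and
#' GQ. Both haploid (`0`, `1`, `.`) and diploid (`0/1`, `0|1`, ...)
#' genotype encodings are accepted; interpretation (het/phased/missing)
#' happens in [filterVariants()].
#'
#' @param path VCF path.
#' @return list with `sites` (data.frame chrom/pos/ref/alt), character
#'   matrix `gt`, numeric matrices `dp` and `gq`, and `samples`.
#' @export
readVcfGeno <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  for (need in c("GT", "DP", "GQ"))
    if (!need %in% fmt) stop("VCF lacks FORMAT field ", need)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  rn <- paste0(sites$chrom, ":", sites$pos)
  rownames(gt) <- rownames(dp) <- rownames(gq) <- rn
  list(sites = sites, gt = gt, dp = dp, gq = gq, samples = colnames(gt))
}

#' Write a genotype matrix as TSV (one row per site)
#'
#' Columns: contig, pos (1-based), ref, alt, then one 0/1/NA column per
#' sample.
#'
#' @param gm A [GenotypeMatrix-class].
#' @param path Output path.
#' @param header Optional comment lines.
#' @export
writeGenotypeMatrix <- function(gm, path, header = NULL) {
  rr <- rowRanges(gm)
  df <- data.frame(contig = as.character(seqnames(rr)), pos = start(rr),
                   ref = rr$ref, alt = rr$alt, check.names = FALSE)
  df <- cbind(df, as.data.frame(assay(gm, "gt"), check.names = FALSE))
  con <- file(path, "w"); on.exit(close(con))
  .writeHeader(con, header)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGenotypeMatrix
#' @export
readGenotypeMatrix <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
  samples <- setdiff(names(tab), c("contig", "pos", "ref", "alt"))
  gt <- as.matrix(tab[, samples, drop = FALSE])
  mode(gt) <- "integer"
  rownames(gt) <- paste0(tab$contig, ":", tab$pos)
  sites <- GRanges(tab$contig, IRanges(tab$pos, width = 1L),
                   ref = tab$ref, alt = tab$alt)
  names(sites) <- rownames(gt)
  se <- SummarizedExperiment(
    assays = list(gt = gt), rowRanges = sites,
    colData = DataFrame(outgroup = rep(FALSE, length(samples)),
                        row.names = samples))
  new("GenotypeMatrix", se)
}
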