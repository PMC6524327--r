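#' Read a BED file of target intervals
#'
#' Reads BED3+ (0-based, half-open) into a `GRanges` object. Only the first
#' three columns are used; track/browser/comment lines are skipped.
#'
#' @param file Path to a BED file.
#' @param strip_chr If `TRUE`, normalise contig names by removing a leading
#'   `"chr"` prefix; capture kits differ in this convention.
#' @return A `GRanges` with 1-based inclusive coordinates (converted at this
#'   boundary; everything downstream is 1-based).
#' @export
read_bed <- function(file, strip_chr = FALSE) {
  lines <- readLines(file)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", which(nf < 3L)[1], " in ", file,
         ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0) | start0 < 0 | end0 <= start0)
  if (length(bad)) {
    stop("malformed BED line ", bad[1], " in ", file)
  }
  if (strip_chr) chrom <- sub("^chr", "", chrom)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
}

#' Write intervals to a BED file
#'
#' @param gr A `GRanges` (1-based inclusive internally).
#' @param file Output path; written as BED3 (0-based half-open).
#' @export
write_bed <- function(gr, file) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Intersect capture-kit target regions
#'
#' Cross-kit analyses are restricted to the base-pair intersection of the
#' kits' target BED files so that all samples are scored over identically
#' targeted regions. A minimum-depth mask can be passed as just another BED
#' in the list. With one input the result is simply its merged intervals.
#'
#' @param beds A list of BED file paths and/or `GRanges` objects (at least
#'   one).
#' @param strip_chr Passed to [read_bed()] for file inputs.
#' @return A merged, sorted, disjoint `GRanges` of the intersection.
#' @export
intersect_beds <- function(beds, strip_chr = FALSE) {
  if (!is.list(beds)) beds <- as.list(beds)
  if (!length(beds)) stop("at least one BED input required")
  grs <- lapply(beds, function(b) {
    gr <- if (is.character(b)) read_bed(b, strip_chr = strip_chr) else b
    GenomicRanges::reduce(gr)
  })
  # kits rarely target identical contig sets; put all inputs on the union
  all_levels <- unique(unlist(lapply(grs, GenomeInfoDb::seqlevels)))
  grs <- lapply(grs, function(g) {
    GenomeInfoDb::seqlevels(g) <- all_levels
    g
  })
  out <- Reduce(function(a, b) {
    GenomicRanges::intersect(a, b, ignore.strand = TRUE)
  }, grs)
  out <- GenomicRanges::sort(GenomicRanges::reduce(out))
  if (!length(out)) warning("empty target-region intersection")
  out
}

#' Read a gene model (exonic intervals per gene)
#'
#' Accepts a 4-column TSV/BED (`chrom`, `start`, `end`, `gene`; 0-based
#' half-open, headerless or with a header) mapping exonic intervals to gene
#' symbols.
#'
#' @param file Path to the gene model file.
#' @param strip_chr As in [read_bed()].
#' @return A `GRanges` with a `gene` metadata column.
#' @export
read_gene_model <- function(file, strip_chr = FALSE) {
  d <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE,
                         comment.char = "#")
  if (ncol(d) < 4L) stop("gene model needs 4 columns: chrom, start, end, gene")
  if (is.na(suppressWarnings(as.numeric(d[1, 2])))) d <- d[-1, , drop = FALSE]
  chrom <- as.character(d[[1]])
  if (strip_chr) chrom <- sub("^chr", "", chrom)
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(as.numeric(d[[2]]) + 1, as.numeric(d[[3]]))
  )
  S4Vectors::mcols(gr)$gene <- as.character(d[[4]])
  gr
}

#' Per-gene targeted length within harmonised regions
#'
#' Sums, for each gene, the overlap in base pairs between the gene model's
#' exonic intervals and the harmonised target regions. Genes with no overlap
#' are omitted (with a warning): they have no targeted length and cannot be
#' length-corrected.
#'
#' @param regions A `GRanges` of target regions (e.g. from
#'   [intersect_beds()]).
#' @param gene_model A `GRanges` with a `gene` metadata column (e.g. from
#'   [read_gene_model()]).
#' @return Named numeric vector: targeted base pairs per gene symbol.
#' @export
gene_targeted_length <- function(regions, gene_model) {
  genes <- unique(S4Vectors::mcols(gene_model)$gene)
  regions <- GenomicRanges::reduce(regions)
  # collapse per-gene exon overlaps so no base is counted twice
  by_gene <- GenomicRanges::reduce(
    GenomicRanges::split(gene_model, S4Vectors::mcols(gene_model)$gene)
  )
  gene_model <- unlist(by_gene, use.names = FALSE)
  S4Vectors::mcols(gene_model)$gene <- rep(names(by_gene), lengths(by_gene))
  hits <- GenomicRanges::findOverlaps(gene_model, regions,
                                      ignore.strand = TRUE)
  if (length(hits)) {
    ov <- IRanges::pintersect(
      gene_model[S4Vectors::queryHits(hits)],
      regions[S4Vectors::subjectHits(hits)]
    )
    bp <- tapply(IRanges::width(ov),
                 S4Vectors::mcols(gene_model)$gene[S4Vectors::queryHits(hits)],
                 sum)
    lengths <- stats::setNames(as.numeric(bp), names(bp))
  } else {
    lengths <- stats::setNames(numeric(0), character(0))
  }
  dropped <- setdiff(genes, names(lengths))
  if (length(dropped)) {
    warning(length(dropped), " gene(s) have no overlap with the target ",
            "regions and are omitted: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  lengths
}
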