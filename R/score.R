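#' Single-variant pathogenicity contribution
#'
#' The per-variant score is `-D * log10(f1 * f2)`, where `D` is the
#' normalised deleteriousness of the mutated allele and `f1`, `f2` are the
#' population frequencies of the two observed alleles. A homozygous genotype
#' passes the allele frequency twice (frequency squared), a heterozygous
#' genotype passes the two observed alleles' frequencies, and a hemizygous
#' genotype (male X) passes the single observed allele's frequency twice.
#' With the default frequency floor of 1e-5 the single-variant score is
#' bounded by 10 (homozygous novel, D = 1); the heterozygote-versus-common-
#' reference limit is 5.
#'
#' @param d Deleteriousness in \[0, 1\].
#' @param f1,f2 Observed-allele population frequencies in (0, 1\].
#' @return Non-negative score(s); vectorised over the inputs.
#' @export
#' @examples
#' variant_score(1, 1e-5, 1e-5)    # 10: theoretical single-variant maximum
#' variant_score(1, 1e-5, 0.99999) # ~5: rare heterozygote limit
#' variant_score(1, 0.5, 0.5)      # 0.60206: common homozygote
variant_score <- function(d, f1, f2) {
  if (any(is.na(d)) || any(d < 0 | d > 1)) {
    stop("deleteriousness D out of range [0, 1]")
  }
  if (any(is.na(f1)) || any(is.na(f2)) ||
      any(f1 <= 0 | f1 > 1) || any(f2 <= 0 | f2 > 1)) {
    stop("allele frequency out of range (0, 1]")
  }
  -d * log10(f1 * f2)
}

#' Aggregate variant contributions to a gene score
#'
#' Variant effects combine additively at the gene level: the gene score is
#' the plain sum of the per-variant contributions observed in that sample.
#'
#' @param contributions Numeric vector of per-variant scores for one
#'   (sample, gene) pair; may be empty.
#' @return The sum; 0 for an empty vector (an invariant gene).
#' @export
gene_score <- function(contributions) {
  if (!length(contributions)) return(0)
  sum(contributions)
}

#' Gene-length correction
#'
#' Larger genes accrue more variants and hence inflated burden scores. The
#' corrected score divides by the gene's targeted length in base pairs and
#' multiplies by the cohort's median targeted gene length (1461 bp by
#' default).
#'
#' @param score Uncorrected gene score(s).
#' @param targeted_length Targeted length of the gene in base pairs (> 0).
#' @param median_length Median targeted gene length constant, bp.
#' @param gene Optional gene symbol used in the error message.
#' @return `score * median_length / targeted_length`.
#' @export
#' @examples
#' length_correct(2, 2922)  # 1: gene twice the median length
length_correct <- function(score, targeted_length, median_length = 1461,
                           gene = NULL) {
  if (any(is.na(targeted_length)) || any(targeted_length <= 0)) {
    stop("nonpositive targeted length",
         if (!is.null(gene)) paste0(" for gene ", gene),
         " (gene absent from target regions)")
  }
  score * median_length / targeted_length
}

# Score one genotype at one site. Returns list(score=, rows=) where rows
# indexes the site's alt-allele rows contributing the gene assignment, or
# NULL for a non-contributing genotype.
.genotype_contribution <- function(alleles, d, f_ref, f_alt, hemizygous) {
  if (is.null(alleles)) return(NULL)               # missing genotype
  alts <- alleles[alleles >= 1L]
  if (!length(alts)) return(NULL)                  # homozygous reference
  if (hemizygous || length(alleles) == 1L) {
    # single observed copy: frequency squared, best-annotated alt drives D
    cand <- unique(alts)
    dd <- d[cand]
    if (all(is.na(dd))) return(NULL)
    k <- cand[which.max(dd)]
    return(list(score = -d[k] * log10(f_alt[k]^2), rows = k))
  }
  a1 <- alleles[1L]; a2 <- alleles[2L]
  f1 <- if (a1 == 0L) f_ref else f_alt[a1]
  f2 <- if (a2 == 0L) f_ref else f_alt[a2]
  cand <- unique(alts)
  dd <- d[cand]
  if (all(is.na(dd))) return(NULL)
  dmax <- max(dd, na.rm = TRUE)
  list(score = -dmax * log10(f1 * f2), rows = cand[!is.na(dd)])
}

#' Compute per-individual, per-gene pathogenicity burden scores
#'
#' The central constructor: runs the full per-variant pipeline (class
#' exclusion, truncating override / metric normalisation, allele-frequency
#' resolution with the rarity floor, zygosity-aware frequency products,
#' within-gene summation) over a multi-sample cohort and returns the
#' samples x genes score matrix as a classed object.
#'
#' Protein-truncating variants receive D = 1 regardless of metric
#' annotation; synonymous and splicing variants are excluded; variants
#' lacking a value for the chosen metric are skipped for that metric.
#' Hemizygous male-X genotypes (and single-allele chrY/MT genotypes) are
#' scored as homozygous (frequency squared). Missing genotypes contribute
#' nothing. A variant annotated to several genes (`"GENE1;GENE2"`)
#' contributes to each.
#'
#' @param vcf_file Path to the cohort VCF, or a pre-read `genepy_cohort`
#'   object (in which case `annotations`, `sex_file` and `info_map` are
#'   ignored).
#' @param annotations Sidecar annotation TSV path or data frame; `NULL` to
#'   read annotations from INFO (see [read_cohort()]).
#' @param metric Deleteriousness metric name (see [genepy_metrics()]).
#' @param regions Target regions: a `GRanges`, a character vector of BED
#'   paths (intersected with [intersect_beds()]), or `NULL` for no region
#'   filter.
#' @param gene_model Gene model (`GRanges` with `gene` column, or a file for
#'   [read_gene_model()]); needed with `corrected = TRUE` unless
#'   `gene_lengths` is given.
#' @param corrected If `TRUE`, length-correct every gene score.
#' @param gene_lengths Optional named vector of targeted lengths (bp) per
#'   gene, bypassing `regions`/`gene_model` for the correction.
#' @param floor Allele-frequency floor (default 1e-5).
#' @param median_length Median targeted gene length constant (bp) for the
#'   correction; `NULL` recomputes it as the median of the supplied targeted
#'   lengths (the constant is cohort-specific by construction).
#' @param sex_file Sample sex TSV for the hemizygosity rule.
#' @param info_map INFO key mapping for annotation-in-INFO input.
#' @param verbose Log per-stage variant counts.
#' @return An object of class `genepy` with components `scores` (samples x
#'   genes matrix), `metric`, `corrected`, `floor`, `median_length`,
#'   `gene_lengths`, and `counts` (per-stage alt-allele tallies).
#' @seealso [summary.genepy()], [gene_zscores()], [compare_gene()]
#' @export
genepy <- function(vcf_file, annotations = NULL, metric = "CADD",
                   regions = NULL, gene_model = NULL, corrected = FALSE,
                   gene_lengths = NULL, floor = 1e-5, median_length = 1461,
                   sex_file = NULL, info_map = NULL, verbose = FALSE) {
  cohort <- if (inherits(vcf_file, "genepy_cohort")) vcf_file else
    read_cohort(vcf_file, annotations = annotations, sex_file = sex_file,
                info_map = info_map)
  spec <- metric_spec(metric)
  v <- cohort$variants
  n_sites <- nrow(cohort$sites)

  if (is.character(regions) && length(regions)) {
    regions <- intersect_beds(as.list(regions))
  }
  if (is.character(gene_model)) gene_model <- read_gene_model(gene_model)

  excluded <- is_excluded_class(v$func_class)
  d <- transform_metric(cohort$raw[, metric], spec, cohort$aux_class)
  d[is_truncating(v$func_class)] <- 1
  d[excluded] <- NA_real_

  if (!is.null(regions)) {
    vgr <- GenomicRanges::GRanges(
      v$chrom, IRanges::IRanges(v$pos, v$pos)
    )
    inside <- IRanges::overlapsAny(vgr, regions, ignore.strand = TRUE)
  } else {
    inside <- rep(TRUE, nrow(v))
  }
  d[!inside] <- NA_real_

  counts <- c(
    read = nrow(v),
    excluded_class = sum(excluded),
    outside_target = sum(!inside & !excluded),
    missing_metric = sum(is.na(d) & !excluded & inside),
    scored = sum(!is.na(d))
  )
  if (verbose) {
    message("alt alleles read: ", counts["read"],
            "; excluded class: ", counts["excluded_class"],
            "; outside target: ", counts["outside_target"],
            "; missing ", metric, ": ", counts["missing_metric"],
            "; scored: ", counts["scored"])
  }

  gene_split <- strsplit(ifelse(is.na(v$gene), "", v$gene), "[;,]")
  gene_split <- lapply(gene_split, function(g) g[nzchar(g)])
  genes <- sort(unique(unlist(gene_split)))
  samples <- cohort$samples
  M <- matrix(0, length(samples), length(genes),
              dimnames = list(samples, genes))

  site_f <- lapply(split(v$af, factor(v$site, levels = seq_len(n_sites))),
                   resolve_allele_frequencies, floor = floor)
  rows_by_site <- split(seq_len(nrow(v)),
                        factor(v$site, levels = seq_len(n_sites)))

  is_male <- rep(FALSE, length(samples))
  if (!is.null(cohort$sex)) {
    sx <- cohort$sex[samples]
    is_male <- !is.na(sx) & sx == "M"
  }

  for (i in seq_len(n_sites)) {
    rows <- rows_by_site[[i]]
    d_site <- d[rows]
    if (all(is.na(d_site))) next
    fr <- site_f[[i]]
    f_ref <- fr[1L]
    f_alt <- fr[-1L]
    chrom <- cohort$sites$chrom[i]
    x_contig <- chrom %in% c("X", "chrX")
    hemi_contig <- chrom %in% c("Y", "chrY", "MT", "M", "chrM", "chrMT")
    g <- cohort$gt[i, ]
    ug <- unique(g)
    parsed <- .parse_gt(ug)
    for (j in seq_along(ug)) {
      sel <- which(g == ug[j] | (is.na(g) & is.na(ug[j])))
      modes <- if (x_contig && any(is_male[sel])) c(FALSE, TRUE) else
        hemi_contig
      for (hemi in unique(modes)) {
        ss <- if (x_contig) sel[is_male[sel] == hemi] else sel
        if (!length(ss)) next
        contrib <- .genotype_contribution(parsed[[j]], d_site, f_ref, f_alt,
                                          hemizygous = hemi || hemi_contig)
        if (is.null(contrib) || contrib$score == 0) next
        target_genes <- unique(unlist(gene_split[rows[contrib$rows]]))
        for (gn in target_genes) {
          M[ss, gn] <- M[ss, gn] + contrib$score
        }
      }
    }
  }

  out_lengths <- gene_lengths
  if (corrected) {
    if (is.null(out_lengths)) {
      if (is.null(regions) || is.null(gene_model)) {
        stop("corrected scores need gene_lengths, or regions + gene_model")
      }
      out_lengths <- gene_targeted_length(regions, gene_model)
    }
    if (is.null(median_length)) {
      median_length <- stats::median(out_lengths)
    }
    missing_len <- setdiff(genes, names(out_lengths))
    if (length(missing_len)) {
      warning(length(missing_len), " gene(s) without targeted length ",
              "dropped from the corrected matrix: ",
              paste(utils::head(missing_len, 5), collapse = ", "),
              if (length(missing_len) > 5) ", ..." else "")
      M <- M[, setdiff(genes, missing_len), drop = FALSE]
    }
    M <- sweep(M, 2, out_lengths[colnames(M)], function(s, len) {
      length_correct(s, len, median_length)
    })
  }

  structure(
    list(scores = M, metric = metric, corrected = corrected, floor = floor,
         median_length = if (corrected) median_length else NA_real_,
         gene_lengths = out_lengths, counts = counts,
         call = match.call()),
    class = "genepy"
  )
}

.corrected_label <- function(corrected) {
  if (isTRUE(corrected)) "length-corrected"
  else if (isFALSE(corrected)) "uncorrected"
  else "correction state unknown"
}

#' @export
print.genepy <- function(x, ...) {
  cat("Gene pathogenicity burden scores (",
      .corrected_label(x$corrected), ")\n",
      sep = "")
  cat("  metric: ", x$metric, ", frequency floor: ", x$floor, "\n", sep = "")
  cat("  ", nrow(x$scores), " samples x ", ncol(x$scores), " genes\n",
      sep = "")
  if (isTRUE(x$corrected)) {
    cat("  median-length constant: ", x$median_length, " bp\n", sep = "")
  }
  invisible(x)
}

#' @export
as.matrix.genepy <- function(x, ...) x$scores

#' Histogram of gene scores at fixed bin width
#'
#' Bins every cell of the score matrix into left-closed bins of fixed width
#' (default 0.01). Scores below 0.01 — the overrepresented invariant bulk —
#' can be dropped so the remaining profile is visible.
#'
#' @param x A `genepy` object or a numeric matrix/vector of scores.
#' @param bin_width Bin width (default 0.01).
#' @param drop_low Drop bins entirely below 0.01 (default `TRUE`).
#' @return Data frame with `bin_start`, `bin_end`, `count`, empty bins
#'   omitted.
#' @export
score_histogram <- function(x, bin_width = 0.01, drop_low = TRUE) {
  vals <- if (inherits(x, "genepy")) as.vector(x$scores) else as.vector(x)
  idx <- floor(vals / bin_width)
  if (drop_low) idx <- idx[vals >= 0.01]
  tab <- table(idx)
  starts <- as.numeric(names(tab)) * bin_width
  data.frame(bin_start = starts, bin_end = starts + bin_width,
             count = as.integer(tab))
}

#' Summarise a score matrix
#'
#' Computes the matrix-level descriptive statistics used to characterise a
#' cohort's score distribution: per-sample invariant-gene counts, overall
#' maximum and mean, coefficient of variation (population sigma / mu),
#' per-sample counts of genes scoring below 0.01, and the binned score
#' histogram.
#'
#' @param object A `genepy` object.
#' @param bin_width Histogram bin width.
#' @param drop_low Drop sub-0.01 histogram bins.
#' @param ... Unused.
#' @return An object of class `summary.genepy`.
#' @export
summary.genepy <- function(object, bin_width = 0.01, drop_low = TRUE, ...) {
  M <- object$scores
  mu <- mean(M)
  sigma <- sqrt(mean((M - mu)^2))
  cv <- if (mu > 0) sigma / mu else NA_real_
  zero_genes <- apply(M, 1, function(r) sum(r == 0))
  low_genes <- apply(M, 1, function(r) sum(r < 0.01))
  structure(
    list(metric = object$metric, corrected = object$corrected,
         n_samples = nrow(M), n_genes = ncol(M),
         zero_genes = zero_genes,
         median_zero_genes = stats::median(zero_genes),
         max = max(M), mean = mu, cv = cv,
         low_genes = low_genes,
         median_low_genes = stats::median(low_genes),
         histogram = score_histogram(M, bin_width, drop_low)),
    class = "summary.genepy"
  )
}

#' @export
print.summary.genepy <- function(x, ...) {
  cat("Score matrix summary (", x$metric, ", ",
      .corrected_label(x$corrected), ")\n",
      sep = "")
  cat(sprintf("  %d samples x %d genes\n", x$n_samples, x$n_genes))
  cat(sprintf("  median invariant genes per sample: %s (%.2f%%)\n",
              format(x$median_zero_genes),
              100 * x$median_zero_genes / x$n_genes))
  cat(sprintf("  max score: %.4g   mean score: %.4g   CV: %s\n",
              x$max, x$mean,
              if (is.na(x$cv)) "undefined" else sprintf("%.4g", x$cv)))
  cat(sprintf("  median genes < 0.01 per sample: %s (%.2f%%)\n",
              format(x$median_low_genes),
              100 * x$median_low_genes / x$n_genes))
  invisible(x)
}

#' Plot the binned score profile
#'
#' @param x A `genepy` object.
#' @param bin_width Histogram bin width (default 0.01).
#' @param drop_low Drop the overrepresented sub-0.01 bins.
#' @param xlim Optional x-axis limits.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.genepy <- function(x, bin_width = 0.01, drop_low = TRUE, xlim = NULL,
                        ...) {
  h <- score_histogram(x, bin_width, drop_low)
  graphics::plot(h$bin_start + bin_width / 2, h$count, type = "h",
                 xlab = "gene score", ylab = "count", xlim = xlim,
                 main = paste0(x$metric,
                               if (isTRUE(x$corrected)) " (corrected)" else ""),
                 ...)
  invisible(h)
}

#' Per-gene Z-score profiles
#'
#' Standardises each gene's scores across the full cohort
#' (`(score - gene mean) / gene sd`, population sd) and returns the profile
#' for selected samples and genes — the transform used to plot individual
#' patients' gene-level profiles on a common scale.
#'
#' @param x A `genepy` object.
#' @param genes Genes to report (default all).
#' @param samples Samples to report (default all).
#' @return Matrix of Z-scores (samples x genes). Zero-variance genes get
#'   Z = 0 everywhere, with a warning.
#' @export
gene_zscores <- function(x, genes = NULL, samples = NULL) {
  M <- x$scores
  mu <- colMeans(M)
  sigma <- sqrt(colMeans(sweep(M, 2, mu)^2))
  flat <- sigma == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance gene(s); Z set to 0: ",
            paste(utils::head(colnames(M)[flat], 5), collapse = ", "),
            if (sum(flat) > 5) ", ..." else "")
    sigma[flat] <- 1
  }
  Z <- sweep(sweep(M, 2, mu), 2, sigma, "/")
  Z[, flat] <- 0
  if (!is.null(genes)) {
    missing <- setdiff(genes, colnames(Z))
    if (length(missing)) stop("gene(s) not in matrix: ",
                              paste(missing, collapse = ", "))
    Z <- Z[, genes, drop = FALSE]
  }
  if (!is.null(samples)) Z <- Z[samples, , drop = FALSE]
  Z
}

#' Write / read a score matrix as TSV
#'
#' Samples as rows, genes as columns, first column `sample_id`; values with
#' six significant digits so analytic anchors survive a round trip.
#'
#' @param x A `genepy` object or a numeric matrix with dimnames.
#' @param file Output path.
#' @export
write_score_matrix <- function(x, file) {
  M <- if (inherits(x, "genepy")) x$scores else x
  df <- data.frame(sample_id = rownames(M),
                   signif(M, 6), check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_score_matrix
#' @return `read_score_matrix` returns the numeric matrix (samples x genes).
#' @export
read_score_matrix <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE,
                          stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  storage.mode(M) <- "double"
  M
}
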