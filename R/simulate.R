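# Synthetic cohorts: a self-contained generator writing the full input
# bundle (VCF + annotation TSV + capture BEDs + gene model + phenotype and
# sex TSVs) with a known ground-truth score matrix, so the whole pipeline is
# testable without external data.

#' Simulation configuration
#'
#' Builds the configuration for [simulate_cohort()]. The defaults describe a
#' desk-scale case/control exome cohort: 170 cases and 170 controls, twenty
#' genes, variant allele frequencies log-uniform between the frequency floor
#' and 0.5, deleteriousness Beta(0.5, 0.5)-distributed, an exome-like
#' functional-class mix, and one causal gene in which 30% of cases but only
#' 5% of controls carry a rare (MAF 1e-4) heterozygous variant of
#' deleteriousness 0.9.
#'
#' @param n_cases,n_controls Sample counts per group.
#' @param genes Optional data frame (`gene`, `length`, `n_variants`)
#'   overriding the generated gene table.
#' @param n_genes Number of genes when `genes` is NULL.
#' @param metrics Metric columns to emit in the annotation TSV; raw values
#'   are produced by inverting each metric's transform so the normalisation
#'   path is exercised, not bypassed.
#' @param maf_range Range for log-uniform MAF sampling.
#' @param d_shape Beta shape parameters for deleteriousness sampling.
#' @param class_probs Named functional-class sampling weights.
#' @param causal Data frame (`gene`, `carrier_case`, `carrier_control`,
#'   `maf`, `d`, `zygosity`) of causal variants, or NULL for none.
#' @param x_genes Gene symbols placed on chrX (hemizygous in males).
#' @param male_fraction Fraction of male samples.
#' @param floor Frequency floor used for the ground truth.
#' @param af_noise Multiplicative lognormal noise sd on annotated MAFs
#'   (0 = annotated MAF equals the sampling MAF).
#' @param mt_np_fraction Fraction of variants given a MutationTaster N/P
#'   class (the rest are A/D), when MutationTaster is among `metrics`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 170, n_controls = 170, genes = NULL,
                       n_genes = 20, metrics = c("CADD", "SIFT", "M-CAP"),
                       maf_range = c(1e-5, 0.5), d_shape = c(0.5, 0.5),
                       class_probs = c("nonsynonymous SNV" = 0.75,
                                       "synonymous SNV" = 0.15,
                                       "splicing" = 0.05,
                                       "stopgain" = 0.04,
                                       "frameshift deletion" = 0.01),
                       causal = data.frame(gene = "GENE001",
                                           carrier_case = 0.30,
                                           carrier_control = 0.05,
                                           maf = 1e-4, d = 0.9,
                                           zygosity = "het"),
                       x_genes = character(0), male_fraction = 0.5,
                       floor = 1e-5, af_noise = 0, mt_np_fraction = 0.25) {
  cfg <- list(n_cases = n_cases, n_controls = n_controls, genes = genes,
              n_genes = n_genes, metrics = metrics, maf_range = maf_range,
              d_shape = d_shape, class_probs = class_probs, causal = causal,
              x_genes = x_genes, male_fraction = male_fraction,
              floor = floor, af_noise = af_noise,
              mt_np_fraction = mt_np_fraction)
  stopifnot(n_cases >= 0, n_controls >= 0,
            male_fraction >= 0, male_fraction <= 1)
  class(cfg) <- "sim_config"
  cfg
}

# Invert the metric transform: raw value whose transform() equals d.
.invert_transform <- function(d, spec, aux_class = NULL) {
  x <- d
  if (identical(spec$conditional_rule, "class_dependent")) {
    flip <- !is.null(aux_class) & aux_class %in% c("N", "P")
    x <- ifelse(flip, 1 - d, d)
  } else if (isTRUE(spec$complement)) {
    x <- 1 - d
  }
  x * (spec$upper_bound - spec$lower_bound) + spec$lower_bound
}

.write_vcf <- function(file, variants, gt, samples) {
  contigs <- unique(variants$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=genepyr-simulate",
    paste0("##contig=<ID=", contigs, ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                variants$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), file)
  invisible(file)
}

.write_annotations <- function(file, variants, metrics, mt_class) {
  specs <- lapply(metrics, metric_spec)
  # full double precision so the pipeline reproduces the ground truth exactly
  ann <- data.frame(chrom = variants$chrom, pos = variants$pos,
                    ref = variants$ref, alt = variants$alt,
                    gene = variants$gene, func_class = variants$class,
                    af = sprintf("%.17g", variants$af_annotated),
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (s in specs) {
    ann[[s$name]] <- sprintf("%.17g",
                             .invert_transform(variants$d, s, mt_class))
  }
  if ("MutationTaster" %in% metrics) ann$MutationTaster_class <- mt_class
  utils::write.table(ann, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

# Ground truth, written directly from the score equation on the simulated
# genotypes (independent of the ingest/transform/scoring pipeline).
.truth_matrix <- function(variants, gt, samples, genes, floor) {
  M <- matrix(0, length(samples), length(genes),
              dimnames = list(samples, genes))
  truncating <- is_truncating(variants$class)
  excluded <- is_excluded_class(variants$class)
  for (i in seq_len(nrow(variants))) {
    if (excluded[i]) next
    d <- if (truncating[i]) 1 else variants$d[i]
    fa <- max(variants$maf[i], floor)
    fr <- max(1 - fa, floor)
    g <- gt[i, ]
    s <- numeric(length(samples))
    s[g == "0/1"] <- -d * log10(fa * fr)
    s[g %in% c("1/1", "1")] <- -d * log10(fa * fa)
    M[, variants$gene[i]] <- M[, variants$gene[i]] + s
  }
  M
}

.write_bundle <- function(dir, variants, gt, samples, sex, groups, genes_df,
                          metrics, mt_class, floor) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    annotations = file.path(dir, "annotations.tsv"),
    bed_a = file.path(dir, "kitA.bed"),
    bed_b = file.path(dir, "kitB.bed"),
    gene_model = file.path(dir, "gene_model.bed"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    sex = file.path(dir, "sex.tsv"),
    truth = file.path(dir, "truth_matrix.tsv")
  )
  .write_vcf(paths$vcf, variants, gt, samples)
  .write_annotations(paths$annotations, variants, metrics, mt_class)
  # two deliberately offset capture kits whose intersection covers the genes
  utils::write.table(
    data.frame(genes_df$chrom, genes_df$start0 - 100,
               genes_df$start0 + genes_df$length + 50),
    paths$bed_a, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(genes_df$chrom, genes_df$start0 - 50,
               genes_df$start0 + genes_df$length + 100),
    paths$bed_b, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(genes_df$chrom, genes_df$start0,
               genes_df$start0 + genes_df$length, genes_df$gene),
    paths$gene_model, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(sample_id = samples, group = groups),
                     paths$phenotypes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample_id = samples, sex = sex),
                     paths$sex, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- .truth_matrix(variants, gt, samples, genes_df$gene, floor)
  write_score_matrix(truth, paths$truth)
  c(paths, list(truth_scores = truth))
}

#' Simulate a fully annotated case/control cohort
#'
#' Writes a complete input bundle under `dir`: a multi-sample VCF with GT
#' genotypes drawn at Hardy-Weinberg proportions from each variant's MAF
#' (hemizygous sampling for males at chrX genes), a sidecar annotation TSV
#' whose raw metric values invert the metric transforms, two offset capture
#' BEDs whose intersection covers every gene, a gene model, phenotype and
#' sex TSVs, and `truth_matrix.tsv` — the expected uncorrected score matrix
#' computed directly from the score equation, independently of the scoring
#' pipeline. Causal variants override Hardy-Weinberg sampling: carriers are
#' drawn per group at the configured carrier fractions.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; the seed fully determines the bundle
#'   (byte-identical reruns).
#' @return Invisibly, a list of file paths plus `truth_scores` (matrix),
#'   `variants` (the simulated variant table) and `config`.
#' @export
simulate_cohort <- function(config = sim_config(), dir = tempfile("cohort"),
                            seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_cases + config$n_controls
  samples <- c(sprintf("CASE%04d", seq_len(config$n_cases)),
               sprintf("CTRL%04d", seq_len(config$n_controls)))
  groups <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
  sex <- ifelse(stats::runif(n) < config$male_fraction, "M", "F")

  genes_df <- config$genes
  if (is.null(genes_df)) {
    genes_df <- data.frame(
      gene = sprintf("GENE%03d", seq_len(config$n_genes)),
      length = sample(300:6000, config$n_genes, replace = TRUE),
      n_variants = stats::rpois(config$n_genes, 6) + 1L,
      stringsAsFactors = FALSE
    )
  }
  genes_df$chrom <- ifelse(genes_df$gene %in% config$x_genes, "chrX", "chr1")
  genes_df$start0 <- 1000000L * seq_len(nrow(genes_df))

  causal <- config$causal
  if (!is.null(causal) && nrow(causal)) {
    bad <- setdiff(causal$gene, genes_df$gene)
    if (length(bad)) stop("causal gene(s) absent from gene list: ",
                          paste(bad, collapse = ", "))
  }

  bases <- c("A", "C", "G", "T")
  vrows <- list()
  gt_rows <- list()
  is_case <- groups == "case"
  for (j in seq_len(nrow(genes_df))) {
    gj <- genes_df[j, ]
    nv <- gj$n_variants
    if (nv == 0L) next
    pos <- sort(sample(seq.int(gj$start0 + 1L, gj$start0 + gj$length), nv))
    maf <- 10^stats::runif(nv, log10(config$maf_range[1]),
                           log10(config$maf_range[2]))
    dvals <- stats::rbeta(nv, config$d_shape[1], config$d_shape[2])
    cls <- sample(names(config$class_probs), nv, replace = TRUE,
                  prob = config$class_probs)
    causal_here <- !is.null(causal) && gj$gene %in% causal$gene
    if (causal_here) {
      ci <- match(gj$gene, causal$gene)
      maf[nv] <- causal$maf[ci]
      dvals[nv] <- causal$d[ci]
      cls[nv] <- "nonsynonymous SNV"
    }
    ref <- sample(bases, nv, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    on_x <- gj$chrom == "chrX"
    for (k in seq_len(nv)) {
      f <- maf[k]
      if (causal_here && k == nv) {
        ci <- match(gj$gene, causal$gene)
        carrier <- ifelse(is_case,
                          stats::runif(n) < causal$carrier_case[ci],
                          stats::runif(n) < causal$carrier_control[ci])
        hom <- identical(causal$zygosity[ci], "hom")
        g <- ifelse(carrier, if (hom) "1/1" else "0/1", "0/0")
        if (on_x) g[sex == "M"] <- ifelse(carrier[sex == "M"], "1", "0")
      } else if (on_x) {
        g <- character(n)
        male <- sex == "M"
        g[male] <- ifelse(stats::runif(sum(male)) < f, "1", "0")
        g[!male] <- sample(c("0/0", "0/1", "1/1"), sum(!male),
                           replace = TRUE,
                           prob = c((1 - f)^2, 2 * f * (1 - f), f^2))
      } else {
        g <- sample(c("0/0", "0/1", "1/1"), n, replace = TRUE,
                    prob = c((1 - f)^2, 2 * f * (1 - f), f^2))
      }
      gt_rows[[length(gt_rows) + 1L]] <- g
    }
    af_ann <- maf
    if (config$af_noise > 0) {
      af_ann <- pmin(0.999, maf * exp(stats::rnorm(nv, 0, config$af_noise)))
    }
    vrows[[length(vrows) + 1L]] <- data.frame(
      chrom = gj$chrom, pos = pos, ref = ref, alt = alt, gene = gj$gene,
      class = cls, maf = maf, af_annotated = af_ann, d = dvals,
      stringsAsFactors = FALSE
    )
  }
  variants <- do.call(rbind, vrows)
  if (is.null(variants)) {
    variants <- data.frame(chrom = character(0), pos = integer(0),
                           ref = character(0), alt = character(0),
                           gene = character(0), class = character(0),
                           maf = numeric(0), af_annotated = numeric(0),
                           d = numeric(0), stringsAsFactors = FALSE)
  }
  gt <- do.call(rbind, gt_rows)
  if (is.null(gt)) gt <- matrix(character(0), 0L, n)
  colnames(gt) <- samples
  mt_class <- if ("MutationTaster" %in% config$metrics) {
    ifelse(stats::runif(nrow(variants)) < config$mt_np_fraction,
           sample(c("N", "P"), nrow(variants), replace = TRUE),
           sample(c("A", "D"), nrow(variants), replace = TRUE))
  } else rep(NA_character_, nrow(variants))

  out <- .write_bundle(dir, variants, gt, samples, sex, groups, genes_df,
                       config$metrics, mt_class, config$floor)
  invisible(c(out, list(variants = variants, gt = gt, config = config,
                        dir = dir)))
}

#' Archetype cohort: the two characteristic score spikes
#'
#' Generates a cohort in which every gene carries exactly one of the two
#' archetypal variants behind the characteristic uncorrected-score spikes:
#' odd genes a common homozygous-prone variant (D = 1, MAF = 0.5; any
#' carrier scores 0.60206) and even genes a very rare heterozygous variant
#' (D = 1, MAF = 0.00001; carriers score ~5). Gene lengths are
#' heterogeneous, so the spikes disperse once scores are length-corrected.
#'
#' @param dir Output directory.
#' @param n_genes Number of genes (alternating archetypes).
#' @param n_samples Number of samples.
#' @param rare_carrier_rate Fraction of samples carrying each rare
#'   archetype variant (the cohort is enriched relative to MAF 1e-5, as a
#'   cohort of observed rare hets is by construction).
#' @param seed Integer seed.
#' @return As [simulate_cohort()].
#' @export
archetype_cohort <- function(dir = tempfile("archetype"), n_genes = 200,
                             n_samples = 40, rare_carrier_rate = 0.25,
                             seed = 1) {
  set.seed(seed)
  samples <- sprintf("S%04d", seq_len(n_samples))
  genes_df <- data.frame(
    gene = sprintf("GENE%03d", seq_len(n_genes)),
    length = round(seq(300, 4500, length.out = n_genes)),
    n_variants = 1L,
    stringsAsFactors = FALSE
  )
  genes_df$chrom <- "chr1"
  genes_df$start0 <- 1000000L * seq_len(n_genes)
  common <- seq_len(n_genes) %% 2L == 1L
  variants <- data.frame(
    chrom = genes_df$chrom,
    pos = genes_df$start0 + 100L,
    ref = "A", alt = "G",
    gene = genes_df$gene,
    class = "nonsynonymous SNV",
    maf = ifelse(common, 0.5, 1e-5),
    d = 1,
    stringsAsFactors = FALSE
  )
  variants$af_annotated <- variants$maf
  gt <- matrix("0/0", n_genes, n_samples,
               dimnames = list(NULL, samples))
  for (i in seq_len(n_genes)) {
    if (common[i]) {
      gt[i, ] <- sample(c("0/0", "0/1", "1/1"), n_samples, replace = TRUE,
                        prob = c(0.25, 0.5, 0.25))
    } else {
      gt[i, ] <- ifelse(stats::runif(n_samples) < rare_carrier_rate,
                        "0/1", "0/0")
    }
  }
  out <- .write_bundle(dir, variants, gt, samples,
                       sex = rep("F", n_samples),
                       groups = rep("case", n_samples),
                       genes_df = genes_df, metrics = "CADD",
                       mt_class = rep(NA_character_, n_genes),
                       floor = 1e-5)
  invisible(c(out, list(variants = variants, gt = gt, dir = dir)))
}
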