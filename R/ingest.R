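#' Read a multi-sample cohort from VCF with annotations
#'
#' Reads a VCF v4.x file with per-sample GT fields and attaches per-alt-allele
#' annotations (gene symbol, functional class, population allele frequency,
#' raw deleteriousness metric values), taken either from a sidecar TSV keyed
#' by `chrom:pos:ref:alt` or from INFO keys.
#'
#' The sidecar TSV must carry columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#' `func_class`, `af`, plus one column per metric (named as in
#' [genepy_metrics()]) and optionally `MutationTaster_class` (prediction
#' class A/D/N/P). Multi-gene assignments are given as `"GENE1;GENE2"` and
#' are split downstream so the variant contributes to each gene.
#'
#' @param vcf_file Path to a (possibly bgzipped) VCF with GT genotypes.
#' @param annotations Path to the sidecar annotation TSV, or a data frame in
#'   the same layout, or `NULL` to read annotations from INFO keys.
#' @param sex_file Optional TSV (`sample_id`, `sex`) marking sample sex for
#'   the hemizygosity rule on chrX; `sex` coded M/F (or male/female).
#' @param info_map Named list mapping annotation roles to INFO keys when
#'   `annotations` is `NULL`; defaults to
#'   `list(gene = "Gene", func_class = "Func", af = "AF")` with metric
#'   values read from INFO keys equal to the metric names.
#' @return An object of class `genepy_cohort`: a list with `sites` (one row
#'   per VCF record), `variants` (one row per alt allele with annotations),
#'   `raw` (variant x metric matrix of raw annotation values), `aux_class`
#'   (MutationTaster classes), `gt` (site x sample genotype strings),
#'   `samples`, and `sex` (named vector or NULL).
#' @export
read_cohort <- function(vcf_file, annotations = NULL, sex_file = NULL,
                        info_map = NULL) {
  vcf <- vcfR::read.vcfR(vcf_file, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {           # single-record VCFs drop to a vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  }
  if (nrow(fix) == 0L) stop("no variant records in ", vcf_file)
  if (ncol(vcf@gt) < 2L) stop("VCF has no sample genotype columns: ", vcf_file)
  if (!all(grepl("(^|:)GT(:|$)", vcf@gt[, "FORMAT"]))) {
    stop("GT missing from FORMAT in ", vcf_file)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) {
    gt <- matrix(gt, nrow = 1L, dimnames = list(NULL, names(gt)))
  }
  samples <- colnames(gt)

  sites <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    stringsAsFactors = FALSE
  )
  alt_list <- strsplit(sites$alt, ",", fixed = TRUE)
  sites$n_alt <- lengths(alt_list)
  if (any(sites$n_alt < 1L)) stop("VCF record without an alt allele")

  site_idx <- rep(seq_len(nrow(sites)), sites$n_alt)
  variants <- data.frame(
    site = site_idx,
    allele = unlist(lapply(sites$n_alt, seq_len)),
    chrom = sites$chrom[site_idx],
    pos = sites$pos[site_idx],
    ref = sites$ref[site_idx],
    alt = unlist(alt_list),
    stringsAsFactors = FALSE
  )

  metrics <- genepy_metrics()
  if (is.null(annotations)) {
    ann <- .annotations_from_info(vcf, variants, info_map, metrics)
  } else {
    ann <- .annotations_from_table(annotations, variants, metrics)
  }
  variants$gene <- ann$gene
  variants$func_class <- ann$func_class
  variants$af <- ann$af

  structure(
    list(sites = sites, variants = variants, raw = ann$raw,
         aux_class = ann$aux_class, gt = gt, samples = samples,
         sex = .read_sex(sex_file, samples)),
    class = "genepy_cohort"
  )
}

.read_sex <- function(sex_file, samples) {
  if (is.null(sex_file)) return(NULL)
  s <- if (is.data.frame(sex_file)) sex_file else
    utils::read.delim(sex_file, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "sex") %in% names(s))) {
    stop("sex file must have columns sample_id, sex")
  }
  sex <- toupper(substr(s$sex, 1, 1))
  names(sex) <- s$sample_id
  missing <- setdiff(samples, names(sex))
  if (length(missing)) {
    warning("no sex recorded for ", length(missing),
            " sample(s); treating as female (diploid X)")
  }
  sex
}

.annotations_from_table <- function(annotations, variants, metrics) {
  ann <- if (is.data.frame(annotations)) annotations else
    utils::read.delim(annotations, stringsAsFactors = FALSE,
                      check.names = FALSE)
  required <- c("chrom", "pos", "ref", "alt", "gene", "func_class", "af")
  if (!all(required %in% names(ann))) {
    stop("annotation table must have columns: ",
         paste(required, collapse = ", "))
  }
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  i <- match(key(variants), key(ann))
  if (anyNA(i)) {
    warning(sum(is.na(i)), " alt allele(s) missing from the annotation ",
            "table; their annotations are treated as missing")
  }
  metric_cols <- intersect(metrics$name, names(ann))
  absent <- setdiff(metrics$name, names(ann))
  raw <- matrix(NA_real_, nrow(variants), nrow(metrics),
                dimnames = list(NULL, metrics$name))
  for (m in metric_cols) raw[, m] <- suppressWarnings(as.numeric(ann[[m]][i]))
  for (m in metric_cols) {
    bad <- !is.na(ann[[m]][i]) & ann[[m]][i] != "" & is.na(raw[, m]) &
      ann[[m]][i] != "."
    if (any(bad)) {
      j <- which(bad)[1]
      stop("non-numeric value '", ann[[m]][i][j], "' for metric ", m,
           " at ", variants$chrom[j], ":", variants$pos[j])
    }
  }
  aux <- if ("MutationTaster_class" %in% names(ann))
    as.character(ann$MutationTaster_class[i]) else
    rep(NA_character_, nrow(variants))
  list(
    gene = as.character(ann$gene[i]),
    func_class = as.character(ann$func_class[i]),
    af = suppressWarnings(as.numeric(ann$af[i])),
    raw = raw,
    aux_class = aux,
    missing_metrics = absent
  )
}

.annotations_from_info <- function(vcf, variants, info_map, metrics) {
  map <- list(gene = "Gene", func_class = "Func", af = "AF")
  if (!is.null(info_map)) map[names(info_map)] <- info_map
  get_info <- function(key) {
    v <- tryCatch(vcfR::extract.info(vcf, element = key),
                  error = function(e) NULL)
    if (is.null(v) || all(is.na(v))) return(NULL)
    v
  }
  per_allele <- function(values) {
    if (is.null(values)) return(rep(NA_character_, nrow(variants)))
    split_vals <- strsplit(as.character(values), ",", fixed = TRUE)
    vapply(seq_len(nrow(variants)), function(j) {
      v <- split_vals[[variants$site[j]]]
      v[min(variants$allele[j], length(v))]
    }, character(1))
  }
  gene <- per_allele(get_info(map$gene))
  func <- per_allele(get_info(map$func_class))
  af_chr <- per_allele(get_info(map$af))
  raw <- matrix(NA_real_, nrow(variants), nrow(metrics),
                dimnames = list(NULL, metrics$name))
  found <- character(0)
  for (m in metrics$name) {
    v <- get_info(m)
    if (!is.null(v)) {
      raw[, m] <- suppressWarnings(as.numeric(per_allele(v)))
      found <- c(found, m)
    }
  }
  if (!length(found)) {
    warning("no metric annotations found in INFO; all metric values missing")
  }
  aux <- per_allele(get_info("MutationTaster_class"))
  list(gene = gene, func_class = func,
       af = suppressWarnings(as.numeric(af_chr)),
       raw = raw, aux_class = aux,
       missing_metrics = setdiff(metrics$name, found))
}

#' Resolve per-allele population frequencies with the rarity floor
#'
#' Applies the lower frequency limit to every alt allele (missing or novel
#' annotations receive exactly the floor), then sets the reference allele
#' frequency to one minus the sum of the alt frequencies, itself floored.
#' The floor conservatively reflects the lowest frequency observable in
#' large population repositories; the default 0.00001 matches ExAC-scale
#' resolution.
#'
#' @param af Numeric vector of annotated alt-allele frequencies (`NA` for
#'   novel/absent alleles), one per alt allele at the site.
#' @param floor Lower frequency limit, in (0, 0.5). Default `1e-5`.
#' @return Numeric vector `c(ref, alt1, alt2, ...)` of frequencies, each in
#'   `[floor, 1]`.
#' @export
#' @examples
#' resolve_allele_frequencies(NA)            # novel: alt at floor
#' resolve_allele_frequencies(c(0.2, 0.1))   # ref = 0.7
resolve_allele_frequencies <- function(af, floor = 1e-5) {
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0 || floor >= 0.5) {
    stop("floor must be a single value in (0, 0.5)")
  }
  if (length(af) < 1L) stop("at least one alt allele frequency required")
  alt <- pmax(ifelse(is.na(af), floor, af), floor)
  ref <- 1 - sum(alt)
  if (ref < floor) {
    if (sum(alt) > 1) {
      warning("alt allele frequencies sum to ", signif(sum(alt), 6),
              " > 1; clamping reference frequency to the floor ",
              "(malformed annotation)")
    }
    ref <- floor
  }
  c(ref, alt)
}

# Parse GT strings ("0/1", "1|0", "1", "./.") into integer allele vectors.
# Returns a list; NULL marks a missing genotype.
.parse_gt <- function(g) {
  parts <- strsplit(as.character(g), "[/|]")
  lapply(parts, function(p) {
    if (length(p) == 0L || any(is.na(p)) || any(p %in% c(".", ""))) {
      return(NULL)
    }
    as.integer(p)
  })
}

#' @export
print.genepy_cohort <- function(x, ...) {
  cat("genepy_cohort:", nrow(x$sites), "sites,", nrow(x$variants),
      "alt alleles,", length(x$samples), "samples\n")
  invisible(x)
}
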