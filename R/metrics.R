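#' Supported deleteriousness metrics
#'
#' Returns the table of the sixteen supported in-silico deleteriousness
#' metrics and the rules used to place each on a common deleteriousness
#' scale `D` in \[0, 1\], where 0 is benign and 1 maximally pathogenic.
#' Bounded metrics (DANN, M-CAP, SIFT, ...) are scored on (0, 1) natively;
#' the five unbounded metrics (CADD, FATHMM, GERP++_RS, MetaSVM, phyloP)
#' carry imposed transformation ranges taken from the extremes observed in
#' dbNSFP (v3.3a). Metrics whose raw scale runs opposite to pathogenicity
#' (FATHMM, PROVEAN, SIFT) take the complement after rescaling;
#' MutationTaster is complemented conditionally on its prediction class.
#'
#' @param file Optional path to a user-supplied TSV overriding the shipped
#'   defaults. Must have columns `name`, `category`, `lower_bound`,
#'   `upper_bound`, `complement`, `conditional_rule`.
#' @return A data frame with one row per metric.
#' @export
#' @examples
#' genepy_metrics()
genepy_metrics <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "metrics.tsv", package = "genepyr")
  }
  m <- utils::read.delim(file, stringsAsFactors = FALSE)
  required <- c("name", "category", "lower_bound", "upper_bound",
                "complement", "conditional_rule")
  if (!all(required %in% names(m))) {
    stop("metric config must have columns: ", paste(required, collapse = ", "))
  }
  if (any(m$lower_bound >= m$upper_bound)) {
    stop("metric config: lower_bound must be < upper_bound for every metric")
  }
  m
}

#' Look up one metric's specification
#'
#' @param name Metric name (one of the sixteen in [genepy_metrics()]).
#' @param metrics Metric table, defaulting to the shipped configuration.
#' @return A one-row list with fields `name`, `category`, `lower_bound`,
#'   `upper_bound`, `complement`, `conditional_rule`.
#' @export
metric_spec <- function(name, metrics = genepy_metrics()) {
  i <- match(name, metrics$name)
  if (is.na(i)) {
    stop("unknown deleteriousness metric '", name, "'; supported: ",
         paste(metrics$name, collapse = ", "))
  }
  as.list(metrics[i, ])
}

#' Normalise raw metric annotations to the deleteriousness scale
#'
#' Linearly rescales raw annotation values onto \[0, 1\] using the metric's
#' (possibly imposed) bounds, clamping out-of-range values to the bounds
#' first, then applies the complement for reverse-directed metrics. For
#' MutationTaster the complement is conditional on the prediction class:
#' raw score is kept for disease classes (A, D) and complemented for
#' neutral/polymorphism classes (N, P); a missing class yields a missing
#' result because the rule cannot be evaluated. Missing raw values are
#' propagated as `NA`.
#'
#' @param raw Numeric vector of raw metric values (`NA` allowed).
#' @param spec A metric specification from [metric_spec()], or a metric name.
#' @param aux_class Optional character vector of MutationTaster prediction
#'   classes (`"A"`, `"D"`, `"N"`, `"P"`), recycled to `length(raw)`.
#' @return Numeric vector of deleteriousness values in \[0, 1\], `NA` where
#'   the input was missing or the conditional rule could not be evaluated.
#' @export
#' @examples
#' transform_metric(c(-7.53, 14.13, 35.79), "CADD")  # 0, 0.5, 1
#' transform_metric(0, "SIFT")                       # complement: 1
transform_metric <- function(raw, spec, aux_class = NULL) {
  if (is.character(spec)) spec <- metric_spec(spec)
  if (!is.numeric(raw)) {
    stop("non-numeric raw value for metric '", spec$name, "'")
  }
  x <- pmin(pmax(raw, spec$lower_bound), spec$upper_bound)
  d <- (x - spec$lower_bound) / (spec$upper_bound - spec$lower_bound)
  if (identical(spec$conditional_rule, "class_dependent")) {
    if (is.null(aux_class)) aux_class <- rep(NA_character_, length(d))
    aux_class <- rep_len(as.character(aux_class), length(d))
    flip <- aux_class %in% c("N", "P")
    keep <- aux_class %in% c("A", "D")
    d[flip] <- 1 - d[flip]
    d[!(flip | keep)] <- NA_real_
  } else if (isTRUE(spec$complement)) {
    d <- 1 - d
  }
  d
}

.truncating_classes <- c("stopgain", "stoploss", "frameshift insertion",
                         "frameshift deletion", "frameshift substitution",
                         "frameshift block substitution")

.excluded_classes <- c("synonymous SNV", "splicing")

#' Protein-truncating functional classes
#'
#' Protein-truncating variants (stop gain/loss, frameshift indels) are not
#' scored by most deleteriousness metrics and are assigned the maximal
#' deleteriousness D = 1, overriding any raw metric annotation.
#'
#' @param functional_class Character vector of annotation classes
#'   (ANNOVAR-style, e.g. `"stopgain"`, `"nonsynonymous SNV"`).
#' @return Logical vector: `TRUE` where the class receives the D = 1
#'   override. Unrecognised classes are simply not truncating.
#' @export
is_truncating <- function(functional_class) {
  tolower(as.character(functional_class)) %in% tolower(.truncating_classes)
}

#' Functional classes excluded from scoring
#'
#' Synonymous and splicing variants are excluded: they contribute to no
#' gene score under any metric.
#'
#' @inheritParams is_truncating
#' @return Logical vector: `TRUE` where the variant must be excluded.
#' @export
is_excluded_class <- function(functional_class) {
  tolower(as.character(functional_class)) %in% tolower(.excluded_classes)
}
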