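#' Rank-sum comparison of gene scores between two groups
#'
#' Compares the per-gene score distribution of cases against controls with
#' the Mann-Whitney U test for unpaired data. Score matrices are heavily
#' zero-inflated, so ties are handled with midranks and the tie-corrected
#' normal approximation; the exact null distribution is used only for tiny
#' untied groups (both n <= 8). Group maxima and means are reported
#' alongside the test.
#'
#' @param case_scores Numeric vector of case scores (non-empty).
#' @param control_scores Numeric vector of control scores (non-empty).
#' @param alternative `"two.sided"` or `"greater"` (cases stochastically
#'   larger).
#' @param gene,metric Optional labels carried into the result.
#' @return An object of class `genepy_test`: list with `gene`, `metric`,
#'   `n_case`, `n_control`, `U` (for the case group), `p_value`,
#'   `alternative`, `max_case`, `max_control`, `mean_case`, `mean_control`,
#'   `tail_fraction` (NA here).
#' @export
compare_gene <- function(case_scores, control_scores,
                         alternative = c("two.sided", "greater"),
                         gene = NA_character_, metric = NA_character_) {
  alternative <- match.arg(alternative)
  if (!length(case_scores) || !length(control_scores)) {
    stop("both groups must be non-empty")
  }
  n1 <- length(case_scores)
  n2 <- length(control_scores)
  pooled <- c(case_scores, control_scores)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1L) {
    # every observation tied across both groups: no evidence either way
    p <- 1
  } else {
    ties <- any(duplicated(pooled))
    wt <- suppressWarnings(stats::wilcox.test(
      case_scores, control_scores, alternative = alternative,
      exact = (!ties && n1 <= 8 && n2 <= 8), correct = TRUE
    ))
    p <- wt$p.value
    U <- unname(wt$statistic)
  }
  structure(
    list(gene = gene, metric = metric, n_case = n1, n_control = n2,
         U = U, p_value = p, alternative = alternative,
         max_case = max(case_scores), max_control = max(control_scores),
         mean_case = mean(case_scores), mean_control = mean(control_scores),
         tail_fraction = NA_real_),
    class = "genepy_test"
  )
}

#' @export
print.genepy_test <- function(x, ...) {
  cat("Mann-Whitney U comparison",
      if (!is.na(x$gene)) paste0("for ", x$gene), "\n")
  cat(sprintf("  n_case = %d, n_control = %d%s\n", x$n_case, x$n_control,
              if (!is.na(x$tail_fraction))
                sprintf(" (top %.0f%% tails)", 100 * x$tail_fraction)
              else ""))
  cat(sprintf("  case  max %.4g, mean %.4g\n", x$max_case, x$mean_case))
  cat(sprintf("  ctrl  max %.4g, mean %.4g\n", x$max_control,
              x$mean_control))
  cat(sprintf("  U = %.4g, p = %.4g (%s)\n", x$U, x$p_value, x$alternative))
  invisible(x)
}

#' Extreme-tail rank-sum comparison
#'
#' For genes where only a minority of cases carry the signal, the full
#' distributions may not separate while their extreme right tails do. This
#' selects the top `ceiling(q * n)` scores within each group independently
#' (ties at the cut are all included) and applies the one-tailed
#' (case > control) rank-sum test to the selected tails.
#'
#' @inheritParams compare_gene
#' @param q Tail fraction in (0, 0.5\], or 1 for the full one-tailed test.
#' @return A `genepy_test` with `tail_fraction = q` and the tail sizes as
#'   `n_case` / `n_control`.
#' @export
compare_tail <- function(case_scores, control_scores, q = 0.05,
                         gene = NA_character_, metric = NA_character_) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 ||
      (q > 0.5 && q != 1)) {
    stop("tail fraction q must be in (0, 0.5] (or 1 for the full test)")
  }
  top <- function(x) {
    k <- ceiling(q * length(x))
    if (k < 1L) stop("tail smaller than one observation")
    cut <- sort(x, decreasing = TRUE)[k]
    x[x >= cut]   # include every value tied with the cut
  }
  res <- compare_gene(top(case_scores), top(control_scores),
                      alternative = "greater", gene = gene, metric = metric)
  res$tail_fraction <- q
  res
}

#' Run case/control validation tests across genes
#'
#' Orchestrates per-gene comparisons over a score matrix: for each selected
#' gene and each requested test, splits the samples by phenotype label and
#' compares score distributions. Emits one row per gene x test, mirroring a
#' per-group max/mean + p-value results table, with a Bonferroni-adjusted
#' p-value column (per number of genes tested).
#'
#' @param x A `genepy` object or a samples x genes numeric matrix.
#' @param phenotypes Data frame (or TSV path) with columns `sample_id` and
#'   `group`; `case_label` marks the case group, all other samples are
#'   controls.
#' @param genes Genes to test (default: all genes in the matrix).
#' @param tests Character vector among `"two_sided"`, `"greater"`, `"tail"`.
#' @param tail_q Tail fraction for `"tail"` tests.
#' @param case_label Phenotype label identifying cases (default `"case"`).
#' @return Data frame with columns `gene`, `metric`, `test`, `tail_q`,
#'   `n_case`, `n_control`, `max_case`, `mean_case`, `max_control`,
#'   `mean_control`, `U`, `p`, `p_bonferroni`.
#' @export
run_validation <- function(x, phenotypes, genes = NULL,
                           tests = "two_sided", tail_q = 0.05,
                           case_label = "case") {
  M <- if (inherits(x, "genepy")) x$scores else as.matrix(x)
  metric <- if (inherits(x, "genepy")) x$metric else NA_character_
  ph <- if (is.data.frame(phenotypes)) phenotypes else
    utils::read.delim(phenotypes, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(ph))) {
    stop("phenotypes must have columns sample_id, group")
  }
  unknown <- setdiff(ph$sample_id, rownames(M))
  if (length(unknown)) {
    stop("phenotype file names sample(s) absent from the matrix: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  grp <- stats::setNames(ph$group, ph$sample_id)[rownames(M)]
  if (anyNA(grp)) {
    stop(sum(is.na(grp)), " matrix sample(s) missing a phenotype label")
  }
  if (is.null(genes)) genes <- colnames(M)
  missing <- setdiff(genes, colnames(M))
  if (length(missing)) stop("gene(s) not in matrix: ",
                            paste(missing, collapse = ", "))
  bad <- setdiff(tests, c("two_sided", "greater", "tail"))
  if (length(bad)) stop("unknown test(s): ", paste(bad, collapse = ", "))

  is_case <- grp == case_label
  if (!any(is_case) || all(is_case)) {
    stop("need both cases ('", case_label, "') and controls in phenotypes")
  }
  rows <- list()
  for (gn in genes) {
    cs <- M[is_case, gn]
    ct <- M[!is_case, gn]
    for (tt in tests) {
      res <- switch(tt,
        two_sided = compare_gene(cs, ct, "two.sided", gene = gn,
                                 metric = metric),
        greater = compare_gene(cs, ct, "greater", gene = gn,
                               metric = metric),
        tail = compare_tail(cs, ct, q = tail_q, gene = gn, metric = metric)
      )
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gn, metric = metric, test = tt,
        tail_q = if (tt == "tail") tail_q else NA_real_,
        n_case = res$n_case, n_control = res$n_control,
        max_case = res$max_case, mean_case = res$mean_case,
        max_control = res$max_control, mean_control = res$mean_control,
        U = res$U, p = res$p_value,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * length(genes))
  out
}
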