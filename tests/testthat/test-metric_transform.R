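test_that("all sixteen metrics map their bounds to {0,1} in the right direction", {
  m <- genepy_metrics()
  expect_equal(nrow(m), 16L)
  for (i in seq_len(nrow(m))) {
    spec <- metric_spec(m$name[i])
    aux <- if (identical(spec$conditional_rule, "class_dependent")) "D"
    at_lower <- transform_metric(spec$lower_bound, spec, aux)
    at_upper <- transform_metric(spec$upper_bound, spec, aux)
    if (isTRUE(spec$complement)) {
      expect_equal(at_lower, 1, info = spec$name)
      expect_equal(at_upper, 0, info = spec$name)
    } else {
      expect_equal(at_lower, 0, info = spec$name)
      expect_equal(at_upper, 1, info = spec$name)
    }
  }
})

test_that("the five imposed ranges match the published extremes", {
  m <- genepy_metrics()
  imposed <- list("CADD" = c(-7.53, 35.79), "FATHMM" = c(-16.13, 10.64),
                  "GERP++_RS" = c(-12.3, 6.17), "MetaSVM" = c(-2, 3),
                  "phyloP" = c(-13.28, 1.2))
  for (nm in names(imposed)) {
    i <- match(nm, m$name)
    expect_equal(c(m$lower_bound[i], m$upper_bound[i]), imposed[[nm]],
                 info = nm)
  }
  # PROVEAN keeps its native -14..14 range; all other bounded metrics (0,1)
  i <- match("PROVEAN", m$name)
  expect_equal(c(m$lower_bound[i], m$upper_bound[i]), c(-14, 14))
  bounded <- setdiff(m$name, c(names(imposed), "PROVEAN"))
  expect_true(all(m$lower_bound[m$name %in% bounded] == 0))
  expect_true(all(m$upper_bound[m$name %in% bounded] == 1))
})

test_that("linear rescaling, complement and clamping behave as specified", {
  expect_equal(transform_metric(14.13, "CADD"), 0.5)
  expect_equal(transform_metric(0, "SIFT"), 1)
  expect_equal(transform_metric(0.7, "phastCons"), 0.7)
  # PROVEAN: rescale from (-14, 14) then complement; raw -14 most damaging
  expect_equal(transform_metric(-14, "PROVEAN"), 1)
  expect_equal(transform_metric(14, "PROVEAN"), 0)
  # out-of-range raw values clamp to the bounds, keeping D in [0, 1]
  expect_equal(transform_metric(99, "CADD"), 1)
  expect_equal(transform_metric(-99, "CADD"), 0)
  expect_equal(transform_metric(1.5, "SIFT"), 0)
  # missing propagates
  expect_true(is.na(transform_metric(NA_real_, "CADD")))
})

test_that("MutationTaster complements conditionally on prediction class", {
  expect_equal(transform_metric(0.9, "MutationTaster", "D"), 0.9)
  expect_equal(transform_metric(0.9, "MutationTaster", "A"), 0.9)
  expect_equal(transform_metric(0.9, "MutationTaster", "N"), 0.1)
  expect_equal(transform_metric(0.9, "MutationTaster", "P"), 0.1)
  # the rule cannot be evaluated without a class
  expect_true(is.na(transform_metric(0.9, "MutationTaster", NA)))
  expect_true(is.na(transform_metric(0.9, "MutationTaster")))
})

test_that("transform is monotone within bounds and always lands in [0,1]", {
  set.seed(42)
  m <- genepy_metrics()
  for (i in seq_len(nrow(m))) {
    spec <- metric_spec(m$name[i])
    aux_sets <- if (identical(spec$conditional_rule, "class_dependent"))
      list(list(cls = "D", dir = 1), list(cls = "N", dir = -1))
    else if (isTRUE(spec$complement)) list(list(cls = NULL, dir = -1))
    else list(list(cls = NULL, dir = 1))
    raw <- sort(runif(50, spec$lower_bound - 2, spec$upper_bound + 2))
    for (a in aux_sets) {
      d <- transform_metric(raw, spec, a$cls)
      expect_true(all(d >= 0 & d <= 1), info = spec$name)
      diffs <- diff(d) * a$dir
      expect_true(all(diffs >= -1e-12), info = spec$name)
    }
  }
})

test_that("transform rejects bad configuration and bad values", {
  expect_error(metric_spec("NotAMetric"), "unknown deleteriousness metric")
  expect_error(transform_metric("abc", "CADD"), "non-numeric")
  bad_cfg <- data.frame(name = "X", category = "composite",
                        lower_bound = 1, upper_bound = 0,
                        complement = FALSE, conditional_rule = "none")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad_cfg, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(genepy_metrics(tmp), "lower_bound")
})

test_that("protein-truncating classes get the D = 1 override", {
  expect_true(is_truncating("stopgain"))
  expect_true(is_truncating("stoploss"))
  expect_true(is_truncating("frameshift deletion"))
  expect_true(is_truncating("frameshift insertion"))
  expect_false(is_truncating("nonsynonymous SNV"))
  expect_false(is_truncating("made-up class"))
})

test_that("synonymous and splicing variants are excluded from every score", {
  expect_true(is_excluded_class("synonymous SNV"))
  expect_true(is_excluded_class("splicing"))
  expect_false(is_excluded_class("nonsynonymous SNV"))
  expect_false(is_excluded_class("stopgain"))
})
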