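test_that("single-variant scores hit the analytic anchors", {
  expect_equal(variant_score(1, 1e-5, 1e-5), 10)
  expect_equal(variant_score(1, 1e-5, 0.99999), 5.000004, tolerance = 1e-7)
  expect_equal(variant_score(1, 0.5, 0.5), 0.60206, tolerance = 1e-6)
  expect_equal(variant_score(0, 0.3, 0.7), 0)
  expect_equal(variant_score(1, 1, 1), 0)
})

test_that("variant_score enforces its contract", {
  expect_error(variant_score(1.2, 0.5, 0.5), "D out of range")
  expect_error(variant_score(-0.1, 0.5, 0.5), "D out of range")
  expect_error(variant_score(0.5, 0, 0.5), "frequency out of range")
  expect_error(variant_score(0.5, 0.5, 1.5), "frequency out of range")
})

test_that("variant_score is monotone in D and in the frequency product", {
  set.seed(1)
  for (rep in 1:25) {
    f1 <- runif(1, 1e-5, 0.999)
    f2 <- runif(1, 1e-5, 0.999)
    d <- sort(runif(2))
    expect_lt(variant_score(d[1], f1, f2), variant_score(d[2], f1, f2))
    f <- sort(runif(2, 1e-5, 0.999))
    expect_gt(variant_score(0.7, f[1], f[1]), variant_score(0.7, f[2], f[2]))
  }
  # bound: every contribution in [0, 10] under the default floor
  d <- runif(200); f1 <- runif(200, 1e-5, 1); f2 <- runif(200, 1e-5, 1)
  s <- variant_score(d, f1, f2)
  expect_true(all(s >= 0 & s <= 10 + 1e-12))
})

test_that("homozygous/heterozygous ratio is ~2 for rare variants", {
  set.seed(2)
  f <- 10^runif(40, -5, -2)   # f <= 0.01
  d <- runif(40, 0.1, 1)
  hom <- variant_score(d, f, f)
  het <- variant_score(d, f, 1 - f)
  expect_true(all(hom / het > 1.99 & hom / het < 2.01))
})

test_that("gene scores are additive sums of contributions", {
  expect_equal(gene_score(numeric(0)), 0)
  expect_equal(gene_score(10), 10)
  expect_equal(gene_score(c(0.60206, 5)), 5.60206)
  set.seed(3)
  a <- runif(7); b <- runif(4)
  expect_equal(gene_score(c(a, b)), gene_score(a) + gene_score(b))
})

test_that("length correction rescales by the median-length constant", {
  expect_equal(length_correct(2, 2922), 1)
  expect_equal(length_correct(5, 1461), 5)
  expect_equal(length_correct(0.6, 487), 1.8)
  expect_error(length_correct(1, 0, gene = "BRCA2"), "BRCA2")
  expect_error(length_correct(1, -5), "nonpositive")
})

test_that("the full pipeline matches the brute-force oracle on the fixture", {
  fix <- write_fixture()
  fit <- genepy(fix$vcf, fix$ann, metric = "CADD", sex_file = fix$sex)
  want <- oracle_matrix()
  expect_equal(colnames(fit$scores), colnames(want))
  expect_equal(fit$scores, want, tolerance = 1e-9)
  # spot checks: hemizygous male X scores as homozygous (frequency squared)
  expect_equal(fit$scores["S1", "GX"], 10, tolerance = 1e-9)
  expect_equal(fit$scores["S5", "GX"], 10, tolerance = 1e-9)
  # female heterozygote at the same locus gets the het limit
  expect_equal(fit$scores["S2", "GX"], 5.000004, tolerance = 1e-6)
  # synonymous site contributed nothing anywhere
  expect_equal(sum(fit$scores[, "G2"] > 0),
               sum(want[, "G2"] > 0))
  # determinism: identical rerun is bit-identical
  fit2 <- genepy(fix$vcf, fix$ann, metric = "CADD", sex_file = fix$sex)
  expect_identical(fit$scores, fit2$scores)
})

test_that("per-stage counts and region filtering are honoured", {
  fix <- write_fixture()
  fit <- genepy(fix$vcf, fix$ann, metric = "CADD", sex_file = fix$sex)
  expect_equal(unname(fit$counts["read"]), 10)
  expect_equal(unname(fit$counts["excluded_class"]), 1)   # synonymous
  expect_equal(unname(fit$counts["missing_metric"]), 1)   # chr1:501
  expect_equal(unname(fit$counts["scored"]), 8)
  # a target mask excluding chr1:601 drops G3's only scoring variant there
  mask <- GenomicRanges::GRanges(c("chr1", "chrX"),
                                 IRanges::IRanges(c(1, 1), c(550, 1e6)))
  fit_masked <- genepy(fix$vcf, fix$ann, metric = "CADD",
                       sex_file = fix$sex, regions = mask)
  expect_equal(unname(fit_masked$counts["outside_target"]), 3)
  expect_true(all(fit_masked$scores[, "G3"] == 0))
})

test_that("samples with no non-reference genotypes get an all-zero row", {
  fix <- write_fixture()
  fit <- genepy(fix$vcf, fix$ann, metric = "CADD", sex_file = fix$sex)
  expect_true(all(fit$scores["S4", c("G1", "G3", "G4")] == 0))
})

test_that("corrected matrices rescale per gene and drop untargeted genes", {
  fix <- write_fixture()
  lengths <- c(G1 = 1461, G2 = 2922, G3 = 487, G4 = 1461, GX = 1461)
  fit <- genepy(fix$vcf, fix$ann, metric = "CADD", sex_file = fix$sex)
  fitc <- genepy(fix$vcf, fix$ann, metric = "CADD", sex_file = fix$sex,
                 corrected = TRUE, gene_lengths = lengths)
  expect_equal(fitc$scores[, "G2"], fit$scores[, "G2"] / 2)
  expect_equal(fitc$scores[, "G1"], fit$scores[, "G1"])
  expect_equal(fitc$scores[, "G3"], fit$scores[, "G3"] * 1461 / 487)
  # gene missing from the lengths is dropped with a warning
  expect_warning(
    fitd <- genepy(fix$vcf, fix$ann, metric = "CADD", sex_file = fix$sex,
                   corrected = TRUE, gene_lengths = lengths[-5]),
    "GX")
  expect_false("GX" %in% colnames(fitd$scores))
})

test_that("matrix summary reproduces the descriptive statistic definitions", {
  obj <- structure(list(scores = matrix(c(1, 3), 1,
                                        dimnames = list("s", c("a", "b"))),
                        metric = "CADD", corrected = FALSE),
                   class = "genepy")
  s <- summary(obj)
  expect_equal(s$mean, 2)
  expect_equal(s$cv, 0.5)  # population sigma / mu
  expect_equal(s$max, 3)
  zeros <- structure(list(scores = matrix(0, 2, 3,
                                          dimnames = list(c("s1", "s2"),
                                                          c("a", "b", "c"))),
                          metric = "CADD", corrected = FALSE),
                     class = "genepy")
  sz <- summary(zeros)
  expect_true(is.na(sz$cv))
  expect_equal(unname(sz$zero_genes), c(3, 3))
  # single spike lands entirely in its 0.01-wide bin
  spike <- matrix(0.602, 3, 2)
  h <- score_histogram(spike)
  expect_equal(nrow(h), 1L)
  expect_equal(h$bin_start, 0.60)
  expect_equal(h$count, 6L)
  # sub-0.01 mass is dropped only when requested
  mixed <- c(0.005, 0.602)
  expect_equal(sum(score_histogram(mixed)$count), 1L)
  expect_equal(sum(score_histogram(mixed, drop_low = FALSE)$count), 2L)
})

test_that("gene Z-score profiles standardise per gene over the cohort", {
  M <- cbind(g1 = c(1, 2, 3), g2 = c(0, 0, 2), g3 = c(1, 1, 1))
  rownames(M) <- paste0("s", 1:3)
  obj <- structure(list(scores = M, metric = "CADD", corrected = FALSE),
                   class = "genepy")
  expect_warning(z <- gene_zscores(obj), "zero-variance")
  expect_equal(unname(z[, "g1"]),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(mean(z[, "g2"]), 0)
  expect_gt(z["s3", "g2"], 0)
  expect_equal(unname(z[, "g3"]), c(0, 0, 0))
  expect_error(suppressWarnings(gene_zscores(obj, genes = "nope")),
               "not in matrix")
  expect_warning(zs <- gene_zscores(obj, genes = "g1", samples = "s2"),
                 "zero-variance")
  expect_equal(dim(zs), c(1L, 1L))
})

test_that("score matrices round-trip through TSV at six significant digits", {
  M <- matrix(c(0.60206, 5.000004, 0, 10), 2,
              dimnames = list(c("s1", "s2"), c("g1", "g2")))
  obj <- structure(list(scores = M, metric = "CADD", corrected = FALSE),
                   class = "genepy")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_matrix(obj, path)
  back <- read_score_matrix(path)
  expect_equal(back, M, tolerance = 1e-6)
  expect_equal(back["s1", "g1"], 0.60206)
})
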