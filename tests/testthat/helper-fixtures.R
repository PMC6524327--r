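# Hand-built cohort fixture and an independent brute-force scorer.
#
# The fixture is written as literal VCF/TSV text (not through the package's
# writers) and the oracle recomputes every score directly from the score
# equation, so pipeline and oracle share no code.

# Ten alt alleles over nine sites, five samples (S1, S3, S5 male).
# Exercises: het/hom/missing genotypes, a multi-allelic site (incl. an
# alt1/alt2 heterozygote), excluded synonymous class, truncating override,
# a missing metric value, a novel allele (af = NA -> floor), male-X
# hemizygosity (haploid GT), and a multi-gene assignment.
fixture_variants <- function() {
  data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr1",
              "chrX", "chr1", "chr1", "chr1"),
    pos = c(101L, 201L, 201L, 301L, 401L, 501L, 101L, 601L, 701L, 801L),
    ref = c("A", "C", "C", "G", "T", "A", "A", "G", "C", "AT"),
    alt = c("G", "T", "G", "A", "C", "T", "G", "C", "A", "A"),
    gene = c("G1", "G1", "G1;G2", "G2", "G2", "G2", "GX", "G3", "G3;G4",
             "G4"),
    class = c("nonsynonymous SNV", "nonsynonymous SNV",
              "nonsynonymous SNV", "synonymous SNV", "stopgain",
              "nonsynonymous SNV", "nonsynonymous SNV",
              "nonsynonymous SNV", "nonsynonymous SNV",
              "frameshift deletion"),
    af = c(0.01, 0.2, 0.1, 0.3, NA, 0.05, 1e-5, 0.5, 0.001, 0.002),
    d = c(0.8, 0.5, 0.9, 0.4, NA, NA, 1.0, 0.3, 0.6, NA),
    stringsAsFactors = FALSE
  )
}

# genotype strings per site (rows follow unique sites, in order)
fixture_gt <- function() {
  m <- rbind(
    c("0/1", "1/1", "./.", "0/0", "0/1"),  # chr1:101
    c("1/2", "0/2", "0/1", "0/0", "2/2"),  # chr1:201 multi-allelic
    c("1/1", "0/1", "0/0", "0/0", "0/1"),  # chr1:301 synonymous
    c("0/0", "0/1", "0/0", "0/0", "0/0"),  # chr1:401 stopgain, novel af
    c("0/1", "0/0", "0/0", "0/1", "0/0"),  # chr1:501 missing CADD
    c("1",   "0/1", "0",   "1/1", "1"),    # chrX:101 hemizygous males
    c("0/1", "0/0", "1/1", "0/0", "0/1"),  # chr1:601
    c("0/0", "0/0", "0/0", "0/0", "0/1"),  # chr1:701 multi-gene
    c("0/0", "0/1", "0/0", "0/0", "0/0")   # chr1:801 frameshift
  )
  colnames(m) <- paste0("S", 1:5)
  m
}

fixture_sex <- function() {
  data.frame(sample_id = paste0("S", 1:5),
             sex = c("M", "F", "M", "F", "M"),
             stringsAsFactors = FALSE)
}

# CADD raw values chosen so a -7.53..35.79 rescale returns v$d exactly;
# site chr1:501 deliberately unannotated (".").
write_fixture <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("fixture")
    dir.create(dir)
  }
  v <- fixture_variants()
  gt <- fixture_gt()
  raw_cadd <- ifelse(is.na(v$d), ".",
                     sprintf("%.17g", v$d * (35.79 - (-7.53)) + (-7.53)))
  sites <- !duplicated(v$pos * 1000 + match(v$chrom, unique(v$chrom)))
  vcf <- file.path(dir, "fixture.vcf")
  alt_by_site <- tapply(v$alt, paste(v$chrom, v$pos), identity)
  keys <- paste(v$chrom, v$pos)[sites]
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##contig=<ID=chrX>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gt)), collapse = "\t"),
    paste(v$chrom[sites], v$pos[sites], ".", v$ref[sites],
          vapply(keys, function(k) paste(alt_by_site[[k]], collapse = ","),
                 ""),
          ".", "PASS", ".", "GT",
          apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  ), vcf)
  ann <- file.path(dir, "fixture_ann.tsv")
  writeLines(c(
    paste(c("chrom", "pos", "ref", "alt", "gene", "func_class", "af",
            "CADD"), collapse = "\t"),
    paste(v$chrom, v$pos, v$ref, v$alt, v$gene, v$class,
          ifelse(is.na(v$af), ".", sprintf("%.17g", v$af)),
          raw_cadd, sep = "\t")
  ), ann)
  sex <- file.path(dir, "fixture_sex.tsv")
  utils::write.table(fixture_sex(), sex, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(vcf = vcf, ann = ann, sex = sex, variants = v, gt = gt)
}

# Brute-force recomputation, straight from the equation. Works on the
# fixture tables; knows nothing about the package internals.
oracle_matrix <- function(v = fixture_variants(), gt = fixture_gt(),
                          sex = fixture_sex(), floor = 1e-5) {
  samples <- colnames(gt)
  genes <- sort(unique(unlist(strsplit(v$gene, ";"))))
  M <- matrix(0, length(samples), length(genes),
              dimnames = list(samples, genes))
  male <- setNames(sex$sex == "M", sex$sample_id)[samples]
  site_key <- paste(v$chrom, v$pos)
  for (key in unique(site_key)) {
    rows <- which(site_key == key)
    chrom <- v$chrom[rows[1]]
    # per-allele frequencies with the floor; ref = 1 - sum(alt)
    fa <- pmax(ifelse(is.na(v$af[rows]), floor, v$af[rows]), floor)
    fr <- max(1 - sum(fa), floor)
    # deleteriousness: truncating -> 1; synonymous/splicing -> excluded
    dd <- v$d[rows]
    dd[v$class[rows] %in% c("stopgain", "stoploss", "frameshift insertion",
                            "frameshift deletion")] <- 1
    dd[v$class[rows] %in% c("synonymous SNV", "splicing")] <- NA
    for (s in seq_along(samples)) {
      g <- gt[match(key, unique(site_key)), s]
      if (g %in% c("./.", ".")) next
      al <- as.integer(strsplit(g, "[/|]")[[1]])
      hemi <- length(al) == 1 || (chrom == "chrX" && male[s])
      alts <- unique(al[al > 0])
      if (!length(alts)) next
      dobs <- dd[alts]
      if (all(is.na(dobs))) next
      if (hemi) {
        k <- alts[which.max(dobs)]
        sc <- -dd[k] * log10(fa[k]^2)
        gset <- strsplit(v$gene[rows[k]], ";")[[1]]
      } else {
        f1 <- if (al[1] == 0) fr else fa[al[1]]
        f2 <- if (al[2] == 0) fr else fa[al[2]]
        sc <- -max(dobs, na.rm = TRUE) * log10(f1 * f2)
        gset <- unique(unlist(strsplit(v$gene[rows[alts[!is.na(dobs)]]],
                                       ";")))
      }
      for (gn in gset) M[s, gn] <- M[s, gn] + sc
    }
  }
  M
}
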