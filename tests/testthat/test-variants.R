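test_that("classify_variant applies the allele length/prefix rules", {
  expect_equal(classify_variant("A", "G"), "SNV")
  expect_equal(classify_variant(c("A", "AT"), c("AT", "A")), c("INS", "DEL"))
  expect_equal(classify_variant("AC", "GT"), "OTHER")
  expect_error(classify_variant("", "A"), "malformed")
  expect_error(classify_variant("A", "AX"), "malformed")
})

test_that("classify_variant agrees with a brute-force rule enumerator", {
  brute <- function(ref, alt) {
    if (nchar(ref) == 1 && nchar(alt) == 1 && ref != alt) return("SNV")
    if (nchar(alt) > nchar(ref) &&
        substr(alt, 1, nchar(ref)) == ref) return("INS")
    if (nchar(ref) > nchar(alt) &&
        substr(ref, 1, nchar(alt)) == alt) return("DEL")
    "OTHER"
  }
  alleles <- unlist(lapply(1:3, function(k)
    apply(expand.grid(rep(list(c("A", "C", "G", "T")), k)), 1, paste,
          collapse = "")))
  pairs <- expand.grid(ref = alleles, alt = alleles,
                       stringsAsFactors = FALSE)
  expected <- mapply(brute, pairs$ref, pairs$alt)
  expect_equal(unname(classify_variant(pairs$ref, pairs$alt)),
               unname(expected))
})

test_that("filter_variants keeps calls per the support/population clauses", {
  # read-support clause alone suffices
  expect_equal(nrow(filter_variants(data.frame(
    alt_reads = 5, vaf = 0.01, pop_freq = 0))), 1)
  # population-frequency exclusion dominates
  expect_equal(nrow(filter_variants(data.frame(
    alt_reads = 2, vaf = 0.03, pop_freq = 0.02))), 0)
  # truth-table enumeration over clause combinations
  calls <- data.frame(
    alt_reads = c(5, 4, 2, 5, 2, 10),
    vaf = c(0.01, 0.02, 0.01, 0.05, 0.03, 0.001),
    pop_freq = c(0, 0.005, 0, 0.02, NA, 0.01))
  oracle <- with(calls, {
    pf <- ifelse(is.na(pop_freq), 0, pop_freq)
    (alt_reads > 4 | vaf >= 0.02) & !(pf > 0.01)
  })
  kept <- filter_variants(calls)
  expect_equal(nrow(kept), sum(oracle))
  expect_equal(kept$alt_reads, calls$alt_reads[oracle])  # order preserved
})

test_that("filter thresholds are strict for reads, inclusive for VAF", {
  expect_equal(nrow(filter_variants(data.frame(
    alt_reads = 4, vaf = 0, pop_freq = 0))), 0)    # 4 reads is not "more than 4"
  expect_equal(nrow(filter_variants(data.frame(
    alt_reads = 0, vaf = 0.02, pop_freq = 0))), 1) # 2% VAF inclusive
  expect_equal(nrow(filter_variants(data.frame(
    alt_reads = 0, vaf = 0.03, pop_freq = 0.01))), 1)  # 1% pop freq not > 1%
  # conjunctive strictness flag
  expect_equal(nrow(filter_variants(data.frame(
    alt_reads = 5, vaf = 0.01, pop_freq = 0), conjunctive = TRUE)), 0)
})

test_that("filtering is monotone in its thresholds", {
  calls <- random_calls(200, seed = 3)
  base <- nrow(filter_variants(calls))
  expect_gte(nrow(filter_variants(calls, max_pop_freq = 0.02)), base)
  expect_gte(nrow(filter_variants(calls, min_alt_reads = 2)), base)
  expect_gte(nrow(filter_variants(calls, min_vaf = 0.01)), base)
  expect_lte(nrow(filter_variants(calls, min_vaf = 0.05)), base)
})

test_that("vectorize_tmb counts per class and drops OTHER with a warning", {
  calls <- data.frame(ref = c("A", "A", "C", "A", "TG", "TA"),
                      alt = c("G", "T", "G", "AT", "T", "T"))
  expect_equal(unname(vectorize_tmb(calls)), c(3, 1, 2))
  expect_equal(unname(vectorize_tmb(calls[0, , drop = FALSE])), c(0, 0, 0))
  mixed <- data.frame(
    ref = c(rep("A", 5), "C", "CT", "GAT", "AC", "TT"),
    alt = c(rep("G", 5), "CT", "C", "G", "GT", "AA"))
  expect_warning(v <- vectorize_tmb(mixed), "2 call")
  expect_equal(sum(v), 8)
  # per-megabase normalization
  v2 <- vectorize_tmb(calls, covered_mb = 2)
  expect_equal(unname(attr(v2, "per_mb")), c(1.5, 0.5, 1))
  expect_error(vectorize_tmb(calls, covered_mb = -1), "positive")
})

test_that("components of the burden vector sum to the non-OTHER call count", {
  set.seed(9)
  for (i in 1:5) {
    n <- sample(5:40, 1)
    refs <- sample(c("A", "C", "AT", "GC"), n, replace = TRUE)
    alts <- sample(c("G", "T", "A", "ATT"), n, replace = TRUE)
    ok <- refs != alts
    calls <- data.frame(ref = refs[ok], alt = alts[ok])
    cls <- classify_variant(calls$ref, calls$alt)
    v <- suppressWarnings(vectorize_tmb(calls))
    expect_equal(sum(v), sum(cls != "OTHER"))
  }
})

test_that("VCF reading splits multi-allelic records and keys by sample", {
  path <- system.file("extdata", "toy.vcf", package = "TMBserval")
  calls <- read_variant_table(path, "vcf")
  expect_named(calls, c("PT01", "PT02"))
  expect_equal(sum(vapply(calls, nrow, integer(1))), 4)
  expect_equal(calls$PT01$mclass, c("SNV", "INS"))
  expect_equal(calls$PT02$mclass, c("INS", "DEL"))
  expect_equal(calls$PT01$pos, c(101L, 202L))       # 1-based preserved
  expect_equal(calls$PT02$vaf[2], 7 / 25)
  # population-frequency annotation flows through to the filter
  tm <- tmb_matrix(calls)
  expect_equal(unname(tm["PT02", ]), c(0, 1, 0))    # DEL at 5% pop freq removed
})

test_that("MAF reading maps SNP->SNV and keys by tumor barcode", {
  path <- system.file("extdata", "toy.maf", package = "TMBserval")
  calls <- read_variant_table(path, "maf")
  expect_named(calls, c("PT01", "PT02"))
  expect_equal(calls$PT01$mclass, c("SNV", "SNV"))
  expect_equal(sort(calls$PT02$mclass), c("DEL", "INS", "SNV"))
  expect_error(read_variant_table(path, "bed"), "arg")
  expect_error(read_variant_table("no/such/file.vcf", "vcf"), "not found")
})

test_that("TSV round trip through write_tmb_table preserves counts", {
  path <- system.file("extdata", "toy.vcf", package = "TMBserval")
  tm <- tmb_matrix(read_variant_table(path, "vcf"))
  out <- tempfile(fileext = ".tsv")
  write_tmb_table(tm, out)
  tab <- read.delim(out)
  expect_equal(nrow(tab), length(tm))
  wide <- reshape(tab, idvar = "patient_id", timevar = "class",
                  direction = "wide")
  expect_equal(unname(as.matrix(wide[, -1])),
               unname(tm[wide$patient_id, ]))
})
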