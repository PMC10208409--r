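#' Classify a variant by its ref/alt alleles
#'
#' Assigns each called variant to one of the burden classes used to build
#' multidimensional TMB vectors: single-nucleotide variants (`SNV`),
#' insertions (`INS`), deletions (`DEL`), or `OTHER` (multi-nucleotide or
#' complex substitutions, which do not enter the default burden vector).
#'
#' The rules are purely allele-based: `SNV` when both alleles are single
#' (distinct) bases; `INS` when the alternate allele extends the reference
#' allele (reference is a proper prefix); `DEL` when the reference extends the
#' alternate.  No indel left-alignment is performed: alleles are classified
#' as given.
#'
#' @param ref,alt character vectors of reference and alternate alleles
#'   (uppercase DNA over `A`,`C`,`G`,`T`,`N`; no symbolic alleles).
#' @return character vector, one of `"SNV"`, `"INS"`, `"DEL"`, `"OTHER"`.
#' @examples
#' classify_variant("A", "G")            # SNV
#' classify_variant(c("A", "AT"), c("AT", "A"))  # INS, DEL
#' classify_variant("AC", "GT")          # OTHER (complex substitution)
#' @export
classify_variant <- function(ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (length(ref) != length(alt))
    stop("'ref' and 'alt' must have equal length")
  bad <- !nzchar(ref) | !nzchar(alt) |
    grepl("[^ACGTN]", ref) | grepl("[^ACGTN]", alt)
  if (any(bad))
    stop("malformed allele(s): ",
         paste(unique(paste0(ref[bad], ">", alt[bad])), collapse = ", "))
  nr <- nchar(ref)
  na <- nchar(alt)
  out <- rep("OTHER", length(ref))
  out[nr == 1L & na == 1L & ref != alt] <- "SNV"
  ins <- na > nr & substr(alt, 1L, nr) == ref
  del <- nr > na & substr(ref, 1L, na) == alt
  out[ins] <- "INS"
  out[del] <- "DEL"
  out
}

#' Filter variant calls on read support, allele fraction and population
#' frequency
#'
#' Applies the standard somatic-call filters used before burden counting: a
#' call is kept when its evidence clause holds -- more than `min_alt_reads`
#' supporting reads *or* a variant allele fraction of at least `min_vaf` --
#' and it is not a known common polymorphism (population frequency above
#' `max_pop_freq` in reference databases such as 1000 Genomes or ExAC).
#'
#' "More than 4 reads" is read literally as a strict inequality (`> 4`, i.e.
#' at least 5); the VAF threshold is inclusive (`>= 0.02`).  A missing
#' population frequency (`NA`) is treated as 0 -- a novel variant -- so only
#' annotated common polymorphisms are excluded.  Set `conjunctive = TRUE` to
#' require both evidence clauses (sensitivity analysis).
#'
#' @param calls data.frame of variant calls with numeric columns
#'   `alt_reads`, `vaf` and (optionally) `pop_freq`.
#' @param min_alt_reads strict read-support threshold (default 4, i.e. keep
#'   when `alt_reads > 4`).
#' @param min_vaf inclusive variant-allele-fraction threshold (default 0.02).
#' @param max_pop_freq exclusive population-frequency ceiling (default 0.01;
#'   calls with `pop_freq > 0.01` are removed).
#' @param conjunctive require both evidence clauses instead of either
#'   (default `FALSE`, the literal disjunctive reading).
#' @return the filtered data.frame, input order preserved.
#' @examples
#' calls <- data.frame(alt_reads = c(5, 2), vaf = c(0.01, 0.03),
#'                     pop_freq = c(0, 0.02))
#' filter_variants(calls)  # first kept, second removed
#' @export
filter_variants <- function(calls, min_alt_reads = 4, min_vaf = 0.02,
                            max_pop_freq = 0.01, conjunctive = FALSE) {
  stopifnot(is.data.frame(calls),
            all(c("alt_reads", "vaf") %in% names(calls)),
            min_alt_reads >= 0, min_vaf >= 0, max_pop_freq >= 0)
  pf <- if ("pop_freq" %in% names(calls)) calls$pop_freq else rep(0, nrow(calls))
  pf[is.na(pf)] <- 0
  reads_ok <- calls$alt_reads > min_alt_reads
  vaf_ok <- calls$vaf >= min_vaf
  support <- if (conjunctive) reads_ok & vaf_ok else reads_ok | vaf_ok
  keep <- support & !(pf > max_pop_freq)
  calls[keep, , drop = FALSE]
}

#' Count filtered calls into a multidimensional TMB vector
#'
#' Tallies a patient's (already filtered) variant calls per mutation class
#' into the burden vector the model consumes, by default
#' `TMB = (SNV, INS, DEL)`.  Calls classified outside the configured class
#' list (e.g. `OTHER`) are dropped with a warning reporting how many.  The
#' class list is configurable so further burden classes (copy-number,
#' microsatellite features, ...) can be appended; the model input dimension
#' `d` follows the class list.
#'
#' @param calls data.frame of filtered calls with columns `ref` and `alt`
#'   (classified on the fly) or a precomputed `mclass` column.
#' @param classes ordered character vector of burden classes
#'   (default `c("SNV","INS","DEL")`).
#' @param covered_mb optional covered-region size in megabases; when given,
#'   a `per_mb` attribute holds counts divided by `covered_mb`.
#' @return named integer vector of class counts (length `length(classes)`),
#'   with attribute `per_mb` when `covered_mb` is supplied.
#' @examples
#' calls <- data.frame(ref = c("A", "A", "C", "A", "TG", "TA"),
#'                     alt = c("G", "T", "G", "AT", "T", "T"))
#' vectorize_tmb(calls)  # 3 SNVs, 1 INS, 2 DELs
#' @export
vectorize_tmb <- function(calls, classes = c("SNV", "INS", "DEL"),
                          covered_mb = NULL) {
  stopifnot(is.data.frame(calls), length(classes) >= 1)
  if (!is.null(covered_mb) && (!is.numeric(covered_mb) || covered_mb <= 0))
    stop("'covered_mb' must be a positive region size in megabases")
  mclass <- if ("mclass" %in% names(calls)) as.character(calls$mclass)
            else if (nrow(calls)) classify_variant(calls$ref, calls$alt)
            else character(0)
  n_other <- sum(!mclass %in% classes)
  if (n_other > 0)
    warning(n_other, " call(s) outside the configured classes were dropped")
  counts <- vapply(classes, function(cl) sum(mclass == cl), integer(1))
  if (!is.null(covered_mb)) attr(counts, "per_mb") <- counts / covered_mb
  counts
}

#' Read per-patient variant calls from VCF, MAF or generic TSV
#'
#' Parses a variant file into one data.frame of calls per patient, ready for
#' [filter_variants()] and [vectorize_tmb()].  Coordinates stay 1-based as in
#' the source.  Multi-allelic VCF records are split into one call per
#' alternate allele; a call is attributed to every sample whose genotype
#' carries that allele.  MAF files are keyed by `Tumor_Sample_Barcode` with
#' `Variant_Type` mapped `SNP -> SNV`; generic TSVs carry an explicit
#' `patient_id` column.
#'
#' @param path path to the variant file.
#' @param format one of `"vcf"`, `"maf"`, `"tsv"`.
#' @param pop_freq_field INFO key (VCF) holding the annotated population
#'   allele frequency (default `"POP_FREQ"`); missing annotation yields `NA`.
#' @return named list of data.frames (one per patient) with columns `chrom`,
#'   `pos`, `ref`, `alt`, `alt_reads`, `vaf`, `pop_freq`, `mclass`.
#' @export
read_variant_table <- function(path, format = c("vcf", "maf", "tsv"),
                               pop_freq_field = "POP_FREQ") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         vcf = .read_vcf_calls(path, pop_freq_field),
         maf = .read_maf_calls(path),
         tsv = .read_tsv_calls(path))
}

.call_frame <- function(chrom, pos, ref, alt, alt_reads, vaf, pop_freq) {
  data.frame(chrom = as.character(chrom), pos = as.integer(pos),
             ref = toupper(as.character(ref)), alt = toupper(as.character(alt)),
             alt_reads = as.numeric(alt_reads), vaf = as.numeric(vaf),
             pop_freq = as.numeric(pop_freq),
             mclass = classify_variant(ref, alt),
             stringsAsFactors = FALSE, row.names = NULL)
}

.read_vcf_calls <- function(path, pop_freq_field) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  if (is.null(samples) || !length(samples))
    stop("VCF has no sample columns: ", path)
  out <- stats::setNames(vector("list", length(samples)), samples)
  if (nrow(fix) == 0) {
    for (s in samples) out[[s]] <- .call_frame(character(0), integer(0),
      character(0), character(0), numeric(0), numeric(0), numeric(0))
    return(out)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  pf <- vcfR::extract.info(v, element = pop_freq_field, as.numeric = TRUE)
  if (is.null(pf)) pf <- rep(NA_real_, nrow(fix))
  for (s in samples) {
    rows <- list()
    for (r in seq_len(nrow(fix))) {
      alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1]]
      g <- gt[r, s]
      if (is.na(g)) next
      gidx <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
      depths <- if (!is.null(ad) && !is.na(ad[r, s]))
        suppressWarnings(as.numeric(strsplit(ad[r, s], ",", fixed = TRUE)[[1]]))
      else rep(NA_real_, length(alts) + 1L)
      tot <- sum(depths, na.rm = TRUE)
      for (a in seq_along(alts)) {
        if (!a %in% gidx) next     # sample does not carry this allele
        ar <- if (length(depths) > a) depths[a + 1L] else NA_real_
        rows[[length(rows) + 1L]] <- .call_frame(
          fix$CHROM[r], fix$POS[r], fix$REF[r], alts[a],
          ar, if (is.finite(ar) && tot > 0) ar / tot else NA_real_, pf[r])
      }
    }
    out[[s]] <- if (length(rows)) do.call(rbind, rows)
      else .call_frame(character(0), integer(0), character(0), character(0),
                       numeric(0), numeric(0), numeric(0))
  }
  out
}

.read_maf_calls <- function(path) {
  maf <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("Chromosome", "Start_Position", "Reference_Allele",
            "Tumor_Seq_Allele2", "Tumor_Sample_Barcode")
  miss <- setdiff(need, names(maf))
  if (length(miss)) stop("MAF lacks required column(s): ",
                         paste(miss, collapse = ", "))
  # MAF encodes indels with "-" alleles; rebuild prefix-style alleles so the
  # allele-length classifier applies uniformly.
  ref <- maf$Reference_Allele
  alt <- maf$Tumor_Seq_Allele2
  ins <- ref == "-"
  del <- alt == "-"
  ref[ins] <- "N"; alt[ins] <- paste0("N", alt[ins])
  alt[del] <- "N"; ref[del] <- paste0("N", ref[del])
  ar <- if ("t_alt_count" %in% names(maf)) maf$t_alt_count else NA_real_
  dp <- if ("t_depth" %in% names(maf)) maf$t_depth else NA_real_
  pf <- if ("ExAC_AF" %in% names(maf)) maf$ExAC_AF else NA_real_
  calls <- .call_frame(maf$Chromosome, maf$Start_Position, ref, alt,
                       ar, ifelse(is.finite(ar) & is.finite(dp) & dp > 0,
                                  ar / dp, NA_real_), pf)
  if ("Variant_Type" %in% names(maf)) {
    vt <- toupper(maf$Variant_Type)
    vt[vt == "SNP"] <- "SNV"
    calls$mclass <- ifelse(vt %in% c("SNV", "INS", "DEL"), vt, calls$mclass)
  }
  split(calls, maf$Tumor_Sample_Barcode)
}

.read_tsv_calls <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "chrom", "pos", "ref", "alt", "alt_reads", "vaf")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("TSV lacks required column(s): ",
                         paste(miss, collapse = ", "))
  if (!"pop_freq" %in% names(tab)) tab$pop_freq <- NA_real_
  calls <- .call_frame(tab$chrom, tab$pos, tab$ref, tab$alt,
                       tab$alt_reads, tab$vaf, tab$pop_freq)
  split(calls, tab$patient_id)
}

#' Build the patient-by-class TMB feature matrix
#'
#' Applies [filter_variants()] and [vectorize_tmb()] to every patient's call
#' list and stacks the burden vectors into the feature matrix the model fits
#' on.
#'
#' @param calls_by_patient named list of call data.frames, as returned by
#'   [read_variant_table()].
#' @param classes ordered burden classes (default `c("SNV","INS","DEL")`).
#' @param covered_mb optional covered megabases for per-Mb normalization.
#' @param ... passed to [filter_variants()].
#' @return numeric matrix, patients in rows (named), classes in columns.
#' @export
tmb_matrix <- function(calls_by_patient, classes = c("SNV", "INS", "DEL"),
                       covered_mb = NULL, ...) {
  stopifnot(is.list(calls_by_patient))
  out <- t(vapply(calls_by_patient, function(calls) {
    kept <- filter_variants(calls, ...)
    as.numeric(suppressWarnings(vectorize_tmb(kept, classes, covered_mb)))
  }, numeric(length(classes))))
  colnames(out) <- classes
  out
}

#' Write per-patient TMB vectors as a tidy TSV
#'
#' @param tmb matrix from [tmb_matrix()] (patients x classes).
#' @param path output path; columns `patient_id`, `class`, `count`
#'   (plus `per_mb` when `covered_mb` is given).
#' @param covered_mb optional covered megabases.
#' @return `path`, invisibly.
#' @export
write_tmb_table <- function(tmb, path, covered_mb = NULL) {
  long <- data.frame(
    patient_id = rep(rownames(tmb), times = ncol(tmb)),
    class = rep(colnames(tmb), each = nrow(tmb)),
    count = as.vector(tmb), stringsAsFactors = FALSE)
  if (!is.null(covered_mb)) long$per_mb <- long$count / covered_mb
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
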