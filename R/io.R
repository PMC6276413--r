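## Readers and writers for the package's on-disk interchange formats:
## cohort tables as CSV, genotype matrices as tab-delimited matrices or
## minimal VCF (GT-only, unphased, biallelic).

#' Write / read a cohort table as CSV
#'
#' @param cohort cohort data.frame with a `subject_id` column.
#' @param path file path.
#' @return `read_cohort_csv` returns the cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(x)) .fail("cohort CSV lacks a subject_id column")
  x
}

#' Write / read a genotype matrix as a tab-delimited table
#'
#' Rows are subjects, columns SNPs, cells 0/1/2 alternate-allele counts
#' (`NA` for missing); the first column holds subject IDs.
#'
#' @param geno integer matrix as from [simulate_genotypes()].
#' @param path file path.
#' @return `read_genotypes_tsv` returns the genotype matrix (annotation
#'   attribute absent unless sidecar data are supplied).
#' @export
write_genotypes_tsv <- function(geno, path) {
  df <- data.frame(subject_id = rownames(geno), geno, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  g <- as.matrix(df[-1])
  storage.mode(g) <- "integer"
  rownames(g) <- df[[1]]
  ok <- g %in% c(0L, 1L, 2L) | is.na(g)
  if (!all(ok)) .fail("genotype values must be 0, 1, 2 or missing")
  if (anyDuplicated(colnames(g))) .fail("rsIDs must be unique")
  if (any(colSums(!is.na(g)) == 0)) .fail("every SNP needs >= 1 observed genotype")
  g
}

#' Write a genotype matrix as a minimal VCF
#'
#' GT-only, unphased ("0/0", "0/1", "1/1", "./." for missing), one ALT
#' allele per site. Positions are synthetic (sequential on chromosome 1)
#' unless the annotation attribute provides them.
#'
#' @param geno genotype matrix (subjects x SNPs).
#' @param path output path (plain text).
#' @return invisibly, the path.
#' @export
write_genotypes_vcf <- function(geno, path) {
  ann <- attr(geno, "annotation")
  m <- ncol(geno)
  if (is.null(ann))
    ann <- data.frame(rsid = colnames(geno), gene = ".",
                      ref = "A", alt = "G")
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=lipidgrs",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t")
  )
  body <- vapply(seq_len(m), function(j) {
    gt <- ifelse(is.na(geno[, j]), "./.", gt_code[geno[, j] + 1L])
    paste(c("1", j * 1000L, ann$rsid[j], ann$ref[j], ann$alt[j], ".",
            "PASS", paste0("GENE=", ann$gene[j]), "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a genotype matrix from a minimal VCF
#'
#' Accepts only the dialect written by [write_genotypes_vcf()]: unphased
#' GT, a single ALT allele. Anything else (phased calls, multiallelic
#' sites) is rejected loudly.
#'
#' @param path VCF file path.
#' @return genotype matrix with annotation attribute.
#' @export
read_genotypes_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) .fail("not a VCF: missing #CHROM header line")
  head_fields <- strsplit(lines[hdr], "\t")[[1]]
  subjects <- head_fields[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  recs <- strsplit(body, "\t")
  m <- length(recs)
  g <- matrix(NA_integer_, length(subjects), m,
              dimnames = list(subjects, vapply(recs, `[[`, "", 3L)))
  ann <- data.frame(rsid = colnames(g),
                    gene = sub("^GENE=", "", vapply(recs, `[[`, "", 8L)),
                    ref = vapply(recs, `[[`, "", 4L),
                    alt = vapply(recs, `[[`, "", 5L))
  if (any(grepl(",", ann$alt, fixed = TRUE)))
    .fail("multiallelic sites are not supported")
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L, "./." = NA_integer_)
  for (j in seq_len(m)) {
    gt <- recs[[j]][-(1:9)]
    if (!all(gt %in% names(code)))
      .fail("unsupported GT value(s) at %s: only unphased 0/0, 0/1, 1/1, ./.",
            ann$rsid[j])
    g[, j] <- code[gt]
  }
  if (anyDuplicated(colnames(g))) .fail("rsIDs must be unique")
  attr(g, "annotation") <- ann
  g
}

#' Simulate a cohort and write its files to disk
#'
#' Writes the cohort CSV, the genotype matrix (TSV and VCF) and a JSON
#' truth record into `dir`.
#'
#' @param spec a [simulation_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, the `sim_cohort` object.
#' @export
simulate_to_files <- function(spec, dir) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$n_subjects < 1) .fail("n_subjects must be positive")
  sim <- simulate_cohort(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_csv(sim$cohort, file.path(dir, "cohort.csv"))
  write_genotypes_tsv(sim$genotypes, file.path(dir, "genotypes.tsv"))
  write_genotypes_vcf(sim$genotypes, file.path(dir, "genotypes.vcf"))
  jsonlite::write_json(
    list(seed = spec$seed, truth = sim$truth),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(sim)
}
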