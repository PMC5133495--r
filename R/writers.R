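#' Write a dosage matrix as a minimal VCF
#'
#' Emits a VCF 4.2 file with one biallelic record per SNP carrying a `DS`
#' FORMAT field (dosage of the ALT = minor allele) alongside a rounded `GT`
#' hard call. Readable back through [read_dosages()].
#'
#' @param dos A `DosageMatrix`.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf_dosages <- function(dos, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", dos$sample_ids), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_along(dos$snp_ids)) {
    d <- dos$dosage[, j]
    gt <- gt_code[pmin(pmax(round(d), 0), 2) + 1L]
    cells <- paste0(gt, ":", formatC(d, format = "g", digits = 10))
    writeLines(paste(c(dos$chrom[j], dos$pos[j], dos$snp_ids[j], "A", "C",
                       ".", "PASS", ".", "GT:DS", cells), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Write a phenotype table
#'
#' @param phe A `PhenotypeTable`.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phe, path, sep = "\t") {
  utils::write.table(as.data.frame(phe), path, quote = FALSE,
                     row.names = FALSE, sep = sep)
  invisible(path)
}

#' Write regions as a BED file
#'
#' Converts the package's 1-based inclusive regions back to BED's 0-based
#' half-open convention (`BED start = start - 1`, `BED end = end`).
#'
#' @param regions Region data frame (see [read_regions()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  bed <- data.frame(regions$chromosome, regions$start - 1L, regions$end,
                    regions$label)
  utils::write.table(bed, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(path)
}

#' Write a simulated dataset as a VCF/PED/phenotype/BED file bundle
#'
#' Materializes an `AnalysisDataset` in the same formats real data would
#' arrive in, so the file-reading path can be exercised end to end.
#'
#' @param ds An `AnalysisDataset`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default `"sim"`).
#' @return Named character vector of the four paths written, invisibly.
#' @export
write_dataset <- function(ds, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, paste0(prefix, ".vcf")),
    ped = file.path(dir, paste0(prefix, ".ped")),
    pheno = file.path(dir, paste0(prefix, ".pheno.tsv")),
    bed = file.path(dir, paste0(prefix, ".bed"))
  )
  write_vcf_dosages(ds$dosages, paths["vcf"])
  write_pedigree(ds$pedigree, paths["ped"])
  write_phenotypes(ds$phenotypes, paths["pheno"])
  chroms <- unique(ds$dosages$chrom)
  regions <- do.call(rbind, lapply(chroms, function(ch) {
    p <- ds$dosages$pos[ds$dosages$chrom == ch]
    data.frame(chromosome = ch, start = min(p), end = max(p),
               label = paste0("region_", ch), stringsAsFactors = FALSE)
  }))
  write_regions(regions, paths["bed"])
  invisible(paths)
}
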