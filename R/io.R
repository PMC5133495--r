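#' Read a PED/FAM-style pedigree file
#'
#' Reads a whitespace-delimited pedigree file with at least five columns
#' (family id, subject id, father id, mother id, sex). `"0"` denotes a
#' missing parent. Any columns beyond the fifth (e.g. a phenotype column in
#' classic PED) are ignored.
#'
#' @param path Path to the pedigree file.
#' @return A `data.frame` of class `PedigreeTable` with columns
#'   `family_id`, `subject_id`, `father_id`, `mother_id` (parent columns are
#'   `NA` when missing) and `sex` (1 = male, 2 = female, `NA` = unknown).
#' @details Subject ids must be unique across the file; every non-missing
#'   parent must itself appear as a subject in the same family, and the
#'   parent-offspring graph must be acyclic. Violations raise errors naming
#'   the offending id.
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 5L)
    stop("pedigree file must have at least 5 columns (fam, id, father, mother, sex)")
  ped <- data.frame(
    family_id  = raw[[1L]],
    subject_id = raw[[2L]],
    father_id  = ifelse(raw[[3L]] == "0", NA_character_, raw[[3L]]),
    mother_id  = ifelse(raw[[4L]] == "0", NA_character_, raw[[4L]]),
    sex        = suppressWarnings(as.integer(raw[[5L]])),
    stringsAsFactors = FALSE
  )
  ped$sex[!(ped$sex %in% c(1L, 2L))] <- NA_integer_
  validate_pedigree(ped)
  class(ped) <- c("PedigreeTable", "data.frame")
  ped
}

#' Write a pedigree table in PED/FAM format
#'
#' Inverse of [read_pedigree()]: missing parents and unknown sex are written
#' as `"0"`.
#'
#' @param ped A `PedigreeTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(
    ped$family_id, ped$subject_id,
    ifelse(is.na(ped$father_id), "0", ped$father_id),
    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    ifelse(is.na(ped$sex), 0L, ped$sex)
  )
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

validate_pedigree <- function(ped) {
  dup <- ped$subject_id[duplicated(ped$subject_id)]
  if (length(dup))
    stop("duplicate subject id: ", dup[1L])
  for (col in c("father_id", "mother_id")) {
    par <- ped[[col]]
    known <- is.na(par) | par %in% ped$subject_id
    if (!all(known))
      stop("unknown parent ", par[!known][1L])
    # parent must live in the same family as the child
    idx <- match(par, ped$subject_id)
    ok <- is.na(par) | ped$family_id[idx] == ped$family_id
    if (!all(ok))
      stop("parent ", par[!ok][1L], " belongs to a different family")
  }
  pedigree_topological_order(ped)  # errors on cycles
  invisible(TRUE)
}

# Parents-before-children ordering (Kahn's algorithm); errors on cycles.
# Returns integer row indices of `ped`.
pedigree_topological_order <- function(ped) {
  n <- nrow(ped)
  fa <- match(ped$father_id, ped$subject_id)
  mo <- match(ped$mother_id, ped$subject_id)
  indeg <- (!is.na(fa)) + (!is.na(mo))
  # children lists
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(fa[i])) kids[[fa[i]]] <- c(kids[[fa[i]]], i)
    if (!is.na(mo[i])) kids[[mo[i]]] <- c(kids[[mo[i]]], i)
  }
  queue <- which(indeg == 0L)
  order <- integer(0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(order) < n)
    stop("pedigree contains a cycle involving subject ",
         ped$subject_id[setdiff(seq_len(n), order)][1L])
  order
}

#' Construct a dosage matrix object
#'
#' Container for minor-allele dosages of `n` samples at `N` biallelic SNPs.
#'
#' @param dosage Numeric `n x N` matrix, entries in `[0, 2]`; rownames are
#'   sample ids, colnames SNP ids.
#' @param chrom Character vector of length `N`.
#' @param pos Integer vector of 1-based positions, strictly increasing within
#'   each chromosome.
#' @return A list of class `DosageMatrix` with elements `dosage`, `chrom`,
#'   `pos`, `sample_ids`, `snp_ids`.
#' @export
dosage_matrix <- function(dosage, chrom, pos) {
  dosage <- as.matrix(dosage)
  stopifnot(!is.null(rownames(dosage)),
            length(chrom) == ncol(dosage), length(pos) == ncol(dosage))
  if (ncol(dosage) > 0L && is.null(colnames(dosage)))
    colnames(dosage) <- paste0(chrom, ":", pos)
  if (anyNA(dosage)) stop("dosage matrix contains missing values")
  if (any(dosage < 0 | dosage > 2)) stop("dosages must lie in [0, 2]")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  structure(list(dosage = dosage, chrom = as.character(chrom),
                 pos = as.integer(pos),
                 sample_ids = rownames(dosage), snp_ids = colnames(dosage)),
            class = "DosageMatrix")
}

#' @export
print.DosageMatrix <- function(x, ...) {
  cat("DosageMatrix:", length(x$sample_ids), "samples x",
      length(x$snp_ids), "SNPs\n")
  invisible(x)
}

# Subset a DosageMatrix by SNP column index, keeping metadata aligned.
subset_snps <- function(dos, j) {
  dosage_matrix(dos$dosage[, j, drop = FALSE], dos$chrom[j], dos$pos[j])
}

#' Read minor-allele dosages from a VCF or plain matrix file
#'
#' Extracts biallelic SNPs inside a region and returns minor-allele dosages
#' for the requested samples, in the requested order. Dosages come from the
#' `DS` FORMAT field when present, otherwise from `GT` hard calls. Columns
#' whose alternate-allele frequency exceeds 0.5 are recoded `2 - d` so that
#' dosages always count the minor allele. Missing entries are imputed to the
#' SNP's sample mean dosage (count reported via message). Multi-allelic sites
#' are skipped with a message.
#'
#' @param path VCF file (plain or bgzipped), or a tab-delimited matrix file
#'   with columns `snp_id`, `chrom`, `pos` followed by one column per sample
#'   (detected by extension `.tsv`/`.txt`).
#' @param region A one-row `Region` data frame (see [read_regions()]); 1-based
#'   inclusive coordinates.
#' @param samples Character vector of sample ids to keep, in output order.
#' @return A [`DosageMatrix`][dosage_matrix].
#' @export
read_dosages <- function(path, region, samples) {
  stopifnot(nrow(region) == 1L)
  if (grepl("\\.(tsv|txt)$", path)) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    chrom <- as.character(tab[[2L]]); pos <- as.integer(tab[[3L]])
    ids <- as.character(tab[[1L]])
    smp <- colnames(tab)[-(1:3)]
    dos <- t(as.matrix(tab[, -(1:3), drop = FALSE]))
    rownames(dos) <- smp
    colnames(dos) <- ids
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcf@fix
    chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
    alt <- fix[, "ALT"]; ref <- fix[, "REF"]
    multi <- grepl(",", alt) | is.na(alt)
    if (any(multi))
      message(sum(multi), " multi-allelic site(s) skipped")
    biallelic <- !multi & nchar(ref) == 1L & nchar(alt) == 1L
    fmt <- vcf@gt[, 1L]
    has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
    if (has_ds) {
      dsm <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    } else {
      gt <- vcfR::extract.gt(vcf, element = "GT")
      dsm <- apply(gt, c(1, 2), function(g) {
        if (is.na(g)) return(NA_real_)
        sum(as.integer(strsplit(g, "[/|]")[[1L]]) > 0L)
      })
    }
    keep <- which(biallelic)
    dos <- t(dsm[keep, , drop = FALSE])
    chrom <- chrom[keep]; pos <- pos[keep]
    colnames(dos) <- fix[keep, "ID"]
    noid <- is.na(colnames(dos)) | colnames(dos) == "."
    colnames(dos)[noid] <- paste0(chrom[noid], ":", pos[noid])
  }

  in_region <- chrom == region$chromosome &
    pos >= region$start & pos <= region$end
  dos <- dos[, in_region, drop = FALSE]
  chrom <- chrom[in_region]; pos <- pos[in_region]

  missing_samples <- setdiff(samples, rownames(dos))
  if (length(missing_samples))
    stop("sample(s) absent from genotype file: ",
         paste(missing_samples, collapse = ", "))
  dos <- dos[samples, , drop = FALSE]

  if (ncol(dos)) {
    n_miss <- sum(is.na(dos))
    if (n_miss) {
      message(n_miss, " missing dosage entr(ies) imputed to SNP mean")
      for (j in seq_len(ncol(dos))) {
        miss <- is.na(dos[, j])
        if (any(miss)) dos[miss, j] <- mean(dos[!miss, j])
      }
    }
    # orient to the minor allele
    flip <- colMeans(dos) / 2 > 0.5
    dos[, flip] <- 2 - dos[, flip, drop = FALSE]
  }
  dosage_matrix(dos, chrom, pos)
}

#' Read test regions from a BED file
#'
#' BED intervals (0-based, half-open) are converted to 1-based inclusive
#' coordinates: `start = BED start + 1`, `end = BED end`.
#'
#' @param path BED file path; the 4th column, when present, becomes the
#'   region label.
#' @return A `data.frame` with columns `chromosome`, `start`, `end`, `label`.
#' @export
read_regions <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- as.data.frame(gr)
  lab <- if ("name" %in% colnames(df) && !all(is.na(df$name))) {
    as.character(df$name)
  } else {
    paste0(df$seqnames, ":", df$start, "-", df$end)
  }
  out <- data.frame(chromosome = as.character(df$seqnames),
                    start = as.integer(df$start), end = as.integer(df$end),
                    label = lab, stringsAsFactors = FALSE)
  bad <- out$start > out$end
  if (any(bad))
    stop("empty region after BED conversion: ", out$label[bad][1L])
  out
}

#' Read a phenotype/covariate table
#'
#' @param path Header-bearing delimited text with columns `sample_id`,
#'   `trait`, `age`, `sex` (extra columns are kept but unused).
#' @param sep Field separator (default tab).
#' @return A `data.frame` of class `PhenotypeTable`.
#' @export
read_phenotypes <- function(path, sep = "\t") {
  phe <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "trait", "age", "sex")
  miss <- setdiff(need, colnames(phe))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  phe$sample_id <- as.character(phe$sample_id)
  if (anyDuplicated(phe$sample_id))
    stop("duplicate sample_id in phenotype table")
  class(phe) <- c("PhenotypeTable", "data.frame")
  phe
}

#' Assemble an aligned analysis dataset
#'
#' Intersects the samples present in the pedigree, the dosage matrix and the
#' phenotype table, drops subjects with missing trait, age or sex (reported
#' via message), and aligns all three components to one shared sample order
#' (pedigree file order restricted to the intersection).
#'
#' @param ped A `PedigreeTable`.
#' @param dos A `DosageMatrix`.
#' @param phe A `PhenotypeTable`.
#' @return A list of class `AnalysisDataset` with elements `pedigree`,
#'   `dosages`, `phenotypes`, `sample_ids`.
#' @export
assemble_dataset <- function(ped, dos, phe) {
  complete <- phe$sample_id[!is.na(phe$trait) & !is.na(phe$age) &
                              !is.na(phe$sex)]
  dropped_incomplete <- setdiff(phe$sample_id, complete)
  if (length(dropped_incomplete))
    message(length(dropped_incomplete),
            " sample(s) dropped for missing trait/age/sex: ",
            paste(utils::head(dropped_incomplete, 5L), collapse = ", "))
  keep <- ped$subject_id[ped$subject_id %in% dos$sample_ids &
                           ped$subject_id %in% complete]
  if (!length(keep))
    stop("no samples shared by pedigree, genotypes and phenotypes")
  n_out <- length(union(union(ped$subject_id, dos$sample_ids),
                        phe$sample_id)) - length(keep)
  if (n_out)
    message(n_out, " sample(s) outside the three-way intersection dropped")
  dos_k <- dosage_matrix(dos$dosage[keep, , drop = FALSE], dos$chrom, dos$pos)
  phe_k <- phe[match(keep, phe$sample_id), , drop = FALSE]
  rownames(phe_k) <- NULL
  structure(list(pedigree = ped, dosages = dos_k, phenotypes = phe_k,
                 sample_ids = keep),
            class = "AnalysisDataset")
}
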