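# Small in-code fixture builders shared across test files.

# Pedigree data frame from parallel vectors ("0"/NA = missing parent).
make_ped <- function(fam, id, father, mother, sex = rep(1L, length(id))) {
  father[father == "0"] <- NA
  mother[mother == "0"] <- NA
  ped <- data.frame(family_id = as.character(fam), subject_id = as.character(id),
                    father_id = as.character(father),
                    mother_id = as.character(mother),
                    sex = as.integer(sex), stringsAsFactors = FALSE)
  class(ped) <- c("PedigreeTable", "data.frame")
  ped
}

# trio: founders "P" (m), "M" (f), child "C"
trio_ped <- function() {
  make_ped("F1", c("P", "M", "C"), c(NA, NA, "P"), c(NA, NA, "M"),
           c(1L, 2L, 1L))
}

# two founder couples, full sibs S1/S2 (of P+M), half sib H (P + M2)
sib_ped <- function() {
  make_ped("F1", c("P", "M", "M2", "S1", "S2", "H"),
           c(NA, NA, NA, "P", "P", "P"), c(NA, NA, NA, "M", "M", "M2"),
           c(1L, 2L, 2L, 1L, 2L, 1L))
}

# DosageMatrix from a plain matrix (samples get ids s1..sn)
make_dos <- function(mat, chrom = NULL, pos = NULL) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("s", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("v", seq_len(ncol(mat)))
  if (is.null(chrom)) chrom <- rep("1", ncol(mat))
  if (is.null(pos)) pos <- seq_len(ncol(mat)) * 100L
  dosage_matrix(mat, chrom, pos)
}

# Write a VCF with given FORMAT cells (list of per-variant character vectors)
write_test_vcf <- function(path, chrom, pos, id, ref, alt, format, cells,
                           samples) {
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
             "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"d\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (i in seq_along(pos)) {
    lines <- c(lines, paste(c(chrom[i], pos[i], id[i], ref[i], alt[i], ".",
                              "PASS", ".", format, cells[[i]]),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

region_df <- function(chrom, start, end, label = "r") {
  data.frame(chromosome = as.character(chrom), start = as.integer(start),
             end = as.integer(end), label = label, stringsAsFactors = FALSE)
}

# Monte-Carlo tail probability of sum_i lambda_i * chisq_1, with SE.
mc_quadform_tail <- function(q, lambda, n_draws, seed) {
  withr::with_seed(seed, {
    draws <- colSums(lambda * matrix(stats::rnorm(length(lambda) * n_draws)^2,
                                     nrow = length(lambda)))
    p <- mean(draws > q)
    list(p = p, se = sqrt(max(p * (1 - p), 1 / n_draws) / n_draws))
  })
}
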