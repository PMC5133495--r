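#' Pedigree kinship coefficient matrix
#'
#' Computes the kinship coefficients phi(i, j) — the probability that one
#' allele sampled at random from subject i and one from subject j are
#' identical by descent — by the standard tabular recursion, processing
#' subjects in a parents-before-children order:
#' \deqn{\phi(i,i) = \tfrac12 (1 + \phi(f_i, m_i)),\qquad
#'       \phi(i,j) = \tfrac12 (\phi(f_i, j) + \phi(m_i, j))}
#' with founders pairwise unrelated (phi = 0) and founder diagonal 1/2.
#' Subjects in different families get phi = 0.
#'
#' This matrix is the familial covariance structure of the polygenic null
#' model: the random family effect has covariance `s2_fam * Phi`.
#'
#' @param ped A [`PedigreeTable`][read_pedigree].
#' @param samples Character vector of subject ids to keep, in output order;
#'   defaults to all pedigree subjects.
#' @return A symmetric `length(samples)` square matrix of class
#'   `KinshipMatrix` with `samples` as dimnames.
#' @export
kinship_matrix <- function(ped, samples = ped$subject_id) {
  unknown <- setdiff(samples, ped$subject_id)
  if (length(unknown))
    stop("sample(s) not in pedigree: ", paste(unknown, collapse = ", "))
  n <- nrow(ped)
  ord <- pedigree_topological_order(ped)
  fa <- match(ped$father_id, ped$subject_id)
  mo <- match(ped$mother_id, ped$subject_id)
  phi <- matrix(0, n, n)
  for (pos_i in seq_along(ord)) {
    i <- ord[pos_i]
    # an unrecorded parent is an unrelated founder: contributes phi = 0
    phi[i, i] <- if (is.na(fa[i]) || is.na(mo[i])) 0.5 else
      0.5 * (1 + phi[fa[i], mo[i]])
    if (pos_i > 1L) {
      earlier <- ord[seq_len(pos_i - 1L)]
      same_fam <- earlier[ped$family_id[earlier] == ped$family_id[i]]
      if (length(same_fam)) {
        pf <- if (is.na(fa[i])) 0 else phi[fa[i], same_fam]
        pm <- if (is.na(mo[i])) 0 else phi[mo[i], same_fam]
        v <- 0.5 * (pf + pm)
        phi[i, same_fam] <- v
        phi[same_fam, i] <- v
      }
    }
  }
  dimnames(phi) <- list(ped$subject_id, ped$subject_id)
  out <- phi[samples, samples, drop = FALSE]
  class(out) <- c("KinshipMatrix", class(out))
  out
}

#' Write a kinship matrix as delimited text
#'
#' Square matrix with an id header row and id first column, for interop with
#' external mixed-model tools.
#'
#' @param kin A `KinshipMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kinship <- function(kin, path) {
  df <- data.frame(id = rownames(kin), unclass(kin), check.names = FALSE)
  utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
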