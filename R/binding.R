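# Binding-affinity novelty: all affinities are predicted IC50-style values
# in nM produced upstream by any MHC class I predictor; this module only
# consumes the numbers.

#' Novel-binding-change configuration
#'
#' Thresholds for the putatively-novel-binding-change rule: a tumor
#' epitope is a strong binder below \code{strong_binding_threshold} nM,
#' and the paired normal epitope must bind at least
#' \code{fold_change_threshold}-fold more weakly (and no tighter than the
#' strong-binding threshold).
#'
#' @param strong_binding_threshold Strong-binder cutoff in nM (default 500).
#' @param fold_change_threshold Minimum normal/tumor affinity ratio
#'   (default 5).
#' @return A list of class \code{novelty_config}.
#' @export
novelty_config <- function(strong_binding_threshold = 500,
                           fold_change_threshold = 5) {
  if (strong_binding_threshold <= 0 || fold_change_threshold <= 0)
    stop("novelty thresholds must be positive", call. = FALSE)
  structure(list(strong_binding_threshold = strong_binding_threshold,
                 fold_change_threshold = fold_change_threshold),
            class = "novelty_config")
}

.check_affinity <- function(x, arg) {
  if (any(is.na(x)) || any(x <= 0))
    stop(sprintf("domain error: '%s' must be positive nM affinities", arg),
         call. = FALSE)
  as.numeric(x)
}

#' Tumor vs. paired normal binding-affinity difference
#'
#' Defined as the tumor affinity subtracted from the normal affinity
#' (normal minus tumor), so the difference is positive when the tumor
#' peptide binds more tightly (lower nM) than its normal counterpart.
#'
#' @param normal_affinity,tumor_affinity Positive affinities in nM
#'   (vectorized, recycled).
#' @return Numeric vector of signed differences in nM.
#' @examples
#' affinity_difference(2500, 400)  # 2100
#' @export
affinity_difference <- function(normal_affinity, tumor_affinity) {
  .check_affinity(normal_affinity, "normal_affinity") -
    .check_affinity(tumor_affinity, "tumor_affinity")
}

#' Putatively novel binding change classifier
#'
#' TRUE iff the tumor epitope binds strongly
#' (\code{tumor_affinity < strong_binding_threshold}), the paired normal
#' epitope does not (\code{normal_affinity >= strong_binding_threshold}),
#' and the normal affinity is at least \code{fold_change_threshold} times
#' the tumor affinity. Boundary conventions follow the rule's wording:
#' tumor strictly below 500 nM, normal at minimum 500 nM, ratio at least
#' 5-fold.
#'
#' @param tumor_affinity,normal_affinity Positive affinities in nM
#'   (vectorized, recycled).
#' @param config A [novelty_config()].
#' @return Logical vector.
#' @examples
#' is_novel_binding(400, 2500)  # TRUE
#' is_novel_binding(400, 1900)  # FALSE (4.75-fold)
#' @export
is_novel_binding <- function(tumor_affinity, normal_affinity,
                             config = novelty_config()) {
  t_a <- .check_affinity(tumor_affinity, "tumor_affinity")
  n_a <- .check_affinity(normal_affinity, "normal_affinity")
  t_a < config$strong_binding_threshold &
    n_a >= config$strong_binding_threshold &
    n_a / t_a >= config$fold_change_threshold
}

# Fast keyed lookup into a (peptide, allele, affinity_nm) table; errors
# name the first absent pair rather than imputing.
.affinity_lookup <- function(affinities, peptides, alleles,
                             required = TRUE) {
  stopifnot(all(c("peptide", "allele", "affinity_nm") %in%
                  names(affinities)))
  key <- paste(affinities$peptide, affinities$allele, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (peptide, allele) rows in affinity table",
         call. = FALSE)
  idx <- match(paste(peptides, alleles, sep = "\r"), key)
  if (required && anyNA(idx)) {
    miss <- which(is.na(idx))[1L]
    stop(sprintf("lookup error: no affinity for peptide '%s', allele '%s'",
                 peptides[miss], alleles[miss]), call. = FALSE)
  }
  affinities$affinity_nm[idx]
}

#' Classify epitope pairs for novel binding changes across alleles
#'
#' Joins each tumor/normal epitope pair with its predicted affinities for
#' every requested allele and applies [affinity_difference()] and
#' [is_novel_binding()]. Every required (peptide, allele) entry must be
#' present in the affinity table; missing entries are an error, never
#' silently imputed.
#'
#' @param pairs data.frame of epitope pairs as produced by
#'   [enumerate_epitope_pairs()] (needs \code{tumor_peptide} and
#'   \code{normal_peptide} columns).
#' @param affinities data.frame with columns \code{peptide},
#'   \code{allele}, \code{affinity_nm}.
#' @param alleles Character vector of HLA allele names to evaluate.
#' @param config A [novelty_config()].
#' @return data.frame with one row per pair x allele: the pair columns
#'   plus \code{allele}, \code{tumor_affinity_nm}, \code{normal_affinity_nm},
#'   \code{difference_nm}, \code{novel_binding}.
#' @export
classify_pairs <- function(pairs, affinities, alleles,
                           config = novelty_config()) {
  stopifnot(is.data.frame(pairs),
            all(c("tumor_peptide", "normal_peptide") %in% names(pairs)))
  if (nrow(pairs) == 0L || length(alleles) == 0L) {
    out <- pairs[integer(0), , drop = FALSE]
    out$allele <- character(0)
    out$tumor_affinity_nm <- out$normal_affinity_nm <-
      out$difference_nm <- numeric(0)
    out$novel_binding <- logical(0)
    return(out)
  }
  grid <- expand.grid(row = seq_len(nrow(pairs)),
                      allele = as.character(alleles),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- pairs[grid$row, , drop = FALSE]
  out$allele <- grid$allele
  out$tumor_affinity_nm <- .affinity_lookup(
    affinities, out$tumor_peptide, out$allele)
  out$normal_affinity_nm <- .affinity_lookup(
    affinities, out$normal_peptide, out$allele)
  out$difference_nm <- affinity_difference(out$normal_affinity_nm,
                                           out$tumor_affinity_nm)
  out$novel_binding <- is_novel_binding(out$tumor_affinity_nm,
                                        out$normal_affinity_nm, config)
  rownames(out) <- NULL
  out
}
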