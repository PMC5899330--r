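# Population-level accounting: cross-patient neoepitope recurrence and
# binding overlap across random six-allele HLA sets.

#' Cross-patient neoepitope recurrence accounting
#'
#' Deduplicates (patient, peptide) rows within each patient, then counts,
#' for every distinct neoepitope sequence, the number of distinct patients
#' carrying it overall and within each disease site, and, for every
#' patient, the fraction of their distinct sequences observed in at least
#' one other patient (within their own disease and across the whole
#' cohort). Counts are of distinct patients, not input rows, and are
#' invariant under row order and duplicated rows.
#'
#' @param table data.frame with columns \code{patient}, \code{disease},
#'   \code{peptide}.
#' @return A list with elements \code{sequences} (peptide,
#'   \code{n_patients_overall}), \code{by_disease} (disease, peptide,
#'   \code{n_patients}), and \code{patients} (patient, disease,
#'   \code{n_distinct}, \code{frac_repeated_within},
#'   \code{frac_repeated_overall}).
#' @export
recurrence_counts <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("patient", "disease", "peptide") %in% names(table)))
  if (nrow(table) == 0L) stop("empty patient-epitope table", call. = FALSE)
  tab <- unique(table[, c("patient", "disease", "peptide")])
  tab <- tab[order(tab$patient, tab$disease, tab$peptide), , drop = FALSE]

  n_overall <- tapply(tab$patient, tab$peptide,
                      function(p) length(unique(p)))
  sequences <- data.frame(peptide = names(n_overall),
                          n_patients_overall = as.integer(n_overall),
                          stringsAsFactors = FALSE, row.names = NULL)

  dkey <- paste(tab$disease, tab$peptide, sep = "\r")
  n_dis <- tapply(tab$patient, dkey, function(p) length(unique(p)))
  parts <- strsplit(names(n_dis), "\r", fixed = TRUE)
  by_disease <- data.frame(
    disease = vapply(parts, `[`, character(1), 1L),
    peptide = vapply(parts, `[`, character(1), 2L),
    n_patients = as.integer(n_dis),
    stringsAsFactors = FALSE, row.names = NULL)

  ov <- sequences$n_patients_overall[match(tab$peptide, sequences$peptide)]
  wi <- by_disease$n_patients[match(dkey, paste(by_disease$disease,
                                                by_disease$peptide,
                                                sep = "\r"))]
  pkey <- paste(tab$patient, tab$disease, sep = "\r")
  patients <- do.call(rbind, lapply(split(seq_len(nrow(tab)), pkey),
    function(idx) data.frame(
      patient = tab$patient[idx[1L]], disease = tab$disease[idx[1L]],
      n_distinct = length(idx),
      frac_repeated_within = mean(wi[idx] >= 2L),
      frac_repeated_overall = mean(ov[idx] >= 2L),
      stringsAsFactors = FALSE)))
  rownames(patients) <- NULL
  list(sequences = sequences, by_disease = by_disease, patients = patients)
}

#' Sample random six-allele HLA sets
#'
#' Draws \code{n_sets} sets of six HLA alleles, each formed by sampling
#' two alleles without replacement from each gene's list (HLA-A, HLA-B,
#' HLA-C) independently. Each set is generated under its own seed derived
#' deterministically from \code{seed} and the set index, so set i is
#' reproducible regardless of \code{n_sets}. The caller's RNG state is
#' left untouched.
#'
#' @param a_alleles,b_alleles,c_alleles Character vectors of at least two
#'   allele names per gene.
#' @param n_sets Number of sets to draw.
#' @param seed Integer seed.
#' @return data.frame with columns \code{set_id}, \code{A1}, \code{A2},
#'   \code{B1}, \code{B2}, \code{C1}, \code{C2}.
#' @export
sample_allele_sets <- function(a_alleles, b_alleles, c_alleles, n_sets,
                               seed = 1L) {
  for (v in list(a_alleles, b_alleles, c_alleles))
    if (length(unique(v)) < 2L)
      stop("sampling error: each gene needs at least 2 distinct alleles",
           call. = FALSE)
  n_sets <- as.integer(n_sets)
  if (is.na(n_sets) || n_sets < 1L)
    stop("n_sets must be a positive integer", call. = FALSE)
  rows <- lapply(seq_len(n_sets), function(i) {
    withr::with_seed(.substream_seed(seed, i), {
      a <- sample(unique(a_alleles), 2L)
      b <- sample(unique(b_alleles), 2L)
      cc <- sample(unique(c_alleles), 2L)
      data.frame(set_id = i, A1 = a[1L], A2 = a[2L], B1 = b[1L],
                 B2 = b[2L], C1 = cc[1L], C2 = cc[2L],
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}

# Deterministic 32-bit-safe substream seed from (seed, index).
.substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 65011) * 33013 + as.numeric(i) * 7919) %%
    2147483647L
}

#' Binding-overlap spectrum of an HLA allele set
#'
#' For one set of six alleles, counts the unique epitope sequences in the
#' affinity table that bind (affinity strictly below
#' \code{strong_threshold} nM) exactly 1, 2, ..., 6 of the six alleles,
#' plus the total binding at least one. The affinity table must cover
#' every (sequence, allele) combination evaluated; the exact-k counts
#' always partition the total.
#'
#' @param affinities Affinity table (\code{peptide}, \code{allele},
#'   \code{affinity_nm}).
#' @param allele_set Character vector of six allele names (or one row of
#'   [sample_allele_sets()] output).
#' @param strong_threshold Strong-binder cutoff in nM (default 500).
#' @return A list with \code{counts} (named integer vector, exact-k counts
#'   for k = 1..6) and \code{total} (epitopes binding >= 1 allele).
#' @export
overlap_spectrum <- function(affinities, allele_set,
                             strong_threshold = 500) {
  if (is.data.frame(allele_set))
    allele_set <- unlist(allele_set[1L, c("A1", "A2", "B1", "B2",
                                          "C1", "C2")], use.names = FALSE)
  allele_set <- as.character(allele_set)
  if (length(allele_set) != 6L)
    stop("allele_set must contain exactly six alleles", call. = FALSE)
  peptides <- sort(unique(affinities$peptide))
  n_bound <- integer(length(peptides))
  for (al in allele_set) {
    aff <- .affinity_lookup(affinities, peptides,
                            rep(al, length(peptides)))
    n_bound <- n_bound + (aff < strong_threshold)
  }
  counts <- vapply(1:6, function(k) sum(n_bound == k), integer(1))
  names(counts) <- as.character(1:6)
  list(counts = counts, total = sum(n_bound >= 1L))
}
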