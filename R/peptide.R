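# Peptides are plain uppercase character strings over the 23-letter
# BLOSUM62 alphabet; all scoring functions are vectorized elementwise and
# recycle scalar arguments, data.frame-style.

.split1 <- function(x) strsplit(x, "", fixed = TRUE)

.check_peptides <- function(x, arg = deparse(substitute(x))) {
  if (!is.character(x) || any(is.na(x)) || any(!nzchar(x)))
    stop(sprintf("'%s' must be non-empty peptide strings", arg),
         call. = FALSE)
  chars <- .split1(x)
  bad <- !vapply(chars, function(p) all(p %in% aa_alphabet()), logical(1))
  if (any(bad))
    stop(sprintf("'%s' contains letters outside the 23-letter alphabet: %s",
                 arg, paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  chars
}

#' MHC anchor positions for an epitope of a given length
#'
#' The class I anchor residues buried in the MHC groove are taken as the
#' second and the last position of the epitope; for 9mers this is the
#' classical \{2, 9\}. The same rule is applied to all lengths, and any
#' scoring function accepts an arbitrary mask, so the default is
#' overridable throughout.
#'
#' @param epitope_length Integer epitope length, at least 3.
#' @return Integer vector of 1-based masked positions, \code{c(2, length)}.
#' @examples
#' anchor_positions(9)   # 2 9
#' @export
anchor_positions <- function(epitope_length) {
  epitope_length <- as.integer(epitope_length)
  if (length(epitope_length) != 1L || is.na(epitope_length) ||
      epitope_length < 3L)
    stop("invalid epitope length: must be a single integer >= 3",
         call. = FALSE)
  c(2L, epitope_length)
}

.check_mask <- function(mask, len) {
  if (is.null(mask) || length(mask) == 0L) return(integer(0))
  mask <- as.integer(mask)
  if (any(is.na(mask)) || any(mask < 1L) || any(mask > len))
    stop(sprintf("mask positions must lie within [1, %d]", len),
         call. = FALSE)
  unique(mask)
}

#' Aggregate BLOSUM62 similarity score between equal-length peptides
#'
#' Sums the substitution-matrix entries at every unmasked position of the
#' two aligned peptides. With \code{mask = NULL} all residues are scored;
#' with \code{mask = anchor_positions(nchar(a))} the anchor residues are
#' excluded, emphasising the T-cell-exposed positions.
#'
#' @param a,b Character vectors of peptides; recycled to a common length,
#'   and paired elements must have equal \code{nchar}.
#' @param mask \code{NULL}, or an integer vector of 1-based positions to
#'   exclude from scoring.
#' @param matrix Substitution matrix, by default [blosum62()].
#' @return Integer vector of scores.
#' @examples
#' blosum_score("KQMNDARHG", "KQMNDARHG", mask = anchor_positions(9))  # 39
#' blosum_score("KQMNDARHG", "KQMNDARHG")                              # 50
#' @export
blosum_score <- function(a, b, mask = NULL, matrix = blosum62()) {
  ca <- .check_peptides(a, "a")
  cb <- .check_peptides(b, "b")
  n <- max(length(ca), length(cb))
  if (length(ca) != n) ca <- rep_len(ca, n)
  if (length(cb) != n) cb <- rep_len(cb, n)
  out <- integer(n)
  for (i in seq_len(n)) {
    pa <- ca[[i]]; pb <- cb[[i]]
    if (length(pa) != length(pb))
      stop(sprintf("alignment-length error: peptides of length %d and %d",
                   length(pa), length(pb)), call. = FALSE)
    keep <- setdiff(seq_along(pa), .check_mask(mask, length(pa)))
    out[i] <- sum(matrix[cbind(pa[keep], pb[keep])])
  }
  out
}

#' Self-normalized percent similarity between equal-length peptides
#'
#' Divides the query/subject similarity score by the query's score against
#' itself and scales to percent, removing the dependence on amino-acid
#' composition. The denominator uses the same mask as the numerator, so
#' each percent scale is internally consistent and bounded above by 100
#' (diagonal dominance); values can be negative for very dissimilar pairs.
#'
#' @inheritParams blosum_score
#' @param query,subject Character vectors of peptides (query supplies the
#'   normalizing self-score).
#' @return Numeric vector of percent similarities (\code{<= 100}).
#' @examples
#' percent_similarity("KQMNDARHG", "KQMNEARHG",
#'                    mask = anchor_positions(9))  # 100 * 35/39
#' @export
percent_similarity <- function(query, subject, mask = NULL,
                               matrix = blosum62()) {
  self <- blosum_score(query, query, mask = mask, matrix = matrix)
  if (any(self <= 0))
    stop("normalization error: non-positive self-score (ambiguity letters)",
         call. = FALSE)
  100 * blosum_score(query, subject, mask = mask, matrix = matrix) / self
}

#' Hamming mismatch count between equal-length peptides
#'
#' Counts differing positions over the full peptide; anchor masking is
#' never applied to mismatch counts.
#'
#' @param a,b Character vectors of peptides, recycled elementwise.
#' @return Integer vector of mismatch counts.
#' @export
mismatch_count <- function(a, b) {
  ca <- .check_peptides(a, "a")
  cb <- .check_peptides(b, "b")
  n <- max(length(ca), length(cb))
  if (length(ca) != n) ca <- rep_len(ca, n)
  if (length(cb) != n) cb <- rep_len(cb, n)
  vapply(seq_len(n), function(i) {
    if (length(ca[[i]]) != length(cb[[i]]))
      stop("alignment-length error: unequal peptide lengths", call. = FALSE)
    sum(ca[[i]] != cb[[i]])
  }, integer(1))
}

#' Enumerate tumor/normal epitope pairs around a missense substitution
#'
#' For each requested epitope length k, slides every window of length k
#' that contains the substituted residue and lies fully inside the
#' protein, emitting the tumor window (carrying the alternate residue) and
#' its paired normal window (carrying the reference residue). A mutation
#' at an interior position yields exactly k windows per length — the
#' 17-mer flanking construction for 9mers.
#'
#' @param protein Single protein sequence (character string).
#' @param protein_position 1-based position of the substituted residue in
#'   the protein.
#' @param ref_aa,alt_aa Reference and alternate single-letter residues;
#'   the protein must carry \code{ref_aa} at \code{protein_position}.
#' @param lengths Integer vector of epitope lengths (default \code{8:11}).
#' @param gene Gene identifier carried through to the output.
#' @return A data.frame with one row per (length, window): columns
#'   \code{gene}, \code{protein_position}, \code{length},
#'   \code{window_start}, \code{window_position} (1-based position of the
#'   substitution within the window), \code{ref_aa}, \code{alt_aa},
#'   \code{tumor_peptide}, \code{normal_peptide}; ordered by
#'   (length, window_start).
#' @export
enumerate_epitope_pairs <- function(protein, protein_position, ref_aa,
                                    alt_aa, lengths = 8:11,
                                    gene = NA_character_) {
  .check_peptides(protein, "protein")
  stopifnot(length(protein) == 1L)
  protein_position <- as.integer(protein_position)
  n <- nchar(protein)
  if (is.na(protein_position) || protein_position < 1L ||
      protein_position > n)
    stop("protein_position outside the protein", call. = FALSE)
  if (!ref_aa %in% aa_alphabet() || !alt_aa %in% aa_alphabet())
    stop("ref_aa/alt_aa must be single letters of the alphabet",
         call. = FALSE)
  if (substr(protein, protein_position, protein_position) != ref_aa)
    stop(sprintf(
      "reference-mismatch error: protein carries '%s' at position %d, not '%s'",
      substr(protein, protein_position, protein_position),
      protein_position, ref_aa), call. = FALSE)
  if (ref_aa == alt_aa)
    stop("not-missense error: ref_aa equals alt_aa", call. = FALSE)
  lengths <- sort(unique(as.integer(lengths)))
  if (any(lengths < 1L) || any(lengths > n))
    stop("each epitope length must lie in [1, protein length]",
         call. = FALSE)
  rows <- list()
  for (k in lengths) {
    starts <- seq.int(max(1L, protein_position - k + 1L),
                      min(protein_position, n - k + 1L))
    for (s in starts) {
      normal <- substr(protein, s, s + k - 1L)
      wp <- protein_position - s + 1L
      tumor <- normal
      substr(tumor, wp, wp) <- alt_aa
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, protein_position = protein_position, length = k,
        window_start = s, window_position = wp, ref_aa = ref_aa,
        alt_aa = alt_aa, tumor_peptide = tumor, normal_peptide = normal,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
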