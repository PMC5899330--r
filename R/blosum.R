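# Cache for the bundled scoring matrix (read once per session).
.neo_cache <- new.env(parent = emptyenv())

#' The bundled BLOSUM62 substitution matrix
#'
#' Returns the standard NCBI half-bit integer BLOSUM62 matrix over the
#' 23-letter alphabet: the 20 standard amino acids plus the ambiguity
#' letters B, Z and X. The matrix is shipped as a plain-text data file and
#' validated on first load: it must be symmetric, and its diagonal must
#' dominate every row over the 20 standard letters
#' (\code{m[a, a] >= m[a, b]}), the property that bounds percent
#' similarity at 100.
#'
#' @return An integer matrix with identical row and column names.
#' @examples
#' m <- blosum62()
#' m["D", "E"]
#' @export
blosum62 <- function() {
  if (is.null(.neo_cache$blosum62)) {
    path <- system.file("extdata", "BLOSUM62.tsv", package = "neoprior")
    if (!nzchar(path)) stop("bundled BLOSUM62.tsv not found", call. = FALSE)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    storage.mode(m) <- "integer"
    if (!identical(rownames(m), colnames(m)) || !identical(m, t(m)))
      stop("bundled BLOSUM62 failed the symmetry check", call. = FALSE)
    std <- setdiff(rownames(m), c("B", "Z", "X"))
    dom <- all(vapply(std, function(a) all(m[a, a] >= m[a, std]), logical(1)))
    if (!dom)
      stop("bundled BLOSUM62 failed the diagonal-dominance check",
           call. = FALSE)
    .neo_cache$blosum62 <- m
  }
  .neo_cache$blosum62
}

#' Amino-acid alphabet accepted by the scoring functions
#'
#' @return Character vector of the 23 accepted single-letter codes
#'   (20 standard amino acids plus B, Z, X).
#' @export
aa_alphabet <- function() rownames(blosum62())

#' @return The 20 standard amino-acid letters (no ambiguity codes).
#' @rdname aa_alphabet
#' @export
aa_standard <- function() setdiff(aa_alphabet(), c("B", "Z", "X"))
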