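# Independent naive oracles used throughout the suite. These deliberately
# avoid the package's code paths: scoring goes through Biostrings' own
# copy of BLOSUM62 and plain double loops.

.oracle_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

naive_score <- function(a, b, mask = integer(0)) {
  m <- .oracle_matrix()
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  keep <- setdiff(seq_along(ca), mask)
  sum(m[cbind(ca[keep], cb[keep])])
}

naive_percent <- function(q, s, mask = integer(0))
  100 * naive_score(q, s, mask) / naive_score(q, q, mask)

# all length-k substrings of protein containing position pos
naive_windows <- function(protein, pos, k) {
  n <- nchar(protein)
  out <- character(0)
  for (s in seq_len(n - k + 1))
    if (s <= pos && pos <= s + k - 1)
      out <- c(out, substr(protein, s, s + k - 1))
  out
}

# double-loop search over data.frame(protein_id, gene_id, sequence)
naive_search <- function(query, proteins, k = nchar(query)) {
  best <- -Inf
  subj <- character(0); pid <- character(0); gid <- character(0)
  for (i in seq_len(nrow(proteins))) {
    s <- proteins$sequence[i]
    if (nchar(s) < k) next
    for (st in seq_len(nchar(s) - k + 1)) {
      w <- substr(s, st, st + k - 1)
      sc <- naive_score(query, w)
      if (sc > best) {
        best <- sc; subj <- w
        pid <- proteins$protein_id[i]; gid <- proteins$gene_id[i]
      } else if (sc == best) {
        subj <- c(subj, w)
        pid <- c(pid, proteins$protein_id[i])
        gid <- c(gid, proteins$gene_id[i])
      }
    }
  }
  list(score = best, subjects = subj, protein_ids = pid, gene_ids = gid)
}

naive_auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

random_peptides <- function(n, len = 9, letters = aa_standard()) {
  vapply(seq_len(n), function(i)
    paste(sample(letters, len, replace = TRUE), collapse = ""),
    character(1))
}

proteome_as_df <- function(proteome) {
  nm <- names(proteome)
  data.frame(protein_id = sub("\\s.*$", "", nm),
             gene_id = sub(".*gene=([^[:space:]]+).*", "\\1", nm),
             sequence = as.character(proteome),
             stringsAsFactors = FALSE)
}
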