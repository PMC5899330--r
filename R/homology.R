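# Exact re-implementation of the fixed-length ungapped closest-peptide
# search. For a fixed query length, fixed alignment length k and fixed
# database, a blastp E-value is a monotone decreasing function of the raw
# ungapped BLOSUM62 score, so "lowest E-value" is implemented exactly as
# "highest raw score" over every length-k window of the database; ties are
# all retained. No E-values, seeds or composition-based statistics are
# computed (an E-value cap is carried in PipelineConfig for provenance
# only).

#' Build a fixed-length peptide window database
#'
#' Enumerates every length-k substring of every input protein, annotated
#' with its protein and gene of origin. Proteins shorter than k contribute
#' nothing. Accepts a FASTA file path, a \code{Biostrings::AAStringSet},
#' or a data.frame with columns \code{protein_id}, \code{gene_id},
#' \code{sequence}. FASTA description lines may carry a
#' \code{gene=<id>} token; when absent the gene id defaults to the protein
#' id.
#'
#' @param x FASTA path, AAStringSet, or data.frame (see Details).
#' @param k Window length (default 9).
#' @param source Database label: one of \code{"human"}, \code{"bacterial"},
#'   \code{"viral"} (free-form labels are accepted).
#' @return An object of class \code{peptide_db}: a list with
#'   \code{windows} (character), \code{protein_id}, \code{gene_id},
#'   \code{k}, \code{source}, and a pre-encoded integer matrix used by the
#'   search.
#' @export
build_peptide_db <- function(x, k = 9, source = "human") {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  recs <- .as_protein_records(x)
  if (nrow(recs) == 0L)
    stop("empty-database error: no input records", call. = FALSE)
  win <- list(); pid <- list(); gid <- list()
  for (i in seq_len(nrow(recs))) {
    s <- recs$sequence[i]
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    win[[length(win) + 1L]] <- substring(s, starts, starts + k - 1L)
    pid[[length(pid) + 1L]] <- rep(recs$protein_id[i], length(starts))
    gid[[length(gid) + 1L]] <- rep(recs$gene_id[i], length(starts))
  }
  windows <- unlist(win, use.names = FALSE)
  if (is.null(windows)) windows <- character(0)
  enc <- if (length(windows)) {
    chars <- .check_peptides(windows, "database windows")
    matrix(match(unlist(chars), aa_alphabet()),
           nrow = length(windows), ncol = k, byrow = TRUE)
  } else matrix(integer(0), 0L, k)
  structure(list(windows = windows,
                 protein_id = unlist(pid, use.names = FALSE),
                 gene_id = unlist(gid, use.names = FALSE),
                 k = k, source = source, enc = enc),
            class = "peptide_db")
}

#' @export
print.peptide_db <- function(x, ...) {
  cat(sprintf("peptide_db (%s): %d windows of length %d from %d proteins\n",
              x$source, length(x$windows), x$k,
              length(unique(x$protein_id))))
  invisible(x)
}

# Normalize DB input forms to data.frame(protein_id, gene_id, sequence).
.as_protein_records <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- Biostrings::readAAStringSet(x)
  if (methods::is(x, "AAStringSet")) {
    nm <- names(x)
    if (is.null(nm)) nm <- rep("", length(x))
    protein_id <- sub("\\s.*$", "", nm)
    gene_id <- ifelse(grepl("gene=", nm),
                      sub(".*gene=([^[:space:]]+).*", "\\1", nm),
                      protein_id)
    return(data.frame(protein_id = protein_id, gene_id = gene_id,
                      sequence = as.character(x),
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("protein_id", "gene_id", "sequence") %in% names(x)))
    return(x[, c("protein_id", "gene_id", "sequence"), drop = FALSE])
  }
  stop("cannot interpret database input (need FASTA path, AAStringSet, ",
       "or data.frame)", call. = FALSE)
}

#' Closest-peptide search (exact, ungapped, fixed length)
#'
#' Scores the query against every window of the database with the
#' all-residue BLOSUM62 sum and returns every window attaining the maximum
#' score. Tied subjects with identical sequences are collapsed into one
#' row whose \code{protein_ids}/\code{gene_ids} carry all origins
#' (comma-joined, sorted). Rows are ordered by subject sequence, so the
#' result is invariant under permutation of the database records.
#'
#' @param query A single peptide of length \code{db$k}.
#' @param db A [build_peptide_db()] database.
#' @param matrix Substitution matrix (default [blosum62()]).
#' @return data.frame of tied best matches with columns \code{subject},
#'   \code{protein_ids}, \code{gene_ids}, \code{raw_score},
#'   \code{sim_nonanchor_pct}, \code{sim_all_pct}, \code{mismatches}.
#' @export
search_closest <- function(query, db, matrix = blosum62()) {
  stopifnot(inherits(db, "peptide_db"))
  if (length(db$windows) == 0L)
    stop("empty-database error: database has no windows", call. = FALSE)
  qc <- .check_peptides(query, "query")
  if (length(qc) != 1L || length(qc[[1L]]) != db$k)
    stop(sprintf("alignment-length error: query must be a single %d-mer",
                 db$k), call. = FALSE)
  qi <- match(qc[[1L]], aa_alphabet())
  scores <- numeric(length(db$windows))
  for (j in seq_len(db$k))
    scores <- scores + matrix[qi[j], ][db$enc[, j]]
  top <- max(scores)
  tie <- which(scores == top)
  subj <- db$windows[tie]
  uniq <- sort(unique(subj))
  join <- function(v) paste(sort(unique(v)), collapse = ",")
  out <- data.frame(
    subject = uniq,
    protein_ids = vapply(uniq, function(s)
      join(db$protein_id[tie[subj == s]]), character(1)),
    gene_ids = vapply(uniq, function(s)
      join(db$gene_id[tie[subj == s]]), character(1)),
    raw_score = as.integer(top),
    stringsAsFactors = FALSE)
  out$sim_nonanchor_pct <- percent_similarity(
    query, out$subject, mask = anchor_positions(db$k), matrix = matrix)
  out$sim_all_pct <- percent_similarity(query, out$subject, mask = NULL,
                                        matrix = matrix)
  out$mismatches <- mismatch_count(query, out$subject)
  rownames(out) <- NULL
  out
}

#' Gene-of-origin match status for a set of tied best matches
#'
#' A neoepitope is \code{"matching"} when any retained top match
#' originates from its own gene (so its closest proteome peptide is its
#' normal counterpart's neighborhood), otherwise \code{"nonmatching"}.
#' Under ties the status is matching if any tied hit matches.
#'
#' @param matches data.frame from [search_closest()].
#' @param gene_of_origin Gene identifier of the query neoepitope.
#' @return \code{"matching"} or \code{"nonmatching"}.
#' @export
gene_match_status <- function(matches, gene_of_origin) {
  if (!is.data.frame(matches) || nrow(matches) == 0L)
    stop("no-hit error: empty match list", call. = FALSE)
  genes <- unlist(strsplit(matches$gene_ids, ",", fixed = TRUE))
  if (!is.na(gene_of_origin) && gene_of_origin %in% genes)
    "matching" else "nonmatching"
}

# One search against a possibly-NULL/empty db; NULL means "no database",
# giving explicit no-hit markers instead of an error (batch semantics).
.search_or_nohit <- function(query, db, matrix) {
  if (is.null(db) || length(db$windows) == 0L) return(NULL)
  search_closest(query, db, matrix = matrix)
}

#' Full novelty profile for one epitope pair at one allele
#'
#' Aggregates all four novelty metrics for a tumor/normal epitope pair:
#' the paired binding-affinity difference and novel-binding flag, the
#' anchor-masked and all-residue paired percent similarities, the closest
#' human match (with both similarity scales, mismatch count, gene-match
#' status, and — when the affinity of the matched human peptide for this
#' allele is present in the input table — the binding-affinity difference
#' against that peptide), the closest bacterial and viral matches, and
#' flags for whether the bacterial/viral match is closer than both human
#' comparators (the paired normal epitope and the closest human match) on
#' the non-anchor and all-residue scales separately.
#'
#' A \code{NULL} database yields no-hit markers (\code{NA} columns) for
#' its source rather than an error. When a human search returns tied
#' subjects, the affinity comparison uses the first tied subject (sorted
#' order) present in the affinity table.
#'
#' @param pair One-row data.frame (or list) with at least
#'   \code{tumor_peptide}, \code{normal_peptide}, \code{gene}.
#' @param human_db,bacterial_db,viral_db [build_peptide_db()] objects or
#'   \code{NULL}.
#' @param affinities Affinity table (\code{peptide}, \code{allele},
#'   \code{affinity_nm}); must cover the tumor and normal peptides for
#'   \code{allele}.
#' @param allele HLA allele name.
#' @param config A [novelty_config()].
#' @param matrix Substitution matrix.
#' @return One-row data.frame (a NoveltyProfile).
#' @export
profile_neoepitope <- function(pair, human_db = NULL, bacterial_db = NULL,
                               viral_db = NULL, affinities, allele,
                               config = novelty_config(),
                               matrix = blosum62()) {
  tumor <- pair$tumor_peptide; normal <- pair$normal_peptide
  gene <- if (!is.null(pair$gene)) pair$gene else NA_character_
  k <- nchar(tumor)
  mask <- anchor_positions(k)
  t_aff <- .affinity_lookup(affinities, tumor, allele)
  n_aff <- .affinity_lookup(affinities, normal, allele)
  prof <- data.frame(
    tumor_peptide = tumor, normal_peptide = normal, gene = gene,
    allele = allele, tumor_affinity_nm = t_aff, normal_affinity_nm = n_aff,
    paired_diff_nm = affinity_difference(n_aff, t_aff),
    novel_binding = is_novel_binding(t_aff, n_aff, config),
    mismatches_paired = mismatch_count(tumor, normal),
    sim_paired_nonanchor = percent_similarity(tumor, normal, mask, matrix),
    sim_paired_all = percent_similarity(tumor, normal, NULL, matrix),
    stringsAsFactors = FALSE)

  side <- function(db, prefix) {
    hits <- .search_or_nohit(tumor, db, matrix)
    cols <- c("subject", "protein_ids", "gene_ids", "raw_score",
              "sim_nonanchor", "sim_all", "mismatches")
    if (is.null(hits)) {
      vals <- list(NA_character_, NA_character_, NA_character_,
                   NA_integer_, NA_real_, NA_real_, NA_integer_)
    } else {
      vals <- list(paste(hits$subject, collapse = ","),
                   paste(hits$protein_ids, collapse = ";"),
                   paste(hits$gene_ids, collapse = ";"),
                   hits$raw_score[1L],
                   hits$sim_nonanchor_pct[1L], hits$sim_all_pct[1L],
                   hits$mismatches[1L])
    }
    names(vals) <- paste(prefix, cols, sep = "_")
    list(vals = vals, hits = hits)
  }

  hu <- side(human_db, "human")
  ba <- side(bacterial_db, "bacterial")
  vi <- side(viral_db, "viral")
  prof <- cbind(prof, as.data.frame(hu$vals, stringsAsFactors = FALSE),
                as.data.frame(ba$vals, stringsAsFactors = FALSE),
                as.data.frame(vi$vals, stringsAsFactors = FALSE))

  prof$human_match_status <- if (is.null(hu$hits)) NA_character_ else
    gene_match_status(hu$hits, gene)
  prof$human_match_diff_nm <- NA_real_
  if (!is.null(hu$hits)) {
    h_aff <- .affinity_lookup(affinities, hu$hits$subject,
                              rep(allele, nrow(hu$hits)), required = FALSE)
    hit <- which(!is.na(h_aff))
    if (length(hit))
      prof$human_match_diff_nm <- affinity_difference(h_aff[hit[1L]], t_aff)
  }

  closer <- function(micro_sim, scale) {
    if (is.na(micro_sim)) return(NA)
    human_best <- suppressWarnings(max(
      prof[[paste0("sim_paired_", scale)]],
      prof[[if (scale == "nonanchor") "human_sim_nonanchor"
            else "human_sim_all"]], na.rm = TRUE))
    micro_sim > human_best
  }
  prof$bacterial_closer_nonanchor <- closer(prof$bacterial_sim_nonanchor,
                                            "nonanchor")
  prof$bacterial_closer_all <- closer(prof$bacterial_sim_all, "all")
  prof$viral_closer_nonanchor <- closer(prof$viral_sim_nonanchor,
                                        "nonanchor")
  prof$viral_closer_all <- closer(prof$viral_sim_all, "all")
  rownames(prof) <- NULL
  prof
}

#' Profile a batch of epitope pairs
#'
#' Applies [profile_neoepitope()] to every row of a pair table for one
#' allele, row-binding the profiles.
#'
#' @inheritParams profile_neoepitope
#' @param pairs data.frame of epitope pairs.
#' @return data.frame of novelty profiles, one row per pair.
#' @export
profile_neoepitopes <- function(pairs, human_db = NULL,
                                bacterial_db = NULL, viral_db = NULL,
                                affinities, allele,
                                config = novelty_config(),
                                matrix = blosum62()) {
  out <- lapply(seq_len(nrow(pairs)), function(i)
    profile_neoepitope(pairs[i, , drop = FALSE], human_db, bacterial_db,
                       viral_db, affinities, allele, config, matrix))
  do.call(rbind, out)
}
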