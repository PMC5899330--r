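# Deterministic synthetic-data generators. These make the whole pipeline
# executable at desk scale with no downloads: a random proteome stands in
# for a reference peptidome, a positional-weight hash stands in for an MHC
# binding predictor, and cohorts are drawn from a known generative model
# so parameter recovery is testable. None of it is biological; it is
# clearly labeled synthetic throughout.

#' Generate a random synthetic proteome
#'
#' Draws \code{n_proteins} protein sequences with lengths uniform on
#' \code{length_range}, residues i.i.d. from the 20 standard amino acids
#' (uniform by default; weights configurable). Record names are
#' \code{prot<i> gene=<gene>}; by default each protein gets its own gene,
#' and \code{n_genes} below \code{n_proteins} recycles gene ids so that
#' gene-sharing (and hence "matching" homology hits across proteins) can
#' be exercised.
#'
#' @param n_proteins Number of records (default 50).
#' @param length_range Integer vector \code{c(min, max)} of protein
#'   lengths (default \code{c(60, 120)}).
#' @param seed Integer seed; the output is a pure function of the
#'   arguments.
#' @param alphabet_weights Optional non-negative weights over
#'   [aa_standard()] (recycled/normalized); default uniform.
#' @param n_genes Number of distinct gene ids (default \code{n_proteins}).
#' @return A \code{Biostrings::AAStringSet} with annotated names.
#' @export
generate_proteome <- function(n_proteins = 50, length_range = c(60, 120),
                              seed = 1L, alphabet_weights = NULL,
                              n_genes = n_proteins) {
  n_proteins <- as.integer(n_proteins)
  if (is.na(n_proteins) || n_proteins < 1L)
    stop("n_proteins must be >= 1", call. = FALSE)
  length_range <- as.integer(length_range)
  if (max(length_range) < 9L)
    stop("fixture error: degenerate length distribution (max < 9)",
         call. = FALSE)
  letters20 <- aa_standard()
  w <- if (is.null(alphabet_weights)) rep(1, 20L) else
    rep_len(alphabet_weights, 20L)
  len_choices <- seq.int(length_range[1L], length_range[2L])
  withr::with_seed(as.integer(seed), {
    lens <- len_choices[sample.int(length(len_choices), n_proteins,
                                   replace = TRUE)]
    seqs <- vapply(lens, function(L)
      paste(sample(letters20, L, replace = TRUE, prob = w), collapse = ""),
      character(1))
  })
  genes <- sprintf("gene%03d", ((seq_len(n_proteins) - 1L) %%
                                  as.integer(n_genes)) + 1L)
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- sprintf("prot%03d gene=%s", seq_len(n_proteins), genes)
  out
}

#' Simulate random neoepitopes from a proteome (the null model)
#'
#' Draws \code{n} length-k windows uniformly over all windows of the
#' proteome (uniform over windows, not proteins), then introduces a single
#' random amino-acid substitution at a position uniform over 1..k, with
#' the substituted letter uniform over the 19 standard letters other than
#' the original (a substitution never repeats the original residue). The
#' source protein and gene are retained for downstream gene-match-status
#' analysis.
#'
#' @param proteome AAStringSet (or FASTA path) of source proteins.
#' @param n Number of simulated neoepitopes.
#' @param k Window length (default 9).
#' @param seed Integer seed.
#' @return data.frame with columns \code{protein_id}, \code{gene_id},
#'   \code{window_start}, \code{source_window}, \code{mutated_position},
#'   \code{original_aa}, \code{substituted_aa}, \code{sequence}.
#' @export
simulate_neoepitopes <- function(proteome, n, k = 9, seed = 1L) {
  recs <- .as_protein_records(proteome)
  k <- as.integer(k)
  lens <- nchar(recs$sequence)
  n_win <- pmax(lens - k + 1L, 0L)
  if (sum(n_win) == 0L)
    stop("fixture error: proteome has no window of length ", k,
         call. = FALSE)
  prot_of <- rep.int(seq_len(nrow(recs)), n_win)
  start_of <- unlist(lapply(n_win, seq_len), use.names = FALSE)
  letters20 <- aa_standard()
  withr::with_seed(as.integer(seed), {
    widx <- sample.int(length(prot_of), n, replace = TRUE)
    pos <- sample.int(k, n, replace = TRUE)
    sub_pick <- sample.int(19L, n, replace = TRUE)
  })
  win <- substring(recs$sequence[prot_of[widx]], start_of[widx],
                   start_of[widx] + k - 1L)
  orig <- substring(win, pos, pos)
  # pick the sub_pick-th letter among the 19 letters != original
  sub <- vapply(seq_len(n), function(i)
    setdiff(letters20, orig[i])[sub_pick[i]], character(1))
  seqs <- win
  substr(seqs, pos, pos) <- sub
  data.frame(protein_id = recs$protein_id[prot_of[widx]],
             gene_id = recs$gene_id[prot_of[widx]],
             window_start = start_of[widx], source_window = win,
             mutated_position = pos, original_aa = orig,
             substituted_aa = sub, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Pseudo-affinity configuration
#'
#' @param range_nm Output affinity range in nM (default
#'   \code{c(1, 50000)}).
#' @param anchor_weight Relative weight of the anchor positions (second
#'   and last residue) in the positional hash (default 3), so that anchor
#'   substitutions swing the pseudo-affinity strongly and novel-binding
#'   cases arise naturally in fixtures.
#' @return A list of class \code{affinity_config}.
#' @export
affinity_config <- function(range_nm = c(1, 50000), anchor_weight = 3) {
  stopifnot(length(range_nm) == 2L, all(range_nm > 0),
            range_nm[2L] > range_nm[1L], anchor_weight > 0)
  structure(list(range_nm = as.numeric(range_nm),
                 anchor_weight = anchor_weight),
            class = "affinity_config")
}

# Deterministic [0,1) hash of a character key: sum of scrambled byte
# codes pushed through two rounds of a 31-bit LCG. Pure, seed-free.
.unit_hash <- function(keys) {
  m <- 2147483647
  vapply(keys, function(key) {
    x <- 104729
    for (b in utf8ToInt(key)) x <- (x * 69069 + b * 2654435761) %% m
    x <- (x * 1103515245 + 12345) %% m
    x <- (x * 1103515245 + 12345) %% m
    x / m
  }, numeric(1), USE.NAMES = FALSE)
}

#' Deterministic pseudo binding-affinity predictor (synthetic)
#'
#' A pure function of (peptide, allele, config) standing in for an MHC
#' class I predictor so pipelines run with no external tool. Each
#' (allele, position, residue) combination hashes to a unit score; the
#' anchor positions (2 and last) carry \code{anchor_weight} times the
#' weight of other positions; the weighted mean is mapped
#' log-uniformly onto \code{range_nm}. The landscape is not biological —
#' it exists so that strong/weak binders and novel-binding changes occur
#' with realistic frequency in fixtures.
#'
#' @param peptide Character vector of peptides.
#' @param allele Allele name(s), recycled.
#' @param config An [affinity_config()].
#' @return Numeric affinities in nM, strictly inside \code{range_nm}.
#' @export
pseudo_affinity <- function(peptide, allele, config = affinity_config()) {
  chars <- .check_peptides(peptide, "peptide")
  n <- max(length(chars), length(allele))
  chars <- rep_len(chars, n)
  allele <- rep_len(as.character(allele), n)
  lo <- log(config$range_nm[1L]); hi <- log(config$range_nm[2L])
  vapply(seq_len(n), function(i) {
    p <- chars[[i]]
    k <- length(p)
    wts <- rep(1, k)
    if (k >= 3L) wts[anchor_positions(k)] <- config$anchor_weight
    u <- .unit_hash(paste(allele[i], seq_len(k), p, sep = "|"))
    s <- sum(wts * u) / sum(wts)
    exp(lo + s * (hi - lo))
  }, numeric(1))
}

#' Generate a synthetic immune-response cohort with known structure
#'
#' Draws predictor vectors from distributions chosen to mimic the scales
#' the pipeline produces (log-uniform nM affinities on [1, 50000];
#' percent similarities normal with the field-typical means/sds — paired
#' 83.5 (6.3), human 84.3 (10.7), bacterial 91.4 (6.6), viral 76.7 (9.1),
#' truncated at 100; paired mismatch counts mostly 1), forms a latent
#' linear score from \code{coefficients}, adds Gaussian noise with sd
#' \code{noise_sd}, and thresholds the latent score at the
#' \code{1 - prevalence} quantile to produce the binary response. The
#' generating truth is returned alongside for recovery tests.
#'
#' @param n Number of records.
#' @param coefficients Named numeric vector: \code{(Intercept)} plus any
#'   subset of the predictor columns (default: the reduced four-predictor
#'   set with coefficients scaled so each term has comparable spread).
#' @param noise_sd Gaussian noise sd on the latent score (default 0.5).
#' @param prevalence Fraction of responders (default 0.3).
#' @param seed Integer seed.
#' @return A list with \code{records} (data.frame of predictors,
#'   \code{latent}, \code{latent_noisy}, \code{response}),
#'   \code{coefficients}, \code{noise_sd}, \code{threshold}.
#' @export
generate_cohort <- function(n = 419,
                            coefficients = c(`(Intercept)` = 0.5,
                                             neo_affinity = -4e-05,
                                             sim_viral = -0.015,
                                             human_match_diff = 2e-05,
                                             mismatches_paired = 0.15),
                            noise_sd = 0.5, prevalence = 0.3, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be >= 2", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1)
    stop("fixture error: infeasible prevalence", call. = FALSE)
  if (!"(Intercept)" %in% names(coefficients))
    stop("coefficients must include an (Intercept) term", call. = FALSE)
  rlogu <- function(m, lo = 1, hi = 50000)
    exp(stats::runif(m, log(lo), log(hi)))
  rsim <- function(m, mean, sd) pmin(stats::rnorm(m, mean, sd), 100)
  withr::with_seed(as.integer(seed), {
    neo <- rlogu(n); nor <- rlogu(n); hum <- rlogu(n)
    rec <- data.frame(
      neo_affinity = neo, normal_affinity = nor,
      paired_diff = nor - neo, human_match_diff = hum - neo,
      mismatches_paired = sample(1:3, n, replace = TRUE,
                                 prob = c(0.7, 0.2, 0.1)),
      sim_paired = rsim(n, 83.5, 6.3), sim_human = rsim(n, 84.3, 10.7),
      sim_bacterial = rsim(n, 91.4, 6.6), sim_viral = rsim(n, 76.7, 9.1),
      stringsAsFactors = FALSE)
    rec$novel_flag <- is_novel_binding(rec$neo_affinity,
                                       rec$normal_affinity)
    noise <- stats::rnorm(n, 0, noise_sd)
  })
  preds <- setdiff(names(coefficients), "(Intercept)")
  miss <- setdiff(preds, names(rec))
  if (length(miss))
    stop("unknown coefficient name(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  latent <- coefficients[["(Intercept)"]] +
    as.numeric(as.matrix(rec[, preds, drop = FALSE]) %*%
                 coefficients[preds])
  latent_noisy <- latent + noise
  threshold <- stats::quantile(latent_noisy, 1 - prevalence, names = FALSE)
  rec$latent <- latent
  rec$latent_noisy <- latent_noisy
  rec$response <- latent_noisy > threshold
  list(records = rec, coefficients = coefficients, noise_sd = noise_sd,
       threshold = threshold)
}
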