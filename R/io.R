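# File interchange: tab-separated, header row, UTF-8, "." for missing
# values; FASTA for sequence databases; JSON for configs, model output and
# run manifests.

#' Read a tab-separated table (\code{"."} = missing)
#'
#' @param path File path.
#' @return data.frame with character/numeric columns as parsed.
#' @export
read_tsv_file <- function(path) {
  if (!file.exists(path)) stop("data error: no such file: ", path,
                               call. = FALSE)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    na.strings = ".", stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

#' Write a tab-separated table (\code{NA} written as \code{"."})
#'
#' @param x data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv_file <- function(x, path) {
  df <- as.data.frame(x)
  for (j in seq_along(df))
    if (is.logical(df[[j]])) df[[j]] <- as.integer(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Read an annotated-variant table
#'
#' Required columns: \code{gene}, \code{protein_position}, \code{ref_aa},
#' \code{alt_aa}, plus either \code{protein_seq} or \code{protein_id}
#' resolvable against a proteome FASTA.
#'
#' @param path Variant TSV path.
#' @param proteome Optional proteome (FASTA path or AAStringSet) used to
#'   resolve \code{protein_id} rows.
#' @return data.frame with a populated \code{protein_seq} column (and a
#'   \code{gene} column, defaulted from the proteome when absent).
#' @export
read_variants <- function(path, proteome = NULL) {
  v <- read_tsv_file(path)
  need <- c("gene", "protein_position", "ref_aa", "alt_aa")
  miss <- setdiff(need, names(v))
  if (length(miss))
    stop("data error: variant table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"protein_seq" %in% names(v)) {
    if (is.null(proteome) || !"protein_id" %in% names(v))
      stop("data error: need protein_seq column or protein_id + proteome",
           call. = FALSE)
    recs <- .as_protein_records(proteome)
    idx <- match(v$protein_id, recs$protein_id)
    if (anyNA(idx))
      stop("data error: protein_id not in proteome: ",
           paste(unique(v$protein_id[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    v$protein_seq <- recs$sequence[idx]
  }
  v$protein_position <- as.integer(v$protein_position)
  v
}

#' Read a peptide/allele binding-affinity table
#'
#' @param path TSV with columns \code{peptide}, \code{allele},
#'   \code{affinity_nm}.
#' @return data.frame.
#' @export
read_affinities <- function(path) {
  a <- read_tsv_file(path)
  miss <- setdiff(c("peptide", "allele", "affinity_nm"), names(a))
  if (length(miss))
    stop("data error: affinity table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  a$affinity_nm <- as.numeric(a$affinity_nm)
  a
}

# Run manifest: config hash, input checksums, package version. Written
# alongside every CLI output so runs are auditable; never read back.
.write_manifest <- function(out_path, inputs, config = NULL) {
  inputs <- inputs[vapply(inputs, function(p)
    is.character(p) && length(p) == 1L && file.exists(p), logical(1))]
  manifest <- list(
    tool = "neoprior",
    version = as.character(utils::packageVersion("neoprior")),
    config = config,
    config_hash = if (is.null(config)) NA_character_ else {
      tmp <- tempfile(); on.exit(unlink(tmp))
      writeLines(jsonlite::toJSON(config, auto_unbox = TRUE), tmp)
      unname(tools::md5sum(tmp))
    },
    inputs = lapply(inputs, function(p) unname(tools::md5sum(p))),
    output = unname(tools::md5sum(out_path)))
  jsonlite::write_json(manifest, paste0(out_path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}
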