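#' Construct a proteome set
#'
#' A proteome set is the package's container for protein records: a data frame
#' with one row per protein and columns `accession`, `organism`, `is_pathogen`,
#' `description` and `sequence`. Sequences are upper-cased and validated
#' against the 20 standard amino acids plus the ambiguity codes B, Z, X, U, O;
#' `J`, `*` and gap characters are rejected.
#'
#' @param accession Character vector of unique, non-empty protein identifiers.
#' @param sequence Character vector of amino-acid sequences (length >= 1 each).
#' @param organism Organism tag(s), recycled to the number of records.
#' @param is_pathogen Logical pathogen flag(s), recycled.
#' @param description Free-text description(s), recycled.
#' @return A data frame of class `proteome_set`.
#' @export
proteome_set <- function(accession, sequence, organism = "unknown",
                         is_pathogen = FALSE, description = "") {
  accession <- as.character(accession)
  sequence <- toupper(as.character(sequence))
  n <- length(accession)
  if (length(sequence) != n) {
    stop("`accession` and `sequence` must have the same length", call. = FALSE)
  }
  if (any(!nzchar(accession))) stop("empty accession", call. = FALSE)
  if (anyDuplicated(accession)) {
    stop("duplicate accession(s): ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "),
         call. = FALSE)
  }
  if (n > 0) {
    empty <- !nzchar(sequence)
    if (any(empty)) {
      stop("record '", accession[which(empty)[1]], "' has an empty sequence",
           call. = FALSE)
    }
    check_sequence_alphabet(sequence, accession)
  }
  df <- data.frame(
    accession = accession,
    organism = rep_len(as.character(organism), n),
    is_pathogen = rep_len(as.logical(is_pathogen), n),
    description = rep_len(as.character(description), n),
    sequence = sequence,
    stringsAsFactors = FALSE)
  class(df) <- c("proteome_set", "data.frame")
  df
}

# Errors with accession and 1-based position of the first illegal character.
check_sequence_alphabet <- function(sequence, accession) {
  bad <- regexpr(sprintf("[^%s]", paste(AA_ALLOWED, collapse = "")), sequence)
  hit <- which(bad > 0)
  if (length(hit) > 0) {
    i <- hit[1]
    stop(sprintf("record '%s': illegal character '%s' at position %d",
                 accession[i], substr(sequence[i], bad[i], bad[i]), bad[i]),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.proteome_set <- function(x, ...) {
  cat(sprintf("Proteome set: %d proteins, %d organism(s), %d pathogen-flagged\n",
              nrow(x), length(unique(x$organism)), sum(x$is_pathogen)))
  if (nrow(x) > 0) {
    show <- utils::head(x, 5)
    show$sequence <- paste0(substr(show$sequence, 1, 30),
                            ifelse(nchar(show$sequence) > 30, "...", ""))
    print.data.frame(show)
    if (nrow(x) > 5) cat("...", nrow(x) - 5, "more\n")
  }
  invisible(x)
}

#' Number of proteins / proteomes in a set
#'
#' @param proteome A `proteome_set`.
#' @return Integer count.
#' @export
n_proteins <- function(proteome) {
  stopifnot(inherits(proteome, "proteome_set"))
  nrow(proteome)
}

#' @rdname n_proteins
#' @export
n_proteomes <- function(proteome) {
  stopifnot(inherits(proteome, "proteome_set"))
  length(unique(proteome$organism))
}

#' Read a protein FASTA file
#'
#' The first whitespace-delimited token of each header is the accession; the
#' remainder is kept as a free-text description. Sequences are upper-cased;
#' parsing is insensitive to line wrapping and trailing whitespace. Records
#' with empty sequences, duplicate accessions, or characters outside the
#' allowed alphabet (20 standard residues plus B, Z, X, U, O) are errors.
#'
#' @param path FASTA file path.
#' @param organism Organism tag applied to every record (overridden per
#'   accession by `metadata`, if given).
#' @param is_pathogen Pathogen flag applied to every record (overridden by
#'   `metadata`).
#' @param metadata Optional path to a sidecar TSV with columns `accession`,
#'   `organism`, `is_pathogen` supplying per-protein metadata.
#' @return A `proteome_set`.
#' @export
read_fasta <- function(path, organism = "unknown", is_pathogen = FALSE,
                       metadata = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # characters the parser would silently drop are format errors here;
  # whitespace (wrapping, trailing blanks) is tolerated
  raw <- readLines(path, warn = FALSE)
  seq_lines <- !startsWith(raw, ">")
  bad <- regexpr("[^-A-Za-z*+.[:space:]]", raw)
  hit <- which(bad > 0 & seq_lines)
  if (length(hit) > 0) {
    stop(sprintf("line %d: illegal character '%s' at column %d",
                 hit[1], substr(raw[hit[1]], bad[hit[1]], bad[hit[1]]),
                 bad[hit[1]]), call. = FALSE)
  }
  seqs <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        invokeRestart("muffleWarning")  # only whitespace was dropped
      }
    })
  if (length(seqs) == 0) stop("no FASTA records in ", path, call. = FALSE)
  headers <- names(seqs)
  acc <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 trimws(sub("^\\S+\\s+", "", headers)), "")
  pr <- proteome_set(acc, as.character(seqs), organism = organism,
                     is_pathogen = is_pathogen, description = desc)
  if (!is.null(metadata)) pr <- apply_metadata(pr, metadata)
  pr
}

#' Apply a sidecar metadata table to a proteome set
#'
#' @param proteome A `proteome_set`.
#' @param path TSV with header columns `accession`, `organism`, `is_pathogen`.
#' @return The updated `proteome_set`.
#' @export
apply_metadata <- function(proteome, path) {
  stopifnot(inherits(proteome, "proteome_set"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "organism", "is_pathogen")
  if (!all(need %in% names(meta))) {
    stop("metadata TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(proteome$accession, meta$accession)
  hit <- !is.na(idx)
  proteome$organism[hit] <- meta$organism[idx[hit]]
  proteome$is_pathogen[hit] <- as.logical(meta$is_pathogen[idx[hit]])
  proteome
}

#' Write a proteome set to FASTA
#'
#' Headers are `accession organism`; sequence lines wrap at 60 columns.
#'
#' @param proteome A `proteome_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  stopifnot(inherits(proteome, "proteome_set"))
  if (nrow(proteome) == 0) {
    file.create(path)
    return(invisible(path))
  }
  seqs <- Biostrings::AAStringSet(proteome$sequence)
  names(seqs) <- paste(proteome$accession, proteome$organism)
  Biostrings::writeXStringSet(seqs, path, width = 60)
  invisible(path)
}
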