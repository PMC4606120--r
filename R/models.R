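#' @keywords internal
"_PACKAGE"

## The 20 standard amino acids, the ambiguity codes the scanner tolerates,
## and the full input alphabet accepted by the FASTA reader.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_AMBIGUOUS <- c("B", "Z", "X", "U", "O")
AA_ALLOWED <- c(AA_STANDARD, AA_AMBIGUOUS)

#' Build a residue composition model
#'
#' A composition model assigns a probability to each of the 20 standard amino
#' acids. A pseudocount is added to every residue before normalization so all
#' probabilities are strictly positive and log-ratios stay finite.
#'
#' @param probs Named numeric vector of non-negative weights. Names must cover
#'   a subset of the 20 standard one-letter amino-acid codes; residues not
#'   named receive weight 0 (plus the pseudocount).
#' @param pseudocount Small positive value added to every residue's weight
#'   before normalization. Default `1e-4`.
#' @return An object of class `composition_model`: a named numeric vector of
#'   20 probabilities summing to 1.
#' @examples
#' m <- composition_model(c(N = 0.5, Q = 0.5))
#' sum(m)
#' @export
composition_model <- function(probs, pseudocount = 1e-4) {
  if (!is.numeric(probs) || is.null(names(probs))) {
    stop("`probs` must be a named numeric vector", call. = FALSE)
  }
  bad <- setdiff(names(probs), AA_STANDARD)
  if (length(bad) > 0) {
    stop("unknown residue(s) in composition model: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyNA(probs) || any(probs < 0)) {
    stop("composition weights must be non-negative and non-missing",
         call. = FALSE)
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    stop("`pseudocount` must be a single positive number", call. = FALSE)
  }
  p <- stats::setNames(numeric(20), AA_STANDARD)
  p[names(probs)] <- probs
  p <- p + pseudocount
  p <- p / sum(p)
  structure(p, class = "composition_model", pseudocount = pseudocount)
}

#' @export
print.composition_model <- function(x, ...) {
  cat("Residue composition model (pseudocount ",
      format(attr(x, "pseudocount")), ")\n", sep = "")
  print(round(unclass(x)[order(unclass(x), decreasing = TRUE)], 4))
  invisible(x)
}

#' Default prion-domain composition model
#'
#' Encodes the composition characteristic of detected prion-like regions:
#' N 30%, Q 21%, S 11%, G 11%, with the remaining 27% spread uniformly over
#' the other 16 residues.
#'
#' @param pseudocount Passed to [composition_model()].
#' @return A `composition_model`.
#' @export
prion_model <- function(pseudocount = 1e-4) {
  w <- stats::setNames(rep(0.27 / 16, 20), AA_STANDARD)
  w[c("N", "Q", "S", "G")] <- c(0.30, 0.21, 0.11, 0.11)
  composition_model(w, pseudocount)
}

#' Default background composition model
#'
#' Average residue frequencies of bacterial proteomes, shipped as an editable
#' TSV fixture (`inst/extdata/background_composition.tsv`). Values are
#' Swiss-Prot-style global frequencies; override with
#' [read_composition_model()] for organism-specific backgrounds.
#'
#' @param pseudocount Passed to [composition_model()].
#' @return A `composition_model`.
#' @export
background_model <- function(pseudocount = 1e-4) {
  path <- system.file("extdata", "background_composition.tsv",
                      package = "prdscan", mustWork = TRUE)
  read_composition_model(path, pseudocount)
}

#' Read a composition model from a TSV file
#'
#' @param path TSV file with columns `residue` and `probability` (one row per
#'   standard amino acid; missing residues get weight 0).
#' @param pseudocount Passed to [composition_model()].
#' @return A `composition_model`.
#' @export
read_composition_model <- function(path, pseudocount = 1e-4) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "probability") %in% names(tab))) {
    stop("composition model file needs columns 'residue' and 'probability'",
         call. = FALSE)
  }
  composition_model(stats::setNames(tab$probability, tab$residue), pseudocount)
}

#' Write a composition model to a TSV file
#'
#' @param model A `composition_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composition_model <- function(model, path) {
  stopifnot(inherits(model, "composition_model"))
  utils::write.table(
    data.frame(residue = names(model), probability = as.numeric(model)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
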