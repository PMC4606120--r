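#' Scanning parameters
#'
#' @param window_length Sliding-window length in residues. Default 60.
#' @param step Window step in residues. Default 1.
#' @param cutoff_bits Bit-score call threshold. Default 50.
#' @param merge_gap Maximum residue gap between qualifying windows merged into
#'   one called region. Default 0 (merge only overlapping/adjacent windows).
#' @param strict_greater If `TRUE`, a window must score strictly above
#'   `cutoff_bits`; the default (`FALSE`) calls at `>=` after rounding scores
#'   to 6 decimal places.
#' @return An object of class `scoring_params`.
#' @export
scoring_params <- function(window_length = 60, step = 1, cutoff_bits = 50,
                           merge_gap = 0, strict_greater = FALSE) {
  if (!is.numeric(window_length) || window_length < 1 ||
      window_length != round(window_length)) {
    stop("`window_length` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(step) || step < 1 || step != round(step)) {
    stop("`step` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(cutoff_bits) || !is.finite(cutoff_bits)) {
    stop("`cutoff_bits` must be finite", call. = FALSE)
  }
  if (!is.numeric(merge_gap) || merge_gap < 0) {
    stop("`merge_gap` must be >= 0", call. = FALSE)
  }
  structure(list(window_length = as.integer(window_length),
                 step = as.integer(step),
                 cutoff_bits = as.numeric(cutoff_bits),
                 merge_gap = as.integer(merge_gap),
                 strict_greater = isTRUE(strict_greater)),
            class = "scoring_params")
}

# Lookup table over raw byte codes: log2(prion/background) for the 20
# standard residues, 0 bits for the ambiguity codes B, Z, X, U, O.
residue_score_table <- function(prion, background) {
  stopifnot(inherits(prion, "composition_model"),
            inherits(background, "composition_model"))
  tab <- numeric(256)
  tab[utf8ToInt(paste(AA_STANDARD, collapse = "")) + 1] <-
    log2(as.numeric(prion) / as.numeric(background))
  tab
}

#' Score a sequence window in bits
#'
#' The bit score of a window is the sum over its residues of
#' `log2(prion[a] / background[a])`; ambiguity codes (B, Z, X, U, O)
#' contribute 0 bits. The score is position-independent: permuting the window
#' leaves it unchanged, and scores are additive over concatenation.
#'
#' @param window Non-empty amino-acid string.
#' @param prion,background `composition_model` objects.
#' @return The window score in bits (a single number).
#' @examples
#' p <- composition_model(c(N = 1, Q = 1))
#' b <- composition_model(c(N = 0.05, Q = 0.05, A = 0.9))
#' window_score("NNQQ", p, b)
#' @export
window_score <- function(window, prion, background) {
  if (!is.character(window) || length(window) != 1 || !nzchar(window)) {
    stop("`window` must be a single non-empty string", call. = FALSE)
  }
  window <- toupper(window)
  check_sequence_alphabet(window, "<window>")
  tab <- residue_score_table(prion, background)
  sum(tab[utf8ToInt(window) + 1])
}

# Window scores at every step position; returns starts and scores.
slide_scores <- function(res_scores, W, step) {
  n <- length(res_scores)
  if (n <= W) return(list(starts = 1L, scores = sum(res_scores), W = n))
  cs <- c(0, cumsum(res_scores))
  starts <- seq.int(1L, n - W + 1L, by = step)
  list(starts = starts, scores = cs[starts + W] - cs[starts], W = W)
}

#' Scan one protein for a prion-like domain
#'
#' Slides a window of `params$window_length` residues along the protein
#' (proteins shorter than the window are scanned as a single window of their
#' own length) and scores each window with [window_score()]. If the maximum
#' window score reaches `params$cutoff_bits`, one call is returned spanning
#' the union of qualifying windows that chain (within `merge_gap` residues) to
#' the maximal one; `score_bits` is that maximum. Other qualifying clusters
#' are reported in the `secondary` attribute as diagnostics, not calls.
#'
#' @param protein One-row `proteome_set` or a list/row with `accession` and
#'   `sequence`.
#' @param prion,background `composition_model` objects.
#' @param params A `scoring_params` object.
#' @return A one-row data frame (accession, start, end, score_bits,
#'   region_sequence) or `NULL` if no window reaches the cutoff.
#' @export
scan_protein <- function(protein, prion = prion_model(),
                         background = background_model(),
                         params = scoring_params()) {
  if (!inherits(params, "scoring_params")) {
    stop("`params` must be a scoring_params object", call. = FALSE)
  }
  seq <- toupper(protein$sequence[1])
  acc <- protein$accession[1]
  tab <- residue_score_table(prion, background)
  res <- scan_core(seq, acc, tab, params)
  res
}

# Shared scanning kernel; `tab` is a residue_score_table().
scan_core <- function(seq, acc, tab, params) {
  rs <- tab[utf8ToInt(seq) + 1]
  sw <- slide_scores(rs, params$window_length, params$step)
  scores <- round(sw$scores, 6)
  best <- which.max(scores)
  qual <- if (params$strict_greater) scores > params$cutoff_bits
          else scores >= params$cutoff_bits
  if (!qual[best]) return(NULL)
  # cluster qualifying windows; keep the cluster containing the maximum
  qi <- which(qual)
  qstart <- sw$starts[qi]
  qend <- qstart + sw$W - 1L
  brk <- c(FALSE, qstart[-1] > qend[-length(qi)] + 1L + params$merge_gap)
  grp <- cumsum(brk)
  gmax <- grp[match(best, qi)]
  sel <- grp == gmax
  start <- min(qstart[sel])
  end <- max(qend[sel])
  call <- data.frame(accession = acc, start = start, end = end,
                     score_bits = scores[best],
                     region_sequence = substr(seq, start, end),
                     stringsAsFactors = FALSE)
  other <- unique(grp[grp != gmax])
  if (length(other) > 0) {
    attr(call, "secondary") <- do.call(rbind, lapply(other, function(g) {
      s <- grp == g
      data.frame(accession = acc, start = min(qstart[s]), end = max(qend[s]),
                 score_bits = max(scores[qi[s]]), stringsAsFactors = FALSE)
    }))
  }
  call
}

#' Scan a whole proteome set for prion-like domains
#'
#' Applies [scan_protein()] to every record, keeping at most one call per
#' protein (the maximal merged region). The result is deterministic given the
#' inputs and parameters.
#'
#' @param proteome A non-empty `proteome_set`.
#' @param prion,background `composition_model` objects.
#' @param params A `scoring_params` object.
#' @return An object of class `prd_scan` with elements `calls` (data frame
#'   with accession, organism, is_pathogen, start, end, score_bits,
#'   region_sequence), `secondary` (diagnostic extra regions), `n_scanned`,
#'   `fraction_positive`, `per_organism` (scanned and called counts), and the
#'   parameters used.
#' @export
scan_proteome <- function(proteome, prion = prion_model(),
                          background = background_model(),
                          params = scoring_params()) {
  stopifnot(inherits(proteome, "proteome_set"))
  if (nrow(proteome) == 0) stop("empty proteome", call. = FALSE)
  if (!inherits(params, "scoring_params")) {
    stop("`params` must be a scoring_params object", call. = FALSE)
  }
  tab <- residue_score_table(prion, background)
  out <- vector("list", nrow(proteome))
  sec <- vector("list", nrow(proteome))
  for (i in seq_len(nrow(proteome))) {
    r <- scan_core(proteome$sequence[i], proteome$accession[i], tab, params)
    if (!is.null(r)) {
      sec[[i]] <- attr(r, "secondary")
      attr(r, "secondary") <- NULL
      r$organism <- proteome$organism[i]
      r$is_pathogen <- proteome$is_pathogen[i]
      out[[i]] <- r
    }
  }
  calls <- do.call(rbind, out)
  if (is.null(calls)) {
    calls <- data.frame(accession = character(), start = integer(),
                        end = integer(), score_bits = numeric(),
                        region_sequence = character(), organism = character(),
                        is_pathogen = logical(), stringsAsFactors = FALSE)
  }
  calls <- calls[, c("accession", "organism", "is_pathogen", "start", "end",
                     "score_bits", "region_sequence")]
  rownames(calls) <- NULL
  scanned <- table(proteome$organism)
  called <- table(factor(calls$organism, levels = names(scanned)))
  structure(list(
    calls = calls,
    secondary = do.call(rbind, sec),
    n_scanned = nrow(proteome),
    fraction_positive = nrow(calls) / nrow(proteome),
    per_organism = data.frame(organism = names(scanned),
                              n_scanned = as.integer(scanned),
                              n_prd = as.integer(called),
                              stringsAsFactors = FALSE),
    params = params),
    class = "prd_scan")
}

#' @export
print.prd_scan <- function(x, ...) {
  cat(sprintf(
    "Prion-like domain scan: %d/%d proteins called (fraction %.4g)\n",
    nrow(x$calls), x$n_scanned, x$fraction_positive))
  cat(sprintf("  window %d, step %d, cutoff %g bits\n",
              x$params$window_length, x$params$step, x$params$cutoff_bits))
  if (nrow(x$calls) > 0) {
    show <- utils::head(x$calls, 5)
    show$region_sequence <- paste0(substr(show$region_sequence, 1, 20), "...")
    print.data.frame(show)
    if (nrow(x$calls) > 5) cat("...", nrow(x$calls) - 5, "more calls\n")
  }
  invisible(x)
}

#' @export
summary.prd_scan <- function(object, ...) {
  cat(sprintf("Scanned %d proteins across %d organism(s); %d calls (%.3g%%)\n",
              object$n_scanned, nrow(object$per_organism),
              nrow(object$calls), 100 * object$fraction_positive))
  print.data.frame(object$per_organism)
  if (nrow(object$calls) > 0) {
    cat("Score (bits): ")
    print(summary(object$calls$score_bits))
  }
  invisible(object)
}

#' @export
as.data.frame.prd_scan <- function(x, ...) x$calls

#' Write / read a call table as TSV
#'
#' Columns: accession, organism, is_pathogen, start, end, score_bits,
#' region_sequence.
#'
#' @param scan A `prd_scan` object (or its `calls` data frame).
#' @param path Output path.
#' @return `path` (write) or the calls data frame (read).
#' @export
write_calls <- function(scan, path) {
  calls <- if (inherits(scan, "prd_scan")) scan$calls else scan
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Pooled residue composition of called regions
#'
#' Pools the `region_sequence` strings of all calls and reports the frequency
#' of each of the 20 standard residues. Ambiguity codes are excluded from both
#' numerator and denominator. Frequencies sum to 1.
#'
#' @param calls A `prd_scan` object or a calls data frame with a
#'   `region_sequence` column.
#' @return Named numeric vector of 20 residue frequencies.
#' @export
composition_summary <- function(calls) {
  df <- if (inherits(calls, "prd_scan")) calls$calls else calls
  if (is.null(df$region_sequence) || nrow(df) == 0) {
    stop("no calls to summarize", call. = FALSE)
  }
  pooled <- paste(df$region_sequence, collapse = "")
  counts <- table(factor(strsplit(pooled, "")[[1]], levels = AA_STANDARD))
  total <- sum(counts)
  if (total == 0) stop("called regions contain no standard residues",
                       call. = FALSE)
  stats::setNames(as.numeric(counts) / total, AA_STANDARD)
}

#' Locate a call relative to a protein's domain architecture
#'
#' @param call One call (row with `accession`, `start`, `end`).
#' @param architecture A `domain_architecture` for the same accession (see
#'   [domain_architecture()]).
#' @return One of `"undomained"`, `"overlapping"`, `"N-terminal"`,
#'   `"C-terminal"`, `"inter-domain"`. A call overlapping any domain by more
#'   than 10% of the call's length is `"overlapping"`; otherwise it is placed
#'   by its midpoint relative to the first and last domain.
#' @export
prd_localization <- function(call, architecture) {
  stopifnot(inherits(architecture, "domain_architecture"))
  if (call$accession[1] != attr(architecture, "accession")) {
    stop("accession mismatch: call is ", call$accession[1], ", architecture is ",
         attr(architecture, "accession"), call. = FALSE)
  }
  if (nrow(architecture) == 0) return("undomained")
  s <- call$start[1]; e <- call$end[1]
  len <- e - s + 1
  ov <- pmax(0, pmin(e, architecture$end) - pmax(s, architecture$start) + 1)
  if (any(ov > 0.10 * len)) return("overlapping")
  mid <- (s + e) / 2
  if (mid < min(architecture$start)) return("N-terminal")
  if (mid > max(architecture$end)) return("C-terminal")
  "inter-domain"
}
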