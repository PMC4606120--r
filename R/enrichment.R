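#' Term contingency counts
#'
#' The four counts behind the enrichment factor: `n_l` hits of a term among
#' the (annotated) PrD-containing proteins, `p_l` annotated proteins in the
#' PrD list, `n_b` hits of the term in the background, and `p_b` total
#' proteins in the background.
#'
#' @param term_id Term identifier.
#' @param n_l,p_l,n_b,p_b Non-negative integer counts satisfying
#'   `0 <= n_l <= min(p_l, n_b)`, `0 < p_l <= p_b`, `0 <= n_b <= p_b`.
#' @return A list of class `term_contingency`.
#' @export
term_contingency <- function(term_id, n_l, p_l, n_b, p_b) {
  v <- c(n_l = n_l, p_l = p_l, n_b = n_b, p_b = p_b)
  if (anyNA(v) || any(v < 0) || any(v != round(v))) {
    stop("contingency counts must be non-negative integers", call. = FALSE)
  }
  if (p_l <= 0) stop("p_l must be > 0", call. = FALSE)
  if (p_l > p_b) stop("p_l must be <= p_b", call. = FALSE)
  if (n_b > p_b) stop("n_b must be <= p_b", call. = FALSE)
  if (n_l > min(p_l, n_b)) {
    stop("n_l must be <= min(p_l, n_b)", call. = FALSE)
  }
  structure(list(term_id = as.character(term_id), n_l = as.integer(n_l),
                 p_l = as.integer(p_l), n_b = as.integer(n_b),
                 p_b = as.integer(p_b)),
            class = "term_contingency")
}

#' Enrichment factor
#'
#' EF = (n_l / p_l) / (n_b / p_b) = (n_l * p_b) / (n_b * p_l): the proportion
#' of hits among the annotated PrD proteins relative to the term's proportion
#' in the background. EF is linear in `n_l` and invariant under scaling
#' (`n_b`, `p_b`) by a common factor.
#'
#' @param c A `term_contingency` (or list with n_l, p_l, n_b, p_b).
#' @return The enrichment factor (a single non-negative number).
#' @examples
#' enrichment_factor(term_contingency("GO:1", 5, 50, 100, 10000))  # 10
#' @export
enrichment_factor <- function(c) {
  if (is.null(c$p_l) || c$p_l <= 0) stop("p_l must be > 0", call. = FALSE)
  if (is.null(c$n_b) || c$n_b == 0) {
    stop("EF undefined: term absent from background (n_b = 0)", call. = FALSE)
  }
  (c$n_l * c$p_b) / (c$n_b * c$p_l)
}

#' One-sided hypergeometric over-representation p-value
#'
#' P[X >= n_l] where X ~ Hypergeometric drawing `p_l` proteins from a
#' background of `p_b` containing `n_b` term-positive proteins. Equivalent to
#' a one-sided Fisher exact test for over-representation.
#'
#' @param c A `term_contingency`.
#' @return The p-value.
#' @export
term_pvalue <- function(c) {
  if (!inherits(c, "term_contingency")) {
    c <- term_contingency(c$term_id %||% "term", c$n_l, c$p_l, c$n_b, c$p_b)
  }
  stats::phyper(c$n_l - 1, c$n_b, c$p_b - c$n_b, c$p_l, lower.tail = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' order-preserving with the input vector. `q >= p` elementwise, and
#' `{q <= alpha}` equals the classical BH rejection set.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same order and length as the input.
#' @export
benjamini_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' GO / Pfam term enrichment over PrD-containing proteins
#'
#' For every term in the chosen namespace, builds the contingency counts,
#' computes the enrichment factor, the one-sided hypergeometric p-value and
#' the Benjamini-Hochberg q-value, and flags terms significant when
#' `log2(EF) > log2_min` and `q < fdr` (defaults: 0.5 and 0.1).
#'
#' For the GO namespace, `p_l` counts only GO-annotated PrD proteins (a
#' protein with no GO terms is not part of the enrichment list); for Pfam,
#' only domain-bearing PrD proteins. The background universe `p_b` is every
#' protein in the annotation table (`background = "all"`) or only annotated
#' ones (`background = "annotated"`). Terms absent from the background are
#' skipped with a warning.
#'
#' @param calls A `prd_scan` object or calls data frame.
#' @param annotations An `annotation_table` covering the background universe.
#' @param namespace `"GO"` or `"Pfam"`.
#' @param background `"all"` (default) or `"annotated"`.
#' @param log2_min Significance requires `log2(EF)` strictly above this.
#' @param fdr Significance requires q strictly below this.
#' @return A data frame of class `prd_enrichment` with columns term_id, n_l,
#'   p_l, n_b, p_b, EF, log2_EF, p_value, q_value, significant; attributes
#'   record the universes and thresholds.
#' @export
run_enrichment <- function(calls, annotations, namespace = c("GO", "Pfam"),
                           background = c("all", "annotated"),
                           log2_min = 0.5, fdr = 0.1) {
  namespace <- match.arg(namespace)
  background <- match.arg(background)
  stopifnot(inherits(annotations, "annotation_table"))
  df <- calls_df(calls)

  term_sets <- function(acc) {
    if (namespace == "GO") {
      annotations$go_terms[intersect(acc, names(annotations$go_terms))]
    } else {
      d <- annotations$domains[annotations$domains$accession %in% acc, ]
      split(d$pfam_id, d$accession)
    }
  }
  bg_sets <- term_sets(annotations$accession)
  bg_sets <- bg_sets[lengths(bg_sets) > 0]
  list_sets <- term_sets(df$accession)
  list_sets <- list_sets[lengths(list_sets) > 0]
  p_l <- length(list_sets)
  if (p_l == 0) {
    stop("empty universe: no annotated PrD-containing protein in the ",
         namespace, " namespace", call. = FALSE)
  }
  p_b <- if (background == "all") length(annotations$accession)
         else length(bg_sets)
  # per-protein presence counts
  n_b <- table(unlist(lapply(bg_sets, unique)))
  n_l <- table(unlist(lapply(list_sets, unique)))
  terms <- sort(names(n_b))
  orphan <- setdiff(names(n_l), terms)
  if (length(orphan) > 0) {
    warning("skipping ", length(orphan),
            " term(s) absent from the background (n_b = 0): ",
            paste(utils::head(orphan, 5), collapse = ", "))
  }
  nb <- as.integer(n_b[terms])
  nl <- as.integer(n_l[terms]); nl[is.na(nl)] <- 0L
  ef <- (nl * p_b) / (nb * p_l)
  pv <- stats::phyper(nl - 1, nb, p_b - nb, p_l, lower.tail = FALSE)
  qv <- benjamini_adjust(pv)
  res <- data.frame(term_id = terms, n_l = nl, p_l = p_l, n_b = nb, p_b = p_b,
                    EF = ef, log2_EF = log2(ef), p_value = pv, q_value = qv,
                    significant = log2(ef) > log2_min & qv < fdr,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, class = c("prd_enrichment", "data.frame"),
            namespace = namespace, background = background,
            log2_min = log2_min, fdr = fdr, p_l = p_l, p_b = p_b)
}

#' @export
print.prd_enrichment <- function(x, ...) {
  cat(sprintf(
    "%s enrichment over %d annotated PrD proteins vs background of %d (%s)\n",
    attr(x, "namespace"), attr(x, "p_l"), attr(x, "p_b"),
    attr(x, "background")))
  cat(sprintf("  %d terms tested, %d significant (log2 EF > %g, q < %g)\n",
              nrow(x), sum(x$significant), attr(x, "log2_min"),
              attr(x, "fdr")))
  sig <- x[x$significant, , drop = FALSE]
  if (nrow(sig) > 0) {
    sig <- sig[order(-sig$EF), , drop = FALSE]
    print.data.frame(utils::head(sig, 10), digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' Write enrichment results to TSV
#'
#' @param results A `prd_enrichment` data frame.
#' @param path Output path.
#' @param map Optional cluster map ([load_cluster_map()]); adds a `cluster`
#'   column.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path, map = NULL) {
  out <- as.data.frame(results)
  if (!is.null(map)) {
    cl <- map[out$term_id]
    cl[is.na(cl)] <- "unclustered"
    out <- cbind(out[, "term_id", drop = FALSE], cluster = cl,
                 out[, setdiff(names(out), "term_id")])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare enrichment between a subset and the full protein list
#'
#' Joins two enrichment results computed over the same background universe
#' and reports per-term EF ratios.
#'
#' @param results_subset,results_full `prd_enrichment` objects with identical
#'   `background` mode and `p_b`.
#' @return List with `paired` (term_id, EF_subset, EF_full, log2_ratio),
#'   `only_subset` and `only_full` (term IDs unique to one side).
#' @export
compare_subsets <- function(results_subset, results_full) {
  stopifnot(inherits(results_subset, "prd_enrichment"),
            inherits(results_full, "prd_enrichment"))
  if (!identical(attr(results_subset, "background"),
                 attr(results_full, "background")) ||
      !identical(attr(results_subset, "p_b"), attr(results_full, "p_b"))) {
    stop("enrichment results were computed over different backgrounds",
         call. = FALSE)
  }
  common <- intersect(results_subset$term_id, results_full$term_id)
  i <- match(common, results_subset$term_id)
  j <- match(common, results_full$term_id)
  lr <- log2(results_subset$EF[i] / results_full$EF[j])
  lr[results_subset$EF[i] == results_full$EF[j]] <- 0  # incl. both zero
  paired <- data.frame(term_id = common,
                       EF_subset = results_subset$EF[i],
                       EF_full = results_full$EF[j],
                       log2_ratio = lr,
                       stringsAsFactors = FALSE)
  list(paired = paired,
       only_subset = setdiff(results_subset$term_id, common),
       only_full = setdiff(results_full$term_id, common))
}
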