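#' Construct an annotation table
#'
#' Maps protein accessions to GO term sets and Pfam domain instances with
#' coordinates, plus organism and pathogen metadata. A protein with an empty
#' GO set is "unannotated" for GO purposes but still participates in the
#' domain census.
#'
#' @param accession Character vector of accessions (one per protein).
#' @param go_terms List of character vectors of GO IDs (one element per
#'   accession; may be empty).
#' @param domains Data frame with columns `accession`, `pfam_id`, `start`,
#'   `end` (zero or more rows per accession; 1-based, start <= end).
#' @param organism,is_pathogen Per-accession metadata, recycled.
#' @return An object of class `annotation_table`.
#' @export
annotation_table <- function(accession, go_terms = NULL, domains = NULL,
                             organism = "unknown", is_pathogen = FALSE) {
  accession <- as.character(accession)
  n <- length(accession)
  if (anyDuplicated(accession)) stop("duplicate accessions", call. = FALSE)
  if (is.null(go_terms)) go_terms <- rep(list(character(0)), n)
  if (length(go_terms) != n) stop("`go_terms` length mismatch", call. = FALSE)
  go_terms <- lapply(go_terms, function(g) unique(as.character(g[nzchar(g)])))
  names(go_terms) <- accession
  if (is.null(domains)) {
    domains <- data.frame(accession = character(), pfam_id = character(),
                          start = integer(), end = integer(),
                          stringsAsFactors = FALSE)
  }
  need <- c("accession", "pfam_id", "start", "end")
  if (!all(need %in% names(domains))) {
    stop("`domains` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(domains) > 0 && any(domains$start > domains$end | domains$start < 1)) {
    stop("domain coordinates must satisfy 1 <= start <= end", call. = FALSE)
  }
  structure(list(
    accession = accession,
    go_terms = go_terms,
    domains = domains[, need],
    organism = stats::setNames(rep_len(as.character(organism), n), accession),
    is_pathogen = stats::setNames(rep_len(as.logical(is_pathogen), n), accession)),
    class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  n_go <- sum(lengths(x$go_terms) > 0)
  cat(sprintf(
    "Annotation table: %d proteins; %d GO-annotated; %d Pfam domain instances\n",
    length(x$accession), n_go, nrow(x$domains)))
  invisible(x)
}

#' Load an annotation table from TSV
#'
#' Expected header columns: `accession`, `go_terms` (semicolon-separated GO
#' IDs, may be empty), `pfam` (semicolon-separated `pfam_id:start-end`
#' triples, may be empty), `organism`, `is_pathogen`. Duplicate accessions are
#' merged by union of their terms and domains. Malformed Pfam fields are
#' reported with their line numbers.
#'
#' @param path TSV file path.
#' @return An `annotation_table`.
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("accession", "go_terms", "pfam", "organism", "is_pathogen")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("annotation TSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  parse_pfam <- function(field, line) {
    if (!nzchar(field)) return(NULL)
    parts <- strsplit(field, ";", fixed = TRUE)[[1]]
    m <- regmatches(parts, regexec("^([^:]+):([0-9]+)-([0-9]+)$", parts))
    bad <- lengths(m) == 0
    if (any(bad)) {
      stop(sprintf("line %d: malformed pfam field '%s'", line,
                   parts[bad][1]), call. = FALSE)
    }
    data.frame(pfam_id = vapply(m, `[`, "", 2),
               start = as.integer(vapply(m, `[`, "", 3)),
               end = as.integer(vapply(m, `[`, "", 4)),
               stringsAsFactors = FALSE)
  }
  acc_all <- unique(tab$accession)
  go <- stats::setNames(rep(list(character(0)), length(acc_all)), acc_all)
  dom <- vector("list", nrow(tab))
  org <- stats::setNames(rep("unknown", length(acc_all)), acc_all)
  pat <- stats::setNames(rep(FALSE, length(acc_all)), acc_all)
  for (i in seq_len(nrow(tab))) {
    a <- tab$accession[i]
    g <- strsplit(tab$go_terms[i], ";", fixed = TRUE)[[1]]
    go[[a]] <- union(go[[a]], g[nzchar(g)])
    d <- parse_pfam(tab$pfam[i], i + 1L)  # +1 for the header line
    if (!is.null(d)) dom[[i]] <- cbind(accession = a, d)
    org[a] <- tab$organism[i]
    pat[a] <- tab$is_pathogen[i] %in% c("1", "TRUE", "true", "T")
  }
  domains <- do.call(rbind, dom)
  annotation_table(acc_all, go_terms = go[acc_all], domains = domains,
                   organism = org[acc_all], is_pathogen = pat[acc_all])
}

#' Write an annotation table to TSV
#'
#' @param annotations An `annotation_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_table"))
  acc <- annotations$accession
  pf <- split(annotations$domains, annotations$domains$accession)
  pfam_field <- vapply(acc, function(a) {
    d <- pf[[a]]
    if (is.null(d) || nrow(d) == 0) return("")
    d <- d[order(d$start), , drop = FALSE]
    paste(sprintf("%s:%d-%d", d$pfam_id, d$start, d$end), collapse = ";")
  }, "")
  out <- data.frame(
    accession = acc,
    go_terms = vapply(annotations$go_terms[acc], paste, "", collapse = ";"),
    pfam = pfam_field,
    organism = annotations$organism[acc],
    is_pathogen = as.integer(annotations$is_pathogen[acc]),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ordered domain architecture of one protein
#'
#' @param annotations An `annotation_table`.
#' @param accession One accession.
#' @return Data frame of class `domain_architecture` (pfam_id, start, end)
#'   ordered by start coordinate, with an `overlapping` attribute flagging
#'   whether any two domains overlap.
#' @export
domain_architecture <- function(annotations, accession) {
  stopifnot(inherits(annotations, "annotation_table"))
  d <- annotations$domains
  d <- d[d$accession == accession, c("pfam_id", "start", "end"), drop = FALSE]
  d <- d[order(d$start, d$end), , drop = FALSE]
  rownames(d) <- NULL
  overl <- nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)])
  structure(d, class = c("domain_architecture", "data.frame"),
            accession = accession, overlapping = overl)
}

# calls argument -> plain calls data frame
calls_df <- function(calls) {
  if (inherits(calls, "prd_scan")) calls$calls else calls
}

#' Pfam domain census over PrD-containing proteins
#'
#' Counts every Pfam domain instance across the called proteins (a domain
#' occurring twice in one protein counts twice) and keeps only domains seen
#' strictly more than `min_count` times, sorted by descending count.
#'
#' @param calls A `prd_scan` object or calls data frame.
#' @param annotations An `annotation_table`.
#' @param min_count Census threshold; domains with count > `min_count` are
#'   kept. Default 5 (the "more than five times" rule).
#' @return Data frame (pfam_id, count), descending by count.
#' @export
pfam_census <- function(calls, annotations, min_count = 5) {
  stopifnot(inherits(annotations, "annotation_table"))
  df <- calls_df(calls)
  d <- annotations$domains
  d <- d[d$accession %in% df$accession, , drop = FALSE]
  if (nrow(d) == 0) {
    return(data.frame(pfam_id = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  counts <- sort(table(d$pfam_id), decreasing = TRUE)
  keep <- counts > min_count
  data.frame(pfam_id = names(counts)[keep],
             count = as.integer(counts[keep]),
             stringsAsFactors = FALSE)
}

#' Multi-domain statistics of PrD-containing proteins
#'
#' @param calls A `prd_scan` object or calls data frame (non-empty).
#' @param annotations An `annotation_table`.
#' @return List with `n_prd`, `n_with_domain`, `pct_with_domain` (of all
#'   PrD proteins, 0 decimals), `n_multidomain` (proteins with >= 2 domain
#'   instances), `pct_multidomain` (of domain-bearing proteins, 0 decimals).
#'   If no protein has a domain, the multidomain percentage is reported as 0
#'   with a warning.
#' @export
multidomain_stats <- function(calls, annotations) {
  stopifnot(inherits(annotations, "annotation_table"))
  df <- calls_df(calls)
  if (nrow(df) == 0) stop("empty call set", call. = FALSE)
  d <- annotations$domains
  inst <- table(factor(d$accession[d$accession %in% df$accession],
                       levels = df$accession))
  n_with <- sum(inst >= 1)
  n_multi <- sum(inst >= 2)
  pct_multi <- if (n_with == 0) {
    warning("no PrD protein has any Pfam domain; multidomain percentage ",
            "reported as 0")
    0
  } else {
    report_fraction(n_multi, n_with, 0)
  }
  list(n_prd = nrow(df),
       n_with_domain = n_with,
       pct_with_domain = report_fraction(n_with, nrow(df), 0),
       n_multidomain = n_multi,
       pct_multidomain = pct_multi)
}

#' Recurrent domain combinations
#'
#' Counts each multi-domain protein's full, start-ordered tuple of Pfam IDs
#' and reports the combinations occurring in at least two proteins.
#' Single-domain proteins contribute no combination.
#'
#' @param calls A `prd_scan` object or calls data frame.
#' @param annotations An `annotation_table`.
#' @return Data frame (combination, count) with combinations joined by `+`,
#'   descending by count.
#' @export
domain_pairs <- function(calls, annotations) {
  stopifnot(inherits(annotations, "annotation_table"))
  df <- calls_df(calls)
  d <- annotations$domains
  d <- d[d$accession %in% df$accession, , drop = FALSE]
  d <- d[order(d$accession, d$start, d$end), , drop = FALSE]
  tup <- vapply(split(d$pfam_id, d$accession), function(ids) {
    if (length(ids) < 2) NA_character_ else paste(ids, collapse = "+")
  }, "")
  tup <- tup[!is.na(tup)]
  if (length(tup) == 0) {
    return(data.frame(combination = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  counts <- sort(table(tup), decreasing = TRUE)
  keep <- counts >= 2
  data.frame(combination = names(counts)[keep],
             count = as.integer(counts[keep]),
             stringsAsFactors = FALSE)
}

#' Load a functional cluster map from YAML
#'
#' The map assigns GO or Pfam IDs to named functional clusters (e.g. "cell
#' wall dynamics", "nucleotide binding"). It is data, not an algorithm: edit
#' the YAML to regroup. IDs absent from the map fall into "unclustered".
#'
#' @param path YAML file mapping `id: cluster` (flat) or
#'   `cluster: [id, id, ...]` (grouped); both layouts are accepted.
#' @return Named character vector: names are IDs, values cluster labels.
#' @export
load_cluster_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (length(y) == 0) return(stats::setNames(character(0), character(0)))
  if (all(lengths(y) == 1) && !any(vapply(y, is.list, TRUE))) {
    return(stats::setNames(as.character(unlist(y)), names(y)))
  }
  ids <- unlist(y, use.names = FALSE)
  map <- stats::setNames(rep(names(y), lengths(y)), ids)
  if (anyDuplicated(ids)) {
    stop("cluster map assigns id(s) to more than one cluster: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  map
}

#' Aggregate counts by functional cluster
#'
#' @param x Data frame with an ID column (`pfam_id` or `term_id`) and a
#'   `count` column (e.g. output of [pfam_census()]), or an enrichment result
#'   (counts taken from `n_l`).
#' @param map Named character vector from [load_cluster_map()] (may be empty).
#' @return Data frame (cluster, count); unmapped IDs are pooled under
#'   "unclustered". Cluster totals conserve the input total.
#' @export
cluster_rollup <- function(x, map = character(0)) {
  id_col <- intersect(c("pfam_id", "term_id", "combination"), names(x))[1]
  if (is.na(id_col)) stop("no id column found", call. = FALSE)
  cnt_col <- if ("count" %in% names(x)) "count" else "n_l"
  if (!cnt_col %in% names(x)) stop("no count column found", call. = FALSE)
  cl <- map[x[[id_col]]]
  cl[is.na(cl)] <- "unclustered"
  agg <- tapply(x[[cnt_col]], cl, sum)
  out <- data.frame(cluster = names(agg), count = as.integer(agg),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$cluster), , drop = FALSE]
}
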