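# Deterministic per-protein substream seed so that record order and count
# never change another record's draws. Kept below 2^31 - 1.
substream_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483647
}

#' Parameters for the synthetic proteome generator
#'
#' Defaults mirror the study conditions the pipeline is designed around: a
#' small fraction (0.3%) of proteins carry one planted prion-like region of
#' 60-150 residues drawn from the N/Q/S/G-biased prion composition (N 30%,
#' Q 21%, S 11%, G 11%), on a background of average bacterial composition.
#'
#' @param n_proteins Number of proteins. Default 10000.
#' @param length_range Protein length (residues), drawn uniformly. Default
#'   c(150, 600).
#' @param background Background `composition_model`.
#' @param prd_fraction Probability a protein carries a planted region.
#'   Default 0.003.
#' @param prd_length_range Planted-region length, uniform. Default c(60, 150).
#' @param prd_model Prion `composition_model` for planted regions.
#' @param organisms Organism tags cycled across proteins. Default "org1".
#' @param pathogen_organisms Subset of `organisms` flagged as pathogens.
#' @param seed Integer seed; every draw is a pure function of (params, seed).
#' @return A list of class `synthetic_proteome_params`.
#' @export
synthetic_proteome_params <- function(n_proteins = 10000,
                                      length_range = c(150, 600),
                                      background = background_model(),
                                      prd_fraction = 0.003,
                                      prd_length_range = c(60, 150),
                                      prd_model = prion_model(),
                                      organisms = "org1",
                                      pathogen_organisms = character(0),
                                      seed = 1) {
  if (prd_fraction < 0 || prd_fraction > 1) {
    stop("`prd_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (length_range[1] < prd_length_range[2]) {
    stop("infeasible lengths: minimum protein length (", length_range[1],
         ") is below the maximum planted-region length (",
         prd_length_range[2], ")", call. = FALSE)
  }
  if (length_range[1] < 1 || prd_length_range[1] < 1) {
    stop("lengths must be >= 1", call. = FALSE)
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 background = background,
                 prd_fraction = prd_fraction,
                 prd_length_range = as.integer(prd_length_range),
                 prd_model = prd_model,
                 organisms = as.character(organisms),
                 pathogen_organisms = as.character(pathogen_organisms),
                 seed = as.integer(seed)),
            class = "synthetic_proteome_params")
}

#' Generate a synthetic proteome with planted prion-like regions
#'
#' Each protein is drawn residue-wise from the background model; a
#' Bernoulli(`prd_fraction`) subset receives one planted segment drawn from
#' the prion model, *replacing* background residues at a uniform random
#' position (lengths stay distribution-exact). Fully reproducible from the
#' seed; per-protein substreams make each record independent of record order.
#'
#' @param params A `synthetic_proteome_params` object.
#' @return List with `proteome` (a `proteome_set`) and `truth` (data frame
#'   accession, prd_start, prd_end for planted proteins only, carrying the
#'   generator params as an attribute).
#' @export
generate_proteome <- function(params = synthetic_proteome_params()) {
  stopifnot(inherits(params, "synthetic_proteome_params"))
  n <- params$n_proteins
  bg_p <- as.numeric(params$background)
  prd_p <- as.numeric(params$prd_model)
  lr <- params$length_range
  pr <- params$prd_length_range
  seqs <- character(n)
  tr_start <- integer(n); tr_end <- integer(n); planted <- logical(n)
  for (i in seq_len(n)) {
    set.seed(substream_seed(params$seed, i))
    L <- sample.int(lr[2] - lr[1] + 1L, 1L) + lr[1] - 1L
    res <- sample(AA_STANDARD, L, replace = TRUE, prob = bg_p)
    if (stats::runif(1) < params$prd_fraction) {
      pl <- sample.int(pr[2] - pr[1] + 1L, 1L) + pr[1] - 1L
      s <- sample.int(L - pl + 1L, 1L)
      res[s:(s + pl - 1L)] <- sample(AA_STANDARD, pl, replace = TRUE,
                                     prob = prd_p)
      planted[i] <- TRUE
      tr_start[i] <- s; tr_end[i] <- s + pl - 1L
    }
    seqs[i] <- paste(res, collapse = "")
  }
  acc <- sprintf("SYN%06d", seq_len(n))
  org <- rep_len(params$organisms, n)
  proteome <- proteome_set(acc, seqs, organism = org,
                           is_pathogen = org %in% params$pathogen_organisms,
                           description = "synthetic")
  truth <- data.frame(accession = acc[planted],
                      prd_start = tr_start[planted],
                      prd_end = tr_end[planted],
                      stringsAsFactors = FALSE)
  attr(truth, "params") <- params
  attr(truth, "n_proteins") <- n
  list(proteome = proteome, truth = truth)
}

#' Parameters for the synthetic annotation generator
#'
#' Defaults mirror the study conditions: only a small fraction (11%) of
#' PrD-carrying proteins are GO-annotated, term baselines are sparse, and
#' planted terms are over-represented among PrD proteins by a controlled
#' fold.
#'
#' @param n_terms Size of the synthetic GO term catalog. Default 50.
#' @param baseline Per-protein probability of each term. Default 0.02.
#' @param planted Data frame (term_id, fold) of terms over-represented among
#'   PrD-truth proteins; `fold >= 1`, assignment probability
#'   `min(1, fold * baseline)` (capped with a warning).
#' @param n_pfam Size of the synthetic Pfam catalog. Default 30.
#' @param domain_count_probs Probabilities of a protein carrying 0, 1, 2, ...
#'   Pfam domain instances. Default c(0.31, 0.414, 0.173, 0.103) (69% with a
#'   domain; 40% of those multi-domain).
#' @param annotated_fraction Fraction of PrD-truth proteins that are
#'   GO-annotated at all. Default 0.11.
#' @param background_annotated_fraction GO-annotated fraction among non-PrD
#'   proteins. Default 1.
#' @param seed Integer seed.
#' @return A list of class `synthetic_annotation_params`.
#' @export
synthetic_annotation_params <- function(n_terms = 50, baseline = 0.02,
                                        planted = NULL, n_pfam = 30,
                                        domain_count_probs =
                                          c(0.31, 0.414, 0.173, 0.103),
                                        annotated_fraction = 0.11,
                                        background_annotated_fraction = 1,
                                        seed = 1) {
  if (is.null(planted)) {
    planted <- data.frame(term_id = character(), fold = numeric(),
                          stringsAsFactors = FALSE)
  }
  if (nrow(planted) > 0 && any(planted$fold < 1)) {
    stop("planted folds must be >= 1", call. = FALSE)
  }
  if (baseline < 0 || baseline > 1 || annotated_fraction < 0 ||
      annotated_fraction > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_terms = as.integer(n_terms), baseline = baseline,
                 planted = planted, n_pfam = as.integer(n_pfam),
                 domain_count_probs = domain_count_probs /
                   sum(domain_count_probs),
                 annotated_fraction = annotated_fraction,
                 background_annotated_fraction = background_annotated_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_annotation_params")
}

#' Generate a synthetic annotation table with planted enriched terms
#'
#' Baseline terms are assigned to annotated proteins independently with
#' probability `baseline`; planted terms are assigned to PrD-truth proteins
#' with probability `min(1, fold * baseline)` and to others at baseline.
#' Pfam architectures are drawn from the domain-count distribution with
#' uniformly chosen domain IDs and evenly spaced coordinates. Reproducible
#' from the seed.
#'
#' @param proteome A `proteome_set` (typically from [generate_proteome()]).
#' @param truth The matching truth data frame from [generate_proteome()].
#' @param params A `synthetic_annotation_params` object.
#' @return List with `annotations` (an `annotation_table`) and `truth` (the
#'   input truth with a `planted_terms` attribute recording term folds).
#' @export
generate_annotations <- function(proteome, truth,
                                 params = synthetic_annotation_params()) {
  stopifnot(inherits(proteome, "proteome_set"),
            inherits(params, "synthetic_annotation_params"))
  if (!all(truth$accession %in% proteome$accession)) {
    stop("truth and proteome are inconsistent", call. = FALSE)
  }
  terms <- sprintf("GO:%07d", seq_len(params$n_terms))
  planted <- params$planted
  if (nrow(planted) > 0) {
    terms <- union(terms, planted$term_id)
    p_planted <- planted$fold * params$baseline
    if (any(p_planted > 1)) {
      warning("fold x baseline exceeds 1 for ",
              sum(p_planted > 1), " planted term(s); capped at 1")
      p_planted <- pmin(1, p_planted)
    }
  }
  pfam <- sprintf("PFS%04d", seq_len(params$n_pfam))
  is_prd <- proteome$accession %in% truth$accession
  L <- nchar(proteome$sequence)
  n <- nrow(proteome)
  go <- vector("list", n)
  dom <- vector("list", n)
  kmax <- length(params$domain_count_probs) - 1L
  for (i in seq_len(n)) {
    set.seed(substream_seed(params$seed + 1000000L, i))
    ann_p <- if (is_prd[i]) params$annotated_fraction
             else params$background_annotated_fraction
    if (stats::runif(1) < ann_p) {
      hit <- stats::runif(params$n_terms) < params$baseline
      g <- terms[seq_len(params$n_terms)][hit]
      if (nrow(planted) > 0) {
        pp <- if (is_prd[i]) p_planted else rep(params$baseline, nrow(planted))
        g <- union(g, planted$term_id[stats::runif(nrow(planted)) < pp])
      }
      go[[i]] <- g
    } else {
      go[[i]] <- character(0)
    }
    k <- sample.int(kmax + 1L, 1L, prob = params$domain_count_probs) - 1L
    if (k > 0) {
      ids <- pfam[sample.int(params$n_pfam, k, replace = TRUE)]
      slot <- floor(L[i] / k)
      dlen <- max(1L, floor(slot / 2))
      starts <- (seq_len(k) - 1L) * slot + 1L
      dom[[i]] <- data.frame(accession = proteome$accession[i],
                             pfam_id = ids, start = starts,
                             end = starts + dlen - 1L,
                             stringsAsFactors = FALSE)
    }
  }
  ann <- annotation_table(proteome$accession, go_terms = go,
                          domains = do.call(rbind, dom),
                          organism = proteome$organism,
                          is_pathogen = proteome$is_pathogen)
  attr(truth, "planted_terms") <- planted
  list(annotations = ann, truth = truth)
}

#' Score PrD calls against the planted truth
#'
#' A call is a true positive if it overlaps its protein's planted interval by
#' at least 50% of the planted interval's length.
#'
#' @param calls A `prd_scan` object or calls data frame.
#' @param truth Truth data frame from [generate_proteome()].
#' @return List with counts (`tp`, `fp`, `fn`), `sensitivity`, `precision`,
#'   and `overlap` (per-true-positive fraction of the planted interval
#'   covered). With no calls, precision is reported as 0 with a warning.
#' @export
score_calls_against_truth <- function(calls, truth) {
  df <- calls_df(calls)
  n_truth <- nrow(truth)
  if (nrow(df) == 0) {
    warning("no calls; precision reported as 0")
    return(list(tp = 0L, fp = 0L, fn = n_truth, sensitivity = 0,
                precision = 0, overlap = numeric(0)))
  }
  i <- match(df$accession, truth$accession)
  ov <- rep(0, nrow(df))
  hit <- !is.na(i)
  ov[hit] <- pmax(0, pmin(df$end[hit], truth$prd_end[i[hit]]) -
                     pmax(df$start[hit], truth$prd_start[i[hit]]) + 1) /
             (truth$prd_end[i[hit]] - truth$prd_start[i[hit]] + 1)
  tp_call <- ov >= 0.5
  tp_acc <- unique(df$accession[tp_call])
  tp <- length(tp_acc)
  fp <- nrow(df) - sum(tp_call)
  fn <- n_truth - tp
  list(tp = tp, fp = as.integer(fp), fn = as.integer(fn),
       sensitivity = if (n_truth > 0) tp / n_truth else NA_real_,
       precision = tp / nrow(df),
       overlap = ov[tp_call])
}

#' Write the planted truth to TSV
#'
#' @param truth Truth data frame from the generators.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pt <- attr(truth, "planted_terms")
  if (!is.null(pt) && nrow(pt) > 0) {
    utils::write.table(pt, sub("(\\.tsv)?$", "_terms.tsv", path),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
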