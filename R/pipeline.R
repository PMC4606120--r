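#' Report a percentage with explicit rounding
#'
#' Computes `100 * numerator / denominator` and rounds half-away-from-zero to
#' the requested number of decimals. Report-level percentages in this package
#' are always produced through this function with the decimals stated per
#' field, so every printed ratio is recomputable from its integer counts.
#'
#' @param numerator,denominator Counts; `denominator > 0`.
#' @param decimals Number of decimal places.
#' @return The rounded percentage.
#' @examples
#' report_fraction(2200, 860337, 1)  # 0.3
#' report_fraction(244, 2200, 2)     # 11.09
#' @export
report_fraction <- function(numerator, denominator, decimals = 0) {
  if (!is.numeric(denominator) || length(denominator) != 1 ||
      denominator <= 0) {
    stop("`denominator` must be a single positive number", call. = FALSE)
  }
  x <- 100 * numerator / denominator
  m <- 10^decimals
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Per-organism breakdown of PrD calls
#'
#' @param scan A `prd_scan` object (needs per-organism scanned counts).
#' @return Data frame (organism, n_scanned, n_prd, pct_of_all_prd,
#'   pct_of_organism_proteome). Shares of all PrDs are percentages of the
#'   total call count (summing to 100 within rounding); the proteome
#'   percentage is calls over proteins scanned for that organism.
#' @export
per_organism_breakdown <- function(scan) {
  stopifnot(inherits(scan, "prd_scan"))
  po <- scan$per_organism
  total <- sum(po$n_prd)
  po$pct_of_all_prd <- if (total > 0) {
    vapply(po$n_prd, report_fraction, 0, denominator = total, decimals = 1)
  } else rep(NA_real_, nrow(po))
  po$pct_of_organism_proteome <- mapply(report_fraction, po$n_prd,
                                        po$n_scanned, 1)
  po[order(-po$n_prd, po$organism), , drop = FALSE]
}

#' Assemble a pipeline configuration
#'
#' Either `fasta` (a path, with optional `metadata` sidecar TSV) or
#' `simulate = TRUE` (synthetic inputs from the in-package generators) must
#' be chosen. All referenced paths are validated here.
#'
#' @param out_dir Output directory (created if absent).
#' @param fasta Optional FASTA path.
#' @param metadata Optional sidecar metadata TSV (accession, organism,
#'   is_pathogen).
#' @param annotations Optional annotation TSV path ([load_annotations()]
#'   format). Required unless simulating.
#' @param cluster_map Optional YAML cluster map path.
#' @param prion,background Composition model files (TSV) or
#'   `composition_model` objects; defaults are the package models.
#' @param scoring A `scoring_params` object.
#' @param namespace,background_universe,log2_min,fdr Enrichment options.
#' @param pathogens Character vector of pathogen organism tags (used when the
#'   FASTA/metadata do not already flag pathogens).
#' @param simulate If `TRUE`, generate synthetic inputs.
#' @param sim_proteome,sim_annotation Generator parameter objects used when
#'   simulating.
#' @param seed Seed for simulated inputs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, fasta = NULL, metadata = NULL,
                            annotations = NULL, cluster_map = NULL,
                            prion = prion_model(),
                            background = background_model(),
                            scoring = scoring_params(),
                            namespace = "GO", background_universe = "all",
                            log2_min = 0.5, fdr = 0.1,
                            pathogens = character(0),
                            simulate = is.null(fasta),
                            sim_proteome = NULL, sim_annotation = NULL,
                            seed = 1) {
  for (p in c(fasta, metadata, annotations, cluster_map)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("configured path does not exist: ", p, call. = FALSE)
    }
  }
  if (!simulate && is.null(fasta)) {
    stop("either `fasta` or `simulate = TRUE` is required", call. = FALSE)
  }
  if (is.character(prion)) prion <- read_composition_model(prion)
  if (is.character(background)) background <- read_composition_model(background)
  if (log2_min < 0 || fdr <= 0 || fdr > 1) {
    stop("enrichment thresholds out of range", call. = FALSE)
  }
  structure(list(out_dir = out_dir, fasta = fasta, metadata = metadata,
                 annotations = annotations, cluster_map = cluster_map,
                 prion = prion, background = background, scoring = scoring,
                 namespace = namespace,
                 background_universe = background_universe,
                 log2_min = log2_min, fdr = fdr, pathogens = pathogens,
                 simulate = simulate,
                 sim_proteome = sim_proteome, sim_annotation = sim_annotation,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full scan / annotate / enrich / census pipeline
#'
#' Executes, in order: input loading (or synthetic generation), the proteome
#' scan, enrichment over the full call set and over the pathogen subset,
#' the Pfam census, multi-domain statistics, cluster rollup and the
#' subset-vs-full comparison; writes every stage's table under
#' `config$out_dir` (calls.tsv, enrichment_go.tsv, enrichment_pfam.tsv,
#' census.tsv, clusters.tsv, summary.tsv, summary.json) and returns a
#' summary report. Deterministic given the configuration (and seed, for
#' simulated inputs).
#'
#' @param config A `pipeline_config` object.
#' @param quiet Suppress per-stage messages.
#' @return An object of class `prd_pipeline`: list with `summary` (the
#'   report), `scan`, `enrichment`, `enrichment_pathogen`, `census`,
#'   `multidomain`, `clusters`, `comparison`, `per_organism` and (when
#'   simulating) `truth`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[prdscan] ", sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL

  if (config$simulate) {
    sp <- config$sim_proteome %||% synthetic_proteome_params(seed = config$seed)
    gen <- generate_proteome(sp)
    proteome <- gen$proteome
    sa <- config$sim_annotation %||%
      synthetic_annotation_params(seed = config$seed)
    ann <- generate_annotations(proteome, gen$truth, sa)
    annotations <- ann$annotations
    truth <- ann$truth
    say("simulated %d proteins (%d with planted regions)",
        nrow(proteome), nrow(truth))
  } else {
    proteome <- read_fasta(config$fasta, metadata = config$metadata)
    if (length(config$pathogens) > 0) {
      proteome$is_pathogen <- proteome$organism %in% config$pathogens
    }
    if (is.null(config$annotations)) {
      stop("stage 'annotate': no annotation table configured", call. = FALSE)
    }
    annotations <- load_annotations(config$annotations)
    say("loaded %d proteins, %d annotated records", nrow(proteome),
        length(annotations$accession))
  }

  scan <- scan_proteome(proteome, config$prion, config$background,
                        config$scoring)
  say("scanned %d proteins: %d calls (%.3g%%)", scan$n_scanned,
      nrow(scan$calls), 100 * scan$fraction_positive)
  write_calls(scan, file.path(config$out_dir, "calls.tsv"))

  map <- if (!is.null(config$cluster_map)) load_cluster_map(config$cluster_map)
         else character(0)

  enr <- tryCatch(
    run_enrichment(scan, annotations, namespace = config$namespace,
                   background = config$background_universe,
                   log2_min = config$log2_min, fdr = config$fdr),
    error = function(e) {
      stop("stage 'enrich': ", conditionMessage(e), call. = FALSE)
    })
  write_enrichment(enr, file.path(config$out_dir, "enrichment_go.tsv"), map)
  say("enrichment: %d terms tested, %d significant", nrow(enr),
      sum(enr$significant))
  enr_pfam <- tryCatch(
    run_enrichment(scan, annotations, namespace = "Pfam",
                   background = config$background_universe,
                   log2_min = config$log2_min, fdr = config$fdr),
    error = function(e) NULL)
  if (!is.null(enr_pfam)) {
    write_enrichment(enr_pfam,
                     file.path(config$out_dir, "enrichment_pfam.tsv"), map)
  }

  path_calls <- scan$calls[scan$calls$is_pathogen, , drop = FALSE]
  enr_path <- NULL; comparison <- NULL
  if (nrow(path_calls) == 0) {
    warning("no pathogen-flagged calls; subset comparison skipped")
  } else {
    enr_path <- tryCatch(
      run_enrichment(path_calls, annotations, namespace = config$namespace,
                     background = config$background_universe,
                     log2_min = config$log2_min, fdr = config$fdr),
      error = function(e) NULL)
    if (!is.null(enr_path)) comparison <- compare_subsets(enr_path, enr)
  }

  census <- pfam_census(scan, annotations)
  utils::write.table(census, file.path(config$out_dir, "census.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  md <- if (nrow(scan$calls) > 0) multidomain_stats(scan, annotations)
        else list(n_prd = 0L, n_with_domain = 0L, pct_with_domain = 0,
                  n_multidomain = 0L, pct_multidomain = 0)
  clusters <- if (nrow(census) > 0) cluster_rollup(census, map) else
    data.frame(cluster = character(), count = integer())
  utils::write.table(clusters, file.path(config$out_dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  org <- per_organism_breakdown(scan)
  n_ann <- if (nrow(scan$calls) > 0) {
    sum(lengths(annotations$go_terms[
      intersect(scan$calls$accession, names(annotations$go_terms))]) > 0)
  } else 0L
  n_path <- nrow(path_calls)
  summary_report <- list(
    n_proteomes = nrow(scan$per_organism),
    n_proteins = scan$n_scanned,
    n_prd = nrow(scan$calls),
    pct_prd = report_fraction(nrow(scan$calls), scan$n_scanned, 1),
    n_annotated = n_ann,
    pct_annotated = if (nrow(scan$calls) > 0)
      report_fraction(n_ann, nrow(scan$calls), 2) else NA_real_,
    n_with_domain = md$n_with_domain,
    pct_with_domain = md$pct_with_domain,
    n_multidomain = md$n_multidomain,
    pct_multidomain = md$pct_multidomain,
    n_pathogen_prd = n_path,
    pct_pathogen_share = if (nrow(scan$calls) > 0)
      report_fraction(n_path, nrow(scan$calls), 0) else NA_real_)
  jsonlite::write_json(summary_report,
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(
    data.frame(field = names(summary_report),
               value = unlist(summary_report)),
    file.path(config$out_dir, "summary.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    write_truth(truth, file.path(config$out_dir, "truth.tsv"))
  }

  structure(list(summary = summary_report, scan = scan, enrichment = enr,
                 enrichment_pfam = enr_pfam, enrichment_pathogen = enr_path,
                 census = census, multidomain = md, clusters = clusters,
                 comparison = comparison, per_organism = org, truth = truth,
                 config = config),
            class = "prd_pipeline")
}

#' @export
print.prd_pipeline <- function(x, ...) {
  s <- x$summary
  cat("Prion-like domain pipeline summary\n")
  cat(sprintf("  proteomes: %d   proteins: %d\n", s$n_proteomes, s$n_proteins))
  cat(sprintf("  PrD calls: %d (%.4g%% of proteins)\n", s$n_prd, s$pct_prd))
  cat(sprintf("  GO-annotated calls: %d (%.4g%%)\n", s$n_annotated,
              s$pct_annotated))
  cat(sprintf("  with Pfam domain: %d (%g%%);  multi-domain: %d (%g%%)\n",
              s$n_with_domain, s$pct_with_domain, s$n_multidomain,
              s$pct_multidomain))
  cat(sprintf("  pathogen-flagged calls: %d (%g%% of all calls)\n",
              s$n_pathogen_prd, s$pct_pathogen_share))
  invisible(x)
}
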