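test_that("the proteome generator is a pure function of (params, seed)", {
  sp <- synthetic_proteome_params(n_proteins = 40, prd_fraction = 0.2,
                                  seed = 13)
  g1 <- generate_proteome(sp)
  g2 <- generate_proteome(sp)
  expect_identical(g1$proteome, g2$proteome)
  expect_identical(g1$truth$accession, g2$truth$accession)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(g1$proteome, f1); write_fasta(g2$proteome, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical output
  g3 <- generate_proteome(synthetic_proteome_params(n_proteins = 40,
                                                    prd_fraction = 0.2,
                                                    seed = 14))
  expect_false(identical(g1$proteome$sequence, g3$proteome$sequence))
})

test_that("per-protein substreams make records independent of set size", {
  p_small <- synthetic_proteome_params(n_proteins = 10, prd_fraction = 0.3,
                                       seed = 21)
  p_large <- synthetic_proteome_params(n_proteins = 25, prd_fraction = 0.3,
                                       seed = 21)
  s <- generate_proteome(p_small)$proteome
  l <- generate_proteome(p_large)$proteome
  expect_identical(s$sequence, l$sequence[1:10])
})

test_that("prd_fraction 0 plants nothing; planted counts track the binomial", {
  g0 <- generate_proteome(synthetic_proteome_params(n_proteins = 30,
                                                    prd_fraction = 0, seed = 1))
  expect_equal(nrow(g0$truth), 0)
  # defaults: n = 10000, fraction 0.003 -> central 99% interval is 10..50
  g <- generate_proteome(synthetic_proteome_params(seed = 20260925))
  expect_gte(nrow(g$truth), stats::qbinom(0.005, 10000, 0.003))
  expect_lte(nrow(g$truth), stats::qbinom(0.995, 10000, 0.003))
})

test_that("planted-count distribution is binomial across many small seeds", {
  # chi-square goodness of fit against Binomial(60, 0.05), 100 seeds
  n <- 60; fr <- 0.05
  counts <- vapply(1:100, function(s) {
    nrow(generate_proteome(synthetic_proteome_params(
      n_proteins = n, prd_fraction = fr, length_range = c(150, 160),
      seed = 5000 + s))$truth)
  }, 0L)
  breaks <- c(-Inf, 1, 2, 3, 4, Inf)  # bins: <=1, 2, 3, 4, >=5
  obs <- table(cut(counts, breaks))
  pr <- c(stats::pbinom(1, n, fr),
          stats::dbinom(2, n, fr), stats::dbinom(3, n, fr),
          stats::dbinom(4, n, fr),
          stats::pbinom(4, n, fr, lower.tail = FALSE))
  gof <- stats::chisq.test(as.integer(obs), p = pr)
  expect_gt(gof$p.value, 0.01)
})

test_that("truth intervals lie inside their proteins and regions match the model", {
  sp <- synthetic_proteome_params(n_proteins = 500, prd_fraction = 1,
                                  length_range = c(150, 200), seed = 17)
  g <- generate_proteome(sp)
  L <- stats::setNames(nchar(g$proteome$sequence), g$proteome$accession)
  expect_true(all(g$truth$prd_start >= 1))
  expect_true(all(g$truth$prd_end <= L[g$truth$accession]))
  expect_true(all(g$truth$prd_end - g$truth$prd_start + 1 >= 60))
  # pooled planted-region composition converges to the generating model
  seqs <- substr(g$proteome$sequence[match(g$truth$accession,
                                           g$proteome$accession)],
                 g$truth$prd_start, g$truth$prd_end)
  expect_gte(sum(nchar(seqs)), 5e4)
  freq <- composition_summary(data.frame(region_sequence = seqs))
  expect_equal(unname(freq["N"]), 0.30, tolerance = 0.01 / 0.30)
  expect_equal(unname(freq["Q"]), 0.21, tolerance = 0.01 / 0.21)
})

test_that("infeasible planted lengths are rejected up front", {
  expect_error(synthetic_proteome_params(length_range = c(100, 200),
                                         prd_length_range = c(60, 150)),
               "infeasible lengths")
  expect_error(synthetic_proteome_params(prd_fraction = 1.5), "prd_fraction")
})

test_that("baseline-only annotations give calibrated enrichment", {
  # fold 1 for every term: empirical EF near 1 for well-populated terms
  sp <- synthetic_proteome_params(n_proteins = 4000, prd_fraction = 0.05,
                                  length_range = c(150, 170), seed = 3)
  g <- generate_proteome(sp)
  ap <- synthetic_annotation_params(n_terms = 12, baseline = 0.3,
                                    annotated_fraction = 1, seed = 3)
  a <- generate_annotations(g$proteome, g$truth, ap)
  calls <- data.frame(accession = g$truth$accession)
  res <- run_enrichment(calls, a$annotations, background = "annotated")
  well <- res[res$n_b >= 200, ]
  expect_gt(nrow(well), 5)
  expect_true(all(well$EF > 0.8 & well$EF < 1.25))
})

test_that("fold x baseline above 1 is capped with a warning", {
  sp <- synthetic_proteome_params(n_proteins = 50, prd_fraction = 0.5,
                                  length_range = c(150, 160), seed = 8)
  g <- generate_proteome(sp)
  ap <- synthetic_annotation_params(baseline = 0.3,
                                    planted = data.frame(term_id = "GO:hot",
                                                         fold = 10),
                                    annotated_fraction = 1, seed = 8)
  expect_warning(a <- generate_annotations(g$proteome, g$truth, ap),
                 "capped at 1")
  # every annotated planted protein carries the capped term
  prd_ann <- intersect(g$truth$accession, names(a$annotations$go_terms))
  has <- vapply(a$annotations$go_terms[prd_ann],
                function(g_) "GO:hot" %in% g_, TRUE)
  expect_true(all(has[lengths(a$annotations$go_terms[prd_ann]) > 0]))
})

test_that("a strongly planted sparse term is recovered in almost every run", {
  # fold 10 on a term with baseline 0.02: flagged significant in >= 18/20
  # seeded runs
  planted <- data.frame(term_id = "GO:9000010", fold = 10)
  flags <- 0
  for (s in 1:20) {
    sp <- synthetic_proteome_params(n_proteins = 3000, prd_fraction = 0.05,
                                    length_range = c(150, 180),
                                    seed = 700 + s)
    g <- generate_proteome(sp)
    ap <- synthetic_annotation_params(planted = planted, baseline = 0.02,
                                      annotated_fraction = 1, seed = 700 + s)
    a <- generate_annotations(g$proteome, g$truth, ap)
    res <- run_enrichment(data.frame(accession = g$truth$accession),
                          a$annotations, background = "annotated")
    flags <- flags + res[res$term_id == "GO:9000010", "significant"]
  }
  expect_gte(flags, 18)
})

test_that("an unannotated PrD list raises the empty-universe error", {
  sp <- synthetic_proteome_params(n_proteins = 100, prd_fraction = 0.3,
                                  length_range = c(150, 160), seed = 5)
  g <- generate_proteome(sp)
  ap <- synthetic_annotation_params(annotated_fraction = 0, seed = 5)
  a <- generate_annotations(g$proteome, g$truth, ap)
  calls <- data.frame(accession = g$truth$accession)
  expect_error(run_enrichment(calls, a$annotations), "empty universe")
})

test_that("calls are scored against truth with the 50% overlap rule", {
  truth <- data.frame(accession = c("p1", "p2"),
                      prd_start = c(101, 51), prd_end = c(200, 150))
  exact <- data.frame(accession = c("p1", "p2"),
                      start = c(101, 51), end = c(200, 150))
  s <- score_calls_against_truth(exact, truth)
  expect_equal(s$sensitivity, 1)
  expect_equal(s$precision, 1)
  # 40% overlap: counted as both a false positive and a missed plant
  shifted <- data.frame(accession = "p1", start = 41, end = 140)
  s2 <- score_calls_against_truth(shifted, truth)
  expect_equal(s2$tp, 0L)
  expect_equal(s2$fp, 1L)
  expect_equal(s2$fn, 2L)
  # exactly 50% overlap counts as recovered
  half <- data.frame(accession = "p1", start = 51, end = 150)
  expect_equal(score_calls_against_truth(half, truth)$tp, 1L)
  expect_warning(s0 <- score_calls_against_truth(
    data.frame(accession = character(), start = integer(),
               end = integer()), truth), "no calls")
  expect_equal(s0$sensitivity, 0)
  expect_equal(s0$precision, 0)
})
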