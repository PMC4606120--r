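test_that("window score matches hand arithmetic on biased windows", {
  m <- contrast_models()
  # four residues, each log2(0.25/0.05) = log2(5)
  expect_equal(window_score("NNQQ", m$prion, m$background), 4 * log2(5),
               tolerance = 1e-9)
  # identical models give exactly zero for any window
  expect_equal(window_score("NQACDEFGHIKLMNPQRSTVWY", m$prion, m$prion), 0)
  expect_equal(window_score("AAAA", m$background, m$background), 0)
})

test_that("ambiguity codes contribute zero bits", {
  m <- contrast_models()
  a_only <- window_score("A", m$prion, m$background)
  expect_equal(window_score("AB", m$prion, m$background), a_only)
  expect_equal(window_score("BZXUO", m$prion, m$background), 0)
})

test_that("window score is additive and permutation-invariant", {
  m <- contrast_models()
  set.seed(42)
  for (i in 1:20) {
    x <- paste(sample(c("N", "Q", "A", "C", "X"), sample(3:30, 1), TRUE),
               collapse = "")
    y <- paste(sample(c("N", "Q", "A", "C"), sample(3:30, 1), TRUE),
               collapse = "")
    expect_equal(window_score(paste0(x, y), m$prion, m$background),
                 window_score(x, m$prion, m$background) +
                   window_score(y, m$prion, m$background),
                 tolerance = 1e-9)
    rev_x <- paste(rev(strsplit(x, "")[[1]]), collapse = "")
    expect_equal(window_score(rev_x, m$prion, m$background),
                 window_score(x, m$prion, m$background))
  }
})

test_that("swapping a residue for one with a higher likelihood ratio raises the score", {
  m <- contrast_models()  # ratio(N) = 5 > ratio(A) = 5/9
  base <- window_score("AAAA", m$prion, m$background)
  expect_gt(window_score("AAAN", m$prion, m$background), base)
})

test_that("window_score rejects empty or invalid input", {
  m <- contrast_models()
  expect_error(window_score("", m$prion, m$background), "non-empty")
  expect_error(window_score("AJ", m$prion, m$background), "illegal character")
})

test_that("scan_protein calls a planted region and skips background proteins", {
  bg <- background_model()
  pm <- prion_model()
  set.seed(11)
  hits <- 0
  for (rep in 1:20) {
    res <- sample(names(bg), 200, replace = TRUE, prob = as.numeric(bg))
    s <- sample(1:(200 - 80 + 1), 1)
    res[s:(s + 79)] <- sample(names(pm), 80, replace = TRUE,
                              prob = as.numeric(pm))
    prot <- list(accession = "x", sequence = paste(res, collapse = ""))
    call <- scan_protein(prot, pm, bg)
    if (!is.null(call)) {
      ov <- max(0, min(call$end, s + 79) - max(call$start, s) + 1)
      if (ov >= 40) hits <- hits + 1
    }
  }
  expect_gte(hits, 19)  # >= 95% of replicates recover >= 50% of the plant
  # pure background composition never reaches 50 bits
  set.seed(12)
  for (rep in 1:5) {
    res <- paste(sample(names(bg), 400, TRUE, prob = as.numeric(bg)),
                 collapse = "")
    expect_null(scan_protein(list(accession = "b", sequence = res), pm, bg))
  }
})

test_that("proteins shorter than the window are scanned as one window", {
  m <- contrast_models()
  prot <- list(accession = "s", sequence = strrep("N", 30))
  call <- scan_protein(prot, m$prion, m$background,
                       scoring_params(window_length = 60, cutoff_bits = 50))
  expect_equal(call$start, 1)
  expect_equal(call$end, 30)
  expect_equal(call$score_bits, round(30 * log2(5), 6))
})

test_that("the cutoff rule is >= by default and > when strict", {
  m <- contrast_models()
  # 10 N residues at log2(5) bits each; cutoff exactly the window score
  sc <- round(10 * log2(5), 6)
  prot <- list(accession = "t", sequence = strrep("N", 10))
  p_ge <- scoring_params(window_length = 10, cutoff_bits = sc)
  p_gt <- scoring_params(window_length = 10, cutoff_bits = sc,
                         strict_greater = TRUE)
  expect_false(is.null(scan_protein(prot, m$prion, m$background, p_ge)))
  expect_null(scan_protein(prot, m$prion, m$background, p_gt))
})

test_that("qualifying windows merge into a single maximal call per protein", {
  m <- contrast_models()
  # two strong segments separated by 100 background-ish residues
  seqc <- paste0(strrep("N", 40), strrep("A", 100), strrep("Q", 40))
  call <- scan_protein(list(accession = "m", sequence = seqc),
                       m$prion, m$background,
                       scoring_params(window_length = 20, cutoff_bits = 30))
  expect_equal(nrow(call), 1)
  # the call covers one whole segment (plus the few flanking residues that
  # still clear the cutoff); the other appears in the diagnostics channel
  sec <- attr(call, "secondary")
  expect_false(is.null(sec))
  expect_equal(call$start, 1)
  expect_true(call$end >= 40 && call$end < 60)
  expect_true(sec$start > 120 && sec$start <= 141)
  expect_equal(sec$end, 180)
})

test_that("scan_proteome conserves per-organism counts and is deterministic", {
  set.seed(5)
  sp <- synthetic_proteome_params(n_proteins = 120, prd_fraction = 0.1,
                                  organisms = c("o1", "o2", "o3"), seed = 9)
  g <- generate_proteome(sp)
  s1 <- scan_proteome(g$proteome)
  s2 <- scan_proteome(g$proteome)
  expect_identical(s1$calls, s2$calls)
  expect_equal(sum(s1$per_organism$n_prd), nrow(s1$calls))
  expect_equal(sum(s1$per_organism$n_scanned), 120)
  expect_equal(s1$fraction_positive, nrow(s1$calls) / 120)
  expect_true(all(table(s1$calls$accession) == 1))  # one call per protein
  expect_error(scan_proteome(proteome_set(character(0), character(0))),
               "empty proteome")
})

test_that("a proteome without biased regions yields zero calls", {
  sp <- synthetic_proteome_params(n_proteins = 50, prd_fraction = 0, seed = 2)
  g <- generate_proteome(sp)
  s <- scan_proteome(g$proteome)
  expect_equal(nrow(s$calls), 0)
  expect_equal(s$fraction_positive, 0)
})

test_that("composition summary pools regions and excludes ambiguity codes", {
  one <- data.frame(region_sequence = "NNQQ", stringsAsFactors = FALSE)
  f <- composition_summary(one)
  expect_equal(unname(f[c("N", "Q")]), c(0.5, 0.5))
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_equal(unname(f["A"]), 0)
  withx <- data.frame(region_sequence = c("NNQQ", "XXBB"),
                      stringsAsFactors = FALSE)
  expect_equal(composition_summary(withx), f)  # X/B drop out entirely
  expect_error(composition_summary(data.frame(region_sequence = character())),
               "no calls")
})

test_that("calls round-trip through the TSV writer", {
  sp <- synthetic_proteome_params(n_proteins = 60, prd_fraction = 0.2,
                                  seed = 4)
  s <- scan_proteome(generate_proteome(sp)$proteome)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_calls(s, path)
  back <- read_calls(path)
  expect_equal(back$accession, s$calls$accession)
  expect_equal(back$score_bits, s$calls$score_bits)
})

test_that("prd_localization classifies calls against domain architectures", {
  dm <- domains_df(rep("p1", 2), c("D1", "D2"), c(100, 300), c(200, 400))
  ann <- make_annotations("p1", domains = dm)
  arch <- domain_architecture(ann, "p1")
  loc <- function(s, e) {
    prd_localization(data.frame(accession = "p1", start = s, end = e), arch)
  }
  expect_equal(loc(5, 70), "N-terminal")
  expect_equal(loc(210, 280), "inter-domain")
  expect_equal(loc(420, 480), "C-terminal")
  expect_equal(loc(150, 250), "overlapping")
  no_dom <- domain_architecture(make_annotations("p2"), "p2")
  expect_equal(
    prd_localization(data.frame(accession = "p2", start = 1, end = 50),
                     no_dom), "undomained")
  expect_error(
    prd_localization(data.frame(accession = "p9", start = 1, end = 50), arch),
    "accession mismatch")
})
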