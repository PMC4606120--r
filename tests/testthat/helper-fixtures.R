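# Shared fixtures and independent oracles, built in code at test time.

# Strong-contrast models whose probabilities are (near-)exactly the stated
# values: a vanishing pseudocount keeps hand arithmetic valid.
exact_model <- function(probs) composition_model(probs, pseudocount = 1e-12)

contrast_models <- function() {
  list(prion = exact_model(c(N = 0.25, Q = 0.25, A = 0.25, C = 0.25)),
       background = exact_model(c(N = 0.05, Q = 0.05, A = 0.45, C = 0.45)))
}

write_tmp_fasta <- function(text) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(text, path)
  path
}

# A small hand-assembled annotation table.
make_annotations <- function(accession, go = NULL, domains = NULL, ...) {
  annotation_table(accession, go_terms = go, domains = domains, ...)
}

domains_df <- function(accession, pfam_id, start, end) {
  data.frame(accession = accession, pfam_id = pfam_id,
             start = start, end = end, stringsAsFactors = FALSE)
}

# Independent brute-force hypergeometric upper tail:
# P[X >= n_l] by direct summation of choose() products over the support.
hyper_tail_oracle <- function(n_l, p_l, n_b, p_b) {
  k <- max(0, n_l):min(n_b, p_l)
  if (n_l > min(n_b, p_l)) return(0)
  sum(choose(n_b, k) * choose(p_b - n_b, p_l - k)) / choose(p_b, p_l)
}

# Independent BH step-up oracle: sort, q_(i) = p_(i) * m / i, enforce
# monotonicity from the largest down, cap at 1, restore input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(1, q)[order(o)]
}

# Classical BH rejection set at level alpha: indices of the k* smallest
# p-values where k* = max{k : p_(k) <= k * alpha / m}.
bh_reject_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= seq_len(m) * alpha / m)
  if (length(ok) == 0) return(integer(0))
  sort(o[seq_len(max(ok))])
}

random_contingency <- function() {
  p_b <- sample(50:5000, 1)
  p_l <- sample(1:p_b, 1)
  n_b <- sample(1:p_b, 1)
  n_l <- sample(0:min(p_l, n_b), 1)
  term_contingency("t", n_l, p_l, n_b, p_b)
}
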