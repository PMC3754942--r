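# independent brute-force oracles used across the suite

# IUPAC expansion by nested loops over the full base alphabet
oracle_expand <- function(codon) {
  iupac <- list(
    a = "A", c = "C", g = "G", t = "T",
    r = c("A", "G"), y = c("C", "T"), s = c("C", "G"), w = c("A", "T"),
    k = c("G", "T"), m = c("A", "C"),
    b = c("C", "G", "T"), d = c("A", "G", "T"), h = c("A", "C", "T"),
    v = c("A", "C", "G"), n = c("A", "C", "G", "T")
  )
  sym <- strsplit(tolower(codon), "")[[1]]
  out <- character(0)
  for (b1 in iupac[[sym[1]]])
    for (b2 in iupac[[sym[2]]])
      for (b3 in iupac[[sym[3]]])
        out <- c(out, paste0(b1, b2, b3))
  sort(out)
}

# translation through Biostrings' genetic code table (independent of the
# package's hard-coded table)
oracle_translate <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

# residue distribution of an equimolar degenerate codon, stops dropped
oracle_distribution <- function(codon) {
  aa <- oracle_translate(oracle_expand(codon))
  aa <- aa[aa != "*"]
  tab <- table(aa)
  tibble::tibble(residue = names(tab), frequency = as.numeric(tab) / sum(tab))
}

# free-receptor concentration in the ternary competition system via the cubic
# polynomial in free M (independent of the package's uniroot solver)
oracle_ternary_free <- function(m_tot, a_tot, b_tot, ka_a, ka_b) {
  # M (1 + KaA At/(1+KaA M) + KaB Bt/(1+KaB M)) = Mt, cleared denominators:
  # KaA KaB M^3
  #   + (KaA + KaB + KaA KaB (At + Bt - Mt)) M^2
  #   + (1 + KaA (At - Mt) + KaB (Bt - Mt)) M - Mt = 0
  co <- c(-m_tot,
          1 + ka_a * (a_tot - m_tot) + ka_b * (b_tot - m_tot),
          ka_a + ka_b + ka_a * ka_b * (a_tot + b_tot - m_tot),
          ka_a * ka_b)
  r <- polyroot(co)
  r <- Re(r[abs(Im(r)) < 1e-8 * max(1, abs(Re(r)))])
  r <- r[r >= -1e-15 & r <= m_tot * (1 + 1e-12)]
  max(min(r, m_tot), 0)
}

# exhaustive best coverage over all subsets of a fixed size
oracle_best_coverage <- function(sets, budget) {
  idx <- utils::combn(length(sets), budget, simplify = FALSE)
  max(vapply(idx, function(i) length(unique(unlist(sets[i]))), integer(1)))
}

random_collection <- function(n, seed) {
  set.seed(seed)
  aas <- c("A", "D", "E", "G", "K", "L", "P", "R", "S", "V")
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(aas, 31, replace = TRUE), collapse = "")
  }, character(1))
  repeat_collection(seqs)
}
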