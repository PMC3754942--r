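#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange group_by summarise mutate filter select bind_rows
#'   left_join ungroup count desc across
#' @importFrom purrr map map_chr map_dbl map_lgl map2 pmap imap reduce
#' @importFrom stringr str_split str_to_upper str_to_lower str_detect str_sub
NULL

# IUPAC nucleotide ambiguity alphabet -> concrete DNA bases
.iupac <- list(
  a = "A", c = "C", g = "G", t = "T",
  r = c("A", "G"), y = c("C", "T"), s = c("C", "G"), w = c("A", "T"),
  k = c("G", "T"), m = c("A", "C"),
  b = c("C", "G", "T"), d = c("A", "G", "T"), h = c("A", "C", "T"),
  v = c("A", "C", "G"), n = c("A", "C", "G", "T")
)

# standard genetic code, DNA codons; "*" marks stop
.genetic_code <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

#' Amino-acid one-letter alphabet
#'
#' The 20 standard residues in alphabetical one-letter order.
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

.check_degenerate_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || is.na(codon)) {
    abort("`codon` must be a single string of three IUPAC symbols.")
  }
  sym <- str_split(str_to_lower(codon), "")[[1]]
  if (length(sym) != 3L) {
    abort(sprintf("degenerate codon '%s' must have exactly 3 symbols, got %d",
                  codon, length(sym)))
  }
  bad <- setdiff(sym, names(.iupac))
  if (length(bad) > 0L) {
    abort(sprintf("invalid IUPAC symbol(s) '%s' in degenerate codon '%s'",
                  paste(unique(bad), collapse = "', '"), codon))
  }
  sym
}

#' Expand a degenerate codon into its concrete codons
#'
#' A degenerate codon is three IUPAC nucleotide ambiguity symbols (e.g. `"vnk"`);
#' it stands for an equimolar pool of every concrete codon matching the pattern.
#'
#' @param codon Single string, three IUPAC symbols (case-insensitive).
#' @return Character vector of distinct upper-case DNA codons; length equals the
#'   product of the per-symbol base counts (1 to 64).
#' @examples
#' expand_degenerate_codon("vnk")  # 3 x 4 x 2 = 24 codons
#' expand_degenerate_codon("tgg")  # "TGG"
#' @export
expand_degenerate_codon <- function(codon) {
  sym <- .check_degenerate_codon(codon)
  bases <- lapply(sym, function(s) .iupac[[s]])
  grid <- expand.grid(b3 = bases[[3]], b2 = bases[[2]], b1 = bases[[1]],
                      stringsAsFactors = FALSE)
  sort(paste0(grid$b1, grid$b2, grid$b3))
}

.check_stop_policy <- function(policy) {
  match.arg(policy, c("drop-renormalize", "error", "amber-as-Gln"))
}

#' Translate a degenerate codon to a residue distribution
#'
#' Each concrete codon in the equimolar expansion is translated with the
#' standard genetic code. Stop codons are handled by `policy`:
#' `"drop-renormalize"` (default) removes all stops and renormalises;
#' `"error"` fails, listing the stop codons; `"amber-as-Gln"` reads TAG as
#' glutamine (amber suppression in supE hosts) while TAA/TGA are still dropped.
#'
#' @param codon Single degenerate codon string.
#' @param policy Stop-codon policy (see above).
#' @return Tibble with columns `residue` and `frequency` (sums to 1), one row
#'   per residue in the support, sorted by residue.
#' @examples
#' translate_degenerate_codon("raa")  # K and E, 0.5 each
#' translate_degenerate_codon("dhk")  # the 13-residue N-cap set, amber dropped
#' @export
translate_degenerate_codon <- function(codon, policy = "drop-renormalize") {
  policy <- .check_stop_policy(policy)
  codons <- expand_degenerate_codon(codon)
  aa <- unname(.genetic_code[codons])
  if (policy == "error" && any(aa == "*")) {
    abort(sprintf("degenerate codon '%s' encodes stop codon(s): %s",
                  codon, paste(codons[aa == "*"], collapse = ", ")))
  }
  if (policy == "amber-as-Gln") {
    aa[codons == "TAG"] <- "Q"
  }
  keep <- aa != "*"
  if (!any(keep)) {
    abort(sprintf("degenerate codon '%s' encodes only stop codons", codon))
  }
  tab <- table(aa[keep])
  tibble(residue = names(tab),
         frequency = as.numeric(tab) / sum(tab)) |>
    arrange(.data$residue)
}

.as_distribution <- function(x, what = "distribution") {
  if (!is.data.frame(x) || !all(c("residue", "frequency") %in% names(x))) {
    abort(sprintf("%s must be a data frame with columns residue, frequency", what))
  }
  x <- as_tibble(x)[, c("residue", "frequency")]
  if (any(x$frequency < 0)) abort(sprintf("%s has negative frequencies", what))
  tot <- sum(x$frequency)
  if (tot <= 0) abort(sprintf("%s has zero total mass", what))
  x |>
    group_by(.data$residue) |>
    summarise(frequency = sum(.data$frequency) / tot, .groups = "drop") |>
    arrange(.data$residue)
}

#' Residue distribution of a weighted cassette mixture
#'
#' Cassettes (degenerate codons mixed at chosen proportions) yield, per
#' position, the weight-average of each cassette's translated distribution.
#' Weights are normalised internally; the result is invariant to rescaling.
#'
#' @param codons Character vector of degenerate codons, one per cassette.
#' @param weights Numeric vector of non-negative mixing weights (sum > 0);
#'   defaults to equimolar cassettes.
#' @param policy Stop-codon policy passed to [translate_degenerate_codon()].
#' @return Tibble with columns `residue`, `frequency` summing to 1.
#' @export
mixture_distribution <- function(codons, weights = NULL, policy = "drop-renormalize") {
  if (length(codons) == 0L) abort("empty cassette list")
  if (is.null(weights)) weights <- rep(1, length(codons))
  if (length(weights) != length(codons)) {
    abort("`weights` must match `codons` in length")
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    abort("weights must be non-negative with positive sum")
  }
  w <- weights / sum(weights)
  purrr::map2(codons, w, function(cd, wi) {
    translate_degenerate_codon(cd, policy) |>
      mutate(frequency = .data$frequency * wi)
  }) |>
    bind_rows() |>
    .as_distribution("mixture")
}

# total-variation distance between two residue/frequency tibbles
.tv_distance <- function(p, q) {
  m <- dplyr::full_join(.as_distribution(p, "p"), .as_distribution(q, "q"),
                        by = "residue", suffix = c("_p", "_q"))
  m[is.na(m)] <- 0
  sum(abs(m$frequency_p - m$frequency_q)) / 2
}

#' Total-variation distance between residue distributions
#'
#' @param p,q Tibbles with columns `residue`, `frequency`.
#' @return Numeric in `[0, 1]`.
#' @export
tv_distance <- function(p, q) .tv_distance(p, q)
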