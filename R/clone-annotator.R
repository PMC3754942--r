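# fixed back-translation table (one codon per residue); Arg/Leu codons chosen
# so consecutive Arg-Leu encodes the BsmBI-like assembly site CGTCTC
.back_codon <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
  H = "CAT", I = "ATT", K = "AAA", L = "CTC", M = "ATG", N = "AAT",
  P = "CCG", Q = "CAG", R = "CGT", S = "TCT", T = "ACC", V = "GTT",
  W = "TGG", Y = "TAT"
)

#' Scaffold specification for clone annotation
#'
#' Describes the repeat-protein scaffold a clone is parsed against: N-cap
#' consensus, 31-residue internal-module consensus, C-cap consensus, the six
#' variable positions, the per-segment mismatch tolerance at non-variable
#' positions, and (optionally) the DNA-level assembly restriction site
#' expected inside each module.
#'
#' @param ncap,module,ccap Consensus residue strings; `module` must be 31
#'   residues.
#' @param var_pos Variable positions within the module (and, for the default
#'   layout, within the equally long N-cap).
#' @param max_mismatch Maximum tolerated mismatch fraction per segment at the
#'   non-variable positions (default 0.2).
#' @param restriction_site DNA string expected once per module span, or `NULL`
#'   to skip the check.
#' @return A `scaffold_spec` list.
#' @export
scaffold_spec <- function(ncap, module, ccap,
                          var_pos = variable_positions(),
                          max_mismatch = 0.2,
                          restriction_site = NULL) {
  if (nchar(module) != .module_length) {
    abort(sprintf("module consensus must be %d residues, got %d",
                  .module_length, nchar(module)))
  }
  if (any(var_pos < 1L | var_pos > nchar(module))) {
    abort("variable positions must lie within the module")
  }
  structure(list(ncap = str_to_upper(ncap), module = str_to_upper(module),
                 ccap = str_to_upper(ccap), var_pos = as.integer(var_pos),
                 max_mismatch = max_mismatch,
                 restriction_site = restriction_site),
            class = "scaffold_spec")
}

#' Default synthetic scaffold
#'
#' A shipped synthetic stand-in for the (unpublished) repeat-protein scaffold
#' consensus: a 31-residue N-cap sharing the module's variable-position
#' layout, a 31-residue internal module whose positions 2-3 (Arg-Leu) carry
#' the CGTCTC assembly restriction site at the DNA level, and a 25-residue
#' C-cap. Intended for fixtures and simulations, not as real sequence data.
#'
#' @return A `scaffold_spec`.
#' @export
default_scaffold <- function() {
  scaffold_spec(
    ncap   = "MRLSPEDAELAARHGDEVSALLAEAKAGDAA",
    module = "ARLELAIALEKAGDEVAALLIAALAADEAEV",
    ccap   = "GRLDEAAEVLREAFEAQQRDPQSGR",
    restriction_site = "CGTCTC"
  )
}

.segment_mismatch <- function(observed, consensus, var_pos = integer(0)) {
  a <- str_split(observed, "")[[1]]
  b <- str_split(consensus, "")[[1]]
  fixed <- setdiff(seq_along(b), var_pos)
  if (length(fixed) == 0L) return(0)
  mean(a[fixed] != b[fixed])
}

#' Annotate a clone protein sequence against a scaffold
#'
#' Segments the sequence into N-cap, k internal 31-residue modules and C-cap
#' by exact length arithmetic (caps anchored at the sequence ends), verifies
#' each segment against its consensus at the non-variable positions, and
#' extracts the residues at the variable positions into a per-motif table.
#'
#' @param sequence Clone protein sequence (one-letter residues).
#' @param spec A [scaffold_spec()].
#' @return A `clone_annotation` list: `n_motifs` (k), `table` (tibble with
#'   one row for the N-cap plus one per motif; columns `motif`, `pos18`,
#'   `pos19`, `pos22`, `pos23`, `pos26`, `pos30`), `spans` (segment
#'   coordinates), `mismatch` (per-segment mismatch fractions).
#' @export
annotate_protein <- function(sequence, spec = default_scaffold()) {
  sequence <- str_to_upper(sequence)
  if (str_detect(sequence, "[^A-Z]")) abort("sequence must be residue letters")
  n_len <- nchar(spec$ncap); c_len <- nchar(spec$ccap)
  rem <- nchar(sequence) - n_len - c_len
  if (rem < 0 || rem %% .module_length != 0) {
    abort(sprintf(paste0("sequence length %d does not fit |N-cap| + 31k + ",
                         "|C-cap| = %d + 31k + %d for any k >= 0"),
                  nchar(sequence), n_len, c_len))
  }
  k <- rem %/% .module_length
  spans <- tibble(
    segment = c("N-cap", if (k > 0) paste0("module_", seq_len(k)), "C-cap"),
    start = c(1, if (k > 0) n_len + 1 + .module_length * (seq_len(k) - 1),
              n_len + .module_length * k + 1),
    end = c(n_len, if (k > 0) n_len + .module_length * seq_len(k),
            nchar(sequence))
  )
  seg_seq <- str_sub(sequence, spans$start, spans$end)
  cons <- c(spec$ncap, rep(spec$module, k), spec$ccap)
  varp <- purrr::map(seq_len(k + 2L), function(i) {
    if (i == k + 2L) integer(0) else spec$var_pos  # caps: N-cap shares layout
  })
  mism <- purrr::pmap_dbl(list(seg_seq, cons, varp), .segment_mismatch)
  if (any(mism > spec$max_mismatch)) {
    worst <- which.max(mism)
    abort(sprintf("segment %s mismatches consensus at %.0f%% of fixed positions (threshold %.0f%%)",
                  spans$segment[worst], 100 * mism[worst],
                  100 * spec$max_mismatch))
  }
  rows <- purrr::map(seq_len(k + 1L), function(i) {
    calls <- str_sub(seg_seq[i], spec$var_pos, spec$var_pos)
    stats::setNames(as.list(calls), paste0("pos", spec$var_pos))
  })
  table <- bind_rows(purrr::map(rows, as_tibble)) |>
    mutate(motif = c("N-cap", if (k > 0) as.character(seq_len(k))),
           .before = 1)
  structure(list(n_motifs = k, table = table, spans = spans,
                 mismatch = stats::setNames(mism, spans$segment)),
            class = "clone_annotation")
}

#' @export
print.clone_annotation <- function(x, ...) {
  cat(sprintf("clone annotation: %d internal motif(s)\n", x$n_motifs))
  print(x$table)
  invisible(x)
}

#' Generate a fixture clone consistent with a scaffold
#'
#' Builds protein and DNA sequences for a clone with the requested residues at
#' the variable positions, back-translated with a fixed codon table (so the
#' DNA is reproducible; `seed` is accepted for interface symmetry with the
#' stochastic generators but the construction is deterministic).
#'
#' @param spec A [scaffold_spec()].
#' @param ncap_residues Character vector, one residue per variable position of
#'   the N-cap (default: the consensus residues).
#' @param modules A matrix/data frame with one row per internal module and one
#'   column per variable position (k rows, 6 columns), or `NULL` for k = 0.
#' @param seed Ignored (deterministic); kept for interface consistency.
#' @return List with `protein` and `dna` strings and `n_motifs`.
#' @export
generate_fixture_clone <- function(spec = default_scaffold(),
                                   ncap_residues = NULL, modules = NULL,
                                   seed = 1L) {
  fill <- function(consensus, residues) {
    s <- str_split(consensus, "")[[1]]
    if (!is.null(residues)) {
      residues <- as.character(unlist(residues))
      if (length(residues) != length(spec$var_pos)) {
        abort(sprintf("expected %d variable residues per segment, got %d",
                      length(spec$var_pos), length(residues)))
      }
      bad <- setdiff(residues, amino_acids())
      if (length(bad)) abort(sprintf("invalid residue(s): %s",
                                     paste(bad, collapse = ", ")))
      s[spec$var_pos] <- residues
    }
    paste(s, collapse = "")
  }
  ncap <- fill(spec$ncap, ncap_residues)
  mods <- character(0)
  if (!is.null(modules)) {
    modules <- as.matrix(as.data.frame(modules))
    mods <- apply(modules, 1, function(r) fill(spec$module, r))
  }
  protein <- paste0(ncap, paste(mods, collapse = ""), spec$ccap)
  dna <- paste(.back_codon[str_split(protein, "")[[1]]], collapse = "")
  list(protein = protein, dna = dna, n_motifs = length(mods))
}

#' Check the reading frame of clone DNA
#'
#' Verifies that the DNA is a clean open reading frame for the scaffold:
#' length a multiple of 3, module-region length consistent with an integer
#' number of modules, no in-frame stop codons, and (when the spec carries a
#' restriction site) one intact site per module span.
#'
#' @param dna DNA string over A/C/G/T.
#' @param spec A [scaffold_spec()].
#' @return A `frame_report` list: `length_ok`, `n_motifs` (NA when the length
#'   equation has no solution), `stop_positions` (codon indices of in-frame
#'   stops), `site_ok`, `in_frame` (overall verdict).
#' @export
check_reading_frame <- function(dna, spec = default_scaffold()) {
  dna <- str_to_upper(dna)
  if (str_detect(dna, "[^ACGT]")) {
    bad <- unique(str_split(gsub("[ACGT]", "", dna), "")[[1]])
    abort(sprintf("non-DNA character(s): %s", paste(bad, collapse = ", ")))
  }
  mod3 <- nchar(dna) %% 3L == 0L
  n_len <- nchar(spec$ncap); c_len <- nchar(spec$ccap)
  rem_aa <- nchar(dna) / 3 - n_len - c_len
  k <- if (mod3 && rem_aa >= 0 && rem_aa %% .module_length == 0) {
    as.integer(rem_aa / .module_length)
  } else NA_integer_
  stops <- integer(0)
  if (mod3) {
    codons <- substring(dna, seq(1, nchar(dna) - 2, 3), seq(3, nchar(dna), 3))
    aa <- unname(.genetic_code[codons])
    stops <- which(aa == "*")
  }
  site_ok <- TRUE
  if (!is.null(spec$restriction_site) && !is.na(k) && k > 0) {
    site_ok <- all(vapply(seq_len(k), function(i) {
      from <- 3 * (n_len + .module_length * (i - 1)) + 1
      to <- 3 * (n_len + .module_length * i)
      str_detect(str_sub(dna, from, to), stringr::fixed(spec$restriction_site))
    }, logical(1)))
  }
  verdict <- mod3 && !is.na(k) && length(stops) == 0L && site_ok
  structure(list(length_ok = mod3 && !is.na(k), n_motifs = k,
                 stop_positions = stops, site_ok = site_ok,
                 in_frame = verdict),
            class = "frame_report")
}

#' @export
print.frame_report <- function(x, ...) {
  cat(sprintf("frame report: %s (motifs: %s, stops: %d, site: %s)\n",
              if (x$in_frame) "in frame" else "NOT in frame",
              ifelse(is.na(x$n_motifs), "no length solution", x$n_motifs),
              length(x$stop_positions),
              ifelse(x$site_ok, "intact", "corrupted")))
  invisible(x)
}

#' Annotate clones from a FASTA file into a variable-position table
#'
#' @param path FASTA of clone protein sequences.
#' @param spec A [scaffold_spec()].
#' @return Tibble with one row per motif of each clone: `clone`, `motif`,
#'   `pos18` ... `pos30`.
#' @export
annotate_fasta <- function(path, spec = default_scaffold()) {
  seqs <- Biostrings::readBStringSet(path)
  purrr::imap(as.list(as.character(seqs)), function(s, nm) {
    ann <- annotate_protein(s, spec)
    mutate(ann$table, clone = nm, .before = 1)
  }) |>
    bind_rows()
}
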