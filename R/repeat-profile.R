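#' Variable positions of the 31-residue internal repeat module
#'
#' The six surface positions randomised to form the binding surface.
#' @return Integer vector `c(18, 19, 22, 23, 26, 30)`.
#' @export
variable_positions <- function() c(18L, 19L, 22L, 23L, 26L, 30L)

.module_length <- 31L

.check_collection <- function(collection) {
  if (!is.data.frame(collection) || !"sequence" %in% names(collection)) {
    abort("a repeat collection is a data frame with a `sequence` column")
  }
  if (nrow(collection) == 0L) abort("empty repeat collection")
  len <- unique(nchar(collection$sequence))
  if (length(len) != 1L) {
    abort("all aligned modules must have the same length")
  }
  invisible(as_tibble(collection))
}

#' Build a repeat collection from aligned module strings
#'
#' @param sequences Character vector of aligned module sequences (gap `"-"`
#'   allowed), all the same length (default alignment length 31).
#' @param id Optional identifiers; defaults to `mod_1 ... mod_n`.
#' @return Tibble with columns `id`, `sequence`, `indels` (number of gap
#'   characters in that module's row).
#' @export
repeat_collection <- function(sequences, id = NULL) {
  if (length(sequences) == 0L) abort("empty repeat collection")
  if (is.null(id)) id <- paste0("mod_", seq_along(sequences))
  out <- tibble(id = as.character(id),
                sequence = str_to_upper(sequences),
                indels = stringr::str_count(.data$sequence, stringr::fixed("-")))
  .check_collection(out)
  out
}

#' Read an aligned repeat collection from FASTA
#'
#' @param path Path to an aligned FASTA file (gaps `"-"`).
#' @return A repeat collection tibble (see [repeat_collection()]).
#' @export
read_repeat_collection <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  repeat_collection(as.character(seqs), id = names(seqs))
}

#' Write an aligned repeat collection to FASTA
#'
#' @param collection Repeat collection tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeat_collection <- function(collection, path) {
  collection <- .check_collection(collection)
  lines <- as.vector(rbind(paste0(">", collection$id), collection$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Curate a collection by indel count
#'
#' Removes modules whose aligned row carries more than `max_indels` gap
#' characters; the natural-collection curation rule (threshold three).
#'
#' @param collection Repeat collection tibble.
#' @param max_indels Maximum tolerated gaps per module (default 3).
#' @return The retained subset, original order preserved.
#' @export
curate_collection <- function(collection, max_indels = 3L) {
  collection <- .check_collection(collection)
  if (max_indels < 0) abort("`max_indels` must be >= 0")
  if (!"indels" %in% names(collection)) {
    collection$indels <- stringr::str_count(collection$sequence, stringr::fixed("-"))
  }
  dplyr::filter(collection, .data$indels <= max_indels)
}

#' Per-position residue frequencies of a collection
#'
#' Empirical marginal distribution at one aligned position; gap-bearing rows
#' are excluded from the denominator at that position.
#'
#' @param collection Repeat collection tibble.
#' @param position 1-based position within the aligned module.
#' @return Tibble with columns `position`, `residue`, `frequency`.
#' @export
position_frequencies <- function(collection, position) {
  collection <- .check_collection(collection)
  len <- nchar(collection$sequence[1])
  if (position < 1L || position > len) {
    abort(sprintf("position %d outside module length %d", position, len))
  }
  res <- str_sub(collection$sequence, position, position)
  res <- res[res != "-"]
  if (length(res) == 0L) abort(sprintf("all-gap column at position %d", position))
  tab <- table(res)
  tibble(position = as.integer(position),
         residue = names(tab),
         frequency = as.numeric(tab) / sum(tab)) |>
    arrange(.data$residue)
}

#' Dipeptide frequencies at an adjacent position pair
#'
#' Joint empirical frequency of the ordered residue pair observed at two
#' aligned positions (18-19 or 22-23 for the repeat scaffold, but any in-range
#' pair is accepted). Rows with a gap at either position are excluded.
#'
#' @param collection Repeat collection tibble.
#' @param pair Integer vector of two positions, e.g. `c(18, 19)`.
#' @return Tibble with columns `pos_a`, `pos_b`, `res_a`, `res_b`,
#'   `dipeptide`, `frequency`, `rank` (ties broken lexicographically on the
#'   dipeptide), sorted by rank.
#' @export
dipeptide_frequencies <- function(collection, pair) {
  collection <- .check_collection(collection)
  if (length(pair) != 2L) abort("`pair` must give two positions")
  len <- nchar(collection$sequence[1])
  if (any(pair < 1L | pair > len)) {
    abort(sprintf("positions (%s) outside module length %d",
                  paste(pair, collapse = ", "), len))
  }
  a <- str_sub(collection$sequence, pair[1], pair[1])
  b <- str_sub(collection$sequence, pair[2], pair[2])
  keep <- a != "-" & b != "-"
  if (!any(keep)) abort("no gap-free observations at this position pair")
  dp <- paste0(a[keep], b[keep])
  tab <- table(dp)
  out <- tibble(pos_a = as.integer(pair[1]), pos_b = as.integer(pair[2]),
                dipeptide = names(tab),
                frequency = as.numeric(tab) / sum(tab)) |>
    mutate(res_a = str_sub(.data$dipeptide, 1, 1),
           res_b = str_sub(.data$dipeptide, 2, 2)) |>
    arrange(desc(.data$frequency), .data$dipeptide) |>
    mutate(rank = dplyr::row_number()) |>
    select("pos_a", "pos_b", "res_a", "res_b", "dipeptide", "frequency", "rank")
  out
}

#' Top-N dipeptides of a dipeptide table
#'
#' @param table Output of [dipeptide_frequencies()].
#' @param n Number of highest-frequency pairs to return (ties broken
#'   lexicographically); must not exceed the number of distinct pairs.
#' @return Character vector of `n` dipeptides.
#' @export
top_dipeptides <- function(table, n) {
  if (n > nrow(table)) {
    abort(sprintf("requested top %d of only %d distinct dipeptides", n, nrow(table)))
  }
  table$dipeptide[order(table$rank)][seq_len(n)]
}

#' Stylized default position profiles for the synthetic collection generator
#'
#' Position-specific residue distributions emulating the qualitative trends of
#' the natural repeat family at the six variable positions: proline commonest
#' at 18 and absent from 22 through 30, small side chains favoured at 23, large
#' polar residues at 30. These are synthetic stand-ins for the (unpublished)
#' natural collection, not measured frequencies.
#'
#' @return Tibble with columns `position`, `residue`, `frequency`; frequencies
#'   sum to 1 within each position.
#' @export
default_position_profiles <- function() {
  spec <- list(
    `18` = c(P = 0.22, A = 0.13, S = 0.11, T = 0.09, D = 0.08, E = 0.07,
             G = 0.06, V = 0.06, K = 0.05, R = 0.04, L = 0.04, Y = 0.03, W = 0.02),
    `19` = c(A = 0.14, Y = 0.12, S = 0.11, E = 0.10, L = 0.09, Q = 0.08,
             N = 0.07, T = 0.07, F = 0.06, R = 0.06, D = 0.05, G = 0.03, W = 0.02),
    `22` = c(R = 0.14, L = 0.12, K = 0.11, E = 0.10, A = 0.09, S = 0.09,
             Q = 0.08, T = 0.07, I = 0.06, Y = 0.05, V = 0.04, F = 0.03, W = 0.02),
    `23` = c(A = 0.20, S = 0.16, T = 0.13, G = 0.11, V = 0.09, N = 0.08,
             D = 0.07, E = 0.06, R = 0.04, Q = 0.03, L = 0.03),
    `26` = c(L = 0.15, A = 0.12, V = 0.11, E = 0.10, R = 0.09, T = 0.08,
             S = 0.08, D = 0.07, Q = 0.06, W = 0.05, Y = 0.05, K = 0.04),
    `30` = c(E = 0.30, K = 0.26, Q = 0.18, R = 0.10, D = 0.07, N = 0.05, S = 0.04)
  )
  purrr::imap(spec, function(fr, pos) {
    tibble(position = as.integer(pos), residue = names(fr),
           frequency = unname(fr) / sum(fr))
  }) |>
    bind_rows() |>
    arrange(.data$position, .data$residue)
}

#' Generate a synthetic aligned repeat collection
#'
#' Draws `n` aligned 31-residue modules whose residues at the variable
#' positions follow the supplied per-position distributions; non-variable
#' positions take a fixed consensus. Adjacent variable pairs (18-19 and 22-23)
#' can be correlated: with probability `coupling` a pair is drawn jointly from
#' `dipeptide_spec`, otherwise independently from the marginals.
#'
#' @param n Number of modules (>= 1).
#' @param profiles Tibble `position`, `residue`, `frequency`
#'   (default [default_position_profiles()]); each position must sum to 1
#'   within `1e-6`.
#' @param coupling Probability in `[0, 1]` of drawing an adjacent pair from the
#'   joint table (default 0, independent positions).
#' @param dipeptide_spec Optional named list of joint tables, names `"18-19"`
#'   and/or `"22-23"`, each a tibble `dipeptide`, `frequency`.
#' @param consensus Fixed 31-residue consensus for the non-variable positions.
#' @param seed Integer seed; the collection is reproducible given the seed.
#' @return A repeat collection tibble.
#' @export
generate_synthetic_collection <- function(n,
                                          profiles = default_position_profiles(),
                                          coupling = 0,
                                          dipeptide_spec = NULL,
                                          consensus = default_scaffold()$module,
                                          seed = 1L) {
  if (n < 1L) abort("`n` must be >= 1")
  if (coupling < 0 || coupling > 1) abort("`coupling` must be in [0, 1]")
  profiles <- as_tibble(profiles)
  sums <- profiles |>
    group_by(.data$position) |>
    summarise(s = sum(.data$frequency), .groups = "drop")
  if (any(abs(sums$s - 1) > 1e-6)) {
    abort("each position's profile must be normalised to 1")
  }
  vp <- sort(unique(profiles$position))
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    code
  }
  draw_pos <- function(pos, k) {
    p <- profiles[profiles$position == pos, ]
    sample(p$residue, k, replace = TRUE, prob = p$frequency)
  }
  withr_seed({
    calls <- matrix("", nrow = n, ncol = length(vp),
                    dimnames = list(NULL, as.character(vp)))
    for (pos in vp) calls[, as.character(pos)] <- draw_pos(pos, n)
    if (coupling > 0 && !is.null(dipeptide_spec)) {
      for (nm in names(dipeptide_spec)) {
        pp <- as.integer(str_split(nm, "-")[[1]])
        if (!all(as.character(pp) %in% colnames(calls))) next
        joint <- as_tibble(dipeptide_spec[[nm]])
        use <- stats::runif(n) < coupling
        if (any(use)) {
          dp <- sample(joint$dipeptide, sum(use), replace = TRUE,
                       prob = joint$frequency)
          calls[use, as.character(pp[1])] <- str_sub(dp, 1, 1)
          calls[use, as.character(pp[2])] <- str_sub(dp, 2, 2)
        }
      }
    }
    base <- str_split(consensus, "")[[1]]
    seqs <- vapply(seq_len(n), function(i) {
      s <- base
      s[vp] <- calls[i, ]
      paste(s, collapse = "")
    }, character(1))
    repeat_collection(seqs, id = sprintf("syn_%05d", seq_len(n)))
  })
}

#' Apply a per-residue multiplier to a target distribution
#'
#' Used to enrich aromatic side chains relative to their frequency in the
#' natural collection before cassette design; the enriched distribution is
#' renormalised.
#'
#' @param distribution Tibble `residue`, `frequency`.
#' @param multipliers Named numeric vector, e.g. `c(Y = 2, W = 2)`; residues
#'   not named keep multiplier 1.
#' @return Renormalised tibble `residue`, `frequency`.
#' @export
boost_residues <- function(distribution, multipliers) {
  d <- .as_distribution(distribution)
  m <- rep(1, nrow(d))
  hit <- d$residue %in% names(multipliers)
  m[hit] <- multipliers[d$residue[hit]]
  if (any(m < 0)) abort("multipliers must be non-negative")
  d$frequency <- d$frequency * m
  .as_distribution(d)
}

#' Plot per-position residue frequencies
#'
#' Bar chart of one or more position profiles, faceted by position; when a
#' second profile is supplied the two are dodged for comparison (e.g. natural
#' versus encoded frequencies).
#'
#' @param profiles Tibble `position`, `residue`, `frequency`.
#' @param comparison Optional second tibble with the same columns.
#' @param labels Length-2 labels for the two sources.
#' @return A ggplot object.
#' @export
plot_position_profiles <- function(profiles, comparison = NULL,
                                   labels = c("target", "achieved")) {
  profiles <- mutate(as_tibble(profiles), source = labels[1])
  if (!is.null(comparison)) {
    comparison <- mutate(as_tibble(comparison), source = labels[2])
    profiles <- bind_rows(profiles, comparison)
  }
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$residue, y = .data$frequency,
                               fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~position, scales = "free_x") +
    ggplot2::labs(x = "residue", y = "frequency", fill = NULL) +
    ggplot2::theme_minimal()
}
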