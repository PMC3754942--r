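#' Degenerate codon sets used to randomise the repeat variable positions
#'
#' The partially randomised codons used to encode side-chain diversity at the
#' adjacent variable-position pairs 18-19 and 22-23 of the internal module, and
#' the simpler N-cap codons (`vnk` for positions 18/19, `dht` for 22/23/26).
#' Position 30 is constrained by the assembly restriction site to Glu/Lys/Gln.
#'
#' @return Named list of character vectors: `pos18`, `pos19`, `pos22`, `pos23`,
#'   `pos30`, `ncap_18_19`, `ncap_22_23_26`.
#' @export
codon_sets <- function() {
  list(
    pos18 = c("hcc", "kac", "bcg", "gwa", "sgt", "ama", "ncg", "tgg", "ctg",
              "tac", "ccg"),
    pos19 = c("gma", "kcg", "cwg", "amc", "twc", "cgc", "gac", "tac", "ggt",
              "tgg"),
    pos22 = c("cgt", "raa", "kct", "cwg", "tac", "ttc", "tgg", "atc", "ayg",
              "gtt"),
    pos23 = c("ryt", "skt", "gma", "rmc", "sag", "mgc", "wct", "gcg", "ggt",
              "tcg", "cgt", "kct", "gct", "gaa", "aac"),
    pos30 = c("gaa", "aaa", "caa"),
    ncap_18_19 = "vnk",
    ncap_22_23_26 = "dht"
  )
}

.dipeptide_set <- function(codon_a, codon_b, policy) {
  da <- translate_degenerate_codon(codon_a, policy)
  db <- translate_degenerate_codon(codon_b, policy)
  as.vector(outer(da$residue, db$residue, paste0))
}

# joint dipeptide distribution of a codon-pair cassette (equimolar bases)
.dipeptide_distribution <- function(codon_a, codon_b, policy) {
  da <- translate_degenerate_codon(codon_a, policy)
  db <- translate_degenerate_codon(codon_b, policy)
  tibble(dipeptide = as.vector(outer(da$residue, db$residue, paste0)),
         frequency = as.vector(outer(da$frequency, db$frequency, `*`)))
}

#' Design constraints for cassette selection
#'
#' @param forbidden_a,forbidden_b Residues disallowed at the first/second
#'   position of the pair (cysteine is excluded everywhere by default; proline
#'   additionally at positions 22, 23, 26).
#' @param policy Stop-codon policy (see [translate_degenerate_codon()]).
#' @return A `design_constraints` list.
#' @export
design_constraints <- function(forbidden_a = "C", forbidden_b = "C",
                               policy = "drop-renormalize") {
  structure(list(forbidden_a = forbidden_a, forbidden_b = forbidden_b,
                 policy = .check_stop_policy(policy)),
            class = "design_constraints")
}

#' Enumerate candidate codon-pair cassettes
#'
#' All ordered pairs from two codon lists, each annotated with the dipeptide
#' set it encodes and whether it violates the forbidden-residue constraints.
#'
#' @param codons_a,codons_b Character vectors of degenerate codons for the
#'   first and second position of the pair.
#' @param constraints A [design_constraints()] object.
#' @return Tibble with columns `codon_a`, `codon_b`, `dipeptides` (list),
#'   `n_dipeptides`, `feasible`.
#' @export
enumerate_cassettes <- function(codons_a, codons_b,
                                constraints = design_constraints()) {
  if (length(codons_a) == 0L || length(codons_b) == 0L) {
    abort("codon lists must be non-empty")
  }
  res_a <- purrr::map(codons_a, ~ translate_degenerate_codon(.x, constraints$policy)$residue)
  res_b <- purrr::map(codons_b, ~ translate_degenerate_codon(.x, constraints$policy)$residue)
  grid <- expand.grid(ia = seq_along(codons_a), ib = seq_along(codons_b))
  out <- tibble(
    codon_a = codons_a[grid$ia],
    codon_b = codons_b[grid$ib],
    dipeptides = purrr::map2(grid$ia, grid$ib,
                             ~ as.vector(outer(res_a[[.x]], res_b[[.y]], paste0))),
    feasible = purrr::map2_lgl(grid$ia, grid$ib, function(i, j) {
      !any(res_a[[i]] %in% constraints$forbidden_a) &&
        !any(res_b[[j]] %in% constraints$forbidden_b)
    })
  ) |>
    mutate(n_dipeptides = purrr::map_int(.data$dipeptides, length)) |>
    arrange(.data$codon_a, .data$codon_b)
  out
}

# deterministic greedy weighted max-coverage + single-swap refinement
.select_max_coverage <- function(candidates, weight_of, budget) {
  n <- nrow(candidates)
  sets <- candidates$dipeptides
  key <- paste(candidates$codon_a, candidates$codon_b)
  coverage_gain <- function(set, covered) {
    new <- setdiff(set, covered)
    if (length(new) == 0L) 0 else sum(weight_of(new))
  }
  selected <- integer(0)
  covered <- character(0)
  for (step in seq_len(min(budget, n))) {
    gains <- vapply(seq_len(n), function(i) {
      if (i %in% selected) return(-Inf)
      coverage_gain(sets[[i]], covered)
    }, numeric(1))
    best <- which(gains == max(gains))
    best <- best[order(key[best])][1]          # lexicographic tie-break
    if (gains[best] <= 0 && length(selected) > 0) break
    selected <- c(selected, best)
    covered <- union(covered, sets[[best]])
  }
  total <- function(idx) {
    u <- unique(unlist(sets[idx]))
    sum(weight_of(u))
  }
  # single-swap local search until no swap improves weighted coverage
  repeat {
    improved <- FALSE
    base <- total(selected)
    for (si in seq_along(selected)) {
      rest <- selected[-si]
      outside <- setdiff(seq_len(n), selected)
      outside <- outside[order(key[outside])]
      for (cand in outside) {
        if (total(c(rest, cand)) > base + 1e-12) {
          selected[si] <- cand
          base <- total(selected)
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  selected
}

#' Select a budget-limited cassette library by maximum coverage
#'
#' Greedy selection maximising the number (mode `"max-coverage"`) or the
#' natural-frequency mass (mode `"target-weighted-coverage"`) of newly covered
#' dipeptides at each step, followed by single-swap local refinement until no
#' swap improves coverage. Deterministic: ties are broken lexicographically on
#' the cassette codon strings. Infeasible candidates (forbidden residues) are
#' never selected.
#'
#' @param candidates Output of [enumerate_cassettes()].
#' @param budget Maximum number of cassettes (>= 1).
#' @param mode `"max-coverage"` or `"target-weighted-coverage"`.
#' @param target For the weighted mode, a dipeptide table
#'   ([dipeptide_frequencies()]) supplying frequencies; dipeptides absent from
#'   it get weight 0.
#' @return A `cassette_library`: the selected candidate rows plus equal
#'   `weight`s, with attributes `covered` (the encoded dipeptide set).
#' @export
select_cassettes <- function(candidates, budget,
                             mode = c("max-coverage", "target-weighted-coverage"),
                             target = NULL) {
  mode <- match.arg(mode)
  if (budget < 1) abort("`budget` must be >= 1")
  feas <- dplyr::filter(candidates, .data$feasible)
  if (nrow(feas) == 0L) abort("no feasible candidate cassettes")
  weight_of <- if (mode == "max-coverage") {
    function(dp) rep(1, length(dp))
  } else {
    if (is.null(target)) abort("weighted mode needs a `target` dipeptide table")
    wts <- stats::setNames(target$frequency, target$dipeptide)
    function(dp) {
      w <- wts[dp]
      w[is.na(w)] <- 0
      unname(w)
    }
  }
  idx <- .select_max_coverage(feas, weight_of, budget)
  lib <- feas[idx, ]
  lib$weight <- rep(1 / nrow(lib), nrow(lib))
  structure(lib, covered = sort(unique(unlist(lib$dipeptides))),
            class = c("cassette_library", class(lib)))
}

#' Distinct dipeptides encoded by a cassette library
#'
#' @param library A `cassette_library`.
#' @return Character vector of dipeptides.
#' @export
encoded_dipeptides <- function(library) {
  sort(unique(unlist(library$dipeptides)))
}

# achieved dipeptide distribution of a weighted library
.achieved_distribution <- function(library, policy = "drop-renormalize") {
  w <- library$weight / sum(library$weight)
  purrr::pmap(list(library$codon_a, library$codon_b, w),
              function(a, b, wi) {
                .dipeptide_distribution(a, b, policy) |>
                  mutate(frequency = .data$frequency * wi)
              }) |>
    bind_rows() |>
    group_by(.data$dipeptide) |>
    summarise(frequency = sum(.data$frequency), .groups = "drop") |>
    arrange(.data$dipeptide)
}

# Euclidean projection onto the probability simplex (Duchi et al. style sort)
.project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

#' Fit cassette mixing weights to a target distribution
#'
#' Minimises the squared distance between the achieved (weight-averaged)
#' dipeptide distribution of a fixed cassette set and a target distribution,
#' over the probability simplex, by projected gradient descent with
#' backtracking line search (monotone in the objective; convergence tolerance
#' `1e-9` on the objective).
#'
#' @param library A `cassette_library`.
#' @param target Tibble `dipeptide`, `frequency` (normalised internally).
#' @param tol Convergence tolerance on the objective decrease.
#' @param max_iter Iteration cap.
#' @return The library with fitted `weight`s; attributes `achieved` (tibble of
#'   the achieved distribution), `objective` (final squared distance), and
#'   `irreducible_mass` (target mass on dipeptides outside the encodable
#'   support, reported with a warning when positive).
#' @export
optimize_weights <- function(library, target, tol = 1e-9, max_iter = 5000L) {
  target <- as_tibble(target)
  tgt <- target |>
    group_by(.data$dipeptide) |>
    summarise(frequency = sum(.data$frequency), .groups = "drop")
  tgt$frequency <- tgt$frequency / sum(tgt$frequency)
  dists <- purrr::map2(library$codon_a, library$codon_b,
                       ~ .dipeptide_distribution(.x, .y, "drop-renormalize"))
  support <- sort(unique(c(unlist(purrr::map(dists, "dipeptide")), tgt$dipeptide)))
  A <- vapply(dists, function(d) {
    v <- stats::setNames(rep(0, length(support)), support)
    v[d$dipeptide] <- v[d$dipeptide] + d$frequency
    v
  }, numeric(length(support)))
  A <- matrix(A, nrow = length(support), dimnames = list(support, NULL))
  t_vec <- stats::setNames(rep(0, length(support)), support)
  t_vec[tgt$dipeptide] <- tgt$frequency
  encodable <- rowSums(A) > 0
  irreducible <- sum(t_vec[!encodable])
  if (irreducible > 1e-12) {
    warn(sprintf("%.4f of target mass lies outside the encodable support",
                 irreducible))
  }
  obj <- function(w) sum((A %*% w - t_vec)^2)
  grad <- function(w) as.vector(2 * t(A) %*% (A %*% w - t_vec))
  w <- rep(1 / ncol(A), ncol(A))
  f <- obj(w)
  step <- 1
  for (it in seq_len(max_iter)) {
    g <- grad(w)
    repeat {
      w_new <- .project_simplex(w - step * g)
      f_new <- obj(w_new)
      if (f_new <= f + 1e-15 || step < 1e-14) break
      step <- step / 2
    }
    if (f - f_new < tol && it > 1) {
      w <- w_new; f <- f_new
      break
    }
    w <- w_new; f <- f_new
    step <- step * 1.5
  }
  library$weight <- w
  achieved <- tibble(dipeptide = support, frequency = as.vector(A %*% w)) |>
    dplyr::filter(.data$frequency > 0)
  structure(library, covered = attr(library, "covered"),
            achieved = achieved, objective = f,
            irreducible_mass = irreducible,
            class = class(library))
}

#' Coverage and divergence metrics of a cassette design
#'
#' @param library A `cassette_library` (weights used if fitted, else equal).
#' @param natural A dipeptide table from [dipeptide_frequencies()] over the
#'   same position pair.
#' @param n Size of the top-N natural dipeptide set (default 100, capped at
#'   the number of distinct natural pairs).
#' @return One-row tibble: `n_encoded` distinct encoded dipeptides,
#'   `top_n`, `top_n_covered` (encoded dipeptides among the top-N natural
#'   ones), `tv` total-variation and `kl` relative-entropy divergence between
#'   achieved and natural distributions.
#' @export
evaluate_design <- function(library, natural, n = 100L) {
  enc <- encoded_dipeptides(library)
  n_eff <- min(n, nrow(natural))
  top <- top_dipeptides(natural, n_eff)
  achieved <- .achieved_distribution(library)
  m <- dplyr::full_join(achieved,
                        natural[, c("dipeptide", "frequency")],
                        by = "dipeptide", suffix = c("_ach", "_nat"))
  m[is.na(m)] <- 0
  kl <- {
    p <- m$frequency_nat; q <- m$frequency_ach
    keep <- p > 0
    if (any(q[keep] == 0)) Inf else sum(p[keep] * log(p[keep] / q[keep]))
  }
  tibble(n_encoded = length(enc),
         top_n = n_eff,
         top_n_covered = length(intersect(enc, top)),
         tv = sum(abs(m$frequency_ach - m$frequency_nat)) / 2,
         kl = kl)
}

#' Plot achieved versus target dipeptide distribution
#'
#' @param library A weighted `cassette_library` (after [optimize_weights()]).
#' @param target Tibble `dipeptide`, `frequency`.
#' @param top_n Show only the `top_n` most frequent target dipeptides.
#' @return A ggplot object.
#' @export
plot_design_match <- function(library, target, top_n = 30L) {
  achieved <- .achieved_distribution(library)
  tgt <- as_tibble(target) |>
    arrange(desc(.data$frequency)) |>
    utils::head(top_n) |>
    mutate(source = "target")
  ach <- achieved |>
    dplyr::filter(.data$dipeptide %in% tgt$dipeptide) |>
    mutate(source = "achieved")
  dat <- bind_rows(tgt[, c("dipeptide", "frequency", "source")], ach)
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(.data$dipeptide, -.data$frequency),
                                    y = .data$frequency, fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "dipeptide", y = "frequency", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
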