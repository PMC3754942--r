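#' Configuration of the circle-assembly library simulator
#'
#' Describes the stochastic model of micro-gene polymerisation: the number of
#' internal repeats per clone is drawn from a repeat-number distribution; each
#' inserted module carries an independent frame-shift defect with probability
#' `eps_mod`; each cap is defective with probability `eps_cap`; the shuffling
#' step introduces fresh per-ligation defects with probability `eps_lig`.
#'
#' @param n_dist Either the string `"geometric"` (truncated geometric on
#'   `0:n_max` with success parameter chosen to give mean `n_mean`) or an
#'   explicit probability vector over `0:(length-1)`.
#' @param n_max Support cap for the geometric family (default 10).
#' @param n_mean Target mean repeat number for the geometric family
#'   (default 2).
#' @param eps_mod Per-module defect probability (default 0.2, the Lib2.0-like
#'   proportion of frame-shifted motifs).
#' @param eps_cap Per-cap defect probability (default 0).
#' @param eps_lig Per-ligation defect probability in the shuffling step
#'   (default 0.03, matching a 97% correct-motif final library).
#' @return An `assembly_config` list with the resolved probability vector
#'   `p_n` over `0:n_max`.
#' @export
assembly_config <- function(n_dist = "geometric", n_max = 10L, n_mean = 2,
                            eps_mod = 0.2, eps_cap = 0, eps_lig = 0.03) {
  for (e in c(eps_mod, eps_cap, eps_lig)) {
    if (e < 0 || e > 1) abort("defect probabilities must lie in [0, 1]")
  }
  if (is.character(n_dist)) {
    n_dist <- match.arg(n_dist, "geometric")
    # solve for the geometric ratio giving the requested truncated mean
    target <- n_mean
    mean_of <- function(r) {
      p <- r^(0:n_max)
      p <- p / sum(p)
      sum((0:n_max) * p)
    }
    if (target <= 0 || target >= n_max) abort("`n_mean` must be in (0, n_max)")
    r <- stats::uniroot(function(r) mean_of(r) - target,
                        c(1e-9, 1 - 1e-9), tol = 1e-12)$root
    p_n <- r^(0:n_max)
    p_n <- p_n / sum(p_n)
  } else {
    p_n <- as.numeric(n_dist)
    if (any(p_n < 0) || abs(sum(p_n) - 1) > 1e-9) {
      abort("explicit `n_dist` must be a probability vector summing to 1")
    }
    n_max <- length(p_n) - 1L
  }
  structure(list(p_n = p_n, n_max = n_max, eps_mod = eps_mod,
                 eps_cap = eps_cap, eps_lig = eps_lig),
            class = "assembly_config")
}

.check_population <- function(population) {
  need <- c("n_modules", "n_defective", "ncap_ok", "ccap_ok")
  if (!is.data.frame(population) || !all(need %in% names(population))) {
    abort("a clone population is a tibble with columns n_modules, n_defective, ncap_ok, ccap_ok")
  }
  as_tibble(population)
}

.in_frame <- function(population) {
  population$n_defective == 0 & population$ncap_ok & population$ccap_ok
}

#' Simulate a circle-assembly clone population
#'
#' Draws `n_clones` clones: repeat number from the configured distribution,
#' each module independently defective with `eps_mod`, caps defective with
#' `eps_cap`. A clone is in frame iff no defect anywhere.
#'
#' @param config An [assembly_config()].
#' @param n_clones Number of clones (>= 1).
#' @param seed Integer seed (reproducible populations).
#' @return Tibble with columns `clone`, `n_modules`, `n_defective`,
#'   `ncap_ok`, `ccap_ok`, `in_frame`.
#' @export
simulate_assembly <- function(config, n_clones, seed = 1L) {
  if (!inherits(config, "assembly_config")) abort("`config` must be an assembly_config")
  if (n_clones < 1) abort("`n_clones` must be >= 1")
  set.seed(seed)
  n_mod <- sample(0:config$n_max, n_clones, replace = TRUE, prob = config$p_n)
  n_def <- stats::rbinom(n_clones, n_mod, config$eps_mod)
  ncap_ok <- stats::runif(n_clones) >= config$eps_cap
  ccap_ok <- stats::runif(n_clones) >= config$eps_cap
  out <- tibble(clone = seq_len(n_clones), n_modules = n_mod,
                n_defective = n_def, ncap_ok = ncap_ok, ccap_ok = ccap_ok)
  out$in_frame <- .in_frame(out)
  out
}

#' Analytic in-frame fraction of the assembly model
#'
#' Exact closed form `(1 - eps_cap)^2 * sum_n p(n) (1 - eps_mod)^n`.
#'
#' @param config An [assembly_config()].
#' @return Numeric in `[0, 1]`.
#' @export
analytic_inframe <- function(config) {
  if (!inherits(config, "assembly_config")) abort("`config` must be an assembly_config")
  (1 - config$eps_cap)^2 *
    sum(config$p_n * (1 - config$eps_mod)^(0:config$n_max))
}

#' Retain only the in-frame clones (phage-display filtration)
#'
#' Mirrors the anti-tag capture step: only clones with a fully coding open
#' reading frame display the N-terminal tag and are retained.
#'
#' @param population A clone population tibble.
#' @return The in-frame subset (possibly empty, with a message).
#' @export
filter_inframe <- function(population) {
  population <- .check_population(population)
  out <- population[.in_frame(population), ]
  if (nrow(out) == 0L) message("filtration retained no clones")
  out
}

#' Shuffle pre-validated modules into a new library
#'
#' Re-assembles clones from the pooled (all-correct) modules of a filtered
#' population: fresh repeat-number draws from the configured distribution, each
#' module placement picking up a new ligation defect with probability
#' `eps_lig`. Caps are taken defect-free (they were validated by filtration).
#'
#' @param filtered A filtered (in-frame) clone population; must be non-empty.
#' @param config An [assembly_config()] supplying `p_n` and `eps_lig`.
#' @param n_clones Number of shuffled clones to assemble (default: size of
#'   `filtered`).
#' @param seed Integer seed.
#' @return A clone population tibble.
#' @export
shuffle_modules <- function(filtered, config, n_clones = nrow(filtered),
                            seed = 1L) {
  filtered <- .check_population(filtered)
  if (nrow(filtered) == 0L) abort("empty module pool: nothing to shuffle")
  if (sum(filtered$n_modules) == 0L) abort("module pool contains no modules")
  set.seed(seed)
  n_mod <- sample(0:config$n_max, n_clones, replace = TRUE, prob = config$p_n)
  n_def <- stats::rbinom(n_clones, n_mod, config$eps_lig)
  out <- tibble(clone = seq_len(n_clones), n_modules = n_mod,
                n_defective = n_def,
                ncap_ok = TRUE, ccap_ok = TRUE)
  out$in_frame <- .in_frame(out)
  out
}

#' Table-style summary statistics of a clone population
#'
#' Computes, on a seeded random sample of `sample_size` clones, the columns of
#' a sequencing-based library characterisation: fraction of correct motifs,
#' fraction of in-frame clones, fraction of in-frame clones with at least one
#' motif, and mean motif number over the in-frame clones (all, and the n >= 1
#' subset).
#'
#' @param population A clone population tibble.
#' @param sample_size Number of clones to sample (default: all).
#' @param seed Integer seed for the sample.
#' @return One-row tibble: `n_sampled`, `n_motifs_seen`,
#'   `frac_correct_motifs`, `frac_inframe`, `frac_inframe_n1`,
#'   `mean_motifs_inframe`, `mean_motifs_inframe_n1`.
#' @export
library_stats <- function(population, sample_size = nrow(population), seed = 1L) {
  population <- .check_population(population)
  if (sample_size < 1) abort("`sample_size` must be >= 1")
  if (sample_size > nrow(population)) {
    abort("`sample_size` exceeds the population size")
  }
  set.seed(seed)
  idx <- if (sample_size == nrow(population)) seq_len(nrow(population))
         else sample(nrow(population), sample_size)
  s <- population[idx, ]
  inf <- .in_frame(s)
  inf1 <- inf & s$n_modules >= 1
  n_mot <- sum(s$n_modules)
  tibble(
    n_sampled = nrow(s),
    n_motifs_seen = n_mot,
    frac_correct_motifs = if (n_mot > 0) 1 - sum(s$n_defective) / n_mot else NA_real_,
    frac_inframe = mean(inf),
    frac_inframe_n1 = mean(inf1),
    mean_motifs_inframe = if (any(inf)) mean(s$n_modules[inf]) else NA_real_,
    mean_motifs_inframe_n1 = if (any(inf1)) mean(s$n_modules[inf1]) else NA_real_
  )
}

#' In-frame fraction predicted by the independent-module error model
#'
#' The shorthand `q ^ n_bar`: probability that a clone with the average motif
#' number is fully coding when each motif is independently correct with
#' probability `q`. Evaluated on a library characterisation row (correct-motif
#' fraction and mean motif number) it reproduces the observed in-frame clone
#' percentage.
#'
#' @param frac_correct_motifs Correct-motif fraction q in `[0, 1]`.
#' @param mean_motifs Average motif number n-bar (>= 0).
#' @return Predicted in-frame fraction.
#' @export
inframe_from_motif_rate <- function(frac_correct_motifs, mean_motifs) {
  if (frac_correct_motifs < 0 || frac_correct_motifs > 1) {
    abort("`frac_correct_motifs` must lie in [0, 1]")
  }
  if (mean_motifs < 0) abort("`mean_motifs` must be >= 0")
  frac_correct_motifs^mean_motifs
}
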