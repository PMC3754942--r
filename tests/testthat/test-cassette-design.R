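test_that("candidate enumeration yields all ordered pairs with dipeptide sets", {
  cs <- codon_sets()
  cand <- enumerate_cassettes(cs$pos18, cs$pos19)
  expect_equal(nrow(cand), 11 * 10)
  cand2 <- enumerate_cassettes(cs$pos22, cs$pos23)
  expect_equal(nrow(cand2), 10 * 15)
  one <- enumerate_cassettes("tgg", "tac")
  expect_equal(nrow(one), 1)
  expect_equal(one$dipeptides[[1]], "WY")
  # dipeptide sets derive from the translation module
  i <- which(cand$codon_a == "ncg" & cand$codon_b == "gma")
  expect_setequal(cand$dipeptides[[i]],
                  as.vector(outer(c("T", "P", "A", "S"), c("E", "A"), paste0)))
})

test_that("forbidden-residue constraints flag infeasible cassettes", {
  cand <- enumerate_cassettes(c("tgt", "gcg"), c("ccg", "gaa"),
                              design_constraints(forbidden_a = "C",
                                                 forbidden_b = "P"))
  # tgt encodes Cys (first slot), ccg encodes Pro (second slot)
  feas <- cand[cand$feasible, ]
  expect_equal(nrow(feas), 1)
  expect_equal(paste(feas$codon_a, feas$codon_b), "gcg gaa")
  expect_error(select_cassettes(cand[!cand$feasible, ], 2), "no feasible")
})

test_that("greedy + swap matches exhaustive search on toy instances", {
  toy <- tibble::tibble(
    codon_a = c("c1", "c2", "c3"), codon_b = "x",
    dipeptides = list(c("AA", "AB"), c("AB", "AC", "AD"), c("AA", "AD")),
    feasible = TRUE
  )
  lib <- select_cassettes(toy, budget = 2)
  expect_equal(length(encoded_dipeptides(lib)),
               oracle_best_coverage(toy$dipeptides, 2))

  # randomized toys: greedy+swap >= (1 - 1/e) * optimum, and here = optimum
  set.seed(8)
  universe <- as.vector(outer(LETTERS[1:5], LETTERS[1:5], paste0))
  for (rep in 1:10) {
    sets <- lapply(1:6, function(i) sample(universe, sample(2:6, 1)))
    cand <- tibble::tibble(codon_a = sprintf("c%02d", 1:6), codon_b = "x",
                           dipeptides = sets, feasible = TRUE)
    k <- 3
    got <- length(encoded_dipeptides(select_cassettes(cand, k)))
    best <- oracle_best_coverage(sets, k)
    expect_gte(got, ceiling((1 - exp(-1)) * best))
    expect_lte(got, best)
  }
})

test_that("budget >= candidate count returns the full encodable union", {
  cs <- codon_sets()
  cand <- enumerate_cassettes(cs$pos18, cs$pos19)
  lib <- select_cassettes(cand, budget = 1000)
  expect_setequal(encoded_dipeptides(lib), unique(unlist(cand$dipeptides)))
  expect_error(select_cassettes(cand, budget = 0), "budget")
})

test_that("selection is deterministic under the lexicographic tie-break", {
  cs <- codon_sets()
  cand <- enumerate_cassettes(cs$pos22, cs$pos23)
  a <- select_cassettes(cand, 10)
  b <- select_cassettes(cand, 10)
  expect_identical(paste(a$codon_a, a$codon_b), paste(b$codon_a, b$codon_b))
})

test_that("weight optimization solves closed-form cases and descends monotonically", {
  # one cassette reproducing the target exactly
  cand <- enumerate_cassettes("tgg", "tac")
  lib <- select_cassettes(cand, 1)
  fit <- optimize_weights(lib, tibble::tibble(dipeptide = "WY", frequency = 1))
  expect_equal(fit$weight, 1)
  expect_lt(attr(fit, "objective"), 1e-18)

  # two disjoint single-dipeptide cassettes: weights equal the target masses
  cand2 <- enumerate_cassettes(c("tgg", "tac"), c("tgg", "tac"))
  lib2 <- select_cassettes(cand2[c(1, 4), ], 2)  # YY and WW cassettes
  tgt <- tibble::tibble(dipeptide = c("WW", "YY"), frequency = c(0.3, 0.7))
  fit2 <- optimize_weights(lib2, tgt)
  w <- setNames(fit2$weight, purrr::map_chr(fit2$dipeptides, 1))
  # objective tolerance 1e-9 bounds the weight error by ~sqrt(1e-9)
  expect_equal(unname(w["WW"]), 0.3, tolerance = 1e-4)
  expect_equal(unname(w["YY"]), 0.7, tolerance = 1e-4)

  # random 3-cassette toy vs grid-search oracle at 0.01 resolution
  set.seed(17)
  cs <- codon_sets()
  pick <- sample(cs$pos22, 3)
  cand3 <- enumerate_cassettes(pick, "gcg")
  lib3 <- select_cassettes(cand3, 3)
  dps <- unique(unlist(cand3$dipeptides))
  tvec <- runif(length(dps)); tvec <- tvec / sum(tvec)
  tgt3 <- tibble::tibble(dipeptide = dps, frequency = tvec)
  fit3 <- optimize_weights(lib3, tgt3)
  A <- sapply(seq_len(nrow(lib3)), function(i) {
    d <- alphareplib:::.dipeptide_distribution(lib3$codon_a[i], lib3$codon_b[i],
                                               "drop-renormalize")
    v <- setNames(rep(0, length(dps)), dps); v[d$dipeptide] <- d$frequency; v
  })
  grid_obj <- Inf
  for (w1 in seq(0, 1, 0.01)) for (w2 in seq(0, 1 - w1, 0.01)) {
    w <- c(w1, w2, 1 - w1 - w2)
    grid_obj <- min(grid_obj, sum((A %*% w - tvec)^2))
  }
  expect_lte(attr(fit3, "objective"), grid_obj + 1e-3)

  # irreducible target mass is reported, not silently dropped
  expect_warning(
    optimize_weights(lib2, tibble::tibble(dipeptide = c("WW", "QQ"),
                                          frequency = c(0.5, 0.5))),
    "outside the encodable support")
})

test_that("no achieved distribution puts mass on forbidden residues", {
  cs <- codon_sets()
  cons <- design_constraints(forbidden_a = c("C", "P"),
                             forbidden_b = c("C", "P"))
  cand <- enumerate_cassettes(cs$pos22, cs$pos23, cons)
  lib <- select_cassettes(cand, 24)
  ach <- alphareplib:::.achieved_distribution(lib)
  bad <- grepl("C|P", ach$dipeptide)
  expect_equal(sum(ach$frequency[bad]), 0)
})

test_that("design metrics equal direct set computations", {
  col <- random_collection(300, seed = 31)
  nat <- dipeptide_frequencies(col, c(18, 19))
  cs <- codon_sets()
  lib <- select_cassettes(enumerate_cassettes(cs$pos18, cs$pos19), 26)
  met <- evaluate_design(lib, nat, n = 50)
  enc <- encoded_dipeptides(lib)
  expect_equal(met$n_encoded, length(enc))
  expect_equal(met$top_n_covered,
               length(intersect(enc, top_dipeptides(nat, 50))))
  expect_gte(met$tv, 0)

  # natural table equal to the encoded set -> full coverage at N = count
  nat_eq <- tibble::tibble(dipeptide = enc, frequency = 1 / length(enc),
                           rank = seq_along(enc))
  met_eq <- evaluate_design(lib, nat_eq, n = length(enc))
  expect_equal(met_eq$top_n_covered, length(enc))

  # empty intersection -> zero coverage
  nat0 <- tibble::tibble(dipeptide = c("CC", "CP"), frequency = c(0.5, 0.5),
                         rank = 1:2)
  expect_equal(evaluate_design(lib, nat0, n = 2)$top_n_covered, 0)
})
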