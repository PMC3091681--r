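test_that("generators are deterministic under a fixed seed", {
  a2 <- generate_expression(6, planted_fractions = c(0, 0.5, 1, 0.25, 0.75, 0.5),
                            seed = 92)
  b2 <- generate_expression(6, planted_fractions = c(0, 0.5, 1, 0.25, 0.75, 0.5),
                            seed = 92)
  expect_identical(a2$matrix, b2$matrix)
  expect_identical(a2$truth$planted, b2$truth$planted)

  s1 <- generate_survival(30, 2, 0.2, seed = 93)
  s2 <- generate_survival(30, 2, 0.2, seed = 93)
  expect_identical(s1, s2)

  m1 <- attr(generate_molecule_set(40, seed = 94), "smiles")
  m2 <- attr(generate_molecule_set(40, seed = 94), "smiles")
  expect_identical(m1, m2)
})

test_that("planted extremes score 0 and 100 on every signature", {
  ge <- generate_expression(4, planted_fractions = c(1, 0, 1, 0), seed = 95)
  sc <- score_dataset(ge$matrix)
  ones <- sc$sample %in% c("S01", "S03")
  expect_true(all(sc$score[ones] == 100))
  expect_true(all(sc$score[!ones] == 0))
})

test_that("paired cohorts recover planted fractions exactly at zero noise", {
  f <- rep(c(0, 0.25, 0.5, 0.75, 1), 2)
  ge <- generate_expression(10, planted_fractions = f, seed = 96)
  sc <- score_dataset(ge$matrix, "all")
  got <- stats::setNames(sc$score, sc$sample)
  want <- 100 * ge$truth$fractions$fraction_all
  expect_equal(unname(got[ge$truth$fractions$sample]), want)
  expect_equal(sort(unique(want)), c(0, 25, 50, 75, 100))

  # sub-signature scores match their realized planted fractions too
  sub <- score_dataset(ge$matrix, c("das", "mss"))
  for (sig in c("das", "mss")) {
    v <- sub[sub$signature == sig, ]
    expect_equal(v$score[match(ge$truth$fractions$sample, v$sample)],
                 100 * ge$truth$fractions[[paste0("fraction_", sig)]])
  }
})

test_that("unpaired cohorts deviate from truth exactly by median miscounts", {
  f <- c(0.3, 0.6, 0.8, 0.4, 0.45)       # odd design, no complements
  ge <- generate_expression(5, planted_fractions = f, seed = 97)
  sig <- load_signature("all")
  m <- filter_to_signature(ge$matrix, sig)
  sc <- score_dataset(ge$matrix, "all")
  got <- sc$score[match(ge$truth$fractions$sample, sc$sample)]
  want <- 100 * ge$truth$fractions$fraction_all
  # identity: the score deviates from the planted fraction exactly by the
  # markers whose value is not strictly on the planted side of the cohort
  # median (cohort-relative scoring has no other loss mechanism)
  med <- apply(m, 1, median)
  nm <- sweep(m, 1, med, "/")
  up <- sig$direction == "up"
  counted <- (nm > 1) == up & nm != 1
  intended <- ge$truth$planted[rownames(m), colnames(m)]
  dev <- colSums(intended & !counted) - colSums(!intended & counted)
  expect_equal((want - got) * 28 / 100, unname(dev), tolerance = 1e-9)
  # ranking of samples still follows the planted fractions
  expect_gte(cor(got, want, method = "spearman"), 0.85)
})

test_that("generator input contracts are enforced", {
  expect_error(generate_expression(1), "at least 2")
  expect_error(generate_expression(4, deflection = 1), "deflection")
  expect_error(generate_expression(4, planted_fractions = 1.2), "fractions")
  expect_error(generate_gi50(1:5, n_compounds = 3, n_active = 4), "n_active")
  expect_error(generate_survival(10, hazard_ratio = -1), "hazard_ratio")
})

test_that("noise-free GI50 planting is recovered exactly by regression", {
  scores <- stats::setNames(runif(30, 0, 1), paste0("L", 1:30))
  g <- generate_gi50(scores, n_compounds = 5, n_active = 5, slope = -3,
                     noise_sd = 0, seed = 98)
  for (i in 1:5) {
    r <- suppressWarnings(fit_gi50_regression(scores, g$panel[i, ]))
    expect_equal(r$slope, -3, tolerance = 1e-10)
    expect_equal(r$intercept, 5, tolerance = 1e-10)
  }
})

test_that("power calibration hits the requested slope-test power", {
  set.seed(99)
  x <- runif(60, 0, 1)
  sd80 <- noise_sd_for_power(-3, x, power = 0.8)
  hits <- 0; reps <- 400
  for (r in seq_len(reps)) {
    y <- 5 - 3 * x + rnorm(60, 0, sd80)
    hits <- hits + (fit_gi50_regression(x, y)$p_slope < 0.05)
  }
  # binomial band: 0.8 +/- 3*sqrt(.8*.2/400) ~ +/- 0.06
  expect_lt(abs(hits / reps - 0.8), 0.06)
})

test_that("generated molecules satisfy the graph invariants", {
  mols <- generate_molecule_set(50, seed = 100)
  expect_length(mols, 50)
  for (mol in mols) {
    expect_s3_class(mol, "mol_graph")
    expect_gte(nrow(mol$atoms), 4)
    expect_lte(nrow(mol$atoms), 8)
    # heteroatoms never exceed their valence
    bo <- tabulate(c(mol$bonds$i, mol$bonds$j), nrow(mol$atoms))
    lim <- c(C = 4, N = 3, O = 2, S = 2)[mol$atoms$element]
    expect_true(all(bo <= lim))
  }
  expect_identical(length(generate_molecule_set(0)), 0L)
})
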