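norm_vector <- function(sig, values) {
  stats::setNames(values, sig$canonical_symbol[seq_along(values)])
}

test_that("median normalization divides by the per-gene cohort median", {
  m <- rbind(A = c(2, 4, 6), B = c(5, 5, 5), C = c(1, 3, NA))
  colnames(m) <- paste0("s", 1:3)
  nm <- median_normalize(m)
  expect_equal(unname(nm["A", ]), c(0.5, 1, 1.5))
  expect_equal(unname(nm["B", ]), c(1, 1, 1))
  # even count of non-missing values: median is the mid-pair mean (2)
  expect_equal(unname(nm["C", ]), c(0.5, 1.5, NA))
  # invariant: median of each gene's non-missing normalized row is 1
  expect_true(all(abs(apply(nm, 1, median, na.rm = TRUE) - 1) < 1e-9))
})

test_that("degenerate genes are excluded and degenerate inputs rejected", {
  m <- rbind(A = c(1, 2), B = c(NA, NA))
  colnames(m) <- c("s1", "s2")
  expect_warning(nm <- median_normalize(m), "degenerate-gene")
  expect_equal(rownames(nm), "A")
  expect_equal(attr(nm, "excluded_genes"), "B")

  expect_error(median_normalize(matrix(1, 2, 1)), "at least 2 samples")
  m2 <- rbind(A = c(-1, 2)); colnames(m2) <- c("s1", "s2")
  expect_error(median_normalize(m2), "positive")
})

test_that("single-sample scoring counts directional markers with strict ties", {
  sig3 <- load_signature("all")[1:3, ]            # up, up, up
  sig3$direction <- c("up", "up", "down")
  attr(sig3, "name") <- "all"
  class(sig3) <- c("senescence_signature", "data.frame")

  s <- score_sample(norm_vector(sig3, c(1.2, 0.8, 0.5)), sig3)
  expect_equal(s$n_expressed, 3L)
  expect_equal(s$n_senescent, 2L)
  expect_equal(s$score, 200 / 3, tolerance = 1e-12)

  # exactly at the median counts non-senescent under the default rule...
  tie <- score_sample(norm_vector(sig3, c(1, 1, 1)), sig3)
  expect_equal(tie$score, 0)
  # ...and senescent when the tie convention is flipped
  tie2 <- score_sample(norm_vector(sig3, c(1, 1, 1)), sig3,
                       ties = "senescent")
  expect_equal(tie2$score, 100)

  # maximal case: every marker deflected its own way
  mx <- score_sample(norm_vector(sig3, c(2, 2, 0.5)), sig3)
  expect_equal(mx$score, 100)

  expect_error(score_sample(norm_vector(sig3, rep(NA_real_, 3)), sig3),
               "unscorable-sample")
})

test_that("missing markers drop out of the score denominator", {
  sig <- load_signature("all")
  vals <- rep(NA_real_, 28)
  up <- sig$direction == "up"
  planted <- c(which(up)[1:14], which(!up)[1:2])       # 16 pro-senescent
  anti <- setdiff(seq_len(28), planted)[1:4]           # 4 anti
  vals[planted] <- ifelse(up[planted], 2, 0.5)
  vals[anti] <- ifelse(up[anti], 0.5, 2)               # 8 stay missing
  s <- score_sample(stats::setNames(vals, sig$canonical_symbol), sig)
  expect_equal(s$n_expressed, 20L)
  expect_equal(s$n_senescent, 16L)
  expect_equal(s$score, 80)
})

test_that("dataset scoring matches the brute-force transliteration", {
  sig <- load_signature("all")
  set.seed(101)
  for (rep_ in 1:25) {
    genes <- sample(sig$canonical_symbol, 6)
    m <- matrix(rlnorm(6 * 5, 6, 1), 6, 5,
                dimnames = list(genes, paste0("s", 1:5)))
    m[runif(30) < 0.1] <- NA
    got <- suppressWarnings(score_dataset(m, "all"))
    want <- bf_score_matrix(m, sig)
    expect_equal(got$n_expressed, want$n_expressed)
    expect_equal(got$n_senescent, want$n_senescent)
    expect_equal(got$score, want$score)
  }
})

test_that("all-signature senescent counts decompose into DAS + mSS", {
  set.seed(7)
  ge <- generate_expression(8, planted_fractions = runif(8), noise_sd = 0.3)
  sc <- score_dataset(ge$matrix)
  wide <- reshape(sc[, c("sample", "signature", "n_senescent")],
                  idvar = "sample", timevar = "signature", direction = "wide")
  expect_equal(wide$n_senescent.all,
               wide$n_senescent.das + wide$n_senescent.mss)
  expect_true(all(sc$score >= 0 & sc$score <= 100))
})

test_that("scores are invariant under per-gene strictly increasing transforms", {
  set.seed(31)
  ge <- generate_expression(9, planted_fractions = runif(9), noise_sd = 0.4)
  m <- ge$matrix
  base <- score_dataset(m)
  expect_equal(score_dataset(m^3), base)
  expect_equal(score_dataset(2 * m), base)
  # and per-gene mixtures of transforms
  m2 <- m
  m2[1:14, ] <- m[1:14, ]^3
  m2[15:28, ] <- 7 * m[15:28, ]
  expect_equal(score_dataset(m2), base)
})

test_that("cohort equal to its own median scores zero everywhere", {
  sym <- load_signature("all")$canonical_symbol
  m <- matrix(5, 28, 3, dimnames = list(sym, paste0("s", 1:3)))
  sc <- score_dataset(m, "all")
  expect_true(all(sc$score == 0))
})

test_that("filtered and global normalization scopes agree on marker scores", {
  set.seed(13)
  ge <- generate_expression(6, planted_fractions = runif(6), noise_sd = 0.2)
  expect_equal(score_dataset(ge$matrix, median_scope = "filtered"),
               score_dataset(ge$matrix, median_scope = "global"))
})

test_that("group summaries report median with min/max bars", {
  sc <- data.frame(sample = paste0("s", 1:7),
                   signature = "all",
                   n_expressed = 28L, n_senescent = 14L,
                   score = c(60, 70, 80, 10, 30, 20, 40))
  class(sc) <- c("senescence_scores", "data.frame")
  groups <- c(s1 = "t", s2 = "t", s3 = "t",
              s4 = "n", s5 = "n", s6 = "n", s7 = "n")
  sm <- summarize_scores(sc, groups)
  tr <- sm[sm$group == "t", ]
  expect_equal(c(tr$median, tr$min, tr$max), c(70, 60, 80))
  nr <- sm[sm$group == "n", ]
  expect_equal(nr$median, 25)               # even n: mid-pair mean
  expect_true(all(sm$min <= sm$median & sm$median <= sm$max))

  expect_error(summarize_scores(sc, groups[-1]), "no group for sample")
  expect_warning(summarize_scores(sc, c(groups, s99 = "ghost")),
                 "empty group")
})
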