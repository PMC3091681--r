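test_that("within-group ranking is ascending with average ties", {
  expect_equal(rank_within_group(c(10, 20, 30)), c(1, 2, 3))
  expect_equal(rank_within_group(c(10, 10, 30)), c(1.5, 1.5, 3))
  set.seed(81)
  v <- runif(20)
  expect_equal(rank_within_group(v), order(order(v)))   # argsort oracle
  expect_warning(rank_within_group(rep(5, 4)), "constant-ranks")
})

test_that("rank correlation is Pearson-on-ranks with a t-based p-value", {
  r <- correlate_rankings(1:8, 1:8)
  expect_equal(r$r, 1)
  expect_equal(correlate_rankings(1:8, 8:1)$r, -1)

  set.seed(82)
  a <- rank_within_group(runif(15)); b <- rank_within_group(runif(15))
  got <- correlate_rankings(a, b)
  rr <- cor(a, b)
  tt <- rr * sqrt(13 / (1 - rr^2))
  expect_equal(got$r, rr)
  expect_equal(got$p, 2 * pt(-abs(tt), 13))
  expect_equal(got$n, 15L)

  expect_error(correlate_rankings(rep(2, 5), 1:5), "undefined-correlation")
})

test_that("per-group signature correlation tables are assembled correctly", {
  set.seed(83)
  ge <- generate_expression(12, planted_fractions = runif(12), noise_sd = 0.5)
  sc <- score_dataset(ge$matrix)
  groups <- stats::setNames(rep(c("mpnst", "lipo"), each = 6),
                            unique(sc$sample))
  tab <- correlate_score_rankings(sc, groups)
  expect_equal(nrow(tab), 2 * 3)          # 2 groups x 3 signature pairs
  expect_true(all(tab$r >= -1 & tab$r <= 1))
  expect_true(all(tab$n == 6))
})

test_that("planted two-group structure is recovered as first-level clusters", {
  set.seed(84)
  mss <- load_signature("mss")
  n_per <- 6
  truth <- rep(1:2, each = n_per)
  base <- rlnorm(16, 6, 1)
  m <- sapply(truth, function(g) {
    fold <- ifelse(seq_len(16) <= 8, ifelse(g == 1, 3, 1 / 3),
                   ifelse(g == 1, 1 / 3, 3))
    base * fold * exp(rnorm(16, 0, 0.1))
  })
  dimnames(m) <- list(mss$canonical_symbol, sprintf("T%02d", seq_len(2 * n_per)))
  cl <- cluster_samples(median_normalize(m))
  expect_equal(max(cl$sample_groups), 2L)
  # Rand index 1: groups agree with truth up to label switching
  expect_equal(length(unique(paste(truth, cl$sample_groups))), 2L)
  # gene axis splits the two opposed gene blocks
  expect_equal(length(unique(paste(rep(1:2, each = 8), cl$gene_groups))),
               max(cl$gene_groups))
})

test_that("clustering is order-invariant and merges duplicates first", {
  set.seed(85)
  m <- matrix(rlnorm(8 * 10, 6, 1), 8, 10,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
  m[, 10] <- m[, 9]                       # duplicate sample
  cl <- cluster_samples(m)
  expect_equal(cl$sample_hclust$height[1], 0)
  first_pair <- sort(-cl$sample_hclust$merge[1, ])
  expect_equal(first_pair, c(9, 10))
  expect_equal(cl$sample_groups[["s9"]], cl$sample_groups[["s10"]])

  same_partition <- function(a, b) {
    b <- b[names(a)]
    length(unique(paste(a, b))) == max(max(a), max(b))
  }
  perm <- sample(10)
  cl2 <- cluster_samples(m[, perm])
  expect_true(same_partition(cl$sample_groups, cl2$sample_groups))

  # rank-based distance: a global strictly increasing transform changes
  # nothing on either axis
  cl3 <- cluster_samples(m^2)
  expect_true(same_partition(cl$sample_groups, cl3$sample_groups))
  expect_true(same_partition(cl$gene_groups, cl3$gene_groups))

  # gene-axis groups additionally survive per-gene monotone transforms,
  # since each gene's profile is ranked within itself
  m4 <- m; m4[1:4, ] <- m[1:4, ]^2; m4[5:8, ] <- 3 * m[5:8, ]
  cl4 <- cluster_samples(m4)
  expect_true(same_partition(cl$gene_groups, cl4$gene_groups))
})

test_that("survival comparison reproduces a hand-computed log-rank test", {
  rec <- data.frame(sample = paste0("p", 1:6),
                    time = c(1, 2, 3, 4, 5, 6), event = 1,
                    age = c(60, 62, 58, 61, 64, 59),
                    sex = c("M", "F", "M", "F", "M", "F"),
                    group = rep(c("A", "B"), each = 3))
  # groups are fully separated in time, so the Cox part warns about an
  # unbounded coefficient; the log-rank arithmetic is what is under test
  cmp <- suppressWarnings(compare_survival(rec))
  expect_equal(cmp$logrank_chisq,
               bf_logrank_chisq(rec$time, rec$event, rec$group),
               tolerance = 1e-10)
  # KM with no censoring equals the empirical survival function
  km <- summary(cmp$km)
  grpA <- as.character(km$strata) == "group=A"
  expect_equal(km$surv[grpA], c(2, 1, 0) / 3)

  # label swap leaves the log-rank p unchanged
  rec2 <- rec; rec2$group <- ifelse(rec$group == "A", "B", "A")
  expect_equal(suppressWarnings(compare_survival(rec2))$logrank_p,
               cmp$logrank_p)
})

test_that("identical groups give a null log-rank test", {
  rec <- data.frame(time = rep(c(2, 4, 6, 8), 2), event = rep(c(1, 1, 0, 1), 2),
                    age = 60, sex = "M",
                    group = rep(c("A", "B"), each = 4))
  cmp <- suppressWarnings(compare_survival(rec))
  expect_equal(cmp$logrank_chisq, 0, tolerance = 1e-12)
  expect_equal(cmp$logrank_p, 1, tolerance = 1e-9)
})

test_that("degenerate survival inputs are signalled", {
  rec <- generate_survival(20, hazard_ratio = 2, censor_rate = 0.2, seed = 86)
  one <- rec; one$group <- "A"
  expect_error(compare_survival(one), "single-group")
  cens <- generate_survival(20, hazard_ratio = 2, censor_rate = 1, seed = 87)
  expect_error(compare_survival(cens), "no-events")
})

test_that("Cox adjustment recovers a planted hazard ratio", {
  rec <- generate_survival(n_per_group = 100, hazard_ratio = 3,
                           censor_rate = 0, seed = 88)
  cmp <- compare_survival(rec)
  beta <- log(cmp$cox_hr[["groupB"]])
  se <- sqrt(diag(vcov(cmp$cox)))[["groupB"]]
  expect_lt(abs(beta - log(3)), 2 * se)
})
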