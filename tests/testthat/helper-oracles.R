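# Independent reference implementations used as oracles.  These are kept
# deliberately naive and separate from the package code paths they check.

# Direct transliteration of the scoring procedure: per-gene median across
# arrays, ratio to median, count markers deflected in their pro-senescence
# direction, percent of expressed markers.
bf_score_matrix <- function(m, sig) {
  out <- NULL
  for (s in colnames(m)) {
    n_expr <- 0L; n_sen <- 0L
    for (g in sig$canonical_symbol) {
      if (!g %in% rownames(m)) next
      med <- stats::median(m[g, ], na.rm = TRUE)
      v <- m[g, s]
      if (is.na(v)) next
      n_expr <- n_expr + 1L
      ratio <- v / med
      dir <- sig$direction[sig$canonical_symbol == g]
      if ((dir == "up" && ratio > 1) || (dir == "down" && ratio < 1))
        n_sen <- n_sen + 1L
    }
    out <- rbind(out, data.frame(sample = s, n_expressed = n_expr,
                                 n_senescent = n_sen,
                                 score = 100 * n_sen / n_expr))
  }
  out
}

# Textbook simple-OLS closed forms.
bf_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b <- sxy / sxx
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  t <- b / se
  list(slope = b, intercept = a, p = 2 * stats::pt(-abs(t), n - 2))
}

# Brute-force graph oracles from an adjacency matrix (BFS distances).
bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(A[v, ] > 0))))
      nxt <- nxt[D[s, nxt] == Inf]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

bf_graph_indices <- function(A) {
  D <- bf_distances(A)
  deg <- rowSums(A > 0)
  m <- sum(A > 0) / 2
  ecc <- apply(D, 1, max)
  dia <- max(D); rad <- min(ecc)
  mu <- m - nrow(A) + 1
  s <- rowSums(D)
  edges <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  list(wiener = sum(D) / 2,
       wiener_polarity = sum(D == 3) / 2,
       zagreb1 = sum(deg^2),
       zagreb2 = sum(deg[edges[, 1]] * deg[edges[, 2]]),
       petitjean = if (rad > 0) (dia - rad) / rad else 0,
       balaban_j = if (m > 0)
         m / (mu + 1) * sum(1 / sqrt(s[edges[, 1]] * s[edges[, 2]])) else 0)
}

mol_adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  A <- matrix(0L, n, n)
  for (k in seq_len(nrow(mol$bonds))) {
    A[mol$bonds$i[k], mol$bonds$j[k]] <- 1L
    A[mol$bonds$j[k], mol$bonds$i[k]] <- 1L
  }
  A
}

# Naive log-rank: loop over distinct event times, accumulate observed and
# expected events in group 1 and the hypergeometric variance.
bf_logrank_chisq <- function(time, event, group) {
  g1 <- group == unique(group)[1]
  o <- e <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}

# A small library of named test graphs (paths, stars, cycles).
graph_fixture_set <- function(max_atoms = 8) {
  fx <- list()
  for (k in 2:max_atoms) {
    fx[[paste0("path", k)]] <- senescore::mol_graph(
      rep("C", k), cbind(seq_len(k - 1), 2:k, 1))
    if (k >= 3) {
      fx[[paste0("cycle", k)]] <- senescore::mol_graph(
        rep("C", k), rbind(cbind(seq_len(k - 1), 2:k, 1), c(k, 1, 1)))
      fx[[paste0("star", k)]] <- senescore::mol_graph(
        rep("C", k), cbind(1, 2:k, 1))
    }
  }
  fx
}
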