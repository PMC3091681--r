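#' Generate an expression matrix with planted senescence fractions
#'
#' Simulates a positive gene x sample expression matrix containing the 28
#' signature markers plus background genes, with a known ("planted")
#' per-sample fraction of markers signalling pro-senescent.  Baseline
#' expression is log-normal (meanlog 6, sdlog 1), mimicking microarray
#' intensity positivity.  In each sample a fraction of the markers is
#' deflected in its pro-senescence direction (up-markers multiplied by
#' \code{deflection}, down-markers divided) and the remaining markers are
#' deflected the opposite way, so no marker sits at its baseline and —
#' at zero noise — no value ties the cohort median.  Background genes are
#' pure multiplicative noise around their baselines.
#'
#' Marker subsets are allocated per sub-signature (\code{round(f * 12)}
#' DAS markers and the complement to \code{round(f * 28)} from mSS), so
#' the planted DAS/mSS fractions track the overall fraction as closely as
#' the one-gene quantum allows.  Samples whose fractions pair to 1
#' (e.g. 0.25 with 0.75) receive complementary marker subsets; in a fully
#' paired cohort every marker is pro-deflected in exactly half the
#' samples, the cohort median falls strictly between the deflected
#' levels, and at zero noise every score equals 100 x its planted
#' fraction exactly.  Unpaired samples are planted by greedy balanced
#' allocation (each marker's cohort count kept as even as the fractions
#' allow) and the deflection magnitude is jittered per value, so in
#' unbalanced or odd cohorts a sample's score deviates from its planted
#' fraction only on genes where the cohort median falls on or beyond the
#' sample's own deflected value.  Scores are cohort-relative by
#' construction, so a cohort whose mean planted fraction is far from 0.5
#' recovers fractions relative to its own median, not absolutely.
#'
#' @param n_samples Number of samples (>= 2).
#' @param planted_fractions Numeric vector in [0,1], recycled to
#'   \code{n_samples}: per-sample fraction of markers planted
#'   pro-senescent (default 0.5).
#' @param n_background_genes Background (non-signature) genes (default 200).
#' @param deflection Fold-change magnitude of the planted deflections
#'   (> 1; default 2).
#' @param noise_sd SD of multiplicative log-normal noise on marker values
#'   (default 0 = noise-free markers).
#' @param seed Optional integer seed.
#' @return List with \code{matrix} (genes x samples, markers first) and
#'   \code{truth}: a list with \code{fractions} (data frame of realized
#'   planted fractions per sample and signature), \code{planted} (28 x
#'   n_samples logical matrix), \code{deflection}, \code{noise_sd},
#'   \code{seed}.
#' @export
generate_expression <- function(n_samples, planted_fractions = 0.5,
                                n_background_genes = 200, deflection = 2,
                                noise_sd = 0, seed = NULL) {
  if (n_samples < 2L) stop("need at least 2 samples", call. = FALSE)
  if (deflection <= 1) stop("deflection must be > 1", call. = FALSE)
  f <- rep_len(planted_fractions, n_samples)
  if (any(f < 0 | f > 1)) stop("fractions must be in [0,1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sig <- load_signature("all")
  markers <- sig$canonical_symbol
  up <- sig$direction == "up"
  is_das <- sig$signature == "das"
  n_das <- sum(is_das); n_mss <- sum(!is_das); n_mark <- length(markers)

  k_all <- round(f * n_mark)
  k_das <- pmin(n_das, pmax(0L, round(f * n_das)))
  k_mss <- pmin(n_mss, pmax(0L, k_all - k_das))
  k_das <- k_all - k_mss     # re-balance if mss clamped

  # complementary pairing: samples whose planted counts sum to the full
  # signature get complementary subsets, balancing each marker across the
  # cohort (see Details)
  planted <- matrix(FALSE, n_mark, n_samples,
                    dimnames = list(markers,
                                    sprintf("S%02d", seq_len(n_samples))))
  paired_with <- rep(NA_integer_, n_samples)
  avail <- seq_len(n_samples)
  for (i in seq_len(n_samples)) {
    if (!i %in% avail) next
    partner <- avail[avail != i &
                       k_das[avail] == n_das - k_das[i] &
                       k_mss[avail] == n_mss - k_mss[i]]
    if (length(partner)) {
      j <- partner[1L]
      paired_with[i] <- j; paired_with[j] <- i
      avail <- setdiff(avail, c(i, j))
    } else {
      avail <- setdiff(avail, i)
    }
  }
  # unpaired samples: greedy balanced allocation — plant the markers least
  # planted so far (random tie-break), keeping per-marker cohort counts as
  # even as the fractions allow
  cnt <- rep(0L, n_mark)
  pick <- function(idx, k) {
    if (k == 0L) return(integer())
    idx[order(cnt[idx] + stats::runif(length(idx), 0, 0.5))][seq_len(k)]
  }
  for (i in seq_len(n_samples)) {
    j <- paired_with[i]
    if (!is.na(j) && j < i) {               # complement of the partner
      planted[, i] <- !planted[, j]
    } else if (is.na(j)) {
      sel <- c(pick(which(is_das), k_das[i]), pick(which(!is_das), k_mss[i]))
      planted[sel, i] <- TRUE
      cnt[sel] <- cnt[sel] + 1L
    } else {                                # first of a pair: random subset
      sel <- c(sample(which(is_das))[seq_len(k_das[i])],
               sample(which(!is_das))[seq_len(k_mss[i])])
      planted[sel, i] <- TRUE
    }
  }

  baseline <- stats::rlnorm(n_mark + n_background_genes, 6, 1)
  # per-value jitter of the deflection magnitude keeps all deflected
  # values distinct, so on any gene the cohort median can coincide with at
  # most one sample's value, and median ties spread across samples
  eta <- matrix(stats::runif(n_mark * n_samples, -0.05, 0.05),
                n_mark, n_samples)
  vals <- matrix(NA_real_, n_mark, n_samples)
  for (i in seq_len(n_samples)) {
    pro <- planted[, i]
    expo <- ifelse(pro == up, 1, -1)        # up & planted or down & anti: x d
    vals[, i] <- baseline[seq_len(n_mark)] *
      (deflection^(1 + eta[, i]))^expo
  }
  if (noise_sd > 0)
    vals <- vals * exp(matrix(stats::rnorm(length(vals), 0, noise_sd),
                              nrow(vals)))
  bg <- matrix(baseline[-seq_len(n_mark)] *
                 exp(stats::rnorm(n_background_genes * n_samples, 0, 0.5)),
               n_background_genes, n_samples)
  m <- rbind(vals, bg)
  dimnames(m) <- list(c(markers, sprintf("BG%04d", seq_len(n_background_genes))),
                      colnames(planted))
  realized <- data.frame(
    sample = colnames(planted),
    fraction_all = colSums(planted) / n_mark,
    fraction_das = colSums(planted[is_das, , drop = FALSE]) / n_das,
    fraction_mss = colSums(planted[!is_das, , drop = FALSE]) / n_mss,
    row.names = NULL)
  list(matrix = m,
       truth = list(fractions = realized, planted = planted,
                    deflection = deflection, noise_sd = noise_sd,
                    seed = seed))
}

#' Generate a GI50 panel with planted score dependence
#'
#' Simulates a compounds x cell-lines growth-inhibition panel on the
#' -log10(GI50 molar) scale.  \code{n_active} compounds depend linearly on
#' the supplied per-line scores (response = intercept + slope x score +
#' Gaussian noise); the remaining compounds are independent noise around
#' the intercept.
#'
#' @param scores Named numeric vector of per-cell-line senescence scores.
#' @param n_compounds Total compounds (default 1000).
#' @param n_active Compounds with a planted linear dependence (default 0).
#' @param slope Planted slope per score percentage point (default -3, on a
#'   score scale of 0-1; use -0.03 if scores are 0-100).
#' @param noise_sd Residual SD (default 1).
#' @param intercept Baseline response (default 5, i.e. 10 uM).
#' @param seed Optional integer seed.
#' @return List with \code{panel} (matrix, rownames \code{CPD0001}...) and
#'   \code{truth} (data frame: \code{compound}, \code{active},
#'   \code{slope}, \code{noise_sd}).
#' @export
generate_gi50 <- function(scores, n_compounds = 1000, n_active = 0,
                          slope = -3, noise_sd = 1, intercept = 5,
                          seed = NULL) {
  if (n_active > n_compounds)
    stop("n_active must not exceed n_compounds", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nl <- length(scores)
  ids <- sprintf("CPD%04d", seq_len(n_compounds))
  panel <- matrix(NA_real_, n_compounds, nl,
                  dimnames = list(ids, names(scores)))
  active <- seq_len(n_compounds) <= n_active
  for (i in seq_len(n_compounds)) {
    mu <- if (active[i]) intercept + slope * scores else rep(intercept, nl)
    panel[i, ] <- mu + stats::rnorm(nl, 0, noise_sd)
  }
  list(panel = panel,
       truth = data.frame(compound = ids, active = active,
                          slope = ifelse(active, slope, 0),
                          noise_sd = noise_sd))
}

#' Residual SD giving a target power for the slope t-test
#'
#' Solves for the Gaussian residual standard deviation at which the
#' two-sided t-test of a simple linear regression slope attains the
#' requested power, given the predictor values actually used — useful for
#' calibrating [generate_gi50()] noise.
#'
#' @param slope True slope.
#' @param x Predictor vector (the per-line scores).
#' @param power Target power (default 0.8).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Residual SD (numeric scalar).
#' @export
noise_sd_for_power <- function(slope, x, power = 0.8, alpha = 0.05) {
  n <- length(x); df <- n - 2L
  sxx <- sum((x - mean(x))^2)
  tcrit <- stats::qt(1 - alpha / 2, df)
  pow <- function(sigma) {
    ncp <- abs(slope) * sqrt(sxx) / sigma
    stats::pt(tcrit, df, ncp, lower.tail = FALSE) +
      stats::pt(-tcrit, df, ncp)
  }
  stats::uniroot(function(s) pow(s) - power,
                 interval = c(1e-8, 1e8 * abs(slope) * sqrt(sxx)))$root
}

#' Generate survival records with a planted group hazard ratio
#'
#' Two groups (A, B) of exponential event times with group-B hazard =
#' \code{hazard_ratio} x group-A hazard, independent exponential
#' censoring calibrated so that about \code{censor_rate} of group-A
#' subjects are censored, ages Normal(60, 10) and sex Bernoulli(0.5),
#' both independent of group.
#'
#' @param n_per_group Subjects per group (default 100).
#' @param hazard_ratio Group-B / group-A hazard (> 0; default 3).
#' @param censor_rate Approximate censored fraction in group A, in [0,1]
#'   (default 0.2; 1 censors everyone).
#' @param base_hazard Group-A event hazard (default 0.1 per time unit).
#' @param seed Optional integer seed.
#' @return Data frame: \code{sample}, \code{time}, \code{event},
#'   \code{age}, \code{sex}, \code{group}; attribute \code{truth} with the
#'   planted parameters.
#' @export
generate_survival <- function(n_per_group = 100, hazard_ratio = 3,
                              censor_rate = 0.2, base_hazard = 0.1,
                              seed = NULL) {
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0", call. = FALSE)
  if (censor_rate < 0 || censor_rate > 1)
    stop("censor_rate must be in [0,1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * n_per_group
  group <- rep(c("A", "B"), each = n_per_group)
  haz <- ifelse(group == "A", base_hazard, base_hazard * hazard_ratio)
  t_event <- stats::rexp(n, haz)
  if (censor_rate >= 1) {
    time <- stats::rexp(n, base_hazard); event <- rep(0L, n)
  } else if (censor_rate == 0) {
    time <- t_event; event <- rep(1L, n)
  } else {
    c_haz <- base_hazard * censor_rate / (1 - censor_rate)
    t_cens <- stats::rexp(n, c_haz)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  }
  out <- data.frame(sample = sprintf("P%03d", seq_len(n)), time = time,
                    event = event, age = stats::rnorm(n, 60, 10),
                    sex = sample(c("M", "F"), n, replace = TRUE),
                    group = group, stringsAsFactors = FALSE)
  attr(out, "truth") <- list(hazard_ratio = hazard_ratio,
                             censor_rate = censor_rate,
                             base_hazard = base_hazard, seed = seed)
  out
}

#' Generate a set of small random molecules
#'
#' Random connected small molecular graphs — paths, rings, stars and
#' singly-branched trees of 4-8 heavy atoms with occasional N/O/S
#' decoration — valid for descriptor computation.  Each molecule carries
#' its SMILES string; under a fixed seed the SMILES list is byte-identical
#' across runs.
#'
#' @param n Number of molecules (0 allowed).
#' @param seed Optional integer seed.
#' @return Named list of \code{mol_graph} objects (names \code{MOL001}...),
#'   each with attribute \code{smiles}; list attribute \code{smiles} gives
#'   the full SMILES character vector.
#' @export
generate_molecule_set <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) return(structure(list(), smiles = character()))
  # decorate positions of degree <= 2 so N/O/S keep chemically sane valences
  decorate <- function(k, bonds) {
    el <- rep("C", k)
    deg <- tabulate(c(bonds[, 1L], bonds[, 2L]), k)
    open <- which(deg <= 2L)
    n_het <- sample(0:min(2L, length(open)), 1L)
    if (n_het > 0) el[sample(open, n_het)] <- sample(c("N", "O", "S"), n_het,
                                                     replace = TRUE)
    el
  }
  out <- list(); smi <- character(n)
  for (i in seq_len(n)) {
    shape <- sample(c("path", "ring", "star", "branched"), 1L)
    k <- if (shape == "star") sample(4:5, 1L) else sample(4:8, 1L)
    if (shape == "path") {
      bonds <- cbind(seq_len(k - 1L), 2:k, 1L)
      el <- decorate(k, bonds)
      s <- paste(el, collapse = "")
    } else if (shape == "ring") {
      bonds <- rbind(cbind(seq_len(k - 1L), 2:k, 1L), c(k, 1L, 1L))
      el <- decorate(k, bonds)
      s <- paste0(el[1L], "1", paste(el[-1L], collapse = ""), "1")
    } else if (shape == "star") {
      bonds <- cbind(1L, 2:k, 1L)
      el <- decorate(k, bonds)       # carbon hub (degree >= 3) stays C
      s <- paste0("C", paste0("(", el[2:(k - 1L)], ")", collapse = ""),
                  el[k])
    } else {
      # path with a single one-atom branch at an interior position
      bp <- sample(2:(k - 2L), 1L)      # branch attachment on the backbone
      backbone <- k - 1L
      bonds <- rbind(cbind(seq_len(backbone - 1L), 2:backbone, 1L),
                     c(bp, k, 1L))
      el <- decorate(k, bonds)          # attachment (degree 3) stays C
      s <- paste0(paste(el[seq_len(bp)], collapse = ""),
                  "(", el[k], ")",
                  paste(el[(bp + 1L):backbone], collapse = ""))
    }
    id <- sprintf("MOL%03d", i)
    mol <- mol_graph(el, bonds)
    attr(mol, "smiles") <- s
    out[[id]] <- mol
    smi[i] <- s
  }
  attr(out, "smiles") <- stats::setNames(smi, names(out))
  out
}
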