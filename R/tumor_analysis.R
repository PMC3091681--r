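#' Rank senescence scores within a tumour group
#'
#' Ascending ranks (1 = lowest score), ties receiving average ranks —
#' ranking within the group smooths the scores before correlating
#' signatures.
#'
#' @param scores Numeric vector of scores for one tumour group and
#'   signature (length >= 3).
#' @return Numeric rank vector.
#' @export
rank_within_group <- function(scores) {
  stopifnot(length(scores) >= 3L)
  if (length(unique(scores)) == 1L)
    warning("constant-ranks: all scores equal; downstream correlation is ",
            "undefined", call. = FALSE)
  rank(scores, ties.method = "average")
}

#' Correlate two within-group score rankings
#'
#' Pearson correlation of two rank vectors (i.e. rank first, then Pearson —
#' kept literal rather than relabelled as Spearman so the tie and p-value
#' behaviour is exactly that of a Pearson test on ranks), with a two-sided
#' p-value from the t distribution on n-2 degrees of freedom.
#'
#' @param ranks_a,ranks_b Equal-length (>= 3) rank vectors, neither
#'   constant.
#' @return One-row data frame: \code{r}, \code{p}, \code{n}.
#' @export
correlate_rankings <- function(ranks_a, ranks_b) {
  stopifnot(length(ranks_a) == length(ranks_b), length(ranks_a) >= 3L)
  if (stats::var(ranks_a) == 0 || stats::var(ranks_b) == 0)
    stop("undefined-correlation: constant rank vector", call. = FALSE)
  ct <- stats::cor.test(ranks_a, ranks_b, method = "pearson",
                        alternative = "two.sided")
  data.frame(r = unname(ct$estimate), p = ct$p.value, n = length(ranks_a))
}

#' Pairwise signature rank correlations per tumour group
#'
#' Convenience wrapper reproducing a correlation-of-rankings table: for
#' each group, scores for each signature are ranked within the group and
#' every signature pair is correlated with [correlate_rankings()].
#'
#' @param scores A \code{senescence_scores} data frame covering >= 2
#'   signatures.
#' @param groups Named character vector (sample -> group) or data frame
#'   with \code{sample}, \code{group}; if omitted all samples form one
#'   group.
#' @return Data frame: \code{group}, \code{signature_a}, \code{signature_b},
#'   \code{r}, \code{p}, \code{n}.
#' @export
correlate_score_rankings <- function(scores, groups = NULL) {
  if (is.null(groups)) {
    groups <- stats::setNames(rep("all_samples", length(unique(scores$sample))),
                              unique(scores$sample))
  } else if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group),
                              as.character(groups$sample))
  }
  scores$group <- groups[scores$sample]
  sigs <- unique(scores$signature)
  out <- list()
  for (g in unique(scores$group)) {
    d <- scores[scores$group == g, ]
    wide <- lapply(sigs, function(s) {
      v <- d[d$signature == s, ]
      stats::setNames(v$score, v$sample)
    })
    samp <- Reduce(intersect, lapply(wide, names))
    for (a in seq_along(sigs)) for (b in seq_along(sigs)) {
      if (a >= b) next
      rc <- correlate_rankings(rank_within_group(wide[[a]][samp]),
                               rank_within_group(wide[[b]][samp]))
      out[[length(out) + 1L]] <- cbind(
        data.frame(group = g, signature_a = sigs[a], signature_b = sigs[b],
                   stringsAsFactors = FALSE), rc)
    }
  }
  do.call(rbind, out)
}

#' Cluster samples (and genes) on the secretory signature
#'
#' Agglomerative hierarchical clustering with distance
#' \eqn{d = 1 - \rho_{Spearman}} and average linkage, applied to both the
#' sample axis and the gene axis of a (typically mSS-restricted,
#' median-normalized) expression matrix.  Because Spearman correlation
#' depends only on ranks, the resulting groups are invariant to any
#' strictly increasing per-gene transform of the data.
#'
#' First-level flat groups are the children of the dendrogram root after
#' collapsing near-tie branches: internal merges whose similarity
#' (\eqn{1 - height}) is within \code{merge_threshold} of the root's are
#' treated as the same split (implemented as a cut at root height minus
#' the threshold).
#'
#' @param m Numeric genes x samples matrix (>= 3 genes, >= 4 samples).
#' @param merge_threshold Similarity width within which branches merge
#'   into one split (default 0.01).
#' @return Object of class \code{mss_clusters}: list with
#'   \code{sample_hclust}, \code{sample_groups} (named integer vector),
#'   \code{gene_hclust}, \code{gene_groups}, \code{dropped} (constant
#'   profiles removed) and \code{merge_threshold}.
#' @export
cluster_samples <- function(m, merge_threshold = 0.01) {
  stopifnot(is.matrix(m))
  const_gene <- apply(m, 1L, function(x) stats::var(x, na.rm = TRUE) == 0)
  const_sample <- apply(m, 2L, function(x) stats::var(x, na.rm = TRUE) == 0)
  dropped <- c(rownames(m)[const_gene], colnames(m)[const_sample])
  if (length(dropped))
    warning("dropping constant profile(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
  m <- m[!const_gene, !const_sample, drop = FALSE]
  if (ncol(m) < 4L || nrow(m) < 3L)
    stop("need >= 4 samples and >= 3 genes after dropping constants",
         call. = FALSE)
  axis_cluster <- function(x) {
    # columns of x are the objects being clustered
    d <- stats::as.dist(1 - stats::cor(x, method = "spearman",
                                       use = "pairwise.complete.obs"))
    hc <- stats::hclust(d, method = "average")
    root_h <- max(hc$height)
    groups <- stats::cutree(hc, h = root_h - merge_threshold)
    list(hclust = hc, groups = groups)
  }
  s <- axis_cluster(m)
  g <- axis_cluster(t(m))
  structure(list(sample_hclust = s$hclust, sample_groups = s$groups,
                 gene_hclust = g$hclust, gene_groups = g$groups,
                 dropped = dropped, merge_threshold = merge_threshold),
            class = "mss_clusters")
}

#' @export
print.mss_clusters <- function(x, ...) {
  cat(sprintf(paste0("mSS clustering: %d samples in %d first-level group(s);",
                     " %d genes in %d group(s)\n"),
              length(x$sample_groups), max(x$sample_groups),
              length(x$gene_groups), max(x$gene_groups)))
  print(table(group = x$sample_groups))
  invisible(x)
}

#' @export
plot.mss_clusters <- function(x, which = c("samples", "genes"), ...) {
  which <- match.arg(which)
  hc <- if (which == "samples") x$sample_hclust else x$gene_hclust
  plot(hc, main = sprintf("mSS clustering (%s)", which),
       xlab = "", sub = "", ...)
  invisible(x)
}

#' Compare survival between sample groups
#'
#' Kaplan-Meier product-limit curves per group, a log-rank test across
#' groups, and a Cox proportional-hazards model adjusting the group effect
#' for age and sex (Efron tie handling).  The adjusted group p-value is a
#' joint Wald test of the group coefficients.  Groups with zero events are
#' kept in the KM estimate but excluded from the Cox fit with a warning.
#'
#' @param records Data frame with columns \code{time} (> 0), \code{event}
#'   (1 = death, 0 = censored), \code{age}, \code{sex} (\code{"M"}/\code{"F"}),
#'   \code{group}; optionally \code{sample}.
#' @return Object of class \code{survival_comparison}: list with \code{km}
#'   (a \code{survfit}), \code{logrank_chisq}, \code{logrank_p},
#'   \code{cox} (the \code{coxph} fit), \code{cox_group_p},
#'   \code{cox_hr} (per non-reference group), \code{n}, \code{n_events}.
#' @export
compare_survival <- function(records) {
  stopifnot(all(c("time", "event", "age", "sex", "group") %in% names(records)))
  stopifnot(all(records$time > 0), all(records$event %in% 0:1))
  records$group <- factor(records$group)
  if (nlevels(records$group) < 2L)
    stop("single-group: need >= 2 groups", call. = FALSE)
  if (sum(records$event) == 0L)
    stop("no-events: all records censored", call. = FALSE)
  km <- survival::survfit(survival::Surv(time, event) ~ group, data = records)
  lr <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = records)
  logrank_p <- stats::pchisq(lr$chisq, df = length(lr$n) - 1L,
                             lower.tail = FALSE)
  ev_by_group <- tapply(records$event, records$group, sum)
  no_event <- names(ev_by_group)[ev_by_group == 0]
  cox_data <- records
  if (length(no_event)) {
    warning("group(s) with zero events excluded from Cox fit: ",
            paste(no_event, collapse = ", "), call. = FALSE)
    cox_data <- droplevels(records[!records$group %in% no_event, ])
  }
  cox <- cox_group_p <- cox_hr <- NULL
  if (nlevels(cox_data$group) >= 2L) {
    # constant adjustment covariates are inestimable and are dropped
    covs <- c("age", "sex")[c(stats::var(cox_data$age) > 0,
                              length(unique(cox_data$sex)) > 1L)]
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                   paste(c("group", covs), collapse = " + ")))
    cox <- survival::coxph(fml, data = cox_data, ties = "efron")
    gi <- grep("^group", names(stats::coef(cox)))
    beta <- stats::coef(cox)[gi]
    V <- stats::vcov(cox)[gi, gi, drop = FALSE]
    wald <- drop(t(beta) %*% solve(V) %*% beta)
    cox_group_p <- stats::pchisq(wald, df = length(gi), lower.tail = FALSE)
    cox_hr <- exp(beta)
  }
  structure(list(km = km, logrank_chisq = unname(lr$chisq),
                 logrank_p = logrank_p, cox = cox,
                 cox_group_p = cox_group_p, cox_hr = cox_hr,
                 n = nrow(records), n_events = sum(records$event)),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("Survival comparison: %d subjects, %d events\n",
              x$n, x$n_events))
  cat(sprintf("  log-rank: chisq = %.3f, p = %.4g\n",
              x$logrank_chisq, x$logrank_p))
  if (!is.null(x$cox_group_p)) {
    cat(sprintf("  Cox (group + age + sex): group p = %.4g; HR = %s\n",
                x$cox_group_p,
                paste(sprintf("%s %.3f", names(x$cox_hr), x$cox_hr),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
plot.survival_comparison <- function(x, ...) {
  plot(x$km, col = seq_along(x$km$strata), lwd = 2,
       xlab = "Time", ylab = "Survival", ...)
  graphics::legend("topright", legend = names(x$km$strata), lwd = 2,
                   col = seq_along(x$km$strata), bty = "n")
  invisible(x)
}
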