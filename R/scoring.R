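#' Median-normalize expression across arrays
#'
#' Divides each gene's values by that gene's median across all samples of
#' the experiment, so that 1 is the cohort-typical level, values > 1 are
#' up-regulated and values < 1 down-regulated relative to the cohort.
#' Missing values stay missing.  Genes whose median is 0 or whose values
#' are all missing cannot be normalized; they are dropped with a warning
#' and listed in the \code{excluded_genes} attribute.
#'
#' Normalization is cohort-relative: scores computed from it are only
#' comparable within the set of arrays normalized together.  At least two
#' samples are required — with one sample every value equals its own
#' median and all scores degenerate to 0.
#'
#' @param m Positive genes x samples matrix (NA = missing).
#' @return Matrix of the same shape (minus excluded genes) of ratios to the
#'   per-gene median, with attribute \code{excluded_genes}.
#' @examples
#' m <- rbind(A = c(2, 4, 6), B = c(5, 5, 5))
#' colnames(m) <- paste0("s", 1:3)
#' median_normalize(m)
#' @export
median_normalize <- function(m) {
  stopifnot(is.matrix(m))
  if (ncol(m) < 2L)
    stop("median normalization needs at least 2 samples; with 1 sample all ",
         "scores are degenerately 0", call. = FALSE)
  if (any(m[!is.na(m)] <= 0))
    stop("expression values must be positive", call. = FALSE)
  med <- apply(m, 1L, stats::median, na.rm = TRUE)
  bad <- is.na(med) | med == 0
  if (any(bad)) {
    warning("degenerate-gene: excluding ", sum(bad),
            " gene(s) with zero or undefined median: ",
            paste(rownames(m)[bad], collapse = ", "), call. = FALSE)
  }
  out <- m[!bad, , drop = FALSE] / med[!bad]
  attr(out, "excluded_genes") <- rownames(m)[bad]
  out
}

marker_is_senescent <- function(value, direction) {
  # strict inequalities: a value exactly at the cohort median (ratio 1)
  # counts non-senescent in both directions
  (direction == "up" & value > 1) | (direction == "down" & value < 1)
}

#' Score one sample against a signature
#'
#' Given a sample's median-normalized values over the markers of a
#' signature, counts the markers signalling in their pro-senescence
#' direction (up-markers above the cohort median, down-markers below) and
#' returns that count as a percentage of the markers expressed (non-missing)
#' in the sample.  A normalized value exactly equal to 1 counts
#' non-senescent under the default strict rule; set
#' \code{ties = "senescent"} to flip that convention.
#'
#' For example, a sample expressing 20 of the 28 combined-signature genes,
#' 16 of them in the pro-senescent direction, scores 80.
#'
#' @param col Named numeric vector of normalized values (names = canonical
#'   symbols); markers missing in the sample are \code{NA}.
#' @param sig A \code{senescence_signature}.
#' @param sample_id Optional sample label carried into the result.
#' @param ties How a value exactly at the median counts
#'   (\code{"non-senescent"}, the default, or \code{"senescent"}).
#' @return One-row data frame: \code{sample}, \code{signature},
#'   \code{n_expressed}, \code{n_senescent}, \code{score} (percent, 0-100).
#' @export
score_sample <- function(col, sig, sample_id = NA_character_,
                         ties = c("non-senescent", "senescent")) {
  stopifnot(inherits(sig, "senescence_signature"))
  ties <- match.arg(ties)
  idx <- match(sig$canonical_symbol, names(col))
  v <- col[idx]
  dir <- sig$direction
  expressed <- !is.na(v)
  n_expressed <- sum(expressed)
  if (n_expressed == 0L)
    stop("unscorable-sample: no signature genes expressed", call. = FALSE)
  sen <- marker_is_senescent(v[expressed], dir[expressed])
  if (ties == "senescent") sen <- sen | v[expressed] == 1
  n_sen <- sum(sen)
  data.frame(sample = sample_id, signature = attr(sig, "name"),
             n_expressed = n_expressed, n_senescent = n_sen,
             score = 100 * n_sen / n_expressed,
             stringsAsFactors = FALSE)
}

#' Score every sample of an experiment against one or more signatures
#'
#' The full scoring pipeline for one experiment: restrict the matrix to
#' signature markers, median-normalize once across all arrays of the
#' experiment, then score each sample against each requested signature.
#' Because the median is taken per gene, normalizing the signature-filtered
#' matrix (default) and normalizing genome-wide before filtering give
#' identical marker ratios; \code{median_scope = "global"} is provided for
#' matrices whose non-signature rows should still be checked/normalized.
#'
#' Samples in which a signature has no expressed markers get an \code{NA}
#' score with a warning rather than aborting the run.
#'
#' @param m Positive gene-level matrix, canonical symbols as rownames.
#' @param signatures Character vector among \code{"all"}, \code{"das"},
#'   \code{"mss"} (default: all three), or a list of
#'   \code{senescence_signature} objects.
#' @param median_scope \code{"filtered"} (normalize the signature-restricted
#'   matrix; default) or \code{"global"} (normalize the full matrix first).
#' @param ties Tie convention passed to [score_sample()].
#' @return Data frame of class \code{senescence_scores} with one row per
#'   sample x signature: \code{sample}, \code{signature}, \code{n_expressed},
#'   \code{n_senescent}, \code{score}.
#' @examples
#' set.seed(1)
#' m <- generate_expression(n_samples = 6,
#'                          planted_fractions = rep(c(1, 0), 3))$matrix
#' head(score_dataset(m))
#' @export
score_dataset <- function(m, signatures = c("all", "das", "mss"),
                          median_scope = c("filtered", "global"),
                          ties = "non-senescent") {
  median_scope <- match.arg(median_scope)
  if (is.character(signatures)) signatures <- lapply(signatures, load_signature)
  stopifnot(all(vapply(signatures, inherits, TRUE, "senescence_signature")))
  union_sig <- do.call(rbind, lapply(signatures, as.data.frame))
  union_sym <- unique(union_sig$canonical_symbol)
  if (median_scope == "global") {
    nm <- median_normalize(m)
    nm <- nm[rownames(nm) %in% union_sym, , drop = FALSE]
  } else {
    keep <- rownames(m) %in% union_sym
    if (!any(keep))
      stop("empty-overlap: no signature genes found in matrix", call. = FALSE)
    nm <- median_normalize(m[keep, , drop = FALSE])
  }
  res <- vector("list", length(signatures) * ncol(nm))
  k <- 0L
  for (sig in signatures) {
    for (j in seq_len(ncol(nm))) {
      k <- k + 1L
      col <- stats::setNames(nm[, j], rownames(nm))
      res[[k]] <- tryCatch(
        score_sample(col, sig, sample_id = colnames(nm)[j], ties = ties),
        error = function(e) {
          warning("sample '", colnames(nm)[j], "', signature '",
                  attr(sig, "name"), "': ", conditionMessage(e),
                  call. = FALSE)
          data.frame(sample = colnames(nm)[j], signature = attr(sig, "name"),
                     n_expressed = 0L, n_senescent = 0L, score = NA_real_,
                     stringsAsFactors = FALSE)
        })
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("senescence_scores", "data.frame")
  out
}

#' @export
print.senescence_scores <- function(x, ...) {
  cat(sprintf("Senescence scores: %d samples x %d signature(s)\n",
              length(unique(x$sample)), length(unique(x$signature))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Summarize scores per sample group
#'
#' Reduces per-sample scores to the median with minimum and maximum per
#' group and signature — the representation used when comparing e.g.
#' treated with untreated cohorts.
#'
#' @param scores A \code{senescence_scores} data frame.
#' @param groups Named character vector mapping sample id to group label,
#'   or a data frame with columns \code{sample} and \code{group}.  Every
#'   scored sample must be covered.
#' @return Data frame: \code{group}, \code{signature}, \code{n},
#'   \code{median}, \code{min}, \code{max}.
#' @export
summarize_scores <- function(scores, groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("sample", "group") %in% names(groups)))
    groups <- stats::setNames(as.character(groups$group),
                              as.character(groups$sample))
  }
  miss <- setdiff(unique(scores$sample), names(groups))
  if (length(miss))
    stop("no group for sample(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  scores$group <- groups[scores$sample]
  empty <- setdiff(unique(groups), scores$group)
  if (length(empty))
    warning("omitting empty group(s): ", paste(empty, collapse = ", "),
            call. = FALSE)
  parts <- split(scores, list(scores$group, scores$signature), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(d) {
    s <- d$score[!is.na(d$score)]
    data.frame(group = d$group[1L], signature = d$signature[1L],
               n = length(s), median = stats::median(s),
               min = min(s), max = max(s), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$signature, out$group), ]
  rownames(out) <- NULL
  out
}
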