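#' Regress growth inhibition on senescence score
#'
#' Ordinary least squares of a compound's per-cell-line growth-inhibition
#' values (GI50 on any consistent scale; conventionally -log10 molar for
#' NCI60-style panels) on the lines' senescence scores.  A negative slope
#' means high-scoring lines are more sensitive to the compound.  Pairs with
#' either value missing are dropped (complete-case).
#'
#' @param scores Numeric vector of per-line scores.
#' @param gi50 Numeric vector of per-line responses, same length/order.
#' @param compound_id Optional label carried into the result.
#' @param signature Optional signature label carried into the result.
#' @return One-row data frame: \code{compound}, \code{signature}, \code{n},
#'   \code{slope}, \code{intercept}, \code{p_slope} (two-sided t-test for
#'   slope != 0), \code{r2}.
#' @export
fit_gi50_regression <- function(scores, gi50, compound_id = NA_character_,
                                signature = NA_character_) {
  stopifnot(length(scores) == length(gi50))
  ok <- !is.na(scores) & !is.na(gi50)
  x <- scores[ok]; y <- gi50[ok]
  if (length(x) < 3L)
    stop("degenerate-regression: fewer than 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0)
    stop("degenerate-regression: constant score vector", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  data.frame(compound = compound_id, signature = signature, n = length(x),
             slope = co["x", "Estimate"],
             intercept = co["(Intercept)", "Estimate"],
             p_slope = co["x", "Pr(>|t|)"], r2 = sm$r.squared,
             stringsAsFactors = FALSE)
}

#' Screen a GI50 panel against the DAS and mSS scores
#'
#' Runs two regressions per compound — growth inhibition on the DAS score
#' and on the mSS score across the cell-line panel — and partitions
#' compounds by which regressions reach significance at \code{alpha}
#' (raw p-values by default, mirroring a plain p < 0.05 screen; set
#' \code{adjust = "BH"} for a Benjamini-Hochberg corrected screen):
#' \code{das_only}, \code{mss_only}, \code{both}, or \code{neither}.
#'
#' @param panel Numeric compounds x cell-lines matrix (rownames = compound
#'   ids, colnames = cell-line ids); NA for untested pairs.
#' @param das_scores,mss_scores Named numeric vectors of per-line scores;
#'   names must cover the panel's cell lines.
#' @param alpha Significance threshold in (0,1); default 0.05.
#' @param min_lines Minimum non-missing lines for a compound to be tested
#'   (default 30).
#' @param adjust P-value adjustment across compounds per signature:
#'   \code{"none"} (default) or \code{"BH"}.
#' @return Object of class \code{compound_screen}: list with
#'   \code{results} (per compound x signature regression table),
#'   \code{classification} (list of compound-id vectors \code{das_only},
#'   \code{mss_only}, \code{both}, \code{neither}), \code{skipped}
#'   (compounds dropped as degenerate/under-replicated) and \code{alpha}.
#' @examples
#' set.seed(2)
#' das <- stats::setNames(runif(40, 20, 90), paste0("L", 1:40))
#' mss <- stats::setNames(runif(40, 20, 90), paste0("L", 1:40))
#' g <- generate_gi50(das, n_compounds = 20, n_active = 5, slope = -3,
#'                    noise_sd = 10)
#' screen_compounds(g$panel, das, mss)
#' @export
screen_compounds <- function(panel, das_scores, mss_scores, alpha = 0.05,
                             min_lines = 30L, adjust = c("none", "BH")) {
  stopifnot(is.matrix(panel), alpha > 0, alpha < 1)
  adjust <- match.arg(adjust)
  lines_ <- colnames(panel)
  if (is.null(lines_)) stop("panel needs cell-line column names", call. = FALSE)
  if (!all(lines_ %in% names(das_scores)) ||
      !all(lines_ %in% names(mss_scores)))
    stop("score vectors must cover every panel cell line", call. = FALSE)
  das <- das_scores[lines_]; mss <- mss_scores[lines_]
  res <- list(); skipped <- character()
  for (cp in rownames(panel)) {
    y <- panel[cp, ]
    if (sum(!is.na(y)) < min_lines) { skipped <- c(skipped, cp); next }
    r <- tryCatch(
      rbind(fit_gi50_regression(das, y, cp, "das"),
            fit_gi50_regression(mss, y, cp, "mss")),
      error = function(e) NULL)
    if (is.null(r)) skipped <- c(skipped, cp) else res[[cp]] <- r
  }
  if (!length(res))
    stop("no compound passed the replication/degeneracy filters", call. = FALSE)
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  p_das <- results$p_slope[results$signature == "das"]
  p_mss <- results$p_slope[results$signature == "mss"]
  if (adjust == "BH") {
    p_das <- stats::p.adjust(p_das, "BH")
    p_mss <- stats::p.adjust(p_mss, "BH")
  }
  ids <- results$compound[results$signature == "das"]
  sig_d <- p_das < alpha; sig_m <- p_mss < alpha
  classification <- list(das_only = ids[sig_d & !sig_m],
                         mss_only = ids[!sig_d & sig_m],
                         both     = ids[sig_d & sig_m],
                         neither  = ids[!sig_d & !sig_m])
  structure(list(results = results, classification = classification,
                 skipped = skipped, alpha = alpha, adjust = adjust),
            class = "compound_screen")
}

#' @export
print.compound_screen <- function(x, ...) {
  n <- vapply(x$classification, length, 0L)
  cat(sprintf(
    "Compound screen (alpha = %g%s): %d compounds tested, %d skipped\n",
    x$alpha, if (x$adjust == "BH") ", BH-adjusted" else "",
    sum(n), length(x$skipped)))
  cat(sprintf("  DAS only: %d   mSS only: %d   both: %d   neither: %d\n",
              n[["das_only"]], n[["mss_only"]], n[["both"]], n[["neither"]]))
  invisible(x)
}

#' @export
summary.compound_screen <- function(object, ...) {
  data.frame(signature = c("das", "mss"),
             n_unique_significant = c(length(object$classification$das_only),
                                      length(object$classification$mss_only)),
             mean_slope = c(
               tryCatch(mean_significant_slope(object, "das"),
                        error = function(e) NA_real_),
               tryCatch(mean_significant_slope(object, "mss"),
                        error = function(e) NA_real_)),
             stringsAsFactors = FALSE)
}

#' Mean regression slope over a signature's unique-significant compounds
#'
#' Arithmetic mean of the fitted slope across the compounds significantly
#' related to exactly one signature (the \code{das_only} or \code{mss_only}
#' set).  A negative mean indicates that high-scoring cell lines are on
#' average more sensitive to those compounds.
#'
#' @param screen A \code{compound_screen} from [screen_compounds()].
#' @param signature \code{"das"} or \code{"mss"}.
#' @return Single numeric mean slope.
#' @export
mean_significant_slope <- function(screen, signature = c("das", "mss")) {
  stopifnot(inherits(screen, "compound_screen"))
  signature <- match.arg(signature)
  set <- screen$classification[[paste0(signature, "_only")]]
  if (!length(set))
    stop("no-significant-compounds for signature '", signature, "'",
         call. = FALSE)
  r <- screen$results
  mean(r$slope[r$signature == signature & r$compound %in% set])
}
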