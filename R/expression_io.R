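#' Read a gene expression matrix
#'
#' Reads gene-level (or probe-level) expression into a numeric genes x
#' samples matrix.  Two dialects are supported:
#'
#' \describe{
#'   \item{\code{tsv}}{UTF-8, tab-delimited; first row holds sample ids,
#'     first column gene/probe ids, an empty cell is missing.}
#'   \item{\code{geo_series_matrix}}{a GEO series-matrix file; only lines
#'     between \code{!series_matrix_table_begin} and
#'     \code{!series_matrix_table_end} are read (the first as the header),
#'     all other lines are treated as metadata and skipped.  Quoted ids are
#'     unquoted.}
#' }
#'
#' Missing cells are recorded as \code{NA}, never coerced to zero.
#' Malformed input (ragged rows, non-numeric cells, missing or duplicated
#' ids) signals an error naming the offending line.
#'
#' @param path Path to the file.
#' @param format \code{"tsv"} (default) or \code{"geo_series_matrix"}.
#' @return Numeric matrix, rownames = gene/probe ids, colnames = sample ids.
#' @seealso [write_expression_matrix()], [collapse_probes()],
#'   [filter_to_signature()]
#' @export
read_expression_matrix <- function(path, format = c("tsv", "geo_series_matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (format == "geo_series_matrix") {
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L) {
      stop("series-matrix sentinels missing or empty table in ", path,
           call. = FALSE)
    }
    offset <- beg            # line numbers reported relative to the file
    lines <- lines[(beg + 1L):(end - 1L)]
  } else {
    offset <- 0L
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("no data rows in ", path, call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  # strsplit drops a trailing empty field; pad so trailing missing cells survive
  width <- length(cells[[1L]])
  cells <- lapply(seq_along(cells), function(i) {
    x <- cells[[i]]
    n_tab <- lengths(regmatches(lines[i], gregexpr("\t", lines[i], fixed = TRUE)))
    if (length(x) < n_tab + 1L) x <- c(x, rep("", n_tab + 1L - length(x)))
    x
  })
  unquote <- function(x) gsub('^"|"$', "", x)
  header <- unquote(cells[[1L]])
  sample_ids <- header[-1L]
  if (length(sample_ids) < 1L || any(!nzchar(sample_ids)))
    stop("malformed header (line ", offset + 1L, "): empty sample id",
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("malformed header (line ", offset + 1L, "): duplicated sample ids",
         call. = FALSE)
  body <- cells[-1L]
  n_col <- length(header)
  rows <- lapply(seq_along(body), function(i) {
    x <- body[[i]]
    line_no <- offset + 1L + i
    if (length(x) != n_col)
      stop("ragged row at line ", line_no, ": expected ", n_col,
           " fields, found ", length(x), call. = FALSE)
    vals <- x[-1L]
    vals[vals %in% c("", "NA", "null")] <- NA_character_
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(num))
    if (length(bad))
      stop("non-numeric cell at line ", line_no, ", column ",
           bad[1L] + 1L, ": '", vals[bad[1L]], "'", call. = FALSE)
    num
  })
  gene_ids <- unquote(vapply(body, `[[`, "", 1L))
  if (any(!nzchar(gene_ids)))
    stop("empty gene id at line ",
         offset + 1L + which(!nzchar(gene_ids))[1L], call. = FALSE)
  m <- do.call(rbind, rows)
  dimnames(m) <- list(gene_ids, sample_ids)
  m
}

#' Write an expression matrix in the package TSV dialect
#'
#' Inverse of [read_expression_matrix()] for the \code{tsv} dialect:
#' missing values are written as empty cells, so a write/read cycle is
#' value-identical.
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  fmt <- function(v) ifelse(is.na(v), "", formatC(v, digits = 15, format = "g"))
  lines <- c(paste(c("gene", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Collapse array probes to gene-level rows
#'
#' Reduces multiple probes per gene symbol to a single gene row.  The
#' \code{median} rule takes the per-sample median over a gene's probes
#' (robust default); \code{max_mean} keeps the single probe with the
#' largest mean expression across samples (ties broken by first probe in
#' input order).  Probes absent from the annotation are dropped and counted.
#'
#' @param m Probe-level matrix from [read_expression_matrix()].
#' @param annotation Named character vector mapping probe id to gene symbol
#'   (names = probe ids), or a data frame with columns \code{probe_id} and
#'   \code{symbol}.  Each probe maps to at most one symbol.
#' @param rule \code{"median"} (default) or \code{"max_mean"}.
#' @return Gene-level matrix (rows ordered by first appearance of each
#'   symbol) with attribute \code{dropped_probes}: the unmapped probe ids.
#' @export
collapse_probes <- function(m, annotation, rule = c("median", "max_mean")) {
  rule <- match.arg(rule)
  if (is.data.frame(annotation)) {
    stopifnot(all(c("probe_id", "symbol") %in% names(annotation)))
    annotation <- stats::setNames(as.character(annotation$symbol),
                                  as.character(annotation$probe_id))
  }
  if (anyDuplicated(names(annotation)))
    stop("annotation maps a probe to more than one symbol", call. = FALSE)
  sym <- annotation[rownames(m)]
  mapped <- !is.na(sym) & nzchar(sym)
  if (!any(mapped)) stop("empty-mapping: annotation covers zero probes",
                         call. = FALSE)
  dropped <- rownames(m)[!mapped]
  m2 <- m[mapped, , drop = FALSE]
  sym <- sym[mapped]
  genes <- unique(sym)
  out <- matrix(NA_real_, length(genes), ncol(m2),
                dimnames = list(genes, colnames(m2)))
  for (g in genes) {
    rows <- m2[sym == g, , drop = FALSE]
    if (nrow(rows) == 1L) {
      out[g, ] <- rows
    } else if (rule == "median") {
      out[g, ] <- apply(rows, 2L, stats::median, na.rm = TRUE)
      out[g, is.nan(out[g, ])] <- NA_real_
    } else {
      means <- rowMeans(rows, na.rm = TRUE)
      out[g, ] <- rows[which.max(means), ]
    }
  }
  attr(out, "dropped_probes") <- dropped
  out
}

#' Restrict an expression matrix to signature genes
#'
#' Keeps only the rows of \code{m} matching the markers of a signature, in
#' signature order.  Row ids must already be canonical symbols (see
#' [resolve_alias()]).  Markers absent from the matrix are reported in the
#' \code{missing_markers} attribute, since percent scores are computed over
#' the markers actually present.
#'
#' @param m Gene-level matrix with canonical symbols as rownames.
#' @param sig A \code{senescence_signature} from [load_signature()].
#' @return Sub-matrix of \code{m} (signature order) with attribute
#'   \code{missing_markers}.
#' @export
filter_to_signature <- function(m, sig) {
  stopifnot(inherits(sig, "senescence_signature"))
  present <- sig$canonical_symbol %in% rownames(m)
  if (!any(present))
    stop("empty-overlap: no signature genes found in matrix", call. = FALSE)
  out <- m[sig$canonical_symbol[present], , drop = FALSE]
  attr(out, "missing_markers") <- sig$canonical_symbol[!present]
  out
}
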