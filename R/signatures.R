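#' Senescence marker signatures
#'
#' The package ships three directional marker signatures describing latent
#' senescence signalling in tumour expression data:
#'
#' \describe{
#'   \item{\code{das}}{12 DNA damage-associated senescence (DAS) markers:
#'     genes of the DNA damage and chromatin response arms of senescence
#'     (e.g. CDKN2A/p16, CDKN1A/p21, TP53BP1, macroH2A variants).  All are
#'     up-regulated in senescence except MKI67 (Ki67), whose loss marks
#'     exit from the cell cycle.}
#'   \item{\code{mss}}{16 modified secretory senescence (mSS) markers:
#'     the senescence messaging secretome / senescence-associated secretory
#'     phenotype (SMS/SASP) genes plus serum-detectable damage markers.
#'     IGF1, IGF2 and WNT2 are down-regulated in senescence; the rest are
#'     up-regulated.}
#'   \item{\code{all}}{the disjoint union of \code{das} and \code{mss}
#'     (28 markers).}
#' }
#'
#' Signatures are data, not code: the packaged table
#' (\code{system.file("extdata", "signatures.tsv", package = "senescore")})
#' has columns \code{signature}, \code{paper_symbol}, \code{canonical_symbol}
#' and \code{direction}, and users may point \code{load_signature()} at an
#' edited copy as marker knowledge evolves.
#'
#' @param name One of \code{"all"}, \code{"das"}, \code{"mss"}.
#' @param config Path to a signature table; defaults to the packaged one.
#' @return An object of class \code{senescence_signature}: a data frame with
#'   columns \code{canonical_symbol}, \code{paper_symbol}, \code{direction}
#'   (\code{"up"}/\code{"down"}) and \code{signature} (\code{"das"} or
#'   \code{"mss"} for each marker), plus attribute \code{name}.
#' @examples
#' sig <- load_signature("das")
#' nrow(sig)                         # 12
#' sig$direction[sig$canonical_symbol == "MKI67"]   # "down"
#' @export
load_signature <- function(name = c("all", "das", "mss"), config = NULL) {
  if (length(name) != 1L || !name %in% c("all", "das", "mss")) {
    stop("invalid-signature: 'name' must be one of \"all\", \"das\", \"mss\"",
         call. = FALSE)
  }
  if (is.null(config)) {
    config <- system.file("extdata", "signatures.tsv", package = "senescore")
  }
  tab <- utils::read.delim(config, stringsAsFactors = FALSE)
  required <- c("signature", "paper_symbol", "canonical_symbol", "direction")
  if (!all(required %in% names(tab))) {
    stop("signature config must have columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (!all(tab$direction %in% c("up", "down"))) {
    stop("signature directions must be 'up' or 'down'", call. = FALSE)
  }
  sub <- if (name == "all") tab else tab[tab$signature == name, , drop = FALSE]
  if (anyDuplicated(sub$canonical_symbol)) {
    stop("duplicate canonical symbols in signature '", name, "'", call. = FALSE)
  }
  out <- sub[, c("canonical_symbol", "paper_symbol", "direction", "signature")]
  rownames(out) <- NULL
  attr(out, "name") <- name
  class(out) <- c("senescence_signature", "data.frame")
  out
}

#' @export
print.senescence_signature <- function(x, ...) {
  cat(sprintf("Senescence signature '%s': %d markers (%d up, %d down)\n",
              attr(x, "name"), nrow(x),
              sum(x$direction == "up"), sum(x$direction == "down")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Resolve gene symbols against the packaged alias table
#'
#' Marker tables in the senescence literature mix protein-style names (p16,
#' Ki67, PAI1) with HGNC symbols; expression platforms use HGNC symbols.
#' This helper maps free-text symbols to canonical symbols using a static,
#' editable alias table.  It is total: symbols with no alias entry are
#' returned unchanged and flagged unresolved.  Canonical symbols (anything
#' appearing in the \code{canonical_symbol} column of the signature table or
#' the alias table) resolve to themselves, which makes the mapping
#' idempotent.
#'
#' @param symbols Character vector of gene symbols (nonempty strings).
#' @param alias_file Path to a two-column (\code{alias},
#'   \code{canonical_symbol}) tab-delimited table; defaults to the packaged
#'   one.
#' @return Character vector of canonical symbols, same length as
#'   \code{symbols}, with a logical attribute \code{resolved} marking which
#'   inputs were recognised (either as an alias or as a canonical symbol).
#' @examples
#' resolve_alias(c("p16", "CDKN2A", "NOTAGENE"))
#' @export
resolve_alias <- function(symbols, alias_file = NULL) {
  stopifnot(is.character(symbols))
  if (any(!nzchar(symbols))) stop("gene symbols must be nonempty", call. = FALSE)
  if (is.null(alias_file)) {
    alias_file <- system.file("extdata", "gene_aliases.tsv", package = "senescore")
  }
  ali <- utils::read.delim(alias_file, stringsAsFactors = FALSE)
  sig <- utils::read.delim(
    system.file("extdata", "signatures.tsv", package = "senescore"),
    stringsAsFactors = FALSE)
  canon <- unique(c(ali$canonical_symbol, sig$canonical_symbol))
  idx <- match(symbols, ali$alias)
  out <- ifelse(is.na(idx), symbols, ali$canonical_symbol[idx])
  attr(out, "resolved") <- !is.na(idx) | symbols %in% canon
  out
}

#' Secretory-signature gene groups driving mesothelioma clustering
#'
#' Returns the packaged table of the two mSS gene groups whose opposed
#' expression separates peritoneal mesothelioma samples into a
#' pro-inflammatory (better-outcome) group and a pro-growth group.  The
#' table is reproduced exactly as published, including two markers (CXCR2
#' and EEF1A1) listed in both groups; these rows carry
#' \code{duplicated_across_groups = TRUE} so downstream code can decide how
#' to treat them.
#'
#' @return Data frame with columns \code{gene_group}, \code{paper_symbol},
#'   \code{canonical_symbol}, \code{duplicated_across_groups}.
#' @export
mesothelioma_gene_groups <- function() {
  utils::read.delim(
    system.file("extdata", "mesothelioma_gene_groups.tsv", package = "senescore"),
    stringsAsFactors = FALSE)
}
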