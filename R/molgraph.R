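#' Molecular graphs
#'
#' A minimal 2D molecule representation for graph-theoretic descriptor
#' computation: heavy atoms with element, formal charge and implicit
#' hydrogen count, and bonds with integer order.  Hydrogens are implicit
#' (counted from standard valences) and the graph must be connected with at
#' least one heavy atom; multi-fragment input should be reduced to its
#' largest fragment first (see [read_smiles()]).
#'
#' @param elements Character vector of element symbols (C, N, O, S, F, Cl,
#'   Br supported).
#' @param bonds Two-column integer matrix (or data frame) of atom index
#'   pairs, plus an \code{order} column (1-3); may have zero rows for a
#'   single atom.
#' @param charges Integer formal charges per atom (default 0).
#' @return Object of class \code{mol_graph}: list with \code{atoms}
#'   (data frame: \code{element}, \code{charge}, \code{nH}) and
#'   \code{bonds} (data frame: \code{i}, \code{j}, \code{order}).
#' @export
mol_graph <- function(elements, bonds, charges = 0L) {
  n <- length(elements)
  if (n < 1L) stop("a molecule needs at least one heavy atom", call. = FALSE)
  if (!all(elements %in% names(.element_data$valence)))
    stop("unsupported element(s): ",
         paste(setdiff(elements, names(.element_data$valence)), collapse = ", "),
         call. = FALSE)
  charges <- rep_len(as.integer(charges), n)
  bonds <- as.data.frame(bonds)
  if (nrow(bonds)) {
    names(bonds)[1:3] <- c("i", "j", "order")
    stopifnot(all(bonds$i >= 1), all(bonds$j >= 1),
              all(bonds$i <= n), all(bonds$j <= n), all(bonds$i != bonds$j),
              all(bonds$order %in% 1:3))
  } else {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  }
  # implicit hydrogens from standard valence, shifted by formal charge
  # (N+ gains a bonding slot, O- loses one)
  bo <- numeric(n)
  for (k in seq_len(nrow(bonds))) {
    bo[bonds$i[k]] <- bo[bonds$i[k]] + bonds$order[k]
    bo[bonds$j[k]] <- bo[bonds$j[k]] + bonds$order[k]
  }
  val <- ifelse(elements == "C",
                .element_data$valence[elements] - abs(charges),
                .element_data$valence[elements] + charges)
  nH <- pmax(0L, as.integer(val - bo))
  m <- structure(list(atoms = data.frame(element = elements, charge = charges,
                                         nH = nH, stringsAsFactors = FALSE),
                      bonds = bonds),
                 class = "mol_graph")
  g <- mol_igraph(m)
  if (igraph::components(g)$no != 1L)
    stop("molecular graph must be connected (keep the largest fragment)",
         call. = FALSE)
  m
}

.element_data <- list(
  valence = c(C = 4L, N = 3L, O = 2L, S = 2L, F = 1L, Cl = 1L, Br = 1L),
  mass = c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, F = 18.998,
           Cl = 35.45, Br = 79.904, H = 1.008),
  electronegativity = c(C = 2.55, N = 3.04, O = 3.44, S = 2.58, F = 3.98,
                        Cl = 3.16, Br = 2.96),
  polarizability = c(C = 1.76, N = 1.10, O = 0.80, S = 2.90, F = 0.56,
                     Cl = 2.18, Br = 3.05),
  vdw_radius = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, F = 1.47,
                 Cl = 1.75, Br = 1.85, H = 1.20),
  z = c(C = 6L, N = 7L, O = 8L, S = 16L, F = 9L, Cl = 17L, Br = 35L),
  zv = c(C = 4L, N = 5L, O = 6L, S = 6L, F = 7L, Cl = 7L, Br = 7L))

mol_igraph <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds)) mol$bonds[, c("i", "j")] else
      data.frame(i = integer(), j = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mol$atoms))))
}

#' @export
print.mol_graph <- function(x, ...) {
  comp <- table(x$atoms$element)
  cat(sprintf("<mol_graph> %d heavy atoms (%s), %d bonds, %d ring(s)\n",
              nrow(x$atoms),
              paste(names(comp), comp, sep = "", collapse = " "),
              nrow(x$bonds),
              nrow(x$bonds) - nrow(x$atoms) + 1L))
  invisible(x)
}

#' Read molecules from SMILES or SDF
#'
#' Parses structures with OpenBabel (via \pkg{ChemmineR}) and pre-processes
#' them for descriptor computation: salts/counterions (dot-separated
#' fragments) are reduced to the largest fragment, hydrogens are completed
#' implicitly, and — optionally — simple physiological-pH charge rules are
#' applied (carboxylic acids deprotonated, non-amide amines protonated).
#' Structures that fail to parse are dropped with a warning and listed in
#' the \code{failed} attribute.
#'
#' @param x Path to a file (one SMILES per line, optional id after
#'   whitespace; or an \code{.sdf} file), or a character vector of SMILES.
#' @param ph_charges Apply the rule-based (de)protonation (default TRUE).
#' @return Named list of \code{mol_graph} objects, attribute \code{failed}
#'   naming unparsable inputs.
#' @export
read_smiles <- function(x, ph_charges = TRUE) {
  if (length(x) == 1L && file.exists(x) && grepl("\\.sdf$", x)) {
    sdfset <- ChemmineR::read.SDFset(x)
    ids <- make.unique(ChemmineR::sdfid(sdfset))
    sdfs <- as.list(ChemmineR::SDFset2SDF(sdfset))
  } else {
    if (length(x) == 1L && file.exists(x)) {
      lines <- readLines(x, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      parts <- strsplit(trimws(lines), "[ \t]+")
      smi <- vapply(parts, `[[`, "", 1L)
      ids <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else p[1L], "")
    } else {
      smi <- x
      ids <- if (is.null(names(x))) x else names(x)
    }
    ids <- make.unique(ids)
    # counterion removal: keep the largest dot-separated fragment
    smi <- vapply(strsplit(smi, ".", fixed = TRUE), function(fr) {
      fr[which.max(nchar(fr))]
    }, "")
    # one bad SMILES aborts a whole OpenBabel batch, so parse per molecule
    sdfs <- lapply(seq_along(smi), function(k) {
      tryCatch(ChemmineR::smiles2sdf(stats::setNames(smi[k], ids[k]))@SDF[[1L]],
               error = function(e) NULL)
    })
  }
  out <- list(); failed <- character()
  for (k in seq_along(sdfs)) {
    m <- if (is.null(sdfs[[k]])) NULL else
      tryCatch(sdf_to_mol(sdfs[[k]]), error = function(e) NULL)
    if (is.null(m)) failed <- c(failed, ids[k]) else out[[ids[k]]] <- m
  }
  if (length(failed))
    warning("bad-molecule: dropped ", length(failed), " unparsable structure(s)",
            call. = FALSE)
  if (ph_charges) out <- lapply(out, apply_ph_charges)
  attr(out, "failed") <- failed
  out
}

sdf_to_mol <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  el <- sub("_.*$", "", rownames(ab))
  heavy <- el != "H"
  idx <- cumsum(heavy)
  bonds <- data.frame(i = integer(), j = integer(), order = integer())
  if (!is.null(bb) && nrow(bb)) {
    keep <- heavy[bb[, 1L]] & heavy[bb[, 2L]]
    bonds <- data.frame(i = idx[bb[keep, 1L]], j = idx[bb[keep, 2L]],
                        order = as.integer(bb[keep, 3L]))
  }
  mol_graph(el[heavy], bonds)
}

#' Apply simple physiological-pH charge rules
#'
#' Rule-based (de)protonation of the commonest ionisable groups at pH ~7.4:
#' carboxylic acid oxygens (\code{-C(=O)-OH}) lose their proton (charge -1)
#' and amine nitrogens (three or fewer single bonds, no double bonds, not
#' bonded to a carbonyl carbon, i.e. not amides) gain one (charge +1).
#' Deliberately minimal; no pKa model.
#'
#' @param mol A \code{mol_graph}.
#' @return A \code{mol_graph} with updated charges and hydrogen counts.
#' @export
apply_ph_charges <- function(mol) {
  a <- mol$atoms; b <- mol$bonds
  n <- nrow(a)
  nbr <- function(i) {
    rbind(data.frame(o = b$j[b$i == i], ord = b$order[b$i == i]),
          data.frame(o = b$i[b$j == i], ord = b$order[b$j == i]))
  }
  charges <- a$charge
  for (i in seq_len(n)) {
    nb <- nbr(i)
    if (a$element[i] == "O" && nrow(nb) == 1L && nb$ord[1L] == 1L &&
        a$nH[i] >= 1L) {
      cpos <- nb$o[1L]
      if (a$element[cpos] == "C") {
        cnb <- nbr(cpos)
        if (any(a$element[cnb$o] == "O" & cnb$ord == 2L)) charges[i] <- -1L
      }
    }
    if (a$element[i] == "N" && a$nH[i] >= 1L && all(nb$ord == 1L)) {
      amide <- any(vapply(nb$o, function(cpos) {
        a$element[cpos] == "C" &&
          any({cn <- nbr(cpos); a$element[cn$o] == "O" & cn$ord == 2L})
      }, TRUE))
      if (!amide) charges[i] <- 1L
    }
  }
  mol_graph(a$element, b, charges)
}
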