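#' Names and order of the 2D descriptor set
#'
#' The package computes a fixed, documented set of 50 open-formula 2D
#' molecular descriptors covering the classic graph-theoretic families:
#' composition counts, Wiener path/polarity indices, Petitjean shape,
#' Zagreb/Platt/Harary/eccentric-connectivity indices, Balaban J,
#' Kier-Hall connectivity (chi) indices in simple and valence form, Kier
#' kappa shape indices, GCUT eigenvalue descriptors over three atomic
#' properties, a fragment-additive topological polar surface area, and
#' additive van der Waals surface/volume approximations.  Every vector
#' returned by [compute_descriptors()] has exactly these names in this
#' order.
#'
#' @return Character vector of 50 descriptor names.
#' @export
descriptor_names <- function() {
  c("n_atoms", "n_bonds", "n_rings", "n_hetero", "n_N", "n_O", "n_S",
    "n_halogen", "frac_hetero", "total_charge", "n_hbond_donor",
    "n_hbond_acceptor", "mol_weight",
    "diameter", "radius", "petitjean", "wiener", "wiener_polarity",
    "harary", "zagreb1", "zagreb2", "platt", "eccentric_connectivity",
    "balaban_j",
    "chi0", "chi1", "chi2", "chi3p", "chi0v", "chi1v", "chi2v", "chi3pv",
    "kappa1", "kappa2", "kappa3",
    paste0("gcut_charge_", 0:3), paste0("gcut_en_", 0:3),
    paste0("gcut_pol_", 0:3),
    "tpsa", "vdw_area", "vdw_volume")
}

#' Compute 2D molecular descriptors
#'
#' Deterministically computes the 50-descriptor vector described in
#' [descriptor_names()] from a heavy-atom molecular graph.  Formulas (all
#' on the hydrogen-suppressed graph; \eqn{d_{ij}} = shortest-path
#' distance, \eqn{\delta_i} = heavy-atom degree):
#'
#' \itemize{
#'   \item Wiener \eqn{W = \sum_{i<j} d_{ij}}; Wiener polarity = number of
#'     pairs at distance exactly 3; Harary \eqn{= \sum_{i<j} 1/d_{ij}}.
#'   \item Petitjean index \eqn{(D - R)/R} with graph diameter \eqn{D} and
#'     radius \eqn{R} (0 for a single atom).
#'   \item Zagreb \eqn{M_1 = \sum_i \delta_i^2},
#'     \eqn{M_2 = \sum_{(i,j) \in E} \delta_i \delta_j}; Platt
#'     \eqn{= \sum_{(i,j) \in E} (\delta_i + \delta_j - 2)}; eccentric
#'     connectivity \eqn{= \sum_i \delta_i \, ecc_i}.
#'   \item Balaban \eqn{J = \frac{m}{\mu + 1} \sum_{(i,j) \in E}
#'     (s_i s_j)^{-1/2}} with distance-row-sums \eqn{s_i}, bond count
#'     \eqn{m}, cyclomatic number \eqn{\mu}.
#'   \item Kier-Hall \eqn{^t\chi = \sum_{paths} \prod (\delta)^{-1/2}} over
#'     simple paths with t = 0..3 vertices/edges; the valence variants use
#'     \eqn{\delta^v = (Z^v - h)/(Z - Z^v - 1)}.
#'   \item Kier kappa shape indices from path counts of length 1-3.
#'   \item GCUT: sorted eigenvalues (smallest, two inner quantiles,
#'     largest) of the matrix with atomic property on the diagonal (formal
#'     charge, Pauling electronegativity, or atomic polarisability) and
#'     \eqn{1/d_{ij}^2} off-diagonal.
#'   \item TPSA: fragment-additive polar surface contributions for N/O/S
#'     environments (classified by hydrogen count, bond orders and charge);
#'     van der Waals surface/volume: additive atomic sphere terms
#'     (hydrogens at 60\% weight), no pairwise overlap correction.
#' }
#'
#' @param mol A \code{mol_graph}.
#' @return Named numeric vector, names exactly [descriptor_names()], all
#'   finite.
#' @examples
#' butane <- mol_graph(rep("C", 4), cbind(1:3, 2:4, 1))
#' compute_descriptors(butane)[c("wiener", "zagreb1", "petitjean")]
#' @export
compute_descriptors <- function(mol) {
  stopifnot(inherits(mol, "mol_graph"))
  a <- mol$atoms; b <- mol$bonds
  n <- nrow(a); m <- nrow(b)
  el <- a$element
  g <- mol_igraph(mol)
  D <- igraph::distances(g)
  deg <- numeric(n)
  adj <- vector("list", n)
  for (k in seq_len(m)) {
    deg[b$i[k]] <- deg[b$i[k]] + 1L; deg[b$j[k]] <- deg[b$j[k]] + 1L
    adj[[b$i[k]]] <- c(adj[[b$i[k]]], b$j[k])
    adj[[b$j[k]]] <- c(adj[[b$j[k]]], b$i[k])
  }
  ed <- .element_data
  off <- D; off[off == 0] <- Inf
  ecc <- apply(D, 1L, max)
  diameter <- max(D); radius <- min(ecc)
  mu <- m - n + 1L

  # simple paths of 2 and 3 edges (unordered), as vertex index lists
  paths2 <- list(); paths3 <- list()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2L) {
      cmb <- utils::combn(sort(nb), 2L)
      for (c_ in seq_len(ncol(cmb)))
        paths2[[length(paths2) + 1L]] <- c(cmb[1L, c_], j, cmb[2L, c_])
    }
  }
  for (k in seq_len(m)) {
    i <- b$i[k]; j <- b$j[k]
    for (u in setdiff(adj[[i]], j)) for (v in setdiff(adj[[j]], i)) {
      if (u != v) {
        key <- c(u, i, j, v)
        if (key[1L] > key[4L] ||
            (key[1L] == key[4L] && key[2L] > key[3L])) key <- rev(key)
        paths3[[length(paths3) + 1L]] <- key
      }
    }
  }
  paths3 <- unique(paths3)

  chi_sum <- function(paths, delta) {
    if (!length(paths)) return(0)
    sum(vapply(paths, function(p) 1 / sqrt(prod(delta[p])), 0))
  }
  delta_v <- (ed$zv[el] - a$nH) / pmax(1, ed$z[el] - ed$zv[el] - 1L)
  safe <- function(x) if (is.finite(x)) x else 0
  chi0 <- sum(ifelse(deg > 0, 1 / sqrt(deg), 0))
  chi1 <- if (m) sum(1 / sqrt(deg[b$i] * deg[b$j])) else 0
  chi0v <- sum(ifelse(delta_v > 0, 1 / sqrt(delta_v), 0))
  chi1v <- if (m) sum(1 / sqrt(delta_v[b$i] * delta_v[b$j])) else 0

  p1 <- m; p2 <- length(paths2); p3 <- length(paths3)
  kappa1 <- safe(n * (n - 1)^2 / p1^2)
  kappa2 <- safe((n - 1) * (n - 2)^2 / p2^2)
  kappa3 <- if (n %% 2L == 1L) safe((n - 1) * (n - 3)^2 / p3^2) else
    safe((n - 3) * (n - 2)^2 / p3^2)

  s <- rowSums(D)
  balaban <- if (m) m / (mu + 1) * sum(1 / sqrt(s[b$i] * s[b$j])) else 0

  gcut <- function(prop) {
    G <- 1 / off^2
    G[!is.finite(G)] <- 0
    diag(G) <- prop
    ev <- sort(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
    ev[pmin(n, pmax(1L, round(c(1, n / 3, 2 * n / 3, n))))]
  }
  gc_charge <- gcut(as.numeric(a$charge))
  gc_en <- gcut(ed$electronegativity[el])
  gc_pol <- gcut(ed$polarizability[el])

  tpsa_contrib <- function(i) {
    e <- el[i]; h <- a$nH[i]; ch <- a$charge[i]
    ords <- c(b$order[b$i == i], b$order[b$j == i])
    has_double <- any(ords >= 2L)
    if (e == "N") {
      if (ch > 0) return(if (h >= 3L) 27.64 else if (h == 2L) 16.61 else 4.44)
      if (has_double) return(12.36)
      if (h >= 2L) return(26.02)
      if (h == 1L) return(12.03)
      return(3.24)
    }
    if (e == "O") {
      if (ch < 0) return(23.06)
      if (has_double) return(17.07)
      if (h >= 1L) return(20.23)
      return(9.23)
    }
    if (e == "S") {
      if (has_double) return(32.09)
      if (h >= 1L) return(38.80)
      return(25.30)
    }
    0
  }
  tpsa <- sum(vapply(seq_len(n), tpsa_contrib, 0))

  r <- ed$vdw_radius[el]
  nH_tot <- sum(a$nH)
  rH <- ed$vdw_radius[["H"]]
  vdw_area <- sum(4 * pi * r^2) + 0.6 * nH_tot * 4 * pi * rH^2
  vdw_vol <- sum(4 / 3 * pi * r^3) + 0.6 * nH_tot * 4 / 3 * pi * rH^3

  out <- c(
    n_atoms = n, n_bonds = m, n_rings = mu,
    n_hetero = sum(el != "C"), n_N = sum(el == "N"), n_O = sum(el == "O"),
    n_S = sum(el == "S"), n_halogen = sum(el %in% c("F", "Cl", "Br")),
    frac_hetero = sum(el != "C") / n, total_charge = sum(a$charge),
    n_hbond_donor = sum(a$nH > 0 & el %in% c("N", "O")),
    n_hbond_acceptor = sum(el %in% c("N", "O")),
    mol_weight = sum(ed$mass[el]) + nH_tot * ed$mass[["H"]],
    diameter = diameter, radius = radius,
    petitjean = if (radius > 0) (diameter - radius) / radius else 0,
    wiener = sum(D) / 2,
    wiener_polarity = sum(D == 3) / 2,
    harary = sum(1 / off[upper.tri(off)]),
    zagreb1 = sum(deg^2),
    zagreb2 = if (m) sum(deg[b$i] * deg[b$j]) else 0,
    platt = if (m) sum(deg[b$i] + deg[b$j] - 2) else 0,
    eccentric_connectivity = sum(deg * ecc),
    balaban_j = balaban,
    chi0 = chi0, chi1 = chi1, chi2 = chi_sum(paths2, deg),
    chi3p = chi_sum(paths3, deg),
    chi0v = chi0v, chi1v = chi1v, chi2v = chi_sum(paths2, delta_v),
    chi3pv = chi_sum(paths3, delta_v),
    kappa1 = kappa1, kappa2 = kappa2, kappa3 = kappa3,
    stats::setNames(gc_charge, paste0("gcut_charge_", 0:3)),
    stats::setNames(gc_en, paste0("gcut_en_", 0:3)),
    stats::setNames(gc_pol, paste0("gcut_pol_", 0:3)),
    tpsa = tpsa, vdw_area = vdw_area, vdw_volume = vdw_vol)
  out <- out[descriptor_names()]
  stopifnot(all(is.finite(out)))
  out
}

#' Descriptor matrix for a set of molecules
#'
#' @param mols List of \code{mol_graph} objects (e.g. from
#'   [read_smiles()] or [generate_molecule_set()]).
#' @return Numeric matrix, one row per molecule, columns
#'   [descriptor_names()].
#' @export
descriptor_matrix <- function(mols) {
  stopifnot(length(mols) >= 1L)
  t(vapply(mols, compute_descriptors,
           stats::setNames(numeric(50), descriptor_names())))
}
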