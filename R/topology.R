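#' Active protons of a restraint network
#'
#' The active protons are the ligand protons involved in at least one
#' protein-ligand distance restraint; the apparent ligand topology is
#' defined over these protons only, so removing restraints can shrink it.
#'
#' @param network An `nmr2_network`.
#' @return The subset of the network's proton tibble appearing in at least
#'   one restraint.
#' @export
active_protons <- function(network) {
  stopifnot(inherits(network, "nmr2_network"))
  dplyr::filter(network$protons,
                .data$proton_id %in% unique(network$restraints$proton_id))
}

#' Ligand length and width over a proton set
#'
#' The length is the maximal proton-proton distance; the width is the
#' longest proton-proton pair vector component orthogonal to the length
#' vector. Both are found by an exhaustive scan over all proton pairs.
#' When several pairs tie for the length, the lexicographically smallest
#' `proton_id` pair defines the length direction.
#'
#' @param protons Tibble with `proton_id`, `x`, `y`, `z` (at least 2 rows).
#' @return One-row tibble with `L_length` and `L_width` (Angstrom).
#' @export
length_width <- function(protons) {
  protons <- as_tibble(protons)
  n <- nrow(protons)
  if (n < 2) abort("length_width needs at least 2 protons")
  xyz <- coords_matrix(protons)
  ids <- as.character(protons$proton_id)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  vecs <- xyz[pairs[, 2], , drop = FALSE] - xyz[pairs[, 1], , drop = FALSE]
  dists <- sqrt(rowSums(vecs^2))
  dmax <- max(dists)
  cand <- which(dists >= dmax - 1e-9)
  # lexicographic tie-break on the sorted proton-id pair
  keys <- vapply(cand, function(k) {
    pr <- sort(c(ids[pairs[k, 1]], ids[pairs[k, 2]]))
    paste(pr, collapse = "\r")
  }, character(1))
  best <- cand[order(keys)][1]
  u <- vecs[best, ] / dists[best]
  perp <- vecs - outer(drop(vecs %*% u), u)
  tibble(L_length = dmax, L_width = max(sqrt(rowSums(perp^2))))
}

#' Ligand topology parameters of a restraint network
#'
#' Computes the dimensionless topology parameters `r_l = L_length / <d>`
#' and `r_w = L_width / <d>`, where the ligand length and width are taken
#' over the active protons and `<d>` is the arithmetic mean of the central
#' restraint distances. Normalizing by the mean restraint distance reflects
#' that longer restraints carry more absolute tolerance; empirically, pose
#' calculations mostly succeed when `r_l + r_w` exceeds about 2.
#'
#' @param network An `nmr2_network` whose protons carry coordinates, or
#'   supply `protons` explicitly.
#' @param protons Optional proton tibble overriding `network$protons`.
#' @return One-row tibble: `L_length`, `L_width`, `mean_d`, `r_l`, `r_w`,
#'   `n_restraints`.
#' @export
topology_parameters <- function(network, protons = NULL) {
  stopifnot(inherits(network, "nmr2_network"))
  pr <- if (is.null(protons)) network$protons else as_tibble(protons)
  act <- dplyr::filter(pr, .data$proton_id %in% network$restraints$proton_id)
  if (any(!is.finite(coords_matrix(act)))) {
    abort("topology_parameters needs proton coordinates")
  }
  lw <- length_width(act)
  mean_d <- mean(network$restraints$d)
  tibble(
    L_length = lw$L_length, L_width = lw$L_width, mean_d = mean_d,
    r_l = lw$L_length / mean_d, r_w = lw$L_width / mean_d,
    n_restraints = nrow(network$restraints)
  )
}

#' Binding-site suitability diagnostics
#'
#' A pocket is a good trilateration frame when it carries at least three
#' methyl-bearing residues distributed around the ligand rather than on one
#' side of it. `one_sided` is true when all methyl carbons lie in a single
#' closed half-space through the ligand centroid (tested via the minimum
#' norm point of the convex hull of the unit direction vectors).
#' `spread_score` is the ratio of smallest to largest singular value of the
#' centered methyl-carbon coordinate matrix: 0 for collinear or planar
#' degenerate layouts, approaching 1 for an isotropic cage.
#'
#' @param methyls Methyl-site tibble.
#' @param ligand_centroid Numeric xyz of the ligand centroid.
#' @return One-row tibble: `n_methyl_residues`, `n_methyl_sites`,
#'   `one_sided`, `spread_score`, `suitable`.
#' @export
site_diagnostics <- function(methyls, ligand_centroid = c(0, 0, 0)) {
  methyls <- as_tibble(methyls)
  n_sites <- nrow(methyls)
  n_res <- dplyr::n_distinct(methyls$residue_number)
  if (n_sites == 0) {
    return(tibble(n_methyl_residues = 0L, n_methyl_sites = 0L,
                  one_sided = TRUE, spread_score = 0, suitable = FALSE))
  }
  dirs <- sweep(coords_matrix(methyls), 2, as.numeric(ligand_centroid))
  nrm <- sqrt(rowSums(dirs^2))
  dirs <- dirs[nrm > 1e-9, , drop = FALSE] / nrm[nrm > 1e-9]
  one_sided <- if (nrow(dirs) == 0) TRUE else min_hull_norm(dirs) > 1e-3
  cen <- sweep(coords_matrix(methyls), 2, colMeans(coords_matrix(methyls)))
  sv <- svd(cen)$d
  spread <- if (n_sites < 3 || max(sv) < 1e-9) 0 else min(sv) / max(sv)
  tibble(
    n_methyl_residues = as.integer(n_res),
    n_methyl_sites = as.integer(n_sites),
    one_sided = one_sided,
    spread_score = spread,
    suitable = n_res >= 3 && !one_sided
  )
}

# Frank-Wolfe minimization of ||sum w_i d_i|| over the simplex. The origin
# lies inside the convex hull of the direction vectors (norm ~ 0) exactly
# when no half-space through the centroid contains all of them.
min_hull_norm <- function(dirs, iters = 300) {
  n <- nrow(dirs)
  w <- rep(1 / n, n)
  x <- drop(w %*% dirs)
  for (k in seq_len(iters)) {
    g <- drop(dirs %*% x)            # gradient direction per vertex
    i <- which.min(g)
    d <- dirs[i, ] - x
    denom <- sum(d^2)
    if (denom < 1e-14) break
    gamma <- max(0, min(1, -sum(x * d) / denom))
    x <- x + gamma * d
    if (sum(x^2) < 1e-10) break
  }
  sqrt(sum(x^2))
}

#' Approximate pocket-to-ligand size ratio
#'
#' Ratio of the effective ellipsoid volume of the binding-site heavy atoms
#' to that of the ligand heavy atoms, where each effective volume is the
#' product of the singular values of the centered coordinate matrix
#' (degenerate directions floored at 0.5 Angstrom). This is an approximate
#' diagnostic of how tightly the pocket wraps the ligand.
#'
#' @param pocket_atoms,ligand_atoms Atom tibbles with `x`, `y`, `z`.
#' @return A single number (>= 0).
#' @export
pocket_ligand_ratio <- function(pocket_atoms, ligand_atoms) {
  vol <- function(df) {
    m <- coords_matrix(as_tibble(df))
    if (nrow(m) < 2) return(NA_real_)
    sv <- pmax(svd(sweep(m, 2, colMeans(m)))$d / sqrt(nrow(m)), 0.5)
    prod(sv)
  }
  vol(pocket_atoms) / vol(ligand_atoms)
}

#' Topology and diagnostics report as JSON
#'
#' @param network An `nmr2_network` with proton coordinates.
#' @param methyls Methyl-site tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology_report <- function(network, methyls, path) {
  tp <- topology_parameters(network)
  prot <- active_protons(network)
  diag <- site_diagnostics(methyls, colMeans(coords_matrix(prot)))
  jsonlite::write_json(c(as.list(tp), diagnostics = list(as.list(diag))),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
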