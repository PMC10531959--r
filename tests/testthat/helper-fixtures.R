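# Programmatic fixtures shared across the test files.

pdb_line <- function(record, serial, name, resname, chain, resno, xyz, element) {
  sprintf("%-6s%5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, name, resname, chain, resno,
          xyz[1], xyz[2], xyz[3], element)
}

# A minimal protonated complex: one VAL and one GLY residue plus a 5-atom
# ligand carrying 3 protons. ALA 99 sits ~7.5 A from the nearest ligand
# proton to exercise the binding-site cutoff.
write_tiny_pdb <- function(path, ligand_copies = 1, with_ligand_h = TRUE) {
  lines <- c(
    pdb_line("ATOM", 1, "N",   "VAL", "A", 1, c(3.0, 2.0, 0.0), "N"),
    pdb_line("ATOM", 2, "CA",  "VAL", "A", 1, c(3.5, 1.0, 0.0), "C"),
    pdb_line("ATOM", 3, "CB",  "VAL", "A", 1, c(3.8, 0.5, 1.2), "C"),
    pdb_line("ATOM", 4, "CG1", "VAL", "A", 1, c(3.0, 0.0, 2.3), "C"),
    pdb_line("ATOM", 5, "CG2", "VAL", "A", 1, c(5.0, 1.2, 1.9), "C"),
    pdb_line("ATOM", 6, "N",   "GLY", "A", 2, c(-3.0, 1.0, 0.0), "N"),
    pdb_line("ATOM", 7, "CA",  "GLY", "A", 2, c(-3.5, 0.0, 0.5), "C"),
    pdb_line("ATOM", 8, "CB",  "ALA", "A", 99, c(0.0, 8.4, 0.0), "C")
  )
  serial <- 9L
  for (copy in seq_len(ligand_copies)) {
    shift <- (copy - 1) * 20
    lines <- c(lines,
      pdb_line("HETATM", serial,      "C1", "LIG", "B", 100L + copy,
               c(0 + shift, 0, 0), "C"),
      pdb_line("HETATM", serial + 1L, "C2", "LIG", "B", 100L + copy,
               c(1.4 + shift, 0, 0), "C"))
    serial <- serial + 2L
    if (with_ligand_h) {
      lines <- c(lines,
        pdb_line("HETATM", serial,      "H1", "LIG", "B", 100L + copy,
                 c(-0.6 + shift, 0.9, 0), "H"),
        pdb_line("HETATM", serial + 1L, "H2", "LIG", "B", 100L + copy,
                 c(2.0 + shift, 0.9, 0), "H"),
        pdb_line("HETATM", serial + 2L, "H3", "LIG", "B", 100L + copy,
                 c(0.7 + shift, -0.9, 0.5), "H"))
      serial <- serial + 3L
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# Hand-built network: protons with coordinates and explicit bounds.
toy_network <- function(tolerance = 0) {
  protons <- tibble::tibble(
    proton_id = c("H1", "H2", "H3"),
    x = c(0, 4, 2), y = c(0, 0, 3), z = c(0, 0, 0)
  )
  restraints <- tibble::tibble(
    label = c("M_1", "M_1", "M_2", "M_2", "M_3", "M_3"),
    proton_id = c("H1", "H2", "H1", "H3", "H2", "H3"),
    d = c(5, 6, 4, 5, 6, 4)
  )
  apply_tolerance(restraint_network(restraints, protons), tolerance)
}

# Independent target-function implementation used by the grid oracle (and
# only there): plain R, no calls into the package's scoring path.
r_score <- function(rot, trans, protons_local, pidx, site_xyz, lower, upper,
                    lig_heavy, rec_heavy, clash_weight = 1, slack = 0,
                    rmin = 2.8) {
  w <- protons_local %*% t(rot) + matrix(trans, nrow(protons_local), 3,
                                         byrow = TRUE)
  d <- sqrt(rowSums((w[pidx, , drop = FALSE] - site_xyz)^2))
  v <- pmax(0, d - upper - slack, lower - slack - d)
  tf <- sum(v^2)
  if (clash_weight > 0 && nrow(rec_heavy) > 0 && nrow(lig_heavy) > 0) {
    hw <- lig_heavy %*% t(rot) + matrix(trans, nrow(lig_heavy), 3, byrow = TRUE)
    dm <- sqrt(outer(rowSums(hw^2), rep(1, nrow(rec_heavy))) +
                 outer(rep(1, nrow(hw)), rowSums(rec_heavy^2)) -
                 2 * hw %*% t(rec_heavy))
    tf <- tf + clash_weight * sum(pmax(0, rmin - dm)^2)
  }
  tf
}

rot_from_euler <- function(a, b, g) {
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  Rz(a) %*% Ry(b) %*% Rz(g)
}

# Exhaustive oracle: every injective assignment x Euler-angle/translation
# grid, refined with Nelder-Mead from the best grid points, all on r_score.
grid_oracle <- function(network, sites, ligand, receptor, clash_weight = 1,
                        slack = 0, angle_step = pi / 6, trans_step = 1,
                        trans_span = 2, refine_from = 5) {
  sites <- sites[order(sites$residue_number, sites$methyl_atom_name), ]
  protons_local <- ligand[ligand$element == "H", ]
  protons_local <- protons_local[order(protons_local$atom), ]
  pm <- as.matrix(protons_local[, c("x", "y", "z")])
  lig_heavy <- as.matrix(ligand[ligand$element != "H", c("x", "y", "z")])
  rec_heavy <- if (is.null(receptor)) matrix(0, 0, 3) else
    as.matrix(receptor[receptor$element != "H", c("x", "y", "z")])
  r <- network$restraints
  pidx <- match(r$proton_id, protons_local$atom)
  labels <- unique(r$label)
  labels <- labels[order(as.integer(sub("^M_", "", labels)))]
  nl <- length(labels); ns <- nrow(sites)
  perms <- all_injections(nl, ns)
  a_seq <- seq(0, 2 * pi - angle_step / 2, by = angle_step)
  b_seq <- seq(0, pi, by = angle_step)
  t_seq <- seq(-trans_span, trans_span, by = trans_step)
  cen <- colMeans(as.matrix(sites[, c("x", "y", "z")]))
  # ligand centroid of the generating pose is near the site centre; search
  # translations around the proton centroid of the network when available
  pcen <- colMeans(as.matrix(network$protons[, c("x", "y", "z")]))
  if (any(!is.finite(pcen))) pcen <- cen
  tgrid <- as.matrix(expand.grid(t_seq, t_seq, t_seq))
  rmin <- 2.8
  best <- Inf
  for (perm in perms) {
    site_xyz <- as.matrix(sites[perm[match(r$label, labels)],
                                c("x", "y", "z")])
    top <- list()
    for (a in a_seq) for (b in b_seq) for (g in a_seq) {
      rot <- rot_from_euler(a, b, g)
      w0 <- pm %*% t(rot)
      base <- pcen - colMeans(w0)
      # translations vectorized: tf for every grid offset at once
      A <- site_xyz - w0[pidx, , drop = FALSE] -
        matrix(base, nrow(site_xyz), 3, byrow = TRUE)
      D <- sqrt(pmax(outer(rowSums(A^2), rep(1, nrow(tgrid))) +
                       outer(rep(1, nrow(A)), rowSums(tgrid^2)) -
                       2 * A %*% t(tgrid), 0))
      V <- pmax(D - r$upper, r$lower - D, 0)  # first arg keeps the dims
      tfs <- colSums(V^2)
      if (clash_weight > 0 && nrow(rec_heavy) > 0) {
        hw0 <- lig_heavy %*% t(rot) +
          matrix(base, nrow(lig_heavy), 3, byrow = TRUE)
        C <- rec_heavy[rep(seq_len(nrow(rec_heavy)), each = nrow(hw0)), ,
                       drop = FALSE] -
          hw0[rep(seq_len(nrow(hw0)), nrow(rec_heavy)), , drop = FALSE]
        DC <- sqrt(pmax(outer(rowSums(C^2), rep(1, nrow(tgrid))) +
                          outer(rep(1, nrow(C)), rowSums(tgrid^2)) -
                          2 * C %*% t(tgrid), 0))
        tfs <- tfs + clash_weight * colSums(pmax(rmin - DC, 0)^2)
      }
      k <- which.min(tfs)
      top[[length(top) + 1L]] <- list(tf = tfs[k],
                                      par = c(a, b, g, base + tgrid[k, ]))
    }
    tfs <- vapply(top, `[[`, numeric(1), "tf")
    for (k in order(tfs)[seq_len(min(refine_from, length(tfs)))]) {
      p0 <- top[[k]]$par
      fn <- function(p) r_score(rot_from_euler(p[1], p[2], p[3]), p[4:6],
                                pm, pidx, site_xyz, r$lower, r$upper,
                                lig_heavy, rec_heavy, clash_weight, slack)
      fit <- stats::optim(p0, fn, method = "Nelder-Mead",
                          control = list(maxit = 800, reltol = 1e-12))
      fit <- stats::optim(fit$par, fn, method = "Nelder-Mead",
                          control = list(maxit = 800, reltol = 1e-12))
      if (fit$value < best) best <- fit$value
    }
  }
  best
}

all_injections <- function(k, n) {
  out <- list()
  rec <- function(prefix) {
    if (length(prefix) == k) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (s in setdiff(seq_len(n), prefix)) rec(c(prefix, s))
  }
  rec(integer(0))
  out
}

# Small random scoring instance used by engine property tests.
random_instance <- function(seed, n_res = 3, n_protons = 4,
                            residue_types = c("ALA", "THR", "MET"),
                            perturb = 0) {
  case <- make_case(
    site_spec = list(n_methyl_residues = n_res, residue_types = residue_types,
                     radius = 5.5),
    ligand_spec = list(n_protons = n_protons, length = 4.5, width = 2.2),
    seed = seed, min_restraints = 6
  )
  if (perturb > 0) {
    net <- case$network
    k <- seq_len(nrow(net$restraints))
    delta <- withr::with_seed(seed + 1,
                              stats::runif(length(k), -perturb, perturb))
    net$restraints$d <- pmax(1, net$restraints$d + delta)
    net$restraints$lower <- net$restraints$d
    net$restraints$upper <- net$restraints$d
    case$network <- net
  }
  case
}
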