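#' Engine configuration
#'
#' Controls the rigid-body search. The search sphere defaults to the
#' methyl-site centroid with radius `max(site-centroid distance) +
#' L_length/2 + 2` Angstrom. Receptor side-chain flexibility is represented
#' by `methyl_slack`, a per-restraint distance slack (Angstrom): methyl
#' carbon displacement under modest chi-angle rotation is sub-Angstrom, so
#' a slack of a few tenths of an Angstrom stands in for explicit torsion
#' sampling when fitting experimental networks. The default is 0: slack is
#' applied independently per restraint, so any non-zero value also relaxes
#' the discrimination between assignments, and in-silico restraint
#' networks are exactly realizable without it. The annealing
#' schedule is geometric; the initial temperature is set from the median
#' target function of random poses.
#'
#' @param seed Integer seed (mandatory; every random draw derives from it).
#' @param search_center Optional xyz; default: methyl-site centroid.
#' @param search_radius Optional radius (Angstrom); default as above.
#' @param n_restarts Annealing restarts per assignment (default 6).
#' @param sa_steps Annealing steps per restart (default 1500).
#' @param cooling Geometric cooling factor per step in (0,1) (default 0.996).
#' @param clash_weight Weight of the soft-sphere clash penalty (default 1).
#' @param methyl_slack Per-restraint distance slack, Angstrom (default 0).
#' @param abandon_tf Assignments whose best tf after `abandon_after`
#'   restarts exceeds this value (Angstrom^2) are not refined further; they
#'   are far outside contention for ranking or contrast (default 15).
#' @param abandon_after Restarts always run before the abandon test
#'   (default 2).
#' @return A list of class `nmr2_engine_config`.
#' @export
engine_config <- function(seed, search_center = NULL, search_radius = NULL,
                          n_restarts = 6, sa_steps = 1500, cooling = 0.996,
                          clash_weight = 1, methyl_slack = 0,
                          abandon_tf = 15, abandon_after = 2) {
  if (missing(seed) || is.null(seed)) abort("engine_config: seed is mandatory")
  stopifnot(n_restarts >= 1, sa_steps >= 1, cooling > 0, cooling < 1,
            clash_weight >= 0, methyl_slack >= 0)
  structure(
    list(seed = as.integer(seed), search_center = search_center,
         search_radius = search_radius, n_restarts = as.integer(n_restarts),
         sa_steps = as.integer(sa_steps), cooling = cooling,
         clash_weight = clash_weight, methyl_slack = methyl_slack,
         abandon_tf = abandon_tf, abandon_after = as.integer(abandon_after)),
    class = "nmr2_engine_config"
  )
}

#' A rigid ligand pose
#'
#' @param rotation Proper 3x3 rotation matrix (det +1).
#' @param translation Numeric xyz translation (Angstrom).
#' @return A list of class `nmr2_pose`.
#' @export
new_pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)),
            abs(det(rotation) - 1) < 1e-6,
            length(translation) == 3)
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "nmr2_pose")
}

#' Apply a pose to coordinates
#'
#' @param xyz n x 3 coordinate matrix or atom tibble with `x`,`y`,`z`.
#' @param pose An `nmr2_pose`.
#' @return Transformed coordinates in the same container type.
#' @export
apply_pose <- function(xyz, pose) {
  if (is.data.frame(xyz)) {
    m <- apply_pose(coords_matrix(xyz), pose)
    xyz$x <- m[, 1]; xyz$y <- m[, 2]; xyz$z <- m[, 3]
    return(xyz)
  }
  sweep(xyz %*% t(pose$rotation), 2, -pose$translation)
}

lex_sites <- function(sites) {
  dplyr::arrange(as_tibble(sites), .data$residue_number, .data$methyl_atom_name)
}

lex_labels <- function(labels) {
  labels[order(as.integer(sub("^M_", "", labels$label))), , drop = FALSE]
}

#' Enumerate methyl-assignment combinations
#'
#' Yields every injective mapping of anonymous labels onto methyl sites
#' consistent with the labels' amino-acid type constraints and same-residue
#' groups, in deterministic lexicographic order (labels by index, candidate
#' sites by residue number then atom name). Labels sharing a same-residue
#' group must map onto methyls of one residue.
#'
#' @param labels Label tibble (`label`, optional `type_constraint` list
#'   column and `group`), e.g. `network$labels`.
#' @param sites Methyl-site tibble.
#' @param network Optional `nmr2_network`; when supplied together with
#'   `prune = TRUE`, geometrically unsatisfiable branches are cut early.
#' @param prune Use feasibility pruning (default FALSE here; [run_nmr2()]
#'   enables it).
#' @param methyl_slack Slack used by the pruning test (Angstrom).
#' @return A tibble with `assignment_id` and list-column `sites` holding a
#'   named character vector (label -> site_id) per assignment.
#' @export
enumerate_assignments <- function(labels, sites, network = NULL,
                                  prune = FALSE, methyl_slack = 0) {
  labels <- lex_labels(as_tibble(labels))
  sites <- lex_sites(sites)
  if (!"type_constraint" %in% names(labels)) {
    labels$type_constraint <- vector("list", nrow(labels))
  }
  if (!"group" %in% names(labels)) labels$group <- NA_character_
  nl <- nrow(labels); ns <- nrow(sites)
  if (nl > ns) {
    abort(paste0("over-determined labels: ", nl, " labels but only ", ns,
                 " candidate sites"))
  }
  cand <- lapply(seq_len(nl), function(i) {
    tc <- labels$type_constraint[[i]]
    ok <- if (is.null(tc)) rep(TRUE, ns) else sites$residue_type %in% tc
    which(ok)
  })
  empty <- which(lengths(cand) == 0)
  if (length(empty)) {
    abort(paste0("unsatisfiable constraint: no candidate site for label '",
                 labels$label[empty[1]], "'"))
  }
  prune_ctx <- if (prune && !is.null(network)) {
    prune_context(network, labels$label, sites, methyl_slack)
  }
  out <- list()
  assign_rec <- function(i, chosen) {
    if (i > nl) {
      out[[length(out) + 1L]] <<- chosen
      return(invisible())
    }
    pool <- setdiff(cand[[i]], chosen)
    grp <- labels$group[i]
    if (!is.na(grp)) {
      mates <- which(labels$group == grp & seq_len(nl) < i)
      if (length(mates)) {
        resnos <- unique(sites$residue_number[chosen[mates]])
        pool <- pool[sites$residue_number[pool] %in% resnos]
      } else {
        # first member of a group: residue must hold >= group size methyls
        size <- sum(labels$group == grp, na.rm = TRUE)
        counts <- table(sites$residue_number)
        pool <- pool[counts[as.character(sites$residue_number[pool])] >= size]
      }
    }
    for (s in pool) {
      nxt <- c(chosen, s)
      if (!is.null(prune_ctx) && !prefix_feasible(prune_ctx, nxt)) next
      assign_rec(i + 1L, nxt)
    }
  }
  assign_rec(1L, integer(0))
  if (!length(out)) {
    if (prune) return(tibble(assignment_id = integer(0),
                             sites = list()))
    abort("no assignment satisfies the constraints")
  }
  tibble(
    assignment_id = seq_along(out),
    sites = lapply(out, function(idx) setNames(sites$site_id[idx], labels$label))
  )
}

# Precompute, for every label pair sharing >= 1 restrained proton, the
# per-shared-proton bounds used by the triangle-inequality pruning test.
prune_context <- function(network, label_order, sites, methyl_slack) {
  r <- network$restraints
  li <- match(r$label, label_order)
  keep <- !is.na(li)
  r <- r[keep, , drop = FALSE]; li <- li[keep]
  by_label <- split(seq_len(nrow(r)), li)
  sm <- coords_matrix(sites)
  dsite <- as.matrix(stats::dist(sm))
  nl <- length(label_order)
  shared <- vector("list", nl)
  for (i in seq_len(nl)) shared[[i]] <- vector("list", nl)
  for (i in seq_len(nl)) {
    ri <- by_label[[as.character(i)]]
    if (is.null(ri)) next
    for (j in seq_len(nl)) {
      if (j >= i) next
      rj <- by_label[[as.character(j)]]
      if (is.null(rj)) next
      common <- intersect(r$proton_id[ri], r$proton_id[rj])
      if (!length(common)) next
      a <- r[ri, ][match(common, r$proton_id[ri]), ]
      b <- r[rj, ][match(common, r$proton_id[rj]), ]
      shared[[i]][[j]] <- list(
        max_sep = min(a$upper + b$upper) + 2 * methyl_slack,
        min_sep = max(pmax(a$lower - b$upper, b$lower - a$upper)) - 2 * methyl_slack
      )
    }
  }
  list(shared = shared, dsite = dsite)
}

prefix_feasible <- function(ctx, chosen) {
  k <- length(chosen)
  if (k < 2) return(TRUE)
  sh <- ctx$shared[[k]]
  for (j in seq_len(k - 1)) {
    b <- sh[[j]]
    if (is.null(b)) next
    d <- ctx$dsite[chosen[k], chosen[j]]
    if (d > b$max_sep || d < b$min_sep) return(FALSE)
  }
  TRUE
}

#' Feasibility test for a partial assignment
#'
#' Returns `FALSE` (prune) when two placed labels restrain a common ligand
#' proton but their site separation is geometrically unsatisfiable: the
#' sites are farther apart than the sum of the two upper bounds, or closer
#' than the largest `lower(one) - upper(other)` over the shared protons.
#' Pruning only removes provably infeasible branches, so the optimal
#' solution is unchanged.
#'
#' @param assignment Named character vector (label -> site_id) for the
#'   placed labels (a prefix is fine).
#' @param network An `nmr2_network`.
#' @param sites Methyl-site tibble.
#' @param methyl_slack Slack relaxing the test (Angstrom, default 0).
#' @return `TRUE` if the prefix is still feasible.
#' @export
feasibility_prune <- function(assignment, network, sites, methyl_slack = 0) {
  sites <- lex_sites(sites)
  labs <- names(assignment)
  ctx <- prune_context(network, labs, sites, methyl_slack)
  idx <- match(assignment, sites$site_id)
  for (k in seq_along(idx)) {
    if (!prefix_feasible(ctx, idx[seq_len(k)])) return(FALSE)
  }
  TRUE
}

# Internal: assemble the C++ scoring inputs for one assignment.
score_inputs <- function(assignment, network, sites, ligand, receptor,
                         config) {
  protons_local <- dplyr::filter(ligand, .data$element == "H")
  protons_local <- dplyr::arrange(protons_local, .data$atom)
  r <- network$restraints
  pidx <- match(r$proton_id, protons_local$atom)
  if (any(is.na(pidx))) {
    abort("ligand conformer lacks proton(s) named in the network")
  }
  site_xyz <- coords_matrix(sites)[match(assignment[r$label], sites$site_id), ,
                                   drop = FALSE]
  if (any(is.na(site_xyz))) abort("assignment references unknown site")
  heavy <- dplyr::filter(ligand, .data$element != "H")
  rec <- if (is.null(receptor) || nrow(receptor) == 0) {
    matrix(0, 0, 3)
  } else {
    coords_matrix(dplyr::filter(receptor, .data$element != "H"))
  }
  list(protons = coords_matrix(protons_local), pidx = as.integer(pidx) - 1L,
       site_xyz = site_xyz, lower = r$lower, upper = r$upper,
       lig_heavy = coords_matrix(heavy), rec_heavy = rec)
}

#' Score a ligand pose against the restraint network
#'
#' The target function is the sum over restraints of squared bound
#' violations, `v = max(0, dist - upper - slack, lower - slack - dist)`
#' with `dist` the posed proton to methyl-carbon distance, plus
#' `clash_weight` times the squared soft-sphere overlaps
#' `max(0, 2.8 - d)^2` between ligand and receptor heavy atoms.
#'
#' @param pose An `nmr2_pose`.
#' @param assignment Named character vector label -> site_id.
#' @param network An `nmr2_network`.
#' @param sites Methyl-site tibble.
#' @param ligand Ligand conformer atom tibble (`atom`, `element`, `x`, `y`,
#'   `z`); proton atom names must match the network's proton ids.
#' @param receptor Optional receptor heavy-atom tibble for the clash term.
#' @param config An `nmr2_engine_config`.
#' @return The target function value (Angstrom^2).
#' @export
score_pose <- function(pose, assignment, network, sites, ligand,
                       receptor = NULL, config = engine_config(seed = 1)) {
  si <- score_inputs(assignment, network, sites, ligand, receptor, config)
  tf_score_cpp(pose$rotation, pose$translation, si$protons, si$pidx,
               si$site_xyz, si$lower, si$upper, si$lig_heavy, si$rec_heavy,
               config$clash_weight, config$methyl_slack, 2.8)
}

# Rodrigues exponential map: axis-angle vector -> rotation matrix.
rot_expmap <- function(w) {
  th <- l2(w)
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Trilaterate each proton restrained >= 4 times (the linearized sphere
# system needs 3 independent difference rows), then Kabsch-fit the
# conformer onto the estimates for a deterministic starting pose.
# Estimates whose residual against the central distances is large (sloppy
# geometry or a wrong assignment) are discarded.
multilateration_init <- function(si) {
  r_by_p <- split(seq_along(si$pidx), si$pidx)
  est <- list()
  for (p in names(r_by_p)) {
    rows <- r_by_p[[p]]
    if (length(rows) < 4) next
    S <- si$site_xyz[rows, , drop = FALSE]
    d <- (si$lower[rows] + si$upper[rows]) / 2
    A <- 2 * sweep(S[-1, , drop = FALSE], 2, S[1, ])
    b <- rowSums(S[-1, , drop = FALSE]^2) - sum(S[1, ]^2) -
      (d[-1]^2 - d[1]^2)
    fit <- tryCatch(qr.solve(A, b), error = function(e) NULL)
    if (is.null(fit)) next
    resid <- max(abs(sqrt(colSums((t(S) - fit)^2)) - d))
    if (resid < 1.5) est[[p]] <- fit
  }
  if (length(est) < 3) return(NULL)
  pi_ <- as.integer(names(est)) + 1L
  P <- si$protons[pi_, , drop = FALSE]
  Q <- do.call(rbind, est)
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  sv <- svd(H)
  D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  list(rotation = R, translation = as.numeric(cq - R %*% cp))
}

#' Optimize a rigid ligand pose for one assignment
#'
#' Multi-start simulated annealing over the six rigid-body degrees of
#' freedom (rotation and translation within the search sphere), seeded
#' deterministically per assignment, followed by a Nelder-Mead polish of
#' the best pose. One restart is initialized from a trilateration estimate
#' of the proton positions when enough restraints allow it. The result is
#' bit-reproducible for a given configuration seed.
#'
#' @inheritParams score_pose
#' @return One-row solution tibble: `tf`, `assignment`, `rotation`,
#'   `translation` (the latter three as list-columns).
#' @export
optimize_pose <- function(assignment, network, sites, ligand,
                          receptor = NULL, config) {
  si <- score_inputs(assignment, network, sites, ligand, receptor, config)
  geom <- search_sphere(sites, ligand, config)
  idx <- match(assignment, lex_sites(sites)$site_id)
  res <- optimize_core(si, geom, derive_seed(config$seed, idx), config)
  best <- res[[1]]
  tibble(tf = best$tf,
         assignment = list(assignment),
         rotation = list(best$rotation),
         translation = list(as.numeric(best$translation)))
}

# Optimize one assignment and return its distinct pose candidates (one per
# annealing restart after gradient refinement, deduplicated by heavy-atom
# rmsd), ordered by tf. Keeping several poses per assignment matters for
# validation: the contrast with the first distinct pose must see pose
# ambiguity inside an assignment, not only across assignments.
optimize_core <- function(si, geom, sub_seed, config) {
  init <- multilateration_init(si)
  init_rot <- if (is.null(init)) matrix(0, 0, 0) else init$rotation
  init_trans <- if (is.null(init)) numeric(0) else init$translation
  res <- sa_optimize_cpp(si$protons, si$pidx, si$site_xyz, si$lower, si$upper,
                         si$lig_heavy, si$rec_heavy, config$clash_weight,
                         config$methyl_slack, 2.8, geom$center, geom$radius,
                         config$n_restarts, config$sa_steps, config$cooling,
                         sub_seed, init_rot, init_trans,
                         config$abandon_tf, config$abandon_after)
  cands <- lapply(seq_along(res$restart_tf), function(k) {
    list(tf = res$restart_tf[k], rotation = res$restart_rot[[k]],
         translation = as.numeric(res$restart_trans[[k]]))
  })
  best <- list(tf = res$tf, rotation = res$rotation,
               translation = as.numeric(res$translation))
  if (best$tf <= config$abandon_tf) {
    best <- polish_pose(best, si, geom, config)
  }
  cands[[length(cands) + 1L]] <- best
  # the annealing can walk away from a good trilateration start at high
  # temperature, so a promising initial estimate is also polished directly
  if (!is.null(init)) {
    tf_init <- tf_score_cpp(init$rotation, init$translation, si$protons,
                            si$pidx, si$site_xyz, si$lower, si$upper,
                            si$lig_heavy, si$rec_heavy, config$clash_weight,
                            config$methyl_slack, 2.8)
    if (tf_init < min(best$tf, config$abandon_tf)) {
      alt <- polish_pose(list(rotation = init$rotation,
                              translation = init$translation,
                              tf = tf_init), si, geom, config)
      cands[[length(cands) + 1L]] <- alt
    }
  }
  dedupe_candidates(cands, si$lig_heavy)
}

# Keep, among near-identical poses (heavy-atom rmsd < 0.5 A), the lowest-tf
# representative; return candidates sorted by tf.
dedupe_candidates <- function(cands, lig_heavy, rmsd_cut = 0.5) {
  ord <- order(vapply(cands, `[[`, numeric(1), "tf"))
  kept <- list()
  coords <- list()
  for (k in ord) {
    p <- cands[[k]]
    w <- lig_heavy %*% t(p$rotation) +
      matrix(p$translation, nrow(lig_heavy), 3, byrow = TRUE)
    dup <- FALSE
    for (c0 in coords) {
      if (sqrt(mean(rowSums((w - c0)^2))) < rmsd_cut) {
        dup <- TRUE
        break
      }
    }
    if (!dup) {
      kept[[length(kept) + 1L]] <- p
      coords[[length(coords) + 1L]] <- w
    }
  }
  kept
}

# Local refinement of the annealed pose. Poses close to the running
# optimum get a tight two-pass refinement (their tf enters the ranking and
# the contrast); clearly uncompetitive ones get a single cheap pass.
polish_pose <- function(res, si, geom, config) {
  R0 <- res$rotation; t0 <- as.numeric(res$translation)
  obj <- function(par) {
    R <- rot_expmap(par[1:3]) %*% R0
    t <- t0 + par[4:6]
    excess <- max(0, l2(t - geom$center) - geom$radius)
    tf_score_cpp(R, t, si$protons, si$pidx, si$site_xyz, si$lower, si$upper,
                 si$lig_heavy, si$rec_heavy, config$clash_weight,
                 config$methyl_slack, 2.8) + 100 * excess^2
  }
  precise <- res$tf < 2 || !is.finite(res$tf)
  fit <- optim(rep(0, 6), obj, method = "Nelder-Mead",
               control = list(maxit = if (precise) 500 else 300,
                              reltol = 1e-10))
  if (precise || fit$value < 2) {
    # second pass tightens convergence near the optimum
    fit <- optim(fit$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-12))
  }
  if (fit$value < res$tf) {
    res$rotation <- rot_expmap(fit$par[1:3]) %*% R0
    res$translation <- t0 + fit$par[4:6]
    res$tf <- fit$value
  }
  res
}

search_sphere <- function(sites, ligand, config) {
  cen <- config$search_center
  rad <- config$search_radius
  sm <- coords_matrix(sites)
  if (is.null(cen)) cen <- colMeans(sm)
  if (is.null(rad)) {
    protons <- dplyr::filter(ligand, .data$element == "H")
    ll <- if (nrow(protons) >= 2) length_width(
      tibble(proton_id = protons$atom, x = protons$x, y = protons$y,
             z = protons$z))$L_length else 0
    rad <- max(sqrt(rowSums(sweep(sm, 2, cen)^2))) + ll / 2 + 2
  }
  list(center = as.numeric(cen), radius = rad)
}

#' Run the full pose calculation
#'
#' Enumerates every methyl-assignment combination consistent with the
#' partial-assignment constraints, optimizes rigid ligand poses for each,
#' and returns all solutions ranked by target function (ties broken by
#' lexicographic assignment order). Every distinct refined pose of every
#' assignment is retained -- several structures per combination, the way
#' the reference protocol ranks its calculated structures -- so the
#' validation step can measure the contrast with the first structurally
#' distinct pose whether the ambiguity lives across assignments or within
#' one.
#'
#' @inheritParams score_pose
#' @param prune Cut geometrically unsatisfiable assignment branches. The
#'   returned optimum is unaffected, but pruned assignments yield no
#'   solution, so the contrast pose used by validation can disappear;
#'   the default (`FALSE`) optimizes every combination the way the
#'   reference procedure does, relying on the cheap abandon heuristic for
#'   hopeless assignments.
#' @param warn_unsuitable Warn when the binding-site diagnostics flag the
#'   pocket as a poor trilateration frame (default `TRUE`).
#' @return An object of class `nmr2_fit`; `tidy()` returns the ranked
#'   solution tibble (`rank`, `tf`, `assignment`, `rotation`,
#'   `translation`).
#' @export
run_nmr2 <- function(network, sites, ligand, receptor = NULL, config,
                     prune = FALSE, warn_unsuitable = TRUE) {
  stopifnot(inherits(network, "nmr2_network"),
            inherits(config, "nmr2_engine_config"))
  sites <- lex_sites(sites)
  if (warn_unsuitable) {
    diag <- site_diagnostics(sites, site_centroid_guess(network, sites))
    if (!diag$suitable) {
      warn(paste0("binding site looks unsuitable for trilateration (",
                  diag$n_methyl_residues, " methyl residues, one_sided = ",
                  diag$one_sided, "); poses may not be resolvable"))
    }
  }
  asg <- enumerate_assignments(network$labels, sites, network = network,
                               prune = prune,
                               methyl_slack = config$methyl_slack)
  if (nrow(asg) == 0) abort("all assignments pruned as infeasible")
  # scoring inputs are identical across assignments except for the methyl
  # coordinates each restraint points at, so they are assembled once
  si <- score_inputs(asg$sites[[1]], network, sites, ligand, receptor, config)
  geom <- search_sphere(sites, ligand, config)
  sm <- coords_matrix(sites)
  label_order <- lex_labels(network$labels)$label
  label_idx <- match(network$restraints$label, label_order)
  res_list <- vector("list", nrow(asg))
  for (k in seq_len(nrow(asg))) {
    a <- asg$sites[[k]]
    idx <- match(a[label_order], sites$site_id)
    si$site_xyz <- sm[idx[label_idx], , drop = FALSE]
    cands <- optimize_core(si, geom, derive_seed(config$seed, idx), config)
    res_list[[k]] <- tibble(
      tf = vapply(cands, `[[`, numeric(1), "tf"),
      assignment = replicate(length(cands), a, simplify = FALSE),
      rotation = lapply(cands, `[[`, "rotation"),
      translation = lapply(cands, function(r) as.numeric(r$translation))
    )
  }
  sols <- dplyr::bind_rows(res_list)
  key <- vapply(sols$assignment, function(a) paste(a, collapse = "|"),
                character(1))
  ord <- order(sols$tf, key)
  sols <- sols[ord, , drop = FALSE]
  sols$rank <- seq_len(nrow(sols))
  sols <- dplyr::select(sols, "rank", dplyr::everything())
  structure(
    list(solutions = sols, network = network, sites = sites, ligand = ligand,
         receptor = receptor, config = config, pruned = prune),
    class = "nmr2_fit"
  )
}

site_centroid_guess <- function(network, sites) {
  pm <- coords_matrix(network$protons)
  if (all(is.finite(pm))) colMeans(pm) else colMeans(coords_matrix(sites))
}

#' @export
print.nmr2_fit <- function(x, ...) {
  n_asg <- dplyr::n_distinct(vapply(x$solutions$assignment, paste,
                                    character(1), collapse = "|"))
  cat("<nmr2_fit>", nrow(x$solutions), "ranked structures from", n_asg,
      "assignments; best tf =", sprintf("%.4f", x$solutions$tf[1]), "A^2\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @export
tidy.nmr2_fit <- function(x, ...) x$solutions

#' @exportS3Method generics::glance
#' @export
glance.nmr2_fit <- function(x, ...) {
  tibble(
    n_solutions = nrow(x$solutions),
    best_tf = x$solutions$tf[1],
    n_restraints = nrow(x$network$restraints),
    tolerance_fraction = x$network$tolerance_fraction,
    seed = x$config$seed
  )
}

#' Best pose of a fit
#'
#' @param fit An `nmr2_fit`.
#' @param rank Which rank to extract (default 1).
#' @return An `nmr2_pose`.
#' @export
best_pose <- function(fit, rank = 1) {
  s <- fit$solutions[rank, ]
  new_pose(s$rotation[[1]], s$translation[[1]])
}

#' Write ranked poses as a multi-model PDB
#'
#' @param fit An `nmr2_fit`.
#' @param path Output path.
#' @param n_models Number of top-ranked poses to write.
#' @return `path`, invisibly.
#' @export
write_poses <- function(fit, path, n_models = 10) {
  n <- min(n_models, nrow(fit$solutions))
  lig <- fit$ligand
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(n)) {
    posed <- apply_pose(lig, best_pose(fit, m))
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(sprintf(
      "HETATM%5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(posed)), substr(posed$atom, 1, 4), "LIG", 1L,
      posed$x, posed$y, posed$z, posed$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write ranked solutions as JSON
#'
#' @param fit An `nmr2_fit`.
#' @param path Output path.
#' @param n Number of top solutions to keep (default all).
#' @return `path`, invisibly.
#' @export
write_solutions <- function(fit, path, n = Inf) {
  s <- head(fit$solutions, n)
  out <- lapply(seq_len(nrow(s)), function(i) {
    list(rank = s$rank[i], tf = s$tf[i],
         assignment = as.list(s$assignment[[i]]),
         rotation = s$rotation[[i]], translation = s$translation[[i]])
  })
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
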