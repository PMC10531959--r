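mk_sites <- function(types, xyz = NULL) {
  n <- length(types)
  atom1 <- c(ALA = "CB", THR = "CG2", MET = "CE")
  out <- tibble::tibble(
    residue_number = 10L * seq_len(n), residue_type = types,
    methyl_atom_name = unname(atom1[types]),
    x = if (is.null(xyz)) seq_len(n) * 3 else xyz[, 1],
    y = if (is.null(xyz)) rep(0, n) else xyz[, 2],
    z = if (is.null(xyz)) rep(0, n) else xyz[, 3]
  )
  out$site_id <- paste0(out$residue_type, out$residue_number, ":",
                        out$methyl_atom_name)
  out
}

test_that("assignment enumeration counts injections under constraints", {
  labels3 <- tibble::tibble(label = c("M_1", "M_2", "M_3"))
  sites4 <- mk_sites(c("ALA", "THR", "MET", "ALA"))
  asg <- enumerate_assignments(labels3, sites4)
  expect_equal(nrow(asg), 24)  # 4 * 3 * 2
  expect_equal(anyDuplicated(vapply(asg$sites, paste, "", collapse = "|")), 0)

  labels3$type_constraint <- list("MET", NULL, NULL)
  asg2 <- enumerate_assignments(labels3, sites4)
  expect_equal(nrow(asg2), 6)  # 1 * 3 * 2
  expect_true(all(vapply(asg2$sites, function(a) a[["M_1"]], "") ==
                    "MET30:CE"))
})

test_that("same-residue groups pair labels onto one residue's methyls", {
  sites <- tibble::tibble(
    residue_number = c(10L, 10L, 20L, 30L),
    residue_type = c("VAL", "VAL", "ALA", "MET"),
    methyl_atom_name = c("CG1", "CG2", "CB", "CE"),
    x = c(0, 2, 5, 8), y = 0, z = 0)
  sites$site_id <- paste0(sites$residue_type, sites$residue_number, ":",
                          sites$methyl_atom_name)
  labels <- tibble::tibble(label = c("M_2", "M_3"),
                           group = c("G1", "G1"))
  asg <- enumerate_assignments(labels, sites)
  expect_equal(nrow(asg), 2)  # the two orders on VAL10's methyls
  for (a in asg$sites) {
    expect_setequal(unname(a), c("VAL10:CG1", "VAL10:CG2"))
  }
})

test_that("enumeration reports impossible inputs", {
  sites2 <- mk_sites(c("ALA", "THR"))
  expect_error(
    enumerate_assignments(tibble::tibble(label = paste0("M_", 1:3)), sites2),
    "over-determined")
  labels <- tibble::tibble(label = "M_1", type_constraint = list("MET"))
  expect_error(enumerate_assignments(labels, sites2), "M_1")
})

test_that("feasibility pruning applies the pair separation bounds", {
  protons <- tibble::tibble(proton_id = "H1", x = 0, y = 0, z = 0)
  net <- restraint_network(
    tibble::tibble(label = c("M_1", "M_2"), proton_id = "H1",
                   d = c(5, 5), lower = c(4, 4), upper = c(5, 5)),
    protons)
  far <- mk_sites(c("ALA", "THR"), xyz = rbind(c(0, 0, 0), c(20, 0, 0)))
  expect_false(feasibility_prune(
    c(M_1 = far$site_id[1], M_2 = far$site_id[2]), net, far))
  near <- mk_sites(c("ALA", "THR"), xyz = rbind(c(0, 0, 0), c(6, 0, 0)))
  expect_true(feasibility_prune(
    c(M_1 = near$site_id[1], M_2 = near$site_id[2]), net, near))
})

test_that("pruning never changes the optimal solution", {
  for (seed in c(11, 23, 37)) {
    case <- random_instance(seed)
    cfg <- engine_config(seed = 5, n_restarts = 3, sa_steps = 600)
    on_ <- run_nmr2(case$network, case$sites, case$ligand, case$receptor,
                    cfg, prune = TRUE, warn_unsuitable = FALSE)
    off <- run_nmr2(case$network, case$sites, case$ligand, case$receptor,
                    cfg, prune = FALSE, warn_unsuitable = FALSE)
    expect_equal(on_$solutions$tf[1], off$solutions$tf[1], tolerance = 1e-9)
    expect_identical(on_$solutions$assignment[[1]],
                     off$solutions$assignment[[1]])
  }
})

test_that("the target function scores bound violations and clashes", {
  protons <- tibble::tibble(proton_id = "H01", x = 0, y = 0, z = 0)
  sites <- mk_sites("ALA", xyz = rbind(c(0, 0, 5)))
  lig <- tibble::tibble(atom = c("C01", "H01"), element = c("C", "H"),
                        x = 0, y = 0, z = c(-1, 0))
  mk_net <- function(lower, upper) {
    restraint_network(
      tibble::tibble(label = "M_1", proton_id = "H01", d = (lower + upper) / 2,
                     lower = lower, upper = upper),
      protons)
  }
  cfg <- engine_config(seed = 1)
  a <- c(M_1 = sites$site_id[1])
  # realized distance 5.0 against bounds (4.5, 5.5): inside, no violation
  expect_equal(score_pose(new_pose(), a, mk_net(4.5, 5.5), sites, lig,
                          config = cfg), 0)
  # push the ligand so the distance becomes 6.0: (6.0 - 5.5)^2 = 0.25
  p <- new_pose(translation = c(0, 0, -1))
  expect_equal(score_pose(p, a, mk_net(4.5, 5.5), sites, lig, config = cfg),
               0.25)
  # realized 5.2 within (4.5, 5.5)
  p2 <- new_pose(translation = c(0, 0, -0.2))
  expect_equal(score_pose(p2, a, mk_net(4.5, 5.5), sites, lig, config = cfg),
               0)
  # a receptor atom 2.0 A from the ligand carbon costs (2.8 - 2.0)^2
  rec <- tibble::tibble(atom = "CW", element = "C", x = 0, y = 2, z = -1)
  expect_equal(score_pose(new_pose(), a, mk_net(4.5, 5.5), sites, lig,
                          receptor = rec, config = cfg),
               0.8^2, tolerance = 1e-12)
})

test_that("tf is zero at the truth pose of an exact network", {
  case <- make_case(seed = 314)
  a <- setNames(case$truth_assignment$site_id, case$truth_assignment$label)
  tf <- score_pose(case$truth_pose, a, case$network, case$sites, case$ligand,
                   case$receptor, engine_config(seed = 1))
  expect_lt(tf, 1e-18)
})

test_that("tf is invariant under a joint rigid transform of the frame", {
  case <- random_instance(7)
  a <- setNames(case$truth_assignment$site_id, case$truth_assignment$label)
  cfg <- engine_config(seed = 1)
  pose <- new_pose(rot_from_euler(0.2, 0.5, 1.0), c(0.5, -0.3, 0.2))
  tf0 <- score_pose(pose, a, case$network, case$sites, case$ligand,
                    case$receptor, cfg)
  rot <- rot_from_euler(2.2, 0.9, -0.4); shift <- c(4, -6, 1)
  move_df <- function(df) {
    m <- as.matrix(df[, c("x", "y", "z")]) %*% t(rot)
    df$x <- m[, 1] + shift[1]; df$y <- m[, 2] + shift[2]
    df$z <- m[, 3] + shift[3]
    df
  }
  pose2 <- new_pose(rot %*% pose$rotation,
                    as.numeric(rot %*% pose$translation + shift))
  tf1 <- score_pose(pose2, a, case$network, move_df(case$sites),
                    case$ligand, move_df(case$receptor), cfg)
  expect_equal(tf1, tf0, tolerance = 1e-9)
})

test_that("pose optimization recovers a ground-truth optimum deterministically", {
  case <- make_case(seed = 2718)
  a <- setNames(case$truth_assignment$site_id, case$truth_assignment$label)
  cfg <- engine_config(seed = 11)
  s1 <- optimize_pose(a, case$network, case$sites, case$ligand,
                      case$receptor, cfg)
  expect_lt(s1$tf, 1e-3)
  p1 <- new_pose(s1$rotation[[1]], s1$translation[[1]])
  expect_lt(pose_rmsd(p1, case$truth_pose, case$ligand), 0.5)
  # bit-identical repeat under the same seed
  s2 <- optimize_pose(a, case$network, case$sites, case$ligand,
                      case$receptor, cfg)
  expect_identical(s1$tf, s2$tf)
  expect_identical(s1$rotation[[1]], s2$rotation[[1]])
})

test_that("widening the tolerance never raises the optimal tf", {
  case <- random_instance(55, perturb = 0.6)  # inconsistent bounds, tf > 0
  a <- setNames(case$truth_assignment$site_id, case$truth_assignment$label)
  cfg <- engine_config(seed = 3)
  tfs <- vapply(c(0, 0.1, 0.2), function(tol) {
    net <- apply_tolerance(case$network, tol)
    optimize_pose(a, net, case$sites, case$ligand, case$receptor, cfg)$tf
  }, numeric(1))
  expect_gt(tfs[1], 0)
  expect_true(all(diff(tfs) <= 1e-6))
})

test_that("the engine matches an exhaustive grid oracle on a tiny instance", {
  case <- random_instance(101, n_res = 3, n_protons = 4)
  cfg <- engine_config(seed = 17)
  fit <- run_nmr2(case$network, case$sites, case$ligand, case$receptor,
                  cfg, warn_unsuitable = FALSE)
  oracle <- grid_oracle(case$network, case$sites, case$ligand, case$receptor)
  expect_lt(abs(fit$solutions$tf[1] - oracle), 0.05)
})

test_that("a full run is reproducible and ranked by tf", {
  case <- random_instance(77)
  cfg <- engine_config(seed = 23)
  f1 <- run_nmr2(case$network, case$sites, case$ligand, case$receptor, cfg,
                 warn_unsuitable = FALSE)
  f2 <- run_nmr2(case$network, case$sites, case$ligand, case$receptor, cfg,
                 warn_unsuitable = FALSE)
  expect_identical(f1$solutions$tf, f2$solutions$tf)
  expect_identical(f1$solutions$assignment, f2$solutions$assignment)
  expect_true(!is.unsorted(f1$solutions$tf))
  # several distinct poses may be kept per assignment, never fewer than one
  n_asg <- nrow(enumerate_assignments(case$network$labels, case$sites))
  keys <- unique(vapply(f1$solutions$assignment, paste, "", collapse = "|"))
  expect_equal(length(keys), n_asg)
  expect_gte(nrow(f1$solutions), n_asg)
})

test_that("an unsuitable site triggers a warning", {
  case <- make_case(site_spec = list(n_methyl_residues = 2,
                                     residue_types = c("ALA", "THR")),
                    seed = 5, min_restraints = 6)
  expect_warning(
    run_nmr2(case$network, case$sites, case$ligand, case$receptor,
             engine_config(seed = 1, n_restarts = 2, sa_steps = 200)),
    "unsuitable")
})
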