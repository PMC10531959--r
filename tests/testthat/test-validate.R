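# Assemble a minimal fit object from explicit poses and tf values.
mock_fit <- function(tfs, poses, ligand = NULL) {
  if (is.null(ligand)) {
    ligand <- tibble::tibble(
      atom = c("C1", "C2", "C3"), element = "C",
      x = c(-1, 1, 0), y = c(0, 0, 1.2), z = 0)
  }
  sols <- tibble::tibble(
    rank = seq_along(tfs), tf = tfs,
    assignment = replicate(length(tfs), c(M_1 = "ALA10:CB"),
                           simplify = FALSE),
    rotation = lapply(poses, function(p) p$rotation),
    translation = lapply(poses, function(p) p$translation)
  )
  structure(list(solutions = sols, ligand = ligand), class = "nmr2_fit")
}

shifted <- function(dx = 0, dy = 0, dz = 0) new_pose(translation = c(dx, dy, dz))

test_that("pose rmsd is the unsuperposed heavy-atom deviation", {
  lig <- tibble::tibble(atom = c("C1", "C2", "H1"),
                        element = c("C", "C", "H"),
                        x = c(-1, 1, 0), y = 0, z = 0)
  p0 <- new_pose()
  expect_equal(pose_rmsd(p0, p0, lig), 0)
  expect_equal(pose_rmsd(p0, shifted(2), lig), 2)
  # 180 degrees about z through the centroid: the two carbons swap places
  # but correspondence is by atom, so each moved by 2
  flip <- new_pose(rotation = rot_from_euler(pi, 0, 0))
  expect_equal(pose_rmsd(p0, flip, lig), 2)
})

test_that("the contrast is measured at the first structurally distinct pose", {
  # rank 2 is within 2 A of rank 1, rank 3 is the first distinct pose
  fit <- mock_fit(c(0, 0.3, 0.5, 4),
                  list(shifted(0), shifted(0.5), shifted(3), shifted(6)))
  val <- compute_tfc(fit)
  expect_equal(val$tfc, 0.5)
  expect_true(val$validated)
  expect_equal(val$contrast$rank, 3)
})

test_that("the 0.2 threshold separates validated from ambiguous results", {
  low <- compute_tfc(mock_fit(c(0, 0.13), list(shifted(0), shifted(4))))
  expect_equal(low$tfc, 0.13)
  expect_false(low$validated)
  ok <- compute_tfc(mock_fit(c(0, 0.5), list(shifted(0), shifted(4))))
  expect_true(ok$validated)
  # equal-tf distinct poses: tfc 0, the classic unresolved outcome
  tie <- compute_tfc(mock_fit(c(0.7, 0.7), list(shifted(0), shifted(4))))
  expect_equal(tie$tfc, 0)
  expect_false(tie$validated)
})

test_that("a single-cluster list yields an infinite contrast with a warning", {
  fit <- mock_fit(c(0, 0.4), list(shifted(0), shifted(0.3)))
  expect_warning(val <- compute_tfc(fit), "single-cluster")
  expect_equal(val$tfc, Inf)
  expect_true(val$validated)
})

test_that("success needs validation, sub-2 A rmsd and matching orientation", {
  ref <- shifted(0)
  ok <- compute_tfc(mock_fit(c(0, 1.5), list(shifted(0.9), shifted(5))))
  row <- classify_success(ok, ref)
  expect_true(row$success)
  expect_equal(row$rmsd_to_reference, 0.9)

  far <- compute_tfc(mock_fit(c(0, 1.5), list(shifted(3.1), shifted(9))))
  expect_false(classify_success(far, ref)$success)

  weak <- compute_tfc(mock_fit(c(0, 0.13), list(shifted(0.5), shifted(5))))
  expect_false(classify_success(weak, ref)$success)

  # flipped principal axis fails the orientation check even at small rmsd
  lig_long <- tibble::tibble(atom = c("C1", "C2", "C3"), element = "C",
                             x = c(-1.2, 0, 1.6), y = c(0, 0.1, 0), z = 0)
  flip <- new_pose(rotation = rot_from_euler(pi, 0, 0))
  flipped <- compute_tfc(mock_fit(c(0, 1.5), list(flip, shifted(5)),
                                  ligand = lig_long))
  row2 <- classify_success(flipped, ref)
  expect_gt(row2$axis_angle_deg, 90)
  expect_false(row2$success)
})

test_that("aggregation reports per-condition and restricted statistics", {
  rows <- tibble::tibble(
    case_id = rep(sprintf("c%02d", 1:10), 2),
    tolerance_fraction = rep(c(0, 0.1), each = 10),
    partial_assignment = FALSE,
    tfc = c(rep(3, 9), 0.1, rep(1.5, 5), rep(0.05, 5)),
    validated = tfc > 0.2,
    rmsd = c(rep(0.5, 10), rep(1.0, 10)),
    success = validated & rmsd < 2,
    r_l = 1.2, r_w = 0.8
  )
  rep_ <- aggregate_report(rows)
  full <- tidy(rep_)[tidy(rep_)$scope == "all", ]
  expect_equal(full$success_rate[full$tolerance_fraction == 0], 0.9)
  expect_equal(full$success_rate[full$tolerance_fraction == 0.1], 0.5)
  # cases c06..c10 fail at 10%, case c10 fails at 0%: converged-all = c01..c05
  expect_setequal(rep_$converged_cases, sprintf("c%02d", 1:5))
  restr <- tidy(rep_)[tidy(rep_)$scope == "converged_all", ]
  expect_equal(unique(restr$n), 5L)
  expect_equal(restr$rmsd_mean, full$rmsd_mean)  # rmsd constant per condition
  expect_false(isTRUE(all.equal(restr$tfc_mean, full$tfc_mean)))
})

test_that("single-observation groups report zero spread", {
  rows <- tibble::tibble(
    case_id = "c1", tolerance_fraction = 0, partial_assignment = FALSE,
    tfc = 2, validated = TRUE, rmsd = 0.4, success = TRUE,
    r_l = 1.5, r_w = 0.9)
  s <- tidy(aggregate_report(rows))
  expect_equal(s$rmsd_sd, c(0, 0))
  expect_equal(s$tfc_sd, c(0, 0))
})

test_that("tfc is non-negative and grows with the distinctness cutoff", {
  case <- random_instance(88)
  fit <- run_nmr2(case$network, case$sites, case$ligand, case$receptor,
                  engine_config(seed = 2, n_restarts = 3, sa_steps = 600),
                  warn_unsuitable = FALSE)
  v1 <- suppressWarnings(compute_tfc(fit, rmsd_cutoff = 1))
  v2 <- suppressWarnings(compute_tfc(fit, rmsd_cutoff = 2))
  v3 <- suppressWarnings(compute_tfc(fit, rmsd_cutoff = 4))
  expect_gte(v1$tfc, 0)
  expect_true(v1$tfc <= v2$tfc && v2$tfc <= v3$tfc)
})
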