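test_that("generated ligands realize the requested length and width", {
  for (spec in list(c(4, 0, 2), c(6, 3, 8), c(3.6, 1.8, 5), c(8, 4.5, 8))) {
    lig <- make_ligand(n_protons = spec[3], length = spec[1],
                       width = spec[2], seed = 7)
    pr <- lig[lig$element == "H", ]
    lw <- length_width(tibble::tibble(proton_id = pr$atom, x = pr$x,
                                      y = pr$y, z = pr$z))
    expect_equal(lw$L_length, spec[1], tolerance = 0.05)
    expect_equal(lw$L_width, spec[2], tolerance = 0.05 * max(spec[2], 1))
  }
  expect_error(make_ligand(4, length = 3, width = 5), "width > length")
  expect_error(make_ligand(2, length = 4, width = 2), "at least 3")
  # two protons span exactly the length when width is 0
  two <- make_ligand(2, length = 4, width = 0, seed = 1)
  expect_equal(sum(two$element == "H"), 2)
  expect_identical(make_ligand(5, 5, 2, seed = 3), make_ligand(5, 5, 2, seed = 3))
})

test_that("site geometries realize their diagnostic classes", {
  spread <- make_site(5, "spread", seed = 11)
  ds <- site_diagnostics(spread$sites, c(0, 0, 0))
  expect_true(ds$suitable)
  one <- make_site(3, "one_sided", seed = 11,
                   residue_types = c("ALA", "THR", "MET"))
  d1 <- site_diagnostics(one$sites, c(0, 0, 0))
  expect_true(d1$one_sided)
  expect_false(d1$suitable)
  two <- make_site(2, "spread", seed = 11, residue_types = c("ALA", "MET"))
  expect_false(site_diagnostics(two$sites, c(0, 0, 0))$suitable)
  # double-methyl residues contribute two carbons ~2.5 A apart
  v <- make_site(1, "spread", seed = 2, residue_types = "VAL")$sites
  expect_equal(nrow(v), 2)
  expect_equal(sqrt(sum((v[1, c("x", "y", "z")] - v[2, c("x", "y", "z")])^2)),
               2.5, tolerance = 0.01)
})

test_that("a generated case is internally consistent", {
  case <- make_case(seed = 321)
  expect_gte(nrow(case$network$restraints), 12)
  expect_gte(min(case$network$restraints$d), 2.5)
  # the network regenerates exactly from receptor + ligand + truth pose
  world <- apply_pose(dplyr::filter(case$ligand, element == "H"),
                      case$truth_pose)
  re <- extract_restraints(
    tibble::tibble(proton_id = world$atom, x = world$x, y = world$y,
                   z = world$z),
    case$sites, max_distance = case$intended$max_distance, seed = 99)
  key <- function(net, truth) {
    m <- merge(net$restraints, truth, by = "label")
    m <- m[order(m$site_id, m$proton_id), c("site_id", "proton_id", "d")]
    rownames(m) <- NULL
    m
  }
  expect_equal(key(re$network, re$truth),
               key(case$network, case$truth_assignment))
  # truth pose scores exactly zero on the zero-tolerance network
  a <- setNames(case$truth_assignment$site_id, case$truth_assignment$label)
  expect_lt(score_pose(case$truth_pose, a, case$network, case$sites,
                       case$ligand, case$receptor, engine_config(seed = 1)),
            1e-18)
})

test_that("partial-assignment emulation grants only true constraints", {
  case <- make_case(seed = 55, pa_fraction = 1)
  labs <- case$network$labels
  info <- dplyr::left_join(case$truth_assignment, case$sites, by = "site_id")
  for (k in seq_len(nrow(labs))) {
    tc <- labs$type_constraint[[k]]
    expect_false(is.null(tc))
    truth_type <- info$residue_type[info$label == labs$label[k]]
    expect_true(truth_type %in% tc)
    if (truth_type %in% c("VAL", "LEU", "ILE")) {
      expect_setequal(tc, c("VAL", "LEU", "ILE"))
    } else {
      expect_identical(tc, truth_type)
    }
  }
  # a fraction constrains ceiling(fraction * n) labels
  half <- make_case(seed = 55, pa_fraction = 0.5)
  n_con <- sum(!vapply(half$network$labels$type_constraint, is.null,
                       logical(1)))
  expect_equal(n_con, ceiling(0.5 * nrow(half$network$labels)))
})

test_that("libraries are deterministic and stratified around the boundary", {
  lib1 <- make_library(8, master_seed = 42)
  lib2 <- make_library(8, master_seed = 42)
  expect_equal(lib1$manifest, lib2$manifest)
  expect_identical(lib1$cases[[3]]$network$restraints,
                   lib2$cases[[3]]$network$restraints)
  sum_r <- lib1$manifest$r_l + lib1$manifest$r_w
  expect_equal(sum(sum_r > 2), 4)
  expect_equal(sum(sum_r < 2), 4)
  expect_true(all(lib1$manifest$n_restraints >= 12))
})

test_that("case bundles write to disk as plain text", {
  case <- make_case(seed = 9,
                    site_spec = list(n_methyl_residues = 3,
                                     residue_types = c("ALA", "THR", "MET")),
                    ligand_spec = list(n_protons = 4, length = 4.5,
                                       width = 2.2),
                    min_restraints = 6)
  dir <- withr::local_tempdir()
  write_case(case, dir)
  expect_true(file.exists(file.path(dir, "restraints.tsv")))
  expect_true(file.exists(file.path(dir, "receptor.pdb")))
  back <- read_restraints(file.path(dir, "restraints.tsv"))
  expect_equal(back$restraints$d, case$network$restraints$d)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$case_id, case$case_id)
})
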