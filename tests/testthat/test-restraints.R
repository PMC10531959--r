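test_that("in-silico extraction measures exact carbon distances under a cutoff", {
  protons <- tibble::tibble(proton_id = "Ha", x = 0, y = 0, z = 0)
  methyls <- tibble::tibble(
    site_id = c("ALA1:CB", "MET2:CE"), residue_number = c(1L, 2L),
    residue_type = c("ALA", "MET"), methyl_atom_name = c("CB", "CE"),
    x = c(0, 8), y = 0, z = c(4, 0)
  )
  ex <- extract_restraints(protons, methyls, max_distance = 6, seed = 1)
  expect_equal(nrow(ex$network$restraints), 1)
  expect_equal(ex$network$restraints$d, 4.0)
  expect_equal(ex$truth$site_id, "ALA1:CB")
  expect_error(
    extract_restraints(protons, methyls[2, ], max_distance = 6, seed = 1),
    "empty network")
})

test_that("restraint count equals the brute-force pair count", {
  for (seed in 1:5) {
    n_p <- 4 + seed %% 3
    n_m <- 3 + seed %% 4
    protons <- withr::with_seed(seed, tibble::tibble(
      proton_id = sprintf("H%d", 1:n_p),
      x = runif(n_p, -3, 3), y = runif(n_p, -3, 3), z = runif(n_p, -3, 3)))
    methyls <- withr::with_seed(seed + 100, tibble::tibble(
      site_id = sprintf("ALA%d:CB", 1:n_m), residue_number = 1:n_m,
      residue_type = "ALA", methyl_atom_name = "CB",
      x = runif(n_m, -7, 7), y = runif(n_m, -7, 7), z = runif(n_m, -7, 7)))
    dmat <- sqrt(outer(protons$x, methyls$x, "-")^2 +
                   outer(protons$y, methyls$y, "-")^2 +
                   outer(protons$z, methyls$z, "-")^2)
    expected <- sum(dmat <= 6.5)
    if (expected == 0) next
    ex <- extract_restraints(protons, methyls, max_distance = 6.5, seed = seed)
    expect_equal(nrow(ex$network$restraints), expected)
  }
})

test_that("anonymization is a pure seeded relabeling", {
  protons <- tibble::tibble(proton_id = c("H1", "H2"),
                            x = c(0, 2), y = 0, z = 0)
  methyls <- tibble::tibble(
    site_id = sprintf("ALA%d:CB", 1:3), residue_number = 1:3,
    residue_type = "ALA", methyl_atom_name = "CB",
    x = c(1, 3, -2), y = c(4, -3, 3), z = c(1, 2, -1)
  )
  a <- extract_restraints(protons, methyls, max_distance = 8, seed = 5)
  b <- extract_restraints(protons, methyls, max_distance = 8, seed = 5)
  expect_identical(a$network$restraints, b$network$restraints)
  expect_identical(a$truth, b$truth)
  c <- extract_restraints(protons, methyls, max_distance = 8, seed = 9)
  # per-site observation multisets are seed-invariant under the truth map
  keyed <- function(ex) {
    m <- merge(ex$network$restraints, ex$truth, by = "label")
    m <- m[order(m$site_id, m$proton_id), c("site_id", "proton_id", "d")]
    rownames(m) <- NULL
    m
  }
  expect_equal(keyed(c), keyed(a))
})

test_that("tolerance scales the limits symmetrically around d", {
  net <- restraint_network(
    tibble::tibble(label = c("M_1", "M_2"), proton_id = c("H1", "H1"),
                   d = c(5, 4)),
    tibble::tibble(proton_id = "H1"))
  t10 <- apply_tolerance(net, 0.10)
  expect_equal(t10$restraints$lower[1], 4.5)
  expect_equal(t10$restraints$upper[1], 5.5)
  t0 <- apply_tolerance(net, 0)
  expect_equal(t0$restraints$lower, t0$restraints$d)
  expect_equal(t0$restraints$upper, t0$restraints$d)
  t20 <- apply_tolerance(net, 0.20)
  expect_equal(t20$restraints$lower[2], 3.2)
  expect_equal(t20$restraints$upper[2], 4.8)
  # bounds widen monotonically with the fraction
  for (f in c(0.05, 0.1, 0.3)) {
    for (g in c(0.35, 0.6)) {
      a <- apply_tolerance(net, f)$restraints
      b <- apply_tolerance(net, g)$restraints
      expect_true(all(b$lower <= a$lower & a$upper <= b$upper))
    }
  }
})

test_that("partial-assignment constraints attach to labels and validate", {
  net <- toy_network()
  net2 <- attach_partial_assignment(net, types = list(M_1 = "MET"),
                                    same_residue = list(c("M_2", "M_3")))
  expect_equal(net2$labels$type_constraint[[which(net2$labels$label == "M_1")]],
               "MET")
  expect_equal(sum(!is.na(net2$labels$group)), 2)
  expect_error(attach_partial_assignment(net, types = list(M_9 = "MET")),
               "unknown label")
  expect_identical(attach_partial_assignment(net)$labels, net$labels)
})

test_that("build-up slopes convert to distances by the sixth-root ratio", {
  tm <- c(0.02, 0.04, 0.06)
  buildups <- tibble::tibble(
    pair = rep(c("ref", "same", "weak"), each = 3),
    mixing_time = rep(tm, 3),
    intensity = c(10 * tm, 10 * tm, 10 * tm / 64)
  )
  out <- noe_to_distances(buildups, list(pair = "ref", d = 3))
  expect_equal(out$d[out$pair == "same"], 3)
  expect_equal(out$d[out$pair == "weak"], 6)  # 64^(1/6) = 2
  # scale invariance of the intensity units
  scaled <- buildups
  scaled$intensity <- scaled$intensity * 37.5
  expect_equal(noe_to_distances(scaled, list(pair = "ref", d = 3))$d, out$d)
  # non-positive slopes are dropped with a warning
  bad <- rbind(buildups,
               tibble::tibble(pair = "neg", mixing_time = tm,
                              intensity = -tm))
  expect_warning(out2 <- noe_to_distances(bad, list(pair = "ref", d = 3)),
                 "non-positive")
  expect_false("neg" %in% out2$pair)
})

test_that("restraint TSV round-trips losslessly and rejects bad bounds", {
  net <- attach_partial_assignment(
    toy_network(tolerance = 0.1),
    types = list(M_1 = c("VAL", "LEU", "ILE")),
    same_residue = list(c("M_1", "M_2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_restraints(net, path)
  back <- read_restraints(path, protons = net$protons)
  expect_equal(back$restraints, net$restraints)
  expect_equal(back$labels$type_constraint, net$labels$type_constraint)
  expect_equal(back$labels$group, net$labels$group)
  expect_equal(back$tolerance_fraction, net$tolerance_fraction)
  # corrupt one bound so lower > upper
  lines <- readLines(path)
  lines[3] <- sub("\t4\\.5\t", "\t9.5\t", lines[3])
  writeLines(lines, path)
  expect_error(read_restraints(path), "lower")
})

test_that("limit files carry one two-decimal bound per restraint", {
  net <- toy_network(tolerance = 0.1)
  up <- withr::local_tempfile(fileext = ".upl")
  lo <- withr::local_tempfile(fileext = ".lol")
  write_upl(net, up)
  write_lol(net, lo)
  upl <- readLines(up)
  expect_length(upl, nrow(net$restraints))
  expect_match(upl[1], "M_1")
  expect_match(upl[1], "5\\.50")
  expect_match(readLines(lo)[1], "4\\.50")
})
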