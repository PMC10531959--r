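#' Construct a semi-ambiguous restraint network
#'
#' A restraint network couples assigned ligand protons to anonymous methyl
#' labels `M_n` through distance bounds. Each restraint carries a central
#' distance `d` (Angstrom) together with lower/upper limits; the labels may
#' carry partial-assignment information (an amino-acid type set and/or a
#' same-residue group).
#'
#' @param restraints Tibble with columns `label`, `proton_id`, `d`, `lower`,
#'   `upper` (`lower`/`upper` default to `d` when absent).
#' @param protons Tibble of ligand protons (`proton_id`, optionally `x`,
#'   `y`, `z`). Coordinates are needed by the topology operations.
#' @param labels Optional tibble with `label`, list-column `type_constraint`
#'   and `group`; defaults to unconstrained labels taken from `restraints`.
#' @param tolerance_fraction Fractional tolerance already applied to the
#'   bounds (bookkeeping only).
#' @return An object of class `nmr2_network`.
#' @export
restraint_network <- function(restraints, protons, labels = NULL,
                              tolerance_fraction = 0) {
  restraints <- as_tibble(restraints)
  if (!"lower" %in% names(restraints)) restraints$lower <- restraints$d
  if (!"upper" %in% names(restraints)) restraints$upper <- restraints$d
  protons <- as_tibble(protons)
  if (!all(c("x", "y", "z") %in% names(protons))) {
    protons$x <- protons$y <- protons$z <- NA_real_
  }
  if (is.null(labels)) {
    labels <- tibble(label = unique(restraints$label))
  }
  labels <- as_tibble(labels)
  if (!"type_constraint" %in% names(labels)) {
    labels$type_constraint <- vector("list", nrow(labels))
  }
  if (!"group" %in% names(labels)) labels$group <- NA_character_
  validate_network(restraints, protons, labels, tolerance_fraction)
  structure(
    list(restraints = restraints, labels = labels, protons = protons,
         tolerance_fraction = tolerance_fraction),
    class = "nmr2_network"
  )
}

validate_network <- function(restraints, protons, labels, tolerance_fraction) {
  if (nrow(restraints) == 0) abort("empty network: no restraints")
  bad <- with(restraints, !(lower > 0 & lower <= d + 1e-9 & d <= upper + 1e-9))
  if (any(bad)) {
    abort(paste0("invalid restraint bounds (need 0 < lower <= d <= upper) at row(s) ",
                 paste(which(bad), collapse = ", ")))
  }
  if (!all(restraints$label %in% labels$label)) {
    abort("restraint references an undeclared label")
  }
  if (!all(restraints$proton_id %in% protons$proton_id)) {
    abort("restraint references an undeclared proton")
  }
  if (anyDuplicated(labels$label)) abort("duplicate anonymous labels")
  if (tolerance_fraction < 0 || tolerance_fraction >= 1) {
    abort("tolerance_fraction must lie in [0, 1)")
  }
  invisible(TRUE)
}

#' @export
print.nmr2_network <- function(x, ...) {
  cat("<nmr2_network>", nrow(x$restraints), "restraints,",
      nrow(x$labels), "anonymous methyls,", nrow(x$protons), "protons;",
      "tolerance", sprintf("%.0f%%", 100 * x$tolerance_fraction),
      "; <d> =", sprintf("%.2f", mean(x$restraints$d)), "A\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @export
tidy.nmr2_network <- function(x, ...) {
  dplyr::left_join(x$restraints, x$labels, by = "label")
}

#' @exportS3Method generics::glance
#' @export
glance.nmr2_network <- function(x, ...) {
  tibble(
    n_restraints = nrow(x$restraints),
    n_labels = nrow(x$labels),
    n_protons = nrow(x$protons),
    mean_d = mean(x$restraints$d),
    tolerance_fraction = x$tolerance_fraction,
    n_constrained = sum(!vapply(x$labels$type_constraint, is.null, logical(1)))
  )
}

#' Measure in-silico restraints and anonymize the methyls
#'
#' Measures every ligand-proton to methyl-carbon distance not exceeding
#' `max_distance` and anonymizes the methyls with labels `M_n` under a
#' seeded shuffle. The central distance is the exact geometric distance to
#' the methyl carbon (measuring to the carbon rather than to the rotor
#' protons is what the customary +0.7 Angstrom carbon markup accounts for).
#' Only methyls that contribute at least one restraint receive a label,
#' mirroring the fact that only observed cross-peaks exist experimentally.
#'
#' @param complex An `nmr2_complex`, or a proton tibble (`proton_id`, `x`,
#'   `y`, `z`) for synthetic inputs.
#' @param methyls Methyl-site tibble ([find_binding_site_methyls()]).
#' @param max_distance Maximum proton-carbon distance in Angstrom
#'   (default 8, chosen to cover observable NOE contacts to carbons).
#' @param seed Integer seed for the anonymizing shuffle.
#' @return A list with `network` (an `nmr2_network`, zero tolerance) and
#'   `truth` (tibble `label`, `site_id`), the ground-truth assignment map.
#'   `truth` exists for benchmarking only and must never be fed to the
#'   engine.
#' @export
extract_restraints <- function(complex, methyls, max_distance = 8, seed = 1) {
  protons <- if (inherits(complex, "nmr2_complex")) {
    ligand_protons(complex)
  } else {
    as_tibble(complex)
  }
  stopifnot(nrow(methyls) >= 1, nrow(protons) >= 1, max_distance > 0)
  pm <- coords_matrix(protons)
  cm <- coords_matrix(methyls)
  dmat <- sqrt(outer(rowSums(pm^2), rep(1, nrow(cm))) +
               outer(rep(1, nrow(pm)), rowSums(cm^2)) - 2 * pm %*% t(cm))
  hits <- which(dmat <= max_distance, arr.ind = TRUE)
  if (nrow(hits) == 0) {
    abort("empty network: no proton-methyl pair within max_distance")
  }
  used_sites <- sort(unique(hits[, 2]))
  perm <- with_seed(seed, sample(length(used_sites)))
  label_of_site <- setNames(paste0("M_", perm), methyls$site_id[used_sites])
  restraints <- tibble(
    label = unname(label_of_site[methyls$site_id[hits[, 2]]]),
    proton_id = protons$proton_id[hits[, 1]],
    d = dmat[hits]
  )
  restraints <- dplyr::arrange(
    restraints,
    as.integer(sub("^M_", "", .data$label)), .data$proton_id
  )
  truth <- tibble(label = unname(label_of_site),
                  site_id = names(label_of_site))
  truth <- dplyr::arrange(truth, as.integer(sub("^M_", "", .data$label)))
  labels <- tibble(label = truth$label)
  network <- restraint_network(restraints, protons, labels,
                               tolerance_fraction = 0)
  list(network = network, truth = truth)
}

#' Apply a fractional distance tolerance
#'
#' Sets, for every restraint, `upper = d * (1 + fraction)` and
#' `lower = d * (1 - fraction)`; the central distance is unchanged. A 10%
#' tolerance therefore places the limits 10% above and below the measured
#' restraint.
#'
#' @param network An `nmr2_network`.
#' @param fraction Tolerance fraction in `[0, 1)`.
#' @return The network with updated bounds and `tolerance_fraction`.
#' @export
apply_tolerance <- function(network, fraction) {
  stopifnot(inherits(network, "nmr2_network"), fraction >= 0, fraction < 1)
  network$restraints$upper <- network$restraints$d * (1 + fraction)
  network$restraints$lower <- network$restraints$d * (1 - fraction)
  network$tolerance_fraction <- fraction
  network
}

#' Attach partial-assignment constraints to anonymous labels
#'
#' Partial assignment encodes coarse knowledge of the anonymous methyls
#' obtained from auxiliary experiments: a constant-time HSQC identifies
#' methionine methyls, an HCCH-TOCSY identifies alanines and threonines and
#' tells whether two methyls belong to the same residue, while valine,
#' leucine and isoleucine methyls are only identifiable as members of that
#' group. Constraints restrict the assignment enumeration; they never name
#' residue numbers.
#'
#' @param network An `nmr2_network`.
#' @param types Named list mapping labels to amino-acid type sets, e.g.
#'   `list(M_1 = "MET", M_2 = c("VAL", "LEU", "ILE"))`.
#' @param same_residue List of character vectors of labels known to share a
#'   residue, e.g. `list(c("M_2", "M_3"))`.
#' @return The network with constraints stored on its labels.
#' @export
attach_partial_assignment <- function(network, types = list(),
                                      same_residue = list()) {
  stopifnot(inherits(network, "nmr2_network"))
  known <- network$labels$label
  for (lab in names(types)) {
    if (!lab %in% known) abort(paste0("constraint on unknown label '", lab, "'"))
    ts <- toupper(types[[lab]])
    if (length(ts) == 0 || !all(ts %in% .methyl_residues)) {
      abort(paste0("invalid type set for label '", lab, "'"))
    }
    network$labels$type_constraint[[match(lab, known)]] <- ts
  }
  for (i in seq_along(same_residue)) {
    grp <- same_residue[[i]]
    if (!all(grp %in% known)) {
      abort(paste0("same-residue group names unknown label(s): ",
                   paste(setdiff(grp, known), collapse = ", ")))
    }
    network$labels$group[match(grp, known)] <- paste0("G", i)
  }
  network
}

#' Convert NOE build-up intensities to distances
#'
#' Fits the initial build-up slope of each cross-peak by least squares
#' through the origin and converts slopes to distances with the isolated
#' spin pair approximation, `d = d_ref * (slope_ref / slope)^(1/6)`,
#' calibrated against a reference pair of known distance. This is an
#' initial-slope scheme, not a relaxation-matrix treatment.
#'
#' @param buildups Tibble with columns `pair`, `mixing_time`, `intensity`
#'   (normalized cross-peak intensity).
#' @param reference List or named vector with `pair` (a value of
#'   `buildups$pair`) and `d` (its known distance, Angstrom).
#' @return Tibble `pair`, `slope`, `d`. Pairs with non-positive slope are
#'   dropped with a warning.
#' @export
noe_to_distances <- function(buildups, reference) {
  buildups <- as_tibble(buildups)
  stopifnot(all(c("pair", "mixing_time", "intensity") %in% names(buildups)))
  slopes <- buildups |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(
      n = dplyr::n(),
      slope = sum(.data$intensity * .data$mixing_time) /
        sum(.data$mixing_time^2),
      .groups = "drop"
    )
  if (any(slopes$n < 2)) {
    abort("each pair needs at least two mixing times")
  }
  ref_pair <- as.character(reference$pair %||% reference[["pair"]])
  d_ref <- as.numeric(reference$d %||% reference[["d"]])
  slope_ref <- slopes$slope[slopes$pair == ref_pair]
  if (length(slope_ref) != 1 || slope_ref <= 0) {
    abort("reference pair absent or has non-positive slope")
  }
  bad <- slopes$slope <= 0
  if (any(bad)) {
    warn(paste0("dropping pair(s) with non-positive build-up slope: ",
                paste(slopes$pair[bad], collapse = ", ")))
    slopes <- slopes[!bad, , drop = FALSE]
  }
  tibble(pair = slopes$pair, slope = slopes$slope,
         d = d_ref * (slope_ref / slopes$slope)^(1 / 6))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write and read restraint networks as TSV
#'
#' The native dialect is a UTF-8 tab-separated table with a header and
#' columns `label`, `proton_id`, `d`, `lower`, `upper`, `type_constraint`
#' (comma-joined, empty when unconstrained) and `group`. A comment line
#' records the tolerance fraction so a write/read cycle is lossless for the
#' restraint table; proton coordinates travel with the ligand conformer,
#' not with the restraints.
#'
#' @param network An `nmr2_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(network, path) {
  stopifnot(inherits(network, "nmr2_network"))
  tab <- dplyr::left_join(network$restraints, network$labels, by = "label")
  tab$type_constraint <- vapply(tab$type_constraint, function(x) {
    if (is.null(x)) "" else paste(x, collapse = ",")
  }, character(1))
  tab$group <- ifelse(is.na(tab$group), "", tab$group)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# tolerance_fraction\t%g", network$tolerance_fraction), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_restraints
#' @param protons Optional proton tibble supplying coordinates for the
#'   protons named in the file.
#' @return `read_restraints()` returns an `nmr2_network`.
#' @export
read_restraints <- function(path, protons = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  tol <- 0
  hdr <- grepl("^# tolerance_fraction", lines)
  if (any(hdr)) {
    tol <- as.numeric(sub(".*\t", "", lines[which(hdr)[1]]))
    lines <- lines[!hdr]
  }
  tab <- tryCatch(
    read.delim(text = lines, sep = "\t", stringsAsFactors = FALSE,
               colClasses = c(label = "character", proton_id = "character",
                              d = "numeric", lower = "numeric",
                              upper = "numeric", type_constraint = "character",
                              group = "character")),
    error = function(e) abort(paste0("malformed restraint TSV: ", conditionMessage(e)))
  )
  need <- c("label", "proton_id", "d", "lower", "upper")
  if (!all(need %in% names(tab))) {
    abort(paste0("malformed restraint TSV: missing column(s) ",
                 paste(setdiff(need, names(tab)), collapse = ", ")))
  }
  bad <- which(!(tab$lower <= tab$d + 1e-9 & tab$d <= tab$upper + 1e-9))
  if (length(bad)) {
    abort(paste0("malformed restraint TSV: lower/upper violate lower <= d <= upper ",
                 "at line(s) ", paste(bad + 2, collapse = ", ")))
  }
  labs <- tab[!duplicated(tab$label), c("label", "type_constraint", "group")]
  labels <- tibble(
    label = labs$label,
    type_constraint = lapply(labs$type_constraint, function(s) {
      if (is.na(s) || s == "") NULL else strsplit(s, ",")[[1]]
    }),
    group = ifelse(is.na(labs$group) | labs$group == "", NA_character_, labs$group)
  )
  if (is.null(protons)) {
    protons <- tibble(proton_id = unique(tab$proton_id))
  }
  restraint_network(tab[, need], protons, labels, tolerance_fraction = tol)
}

#' Write CYANA-style upper/lower limit files
#'
#' Emits one line per restraint with the anonymous label, the ligand proton
#' and the bound in Angstrom formatted to two decimals (`.upl` upper
#' limits, `.lol` lower limits).
#'
#' @param network An `nmr2_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_upl <- function(network, path) {
  write_limits(network, path, "upper")
}

#' @rdname write_upl
#' @export
write_lol <- function(network, path) {
  write_limits(network, path, "lower")
}

write_limits <- function(network, path, which) {
  stopifnot(inherits(network, "nmr2_network"))
  r <- network$restraints
  writeLines(sprintf("%-8s %-8s %8.2f", r$label, r$proton_id, r[[which]]), path)
  invisible(path)
}
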