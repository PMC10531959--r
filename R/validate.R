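#' Heavy-atom rmsd between two ligand poses
#'
#' Root-mean-square deviation over the ligand heavy atoms, computed in the
#' fixed receptor frame WITHOUT re-superposition: the poses share the
#' receptor frame, and superposing them would erase exactly the
#' binding-mode difference being measured.
#'
#' @param poseA,poseB `nmr2_pose` objects.
#' @param ligand Ligand conformer atom tibble.
#' @return rmsd in Angstrom.
#' @export
pose_rmsd <- function(poseA, poseB, ligand) {
  heavy <- dplyr::filter(as_tibble(ligand), .data$element != "H")
  if (nrow(heavy) == 0) abort("ligand has no heavy atoms")
  a <- apply_pose(coords_matrix(heavy), poseA)
  b <- apply_pose(coords_matrix(heavy), poseB)
  sqrt(mean(rowSums((a - b)^2)))
}

#' Target function contrast of a ranked solution list
#'
#' The target function contrast (TFC) is the difference between the target
#' function of the first solution whose pose differs from the rank-1 pose
#' by more than `rmsd_cutoff` (default 2 Angstrom, heavy atoms, no
#' re-superposition) and the target function of the rank-1 solution. The
#' best-ranked structure is validated when the TFC exceeds the threshold
#' (default 0.2). When no solution is structurally distinct the TFC is
#' reported as `Inf` and the result validated with a loud warning, since a
#' single-cluster outcome cannot arise from a healthy combinatorial run.
#'
#' @param fit An `nmr2_fit` (all ranked solutions retained).
#' @param rmsd_cutoff Distinct-pose criterion, Angstrom (default 2).
#' @param threshold Validation threshold on the TFC (default 0.2).
#' @return An object of class `nmr2_validation` with fields `tfc`,
#'   `validated`, `best` (rank-1 row), `contrast` (contrast row or `NULL`),
#'   `rmsd_cutoff`, `threshold`.
#' @export
compute_tfc <- function(fit, rmsd_cutoff = 2, threshold = 0.2) {
  stopifnot(inherits(fit, "nmr2_fit"))
  sols <- fit$solutions
  if (nrow(sols) == 0) abort("empty solution list")
  p1 <- best_pose(fit, 1)
  contrast_idx <- NA_integer_
  for (i in seq_len(nrow(sols))[-1]) {
    if (pose_rmsd(p1, best_pose(fit, i), fit$ligand) > rmsd_cutoff) {
      contrast_idx <- i
      break
    }
  }
  if (is.na(contrast_idx)) {
    warn(paste0("no solution differs from rank 1 by > ", rmsd_cutoff,
                " A rmsd; TFC reported as Inf (single-cluster outcome)"))
    tfc <- Inf
  } else {
    tfc <- sols$tf[contrast_idx] - sols$tf[1]
  }
  structure(
    list(tfc = tfc, validated = tfc > threshold,
         best = sols[1, ],
         contrast = if (is.na(contrast_idx)) NULL else sols[contrast_idx, ],
         rmsd_cutoff = rmsd_cutoff, threshold = threshold, fit = fit),
    class = "nmr2_validation"
  )
}

#' @export
print.nmr2_validation <- function(x, ...) {
  cat("<nmr2_validation> TFC =", sprintf("%.3f", x$tfc),
      if (x$validated) "(validated)" else "(NOT validated)", "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @export
tidy.nmr2_validation <- function(x, ...) {
  tibble(
    tfc = x$tfc, validated = x$validated, best_tf = x$best$tf,
    contrast_tf = if (is.null(x$contrast)) NA_real_ else x$contrast$tf,
    rmsd_cutoff = x$rmsd_cutoff, threshold = x$threshold
  )
}

#' @exportS3Method generics::glance
#' @export
glance.nmr2_validation <- function(x, ...) tidy(x)

ligand_principal_axis <- function(coords) {
  cen <- sweep(coords, 2, colMeans(coords))
  ax <- svd(cen)$v[, 1]
  # orient the axis consistently using the atom with the largest projection
  k <- which.max(abs(cen %*% ax))
  if (sum(cen[k, ] * ax) < 0) ax <- -ax
  list(axis = ax, anchor = k)
}

#' Classify a validated result against a reference pose
#'
#' Success requires (i) a validated TFC, (ii) heavy-atom rmsd to the
#' reference pose below 2 Angstrom, and (iii) matching fragment
#' orientation. The orientation test is an automated stand-in for a visual
#' overlay inspection: the angle between the ligand principal axes of the
#' best and reference poses (signs fixed by atom correspondence) must be
#' below `max_axis_angle` degrees.
#'
#' @param result An `nmr2_validation`.
#' @param reference_pose The reference (e.g. crystallographic or
#'   ground-truth) `nmr2_pose`, in the same receptor frame.
#' @param rmsd_limit Success rmsd criterion, Angstrom (default 2).
#' @param max_axis_angle Orientation criterion, degrees (default 90).
#' @return One-row tibble: `success`, `validated`, `rmsd_to_reference`,
#'   `axis_angle_deg`.
#' @export
classify_success <- function(result, reference_pose, rmsd_limit = 2,
                             max_axis_angle = 90) {
  stopifnot(inherits(result, "nmr2_validation"))
  fit <- result$fit
  bp <- best_pose(fit, 1)
  rmsd <- pose_rmsd(bp, reference_pose, fit$ligand)
  heavy <- dplyr::filter(fit$ligand, .data$element != "H")
  a <- ligand_principal_axis(apply_pose(coords_matrix(heavy), bp))
  b <- ligand_principal_axis(apply_pose(coords_matrix(heavy), reference_pose))
  ang <- acos(pmin(1, pmax(-1, sum(a$axis * b$axis)))) * 180 / pi
  tibble(
    success = result$validated && rmsd < rmsd_limit && ang < max_axis_angle,
    validated = result$validated,
    rmsd_to_reference = rmsd,
    axis_angle_deg = ang
  )
}

#' Aggregate a benchmark table
#'
#' Summarizes benchmark rows per condition (tolerance and partial
#' assignment): success rate, rmsd and TFC mean and standard deviation,
#' and mean topology parameters split by success. Two scopes are reported:
#' `"all"` uses every row of a condition; `"converged_all"` restricts the
#' rmsd/TFC statistics to the cases that validated under every condition,
#' so conditions are compared on a common population.
#'
#' @param rows Tibble of benchmark rows with columns `case_id`,
#'   `tolerance_fraction`, `partial_assignment`, `tfc`, `rmsd`,
#'   `validated`, `success`, `r_l`, `r_w` (e.g. from [run_benchmark()]).
#' @return An object of class `nmr2_report`; `tidy()` returns the summary
#'   tibble.
#' @export
aggregate_report <- function(rows) {
  rows <- as_tibble(rows)
  stopifnot(nrow(rows) >= 1)
  conv_all <- rows |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(all_ok = all(.data$validated), .groups = "drop") |>
    dplyr::filter(.data$all_ok) |>
    dplyr::pull(.data$case_id)
  summarize_scope <- function(df, scope) {
    df |>
      dplyr::group_by(.data$tolerance_fraction, .data$partial_assignment) |>
      dplyr::summarise(
        scope = scope,
        n = dplyr::n(),
        success_rate = mean(.data$success),
        rmsd_mean = mean(.data$rmsd),
        rmsd_sd = ifelse(dplyr::n() > 1, sd(.data$rmsd), 0),
        tfc_mean = mean(.data$tfc[is.finite(.data$tfc)]),
        tfc_sd = ifelse(sum(is.finite(.data$tfc)) > 1,
                        sd(.data$tfc[is.finite(.data$tfc)]), 0),
        r_l_success = mean(.data$r_l[.data$success]),
        r_w_success = mean(.data$r_w[.data$success]),
        r_l_fail = mean(.data$r_l[!.data$success]),
        r_w_fail = mean(.data$r_w[!.data$success]),
        .groups = "drop"
      )
  }
  full <- summarize_scope(rows, "all")
  restricted <- summarize_scope(
    dplyr::filter(rows, .data$case_id %in% conv_all), "converged_all")
  out <- dplyr::bind_rows(full, restricted)
  structure(list(summary = out, rows = rows, converged_cases = conv_all),
            class = "nmr2_report")
}

#' @export
print.nmr2_report <- function(x, ...) {
  cat("<nmr2_report>", dplyr::n_distinct(x$rows$case_id), "cases,",
      nrow(x$summary[x$summary$scope == "all", ]), "conditions\n")
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @export
tidy.nmr2_report <- function(x, ...) x$summary

#' @exportS3Method generics::glance
#' @export
glance.nmr2_report <- function(x, ...) {
  tibble(n_cases = dplyr::n_distinct(x$rows$case_id),
         n_conditions = nrow(x$summary[x$summary$scope == "all", ]),
         n_converged_all = length(x$converged_cases))
}

#' Convenience two-sample t-test on rmsd distributions
#'
#' Thin wrapper around [stats::t.test()] comparing the rmsd values of two
#' benchmark conditions.
#'
#' @param rows Benchmark row tibble.
#' @param tol_a,tol_b Tolerance fractions of the two conditions.
#' @param pa_a,pa_b Partial-assignment flags of the two conditions.
#' @return The `htest` object.
#' @export
rmsd_t_test <- function(rows, tol_a, tol_b, pa_a = FALSE, pa_b = FALSE) {
  a <- rows$rmsd[rows$tolerance_fraction == tol_a &
                   rows$partial_assignment == pa_a]
  b <- rows$rmsd[rows$tolerance_fraction == tol_b &
                   rows$partial_assignment == pa_b]
  stats::t.test(a, b)
}
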