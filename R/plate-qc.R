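#' Z-prime plate quality factor
#'
#' `1 - 3 (sd_p + sd_n) / |mean_p - mean_n|` computed from the in-plate
#' positive- and negative-control well POS values. Sample (n-1) standard
#' deviations; the absolute mean difference keeps the statistic meaningful
#' for assays where the positive control reads low.
#'
#' @param pos_values,neg_values control well POS values (%), at least two
#'   per group.
#' @return the Z-prime factor (dimensionless, always <= 1).
#' @export
z_prime <- function(pos_values, neg_values) {
  if (length(pos_values) < 2 || length(neg_values) < 2)
    stop("need at least 2 control values per group", call. = FALSE)
  mu_p <- mean(pos_values); mu_n <- mean(neg_values)
  if (mu_p == mu_n)
    stop("degenerate controls: positive and negative means are equal",
         call. = FALSE)
  1 - 3 * (sd(pos_values) + sd(neg_values)) / abs(mu_p - mu_n)
}

#' QC report for one plate from its control well summaries
#'
#' @param wells well-summary data.frame for one plate (from
#'   [gate_plate()] or the well-level simulator).
#' @param plate_map plate-map rows for the same plate.
#' @param pos_role,neg_role plate-map roles supplying the controls; the
#'   checkpoint screen uses the checkpoint-ablating siRNA wells as
#'   positive and the mock (lipid-only) wells as negative controls.
#' @param threshold plate acceptance threshold on Z-prime.
#' @return one-row data.frame
#'   `plate_id,mu_p,sigma_p,mu_n,sigma_n,z_prime,accepted`.
#' @export
qc_plate <- function(wells, plate_map, pos_role = "pos_control",
                     neg_role = "mock", threshold = 0.2) {
  plate <- unique(plate_map$plate_id)
  if (length(plate) != 1) stop("qc_plate expects a single plate", call. = FALSE)
  pv <- wells$pos_fraction[wells$well %in%
                             plate_map$well[plate_map$role == pos_role]]
  nv <- wells$pos_fraction[wells$well %in%
                             plate_map$well[plate_map$role == neg_role]]
  zp <- z_prime(pv, nv)
  data.frame(plate_id = plate,
             mu_p = mean(pv), sigma_p = sd(pv),
             mu_n = mean(nv), sigma_n = sd(nv),
             z_prime = zp, accepted = zp >= threshold,
             stringsAsFactors = FALSE)
}

#' Accept or reject a triplicate plate set on Z-prime
#'
#' A set is rejected (for rerun) when any of its plates falls strictly
#' below the threshold; a plate exactly at the threshold is accepted.
#'
#' @param plate_reports data.frame with columns `plate_id` and `z_prime`
#'   (e.g. rbind-ed [qc_plate()] rows), one row per plate in the set.
#' @param threshold rejection threshold.
#' @return list with `accepted` (logical), `offending` (plate ids below
#'   threshold), `threshold`, and the per-plate `reports`.
#' @export
qc_plate_set <- function(plate_reports, threshold = 0.2) {
  if (is.null(plate_reports) || nrow(plate_reports) == 0)
    stop("empty plate set", call. = FALSE)
  bad <- plate_reports$z_prime < threshold
  list(accepted = !any(bad),
       offending = plate_reports$plate_id[bad],
       threshold = threshold,
       reports = plate_reports)
}
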