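#' Library z-scores of per-target mean POS values
#'
#' Standardizes each target's triplicate-mean responder percentage against
#' the mean and standard deviation of all library target means from the
#' same run, so z measures the target's position within the library
#' distribution.
#'
#' @param target_means named numeric vector (target id -> mean POS %).
#' @return named numeric vector of z-scores.
#' @export
z_scores <- function(target_means) {
  if (length(target_means) < 10)
    stop("need at least 10 targets for a population z-score", call. = FALSE)
  s <- sd(target_means)
  if (!is.finite(s))
    stop("population spread undefined (missing values?)", call. = FALSE)
  if (s == 0) return(target_means * 0)  # degenerate library: all at the mean
  (target_means - mean(target_means)) / s
}

#' Aggregate well summaries into per-target screen statistics
#'
#' Joins the well summaries with the plate map (restricted to one run,
#' e.g. the irradiated plate set), averages the replicate library wells per
#' target, and computes library z-scores. The fold-reduction baseline is
#' the pooled mean POS of the requested control role across the plate set.
#'
#' @param wells well-summary data.frame.
#' @param plate_map matching plate-map rows for one treatment run.
#' @param baseline_role `"mock"` (default), `"nt"`, or `"population"`
#'   (library mean) as the fold-reduction baseline.
#' @return list with `targets` (data.frame
#'   `target_id,mean_pos,sd_pos,z_score,n_rep`) and `baseline_mean` (%).
#' @export
screen_targets <- function(wells, plate_map, baseline_role = "mock") {
  m <- merge(plate_map, wells, by = c("plate_id", "well"))
  lib <- m[m$role == "library" & !is.na(m$target_id), ]
  if (nrow(lib) == 0) stop("no library wells found", call. = FALSE)
  agg <- aggregate(pos_fraction ~ target_id, lib, function(v)
    c(mean = mean(v), sd = sd(v), n = length(v)))
  targets <- data.frame(target_id = agg$target_id,
                        mean_pos = agg$pos_fraction[, "mean"],
                        sd_pos = agg$pos_fraction[, "sd"],
                        n_rep = agg$pos_fraction[, "n"],
                        stringsAsFactors = FALSE)
  targets$z_score <- z_scores(setNames(targets$mean_pos, targets$target_id))
  baseline_mean <- if (baseline_role == "population") {
    mean(targets$mean_pos)
  } else {
    ctrl <- m[m$role == baseline_role, ]
    if (nrow(ctrl) == 0)
      stop("no wells with role '", baseline_role, "' for the baseline",
           call. = FALSE)
    mean(ctrl$pos_fraction)
  }
  list(targets = targets, baseline_mean = baseline_mean)
}

#' Grade z-scoring targets by fold reduction of the responder percentage
#'
#' Targets with z below the cut are graded on the fold by which their
#' knockdown prevented the responder shift: strong (fold >= 2), average
#' (1.6 <= fold < 2), weak (1.4 <= fold < 1.6); anything else is `none`.
#' Class boundaries are closed on the left.
#'
#' @param targets data.frame with `target_id`, `mean_pos`, `z_score`
#'   (e.g. `screen_targets()$targets`).
#' @param baseline_mean baseline mean POS (%) for the fold ratio.
#' @param z_cut z-score hit threshold (strict `<`).
#' @param fold_bounds increasing boundaries of the weak/average/strong
#'   classes.
#' @return the input with `fold_reduction` and `hit_class` columns added.
#' @export
grade_hits <- function(targets, baseline_mean, z_cut = -1.5,
                       fold_bounds = c(weak = 1.4, average = 1.6, strong = 2.0)) {
  if (baseline_mean <= 0 || any(targets$mean_pos <= 0))
    stop("means must be positive to form fold reductions", call. = FALSE)
  fold <- baseline_mean / targets$mean_pos
  cls <- rep("none", nrow(targets))
  is_hit <- targets$z_score < z_cut
  cls[is_hit & fold >= fold_bounds[["weak"]]]    <- "weak"
  cls[is_hit & fold >= fold_bounds[["average"]]] <- "average"
  cls[is_hit & fold >= fold_bounds[["strong"]]]  <- "strong"
  targets$fold_reduction <- fold
  targets$hit_class <- cls
  targets
}

#' Flag hits that also score in the unirradiated counterscreen
#'
#' A hit whose unirradiated z-score falls below the floor is flagged
#' nonspecific (it perturbs the readout without radiation) and excluded
#' from the validated candidate list; hits missing from the counterscreen
#' are retained but flagged untested.
#'
#' @param hits graded hit table from [grade_hits()].
#' @param unirradiated_z named numeric vector (target id -> z in the
#'   unirradiated run).
#' @param z_floor specificity floor (strict `<` flags).
#' @return `hits` with `counterscreen_z`, `counterscreen_flag`
#'   (`specific`/`nonspecific`/`untested`) and `candidate` (logical)
#'   columns.
#' @export
counterscreen_filter <- function(hits, unirradiated_z, z_floor = -1.3) {
  cz <- unname(unirradiated_z[hits$target_id])
  flag <- ifelse(is.na(cz), "untested",
                 ifelse(cz < z_floor, "nonspecific", "specific"))
  hits$counterscreen_z <- cz
  hits$counterscreen_flag <- flag
  hits$candidate <- hits$hit_class != "none" & flag != "nonspecific"
  hits
}

#' Validate pooled hits by single-oligonucleotide deconvolution
#'
#' An oligonucleotide is active when it meets the same criteria as a
#' weak-or-better pool hit (z below the cut and fold at or above the
#' floor); a target validates when at least `min_active` of its oligos are
#' active. Targets tested with fewer than two oligos cannot be assessed.
#'
#' @param oligo_results data.frame with columns `target_id`, `oligo_id`,
#'   `z_score`, `fold_reduction`.
#' @param min_active active oligos required for validation.
#' @param z_cut,fold_min activity criteria per oligo.
#' @return data.frame `target_id,n_oligos,n_active,validated,status`;
#'   `validated` is `NA` when deconvolution is insufficient.
#' @export
validate_deconvolution <- function(oligo_results, min_active = 2,
                                   z_cut = -1.5, fold_min = 1.4) {
  req <- c("target_id", "oligo_id", "z_score", "fold_reduction")
  if (!all(req %in% names(oligo_results)))
    stop("oligo_results needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  res <- lapply(split(oligo_results, oligo_results$target_id), function(d) {
    n <- nrow(d)
    active <- sum(d$z_score < z_cut & d$fold_reduction >= fold_min)
    if (n < 2)
      data.frame(target_id = d$target_id[1], n_oligos = n, n_active = active,
                 validated = NA, status = "insufficient_deconvolution",
                 stringsAsFactors = FALSE)
    else
      data.frame(target_id = d$target_id[1], n_oligos = n, n_active = active,
                 validated = active >= min_active,
                 status = if (active >= min_active) "validated" else "not_validated",
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Count table rows below a z-score threshold
#'
#' Convenience for hit tallies on per-target summary tables.
#'
#' @param targets data.frame with a z-score column, or a numeric vector.
#' @param cut threshold (strict `<`).
#' @param column z-score column name for data.frame input.
#' @export
count_z_below <- function(targets, cut, column = "zscore") {
  z <- if (is.numeric(targets)) targets else targets[[column]]
  if (is.null(z)) stop("no z-score column '", column, "'", call. = FALSE)
  sum(z < cut, na.rm = TRUE)
}
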