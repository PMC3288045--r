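#' 96-well plate layout with in-plate triplicate controls
#'
#' Row A carries the controls: wells A01-A03 positive control
#' (checkpoint-ablating siRNA), A04-A06 mock (lipid only), A07-A09
#' non-targeting siRNA. The remaining 87 wells take library targets in
#' order; a final partial plate simply leaves trailing wells empty.
#'
#' @param target_ids character vector of library targets for this plate
#'   (at most 87).
#' @return data.frame with columns `well`, `role`, `target_id`.
#' @export
plate_layout <- function(target_ids) {
  if (length(target_ids) > 87)
    stop("a 96-well plate holds at most 87 library wells", call. = FALSE)
  wells <- sprintf("%s%02d", rep(LETTERS[1:8], each = 12), rep(1:12, 8))
  role <- c(rep("pos_control", 3), rep("mock", 3), rep("nt", 3),
            rep("library", length(target_ids)))
  data.frame(well = wells[seq_along(role)],
             role = role,
             target_id = c(rep(NA_character_, 9), target_ids),
             stringsAsFactors = FALSE)
}

true_fraction_for <- function(role, effect, treatment_gy, cfg) {
  b <- cfg$baseline_pos; ir <- cfg$ir_pos
  e <- ifelse(role == "pos_control", cfg$pos_control_effect,
              ifelse(role == "library", effect, 0))
  ifelse(treatment_gy <= 0, b, b + (ir - b) * (1 - e))
}

#' Simulate a full synthetic screen (irradiated run plus counterscreen)
#'
#' Generates triplicate 96-well plate sets for an irradiated (5 Gy) and an
#' unirradiated run. Knockdown acts on the mixture weight (the fraction of
#' responder cells), never on the component intensities. With
#' `level = "cell"` per-cell intensity tables are produced for the gating
#' stage; with `level = "well"` the per-well responder fractions are drawn
#' directly at the binomial level (same statistical model, including the
#' small gate spill `pnorm(-separation_sigma)` per component), which is the
#' fast path for screen-scale hit-calling studies.
#'
#' @param config a [screen_config()].
#' @param level `"cell"` or `"well"`.
#' @param seed overrides `config$seed` when given.
#' @return list of class `g1_screen_sim` with elements `plate_map`,
#'   `truth` (true responder fraction per well), `cells` (per-cell table,
#'   cell level only), `wells` (well summaries, well level only), `config`,
#'   `level`.
#' @export
simulate_screen <- function(config, level = c("cell", "well"),
                            seed = config$seed) {
  stopifnot(inherits(config, "screen_config"))
  level <- match.arg(level)
  set.seed(seed)

  ids <- sprintf("TGT_%04d", seq_len(config$n_targets))
  eff <- setNames(rep(0, config$n_targets), ids)
  if (!is.null(config$planted_hits)) {
    ph <- config$planted_hits
    unknown <- setdiff(ph$target_id, ids)
    # planted ids outside TGT_* replace library ids in place so the truth
    # table and plate map stay aligned
    if (length(unknown)) {
      stopifnot(length(unknown) <= config$n_targets)
      ids[seq_along(unknown)] <- unknown
      eff <- setNames(rep(0, config$n_targets), ids)
    }
    eff[ph$target_id] <- ph$effect_size
  }

  n_plates <- ceiling(config$n_targets / 87)
  maps <- vector("list", n_plates * config$replicates * 2)
  k <- 0
  for (p in seq_len(n_plates)) {
    idx <- ((p - 1) * 87 + 1):min(p * 87, config$n_targets)
    lay <- plate_layout(ids[idx])
    for (r in seq_len(config$replicates)) {
      for (gy in c(5, 0)) {
        k <- k + 1
        m <- lay
        m$plate_id <- sprintf("P%02d_R%d_%s", p, r, if (gy > 0) "IR" else "C")
        m$oligo_id <- "pool"
        m$treatment_gy <- gy
        m$replicate <- r
        maps[[k]] <- m
      }
    }
  }
  plate_map <- do.call(rbind, maps)
  plate_map <- plate_map[, c("plate_id", "well", "role", "target_id",
                             "oligo_id", "treatment_gy", "replicate")]

  p0 <- true_fraction_for(plate_map$role,
                          ifelse(is.na(plate_map$target_id), 0,
                                 eff[plate_map$target_id]),
                          plate_map$treatment_gy, config)
  p_true <- pmin(pmax(p0 + rnorm(nrow(plate_map), 0, config$well_noise_sd),
                      1e-3), 0.999)
  truth <- cbind(plate_map[, c("plate_id", "well", "role", "target_id",
                               "treatment_gy", "replicate")],
                 true_fraction = p_true)

  n_cells <- pmax(1L, rpois(nrow(plate_map), config$cells_per_well))
  out <- list(plate_map = plate_map, truth = truth, config = config,
              level = level, cells = NULL, wells = NULL)

  im <- config$intensity
  if (level == "well") {
    eps <- pnorm(-im$separation_sigma)
    p_obs <- p_true * (1 - eps) + (1 - p_true) * eps
    n_resp <- rbinom(nrow(plate_map), n_cells, p_obs)
    out$wells <- data.frame(plate_id = plate_map$plate_id,
                            well = plate_map$well,
                            metric = "POS-LoRBPS780",
                            n_cells = n_cells,
                            pos_fraction = 100 * n_resp / n_cells,
                            flag_low_cells = n_cells < config$min_cells,
                            stringsAsFactors = FALSE)
  } else {
    widx <- rep(seq_len(nrow(plate_map)), n_cells)
    total <- length(widx)
    resp <- rbinom(total, 1L, p_true[widx]) == 1L
    cells <- data.frame(
      plate_id = plate_map$plate_id[widx],
      well = plate_map$well[widx],
      cell_id = sequence(n_cells),
      ch_dna = rlnorm(total, im$dna_meanlog, im$dna_sdlog),
      ch_marker = rlnorm(total, ifelse(resp, im$lo_meanlog, im$hi_meanlog),
                         im$sdlog),
      ch_gfp_nuc = NA_real_,
      ch_gfp_cyto = NA_real_,
      stringsAsFactors = FALSE)
    out$cells <- cells
  }
  class(out) <- "g1_screen_sim"
  out
}

#' @export
print.g1_screen_sim <- function(x, ...) {
  cat("Synthetic checkpoint screen:", x$config$n_targets, "targets,",
      x$config$replicates, "replicates, level =", x$level, "\n")
  cat("  plates:", length(unique(x$plate_map$plate_id)),
      " wells:", nrow(x$plate_map), "\n")
  if (!is.null(x$cells)) cat("  cells:", nrow(x$cells), "\n")
  invisible(x)
}

#' Simulate one well of the G1 reporter assay
#'
#' Nuclear and cytoplasmic reporter intensities are independent
#' log-normals whose location ratio encodes cell-cycle state: G1 cells
#' draw the nuclear signal from the high and the cytoplasmic from the low
#' component, post-G1 cells the reverse.
#'
#' @param n_cells cells imaged.
#' @param g1_fraction true fraction of G1 cells in \[0,1\].
#' @param model an [intensity_model()].
#' @param plate_id,well identifiers copied into the records.
#' @return per-cell data.frame in the standard column layout.
#' @export
simulate_reporter_well <- function(n_cells, g1_fraction,
                                   model = intensity_model(),
                                   plate_id = "P01_R1_IR", well = "B01") {
  stopifnot(n_cells >= 1, g1_fraction >= 0, g1_fraction <= 1)
  g1 <- rbinom(n_cells, 1L, g1_fraction) == 1L
  data.frame(
    plate_id = plate_id, well = well, cell_id = seq_len(n_cells),
    ch_dna = rlnorm(n_cells, model$dna_meanlog, model$dna_sdlog),
    ch_marker = rlnorm(n_cells, model$hi_meanlog, model$sdlog),
    ch_gfp_nuc = rlnorm(n_cells, ifelse(g1, model$g1_hi_meanlog,
                                        model$g1_lo_meanlog), model$g1_sdlog),
    ch_gfp_cyto = rlnorm(n_cells, ifelse(g1, model$g1_lo_meanlog,
                                         model$g1_hi_meanlog), model$g1_sdlog),
    stringsAsFactors = FALSE)
}

#' Simulate ATP-luminescence viability readouts across knockdown arms
#'
#' @param config a [screen_config()]; the survival fractions come from its
#'   [viability_model()].
#' @param arms arm labels drawn from the model's arms (canonically
#'   `mock_nt`, `target_nt`, `mock_cokd`, `target_cokd`).
#' @param tech_reps technical replicates per arm and dose.
#' @param seed overrides `config$seed`.
#' @return data.frame `arm,target,co_kd,dose_gy,tech_rep,value` with
#'   positive luminescence values.
#' @export
simulate_viability_arms <- function(config,
                                    arms = names(config$viability$survival),
                                    tech_reps = 3, seed = config$seed) {
  stopifnot(inherits(config, "screen_config"))
  vm <- config$viability
  unknown <- setdiff(arms, names(vm$survival))
  if (length(unknown))
    stop("unknown viability arm label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  set.seed(seed)
  grid <- expand.grid(arm = arms, dose_i = seq_along(vm$doses),
                      tech_rep = seq_len(tech_reps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  surv <- mapply(function(a, i) vm$survival[[a]][i], grid$arm, grid$dose_i)
  val <- vm$base_lum * surv * exp(rnorm(nrow(grid), 0, vm$noise_sdlog))
  data.frame(arm = grid$arm,
             target = ifelse(grepl("^mock", grid$arm), "mock", "target"),
             co_kd = ifelse(grepl("cokd$", grid$arm), "coKD", "NT"),
             dose_gy = vm$doses[grid$dose_i],
             tech_rep = grid$tech_rep,
             value = val,
             stringsAsFactors = FALSE)
}

#' Simulate a per-target phenotype-profile matrix with planted groups
#'
#' Each group has a characteristic vector of normalized assay means
#' (relative to mock = 1); rows are drawn as the group profile plus iid
#' Gaussian noise. The default two groups emulate checkpoint-suppressing
#' knockdowns that do (group `"I"`) or do not (group `"II"`) also suppress
#' IR-induced p21 positivity.
#'
#' @param groups named character vector mapping target id to group label.
#' @param noise_sd SD of the additive noise on each matrix cell.
#' @param group_profiles named list of per-group assay-mean vectors; the
#'   built-in profiles cover groups `"I"` and `"II"`.
#' @param seed RNG seed.
#' @return numeric matrix, rows = targets, columns = assays.
#' @export
simulate_profile_matrix <- function(groups, noise_sd = 0.05,
                                    group_profiles = NULL, seed = 1L) {
  if (length(groups) < 2)
    stop("at least 2 targets are required", call. = FALSE)
  if (is.null(group_profiles))
    group_profiles <- list(
      # suppressed checkpoint AND suppressed p21 induction
      I  = c(lo_rb_ir = 0.40, p21_ir = 0.35, g1_ir = 0.55,
             surv_2gy = 0.70, surv_5gy = 0.45),
      # suppressed checkpoint with preserved p21 induction
      II = c(lo_rb_ir = 0.40, p21_ir = 0.95, g1_ir = 0.60,
             surv_2gy = 0.75, surv_5gy = 0.50))
  miss <- setdiff(unique(groups), names(group_profiles))
  if (length(miss))
    stop("no profile defined for group(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  set.seed(seed)
  prof <- do.call(rbind, group_profiles[groups])
  m <- prof + matrix(rnorm(length(prof), 0, noise_sd), nrow(prof))
  rownames(m) <- names(groups)
  colnames(m) <- names(group_profiles[[1]])
  m
}
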