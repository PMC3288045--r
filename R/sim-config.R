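#' Intensity model for simulated per-cell fluorescence
#'
#' Per-cell marker intensities are drawn from a two-component log-normal
#' mixture: a "high" population (normal marker signal) and a "low"
#' population (responder cells that have lost the signal). The mixture
#' weight of the low component is the well's true responder fraction.
#'
#' `separation_sigma` is the distance, in units of `sdlog`, between each
#' component's log-mean and the midpoint gate: the two component centres sit
#' `2 * separation_sigma * sdlog` apart on the log scale, so a gate at the
#' density crossing misassigns about `pnorm(-separation_sigma)` of each
#' component.
#'
#' @param hi_meanlog log-mean of the high-signal population (log AFU).
#' @param sdlog common log-sd of both components.
#' @param separation_sigma per-side separation between each component centre
#'   and the midpoint gate, in units of `sdlog`.
#' @param dna_meanlog,dna_sdlog DNA-stain channel (used only for object
#'   identification, never gated).
#' @param g1_hi_meanlog,g1_lo_meanlog,g1_sdlog G1 reporter compartment
#'   signals: a G1 cell draws its nuclear intensity from the high and its
#'   cytoplasmic intensity from the low log-normal; a non-G1 cell the
#'   reverse.
#' @return A list of class `intensity_model`.
#' @export
intensity_model <- function(hi_meanlog = log(500), sdlog = 0.25,
                            separation_sigma = 3,
                            dna_meanlog = log(1000), dna_sdlog = 0.3,
                            g1_hi_meanlog = log(80), g1_lo_meanlog = log(20),
                            g1_sdlog = 0.15) {
  stopifnot(sdlog > 0, separation_sigma > 0, g1_sdlog > 0,
            g1_hi_meanlog > g1_lo_meanlog)
  structure(list(hi_meanlog = hi_meanlog,
                 lo_meanlog = hi_meanlog - 2 * separation_sigma * sdlog,
                 sdlog = sdlog,
                 separation_sigma = separation_sigma,
                 dna_meanlog = dna_meanlog, dna_sdlog = dna_sdlog,
                 g1_hi_meanlog = g1_hi_meanlog, g1_lo_meanlog = g1_lo_meanlog,
                 g1_sdlog = g1_sdlog),
            class = "intensity_model")
}

#' Viability model for ATP-luminescence survival arms
#'
#' Survival fractions per arm and dose; readouts are drawn as
#' `base_lum * survival * exp(rnorm(1, 0, noise_sdlog))`, i.e. positive
#' with multiplicative log-normal noise. The four canonical arms cross
#' target knockdown with a co-knockdown background (e.g. CHK1).
#'
#' The defaults emulate a target whose knockdown sensitizes only in the
#' co-knockdown background: the target/NT arm matches the mock/NT arm
#' (multiplicative-null, interaction index 0 in expectation) while the
#' target/co-knockdown arm falls well below the multiplicative expectation
#' of the mock/co-knockdown arm.
#'
#' @param survival named list mapping arm label to a numeric vector of
#'   survival fractions, one per dose in `doses`. Dose 0 must be 1.
#' @param doses radiation doses in Gy.
#' @param base_lum expected luminescence (AFU) of an untreated well.
#' @param noise_sdlog log-sd of the multiplicative noise.
#' @export
viability_model <- function(survival = list(
                              mock_nt     = c(1, 0.75, 0.45),
                              target_nt   = c(1, 0.75, 0.45),
                              mock_cokd   = c(1, 0.70, 0.40),
                              target_cokd = c(1, 0.45, 0.18)),
                            doses = c(0, 2, 5),
                            base_lum = 5e5, noise_sdlog = 0.05) {
  stopifnot(all(doses >= 0), base_lum > 0, noise_sdlog >= 0)
  for (arm in names(survival)) {
    s <- survival[[arm]]
    if (length(s) != length(doses) || any(s <= 0) || any(s > 1.0000001))
      stop("survival fractions for arm '", arm,
           "' must be in (0,1], one per dose", call. = FALSE)
    if (abs(s[doses == 0] - 1) > 1e-12)
      stop("dose-0 survival must be 1 for arm '", arm, "'", call. = FALSE)
  }
  structure(list(survival = survival, doses = doses,
                 base_lum = base_lum, noise_sdlog = noise_sdlog),
            class = "viability_model")
}

#' Configuration of a synthetic checkpoint screen
#'
#' Defines the study conditions emulated by [simulate_screen()]: a
#' kinome-scale library screened in 96-well triplicate plate sets, each
#' plate carrying triplicate positive-control (checkpoint-ablating siRNA),
#' mock (lipid-only) and non-targeting wells, with a parallel unirradiated
#' counterscreen. Knockdown of a planted hit suppresses the IR-induced
#' shift of cells into the low-marker responder population by its effect
#' size; it does not move the mixture component locations.
#'
#' @param n_targets number of library targets (one gene, one well).
#' @param planted_hits `NULL` for a null screen, or a data.frame with
#'   columns `target_id`, `hit_class`, `effect_size` (fractional
#'   suppression of the IR-induced responder shift, in \[0,1\]). See
#'   [default_planted_hits()].
#' @param cells_per_well expected cells imaged per well (Poisson).
#' @param baseline_pos responder fraction without IR, in \[0,1\].
#' @param ir_pos responder fraction after IR in checkpoint-competent wells.
#' @param pos_control_effect effect size of the positive-control siRNA
#'   (1 = full suppression back to baseline).
#' @param well_noise_sd SD of Gaussian well-to-well jitter added to the
#'   true responder fraction (transfection and plate effects).
#' @param intensity an [intensity_model()].
#' @param viability a [viability_model()].
#' @param replicates plates per set (technical triplicate).
#' @param min_cells QC floor on imaged cells per well.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return A validated list of class `screen_config`.
#' @export
screen_config <- function(n_targets = 779, planted_hits = NULL,
                          cells_per_well = 2500,
                          baseline_pos = 0.05, ir_pos = 0.45,
                          pos_control_effect = 1,
                          well_noise_sd = 0.015,
                          intensity = intensity_model(),
                          viability = viability_model(),
                          replicates = 3, min_cells = 1500,
                          seed = 1L) {
  frac_ok <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  if (!frac_ok(baseline_pos) || !frac_ok(ir_pos) || !frac_ok(pos_control_effect))
    stop("fractions and effect sizes must lie in [0,1]", call. = FALSE)
  if (ir_pos <= baseline_pos)
    stop("ir_pos must exceed baseline_pos (IR shifts cells into the responder population)",
         call. = FALSE)
  if (n_targets < 1 || cells_per_well < 1 || replicates < 1)
    stop("n_targets, cells_per_well and replicates must be positive", call. = FALSE)
  if (!is.null(planted_hits)) {
    req <- c("target_id", "hit_class", "effect_size")
    if (!is.data.frame(planted_hits) || !all(req %in% names(planted_hits)))
      stop("planted_hits needs columns target_id, hit_class, effect_size",
           call. = FALSE)
    if (any(planted_hits$effect_size < 0 | planted_hits$effect_size > 1))
      stop("effect sizes must lie in [0,1]", call. = FALSE)
  }
  stopifnot(inherits(intensity, "intensity_model"),
            inherits(viability, "viability_model"))
  structure(list(n_targets = as.integer(n_targets),
                 planted_hits = planted_hits,
                 cells_per_well = cells_per_well,
                 baseline_pos = baseline_pos, ir_pos = ir_pos,
                 pos_control_effect = pos_control_effect,
                 well_noise_sd = well_noise_sd,
                 intensity = intensity, viability = viability,
                 replicates = as.integer(replicates),
                 min_cells = as.integer(min_cells),
                 seed = as.integer(seed)),
            class = "screen_config")
}

#' Effect size that produces a given true fold reduction
#'
#' The screen grades hits by fold reduction of the mean responder
#' percentage relative to the mock baseline (which sits at `ir_pos`).
#' A target whose knockdown suppresses the IR-induced shift by effect size
#' `e` has true responder fraction `b + (ir - b) (1 - e)`; inverting for a
#' target mean of `ir / fold` gives the effect size planted here.
#'
#' @param fold target true fold reduction (>= 1).
#' @param baseline_pos,ir_pos as in [screen_config()].
#' @return effect size in \[0,1\].
#' @export
effect_for_fold <- function(fold, baseline_pos = 0.05, ir_pos = 0.45) {
  stopifnot(fold >= 1)
  e <- (ir_pos - ir_pos / fold) / (ir_pos - baseline_pos)
  if (any(e > 1))
    stop("fold exceeds the dynamic range ir_pos/baseline_pos", call. = FALSE)
  e
}

#' Default planted-hit table: 12 strong, 18 average, 11 weak
#'
#' True fold reductions 2.5 / 1.8 / 1.5 for the strong / average / weak
#' classes, converted to effect sizes with [effect_for_fold()].
#'
#' @param baseline_pos,ir_pos as in [screen_config()].
#' @export
default_planted_hits <- function(baseline_pos = 0.05, ir_pos = 0.45) {
  cls  <- c(rep("strong", 12), rep("average", 18), rep("weak", 11))
  fold <- c(rep(2.5, 12), rep(1.8, 18), rep(1.5, 11))
  data.frame(target_id = sprintf("HIT_%s_%02d", toupper(substr(cls, 1, 3)),
                                 seq_along(cls)),
             hit_class = cls,
             true_fold = fold,
             effect_size = effect_for_fold(fold, baseline_pos, ir_pos),
             stringsAsFactors = FALSE)
}
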