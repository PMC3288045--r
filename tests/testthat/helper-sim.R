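# Shared fixtures, all generated in code.

# pure log-normal control samples for gate tests
lognormal_cells <- function(n, median, sdlog, channel = "ch_marker",
                            well = "A07", plate = "P01_R1_IR") {
  df <- data.frame(plate_id = plate, well = well, cell_id = seq_len(n),
                   ch_dna = 1000, ch_marker = NA_real_,
                   ch_gfp_nuc = NA_real_, ch_gfp_cyto = NA_real_)
  df[[channel]] <- rlnorm(n, log(median), sdlog)
  df
}

# mixture control sample: fraction `w` of cells in the low component
mixture_intensities <- function(n, w, model = intensity_model()) {
  low <- rbinom(n, 1, w) == 1
  rlnorm(n, ifelse(low, model$lo_meanlog, model$hi_meanlog), model$sdlog)
}

# small two-hit screen used across module tests
small_screen_config <- function(seed = 7, n_targets = 40) {
  screen_config(
    n_targets = n_targets,
    planted_hits = data.frame(
      target_id = c("TGT_0001", "TGT_0002"),
      hit_class = c("strong", "weak"),
      effect_size = effect_for_fold(c(2.5, 1.5))),
    seed = seed)
}

default_groups <- c(PRPK = "I", STK4 = "I", CDK4 = "I", CDKN1A = "I",
                    TP53 = "I", DYRK1A = "II", PRKACG = "II", HK1 = "II")
group_I <- names(default_groups)[default_groups == "I"]
group_II <- names(default_groups)[default_groups == "II"]
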