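plate_set_id <- function(plate_id) sub("_R[0-9]+_", "_", plate_id)

#' Run the full screen analysis chain on a synthetic screen
#'
#' Executes, in order: simulation (unless given a pre-simulated screen),
#' control-anchored gating per plate, Z-prime QC per plate with
#' plate-set accept/reject, hit calling on the irradiated run with the
#' unirradiated run as counterscreen, viability interaction analysis, and
#' phenotype-profile clustering. A rejected plate set halts the pipeline
#' after QC with a rejection report (the screen would be rerun). When
#' `out_dir` is given every stage output is written as CSV stamped with
#' the resolved-config hash; on re-run a stage whose output file already
#' carries the current hash is read back instead of recomputed.
#'
#' @param sim a [screen_config()] (simulated here) or an existing
#'   [simulate_screen()] result.
#' @param run_cfg a [run_config()].
#' @param out_dir optional output directory.
#' @param level simulation level when `sim` is a config.
#' @return list of class `g1_pipeline`: `status` (`"ok"` or
#'   `"rejected_qc"`), `wells`, `gates`, `qc`, `qc_sets`, `targets`,
#'   `baseline_mean`, `hits`, `viability`, `clustering`, `hash`.
#' @export
run_pipeline <- function(sim, run_cfg = run_config(), out_dir = NULL,
                         level = c("cell", "well")) {
  level <- match.arg(level)
  if (inherits(sim, "screen_config")) {
    cfg <- sim
    hash <- config_hash(unclass(cfg), unclass(run_cfg), level)
    reuse <- function(f) !is.null(out_dir) && file.exists(f) &&
      identical(file_config_hash(f), hash)
    wells_file <- if (!is.null(out_dir)) file.path(out_dir, "wells.csv")
    sim <- NULL
    if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                      showWarnings = FALSE)
    if (!is.null(wells_file) && reuse(wells_file)) {
      wells <- read_well_summaries(wells_file)
      plate_map <- read_plate_map(file.path(out_dir, "plate_map.csv"))
      gates <- NULL
    } else {
      sim <- simulate_screen(cfg, level = level)
      plate_map <- sim$plate_map
      gated <- gate_simulated(sim, run_cfg)
      wells <- gated$wells
      gates <- gated$gates
      if (!is.null(out_dir)) {
        write_table(plate_map, file.path(out_dir, "plate_map.csv"), hash)
        write_table(wells, wells_file, hash)
      }
    }
  } else if (inherits(sim, "g1_screen_sim")) {
    cfg <- sim$config
    hash <- config_hash(unclass(cfg), unclass(run_cfg), sim$level)
    plate_map <- sim$plate_map
    gated <- gate_simulated(sim, run_cfg)
    wells <- gated$wells
    gates <- gated$gates
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_table(plate_map, file.path(out_dir, "plate_map.csv"), hash)
      write_table(wells, file.path(out_dir, "wells.csv"), hash)
    }
  } else stop("sim must be a screen_config or a simulate_screen() result",
              call. = FALSE)

  # --- QC ------------------------------------------------------------
  qc <- do.call(rbind, lapply(split(plate_map, plate_map$plate_id),
                              function(pm) {
    qc_plate(wells[wells$plate_id == pm$plate_id[1], ], pm,
             threshold = run_cfg$zprime_threshold)
  }))
  rownames(qc) <- NULL
  # Z-prime gating applies to the irradiated run only: without IR the
  # controls span no assay window, so the counterscreen plates are
  # reported but cannot be held to the threshold.
  treat_by_plate <- tapply(plate_map$treatment_gy, plate_map$plate_id, max)
  qc_ir <- qc[treat_by_plate[qc$plate_id] > 0, ]
  qc_sets <- lapply(split(qc_ir, plate_set_id(qc_ir$plate_id)), qc_plate_set,
                    threshold = run_cfg$zprime_threshold)
  if (!is.null(out_dir)) write_table(qc, file.path(out_dir, "qc.csv"), hash)
  rejected <- Filter(function(s) !s$accepted, qc_sets)
  if (length(rejected)) {
    res <- list(status = "rejected_qc", qc = qc, qc_sets = qc_sets,
                rejected_sets = names(rejected), wells = wells,
                gates = if (exists("gates")) gates, hash = hash)
    class(res) <- "g1_pipeline"
    return(res)
  }

  # --- hit calling ---------------------------------------------------
  ir <- plate_map$treatment_gy > 0
  scr <- screen_targets(wells, plate_map[ir, ],
                        baseline_role = run_cfg$baseline_role)
  graded <- grade_hits(scr$targets, scr$baseline_mean,
                       z_cut = run_cfg$z_cut,
                       fold_bounds = run_cfg$fold_bounds)
  ctr <- screen_targets(wells, plate_map[!ir, ],
                        baseline_role = run_cfg$baseline_role)
  hits <- counterscreen_filter(
    graded, setNames(ctr$targets$z_score, ctr$targets$target_id),
    z_floor = run_cfg$counterscreen_floor)
  if (!is.null(out_dir)) {
    write_table(hits, file.path(out_dir, "hits.csv"), hash)
    write_target_summary_table(graded,
                               file.path(out_dir, "target_summary.csv"), hash)
  }

  # --- viability interaction -----------------------------------------
  viab <- survival_curves(simulate_viability_arms(cfg),
                          direction = "decreases",
                          tol = run_cfg$interaction_tol)
  if (!is.null(out_dir)) {
    write_table(viab$curves, file.path(out_dir, "survival_curves.csv"), hash)
    write_table(viab$indices, file.path(out_dir, "interaction_indices.csv"),
                hash)
  }

  # --- phenotype clustering ------------------------------------------
  groups <- c(PRPK = "I", STK4 = "I", CDK4 = "I", CDKN1A = "I", TP53 = "I",
              DYRK1A = "II", PRKACG = "II", HK1 = "II")
  profiles <- simulate_profile_matrix(groups,
                                      noise_sd = run_cfg$profile_noise_sd,
                                      seed = cfg$seed)
  clustering <- cluster_targets(profiles, k = run_cfg$cluster_k,
                                dist_method = run_cfg$cluster_dist,
                                linkage = run_cfg$cluster_linkage)
  if (!is.null(out_dir)) {
    write_table(data.frame(target = names(clustering$groups),
                           group = clustering$groups),
                file.path(out_dir, "cluster_groups.csv"), hash)
    write_dendrogram(clustering, file.path(out_dir, "dendrogram.nwk"))
    jsonlite::write_json(list(config_hash = hash,
                              run_config = unclass(run_cfg),
                              seed = cfg$seed),
                         file.path(out_dir, "resolved_config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  res <- list(status = "ok", wells = wells,
              gates = if (exists("gates")) gates,
              qc = qc, qc_sets = qc_sets,
              targets = graded, baseline_mean = scr$baseline_mean,
              hits = hits, viability = viab, clustering = clustering,
              hash = hash)
  class(res) <- "g1_pipeline"
  res
}

# Gate a simulated screen. Cell level: control-anchored gates are derived
# on the irradiated plates, where the responder shift separates the control
# histograms; the paired unirradiated plate (same plate and replicate)
# inherits its partner's gate, since without IR the positive-control and
# non-targeting histograms coincide and carry no gating information.
# Well level: the binomial well summaries pass through unchanged.
gate_simulated <- function(sim, run_cfg) {
  if (sim$level == "well") return(list(wells = sim$wells, gates = NULL))
  pm_all <- sim$plate_map
  treat <- tapply(pm_all$treatment_gy, pm_all$plate_id, max)
  ir_ids <- names(treat)[treat > 0]
  c_ids <- names(treat)[treat == 0]
  gates <- list()
  wells <- list()
  for (pid in ir_ids) {
    pm <- pm_all[pm_all$plate_id == pid, ]
    g <- gate_plate(sim$cells[sim$cells$plate_id == pid, ], pm,
                    channel = run_cfg$gate_channel,
                    direction = run_cfg$gate_direction,
                    min_cells = run_cfg$min_cells)
    gates[[pid]] <- g$gate
    wells[[pid]] <- g$wells
  }
  for (pid in c_ids) {
    partner <- sub("_C$", "_IR", pid)
    cells <- sim$cells[sim$cells$plate_id == pid, ]
    if (partner %in% names(gates)) {
      gate <- gates[[partner]]
      ws <- do.call(rbind, lapply(split(cells, cells$well), pos_fraction,
                                  gate = gate,
                                  min_cells = run_cfg$min_cells))
      rownames(ws) <- NULL
      gates[[pid]] <- gate
      wells[[pid]] <- ws
    } else {
      g <- gate_plate(cells, pm_all[pm_all$plate_id == pid, ],
                      channel = run_cfg$gate_channel,
                      direction = run_cfg$gate_direction,
                      min_cells = run_cfg$min_cells)
      gates[[pid]] <- g$gate
      wells[[pid]] <- g$wells
    }
  }
  list(wells = do.call(rbind, c(wells, make.row.names = FALSE)),
       gates = gates)
}

#' @export
print.g1_pipeline <- function(x, ...) {
  cat("Screen pipeline:", x$status, "\n")
  if (x$status == "rejected_qc") {
    cat("  rejected plate set(s):", paste(x$rejected_sets, collapse = ", "),
        "\n")
    return(invisible(x))
  }
  zp_ir <- unlist(lapply(x$qc_sets, function(s) s$reports$z_prime))
  cat("  plates:", nrow(x$qc), " median assay-plate Z' =",
      signif(median(zp_ir), 3), "\n")
  tab <- table(factor(x$hits$hit_class,
                      levels = c("strong", "average", "weak", "none")))
  cat("  hit classes:", paste(names(tab), tab, sep = "=", collapse = " "),
      "\n")
  cat("  candidates after counterscreen:", sum(x$hits$candidate), "\n")
  invisible(x)
}
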