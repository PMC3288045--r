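per_cell_cols <- c("plate_id", "well", "cell_id", "ch_dna", "ch_marker",
                   "ch_gfp_nuc", "ch_gfp_cyto")
plate_map_cols <- c("plate_id", "well", "role", "target_id", "oligo_id",
                    "treatment_gy", "replicate")
well_summary_cols <- c("plate_id", "well", "metric", "n_cells",
                       "pos_fraction", "flag_low_cells")

check_columns <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(df)
}

read_csv_commented <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

write_csv_commented <- function(df, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# config_hash: ", config_hash), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

file_config_hash <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "# config_hash: "))
    sub("^# config_hash: ", "", first)
  else NA_character_
}

#' Read a per-cell intensity table
#'
#' CSV with header `plate_id,well,cell_id,ch_dna,ch_marker,ch_gfp_nuc,
#' ch_gfp_cyto`; the reporter columns may be empty when the G1 reporter is
#' absent. Unknown columns are preserved; rows with non-numeric intensity
#' entries are dropped and counted in the `n_malformed` attribute.
#'
#' @param path CSV path.
#' @return data.frame of typed cell records.
#' @export
read_per_cell_table <- function(path) {
  df <- read_csv_commented(path)
  check_columns(df, per_cell_cols, "per-cell table")
  num_cols <- c("ch_dna", "ch_marker", "ch_gfp_nuc", "ch_gfp_cyto")
  for (cc in num_cols) {
    if (!is.numeric(df[[cc]])) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  }
  bad <- is.na(df$ch_dna) | is.na(df$ch_marker)
  out <- df[!bad, , drop = FALSE]
  attr(out, "n_malformed") <- sum(bad)
  out
}

#' Read a plate-map table
#'
#' @param path CSV with header
#'   `plate_id,well,role,target_id,oligo_id,treatment_gy,replicate`.
#' @export
read_plate_map <- function(path) {
  df <- read_csv_commented(path)
  check_columns(df, plate_map_cols, "plate map")
  df$treatment_gy <- as.numeric(df$treatment_gy)
  if (any(df$treatment_gy < 0, na.rm = TRUE))
    stop("treatment_gy must be non-negative", call. = FALSE)
  df
}

#' Read a well-summary table
#' @param path CSV with header
#'   `plate_id,well,metric,n_cells,pos_fraction,flag_low_cells`.
#' @export
read_well_summaries <- function(path) {
  df <- read_csv_commented(path)
  check_columns(df, well_summary_cols, "well summary table")
  df
}

#' Write a table with an audit header
#'
#' All pipeline outputs are plain CSV with an optional
#' `# config_hash: <md5>` first line identifying the resolved run
#' configuration that produced them.
#'
#' @param df table to write.
#' @param path output path.
#' @param config_hash hash string from [config_hash()], or `NULL`.
#' @export
write_table <- function(df, path, config_hash = NULL) {
  write_csv_commented(df, path, config_hash)
}

#' Read a per-target screen summary table
#'
#' Column layout `target,average,sd,zscore`: official gene symbol, mean
#' responder percentage over the replicate wells, its standard deviation,
#' and the library z-score.
#'
#' @param path CSV path.
#' @return data.frame, one record per target; duplicate symbols and
#'   non-numeric statistics are rejected.
#' @export
read_target_summary_table <- function(path) {
  df <- read_csv_commented(path)
  if (nrow(df) == 0) stop("empty target summary table: ", path, call. = FALSE)
  check_columns(df, c("target", "average", "sd", "zscore"),
                "target summary table")
  dup <- unique(df$target[duplicated(df$target)])
  if (length(dup))
    stop("duplicate target symbol(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  for (cc in c("average", "sd", "zscore")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v) && !anyNA(df[[cc]]))
      stop("non-numeric '", cc, "' at row ",
           paste(which(is.na(v)), collapse = ", "), call. = FALSE)
    df[[cc]] <- v
  }
  df
}

#' Write a per-target screen summary table
#' @param targets data.frame with `target_id`, `mean_pos`, `sd_pos`,
#'   `z_score` columns (as from [screen_targets()]).
#' @param path output CSV.
#' @param config_hash optional audit hash.
#' @export
write_target_summary_table <- function(targets, path, config_hash = NULL) {
  out <- data.frame(target = targets$target_id, average = targets$mean_pos,
                    sd = targets$sd_pos, zscore = targets$z_score)
  write_csv_commented(out, path, config_hash)
}

#' Analysis thresholds and parameters for a pipeline run
#'
#' Collects every decision threshold of the analysis chain with its
#' default: hit z-score cut (-1.5), strong-screen reporting cut (-2),
#' counterscreen specificity floor (-1.3), fold-class boundaries
#' (1.4/1.6/2.0), Z-prime plate acceptance (0.2), minimum cells per well
#' (1500), G1 ratio threshold (2.0), interaction tolerance (0.02), and
#' clustering parameters.
#'
#' @param ... overrides of the defaults.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(z_cut = -1.5, strong_z = -2, counterscreen_floor = -1.3,
              fold_bounds = c(weak = 1.4, average = 1.6, strong = 2.0),
              zprime_threshold = 0.2, min_cells = 1500L,
              g1_ratio_threshold = 2.0, interaction_tol = 0.02,
              baseline_role = "mock",
              gate_channel = "ch_marker", gate_direction = "below",
              cluster_k = 2L, cluster_dist = "euclidean",
              cluster_linkage = "complete", profile_noise_sd = 0.05)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown run_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  stopifnot(cfg$z_cut < 0, cfg$counterscreen_floor < 0,
            all(diff(cfg$fold_bounds) > 0), cfg$g1_ratio_threshold > 0,
            cfg$interaction_tol >= 0, cfg$min_cells >= 1)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON or YAML
#'
#' Fields present in the file override the [run_config()] defaults.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = ,
                yml = yaml::read_yaml(path),
                stop("config must be .json or .yaml", call. = FALSE))
  if (!is.null(raw$fold_bounds)) raw$fold_bounds <-
      setNames(as.numeric(raw$fold_bounds), c("weak", "average", "strong"))
  do.call(run_config, raw)
}

#' MD5 hash of a resolved configuration
#'
#' Used to stamp every output file and to decide whether a pipeline stage
#' may be reused on re-run.
#'
#' @param ... configuration objects (any serializable R objects).
#' @return 32-character hash string.
#' @export
config_hash <- function(...) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(list(...)), collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}
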