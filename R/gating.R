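channel_values <- function(cells, channel) {
  if (is.numeric(cells)) return(cells)
  if (!is.data.frame(cells) || !channel %in% names(cells))
    stop("channel '", channel, "' not found in cell records", call. = FALSE)
  cells[[channel]]
}

#' Derive an intensity gate from in-plate control wells
#'
#' Finds the responder threshold as the crossing point of the kernel
#' density estimates of the pooled negative-control and positive-control
#' log-intensities, searched strictly between the two control medians.
#' When no unique crossing exists in that interval the gate falls back to
#' the midpoint of the log medians (the geometric mean of the medians).
#' Working on the log scale makes the gate equivariant under a common
#' positive rescaling of all intensities.
#'
#' @param neg_control_cells,pos_control_cells cell records (data.frames
#'   with the channel column) or numeric intensity vectors, pooled from
#'   the in-plate non-targeting and control-target wells.
#' @param channel channel column name, e.g. `"ch_marker"`.
#' @param direction `"below"` (responders fall below the gate, as for loss
#'   of phosphorylated RB1) or `"above"` (as for p21 positivity over a
#'   knockdown background).
#' @param min_cells minimum cells per control group.
#' @param min_fold_sep minimum fold separation of the control medians;
#'   below this the controls are considered indistinguishable.
#' @param provenance optional list (plate, wells, ...) recorded in the
#'   gate for audit.
#' @return list of class `gate_spec` with `channel`, `threshold` (AFU),
#'   `direction`, `method`, `derivation`.
#' @export
derive_gate <- function(neg_control_cells, pos_control_cells, channel,
                        direction = c("below", "above"),
                        min_cells = 500, min_fold_sep = 1.2,
                        provenance = NULL) {
  direction <- match.arg(direction)
  xn <- channel_values(neg_control_cells, channel)
  xp <- channel_values(pos_control_cells, channel)
  xn <- xn[is.finite(xn) & xn > 0]
  xp <- xp[is.finite(xp) & xp > 0]
  if (length(xn) < min_cells || length(xp) < min_cells)
    stop("need at least ", min_cells, " cells per control group", call. = FALSE)
  ln <- log(xn); lp <- log(xp)
  mn <- median(ln); mp <- median(lp)
  if (abs(mn - mp) < log(min_fold_sep))
    stop("no separation between control distributions (median fold < ",
         min_fold_sep, ")", call. = FALSE)

  # Densities are compared over the full pooled range: when the controls
  # are two-population mixtures differing mainly in mixing weight (the
  # realistic screen situation), the difference of the two histograms
  # changes sign exactly where the two underlying components cross, which
  # need not lie between the mixture medians. Sign changes are only
  # trusted where the densities are non-negligible.
  grid_n <- 2048
  lo <- min(quantile(ln, 0.001), quantile(lp, 0.001))
  hi <- max(quantile(ln, 0.999), quantile(lp, 0.999))
  # a common bandwidth keeps the difference of the two estimates
  # proportional to the difference of the smoothed components, so the
  # crossing is not shifted by unequal smoothing of the two samples
  bw <- (bw.nrd0(ln) + bw.nrd0(lp)) / 2
  dn <- density(ln, bw = bw, n = grid_n, from = lo, to = hi)
  dp <- density(lp, bw = bw, n = grid_n, from = lo, to = hi)
  dd <- dn$y - dp$y
  informative <- pmax(dn$y, dp$y) > 0.01 * max(dn$y, dp$y)
  flips <- which(sign(dd[-1]) * sign(dd[-grid_n]) < 0 &
                   informative[-1] & informative[-grid_n])
  root_at <- function(i)
    dn$x[i] + (dn$x[i + 1] - dn$x[i]) * dd[i] / (dd[i] - dd[i + 1])
  if (length(flips) > 1) {
    # several crossings: the densities are equal at each, so score each by
    # that shared height and keep the substantive one; tail artifacts
    # cross where both densities are near zero
    height <- pmin(dn$y[flips], dp$y[flips])
    flips <- flips[which.max(height)]
  }
  if (length(flips) == 1) {
    root <- root_at(flips)
    method <- "kde_crossing"
  } else {
    root <- (mn + mp) / 2
    method <- "log_median_midpoint"
  }
  structure(list(channel = channel,
                 threshold = exp(root),
                 direction = direction,
                 method = method,
                 derivation = c(list(n_neg = length(xn), n_pos = length(xp),
                                     median_neg = exp(mn), median_pos = exp(mp)),
                                provenance)),
            class = "gate_spec")
}

#' @export
print.gate_spec <- function(x, ...) {
  cat(sprintf("Gate on %s: responders %s %.4g AFU (%s; neg median %.4g, pos median %.4g)\n",
              x$channel, x$direction, x$threshold, x$method,
              x$derivation$median_neg, x$derivation$median_pos))
  invisible(x)
}

well_ids <- function(cells) {
  list(plate_id = if ("plate_id" %in% names(cells)) cells$plate_id[1] else NA_character_,
       well = if ("well" %in% names(cells)) cells$well[1] else NA_character_)
}

#' Per-well responder fraction under an intensity gate
#'
#' @param cells cell records from a single well.
#' @param gate a `gate_spec` from [derive_gate()].
#' @param min_cells wells with fewer cells are reported but flagged
#'   unreliable.
#' @param metric metric name carried into the summary.
#' @return one-row data.frame (`plate_id,well,metric,n_cells,pos_fraction,
#'   flag_low_cells`), the well summary.
#' @export
pos_fraction <- function(cells, gate, min_cells = 1500,
                         metric = "POS-LoRBPS780") {
  stopifnot(inherits(gate, "gate_spec"))
  if (is.null(cells) || nrow(cells) == 0)
    stop("no cells in well", call. = FALSE)
  x <- channel_values(cells, gate$channel)
  if (all(is.na(x)))
    stop("channel '", gate$channel, "' is empty for this well", call. = FALSE)
  n <- length(x)
  hit <- if (gate$direction == "below") x < gate$threshold else x > gate$threshold
  id <- well_ids(cells)
  data.frame(plate_id = id$plate_id, well = id$well, metric = metric,
             n_cells = n, pos_fraction = 100 * sum(hit) / n,
             flag_low_cells = n < min_cells, stringsAsFactors = FALSE)
}

#' Per-well G1 fraction from the nuclear/cytoplasmic reporter ratio
#'
#' Cells whose nuclear:cytoplasmic reporter ratio is `ratio_threshold` or
#' greater are counted as G1. Cells with non-positive or missing
#' cytoplasmic signal are dropped from the denominator; their count is
#' attached as attribute `n_dropped`.
#'
#' @param cells cell records from a single well, with `ch_gfp_nuc` and
#'   `ch_gfp_cyto` present.
#' @param ratio_threshold dimensionless threshold (inclusive).
#' @param min_cells low-cell-count flag threshold on evaluable cells.
#' @return one-row well-summary data.frame, metric `POS-G1`.
#' @export
g1_fraction <- function(cells, ratio_threshold = 2.0, min_cells = 1500) {
  stopifnot(ratio_threshold > 0)
  if (is.null(cells) || nrow(cells) == 0)
    stop("no cells in well", call. = FALSE)
  if (!all(c("ch_gfp_nuc", "ch_gfp_cyto") %in% names(cells)) ||
      all(is.na(cells$ch_gfp_nuc)))
    stop("reporter channels (ch_gfp_nuc, ch_gfp_cyto) absent", call. = FALSE)
  ok <- !is.na(cells$ch_gfp_nuc) & !is.na(cells$ch_gfp_cyto) &
    cells$ch_gfp_cyto > 0
  n_dropped <- sum(!ok)
  n <- sum(ok)
  if (n == 0) stop("no evaluable cells (all cytoplasmic signals missing)",
                   call. = FALSE)
  ratio <- cells$ch_gfp_nuc[ok] / cells$ch_gfp_cyto[ok]
  id <- well_ids(cells)
  out <- data.frame(plate_id = id$plate_id, well = id$well, metric = "POS-G1",
                    n_cells = n,
                    pos_fraction = 100 * sum(ratio >= ratio_threshold) / n,
                    flag_low_cells = n < min_cells, stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Gate every well of a plate against its in-plate controls
#'
#' Pools the plate's non-targeting wells (negative) and positive-control
#' wells, derives the gate with [derive_gate()], then summarises every
#' well on the plate with [pos_fraction()].
#'
#' @param cells per-cell table for one plate.
#' @param plate_map plate-map rows for the same plate.
#' @param channel gated channel.
#' @param direction gate direction (see [derive_gate()]).
#' @param min_cells low-cell-count threshold.
#' @param ... passed to [derive_gate()].
#' @return list with `gate` (the `gate_spec`) and `wells` (well-summary
#'   data.frame, one row per well).
#' @export
gate_plate <- function(cells, plate_map, channel = "ch_marker",
                       direction = "below", min_cells = 1500, ...) {
  plate <- unique(plate_map$plate_id)
  if (length(plate) != 1)
    stop("gate_plate expects a single plate", call. = FALSE)
  neg_wells <- plate_map$well[plate_map$role == "nt"]
  pos_wells <- plate_map$well[plate_map$role == "pos_control"]
  gate <- derive_gate(cells[cells$well %in% neg_wells, ],
                      cells[cells$well %in% pos_wells, ],
                      channel = channel, direction = direction,
                      provenance = list(plate = plate,
                                        neg_wells = neg_wells,
                                        pos_wells = pos_wells), ...)
  by_well <- split(cells, cells$well)
  wells <- do.call(rbind, lapply(by_well, pos_fraction, gate = gate,
                                 min_cells = min_cells))
  rownames(wells) <- NULL
  list(gate = gate, wells = wells)
}
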