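#' Normalize observations to the mean of a matched reference
#'
#' @param values numeric readouts (POS % or luminescence).
#' @param reference readouts of the matched mock/untreated condition.
#' @return `values / mean(reference)`; dimensionless, the reference itself
#'   maps to 1 in expectation.
#' @export
normalize_relative <- function(values, reference) {
  ref <- mean(reference)
  if (!is.finite(ref) || ref <= 0)
    stop("reference mean must be positive", call. = FALSE)
  values / ref
}

#' Collapse technical replicates to one value per biological replicate
#'
#' Paired tests are run across biological replicates only; averaging the
#' technical triplicate first avoids overstating the degrees of freedom.
#'
#' @param values readouts.
#' @param bio_rep biological replicate labels, parallel to `values`.
#' @return named numeric vector of per-biological-replicate means, in
#'   sorted label order.
#' @export
bio_rep_means <- function(values, bio_rep) {
  m <- tapply(values, bio_rep, mean)
  setNames(as.vector(m), names(m))
}

#' Paired Student's t-test across biological replicates
#'
#' Thin, contract-checked front end to [stats::t.test()] with
#' `paired = TRUE`. Degenerate difference vectors are resolved explicitly:
#' all differences zero gives t = 0, p = 1; constant nonzero differences
#' give the limiting p = 0.
#'
#' @param values_a,values_b per-biological-replicate means, paired by
#'   position, equal length >= 2.
#' @return list with `t`, `df` (= n - 1), `p` (two-sided), `mean_diff`.
#' @export
paired_t <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("paired vectors must have equal length", call. = FALSE)
  if (length(values_a) < 2)
    stop("need at least 2 pairs", call. = FALSE)
  d <- values_a - values_b
  n <- length(d)
  if (sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0))
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                mean_diff = mean(d)))
  }
  ht <- t.test(values_a, values_b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate))
}

#' Knockdown-by-treatment interaction index
#'
#' With all four readouts expressed relative to the untreated mock
#' (`Cc`), the multiplicative expectation of the combined response is
#' `(Rc/Cc) * (C_IR/Cc)`, and the index is that expectation minus the
#' observed combined response `R_IR/Cc`. A multiplicative (independent)
#' combination gives index 0 exactly.
#'
#' Classification compares the treatment-induced effect in the two arms in
#' the assay's response direction: the interaction is synergistic when the
#' IR effect in the target-knockdown arm exceeds the IR effect in the mock
#' arm, antagonistic in the opposite case, and `none` when the index is
#' within `tol` of zero. For an IR-decreases-readout assay (viability) a
#' positive index is therefore synergistic sensitization; for an
#' IR-increases-readout assay (p21, G1 positivity) a positive index marks
#' antagonism of the induction.
#'
#' @param Cc untreated mock readout (> 0).
#' @param Rc untreated target-knockdown readout.
#' @param C_IR irradiated mock readout.
#' @param R_IR irradiated target-knockdown readout.
#' @param direction `"decreases"` (IR lowers the readout, e.g. viability)
#'   or `"increases"` (IR raises it, e.g. p21 positivity).
#' @param tol absolute index below which the interaction is classed
#'   `none`.
#' @return list of class `interaction_result` with the three ratios,
#'   `expected`, `observed`, `index`, `classification`, `direction`.
#' @export
interaction_index <- function(Cc, Rc, C_IR, R_IR,
                              direction = c("decreases", "increases"),
                              tol = 0.02) {
  direction <- match.arg(direction)
  if (!is.finite(Cc) || Cc <= 0) stop("Cc must be positive", call. = FALSE)
  if (any(c(Rc, C_IR, R_IR) < 0))
    stop("readouts must be non-negative", call. = FALSE)
  rc <- Rc / Cc; cir <- C_IR / Cc; rir <- R_IR / Cc
  expected <- rc * cir
  index <- expected - rir
  # IR effect per arm, oriented so that larger = stronger response
  eff_c <- (C_IR - Cc) / Cc
  eff_r <- if (Rc > 0) (R_IR - Rc) / Rc else NA_real_
  if (direction == "decreases") { eff_c <- -eff_c; eff_r <- -eff_r }
  classification <- if (abs(index) < tol) "none"
    else if (is.na(eff_r)) "none"
    else if (eff_r > eff_c) "synergistic"
    else "antagonistic"
  structure(list(Rc_Cc = rc, C_IR_Cc = cir, R_IR_Cc = rir,
                 expected = expected, observed = rir, index = index,
                 classification = classification, direction = direction,
                 tol = tol),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("Interaction index %.4f (%s; expected %.4f, observed %.4f; IR %s readout)\n",
              x$index, x$classification, x$expected, x$observed, x$direction))
  invisible(x)
}

#' Normalized survival curves and per-background interaction indices
#'
#' Averages the viability readouts per (target, background, dose),
#' normalizes each arm to its own untreated control, and computes the
#' knockdown-by-IR interaction index at each positive dose within each
#' co-knockdown background (mock arm = C, target arm = R).
#'
#' @param obs data.frame with columns `target` (`"mock"` or a target
#'   label), `co_kd` (background label), `dose_gy`, `value`
#'   (luminescence), e.g. from [simulate_viability_arms()].
#' @param mock_label value of `target` identifying the mock arm.
#' @param direction assay response direction passed to
#'   [interaction_index()].
#' @param tol interaction tolerance.
#' @return list with `curves` (data.frame
#'   `target,co_kd,dose_gy,mean_value,survival`) and `indices` (data.frame
#'   `target,co_kd,dose_gy,index,classification`).
#' @export
survival_curves <- function(obs, mock_label = "mock",
                            direction = "decreases", tol = 0.02) {
  req <- c("target", "co_kd", "dose_gy", "value")
  if (!all(req %in% names(obs)))
    stop("obs needs columns ", paste(req, collapse = ", "), call. = FALSE)
  agg <- aggregate(value ~ target + co_kd + dose_gy, obs, mean)
  names(agg)[names(agg) == "value"] <- "mean_value"

  curves <- do.call(rbind, lapply(split(agg, agg[c("target", "co_kd")],
                                        drop = TRUE), function(d) {
    d0 <- d$mean_value[d$dose_gy == 0]
    if (length(d0) != 1)
      stop("arm ", d$target[1], "/", d$co_kd[1],
           " is missing its dose-0 reference", call. = FALSE)
    d$survival <- d$mean_value / d0
    d
  }))
  rownames(curves) <- NULL

  idx <- list()
  for (bg in unique(curves$co_kd)) {
    cc <- curves[curves$target == mock_label & curves$co_kd == bg, ]
    if (nrow(cc) == 0)
      stop("no mock arm in background '", bg, "'", call. = FALSE)
    for (tg in setdiff(unique(curves$target[curves$co_kd == bg]), mock_label)) {
      rr <- curves[curves$target == tg & curves$co_kd == bg, ]
      for (d in setdiff(sort(unique(rr$dose_gy)), 0)) {
        ii <- interaction_index(
          Cc = cc$mean_value[cc$dose_gy == 0],
          Rc = rr$mean_value[rr$dose_gy == 0],
          C_IR = cc$mean_value[cc$dose_gy == d],
          R_IR = rr$mean_value[rr$dose_gy == d],
          direction = direction, tol = tol)
        idx[[length(idx) + 1]] <- data.frame(
          target = tg, co_kd = bg, dose_gy = d,
          index = ii$index, classification = ii$classification,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(curves = curves, indices = do.call(rbind, idx))
}
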