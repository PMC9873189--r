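## Four-stage normalization for targeted hybridization count panels:
##   1. positive-control geometric-mean scaling  (per sample)
##   2. reference-lane probe calibration         (per probe x plate)
##   3. attenuation correction                   (per probe, scoped samples)
##   4. housekeeping normalization               (per sample; per-timepoint
##      for transcription-inhibited treatments)
## Each step records the factors it applied so the full audit trail is
## reconstructible.

geomean <- function(x) exp(mean(log(x)))

#' Positive-control normalization
#'
#' Scales every sample by the geometric mean of its top-3 positive-control
#' spike-in probes so that hybridization efficiency is equalized across
#' samples. "Top 3" means the three positive-control probes with the largest
#' mean raw count across samples (the highest-concentration, least-noisy
#' spike-ins). For sample \eqn{s} with top-3 geometric mean \eqn{g_s}, the
#' factor is \eqn{f_s = \bar g / g_s} with \eqn{\bar g} the arithmetic mean
#' of the \eqn{g_s}; all counts in \eqn{s} are multiplied by \eqn{f_s}.
#'
#' @param matrix a stage-\code{raw} [count_matrix()] with at least three
#'   positive-control probes, all with positive counts.
#' @return A list with the stage-\code{pc_normalized} matrix (`matrix`) and
#'   the per-sample factors (`factors`, named numeric vector).
#' @export
positive_control_normalize <- function(matrix) {
  require_stage(matrix, "raw", "positive_control_normalize")
  pc <- matrix$probes$probe_class == "positive_control"
  if (sum(pc) < 3L)
    stop("need >= 3 positive-control probes, found ", sum(pc))
  pc_counts <- matrix$counts[pc, , drop = FALSE]
  if (any(pc_counts <= 0)) {
    bad <- which(pc_counts <= 0, arr.ind = TRUE)[1L, 2L]
    stop("zero positive-control count in sample ",
         matrix$samples$sample_id[bad])
  }
  top3 <- order(rowMeans(pc_counts), decreasing = TRUE)[1:3]
  g <- apply(pc_counts[top3, , drop = FALSE], 2L, geomean)
  f <- mean(g) / g
  matrix$counts <- sweep(matrix$counts, 2L, f, `*`)
  matrix$factors$pc_factor_per_sample <- f
  matrix$factors$pc_top3_probes <- rownames(pc_counts)[top3]
  matrix <- advance_stage(matrix, "pc_normalized")
  list(matrix = matrix, factors = f)
}

#' Reference-lane probe calibration
#'
#' When a run spans several plates, each plate carries a reference lane
#' loaded with the same sample, which is used to calibrate probe-specific
#' efficiency differences between plates. For endogenous and housekeeping
#' probe \eqn{p} on plate \eqn{q}, the factor is the mean reference-lane
#' count of \eqn{p} over plates divided by the reference-lane count of
#' \eqn{p} on plate \eqn{q}; all counts of \eqn{p} on plate \eqn{q} are
#' multiplied by it. A zero reference count yields factor 1 with a warning.
#' Reference-lane wells stay in the matrix but remain flagged and are
#' excluded from biological analyses.
#'
#' @param matrix a stage-\code{pc_normalized} [count_matrix()] whose
#'   metadata flags exactly one reference-lane sample per plate, with at
#'   least two plates.
#' @return A list with the stage-\code{calibrated} matrix (`matrix`) and the
#'   probe x plate factor matrix (`factors`).
#' @export
reference_lane_calibrate <- function(matrix) {
  require_stage(matrix, "pc_normalized", "reference_lane_calibrate")
  plates <- unique(matrix$samples$plate)
  if (length(plates) < 2L) stop(">=2 plates required")
  ref_idx <- integer(length(plates))
  for (i in seq_along(plates)) {
    r <- which(matrix$samples$plate == plates[i] &
                 matrix$samples$is_reference_lane)
    if (length(r) != 1L)
      stop("plate ", plates[i], " must have exactly one reference lane, ",
           "found ", length(r))
    ref_idx[i] <- r
  }
  target <- matrix$probes$probe_class %in% c("endogenous", "housekeeping")
  ref_counts <- matrix$counts[target, ref_idx, drop = FALSE]
  colnames(ref_counts) <- plates
  fac <- matrix(1, nrow = sum(target), ncol = length(plates),
                dimnames = list(matrix$probes$probe_id[target], plates))
  for (p in seq_len(nrow(ref_counts))) {
    rc <- ref_counts[p, ]
    if (any(rc <= 0)) {
      warning("zero reference-lane count for probe ",
              rownames(ref_counts)[p], "; calibration factor set to 1")
      next
    }
    fac[p, ] <- mean(rc) / rc
  }
  for (i in seq_along(plates)) {
    on_plate <- matrix$samples$plate == plates[i]
    matrix$counts[target, on_plate] <-
      matrix$counts[target, on_plate, drop = FALSE] * fac[, i]
  }
  matrix$factors$lane_calibration <- fac
  matrix <- advance_stage(matrix, "calibrated")
  list(matrix = matrix, factors = fac)
}

#' Estimate probe attenuation factors from a titration run
#'
#' High-abundance targets are deliberately attenuated with inactive probes
#' (aiming for ~90% count reduction) to keep them in dynamic range. The
#' actual factor is measured in a titration run: the ratio of the
#' unattenuated to the attenuated count per probe, averaged arithmetically
#' over pairs when a probe was titrated more than once.
#'
#' @param titration data.frame with columns \code{probe_id},
#'   \code{count_unattenuated}, \code{count_attenuated} (both positive).
#' @return Named numeric vector of attenuation factors (>= values near the
#'   nominal 10 for a 90% reduction).
#' @export
estimate_attenuation_factor <- function(titration) {
  stopifnot(all(c("probe_id", "count_unattenuated", "count_attenuated") %in%
                  names(titration)))
  if (any(titration$count_attenuated <= 0))
    stop("attenuated count must be > 0")
  if (any(titration$count_unattenuated <= 0))
    stop("unattenuated count must be > 0")
  ratio <- titration$count_unattenuated / titration$count_attenuated
  avg <- tapply(ratio, titration$probe_id, mean)
  stats::setNames(as.numeric(avg), names(avg))[unique(titration$probe_id)]
}

#' Apply attenuation correction
#'
#' Multiplies the counts of attenuated probes by their measured attenuation
#' factor, but only in the samples that were actually run with attenuation
#' (low-iron samples and iron-recovery samples within 30 min of iron
#' addition, in the original design). Other samples are untouched.
#'
#' @param matrix a stage-\code{calibrated} (or, for single-plate runs where
#'   calibration was skipped, stage-\code{pc_normalized}) [count_matrix()].
#' @param factors named numeric vector of attenuation factors covering every
#'   probe flagged \code{attenuated}.
#' @param attenuated_sample_ids character vector of sample ids that were run
#'   attenuated (see [attenuated_samples()]).
#' @return The stage-\code{attenuation_corrected} matrix.
#' @export
attenuation_correct <- function(matrix, factors, attenuated_sample_ids) {
  if (!matrix$stage %in% c("pc_normalized", "calibrated"))
    stop("attenuation_correct requires a pc_normalized or calibrated matrix")
  att <- matrix$probes$attenuated
  need <- matrix$probes$probe_id[att]
  miss <- setdiff(need, names(factors))
  if (length(miss))
    stop("attenuated probe(s) without a factor: ",
         paste(miss, collapse = ", "))
  scols <- matrix$samples$sample_id %in% attenuated_sample_ids
  if (any(att) && any(scols)) {
    f <- unname(factors[matrix$probes$probe_id[att]])
    matrix$counts[att, scols] <-
      matrix$counts[att, scols, drop = FALSE] * f
  }
  matrix$factors$attenuation_applied <- factors[need]
  matrix$factors$attenuated_sample_ids <- attenuated_sample_ids
  advance_stage(matrix, "attenuation_corrected")
}

#' Identify the samples that were run with probe attenuation
#'
#' Default rule from the original design: all low-iron samples plus
#' iron-recovery samples taken within 30 min of iron addition.
#'
#' @param samples a sample-metadata data.frame (see [count_matrix()]).
#' @param rec_window_min attenuation window for iron-recovery samples,
#'   minutes (default 30).
#' @return Character vector of sample ids.
#' @export
attenuated_samples <- function(samples, rec_window_min = 30) {
  sel <- samples$treatment == "low" |
    (samples$treatment == "rec" & samples$time_min <= rec_window_min)
  samples$sample_id[sel]
}

#' Housekeeping normalization
#'
#' Corrects RNA loading differences with a single housekeeping probe. In
#' \code{global} mode the reference \eqn{R} is the arithmetic mean of the
#' housekeeping counts over all in-scope samples and each sample is scaled
#' by \eqn{R / hk(s)}. For transcription-inhibited (actinomycin-D) samples
#' the housekeeping transcript itself degrades, so those treatments use the
#' \code{per_timepoint} mode: at each timepoint \eqn{t}, \eqn{R_t} is the
#' arithmetic mean of the housekeeping counts of the scoped samples at
#' \eqn{t}, and each such sample is scaled by \eqn{R_t / hk(s)}. Within-
#' timepoint loading variation is removed while the decaying time trend is
#' preserved. Mode \code{split} (the pipeline default) applies the global
#' scheme to all non-inhibited samples and the per-timepoint scheme to the
#' treatments in \code{group_scope}, in one pass.
#'
#' @param matrix a stage-\code{attenuation_corrected} [count_matrix()].
#' @param hk_probe probe id of the housekeeping gene; must have positive
#'   counts in scope.
#' @param mode \code{"global"}, \code{"per_timepoint"} or \code{"split"}.
#' @param group_scope treatments handled per-timepoint (default
#'   \code{c("actd", "actd_fe")}, pooled at shared timepoints).
#' @param pool_scope if \code{FALSE}, per-timepoint means are computed per
#'   treatment instead of pooling the scoped treatments.
#' @return A list with the stage-\code{fully_normalized} matrix (`matrix`)
#'   and the per-sample factors (`factors`).
#' @export
housekeeping_normalize <- function(matrix, hk_probe,
                                   mode = c("split", "global",
                                            "per_timepoint"),
                                   group_scope = c("actd", "actd_fe"),
                                   pool_scope = TRUE) {
  require_stage(matrix, "attenuation_corrected", "housekeeping_normalize")
  mode <- match.arg(mode)
  pi <- match(hk_probe, matrix$probes$probe_id)
  if (is.na(pi)) stop("housekeeping probe not found: ", hk_probe)
  hk <- matrix$counts[pi, ]
  smp <- matrix$samples
  bio <- biological_samples(matrix)
  in_scope_grp <- smp$treatment %in% group_scope & bio

  f <- rep(1, ncol(matrix$counts))
  names(f) <- smp$sample_id

  global_set <- switch(mode,
    global = bio & !in_scope_grp,
    per_timepoint = rep(FALSE, nrow(smp)),
    split = bio & !in_scope_grp)
  tp_set <- switch(mode,
    global = rep(FALSE, nrow(smp)),
    per_timepoint = in_scope_grp,
    split = in_scope_grp)

  check <- global_set | tp_set
  if (any(hk[check] <= 0))
    stop("housekeeping count <= 0 in sample ",
         smp$sample_id[check & hk <= 0][1L])

  if (any(global_set)) {
    R <- mean(hk[global_set])
    f[global_set] <- R / hk[global_set]
    matrix$factors$hk_reference_global <- R
  }
  if (any(tp_set)) {
    grp <- if (pool_scope) as.character(smp$time_min) else
      paste(smp$treatment, smp$time_min)
    for (g in unique(grp[tp_set])) {
      idx <- tp_set & grp == g
      if (sum(idx) == 1L)
        warning("single sample in per-timepoint group ", g,
                "; housekeeping factor set to 1")
      else
        f[idx] <- mean(hk[idx]) / hk[idx]
    }
  }
  matrix$counts <- sweep(matrix$counts, 2L, f, `*`)
  matrix$factors$hk_factor_per_sample <- f
  matrix$factors$hk_mode <- mode
  matrix$factors$hk_probe <- hk_probe
  matrix <- advance_stage(matrix, "fully_normalized")
  list(matrix = matrix, factors = f)
}

#' Run the full normalization pipeline
#'
#' Applies, in order: positive-control normalization, reference-lane probe
#' calibration (skipped with a warning for single-plate runs), attenuation
#' correction, and housekeeping normalization (global for ordinary samples,
#' per-timepoint for transcription-inhibited treatments). Returns the
#' fully normalized matrix and the complete factor audit trail.
#'
#' @param matrix a stage-\code{raw} [count_matrix()].
#' @param hk_probe housekeeping probe id.
#' @param titration optional data.frame for
#'   [estimate_attenuation_factor()]; if omitted and attenuated probes
#'   exist, the annotation's \code{attenuation_factor} column is used.
#' @param attenuated_sample_ids sample ids run with attenuation; default
#'   [attenuated_samples()] applied to the metadata.
#' @param actd_treatments treatments normalized per-timepoint.
#' @param pool_actd pool the inhibited treatments at shared timepoints when
#'   computing per-timepoint housekeeping means.
#' @return A list with the stage-\code{fully_normalized} `matrix` and the
#'   accumulated `factors` audit list.
#' @export
normalize_pipeline <- function(matrix, hk_probe, titration = NULL,
                               attenuated_sample_ids = NULL,
                               actd_treatments = c("actd", "actd_fe"),
                               pool_actd = TRUE) {
  require_stage(matrix, "raw", "normalize_pipeline")
  step <- positive_control_normalize(matrix)
  m <- step$matrix

  if (length(unique(m$samples$plate)) >= 2L &&
      any(m$samples$is_reference_lane)) {
    m <- reference_lane_calibrate(m)$matrix
  } else {
    warning("single-plate run: reference-lane calibration skipped")
  }

  att_probes <- m$probes$probe_id[m$probes$attenuated]
  fac <- if (!is.null(titration)) estimate_attenuation_factor(titration)
  else stats::setNames(m$probes$attenuation_factor[m$probes$attenuated],
                       att_probes)
  if (is.null(attenuated_sample_ids))
    attenuated_sample_ids <- attenuated_samples(m$samples)
  m <- attenuation_correct(m, fac, attenuated_sample_ids)

  hk <- housekeeping_normalize(m, hk_probe, mode = "split",
                               group_scope = actd_treatments,
                               pool_scope = pool_actd)
  list(matrix = hk$matrix, factors = hk$matrix$factors)
}
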