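#' Integrated EMG over a segment
#'
#' The rectangle-rule time integral of the activation envelope,
#' `sum(values) * dt`, in %MVC-seconds. Proportional to the neural energy
#' the motor neuron pool spends activating the muscle over the segment.
#'
#' @param env An [emg_envelope()].
#' @param segment `c(start, end)` sample indices, or `NULL` for the full
#'   record.
#' @return A single number (%MVC * s).
#' @export
#' @examples
#' integrated_emg(emg_envelope(c(1, 2, 3), dt = 0.5))  # 3
integrated_emg <- function(env, segment = NULL) {
  seg <- resolve_segment(segment, length(env$values))
  sum(env$values[seg[1]:seg[2]]) * env$dt
}

#' Interaction trend signal
#'
#' The per-sample normalized difference between the NoExo and Exo envelopes:
#' `I_Trend(i) = 100 * (E_NoExo(i) - E_Exo(i)) / sum_j E_NoExo(j)`, with the
#' sum taken over the same analysis segment. The sampling interval cancels
#' between numerator and denominator, so the trend is expressed directly in
#' percent of the baseline neural energy of the segment. Positive samples
#' mark instants where the device reduces muscle activity (assistance),
#' negative samples where it increases it (resistance).
#'
#' @param pair An [aligned_pair()].
#' @param segment `c(start, end)` sample indices, or `NULL` for the full
#'   pair.
#' @param scope Label recorded on the result (e.g. a phase name).
#' @return An object of class `itrend`: list with `values`
#'   (percent-per-sample contributions), `dt`, `segment`, `scope`.
#' @export
#' @examples
#' p <- aligned_pair(emg_envelope(c(2, 2), dt = 1),
#'                   emg_envelope(c(1, 1), dt = 1, condition = "Exo"))
#' i_trend(p)$values  # 25 25
i_trend <- function(pair, segment = NULL, scope = "full_task") {
  stopifnot(inherits(pair, "aligned_pair"))
  n <- length(pair$noexo$values)
  seg <- resolve_segment(segment, n)
  idx <- seg[1]:seg[2]
  eno <- pair$noexo$values[idx]
  eexo <- pair$exo$values[idx]
  denom <- sum(eno)
  if (!is.finite(denom) || denom <= 0) {
    abort_iba(
      "undefined normalization: NoExo envelope integrates to zero over the segment",
      "iba_degenerate")
  }
  structure(list(values = 100 * (eno - eexo) / denom,
                 dt = pair$noexo$dt, segment = seg,
                 scope = as.character(scope)[1]),
            class = "itrend")
}

#' Assistive, resistive, and overall interaction indices
#'
#' Collapses an interaction trend into three percentages: AII sums the
#' nonnegative samples (assistance), RII is the magnitude of the sum of the
#' negative samples (resistance), and OII = AII - RII balances the two.
#' Zero-valued samples belong to the assistive partition; they contribute
#' nothing numerically but make the partition deterministic. Summation runs
#' in ascending sample order so that `oii == aii - rii` holds bit for bit.
#' For nonnegative envelopes OII also equals the mean-based percentage
#' variation of the same segment.
#'
#' @param trend An [i_trend()] result (or a bare numeric trend vector).
#' @return An object of class `interaction_indices`: list with `aii`, `rii`,
#'   `oii` (percent) and `scope`.
#' @export
#' @examples
#' interaction_indices(i_trend(aligned_pair(
#'   emg_envelope(c(1, 3), dt = 1),
#'   emg_envelope(c(3, 1), dt = 1, condition = "Exo"))))
interaction_indices <- function(trend) {
  if (inherits(trend, "itrend")) {
    v <- trend$values
    scope <- trend$scope
  } else if (is.numeric(trend)) {
    v <- as.numeric(trend)
    scope <- "full_task"
  } else {
    abort_iba("trend must be an itrend object or numeric vector",
              "iba_validation")
  }
  if (anyNA(v) || !all(is.finite(v))) {
    abort_iba("trend contains non-finite values", "iba_format_error")
  }
  aii <- sum(v[v >= 0])
  rii <- abs(sum(v[v < 0]))
  oii <- aii - rii
  structure(list(aii = aii, rii = rii, oii = oii, scope = scope),
            class = "interaction_indices")
}

#' Analyze an aligned pair at full-task and/or per-phase scope
#'
#' Computes the interaction trend and its indices for the requested scopes.
#' At full-task scope the normalizing NoExo integral spans the whole pair;
#' at per-phase scope it is restricted to each phase, so the phase indices
#' are expressed in percent of the energy that phase itself requires. The
#' mean-based percentage variation of the same scope is emitted alongside
#' for the cross-check that OII and MeanPV coincide.
#'
#' @param pair An [aligned_pair()].
#' @param scope `"full_task"`, `"per_phase"`, or both (the default).
#' @return An object of class `iba_analysis`: list with `indices` (a
#'   `data.frame` with columns `scope`, `phase`, `n_samples`, `aii`, `rii`,
#'   `oii`, `mean_pv`) and `trends` (named list of [i_trend()] objects, one
#'   per row).
#' @export
#' @examples
#' spec <- trial_spec(seed = 11)
#' tr <- simulate_trial(spec)
#' pair <- aligned_pair(tr$truth$noexo, tr$truth$exo, tr$truth$phases)
#' analyze_pair(pair)$indices
analyze_pair <- function(pair, scope = c("full_task", "per_phase")) {
  stopifnot(inherits(pair, "aligned_pair"))
  scope <- match.arg(scope, several.ok = TRUE)
  rows <- list()
  trends <- list()
  add <- function(scope_label, phase_label, seg) {
    tr <- i_trend(pair, segment = seg, scope = phase_label)
    ix <- interaction_indices(tr)
    idx <- seg[1]:seg[2]
    m0 <- mean(pair$noexo$values[idx])
    m1 <- mean(pair$exo$values[idx])
    key <- sprintf("%02d_%s", length(rows) + 1L, phase_label)
    rows[[key]] <<- data.frame(
      scope = scope_label, phase = phase_label,
      n_samples = length(idx),
      aii = ix$aii, rii = ix$rii, oii = ix$oii,
      mean_pv = 100 * (m0 - m1) / m0,
      stringsAsFactors = FALSE)
    trends[[key]] <<- tr
  }
  if ("full_task" %in% scope) {
    add("full_task", "full_task", c(1L, length(pair$noexo$values)))
  }
  if ("per_phase" %in% scope) {
    for (k in seq_len(nrow(pair$phases))) {
      add("per_phase", pair$phases$label[k],
          c(pair$phases$start[k], pair$phases$end[k]))
    }
  }
  indices <- do.call(rbind, rows)
  rownames(indices) <- NULL
  structure(list(indices = indices, trends = trends),
            class = "iba_analysis")
}

#' Aggregate interaction indices across subjects
#'
#' Per-subject indices are computed first and averaged afterwards, so the
#' OII/MeanPV identity is preserved within each subject. Groups must include
#' the phase (scope) among their keys; mixing scopes in one group is an
#' error.
#'
#' @param indices A `data.frame` of per-subject index rows, e.g. the
#'   `indices` component of a [run_pipeline()] result; must contain the
#'   grouping columns and `aii`, `rii`, `oii`.
#' @param by Character vector of grouping columns (default
#'   `c("device", "muscle", "phase")`).
#' @return A `data.frame` with one row per group: `n` subjects and
#'   mean/standard deviation of each index.
#' @export
aggregate_indices <- function(indices,
                              by = c("device", "muscle", "phase")) {
  if (!is.data.frame(indices) || nrow(indices) == 0L) {
    abort_iba("indices must be a non-empty data.frame", "iba_validation")
  }
  if (!("phase" %in% by)) {
    abort_iba("grouping must include 'phase': mixing scopes in one group",
              "iba_grouping")
  }
  missing_cols <- setdiff(c(by, "aii", "rii", "oii"), names(indices))
  if (length(missing_cols) > 0L) {
    abort_iba(sprintf("indices is missing columns: %s",
                      paste(missing_cols, collapse = ", ")),
              "iba_validation")
  }
  g <- indices[by]
  agg <- function(f) stats::aggregate(indices[c("aii", "rii", "oii")],
                                      by = g, FUN = f)
  means <- agg(mean)
  sds <- agg(function(x) if (length(x) > 1L) stats::sd(x) else 0)
  ns <- stats::aggregate(list(n = indices$aii), by = g, FUN = length)
  out <- means
  names(out)[names(out) %in% c("aii", "rii", "oii")] <-
    c("aii_mean", "rii_mean", "oii_mean")
  out$aii_sd <- sds$aii
  out$rii_sd <- sds$rii
  out$oii_sd <- sds$oii
  out$n <- ns$n
  out[c(by, "n", "aii_mean", "aii_sd", "rii_mean", "rii_sd",
        "oii_mean", "oii_sd")]
}

#' Pointwise mean interaction trend across subjects
#'
#' Averages trend signals sample by sample on the common time-normalized
#' grid, for group-level trend plots.
#'
#' @param trends A list of [i_trend()] objects (or numeric vectors) of equal
#'   length.
#' @return A numeric vector: the mean trend.
#' @export
mean_trend <- function(trends) {
  if (length(trends) == 0L) abort_iba("no trends to average", "iba_validation")
  vs <- lapply(trends, function(t) if (inherits(t, "itrend")) t$values else
    as.numeric(t))
  lens <- vapply(vs, length, integer(1))
  if (length(unique(lens)) != 1L) {
    abort_iba("trends must share a common grid (equal lengths)",
              "iba_alignment")
  }
  colMeans(do.call(rbind, vs))
}

#' Export interaction trend traces for plotting
#'
#' Flattens the trends of an [analyze_pair()] result into a long
#' `data.frame` (`phase`, `normalized_time` in [0, 1], `i_trend`), the
#' layout used for per-phase trend panels.
#'
#' @param analysis An `iba_analysis` object.
#' @return A `data.frame`.
#' @export
trend_traces <- function(analysis) {
  stopifnot(inherits(analysis, "iba_analysis"))
  out <- lapply(names(analysis$trends), function(key) {
    tr <- analysis$trends[[key]]
    m <- length(tr$values)
    data.frame(phase = tr$scope,
               normalized_time = if (m > 1L) seq(0, 1, length.out = m) else 0,
               i_trend = tr$values, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.interaction_indices <- function(x, ...) {
  cat(sprintf("<interaction_indices> [%s] AII %.2f%%  RII %.2f%%  OII %.2f%%\n",
              x$scope, x$aii, x$rii, x$oii))
  invisible(x)
}

#' @export
print.iba_analysis <- function(x, ...) {
  cat("<iba_analysis>\n")
  print.data.frame(x$indices, digits = 4)
  invisible(x)
}
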