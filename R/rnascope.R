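#' Derive a channel detection threshold from a no-probe control
#'
#' The threshold is the mean of the control cells' per-cell maximum
#' intensities plus three sample (n-1 denominator) standard deviations: any
#' object in the probe section must exceed what background alone produced in
#' adjacent control tissue.
#'
#' @param control data.frame from [read_control_table()].
#' @param channel channel (probe) name.
#' @return list with `channel`, `threshold`, `n_control_cells`, `mean_max`,
#'   `sd_max`.
#' @export
derive_threshold <- function(control, channel) {
  x <- control$max_intensity[control$channel == channel]
  if (length(x) < 2L) {
    stop_stage("rnascope_quant", "need >= 2 control cells for channel '",
               channel, "' (got ", length(x), "); SD is undefined otherwise")
  }
  m <- mean(x)
  s <- sd(x)
  list(channel = channel, threshold = m + 3 * s,
       n_control_cells = length(x), mean_max = m, sd_max = s)
}

#' Derive thresholds for every channel in a control table
#'
#' @param control data.frame from [read_control_table()].
#' @return named list of [derive_threshold()] results, one per channel.
#' @export
derive_thresholds <- function(control) {
  channels <- unique(control$channel)
  setNames(lapply(channels, derive_threshold, control = control), channels)
}

#' Resolve a fluorescent object's integral intensity into a molecule count
#'
#' Divides the background-subtracted integral intensity by the calibrated
#' mean integral intensity of a single signal, rounding half-up. Any object
#' that passed the channel threshold represents at least one molecule, so
#' the count is clamped to >= 1; an object dimmer than the background (which
#' should not survive thresholding) clamps to 1 with a warning.
#'
#' @param integral_intensity object integral intensity (a.u.).
#' @param single_signal_mean_intensity calibrated mean single-signal integral
#'   intensity (a.u.), > 0.
#' @param background average background integral intensity (a.u.).
#' @return integer molecule count >= 1.
#' @export
resolve_cluster <- function(integral_intensity, single_signal_mean_intensity,
                            background = 0) {
  if (single_signal_mean_intensity <= 0) {
    stop_stage("rnascope_quant", "single_signal_mean_intensity must be > 0")
  }
  if (any(integral_intensity < background)) {
    warning("object integral intensity below background; count clamped to 1",
            call. = FALSE)
  }
  counts <- round_half_up((integral_intensity - background) /
                            single_signal_mean_intensity)
  as.integer(pmax(1, counts))
}

#' Per-cell, per-channel molecule counts from a signal table
#'
#' Objects with integral intensity strictly above the channel threshold are
#' resolved with [resolve_cluster()] and summed per cell; sub-threshold
#' objects are discarded. Cells with no surviving objects get count 0 (the
#' cell roster defaults to the cells present in `signals`; pass `cells` to
#' include imaged cells with no signal at all).
#'
#' @param signals data.frame from [read_signal_table()].
#' @param thresholds named list from [derive_thresholds()] (or any list with
#'   `$threshold` per channel).
#' @param calibration named list per channel:
#'   `list(single_signal_mean_intensity =, background =)`.
#' @param cells optional data.frame with columns `cell_id`, `animal_id`,
#'   `section_id`, `condition` giving the full cell roster.
#' @return data.frame: `cell_id`, `animal_id`, `section_id`, `condition`,
#'   then one integer count column per channel.
#' @export
cell_molecule_counts <- function(signals, thresholds, calibration,
                                 cells = NULL) {
  channels <- unique(signals$channel)
  missing_thr <- setdiff(channels, names(thresholds))
  if (length(missing_thr) > 0L) {
    stop_stage("rnascope_quant", "no threshold for channel(s): ",
               paste(missing_thr, collapse = ", "))
  }
  missing_cal <- setdiff(channels, names(calibration))
  if (length(missing_cal) > 0L) {
    stop_stage("rnascope_quant", "no calibration for channel(s): ",
               paste(missing_cal, collapse = ", "))
  }
  if (is.null(cells)) {
    cells <- unique(signals[, c("cell_id", "animal_id", "section_id",
                                "condition")])
  } else {
    for (col in c("animal_id", "section_id", "condition")) {
      if (!col %in% names(cells)) cells[[col]] <- NA_character_
    }
    cells <- unique(cells[, c("cell_id", "animal_id", "section_id",
                              "condition")])
  }
  if (anyDuplicated(cells$cell_id)) {
    stop_stage("rnascope_quant", "cell roster has duplicated cell_id")
  }
  out <- cells
  all_channels <- union(channels, union(names(thresholds), names(calibration)))
  for (ch in all_channels) {
    counts <- integer(nrow(cells))
    sub <- signals[signals$channel == ch, , drop = FALSE]
    if (nrow(sub) > 0L) {
      pass <- sub$integral_intensity > thresholds[[ch]]$threshold
      sub <- sub[pass, , drop = FALSE]
      if (nrow(sub) > 0L) {
        cal <- calibration[[ch]]
        mol <- resolve_cluster(sub$integral_intensity,
                               cal$single_signal_mean_intensity,
                               cal$background %||% 0)
        agg <- tapply(mol, sub$cell_id, sum)
        idx <- match(names(agg), cells$cell_id)
        if (anyNA(idx)) {
          stop_stage("rnascope_quant", "signal cell(s) absent from roster: ",
                     paste(utils::head(names(agg)[is.na(idx)], 5L),
                           collapse = ", "))
        }
        counts[idx] <- as.integer(agg)
      }
    }
    out[[ch]] <- counts
  }
  rownames(out) <- NULL
  out
}

#' Classify cells by per-channel positivity rules
#'
#' A cell is positive for a channel iff its molecule count is at least the
#' rule's minimum (e.g. `c(Gal = 2, Calcr = 2, Fos = 5)`). Labels are
#' non-exclusive; composite classes are conjunctions of channel positivity.
#'
#' @param counts data.frame from [cell_molecule_counts()].
#' @param rules named integer vector, channel -> minimum molecule count.
#' @return `counts` with one added logical column `<channel>_pos` per rule.
#' @export
classify_cells <- function(counts, rules) {
  missing <- setdiff(names(rules), names(counts))
  if (length(missing) > 0L) {
    stop_stage("rnascope_quant", "rules reference unknown channel(s): ",
               paste(missing, collapse = ", "))
  }
  if (any(rules < 1)) {
    stop_stage("rnascope_quant", "positivity rules must be >= 1 molecule")
  }
  for (ch in names(rules)) {
    counts[[paste0(ch, "_pos")]] <- counts[[ch]] >= rules[[ch]]
  }
  counts
}

#' Composite (conjunction) positivity across channels
#'
#' @param classified data.frame from [classify_cells()].
#' @param channels channels whose positivity must all hold.
#' @return logical vector, one entry per cell.
#' @export
composite_positive <- function(classified, channels) {
  cols <- paste0(channels, "_pos")
  missing <- setdiff(cols, names(classified))
  if (length(missing) > 0L) {
    stop_stage("rnascope_quant", "not classified for: ",
               paste(missing, collapse = ", "))
  }
  Reduce(`&`, classified[cols])
}

#' Positive-cell rate per 1000 cells
#'
#' @param n_positive number of positive cells.
#' @param n_total_cells total cells in the region (>= 1).
#' @return `1000 * n_positive / n_total_cells`.
#' @export
positives_per_1000 <- function(n_positive, n_total_cells) {
  if (any(n_total_cells < 1)) {
    stop_stage("rnascope_quant", "n_total_cells must be >= 1")
  }
  if (any(n_positive < 0) || any(n_positive > n_total_cells)) {
    stop_stage("rnascope_quant", "need 0 <= n_positive <= n_total_cells")
  }
  1000 * n_positive / n_total_cells
}

#' Semi-quantitative H-score of a molecule-count population
#'
#' Weighted sum of cell percentages over count bins: weight 0 for 0
#' molecules, 1 for 1-3, 2 for 4-9, 3 for 10-15, 4 for 16+; range 0-400.
#'
#' @param counts non-negative integer molecule counts, one per cell.
#' @return H-score in \[0, 400\].
#' @export
h_score <- function(counts) {
  if (length(counts) == 0L) {
    stop_stage("rnascope_quant", "h_score of an empty population")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_stage("rnascope_quant", "molecule counts must be non-negative integers")
  }
  weights <- findInterval(counts, c(1, 4, 10, 16))  # 0..4
  sum(weights) / length(counts) * 100
}

#' Fold change of mean molecule counts between two cell classes
#'
#' @param counts data.frame from [cell_molecule_counts()].
#' @param channel channel (gene) whose counts are compared.
#' @param class_a,class_b logical vectors over the rows of `counts`, or
#'   predicate functions taking `counts` and returning such vectors.
#' @return `mean(counts in class_a) / mean(counts in class_b)`.
#' @export
fold_change_classes <- function(counts, channel, class_a, class_b) {
  if (!channel %in% names(counts)) {
    stop_stage("rnascope_quant", "unknown channel: ", channel)
  }
  if (is.function(class_a)) class_a <- class_a(counts)
  if (is.function(class_b)) class_b <- class_b(counts)
  if (!any(class_a) || !any(class_b)) {
    stop_stage("rnascope_quant", "both cell classes must be non-empty")
  }
  mean_a <- mean(counts[[channel]][class_a])
  mean_b <- mean(counts[[channel]][class_b])
  if (mean_b == 0) {
    stop_stage("rnascope_quant", "denominator class has zero mean count")
  }
  mean_a / mean_b
}

#' Estimate the single-signal mean intensity from an object table
#'
#' Heuristic calibration helper: the median integral intensity of objects
#' below the channel's 50th intensity percentile (the dimmer half, which is
#' dominated by single molecules rather than clusters). Never applied
#' silently -- quantification always takes an explicit calibration value.
#'
#' @param signals data.frame from [read_signal_table()].
#' @param channel channel name.
#' @return estimated single-signal mean integral intensity (a.u.).
#' @export
estimate_single_intensity <- function(signals, channel) {
  x <- signals$integral_intensity[signals$channel == channel]
  if (length(x) == 0L) {
    stop_stage("rnascope_quant", "no objects for channel: ", channel)
  }
  median(x[x <= stats::quantile(x, 0.5)])
}

#' Per-animal quantification summary
#'
#' The animal is the experimental unit: all cross-animal statistics are
#' computed on per-animal aggregates. For each animal this reports total
#' cells, and per channel the positive-cell count, positives per 1000 cells
#' and the H-score of the pooled (across sections) molecule counts.
#'
#' @param counts data.frame from [cell_molecule_counts()].
#' @param rules named positivity rules (channel -> min molecules).
#' @return data.frame, one row per animal x channel: `animal_id`,
#'   `condition`, `channel`, `n_cells`, `n_positive`, `per_1000`, `h_score`.
#' @export
summarize_by_animal <- function(counts, rules) {
  classified <- classify_cells(counts, rules)
  animals <- unique(counts$animal_id)
  rows <- list()
  for (an in animals) {
    sub <- classified[classified$animal_id == an, , drop = FALSE]
    for (ch in names(rules)) {
      n_pos <- sum(sub[[paste0(ch, "_pos")]])
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = an,
        condition = sub$condition[1L],
        channel = ch,
        n_cells = nrow(sub),
        n_positive = n_pos,
        per_1000 = positives_per_1000(n_pos, nrow(sub)),
        h_score = h_score(sub[[ch]]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
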