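# Correlation and morph-trend statistics: manipulation-level and audio-
# feature correlations with the color channels of the induced percepts, and
# the ΔE-to-origin trend analysis across morph stages.

#' Group-mean color channel across manipulation levels
#'
#' For one instrument series, averages a color channel across subjects (and
#' presentations) at every manipulation level — original = level 0, then
#' k = 1..10 removed partials, or morph stages 0..6. Channels are
#' saturation `"S"` and lightness `"L"` (from HSL, in \[0, 1\]) and the
#' RGB channels `"R"`, `"G"`, `"B"` (0..255). Hue is refused: a circular
#' variable must not enter a linear correlation.
#'
#' @param responses response table with `r,g,b` columns.
#' @param stimuli stimulus metadata: data.frame with `stimulus_id` and
#'   `level` (and any further columns); only rows whose ids appear in it
#'   are used.
#' @param channel one of `"S"`, `"L"`, `"R"`, `"G"`, `"B"`.
#' @return data.frame with `level` and `value`, ordered by level.
#' @export
channel_series <- function(responses, stimuli, channel) {
  if (toupper(channel) %in% c("H", "HUE"))
    stop("hue is a circular variable; refusing to build a linear series ",
         "for correlation")
  channel <- match.arg(toupper(channel), c("S", "L", "R", "G", "B"))
  stopifnot(all(c("stimulus_id", "level") %in% names(stimuli)))
  df <- merge(responses, stimuli[, c("stimulus_id", "level")],
              by = "stimulus_id")
  if (nrow(df) == 0) stop("no responses match the given stimuli")
  rgb <- as.matrix(df[, c("r", "g", "b")])
  vals <- switch(channel,
    S = rgb_to_hsl(rgb)[, "s"],
    L = rgb_to_hsl(rgb)[, "l"],
    R = rgb[, 1], G = rgb[, 2], B = rgb[, 3])
  agg <- stats::aggregate(vals, by = list(level = df$level), FUN = mean)
  names(agg)[2] <- "value"
  agg[order(agg$level), , drop = FALSE]
}

#' Pearson correlation with Bonferroni-adjusted significance
#'
#' Pearson r with the two-sided p-value from the t distribution, the
#' Bonferroni-adjusted alpha (0.05 / `bonferroni_n`), a significance flag
#' against that adjusted threshold, and the conventional star coding at
#' the uncorrected 0.05 / 0.01 / 0.001 levels (stars follow table
#' conventions; the corrected flag is carried separately).
#'
#' @param xs,ys numeric vectors (n >= 3, finite, nonzero variance).
#' @param bonferroni_n number of tests in the family; 1 disables the
#'   correction.
#' @param label optional pair label carried into the result.
#' @return one-row data.frame: `label`, `r`, `p`, `n`, `alpha_corrected`,
#'   `significant`, `stars`.
#' @export
correlate_series <- function(xs, ys, bonferroni_n = 1, label = NA_character_) {
  stopifnot(length(xs) == length(ys))
  if (length(xs) < 3) stop("need at least 3 points to correlate")
  if (!all(is.finite(xs)) || !all(is.finite(ys)))
    stop("correlation inputs must be finite")
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("correlation undefined for zero-variance input")
  ct <- stats::cor.test(xs, ys, method = "pearson",
                        alternative = "two.sided")
  r <- unname(ct$estimate)
  p <- ct$p.value
  alpha <- 0.05 / bonferroni_n
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
           if (p < 0.05) "*" else ""
  data.frame(label = label, r = r, p = p, n = length(xs),
             alpha_corrected = alpha, significant = p < alpha,
             stars = stars, stringsAsFactors = FALSE)
}

#' Color-distance curves across morph stages
#'
#' For one morph direction (source -> target), computes per subject the
#' CIEDE2000 distance between each reference color — the subject's two
#' picks for the source original — and the subject's pick at every stage.
#' Stage 0 and stage 6 carry the two repeated original picks (source and
#' target respectively) as separate points, stages 1..5 the five morphed
#' sounds; this yields the "2 x 2" curve pairs of the design (two
#' references per direction, both directions of an instrument pair).
#'
#' @param responses response table.
#' @param stimuli stimulus metadata with `stimulus_id` and `stage`
#'   (0..6) for this morph direction; stage 0 and 6 rows are the source
#'   and target originals.
#' @param subjects subjects to include (default: all in `responses`).
#' @return data.frame with `subject_id`, `ref` (1 or 2), `stage`,
#'   `presentation`, `de`. Subjects whose reference picks are missing are
#'   flagged via attribute `partial_subjects`.
#' @export
morph_distance_curves <- function(responses, stimuli, subjects = NULL) {
  stopifnot(all(c("stimulus_id", "stage") %in% names(stimuli)))
  if (is.null(subjects)) subjects <- unique(responses$subject_id)
  df <- merge(responses, stimuli[, c("stimulus_id", "stage")],
              by = "stimulus_id")
  src_id <- stimuli$stimulus_id[stimuli$stage == 0][1]
  rows <- list()
  partial <- character()
  for (s in subjects) {
    sub <- df[df$subject_id == s, , drop = FALSE]
    refs <- sub[sub$stimulus_id == src_id, , drop = FALSE]
    refs <- refs[order(refs$presentation), , drop = FALSE]
    if (nrow(refs) < 2) {
      partial <- c(partial, s)
      if (nrow(refs) == 0) next
    }
    ref_lab <- srgb_to_lab(as.matrix(refs[, c("r", "g", "b")]))
    resp_lab <- srgb_to_lab(as.matrix(sub[, c("r", "g", "b")]))
    for (i in seq_len(nrow(refs))) {
      de <- delta_e_ciede2000(ref_lab[rep(i, nrow(sub)), , drop = FALSE],
                              resp_lab)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s, ref = i, stage = sub$stage,
        presentation = sub$presentation, de = de,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(subject_id = character(), ref = integer(),
                      stage = integer(), presentation = integer(),
                      de = numeric())
  rownames(out) <- NULL
  attr(out, "partial_subjects") <- partial
  out
}

#' Trend-line slope and range of a morph distance curve
#'
#' Ordinary least squares of ΔE against the ordinal stage index, pooled
#' over all curve points. `mode = "overall"` uses stages 0..6 (both
#' repeated-original picks at each endpoint enter as separate points);
#' `mode = "morphed_only"` restricts to the morphed stages 1..5. The range
#' is the spread (max - min) of the fitted values over the included
#' stages. The slope is invariant under adding a constant to all ΔE.
#'
#' @param curves data.frame from [morph_distance_curves()] (needs `stage`
#'   and `de`), or any data.frame with those columns.
#' @param mode `"overall"` or `"morphed_only"`.
#' @return list with `slope` (ΔE per stage), `range` (ΔE), `n` (points).
#' @export
trend_stats <- function(curves, mode = c("overall", "morphed_only")) {
  mode <- match.arg(mode)
  df <- curves
  if (mode == "morphed_only")
    df <- df[df$stage >= 1 & df$stage <= 5, , drop = FALSE]
  if (length(unique(df$stage)) < 2)
    stop("need at least two distinct stages to fit a trend")
  fit <- stats::lm(de ~ stage, data = df)
  slope <- unname(stats::coef(fit)[2])
  fitted_span <- range(stats::predict(fit,
    newdata = data.frame(stage = range(df$stage))))
  list(slope = slope, range = diff(fitted_span), n = nrow(df))
}

#' Per-pair trend table across groups
#'
#' Assembles the morph trend report: for every morph direction and every
#' group, the overall and morphed-only trend slope and range, with a
#' closing `Mean` row per column. The groups are those produced by
#' [partition_groups()]; "best synesthetes" are the two subjects with the
#' lowest mean ΔE.
#'
#' @param curves_by_pair named list (pair label -> curves data.frame from
#'   [morph_distance_curves()], covering all subjects).
#' @param groups named list (group label -> character vector of subject
#'   ids).
#' @return list with data.frames `slope` and `range`; columns are
#'   `<group>_overall` and `<group>_morphed`, rows the pairs plus `Mean`.
#' @export
group_trend_table <- function(curves_by_pair, groups) {
  stopifnot(length(curves_by_pair) > 0, length(groups) > 0)
  pair_names <- names(curves_by_pair)
  cols_slope <- list(); cols_range <- list()
  for (g in names(groups)) {
    for (mode in c("overall", "morphed_only")) {
      key <- paste0(g, if (mode == "overall") "_overall" else "_morphed")
      st <- vapply(curves_by_pair, function(cv) {
        sel <- cv[cv$subject_id %in% groups[[g]], , drop = FALSE]
        ts <- trend_stats(sel, mode)
        c(ts$slope, ts$range)
      }, numeric(2))
      cols_slope[[key]] <- st[1, ]
      cols_range[[key]] <- st[2, ]
    }
  }
  finish <- function(cols) {
    df <- data.frame(pair = pair_names, as.data.frame(cols),
                     stringsAsFactors = FALSE)
    mean_row <- c(list(pair = "Mean"), lapply(cols, mean))
    rbind(df, as.data.frame(mean_row, stringsAsFactors = FALSE))
  }
  list(slope = finish(cols_slope), range = finish(cols_range))
}

#' Column means of a per-pair trend table
#'
#' Averages the per-pair trend values of each numeric column — the `Mean`
#' row of the trend report tables.
#'
#' @param trend_table data.frame with a `pair` label column and numeric
#'   trend columns (e.g. from [reference_morph_trends()]).
#' @return named numeric vector of column means.
#' @export
trend_table_means <- function(trend_table) {
  num <- vapply(trend_table, is.numeric, logical(1))
  colMeans(trend_table[, num, drop = FALSE])
}
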