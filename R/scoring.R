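# Objective synesthesia assessment: each original instrument sound is
# presented twice; the CIEDE2000 difference between a subject's two picks,
# averaged over instruments, scores the consistency of the timbre-induced
# color and assigns a grade. Subjects grading better than "poor" form the
# synesthete group.

GRADE_LEVELS <- c("excellent", "very_well", "satisfactory", "poor")

#' Grade a mean repeat-distance score
#'
#' Half-open consistency bands on the mean repeat ΔE: `[0, 10)` excellent,
#' `[10, 13)` very well, `[13, 16)` satisfactory, `>= 16` poor (no
#' timbre-color synesthesia). The bands partition `[0, Inf)`, so every
#' valid mean maps to exactly one grade.
#'
#' @param mean_de numeric vector of mean ΔE scores (>= 0).
#' @return factor with levels excellent, very_well, satisfactory, poor.
#' @export
#' @examples
#' classify_grade(c(7.296, 10.745, 13.856, 19.358))
classify_grade <- function(mean_de) {
  if (anyNA(mean_de) || any(mean_de < 0))
    stop("mean ΔE scores must be nonnegative and non-missing")
  cut(mean_de, breaks = c(0, 10, 13, 16, Inf), labels = GRADE_LEVELS,
      right = FALSE, include.lowest = TRUE)
}

#' Repeat-presentation color distance
#'
#' CIEDE2000 difference between a subject's first and second color pick for
#' the same stimulus. Returns `NA` (missing) when either presentation is
#' absent or flagged missing; more than two presentations of an original
#' stimulus violate the repeat design and raise an error.
#'
#' @param responses a response table (see [simulate_responses()] /
#'   [read_responses()]): columns `subject_id`, `stimulus_id`,
#'   `presentation`, `r`, `g`, `b`, optional logical `missing`.
#' @param subject,stimulus identifiers selecting the response pair.
#' @return a single ΔE value, or `NA` if a presentation is missing.
#' @export
repeat_distance <- function(responses, subject, stimulus) {
  sel <- responses[responses$subject_id == subject &
                   responses$stimulus_id == stimulus, , drop = FALSE]
  if (nrow(sel) > 2)
    stop("more than two presentations recorded for subject ", subject,
         ", stimulus ", stimulus)
  if ("missing" %in% names(sel))
    sel <- sel[!sel$missing, , drop = FALSE]
  if (nrow(sel) < 2) return(NA_real_)
  lab <- srgb_to_lab(as.matrix(sel[, c("r", "g", "b")]))
  delta_e_ciede2000(lab[1, ], lab[2, ])
}

#' Aggregate per-instrument repeat distances into a subject score
#'
#' Total = sum of the non-missing per-instrument ΔE values; mean = total
#' divided by the number of non-missing values (a missing repeat is
#' excluded from both the numerator and the denominator). The mean is then
#' graded by [classify_grade()]. Permutation-invariant in its entries.
#'
#' @param per_instrument named numeric vector of per-instrument ΔE values;
#'   `NA` marks a missing repeat.
#' @return list with `total_de`, `n_valid`, `mean_de`, `grade`.
#' @export
#' @examples
#' score_subject(c(flute = 0.35, violin = 16.06, horns = NA,
#'                 piano = 0.86, oboe = 25.71))  # mean 42.98 / 4 = 10.745
score_subject <- function(per_instrument) {
  valid <- per_instrument[!is.na(per_instrument)]
  if (length(valid) == 0)
    stop("subject has no valid repeat distances and cannot be scored")
  if (any(valid < 0)) stop("ΔE values must be nonnegative")
  total <- sum(valid)
  m <- total / length(valid)
  list(total_de = total, n_valid = length(valid), mean_de = m,
       grade = classify_grade(m))
}

#' Score every subject of a response table
#'
#' Computes the per-instrument repeat ΔE for each subject over the original
#' (twice-presented) stimuli and aggregates with [score_subject()],
#' producing a consistency report shaped like the per-subject score table
#' of the study design: one row per subject with per-instrument ΔE, total,
#' n_valid, mean and grade columns.
#'
#' @param responses response table (see [repeat_distance()]).
#' @param original_stimuli named character vector mapping stimulus id to
#'   instrument label for the twice-presented originals.
#' @return data.frame, one row per subject.
#' @export
score_subjects <- function(responses, original_stimuli) {
  stopifnot(length(original_stimuli) >= 1, !is.null(names(original_stimuli)))
  subjects <- unique(responses$subject_id)
  instruments <- unname(original_stimuli)
  de <- matrix(NA_real_, nrow = length(subjects),
               ncol = length(original_stimuli),
               dimnames = list(subjects, instruments))
  for (s in seq_along(subjects)) {
    for (j in seq_along(original_stimuli)) {
      de[s, j] <- repeat_distance(responses, subjects[s],
                                  names(original_stimuli)[j])
    }
  }
  score_table(de, subject_ids = subjects)
}

#' Score a matrix of per-instrument repeat distances
#'
#' The aggregation half of [score_subjects()], applied directly to a matrix
#' of per-instrument ΔE values (rows = subjects) — e.g. an already
#' published score table whose totals, means and grades are to be
#' recomputed.
#'
#' @param de numeric matrix of ΔE values, `NA` for missing repeats.
#' @param subject_ids row identifiers.
#' @return data.frame with per-instrument columns plus `total_de`,
#'   `n_valid`, `mean_de`, `grade`.
#' @export
score_table <- function(de, subject_ids = rownames(de)) {
  de <- as.matrix(de)
  if (is.null(subject_ids)) subject_ids <- as.character(seq_len(nrow(de)))
  scores <- apply(de, 1, score_subject)
  out <- data.frame(subject_id = as.character(subject_ids),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(de, row.names = FALSE))
  out$total_de <- vapply(scores, `[[`, numeric(1), "total_de")
  out$n_valid <- vapply(scores, `[[`, numeric(1), "n_valid")
  out$mean_de <- vapply(scores, `[[`, numeric(1), "mean_de")
  out$grade <- factor(vapply(scores, function(s) as.character(s$grade),
                             character(1)), levels = GRADE_LEVELS)
  rownames(out) <- NULL
  out
}

#' Partition scored subjects into synesthetes and non-synesthetes
#'
#' Subjects whose grade is anything better than poor count as timbre-color
#' synesthetes; the census tabulates their grades. The partition uses the
#' mean-ΔE grade only — no secondary criteria.
#'
#' @param scores data.frame from [score_subjects()]/[score_table()] (needs
#'   `subject_id`, `mean_de`, `grade`).
#' @return list with data.frames `synesthetes` and `non_synesthetes`, and
#'   `census`, a named count of grades within the synesthete group.
#' @export
partition_groups <- function(scores) {
  if (nrow(scores) == 0) {
    empty <- scores
    return(list(synesthetes = empty, non_synesthetes = empty,
                census = table(factor(character(),
                                      levels = GRADE_LEVELS[1:3]))))
  }
  syn <- scores[scores$grade != "poor", , drop = FALSE]
  non <- scores[scores$grade == "poor", , drop = FALSE]
  list(synesthetes = syn, non_synesthetes = non,
       census = table(factor(as.character(syn$grade),
                             levels = GRADE_LEVELS[1:3])))
}

#' Read and write response tables
#'
#' Response CSVs carry one row per (subject, stimulus, presentation) with
#' the picked color serialised both as `#RRGGBB` hex and as `h,s,l`
#' columns; the reader accepts either form (or raw `r,g,b`) and
#' reconstructs the rest.
#'
#' @param path CSV path.
#' @param responses response table to write.
#' @return `read_responses`: response table with `r,g,b`, `hex` and
#'   `h,s,l` columns; `write_responses`: `path`, invisibly.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "stimulus_id", "presentation")
  if (!all(need %in% names(df)))
    stop("response CSV must have columns ", paste(need, collapse = ", "))
  if (!all(c("r", "g", "b") %in% names(df))) {
    if ("hex" %in% names(df)) {
      rgb <- hex_to_rgb(df$hex)
    } else if (all(c("h", "s", "l") %in% names(df))) {
      rgb <- hsl_to_rgb(as.matrix(df[, c("h", "s", "l")]))
    } else {
      stop("response CSV needs r,g,b or hex or h,s,l color columns")
    }
    df$r <- rgb[, 1]; df$g <- rgb[, 2]; df$b <- rgb[, 3]
  }
  .complete_color_columns(df)
}

#' @rdname read_responses
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(.complete_color_columns(responses), path,
                   row.names = FALSE)
  invisible(path)
}

.complete_color_columns <- function(df) {
  rgb <- as.matrix(df[, c("r", "g", "b")])
  df$hex <- rgb_to_hex(rgb)
  hsl <- rgb_to_hsl(rgb)
  df$h <- hsl[, "h"]; df$s <- hsl[, "s"]; df$l <- hsl[, "l"]
  df
}

#' Published reference consistency table
#'
#' The per-subject repeat-ΔE reference table shipped with the package
#' (20 subjects by 5 instruments, including one missing repeat and the
#' printed totals and means), used by the acceptance checks to verify the
#' scoring arithmetic and the group partition.
#'
#' @return data.frame with columns `case`, the five instrument ΔE columns,
#'   and the printed `total` and `mean`.
#' @export
reference_consistency <- function() {
  utils::read.csv(system.file("extdata", "consistency_reference.csv",
                              package = "timbrecolor"),
                  stringsAsFactors = FALSE)
}

#' Published reference morph trend tables
#'
#' Per-pair trend-line slopes (`"slope"`) or ranges (`"range"`) of the
#' morph color-distance curves for the three groups (synesthetes,
#' non-synesthetes, best synesthetes), overall and morphed-sounds-only, as
#' shipped with the package for the trend-table averaging checks.
#'
#' @param what `"slope"` or `"range"`.
#' @return data.frame with a `pair` column and six value columns.
#' @export
reference_morph_trends <- function(what = c("slope", "range")) {
  what <- match.arg(what)
  utils::read.csv(system.file("extdata",
                              paste0("morph_trend_", what, "s.csv"),
                              package = "timbrecolor"),
                  stringsAsFactors = FALSE)
}
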