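# Synthetic-cohort generator: subject profiles with stable instrument ->
# color anchors in CIELAB, audio-feature-modulated response colors, and
# isotropic Lab jitter calibrated so each profile's expected repeat-ΔE
# score lands on its target grade. Non-synesthete profiles have near-zero
# feature coefficients and large jitter (weakly consistent choices).

FEATURE_NAMES <- c("spectral_centroid", "harmonicity_strength",
                   "percussive_loudness")

# Default per-subject target mean ΔE values: the 20 scores of the
# published reference consistency table (2 excellent, 4 very well,
# 4 satisfactory, 10 poor).
.default_targets <- function() {
  ref <- reference_consistency()
  sort_idx <- order(ref$mean)
  ref$mean[sort_idx]
}

# Random anchor colors inside a comfortably in-gamut Lab box.
.draw_anchors <- function(n_instruments) {
  repeat {
    lab <- cbind(L = stats::runif(n_instruments, 35, 75),
                 a = stats::runif(n_instruments, -40, 40),
                 b = stats::runif(n_instruments, -40, 40))
    if (!any(attr(lab_to_srgb(lab), "clamped"))) return(lab)
  }
}

#' Calibrate the Lab jitter width for a target repeat-distance score
#'
#' Monte-Carlo search for the isotropic Lab jitter standard deviation
#' `sigma` such that the expected CIEDE2000 distance between two
#' independently jittered copies of an anchor (averaged over the given
#' anchors, after sRGB gamut clamping) matches `target_mean_de` within the
#' given relative tolerance. Monotone in `sigma`; solved by bisection with
#' common random numbers.
#'
#' @param target_mean_de target expected repeat ΔE (>= 0).
#' @param anchors Lab anchor matrix (rows = instruments) the subject's
#'   score is averaged over.
#' @param n_mc Monte-Carlo draws per anchor and evaluation.
#' @param seed RNG seed for the draws.
#' @param tol relative tolerance on the achieved expectation.
#' @param sigma_max largest admissible sigma.
#' @return calibrated sigma; the achieved expectation is attached as
#'   attribute `achieved_mean_de`.
#' @export
calibrate_jitter <- function(target_mean_de, anchors, n_mc = 2000L,
                             seed = 1L, tol = 0.02, sigma_max = 300) {
  stopifnot(target_mean_de >= 0)
  if (target_mean_de == 0)
    return(structure(0, achieved_mean_de = 0))
  anchors <- .as_color_matrix(anchors, "Lab")
  n_a <- nrow(anchors)
  z <- with_seed(seed, array(stats::rnorm(n_a * n_mc * 6),
                             dim = c(n_a * n_mc, 6)))
  base <- anchors[rep(seq_len(n_a), each = n_mc), , drop = FALSE]
  expected_de <- function(sigma) {
    lab1 <- .clamp_lab(base + sigma * z[, 1:3])
    lab2 <- .clamp_lab(base + sigma * z[, 4:6])
    mean(delta_e_ciede2000(lab1, lab2))
  }
  if (expected_de(sigma_max) < target_mean_de)
    stop("target mean ΔE ", target_mean_de,
         " is unreachable within the sRGB gamut")
  lo <- 0; hi <- sigma_max
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    e <- expected_de(mid)
    if (abs(e - target_mean_de) / target_mean_de <= tol) break
    if (e < target_mean_de) lo <- mid else hi <- mid
  }
  structure(mid, achieved_mean_de = e)
}

# Round-trip a Lab color through the clamped sRGB cube (what a picker
# records) and back.
.clamp_lab <- function(lab) {
  srgb_to_lab(lab_to_srgb(lab))
}

#' Build a synthetic subject cohort
#'
#' Creates subject profiles with per-instrument Lab color anchors,
#' feature-modulation coefficients, and jitter calibrated per subject via
#' [calibrate_jitter()] so that each expected mean repeat ΔE hits its
#' target. The default targets are the 20 mean scores of the reference
#' consistency table — 2 excellent, 4 very-well, 4 satisfactory and 10
#' poor — so the cohort is a synthetic twin of the study's score
#' distribution. Synesthete-grade profiles carry the planted
#' instrument-independent coefficient signs (lightness rises with spectral
#' centroid, blue rises — b* falls — with percussive loudness, a* rises
#' weakly with harmonicity strength); poor profiles have zero
#' coefficients.
#'
#' @param target_means per-subject target mean ΔE values (default: the
#'   reference table's 20 means).
#' @param instruments instrument labels anchoring the color map.
#' @param seed RNG seed (anchors and calibration draws).
#' @param coeff_scale Lab units of channel shift per within-instrument
#'   standard deviation of a feature.
#' @param n_mc Monte-Carlo draws per calibration.
#' @return list of profile lists (`subject_id`, `target_mean_de`,
#'   `target_grade`, `anchors`, `coeffs`, `sigma`), class
#'   `timbre_cohort`.
#' @export
make_cohort <- function(target_means = NULL,
                        instruments = c("flute", "violin", "horn",
                                        "piano", "oboe"),
                        seed = 1L, coeff_scale = 5, n_mc = 2000L) {
  if (is.null(target_means)) target_means <- .default_targets()
  grades <- classify_grade(target_means)
  syn_coeffs <- rbind(
    spectral_centroid = c(L = coeff_scale, a = 0, b = 0),
    harmonicity_strength = c(L = 0, a = 0.4 * coeff_scale, b = 0),
    percussive_loudness = c(L = 0, a = 0, b = -coeff_scale))
  zero_coeffs <- syn_coeffs * 0
  profiles <- vector("list", length(target_means))
  for (i in seq_along(target_means)) {
    anchors <- with_seed(seed * 1000L + i, .draw_anchors(length(instruments)))
    rownames(anchors) <- instruments
    sigma <- calibrate_jitter(target_means[i], anchors,
                              n_mc = n_mc, seed = seed * 1000L + i)
    profiles[[i]] <- list(
      subject_id = sprintf("sub%02d", i),
      target_mean_de = target_means[i],
      target_grade = as.character(grades[i]),
      anchors = anchors,
      coeffs = if (grades[i] == "poor") zero_coeffs else syn_coeffs,
      sigma = as.numeric(sigma))
  }
  structure(profiles, class = "timbre_cohort")
}

# Standardise features within instrument: offset from the level-0
# (original) value, scaled by the within-instrument standard deviation
# across levels.
.standardise_features <- function(stimulus_features) {
  df <- stimulus_features
  for (fn in FEATURE_NAMES) {
    zcol <- paste0("z_", fn)
    df[[zcol]] <- 0
    for (ins in unique(df$instrument)) {
      sel <- df$instrument == ins
      x <- df[[fn]][sel]
      base <- x[df$level[sel] == 0][1]
      s <- stats::sd(x)
      df[[zcol]][sel] <- if (is.na(s) || s == 0) 0 else (x - base) / s
    }
  }
  df
}

#' Simulate a response table for a cohort
#'
#' Every subject responds to every stimulus with a color drawn as
#' `anchor(instrument) + coeffs' z(features) + N(0, sigma^2 I)` in Lab,
#' clamped to the sRGB gamut and recorded as an 8-bit picker color.
#' Stimuli of type `"original"` are presented twice (independently
#' jittered), all others once. Deterministic for a given seed.
#'
#' @param cohort profiles from [make_cohort()].
#' @param stimulus_features data.frame with `stimulus_id`, `instrument`,
#'   `type` (`"original"`, `"partial"` or `"morph"`), `level`, and the
#'   three feature columns of [audio_features()].
#' @param seed RNG seed.
#' @return response table: `subject_id`, `stimulus_id`, `presentation`,
#'   `r`, `g`, `b`, `hex`, `h`, `s`, `l`.
#' @export
simulate_responses <- function(cohort, stimulus_features, seed = 1L) {
  stopifnot(inherits(cohort, "timbre_cohort"),
            all(c("stimulus_id", "instrument", "type", "level")
                %in% names(stimulus_features)),
            all(FEATURE_NAMES %in% names(stimulus_features)))
  sf <- .standardise_features(stimulus_features)
  sf$n_pres <- ifelse(sf$type == "original", 2L, 1L)
  idx <- rep(seq_len(nrow(sf)), sf$n_pres)
  pres <- unlist(lapply(sf$n_pres, seq_len))
  zmat <- as.matrix(sf[, paste0("z_", FEATURE_NAMES)])[idx, , drop = FALSE]
  with_seed(seed, {
    out <- lapply(cohort, function(p) {
      base <- p$anchors[sf$instrument[idx], , drop = FALSE] +
        zmat %*% p$coeffs
      lab <- base + matrix(stats::rnorm(length(idx) * 3, sd = p$sigma),
                           ncol = 3)
      rgb <- lab_to_srgb(lab)
      data.frame(subject_id = p$subject_id,
                 stimulus_id = sf$stimulus_id[idx],
                 presentation = pres,
                 r = rgb[, 1], g = rgb[, 2], b = rgb[, 3],
                 stringsAsFactors = FALSE)
    })
    .complete_color_columns(do.call(rbind, out))
  })
}

#' Simulate a full cohort study
#'
#' Convenience wrapper: build (or reuse) a cohort, simulate its response
#' table over the given stimulus set, and return both together with the
#' planted ground truth (targets, grades, coefficient signs).
#'
#' @param stimulus_features stimulus/feature table as in
#'   [simulate_responses()].
#' @param cohort optional pre-built cohort; built with defaults otherwise.
#' @param seed RNG seed (cohort construction uses `seed`, responses
#'   `seed + 1`).
#' @return list with `responses`, `cohort`, `truth`.
#' @export
simulate_cohort <- function(stimulus_features, cohort = NULL, seed = 1L) {
  if (is.null(cohort)) cohort <- make_cohort(seed = seed)
  responses <- simulate_responses(cohort, stimulus_features,
                                  seed = seed + 1L)
  truth <- data.frame(
    subject_id = vapply(cohort, `[[`, character(1), "subject_id"),
    target_mean_de = vapply(cohort, `[[`, numeric(1), "target_mean_de"),
    target_grade = vapply(cohort, `[[`, character(1), "target_grade"),
    sigma = vapply(cohort, `[[`, numeric(1), "sigma"),
    stringsAsFactors = FALSE)
  truth$is_synesthete <- truth$target_grade != "poor"
  list(responses = responses, cohort = cohort, truth = truth)
}

#' Synthesize the partial-reduction study and extract its features
#'
#' Builds the 55-stimulus set (5 presets, original plus k = 1..10 removed
#' partials, loudness-matched) and runs the feature extractor, returning
#' the stimulus/feature table the simulator and the correlation analyses
#' consume. This is the expensive step of a full pipeline run (about a
#' minute); downstream cohort replicates reuse its output.
#'
#' @param presets named list of [tone_spec()] presets; defaults to the
#'   shipped instrument presets.
#' @param seed synthesis seed.
#' @return data.frame with `stimulus_id`, `instrument`, `type`, `level`
#'   and the three feature columns plus `hpr`.
#' @export
partial_study_features <- function(presets = tone_presets(), seed = 1L) {
  rows <- list()
  for (ins in names(presets)) {
    series <- partial_series(presets[[ins]], seed = seed)
    feats <- extract_features(series)
    feats$stimulus_id <- paste0(ins, "_", names(series))
    feats$instrument <- ins
    feats$level <- 0:(length(series) - 1L)
    feats$type <- ifelse(feats$level == 0, "original", "partial")
    rows[[ins]] <- feats
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("stimulus_id", "instrument", "type", "level",
          "spectral_centroid", "harmonicity_strength",
          "percussive_loudness", "hpr")]
}

#' Score and analyse one simulated cohort replicate
#'
#' Runs the scoring pipeline on a simulated response table and checks (a)
#' whether the recovered synesthete/non-synesthete partition matches the
#' planted one exactly, with the planted grade census, and (b) whether the
#' planted correlation signs (lightness up with spectral centroid, blue up
#' with percussive loudness) are recovered on every instrument's
#' partial-reduction series from the synesthete group means.
#'
#' @param cohort cohort from [make_cohort()].
#' @param stimulus_features table from [partial_study_features()].
#' @param seed response seed for this replicate.
#' @return one-row data.frame: `partition_exact`, `census_ok`,
#'   `n_synesthetes`, `subject_accuracy`, `signs_ok`.
#' @export
cohort_replicate <- function(cohort, stimulus_features, seed) {
  sim <- simulate_cohort(stimulus_features, cohort = cohort, seed = seed)
  originals <- stimulus_features[stimulus_features$type == "original", ]
  orig_map <- stats::setNames(originals$instrument, originals$stimulus_id)
  scores <- score_subjects(sim$responses, orig_map)
  part <- partition_groups(scores)
  truth <- sim$truth
  got_syn <- sort(part$synesthetes$subject_id)
  want_syn <- sort(truth$subject_id[truth$is_synesthete])
  merged <- merge(scores, truth, by = "subject_id")
  accuracy <- mean((merged$grade != "poor") == merged$is_synesthete)
  want_census <- table(factor(truth$target_grade[truth$is_synesthete],
                              levels = GRADE_LEVELS[1:3]))
  census_ok <- all(as.integer(part$census) == as.integer(want_census))

  syn_resp <- sim$responses[sim$responses$subject_id %in% want_syn, ]
  signs_ok <- TRUE
  for (ins in unique(stimulus_features$instrument)) {
    stim <- stimulus_features[stimulus_features$instrument == ins, ]
    sL <- channel_series(syn_resp, stim, "L")
    sB <- channel_series(syn_resp, stim, "B")
    feats <- stim[order(stim$level), ]
    r_cent <- stats::cor(feats$spectral_centroid, sL$value)
    r_ploud <- stats::cor(feats$percussive_loudness, sB$value)
    if (!(r_cent > 0 && r_ploud > 0)) signs_ok <- FALSE
  }
  data.frame(partition_exact = identical(got_syn, want_syn),
             census_ok = census_ok,
             n_synesthetes = nrow(part$synesthetes),
             subject_accuracy = accuracy,
             signs_ok = signs_ok)
}

#' Run seeded cohort replicates
#'
#' @param stimulus_features table from [partial_study_features()].
#' @param n_reps number of replicates.
#' @param seed base seed; replicate `i` uses `seed + i` for responses.
#' @param cohort optional fixed cohort (built once from `seed` otherwise).
#' @return data.frame with one row per replicate (see
#'   [cohort_replicate()]).
#' @export
cohort_replicates <- function(stimulus_features, n_reps = 100L, seed = 1L,
                              cohort = NULL) {
  if (is.null(cohort)) cohort <- make_cohort(seed = seed)
  out <- lapply(seq_len(n_reps), function(i)
    cohort_replicate(cohort, stimulus_features, seed = seed + i))
  do.call(rbind, out)
}
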