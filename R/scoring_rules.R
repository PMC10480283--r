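#' Classify the seven staging features as high, low, or neutral risk
#'
#' Maps each structured baseline-staging feature of a rectal tumor to a
#' high/low/neutral risk class and counts the high- and low-risk criteria.
#' The seven features and their rules are:
#'
#' * T-stage: high if T3c, T3d, or T4; low if T1, T2, T3a, or T3b.
#' * Tumor size (craniocaudal, cm): high if > 5, low if < 3, neutral in
#'   \[3, 5\] (boundaries inclusive of neutral).
#' * Signal: high if heterogeneous, low if homogeneous.
#' * Shape: high if irregular, low if regular.
#' * N-stage: high if N1 or N2, low if N0.
#' * EMVI: high if present, low if absent.
#' * MRF invasion: high if present, low if absent.
#'
#' @param staging Data frame with columns `t_stage` (one of `"t1"`, `"t2"`,
#'   `"t3a"`, `"t3b"`, `"t3c"`, `"t3d"`, `"t4"`), `size_cm` (positive numeric),
#'   `signal` (`"homogeneous"`/`"heterogeneous"`), `shape`
#'   (`"regular"`/`"irregular"`), `n_stage` (`"n0"`/`"n1"`/`"n2"`), `emvi` and
#'   `mrf` (logical). Any other columns (e.g. `patient_id`, `reader_id`) are
#'   carried through.
#' @return A tibble: the input plus `risk_<feature>` columns (each
#'   `"high"`/`"low"`/`"neutral"`) and integer counts `n_high`, `n_low`.
#' @examples
#' staging <- tibble::tibble(
#'   t_stage = c("t4", "t2", "t3b"), size_cm = c(6.2, 2, 4),
#'   signal = c("heterogeneous", "homogeneous", "heterogeneous"),
#'   shape = c("irregular", "regular", "regular"),
#'   n_stage = c("n2", "n0", "n0"),
#'   emvi = c(TRUE, FALSE, FALSE), mrf = c(TRUE, FALSE, FALSE)
#' )
#' classify_features(staging)
#' @export
classify_features <- function(staging) {
  staging <- validate_staging(staging)
  risk <- function(high, low) {
    dplyr::case_when(high ~ "high", low ~ "low", .default = "neutral")
  }
  out <- dplyr::mutate(
    tibble::as_tibble(staging),
    risk_t_stage = risk(.data$t_stage %in% c("t3c", "t3d", "t4"),
                        .data$t_stage %in% c("t1", "t2", "t3a", "t3b")),
    risk_size    = risk(.data$size_cm > 5, .data$size_cm < 3),
    risk_signal  = risk(.data$signal == "heterogeneous",
                        .data$signal == "homogeneous"),
    risk_shape   = risk(.data$shape == "irregular", .data$shape == "regular"),
    risk_n_stage = risk(.data$n_stage %in% c("n1", "n2"), .data$n_stage == "n0"),
    risk_emvi    = risk(.data$emvi, !.data$emvi),
    risk_mrf     = risk(.data$mrf, !.data$mrf)
  )
  risk_cols <- paste0("risk_", c("t_stage", "size", "signal", "shape",
                                 "n_stage", "emvi", "mrf"))
  rm <- as.matrix(out[risk_cols])
  out$n_high <- as.integer(rowSums(rm == "high"))
  out$n_low  <- as.integer(rowSums(rm == "low"))
  out
}

validate_staging <- function(staging) {
  needed <- c("t_stage", "size_cm", "signal", "shape", "n_stage", "emvi", "mrf")
  missing <- setdiff(needed, names(staging))
  if (length(missing) > 0) {
    abort(paste0("staging table lacks columns: ",
                 paste(missing, collapse = ", ")))
  }
  staging$t_stage <- tolower(as.character(staging$t_stage))
  staging$signal  <- tolower(as.character(staging$signal))
  staging$shape   <- tolower(as.character(staging$shape))
  staging$n_stage <- tolower(as.character(staging$n_stage))
  check_levels <- function(x, levels, what) {
    bad <- setdiff(unique(x[!is.na(x)]), levels)
    if (length(bad) > 0) {
      abort(paste0("invalid ", what, " value(s): ", paste(bad, collapse = ", ")))
    }
  }
  check_levels(staging$t_stage, T_STAGE_LEVELS, "t_stage")
  check_levels(staging$signal, c("homogeneous", "heterogeneous"), "signal")
  check_levels(staging$shape, c("regular", "irregular"), "shape")
  check_levels(staging$n_stage, N_STAGE_LEVELS, "n_stage")
  if (any(staging$size_cm <= 0, na.rm = TRUE)) {
    abort("size_cm must be positive")
  }
  if (!is.logical(staging$emvi) || !is.logical(staging$mrf)) {
    abort("emvi and mrf must be logical")
  }
  staging
}

#' Five-point confidence score from high-/low-risk criterion counts
#'
#' Assigns the 5-point confidence of (near-)complete response from the
#' number of high-risk and low-risk criteria met (out of 7). Rules are
#' evaluated extremes first so that a profile always receives its most
#' extreme applicable category:
#'
#' * 1 (highly unlikely): all 7 criteria high risk.
#' * 2 (unlikely): at least 5 high-risk criteria.
#' * 5 (highly likely): at least 5 low-risk criteria.
#' * 4 (likely): at least 3 low-risk criteria.
#' * 3 (equivocal): anything else.
#'
#' @param n_high,n_low Integer vectors, counts of high- and low-risk criteria
#'   with `n_high + n_low <= 7`.
#' @return Integer vector of scores in 1..5.
#' @examples
#' five_point_score(n_high = 7, n_low = 0)  # 1
#' five_point_score(n_high = 0, n_low = 6)  # 5
#' @export
five_point_score <- function(n_high, n_low) {
  stopifnot(length(n_high) == length(n_low))
  if (any(n_high + n_low > 7, na.rm = TRUE) ||
      any(n_high < 0 | n_low < 0, na.rm = TRUE)) {
    abort("n_high + n_low must be within 0..7 and counts non-negative")
  }
  dplyr::case_when(
    n_high == 7 ~ 1L,
    n_high >= 5 ~ 2L,
    n_low  >= 5 ~ 5L,
    n_low  >= 3 ~ 4L,
    .default = 3L
  )
}

#' Four-point risk score: count of obvious high-risk features
#'
#' One point for each of: obvious macroscopic MRF invasion, high-risk
#' (bulky, T3c-4) T-stage, obvious nodal involvement, obvious EMVI.
#'
#' @param mrf_obvious,t_high_risk,nodal_obvious,emvi_obvious Logical vectors.
#' @return Integer vector of scores in 0..4.
#' @examples
#' four_point_score(TRUE, TRUE, TRUE, TRUE)    # 4
#' four_point_score(TRUE, FALSE, FALSE, FALSE) # 1
#' @export
four_point_score <- function(mrf_obvious, t_high_risk, nodal_obvious,
                             emvi_obvious) {
  args <- list(mrf_obvious, t_high_risk, nodal_obvious, emvi_obvious)
  if (!all(vapply(args, is.logical, logical(1)))) {
    abort("all four feature indicators must be logical")
  }
  as.integer(mrf_obvious) + as.integer(t_high_risk) +
    as.integer(nodal_obvious) + as.integer(emvi_obvious)
}

#' Dichotomised (2-point) risk score
#'
#' Returns 1 (unlikely to reach a good or complete response) for tumors with
#' a high-risk T-stage (T3c, T3d, or T4, regardless of MRF status) or with
#' obvious MRF invasion at a lower T-stage; returns 0 (likely) otherwise.
#' The "likely" branch requires a free (or at most borderline) mesorectal
#' fascia, which is why MRF invasion alone is sufficient for a score of 1.
#'
#' @param t_stage Character vector of T-stages (`"t1"` .. `"t4"`).
#' @param mrf Logical vector, obvious MRF invasion present.
#' @return Integer vector of scores in \{0, 1\}.
#' @examples
#' two_point_score("t2", FALSE)  # 0
#' two_point_score("t3a", TRUE)  # 1
#' @export
two_point_score <- function(t_stage, mrf) {
  t_stage <- tolower(as.character(t_stage))
  bad <- setdiff(unique(t_stage[!is.na(t_stage)]), T_STAGE_LEVELS)
  if (length(bad) > 0) {
    abort(paste0("invalid t_stage value(s): ", paste(bad, collapse = ", ")))
  }
  if (!is.logical(mrf)) abort("mrf must be logical")
  as.integer(t_stage %in% c("t3c", "t3d", "t4") | mrf)
}

#' Dichotomise a score into a binary response prediction
#'
#' Converts a method's score into the fixed published positive/negative call,
#' where positive means predicted (near-)complete responder: 5-point scores
#' 4-5 are positive (1-3 negative); 4-point scores 0-1 are positive (2-4
#' negative); 2-point score 0 is positive.
#'
#' @param method Character vector in `c("five_point", "four_point",
#'   "two_point")` (recycled if length 1).
#' @param value Integer vector of scores.
#' @return Logical vector, `TRUE` = predicted (near-)complete responder.
#' @examples
#' dichotomize("five_point", c(3, 4))  # FALSE TRUE
#' dichotomize("four_point", c(1, 2))  # TRUE FALSE
#' @export
dichotomize <- function(method, value) {
  if (length(method) == 1) method <- rep(method, length(value))
  stopifnot(length(method) == length(value))
  bad <- setdiff(unique(method), SCORE_METHODS)
  if (length(bad) > 0) {
    abort(paste0("unknown scoring method: ", paste(bad, collapse = ", ")))
  }
  ok <- !is.na(value) &
    ((method == "five_point" & value %in% 1:5) |
     (method == "four_point" & value %in% 0:4) |
     (method == "two_point"  & value %in% 0:1))
  if (any(!ok & !is.na(value))) {
    abort("score value outside the method's admissible range")
  }
  dplyr::case_when(
    method == "five_point" ~ value >= 4,
    method == "four_point" ~ value <= 1,
    method == "two_point"  ~ value == 0
  )
}

#' Score a staging-assessment table with all three methods
#'
#' Applies the 5-point, 4-point, and 2-point scoring systems to a
#' structured staging-assessment table (one row per reader-patient
#' assessment, or per patient for single-rater tables) and returns the
#' scores in long format.
#'
#' The 5-point score is derived from the seven staging features via
#' [classify_features()]; the 4-point score from the four "obvious
#' high-risk feature" booleans (`mrf_obvious`, `t_high_risk`,
#' `nodal_obvious`, `emvi_obvious`), which are taken as independently
#' recorded judgements — if absent they are derived from the staging
#' features (`t_high_risk` from T-stage T3c-4, the others from the
#' corresponding feature flags); the 2-point score from T-stage and MRF.
#'
#' @param staging Staging-assessment data frame (see [classify_features()]);
#'   id columns `patient_id` and, if present, `reader_id` are preserved.
#' @return Long tibble with columns `patient_id`, (`reader_id`,) `method`,
#'   `score`.
#' @seealso [check_four_point_consistency()] to audit independently recorded
#'   4-point booleans against the staging features.
#' @export
score_assessments <- function(staging) {
  cls <- classify_features(staging)
  four_cols <- c("mrf_obvious", "t_high_risk", "nodal_obvious", "emvi_obvious")
  if (!all(four_cols %in% names(cls))) {
    cls$mrf_obvious   <- cls$mrf
    cls$t_high_risk   <- cls$t_stage %in% c("t3c", "t3d", "t4")
    cls$nodal_obvious <- cls$n_stage %in% c("n1", "n2")
    cls$emvi_obvious  <- cls$emvi
  }
  ids <- intersect(c("patient_id", "reader_id"), names(cls))
  if (!"patient_id" %in% ids) abort("staging table needs a patient_id column")
  scored <- dplyr::mutate(
    cls,
    five_point = five_point_score(.data$n_high, .data$n_low),
    four_point = four_point_score(.data$mrf_obvious, .data$t_high_risk,
                                  .data$nodal_obvious, .data$emvi_obvious),
    two_point  = two_point_score(.data$t_stage, .data$mrf)
  )
  tidyr::pivot_longer(
    dplyr::select(scored, dplyr::all_of(c(ids, SCORE_METHODS))),
    cols = dplyr::all_of(SCORE_METHODS),
    names_to = "method", values_to = "score"
  )
}

#' Audit 4-point feature booleans against the staging features
#'
#' The four 4-point booleans are recorded independently of the structured
#' staging features, so a reader may e.g. stage a tumor T3c yet not mark
#' `t_high_risk` as obvious. This utility flags such inconsistencies
#' without enforcing anything.
#'
#' @param staging Staging table carrying both the seven staging features and
#'   the four 4-point booleans.
#' @return Tibble of rows with at least one inconsistency, with logical
#'   columns `consistent_<feature>`.
#' @export
check_four_point_consistency <- function(staging) {
  staging <- validate_staging(staging)
  four_cols <- c("mrf_obvious", "t_high_risk", "nodal_obvious", "emvi_obvious")
  missing <- setdiff(four_cols, names(staging))
  if (length(missing) > 0) {
    abort(paste0("missing 4-point columns: ", paste(missing, collapse = ", ")))
  }
  out <- dplyr::mutate(
    tibble::as_tibble(staging),
    consistent_mrf   = .data$mrf_obvious == .data$mrf,
    consistent_t     = .data$t_high_risk ==
      (.data$t_stage %in% c("t3c", "t3d", "t4")),
    consistent_nodal = .data$nodal_obvious == (.data$n_stage %in% c("n1", "n2")),
    consistent_emvi  = .data$emvi_obvious == .data$emvi
  )
  dplyr::filter(out, !(.data$consistent_mrf & .data$consistent_t &
                         .data$consistent_nodal & .data$consistent_emvi))
}
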