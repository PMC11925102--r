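#' Aggregate an ordinal behavioral test score
#'
#' Ledge-walking and hindlimb-clasping tests are scored 0-3 on each of three
#' trials; the reported score for a time point is the arithmetic mean of the
#' three trials (non-integer means are expected).
#'
#' @param trial_scores Integer vector of exactly 3 scores, each in 0..3.
#' @return Mean score in `[0, 3]`.
#' @examples
#' aggregate_score(c(1, 2, 3))
#' @export
aggregate_score <- function(trial_scores) {
  .assert(length(trial_scores) == 3, "exactly 3 trial scores required")
  .assert(all(trial_scores %in% 0:3), "trial scores must be integers in 0..3")
  mean(trial_scores)
}

#' Aggregate a sheet of behavioral scores
#'
#' @param sheet A data frame with columns `mouse`, `test`, `timepoint`,
#'   `trial` (1..3) and `score`.
#' @return A tibble with one row per (`mouse`, `test`, `timepoint`) and the
#'   mean `score`.
#' @export
aggregate_score_sheet <- function(sheet) {
  need <- c("mouse", "test", "timepoint", "trial", "score")
  .assert(all(need %in% names(sheet)),
          paste0("sheet missing column(s): ",
                 paste(setdiff(need, names(sheet)), collapse = ", ")))
  dplyr::summarise(
    dplyr::group_by(sheet, .data$mouse, .data$test, .data$timepoint),
    score = aggregate_score(.data$score),
    .groups = "drop"
  )
}

#' Novel-object-recognition discrimination score
#'
#' `(t_novel - t_familiar) / (t_novel + t_familiar)`: +1 means exclusive
#' exploration of the novel object, 0 equal time on both, -1 exclusive
#' exploration of the familiar one. Zero total exploration is undefined and
#' returns `NA` with a warning.
#'
#' @param t_novel Seconds exploring the novel object (>= 0).
#' @param t_familiar Seconds exploring the familiar object (>= 0).
#' @return Score(s) in `[-1, 1]` (vectorized).
#' @examples
#' nor_discrimination(60, 40)
#' @export
nor_discrimination <- function(t_novel, t_familiar) {
  .assert(all(t_novel >= 0) && all(t_familiar >= 0),
          "exploration times must be >= 0")
  total <- t_novel + t_familiar
  if (any(total == 0)) {
    rlang::warn("zero total exploration time: discrimination undefined (NA)")
  }
  ifelse(total > 0, (t_novel - t_familiar) / total, NA_real_)
}

#' Total-protein (Ponceau) normalization of immunoblot lanes
#'
#' Per-blot normalization by the printed rule: the lane normalization
#' factor is each lane's total-protein optical density divided by the
#' highest total-protein density on the blot (so the densest lane has
#' factor 1), and the normalized signal is the observed target signal
#' divided by that factor. Invariant to a global rescaling of the
#' total-protein densities.
#'
#' @param lanes A data frame with columns `target_signal` (>= 0) and
#'   `total_protein` (> 0); other columns (lane/animal/group ids) pass
#'   through.
#' @return `lanes` with `norm_factor` and `normalized_signal` appended.
#' @examples
#' ponceau_normalize(tibble::tibble(lane = 1:2,
#'                                  target_signal = c(50, 30),
#'                                  total_protein = c(200, 100)))
#' @export
ponceau_normalize <- function(lanes) {
  .assert(all(c("target_signal", "total_protein") %in% names(lanes)),
          "`lanes` needs columns target_signal and total_protein")
  .assert(nrow(lanes) >= 1, "at least one lane required")
  .assert(all(lanes$total_protein > 0), "total_protein must be > 0")
  .assert(all(lanes$target_signal >= 0), "target_signal must be >= 0")
  factor <- lanes$total_protein / max(lanes$total_protein)
  lanes$norm_factor <- factor
  lanes$normalized_signal <- lanes$target_signal / factor
  lanes
}
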