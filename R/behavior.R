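#' Normalized duration bias
#'
#' For each trial k of duration category t, the bias is the relative
#' deviation of the trial's value (a human report or a model-predicted
#' duration) from the subject's mean value over that category:
#' \deqn{bias_{tk} = (x_{tk} - \bar x_t) / \bar x_t}
#' Positive bias means overestimation relative to the subject's own
#' average for that category. Biases therefore sum to zero within each
#' (subject, category) group and are invariant to rescaling a subject's
#' values by a positive constant.
#'
#' @param records Data frame with columns `subject`, `trial`,
#'   `duration_category_s`, `scene`, `value_s` (report or prediction,
#'   seconds).
#' @return A `bias_table` data frame: the input plus `category_mean_s`
#'   (the subject's mean value for the category) and `bias`.
#' @export
normalized_bias <- function(records) {
  assert_columns(records, c("subject", "trial", "duration_category_s",
                            "scene", "value_s"), "records")
  if (nrow(records) == 0) stop_("records is empty")
  grp <- interaction(records$subject, records$duration_category_s, drop = TRUE)
  means <- ave(records$value_s, grp)
  zero <- abs(means) < .Machine$double.eps
  if (any(zero)) {
    bad <- unique(records[zero, c("subject", "duration_category_s")])
    stop_("zero category mean for (subject, category): %s",
          paste(sprintf("(%s, %g s)", bad$subject, bad$duration_category_s),
                collapse = ", "))
  }
  out <- records
  out$category_mean_s <- means
  out$bias <- (records$value_s - means) / means
  class(out) <- c("bias_table", "data.frame")
  out
}

#' Scene-wise summary of normalized bias
#'
#' Averages bias within subject and scene first, then across subjects,
#' reporting the standard error of the mean (SEM) across subjects.
#'
#' @param table A `bias_table` from [normalized_bias()].
#' @return Data frame with one row per scene: `scene`, `mean_bias`
#'   (across-subject mean of subject means), `sem` (across-subject
#'   SD / sqrt(n)), `n_subjects`.
#' @export
mean_bias_by_scene <- function(table) {
  assert_columns(table, c("subject", "scene", "bias"), "bias table")
  if (nrow(table) == 0) stop_("bias table is empty")
  scenes <- sort(unique(table$scene))
  if (length(scenes) < 2)
    stop_("both scenes must be present; found only: %s",
          paste(scenes, collapse = ", "))
  out <- lapply(scenes, function(sc) {
    sub <- table[table$scene == sc, ]
    if (nrow(sub) == 0) stop_("scene '%s' has no trials", sc)
    per_subject <- tapply(sub$bias, sub$subject, mean)
    per_subject <- per_subject[!is.na(per_subject)]
    n <- length(per_subject)
    data.frame(scene = sc, mean_bias = mean(per_subject),
               sem = if (n > 1) sd(per_subject) / sqrt(n) else 0,
               n_subjects = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# bias table from a cohort's behavioral reports
#' Normalized bias of the human reports in a cohort
#'
#' Convenience wrapper applying [normalized_bias()] to a cohort's
#' behavioral table, with the true video duration as the category.
#'
#' @param cohort A `bold_cohort`.
#' @return A `bias_table`.
#' @export
human_bias <- function(cohort) {
  b <- cohort$behavior
  normalized_bias(data.frame(subject = b$subject, trial = b$trial,
                             duration_category_s = b$duration_s,
                             scene = b$scene, value_s = b$report_s,
                             stringsAsFactors = FALSE))
}
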