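#' Half-away-from-zero rounding for reports
#'
#' Clinical tables are reported either as integers or at one decimal
#' place, always rounding halves away from zero (so 6.666... -> 6.7 and
#' -7.95 -> -8 in integer mode); R's default banker's rounding would not
#' reproduce that convention.
#'
#' @param value Finite numeric value(s).
#' @param mode `"integer"` or `"one_decimal"`.
#' @return Rounded value(s).
#' @export
round_for_report <- function(value, mode = c("integer", "one_decimal")) {
  mode <- match.arg(mode)
  f <- if (mode == "integer") 1 else 10
  sign(value) * floor(abs(value) * f + 0.5) / f
}

#' Compare a subject's joint kinematics to a reference
#'
#' Two sign conventions coexist in clinical comparison tables and both are
#' preserved, labelled on the record, rather than unified:
#' * `range_diff` = demo ROM - subject ROM (a positive value means the
#'   subject moved through less range than the demonstration);
#' * `max_diff` / `min_diff` = user - ideal for the extreme angles (a
#'   positive `max_diff` means the user overshot the ideal peak).
#'
#' @param user,ideal `kinematic_summary` objects (or lists with `rom`,
#'   `theta_max`, `theta_min` in degrees).
#' @param joint Joint name for the feedback message.
#' @param tolerance Deviation (degrees) under which no feedback is raised.
#' @return A `joint_comparison` with the diffs, conventions, and
#'   `feedback_text`.
#' @export
compare_joint <- function(user, ideal, joint, tolerance = 5) {
  cmp <- structure(list(
    joint = joint,
    range_diff = ideal$rom - user$rom,
    max_diff = user$theta_max - ideal$theta_max,
    min_diff = user$theta_min - ideal$theta_min,
    conventions = c(range_diff = "demo - subject", max_diff = "user - ideal",
                    min_diff = "user - ideal"),
    tolerance = tolerance
  ), class = "joint_comparison")
  cmp$feedback_text <- feedback_text(cmp, tolerance)
  cmp
}

#' @export
print.joint_comparison <- function(x, ...) {
  cat(sprintf("<joint_comparison> %s: range diff %+.2f, max diff %+.2f, min diff %+.2f\n  %s\n",
              x$joint, x$range_diff, x$max_diff, x$min_diff, x$feedback_text))
  invisible(x)
}

#' Clinician-style feedback message for a joint comparison
#'
#' Template family: deviations within tolerance (boundary inclusive) give
#' "No significant deviation"; a subject peak exceeding the demo peak by
#' more than the tolerance gives "<joint> extending X deg more than demo";
#' a range shortfall beyond tolerance gives "<joint> flexing X deg less
#' than demo". Degrees are rounded to the nearest integer for the message.
#'
#' @param comparison A `joint_comparison`.
#' @param tolerance Degrees; boundary inclusive.
#' @return A single message string.
#' @export
feedback_text <- function(comparison, tolerance = 5) {
  label <- gsub("_", " ", comparison$joint)
  over <- comparison$max_diff          # user peak beyond ideal peak
  short <- comparison$range_diff       # range shortfall vs demo
  if (over > tolerance) {
    sprintf("%s extending %d° more than demo", label,
            round_for_report(over, "integer"))
  } else if (short > tolerance) {
    sprintf("%s flexing %d° less than demo", label,
            round_for_report(short, "integer"))
  } else {
    "No significant deviation"
  }
}

#' Relative ROM deviation from a clinician measurement
#'
#' `|automated - clinician| / clinician * 100`, rounded to one decimal
#' place for reporting.
#'
#' @param automated Automated ROM in degrees.
#' @param clinician Clinician (goniometric) ROM in degrees, `> 0`.
#' @return Deviation percentage (1 d.p.).
#' @export
rom_deviation_percent <- function(automated, clinician) {
  if (clinician <= 0) stop("clinician ROM must be positive")
  round_for_report(abs(automated - clinician) / clinician * 100, "one_decimal")
}

#' Build a feedback report across joints
#'
#' @param comparisons List of `joint_comparison` objects.
#' @param rounding `"integer"` or `"one_decimal"` for the tabulated diffs.
#' @return A `feedback_report` with a `table` data frame and the messages.
#' @export
feedback_report <- function(comparisons, rounding = c("integer", "one_decimal")) {
  rounding <- match.arg(rounding)
  tab <- do.call(rbind, lapply(comparisons, function(cj) {
    data.frame(joint = cj$joint,
               range_diff = round_for_report(cj$range_diff, rounding),
               max_diff = round_for_report(cj$max_diff, rounding),
               min_diff = round_for_report(cj$min_diff, rounding),
               feedback = cj$feedback_text,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, rounding = rounding), class = "feedback_report")
}

#' @export
print.feedback_report <- function(x, ...) {
  cat(sprintf("<feedback_report> (%s rounding)\n", x$rounding))
  print(x$table)
  invisible(x)
}
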