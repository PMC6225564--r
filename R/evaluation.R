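## Landmark-based accuracy evaluation: target registration error is the 3D
## Euclidean distance between each transformed CBCT landmark and its CT
## counterpart, summarised the way clinical registration studies report it
## (median with range, fractions below 3/5/10 mm, cumulative curve,
## per-case means).

#' Read landmarks from a plain-text file
#'
#' Format: one landmark per line, `label x y z` with coordinates in mm;
#' blank lines and lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return A data frame with columns `label, x, y, z`.
#' @export
read_landmarks <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(data.frame(label = character(), x = numeric(), y = numeric(),
                      z = numeric()))
  parts <- strsplit(lines, "\\s+")
  bad <- vapply(parts, length, 1L) != 4L
  if (any(bad))
    stop("malformed landmark line(s): ", paste(lines[bad], collapse = "; "))
  data.frame(label = vapply(parts, `[`, "", 1L),
             x = as.numeric(vapply(parts, `[`, "", 2L)),
             y = as.numeric(vapply(parts, `[`, "", 3L)),
             z = as.numeric(vapply(parts, `[`, "", 4L)))
}

#' Write landmarks to a plain-text file
#' @param landmarks data frame with columns `label, x, y, z` (mm).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_landmarks <- function(landmarks, path) {
  writeLines(c("# label x y z (mm)",
               sprintf("%s %.17g %.17g %.17g", landmarks$label,
                       landmarks$x, landmarks$y, landmarks$z)), path)
  invisible(path)
}

#' Landmark registration errors
#'
#' For each label, the error is the Euclidean distance in mm between the
#' transformed CBCT landmark and the CT landmark with the same label.
#' Matching is label-keyed, so file ordering is irrelevant.
#'
#' @param landmarks_cbct,landmarks_ct data frames with columns
#'   `label, x, y, z`; the label sets must match one-to-one.
#' @param transform final CBCT-to-CT map (affine, TPS, function, or `NULL`
#'   for identity).
#' @return Named numeric vector of errors (mm), one per label, in the order
#'   of `landmarks_cbct`.
#' @export
landmark_errors <- function(landmarks_cbct, landmarks_ct, transform = NULL) {
  la <- landmarks_cbct$label; lb <- landmarks_ct$label
  if (anyDuplicated(la) || anyDuplicated(lb))
    stop("duplicate landmark labels")
  missing_ct <- setdiff(la, lb)
  missing_cbct <- setdiff(lb, la)
  if (length(missing_ct) || length(missing_cbct))
    stop("landmark label mismatch; unmatched: ",
         paste(c(missing_ct, missing_cbct), collapse = ", "))
  ct <- landmarks_ct[match(la, lb), , drop = FALSE]
  p <- apply_transform(transform, as.matrix(landmarks_cbct[, c("x", "y", "z")]))
  err <- sqrt(rowSums((p - as.matrix(ct[, c("x", "y", "z")]))^2))
  names(err) <- la
  err
}

#' Summarise registration errors
#'
#' Median uses the midpoint-of-the-middle-two convention for even counts;
#' the fractions use strict `<` comparisons at 3, 5 and 10 mm.
#'
#' @param errors non-empty numeric vector of errors (mm).
#' @return A list of class `error_summary`: `errors`, `n`, `median`, `min`,
#'   `max`, `mean`, `sd`, `frac_lt_3`, `frac_lt_5`, `frac_lt_10`.
#' @export
summarize_errors <- function(errors) {
  errors <- as.numeric(errors)
  if (length(errors) == 0L) stop("cannot summarise an empty error list")
  structure(list(
    errors = errors, n = length(errors),
    median = stats::median(errors), min = min(errors), max = max(errors),
    mean = mean(errors), sd = stats::sd(errors),
    frac_lt_3 = mean(errors < 3),
    frac_lt_5 = mean(errors < 5),
    frac_lt_10 = mean(errors < 10)), class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("registration error over %d landmarks (mm):\n", x$n))
  cat(sprintf("  median %.2f (range %.2f-%.2f), mean %.2f (SD %.2f)\n",
              x$median, x$min, x$max, x$mean,
              if (is.na(x$sd)) 0 else x$sd))
  cat(sprintf("  < 3 mm: %.0f%%   < 5 mm: %.0f%%   < 10 mm: %.0f%%\n",
              100 * x$frac_lt_3, 100 * x$frac_lt_5, 100 * x$frac_lt_10))
  invisible(x)
}

#' Empirical cumulative error curve
#'
#' @param errors non-empty numeric vector of errors (mm).
#' @return A list with `thresholds` (sorted unique errors) and `fraction`
#'   (right-continuous empirical CDF reaching 1 at the maximum error).
#' @export
cumulative_curve <- function(errors) {
  errors <- as.numeric(errors)
  if (length(errors) == 0L) stop("cannot build a curve from an empty list")
  thr <- sort(unique(errors))
  list(thresholds = thr, fraction = stats::ecdf(errors)(thr))
}

#' Per-case mean error
#'
#' @param errors_by_case named list mapping case identifier to a non-empty
#'   numeric vector of landmark errors (mm).
#' @return Named numeric vector of per-case arithmetic means.
#' @export
per_case_mean <- function(errors_by_case) {
  stopifnot(is.list(errors_by_case))
  lens <- lengths(errors_by_case)
  if (any(lens == 0L))
    stop("case(s) with no errors: ",
         paste(names(errors_by_case)[lens == 0L], collapse = ", "))
  vapply(errors_by_case, mean, numeric(1))
}

#' Write per-landmark errors as a tidy CSV (`case,label,error_mm`)
#'
#' @param errors_by_case named list of named error vectors (as produced by
#'   [landmark_errors()] per case).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_error_table <- function(errors_by_case, path) {
  rows <- do.call(rbind, lapply(names(errors_by_case), function(cs) {
    e <- errors_by_case[[cs]]
    data.frame(case = cs, label = names(e), error_mm = as.numeric(e))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
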