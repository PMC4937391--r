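#' Landmark set across the three image states
#'
#' Per-landmark coordinates in the pre-retraction image, the model-predicted
#' image, and the measured post-retraction image (all mm, world space).
#'
#' @param id landmark identifiers.
#' @param pre,predicted,measured `n x 3` coordinate matrices (mm); the
#'   latter two may be `NULL` until filled in.
#' @return object of class `landmark_set` (a data.frame).
#' @export
landmark_set <- function(id, pre, predicted = NULL, measured = NULL) {
  pre <- matrix(pre, ncol = 3L)
  n <- length(id)
  stopifnot(nrow(pre) == n)
  df <- data.frame(id = id, pre.x = pre[, 1], pre.y = pre[, 2],
                   pre.z = pre[, 3])
  for (nm in c("predicted", "measured")) {
    m <- get(nm)
    if (!is.null(m)) {
      m <- matrix(m, ncol = 3L)
      stopifnot(nrow(m) == n)
      df[[paste0(nm, ".x")]] <- m[, 1]
      df[[paste0(nm, ".y")]] <- m[, 2]
      df[[paste0(nm, ".z")]] <- m[, 3]
    }
  }
  if (!all(is.finite(as.matrix(df[, -1])))) stop("coordinates must be finite")
  class(df) <- c("landmark_set", "data.frame")
  df
}

lm_coords <- function(lm, state) {
  cols <- paste0(state, c(".x", ".y", ".z"))
  if (!all(cols %in% names(lm)))
    stop("landmark set has no '", state, "' coordinates")
  as.matrix(lm[, cols])
}

check_ids <- function(a, b) {
  if (length(a) != length(b) || !all(a == b))
    stop("landmark ids do not match")
}

#' Forecast error
#'
#' Euclidean distance between each landmark's model-predicted and measured
#' post-retraction position.
#'
#' @param predicted,measured `n x 3` coordinate matrices (mm), or a
#'   [landmark_set()] as the first argument.
#' @param ids optional id vectors checked for agreement.
#' @return per-landmark forecast error, mm.
#' @export
forecast_error <- function(predicted, measured = NULL, ids = NULL) {
  if (inherits(predicted, "landmark_set")) {
    lm <- predicted
    predicted <- lm_coords(lm, "predicted")
    measured <- lm_coords(lm, "measured")
  }
  if (!is.null(ids)) check_ids(ids[[1]], ids[[2]])
  predicted <- matrix(predicted, ncol = 3L)
  measured <- matrix(measured, ncol = 3L)
  stopifnot(nrow(predicted) == nrow(measured))
  sqrt(rowSums((predicted - measured)^2))
}

#' Per-landmark prediction accuracy
#'
#' `100 * (1 - forecast_error / displacement)`, where the displacement in
#' the denominator is the measured displacement `||measured - pre||`
#' (default) or, alternatively, the predicted displacement
#' `||predicted - pre||`. Landmarks whose denominator displacement is (near)
#' zero are flagged `NA` and excluded from means.
#'
#' @param lm a [landmark_set()] with all three states, or `pre` coordinates.
#' @param predicted,measured coordinate matrices when `lm` is a matrix.
#' @param denominator `"measured"` or `"predicted"` displacement.
#' @param min_displacement threshold (mm) below which a landmark is flagged.
#' @return per-landmark accuracy, % (may exceed no bound below, but is
#'   capped at 100 from above only by a perfect prediction; negative values
#'   indicate forecasts worse than predicting no motion).
#' @export
prediction_accuracy <- function(lm, predicted = NULL, measured = NULL,
                                denominator = c("measured", "predicted"),
                                min_displacement = 1e-9) {
  denominator <- match.arg(denominator)
  if (inherits(lm, "landmark_set")) {
    pre <- lm_coords(lm, "pre")
    predicted <- lm_coords(lm, "predicted")
    measured <- lm_coords(lm, "measured")
  } else pre <- matrix(lm, ncol = 3L)
  fe <- forecast_error(predicted, measured)
  disp <- if (denominator == "measured")
    sqrt(rowSums((matrix(measured, ncol = 3) - pre)^2))
  else sqrt(rowSums((matrix(predicted, ncol = 3) - pre)^2))
  acc <- 100 * (1 - fe / disp)
  acc[disp < min_displacement] <- NA_real_
  acc
}

#' Dice similarity coefficient
#'
#' `DSC (%) = 2 |A intersect B| / (|A| + |B|) * 100` between two binary
#' masks on the same grid.
#'
#' @param a,b logical/0-1 arrays (or [vol3d()]s) of identical dimensions.
#' @return DSC in percent.
#' @export
dice_coefficient <- function(a, b) {
  if (inherits(a, "vol3d")) a <- a$data
  if (inherits(b, "vol3d")) b <- b$data
  if (!identical(dim(a), dim(b))) stop("masks must share one grid")
  a <- a > 0; b <- b > 0
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) stop("Dice undefined: both masks are empty")
  200 * sum(a & b) / (na + nb)
}

#' Target registration error
#'
#' Euclidean distance between corresponding landmarks in two aligned
#' images; the per-subject mean quantifies residual navigation misalignment.
#'
#' @param a,b `n x 3` landmark coordinate matrices, mm.
#' @param ids optional list of two id vectors checked for agreement.
#' @return list with `per_landmark` (mm) and `mean` (mm).
#' @export
target_registration_error <- function(a, b, ids = NULL) {
  if (!is.null(ids)) check_ids(ids[[1]], ids[[2]])
  a <- matrix(a, ncol = 3L); b <- matrix(b, ncol = 3L)
  stopifnot(nrow(a) == nrow(b))
  d <- sqrt(rowSums((a - b)^2))
  list(per_landmark = d, mean = mean(d))
}

#' Summary statistics in the report convention
#'
#' Mean, SD, min and max of a metric, optionally per group; values are kept
#' at full precision with a one-decimal rounded copy (half-up) matching the
#' report convention.
#'
#' @param values numeric metric values (NAs dropped with a warning).
#' @param grouping optional factor of the same length.
#' @param sd_type `"sample"` (n-1) or `"population"`.
#' @return data.frame with columns `group`, `n`, `mean`, `sd`, `min`, `max`
#'   and their `.r1` one-decimal copies.
#' @export
summarize_metric <- function(values, grouping = NULL,
                             sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(values) == 0) stop("empty input")
  if (anyNA(values)) {
    warning(sum(is.na(values)), " value(s) excluded (undefined)")
    keep <- !is.na(values)
    values <- values[keep]
    if (!is.null(grouping)) grouping <- grouping[keep]
    if (length(values) == 0) stop("empty input after NA removal")
  }
  if (is.null(grouping)) grouping <- rep("all", length(values))
  sdfun <- function(v) {
    if (length(v) == 1) return(0)
    s <- sd(v)
    if (sd_type == "population") s * sqrt((length(v) - 1) / length(v)) else s
  }
  groups <- split(values, grouping)
  out <- data.frame(group = names(groups),
                    n = vapply(groups, length, integer(1)),
                    mean = vapply(groups, mean, numeric(1)),
                    sd = vapply(groups, sdfun, numeric(1)),
                    min = vapply(groups, min, numeric(1)),
                    max = vapply(groups, max, numeric(1)),
                    row.names = NULL)
  for (col in c("mean", "sd", "min", "max"))
    out[[paste0(col, ".r1")]] <- round_half_up(out[[col]], 1)
  out
}

# round-half-up to d decimals (report convention; R's round() is banker's)
round_half_up <- function(x, d = 1) floor(x * 10^d + 0.5) / 10^d

#' Full metrics report for a landmark set
#'
#' Per-landmark forecast errors and prediction accuracies plus their
#' summaries; optionally Dice overlap between predicted and measured masks
#' and the initial / model-updated TRE.
#'
#' @param lm a [landmark_set()] with pre, predicted and measured states.
#' @param mask_predicted,mask_measured optional binary masks for the DSC.
#' @param denominator passed to [prediction_accuracy()].
#' @return object of class `metrics_report`.
#' @export
metrics_report <- function(lm, mask_predicted = NULL, mask_measured = NULL,
                           denominator = "measured") {
  fe <- forecast_error(lm)
  acc <- prediction_accuracy(lm, denominator = denominator)
  pre <- lm_coords(lm, "pre")
  meas <- lm_coords(lm, "measured")
  pred <- lm_coords(lm, "predicted")
  tre0 <- target_registration_error(meas, pre)
  tre1 <- target_registration_error(meas, pred)
  per_landmark <- data.frame(id = lm$id, forecast_error = fe, accuracy = acc,
                             tre_initial = tre0$per_landmark,
                             tre_updated = tre1$per_landmark)
  rep <- list(per_landmark = per_landmark,
              forecast_error = suppressWarnings(summarize_metric(fe)),
              accuracy = suppressWarnings(summarize_metric(acc)),
              tre_initial = tre0$mean, tre_updated = tre1$mean,
              dsc = if (!is.null(mask_predicted))
                dice_coefficient(mask_predicted, mask_measured) else NA_real_)
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  forecast error: %.1f +/- %.1f mm (max %.1f)\n",
              x$forecast_error$mean, x$forecast_error$sd,
              x$forecast_error$max))
  cat(sprintf("  prediction accuracy: %.1f +/- %.1f %% (min %.1f)\n",
              x$accuracy$mean, x$accuracy$sd, x$accuracy$min))
  cat(sprintf("  TRE initial %.1f mm -> model-updated %.1f mm\n",
              x$tre_initial, x$tre_updated))
  if (!is.na(x$dsc)) cat(sprintf("  DSC %.1f %%\n", x$dsc))
  invisible(x)
}

#' Published seven-subject porcine retraction study summaries
#'
#' Loads the per-subject summary table (forecast error, prediction accuracy,
#' Dice coefficient, initial and model-updated TRE for seven porcine
#' subjects) or the 14-landmark table of subject 1, shipped as plain CSV in
#' `inst/extdata`.
#'
#' @param which `"subjects"` or `"subject1_landmarks"`.
#' @return data.frame.
#' @export
load_study_table <- function(which = c("subjects", "subject1_landmarks")) {
  which <- match.arg(which)
  f <- c(subjects = "swine_subject_summary.csv",
         subject1_landmarks = "swine_subject1_landmarks.csv")[[which]]
  read.csv(system.file("extdata", f, package = "retractsim"))
}
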