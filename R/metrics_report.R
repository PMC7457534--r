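# round half away from zero (printed tables use commercial rounding, which
# base::round's round-half-even would not reproduce, e.g. 1.875 -> 1.9)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Error percentage of an estimate
#'
#' \code{|estimated - measured| / measured * 100}, the relative error of a
#' trait estimate against its direct measurement, rounded half-up to
#' \code{digits} decimals (the reporting convention; pass \code{digits =
#' NULL} for the unrounded value).
#'
#' @param measured direct measurement (> 0).
#' @param estimated model estimate.
#' @param digits decimals to round to (default 1).
#' @return error percentage.
#' @export
error_percentage <- function(measured, estimated, digits = 1) {
  if (any(measured <= 0)) stop("'measured' must be positive")
  e <- abs(estimated - measured) / measured * 100
  if (is.null(digits)) e else round_half_up(e, digits)
}

#' Error percentage over plant height
#'
#' \code{|estimated - measured| / plant_height * 100}: the error normalised
#' by the plant height instead of the trait's own magnitude, which makes
#' errors of differently sized organs comparable.
#'
#' @inheritParams error_percentage
#' @param plant_height plant height (mm, > 0).
#' @return error percentage over plant height.
#' @export
error_over_plant_height <- function(measured, estimated, plant_height,
                                    digits = 1) {
  if (any(plant_height <= 0)) stop("'plant_height' must be positive")
  e <- abs(estimated - measured) / plant_height * 100
  if (is.null(digits)) e else round_half_up(e, digits)
}

#' Leaf inclination error
#'
#' Absolute difference between estimated and measured leaf inclination
#' angles, rounded to whole degrees.
#'
#' @param measured,estimated angles in [0, 90] degrees.
#' @return error in degrees (integer-rounded).
#' @export
inclination_error <- function(measured, estimated) {
  if (any(measured < 0 | measured > 90 | estimated < 0 | estimated > 90))
    stop("angles must be in [0, 90] degrees")
  round_half_up(abs(estimated - measured), 0)
}

#' Build an error table from extracted traits and ground truth
#'
#' One entry per organ and trait: the direct measurement, the estimate, the
#' relative error percentage, the error percentage over plant height and
#' (for inclinations) the degree error. NG organs (missing from the model)
#' propagate as NG entries. Per-trait averages over the non-NG organs are
#' computed both from the unrounded errors and from the printed (rounded)
#' entries; the table keeps full precision internally.
#'
#' @param traits a \code{trait_set} (see \code{\link{extract_traits}}).
#' @param ground_truth a \code{ground_truth}.
#' @param plant_height plant height used as the Eq.-over-height denominator
#'   (mm); defaults to the ground-truth plant height.
#' @param method optional method tag carried into the table.
#' @return an object of class \code{error_table}: \code{entries} (data
#'   frame) and \code{averages}.
#' @export
build_error_table <- function(traits, ground_truth,
                              plant_height = ground_truth$plant_height,
                              method = NA_character_) {
  gt <- ground_truth$organs
  est <- traits$organs
  if (!all(gt$organ %in% est$organ))
    stop("organ ids in ground truth and traits do not match")
  trait_cols <- c(area = "area_cm2", length = "length_mm",
                  width = "width_mm", inclination = "inclination_deg",
                  height = "height_mm")
  rows <- list()
  for (i in seq_len(nrow(gt))) {
    j <- match(gt$organ[i], est$organ)
    for (tr in names(trait_cols)) {
      m <- gt[[trait_cols[[tr]]]][i]
      if (is.na(m)) next
      e <- est[[trait_cols[[tr]]]][j]
      ng <- isTRUE(est$ng[j]) || is.na(e)
      rows[[length(rows) + 1L]] <- data.frame(
        organ = gt$organ[i], type = gt$type[i], trait = tr,
        measured = m,
        estimated = if (ng) NA_real_ else e,
        error_pct = if (ng) NA_real_ else
          error_percentage(m, e, digits = NULL),
        error_over_height_pct = if (ng) NA_real_ else
          error_over_plant_height(m, e, plant_height, digits = NULL),
        error_deg = if (ng || tr != "inclination") NA_real_ else
          inclination_error(m, e),
        ng = ng, stringsAsFactors = FALSE)
    }
  }
  entries <- do.call(rbind, rows)
  avg <- do.call(rbind, lapply(
    split(entries, paste(entries$type, entries$trait)), function(d) {
    ok <- !d$ng
    data.frame(
      type = d$type[1L],
      trait = d$trait[1L],
      n = sum(ok),
      measured_mean = mean(d$measured),
      estimated_mean = if (any(ok)) mean(d$estimated[ok]) else NA_real_,
      error_pct = if (any(ok)) mean(d$error_pct[ok]) else NA_real_,
      error_pct_printed = if (any(ok))
        mean(round_half_up(d$error_pct[ok], 1)) else NA_real_,
      error_over_height_pct = if (any(ok))
        mean(d$error_over_height_pct[ok]) else NA_real_,
      error_over_height_pct_printed = if (any(ok))
        mean(round_half_up(d$error_over_height_pct[ok], 1)) else NA_real_,
      stringsAsFactors = FALSE)
  }))
  rownames(avg) <- NULL
  structure(list(entries = entries, averages = avg,
                 plant_height = plant_height, method = method),
            class = "error_table")
}

#' @export
print.error_table <- function(x, digits = 1, ...) {
  if (!is.na(x$method)) cat("method:", x$method, "\n")
  d <- x$entries
  d$error_pct <- round_half_up(d$error_pct, digits)
  d$error_over_height_pct <- round_half_up(d$error_over_height_pct, digits)
  d$estimated <- round_half_up(d$estimated, digits)
  d$ng <- ifelse(d$ng, "NG", "")
  print(d, row.names = FALSE)
  cat("averages (over non-NG organs):\n")
  a <- x$averages
  a$error_pct <- round_half_up(a$error_pct, digits)
  a$error_over_height_pct <- round_half_up(a$error_over_height_pct, digits)
  print(a[, c("trait", "n", "error_pct", "error_over_height_pct")],
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.error_table <- function(x, ...) x$entries
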