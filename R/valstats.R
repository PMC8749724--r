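#' Round half away from zero
#'
#' Reporting convention for all printed percentages and statistics: ordinary
#' half-up rounding (0.005 -> 0.01), unlike base [round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Error odds of a condition
#'
#' The per-condition error measure: unusable episodes per detected breath,
#' expressed as a percentage, `100 * unusable / detected`.
#'
#' @param detected Detected-breathing count (> 0).
#' @param unusable Unusable-data count (>= 0).
#' @return Percentage (not rounded).
#' @export
#' @examples
#' error_odds(86, 14)  # 16.28 %
error_odds <- function(detected, unusable) {
  if (any(detected <= 0)) {
    stop("error odds are undefined when detected = 0", call. = FALSE)
  }
  if (any(unusable < 0)) stop("counts must be non-negative", call. = FALSE)
  100 * unusable / detected
}

check_tally_grid <- function(tallies,
                             angles = c(45, 90, 135),
                             displacements = c(500, 1000, 1500)) {
  need <- c("angle_deg", "displacement_um", "detected_no_ir",
            "unusable_no_ir", "detected_ir", "unusable_ir")
  if (!all(need %in% names(tallies))) {
    stop("tally grid must carry columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  got <- paste(tallies$angle_deg, tallies$displacement_um)
  want <- paste(rep(angles, each = length(displacements)),
                rep(displacements, length(angles)))
  if (nrow(tallies) != length(want) || !setequal(got, want) ||
      anyDuplicated(got)) {
    stop("incomplete condition grid: need every combination of angles (",
         paste(angles, collapse = ", "), ") and displacements (",
         paste(displacements, collapse = ", "), ")", call. = FALSE)
  }
  invisible(tallies)
}

#' Per-displacement summaries of the error odds
#'
#' For each commanded displacement level, the mean and sample standard
#' deviation (n - 1 denominator) of the three per-angle error-odds
#' percentages.
#'
#' @param tallies Condition-tally data frame covering the full 3 x 3 grid.
#' @param with_ir Use the with-IR counts instead of the no-IR counts.
#' @param displacements Displacement levels, in the order to report.
#' @return Data frame with `displacement_um`, `mean_pct`, `sd_pct` (half-up,
#'   2 dp), `n_items`, plus full-precision `mean_pct_raw` and `sd_pct_raw` —
#'   downstream aggregation works on the raw values so the reported overall
#'   figures never inherit intermediate rounding.
#' @export
displacement_summary <- function(tallies, with_ir = FALSE,
                                 displacements = c(500, 1000, 1500)) {
  check_tally_grid(tallies, displacements = displacements)
  det <- if (with_ir) tallies$detected_ir else tallies$detected_no_ir
  uns <- if (with_ir) tallies$unusable_ir else tallies$unusable_no_ir
  odds <- error_odds(det, uns)
  out <- lapply(displacements, function(d) {
    o <- odds[tallies$displacement_um == d]
    data.frame(displacement_um = d,
               mean_pct = round_half_up(mean(o), 2),
               sd_pct = round_half_up(stats::sd(o), 2),
               n_items = length(o),
               mean_pct_raw = mean(o),
               sd_pct_raw = stats::sd(o))
  })
  do.call(rbind, out)
}

#' Overall summary across displacement levels
#'
#' Mean and sample standard deviation of the three displacement-level mean
#' error odds — the headline error figure of a protocol run.
#'
#' @param level_means Exactly three displacement-level means (percent).
#' @return List with `mean_pct`, `sd_pct`, `n_items`, 2 dp.
#' @export
overall_summary <- function(level_means) {
  if (length(level_means) != 3L) {
    stop("expected exactly 3 displacement-level means", call. = FALSE)
  }
  list(mean_pct = round_half_up(mean(level_means), 2),
       sd_pct = round_half_up(stats::sd(level_means), 2),
       n_items = 3L)
}

#' Pool a condition grid into a 2 x 2 contingency table
#'
#' Sums the detected and unusable counts over all nine conditions, for the
#' no-IR and with-IR modes: rows are acquisition mode, columns the detection
#' outcome.
#'
#' @param tallies Condition-tally data frame covering the full grid.
#' @return A 2 x 2 integer matrix, rows `no_ir`/`with_ir`, columns
#'   `detected`/`unusable`.
#' @export
pooled_table <- function(tallies) {
  check_tally_grid(tallies)
  tab <- matrix(c(sum(tallies$detected_no_ir), sum(tallies$unusable_no_ir),
                  sum(tallies$detected_ir), sum(tallies$unusable_ir)),
                nrow = 2, byrow = TRUE,
                dimnames = list(mode = c("no_ir", "with_ir"),
                                outcome = c("detected", "unusable")))
  if (sum(tab) == 0) stop("empty contingency table", call. = FALSE)
  tab
}

#' Pearson chi-square test for a 2 x 2 table
#'
#' Closed-form Pearson statistic without continuity correction,
#' \deqn{\chi^2 = n (ad - bc)^2 / (r_1 r_2 c_1 c_2),}
#' with the p-value from the chi-square distribution on 1 degree of freedom.
#'
#' @param table 2 x 2 matrix of counts (see [pooled_table()]).
#' @return List with `statistic`, `p_value`, `df = 1`, `n`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(812, 88, 864, 36), 2, byrow = TRUE))
chi_square_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0))
  n <- sum(table)
  if (n == 0) stop("empty table", call. = FALSE)
  r <- rowSums(table); cl <- colSums(table)
  if (any(r == 0) || any(cl == 0)) {
    stop("chi-square is undefined with a zero margin", call. = FALSE)
  }
  a <- table[1, 1]; b <- table[1, 2]; cc <- table[2, 1]; d <- table[2, 2]
  stat <- n * (a * d - b * cc)^2 / (r[1] * r[2] * cl[1] * cl[2])
  list(statistic = unname(stat),
       p_value = stats::pchisq(unname(stat), df = 1, lower.tail = FALSE),
       df = 1L, n = n)
}

#' Odds ratio of a 2 x 2 table
#'
#' Ratio of the error odds between the two acquisition modes,
#' `(b/a) / (d/c)` for rows (no-IR, with-IR) and columns (detected,
#' unusable): how many times higher the odds of an unusable episode are
#' without the infrared channel.
#'
#' @param table 2 x 2 matrix of counts.
#' @return The odds ratio (not rounded).
#' @export
odds_ratio_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0))
  a <- table[1, 1]; b <- table[1, 2]; cc <- table[2, 1]; d <- table[2, 2]
  if (a == 0 || d == 0 || cc == 0) {
    stop("odds ratio undefined with a zero reference cell; add an explicit ",
         "continuity constant to the counts if one is wanted", call. = FALSE)
  }
  (b / a) / (d / cc)
}

#' All headline validation statistics of a condition grid
#'
#' Convenience wrapper computing every aggregate the validation layer
#' reports: pooled counts, chi-square and odds ratio, per-displacement error
#' summaries for both modes, and the two overall figures.
#'
#' @param tallies Condition-tally data frame covering the full grid.
#' @return Nested list of statistics (2 dp where rounded).
#' @export
summary_statistics <- function(tallies) {
  check_tally_grid(tallies)
  tab <- pooled_table(tallies)
  chi <- chi_square_2x2(tab)
  lev0 <- displacement_summary(tallies, with_ir = FALSE)
  lev1 <- displacement_summary(tallies, with_ir = TRUE)
  list(
    pooled = tab,
    chi_square = round_half_up(chi$statistic, 2),
    p_value = chi$p_value,
    p_label = if (chi$p_value < 0.001) "< 0.001" else
      sprintf("= %.3f", chi$p_value),
    odds_ratio = tryCatch(round_half_up(odds_ratio_2x2(tab), 2),
                          error = function(e) NA_real_),
    by_displacement_no_ir = lev0,
    by_displacement_ir = lev1,
    overall_no_ir = overall_summary(lev0$mean_pct_raw),
    overall_ir = overall_summary(lev1$mean_pct_raw)
  )
}

#' Compare a candidate grid's statistics against a reference grid
#'
#' Recomputes every headline aggregate from both grids and reports them side
#' by side. For the reference grid the recomputed values are checked at
#' 2-decimal equality against its own aggregates, so a reference compared
#' with itself passes everywhere; a simulated grid is expected to match only
#' qualitatively and the comparison is informative, not a gate.
#'
#' @param tallies Candidate condition-tally grid.
#' @param reference Reference condition-tally grid (e.g.
#'   [load_reference_fixture()]).
#' @return Data frame with `quantity`, `reference`, `candidate`, `pass`
#'   (2-dp equality).
#' @export
validate_against_reference <- function(tallies, reference) {
  sr <- summary_statistics(reference)
  sc <- summary_statistics(tallies)
  flat <- function(s) {
    c(detected_no_ir = unname(s$pooled["no_ir", "detected"]),
      unusable_no_ir = unname(s$pooled["no_ir", "unusable"]),
      detected_with_ir = unname(s$pooled["with_ir", "detected"]),
      unusable_with_ir = unname(s$pooled["with_ir", "unusable"]),
      chi_square = s$chi_square,
      odds_ratio = s$odds_ratio,
      stats::setNames(s$by_displacement_no_ir$mean_pct,
                      paste0("mean_no_ir_", s$by_displacement_no_ir$displacement_um)),
      stats::setNames(s$by_displacement_no_ir$sd_pct,
                      paste0("sd_no_ir_", s$by_displacement_no_ir$displacement_um)),
      stats::setNames(s$by_displacement_ir$mean_pct,
                      paste0("mean_ir_", s$by_displacement_ir$displacement_um)),
      stats::setNames(s$by_displacement_ir$sd_pct,
                      paste0("sd_ir_", s$by_displacement_ir$displacement_um)),
      overall_mean_no_ir = s$overall_no_ir$mean_pct,
      overall_sd_no_ir = s$overall_no_ir$sd_pct,
      overall_mean_ir = s$overall_ir$mean_pct,
      overall_sd_ir = s$overall_ir$sd_pct)
  }
  fr <- flat(sr); fc <- flat(sc)
  data.frame(quantity = names(fr),
             reference = unname(fr),
             candidate = unname(fc[names(fr)]),
             pass = round_half_up(unname(fr), 2) ==
               round_half_up(unname(fc[names(fr)]), 2),
             row.names = NULL)
}
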