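#' Estimation error metrics
#'
#' Errors are `e = est - ref`.  `RMSE = sqrt(mean(e^2))`, `ME = mean(e)`,
#' `STD` = sample SD of `e`, `MAE = mean(|e|)` and `r` = Pearson correlation
#' of estimates against references (`NA` when either series is constant).
#' The algebraic identity `RMSE^2 = ME^2 + STD^2 * (n-1)/n` holds for every
#' report.
#'
#' @param est,ref equal-length numeric vectors (mmHg).
#' @return list with `rmse`, `me`, `std`, `mae`, `r`, `n`.
#' @export
error_metrics <- function(est, ref) {
  if (length(est) != length(ref)) stop_pulsebp("length mismatch")
  n <- length(est)
  if (n < 2) stop_pulsebp("need at least 2 paired values")
  e <- est - ref
  r <- if (stats::sd(est) == 0 || stats::sd(ref) == 0) NA_real_
       else stats::cor(est, ref)
  list(rmse = sqrt(mean(e^2)), me = mean(e), std = stats::sd(e),
       mae = mean(abs(e)), r = r, n = n)
}

#' AAMI compliance check
#'
#' A device passes when |mean error| <= 5 mmHg, error SD <= 8 mmHg, and the
#' evaluation population has at least 35 subjects (the special-population
#' requirement).
#'
#' @param me,std mean error and error SD in mmHg.
#' @param n_subjects evaluation population size.
#' @return list with `me_ok`, `std_ok`, `n_ok`, `pass`.
#' @export
aami_check <- function(me, std, n_subjects) {
  if (std < 0) stop_pulsebp("negative error SD")
  me_ok <- abs(me) <= 5
  std_ok <- std <= 8
  n_ok <- n_subjects >= 35
  list(me_ok = me_ok, std_ok = std_ok, n_ok = n_ok,
       pass = me_ok && std_ok && n_ok)
}

bhs_thresholds <- data.frame(grade = c("A", "B", "C"),
                             cp5 = c(60, 50, 40),
                             cp10 = c(85, 75, 65),
                             cp15 = c(95, 90, 85))

#' BHS cumulative-percentage grading
#'
#' Cumulative percentages of absolute errors within 5, 10 and 15 mmHg
#' (inclusive thresholds); the grade is the best of A/B/C whose three
#' cumulative-percentage thresholds are all met, else D
#' (A: 60/85/95, B: 50/75/90, C: 40/65/85).
#'
#' @param abs_errors non-empty vector of absolute errors (mmHg).
#' @return list with `cp5`, `cp10`, `cp15` (percent) and `grade`.
#' @export
bhs_grade <- function(abs_errors) {
  if (!length(abs_errors)) stop_pulsebp("empty error vector")
  cp <- vapply(c(5, 10, 15),
               function(t) 100 * mean(abs_errors <= t), numeric(1))
  grade <- "D"
  for (g in seq_len(nrow(bhs_thresholds))) {
    th <- bhs_thresholds[g, ]
    if (cp[1] >= th$cp5 && cp[2] >= th$cp10 && cp[3] >= th$cp15) {
      grade <- th$grade
      break
    }
  }
  list(cp5 = cp[1], cp10 = cp[2], cp15 = cp[3], grade = grade)
}

#' Bland-Altman agreement statistics
#'
#' Bias (mean difference) and limits of agreement `ME +/- 1.96 * STD`,
#' with the percentage of points inside the limits.
#'
#' @param est,ref paired series (mmHg).
#' @return list with `bias`, `lower`, `upper`, `pct_within` and logical
#'   `degenerate` (zero error SD: both limits equal the bias).
#' @export
bland_altman <- function(est, ref) {
  m <- error_metrics(est, ref)
  e <- est - ref
  lower <- m$me - 1.96 * m$std
  upper <- m$me + 1.96 * m$std
  list(bias = m$me, lower = lower, upper = upper,
       pct_within = 100 * mean(e >= lower & e <= upper),
       degenerate = m$std == 0)
}

#' Error metrics stratified by beat type
#'
#' @param est,ref paired series (mmHg).
#' @param types rhythm label per beat.
#' @return data frame with one row per beat type plus an `"overall"` row;
#'   strata with fewer than 2 beats report `NA` metrics.
#' @export
evaluate_by_beat_type <- function(est, ref, types) {
  if (length(est) != length(ref) || length(est) != length(types))
    stop_pulsebp("length mismatch")
  one <- function(label, idx) {
    if (length(idx) < 2)
      return(data.frame(beat_type = label, n = length(idx),
                        rmse = NA_real_, me = NA_real_, std = NA_real_,
                        mae = NA_real_, r = NA_real_,
                        stringsAsFactors = FALSE))
    m <- error_metrics(est[idx], ref[idx])
    data.frame(beat_type = label, n = m$n, rmse = m$rmse, me = m$me,
               std = m$std, mae = m$mae, r = m$r, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(unique(types), function(ty)
    one(ty, which(types == ty))))
  out <- rbind(out, one("overall", seq_along(est)))
  rownames(out) <- NULL
  out
}
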