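# Luminescence-assay statistics: AUC responses, the positive-response rule,
# Fisher enrichment and dose-response (Hill) fits.
#
# The positive-response rule is deliberately strict: a row is positive only
# when its mean AUC exceeds the RLU threshold AND its BH-adjusted one-sided
# t-test q-value against the buffer control is below q_max (strict
# inequalities on both). The unit of replication is the independent
# experiment: duplicate wells are averaged per experiment before testing, so
# wells never inflate the degrees of freedom.

#' Area under a baseline-subtracted luminescence curve
#'
#' Baseline is the mean signal before stimulus onset; the AUC is the
#' trapezoidal integral of (signal - baseline) from onset to the last
#' sample. The value is signed (negative areas are not floored).
#'
#' @param time Strictly increasing sample times (seconds).
#' @param signal Luminescence (RLU), same length as `time`.
#' @param onset Stimulus-onset time; must not lie after the last sample.
#' @return AUC in RLU x seconds (conventionally reported as RLU).
#' @export
auc <- function(time, signal, onset = time[1]) {
  stopifnot(length(time) == length(signal), length(time) >= 2,
            all(diff(time) > 0))
  if (onset > time[length(time)]) stop("onset after last sample")
  baseline <- if (any(time < onset)) mean(signal[time < onset]) else 0
  keep <- time >= onset
  t2 <- time[keep]; y2 <- signal[keep] - baseline
  if (!any(time == onset) && any(time < onset)) {     # interpolate at onset
    y0 <- stats::approx(time, signal, xout = onset)$y - baseline
    t2 <- c(onset, t2); y2 <- c(y0, y2)
  }
  if (length(t2) < 2) return(0)
  sum(diff(t2) * (utils::head(y2, -1) + utils::tail(y2, -1)) / 2)
}

#' Call positive responses on an assay table
#'
#' Duplicate wells are averaged per independent experiment; each
#' (receptor pair, ligand) row is tested against that pair's buffer-control
#' experiments with a one-sided Welch t-test (treatment > control); p-values
#' are BH-adjusted across all ligand rows of the same receptor pair; a row is
#' positive iff mean AUC > `threshold` and q < `q_max`. Rows with fewer than
#' two experiments are flagged untestable.
#'
#' @param table Data frame with columns `pair`, `ligand`, `experiment`,
#'   `well`, `auc`, `is_control` (control rows carry the buffer wells).
#' @param threshold RLU threshold (strict).
#' @param q_max FDR threshold (strict).
#' @return Data frame with one row per (pair, ligand): `mean_auc`, `n_exp`,
#'   `p`, `q`, `call` (`"positive"`/`"negative"`/`"untestable"`).
#' @export
call_responders <- function(table, threshold = 10000, q_max = 0.01) {
  need <- c("pair", "ligand", "experiment", "auc", "is_control")
  stopifnot(all(need %in% names(table)))
  # average duplicate wells within experiment
  agg <- stats::aggregate(auc ~ pair + ligand + experiment + is_control,
                          data = table, FUN = mean)
  out <- list()
  for (p in unique(agg$pair)) {
    sub <- agg[agg$pair == p, ]
    ctrl <- sub$auc[sub$is_control]
    rows <- unique(sub$ligand[!sub$is_control])
    res <- data.frame(pair = p, ligand = rows, mean_auc = NA_real_,
                      n_exp = NA_integer_, p = NA_real_, q = NA_real_,
                      call = "untestable")
    for (i in seq_along(rows)) {
      x <- sub$auc[!sub$is_control & sub$ligand == rows[i]]
      res$mean_auc[i] <- mean(x)
      res$n_exp[i] <- length(x)
      if (length(x) >= 2 && length(ctrl) >= 2)
        res$p[i] <- .welch_p_greater(x, ctrl)
    }
    testable <- !is.na(res$p)
    res$q[testable] <- stats::p.adjust(res$p[testable], method = "BH")
    res$call[testable] <- ifelse(res$mean_auc[testable] > threshold &
                                   res$q[testable] < q_max,
                                 "positive", "negative")
    out[[p]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# One-sided Welch t-test p-value, H1: mean(x) > mean(y).
.welch_p_greater <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x) / nx; vy <- stats::var(y) / ny
  se <- sqrt(vx + vy)
  if (se == 0) return(if (mean(x) > mean(y)) 0 else 1)
  tstat <- (mean(x) - mean(y)) / se
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  stats::pt(tstat, df, lower.tail = FALSE)
}

#' One-sided Fisher enrichment (hypergeometric upper tail)
#'
#' Probability of selecting at least `n_selected_in_class` members of a class
#' of size `n_class` when drawing `n_selected` items from `n_total` without
#' replacement.
#'
#' @param n_total Total items.
#' @param n_class Items in the class.
#' @param n_selected Items drawn.
#' @param n_selected_in_class Drawn items that are in the class.
#' @return One-sided p-value, `P[X >= n_selected_in_class]`.
#' @export
fisher_enrichment <- function(n_total, n_class, n_selected, n_selected_in_class) {
  if (n_selected_in_class < 0 || n_class > n_total || n_selected > n_total ||
      n_selected_in_class > min(n_class, n_selected))
    stop("inconsistent margins")
  stats::phyper(n_selected_in_class - 1, n_class, n_total - n_class,
                n_selected, lower.tail = FALSE)
}

#' Fit a Hill dose-response curve
#'
#' Least-squares fit of `R = Rmax * c^h / (EC50^h + c^h)` via
#' [minpack.lm::nlsLM()]. Non-convergence is reported, not raised.
#'
#' @param concentrations Dose values (mM), at least 4 distinct points.
#' @param responses Mean responses (RLU), same length.
#' @param flat_tol Responses whose range is below this value are flagged flat
#'   and returned with `Rmax = 0` without fitting.
#' @return List with `EC50`, `hill`, `Rmax`, `converged`, `flat`, and the
#'   `fit` object (or `NULL`).
#' @export
hill_fit <- function(concentrations, responses, flat_tol = 1e-6) {
  stopifnot(length(concentrations) == length(responses))
  if (length(unique(concentrations)) < 4)
    stop("at least 4 dose points required")
  o <- order(concentrations)
  conc <- concentrations[o]; resp <- responses[o]
  if (diff(range(resp)) < flat_tol)
    return(list(EC50 = NA_real_, hill = NA_real_, Rmax = 0,
                converged = TRUE, flat = TRUE, fit = NULL))
  start <- list(Rmax = max(resp),
                EC50 = stats::median(conc[conc > 0]),
                h = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(resp ~ Rmax * conc^h / (EC50^h + conc^h),
                      start = start,
                      lower = c(Rmax = 0, EC50 = 1e-9, h = 0.05),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(EC50 = NA_real_, hill = NA_real_, Rmax = NA_real_,
                converged = FALSE, flat = FALSE, fit = NULL))
  cf <- stats::coef(fit)
  list(EC50 = unname(cf["EC50"]), hill = unname(cf["h"]),
       Rmax = unname(cf["Rmax"]), converged = TRUE, flat = FALSE, fit = fit)
}
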