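#' Fit a Hill dose-response curve
#'
#' Nonlinear least squares of the four-parameter Hill model on per-dose
#' means (replicates weighted equally),
#' `y = bottom + (top - bottom) * ec50^h / (ec50^h + c^h)` for a decreasing
#' response (the increasing form swaps the asymptote roles). EC50 is fitted
#' on the log scale with multi-start initialization over a grid spanning
#' the observed concentration range; the best converged start by residual
#' sum of squares is returned. The Hill coefficient is free by default and
#' may be fixed (e.g. `fix_hill = 1`).
#'
#' @param concentrations_nM Dose levels (>= 4 distinct).
#' @param values Responses, one per concentration entry (replicates are
#'   averaged per dose before fitting).
#' @param direction `"decreasing"` or `"increasing"`.
#' @param fix_hill Optional fixed Hill coefficient.
#' @param fix_bottom Optional fixed floor asymptote (e.g. 0 when the
#'   saturating response is known to vanish); a free floor is poorly
#'   identified -- and biases the EC50 -- when the EC50 lies near the top
#'   of the tested concentration range.
#' @param n_starts EC50 grid size for multi-start.
#' @param r2_poor Threshold below which the fit is flagged poor.
#' @return Object of class `hill_fit`: `ec50_nM`, `hill_coef`, `top`,
#'   `bottom`, `rss`, `r_squared`, `converged`, `poor_fit`, `se` (named
#'   standard errors), `direction`.
#' @export
fit_hill <- function(concentrations_nM, values,
                     direction = c("decreasing", "increasing"),
                     fix_hill = NULL, fix_bottom = NULL, n_starts = 5,
                     r2_poor = 0.5) {
  direction <- match.arg(direction)
  if (any(!is.finite(values)) || any(!is.finite(concentrations_nM)))
    stop("finite concentrations and values required", call. = FALSE)
  means <- tapply(values, concentrations_nM, mean)
  conc <- as.numeric(names(means))
  y <- as.numeric(means)
  if (length(conc) < 4)
    stop("Hill fitting needs >= 4 distinct concentrations", call. = FALSE)
  cpos <- conc[conc > 0]
  grid <- exp(seq(log(min(cpos)), log(max(cpos)), length.out = n_starts))
  span <- max(y) - min(y)
  if (span <= 0) span <- max(abs(y), 1)
  # top is parameterized as bottom + span with span >= 0, so the fitted
  # curve always has the requested monotone direction
  best <- NULL
  for (e0 in grid) {
    start <- list(span = max(span, 1e-6), lec50 = log(e0))
    lower <- c(span = 0, lec50 = log(min(cpos)) - 7)
    upper <- c(span = Inf, lec50 = log(max(cpos)) + 7)
    if (is.null(fix_bottom)) {
      start$bottom <- max(0, min(y))
      lower <- c(lower, bottom = 0); upper <- c(upper, bottom = Inf)
      bexpr <- quote(bottom)
    } else bexpr <- fix_bottom
    hexpr <- if (is.null(fix_hill)) quote(exp(lh)) else fix_hill
    form <- eval(bquote(
      y ~ hill_response(conc, .(bexpr) + span, .(bexpr), exp(lec50),
                        .(hexpr), direction = direction)))
    environment(form) <- environment()
    if (is.null(fix_hill)) {
      start$lh <- 0
      lower <- c(lower, lh = log(0.2)); upper <- c(upper, lh = log(10))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = list(y = y, conc = conc),
                        start = start, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    out <- list(ec50_nM = NA_real_, hill_coef = NA_real_, top = NA_real_,
                bottom = NA_real_, rss = NA_real_, r_squared = NA_real_,
                converged = FALSE, poor_fit = TRUE, se = NULL,
                direction = direction)
    class(out) <- "hill_fit"
    return(out)
  }
  cf <- coef(best$fit)
  se <- tryCatch(sqrt(diag(vcov(best$fit))), error = function(e) NULL)
  ec50 <- exp(cf[["lec50"]])
  bottom <- if (is.null(fix_bottom)) cf[["bottom"]] else fix_bottom
  se_out <- NULL
  if (!is.null(se)) {
    se_out <- c(span = unname(se["span"]),
                ec50_nM = ec50 * unname(se["lec50"]))  # delta method
    if ("bottom" %in% names(cf)) se_out["bottom"] <- unname(se["bottom"])
    if ("lh" %in% names(cf))
      se_out["hill_coef"] <- exp(cf[["lh"]]) * unname(se["lh"])
  }
  r2 <- 1 - best$rss / sum((y - mean(y))^2)
  out <- list(
    ec50_nM = ec50,
    hill_coef = if (is.null(fix_hill)) exp(cf[["lh"]]) else fix_hill,
    top = bottom + cf[["span"]],
    bottom = bottom,
    rss = best$rss, r_squared = r2,
    converged = TRUE, poor_fit = r2 < r2_poor,
    se = se_out, direction = direction)
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Hill fit: NOT converged\n")
  } else {
    cat(sprintf(
      "Hill fit (%s): EC50 = %.2f nM, h = %.2f, top = %.3g, bottom = %.3g, R^2 = %.3f%s\n",
      x$direction, x$ec50_nM, x$hill_coef, x$top, x$bottom, x$r_squared,
      if (x$poor_fit) " [poor fit]" else ""))
  }
  invisible(x)
}

#' Ratio of two fitted EC50s
#'
#' Relative potency of two dose-response fits (e.g. how much higher one
#' subtype's EC50 is than another's). Reported to two decimals by
#' convention; the exact ratio is returned.
#'
#' @param fit_a,fit_b Converged [fit_hill()] results.
#' @return `fit_a$ec50_nM / fit_b$ec50_nM`.
#' @export
ec50_ratio <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "hill_fit"), inherits(fit_b, "hill_fit"))
  if (!fit_a$converged || !fit_b$converged)
    stop("EC50 ratio requires converged fits", call. = FALSE)
  fit_a$ec50_nM / fit_b$ec50_nM
}

#' Linear fit on the low-concentration range
#'
#' Ordinary least squares on per-dose means restricted to concentrations at
#' or below `upper_nM` (default 500 nM; data above the cutoff are excluded
#' because of offset effects and cannot influence the fit).
#'
#' @param concentrations_nM Dose levels.
#' @param values Responses (replicates averaged per dose).
#' @param upper_nM Inclusive fit-range upper bound.
#' @return Object of class `linear_fit`: `slope_per_nM`, `intercept`,
#'   `r_squared`, `upper_nM`, `n_doses`.
#' @export
fit_linear_low_conc <- function(concentrations_nM, values, upper_nM = 500) {
  means <- tapply(values, concentrations_nM, mean)
  conc <- as.numeric(names(means))
  keep <- conc <= upper_nM
  if (sum(keep) < 3)
    stop("linear fit needs >= 3 distinct concentrations <= ", upper_nM,
         " nM", call. = FALSE)
  x <- conc[keep]; y <- as.numeric(means)[keep]
  fit <- lm(y ~ x)
  # summary.lm warns on an exactly collinear (noise-free) fit
  r2 <- if (var(y) > 0)
    suppressWarnings(summary(fit)$r.squared) else NA_real_
  structure(list(slope_per_nM = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, upper_nM = upper_nM,
                 n_doses = sum(keep)),
            class = "linear_fit")
}

#' Run the full dose-response analysis over measured cohorts
#'
#' Assembles per-subtype, per-metric dose series from a long table of
#' measured invasion metrics and applies the model the metric calls for:
#' Hill fits for area and distance metrics (decreasing for invasive
#' metrics, increasing for the normalized non-invasive area), linear
#' low-concentration fits for roots and tips. Failures of individual fits
#' are recorded without aborting the others. Zero-concentration-only input
#' yields baselines and no fits.
#'
#' @param data Long data.frame with columns `subtype`, `concentration_nM`,
#'   `metric`, `value`.
#' @param hill_metrics Metrics fitted with the Hill model.
#' @param linear_metrics Metrics fitted linearly below the cutoff.
#' @param upper_nM Linear-fit cutoff.
#' @param ... Further arguments to [fit_hill()] (e.g. `fix_hill`,
#'   `fix_bottom`).
#' @return List with `fits` (nested list by subtype then metric), and
#'   `table` (one row per subtype x metric with fit type, parameters, and
#'   status).
#' @export
dose_response_pipeline <- function(data,
                                   hill_metrics = c("invasive_area_um2",
                                                    "max_invasive_distance_um",
                                                    "noninvasive_area_norm"),
                                   linear_metrics = c("roots", "tips"),
                                   upper_nM = 500, ...) {
  need <- c("subtype", "concentration_nM", "metric", "value")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  fits <- list(); rows <- list()
  for (st in unique(data$subtype)) {
    for (me in unique(data$metric)) {
      d <- data[data$subtype == st & data$metric == me, ]
      if (!nrow(d)) next
      base <- mean(d$value[d$concentration_nM == min(d$concentration_nM)])
      n_doses <- length(unique(d$concentration_nM))
      entry <- list(baseline = base, fit = NULL, error = NULL)
      kind <- NA_character_; ec50 <- NA_real_; slope <- NA_real_
      status <- "baseline-only"
      if (n_doses >= 2) {
        if (me %in% hill_metrics) {
          kind <- "hill"
          dirn <- if (me == "noninvasive_area_norm") "increasing"
          else "decreasing"
          res <- tryCatch(
            fit_hill(d$concentration_nM, d$value, direction = dirn, ...),
            error = function(e) e)
          if (inherits(res, "error")) {
            entry$error <- conditionMessage(res); status <- "failed"
          } else {
            entry$fit <- res
            ec50 <- res$ec50_nM
            status <- if (res$converged) "ok" else "not converged"
          }
        } else if (me %in% linear_metrics) {
          kind <- "linear"
          res <- tryCatch(
            fit_linear_low_conc(d$concentration_nM, d$value, upper_nM),
            error = function(e) e)
          if (inherits(res, "error")) {
            entry$error <- conditionMessage(res); status <- "failed"
          } else {
            entry$fit <- res; slope <- res$slope_per_nM; status <- "ok"
          }
        }
      }
      fits[[st]][[me]] <- entry
      rows[[length(rows) + 1L]] <- data.frame(
        subtype = st, metric = me, model = kind, baseline = base,
        ec50_nM = ec50, slope_per_nM = slope, status = status,
        stringsAsFactors = FALSE)
    }
  }
  list(fits = fits, table = do.call(rbind, rows))
}
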