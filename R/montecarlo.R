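#' Run the Monte Carlo estimation study
#'
#' Repeats draw -> sample-truth -> fit cycles: each repetition draws a
#' fresh hierarchical sample from the model under its own stored seed,
#' computes the true sample effects by potential-outcome replay, and fits
#' every estimand in the roster. Repetitions are mutually independent (a
#' per-repetition seed stream is derived once from the master seed), so
#' execution order cannot affect results and any single repetition can be
#' reproduced in isolation. Repetitions whose sample is degenerate (e.g.
#' a constant treatment among selected organizations) are recorded as
#' failures and excluded from summaries, never resampled; more than 1% of
#' failures aborts the run as a model misconfiguration signal.
#'
#' @param model a [juncture_model()]; its identification claims are
#'   certified with [validate_claims()] before any simulation.
#' @param reps number of repetitions (>= 2).
#' @param seed master seed.
#' @param roster list of `estimand_spec`s; defaults to
#'   [cbt_estimand_roster()].
#' @param hierarchy optional hierarchy override passed to every draw.
#' @param progress_every print progress to stderr every this many
#'   repetitions; 0 silences it.
#' @param max_failure_rate abort when more than this fraction of
#'   repetitions fails (default 1%, a misconfiguration signal at the
#'   default hierarchy; deliberately tiny designs, where degenerate
#'   samples are an expected feature, may raise it).
#' @return An object of class `mc_result`: list with `records` (one row
#'   per repetition x estimand x specification: `rep`, `seed`, `estimand`,
#'   `specification`, `estimate`, `se`, `n_used`, `truth`, `rel_bias`),
#'   `failures` (data frame of failed repetitions and reasons), `reps`,
#'   `master_seed`.
#' @export
run_mc <- function(model, reps = 1000, seed = 1, roster = NULL,
                   hierarchy = NULL, progress_every = 0,
                   max_failure_rate = 0.01) {
  stopifnot(inherits(model, "juncture_model"))
  reps <- as.integer(reps)
  if (reps < 2L) stop_input("reps must be at least 2")
  claims <- validate_claims(model)
  if (!all(claims$pass)) {
    stop_structural("model fails identification claim(s): ",
                    paste(claims$claim[!claims$pass], collapse = ", "))
  }
  if (is.null(roster)) roster <- cbt_estimand_roster(model)

  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)

  rows <- vector("list", reps)
  failures <- list()
  for (r in seq_len(reps)) {
    res <- tryCatch({
      cfg <- population_config(
        organizations = hierarchy[["organizations"]],
        practitioners_per_organization =
          hierarchy[["practitioners_per_organization"]],
        patients_per_practitioner = hierarchy[["patients_per_practitioner"]],
        seed = rep_seeds[r])
      data <- draw_population(model, cfg)
      truths <- true_sample_effects(model, data)
      ests <- lapply(roster, fit_effect, data = data)
      data.frame(
        rep = r, seed = rep_seeds[r],
        estimand = vapply(ests, `[[`, character(1), "estimand"),
        specification = vapply(ests, `[[`, character(1), "specification"),
        estimate = vapply(ests, `[[`, numeric(1), "estimate"),
        se = vapply(ests, `[[`, numeric(1), "se"),
        n_used = vapply(ests, `[[`, integer(1), "n_used"),
        truth = unname(truths[vapply(ests, `[[`, character(1), "estimand")]),
        row.names = NULL)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(rep = r, seed = rep_seeds[r], reason = conditionMessage(res))
    } else {
      rows[[r]] <- res
    }
    if (progress_every > 0 && r %% progress_every == 0) {
      message("repetition ", r, "/", reps)
    }
  }
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(rep = integer(), seed = integer(), reason = character())
  if (nrow(failures) > max_failure_rate * reps) {
    stop_structural(nrow(failures), " of ", reps, " repetitions failed (> ",
                    100 * max_failure_rate, "%): likely model or coefficient ",
                    "misconfiguration. First reason: ", failures$reason[1L])
  }
  records <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  records$rel_bias <- (records$estimate - records$truth) / records$truth
  structure(
    list(records = records, failures = failures, reps = reps,
         master_seed = as.integer(seed)),
    class = "mc_result"
  )
}

#' @export
print.mc_result <- function(x, ...) {
  cat("Monte Carlo study: ", x$reps, " repetitions (",
      nrow(x$failures), " failed), ",
      length(unique(paste(x$records$estimand, x$records$specification))),
      " estimand x specification pairs\n", sep = "")
  invisible(x)
}

#' Summarise a Monte Carlo study into relative-bias statistics
#'
#' For each (estimand, specification): the mean relative bias over
#' repetitions (`(estimate_r - truth_r) / truth_r`, averaged), the
#' empirical standard error of the relative bias (its standard deviation
#' across repetitions), and a 95% confidence interval for the mean,
#' `mean +/- 1.96 * empirical SE / sqrt(R)`. A secondary `rel_bias_rom`
#' column reports the ratio-of-means alternative,
#' `mean(estimate)/mean(truth) - 1`. Any repetition with a zero truth
#' makes relative bias undefined and raises an error suggesting a
#' coefficient change.
#'
#' @param object an `mc_result` (or its `records` data frame via
#'   [summarize_mc()]).
#' @param ... ignored.
#' @return An object of class `mc_summary`: a data frame with one row per
#'   (estimand, specification) and columns `estimand`, `specification`,
#'   `mean_rel_bias`, `emp_se`, `ci_lower`, `ci_upper`, `rel_bias_rom`,
#'   `emp_se_estimate`, `reps_used`; attributes `max_abs_mean_rel_bias`
#'   and `n_ci_excluding_zero`.
#' @export
summary.mc_result <- function(object, ...) {
  summarize_mc(object$records)
}

#' @rdname summary.mc_result
#' @param records a records data frame as produced by [run_mc()] (e.g.
#'   re-read from the CSV written by [write_estimates()]).
#' @export
summarize_mc <- function(records) {
  need <- c("estimand", "specification", "estimate", "truth")
  if (!all(need %in% names(records))) {
    stop_input("records must have columns: ", paste(need, collapse = ", "))
  }
  if (!nrow(records)) stop_input("no repetitions to summarise")
  if (any(records$truth == 0)) {
    stop_input("relative bias undefined: some repetitions have a zero true ",
               "effect; change the model coefficients")
  }
  if (is.null(records$rel_bias)) {
    records$rel_bias <- (records$estimate - records$truth) / records$truth
  }
  key <- interaction(records$estimand, records$specification, drop = TRUE)
  if (min(table(key)) < 2L) stop_input("need at least 2 repetitions per estimand")
  agg <- lapply(split(records, key), function(g) {
    m <- mean(g$rel_bias)
    s <- stats::sd(g$rel_bias)
    R <- nrow(g)
    data.frame(
      estimand = g$estimand[1L], specification = g$specification[1L],
      mean_rel_bias = m, emp_se = s,
      ci_lower = m - 1.96 * s / sqrt(R),
      ci_upper = m + 1.96 * s / sqrt(R),
      rel_bias_rom = mean(g$estimate) / mean(g$truth) - 1,
      emp_se_estimate = stats::sd(g$estimate),
      reps_used = R)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$estimand, out$specification), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "max_abs_mean_rel_bias") <- max(abs(out$mean_rel_bias))
  attr(out, "n_ci_excluding_zero") <- sum(out$ci_lower > 0 | out$ci_upper < 0)
  class(out) <- c("mc_summary", "data.frame")
  out
}

#' @export
print.mc_summary <- function(x, ...) {
  cat("Relative effect bias over", max(x$reps_used), "repetitions\n")
  df <- data.frame(
    parameter = estimand_label(x$estimand, x$specification),
    `mean rel. bias` = sprintf("%+.4f%%", 100 * x$mean_rel_bias),
    `95% CI` = sprintf("[%+.4f%%, %+.4f%%]",
                       100 * x$ci_lower, 100 * x$ci_upper),
    `emp. SE` = sprintf("%.4f", x$emp_se),
    check.names = FALSE)
  print(df, row.names = FALSE)
  cat(sprintf("max |mean relative bias|: %.4f%%; CIs excluding zero: %d/%d\n",
              100 * attr(x, "max_abs_mean_rel_bias"),
              attr(x, "n_ci_excluding_zero"), nrow(x)))
  invisible(x)
}

estimand_label <- function(estimand, specification) {
  lab <- sub("^(ate|ame)_([^_]+)_([^_]+)$", "\\2->\\3", estimand)
  ifelse(specification == "full", paste0(lab, " (full)"),
         ifelse(specification == "short" &
                  estimand %in% c("ate_D2_X4", "ate_D2_X5"),
                lab, paste0(lab, " (short)")))
}

#' Export per-repetition estimates as tidy CSV
#'
#' One row per repetition x estimand x specification with columns
#' `rep`, `seed`, `estimand`, `specification`, `estimate`, `se`,
#' `n_used`, `truth`, `rel_bias`. Summaries are recomputable from this
#' file alone via [summarize_mc()].
#'
#' @param result an `mc_result`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(result, path) {
  stopifnot(inherits(result, "mc_result"))
  utils::write.csv(result$records, path, row.names = FALSE)
  invisible(path)
}

#' Render the relative-bias figure
#'
#' One point with its 95% confidence interval per (estimand,
#' specification), in the style of a Monte Carlo bias plot: abscissa
#' labels name the effect direction (e.g. `D2->X4`), the ordinate is mean
#' relative bias with a dashed zero line. The underlying numbers are also
#' written next to the figure as a CSV.
#'
#' @param summary an `mc_summary`.
#' @param path figure file path; `.pdf` or `.png`.
#' @return `path`, invisibly; a sibling `<path>.csv` holds the plotted
#'   numbers.
#' @export
render_bias_figure <- function(summary, path) {
  if (!inherits(summary, "mc_summary") || !nrow(summary)) {
    stop_input("non-empty mc_summary required")
  }
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    grDevices::png(path, width = 1400, height = 800, res = 150)
  } else if (grepl("\\.pdf$", path, ignore.case = TRUE)) {
    grDevices::pdf(path, width = 9, height = 5)
  } else {
    stop_input("unsupported figure extension (use .pdf or .png): ", path)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  plot(summary)
  csv <- paste0(sub("\\.(pdf|png)$", "", path, ignore.case = TRUE), ".csv")
  utils::write.csv(as.data.frame(summary), csv, row.names = FALSE)
  invisible(path)
}

#' @export
#' @rdname render_bias_figure
#' @param x an `mc_summary`.
#' @param ... passed on to [graphics::plot.default()].
plot.mc_summary <- function(x, ...) {
  k <- nrow(x)
  labs <- estimand_label(x$estimand, x$specification)
  ylim <- range(0, x$ci_lower, x$ci_upper)
  op <- graphics::par(mar = c(7, 4.5, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(seq_len(k), x$mean_rel_bias, xlim = c(0.5, k + 0.5),
                 ylim = ylim, pch = 19, xaxt = "n",
                 xlab = "", ylab = "Relative effect bias",
                 main = "Monte Carlo relative bias with 95% CI", ...)
  graphics::axis(1, at = seq_len(k), labels = labs, las = 2, cex.axis = 0.85)
  graphics::segments(seq_len(k), x$ci_lower, seq_len(k), x$ci_upper)
  graphics::abline(h = 0, lty = 2, col = "grey40")
  invisible(x)
}
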