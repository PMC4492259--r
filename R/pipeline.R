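# Orchestration: configuration, dataset generation, the per-cell x
# per-period fitting loop, and the period report.  Plain CSV is the
# canonical interchange format; every table has a header row and
# ISO-8601 dates.

#' Default run configuration
#'
#' @param n_cells,n_years Synthetic panel dimensions.
#' @param seed Master seed for every random stream of the run.
#' @param model Model variant passed to [fit_model()].
#' @param threshold Per-period eligibility threshold (deaths).
#' @param base_rate,true_rm25 Generator parameters (see [make_panel()]).
#' @param adaptation Optional adaptation block (see [make_panel()]).
#' @param periods Period layout (see [period_specs()]); `NULL` derives
#'   equal thirds of the panel span.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(n_cells = 12, n_years = 42, seed = 1,
                       model = "eq1", threshold = 7500, base_rate = 3,
                       true_rm25 = 1.2, adaptation = NULL, periods = NULL) {
  structure(list(n_cells = n_cells, n_years = n_years, seed = seed,
                 model = model, threshold = threshold,
                 base_rate = base_rate, true_rm25 = true_rm25,
                 adaptation = adaptation, periods = periods),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file with any of the [run_config()] fields.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[intersect(names(vals), names(formals(run_config)))])
}

#' Generate a dataset directory
#'
#' Writes `climate.csv` (date, cell_id, tmean, precip, pressure),
#' `deaths.csv` (date, cell_id, deaths), `truth.csv` and `manifest.json`
#' (config, seed and a parameter hash) under `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The `synthetic_panel`, invisibly.
#' @export
run_generate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable")
  syn <- make_panel(config$n_cells, config$n_years, config$seed,
                    base_rate = config$base_rate,
                    true_rm25 = config$true_rm25,
                    adaptation = config$adaptation)
  p <- syn$panel
  write_csv(p[c("date", "cell_id", "tmean", "precip", "pressure")],
            file.path(out_dir, "climate.csv"))
  write_csv(p[c("date", "cell_id", "deaths")],
            file.path(out_dir, "deaths.csv"))
  write_csv(syn$truth, file.path(out_dir, "truth.csv"))
  cfg <- unclass(config)
  manifest <- list(config = cfg, param_hash = config_hash(cfg),
                   created = "generated by mmtgrid::run_generate")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(syn)
}

# md5 of the canonical JSON serialization of the config.
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a dataset directory back into a panel
#' @param dir Directory written by [run_generate()].
#' @return List with `panel` (climate joined with deaths) and `truth`.
#' @export
read_dataset <- function(dir) {
  climate <- read_csv(file.path(dir, "climate.csv"))
  deaths <- read_csv(file.path(dir, "deaths.csv"))
  panel <- merge(climate, deaths, by = c("date", "cell_id"), sort = FALSE)
  panel <- panel[order(panel$cell_id, panel$date), ]
  rownames(panel) <- NULL
  list(panel = panel, truth = read_csv(file.path(dir, "truth.csv")))
}

#' Fit every eligible cell in every period
#'
#' Runs [fit_model()] per (cell, period), keeping cells whose death count
#' strictly exceeds the threshold in every period.  Failures in
#' individual cells are logged and skipped; the run fails only when every
#' cell fails.
#'
#' @param config A [run_config()].
#' @param panel Long panel `data.frame` (as from [make_panel()] or
#'   [read_dataset()]).
#' @param periods Optional [period_specs()] table; defaults to equal
#'   thirds of the panel span.
#' @param verbose Log one line per cell fit.
#' @return `data.frame` of curve-summary rows (one per cell x period),
#'   with the curves attached as attribute `curves` (list keyed by
#'   `cell_id.period_id`).
#' @export
run_fit <- function(config, panel, periods = NULL, verbose = FALSE) {
  periods <- periods %||% config$periods %||% default_periods(panel)
  by_period <- split_periods(panel, periods)
  cells <- unique(panel$cell_id)
  # eligibility must hold in all periods simultaneously
  deaths_by <- vapply(by_period, function(pp)
    as.numeric(tapply(pp$deaths, factor(pp$cell_id, levels = cells), sum)),
    numeric(length(cells)))
  deaths_by <- matrix(deaths_by, nrow = length(cells))
  eligible <- apply(square_eligibility(deaths_by, config$threshold), 1, all)
  if (!any(eligible)) warning("no cell passes the eligibility threshold")
  rows <- list()
  curves <- list()
  n_fail <- 0L
  for (cell in cells[eligible]) {
    for (pid in names(by_period)) {
      dat <- by_period[[pid]]
      dat <- dat[dat$cell_id == cell, , drop = FALSE]
      res <- tryCatch({
        fit <- fit_model(dat, spec = config$model)
        row <- summarize_curve(fit, cell_id = cell, period_id = pid,
                               threshold = config$threshold)
        if (verbose)
          message(sprintf(
            "fit cell=%s period=%s deviance=%.1f edf=%.1f mmt=%.1f lambda=%s",
            cell, pid, fit$deviance, fit$edf, row$mmt,
            paste(signif(fit$lambda, 2), collapse = "/")))
        curves[[paste(cell, pid, sep = ".")]] <- attr(row, "curve")
        row
      }, error = function(e) {
        message("cell ", cell, " period ", pid, " failed: ",
                conditionMessage(e))
        n_fail <<- n_fail + 1L
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0L && sum(eligible) > 0L)
    stop("all cell fits failed")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(0), period_id = character(0))
  attr(out, "curves") <- curves
  attr(out, "periods") <- periods
  out
}

default_periods <- function(panel) {
  dates <- as.Date(panel$date)
  y0 <- as.integer(format(min(dates), "%Y"))
  y1 <- as.integer(format(max(dates), "%Y"))
  span <- y1 - y0 + 1L
  each <- span %/% 3L
  if (each < 1L) stop("panel too short to split into periods")
  period_specs(start_year = y0, n_periods = 3L, years_each = each)
}

#' Produce the period report
#'
#' Writes Table-1-style period summaries, pairwise Wilcoxon shift tests
#' for MMT / RM25 / RM25-18, the spatial MST-MMT regression at the first
#' period, and the predicted-vs-observed MMT change between the first and
#' last periods.
#'
#' @param config A [run_config()].
#' @param summaries Curve-summary table from [run_fit()].
#' @param panel The long panel the summaries came from.
#' @param out_dir Optional directory; when given, `summary.csv`,
#'   `tests.csv` and `regression.csv` are written there.
#' @return List with `summary` (one row per period), `tests` (Wilcoxon
#'   results), `regression` and `mmt_change`.
#' @export
run_report <- function(config, summaries, panel, out_dir = NULL) {
  periods <- attr(summaries, "periods") %||% default_periods(panel)
  pids <- periods$period_id
  if (!all(pids %in% summaries$period_id)) stop("missing periods in summaries")
  by_period <- split_periods(panel, periods)

  # cells U/J-shaped and eligible in every period
  keep <- Reduce(intersect, lapply(pids, function(p) {
    s <- summaries[summaries$period_id == p, ]
    s$cell_id[s$uj_shaped & s$eligible]
  }))
  summ <- lapply(pids, function(p) {
    s <- summaries[summaries$period_id == p & summaries$cell_id %in% keep, ]
    summarize_period(s, by_period[[p]])
  })
  summary_tab <- do.call(rbind, summ)

  tests <- NULL
  if (length(pids) >= 2L && length(keep) >= 5L) {
    get <- function(p, v) {
      s <- summaries[summaries$period_id == p & summaries$cell_id %in% keep, ]
      s[[v]][match(keep, s$cell_id)]
    }
    pairs <- utils::combn(pids, 2L, simplify = FALSE)
    tests <- do.call(rbind, lapply(pairs, function(pr)
      do.call(rbind, lapply(c("mmt", "rm25", "rm25_18"), function(v) {
        w <- wilcoxon_signed_rank(get(pr[1L], v), get(pr[2L], v))
        data.frame(comparison = paste(pr, collapse = "-"), variable = v,
                   W = w$W, n = w$n, p = w$p, method = w$method)
      }))))
  } else if (length(pids) < 2L) {
    message("single period: shift tests skipped")
  }

  first <- pids[1L]; last <- pids[length(pids)]
  s1 <- summaries[summaries$period_id == first & summaries$cell_id %in% keep, ]
  mst1 <- vapply(keep, function(cell) {
    ci <- by_period[[first]]
    ci <- ci[ci$cell_id == cell, ]
    seasonal_means(ci$date, ci$tmean)$mst
  }, numeric(1))
  reg <- spatial_regression(s1$mmt[match(keep, s1$cell_id)], mst1)

  mmt_change <- NULL
  if (length(pids) >= 2L) {
    slast <- summaries[summaries$period_id == last & summaries$cell_id %in% keep, ]
    mst_last <- vapply(keep, function(cell) {
      ci <- by_period[[last]]
      ci <- ci[ci$cell_id == cell, ]
      seasonal_means(ci$date, ci$tmean)$mst
    }, numeric(1))
    delta_mst <- mean(mst_last) - mean(mst1)
    pred <- predicted_mmt_change(reg$slope, reg$ci, delta_mst)
    observed <- mean(slast$mmt[match(keep, slast$cell_id)]) -
      mean(s1$mmt[match(keep, s1$cell_id)])
    mmt_change <- list(delta_mst = delta_mst, predicted = pred$point,
                       predicted_ci = pred$ci, observed = round(observed, 1))
  }

  out <- list(summary = summary_tab, tests = tests, regression = reg,
              mmt_change = mmt_change, cells = keep)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_csv(summary_tab, file.path(out_dir, "summary.csv"))
    if (!is.null(tests)) write_csv(tests, file.path(out_dir, "tests.csv"))
    write_csv(data.frame(slope = reg$slope, ci_low = reg$ci[1L],
                         ci_high = reg$ci[2L], r = reg$r, p = reg$p,
                         n = reg$n),
              file.path(out_dir, "regression.csv"))
  }
  out
}

#' Run generate, fit and report in one call
#' @inheritParams run_generate
#' @param out_dir Directory for all outputs.
#' @param verbose Passed to [run_fit()].
#' @return The [run_report()] result, with the curve summaries attached
#'   as `$summaries`.
#' @export
run_all <- function(config, out_dir, verbose = FALSE) {
  syn <- run_generate(config, out_dir)
  summaries <- run_fit(config, syn$panel, verbose = verbose)
  write_csv(summaries, file.path(out_dir, "curve_summaries.csv"))
  rep <- run_report(config, summaries, syn$panel, out_dir = out_dir)
  rep$summaries <- summaries
  rep
}

#' Plot a fitted temperature-mortality curve
#'
#' Relative-risk view of one curve: `exp(s1(T) - s1(MMT))` against
#' temperature, with the MMT marked.
#'
#' @param curve 301 curve values from [eval_curve()].
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the relative-risk values.
#' @export
plot_curve <- function(curve, main = "Temperature-mortality curve", ...) {
  tg <- curve_grid()
  mmt <- extract_mmt(curve)
  rr <- exp(curve - min(curve))
  graphics::plot(tg, rr, type = "l", xlab = "Daily mean temperature (°C)",
                 ylab = "Relative mortality (vs MMT)", main = main, ...)
  graphics::abline(v = mmt, lty = 2, col = "grey40")
  invisible(rr)
}

write_csv <- function(x, path) {
  x <- as.data.frame(x)
  for (cl in names(x)) if (inherits(x[[cl]], "Date"))
    x[[cl]] <- format(x[[cl]], "%Y-%m-%d")
  utils::write.csv(x, path, row.names = FALSE)
}

read_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("date" %in% names(x)) x$date <- as.Date(x$date)
  x
}
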