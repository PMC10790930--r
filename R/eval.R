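#' Success weighted by path length (SPL)
#'
#' For one episode, `S * l / max(p, l)`: 0 on failure, 1 for a success
#' along a shortest path, discounted by the excess path length otherwise.
#' The set-level SPL is the arithmetic mean over episodes.
#'
#' @param success logical success flag(s).
#' @param shortest shortest path length(s) in cells (>= 1 for feasible
#'   episodes).
#' @param taken executed path length(s), counting every attempted move.
#' @return numeric SPL value(s) in \[0, 1\].
#' @export
spl <- function(success, shortest, taken) {
  if (any(success & taken == 0 & shortest >= 1))
    stop("a successful episode cannot have zero taken path length")
  ifelse(success, shortest / pmax(taken, shortest), 0)
}

#' Aggregate learning curves of one training mode
#'
#' Pointwise bootstrap over runs (whole runs are resampled, matching the
#' several-trained-models design): mean SPL curve with a 95% band, plus
#' the final performance — the mean SPL over the last `final_window`
#' episodes per run, summarized across runs with [bootstrap_mean()]
#' (1,000 iterations by default).
#'
#' @param curves list of `run_curve` objects (equal episode counts, >= 2).
#' @param n_boot bootstrap iterations.
#' @param final_window terminal episodes averaged per run.
#' @param seed integer seed.
#' @param alpha,bonferroni_m interval parameters passed through.
#' @return an object of class `run_aggregate`: `mean_curve`, `band_low`,
#'   `band_high` (per episode), `per_run_final`, `final`
#'   (a [bootstrap_mean()] summary), `n_runs`, `final_window`.
#' @export
aggregate_runs <- function(curves, n_boot = 1000, final_window = 50,
                           seed = 1, alpha = 0.05, bonferroni_m = 1) {
  stopifnot(length(curves) >= 2)
  lens <- vapply(curves, nrow, integer(1))
  if (length(unique(lens)) != 1) stop("curves have mismatched lengths")
  m <- do.call(rbind, lapply(curves, function(c) c$spl))
  n_runs <- nrow(m); n_ep <- ncol(m)
  fw <- min(final_window, n_ep)
  boot <- with_seed(derive_seed(seed, 11), {
    idx <- matrix(sample.int(n_runs, n_boot * n_runs, replace = TRUE),
                  n_boot, n_runs)
    t(apply(idx, 1, function(i) colMeans(m[i, , drop = FALSE])))
  })
  per_run_final <- rowMeans(m[, (n_ep - fw + 1):n_ep, drop = FALSE])
  structure(list(
    mean_curve = colMeans(boot),
    band_low = apply(boot, 2, stats::quantile, alpha / 2),
    band_high = apply(boot, 2, stats::quantile, 1 - alpha / 2),
    per_run_final = per_run_final,
    final = bootstrap_mean(per_run_final, n_boot = n_boot, alpha = alpha,
                           bonferroni_m = bonferroni_m,
                           seed = derive_seed(seed, 12)),
    n_runs = n_runs, final_window = fw), class = "run_aggregate")
}

#' @export
print.run_aggregate <- function(x, ...) {
  cat(sprintf("<run_aggregate: %d runs, final (last %d ep): ", x$n_runs,
              x$final_window))
  print(x$final)
  invisible(x)
}

#' Compare training modes
#'
#' Aggregates each mode's curves and, when a `"sparse"` mode is present,
#' attaches the CI-overlap verdict of every other mode against it.
#'
#' @param mode_curves named list; each element a list of `run_curve`s.
#' @param ... passed to [aggregate_runs()].
#' @return an object of class `comparison_report`.
#' @export
comparison_report <- function(mode_curves, ...) {
  agg <- lapply(mode_curves, aggregate_runs, ...)
  verdicts <- NULL
  if ("sparse" %in% names(agg)) {
    others <- setdiff(names(agg), "sparse")
    verdicts <- vapply(others, function(mode)
      ci_overlap_verdict(agg[[mode]]$final, agg$sparse$final), character(1))
  }
  structure(list(modes = agg, verdicts = verdicts),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  for (nm in names(x$modes)) {
    f <- x$modes[[nm]]$final
    cat(sprintf("  %-12s final SPL %.3f [%.3f, %.3f]\n", nm, f$mean,
                f$ci_low, f$ci_high))
  }
  if (!is.null(x$verdicts))
    for (nm in names(x$verdicts))
      cat(sprintf("  %s vs sparse: %s\n", nm, x$verdicts[nm]))
  invisible(x)
}

#' Serialize / restore a comparison report
#'
#' @param report a [comparison_report()]. @param path JSON file path.
#' @return `write_report` returns `path` invisibly; `read_report` the
#'   restored report (numerically lossless).
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    list(modes = lapply(report$modes, function(a)
      list(mean_curve = a$mean_curve, band_low = a$band_low,
           band_high = a$band_high, per_run_final = a$per_run_final,
           final = unclass(a$final), n_runs = a$n_runs,
           final_window = a$final_window)),
      verdicts = as.list(report$verdicts)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  modes <- lapply(raw$modes, function(a) {
    a$final <- structure(a$final, class = "bootstrap_summary")
    structure(a, class = "run_aggregate")
  })
  verdicts <- unlist(raw$verdicts)
  structure(list(modes = modes, verdicts = verdicts),
            class = "comparison_report")
}

parse_mode <- function(mode) {
  parts <- strsplit(mode, ":", fixed = TRUE)[[1]]
  list(name = parts[1],
       value = if (length(parts) > 1) as.numeric(parts[2]) else NA_real_)
}

#' Run a declarative simulation experiment
#'
#' Executes the full pipeline for a configuration given as a YAML file or
#' a list: builds the world, trains an HF policy per guided mode, trains
#' the DDPG agent for every (mode, seed) pair and writes the comparison
#' report plus per-run curves (CSV) and the echoed configuration to
#' `out_dir`. Supported modes: `sparse`, `hf-oracle`, `hf-noisy:<p>`,
#' `hf-bci-sim:<accuracy>`.
#'
#' @param config path to a YAML file or a named list with fields `world`
#'   (list: `dims`, optional `max_steps`), `modes`, `seeds`, `episodes`,
#'   and optionally `ddpg` (overrides of [ddpg_config()] fields),
#'   `hf_labels`, `final_window`.
#' @param out_dir output directory (created).
#' @return the [comparison_report()], invisibly; artifacts on disk.
#' @export
run_experiment <- function(config, out_dir = tempfile("runs")) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  for (field in c("world", "modes", "seeds", "episodes"))
    if (is.null(config[[field]]))
      stop(sprintf("config field missing: %s", field))
  known <- c("sparse", "hf-oracle", "hf-noisy", "hf-bci-sim")
  for (m in config$modes)
    if (!parse_mode(m)$name %in% known)
      stop(sprintf("unknown mode '%s' (supported: %s)", m,
                   paste(known, collapse = ", ")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  over <- config$ddpg %||% list()
  over$episodes <- config$episodes
  if (!is.null(config$world$max_steps)) over$max_steps <- config$world$max_steps
  bad <- setdiff(names(over), names(formals(ddpg_config)))
  if (length(bad) > 0)
    stop(sprintf("unknown ddpg config field(s): %s", paste(bad, collapse = ", ")))
  cfg <- do.call(ddpg_config, over)

  make_world <- function() {
    do.call(grid_world, c(list(dims = unlist(config$world$dims)),
                          config$world[setdiff(names(config$world),
                                               c("dims", "max_steps"))],
                          list(max_steps = cfg$max_steps)))
  }
  mode_curves <- list()
  for (m in config$modes) {
    pm <- parse_mode(m)
    curves <- list()
    for (s in config$seeds) {
      w <- make_world()
      hf <- if (pm$name == "sparse") NULL else {
        ch <- switch(pm$name,
                     "hf-oracle" = feedback_channel("oracle"),
                     "hf-noisy" = feedback_channel("noisy",
                                                   flip_prob = pm$value),
                     "hf-bci-sim" = feedback_channel("bci_sim",
                                                     accuracy = pm$value))
        train_hf_policy(w, ch, n_labels = config$hf_labels %||% 1000,
                        seed = derive_seed(s, 21))
      }
      curve <- train_ddpg(w, hf = hf, cfg = cfg, seed = derive_seed(s, 22))
      utils::write.csv(as.data.frame(curve),
                       file.path(out_dir, sprintf("curve_%s_seed%s.csv",
                                                  gsub("[:.]", "-", m), s)),
                       row.names = FALSE)
      curves[[length(curves) + 1]] <- curve
    }
    mode_curves[[if (pm$name == "sparse") "sparse" else m]] <- curves
  }
  report <- comparison_report(mode_curves,
                              final_window = config$final_window %||% 50,
                              seed = derive_seed(config$seeds[[1]], 23))
  write_report(report, file.path(out_dir, "report.json"))
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
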