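# End-to-end orchestration: synthetic cohort -> composite series ->
# characterization -> embedding (global and directional) -> attractor
# geometry -> RQA, plus the reporting operations that summarize measure
# tables (row/column means and the global-vs-directional setting
# differences).

#' Analysis configuration
#'
#' Bundles every knob of the end-to-end analysis; all randomness is driven
#' by the explicit `seed` (no wall-clock seeding).
#'
#' @param n_subjects cohort size per (landmark, task).
#' @param tasks,landmarks labels analyzed.
#' @param length_range trial length interval in frames.
#' @param noise_sd additive noise level of the synthetic cohort.
#' @param seed master integer seed.
#' @param resample_length per-trial resampled length.
#' @param quantile_p lower-tail probability for [quantile_reduce()].
#' @param max_lag AMI lag horizon.
#' @param max_dim FNN dimension horizon.
#' @param radius_fraction recurrence radius as fraction of diameter.
#' @param l_min,v_min minimum line lengths for RQA.
#' @param modes subset of `c("global", "directional")`.
#' @param out_dir optional directory where report tables are written as CSV.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(n_subjects = 15, tasks = c("jazz", "classic"),
                            landmarks = c("LKNE", "CoM"),
                            length_range = c(101L, 250L), noise_sd = 0.01,
                            seed = 1, resample_length = 300,
                            quantile_p = 0.1, max_lag = 100, max_dim = 10,
                            radius_fraction = 0.01, l_min = 2, v_min = 2,
                            modes = c("global", "directional"),
                            out_dir = NULL) {
  stopifnot(n_subjects >= 1, max_lag >= 2, max_dim >= 2, radius_fraction > 0,
            l_min >= 2, v_min >= 2, resample_length >= 2)
  modes <- match.arg(modes, several.ok = TRUE)
  structure(as.list(environment()), class = "analysis_config")
}

# Composite 3-column matrix + per-coordinate reduced series for one
# (landmark, task): per-coordinate reduction for directional series, and a
# shared-survivor reduction (rows where all three coordinates survive their
# own thresholds) for the global multivariate stage.
.build_series_set <- function(cohort, config) {
  normed <- lapply(cohort, function(tr) {
    normalize_by_max(resample_to_fixed_length(tr, config$resample_length))
  })
  comps <- build_composite(normed, seed = config$seed)
  raw <- vapply(comps, `[[`, numeric(length(comps$x$values)), "values")
  directional <- lapply(comps, quantile_reduce, p_low = config$quantile_p)
  keep <- rep(TRUE, nrow(raw))
  if (config$quantile_p > 0) {
    for (j in seq_len(ncol(raw))) {
      q <- stats::quantile(raw[, j], config$quantile_p, type = 7, names = FALSE)
      keep <- keep & raw[, j] >= q
    }
  }
  list(composites = comps, directional = directional,
       global_matrix = raw[keep, , drop = FALSE])
}

# Characterize + embed + RQA + hull for one (landmark, task).
.analyze_combo <- function(landmark, task, config) {
  cohort <- generate_pirouette_cohort(
    config$n_subjects, task = task, landmark = landmark,
    length_range = config$length_range, noise_sd = config$noise_sd,
    seed = config$seed + 97L * match(landmark, c("LKNE", "CoM")) +
      389L * match(task, c("jazz", "classic"))
  )
  ss <- .build_series_set(cohort, config)

  glob_delays <- estimate_delays(ss$global_matrix, max_lag = config$max_lag)
  glob_fnn <- false_nearest_neighbors(ss$global_matrix,
                                      tau = glob_delays$global_tau,
                                      max_dim = config$max_dim)
  coords <- c("x", "y", "z")
  per_coord <- lapply(coords, function(coord) {
    v <- ss$directional[[coord]]$values
    dl <- estimate_delays(v, max_lag = config$max_lag)
    fn <- false_nearest_neighbors(v, tau = dl$per_column_tau[[1]],
                                  max_dim = config$max_dim)
    hur <- hurst_rs(v)
    params <- list(
      global = list(tau = glob_delays$global_tau, D = glob_fnn$selected_D),
      directional = list(tau = dl$per_column_tau[[1]], D = fn$selected_D)
    )
    res <- lapply(config$modes, function(mode) {
      p <- params[[mode]]
      emb <- delay_embed(v, D = p$D, tau = p$tau, mode = mode)
      hull <- tryCatch(
        convex_hull_volume(emb, source = list(landmark = landmark, task = task,
                                              coordinate = coord, mode = mode)),
        error = function(e) NULL
      )
      lye <- rosenstein_lye(v, D = max(p$D, 2), tau = p$tau,
                            max_steps = min(100, length(v) %/% 4))
      rqa <- rqa_analysis(emb, radius_fraction = config$radius_fraction,
                          l_min = config$l_min, v_min = config$v_min)
      list(params = p, hull = hull, lye = lye, rqa = rqa)
    })
    names(res) <- config$modes
    list(coordinate = coord, hurst = hur, delays = dl, fnn = fn, modes = res)
  })
  names(per_coord) <- coords
  list(landmark = landmark, task = task, global_delays = glob_delays,
       global_fnn = glob_fnn, coords = per_coord,
       n_composite = length(ss$composites$x$values),
       n_reduced = vapply(ss$directional, function(s) length(s$values),
                          integer(1)))
}

#' Run the full pirouette-dynamics analysis
#'
#' Executes, for every (landmark, task) pair in the configuration:
#' synthetic-cohort generation, composite-series construction and quantile
#' reduction, Hurst estimation, delay and dimension selection in global and
#' directional settings, per-coordinate delay embedding, Rosenstein
#' Lyapunov estimation, convex-hull volume, and RQA. Identical
#' configurations (and seeds) give identical reports.
#'
#' @param config an [analysis_config()].
#' @return Object of class `summary_report` with `hurst_table`, `lye_table`,
#'   `rqa_table` (one row per landmark/task/coordinate with `all*`/`d*`
#'   measure columns), `setting_difference_table`, `hull_table`,
#'   `embedding_table` and the raw per-combination results in `details`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  combos <- expand.grid(landmark = config$landmarks, task = config$tasks,
                        stringsAsFactors = FALSE)
  details <- lapply(seq_len(nrow(combos)), function(i) {
    .analyze_combo(combos$landmark[i], combos$task[i], config)
  })

  short_task <- c(jazz = "J", classic = "C")
  rows <- list(); hull_rows <- list(); hurst_rows <- list(); lye_rows <- list()
  emb_rows <- list()
  for (d in details) {
    for (coord in names(d$coords)) {
      pc <- d$coords[[coord]]
      label <- sprintf("%s%s_%s", d$landmark, coord, short_task[[d$task]])
      g <- pc$modes$global; dd <- pc$modes$directional
      row <- data.frame(series = label, landmark = d$landmark, task = d$task,
                        coordinate = coord)
      if (!is.null(g)) {
        row <- cbind(row, data.frame(
          allREC = g$rqa$rec, allDET = g$rqa$det, allLMAX = g$rqa$lmax,
          allENT = g$rqa$ent, allLAM = g$rqa$lam, allTT = g$rqa$tt))
      }
      if (!is.null(dd)) {
        row <- cbind(row, data.frame(
          dREC = dd$rqa$rec, dDET = dd$rqa$det, dLMAX = dd$rqa$lmax,
          dENT = dd$rqa$ent, dLAM = dd$rqa$lam, dTT = dd$rqa$tt))
      }
      rows[[label]] <- row
      hurst_rows[[label]] <- data.frame(series = label, H = pc$hurst$H)
      lye_rows[[label]] <- data.frame(
        series = label,
        allLyE = if (!is.null(g)) g$lye$lye else NA_real_,
        dLyE = if (!is.null(dd)) dd$lye$lye else NA_real_)
      hull_rows[[label]] <- data.frame(
        series = label,
        allCHV = if (!is.null(g) && !is.null(g$hull)) g$hull$volume else NA_real_,
        dCHV = if (!is.null(dd) && !is.null(dd$hull)) dd$hull$volume else NA_real_)
      emb_rows[[label]] <- data.frame(
        series = label,
        global_tau = d$global_delays$global_tau, global_D = d$global_fnn$selected_D,
        dir_tau = pc$delays$per_column_tau[[1]], dir_D = pc$fnn$selected_D)
    }
  }
  rqa_table <- do.call(rbind, rows); rownames(rqa_table) <- NULL
  report <- structure(
    list(
      rqa_table = rqa_table,
      hurst_table = do.call(rbind, hurst_rows),
      lye_table = do.call(rbind, lye_rows),
      hull_table = do.call(rbind, hull_rows),
      embedding_table = do.call(rbind, emb_rows),
      setting_difference_table =
        if (all(c("global", "directional") %in% config$modes)) {
          summarize_setting_differences(rqa_table)
        } else NULL,
      config = config, details = details
    ),
    class = "summary_report"
  )
  for (nm in c("hurst_table", "lye_table", "hull_table", "embedding_table")) {
    rownames(report[[nm]]) <- NULL
  }
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.summary_report <- function(x, ...) {
  cat(sprintf("<summary_report> %d series rows; seed %d\n",
              nrow(x$rqa_table), x$config$seed))
  print(x$rqa_table, digits = 4)
  invisible(x)
}

#' Write report tables to CSV
#'
#' @param report a `summary_report`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- c("rqa_table", "hurst_table", "lye_table", "hull_table",
            "embedding_table", "setting_difference_table")
  for (nm in tabs) {
    if (!is.null(report[[nm]])) {
      utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Mean percentage difference between global and directional settings
#'
#' For every measure (REC, DET, LMAX, ENT, LAM, TT) and task, averages the
#' per-series [percentage_difference()] between the `all*` (global) and
#' `d*` (directional) columns. Each per-series difference is rounded
#' (half away from zero) to 2 decimals before averaging, and the mean is
#' reported to 2 decimals, matching the convention of the published summary
#' tables. Series where both settings give the same value contribute 0;
#' series where either value is non-positive (so no ratio is defined, e.g.
#' a zero trapping time) are excluded from that measure's average.
#'
#' @param rqa_table data frame with a `task` column (or series labels ending
#'   `_J` / `_C`) and paired `all<M>` / `d<M>` columns.
#' @return Data frame: one row per task, one column per measure.
#' @export
summarize_setting_differences <- function(rqa_table) {
  measures <- c("REC", "DET", "LMAX", "ENT", "LAM", "TT")
  if (!all(c(paste0("all", measures), paste0("d", measures)) %in%
           names(rqa_table))) {
    arg_error("rqa_table must contain paired all*/d* columns for all measures")
  }
  task <- if ("task" %in% names(rqa_table)) {
    rqa_table$task
  } else {
    ifelse(grepl("_J$", rqa_table$series), "jazz", "classic")
  }
  out <- lapply(unique(task), function(tk) {
    sub <- rqa_table[task == tk, , drop = FALSE]
    vals <- vapply(measures, function(m) {
      a <- sub[[paste0("all", m)]]
      b <- sub[[paste0("d", m)]]
      d <- mapply(function(ai, bi) {
        if (isTRUE(all.equal(ai, bi))) return(0)
        if (ai <= 0 || bi <= 0) return(NA_real_)
        percentage_difference(ai, bi)
      }, a, b)
      round_half_away(mean(round_half_away(d, 2), na.rm = TRUE), 2)
    }, numeric(1))
    cbind(data.frame(task = tk), as.data.frame(as.list(vals)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean of selected table cells, rounded to 2 decimals
#'
#' @param table data frame or matrix.
#' @param rows,cols optional row / column selectors (indices, names or
#'   logical); defaults to everything numeric.
#' @return Arithmetic mean rounded (half away from zero) to 2 decimals.
#' @export
summarize_means <- function(table, rows = NULL, cols = NULL) {
  tb <- as.data.frame(table)
  if (!is.null(rows)) tb <- tb[rows, , drop = FALSE]
  if (!is.null(cols)) tb <- tb[, cols, drop = FALSE]
  num <- unlist(tb[vapply(tb, is.numeric, logical(1))], use.names = FALSE)
  if (!length(num)) arg_error("no numeric cells selected")
  round_half_away(mean(num), 2)
}

# ---------------------------------------------------------------------------
# published reference tables (transcribed)
# ---------------------------------------------------------------------------

#' Published reference summary tables
#'
#' Transcriptions of the summary tables reported by the published
#' motion-capture study of 15 professional dancers that this package's
#' synthetic workflow emulates: per-coordinate Hurst exponents, largest
#' Lyapunov exponents, the 12-row RQA table (global `all*` and directional
#' `d*` settings), and the task-level mean percentage differences between
#' the two settings. They feed the reporting operations and their tests;
#' they are not outputs of this package's computations.
#'
#' @param which one of `"hurst"`, `"lyapunov"`, `"rqa"`,
#'   `"setting_difference"`.
#' @return A data frame.
#' @export
reference_table <- function(which = c("hurst", "lyapunov", "rqa",
                                      "setting_difference")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("reference_", which, ".csv"),
                      package = "pirodyn", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}
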