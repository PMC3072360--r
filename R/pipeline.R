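measure_order <- c("Mean", "SD", "Skew", "Kurtosis", "lambda1", "alpha")
measure_fields <- c(Mean = "S1", SD = "S2", Skew = "S3", Kurtosis = "S4",
                    lambda1 = "Lambda1", alpha = "alpha")

#' Two-group comparison of per-cell measure sets
#'
#' Pooled-variance two-sample t test per measure, comparing group `a`
#' against group `b` (t is computed on `mean(a) - mean(b)`), with
#' `df = n1 + n2 - 2`. Measures missing in some cells are compared on the
#' available subsets with correspondingly reduced df and flagged. No
#' multiple-testing correction is applied across the six measures.
#'
#' @param a,b lists of `measure_set` objects (each measure present in at
#'   least 2 members per group).
#' @param alternative `"greater"` (one-tailed, `a > b`; default), `"less"`,
#'   `"two.sided"`, or `"directional"` (one-tailed in the direction of the
#'   observed difference, i.e. `P(T > |t|)`).
#' @return list of class `group_comparison` with a per-measure `table`
#'   (means, SDs, t, df, p, n1, n2, subset flag) in the order Mean, SD,
#'   Skew, Kurtosis, lambda1, alpha, plus `n1`, `n2`, `alternative`.
#' @export
compare_groups <- function(a, b, alternative = c("greater", "less",
                                                 "two.sided", "directional")) {
  alternative <- match.arg(alternative)
  if (length(a) < 2 || length(b) < 2)
    md_error("morphodyn_insufficient_group", "need >= 2 cells per group")
  pull <- function(g, f) vapply(g, function(m) as.numeric(m[[f]]), numeric(1))
  rows <- lapply(names(measure_fields), function(nm) {
    f <- measure_fields[[nm]]
    va <- pull(a, f); vb <- pull(b, f)
    ka <- va[is.finite(va)]; kb <- vb[is.finite(vb)]
    if (length(ka) < 2 || length(kb) < 2)
      md_error("morphodyn_insufficient_group",
               sprintf("measure %s present in < 2 cells of a group", nm))
    n1 <- length(ka); n2 <- length(kb)
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * stats::var(ka) + (n2 - 1) * stats::var(kb)) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    dm <- mean(ka) - mean(kb)
    # two identical constant groups compare as t = 0, not 0/0
    t <- if (se == 0) { if (dm == 0) 0 else sign(dm) * Inf } else dm / se
    p <- switch(alternative,
                greater = stats::pt(t, df, lower.tail = FALSE),
                less = stats::pt(t, df),
                two.sided = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
                directional = stats::pt(abs(t), df, lower.tail = FALSE))
    data.frame(measure = nm, mean_a = mean(ka), sd_a = stats::sd(ka),
               mean_b = mean(kb), sd_b = stats::sd(kb),
               t = t, df = df, p = p, n1 = n1, n2 = n2,
               subset = (n1 < length(va) || n2 < length(vb)))
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab, n1 = length(a), n2 = length(b),
                 alternative = alternative),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> n1 = %d, n2 = %d, alternative = %s\n",
              x$n1, x$n2, x$alternative))
  print(format(x$table, digits = 4), row.names = FALSE)
  cat("note: no multiple-testing correction across measures\n")
  invisible(x)
}

#' Before/after comparison within one recording
#'
#' Splits an R(t) series at `split_index`, runs [measure_battery()] on each
#' segment, and reports per-measure signed deltas (after minus before)
#' together with whether each delta direction matches the canonical
#' treadmilling-versus-idling contrast (SD up, Skew up, lambda1 down, alpha
#' down).
#'
#' @param series an [r_series()].
#' @param split_index last sample of the "before" segment; both segments
#'   must have at least 100 samples.
#' @return list of class `before_after` with `before`, `after`
#'   (measure sets), `delta` (named numeric), and `direction_match` (named
#'   logical for SD, Skew, lambda1, alpha).
#' @export
before_after <- function(series, split_index) {
  stopifnot(inherits(series, "r_series"))
  n <- series$n
  if (split_index < 100 || n - split_index < 100)
    md_error("morphodyn_too_short", "both segments must have >= 100 samples")
  seg <- function(idx, lab) {
    r_series(series$values[idx], dt = series$dt,
             cell_id = paste0(series$cell_id, "_", lab), state_label = "unknown")
  }
  mb <- measure_battery(seg(1:split_index, "before"))
  ma <- measure_battery(seg((split_index + 1):n, "after"))
  delta <- vapply(names(measure_fields), function(nm) {
    as.numeric(ma[[measure_fields[[nm]]]]) - as.numeric(mb[[measure_fields[[nm]]]])
  }, numeric(1))
  expected <- c(SD = 1, Skew = 1, lambda1 = -1, alpha = -1)
  match_dir <- vapply(names(expected), function(nm) {
    isTRUE(sign(delta[[nm]]) == expected[[nm]])
  }, logical(1))
  structure(list(before = mb, after = ma, delta = delta,
                 direction_match = match_dir, split_index = split_index),
            class = "before_after")
}

#' @export
print.before_after <- function(x, ...) {
  cat(sprintf("<before_after> split at sample %d\n", x$split_index))
  d <- data.frame(measure = names(x$delta), delta = unname(x$delta))
  print(format(d, digits = 4), row.names = FALSE)
  cat("directions matching the treadmilling contrast:",
      paste(names(which(x$direction_match)), collapse = ", "), "\n")
  invisible(x)
}

#' Run a full analysis pipeline from a config
#'
#' Orchestrates simulate/load -> R(t) -> measure battery -> group comparison
#' and writes a run directory containing per-cell R(t) CSVs, a measure
#' table, a comparison table (when two groups are present) and a JSON
#' report with a config echo. Identical config + seed give byte-identical
#' report JSON.
#'
#' @param config a list (or path to a JSON file) with fields:
#'   \describe{
#'     \item{cells}{list of cell entries; each has `id`, and either `state`
#'       (+ optional `seed`, simulation overrides) for synthetic cells,
#'       `path` to a mask movie (TIFF/PNG dir), or `r_csv` pointing at a
#'       precomputed R(t) CSV.}
#'     \item{groups}{optional named list mapping two group labels to vectors
#'       of cell ids; when present, the first group is compared against the
#'       second.}
#'     \item{dt}{sampling interval (default 2).}
#'     \item{seed}{root seed; cell-level seeds default to
#'       `child_seed(seed, id)`.}
#'     \item{alternative}{tail for [compare_groups()] (default
#'       "directional").}
#'     \item{figures}{write per-cell recurrence-plot and scalogram PNGs
#'       (default FALSE).}
#'   }
#' @param out_dir output directory (created if needed).
#' @return the report list, invisibly; side effect: files under `out_dir`.
#' @details Per-cell failures are quarantined with their reasons in the
#'   report; the run fails only if every cell fails.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dt <- config$dt %||% 2
  seed <- config$seed %||% 1
  alternative <- config$alternative %||% "directional"
  figures <- isTRUE(config$figures)
  cells <- config$cells
  if (is.data.frame(cells)) cells <- split(cells, seq_len(nrow(cells)))
  if (!length(cells)) md_error("morphodyn_domain", "config has no cells")

  series_list <- list(); measures <- list(); quarantine <- list()
  for (cell in cells) {
    cell <- as.list(cell)
    id <- cell$id %||% md_error("morphodyn_domain", "cell entry without id")
    res <- tryCatch({
      rs <- if (!is.null(cell$state)) {
        p <- synthetic_params(state = cell$state, n = cell$n %||% 900, dt = dt,
                              seed = cell$seed %||% child_seed(seed, id))
        simulate_roundness_series(p)
      } else if (!is.null(cell$path)) {
        frames <- read_mask_stack(cell$path, dt = dt)
        roundness_series(frames, dt = dt, cell_id = id)
      } else if (!is.null(cell$r_csv)) {
        read_r_series(cell$r_csv, cell_id = id)
      } else md_error("morphodyn_domain", "cell entry needs state, path or r_csv")
      rs$cell_id <- id
      rs
    }, error = function(e) e)
    if (inherits(res, "error")) {
      quarantine[[id]] <- conditionMessage(res)
      message(sprintf("[morphodyn] cell %s quarantined: %s", id, conditionMessage(res)))
      next
    }
    series_list[[id]] <- res
    measures[[id]] <- measure_battery(res)
    write_r_series(res, file.path(out_dir, paste0("r_", id, ".csv")))
    if (figures) {
      rp <- recurrence_plot(res, eps_quantile = 0.1)
      write_recurrence_png(rp, file.path(out_dir, paste0("rp_", id, ".png")))
      sc <- morlet_cwt(res)
      write_scalogram(sc, png_path = file.path(out_dir, paste0("cwt_", id, ".png")))
    }
  }
  if (!length(measures))
    md_error("morphodyn_domain", "all cells failed; nothing to report")

  mtab <- do.call(rbind, lapply(measures, measure_row))
  utils::write.csv(mtab, file.path(out_dir, "measures.csv"),
                   row.names = FALSE, quote = FALSE)

  comparison <- NULL
  if (!is.null(config$groups) && length(config$groups) >= 2) {
    gl <- names(config$groups)
    ga <- measures[intersect(unlist(config$groups[[gl[1]]]), names(measures))]
    gb <- measures[intersect(unlist(config$groups[[gl[2]]]), names(measures))]
    comparison <- compare_groups(unname(ga), unname(gb), alternative = alternative)
    utils::write.csv(comparison$table, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  report <- list(
    package = "morphodyn",
    version = as.character(utils::packageVersion("morphodyn")),
    seed = seed,
    config = config,
    n_cells = length(measures),
    quarantined = quarantine,
    measures = lapply(measures, function(m) unclass(m)[c("cell_id", "state_label",
      "S1", "S2", "S3", "S4", "Lambda1", "alpha", "slowest_period_min")]),
    comparison = if (!is.null(comparison)) comparison$table else NULL,
    note = "no multiple-testing correction applied across measures"
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Thin shell over the package functions; the script `inst/cli/morphodyn`
#' forwards `commandArgs(TRUE)` here. Verbs:
#' \preformatted{
#' simulate  --state S --n 900 --dt 2 --seed 1 --out movie.tiff [--truth t.json]
#' roundness --in movie.tiff --dt 2 --out r.csv [--metrics m.csv]
#' measures  --in r.csv --out measures.json
#' embed     --in r.csv --M 8 --out psi.csv
#' rp        --in r.csv --dim 3 --tau 1 --eps 1 --out rp.png
#' cwt       --in r.csv --scales 64 --out scalogram.png [--matrix sc.csv]
#' run       --config run.json --out DIR
#' }
#'
#' @param args character vector of arguments (verb first).
#' @return invisibly, the main object produced by the verb.
#' @export
morphodyn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: morphodyn <verb> [--flag value ...]", call. = FALSE)
  verb <- args[1]
  opts <- parse_cli_flags(args[-1])
  get_num <- function(k, d) if (is.null(opts[[k]])) d else as.numeric(opts[[k]])
  switch(verb,
    simulate = {
      p <- synthetic_params(state = opts$state %||% "idling",
                            n = get_num("n", 900), dt = get_num("dt", 2),
                            r0 = get_num("r0", 60),
                            grid = if (is.null(opts$grid)) NULL else as.integer(opts$grid),
                            seed = get_num("seed", 1))
      rec <- simulate_state(p)
      write_recording(rec, opts$out %||% "movie.tiff", truth_path = opts$truth)
      message("wrote ", opts$out %||% "movie.tiff")
      invisible(rec)
    },
    roundness = {
      frames <- read_mask_stack(opts[["in"]], dt = get_num("dt", 2))
      rs <- roundness_series(frames, dt = get_num("dt", 2), validate = FALSE)
      write_r_series(rs, opts$out %||% "r.csv")
      if (!is.null(opts$metrics)) write_frame_metrics(rs, opts$metrics)
      invisible(rs)
    },
    measures = {
      rs <- read_r_series(opts[["in"]])
      ms <- measure_battery(rs)
      jsonlite::write_json(unclass(ms), opts$out %||% "measures.json",
                           auto_unbox = TRUE, digits = NA, na = "null")
      invisible(ms)
    },
    embed = {
      rs <- read_r_series(opts[["in"]])
      bk <- bk_embed(rs, M = get_num("M", 8))
      write_bk_csv(bk, opts$out %||% "psi.csv")
      invisible(bk)
    },
    rp = {
      rs <- read_r_series(opts[["in"]])
      rp <- recurrence_plot(rs, dim = get_num("dim", 3), tau = get_num("tau", 1),
                            eps = get_num("eps", 1))
      write_recurrence_png(rp, opts$out %||% "rp.png")
      invisible(rp)
    },
    cwt = {
      rs <- read_r_series(opts[["in"]])
      sc <- morlet_cwt(rs, n_scales = get_num("scales", 64))
      write_scalogram(sc, csv_path = opts$matrix,
                      png_path = opts$out %||% "scalogram.png")
      invisible(sc)
    },
    run = {
      invisible(run_pipeline(opts$config, opts$out %||% "morphodyn_run"))
    },
    stop("unknown verb: ", verb, call. = FALSE)
  )
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("expected --flag, got: ", a, call. = FALSE)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      opts[[key]] <- TRUE; i <- i + 1
    } else {
      opts[[key]] <- args[i + 1]; i <- i + 2
    }
  }
  opts
}
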