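# Pipeline orchestration: configuration, stage execution, reports.
#
# A pipeline config is a JSON file (or equivalent R list) with:
#   seed               integer, drives every stochastic stage
#   outdir             output directory
#   reference_product  label of the reference rows (default "Reference")
#   points    {file}  OR  inline {product_id, run_label, arc, auc, ...}
#     - summary mode: the five (ARC, AUC) points enter directly,
#       bypassing the raw IVRT/tape-strip stages
#   ivrt      {files: {data, meta}}  OR  {simulate: {runs: [...], config: {...}}}
#   ts        {files: {strips, tewl}} OR {simulate: {product_scale: {...},
#                                                    config: {...}}}
#   switches  {time_window, drop_first_n, ci_method, ci_level,
#              lower_ratio, upper_ratio, pooling, average_replicates,
#              anchor_zero, position}
# Exactly one of {files, simulate} per data kind; `points` excludes both.

default_switches <- function() {
  list(time_window = NULL, drop_first_n = 0, ci_method = "log-t",
       ci_level = 0.90, lower_ratio = 0.7999, upper_ratio = 1.2501,
       pooling = "mean", average_replicates = TRUE, anchor_zero = FALSE,
       position = "midpoint", thickness_on_unidentifiable = "exclude")
}

#' Validate a pipeline configuration
#'
#' @param x Path to a JSON config file, or a list with the same fields.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) jsonlite::read_json(x, simplifyVector = TRUE)
         else x
  if (!is.list(cfg)) stop("config must be a list or a JSON file path",
                          call. = FALSE)
  cfg$seed <- if (is.null(cfg$seed)) 1L else check_count(cfg$seed, "seed",
                                                         lower = 0L)
  if (is.null(cfg$outdir)) stop_field("outdir", "must be supplied")
  if (is.null(cfg$reference_product)) cfg$reference_product <- "Reference"
  sw <- default_switches()
  for (nm in names(cfg$switches)) {
    if (!nm %in% names(sw))
      stop_field(paste0("switches.", nm), "is not a recognised switch")
    sw[[nm]] <- cfg$switches[[nm]]
  }
  cfg$switches <- sw

  has_points <- !is.null(cfg$points)
  for (kind in c("ivrt", "ts")) {
    blk <- cfg[[kind]]
    if (has_points) {
      if (!is.null(blk))
        stop_field(kind, "must be absent when summary `points` are given")
      next
    }
    if (is.null(blk))
      stop_field(kind, "must be supplied (files or simulate block)")
    n_modes <- sum(!is.null(blk$files), !is.null(blk$simulate))
    if (n_modes != 1L)
      stop_field(kind, "needs exactly one of `files` or `simulate`")
  }
  structure(cfg, class = "pipeline_config")
}

derive_seed <- function(seed, offset)
  as.integer((as.numeric(seed) * 31 + offset) %% 2147483647)

# ---- stages -----------------------------------------------------------

stage_ivrt_data <- function(cfg) {
  blk <- cfg$ivrt
  if (!is.null(blk$files))
    return(read_ivrt_csv(blk$files$data, blk$files$meta))
  sim <- blk$simulate
  base <- sim$config %||% list()
  run_list <- sim$runs
  if (is.data.frame(run_list))  # from jsonlite simplification
    run_list <- lapply(seq_len(nrow(run_list)), function(i)
      list(run_id = run_list$run_id[i], products = run_list$products[[i]]))
  runs <- list()
  k <- 0L
  for (run in run_list) {
    prods <- run$products
    if (!is.data.frame(prods))
      prods <- do.call(rbind, lapply(prods, as.data.frame))
    for (i in seq_len(nrow(prods))) {
      k <- k + 1L
      conf <- do.call(ivrt_sim_config, c(
        list(true_arc = prods$true_arc[i], seed = derive_seed(cfg$seed, k)),
        base))
      runs[[paste(run$run_id, prods$product_id[i], sep = ".")]] <-
        simulate_ivrt_run(conf, prods$product_id[i], prods$role[i])
    }
  }
  runs
}

stage_ts_data <- function(cfg) {
  blk <- cfg$ts
  if (!is.null(blk$files))
    return(list(sites = read_tape_strip_csv(blk$files$strips),
                tewl = read_tewl_csv(blk$files$tewl)))
  sim <- blk$simulate
  base <- sim$config %||% list()
  conf <- do.call(ts_sim_config, c(
    list(seed = derive_seed(cfg$seed, 1000L)), base))
  scale <- unlist(sim$product_scale)
  study <- simulate_tape_strip_study(conf, names(scale), scale)
  list(sites = study$sites, tewl = study$tewl, config = conf)
}

stage_ts_analysis <- function(ts, cfg) {
  sw <- cfg$switches
  area <- ts$sites[[1]]$site_area
  density <- if (!is.null(ts$config)) ts$config$sc_density else 1.0
  thickness <- estimate_sc_thickness_all(
    ts$tewl, site_area = area, sc_density = density,
    on_unidentifiable = sw$thickness_on_unidentifiable)
  products <- unique(vapply(ts$sites, function(s) as.character(s$product_id),
                            ""))
  products <- products[!is.na(products)]
  aucs <- lapply(products, function(prod) {
    profs <- lapply(Filter(function(s) identical(as.character(s$product_id),
                                                 prod) &&
                             s$participant_id %in% names(thickness),
                           ts$sites),
                    function(s) relative_depth_profile(
                      s, L = thickness[[s$participant_id]],
                      sc_density = density,
                      drop_first_n = sw$drop_first_n,
                      position = sw$position))
    study_auc(profs, average_replicates = sw$average_replicates,
              anchor_zero = sw$anchor_zero)
  })
  names(aucs) <- products
  list(thickness = thickness, aucs = aucs)
}

# Build correlation points from per-run ARCs and per-product AUCs: one
# point per (run, product), a product measured in several runs enters
# once per run against its single observed AUC.
build_points <- function(arcs, aucs) {
  rows <- lapply(names(arcs), function(key) {
    a <- arcs[[key]]
    run_label <- sub("\\.[^.]*$", "", key)
    auc <- aucs[[a$product_id]]
    if (is.null(auc))
      stop("no tape-strip AUC for product ", a$product_id, call. = FALSE)
    ivivc_points(a$product_id, run_label, a$arc_mean, auc$auc_mean,
                 a$arc_sd, auc$auc_sd)
  })
  structure(do.call(rbind, rows), class = c("ivivc_points", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- reports ----------------------------------------------------------

format_table1 <- function(points, model) {
  pred <- round(predict_auc(model, points$arc), 2)
  obs <- sprintf("%.2f%s", round(points$auc, 2),
                 ifelse(is.na(points$auc_sd), "",
                        sprintf(" +/- %.2f", round(points$auc_sd, 2))))
  arc <- sprintf("%.2f%s", round(points$arc, 2),
                 ifelse(is.na(points$arc_sd), "",
                        sprintf(" +/- %.2f", round(points$arc_sd, 2))))
  c("| Product (run) | AUC (ug.% skin depth) | ARC (ug/cm2/min^1/2) | Predicted AUC |",
    "|---|---|---|---|",
    sprintf("| %s (%s) | %s | %s | %.2f |", points$product_id,
            points$run_label, obs, arc, pred))
}

format_table2 <- function(bounds) {
  c("| BE limits | Predicted AUC (ug.% skin depth) | ARC (ug/cm2/min^1/2) |",
    "|---|---|---|",
    sprintf("| %.4f (lower) | %.2f | %.2f |", bounds$lower_ratio,
            round(bounds$auc_lower, 2), round(bounds$arc_lower, 2)),
    sprintf("| %.4f (upper) | %.2f | %.2f |", bounds$upper_ratio,
            round(bounds$auc_upper, 2), round(bounds$arc_upper, 2)))
}

#' Run the full IVIVC pipeline
#'
#' Executes (optional) simulation, the IVRT and tape-strip analyses, the
#' Level C fit, and the bioequivalence classification, writing all
#' intermediate CSVs, a markdown report with the correlation and
#' BE-limit tables, and a run log recording the configuration hash and
#' every analysis switch.
#'
#' @param config A [pipeline_config()], a list coercible to one, or a
#'   JSON file path.
#' @return Invisibly, a list with `points`, `model`, `bounds`,
#'   `verdicts`, `cv`, `ratio_cis` and the output `paths`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(config = file.path(cfg$outdir, "config.json"))
  jsonlite::write_json(unclass(cfg), paths$config, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  cfg_hash <- unname(tools::md5sum(paths$config))

  ratio_cis <- list()
  if (!is.null(cfg$points)) {
    points <- if (!is.null(cfg$points$file))
      read_ivivc_points_csv(cfg$points$file)
    else ivivc_points(cfg$points$product_id, cfg$points$run_label,
                      cfg$points$arc, cfg$points$auc,
                      cfg$points$arc_sd %||% NA_real_,
                      cfg$points$auc_sd %||% NA_real_)
  } else {
    runs <- stage_ivrt_data(cfg)
    paths$ivrt_data <- file.path(cfg$outdir, "ivrt_data.csv")
    paths$ivrt_meta <- file.path(cfg$outdir, "ivrt_meta.csv")
    write_ivrt_csv(runs, paths$ivrt_data, paths$ivrt_meta)
    arcs <- lapply(runs, run_arc, time_window = cfg$switches$time_window)

    # within-run test/reference ratio CIs where both roles are present
    run_of <- sub("\\.[^.]*$", "", names(arcs))
    for (rl in unique(run_of)) {
      members <- arcs[run_of == rl]
      refs <- Filter(function(a) a$role == "reference", members)
      tests <- Filter(function(a) a$role == "test", members)
      if (length(refs) == 1L)
        for (tt in tests)
          ratio_cis[[paste(rl, tt$product_id, sep = ".")]] <-
            release_ratio_ci(tt, refs[[1]], level = cfg$switches$ci_level,
                             method = cfg$switches$ci_method)
    }

    ts <- stage_ts_data(cfg)
    paths$ts_strips <- file.path(cfg$outdir, "tape_strips.csv")
    paths$ts_tewl <- file.path(cfg$outdir, "tewl.csv")
    write_tape_strip_csv(ts$sites, paths$ts_strips)
    write_tewl_csv(ts$tewl, paths$ts_tewl)
    dpk <- stage_ts_analysis(ts, cfg)
    points <- build_points(arcs, dpk$aucs)
  }

  paths$points <- file.path(cfg$outdir, "ivivc_points.csv")
  write_ivivc_points_csv(points, paths$points)

  model <- fit_level_c(points)
  ref_rows <- points$product_id == cfg$reference_product
  if (!any(ref_rows))
    stop("no points for reference product ", cfg$reference_product,
         call. = FALSE)
  bounds <- be_limits(model, points$arc[ref_rows],
                      lower_ratio = cfg$switches$lower_ratio,
                      upper_ratio = cfg$switches$upper_ratio,
                      pooling = cfg$switches$pooling)
  test_rows <- points[!ref_rows, , drop = FALSE]
  verdicts <- lapply(seq_len(nrow(test_rows)), function(i)
    classify_be(test_rows$arc[i], bounds,
                product_id = test_rows$product_id[i]))
  cv <- prediction_cv(points$auc, round(predict_auc(model, points$arc), 2))

  paths$verdicts <- file.path(cfg$outdir, "verdicts.csv")
  write_verdict_csv(verdicts, bounds, paths$verdicts)
  paths$model <- file.path(cfg$outdir, "model.json")
  jsonlite::write_json(
    list(slope = model$slope, intercept = model$intercept,
         r_squared = model$r_squared, n_points = model$n,
         pooled_reference_arc = bounds$pooled_reference_arc,
         max_prediction_cv_percent = cv$max_cv),
    paths$model, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  report <- c(
    "# Level C IVIVC report", "",
    sprintf("Model: AUC = %.4f * ARC + %.3f (R^2 = %.3f, n = %d)",
            model$slope, model$intercept, model$r_squared, model$n),
    sprintf("Max observed-vs-predicted CV: %.2f%%", cv$max_cv), "",
    "## Correlation and predictions", "",
    format_table1(points, model), "",
    "## Bioequivalence limits", "",
    format_table2(bounds), "",
    "## Verdicts", "",
    vapply(verdicts, function(v)
      sprintf("- %s: ARC %.2f, predicted AUC %.2f -> %s", v$product_id,
              round(v$arc, 2), round(v$predicted_auc, 2), v$verdict), ""),
    "")
  paths$report <- file.path(cfg$outdir, "report.md")
  writeLines(report, paths$report)

  log_lines <- c(
    sprintf("config_md5: %s", cfg_hash),
    sprintf("seed: %d", cfg$seed),
    "decisions:",
    sprintf("  ci_method: %s (ratio CI on mean log-slopes)",
            cfg$switches$ci_method),
    sprintf("  pooling: %s (reference run ARCs)", cfg$switches$pooling),
    sprintf("  ratio_bounds: %.4f-%.4f", cfg$switches$lower_ratio,
            cfg$switches$upper_ratio),
    sprintf("  drop_first_n: %d", cfg$switches$drop_first_n),
    sprintf("  strip_position: %s", cfg$switches$position),
    sprintf("  average_replicates: %s", cfg$switches$average_replicates),
    sprintf("  anchor_zero: %s", cfg$switches$anchor_zero),
    sprintf("  thickness_on_unidentifiable: %s",
            cfg$switches$thickness_on_unidentifiable),
    sprintf("  time_window: %s",
            if (is.null(cfg$switches$time_window)) "all points"
            else paste(cfg$switches$time_window, collapse = "-")),
    "  intercept: estimated, not forced through origin",
    "  rounding: half-to-even at 2 decimals in reports")
  if (length(ratio_cis))
    log_lines <- c(log_lines, "ratio_cis:",
                   vapply(names(ratio_cis), function(nm) {
                     ci <- ratio_cis[[nm]]
                     sprintf("  %s: %.2f (%.2f-%.2f)", nm, ci$ratio,
                             ci$lower, ci$upper)
                   }, ""))
  paths$log <- file.path(cfg$outdir, "run_log.txt")
  writeLines(log_lines, paths$log)

  invisible(list(points = points, model = model, bounds = bounds,
                 verdicts = verdicts, cv = cv, ratio_cis = ratio_cis,
                 paths = paths))
}

# ---- command-line entry ----------------------------------------------

parse_cli_args <- function(args) {
  if (length(args) < 1L)
    stop("usage: <subcommand> --config <file> [--outdir <dir>] ",
         "[--seed <int>]", call. = FALSE)
  out <- list(subcommand = args[[1]])
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[[i]])
    if (i + 1L > length(rest)) stop("missing value for --", key,
                                    call. = FALSE)
    out[[key]] <- rest[[i + 1L]]
    i <- i + 2L
  }
  out
}

#' Command-line entry point
#'
#' Dispatches the subcommands `all` (full pipeline), `simulate` (write
#' synthetic CSVs only), `ivrt`, `ts`, `ivivc` and `be` (each stage on
#' its CSV inputs). Invoked by the `inst/cli/dermivivc.R` script; usable
#' directly as `pipeline_main(c("all", "--config", "cfg.json"))`.
#'
#' @param args Character vector of arguments.
#' @return Invisibly, the result of the stage that ran.
#' @export
pipeline_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  opts <- parse_cli_args(args)
  if (is.null(opts$config)) stop("--config is required", call. = FALSE)
  cfg <- pipeline_config(opts$config)
  if (!is.null(opts$outdir)) cfg$outdir <- opts$outdir
  if (!is.null(opts$seed)) cfg$seed <- check_count(as.numeric(opts$seed),
                                                   "seed", lower = 0L)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  res <- switch(
    opts$subcommand,
    all = run_pipeline(cfg),
    simulate = {
      out <- list()
      if (!is.null(cfg$ivrt$simulate)) {
        runs <- stage_ivrt_data(cfg)
        write_ivrt_csv(runs, file.path(cfg$outdir, "ivrt_data.csv"),
                       file.path(cfg$outdir, "ivrt_meta.csv"))
        out$runs <- runs
      }
      if (!is.null(cfg$ts$simulate)) {
        ts <- stage_ts_data(cfg)
        write_tape_strip_csv(ts$sites, file.path(cfg$outdir,
                                                 "tape_strips.csv"))
        write_tewl_csv(ts$tewl, file.path(cfg$outdir, "tewl.csv"))
        out$ts <- ts
      }
      out
    },
    ivrt = {
      runs <- stage_ivrt_data(cfg)
      arcs <- lapply(runs, run_arc, time_window = cfg$switches$time_window)
      tab <- do.call(rbind, lapply(names(arcs), function(k)
        data.frame(run_product = k, product_id = arcs[[k]]$product_id,
                   role = arcs[[k]]$role,
                   arc_mean = round(arcs[[k]]$arc_mean, 2),
                   arc_sd = round(arcs[[k]]$arc_sd, 2),
                   n_cells = arcs[[k]]$n_cells)))
      write.csv(tab, file.path(cfg$outdir, "arc_results.csv"),
                row.names = FALSE, quote = FALSE)
      arcs
    },
    ts = {
      ts <- stage_ts_data(cfg)
      dpk <- stage_ts_analysis(ts, cfg)
      tab <- do.call(rbind, lapply(dpk$aucs, function(a)
        data.frame(product_id = a$product_id,
                   auc_mean = round(a$auc_mean, 2),
                   auc_sd = round(a$auc_sd, 2),
                   n_participants = a$n_participants)))
      write.csv(tab, file.path(cfg$outdir, "auc_results.csv"),
                row.names = FALSE, quote = FALSE)
      dpk
    },
    ivivc = {
      points <- read_ivivc_points_csv(cfg$points$file)
      model <- fit_level_c(points)
      jsonlite::write_json(
        list(slope = model$slope, intercept = model$intercept,
             r_squared = model$r_squared, n_points = model$n),
        file.path(cfg$outdir, "model.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE)
      model
    },
    be = run_pipeline(cfg),
    stop("unknown subcommand: ", opts$subcommand, call. = FALSE)
  )
  invisible(res)
}
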