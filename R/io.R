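# CSV input/output. Readers validate the header and the physical
# constraints, reporting offending rows by line number; writers emit the
# identical dialect so write-then-read is the identity.

check_columns <- function(df, expected, what) {
  missing <- setdiff(expected, names(df))
  extra <- setdiff(names(df), expected)
  if (length(missing) || length(extra))
    stop(sprintf("%s: schema mismatch (missing: %s; unexpected: %s)", what,
                 if (length(missing)) paste(missing, collapse = ", ") else "none",
                 if (length(extra)) paste(extra, collapse = ", ") else "none"),
         call. = FALSE)
  invisible(df)
}

#' Write / read IVRT runs as CSV
#'
#' Long format: `run_id, product_id, role, cell_id, time_min,
#' conc_ug_per_ml`, with a companion metadata CSV `run_id,
#' cell_volume_ml, sample_volume_ml, orifice_diameter_mm, temperature_c`.
#'
#' @param runs Named list of `ivrt_run` objects (names are run ids).
#' @param data_path,meta_path Paths of the data and metadata CSVs.
#' @return `write_ivrt_csv`: the paths, invisibly. `read_ivrt_csv`: a
#'   named list of `ivrt_run`s.
#' @export
write_ivrt_csv <- function(runs, data_path, meta_path) {
  rows <- do.call(rbind, lapply(names(runs), function(id) {
    r <- runs[[id]]
    do.call(rbind, lapply(rownames(r$conc), function(cid)
      data.frame(run_id = id, product_id = r$product_id, role = r$role,
                 cell_id = cid, time_min = r$times,
                 conc_ug_per_ml = r$conc[cid, ])))
  }))
  rownames(rows) <- NULL
  write.csv(rows, data_path, row.names = FALSE, quote = FALSE)
  meta <- do.call(rbind, lapply(names(runs), function(id) {
    r <- runs[[id]]
    data.frame(run_id = id, cell_volume_ml = r$cell_volume,
               sample_volume_ml = r$sample_volume,
               orifice_diameter_mm = sqrt(4 * r$orifice_area / pi) * 10,
               temperature_c = r$temperature)
  }))
  write.csv(meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(c(data = data_path, meta = meta_path))
}

#' @rdname write_ivrt_csv
#' @export
read_ivrt_csv <- function(data_path, meta_path) {
  df <- read.csv(data_path, stringsAsFactors = FALSE)
  check_columns(df, c("run_id", "product_id", "role", "cell_id",
                      "time_min", "conc_ug_per_ml"), "IVRT data CSV")
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  check_columns(meta, c("run_id", "cell_volume_ml", "sample_volume_ml",
                        "orifice_diameter_mm", "temperature_c"),
                "IVRT metadata CSV")
  bad <- which(df$conc_ug_per_ml < 0)
  if (length(bad))
    stop("negative concentration at data row(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  runs <- lapply(unique(df$run_id), function(id) {
    d <- df[df$run_id == id, ]
    m <- meta[meta$run_id == id, ]
    if (nrow(m) != 1L)
      stop("metadata missing or duplicated for run ", id, call. = FALSE)
    times <- sort(unique(d$time_min))
    cells <- unique(d$cell_id)
    conc <- matrix(NA_real_, length(cells), length(times),
                   dimnames = list(cells, times))
    for (i in seq_len(nrow(d)))
      conc[d$cell_id[i], as.character(d$time_min[i])] <- d$conc_ug_per_ml[i]
    if (anyNA(conc))
      stop("run ", id, ": incomplete cell x time grid", call. = FALSE)
    ivrt_run(unique(d$product_id), unique(d$role), times, conc,
             cell_volume = m$cell_volume_ml,
             sample_volume = m$sample_volume_ml,
             orifice_diameter = m$orifice_diameter_mm,
             temperature = m$temperature_c)
  })
  names(runs) <- unique(df$run_id)
  runs
}

#' Write / read tape-strip sites as CSV
#'
#' Long format: `participant_id, site, product_id, strip_index,
#' pre_weight_ug, post_weight_ug, drug_ug, site_area_cm2,
#' application_time_min` (the last two constant within a site).
#'
#' @param sites List of [strip_site()] objects.
#' @param path CSV path.
#' @return `write_tape_strip_csv`: the path, invisibly.
#'   `read_tape_strip_csv`: a list of `strip_site`s.
#' @export
write_tape_strip_csv <- function(sites, path) {
  rows <- do.call(rbind, lapply(sites, function(s)
    data.frame(participant_id = s$participant_id, site = s$site,
               product_id = s$product_id,
               strip_index = s$strips$index,
               pre_weight_ug = s$strips$pre_weight,
               post_weight_ug = s$strips$post_weight,
               drug_ug = s$strips$drug_amount,
               site_area_cm2 = s$site_area,
               application_time_min = s$application_time)))
  rownames(rows) <- NULL
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tape_strip_csv
#' @export
read_tape_strip_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("participant_id", "site", "product_id", "strip_index",
                      "pre_weight_ug", "post_weight_ug", "drug_ug",
                      "site_area_cm2", "application_time_min"),
                "tape-strip CSV")
  bad <- which(df$drug_ug < 0)
  if (length(bad))
    stop("negative drug amount at row(s) ", paste(bad + 1L, collapse = ", "),
         call. = FALSE)
  key <- paste(df$participant_id, df$site, sep = ".")
  lapply(split(df, factor(key, levels = unique(key))), function(d) {
    d <- d[order(d$strip_index), ]
    strip_site(d$participant_id[1], d$site[1], d$product_id[1],
               d$pre_weight_ug, d$post_weight_ug, d$drug_ug,
               site_area = d$site_area_cm2[1],
               application_time = d$application_time_min[1])
  })
}

#' Write / read TEWL series as CSV
#'
#' Columns: `participant_id, cum_mass_ug, tewl`.
#'
#' @param series List of [tewl_series()] objects.
#' @param path CSV path.
#' @return `write_tewl_csv`: the path, invisibly. `read_tewl_csv`: a
#'   named list of `tewl_series` (by participant).
#' @export
write_tewl_csv <- function(series, path) {
  rows <- do.call(rbind, lapply(series, function(s)
    data.frame(participant_id = s$participant_id,
               cum_mass_ug = s$readings$cum_mass,
               tewl = s$readings$tewl)))
  rownames(rows) <- NULL
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tewl_csv
#' @export
read_tewl_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("participant_id", "cum_mass_ug", "tewl"), "TEWL CSV")
  out <- lapply(split(df, factor(df$participant_id,
                                 levels = unique(df$participant_id))),
                function(d) tewl_series(d$participant_id[1], d$cum_mass_ug,
                                        d$tewl))
  out
}

#' Write / read Level C correlation points as CSV
#'
#' Columns: `product_id, run_label, arc, auc, arc_sd, auc_sd`.
#'
#' @param points An [ivivc_points()] data frame.
#' @param path CSV path.
#' @return `write_ivivc_points_csv`: the path, invisibly.
#'   `read_ivivc_points_csv`: an `ivivc_points` data frame.
#' @export
write_ivivc_points_csv <- function(points, path) {
  write.csv(points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ivivc_points_csv
#' @export
read_ivivc_points_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("product_id", "run_label", "arc", "auc", "arc_sd",
                      "auc_sd"), "IVIVC points CSV")
  if (nrow(df) == 0) return(structure(df, class = c("ivivc_points",
                                                    "data.frame")))
  ivivc_points(df$product_id, df$run_label, df$arc, df$auc, df$arc_sd,
               df$auc_sd)
}

#' Write BE verdicts as CSV
#'
#' Columns: `product_id, arc, predicted_auc, arc_lower, arc_upper,
#' verdict`.
#'
#' @param verdicts List of `be_verdict`s.
#' @param bounds The [be_limits()] used.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_verdict_csv <- function(verdicts, bounds, path) {
  rows <- do.call(rbind, lapply(verdicts, function(v)
    data.frame(product_id = v$product_id, arc = round(v$arc, 2),
               predicted_auc = round(v$predicted_auc, 2),
               arc_lower = round(bounds$arc_lower, 2),
               arc_upper = round(bounds$arc_upper, 2),
               verdict = v$verdict)))
  rownames(rows) <- NULL
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
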