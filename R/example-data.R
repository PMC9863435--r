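#' Published summary points for the metronidazole cream study
#'
#' The five (ARC, AUC) summary points from the comparative study of a
#' 0.75% metronidazole reference cream against three test creams (T1
#' 0.75%, T2 0.56%, T3 0.95% MTZ): mean ARC per IVRT run (n = 6 cells)
#' and mean tape-strip AUC per product (n = 10 participants). The
#' reference was run twice (run 1 against T1, run 2 against T2/T3) and
#' contributes one point per run against its single observed AUC.
#'
#' These are reported study-level summaries, not raw data; the raw
#' per-cell and per-strip records were not published, which is why the
#' raw-stage machinery in this package is validated against the
#' synthetic generator instead.
#'
#' @return An [ivivc_points()] data frame with five rows.
#' @export
example_ivivc_points <- function() {
  read_ivivc_points_csv(system.file("extdata", "mtz_ivivc_points.csv",
                                    package = "dermivivc", mustWork = TRUE))
}
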