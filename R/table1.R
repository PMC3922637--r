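#' Per-patient program outputs for the 25-patient ischemia panel
#'
#' The packaged per-patient quantification table: ischemic extent and SD%
#' (both percent of left ventricle / percent of maximum score) reported by
#' four commercial software packages - EXINI, ECT (Emory Cardiac Toolbox),
#' QPS (Quantitative Perfusion SPECT) and 4DM (4D-MSPECT, columns
#' \code{dm4_*}) - for 25 patients with reversible ischemia, plus the
#' median and range of the extents delineated by 11 physicians.
#'
#' @return data.frame with 25 rows and columns \code{patient},
#'   \code{exini_extent}, \code{exini_sdpct}, \code{ect_extent},
#'   \code{ect_sdpct}, \code{qps_extent}, \code{qps_sdpct},
#'   \code{dm4_extent}, \code{dm4_sdpct}, \code{phys_median},
#'   \code{phys_min}, \code{phys_max}.
#' @examples
#' t1 <- table1Fixture()
#' columnSummary(t1$exini_extent)$mean  # 17.0
#' @export
table1Fixture <- function() {
  path <- system.file("extdata", "table1.csv", package = "polarQuant",
                      mustWork = TRUE)
  utils::read.csv(path)
}
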