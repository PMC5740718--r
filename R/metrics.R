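#' Lung-function metric registry
#'
#' The pipeline runs six analyses: intra-pair differences in the three
#' follow-up z-scores (cross-sectional flavour) and in the three z-score
#' changes over the follow-up period (longitudinal flavour). Intra-pair
#' differences of zFEV1, zFVC and their changes are strongly right-skewed
#' and enter the regression log-transformed; the two FEV1/FVC ratio metrics
#' enter untransformed.
#'
#' @return A data.frame with one row per analysis metric: `metric` (label),
#'   `measure` (underlying spirometry measure), `flavour`
#'   (`"cross-sectional"` or `"longitudinal"`), and `log_transform`.
#' @export
#' @examples
#' lung_metrics()
lung_metrics <- function() {
  data.frame(
    metric = c("zFEV1", "zFVC", "zFEV1/FVC",
               "zFEV1-change", "zFVC-change", "zFEV1/FVC-change"),
    measure = rep(c("FEV1", "FVC", "FEV1/FVC"), 2),
    flavour = rep(c("cross-sectional", "longitudinal"), each = 3),
    log_transform = rep(c(TRUE, TRUE, FALSE), 2),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
metric_info <- function(metric) {
  reg <- lung_metrics()
  i <- match(metric, reg$metric)
  if (is.na(i)) {
    stop("unknown lung-function metric: '", metric, "'", call. = FALSE)
  }
  reg[i, ]
}

# z-score panel column holding the pair-ordering value for a metric
metric_panel_column <- function(metric) {
  info <- metric_info(metric)
  stub <- c("FEV1" = "zFEV1", "FVC" = "zFVC", "FEV1/FVC" = "zFEV1FVC")[[info$measure]]
  if (info$flavour == "cross-sectional") paste0(stub, "_followup") else paste0(stub, "_change")
}

#' Leukocyte subtypes adjusted for in the regression models
#'
#' Order matches the haematology panel used for cell-composition adjustment:
#' monocytes, lymphocytes, basophils, neutrophils, eosinophils.
#' @return Character vector of the five cell-type labels.
#' @export
blood_cell_types <- function() {
  c("monocytes", "lymphocytes", "basophils", "neutrophils", "eosinophils")
}
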