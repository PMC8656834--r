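#' Published township incidence summary values
#'
#' Returns the published reference summaries shipped with the package:
#' median/IQR of township AMI incidence per stratum and period
#' (`"table1"`), or 10th/90th percentiles with the printed gap and ratio
#' (`"table2"`). These are printed values from a published township-level
#' AMI surveillance study, included so that the arithmetic connecting
#' them (percent changes, inequality gap and ratio) can be recomputed and
#' checked; they are inputs, not outputs of this package.
#'
#' @param which `"table1"` or `"table2"`.
#' @return a data.frame in long format (`row`, `period`, value columns).
#'   Rows are `total`, per-sex (`males`, `females`), and `sex:age` strata.
#' @export
published_summary <- function(which = c("table1", "table2")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("published_", which, ".csv"),
                      package = "amimap", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
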