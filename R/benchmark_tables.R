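#' Published per-disease ICD-10 annotation benchmark
#'
#' The per-disease mean accuracies (percent, with standard deviations)
#' reported for the deep-ensemble coder and two comparison methods — a
#' multiview KNN and a convolutional network — on a 2835-record clinical
#' dataset of 21 diseases. The underlying records are not deposited; this
#' table is a published summary, shipped so that report-level operations
#' such as [count_best_method()] can be exercised against real numbers.
#'
#' @return A data frame with columns `no`, `name`, `size`, and
#'   `{ensemble,mvknn,cnn}_{mean,sd}`.
#' @export
#' @examples
#' b <- icd10_benchmark()
#' count_best_method(b[, c("ensemble_mean", "mvknn_mean", "cnn_mean")])
icd10_benchmark <- function() {
  path <- system.file("extdata", "icd10_annotation_benchmark.csv",
                      package = "tcmensemble", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
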