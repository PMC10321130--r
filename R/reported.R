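# Accessors for the previously reported evaluation tables bundled with the
# package: the per-clusterer classifier metrics (sensitivity/specificity/
# accuracy for each of the 6 x 10 clusterer-classifier pairs) and the
# per-clusterer average entropies of the two EEG classes. They serve as
# arithmetic references: every reported benchmark row was obtained on
# balanced classes, so its accuracy must equal the mean of its sensitivity
# and specificity, and the entropy table's Average row must equal its column
# means.

#' Reported benchmark metrics bundled with the package
#'
#' @return data frame with columns `clusterer`, `classifier`, `sensitivity`,
#'   `specificity`, `accuracy` (percentages), one row per clusterer x
#'   classifier pair.
#' @export
reported_benchmark <- function() {
  read.csv(system.file("extdata", "reported_benchmark.csv",
                       package = "seizclust"),
           stringsAsFactors = FALSE)
}

#' Reported per-clusterer average entropies bundled with the package
#'
#' @return data frame with columns `clusterer`, `apen_A`, `apen_E`,
#'   `shannon_A`, `shannon_E`, `sampen_A`, `sampen_E`.
#' @export
reported_entropy <- function() {
  read.csv(system.file("extdata", "reported_entropy.csv",
                       package = "seizclust"),
           stringsAsFactors = FALSE)
}
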