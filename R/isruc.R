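# Published stage-distribution arithmetic for the ISRUC-Sleep benchmark
# subgroups, used to parameterise realistic class imbalance in simulations.

#' Stage distribution of the ISRUC-Sleep subgroups
#'
#' Epoch counts per stage as reported for ISRUC-S1 (100 healthy subjects)
#' and ISRUC-S3 (10 subjects with suspected sleep disorders), shipped as a
#' plain TSV. N2 dominates both cohorts and N1 is the minority class — the
#' natural imbalance of overnight sleep architecture.
#'
#' @return data frame with columns dataset, subjects, total and the five
#'   per-stage counts.
#' @export
isruc_stage_table <- function() {
  utils::read.delim(system.file("extdata", "isruc_stage_distribution.tsv",
                                package = "sleepgcn"),
                    stringsAsFactors = FALSE)
}

#' Per-stage proportions from a stage-count row
#'
#' @param counts named numeric vector of per-stage epoch counts
#'   (W, N1, N2, N3, R).
#' @return proportions summing to 1.
#' @export
stage_proportions <- function(counts) {
  counts <- counts[sleep_stages()]
  counts / sum(counts)
}
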