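#' Published summary tables of the ten-sample CLL reference cohort
#'
#' The package ships the per-sample summary counts reported for the
#' ten-patient chronic lymphocytic leukemia cohort (samples T1-T10) on
#' which the two pipelines were originally evaluated; the underlying raw
#' sequencing data are not publicly deposited, so these printed counts are
#' the recomputable ground truth for the summary arithmetic.
#' \describe{
#'   \item{de}{per-sample differentially expressed gene counts (PComp
#'     up/down/total), the transcriptomic-array counts, and the overlap
#'     between the two methods.}
#'   \item{fusions}{per-sample, per-caller fusion counts and
#'     array-validated TP counts, plus the published TP-rate percentages.}
#'   \item{overlap}{per-caller identified/TP/FP/FN bookkeeping over the
#'     29-fusion truth universe defined by the array overlap.}
#' }
#'
#' @return list of three data.frames: \code{de}, \code{fusions},
#'   \code{overlap}.
#' @examples
#' tabs <- cohortSummaryTables()
#' sum(tabs$de$pcomp_total)   # 15200
#' @export
cohortSummaryTables <- function() {
    path <- function(f) system.file("extdata", f, package = "PCompFusion",
                                    mustWork = TRUE)
    list(de = utils::read.delim(path("cohort_de_counts.tsv"),
                                check.names = FALSE),
         fusions = utils::read.delim(path("cohort_fusion_counts.tsv"),
                                     check.names = FALSE),
         overlap = utils::read.delim(path("cohort_overlap_counts.tsv"),
                                     check.names = FALSE))
}
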