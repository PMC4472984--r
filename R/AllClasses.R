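#' @import methods
#' @importFrom stats pt rnorm sd setNames aggregate
#' @importFrom utils read.csv read.delim write.table
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Experiment design for a qPCR screen
#'
#' Holds the analysis contract for a contrasting-genotype RT-qPCR screen: the
#' reference gene used for normalization, how free-text treatment labels map
#' onto the control/stress dichotomy, which cultivar is the stress-tolerant
#' and which the stress-sensitive genotype, and the decision thresholds
#' (minimum fold change and significance level) applied by every calling
#' stage.
#'
#' @slot reference_gene gene identifier of the internal-control gene
#'   (e.g. \code{"IF4a"}); its Cq must be present in every sample.
#' @slot control_treatment,stress_treatment the treatment labels used in
#'   input tables (e.g. \code{"water"}, \code{"dehydration"}); mapped to the
#'   canonical levels \code{"control"} and \code{"stress"} on import.
#' @slot tolerant_cultivar,sensitive_cultivar cultivar labels; must differ.
#' @slot fold_threshold minimum linear fold change (>= 1) for a call;
#'   default 2. Comparisons are inclusive ("at least two-fold").
#' @slot alpha significance level for the one-tailed t test; default 0.05.
#' @slot timepoints numeric vector of sampling times in hours.
#' @slot aggregate \code{"per_replicate"} (mean of per-replicate RQ values,
#'   Livak-style, the default) or \code{"of_means"} (2^-ddCt of mean dCt).
#' @slot test_scale scale on which the t test is run: \code{"delta_ct"}
#'   (default) or \code{"rq"}.
#'
#' @seealso [QpcrDesign()], [readQpcrDesign()]
#' @exportClass QpcrDesign
setClass("QpcrDesign",
  representation(
    reference_gene     = "character",
    control_treatment  = "character",
    stress_treatment   = "character",
    tolerant_cultivar  = "character",
    sensitive_cultivar = "character",
    fold_threshold     = "numeric",
    alpha              = "numeric",
    timepoints         = "numeric",
    aggregate          = "character",
    test_scale         = "character"
  )
)

setValidity("QpcrDesign", function(object) {
  msg <- character()
  scalar <- function(x) length(x) == 1L && !is.na(x)
  for (s in c("reference_gene", "control_treatment", "stress_treatment",
              "tolerant_cultivar", "sensitive_cultivar"))
    if (!scalar(slot(object, s)) || !nzchar(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a non-empty string", s))
  if (scalar(object@tolerant_cultivar) && scalar(object@sensitive_cultivar) &&
      identical(object@tolerant_cultivar, object@sensitive_cultivar))
    msg <- c(msg, "tolerant and sensitive cultivars must differ")
  if (!scalar(object@fold_threshold) || object@fold_threshold < 1)
    msg <- c(msg, "fold_threshold must be a single number >= 1")
  if (!scalar(object@alpha) || object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie strictly between 0 and 1")
  if (length(object@timepoints) < 1L || anyNA(object@timepoints) ||
      any(object@timepoints <= 0))
    msg <- c(msg, "timepoints must be positive hours")
  if (!object@aggregate %in% c("per_replicate", "of_means"))
    msg <- c(msg, "aggregate must be 'per_replicate' or 'of_means'")
  if (!object@test_scale %in% c("delta_ct", "rq"))
    msg <- c(msg, "test_scale must be 'delta_ct' or 'rq'")
  if (length(msg)) msg else TRUE
})

#' Container for a validated table of Cq measurements
#'
#' A [SummarizedExperiment::SummarizedExperiment] with a single \code{"cq"}
#' assay (genes in rows, samples in columns) and sample annotation columns
#' \code{cultivar}, \code{tissue}, \code{treatment} (canonicalized to
#' \code{control}/\code{stress}), \code{timepoint_h} and \code{bio_replicate}.
#' The [QpcrDesign-class] it was validated against is kept in
#' \code{metadata(x)$design}.
#'
#' Invariants enforced by the validity method: every Cq lies in (0, 45]
#' (the cycle range of a standard qPCR run), no measurement is missing
#' (absent replicates are an error, not an NA), each
#' (gene, cultivar, tissue, treatment, timepoint, replicate) key occurs once,
#' and the reference gene is measured in every sample.
#'
#' @seealso [CqExperiment()], [readCqTable()]
#' @exportClass CqExperiment
setClass("CqExperiment", contains = "SummarizedExperiment")

setValidity("CqExperiment", function(object) {
  msg <- character()
  if (!"cq" %in% SummarizedExperiment::assayNames(object))
    return("assay 'cq' is required")
  cd <- SummarizedExperiment::colData(object)
  need <- c("cultivar", "tissue", "treatment", "timepoint_h", "bio_replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("missing sample annotation column(s):",
                 paste(miss, collapse = ", ")))
  if (!all(cd$treatment %in% c("control", "stress")))
    msg <- c(msg, "treatment must be canonicalized to 'control'/'stress'")
  cq <- SummarizedExperiment::assay(object, "cq")
  if (anyNA(cq))
    msg <- c(msg, "missing Cq values are not allowed (complete replication required)")
  else if (any(cq <= 0 | cq > 45))
    msg <- c(msg, "all Cq values must lie in (0, 45]")
  key <- paste(cd$cultivar, cd$tissue, cd$treatment, cd$timepoint_h,
               cd$bio_replicate, sep = "\r")
  if (anyDuplicated(key))
    msg <- c(msg, "duplicate sample keys (cultivar/tissue/treatment/timepoint/replicate)")
  des <- S4Vectors::metadata(object)$design
  if (is.null(des) || !is(des, "QpcrDesign"))
    msg <- c(msg, "metadata(object)$design must hold a QpcrDesign")
  else if (!des@reference_gene %in% rownames(object))
    msg <- c(msg, sprintf("reference gene '%s' absent from the table",
                          des@reference_gene))
  if (length(msg)) msg else TRUE
})

#' Tissue-overlap partition of responsive genes
#'
#' Result of [vennPartition()]: per-direction membership of responsive genes
#' across two tissues, with genes showing opposite significant directions
#' across timepoints in either tissue set aside in \code{excluded_mixed}
#' rather than partitioned.
#'
#' Within each direction the three sets (\code{*_both}, \code{*_root_only},
#' \code{*_leaf_only}) are pairwise disjoint; a gene cleanly induced in one
#' tissue and repressed in the other legitimately appears in one up-set and
#' one down-set. \code{excluded_mixed} is disjoint from all six.
#'
#' @slot up_both,up_root_only,up_leaf_only,down_both,down_root_only,down_leaf_only
#'   character vectors of gene identifiers.
#' @slot excluded_mixed genes dropped for mixed (opposite-direction) patterns.
#' @slot tissues the two tissue labels, first = "root side" of the slot names.
#' @exportClass VennPartition
setClass("VennPartition",
  representation(
    up_both        = "character",
    up_root_only   = "character",
    up_leaf_only   = "character",
    down_both      = "character",
    down_root_only = "character",
    down_leaf_only = "character",
    excluded_mixed = "character",
    tissues        = "character"
  )
)

setValidity("VennPartition", function(object) {
  msg <- character()
  ups <- list(object@up_both, object@up_root_only, object@up_leaf_only)
  dns <- list(object@down_both, object@down_root_only, object@down_leaf_only)
  disjoint <- function(sets) {
    all_genes <- unlist(sets)
    !anyDuplicated(all_genes)
  }
  if (!disjoint(ups)) msg <- c(msg, "up-sets are not pairwise disjoint")
  if (!disjoint(dns)) msg <- c(msg, "down-sets are not pairwise disjoint")
  if (length(intersect(object@excluded_mixed, unlist(c(ups, dns)))))
    msg <- c(msg, "excluded_mixed overlaps a directional set")
  if (length(object@tissues) != 2L)
    msg <- c(msg, "exactly two tissues required")
  if (length(msg)) msg else TRUE
})

#' Scenario specification for the synthetic Cq generator
#'
#' Programmed ground truth for [simulateCq()]: the factorial design levels,
#' the control-condition target dCt (\code{baseline_dct}, in cycles, indexed
#' gene x cultivar x tissue x timepoint so that cross-genotype baseline
#' differences and their change between sampling times can be encoded), the
#' true stress log2 fold change per design cell (\code{true_log2fc}), the
#' reference-gene Cq level, and the biological noise SD on the Cq scale.
#'
#' @slot genes,cultivars,tissues,timepoints design levels.
#' @slot treatments length-2 character, \code{c(control, stress)} labels as
#'   they should appear in the generated table.
#' @slot n_replicates biological replicates per cell (default 3).
#' @slot baseline_dct numeric array \code{[gene, cultivar, tissue, timepoint]}:
#'   control-condition target-minus-reference Cq truth.
#' @slot true_log2fc numeric array with the same dimensions: stress-vs-control
#'   log2 fold change (positive = induced, so stress dCt is lowered by this
#'   amount).
#' @slot reference_ct reference-gene Cq level (default 20 cycles).
#' @slot noise_sd biological noise SD in cycles (>= 0).
#' @slot placeholder logical array marking cells whose magnitude is a
#'   conventional placeholder rather than an externally reported value; may
#'   be a 0-length logical when unused.
#' @seealso [CqScenario()], [paperScenario()], [simulateCq()],
#'   [deriveTruthTable()]
#' @exportClass CqScenario
setClass("CqScenario",
  representation(
    genes        = "character",
    cultivars    = "character",
    tissues      = "character",
    treatments   = "character",
    timepoints   = "numeric",
    n_replicates = "integer",
    baseline_dct = "array",
    true_log2fc  = "array",
    reference_ct = "numeric",
    noise_sd     = "numeric",
    placeholder  = "ANY"
  )
)

setValidity("CqScenario", function(object) {
  msg <- character()
  dims <- c(length(object@genes), length(object@cultivars),
            length(object@tissues), length(object@timepoints))
  if (any(dims < 1L)) msg <- c(msg, "all design levels must be non-empty")
  if (length(object@treatments) != 2L)
    msg <- c(msg, "treatments must be c(control_label, stress_label)")
  for (s in c("baseline_dct", "true_log2fc")) {
    a <- slot(object, s)
    if (!identical(unname(dim(a)), as.integer(unname(dims))))
      msg <- c(msg, sprintf("%s must be a [gene, cultivar, tissue, timepoint] array", s))
    else if (anyNA(a))
      msg <- c(msg, sprintf("%s must fully cover the design (no NA)", s))
  }
  if (object@n_replicates < 2L)
    msg <- c(msg, "n_replicates must be >= 2 (variance must be estimable)")
  if (length(object@noise_sd) != 1L || is.na(object@noise_sd) ||
      object@noise_sd < 0)
    msg <- c(msg, "noise_sd must be a single non-negative number")
  if (length(msg)) msg else TRUE
})
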