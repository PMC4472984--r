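.scen_dimnames <- function(genes, cultivars, tissues, timepoints) {
  list(gene = genes, cultivar = cultivars, tissue = tissues,
       timepoint = as.character(timepoints))
}

.scen_array <- function(value, dn, what) {
  dims <- lengths(dn)
  if (is.array(value)) {
    if (!identical(unname(dim(value)), unname(as.integer(dims))))
      stop(what, " array has wrong dimensions")
    dimnames(value) <- dn
    return(value)
  }
  if (length(value) == 1L)
    return(array(as.numeric(value), dim = dims, dimnames = dn))
  stop(what, " must be a scalar or a [gene, cultivar, tissue, timepoint] array")
}

#' Construct a synthetic-Cq scenario
#'
#' @param genes gene identifiers (the reference gene is added separately by
#'   the generator and must not appear here).
#' @param cultivars,tissues,timepoints design levels.
#' @param treatments length-2 labels \code{c(control, stress)} for the
#'   generated table.
#' @param n_replicates biological replicates per cell (default 3, the
#'   standard design this generator emulates).
#' @param baseline_dct control-condition target dCt truth: scalar or
#'   \code{[gene, cultivar, tissue, timepoint]} array (cycles).
#' @param true_log2fc stress-vs-control log2 fold change truth: scalar or
#'   array of the same shape.
#' @param reference_ct reference-gene Cq level (default 20 cycles).
#' @param noise_sd biological Gaussian noise SD on the Cq scale (default 0).
#' @param placeholder optional logical array flagging conventional
#'   placeholder magnitudes.
#' @return A validated [CqScenario-class].
#' @export
CqScenario <- function(genes, cultivars, tissues,
                       treatments = c("control", "stress"),
                       timepoints = c(2, 5), n_replicates = 3L,
                       baseline_dct = 5, true_log2fc = 0,
                       reference_ct = 20, noise_sd = 0,
                       placeholder = logical(0)) {
  dn <- .scen_dimnames(genes, cultivars, tissues, timepoints)
  new("CqScenario",
      genes = as.character(genes), cultivars = as.character(cultivars),
      tissues = as.character(tissues), treatments = as.character(treatments),
      timepoints = as.numeric(timepoints),
      n_replicates = as.integer(n_replicates),
      baseline_dct = .scen_array(baseline_dct, dn, "baseline_dct"),
      true_log2fc = .scen_array(true_log2fc, dn, "true_log2fc"),
      reference_ct = as.numeric(reference_ct),
      noise_sd = as.numeric(noise_sd),
      placeholder = placeholder)
}

setMethod("show", "CqScenario", function(object) {
  cat("CqScenario:", length(object@genes), "genes x",
      length(object@cultivars), "cultivars x", length(object@tissues),
      "tissues x 2 treatments x", length(object@timepoints),
      "timepoints x", object@n_replicates, "replicates\n")
  cat("  reference Cq:", object@reference_ct, " noise SD:",
      object@noise_sd, "cycles\n")
})

#' Default analysis design for a scenario
#'
#' Convenience constructor of a [QpcrDesign-class] matching a scenario's
#' levels: treatments map from the scenario's labels, the first cultivar
#' plays the tolerant role and the second the sensitive role (a dummy label
#' is used for single-cultivar scenarios, which support response calling
#' but not genotype contrasts).
#'
#' @param spec a [CqScenario-class].
#' @param reference_gene name the generator gives the reference gene.
#' @param ... passed to [QpcrDesign()] (thresholds, test scale, ...).
#' @return A [QpcrDesign-class].
#' @export
scenarioDesign <- function(spec, reference_gene = "REF", ...) {
  stopifnot(is(spec, "CqScenario"))
  QpcrDesign(reference_gene = reference_gene,
             control_treatment = spec@treatments[1],
             stress_treatment = spec@treatments[2],
             tolerant_cultivar = spec@cultivars[1],
             sensitive_cultivar = if (length(spec@cultivars) >= 2L)
               spec@cultivars[2] else paste0(spec@cultivars[1], ".none"),
             timepoints = spec@timepoints, ...)
}

#' Simulate a Cq table with programmed ground truth
#'
#' Noise is additive Gaussian on the Cq scale, the standard qPCR error model
#' (multiplicative log-scale noise on expression). For each sample (cultivar
#' x tissue x treatment x timepoint x replicate) one reference Cq is drawn,
#' \code{reference_ct + N(0, noise_sd)}, and shared by all target genes of
#' that sample, mirroring same-sample normalization (reference noise cancels
#' within a replicate's dCt). Each target gene then gets
#' \code{Cq = refCq + baseline_dct - true_log2fc*[stress] + N(0, noise_sd)}.
#' Fully reproducible from \code{seed}.
#'
#' @param spec a [CqScenario-class].
#' @param design a [QpcrDesign-class] naming the reference gene and mapping
#'   the scenario's treatment labels; default [scenarioDesign()].
#' @param seed integer seed for the generator (RNG state is restored on
#'   exit).
#' @return A validated [CqExperiment-class] whose rows are the scenario
#'   genes plus the reference gene.
#' @examples
#' sc <- CqScenario(genes = c("g1", "g2"), cultivars = "T", tissues = "root",
#'                  true_log2fc = 2, noise_sd = 0)
#' responseCalls(simulateCq(sc, seed = 1))
#' @export
simulateCq <- function(spec, design = scenarioDesign(spec), seed = 1L) {
  stopifnot(is(spec, "CqScenario"), is(design, "QpcrDesign"))
  ref <- design@reference_gene
  if (ref %in% spec@genes)
    stop("reference gene name '", ref, "' collides with a scenario gene")
  if (!is.null(.GlobalEnv$.Random.seed)) {
    old <- .GlobalEnv$.Random.seed
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else on.exit(rm(".Random.seed", envir = .GlobalEnv))
  set.seed(as.integer(seed))

  samples <- expand.grid(bio_replicate = seq_len(spec@n_replicates),
                         timepoint_h = spec@timepoints,
                         treatment = spec@treatments,
                         tissue = spec@tissues,
                         cultivar = spec@cultivars,
                         stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
  ng <- length(spec@genes)
  recs <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    sm <- samples[i, ]
    ref_cq <- spec@reference_ct + stats::rnorm(1, 0, spec@noise_sd)
    ti <- as.character(sm$timepoint_h)
    base <- spec@baseline_dct[, sm$cultivar, sm$tissue, ti]
    lfc <- if (identical(sm$treatment, spec@treatments[2]))
      spec@true_log2fc[, sm$cultivar, sm$tissue, ti] else 0
    cq <- ref_cq + base - lfc + stats::rnorm(ng, 0, spec@noise_sd)
    recs[[i]] <- data.frame(
      gene_id = c(spec@genes, ref),
      cultivar = sm$cultivar, tissue = sm$tissue, treatment = sm$treatment,
      timepoint_h = sm$timepoint_h, bio_replicate = sm$bio_replicate,
      cq = c(cq, ref_cq))
  }
  CqExperiment(do.call(rbind, recs), design)
}

#' Analytic truth table of a scenario
#'
#' Applies the calling rules to the scenario's noiseless means: p-values are
#' taken as 0 wherever the programmed means differ and uninformative
#' otherwise, so a call reduces to the (inclusive) fold-change gate. The
#' result is what the full pipeline must reproduce on data simulated at
#' \code{noise_sd = 0}.
#'
#' @param spec a [CqScenario-class].
#' @param design a [QpcrDesign-class]; supplies thresholds and cultivar
#'   roles. Genotype-contrast truth is emitted only when both design
#'   cultivars are scenario levels.
#' @return list with \code{response_calls} (per gene x cultivar x tissue x
#'   timepoint: \code{true_fold}, \code{call}, \code{pattern}),
#'   \code{contrast_calls} (per gene x tissue x treatment x timepoint:
#'   \code{true_ratio}, \code{call}), and \code{state} (the implied state
#'   matrix, \code{NULL} without both cultivars).
#' @export
deriveTruthTable <- function(spec, design = scenarioDesign(spec)) {
  stopifnot(is(spec, "CqScenario"), is(design, "QpcrDesign"))
  lth <- log2(design@fold_threshold)
  dn <- dimnames(spec@true_log2fc)
  grid <- expand.grid(gene_id = dn$gene, cultivar = dn$cultivar,
                      tissue = dn$tissue, timepoint_h = spec@timepoints,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  lfc <- as.vector(spec@true_log2fc)
  resp <- data.frame(grid, true_fold = 2^lfc,
                     call = ifelse(lfc >= lth, "up",
                                   ifelse(lfc <= -lth, "down", "unchanged")))
  pat <- tapply(resp$call,
                paste(resp$gene_id, resp$cultivar, resp$tissue, sep = "\r"),
                classifyPattern)
  resp$pattern <- as.character(pat[paste(resp$gene_id, resp$cultivar,
                                         resp$tissue, sep = "\r")])

  contr <- NULL; state <- NULL
  if (all(c(design@tolerant_cultivar, design@sensitive_cultivar) %in%
          spec@cultivars)) {
    cg <- expand.grid(gene_id = dn$gene, tissue = dn$tissue,
                      treatment = c("control", "stress"),
                      timepoint_h = spec@timepoints,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    dct <- function(cv, tr, g, ti, tp) {
      b <- spec@baseline_dct[cbind(g, cv, ti, tp)]
      ifelse(tr == "stress", b - spec@true_log2fc[cbind(g, cv, ti, tp)], b)
    }
    tp <- as.character(cg$timepoint_h)
    l2r <- dct(design@sensitive_cultivar, cg$treatment, cg$gene_id,
               cg$tissue, tp) -
      dct(design@tolerant_cultivar, cg$treatment, cg$gene_id, cg$tissue, tp)
    contr <- data.frame(cg, true_ratio = 2^l2r,
                        call = ifelse(l2r >= lth, "higher",
                                      ifelse(l2r <= -lth, "lower",
                                             "similar")))
    state <- buildStateMatrix(
      stats::setNames(resp[, c("gene_id", "cultivar", "tissue", "pattern")],
                      c("gene_id", "cultivar", "tissue", "pattern")),
      contr, design)
  }
  list(response_calls = resp, contrast_calls = contr, state = state)
}
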