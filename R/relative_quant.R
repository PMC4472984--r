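.rowVars <- function(m) {
  if (ncol(m) < 2L) stop("need >= 2 replicates to estimate variance")
  rowSums((m - rowMeans(m))^2) / (ncol(m) - 1L)
}

# genes x samples dCt matrix: Cq(target) - Cq(reference) within each sample
.deltaCtMatrix <- function(x, design = qpcrDesign(x)) {
  cq <- SummarizedExperiment::assay(x, "cq")
  ref <- design@reference_gene
  if (!ref %in% rownames(cq))
    stop("reference gene '", ref, "' absent from the table")
  sweep(cq, 2L, cq[ref, ], "-")
}

#' Reference-normalized dCt values
#'
#' For every target gene and biological replicate,
#' dCt = Cq(target) - Cq(reference) within the same sample, the
#' log2-scale reference-normalized expression of the 2^-ddCt method. The
#' reference gene itself yields all-zero values and is dropped unless
#' \code{include_reference = TRUE}.
#'
#' @param x a [CqExperiment-class].
#' @param design a [QpcrDesign-class]; defaults to the one stored in \code{x}.
#' @param include_reference keep the reference gene's (all-zero) rows?
#' @return data.frame with columns \code{gene_id}, \code{cultivar},
#'   \code{tissue}, \code{treatment}, \code{timepoint_h},
#'   \code{bio_replicate}, \code{delta_ct}.
#' @examples
#' des <- QpcrDesign(reference_gene = "ref", tolerant_cultivar = "T",
#'                   sensitive_cultivar = "S", timepoints = 2)
#' rec <- expand.grid(gene_id = c("g1", "ref"), cultivar = "T",
#'                    tissue = "root", treatment = c("control", "stress"),
#'                    timepoint_h = 2, bio_replicate = 1:3)
#' rec$cq <- ifelse(rec$gene_id == "ref", 20, 24)
#' deltaCt(CqExperiment(rec, des))
#' @export
deltaCt <- function(x, design = qpcrDesign(x), include_reference = FALSE) {
  d <- .deltaCtMatrix(x, design)
  if (!include_reference)
    d <- d[setdiff(rownames(d), design@reference_gene), , drop = FALSE]
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  out <- data.frame(
    gene_id = rep(rownames(d), times = ncol(d)),
    cd[rep(seq_len(nrow(cd)), each = nrow(d)),
       c("cultivar", "tissue", "treatment", "timepoint_h", "bio_replicate")],
    delta_ct = as.vector(d), row.names = NULL)
  out
}

#' Relative quantity from a target and a calibrator dCt set
#'
#' The elementary 2^-ddCt computation: with calibrator mean dCt m,
#' per-replicate RQ_i = 2^-(dCt_i - m); \code{mean_rq} is their mean
#' (\code{aggregate = "per_replicate"}, Livak-style, matching figures that
#' show SE bars of biological replicates on the linear RQ scale) or
#' 2^-(mean(dCt) - m) (\code{aggregate = "of_means"}). \code{se_rq} is
#' sd(RQ_i)/sqrt(n) in either mode. When the target is its own calibrator
#' the reported mean is pinned to exactly 1 (\code{self_calibrated = TRUE}),
#' the convention used when figures state normalization "to a value of 1" in
#' the control; the unpinned mean is returned alongside.
#'
#' @param target,calibrator numeric vectors of per-replicate dCt values
#'   (>= 2 each).
#' @param aggregate see above.
#' @param self_calibrated pin the reported mean to 1.
#' @return list with \code{mean_rq}, \code{se_rq}, \code{n},
#'   \code{mean_rq_raw} (unpinned).
#' @examples
#' rqFromDeltaCt(c(2, 2, 2), c(3, 3, 3))$mean_rq   # ddCt = -1 -> RQ 2
#' @export
rqFromDeltaCt <- function(target, calibrator,
                          aggregate = c("per_replicate", "of_means"),
                          self_calibrated = FALSE) {
  aggregate <- match.arg(aggregate)
  if (length(target) < 2L || length(calibrator) < 2L)
    stop("target and calibrator need >= 2 replicates each")
  rq <- 2^-(target - mean(calibrator))
  raw <- if (aggregate == "per_replicate") mean(rq)
         else 2^-(mean(target) - mean(calibrator))
  list(mean_rq = if (self_calibrated) 1 else raw,
       se_rq = stats::sd(rq) / sqrt(length(rq)),
       n = length(rq),
       mean_rq_raw = raw)
}

#' Calibrated 2^-ddCt relative expression for every design cell
#'
#' Computes per-condition mean relative quantity (RQ) with replicate
#' standard errors, calibrated against the control-treatment sample of the
#' same gene, cultivar, tissue and timepoint, so that each genotype's
#' control sits at RQ = 1. Because this within-genotype calibration erases
#' between-genotype baseline differences, cross-cultivar comparisons must
#' use [genotypeContrasts()] (dCt-based), never these RQ values.
#'
#' @param x a [CqExperiment-class].
#' @param design a [QpcrDesign-class]; its \code{aggregate} slot selects the
#'   RQ aggregation mode (see [rqFromDeltaCt()]).
#' @return data.frame with one row per gene x cultivar x tissue x treatment
#'   x timepoint: \code{mean_rq}, \code{se_rq}, \code{n},
#'   \code{calibrator_treatment}.
#' @export
relativeExpression <- function(x, design = qpcrDesign(x)) {
  d <- .deltaCtMatrix(x, design)
  d <- d[setdiff(rownames(d), design@reference_gene), , drop = FALSE]
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  cells <- unique(cd[, c("cultivar", "tissue", "treatment", "timepoint_h")])
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    sel <- cd$cultivar == cell$cultivar & cd$tissue == cell$tissue &
      cd$treatment == cell$treatment & cd$timepoint_h == cell$timepoint_h
    cal <- cd$cultivar == cell$cultivar & cd$tissue == cell$tissue &
      cd$treatment == "control" & cd$timepoint_h == cell$timepoint_h
    if (sum(sel) < 2L || sum(cal) < 2L)
      stop("fewer than 2 replicates for cell (", cell$cultivar, ", ",
           cell$tissue, ", ", cell$treatment, ", ", cell$timepoint_h, " h)")
    dt <- d[, sel, drop = FALSE]
    dc <- d[, cal, drop = FALSE]
    rq <- 2^-(dt - rowMeans(dc))
    raw <- if (design@aggregate == "per_replicate") rowMeans(rq)
           else 2^-(rowMeans(dt) - rowMeans(dc))
    pin <- cell$treatment == "control"
    out[[i]] <- data.frame(
      gene_id = rownames(d), cell, row.names = NULL,
      mean_rq = if (pin) rep(1, nrow(d)) else raw,
      se_rq = sqrt(.rowVars(rq)) / sqrt(ncol(rq)),
      n = ncol(rq),
      mean_rq_raw = raw,
      calibrator_treatment = "control")
  }
  res <- do.call(rbind, out)
  res <- res[order(res$gene_id, res$cultivar, res$tissue, res$treatment,
                   res$timepoint_h), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Human-readable fold label
#'
#' Repression is conventionally reported as "n-fold down" with n = 1/RQ.
#'
#' @param fc positive linear fold change(s).
#' @param digits significant digits (default 3).
#' @return character vector like \code{"17.5-fold down"}.
#' @export
foldLabel <- function(fc, digits = 3) {
  stopifnot(all(fc > 0))
  ifelse(fc >= 1,
         sprintf("%s-fold up", signif(fc, digits)),
         sprintf("%s-fold down", signif(1 / fc, digits)))
}
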