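#' Tolerant-vs-sensitive expression contrasts
#'
#' Compares the two genotypes per gene x tissue x treatment x timepoint on
#' the reference-normalized dCt scale:
#' ratio = 2^-(mean dCt tolerant - mean dCt sensitive), with a one-tailed
#' t test on the two dCt replicate sets. A cell is \code{"higher"} if
#' ratio >= threshold and p < alpha, \code{"lower"} if ratio <= 1/threshold
#' and p < alpha, otherwise \code{"similar"} (thresholds inclusive).
#'
#' Contrasts are deliberately computed from dCt, never from calibrated RQ:
#' within-genotype calibration pins both genotypes' controls to 1 and
#' destroys the between-genotype baseline differences these contrasts exist
#' to measure.
#'
#' @param x a [CqExperiment-class] containing both cultivars.
#' @param design a [QpcrDesign-class] naming the tolerant and sensitive
#'   cultivar; defaults to the one stored in \code{x}.
#' @return data.frame with one row per gene x tissue x treatment x
#'   timepoint: \code{ratio} (tolerant/sensitive, linear), \code{p_value},
#'   \code{call}.
#' @export
genotypeContrasts <- function(x, design = qpcrDesign(x)) {
  d <- .deltaCtMatrix(x, design)
  d <- d[setdiff(rownames(d), design@reference_gene), , drop = FALSE]
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  for (cv in c(design@tolerant_cultivar, design@sensitive_cultivar))
    if (!cv %in% cd$cultivar)
      stop("cultivar '", cv, "' absent from the table")
  combos <- unique(cd[, c("tissue", "treatment", "timepoint_h")])
  out <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    in_cell <- cd$tissue == cb$tissue & cd$treatment == cb$treatment &
      cd$timepoint_h == cb$timepoint_h
    tl <- in_cell & cd$cultivar == design@tolerant_cultivar
    sn <- in_cell & cd$cultivar == design@sensitive_cultivar
    if (sum(tl) < 2L || sum(sn) < 2L)
      stop("fewer than 2 replicates per cultivar for (", cb$tissue, ", ",
           cb$treatment, ", ", cb$timepoint_h, " h)")
    dt <- d[, tl, drop = FALSE]; dsn <- d[, sn, drop = FALSE]
    ratio <- 2^-(rowMeans(dt) - rowMeans(dsn))
    p <- .one_tailed_p_vec(rowMeans(dt), .rowVars(dt), ncol(dt),
                           rowMeans(dsn), .rowVars(dsn), ncol(dsn))
    out[[i]] <- data.frame(gene_id = rownames(d), cb, row.names = NULL,
                           ratio = unname(ratio), p_value = p,
                           call = .direction_call(ratio, p,
                                                  design@fold_threshold,
                                                  design@alpha,
                                                  c("higher", "lower",
                                                    "similar")))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$gene_id, res$tissue, res$treatment, res$timepoint_h), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
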