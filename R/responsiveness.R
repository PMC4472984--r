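#' One-tailed unpaired equal-variance t test
#'
#' Pooled-variance Student t test with the tail taken in the direction of
#' the observed mean difference (equivalently, half the two-tailed p).
#' Degenerate inputs follow fixed conventions so that zero-noise synthetic
#' data remain analyzable: if both groups are constant with equal means the
#' test is uninformative and p = 0.5 (t = 0); if the pooled variance is zero
#' but the means differ, p = 0 and the result carries attribute
#' \code{zero_variance = TRUE} as a warning flag.
#'
#' @param group_a,group_b numeric vectors, >= 2 values each.
#' @return one-tailed p-value in [0, 1] (possibly with attribute
#'   \code{zero_variance}).
#' @examples
#' oneTailedT(c(1, 2, 3), c(1, 2, 3))   # 0.5
#' oneTailedT(c(5, 6, 7), c(1, 2, 3))   # pooled t with df = 4
#' @export
oneTailedT <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs >= 2 values")
  n1 <- length(group_a); n2 <- length(group_b)
  sp2 <- ((n1 - 1) * stats::var(group_a) + (n2 - 1) * stats::var(group_b)) /
    (n1 + n2 - 2)
  diff <- mean(group_a) - mean(group_b)
  if (sp2 == 0) {
    if (diff == 0) return(0.5)
    p <- 0
    attr(p, "zero_variance") <- TRUE
    return(p)
  }
  tstat <- diff / sqrt(sp2 * (1 / n1 + 1 / n2))
  stats::pt(abs(tstat), df = n1 + n2 - 2, lower.tail = FALSE)
}

# vectorized one-tailed p over rows: means/vars are per-gene vectors
.one_tailed_p_vec <- function(m1, v1, n1, m2, v2, n2) {
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  diff <- m1 - m2
  p <- rep(NA_real_, length(diff))
  zv <- sp2 == 0
  p[zv & diff == 0] <- 0.5
  p[zv & diff != 0] <- 0
  ok <- !zv
  tstat <- diff[ok] / sqrt(sp2[ok] * (1 / n1 + 1 / n2))
  p[ok] <- stats::pt(abs(tstat), df = n1 + n2 - 2, lower.tail = FALSE)
  p
}

# direction call from a linear fold/ratio and p-value, inclusive thresholds
.direction_call <- function(fc, p, threshold, alpha, labels) {
  out <- rep(labels[3], length(fc))
  out[fc >= threshold & p < alpha] <- labels[1]
  out[fc <= 1 / threshold & p < alpha] <- labels[2]
  out
}

#' Classify per-timepoint direction calls into an overall pattern
#'
#' A gene is \code{"mixed"} iff its timepoint calls contain both an up and a
#' down (opposite significant directions at different times),
#' \code{"unchanged"} iff no call is directional, otherwise the single
#' direction present. Mixed genes still count as responsive but carry a flag
#' consumed by [vennPartition()].
#'
#' @param calls character vector of \code{"up"}/\code{"down"}/
#'   \code{"unchanged"} timepoint calls (>= 1).
#' @return one of \code{"up"}, \code{"down"}, \code{"mixed"},
#'   \code{"unchanged"}.
#' @export
classifyPattern <- function(calls) {
  if (length(calls) < 1L) stop("at least one timepoint call required")
  stopifnot(all(calls %in% c("up", "down", "unchanged")))
  has_up <- "up" %in% calls
  has_dn <- "down" %in% calls
  if (has_up && has_dn) "mixed"
  else if (has_up) "up"
  else if (has_dn) "down"
  else "unchanged"
}

#' Stress-responsiveness calls per gene, cultivar, tissue and timepoint
#'
#' For each timepoint, the stress-vs-control fold change is
#' 2^-(mean stress dCt - mean control dCt); a gene is called \code{up} if
#' fold >= threshold and p < alpha, \code{down} if fold <= 1/threshold and
#' p < alpha (thresholds inclusive: "at least two-fold" counts), otherwise
#' \code{unchanged}. The one-tailed t test runs on the dCt replicates by
#' default (approximately normal, variance-homogeneous) or on linear
#' per-replicate RQ values when \code{design@test_scale == "rq"}. The
#' overall \code{pattern} per gene x cultivar x tissue follows
#' [classifyPattern()]: responsive at >= 1 timepoint suffices.
#'
#' @param x a [CqExperiment-class].
#' @param design a [QpcrDesign-class]; defaults to the one stored in \code{x}.
#' @return data.frame with one row per gene x cultivar x tissue x timepoint:
#'   \code{fold_change}, \code{p_value}, \code{call}, and the per-gene
#'   \code{pattern} repeated across its timepoints.
#' @export
responseCalls <- function(x, design = qpcrDesign(x)) {
  d <- .deltaCtMatrix(x, design)
  d <- d[setdiff(rownames(d), design@reference_gene), , drop = FALSE]
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  combos <- unique(cd[, c("cultivar", "tissue", "timepoint_h")])
  out <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    in_cell <- cd$cultivar == cb$cultivar & cd$tissue == cb$tissue &
      cd$timepoint_h == cb$timepoint_h
    s <- in_cell & cd$treatment == "stress"
    c0 <- in_cell & cd$treatment == "control"
    if (sum(s) < 2L || sum(c0) < 2L)
      stop("fewer than 2 replicates for (", cb$cultivar, ", ", cb$tissue,
           ", ", cb$timepoint_h, " h)")
    ds <- d[, s, drop = FALSE]; dc <- d[, c0, drop = FALSE]
    fc <- 2^-(rowMeans(ds) - rowMeans(dc))
    if (design@test_scale == "rq") { ts <- 2^-ds; tc <- 2^-dc }
    else { ts <- ds; tc <- dc }
    p <- .one_tailed_p_vec(rowMeans(ts), .rowVars(ts), ncol(ts),
                           rowMeans(tc), .rowVars(tc), ncol(tc))
    out[[i]] <- data.frame(gene_id = rownames(d), cb, row.names = NULL,
                           fold_change = unname(fc), p_value = p,
                           call = .direction_call(fc, p,
                                                  design@fold_threshold,
                                                  design@alpha,
                                                  c("up", "down", "unchanged")))
  }
  res <- do.call(rbind, out)
  pat <- tapply(res$call,
                paste(res$gene_id, res$cultivar, res$tissue, sep = "\r"),
                classifyPattern)
  res$pattern <- as.character(pat[paste(res$gene_id, res$cultivar,
                                        res$tissue, sep = "\r")])
  res <- res[order(res$gene_id, res$cultivar, res$tissue, res$timepoint_h), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
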