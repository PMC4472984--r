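#' Partition responsive genes across two tissues
#'
#' Venn-style overlap analysis of per-gene response patterns in two tissues
#' of the same cultivar. Genes with a \code{mixed} pattern (opposite
#' significant directions across timepoints) in either tissue are wholly set
#' aside in \code{excluded_mixed} and take no part in the partition, even if
#' cleanly directional in the other tissue. Remaining genes join, per
#' direction, \code{*_both} when both tissues share the direction and
#' \code{*_root_only}/\code{*_leaf_only} otherwise; a gene induced in one
#' tissue and repressed in the other therefore appears in one up-set and one
#' down-set. Genes unchanged in both tissues appear nowhere.
#'
#' @param root_calls,leaf_calls data.frames with columns \code{gene_id} and
#'   \code{pattern} (one row per gene, e.g. unique rows of
#'   [responseCalls()] output for one tissue). If a \code{cultivar} column
#'   is present it must name the same single cultivar in both inputs. The
#'   two gene universes must coincide.
#' @return A [VennPartition-class].
#' @examples
#' pat <- paperResponsePatterns()
#' ilc <- split(pat[pat$cultivar == "ILC482", ], pat$tissue[pat$cultivar == "ILC482"])
#' vennPartition(ilc$root, ilc$leaf)
#' @export
vennPartition <- function(root_calls, leaf_calls) {
  pick <- function(df, side) {
    stopifnot(is.data.frame(df),
              all(c("gene_id", "pattern") %in% colnames(df)))
    df <- unique(df[, intersect(c("gene_id", "cultivar", "pattern"),
                                colnames(df))])
    if (anyDuplicated(df$gene_id))
      stop("conflicting patterns for one gene in the ", side, " input")
    stopifnot(all(df$pattern %in% .PATTERN_LEVELS))
    df
  }
  r <- pick(root_calls, "first")
  l <- pick(leaf_calls, "second")
  if ("cultivar" %in% colnames(r) && "cultivar" %in% colnames(l)) {
    cv <- unique(c(r$cultivar, l$cultivar))
    if (length(cv) != 1L)
      stop("both inputs must come from the same single cultivar; got: ",
           paste(cv, collapse = ", "))
  }
  if (!setequal(r$gene_id, l$gene_id))
    stop("gene universes differ between the two tissues")
  pr <- stats::setNames(r$pattern, r$gene_id)
  pl <- stats::setNames(l$pattern, l$gene_id)[names(pr)]

  excl <- names(pr)[pr == "mixed" | pl == "mixed"]
  keep <- setdiff(names(pr), excl)
  member <- function(dir) {
    in_r <- keep[pr[keep] == dir]
    in_l <- keep[pl[keep] == dir]
    list(both = sort(intersect(in_r, in_l)),
         r_only = sort(setdiff(in_r, in_l)),
         l_only = sort(setdiff(in_l, in_r)))
  }
  up <- member("up"); dn <- member("down")
  tissues <- c(
    if ("tissue" %in% colnames(root_calls))
      unique(root_calls$tissue) else "tissue1",
    if ("tissue" %in% colnames(leaf_calls))
      unique(leaf_calls$tissue) else "tissue2")
  new("VennPartition",
      up_both = up$both, up_root_only = up$r_only, up_leaf_only = up$l_only,
      down_both = dn$both, down_root_only = dn$r_only,
      down_leaf_only = dn$l_only,
      excluded_mixed = sort(excl), tissues = tissues)
}

.VENN_SLOTS <- c("up_both", "up_root_only", "up_leaf_only",
                 "down_both", "down_root_only", "down_leaf_only",
                 "excluded_mixed")

#' Gene members of a VennPartition set
#' @param x a [VennPartition-class].
#' @param set one of \code{up_both}, \code{up_root_only},
#'   \code{up_leaf_only}, \code{down_both}, \code{down_root_only},
#'   \code{down_leaf_only}, \code{excluded_mixed}.
#' @return character vector of gene identifiers.
#' @export
vennMembers <- function(x, set = .VENN_SLOTS) {
  stopifnot(is(x, "VennPartition"))
  slot(x, match.arg(set))
}

#' @describeIn vennPartition flatten a partition to a per-gene table with
#'   one row per (gene, set) membership.
#' @param x a [VennPartition-class].
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "VennPartition", function(x, ...) {
  rows <- lapply(.VENN_SLOTS, function(s) {
    genes <- slot(x, s)
    if (!length(genes)) return(NULL)
    data.frame(gene_id = genes, set = s)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(gene_id = character(),
                                      set = character())
  rownames(out) <- NULL
  out
})

setMethod("show", "VennPartition", function(object) {
  cat("VennPartition (", object@tissues[1], " vs ", object@tissues[2],
      ")\n", sep = "")
  for (s in .VENN_SLOTS) {
    genes <- slot(object, s)
    cat(sprintf("  %-15s n=%2d  %s\n", s, length(genes),
                paste(genes, collapse = ", ")))
  }
})
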