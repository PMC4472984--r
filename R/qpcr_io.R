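#' Construct a QpcrDesign
#'
#' @param reference_gene gene identifier of the internal-control gene.
#' @param control_treatment,stress_treatment treatment labels as they appear
#'   in input tables; mapped to canonical \code{control}/\code{stress} levels
#'   on import so that field vocabularies ("water", "dehydration", ...) need
#'   not be hard-coded.
#' @param tolerant_cultivar,sensitive_cultivar genotype labels; must differ.
#' @param fold_threshold minimum linear fold change for any call (inclusive);
#'   default 2.
#' @param alpha significance level for the one-tailed t test; default 0.05.
#' @param timepoints sampling times in hours.
#' @param aggregate RQ aggregation mode, \code{"per_replicate"} (default) or
#'   \code{"of_means"}; see [relativeExpression()].
#' @param test_scale scale for the t test, \code{"delta_ct"} (default) or
#'   \code{"rq"}; see [responseCalls()].
#' @return A validated [QpcrDesign-class] object.
#' @examples
#' QpcrDesign(reference_gene = "IF4a",
#'            control_treatment = "water", stress_treatment = "dehydration",
#'            tolerant_cultivar = "ILC482", sensitive_cultivar = "Hashem",
#'            timepoints = c(2, 5))
#' @export
QpcrDesign <- function(reference_gene,
                       control_treatment = "control",
                       stress_treatment = "stress",
                       tolerant_cultivar,
                       sensitive_cultivar,
                       fold_threshold = 2,
                       alpha = 0.05,
                       timepoints = c(2, 5),
                       aggregate = c("per_replicate", "of_means"),
                       test_scale = c("delta_ct", "rq")) {
  new("QpcrDesign",
      reference_gene     = as.character(reference_gene),
      control_treatment  = as.character(control_treatment),
      stress_treatment   = as.character(stress_treatment),
      tolerant_cultivar  = as.character(tolerant_cultivar),
      sensitive_cultivar = as.character(sensitive_cultivar),
      fold_threshold     = as.numeric(fold_threshold),
      alpha              = as.numeric(alpha),
      timepoints         = as.numeric(timepoints),
      aggregate          = match.arg(aggregate),
      test_scale         = match.arg(test_scale))
}

#' Read an experiment design from YAML
#'
#' Expected keys mirror the [QpcrDesign()] arguments; the threshold may be
#' given as \code{fold_change_threshold} or \code{fold_threshold}.
#'
#' @param path path to a YAML file.
#' @return A validated [QpcrDesign-class].
#' @export
readQpcrDesign <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  y <- yaml::read_yaml(path)
  thr <- y$fold_change_threshold
  if (is.null(thr)) thr <- y$fold_threshold
  if (is.null(thr)) thr <- 2
  QpcrDesign(
    reference_gene     = y$reference_gene,
    control_treatment  = if (is.null(y$control_treatment)) "control" else y$control_treatment,
    stress_treatment   = if (is.null(y$stress_treatment)) "stress" else y$stress_treatment,
    tolerant_cultivar  = y$tolerant_cultivar,
    sensitive_cultivar = y$sensitive_cultivar,
    fold_threshold     = thr,
    alpha              = if (is.null(y$alpha)) 0.05 else y$alpha,
    timepoints         = if (is.null(y$timepoints)) c(2, 5) else unlist(y$timepoints),
    aggregate          = if (is.null(y$aggregate)) "per_replicate" else y$aggregate,
    test_scale         = if (is.null(y$test_scale)) "delta_ct" else y$test_scale)
}

setMethod("show", "QpcrDesign", function(object) {
  cat("QpcrDesign\n")
  cat("  reference gene:    ", object@reference_gene, "\n")
  cat("  treatments:        ", object@control_treatment, "(control) /",
      object@stress_treatment, "(stress)\n")
  cat("  cultivars:         ", object@tolerant_cultivar, "(tolerant) /",
      object@sensitive_cultivar, "(sensitive)\n")
  cat("  timepoints (h):    ", paste(object@timepoints, collapse = ", "), "\n")
  cat("  call thresholds:    fold >=", object@fold_threshold,
      " P <", object@alpha, "\n")
  cat("  aggregate / test:  ", object@aggregate, "/", object@test_scale, "\n")
})

.CQ_COLUMNS <- c("gene_id", "cultivar", "tissue", "treatment",
                 "timepoint_h", "bio_replicate", "cq")

# Map free-text treatment labels onto canonical control/stress levels.
.map_treatment <- function(labels, design) {
  out <- rep(NA_character_, length(labels))
  out[labels %in% c(design@control_treatment, "control")] <- "control"
  out[labels %in% c(design@stress_treatment, "stress")] <- "stress"
  if (anyNA(out)) {
    bad <- unique(labels[is.na(out)])
    stop("unrecognized treatment label(s): ", paste(bad, collapse = ", "),
         " (design maps '", design@control_treatment, "' and '",
         design@stress_treatment, "')")
  }
  out
}

#' Build a CqExperiment from long-format records
#'
#' @param records data.frame with columns \code{gene_id}, \code{cultivar},
#'   \code{tissue}, \code{treatment}, \code{timepoint_h},
#'   \code{bio_replicate}, \code{cq} (one row per measurement).
#' @param design a [QpcrDesign-class]; treatment labels are mapped through it.
#' @return A validated [CqExperiment-class].
#' @export
CqExperiment <- function(records, design) {
  stopifnot(is.data.frame(records), is(design, "QpcrDesign"))
  miss <- setdiff(.CQ_COLUMNS, colnames(records))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  records$treatment <- .map_treatment(as.character(records$treatment), design)
  records$cq <- as.numeric(records$cq)

  bad <- which(!is.finite(records$cq) | records$cq <= 0 | records$cq > 45)
  if (length(bad))
    stop("Cq out of range (0, 45] at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))

  key <- do.call(paste, c(records[.CQ_COLUMNS[1:6]], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicate (gene, cultivar, tissue, treatment, timepoint, replicate) ",
         "key at row(s): ", paste(utils::head(dup, 5), collapse = ", "))
  }

  sample_key <- do.call(paste, c(records[.CQ_COLUMNS[2:6]], sep = "\r"))
  samples <- unique(records[.CQ_COLUMNS[2:6]])
  usample <- do.call(paste, c(samples, sep = "\r"))
  genes <- unique(as.character(records$gene_id))

  # reference gene must be measured in every sample cell
  ref_in <- usample %in% sample_key[records$gene_id == design@reference_gene]
  if (!all(ref_in)) {
    cell <- samples[which(!ref_in)[1], ]
    stop(sprintf(paste0("reference gene '%s' is missing for cell ",
                        "(cultivar=%s, tissue=%s, treatment=%s, ",
                        "timepoint_h=%s, bio_replicate=%s)"),
                 design@reference_gene, cell$cultivar, cell$tissue,
                 cell$treatment, cell$timepoint_h, cell$bio_replicate))
  }

  cq <- matrix(NA_real_, nrow = length(genes), ncol = nrow(samples),
               dimnames = list(genes, NULL))
  cq[cbind(match(records$gene_id, genes), match(sample_key, usample))] <-
    records$cq
  if (anyNA(cq)) {
    hole <- which(is.na(cq), arr.ind = TRUE)[1, ]
    cell <- samples[hole[2], ]
    stop(sprintf(paste0("gene '%s' has no Cq for cell (cultivar=%s, ",
                        "tissue=%s, treatment=%s, timepoint_h=%s, ",
                        "bio_replicate=%s); absent replicates are an error"),
                 genes[hole[1]], cell$cultivar, cell$tissue, cell$treatment,
                 cell$timepoint_h, cell$bio_replicate))
  }

  cd <- S4Vectors::DataFrame(samples)
  colnames(cq) <- rownames(cd) <-
    paste(samples$cultivar, samples$tissue, samples$treatment,
          paste0(samples$timepoint_h, "h"),
          paste0("r", samples$bio_replicate), sep = ".")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(cq = cq), colData = cd,
    metadata = list(design = design))
  new("CqExperiment", se)
}

#' Read and validate a long-format Cq table
#'
#' The only accepted dialect is tidy long CSV (UTF-8, header
#' \code{gene_id,cultivar,tissue,treatment,timepoint_h,bio_replicate,cq});
#' wide vendor exports and instrument-native formats are out of scope.
#'
#' @param path CSV file path.
#' @param design a [QpcrDesign-class] used to map treatment labels and to
#'   check that the reference gene is present in every sample.
#' @return A validated [CqExperiment-class].
#' @export
readCqTable <- function(path, design) {
  if (!file.exists(path)) stop("Cq table not found: ", path)
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8")
  miss <- setdiff(.CQ_COLUMNS, colnames(records))
  if (length(miss))
    stop("Cq table header must name ", paste(.CQ_COLUMNS, collapse = ","),
         "; missing: ", paste(miss, collapse = ", "))
  CqExperiment(records, design)
}

#' Export a CqExperiment as a long-format CSV
#'
#' Inverse of [readCqTable()] up to row order and treatment canonicalization.
#'
#' @param x a [CqExperiment-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeCqTable <- function(x, path) {
  stopifnot(is(x, "CqExperiment"))
  utils::write.csv(as.data.frame(cqRecords(x)), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Long-format view of a CqExperiment
#'
#' @param x a [CqExperiment-class].
#' @return data.frame with one row per measurement, columns as in the CSV
#'   dialect read by [readCqTable()].
#' @export
cqRecords <- function(x) {
  stopifnot(is(x, "CqExperiment"))
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  cq <- SummarizedExperiment::assay(x, "cq")
  out <- data.frame(
    gene_id = rep(rownames(cq), times = ncol(cq)),
    cd[rep(seq_len(nrow(cd)), each = nrow(cq)),
       c("cultivar", "tissue", "treatment", "timepoint_h", "bio_replicate")],
    cq = as.vector(cq),
    row.names = NULL)
  out[order(out$gene_id, out$cultivar, out$tissue, out$treatment,
            out$timepoint_h, out$bio_replicate), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Design accessor for a CqExperiment
#' @param x a [CqExperiment-class].
#' @return the [QpcrDesign-class] the table was validated against.
#' @export
qpcrDesign <- function(x) {
  stopifnot(is(x, "CqExperiment"))
  S4Vectors::metadata(x)$design
}

#' Write a result table as TSV
#'
#' Tab-separated, stable column order (as in the data.frame), numeric
#' columns serialized at 6 significant digits.
#'
#' @param results data.frame produced by a pipeline stage (may have 0 rows:
#'   a header-only file is written).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(results, path) {
  stopifnot(is.data.frame(results))
  out <- results
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  tryCatch(
    suppressWarnings(utils::write.table(out, path, sep = "\t",
                                        quote = FALSE, row.names = FALSE,
                                        na = "NA")),
    error = function(e) stop("cannot write report to '", path, "': ",
                             conditionMessage(e)))
  invisible(path)
}

#' Read back a TSV report written by [writeReport()]
#' @param path report path.
#' @return data.frame.
#' @export
readReport <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

.extdata <- function(file) {
  p <- system.file("extdata", file, package = "ddCtScreen", mustWork = FALSE)
  if (!nzchar(p) || !file.exists(p))
    stop("packaged fixture '", file, "' not found; installation is corrupt")
  p
}

.PATTERN_LEVELS  <- c("up", "down", "mixed", "unchanged")
.CONTRAST_LEVELS <- c("higher", "lower", "similar", "unknown")

#' Packaged qualitative response patterns of the chickpea NAC screen
#'
#' Per-gene dehydration-response pattern (up/down/mixed/unchanged) for the 19
#' CaNAC genes in each cultivar x tissue, transcribed from the screen's
#' published qualitative results.
#'
#' @return data.frame with columns \code{gene_id}, \code{cultivar},
#'   \code{tissue}, \code{pattern}.
#' @seealso [paperCallMatrix()]
#' @export
paperResponsePatterns <- function() {
  pat <- utils::read.delim(.extdata("canac_response_patterns.tsv"),
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "cultivar", "tissue", "pattern")
  if (!identical(colnames(pat), need) ||
      !all(pat$pattern %in% .PATTERN_LEVELS))
    stop("response-pattern fixture is corrupted")
  if (length(unique(pat$gene_id)) != 19L ||
      nrow(pat) != 19L * 2L * 2L || anyDuplicated(pat[, 1:3]))
    stop("response-pattern fixture is incomplete")
  pat
}

#' Packaged cross-cultivar contrast calls of the chickpea NAC screen
#'
#' Tolerant-vs-sensitive expression contrast call (higher/lower/similar) per
#' gene x tissue x treatment x timepoint. Cells whose identity the published
#' prose does not enumerate are recorded as \code{"unknown"}; cells
#' transcribed from an internally inconsistent sentence (the
#' dehydration-2h root enumeration mislabeled as a water-control comparison)
#' carry \code{ambiguous = TRUE}.
#'
#' @return data.frame with columns \code{gene_id}, \code{tissue},
#'   \code{treatment}, \code{timepoint_h}, \code{call}, \code{ambiguous}.
#' @seealso [paperCallMatrix()]
#' @export
paperContrastCalls <- function() {
  con <- utils::read.delim(.extdata("canac_contrast_calls.tsv"),
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "tissue", "treatment", "timepoint_h", "call",
            "ambiguous")
  if (!identical(colnames(con), need) ||
      !all(con$call %in% .CONTRAST_LEVELS) || !is.logical(con$ambiguous))
    stop("contrast-call fixture is corrupted")
  if (nrow(con) != 19L * 2L * 2L * 2L || anyDuplicated(con[, 1:4]))
    stop("contrast-call fixture is incomplete")
  con
}

#' Packaged qualitative state matrix of the chickpea NAC screen
#'
#' Joins [paperResponsePatterns()] and [paperContrastCalls()] into the wide
#' per-gene x tissue state matrix consumed by [selectCandidates()]:
#' dehydration pattern in the tolerant (ILC482) and sensitive (Hashem)
#' cultivar plus the four cross-cultivar contrast cells. Repeated calls
#' return identical objects (the fixture is constant).
#'
#' @return data.frame with columns \code{gene_id}, \code{tissue},
#'   \code{pattern_tolerant}, \code{pattern_sensitive},
#'   \code{contrast_<treatment>_<timepoint>h} and matching
#'   \code{ambiguous_<treatment>_<timepoint>h} flags.
#' @examples
#' m <- paperCallMatrix()
#' subset(m, gene_id == "CaNAC02" & tissue == "root")$pattern_tolerant
#' @export
paperCallMatrix <- function() {
  pat <- paperResponsePatterns()
  con <- paperContrastCalls()
  tol <- pat[pat$cultivar == "ILC482", ]
  sen <- pat[pat$cultivar == "Hashem", ]
  m <- merge(
    stats::setNames(tol[, c("gene_id", "tissue", "pattern")],
                    c("gene_id", "tissue", "pattern_tolerant")),
    stats::setNames(sen[, c("gene_id", "tissue", "pattern")],
                    c("gene_id", "tissue", "pattern_sensitive")),
    by = c("gene_id", "tissue"))
  for (tr in c("control", "stress")) {
    for (tp in sort(unique(con$timepoint_h))) {
      cc <- con[con$treatment == tr & con$timepoint_h == tp, ]
      col <- sprintf("contrast_%s_%gh", tr, tp)
      m[[col]] <- cc$call[match(paste(m$gene_id, m$tissue),
                                paste(cc$gene_id, cc$tissue))]
      m[[sprintf("ambiguous_%s_%gh", tr, tp)]] <-
        cc$ambiguous[match(paste(m$gene_id, m$tissue),
                           paste(cc$gene_id, cc$tissue))]
    }
  }
  if (anyNA(m)) stop("call-matrix fixtures do not align")
  m <- m[order(m$tissue, m$gene_id), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Packaged RT-qPCR primer metadata for the chickpea NAC screen
#'
#' Gene-specific primer pairs for the 19 CaNAC genes plus the IF4a
#' reference-gene primers, shipped as metadata only (primer design itself is
#' out of scope).
#'
#' @return data.frame with columns \code{gene_id}, \code{role},
#'   \code{forward_primer}, \code{reverse_primer}.
#' @export
canacPrimers <- function() {
  pr <- utils::read.delim(.extdata("canac_primers.tsv"),
                          stringsAsFactors = FALSE)
  if (!identical(colnames(pr), c("gene_id", "role", "forward_primer",
                                 "reverse_primer")) || nrow(pr) != 20L)
    stop("primer fixture is corrupted")
  pr
}
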