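.PIPELINE_STAGES <- c("quantify", "respond", "contrast", "venn", "select")
.STAGE_FILES <- c(quantify = "relative_expression.tsv",
                  respond = "response_calls.tsv",
                  contrast = "contrasts.tsv",
                  venn = "venn.tsv",
                  select = "candidates.tsv")

#' Run the full screen pipeline
#'
#' Orchestrates the stages end to end on a validated Cq table:
#' \code{quantify} (calibrated 2^-ddCt relative expression),
#' \code{respond} (per-timepoint responsiveness calls and patterns),
#' \code{contrast} (tolerant-vs-sensitive dCt contrasts), \code{venn}
#' (two-tissue overlap partition per cultivar, mixed-pattern genes
#' excluded) and \code{select} (Group-1/Group-2 candidate calls per
#' tissue). Each stage writes a fixed-name TSV into \code{out_dir} plus a
#' \code{summary.tsv} of call counts, Venn margins and candidate lists.
#' Thresholds are echoed to the log so every call is auditable; outputs are
#' deterministic given the input table. Existing output files are never
#' silently overwritten.
#'
#' @param cq a [CqExperiment-class], or the path of a long-format CSV to be
#'   read with [readCqTable()].
#' @param design a [QpcrDesign-class] (required when \code{cq} is a path;
#'   defaults to the design stored in the experiment otherwise).
#' @param out_dir output directory, created if needed.
#' @param stages subset of \code{quantify, respond, contrast, venn, select};
#'   dependencies are enforced (\code{venn} needs \code{respond};
#'   \code{select} needs \code{respond} and \code{contrast}).
#' @param rule_profile rule profile for [selectCandidates()].
#' @param force overwrite existing outputs.
#' @param quiet suppress log messages.
#' @return invisibly, a list with the stage result objects and the written
#'   file paths.
#' @export
runPipeline <- function(cq, design = NULL, out_dir = ".",
                        stages = .PIPELINE_STAGES,
                        rule_profile = c("paper", "literal"),
                        force = FALSE, quiet = FALSE) {
  rule_profile <- match.arg(rule_profile)
  stages <- match.arg(stages, .PIPELINE_STAGES, several.ok = TRUE)
  log <- function(...) if (!quiet) message("[ddCtScreen] ", ...)
  if (is.character(cq)) {
    if (is.null(design))
      stop("stage quantify: a design is required to read '", cq, "'")
    cq <- readCqTable(cq, design)
  }
  stopifnot(is(cq, "CqExperiment"))
  if (is.null(design)) design <- qpcrDesign(cq)

  need <- function(stage, deps)
    if (stage %in% stages && !all(deps %in% stages))
      stop("stage ", stage, " requires stage(s): ",
           paste(setdiff(deps, stages), collapse = ", "))
  need("venn", "respond")
  need("select", c("respond", "contrast"))

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  outfiles <- file.path(out_dir, c(.STAGE_FILES[stages], "summary.tsv"))
  clash <- outfiles[file.exists(outfiles)]
  if (length(clash) && !force)
    stop("output file(s) already exist (use force = TRUE): ",
         paste(basename(clash), collapse = ", "))

  log("thresholds: fold >= ", design@fold_threshold, ", alpha < ",
      design@alpha, ", test scale ", design@test_scale,
      ", aggregate ", design@aggregate)
  results <- list()
  summary_rows <- list()
  add_summary <- function(section, key, value)
    summary_rows[[length(summary_rows) + 1L]] <<-
      data.frame(section = section, key = key, value = as.character(value))

  emit <- function(stage, df) {
    path <- file.path(out_dir, .STAGE_FILES[[stage]])
    writeReport(df, path)
    log("stage ", stage, ": wrote ", path, " (", nrow(df), " rows)")
    path
  }
  paths <- character()

  if ("quantify" %in% stages) {
    results$relative_expression <- relativeExpression(cq, design)
    paths["quantify"] <- emit("quantify", results$relative_expression)
  }
  if ("respond" %in% stages) {
    rc <- responseCalls(cq, design)
    results$response_calls <- rc
    paths["respond"] <- emit("respond", rc)
    counts <- aggregate(list(n = rc$call),
                        rc[, c("cultivar", "tissue", "timepoint_h", "call")],
                        FUN = length)
    for (i in seq_len(nrow(counts)))
      if (counts$call[i] != "unchanged")
        add_summary("response_counts",
                    paste(counts$cultivar[i], counts$tissue[i],
                          paste0(counts$timepoint_h[i], "h"),
                          counts$call[i]),
                    counts$n[i])
    pat <- unique(rc[, c("gene_id", "cultivar", "tissue", "pattern")])
    rcount <- aggregate(list(n = pat$pattern != "unchanged"),
                        pat[, c("cultivar", "tissue")], FUN = sum)
    for (i in seq_len(nrow(rcount)))
      add_summary("responsive_genes",
                  paste(rcount$cultivar[i], rcount$tissue[i]), rcount$n[i])
  }
  if ("contrast" %in% stages) {
    results$contrasts <- genotypeContrasts(cq, design)
    paths["contrast"] <- emit("contrast", results$contrasts)
  }
  if ("venn" %in% stages) {
    pat <- unique(results$response_calls[, c("gene_id", "cultivar", "tissue",
                                             "pattern")])
    tissues <- sort(unique(pat$tissue))
    if (length(tissues) != 2L)
      stop("stage venn: exactly two tissues required, found ",
           length(tissues))
    venns <- list(); vtab <- list()
    for (cv in unique(pat$cultivar)) {
      sub <- pat[pat$cultivar == cv, ]
      vp <- vennPartition(sub[sub$tissue == tissues[1], ],
                          sub[sub$tissue == tissues[2], ])
      venns[[cv]] <- vp
      df <- as.data.frame(vp)
      vtab[[cv]] <- data.frame(cultivar = rep(cv, nrow(df)), df)
      for (s in .VENN_SLOTS)
        add_summary("venn", paste(cv, s), length(vennMembers(vp, s)))
    }
    results$venn <- venns
    vdf <- do.call(rbind, vtab)
    rownames(vdf) <- NULL
    writeReport(vdf, file.path(out_dir, "venn.tsv"))
    log("stage venn: wrote ", file.path(out_dir, "venn.tsv"))
    paths["venn"] <- file.path(out_dir, "venn.tsv")
  }
  if ("select" %in% stages) {
    state <- buildStateMatrix(results$response_calls, results$contrasts,
                              design)
    sel <- do.call(rbind, lapply(unique(state$tissue), function(ti)
      selectCandidates(state, ti, design, profile = rule_profile)))
    results$state_matrix <- state
    results$candidates <- sel
    paths["select"] <- emit("select", sel)
    for (ti in unique(sel$tissue))
      for (gr in c("group1", "group2"))
        add_summary("candidates", paste(ti, gr),
                    paste(sel$gene_id[sel$tissue == ti & sel$group == gr],
                          collapse = ","))
  }

  sm <- if (length(summary_rows)) do.call(rbind, summary_rows)
        else data.frame(section = character(), key = character(),
                        value = character())
  writeReport(sm, file.path(out_dir, "summary.tsv"))
  paths["summary"] <- file.path(out_dir, "summary.tsv")
  results$summary <- sm
  results$paths <- paths
  log("done: ", length(stages), " stage(s) completed")
  invisible(results)
}
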