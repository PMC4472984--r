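#' Assemble the per-gene qualitative state matrix
#'
#' Joins the two cultivars' response patterns and the cross-cultivar
#' contrast calls into one row per gene x tissue, the evidence table the
#' candidate rule engine consumes. Patterns and calls are copied verbatim
#' from the upstream results.
#'
#' @param responses [responseCalls()] output (or any data.frame with
#'   \code{gene_id}, \code{cultivar}, \code{tissue}, \code{pattern})
#'   covering both design cultivars.
#' @param contrasts [genotypeContrasts()] output (or any data.frame with
#'   \code{gene_id}, \code{tissue}, \code{treatment}, \code{timepoint_h},
#'   \code{call}).
#' @param design a [QpcrDesign-class]; declares the cultivar roles and the
#'   timepoints every gene must cover.
#' @return data.frame with columns \code{gene_id}, \code{tissue},
#'   \code{pattern_tolerant}, \code{pattern_sensitive} and one
#'   \code{contrast_<treatment>_<timepoint>h} column per cell.
#' @export
buildStateMatrix <- function(responses, contrasts, design) {
  stopifnot(is.data.frame(responses), is.data.frame(contrasts),
            is(design, "QpcrDesign"))
  pat <- unique(responses[, c("gene_id", "cultivar", "tissue", "pattern")])
  if (anyDuplicated(pat[, c("gene_id", "cultivar", "tissue")]))
    stop("conflicting patterns for a gene x cultivar x tissue")
  if (nrow(pat) == 0L) {
    out <- data.frame(gene_id = character(), tissue = character(),
                      pattern_tolerant = character(),
                      pattern_sensitive = character())
    for (tr in c("control", "stress"))
      for (tp in design@timepoints)
        out[[sprintf("contrast_%s_%gh", tr, tp)]] <- character()
    return(out)
  }
  tol <- pat[pat$cultivar == design@tolerant_cultivar, ]
  sen <- pat[pat$cultivar == design@sensitive_cultivar, ]
  m <- merge(
    stats::setNames(tol[, c("gene_id", "tissue", "pattern")],
                    c("gene_id", "tissue", "pattern_tolerant")),
    stats::setNames(sen[, c("gene_id", "tissue", "pattern")],
                    c("gene_id", "tissue", "pattern_sensitive")),
    by = c("gene_id", "tissue"), all = TRUE)
  universe <- unique(pat[, c("gene_id", "tissue")])
  missing_cells <- character()
  if (anyNA(m$pattern_tolerant))
    missing_cells <- c(missing_cells, sprintf(
      "pattern[%s] for %s/%s", design@tolerant_cultivar,
      m$gene_id[is.na(m$pattern_tolerant)],
      m$tissue[is.na(m$pattern_tolerant)]))
  if (anyNA(m$pattern_sensitive))
    missing_cells <- c(missing_cells, sprintf(
      "pattern[%s] for %s/%s", design@sensitive_cultivar,
      m$gene_id[is.na(m$pattern_sensitive)],
      m$tissue[is.na(m$pattern_sensitive)]))
  for (tr in c("control", "stress")) {
    for (tp in design@timepoints) {
      cc <- contrasts[contrasts$treatment == tr &
                        contrasts$timepoint_h == tp, ]
      col <- sprintf("contrast_%s_%gh", tr, tp)
      m[[col]] <- cc$call[match(paste(m$gene_id, m$tissue),
                                paste(cc$gene_id, cc$tissue))]
      if (anyNA(m[[col]]))
        missing_cells <- c(missing_cells,
                           sprintf("%s for %s/%s", col,
                                   m$gene_id[is.na(m[[col]])],
                                   m$tissue[is.na(m[[col]])]))
    }
  }
  if (length(missing_cells))
    stop("state matrix has coverage gaps: ",
         paste(utils::head(missing_cells, 10), collapse = "; "))
  m <- m[order(m$tissue, m$gene_id), , drop = FALSE]
  rownames(m) <- NULL
  m
}

# per-row predicate evaluation shared by both rule profiles;
# "unknown" contrast cells carry no evidence and behave as "similar"
.state_predicates <- function(row) {
  cc <- unlist(row[grep("^contrast_", names(row))])
  ctrl <- cc[grep("^contrast_control_", names(cc))]
  list(
    higher_any    = any(cc == "higher"),
    lower_any     = any(cc == "lower"),
    control_lower = any(ctrl == "lower"),
    tol           = row[["pattern_tolerant"]],
    sen           = row[["pattern_sensitive"]]
  )
}

.criterion_label <- function(pr) {
  tol_upish <- pr$tol %in% c("up", "mixed")
  if (pr$tol == "up" && pr$sen == "unchanged") "criterion_i_iii"
  else if (tol_upish && pr$sen %in% c("up", "mixed")) "criterion_ii"
  else if (pr$tol %in% c("up", "unchanged") && pr$sen == "down")
    "criterion_iii"
  else "operational_rule"
}

#' Select overexpression and knock-down candidate genes
#'
#' Applies the two-group selection rules to a qualitative state matrix
#' (from [buildStateMatrix()] or [paperCallMatrix()]) for one tissue.
#'
#' The default \code{"paper"} profile is the operational form of the
#' published criteria, reverse-engineered so that it reproduces the
#' published selections exactly: a gene joins \strong{Group 1}
#' (overexpression candidates) iff it is \emph{higher} in the tolerant
#' cultivar in at least one (treatment, timepoint) cell, is \emph{lower} at
#' no water-control cell (the control-lower veto that excludes genes like
#' CaNAC27, higher only under late dehydration but constitutively lower),
#' and is not down-regulated in the tolerant cultivar while the sensitive
#' cultivar is up or unchanged. A gene joins \strong{Group 2} (knock-down
#' candidates) iff it is \emph{lower} in at least one cell and neither
#' cultivar's pattern contains an up call (mixed counts as containing up).
#' A gene satisfying both rule sets is reported Group 1 (explicit
#' precedence). \code{"unknown"} contrast cells carry no evidence and are
#' treated as \code{similar}.
#'
#' The \code{"literal"} profile instead transcribes the stated criteria
#' (i)-(iii) and the Group-2 sentence word for word; it differs from the
#' operational profile on genes such as CaNAC27 (admitted by literal (ii))
#' and CaNAC04 in leaves (down-regulated in both cultivars, excluded by a
#' literal reading but selected operationally via its higher-in-tolerant
#' contrasts).
#'
#' @param state state matrix data.frame.
#' @param tissue tissue to select within (must be present in \code{state}).
#' @param design a [QpcrDesign-class] (declares timepoints; thresholds were
#'   applied upstream).
#' @param profile \code{"paper"} (default) or \code{"literal"}.
#' @return data.frame with one row per gene: \code{gene_id}, \code{tissue},
#'   \code{group} (\code{group1}/\code{group2}/\code{none}) and a
#'   \code{trace} of the satisfied/failed predicates (semicolon-joined).
#' @examples
#' sel <- selectCandidates(paperCallMatrix(), "root",
#'                         readQpcrDesign(system.file("extdata",
#'                           "canac_design.yaml", package = "ddCtScreen")))
#' sel$gene_id[sel$group == "group1"]
#' @export
selectCandidates <- function(state, tissue, design,
                             profile = c("paper", "literal")) {
  profile <- match.arg(profile)
  stopifnot(is.data.frame(state))
  if (!tissue %in% state$tissue)
    stop("tissue '", tissue, "' absent from the state matrix")
  st <- state[state$tissue == tissue, , drop = FALSE]
  res <- lapply(seq_len(nrow(st)), function(i) {
    pr <- .state_predicates(st[i, ])
    if (profile == "paper") {
      g1_parts <- c(
        higher_in_tolerant  = pr$higher_any,
        no_control_lower    = !pr$control_lower,
        not_down_vs_up_or_unchanged =
          !(pr$tol == "down" && pr$sen %in% c("up", "unchanged")))
      g2_parts <- c(
        lower_in_tolerant = pr$lower_any,
        tolerant_never_up = !pr$tol %in% c("up", "mixed"),
        sensitive_never_up = !pr$sen %in% c("up", "mixed"))
    } else {
      tol_up <- pr$tol == "up"
      g1_parts <- c(
        criterion_i  = tol_up && pr$sen == "unchanged" && pr$higher_any,
        criterion_ii = tol_up && pr$sen == "up" && pr$higher_any,
        criterion_iii = (tol_up && pr$sen == "unchanged") ||
          (pr$tol %in% c("up", "unchanged") && pr$sen == "down"))
      g2_parts <- c(
        both_unchanged_or_down =
          pr$tol %in% c("unchanged", "down") &&
          pr$sen %in% c("unchanged", "down"),
        lower_in_tolerant = pr$lower_any)
    }
    group1 <- if (profile == "paper") all(g1_parts) else any(g1_parts)
    group2 <- !group1 && all(g2_parts)
    group <- if (group1) "group1" else if (group2) "group2" else "none"
    fmt <- function(parts) paste(sprintf("%s:%s", names(parts),
                                         ifelse(parts, "yes", "no")),
                                 collapse = ";")
    trace <- if (group == "group1") {
      paste(fmt(g1_parts),
            if (profile == "paper")
              paste0("instantiates:", .criterion_label(pr)),
            sep = ";")
    } else if (group == "group2") fmt(g2_parts)
    else paste("group1", fmt(g1_parts), "group2", fmt(g2_parts), sep = ";")
    data.frame(gene_id = st$gene_id[i], tissue = tissue, group = group,
               trace = trace)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
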