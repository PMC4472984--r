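# Independent literal transcription of the operational selection rule,
# used as the enumeration oracle.
oracle_group <- function(pt, ps, cc2, cc5, cs2, cs5) {
  cells <- c(cc2, cc5, cs2, cs5)
  cells[cells == "unknown"] <- "similar"
  higher_any <- "higher" %in% cells
  lower_any <- "lower" %in% cells
  control_lower <- "lower" %in% c(cc2, cc5)
  g1 <- higher_any && !control_lower &&
    !(pt == "down" && (ps == "up" || ps == "unchanged"))
  tol_up <- pt == "up" || pt == "mixed"
  sen_up <- ps == "up" || ps == "mixed"
  g2 <- lower_any && !tol_up && !sen_up
  if (g1) "group1" else if (g2) "group2" else "none"
}

state_row <- function(pt, ps, cc2, cc5, cs2, cs5, gene = "g", tissue = "root") {
  data.frame(gene_id = gene, tissue = tissue,
             pattern_tolerant = pt, pattern_sensitive = ps,
             contrast_control_2h = cc2, contrast_control_5h = cc5,
             contrast_stress_2h = cs2, contrast_stress_5h = cs5)
}

test_that("the screen's state matrix yields the published selections", {
  des <- paperDesign()
  m <- paperCallMatrix()
  root <- selectCandidates(m, "root", des)
  leaf <- selectCandidates(m, "leaf", des)
  g1r <- root$gene_id[root$group == "group1"]
  g1l <- leaf$gene_id[leaf$group == "group1"]
  expect_setequal_sorted(g1r, c("CaNAC04", "CaNAC16", "CaNAC24"))
  expect_setequal_sorted(g1l, c("CaNAC04", "CaNAC05", "CaNAC16"))
  expect_identical(root$gene_id[root$group == "group2"], "CaNAC02")
  expect_identical(leaf$gene_id[leaf$group == "group2"], "CaNAC02")
  expect_setequal_sorted(union(g1r, g1l),
                         c("CaNAC04", "CaNAC05", "CaNAC16", "CaNAC24"))

  # the constitutively-lower gene induced late is vetoed from Group 1
  c27 <- root[root$gene_id == "CaNAC27", ]
  expect_identical(c27$group, "none")
  expect_match(c27$trace, "no_control_lower:no")
  # a selected gene's trace names the criterion it instantiates
  expect_match(root$trace[root$gene_id == "CaNAC16"], "criterion_ii")

  # all-unchanged, all-similar matrix selects nothing
  g <- sprintf("g%d", 1:4)
  empty <- state_row(rep("unchanged", 4), "unchanged", "similar", "similar",
                     "similar", "similar", gene = g)
  sel <- selectCandidates(empty, "root", des)
  expect_true(all(sel$group == "none"))
  expect_true(all(nzchar(sel$trace)))

  expect_error(selectCandidates(m, "stem", des), "absent")
})

test_that("selection agrees with the literal-transcription oracle over all 1296 single-gene matrices", {
  des <- paperDesign()
  pats <- c("up", "down", "mixed", "unchanged")
  cons <- c("higher", "lower", "similar")
  grid <- expand.grid(pt = pats, ps = pats, cc2 = cons, cc5 = cons,
                      cs2 = cons, cs5 = cons, stringsAsFactors = FALSE)
  expect_identical(nrow(grid), 1296L)
  state <- state_row(grid$pt, grid$ps, grid$cc2, grid$cc5, grid$cs2,
                     grid$cs5, gene = sprintf("g%04d", seq_len(nrow(grid))))
  got <- selectCandidates(state, "root", des)
  want <- vapply(seq_len(nrow(grid)), function(i)
    oracle_group(grid$pt[i], grid$ps[i], grid$cc2[i], grid$cc5[i],
                 grid$cs2[i], grid$cs5[i]), "")
  expect_identical(got$group, want)

  # mutual exclusivity holds over the enumeration (group1 precedence)
  expect_true(all(got$group %in% c("group1", "group2", "none")))
  expect_true(all(nzchar(got$trace[got$group != "none"])))

  # monotonicity: upgrading any similar cell to higher never demotes group1
  g1_idx <- which(got$group == "group1")
  cols <- c("cc2", "cc5", "cs2", "cs5")
  set.seed(1)
  for (i in sample(g1_idx, 60)) {
    for (cl in cols[grid[i, cols] == "similar"]) {
      up <- grid[i, ]
      up[[cl]] <- "higher"
      sel <- selectCandidates(
        state_row(up$pt, up$ps, up$cc2, up$cc5, up$cs2, up$cs5),
        "root", des)
      expect_identical(sel$group, "group1")
    }
  }
})

test_that("unknown contrast cells carry no evidence", {
  des <- paperDesign()
  s1 <- state_row("up", "up", "similar", "similar", "unknown", "unknown")
  expect_identical(selectCandidates(s1, "root", des)$group, "none")
  s2 <- state_row("down", "down", "unknown", "unknown", "lower", "unknown")
  expect_identical(selectCandidates(s2, "root", des)$group, "group2")
})

test_that("the literal profile transcribes criteria (i)-(iii) verbatim", {
  des <- paperDesign()
  m <- paperCallMatrix()
  root <- selectCandidates(m, "root", des, profile = "literal")
  leaf <- selectCandidates(m, "leaf", des, profile = "literal")
  # literal (ii) admits the gene the operational control-lower veto excludes
  expect_identical(root$group[root$gene_id == "CaNAC27"], "group1")
  # literal reading drops the leaf gene that is down-regulated in both
  # cultivars despite its higher-in-tolerant contrasts
  expect_identical(leaf$group[leaf$gene_id == "CaNAC04"], "none")

  # spot predicates
  expect_identical(selectCandidates(
    state_row("up", "unchanged", "similar", "similar", "higher", "similar"),
    "root", des, profile = "literal")$group, "group1")     # criterion (i)
  expect_identical(selectCandidates(
    state_row("unchanged", "down", "similar", "similar", "similar",
              "similar"),
    "root", des, profile = "literal")$group, "group1")     # criterion (iii)
  expect_identical(selectCandidates(
    state_row("down", "down", "lower", "similar", "similar", "similar"),
    "root", des, profile = "literal")$group, "group2")
})

test_that("state matrices are assembled verbatim and report coverage gaps", {
  des <- tiny_design()
  resp <- expand.grid(gene_id = c("g1", "g2"), cultivar = c("TOL", "SEN"),
                      tissue = "root", stringsAsFactors = FALSE)
  resp$pattern <- c("up", "down", "unchanged", "up")
  contr <- expand.grid(gene_id = c("g1", "g2"), tissue = "root",
                       treatment = c("control", "stress"),
                       timepoint_h = c(2, 5), stringsAsFactors = FALSE)
  contr$call <- "similar"
  st <- buildStateMatrix(resp, contr, des)
  expect_identical(st$pattern_tolerant, c("up", "down"))
  expect_identical(st$pattern_sensitive, c("unchanged", "up"))
  expect_true(all(st$contrast_control_2h == "similar"))

  expect_error(buildStateMatrix(resp, contr[contr$timepoint_h != 5, ], des),
               "coverage gaps")
  expect_error(buildStateMatrix(resp[resp$cultivar == "TOL", ], contr, des),
               "coverage gaps")
  # empty inputs give an empty matrix with the full schema
  empty <- buildStateMatrix(resp[0, ], contr[0, ], des)
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("pattern_tolerant", "contrast_stress_5h") %in%
                    colnames(empty)))
})
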