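calls_df <- function(genes, patterns, tissue) {
  data.frame(gene_id = genes, tissue = tissue, pattern = patterns)
}

# independent per-gene case analysis used as the enumeration oracle
brute_force_partition <- function(root_pat, leaf_pat) {
  sets <- list(up_both = character(), up_root_only = character(),
               up_leaf_only = character(), down_both = character(),
               down_root_only = character(), down_leaf_only = character(),
               excluded_mixed = character())
  for (g in names(root_pat)) {
    r <- root_pat[[g]]; l <- leaf_pat[[g]]
    if (r == "mixed" || l == "mixed") {
      sets$excluded_mixed <- c(sets$excluded_mixed, g)
      next
    }
    if (r == "up" && l == "up") sets$up_both <- c(sets$up_both, g)
    if (r == "up" && l != "up") sets$up_root_only <- c(sets$up_root_only, g)
    if (r != "up" && l == "up") sets$up_leaf_only <- c(sets$up_leaf_only, g)
    if (r == "down" && l == "down") sets$down_both <- c(sets$down_both, g)
    if (r == "down" && l != "down")
      sets$down_root_only <- c(sets$down_root_only, g)
    if (r != "down" && l == "down")
      sets$down_leaf_only <- c(sets$down_leaf_only, g)
  }
  lapply(sets, sort)
}

test_that("the screen's partition: 10 induced and 1 repressed in both tissues", {
  pat <- paperResponsePatterns()
  ilc <- pat[pat$cultivar == "ILC482", ]
  vp <- vennPartition(ilc[ilc$tissue == "root", ],
                      ilc[ilc$tissue == "leaf", ])
  expect_length(vennMembers(vp, "up_both"), 10)
  expect_length(vennMembers(vp, "down_both"), 1)
  expect_identical(vennMembers(vp, "down_both"), "CaNAC02")
  expect_identical(vennMembers(vp, "excluded_mixed"), "CaNAC24")
  # the gene with clean opposite tissue directions sits in one up-set and
  # one down-set
  expect_true("CaNAC46" %in% vennMembers(vp, "down_root_only"))
  expect_true("CaNAC46" %in% vennMembers(vp, "up_leaf_only"))
})

test_that("degenerate input: all genes unchanged gives empty sets", {
  g <- sprintf("g%d", 1:5)
  vp <- vennPartition(calls_df(g, "unchanged", "root"),
                      calls_df(g, "unchanged", "leaf"))
  for (s in c("up_both", "up_root_only", "up_leaf_only", "down_both",
              "down_root_only", "down_leaf_only", "excluded_mixed"))
    expect_length(vennMembers(vp, s), 0)
})

test_that("partition equals exhaustive per-gene case analysis on random calls", {
  lv <- c("up", "down", "mixed", "unchanged")
  set.seed(17)
  for (rep in 1:25) {
    g <- sprintf("g%02d", 1:12)
    rp <- setNames(sample(lv, 12, replace = TRUE), g)
    lp <- setNames(sample(lv, 12, replace = TRUE), g)
    vp <- vennPartition(calls_df(g, unname(rp), "root"),
                        calls_df(g, unname(lp), "leaf"))
    oracle <- brute_force_partition(as.list(rp), as.list(lp))
    for (s in names(oracle))
      expect_identical(vennMembers(vp, s), oracle[[s]], label = s)

    # conservation: root-responsive genes are fully accounted for
    root_resp <- sum(rp %in% c("up", "down", "mixed"))
    counted <- length(vennMembers(vp, "up_both")) +
      length(vennMembers(vp, "up_root_only")) +
      length(vennMembers(vp, "down_both")) +
      length(vennMembers(vp, "down_root_only")) +
      sum(rp[vennMembers(vp, "excluded_mixed")] %in%
            c("up", "down", "mixed"))
    expect_identical(counted, root_resp)

    # symmetry: swapping tissues swaps the *_only sets and fixes *_both
    sw <- vennPartition(calls_df(g, unname(lp), "leaf"),
                        calls_df(g, unname(rp), "root"))
    expect_identical(vennMembers(sw, "up_both"), vennMembers(vp, "up_both"))
    expect_identical(vennMembers(sw, "up_root_only"),
                     vennMembers(vp, "up_leaf_only"))
    expect_identical(vennMembers(sw, "down_leaf_only"),
                     vennMembers(vp, "down_root_only"))
    expect_identical(vennMembers(sw, "excluded_mixed"),
                     vennMembers(vp, "excluded_mixed"))
  }
})

test_that("mismatched gene universes and mixed cultivars are rejected", {
  expect_error(vennPartition(calls_df(c("a", "b"), "up", "root"),
                             calls_df(c("a", "c"), "up", "leaf")),
               "universes differ")
  r <- calls_df(c("a", "b"), "up", "root"); r$cultivar <- "TOL"
  l <- calls_df(c("a", "b"), "up", "leaf"); l$cultivar <- "SEN"
  expect_error(vennPartition(r, l), "same single cultivar")
})

test_that("a partition flattens to a tidy membership table", {
  pat <- paperResponsePatterns()
  ilc <- pat[pat$cultivar == "ILC482", ]
  vp <- vennPartition(ilc[ilc$tissue == "root", ],
                      ilc[ilc$tissue == "leaf", ])
  df <- as.data.frame(vp)
  expect_identical(colnames(df), c("gene_id", "set"))
  expect_identical(sum(df$set == "up_both"), 10L)
})
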