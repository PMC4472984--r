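test_that("zero-noise simulation reproduces the programmed truth exactly", {
  sc <- effect_scenario(lfc = 2, n_genes = 4, noise_sd = 0)
  cq <- simulateCq(sc, seed = 1)
  re <- relativeExpression(cq)
  expect_equal(re$mean_rq[re$treatment == "stress"],
               rep(4, sum(re$treatment == "stress")), tolerance = 1e-12)
})

test_that("simulation is deterministic in the seed and seeds are isolated", {
  sc <- effect_scenario(lfc = 1, n_genes = 5, noise_sd = 0.3)
  a <- simulateCq(sc, seed = 7)
  b <- simulateCq(sc, seed = 7)
  c <- simulateCq(sc, seed = 8)
  expect_identical(SummarizedExperiment::assay(a, "cq"),
                   SummarizedExperiment::assay(b, "cq"))
  expect_false(identical(SummarizedExperiment::assay(a, "cq"),
                         SummarizedExperiment::assay(c, "cq")))
  # the generator restores the caller's RNG state
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulateCq(sc, seed = 7)); after <- runif(1)
  expect_identical(before, after)
})

test_that("analytic truth table applies inclusive thresholds to noiseless means", {
  # exactly two-fold counts as responsive
  sc1 <- effect_scenario(lfc = 1, timepoints = 2)
  tt1 <- deriveTruthTable(sc1)
  expect_true(all(tt1$response_calls$call == "up"))
  # no programmed effect: everything unchanged and similar
  sc0 <- CqScenario(genes = c("g1", "g2"), cultivars = c("A", "B"),
                    tissues = "root", true_log2fc = 0, baseline_dct = 5)
  tt0 <- deriveTruthTable(sc0)
  expect_true(all(tt0$response_calls$call == "unchanged"))
  expect_true(all(tt0$contrast_calls$call == "similar"))
  expect_true(all(tt0$state$pattern_tolerant == "unchanged"))
})

test_that("truth table equals the full pipeline run at zero noise on random specs", {
  set.seed(23)
  for (rep in 1:3) {
    dn <- list(gene = sprintf("g%02d", 1:8), cultivar = c("A", "B"),
               tissue = c("root", "leaf"), timepoint = c("2", "5"))
    # dyadic effect sizes keep replicate means exact, so boundary cells
    # (true fold exactly at threshold) are decided identically by the
    # analytic rule and the floating-point pipeline
    lfc <- array(sample(c(-3, -1.25, 0, 0.75, 1, 2.5), prod(lengths(dn)),
                        replace = TRUE), dim = lengths(dn), dimnames = dn)
    base <- array(sample(c(3, 4, 5, 6), prod(lengths(dn)), replace = TRUE),
                  dim = lengths(dn), dimnames = dn)
    sc <- CqScenario(genes = dn$gene, cultivars = dn$cultivar,
                     tissues = dn$tissue,
                     treatments = c("water", "dehydration"),
                     timepoints = c(2, 5), baseline_dct = base,
                     true_log2fc = lfc, noise_sd = 0)
    des <- scenarioDesign(sc)
    tt <- deriveTruthTable(sc, des)
    cq <- simulateCq(sc, design = des, seed = rep)
    rc <- responseCalls(cq, des)
    key <- paste(rc$gene_id, rc$cultivar, rc$tissue, rc$timepoint_h)
    tr <- tt$response_calls
    tr <- tr[match(key, paste(tr$gene_id, tr$cultivar, tr$tissue,
                              tr$timepoint_h)), ]
    expect_identical(rc$call, tr$call)
    expect_identical(rc$pattern, tr$pattern)
    expect_equal(rc$fold_change, tr$true_fold, tolerance = 1e-9)

    ct <- genotypeContrasts(cq, des)
    kc <- paste(ct$gene_id, ct$tissue, ct$treatment, ct$timepoint_h)
    tc <- tt$contrast_calls
    tc <- tc[match(kc, paste(tc$gene_id, tc$tissue, tc$treatment,
                             tc$timepoint_h)), ]
    expect_identical(ct$call, tc$call)
    expect_equal(ct$ratio, tc$true_ratio, tolerance = 1e-9)
  }
})

test_that("directional-call recovery matches an independent re-implementation", {
  # independent generator + caller: dCt difference of means plus pooled t
  independent_rate <- function(n_genes, lfc, sd, n, seed) {
    set.seed(seed)
    hits <- 0L
    for (g in seq_len(n_genes)) {
      dct_c <- rnorm(n, 0, sd)
      dct_s <- -lfc + rnorm(n, 0, sd)
      fc <- 2^-(mean(dct_s) - mean(dct_c))
      p <- stats::t.test(dct_s, dct_c, var.equal = TRUE)$p.value / 2
      if (fc >= 2 && p < 0.05) hits <- hits + 1L
    }
    hits / n_genes
  }
  pipeline_rate <- function(n_genes, lfc, sd, seed) {
    sc <- effect_scenario(lfc = lfc, n_genes = n_genes, noise_sd = sd,
                          timepoints = 2)
    rc <- responseCalls(simulateCq(sc, seed = seed))
    mean(rc$call == "up")
  }
  # saturated regime: both implementations recover essentially everything
  expect_equal(pipeline_rate(500, 2, 0.25, 31),
               independent_rate(500, 2, 0.25, 3, 32), tolerance = 0.02)
  # boundary regime (true fold exactly at threshold): rates are
  # intermediate and must agree within binomial error
  r_pkg <- pipeline_rate(2000, 1, 0.25, 33)
  r_ind <- independent_rate(2000, 1, 0.25, 3, 34)
  expect_gt(r_pkg, 0.2); expect_lt(r_pkg, 0.8)
  expect_equal(r_pkg, r_ind, tolerance = 0.06)
})

test_that("the packaged screen scenario encodes the printed magnitudes", {
  sc <- paperScenario()
  expect_identical(length(sc@genes), 19L)
  expect_identical(sc@n_replicates, 3L)
  expect_identical(sc@treatments, c("water", "dehydration"))
  # strongest reported inductions and repressions
  expect_gte(2^sc@true_log2fc["CaNAC27", "ILC482", "root", "5"], 300)
  expect_gte(2^sc@true_log2fc["CaNAC67", "ILC482", "leaf", "5"], 400)
  expect_equal(2^-sc@true_log2fc["CaNAC02", "ILC482", "root", "5"], 17.5)
  expect_equal(2^-sc@true_log2fc["CaNAC02", "ILC482", "leaf", "5"], 9.2)
  expect_equal(2^-sc@true_log2fc["CaNAC24", "ILC482", "leaf", "2"], 3.8)
  expect_equal(2^sc@true_log2fc["CaNAC24", "ILC482", "leaf", "5"], 2.1)
  # control-condition contrast folds of the flagship genes
  b <- sc@baseline_dct
  expect_equal(2^(b["CaNAC16", "Hashem", "root", "2"] -
                    b["CaNAC16", "ILC482", "root", "2"]), 20.73)
  expect_equal(2^(b["CaNAC02", "Hashem", "leaf", "5"] -
                    b["CaNAC02", "ILC482", "leaf", "5"]), 1 / 16.87)
  # placeholder flags mark exactly the cells without printed magnitudes
  expect_false(any(sc@placeholder["CaNAC02", , "root", "5"]))
  expect_true(all(sc@placeholder["CaNAC19", , , ]))
})

test_that("invalid scenarios fail before any sampling", {
  expect_error(CqScenario(genes = "g", cultivars = "A", tissues = "t",
                          noise_sd = -1), "non-negative")
  expect_error(CqScenario(genes = "g", cultivars = "A", tissues = "t",
                          n_replicates = 1), ">= 2")
  expect_error(CqScenario(genes = c("g1", "g2"), cultivars = "A",
                          tissues = "t",
                          true_log2fc = array(0, dim = c(1, 1, 1, 2))),
               "dimensions")
})
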