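test_that("outlier-UMI filter drops dominant UMIs within a condition", {
  tab <- makeCountTable(list(
    list(construct_id = "X", umi = "AAAAAA", count = 90),
    list(construct_id = "X", umi = "CCCCCC", count = 5),
    list(construct_id = "X", umi = "GGGGGG", count = 5)))
  out <- umiCounts(filterOutlierUmis(tab, filterConfig()))
  expect_false("AAAAAA" %in% out$umi)
  expect_equal(nrow(out), 2L)
  # ten balanced UMIs: nothing removed at threshold 0.5
  even <- makeCountTable(lapply(1:10, function(i)
    list(construct_id = "X", umi = paste0("UMI", i), count = 10)))
  expect_equal(nrow(umiCounts(filterOutlierUmis(even, filterConfig()))), 10L)
  # threshold 1 is vacuous
  expect_equal(umiCounts(filterOutlierUmis(tab,
                 filterConfig(umi_outlier_fraction = 1))),
               umiCounts(tab))
})

test_that("global outlier scope removes a flagged UMI from all conditions", {
  rows <- list(
    list(construct_id = "X", umi = "AAAAAA", condition = "bin1", count = 90),
    list(construct_id = "X", umi = "CCCCCC", condition = "bin1", count = 10),
    list(construct_id = "X", umi = "AAAAAA", condition = "bin2", count = 10),
    list(construct_id = "X", umi = "CCCCCC", condition = "bin2", count = 90))
  tab <- makeCountTable(rows)
  per_cond <- umiCounts(filterOutlierUmis(tab, filterConfig()))
  expect_equal(nrow(per_cond), 2L)  # each condition loses its own outlier
  global <- umiCounts(filterOutlierUmis(
    tab, filterConfig(outlier_scope = "global")))
  expect_equal(nrow(global), 0L)  # both UMIs flagged somewhere
})

test_that("UMI prefix grouping yields 64 or 16 groups on saturating UMIs", {
  all_umis <- do.call(paste0, expand.grid(rep(list(c("A","C","G","T")), 6)))
  tab <- makeCountTable(lapply(all_umis, function(u)
    list(construct_id = "X", umi = u, count = 1)))
  g3 <- groupAndNormalize(tab, filterConfig(umi_prefix_length = 3))
  expect_equal(length(unique(g3$umi_group)), 64L)
  g2 <- groupAndNormalize(tab, filterConfig(umi_prefix_length = 2))
  expect_equal(length(unique(g2$umi_group)), 16L)
  g0 <- groupAndNormalize(tab, filterConfig(umi_prefix_length = 0))
  expect_equal(unique(g0$umi_group), "all")
})

test_that("normalization rescales each condition to the target mean", {
  tab <- makeCountTable(list(
    list(construct_id = "X", umi = "AAAAAA", count = 10),
    list(construct_id = "Y", umi = "CCCCCC", count = 30)))
  g <- groupAndNormalize(tab, filterConfig(umi_prefix_length = 0))
  expect_equal(sort(g$norm_count), c(50, 150))
  expect_equal(mean(g$norm_count), 100)
  # idempotence: renormalizing normalized counts is a no-op
  tab2 <- makeCountTable(lapply(seq_len(nrow(g)), function(i)
    list(construct_id = g$construct_id[i], umi = "AAAAAA",
         count = g$norm_count[i])))
  g2 <- groupAndNormalize(tab2, filterConfig(umi_prefix_length = 0))
  expect_equal(sort(g2$norm_count), sort(g$norm_count))
})

test_that("activation score is the MFI-weighted sum with coverage gating", {
  expect_equal(activationScore(c(25, 25, 25, 25), c(1, 2, 3, 4)), 250)
  expect_equal(activationScore(c(0, 0, 0, 100), c(1, 2, 3, 4)), 400)
  expect_true(is.na(activationScore(c(1, 1, 1, 1), c(1, 2, 3, 4),
                                    min_bin_sum = 10)))
  expect_error(activationScore(c(1, 1, 1, 1), c(4, 3, 2, 1)),
               class = "combiscreen_invalid_argument")
  # moving read mass to a higher bin strictly increases the score
  withr::with_seed(7, {
    for (i in 1:20) {
      prof <- runif(4, 0, 100)
      mfi <- sort(runif(4, 1, 50))
      base <- activationScore(prof, mfi)
      if (prof[1] >= 5)
        expect_gt(activationScore(prof + c(-5, 0, 0, 5), mfi), base)
    }
  })
})

test_that("screen scores average UMI groups then replicates", {
  # two groups in one replicate, one group in the other; flat MFI 1..4
  rows <- list()
  add <- function(umi, cond, rep_, count)
    list(construct_id = "X", umi = umi, condition = cond,
         replicate = rep_, count = count)
  # replicate 1, group AA: all mass in bin4 -> score 400
  # replicate 1, group CC: all mass in bin1 -> score 100
  # replicate 2, group GG: all mass in bin3 -> score 300
  rows <- list(add("AAAAAA", "bin4", 1L, 10), add("CCCCCC", "bin1", 1L, 10),
               add("GGGGGG", "bin3", 2L, 10))
  tab <- makeCountTable(rows)
  mfi <- rbind(flatMfi(replicate = 1L), flatMfi(replicate = 2L))
  # single-UMI fixture: disable the outlier filter (a lone UMI is 100%
  # of its construct's reads and would otherwise be discarded)
  sc <- scoreActivationScreen(tab, mfi,
                              filterConfig(umi_prefix_length = 2,
                                           min_bin_sum = 0,
                                           umi_outlier_fraction = 1))
  a <- activationScores(sc)
  # within rep 1 mean(400, 100) = 250; rep 2 = 300; final mean 275
  expect_equal(a$activation_score, 275)
  expect_equal(a$n_groups, 3L)
})

test_that("scores are invariant to sequencing depth per condition", {
  sim <- simulateScreen(smallSimConfig(seed = 19))
  cfg <- filterConfig(umi_prefix_length = 2)
  base <- scoreScreen(simCounts(sim), simMfi(sim), cfg)
  x <- umiCounts(simCounts(sim))
  x$count <- x$count * 7
  scaled <- scoreScreen(umiCountTable(x), simMfi(sim), cfg)
  expect_equal(activationScores(scaled), activationScores(base))
  expect_equal(toxicityScores(scaled), toxicityScores(base))
})

test_that("toxicity score matches the signed log2 depletion formula", {
  expect_equal(toxicityScore(100, 100), 0)
  expect_equal(toxicityScore(0, 100), log2(101), tolerance = 1e-12)
  expect_equal(toxicityScore(100, 0), -log2(101), tolerance = 1e-12)
  # antisymmetry under swapping cells and plasmid
  withr::with_seed(3, {
    a <- runif(20, 0, 500); b <- runif(20, 0, 500)
    expect_equal(toxicityScore(a, b), -toxicityScore(b, a))
  })
  expect_error(toxicityScore(-1, 10),
               class = "combiscreen_invalid_argument")
  expect_equal(toxicityScore(0, 100, negate = FALSE), -log2(101))
})

test_that("toxicity screen averages populations and needs plasmid data", {
  mk <- function(cid, cond, tg, rp, count)
    list(construct_id = cid, umi = "AAAAAA", condition = cond,
         target = tg, replicate = rp, count = count)
  # two targets x two replicates; construct X depleted 4x in cells
  rows <- list()
  for (tg in c("tA", "tB")) for (rp in 1:2) {
    rows <- c(rows, list(mk("X", "unsorted", tg, rp, 25),
                         mk("Y", "unsorted", tg, rp, 100),
                         mk("X", "plasmid", tg, rp, 100),
                         mk("Y", "plasmid", tg, rp, 100)))
  }
  tab <- makeCountTable(rows)
  cfg1 <- filterConfig(umi_outlier_fraction = 1)  # single-UMI fixture
  sc <- scoreToxicityScreen(tab, cfg1)
  tox <- toxicityScores(sc)
  expect_equal(tox$n_populations, c(4L, 4L))
  expect_gt(tox$toxicity_score[tox$construct_id == "X"], 0)
  expect_lt(tox$toxicity_score[tox$construct_id == "Y"], 0)
  # the average equals the mean of the four population scores
  per_pop <- scoreMetadata(sc)$per_population
  expect_equal(tox$toxicity_score[tox$construct_id == "X"],
               mean(per_pop$toxicity_score[per_pop$construct_id == "X"]))
  # reporter targets are excluded via toxicity_targets
  sc2 <- scoreToxicityScreen(tab, cfg1, toxicity_targets = "tA")
  expect_equal(unique(scoreMetadata(sc2)$per_population$target), "tA")
  no_plasmid <- makeCountTable(list(mk("X", "unsorted", "tA", 1, 10)))
  expect_error(scoreToxicityScreen(no_plasmid, filterConfig()),
               class = "combiscreen_invalid_argument")
})

test_that("per-population toxicity averages to stated worked example", {
  # population scores {1, 1, 3, 3} average to 2
  expect_equal(mean(c(1, 1, 3, 3)), 2)
  mk <- function(cid, cond, tg, rp, count)
    list(construct_id = cid, umi = "AAAAAA", condition = cond,
         target = tg, replicate = rp, count = count)
  rows <- list()
  # X depleted 2x in tA populations, 8x in tB (plus pseudoread effects
  # cancel because Y anchors the normalization identically)
  for (rp in 1:2) {
    rows <- c(rows, list(mk("X", "unsorted", "tA", rp, 50),
                         mk("Y", "unsorted", "tA", rp, 150),
                         mk("X", "plasmid", "tA", rp, 100),
                         mk("Y", "plasmid", "tA", rp, 100),
                         mk("X", "unsorted", "tB", rp, 20),
                         mk("Y", "unsorted", "tB", rp, 180),
                         mk("X", "plasmid", "tB", rp, 100),
                         mk("Y", "plasmid", "tB", rp, 100)))
  }
  sc <- scoreToxicityScreen(makeCountTable(rows),
                            filterConfig(umi_outlier_fraction = 1))
  per_pop <- scoreMetadata(sc)$per_population
  x <- per_pop[per_pop$construct_id == "X", ]
  expect_equal(toxicityScores(sc)$toxicity_score[
    toxicityScores(sc)$construct_id == "X"], mean(x$toxicity_score))
})

test_that("neutral simulated screens give near-zero toxicity", {
  cfg <- simConfig(n_ads = 6, n_pfs = 0, arity = 1, n_cells = 2e5,
                   read_depth = 2e5, passages = 4, seed = 23)
  parts <- makePartLibrary(6, 0, seed = 23)
  latent <- makeLatentParams(parts, seed = 23)
  latent$part_params$fitness_cost[] <- 0  # all constructs neutral
  sim <- simulateScreen(cfg, latent = latent)
  tox <- toxicityScores(scoreToxicityScreen(simCounts(sim), filterConfig()))
  expect_lt(max(abs(tox$toxicity_score)), 0.35)
})
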