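test_that("composition features match hand values and are case-insensitive", {
  expect_equal(unname(compositionFeatures("EEEE")["ncpr"]), -1)
  expect_equal(unname(compositionFeatures("KKDD")["ncpr"]), 0)
  expect_equal(unname(compositionFeatures("AAAA")["f_disorder"]), 1)
  expect_equal(unname(compositionFeatures("IIII")["f_disorder"]), 0)
  # histidine is charge-neutral
  expect_equal(unname(compositionFeatures("HHHH")["ncpr"]), 0)
  # Kyte-Doolittle mean rescaled to [0, 9]: I = 4.5 -> 9, R = -4.5 -> 0
  expect_equal(unname(compositionFeatures("IIII")["hydropathy"]), 9)
  expect_equal(unname(compositionFeatures("RRRR")["hydropathy"]), 0)
  expect_equal(compositionFeatures("eKpW"), compositionFeatures("EKPW"))
  expect_error(compositionFeatures("AXB"),
               class = "combiscreen_invalid_argument")
})

test_that("feature ranges hold over random sequences", {
  withr::with_seed(17, {
    for (i in 1:25) {
      s <- paste0(sample(c("A","R","N","D","C","Q","E","G","H","I","L",
                           "K","M","F","P","S","T","W","Y","V"),
                         sample(10:40, 1), replace = TRUE), collapse = "")
      f <- compositionFeatures(s)
      expect_true(f["ncpr"] >= -1 && f["ncpr"] <= 1)
      expect_true(f["f_disorder"] >= 0 && f["f_disorder"] <= 1)
      expect_true(f["hydropathy"] >= 0 && f["hydropathy"] <= 9)
      k <- kappaScore(s)
      if (!is.na(k)) expect_true(k >= 0 && k <= 1 + 1e-12)
    }
  })
})

test_that("segregated arrangements score 1 and are maximal (brute force)", {
  # exhaustive over all 252 distinct arrangements of 5 E + 5 K
  seqs <- allArrangements(c(rep("E", 5), rep("K", 5)))
  expect_length(seqs, choose(10, 5))
  vals <- vapply(seqs, kappaScore, numeric(1))
  expect_equal(unname(vals["EEEEEKKKKK"]), 1)
  expect_equal(unname(vals["KKKKKEEEEE"]), 1)
  expect_equal(max(vals), 1)
  # the alternating sequence attains the brute-force minimum
  expect_equal(unname(vals["EKEKEKEKEK"]), min(vals))
})

test_that("patterning handles neutral spacers and undefined groups", {
  # omega undefined without both hydrophobic and acidic residues
  expect_true(is.na(omegaScore("GGGGGGGG")))
  expect_true(is.na(kappaScore("EEEEEEEE")))  # no positives
  # neutral residues dilute but keep the score in [0, 1]
  v <- kappaScore("EEGGKKGGEEKK")
  expect_true(v >= 0 && v <= 1)
  expect_error(kappaScore("EK"), class = "combiscreen_invalid_argument")
  expect_error(blobPatterning("EKEKEKEKEK", c("E", "K"), c("K")),
               class = "combiscreen_invalid_argument")
  # omega uses hydrophobe-vs-acidic groups: segregated scores high,
  # intermixed scores low
  expect_gt(omegaScore("WFYLWDEDEDE"), omegaScore("WDEWDEWDEWL"))
})

test_that("Monte-Carlo normalizer agrees with the segregated normalizer", {
  withr::with_seed(31, {
    s <- "EEKGEKKGEEKGKE"
    a <- kappaScore(s)
    b <- kappaScore(s, normalizer = "shuffle", n_shuffle = 500)
    # shuffle max can only be <= segregated max, so b >= a; close in practice
    expect_gte(b, a - 1e-12)
    expect_lt(abs(a - b), 0.15)
  })
})

test_that("native position profile flags overlapped twentieths", {
  full <- nativePositionProfile(1, 100, 100)
  expect_equal(full$start, 0)
  expect_equal(full$end, 1)
  expect_true(all(full$sections))
  half <- nativePositionProfile(51, 50, 100)
  expect_equal(half$start, 0.5)
  expect_equal(half$end, 1)
  expect_equal(which(half$sections), 11:20)
  # flags are contiguous and start <= end always
  withr::with_seed(41, {
    for (i in 1:30) {
      Lp <- sample(50:500, 1)
      Ld <- sample(1:Lp, 1)
      N <- sample(1:(Lp - Ld + 1), 1)
      p <- nativePositionProfile(N, Ld, Lp)
      expect_lte(p$start, p$end)
      on <- which(p$sections)
      expect_true(length(on) >= 1)
      expect_equal(on, seq(min(on), max(on)))
    }
  })
  expect_error(nativePositionProfile(1, 0, 100),
               class = "combiscreen_invalid_argument")
  expect_error(nativePositionProfile(60, 50, 100),
               class = "combiscreen_invalid_argument")
})

test_that("section frequencies aggregate hit and miss groups", {
  ctx <- data.frame(ad_id = c("a", "b", "c"),
                    N = c(1, 51, 1), Ld = c(50, 50, 100),
                    Lp = c(100, 100, 100))
  freq <- sectionFrequencies(ctx, hit = c(TRUE, TRUE, FALSE))
  # hits: one N-terminal, one C-terminal domain -> every section at 0.5
  expect_equal(freq$freq_hit, rep(0.5, 20))
  expect_equal(freq$freq_miss, rep(1, 20))
})

test_that("hit calling is boundary-inclusive on fold change", {
  fc <- rbind(a = c(2.0, 1.0, 1.0),
              b = c(1.99, 1.99, 1.99),
              c = c(0.5, 3.0, 1.0))
  h <- callHits(fc)
  expect_equal(unname(h), c(TRUE, FALSE, TRUE))
  # min_targets raises the bar
  expect_equal(unname(callHits(fc, min_targets = 2)), rep(FALSE, 3))
  expect_error(callHits(rbind(c(-1, 2))),
               class = "combiscreen_invalid_argument")
})

test_that("hit/miss t-test behaves under identity, separation and label swap", {
  same <- c(1, 2, 3, 4)
  r0 <- compareHitsMisses(c(same, same),
                          c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 4)))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  withr::with_seed(53, {
    x <- c(rnorm(50, 0), rnorm(50, 3))
    lab <- rep(c(FALSE, TRUE), each = 50)
    r1 <- compareHitsMisses(x, lab)
    expect_lt(r1$p, 1e-4)
    r2 <- compareHitsMisses(x, !lab)
    expect_equal(r2$t, -r1$t)
    expect_equal(r2$p, r1$p)
  })
  expect_error(compareHitsMisses(c(1, 2, 3), c(TRUE, FALSE, FALSE)),
               class = "combiscreen_insufficient_data")
  # Welch flag runs and returns finite stats
  withr::with_seed(54, {
    rw <- compareHitsMisses(rnorm(20), rep(c(TRUE, FALSE), 10),
                            welch = TRUE)
  })
  expect_true(is.finite(rw$t))
})

test_that("confusion metrics match their definitions", {
  # TP=2 FN=1 FP=3
  pred <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)
  hit <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  r <- predictorConfusion(pred, hit)
  expect_equal(r$sensitivity, 2 / 3, tolerance = 1e-12)
  expect_equal(r$precision, 2 / 5)
  # perfect predictor
  p2 <- predictorConfusion(hit, hit)
  expect_equal(c(p2$sensitivity, p2$precision), c(1, 1))
  # all-positive predictor: sensitivity 1, precision = prevalence
  withr::with_seed(9, {
    truth <- runif(200) < 0.3
  })
  p3 <- predictorConfusion(rep(TRUE, 200), truth)
  expect_equal(p3$sensitivity, 1)
  expect_equal(p3$precision, mean(truth))
  # degenerate denominators are flagged
  p4 <- predictorConfusion(rep(FALSE, 4), rep(FALSE, 4))
  expect_true("sensitivity" %in% p4$undefined &&
                "precision" %in% p4$undefined)
})

test_that("feature tables cover a FASTA-loaded sequence set", {
  seqs <- c(ad1 = "DEDEDLFWYDE", ad2 = "KKKKRRRRKKKK",
            ad3 = "GGG")  # too short for patterning
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(seqs), "\n", seqs), f)
  loaded <- Biostrings::readAAStringSet(f)
  ft <- featureTable(loaded)
  expect_equal(ft$ad_id, names(seqs))
  expect_equal(ft$length, unname(nchar(seqs)))
  expect_true(is.na(ft$kappa[3]) && is.na(ft$omega[3]))
  expect_false(is.na(ft$omega[1]))
})
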