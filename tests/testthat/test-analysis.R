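partsFixture <- function() makePartLibrary(5, 2, seed = 13)  # A01..A05 AD, A06/A07 PF inert

scoresFor <- function(ids, values) {
  data.frame(construct_id = ids, activation_score = values,
             stringsAsFactors = FALSE)
}

test_that("order-symmetric scores give r = 1 and the exact pair count", {
  parts <- partsFixture()
  cons <- enumerateConstructs(parts, 2)
  # score depends only on the unordered part set -> perfect symmetry
  sym <- vapply(strsplit(cons$construct_id, "-"),
                function(p) sum(match(sort(p), parts$part_id)^2),
                numeric(1))
  res <- orderEffectCorrelation(scoresFor(cons$construct_id, sym))
  expect_equal(res$r, 1.0)
  n <- nrow(parts)
  expect_equal(res$n_pairs, n * (n - 1) / 2)  # palindromes excluded
  expect_false(any(res$pairs$forward == res$pairs$reverse))
})

test_that("independent random scores give near-zero order correlation", {
  parts <- makePartLibrary(12, 0, seed = 29)
  cons <- enumerateConstructs(parts, 2)
  withr::with_seed(29, {
    res <- orderEffectCorrelation(
      scoresFor(cons$construct_id, rnorm(nrow(cons))))
  })
  expect_lt(abs(res$r), 0.25)  # 66 pairs, null sd ~ 0.12
})

test_that("order correlation is symmetric in pair orientation labels", {
  parts <- partsFixture()
  cons <- enumerateConstructs(parts, 2)
  withr::with_seed(5, {
    s <- scoresFor(cons$construct_id, rnorm(nrow(cons)))
  })
  res <- orderEffectCorrelation(s)
  flipped <- cor(res$pairs$score_reverse, res$pairs$score_forward)
  expect_equal(res$r, flipped)
})

test_that("tripartite order pairs can be restricted to exactly two ADs", {
  parts <- partsFixture()
  cons <- enumerateConstructs(parts, 3)
  withr::with_seed(8, {
    s <- scoresFor(cons$construct_id, rnorm(nrow(cons)))
  })
  res <- orderEffectCorrelation(s, parts = parts, require_exact_n_ads = 2)
  n_ads_of <- function(ids) vapply(strsplit(ids, "-"), function(p)
    sum(parts$klass[match(p, parts$part_id)] == "AD"), integer(1))
  expect_true(all(n_ads_of(res$pairs$forward) == 2L))
  expect_error(orderEffectCorrelation(s[1:2, ]),
               class = "combiscreen_insufficient_data")
})

test_that("position effect pools the right constructs and rejects PFs", {
  parts <- partsFixture()
  cons <- enumerateConstructs(parts, 2)
  s <- scoresFor(cons$construct_id, seq_len(nrow(cons)))
  eff <- positionEffect(s, parts, "A02", 1)
  expect_equal(eff$n_constructs, nrow(parts))  # 7 partners at position 2
  expect_error(positionEffect(s, parts, "A06", 1),
               class = "combiscreen_invalid_argument")
  # constant scores give a constant median at every position
  s2 <- scoresFor(cons$construct_id, rep(3.5, nrow(cons)))
  expect_equal(positionEffect(s2, parts, "A01", 1)$median_score, 3.5)
  expect_equal(positionEffect(s2, parts, "A01", 2)$median_score, 3.5)
})

test_that("position medians recover an injected positional bias", {
  parts <- partsFixture()
  cons <- enumerateConstructs(parts, 2)
  tup <- strsplit(cons$construct_id, "-")
  # A01 is worth 10 at position 1 but only 1 at position 2
  val <- vapply(tup, function(p)
    10 * (p[1] == "A01") + 1 * (p[2] == "A01") + 2, numeric(1))
  s <- scoresFor(cons$construct_id, val)
  m1 <- positionEffect(s, parts, "A01", 1)$median_score
  m2 <- positionEffect(s, parts, "A01", 2)$median_score
  expect_gt(m1, m2)
})

test_that("copy-number strata enumerate the worked filler arrangements", {
  # bipartite, one copy, two fillers: AD-F1, AD-F2, F1-AD, F2-AD
  ids <- copyNumberConstructs("A01", 1, 2, c("A06", "A07"))
  expect_setequal(ids, c("A01-A06", "A01-A07", "A06-A01", "A07-A01"))
  # bipartite two copies: the homodimer only
  expect_equal(copyNumberConstructs("A01", 2, 2, c("A06", "A07")),
               "A01-A01")
  # tripartite one copy: 3 positions x 2^2 fillers = 12
  expect_equal(length(copyNumberConstructs("A01", 1, 3, c("A06", "A07"))),
               12L)
  expect_error(copyNumberConstructs("A01", 3, 2, "A06"),
               class = "combiscreen_invalid_argument")
})

test_that("copy-number effect takes the median over scored arrangements", {
  parts <- partsFixture()
  cons <- enumerateConstructs(parts, 2)
  s <- scoresFor(cons$construct_id, seq_len(nrow(cons)))
  eff <- copyNumberEffect(s, parts, "A01", 1, arity = 2)
  ids <- attr(eff, "construct_ids")
  expect_equal(sort(ids), sort(c("A01-A06", "A01-A07", "A06-A01",
                                 "A07-A01")))
  expect_equal(eff$median_score,
               median(s$activation_score[match(ids, s$construct_id)]))
  k2 <- copyNumberEffect(s, parts, "A01", 2, arity = 2)
  expect_equal(k2$median_score,
               s$activation_score[s$construct_id == "A01-A01"])
  expect_error(copyNumberEffect(s, parts, "A06", 1, arity = 2),
               class = "combiscreen_invalid_argument")
})

test_that("exactly additive scores give additivity r = 1", {
  parts <- partsFixture()
  singles <- enumerateConstructs(parts, 1)
  part_vals <- setNames(c(5, 3, 8, 1, 6, 0, 0), parts$part_id)
  s1 <- scoresFor(singles$construct_id,
                  unname(part_vals[singles$construct_id]))
  cons <- enumerateConstructs(parts, 2)
  obs <- vapply(strsplit(cons$construct_id, "-"),
                function(p) sum(part_vals[p]), numeric(1))
  res <- additivityCheck(s1, scoresFor(cons$construct_id, obs))
  expect_equal(res$r, 1.0)
  expect_equal(res$table$predicted, res$table$observed)
  expect_length(res$skipped, 0)
})

test_that("a poisoned interaction shows up as the largest residual", {
  parts <- partsFixture()
  singles <- enumerateConstructs(parts, 1)
  part_vals <- setNames(c(5, 3, 8, 1, 6, 0, 0), parts$part_id)
  s1 <- scoresFor(singles$construct_id,
                  unname(part_vals[singles$construct_id]))
  cons <- enumerateConstructs(parts, 2)
  obs <- vapply(strsplit(cons$construct_id, "-"),
                function(p) sum(part_vals[p]), numeric(1))
  poisoned <- which(cons$construct_id == "A03-A05")
  obs[poisoned] <- obs[poisoned] - 9
  res <- additivityCheck(s1, scoresFor(cons$construct_id, obs))
  worst <- res$table$construct_id[which.max(abs(res$table$residual))]
  expect_equal(worst, "A03-A05")
  # missing single scores are skipped and reported
  res2 <- additivityCheck(s1[-1, ], scoresFor(cons$construct_id, obs))
  expect_true(all(grepl("A01", res2$skipped)))
  expect_equal(nrow(res2$table) + length(res2$skipped), nrow(cons))
})

test_that("effect summaries produce one tidy row per part and stratum", {
  parts <- partsFixture()
  cons <- enumerateConstructs(parts, 2)
  withr::with_seed(2, {
    s <- scoresFor(cons$construct_id, runif(nrow(cons)))
  })
  eff <- effectSummaries(s, parts, 2)
  expect_setequal(unique(eff$analysis), c("position", "copy_number"))
  n_ads <- sum(parts$klass == "AD")
  expect_equal(sum(eff$analysis == "position"), n_ads * 2)
  expect_equal(sum(eff$analysis == "copy_number"), n_ads * 2)
})
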