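# Screen scoring: UMI outlier filtering, prefix grouping, per-condition
# normalization, fluorescence-weighted activation scores and dropout
# toxicity scores.

#' Filtering and normalization configuration
#'
#' @param umi_outlier_fraction a UMI is discarded when its count exceeds
#'   this fraction of its construct's total within a condition
#' @param outlier_scope `"condition"` removes the UMI only from the
#'   offending condition; `"global"` removes it from every condition of
#'   the same population (replicate x target)
#' @param umi_prefix_length UMIs are pooled by their first-k-nt prefix:
#'   3 gives 64 groups, 2 gives 16, 0 aggregates all UMIs into a single
#'   group per construct (used when coverage is low, as in a tripartite
#'   screen)
#' @param normalization_target mean normalized count over scored groups
#'   per condition
#' @param min_bin_sum coverage threshold: minimum summed normalized reads
#'   over the four sorted bins for a UMI group to be scored. `NULL` picks
#'   40 for aggregated UMIs (`umi_prefix_length = 0`) and 10 otherwise
#'   (the aggregated analysis uses a stricter threshold)
#' @param pseudoread additive constant in the toxicity ratio, preventing
#'   zero counts from scoring as infinitely toxic
#' @param negate_toxicity report toxicity as `-log2(cells/plasmid)`
#'   (higher = more toxic); `FALSE` flips the sign convention
#' @return a validated list of class `FilterConfig`
#' @export
filterConfig <- function(umi_outlier_fraction = 0.5,
                         outlier_scope = c("condition", "global"),
                         umi_prefix_length = 2,
                         normalization_target = 100,
                         min_bin_sum = NULL,
                         pseudoread = 1,
                         negate_toxicity = TRUE) {
  outlier_scope <- match.arg(outlier_scope)
  if (umi_outlier_fraction <= 0 || umi_outlier_fraction > 1)
    stopInvalid("umi_outlier_fraction must be in (0, 1]")
  if (!umi_prefix_length %in% c(0, 2, 3))
    stopInvalid("umi_prefix_length must be 0, 2 or 3")
  if (normalization_target <= 0)
    stopInvalid("normalization_target must be positive")
  min_bin_sum <- min_bin_sum %||% (if (umi_prefix_length == 0) 40 else 10)
  if (min_bin_sum < 0) stopInvalid("min_bin_sum must be non-negative")
  structure(list(umi_outlier_fraction = umi_outlier_fraction,
                 outlier_scope = outlier_scope,
                 umi_prefix_length = as.integer(umi_prefix_length),
                 normalization_target = normalization_target,
                 min_bin_sum = min_bin_sum,
                 pseudoread = pseudoread,
                 negate_toxicity = isTRUE(negate_toxicity)),
            class = "FilterConfig")
}

asCountDT <- function(table) {
  x <- if (is(table, "UmiCountTable")) umiCounts(table) else table
  as.data.table(x)
}

#' Remove PCR-outlier UMIs
#'
#' Within each (construct, condition, replicate, target), discards any
#' UMI whose count strictly exceeds `umi_outlier_fraction` of that
#' construct's condition total — protecting scores against PCR jackpots
#' and amplicon contamination. With `outlier_scope = "global"` a UMI
#' flagged in any condition is removed from every condition of the same
#' population.
#'
#' @param table a [UmiCountTable-class] (or its data.frame)
#' @param cfg a [filterConfig()]
#' @return a filtered [UmiCountTable-class]
#' @export
filterOutlierUmis <- function(table, cfg = filterConfig()) {
  dt <- asCountDT(table)
  if (!nrow(dt)) return(umiCountTable(as.data.frame(dt)))
  frac <- cfg$umi_outlier_fraction
  dt[, "ctot" := sum(.SD$count),
     by = c("construct_id", "condition", "replicate", "target")]
  flagged <- dt$count > frac * dt$ctot
  if (cfg$outlier_scope == "global") {
    bad <- unique(dt[flagged, c("construct_id", "umi", "replicate",
                                "target")])
    bad[, "drop_umi" := TRUE]
    dt <- merge(dt, bad, all.x = TRUE,
                by = c("construct_id", "umi", "replicate", "target"))
    keep <- is.na(dt$drop_umi)
    dt[, "drop_umi" := NULL]
  } else {
    keep <- !flagged
  }
  dt <- dt[keep, ]
  dt[, "ctot" := NULL]
  umiCountTable(as.data.frame(dt))
}

#' Pool UMIs by prefix and normalize per condition
#'
#' UMIs are pooled into groups by their first-k-nt prefix
#' (`umi_prefix_length = 0` pools everything into one group per
#' construct). Within each (condition, replicate, target), all group
#' counts are rescaled by a single scalar so that the mean count over
#' groups equals `normalization_target`, correcting for unequal
#' sequencing depth between bins. Conditions whose total count is zero
#' cannot be normalized and are dropped with a warning.
#'
#' @param table a [UmiCountTable-class] (typically after
#'   [filterOutlierUmis()])
#' @param cfg a [filterConfig()]
#' @return data.frame (`construct_id`, `umi_group`, `condition`,
#'   `replicate`, `target`, `count`, `norm_count`)
#' @export
groupAndNormalize <- function(table, cfg = filterConfig()) {
  dt <- asCountDT(table)
  k <- cfg$umi_prefix_length
  if (!nrow(dt)) {
    return(data.frame(construct_id = character(0),
                      umi_group = character(0), condition = character(0),
                      replicate = integer(0), target = character(0),
                      count = numeric(0), norm_count = numeric(0)))
  }
  dt[, "umi_group" := if (k == 0L) "all" else substr(dt$umi, 1L, k)]
  g <- dt[, list(count = sum(.SD$count)),
          by = c("construct_id", "umi_group", "condition", "replicate",
                 "target")]
  g[, "condmean" := mean(.SD$count),
    by = c("condition", "replicate", "target")]
  dead <- g$condmean <= 0
  if (any(dead)) {
    bad <- unique(g[dead, c("condition", "replicate", "target")])
    warning("dropping ", nrow(bad),
            " condition(s) with zero total reads (cannot normalize)")
    g <- g[!dead, ]
  }
  g[, "norm_count" := cfg$normalization_target * g$count / g$condmean]
  g[, "condmean" := NULL]
  setorder(g, target, replicate, condition, construct_id, umi_group)
  as.data.frame(g)
}

#' Fluorescence-weighted activation score of one bin profile
#'
#' The activation score of a sufficiently covered UMI group is the sum
#' over the four sort bins of its normalized reads weighted by the bin's
#' mean fluorescence intensity:
#' `sum(normalized_reads_bin * MFI_bin)`. Profiles whose summed
#' normalized reads fall below `min_bin_sum` are not scored (`NA`).
#'
#' @param profile numeric(4): normalized reads in `bin1..bin4`
#' @param mfi numeric(4): strictly increasing bin mean fluorescence
#'   intensities
#' @param min_bin_sum coverage threshold (default 0: always score)
#' @return the score, or `NA_real_` when coverage is insufficient
#' @examples
#' activationScore(c(25, 25, 25, 25), c(1, 2, 3, 4))  # 250
#' activationScore(c(0, 0, 0, 100), c(1, 2, 3, 4))    # 400
#' @export
activationScore <- function(profile, mfi, min_bin_sum = 0) {
  if (length(profile) != 4L || length(mfi) != 4L)
    stopInvalid("profile and mfi must have length 4")
  if (any(!is.finite(profile)) || any(profile < 0))
    stopInvalid("profile must be finite and non-negative")
  if (any(diff(mfi) <= 0))
    stopInvalid("mfi must be strictly increasing from bin1 to bin4")
  if (sum(profile) < min_bin_sum) return(NA_real_)
  sum(profile * mfi)
}

BIN_LEVELS <- paste0("bin", 1:4)

#' Score an activation screen
#'
#' Full scoring chain on a raw count table: drop control constructs,
#' remove outlier UMIs, pool UMIs by prefix, normalize each sorted-bin
#' condition to the target mean, discard UMI groups below the coverage
#' threshold, score each surviving group by [activationScore()] with the
#' per-replicate bin MFIs, average group scores within replicate, and
#' average replicates.
#'
#' @param table a raw [UmiCountTable-class]
#' @param mfi data.frame (`target`, `replicate`, `bin`, `mfi`) of bin
#'   mean fluorescence intensities, as measured per sort
#' @param cfg a [filterConfig()]
#' @param drop_controls drop `control:*` construct ids before scoring
#' @return a [ScreenScores-class]: activation scores, per-target coverage
#'   (fraction of constructs with at least one scored group), and the
#'   applied thresholds in `scoreMetadata()`
#' @export
scoreActivationScreen <- function(table, mfi, cfg = filterConfig(),
                                  drop_controls = TRUE) {
  dt <- asCountDT(table)
  if (drop_controls) dt <- dt[!isControlId(dt$construct_id), ]
  universe <- unique(dt[dt$condition %in% BIN_LEVELS,
                        c("construct_id", "target")])
  dt <- dt[dt$condition %in% BIN_LEVELS, ]
  filt <- filterOutlierUmis(umiCountTable(as.data.frame(dt)), cfg)
  g <- as.data.table(groupAndNormalize(filt, cfg))
  wide <- dcast(g, construct_id + umi_group + replicate + target ~ condition,
                value.var = "norm_count", fill = 0)
  for (b in setdiff(BIN_LEVELS, names(wide))) wide[, (b) := 0]
  profile <- as.matrix(wide[, BIN_LEVELS, with = FALSE])
  wide <- wide[rowSums(profile) >= cfg$min_bin_sum, ]
  if (!nrow(wide)) {
    act <- data.frame(construct_id = character(0), target = character(0),
                      activation_score = numeric(0), n_groups = integer(0))
  } else {
    m <- as.data.table(mfi)
    m <- dcast(m, target + replicate ~ bin, value.var = "mfi")
    wide <- merge(wide, m, by = c("target", "replicate"),
                  suffixes = c("", ".mfi"))
    if (!nrow(wide)) stopInvalid("no MFI rows match the count table")
    mfimat <- as.matrix(wide[, paste0(BIN_LEVELS, ".mfi"), with = FALSE])
    binmat <- as.matrix(wide[, BIN_LEVELS, with = FALSE])
    if (any(matrixStats_rowDiffsNonPos(mfimat)))
      stopInvalid("bin MFIs must be strictly increasing within each sort")
    wide[, "group_score" := rowSums(binmat * mfimat)]
    per_rep <- wide[, list(rep_score = mean(.SD$group_score),
                           n_groups = .N),
                    by = c("construct_id", "target", "replicate")]
    act <- per_rep[, list(activation_score = mean(.SD$rep_score),
                          n_groups = as.integer(sum(.SD$n_groups))),
                   by = c("construct_id", "target")]
    setorder(act, target, construct_id)
    act <- as.data.frame(act)
  }
  cov <- as.data.table(universe)[, list(n_constructs = .N), by = "target"]
  scored <- as.data.table(act)[, list(n_scored = .N), by = "target"]
  cov <- merge(cov, scored, by = "target", all.x = TRUE)
  cov[is.na(cov$n_scored), "n_scored" := 0L]
  cov[, "fraction_scored" := cov$n_scored / cov$n_constructs]
  new("ScreenScores", activation = act, toxicity = data.frame(),
      coverage = as.data.frame(cov),
      metadata = unclass(cfg))
}

# any non-positive consecutive difference across the 4 MFI columns
matrixStats_rowDiffsNonPos <- function(m) {
  (m[, 2] <= m[, 1]) | (m[, 3] <= m[, 2]) | (m[, 4] <= m[, 3])
}

#' Dropout toxicity score
#'
#' Toxic constructs deplete from transduced cells relative to the
#' plasmid pool; the score is
#' `-log2((cells + pseudoread) / (plasmid + pseudoread))` on normalized
#' counts, so higher values mean more toxic. A construct absent from
#' cells but well represented in plasmid receives a large positive
#' score.
#'
#' @param reads_cells,reads_plasmid normalized read counts (non-negative,
#'   vectorized)
#' @param pseudoread additive constant (default 1)
#' @param negate keep the higher-is-more-toxic sign convention
#' @return numeric vector of toxicity scores
#' @examples
#' toxicityScore(100, 100)          # 0
#' toxicityScore(0, 100)            # log2(101) ~ 6.66
#' @export
toxicityScore <- function(reads_cells, reads_plasmid, pseudoread = 1,
                          negate = TRUE) {
  if (any(reads_cells < 0) || any(reads_plasmid < 0))
    stopInvalid("normalized read counts must be non-negative")
  s <- log2((reads_cells + pseudoread) / (reads_plasmid + pseudoread))
  if (negate) -s else s
}

#' Score a dropout toxicity screen
#'
#' Per population (target x replicate): removes control constructs,
#' applies the outlier-UMI filter to the unsorted cell counts only
#' (plasmid libraries carry no clonal outliers), pools all UMIs into a
#' single group per construct, normalizes cells and plasmid conditions
#' to the same target mean, and computes [toxicityScore()]. Population
#' scores are then averaged over the populations listed in
#' `toxicity_targets` (reporter populations derived from the same
#' transductions are excluded to avoid double counting).
#'
#' @param table a raw [UmiCountTable-class] containing `unsorted` and
#'   `plasmid` conditions
#' @param cfg a [filterConfig()]
#' @param toxicity_targets targets whose populations are averaged
#'   (default: all targets present)
#' @param drop_controls drop `control:*` construct ids
#' @return a [ScreenScores-class] with the `toxicity` slot filled;
#'   per-population scores are kept in `scoreMetadata()$per_population`
#' @export
scoreToxicityScreen <- function(table, cfg = filterConfig(),
                                toxicity_targets = NULL,
                                drop_controls = TRUE) {
  dt <- asCountDT(table)
  if (drop_controls) dt <- dt[!isControlId(dt$construct_id), ]
  toxicity_targets <- toxicity_targets %||% unique(dt$target)
  dt <- dt[dt$target %in% toxicity_targets &
             dt$condition %in% c("unsorted", "plasmid"), ]
  if (!nrow(dt[dt$condition == "plasmid", ]))
    stopInvalid("missing plasmid condition")
  if (!nrow(dt[dt$condition == "unsorted", ]))
    stopInvalid("missing unsorted-cells condition")

  cells <- filterOutlierUmis(
    umiCountTable(as.data.frame(dt[dt$condition == "unsorted", ])), cfg)
  plasmid <- umiCountTable(as.data.frame(dt[dt$condition == "plasmid", ]))

  pool_cfg <- cfg
  pool_cfg$umi_prefix_length <- 0L
  gc_ <- as.data.table(groupAndNormalize(cells, pool_cfg))
  gp <- as.data.table(groupAndNormalize(plasmid, pool_cfg))

  pops <- unique(rbind(gc_[, c("target", "replicate")],
                       gp[, c("target", "replicate")]))
  per_pop <- lapply(seq_len(nrow(pops)), function(i) {
    tg <- pops$target[i]; rp <- pops$replicate[i]
    cc <- gc_[gc_$target == tg & gc_$replicate == rp,
              c("construct_id", "norm_count")]
    pp <- gp[gp$target == tg & gp$replicate == rp,
             c("construct_id", "norm_count")]
    if (!nrow(pp)) stopInvalid("population ", tg, ".", rp,
                               " lacks a plasmid condition")
    m <- merge(cc, pp, by = "construct_id", all = TRUE,
               suffixes = c("_cells", "_plasmid"))
    m[is.na(m$norm_count_cells), "norm_count_cells" := 0]
    m[is.na(m$norm_count_plasmid), "norm_count_plasmid" := 0]
    data.frame(construct_id = m$construct_id, target = tg, replicate = rp,
               toxicity_score = toxicityScore(
                 m$norm_count_cells, m$norm_count_plasmid,
                 cfg$pseudoread, cfg$negate_toxicity),
               stringsAsFactors = FALSE)
  })
  per_pop <- as.data.table(rbindlist(per_pop))
  tox <- per_pop[, list(toxicity_score = mean(.SD$toxicity_score),
                        n_populations = .N),
                 by = "construct_id"]
  setorder(tox, construct_id)
  new("ScreenScores", activation = data.frame(),
      toxicity = as.data.frame(tox), coverage = data.frame(),
      metadata = c(unclass(cfg),
                   list(toxicity_targets = toxicity_targets,
                        per_population = as.data.frame(per_pop))))
}

#' Score a full screen (activation + toxicity)
#'
#' Convenience wrapper running [scoreActivationScreen()] and
#' [scoreToxicityScreen()] on the same table and merging the results.
#'
#' @inheritParams scoreActivationScreen
#' @inheritParams scoreToxicityScreen
#' @return a [ScreenScores-class] with both slots filled
#' @export
scoreScreen <- function(table, mfi, cfg = filterConfig(),
                        toxicity_targets = NULL, drop_controls = TRUE) {
  act <- scoreActivationScreen(table, mfi, cfg, drop_controls)
  tox <- scoreToxicityScreen(table, cfg, toxicity_targets, drop_controls)
  new("ScreenScores", activation = activationScores(act),
      toxicity = toxicityScores(tox), coverage = scoreCoverage(act),
      metadata = c(scoreMetadata(act),
                   scoreMetadata(tox)[c("toxicity_targets",
                                        "per_population")]))
}
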