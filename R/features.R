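# Biochemical featurization of activation-domain sequences: composition
# metrics, blob-based charge/hydrophobe patterning (kappa, omega),
# native-protein position profiles, hit calling and group statistics.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Kyte-Doolittle hydropathy scale
KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# disorder-promoting residues (standard set; histidine is neutral for
# charge metrics at physiological pH)
DISORDER_SET <- c("T", "A", "G", "R", "D", "H", "Q", "K", "S", "E", "P")
POSITIVE_SET <- c("K", "R")
NEGATIVE_SET <- c("D", "E")
HYDROPHOBE_SET <- c("W", "F", "Y", "L")

aaVector <- function(seq) {
  v <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(v), AA20)
  if (length(bad))
    stopInvalid("unknown residue letter(s): ", paste(bad, collapse = ", "))
  v
}

#' Composition features of an amino-acid sequence
#'
#' Net charge per residue (`(K+R - D-E)/length`, histidine neutral),
#' mean Kyte-Doolittle hydropathy rescaled linearly from `[-4.5, 4.5]`
#' to `[0, 9]`, and the fraction of disorder-promoting residues
#' (`T,A,G,R,D,H,Q,K,S,E,P`). Case-insensitive.
#'
#' @param seq amino-acid string over the 20-letter alphabet
#' @param disorder_set residue set counted as disorder-promoting
#' @return named numeric: `ncpr` in `[-1, 1]`, `hydropathy` in `[0, 9]`,
#'   `f_disorder` in `[0, 1]`
#' @examples
#' compositionFeatures("EEEE")["ncpr"]  # -1
#' @export
compositionFeatures <- function(seq, disorder_set = DISORDER_SET) {
  v <- aaVector(seq)
  n <- length(v)
  if (!n) stopInvalid("sequence must be non-empty")
  c(ncpr = (sum(v %in% POSITIVE_SET) - sum(v %in% NEGATIVE_SET)) / n,
    hydropathy = mean(KYTE_DOOLITTLE[v]) + 4.5,
    f_disorder = sum(v %in% disorder_set) / n)
}

# local asymmetry of one window or sequence: (fA - fB)^2 / (fA + fB),
# zero when neither group is present
blobSigma <- function(fa, fb) {
  s <- fa + fb
  ifelse(s == 0, 0, (fa - fb)^2 / s)
}

# mean squared deviation of sliding-window sigma from whole-sequence
# sigma, for ternary indicator vectors isA/isB and blob size g
blobDelta <- function(isA, isB, g) {
  L <- length(isA)
  nw <- L - g + 1L
  ca <- cumsum(c(0L, isA)); cb <- cumsum(c(0L, isB))
  fa <- (ca[(g + 1L):(L + 1L)] - ca[1:nw]) / g
  fb <- (cb[(g + 1L):(L + 1L)] - cb[1:nw]) / g
  sig_seq <- blobSigma(sum(isA) / L, sum(isB) / L)
  mean((blobSigma(fa, fb) - sig_seq)^2)
}

# deterministic delta_max: exact maximum over all arrangements in which
# each group forms one contiguous block (neutrals split into up to three
# runs around the blocks). Fully segregating each group maximizes the
# spread of window sigma, but when neutrals are present the blocks'
# placement matters (interior blocks are covered by more windows than
# terminal ones), so all split positions are searched. With no neutrals
# this is exactly the classic all-A-then-all-B arrangement.
blobDeltaMax <- function(nA, nB, nN, g) {
  L <- nA + nB + nN
  best <- 0
  for (n1 in 0:nN) {
    for (n2 in 0:(nN - n1)) {
      isA <- integer(L); isB <- integer(L)
      isA[(n1 + 1):(n1 + nA)] <- 1L
      isB[(n1 + nA + n2 + 1):(n1 + nA + n2 + nB)] <- 1L
      best <- max(best, blobDelta(isA, isB, g))
    }
  }
  best
}

#' Blob-based two-group patterning score
#'
#' Quantifies how segregated (vs intermixed) two residue groups are
#' along a sequence. Residues are ternary-mapped to group A, group B or
#' neutral; for each blob size `g` the local asymmetry
#' `sigma = (fA - fB)^2 / (fA + fB)` is computed over all sliding
#' windows, and `delta(g)` is the mean squared deviation of window sigma
#' from the whole-sequence sigma. The score is the mean over blob sizes
#' of `delta(g) / delta_max(g)`, where `delta_max(g)` is the maximum
#' delta over all maximally segregated arrangements of the same
#' composition (one contiguous A block and one contiguous B block, with
#' the neutral residues split around them in every possible way; with no
#' neutrals this is the classic all-A-then-all-B sequence). 0 =
#' perfectly mixed, 1 = fully segregated; undefined (`NA`) when either
#' group is absent.
#'
#' `kappaScore()` applies charged groups (A = K/R, B = D/E);
#' `omegaScore()` applies hydrophobe-vs-acidic groups
#' (A = W/F/Y/L, B = D/E). Lower omega = greater acidic-hydrophobe
#' mixing, the regime associated with strong activators.
#'
#' @param seq amino-acid string
#' @param group_a,group_b disjoint residue sets
#' @param blob_sizes sliding-window widths (default 5 and 6)
#' @param normalizer `"segregated"` (deterministic, default) or
#'   `"shuffle"` (Monte-Carlo max over random shuffles, for
#'   cross-checking)
#' @param n_shuffle shuffles used when `normalizer = "shuffle"`
#' @return score in `[0, 1]`, or `NA_real_` when undefined
#' @examples
#' kappaScore("EEEEEKKKKK")  # 1: fully segregated
#' kappaScore("EKEKEKEKEK") < 0.1
#' @export
blobPatterning <- function(seq, group_a, group_b, blob_sizes = c(5, 6),
                           normalizer = c("segregated", "shuffle"),
                           n_shuffle = 2000) {
  normalizer <- match.arg(normalizer)
  if (length(intersect(group_a, group_b)))
    stopInvalid("groups must be disjoint")
  v <- aaVector(seq)
  L <- length(v)
  if (L < max(blob_sizes))
    stopInvalid("sequence shorter than the largest blob size")
  isA <- as.integer(v %in% group_a)
  isB <- as.integer(v %in% group_b)
  nA <- sum(isA); nB <- sum(isB)
  if (nA == 0L || nB == 0L) return(NA_real_)

  ratios <- vapply(blob_sizes, function(g) {
    d <- blobDelta(isA, isB, g)
    dmax <- if (normalizer == "segregated") {
      blobDeltaMax(nA, nB, L - nA - nB, g)
    } else {
      reps <- vapply(seq_len(n_shuffle), function(i) {
        ord <- sample.int(L)
        blobDelta(isA[ord], isB[ord], g)
      }, numeric(1))
      max(c(reps, blobDeltaMax(nA, nB, L - nA - nB, g)))
    }
    if (dmax == 0) NA_real_ else d / dmax
  }, numeric(1))
  if (all(is.na(ratios))) return(NA_real_)
  mean(ratios, na.rm = TRUE)
}

#' @rdname blobPatterning
#' @param ... passed on to [blobPatterning()]
#' @export
kappaScore <- function(seq, ...) {
  blobPatterning(seq, POSITIVE_SET, NEGATIVE_SET, ...)
}

#' @rdname blobPatterning
#' @export
omegaScore <- function(seq, ...) {
  blobPatterning(seq, HYDROPHOBE_SET, NEGATIVE_SET, ...)
}

#' Feature table for a set of AD sequences
#'
#' @param sequences named character vector (or `Biostrings::AAStringSet`)
#'   of AD amino-acid sequences
#' @return data.frame (`ad_id`, `length`, `ncpr`, `hydropathy`,
#'   `f_disorder`, `kappa`, `omega`); kappa/omega are `NA` where a
#'   residue group is absent or the sequence is shorter than the largest
#'   blob
#' @export
featureTable <- function(sequences) {
  if (is(sequences, "AAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  stopifnot(!is.null(names(sequences)))
  rows <- lapply(names(sequences), function(id) {
    s <- sequences[[id]]
    comp <- compositionFeatures(s)
    pat <- function(f) tryCatch(f(s), combiscreen_invalid_argument =
                                  function(e) NA_real_)
    data.frame(ad_id = id, length = nchar(s),
               ncpr = comp[["ncpr"]], hydropathy = comp[["hydropathy"]],
               f_disorder = comp[["f_disorder"]],
               kappa = pat(kappaScore), omega = pat(omegaScore),
               stringsAsFactors = FALSE)
  })
  as.data.frame(rbindlist(rows))
}

#' Position of a domain within its native protein
#'
#' For a domain of length `Ld` starting at residue `N` (1-based) of a
#' protein of length `Lp`: `start = (N-1)/Lp`, `end = (N-1+Ld)/Lp`, so a
#' domain starting at the first residue has start 0 and one running to
#' the last residue has end 1. The protein is divided into 20 equal
#' sections and every section the domain overlaps is flagged.
#'
#' @param N 1-based start residue of the domain in the native protein
#' @param Ld domain length (>= 1)
#' @param Lp native protein length (`N - 1 + Ld <= Lp`)
#' @param n_sections number of equal-length sections (default 20)
#' @return list: `start`, `end` (relative coordinates) and `sections`
#'   (logical flags, one per section)
#' @examples
#' p <- nativePositionProfile(51, 50, 100)
#' which(p$sections)  # 11:20
#' @export
nativePositionProfile <- function(N, Ld, Lp, n_sections = 20L) {
  if (N < 1 || Ld < 1 || Lp < 1 || N - 1 + Ld > Lp)
    stopInvalid("invalid native context: need 1 <= N and N-1+Ld <= Lp")
  start <- (N - 1) / Lp
  end <- (N - 1 + Ld) / Lp
  i <- seq_len(n_sections)
  sections <- (start < i / n_sections) & (end > (i - 1) / n_sections)
  list(start = start, end = end, sections = sections)
}

#' Section-overlap frequencies for hits and misses
#'
#' Aggregates [nativePositionProfile()] flags over a table of native
#' contexts, reporting how often hits and misses are sourced from
#' domains overlapping each of the 20 native-protein sections (relative
#' to the group size; a domain spanning several sections counts in each).
#'
#' @param contexts data.frame with columns `ad_id`, `N`, `Ld`, `Lp`
#' @param hit logical vector aligned with `contexts` rows
#' @param n_sections number of sections
#' @return data.frame (`section`, `freq_hit`, `freq_miss`)
#' @export
sectionFrequencies <- function(contexts, hit, n_sections = 20L) {
  stopifnot(nrow(contexts) == length(hit))
  flags <- t(vapply(seq_len(nrow(contexts)), function(i)
    nativePositionProfile(contexts$N[i], contexts$Ld[i], contexts$Lp[i],
                          n_sections)$sections, logical(n_sections)))
  data.frame(section = seq_len(n_sections),
             freq_hit = if (any(hit)) colMeans(flags[hit, , drop = FALSE])
                        else rep(NA_real_, n_sections),
             freq_miss = if (any(!hit)) colMeans(flags[!hit, , drop = FALSE])
                         else rep(NA_real_, n_sections))
}

#' Call hits from per-target fold changes
#'
#' A hit produces `fold_threshold`-fold or greater activation on at
#' least `min_targets` targets (boundary inclusive).
#'
#' @param fold_changes numeric matrix or data.frame, one row per AD and
#'   one column per target (positive fold changes)
#' @param fold_threshold hit threshold (default 2)
#' @param min_targets minimum number of targets at/above threshold
#' @return logical vector of hit calls, named by rownames
#' @examples
#' callHits(rbind(a = c(2, 1, 1), b = c(1.99, 1.99, 1.99)))
#' @export
callHits <- function(fold_changes, fold_threshold = 2.0,
                     min_targets = 1L) {
  m <- as.matrix(fold_changes)
  if (any(m <= 0, na.rm = TRUE))
    stopInvalid("fold changes must be positive")
  hits <- rowSums(m >= fold_threshold, na.rm = TRUE) >= min_targets
  setNames(as.logical(hits), rownames(m))
}

#' Unpaired two-sided t-test between hits and misses
#'
#' Compares a feature between the hit and miss groups with an unpaired
#' two-sided t-test (pooled variance by default; `welch = TRUE` drops
#' the equal-variance assumption). Missing feature values are excluded.
#' The sign convention is hits minus misses, so swapping labels negates
#' `t` and leaves `p` unchanged.
#'
#' @param values numeric feature values
#' @param hit logical group labels aligned with `values`
#' @param welch use Welch's correction
#' @return list: `t`, `p`, `mean_hit`, `mean_miss`, `n_hit`, `n_miss`
#' @export
compareHitsMisses <- function(values, hit, welch = FALSE) {
  stopifnot(length(values) == length(hit))
  keep <- !is.na(values) & !is.na(hit)
  x <- values[keep & hit]
  y <- values[keep & !hit]
  if (length(x) < 2L || length(y) < 2L)
    stopInsufficient("each group needs at least 2 values")
  tt <- t.test(x, y, var.equal = !welch, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_hit = mean(x), mean_miss = mean(y),
       n_hit = length(x), n_miss = length(y))
}

#' Confusion metrics for an external AD predictor
#'
#' Sensitivity (`TP / (TP + FN)`) and precision (`TP / (TP + FP)`) of
#' predicted activity labels against the screen's hit calls. A metric
#' with a zero denominator is returned as `NA` with a flag.
#'
#' @param predicted logical predictions, aligned with `hit`
#' @param hit logical ground-truth hit calls
#' @return list: `sensitivity`, `precision`, `tp`, `fp`, `fn`, `tn`,
#'   `undefined` (character vector of metrics with zero denominators)
#' @export
predictorConfusion <- function(predicted, hit) {
  stopifnot(length(predicted) == length(hit))
  keep <- !is.na(predicted) & !is.na(hit)
  p <- predicted[keep]; h <- hit[keep]
  tp <- sum(p & h); fp <- sum(p & !h)
  fn <- sum(!p & h); tn <- sum(!p & !h)
  undef <- character(0)
  sens <- if (tp + fn == 0) { undef <- c(undef, "sensitivity"); NA_real_ }
          else tp / (tp + fn)
  prec <- if (tp + fp == 0) { undef <- c(undef, "precision"); NA_real_ }
          else tp / (tp + fp)
  list(sensitivity = sens, precision = prec,
       tp = tp, fp = fp, fn = fn, tn = tn, undefined = undef)
}
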