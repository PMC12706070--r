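# Construct-level analyses: order effects, positional effects,
# copy-number effects with inert fillers, and additivity checks.

scoreLookup <- function(scores, value_col) {
  stopifnot(value_col %in% names(scores))
  setNames(scores[[value_col]], scores$construct_id)
}

partClassLookup <- function(parts) {
  list(klass = setNames(parts$klass, parts$part_id),
       inert = setNames(parts$inert, parts$part_id))
}

countAds <- function(construct_id, parts) {
  kl <- setNames(parts$klass, parts$part_id)
  vapply(constructTuple(construct_id),
         function(p) sum(kl[p] == "AD"), integer(1))
}

#' Correlation between order-reversed construct pairs
#'
#' Pairs every construct with its part-order reversal (`A-B` with `B-A`)
#' and computes the Pearson correlation between the two score vectors,
#' one data point per unordered pair. Palindromic constructs (their own
#' reversal, e.g. `A-A` or `A-B-A`) carry no order information and are
#' excluded. A correlation near 1 means order does not matter; lower
#' values indicate order-sensitive behavior.
#'
#' @param scores data.frame with `construct_id` and a score column
#' @param value_col name of the score column
#' @param parts part annotation (required when `require_exact_n_ads` is
#'   used)
#' @param require_exact_n_ads restrict to constructs containing exactly
#'   this many AD parts (e.g. 2 for tripartite constructs with exactly
#'   two ADs and one PF)
#' @return list: `pairs` (data.frame `forward`, `reverse`,
#'   `score_forward`, `score_reverse`), `r` (Pearson), `n_pairs`
#' @export
orderEffectCorrelation <- function(scores, value_col = "activation_score",
                                   parts = NULL,
                                   require_exact_n_ads = NULL) {
  s <- scoreLookup(scores, value_col)
  ids <- names(s)
  if (!is.null(require_exact_n_ads)) {
    if (is.null(parts))
      stopInvalid("parts annotation needed for require_exact_n_ads")
    ids <- ids[countAds(ids, parts) == require_exact_n_ads]
  }
  rev_ids <- reverseConstruct(ids)
  usable <- ids[ids != rev_ids & rev_ids %in% names(s)]
  fwd <- usable[usable < reverseConstruct(usable)]  # list each pair once
  if (length(fwd) < 3L)
    stopInsufficient("fewer than 3 usable order-reversed pairs")
  rev_of <- reverseConstruct(fwd)
  pairs <- data.frame(forward = fwd, reverse = rev_of,
                      score_forward = unname(s[fwd]),
                      score_reverse = unname(s[rev_of]),
                      stringsAsFactors = FALSE)
  list(pairs = pairs,
       r = cor(pairs$score_forward, pairs$score_reverse,
               method = "pearson"),
       n_pairs = nrow(pairs))
}

#' Median score of a part at a fusion position
#'
#' Pools all constructs carrying the given AD at the given 1-based
#' position (position 1 = closest to the scaffold) and reports the
#' median score. Only activation domains are evaluated; protein folders
#' are considered inert and rejected.
#'
#' @param scores data.frame with `construct_id` and a score column
#' @param parts part annotation data.frame
#' @param part an AD part id
#' @param position 1-based position within the fusion
#' @param value_col name of the score column
#' @return data.frame (`part_id`, `stratum`, `median_score`,
#'   `n_constructs`)
#' @export
positionEffect <- function(scores, parts, part, position,
                           value_col = "activation_score") {
  kl <- setNames(parts$klass, parts$part_id)
  if (is.na(kl[part])) stopInvalid("unknown part: ", part)
  if (kl[part] != "AD")
    stopInvalid("positional effects are evaluated for ADs only")
  tup <- constructTuple(scores$construct_id)
  hit <- vapply(tup, function(p)
    length(p) >= position && p[position] == part, logical(1))
  if (!any(hit)) stopInsufficient("no constructs with ", part,
                                  " at position ", position)
  vals <- scores[[value_col]][hit]
  data.frame(part_id = part, stratum = as.integer(position),
             median_score = median(vals, na.rm = TRUE),
             n_constructs = sum(hit), stringsAsFactors = FALSE)
}

#' Enumerate filler arrangements for a copy-number stratum
#'
#' All constructs with exactly `k` copies of `part` and inert fillers in
#' the remaining positions (fillers may differ across positions):
#' `choose(arity, k) * length(fillers)^(arity - k)` constructs.
#'
#' @param part the AD part id
#' @param k copy number
#' @param arity construct arity
#' @param fillers character vector of inert filler part ids
#' @return character vector of construct ids
#' @export
copyNumberConstructs <- function(part, k, arity, fillers) {
  if (k > arity) stopInvalid("copy number k cannot exceed arity")
  if (k < 1) stopInvalid("copy number k must be at least 1")
  pos_sets <- combn(arity, k, simplify = FALSE)
  out <- character(0)
  for (ps in pos_sets) {
    free <- setdiff(seq_len(arity), ps)
    fills <- if (length(free))
      do.call(expand.grid, c(rep(list(fillers), length(free)),
                             list(stringsAsFactors = FALSE)))
    else data.frame(row.names = 1)
    for (r in seq_len(nrow(fills))) {
      tup <- character(arity)
      tup[ps] <- part
      if (length(free)) tup[free] <- unlist(fills[r, ], use.names = FALSE)
      out <- c(out, paste(tup, collapse = "-"))
    }
  }
  unique(out)
}

#' Median score of a part at a copy number
#'
#' Scores all arrangements of exactly `k` copies of an AD with inert
#' protein-folder fillers in the remaining positions (e.g. for one copy
#' in a bipartite screen with fillers X and Y: `AD-X`, `AD-Y`, `X-AD`,
#' `Y-AD`) and reports their median.
#'
#' @param scores data.frame with `construct_id` and a score column
#' @param parts part annotation data.frame
#' @param part an AD part id
#' @param k copy number
#' @param arity construct arity (default: inferred from the scores table)
#' @param fillers filler part ids (default: the parts flagged `inert`)
#' @param value_col name of the score column
#' @return data.frame (`part_id`, `stratum` = k, `median_score`,
#'   `n_constructs`) with the enumerated ids in
#'   `attr(, "construct_ids")`
#' @export
copyNumberEffect <- function(scores, parts, part, k, arity = NULL,
                             fillers = NULL,
                             value_col = "activation_score") {
  kl <- setNames(parts$klass, parts$part_id)
  if (is.na(kl[part])) stopInvalid("unknown part: ", part)
  if (kl[part] != "AD")
    stopInvalid("copy-number effects are evaluated for ADs only")
  fillers <- fillers %||% parts$part_id[parts$inert]
  if (!length(fillers)) stopInvalid("no inert filler parts available")
  arity <- arity %||%
    max(lengths(constructTuple(scores$construct_id)))
  ids <- copyNumberConstructs(part, k, arity, fillers)
  vals <- scoreLookup(scores, value_col)[ids]
  found <- !is.na(vals)
  if (!any(found)) stopInsufficient("no scored constructs in stratum")
  out <- data.frame(part_id = part, stratum = as.integer(k),
                    median_score = median(vals[found]),
                    n_constructs = sum(found), stringsAsFactors = FALSE)
  attr(out, "construct_ids") <- ids
  out
}

#' Additivity of multi-domain scores
#'
#' Predicts each multi-domain construct's score as the sum of its parts'
#' single-domain scores and correlates prediction with observation
#' (Pearson). High correlation reproduces the additive behavior of
#' bipartite fusions; large residuals flag interacting (non-additive)
#' combinations.
#'
#' @param single_scores data.frame of single-domain scores
#'   (`construct_id` = part id)
#' @param multi_scores data.frame of multi-domain scores
#' @param value_col score column name (same in both tables)
#' @return list: `table` (data.frame `construct_id`, `predicted`,
#'   `observed`, `residual`), `r` (Pearson), `skipped` (construct ids
#'   lacking a part score)
#' @export
additivityCheck <- function(single_scores, multi_scores,
                            value_col = "activation_score") {
  s1 <- scoreLookup(single_scores, value_col)
  tup <- constructTuple(multi_scores$construct_id)
  pred <- vapply(tup, function(p) sum(s1[p]), numeric(1))
  skipped <- multi_scores$construct_id[is.na(pred)]
  keep <- !is.na(pred) & !is.na(multi_scores[[value_col]])
  tab <- data.frame(construct_id = multi_scores$construct_id[keep],
                    predicted = pred[keep],
                    observed = multi_scores[[value_col]][keep],
                    stringsAsFactors = FALSE)
  tab$residual <- tab$observed - tab$predicted
  r <- if (nrow(tab) >= 3L)
    cor(tab$predicted, tab$observed, method = "pearson") else NA_real_
  list(table = tab, r = r, skipped = skipped)
}

#' Tidy summaries over all parts and strata
#'
#' Convenience loops over [positionEffect()] and [copyNumberEffect()]
#' for every AD, returning one tidy row per (part, stratum).
#'
#' @inheritParams positionEffect
#' @param arity construct arity
#' @param fillers filler ids for the copy-number summary
#' @return data.frame of stacked effect summaries with an `analysis`
#'   column (`position` or `copy_number`)
#' @export
effectSummaries <- function(scores, parts, arity,
                            value_col = "activation_score",
                            fillers = NULL) {
  ads <- parts$part_id[parts$klass == "AD"]
  rows <- list()
  for (p in ads) {
    for (pos in seq_len(arity)) {
      r <- tryCatch(positionEffect(scores, parts, p, pos, value_col),
                    combiscreen_insufficient_data = function(e) NULL)
      if (!is.null(r)) { r$analysis <- "position"; rows[[length(rows) + 1L]] <- r }
    }
    for (k in seq_len(arity)) {
      r <- tryCatch(copyNumberEffect(scores, parts, p, k, arity,
                                     fillers, value_col),
                    combiscreen_insufficient_data = function(e) NULL)
      if (!is.null(r)) {
        attr(r, "construct_ids") <- NULL
        r$analysis <- "copy_number"; rows[[length(rows) + 1L]] <- r
      }
    }
  }
  as.data.frame(rbindlist(rows))
}
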