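# Part libraries and combinatorial construct enumeration.

AD_RESIDUE_POOL <- c(D = 0.16, E = 0.16, L = 0.09, F = 0.05, W = 0.03,
                     Y = 0.04, S = 0.08, T = 0.05, A = 0.07, G = 0.05,
                     Q = 0.06, N = 0.04, P = 0.04, M = 0.02, V = 0.03,
                     I = 0.03)
PF_RESIDUE_POOL <- c(A = 0.11, G = 0.10, V = 0.08, L = 0.09, I = 0.06,
                     S = 0.08, T = 0.07, K = 0.07, E = 0.07, D = 0.05,
                     N = 0.05, Q = 0.04, F = 0.04, Y = 0.03, P = 0.04,
                     R = 0.02)

randomAaSequence <- function(n, pool) {
  len <- sample(30:60, 1L)
  paste0(sample(names(pool), len, replace = TRUE, prob = pool), collapse = "")
}

#' Generate a barcoded part library
#'
#' Creates `n_ads` activation-domain parts and `n_pfs` protein-folder
#' parts, each with a unique 8-nt barcode and a random amino-acid
#' sequence (acidic/hydrophobe-biased for ADs, generic globular
#' composition for PFs). Two PFs are flagged `inert` (filler-eligible);
#' any further PFs are excluded from filler sets, mirroring screens in
#' which only a subset of folders is treated as inert.
#'
#' @param n_ads,n_pfs part counts
#' @param barcode_length barcode width in nt
#' @param seed integer seed
#' @return data.frame with columns `part_id`, `klass` (`AD`/`PF`),
#'   `inert`, `barcode`, `sequence`
#' @examples
#' parts <- makePartLibrary(22, 3, seed = 1)
#' table(parts$klass)
#' @export
makePartLibrary <- function(n_ads = 22, n_pfs = 3, barcode_length = 8,
                            seed = 1L) {
  withr::with_seed(deriveSeed(seed, "parts"), {
    n <- n_ads + n_pfs
    ids <- sprintf("A%02d", seq_len(n))
    klass <- c(rep("AD", n_ads), rep("PF", n_pfs))
    inert <- c(rep(FALSE, n_ads),
               if (n_pfs > 0) rep(TRUE, min(2L, n_pfs)) else logical(0),
               if (n_pfs > 2) rep(FALSE, n_pfs - 2L) else logical(0))
    barcodes <- uniqueRandomDna(n, barcode_length)
    seqs <- vapply(seq_len(n), function(i) {
      randomAaSequence(1L, if (klass[i] == "AD") AD_RESIDUE_POOL else PF_RESIDUE_POOL)
    }, character(1))
    data.frame(part_id = ids, klass = klass, inert = inert,
               barcode = barcodes, sequence = seqs,
               stringsAsFactors = FALSE)
  })
}

#' Enumerate all ordered part combinations
#'
#' Forms every ordered tuple (with repetition) of `arity` parts; for a
#' 25-part library this yields 25 single-domain, 625 bipartite and 15,625
#' tripartite constructs. Position 1 is the part closest to the scaffold.
#' Order matters: `A01-A02` and `A02-A01` are distinct constructs.
#'
#' @param parts part library data.frame (needs a `part_id` column)
#' @param arity 1, 2 or 3 parts per construct
#' @return data.frame with `construct_id` (dash-joined part ids in
#'   position order), `arity`, and part columns `p1..p3` (`NA` beyond
#'   `arity`); one row per construct, `nrow = nrow(parts)^arity`
#' @examples
#' parts <- makePartLibrary(3, 0, seed = 1)
#' nrow(enumerateConstructs(parts, 2))  # 9
#' @export
enumerateConstructs <- function(parts, arity) {
  if (!length(arity) == 1L || !arity %in% 1:3)
    stopInvalid("arity must be 1, 2 or 3")
  ids <- as.character(parts$part_id)
  if (!length(ids)) stopInvalid("parts must be non-empty")
  if (anyDuplicated(ids)) stopInvalid("duplicate part_id")
  grid <- do.call(expand.grid,
                  c(rep(list(ids), arity),
                    list(stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)))
  # expand.grid varies the first factor fastest; reorder so position 1 is
  # the slowest-varying column, giving a stable lexicographic enumeration
  grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
  names(grid) <- paste0("p", seq_len(arity))
  out <- data.frame(
    construct_id = apply(grid, 1L, paste, collapse = "-"),
    arity = as.integer(arity), stringsAsFactors = FALSE)
  for (k in 1:3)
    out[[paste0("p", k)]] <- if (k <= arity) grid[[paste0("p", k)]] else NA_character_
  rownames(out) <- NULL
  out
}

# ordered part-id tuple of a construct row or construct_id string
constructTuple <- function(construct_id) strsplit(construct_id, "-", fixed = TRUE)

#' Reverse the part order of constructs
#'
#' @param construct_id character vector of dash-joined construct ids
#' @return character vector with each tuple reversed
#'   (`reverseConstruct(reverseConstruct(x)) == x`)
#' @export
reverseConstruct <- function(construct_id) {
  vapply(constructTuple(construct_id),
         function(p) paste(rev(p), collapse = "-"), character(1))
}

# barcode tuple (position order) for a vector of construct ids
constructBarcodes <- function(construct_id, parts) {
  bc <- setNames(parts$barcode, parts$part_id)
  lapply(constructTuple(construct_id), function(p) unname(bc[p]))
}
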