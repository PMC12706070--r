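# Shared fixtures: all generated in code, sized for fast unit runs.

# a small screen simulation reused across test files
smallSimConfig <- function(seed = 3L, arity = 2, ...) {
  simConfig(n_ads = 8, n_pfs = 2, arity = arity, n_cells = 5e4,
            read_depth = 5e4, seed = seed, ...)
}

# hand-built UMI count table
makeCountTable <- function(rows) {
  defaults <- list(condition = "bin1", replicate = 1L,
                   target = "targetA")
  rows <- lapply(rows, function(r) {
    for (k in names(defaults)) if (is.null(r[[k]])) r[[k]] <- defaults[[k]]
    as.data.frame(r, stringsAsFactors = FALSE)
  })
  umiCountTable(do.call(rbind, rows))
}

# flat MFI table for a single target/replicate
flatMfi <- function(target = "targetA", replicate = 1L,
                    mfi = c(1, 2, 3, 4)) {
  data.frame(target = target, replicate = as.integer(replicate),
             bin = paste0("bin", 1:4), mfi = mfi)
}

# fixed-seed unique DNA strings for hand-built cell tables
randomDnaFixture <- function(n, width = 6) {
  withr::with_seed(99, {
    apply(matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
                 nrow = n), 1, paste0, collapse = "")
  })
}

# barcode tuples (position order) for construct ids, or pass-through for
# ready-made tuples
constructBarcodesFixture <- function(ids, parts) {
  bc <- setNames(parts$barcode, parts$part_id)
  lapply(strsplit(ids, "-", fixed = TRUE),
         function(p) unname(bc[p]))
}

# named lookup defaulting to 0 for absent keys
lookup0 <- function(v, k) if (k %in% names(v)) v[[k]] else 0

# all distinct arrangements of a multiset of residues (for brute-force
# patterning oracles); returns character vector of sequences
allArrangements <- function(residues) {
  residues <- sort(residues)
  rec <- function(v) {
    if (length(v) == 1L) return(v)
    out <- character(0)
    for (u in unique(v)) {
      rest <- v[-match(u, v)]
      out <- c(out, paste0(u, rec(rest)))
    }
    out
  }
  unique(rec(residues))
}
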