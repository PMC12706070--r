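# Scar-anchored read encoding and decoding.
#
# Read structure (block_order = "innermost_last"):
#   [anchor][block arity][scar][block arity-1]...[scar][block 1][terminal]
# where each block is an 8-nt part barcode followed by a 6-nt UMI.
# The clone-identifying UMI sits in the position-1 block; filler-block
# UMIs are a deterministic rotation of it, so encoding is invertible.

REJECTION_REASONS <- c("missing_anchor", "truncated_block",
                       "invalid_barcode", "invalid_umi", "missing_scar",
                       "too_many_blocks", "unknown_barcode", "ambiguous")

# rotate every nucleotide j steps around A->C->G->T (filler-block UMIs)
rotateDna <- function(x, j) {
  j <- j %% 4L
  if (j == 0L) return(x)
  from <- "ACGT"
  to <- paste0(substring("ACGTACGT", j + 1L, j + 4L))
  chartr(from, to, x)
}

#' Encode construct reads in the scar-delimited layout
#'
#' Inverse of [parseRead()]: builds well-formed reads for clones of the
#' given constructs. Each block carries the part barcode of its position
#' and a UMI; the position-1 block carries the clone UMI and filler
#' blocks carry deterministic rotations of it.
#'
#' @param barcode_tuples list of character vectors: per read, the part
#'   barcodes in position order (position 1 first)
#' @param umis character vector of clone UMIs (one per read)
#' @param layout a [ReadLayout-class]
#' @return character vector of reads
#' @export
encodeRead <- function(barcode_tuples, umis, layout) {
  stopifnot(length(barcode_tuples) == length(umis))
  vapply(seq_along(umis), function(i) {
    bc <- barcode_tuples[[i]]
    blocks <- vapply(seq_along(bc), function(pos) {
      paste0(bc[pos], if (pos == 1L) umis[i] else rotateDna(umis[i], pos - 1L))
    }, character(1))
    if (layout@block_order == "innermost_last") blocks <- rev(blocks)
    paste0(layout@upstream_anchor,
           paste(blocks, collapse = layout@scar), layout@terminal)
  }, character(1))
}

#' Parse reads into barcode tuples and UMIs
#'
#' Anchors on the upstream anchor (exact, case-insensitive, forward
#' strand), walks scar-delimited (barcode, UMI) blocks, and returns the
#' per-position barcodes and UMIs, or a typed rejection. Reads lacking
#' any expected feature are rejected, never errored: rejections are data.
#' `N` inside a barcode rejects the read; `N` inside a UMI is retained
#' as a distinct symbol.
#'
#' @param reads character vector of reads over `A,C,G,T,N`
#' @param layout a [ReadLayout-class]
#' @param max_arity maximum number of blocks to accept
#' @return data.frame with `status` (`ok`/`rejected`), `reason`,
#'   `n_blocks`, `bc1..bc3`, `umi1..umi3` (position order: `bc1` is the
#'   scaffold-proximal position) and `umi` (the clone UMI, = `umi1`)
#' @export
parseReads <- function(reads, layout, max_arity = 3L) {
  reads <- toupper(reads)
  n <- length(reads)
  bw <- layout@barcode_length
  uw <- layout@umi_length
  blk <- bw + uw
  sc <- nchar(layout@scar)
  a <- nchar(layout@upstream_anchor)

  status <- rep("ok", n)
  reason <- rep(NA_character_, n)
  nb <- integer(n)
  bc <- matrix(NA_character_, n, max_arity)
  um <- matrix(NA_character_, n, max_arity)

  bad <- substr(reads, 1L, a) != layout@upstream_anchor
  status[bad] <- "rejected"; reason[bad] <- "missing_anchor"

  active <- which(!bad)
  pos <- a + 1L
  k <- 0L
  while (length(active) && k < max_arity) {
    k <- k + 1L
    b <- substr(reads[active], pos, pos + bw - 1L)
    u <- substr(reads[active], pos + bw, pos + blk - 1L)
    short <- nchar(u) < uw
    badbc <- !short & grepl("[^ACGT]", b)
    badumi <- !short & !badbc & grepl("[^ACGTN]", u)
    rej <- short | badbc | badumi
    if (any(rej)) {
      i <- active[rej]
      status[i] <- "rejected"
      reason[i] <- ifelse(short[rej], "truncated_block",
                          ifelse(badbc[rej], "invalid_barcode",
                                 "invalid_umi"))
      active <- active[!rej]
      b <- b[!rej]; u <- u[!rej]
    }
    if (!length(active)) break
    bc[active, k] <- b
    um[active, k] <- u
    nb[active] <- k
    tail_start <- pos + blk
    nxt <- substr(reads[active], tail_start, tail_start + sc - 1L)
    more <- nxt == layout@scar
    # a read ends after its last block: remainder must be empty or the
    # terminal context (possibly truncated by read length)
    tails <- substr(reads[active], tail_start, nchar(reads[active]))
    done_ok <- !more &
      (tails == "" | startsWith(tails, layout@terminal) |
         startsWith(layout@terminal, tails))
    bad_tail <- !more & !done_ok
    if (any(bad_tail)) {
      i <- active[bad_tail]
      status[i] <- "rejected"; reason[i] <- "missing_scar"
      nb[i] <- 0L
    }
    active <- active[more]
    pos <- pos + blk + sc
  }
  if (length(active)) {  # still expecting more blocks past max_arity
    status[active] <- "rejected"; reason[active] <- "too_many_blocks"
    nb[active] <- 0L
  }

  # convert read order to position order
  out <- data.frame(status = status, reason = reason, n_blocks = nb,
                    stringsAsFactors = FALSE)
  for (j in seq_len(max_arity)) {
    out[[paste0("bc", j)]] <- NA_character_
    out[[paste0("umi", j)]] <- NA_character_
  }
  ok <- which(status == "ok")
  for (arity in unique(nb[ok])) {
    i <- ok[nb[ok] == arity]
    ord <- if (layout@block_order == "innermost_last")
      rev(seq_len(arity)) else seq_len(arity)
    for (j in seq_len(arity)) {
      out[[paste0("bc", j)]][i] <- bc[i, ord[j]]
      out[[paste0("umi", j)]][i] <- um[i, ord[j]]
    }
  }
  out$umi <- out$umi1
  out
}

#' @rdname parseReads
#' @param read a single read
#' @return `parseRead` returns a list: either
#'   `list(barcodes=, umis=, umi=)` on success or
#'   `list(rejected=TRUE, reason=)`
#' @export
parseRead <- function(read, layout, max_arity = 3L) {
  p <- parseReads(read, layout, max_arity)
  if (p$status != "ok") return(list(rejected = TRUE, reason = p$reason))
  k <- p$n_blocks
  list(barcodes = unlist(p[paste0("bc", seq_len(k))], use.names = FALSE),
       umis = unlist(p[paste0("umi", seq_len(k))], use.names = FALSE),
       umi = p$umi)
}

# resolve one barcode against the map; returns part id, "control:<type>",
# or a rejection reason
resolveBarcode <- function(b, map, max_mismatch) {
  pb <- partBarcodes(map)
  cb <- controlBarcodes(map)
  if (b %in% names(pb)) return(unname(pb[b]))
  if (b %in% names(cb)) return(controlId(unname(cb[b])))
  if (max_mismatch >= 1L) {
    all_bc <- c(names(pb), names(cb))
    d <- vapply(all_bc, hammingDistance, integer(1), a = b)
    hit <- which(d <= max_mismatch)
    if (length(hit) == 1L) {
      h <- all_bc[hit]
      return(if (h %in% names(pb)) unname(pb[h])
             else controlId(unname(cb[h])))
    }
    if (length(hit) > 1L) return("reject:ambiguous")
  }
  "reject:unknown_barcode"
}

#' Call constructs from parsed reads
#'
#' Matches each positional barcode against the [BarcodeMap-class],
#' exactly by default or within Hamming distance 1 when unambiguous.
#' Reads containing any control-associated barcode are labeled `control`
#' and excluded from scoring downstream; reads with an unmatched barcode
#' are rejected (`unknown_barcode`), and Hamming-1 ties reject as
#' `ambiguous`.
#'
#' @param parsed data.frame from [parseReads()]
#' @param map a [BarcodeMap-class]
#' @param max_mismatch 0 (exact, default) or 1
#' @return `parsed` with added columns `call_status`
#'   (`ok`/`control`/`rejected`), `construct_id` and `control_type`
#' @export
callConstruct <- function(parsed, map, max_mismatch = 0L) {
  if (!max_mismatch %in% c(0L, 1L))
    stopInvalid("max_mismatch must be 0 or 1")
  n <- nrow(parsed)
  call_status <- parsed$status
  construct_id <- rep(NA_character_, n)
  control_type <- rep(NA_character_, n)
  reason <- parsed$reason

  ok <- which(parsed$status == "ok")
  if (length(ok)) {
    seen <- unique(unlist(parsed[ok, paste0("bc", 1:3)], use.names = FALSE))
    seen <- seen[!is.na(seen)]
    lut <- vapply(seen, resolveBarcode, character(1), map = map,
                  max_mismatch = max_mismatch)
    for (i in ok) {
      k <- parsed$n_blocks[i]
      res <- lut[unlist(parsed[i, paste0("bc", seq_len(k))],
                        use.names = FALSE)]
      if (any(startsWith(res, "reject:"))) {
        call_status[i] <- "rejected"
        reason[i] <- sub("^reject:", "", res[startsWith(res, "reject:")][1])
      } else if (any(startsWith(res, "control:"))) {
        call_status[i] <- "control"
        control_type[i] <- sub("^control:", "",
                               res[startsWith(res, "control:")][1])
        construct_id[i] <- res[startsWith(res, "control:")][1]
      } else {
        construct_id[i] <- paste(res, collapse = "-")
      }
    }
  }
  parsed$call_status <- ifelse(call_status == "ok", "ok", call_status)
  parsed$construct_id <- construct_id
  parsed$control_type <- control_type
  parsed$reason <- reason
  parsed
}

#' Tabulate called reads into a UMI count table
#'
#' @param calls data.frame from [callConstruct()]; only `call_status ==
#'   "ok"` (non-control) rows may be present or `drop_other = TRUE`
#' @param condition,replicate,target labels for the output rows
#' @param drop_other silently drop control/rejected rows instead of
#'   erroring
#' @return a [UmiCountTable-class]; the table total equals the number of
#'   accepted non-control calls
#' @export
tabulateCounts <- function(calls, condition, replicate = 1L,
                           target = "targetA", drop_other = FALSE) {
  bad <- calls$call_status != "ok"
  if (any(bad)) {
    if (!drop_other)
      stopInvalid("calls contain non-accepted rows; set drop_other = TRUE")
    calls <- calls[!bad, , drop = FALSE]
  }
  if (!nrow(calls))
    return(umiCountTable(data.frame(construct_id = character(0),
                                    umi = character(0),
                                    condition = character(0),
                                    replicate = integer(0),
                                    target = character(0),
                                    count = numeric(0))))
  dt <- data.table(construct_id = calls$construct_id, umi = calls$umi)
  dt <- dt[, list(count = as.numeric(.N)), by = c("construct_id", "umi")]
  dt[, c("condition", "replicate", "target") :=
       list(condition, as.integer(replicate), target)]
  setorder(dt, construct_id, umi)
  umiCountTable(as.data.frame(dt)[, UMI_COUNT_COLS])
}

#' Extract counts from raw reads with full accounting
#'
#' One-call wrapper: parse, call, tabulate. The accounting invariant
#' `accepted + rejected + control == total` holds per invocation.
#'
#' @param reads character vector of reads (e.g. from [readFastqReads()])
#' @param layout a [ReadLayout-class]
#' @param map a [BarcodeMap-class]
#' @param condition,replicate,target labels for the output rows
#' @param max_mismatch barcode mismatch tolerance (0 or 1)
#' @return list: `table` ([UmiCountTable-class] of accepted non-control
#'   reads), `accounting` (named counts: total, accepted, control,
#'   rejected), `rejections` (data.frame reason -> count),
#'   `controls` (data.frame control_type -> count)
#' @export
extractCounts <- function(reads, layout, map, condition,
                          replicate = 1L, target = "targetA",
                          max_mismatch = 0L) {
  calls <- callConstruct(parseReads(reads, layout), map, max_mismatch)
  acc <- c(total = nrow(calls),
           accepted = sum(calls$call_status == "ok"),
           control = sum(calls$call_status == "control"),
           rejected = sum(calls$call_status == "rejected"))
  rej <- table(calls$reason[calls$call_status == "rejected"])
  ctl <- table(calls$control_type[calls$call_status == "control"])
  list(table = tabulateCounts(calls[calls$call_status == "ok", ,
                                    drop = FALSE],
                              condition, replicate, target),
       accounting = acc,
       rejections = data.frame(reason = names(rej),
                               count = as.integer(rej),
                               stringsAsFactors = FALSE),
       controls = data.frame(control_type = names(ctl),
                             count = as.integer(ctl),
                             stringsAsFactors = FALSE))
}

#' Read/write FASTQ for screen reads
#'
#' Thin wrappers over Biostrings FASTQ IO. Quality strings are constant
#' (the simulator has no base-quality model).
#'
#' @param file path to a FASTQ file
#' @return `readFastqReads`: character vector of reads
#' @export
readFastqReads <- function(file) {
  unname(as.character(Biostrings::readDNAStringSet(file, format = "fastq")))
}

#' @rdname readFastqReads
#' @param reads character vector of reads to write
#' @export
writeFastqReads <- function(reads, file) {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("read%06d", seq_along(reads))
  Biostrings::writeXStringSet(x, file, format = "fastq")
  invisible(file)
}

#' Emit simulated reads for one condition of a screen
#'
#' Expands a [UmiCountTable-class] condition into the read layout so the
#' extraction stage can be exercised end to end. Control constructs are
#' encoded with their control barcode at every position.
#'
#' @param sim a [ScreenSim-class]
#' @param condition,replicate,target which condition to expand
#' @param layout a [ReadLayout-class]
#' @return character vector of reads (one per sequenced read)
#' @export
simulatedReads <- function(sim, condition, replicate = 1L,
                           target = NULL, layout = readLayout()) {
  target <- target %||% sim@config@targets[1]
  x <- umiCounts(simCounts(sim))
  x <- x[x$condition == condition & x$replicate == replicate &
           x$target == target, , drop = FALSE]
  if (!nrow(x)) return(character(0))
  cb <- controlBarcodes(simBarcodeMap(sim))
  ctl_bc <- setNames(names(cb), controlId(unname(cb)))
  tuples <- vector("list", nrow(x))
  is_ctl <- isControlId(x$construct_id)
  if (any(!is_ctl))
    tuples[!is_ctl] <- constructBarcodes(x$construct_id[!is_ctl],
                                         simParts(sim))
  if (any(is_ctl))
    tuples[is_ctl] <- lapply(x$construct_id[is_ctl], function(id)
      rep(unname(ctl_bc[id]), sim@config@arity))
  reads <- encodeRead(tuples, x$umi, layout)
  rep(reads, times = x$count)
}
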