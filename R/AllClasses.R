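#' @title Classes for combinatorial activator screens
#' @name combiscreen-classes
#' @description
#' S4 containers used across the package: simulation configuration
#' ([SimConfig-class]), amplicon read layout ([ReadLayout-class]), barcode
#' to part mapping ([BarcodeMap-class]), the long-format UMI count table
#' ([UmiCountTable-class]), per-construct screen scores
#' ([ScreenScores-class]) and the full synthetic screen bundle
#' ([ScreenSim-class]).
NULL

# ---------------------------------------------------------------------------
# SimConfig

#' Simulation configuration for a synthetic combinatorial screen
#'
#' Holds every parameter of the generative model: library composition,
#' lentiviral transduction, passaging, sorting gates, sequencing depth and
#' artifact injection. A fixed `seed` fully determines the simulator output.
#'
#' Defaults emulate the screened system: 22 activation domains plus 3
#' protein folders (two of them inert fillers), transduction at MOI 0.1,
#' four extreme sort gates of 12.5% of the population each, 6-nt UMIs,
#' 8-nt part barcodes, two replicates on two endogenous targets.
#'
#' @slot n_ads,n_pfs numbers of activation-domain and protein-folder parts
#' @slot arity parts per construct (1, 2 or 3)
#' @slot moi mean lentiviral integrations per cell (Poisson)
#' @slot n_cells cells exposed to virus per population
#' @slot passages growth passages before harvest; depletion is
#'   `2^(-fitness_cost * passages)`
#' @slot umi_length UMI width in nt
#' @slot barcode_length part-barcode width in nt
#' @slot bin_fractions widths of the four sort gates (fractions of the
#'   ranked population; two lower-extreme, two upper-extreme)
#' @slot read_depth reads sampled per sequenced condition
#' @slot jackpot_prob,jackpot_factor probability that a (construct, UMI)
#'   unit is PCR-jackpotted, and the count multiplier applied when it is
#' @slot control_fractions named plasmid spike fractions for
#'   `supernatant`, `multi_copy` and `mutant_scaffold` controls
#' @slot noise_sd log-scale fluorescence noise SD
#' @slot baseline baseline fluorescence added to summed part strengths
#' @slot order_sensitivity permute pairwise interaction terms by position
#'   (emulates order-dependent tripartite behavior)
#' @slot targets names of the sorted screen populations
#' @slot toxicity_targets targets whose unsorted populations enter the
#'   toxicity average (reporter populations are excluded)
#' @slot n_replicates biological replicates per target
#' @slot seed integer seed determining all randomness
#' @seealso [simConfig()], [simulateScreen()]
#' @exportClass SimConfig
setClass("SimConfig", representation(
  n_ads = "integer", n_pfs = "integer", arity = "integer",
  moi = "numeric", n_cells = "integer", passages = "numeric",
  umi_length = "integer", barcode_length = "integer",
  bin_fractions = "numeric", read_depth = "numeric",
  jackpot_prob = "numeric", jackpot_factor = "numeric",
  control_fractions = "numeric", noise_sd = "numeric",
  baseline = "numeric", order_sensitivity = "logical",
  targets = "character", toxicity_targets = "character",
  n_replicates = "integer", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (!object@arity %in% 1:3) msg <- c(msg, "arity must be 1, 2 or 3")
  if (length(object@bin_fractions) != 4L)
    msg <- c(msg, "bin_fractions must have length 4 (two lower, two upper gates)")
  if (sum(object@bin_fractions) > 1 + 1e-12)
    msg <- c(msg, "bin_fractions must sum to at most 1")
  if (any(object@bin_fractions <= 0))
    msg <- c(msg, "bin_fractions must be positive")
  if (object@moi <= 0) msg <- c(msg, "moi must be positive")
  if (object@read_depth <= 0) msg <- c(msg, "read_depth must be positive")
  if (object@n_ads < 1L) msg <- c(msg, "need at least one AD part")
  if (!all(object@toxicity_targets %in% object@targets))
    msg <- c(msg, "toxicity_targets must be a subset of targets")
  if (length(msg)) msg else TRUE
})

#' Construct a [SimConfig-class]
#'
#' @param n_ads,n_pfs library composition (default 22 ADs + 3 PFs = 25 parts)
#' @param arity parts per construct
#' @param moi mean integrations per cell
#' @param n_cells cells per population
#' @param passages growth passages applied before harvest
#' @param umi_length,barcode_length tag widths in nt
#' @param bin_fractions four sort-gate widths
#' @param read_depth reads per condition
#' @param jackpot_prob,jackpot_factor PCR jackpot model
#' @param control_fractions named spike fractions (see [SimConfig-class])
#' @param noise_sd log-scale fluorescence noise
#' @param baseline baseline fluorescence
#' @param order_sensitivity position-permuted interactions flag
#' @param targets,toxicity_targets screened populations and the subset used
#'   for toxicity averaging
#' @param n_replicates replicates per target
#' @param seed integer seed
#' @return a validated [SimConfig-class]
#' @examples
#' cfg <- simConfig(arity = 2, n_cells = 1e5, seed = 1)
#' cfg
#' @export
simConfig <- function(n_ads = 22, n_pfs = 3, arity = 2, moi = 0.1,
                      n_cells = 1e6, passages = 4, umi_length = 6,
                      barcode_length = 8, bin_fractions = rep(0.125, 4),
                      read_depth = 1e6, jackpot_prob = 0.0,
                      jackpot_factor = 10,
                      control_fractions = c(supernatant = 0.015,
                                            multi_copy = 0.015,
                                            mutant_scaffold = 0.015),
                      noise_sd = 0.5, baseline = 1,
                      order_sensitivity = FALSE,
                      targets = c("targetA", "targetB"),
                      toxicity_targets = targets,
                      n_replicates = 2, seed = 1L) {
  new("SimConfig",
      n_ads = as.integer(n_ads), n_pfs = as.integer(n_pfs),
      arity = as.integer(arity), moi = as.numeric(moi),
      n_cells = as.integer(n_cells), passages = as.numeric(passages),
      umi_length = as.integer(umi_length),
      barcode_length = as.integer(barcode_length),
      bin_fractions = as.numeric(bin_fractions),
      read_depth = as.numeric(read_depth),
      jackpot_prob = as.numeric(jackpot_prob),
      jackpot_factor = as.numeric(jackpot_factor),
      control_fractions = control_fractions,
      noise_sd = as.numeric(noise_sd), baseline = as.numeric(baseline),
      order_sensitivity = isTRUE(order_sensitivity),
      targets = targets, toxicity_targets = toxicity_targets,
      n_replicates = as.integer(n_replicates), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@n_ads, "ADs +", object@n_pfs, "PFs, arity",
      object@arity, "\n  MOI", object@moi, "|", object@n_cells, "cells |",
      object@passages, "passages |", format(object@read_depth, big.mark = ","),
      "reads/condition\n  targets:", paste(object@targets, collapse = ", "),
      "x", object@n_replicates, "replicates | seed", object@seed, "\n")
})

# ---------------------------------------------------------------------------
# ReadLayout

#' Amplicon read layout
#'
#' Describes the scar-delimited structure of a sequencing read:
#' an upstream anchor, then one (barcode, UMI) block per part position,
#' blocks separated by the cloning scar, and optional terminal context.
#' With `block_order = "innermost_last"` (the default, reflecting iterative
#' insertion between the previous ORF and its barcode) the block of
#' position 1 — the part closest to the scaffold — is read last.
#'
#' @slot upstream_anchor,scar,terminal DNA strings; anchor and scar must be
#'   non-empty and distinct
#' @slot barcode_length,umi_length block widths in nt
#' @slot block_order `"innermost_last"` or `"innermost_first"`
#' @seealso [readLayout()], [parseRead()], [encodeRead()]
#' @exportClass ReadLayout
setClass("ReadLayout", representation(
  upstream_anchor = "character", scar = "character", terminal = "character",
  barcode_length = "integer", umi_length = "integer",
  block_order = "character"))

setValidity("ReadLayout", function(object) {
  msg <- character(0)
  if (!nzchar(object@upstream_anchor)) msg <- c(msg, "upstream_anchor must be non-empty")
  if (!nzchar(object@scar)) msg <- c(msg, "scar must be non-empty")
  if (identical(object@upstream_anchor, object@scar))
    msg <- c(msg, "anchor and scar must be distinct")
  if (!object@block_order %in% c("innermost_last", "innermost_first"))
    msg <- c(msg, "block_order must be innermost_last or innermost_first")
  if (length(msg)) msg else TRUE
})

#' Construct a [ReadLayout-class]
#'
#' @param upstream_anchor,scar,terminal anchor sequences (defaults are the
#'   fused-restriction-site style scars used by the simulator)
#' @param barcode_length,umi_length block widths
#' @param block_order see [ReadLayout-class]
#' @return a validated [ReadLayout-class]
#' @export
readLayout <- function(upstream_anchor = "TGTACACT", scar = "CGTACGCT",
                       terminal = "GCTAGCGA", barcode_length = 8,
                       umi_length = 6, block_order = "innermost_last") {
  new("ReadLayout", upstream_anchor = toupper(upstream_anchor),
      scar = toupper(scar), terminal = toupper(terminal),
      barcode_length = as.integer(barcode_length),
      umi_length = as.integer(umi_length), block_order = block_order)
}

setMethod("show", "ReadLayout", function(object) {
  cat("ReadLayout: anchor", object@upstream_anchor, "| scar", object@scar,
      "| block", object@barcode_length, "nt barcode +", object@umi_length,
      "nt UMI |", object@block_order, "\n")
})

# ---------------------------------------------------------------------------
# BarcodeMap

#' Barcode-to-part mapping with control barcodes
#'
#' @slot part_ids character vector of part identifiers, named by their 8-nt
#'   barcodes (the mapping barcode -> part, required injective)
#' @slot control_types character vector of control labels
#'   (`supernatant`, `multi_copy`, `mutant_scaffold`), named by their
#'   barcodes; disjoint from part barcodes
#' @seealso [barcodeMap()], [callConstruct()]
#' @exportClass BarcodeMap
setClass("BarcodeMap", representation(
  part_ids = "character", control_types = "character"))

setValidity("BarcodeMap", function(object) {
  msg <- character(0)
  bc <- names(object@part_ids)
  if (is.null(bc) || any(!nzchar(bc)))
    msg <- c(msg, "part_ids must be named by barcodes")
  if (anyDuplicated(bc)) msg <- c(msg, "duplicate part barcode")
  if (anyDuplicated(object@part_ids)) msg <- c(msg, "mapping must be injective")
  cb <- names(object@control_types)
  if (length(object@control_types) && is.null(cb))
    msg <- c(msg, "control_types must be named by barcodes")
  if (length(intersect(bc, cb)))
    msg <- c(msg, "control barcodes must be disjoint from part barcodes")
  if (length(msg)) msg else TRUE
})

#' Construct a [BarcodeMap-class]
#'
#' @param parts data.frame with columns `part_id` and `barcode`
#' @param controls optional data.frame with columns `control_type` and
#'   `barcode`
#' @return a validated [BarcodeMap-class]
#' @export
barcodeMap <- function(parts, controls = NULL) {
  p <- setNames(as.character(parts$part_id), toupper(parts$barcode))
  ct <- if (!is.null(controls) && nrow(controls))
    setNames(as.character(controls$control_type), toupper(controls$barcode))
  else setNames(character(0), character(0))
  new("BarcodeMap", part_ids = p, control_types = ct)
}

setMethod("show", "BarcodeMap", function(object) {
  cat("BarcodeMap:", length(object@part_ids), "part barcodes,",
      length(object@control_types), "control barcodes\n")
})

#' Accessors for BarcodeMap
#' @param x a [BarcodeMap-class]
#' @return `partBarcodes` returns the barcode->part_id named vector;
#'   `controlBarcodes` the barcode->control_type named vector.
#' @export
partBarcodes <- function(x) x@part_ids

#' @rdname partBarcodes
#' @export
controlBarcodes <- function(x) x@control_types

# ---------------------------------------------------------------------------
# UmiCountTable

#' Long-format UMI-resolved count table
#'
#' One row per (construct, UMI, condition, replicate, target) with a
#' non-negative integer read (or cell) count. Conditions are the four sort
#' bins `bin1..bin4`, `unsorted`, and `plasmid`.
#'
#' @slot counts a data.frame with columns `construct_id`, `umi`,
#'   `condition`, `replicate`, `target`, `count`
#' @seealso [umiCountTable()], [umiCounts()], [filterOutlierUmis()],
#'   [groupAndNormalize()]
#' @exportClass UmiCountTable
setClass("UmiCountTable", representation(counts = "data.frame"))

UMI_COUNT_COLS <- c("construct_id", "umi", "condition", "replicate",
                    "target", "count")

setValidity("UmiCountTable", function(object) {
  x <- object@counts
  msg <- character(0)
  missing_cols <- setdiff(UMI_COUNT_COLS, names(x))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(x)) {
    if (any(x$count < 0)) msg <- c(msg, "counts must be non-negative")
    if (anyDuplicated(x[, c("construct_id", "umi", "condition",
                            "replicate", "target")]))
      msg <- c(msg, "(construct, umi, condition, replicate, target) must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a [UmiCountTable-class]
#'
#' @param counts data.frame with the columns listed in
#'   [UmiCountTable-class]; extra columns are dropped
#' @return a validated [UmiCountTable-class]
#' @export
umiCountTable <- function(counts) {
  x <- as.data.frame(counts)[, UMI_COUNT_COLS, drop = FALSE]
  x$count <- as.numeric(x$count)
  new("UmiCountTable", counts = x)
}

#' Extract the underlying count data.frame
#' @param x a [UmiCountTable-class]
#' @return data.frame of counts
#' @export
umiCounts <- function(x) {
  stopifnot(is(x, "UmiCountTable"))
  x@counts
}

setMethod("show", "UmiCountTable", function(object) {
  x <- object@counts
  cat("UmiCountTable:", nrow(x), "rows |",
      length(unique(x$construct_id)), "constructs |",
      "conditions:", paste(sort(unique(x$condition)), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# ScreenScores

#' Per-construct screen scores
#'
#' @slot activation data.frame (`construct_id`, `target`,
#'   `activation_score`, `n_groups`): replicate-averaged
#'   fluorescence-weighted scores and the number of scored UMI groups
#' @slot toxicity data.frame (`construct_id`, `toxicity_score`):
#'   replicate- and target-averaged dropout scores (higher = more toxic)
#' @slot coverage data.frame of per-target scored-construct fractions
#' @slot metadata list echoing every filtering threshold applied
#' @seealso [scoreActivationScreen()], [scoreToxicityScreen()]
#' @exportClass ScreenScores
setClass("ScreenScores", representation(
  activation = "data.frame", toxicity = "data.frame",
  coverage = "data.frame", metadata = "list"))

#' Accessors for ScreenScores
#' @param x a [ScreenScores-class]
#' @return the corresponding data.frame (see [ScreenScores-class])
#' @export
activationScores <- function(x) { stopifnot(is(x, "ScreenScores")); x@activation }

#' @rdname activationScores
#' @export
toxicityScores <- function(x) { stopifnot(is(x, "ScreenScores")); x@toxicity }

#' @rdname activationScores
#' @export
scoreCoverage <- function(x) { stopifnot(is(x, "ScreenScores")); x@coverage }

#' @rdname activationScores
#' @export
scoreMetadata <- function(x) { stopifnot(is(x, "ScreenScores")); x@metadata }

setMethod("show", "ScreenScores", function(object) {
  cat("ScreenScores:", nrow(object@activation), "activation rows |",
      nrow(object@toxicity), "toxicity rows\n")
  if (nrow(object@coverage)) {
    cat("  coverage (fraction of constructs scored):\n")
    print(object@coverage, row.names = FALSE)
  }
})

# ---------------------------------------------------------------------------
# ScreenSim

#' A complete synthetic screen with ground truth
#'
#' Bundle returned by [simulateScreen()]: the part library, the enumerated
#' constructs, the latent generative parameters (ground truth), plasmid
#' abundances, the simulated [UmiCountTable-class], per-bin mean
#' fluorescence intensities, the [BarcodeMap-class] and the
#' [SimConfig-class] used.
#'
#' @slot parts data.frame (`part_id`, `klass`, `inert`, `barcode`,
#'   `sequence`)
#' @slot constructs data.frame (`construct_id`, `arity`, `p1`..`p3`)
#' @slot latent list: `part_params` (per-part `base_strength`,
#'   `fitness_cost`), `interactions` (part x part matrix),
#'   `construct_truth` (per-construct summed strength/cost)
#' @slot plasmid data.frame (`construct_id`, `abundance`)
#' @slot counts [UmiCountTable-class]
#' @slot mfi data.frame (`target`, `replicate`, `bin`, `mfi`)
#' @slot barcode_map [BarcodeMap-class]
#' @slot config [SimConfig-class]
#' @exportClass ScreenSim
setClass("ScreenSim", representation(
  parts = "data.frame", constructs = "data.frame", latent = "list",
  plasmid = "data.frame", counts = "UmiCountTable", mfi = "data.frame",
  barcode_map = "BarcodeMap", config = "SimConfig"))

setMethod("show", "ScreenSim", function(object) {
  cat("ScreenSim:", nrow(object@constructs), "constructs (arity",
      object@config@arity, ") |", nrow(umiCounts(object@counts)),
      "count rows | seed", object@config@seed, "\n")
})

#' Accessors for ScreenSim
#' @param x a [ScreenSim-class]
#' @return the corresponding component (see [ScreenSim-class])
#' @export
simParts <- function(x) { stopifnot(is(x, "ScreenSim")); x@parts }

#' @rdname simParts
#' @export
simConstructs <- function(x) { stopifnot(is(x, "ScreenSim")); x@constructs }

#' @rdname simParts
#' @export
simLatent <- function(x) { stopifnot(is(x, "ScreenSim")); x@latent }

#' @rdname simParts
#' @export
simCounts <- function(x) { stopifnot(is(x, "ScreenSim")); x@counts }

#' @rdname simParts
#' @export
simMfi <- function(x) { stopifnot(is(x, "ScreenSim")); x@mfi }

#' @rdname simParts
#' @export
simBarcodeMap <- function(x) { stopifnot(is(x, "ScreenSim")); x@barcode_map }

#' @rdname simParts
#' @export
simPlasmid <- function(x) { stopifnot(is(x, "ScreenSim")); x@plasmid }
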