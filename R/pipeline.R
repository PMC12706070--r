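# Pipeline orchestration: plain-TSV interchange between stages, a JSON
# manifest recording config, seed, versions and every threshold applied,
# and a single entry point running simulate -> extract -> score ->
# analyze -> features.

#' TSV readers/writers for pipeline tables
#'
#' All stages exchange plain TSVs with headers; these are thin
#' data.table wrappers fixing separators and types.
#'
#' @param x data.frame to write
#' @param file path
#' @return `readTsv` returns a data.frame
#' @export
writeTsv <- function(x, file) {
  data.table::fwrite(as.data.frame(x), file, sep = "\t")
  invisible(file)
}

#' @rdname writeTsv
#' @export
readTsv <- function(file) {
  as.data.frame(data.table::fread(file, sep = "\t"))
}

#' Write all tables of a simulated screen
#'
#' Emits the fixture set: `parts.tsv`, `constructs.tsv`,
#' `latent_truth.tsv` (ground truth), `plasmid.tsv`, `counts.tsv`,
#' `mfi.tsv` and `barcode_map.tsv`.
#'
#' @param sim a [ScreenSim-class]
#' @param dir output directory (created if needed)
#' @param fastq also write per-condition FASTQ files of the sequenced
#'   reads (only sensible at small scale)
#' @param layout [ReadLayout-class] used when `fastq = TRUE`
#' @return invisibly, the named vector of written paths
#' @export
writeScreenSim <- function(sim, dir, fastq = FALSE,
                           layout = readLayout()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(parts = file.path(dir, "parts.tsv"),
             constructs = file.path(dir, "constructs.tsv"),
             latent = file.path(dir, "latent_truth.tsv"),
             plasmid = file.path(dir, "plasmid.tsv"),
             counts = file.path(dir, "counts.tsv"),
             mfi = file.path(dir, "mfi.tsv"),
             barcodes = file.path(dir, "barcode_map.tsv"))
  writeTsv(simParts(sim), paths["parts"])
  writeTsv(simConstructs(sim), paths["constructs"])
  writeTsv(simLatent(sim)$construct_truth, paths["latent"])
  writeTsv(simPlasmid(sim), paths["plasmid"])
  writeTsv(umiCounts(simCounts(sim)), paths["counts"])
  writeTsv(simMfi(sim), paths["mfi"])
  bm <- simBarcodeMap(sim)
  writeTsv(rbind(
    data.frame(barcode = names(partBarcodes(bm)),
               id = unname(partBarcodes(bm)), type = "part"),
    data.frame(barcode = names(controlBarcodes(bm)),
               id = unname(controlBarcodes(bm)), type = "control")),
    paths["barcodes"])
  if (fastq) {
    x <- umiCounts(simCounts(sim))
    combos <- unique(x[, c("condition", "replicate", "target")])
    for (i in seq_len(nrow(combos))) {
      f <- file.path(dir, sprintf("reads_%s_%s_rep%d.fastq",
                                  combos$target[i], combos$condition[i],
                                  combos$replicate[i]))
      writeFastqReads(simulatedReads(sim, combos$condition[i],
                                     combos$replicate[i],
                                     combos$target[i], layout), f)
      paths[paste0("fastq.", i)] <- f
    }
  }
  invisible(paths)
}

#' Read a barcode map TSV
#' @param file TSV written by [writeScreenSim()] (columns `barcode`,
#'   `id`, `type`)
#' @return a [BarcodeMap-class]
#' @export
readBarcodeMap <- function(file) {
  x <- readTsv(file)
  barcodeMap(data.frame(part_id = x$id[x$type == "part"],
                        barcode = x$barcode[x$type == "part"]),
             if (any(x$type == "control"))
               data.frame(control_type = x$id[x$type == "control"],
                          barcode = x$barcode[x$type == "control"])
             else NULL)
}

defaultRunConfig <- function() {
  list(seed = 1L, outdir = "combiscreen_run",
       simulate = list(n_ads = 22, n_pfs = 3, arity = 2, moi = 0.1,
                       n_cells = 1e6, passages = 4, read_depth = 1e6,
                       jackpot_prob = 0, jackpot_factor = 10,
                       noise_sd = 0.5, fastq = FALSE),
       score = list(umi_outlier_fraction = 0.5, umi_prefix_length = 2,
                    normalization_target = 100, min_bin_sum = NULL,
                    pseudoread = 1),
       analyze = list(value_col = "activation_score"))
}

mergeConfig <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]))
      mergeConfig(base[[k]], override[[k]]) else override[[k]]
  }
  base
}

#' Run the full screen pipeline
#'
#' Orchestrates simulate -> (optional FASTQ extract round trip) ->
#' activation and toxicity scoring -> combinatorial analyses, writing
#' every stage output as TSV under `config$outdir` plus a
#' `manifest.json` that records the full effective configuration, the
#' seed, the package version and all applied thresholds. Reruns with an
#' identical manifest reproduce identical outputs.
#'
#' @param config nested list (or path to a YAML file) overriding the
#'   defaults: global `seed`, `outdir`, and `simulate` / `score` /
#'   `analyze` stage blocks. `simulate = NULL` skips simulation and
#'   reads `counts.tsv` / `mfi.tsv` already present in `outdir`
#'   (resume from intermediate tables).
#' @return invisibly, a list with the stage results (`sim`, `scores`,
#'   `analysis`, `manifest`)
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- mergeConfig(defaultRunConfig(), config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log_ <- function(...) message("[combiscreen] ", ...)

  sim <- NULL
  if (!is.null(cfg$simulate)) {
    sc <- cfg$simulate
    simcfg <- simConfig(n_ads = sc$n_ads, n_pfs = sc$n_pfs,
                        arity = sc$arity, moi = sc$moi,
                        n_cells = sc$n_cells, passages = sc$passages,
                        read_depth = sc$read_depth,
                        jackpot_prob = sc$jackpot_prob,
                        jackpot_factor = sc$jackpot_factor,
                        noise_sd = sc$noise_sd, seed = cfg$seed)
    log_("simulating ", simcfg@n_ads + simcfg@n_pfs, " parts, arity ",
         simcfg@arity)
    sim <- simulateScreen(simcfg)
    writeScreenSim(sim, cfg$outdir, fastq = isTRUE(sc$fastq))
    counts <- simCounts(sim)
    mfi <- simMfi(sim)
  } else {
    counts_path <- file.path(cfg$outdir, "counts.tsv")
    mfi_path <- file.path(cfg$outdir, "mfi.tsv")
    if (!file.exists(counts_path) || !file.exists(mfi_path))
      stop("no simulate block and no counts.tsv/mfi.tsv in outdir")
    counts <- umiCountTable(readTsv(counts_path))
    mfi <- readTsv(mfi_path)
  }

  fc <- filterConfig(
    umi_outlier_fraction = cfg$score$umi_outlier_fraction,
    umi_prefix_length = cfg$score$umi_prefix_length,
    normalization_target = cfg$score$normalization_target,
    min_bin_sum = cfg$score$min_bin_sum,
    pseudoread = cfg$score$pseudoread)
  log_("scoring ", nrow(umiCounts(counts)), " count rows")
  scores <- scoreScreen(counts, mfi, fc)
  writeTsv(activationScores(scores),
           file.path(cfg$outdir, "activation_scores.tsv"))
  writeTsv(toxicityScores(scores),
           file.path(cfg$outdir, "toxicity_scores.tsv"))
  writeTsv(scoreCoverage(scores),
           file.path(cfg$outdir, "coverage_report.tsv"))

  analysis <- NULL
  if (!is.null(cfg$analyze) && !is.null(sim)) {
    act <- activationScores(scores)
    act1 <- act[act$target == unique(act$target)[1], ]
    parts <- simParts(sim)
    analysis <- list()
    analysis$order <- tryCatch(
      orderEffectCorrelation(act1, cfg$analyze$value_col),
      combiscreen_insufficient_data = function(e) NULL)
    analysis$effects <- tryCatch(
      effectSummaries(act1, parts, simConstructs(sim)$arity[1],
                      cfg$analyze$value_col),
      error = function(e) NULL)
    if (!is.null(analysis$order)) {
      writeTsv(analysis$order$pairs,
               file.path(cfg$outdir, "order_pairs.tsv"))
    }
    if (!is.null(analysis$effects)) {
      writeTsv(analysis$effects,
               file.path(cfg$outdir, "effect_summaries.tsv"))
    }
  }

  manifest <- list(
    package = "combiscreen",
    version = as.character(packageVersion("combiscreen")),
    seed = cfg$seed,
    config = cfg,
    thresholds = unclass(fc)[c("umi_outlier_fraction", "outlier_scope",
                               "umi_prefix_length",
                               "normalization_target", "min_bin_sum",
                               "pseudoread")])
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_("done; outputs in ", cfg$outdir)
  invisible(list(sim = sim, scores = scores, analysis = analysis,
                 manifest = manifest))
}
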