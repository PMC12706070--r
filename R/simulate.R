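# Synthetic combinatorial screen simulator.
#
# Generative model, per screened population:
#   integrations/cell ~ Poisson(moi); infected cells keep one construct
#   drawn proportional to (packagable) plasmid abundance and receive a
#   fresh random UMI; clones deplete as 2^(-fitness_cost * passages);
#   per-cell fluorescence = exp(log(baseline + sum part strengths +
#   interactions) + N(0, noise_sd)); the ranked population is gated into
#   four extreme bins; reads are drawn multinomially per condition with
#   optional PCR-jackpot inflation and spiked control barcodes.

CONTROL_TYPES <- c("supernatant", "multi_copy", "mutant_scaffold")

controlId <- function(type) paste0("control:", type)

#' Is a construct id a built-in control?
#' @param construct_id character vector
#' @return logical vector
#' @export
isControlId <- function(construct_id) startsWith(construct_id, "control:")

#' Draw latent generative parameters for a part library
#'
#' Activation-domain strengths are log-normal (median 20 fluorescence
#' units, log-SD 0.9); protein folders contribute no activation. Every
#' part carries a gamma-distributed per-passage fitness cost
#' (shape 1.5, mean 0.25 log2 units), so construct toxicity — the sum of
#' part costs — varies continuously across the library. The pairwise
#' interaction matrix defaults to zero.
#'
#' @param parts part library data.frame (see [makePartLibrary()])
#' @param seed integer seed
#' @param strength_meanlog,strength_sdlog log-normal AD strength parameters
#' @param cost_shape,cost_mean gamma fitness-cost parameters (per passage,
#'   log2 growth deficit)
#' @return list with `part_params` (per-part `base_strength`,
#'   `fitness_cost`) and `interactions` (zero part x part matrix)
#' @export
makeLatentParams <- function(parts, seed = 1L, strength_meanlog = log(20),
                             strength_sdlog = 0.9, cost_shape = 1.5,
                             cost_mean = 0.25) {
  withr::with_seed(deriveSeed(seed, "latent"), {
    n <- nrow(parts)
    strength <- rlnorm(n, strength_meanlog, strength_sdlog)
    strength[parts$klass == "PF"] <- 0  # folders are activation-inert
    cost <- rgamma(n, shape = cost_shape, rate = cost_shape / cost_mean)
    pp <- data.frame(part_id = parts$part_id,
                     base_strength = strength, fitness_cost = cost,
                     stringsAsFactors = FALSE)
    inter <- matrix(0, n, n, dimnames = list(parts$part_id, parts$part_id))
    list(part_params = pp, interactions = inter)
  })
}

#' Ground-truth summed strength and fitness cost per construct
#'
#' Construct strength is the sum of its parts' base strengths plus all
#' ordered pairwise interaction terms; with `order_sensitivity = FALSE`
#' the interaction matrix is symmetrized so order-reversed constructs are
#' exactly equivalent. Construct fitness cost is the sum of part costs.
#'
#' @param constructs construct table from [enumerateConstructs()]
#' @param latent list from [makeLatentParams()]
#' @param order_sensitivity use position-ordered (asymmetric) interaction
#'   terms
#' @return data.frame (`construct_id`, `strength`, `fitness_cost`)
#' @export
constructTruth <- function(constructs, latent, order_sensitivity = FALSE) {
  pp <- latent$part_params
  st <- setNames(pp$base_strength, pp$part_id)
  co <- setNames(pp$fitness_cost, pp$part_id)
  inter <- latent$interactions
  if (!order_sensitivity) inter <- (inter + t(inter)) / 2
  tup <- constructTuple(constructs$construct_id)
  strength <- vapply(tup, function(p) {
    s <- sum(st[p])
    if (length(p) > 1L) {
      ij <- combn(seq_along(p), 2L)
      s <- s + sum(inter[cbind(p[ij[1, ]], p[ij[2, ]])])
    }
    s
  }, numeric(1))
  cost <- vapply(tup, function(p) sum(co[p]), numeric(1))
  data.frame(construct_id = constructs$construct_id,
             strength = strength, fitness_cost = cost,
             stringsAsFactors = FALSE)
}

#' Simulate lentiviral transduction and growth of a cell pool
#'
#' Integrations per cell are Poisson(`moi`); an infected cell keeps a
#' single construct drawn proportional to plasmid abundance (real screens
#' aim for single copy at MOI 0.1). Each transduction event receives a
#' fresh random UMI; clones then deplete deterministically as
#' `2^(-fitness_cost * passages)`.
#'
#' Built-in controls, when present in `plasmid_abundances` under ids
#' `control:supernatant` etc., behave as in the screens: the supernatant
#' control is strongly attenuated in cells (residual unpackaged plasmid
#' carryover only); the multi-copy control survives
#' selection only in cells carrying a second (resistant) integration;
#' the mutant-scaffold control transduces normally.
#'
#' @param constructs construct table, or any data.frame with
#'   `construct_id`
#' @param plasmid_abundances non-negative numeric, one per construct
#'   (at least one positive)
#' @param config a [SimConfig-class]
#' @param fitness_cost numeric per-construct per-passage log2 cost
#'   (default all zero)
#' @param seed integer seed (default derived from `config@seed`)
#' @return data.frame (`construct_id`, `umi`, `cell_count`) — a clonal
#'   cell population; `cell_count` is real-valued after growth
#' @export
simulateCellPool <- function(constructs, plasmid_abundances, config,
                             fitness_cost = NULL, seed = NULL) {
  ids <- constructs$construct_id
  ab <- as.numeric(plasmid_abundances)
  if (length(ab) != length(ids))
    stopInvalid("plasmid_abundances must match constructs")
  if (any(ab < 0) || !any(ab > 0))
    stopInvalid("plasmid abundances must be non-negative with at least one positive")
  if (is.null(fitness_cost)) fitness_cost <- numeric(length(ids))
  cost <- setNames(as.numeric(fitness_cost), ids)
  seed <- seed %||% deriveSeed(config@seed, "cellpool")

  withr::with_seed(seed, {
    k <- rpois(config@n_cells, config@moi)
    n_inf <- sum(k >= 1L)
    if (n_inf == 0L)
      return(data.frame(construct_id = character(0), umi = character(0),
                        cell_count = numeric(0)))
    # supernatant control is not packaged into virions; residual plasmid
    # carryover in the media leaves a strongly attenuated trace in cells
    pack <- ab
    pack[ids == controlId("supernatant")] <-
      0.02 * pack[ids == controlId("supernatant")]
    draw1 <- sample.int(length(ids), n_inf, replace = TRUE, prob = pack)
    kept <- draw1
    multi <- which(k[k >= 1L] >= 2L)
    mc_idx <- which(ids == controlId("multi_copy"))
    if (length(multi)) {
      draw2 <- sample.int(length(ids), length(multi), replace = TRUE,
                          prob = pack)
      pick2 <- runif(length(multi)) < 0.5
      kept[multi][pick2] <- draw2[pick2]
    }
    # puromycin selection: single-copy multi-copy-control cells die
    if (length(mc_idx)) {
      single <- setdiff(seq_len(n_inf), multi)
      keep <- rep(TRUE, n_inf)
      keep[single] <- kept[single] != mc_idx
      kept <- kept[keep]
    }
    umis <- randomDna(length(kept), config@umi_length)
    pool <- data.table(construct_id = ids[kept], umi = umis)
    pool <- pool[, list(cell_count = as.numeric(.N)),
                 by = c("construct_id", "umi")]
    pool[, "cell_count" := pool$cell_count *
           2^(-cost[pool$construct_id] * config@passages)]
    setorder(pool, construct_id, umi)
    as.data.frame(pool)
  })
}

#' Sort a cell population into four extreme fluorescence bins
#'
#' Per-cell fluorescence is `exp(log(baseline + strength) +
#' N(0, noise_sd))` where `strength` is the construct's summed latent
#' strength. Cells are ranked (ties broken by construct id then UMI, for
#' determinism) and gated at population quantiles into bins covering the
#' two lower and two upper extremes (default 12.5% each); the middle of
#' the distribution is discarded, as in extreme-bin FACS sorting.
#'
#' @param cells cell population data.frame (`construct_id`, `umi`,
#'   `cell_count`) from [simulateCellPool()]
#' @param strengths named numeric: summed latent strength per construct
#'   (missing constructs get 0)
#' @param config a [SimConfig-class]
#' @param n_sort number of cells to sort (default: the rounded population
#'   size; drawn multinomially from clone weights)
#' @param seed integer seed
#' @return list with `bins` — data.frame (`construct_id`, `umi`, `bin`,
#'   `cell_count`) for `bin1..bin4` (bin4 = brightest) — and `mfi`, the
#'   four per-bin mean fluorescence intensities
#' @export
simulateSort <- function(cells, strengths, config, n_sort = NULL,
                         seed = NULL) {
  if (!nrow(cells)) stopInvalid("empty cell population")
  n <- n_sort %||% round(sum(cells$cell_count))
  if (n < 8) stopInvalid("need at least 8 cells to gate four bins")
  seed <- seed %||% deriveSeed(config@seed, "sort")

  withr::with_seed(seed, {
    idx <- sample.int(nrow(cells), n, replace = TRUE,
                      prob = cells$cell_count)
    cid <- cells$construct_id[idx]
    umi <- cells$umi[idx]
    s <- strengths[cid]
    s[is.na(s)] <- 0
    fluor <- exp(log(config@baseline + s) + rnorm(n, 0, config@noise_sd))
    ord <- order(fluor, cid, umi, method = "radix")
    f <- config@bin_fractions
    c1 <- round(n * f[1]); c2 <- round(n * (f[1] + f[2]))
    c3 <- n - round(n * (f[3] + f[4])); c4 <- n - round(n * f[4])
    bin_of <- rep(NA_character_, n)
    bin_of[ord[seq_len(c1)]] <- "bin1"
    if (c2 > c1) bin_of[ord[(c1 + 1):c2]] <- "bin2"
    if (c4 > c3) bin_of[ord[(c3 + 1):c4]] <- "bin3"
    if (n > c4) bin_of[ord[(c4 + 1):n]] <- "bin4"
    keep <- !is.na(bin_of)
    mfi <- vapply(paste0("bin", 1:4),
                  function(b) mean(fluor[which(bin_of == b)]), numeric(1))
    bins <- data.table(construct_id = cid[keep], umi = umi[keep],
                       bin = bin_of[keep])
    bins <- bins[, list(cell_count = as.numeric(.N)),
                 by = c("construct_id", "umi", "bin")]
    setorder(bins, bin, construct_id, umi)
    list(bins = as.data.frame(bins), mfi = mfi)
  })
}

# Multinomial read sampling over (construct, umi) weights, with PCR
# jackpots: each unit's sampled count is inflated by jackpot_factor with
# probability jackpot_prob.
sampleReads <- function(weights, depth, jackpot_prob = 0,
                        jackpot_factor = 1) {
  if (depth <= 0) stopInvalid("read_depth must be positive")
  w <- weights$weight
  counts <- as.numeric(rmultinom(1L, size = depth, prob = w))
  if (jackpot_prob > 0) {
    jack <- runif(length(counts)) < jackpot_prob
    counts[jack] <- counts[jack] * jackpot_factor
  }
  out <- data.table(construct_id = weights$construct_id,
                    umi = weights$umi, count = counts)
  as.data.frame(out[out$count > 0, ])
}

#' Simulate sequencing of screen conditions
#'
#' Draws `config@read_depth` reads per condition, multinomially over
#' (construct, UMI) cell counts, applying the PCR-jackpot model.
#'
#' @param conditions named list of weight data.frames (`construct_id`,
#'   `umi`, `weight`), one per condition (e.g. `bin1..bin4`, `unsorted`,
#'   `plasmid`)
#' @param config a [SimConfig-class]
#' @param replicate,target labels stamped on the output rows
#' @param seed integer seed
#' @return a [UmiCountTable-class] data.frame fragment (not yet wrapped)
#' @export
simulateSequencing <- function(conditions, config, replicate = 1L,
                               target = "targetA", seed = NULL) {
  seed <- seed %||% deriveSeed(config@seed, "seq")
  withr::with_seed(seed, {
    out <- lapply(names(conditions), function(cond) {
      w <- conditions[[cond]]
      if (!nrow(w)) return(NULL)
      r <- sampleReads(w, config@read_depth, config@jackpot_prob,
                       config@jackpot_factor)
      r$condition <- cond
      r
    })
    tab <- rbindlist(out)
    tab[, c("replicate", "target") := list(as.integer(replicate), target)]
    as.data.frame(tab)[, UMI_COUNT_COLS]
  })
}

# plasmid pool: per-construct abundance split over a few cloning UMIs
plasmidWeights <- function(plasmid, umis_per_construct, umi_length, seed) {
  withr::with_seed(seed, {
    n <- nrow(plasmid)
    k <- umis_per_construct
    w <- data.table(
      construct_id = rep(plasmid$construct_id, each = k),
      umi = randomDna(n * k, umi_length),
      weight = rep(plasmid$abundance / k, each = k))
    # random UMIs can collide within a construct; merge such rows
    w <- w[, list(weight = sum(.SD$weight)),
           by = c("construct_id", "umi")]
    as.data.frame(w)
  })
}

#' Simulate a complete combinatorial activator screen
#'
#' End-to-end generator with known ground truth: builds the part library,
#' enumerates all ordered constructs, draws latent strengths and fitness
#' costs, spikes barcoded controls into the plasmid pool, and for every
#' target x replicate simulates transduction, growth, four-bin sorting
#' and sequencing of the four bins plus the unsorted population and the
#' plasmid library.
#'
#' @param config a [SimConfig-class]; `config@seed` determines the entire
#'   output (identical configs give identical screens)
#' @param latent optionally, a pre-built latent parameter list from
#'   [makeLatentParams()] (must match the library size)
#' @return a [ScreenSim-class]
#' @examples
#' sim <- simulateScreen(simConfig(n_ads = 4, n_pfs = 2, arity = 2,
#'                                 n_cells = 2e4, read_depth = 2e4,
#'                                 seed = 7))
#' sim
#' @export
simulateScreen <- function(config, latent = NULL) {
  parts <- makePartLibrary(config@n_ads, config@n_pfs,
                           config@barcode_length, seed = config@seed)
  constructs <- enumerateConstructs(parts, config@arity)
  if (is.null(latent)) latent <- makeLatentParams(parts, seed = config@seed)
  truth <- constructTruth(constructs, latent, config@order_sensitivity)

  # plasmid pool: log-normal jitter around equal representation,
  # controls spiked at configured fractions of the total
  cf <- config@control_fractions
  plasmid <- withr::with_seed(deriveSeed(config@seed, "plasmid"), {
    ab <- rlnorm(nrow(constructs), 0, 0.3)
    df <- data.frame(construct_id = constructs$construct_id,
                     abundance = ab, stringsAsFactors = FALSE)
    if (length(cf) && sum(cf) > 0) {
      stopifnot(sum(cf) < 1)
      ctl <- data.frame(construct_id = controlId(names(cf)),
                        abundance = cf / (1 - sum(cf)) * sum(ab),
                        stringsAsFactors = FALSE)
      df <- rbind(df, ctl)
    }
    df
  })

  cost <- setNames(truth$fitness_cost, truth$construct_id)
  strength <- setNames(truth$strength, truth$construct_id)
  all_ids <- plasmid$construct_id
  cost_all <- ifelse(is.na(cost[all_ids]), 0, cost[all_ids])
  strength_all <- setNames(ifelse(is.na(strength[all_ids]), 0,
                                  strength[all_ids]), all_ids)

  # control barcodes (one per control, reused at every position)
  ctl_types <- intersect(CONTROL_TYPES, names(cf)[cf > 0])
  bmap <- withr::with_seed(deriveSeed(config@seed, "ctlbc"), {
    taken <- parts$barcode
    cb <- character(0)
    while (length(cb) < length(ctl_types)) {
      cand <- setdiff(uniqueRandomDna(length(ctl_types) + 4L,
                                      config@barcode_length), taken)
      cb <- unique(c(cb, cand))
    }
    barcodeMap(parts,
               if (length(ctl_types))
                 data.frame(control_type = ctl_types,
                            barcode = cb[seq_along(ctl_types)])
               else NULL)
  })

  tabs <- list()
  mfis <- list()
  for (target in config@targets) {
    for (rep_i in seq_len(config@n_replicates)) {
      tag <- paste0(target, ".", rep_i)
      pool <- simulateCellPool(
        plasmid, plasmid$abundance, config,
        fitness_cost = cost_all,
        seed = deriveSeed(config@seed, paste0("pool.", tag)))
      sorted <- simulateSort(
        pool, strength_all, config,
        seed = deriveSeed(config@seed, paste0("sort.", tag)))
      conds <- split(
        data.frame(construct_id = sorted$bins$construct_id,
                   umi = sorted$bins$umi,
                   weight = sorted$bins$cell_count,
                   stringsAsFactors = FALSE),
        sorted$bins$bin)
      conds$unsorted <- data.frame(construct_id = pool$construct_id,
                                   umi = pool$umi,
                                   weight = pool$cell_count,
                                   stringsAsFactors = FALSE)
      conds$plasmid <- plasmidWeights(
        plasmid, umis_per_construct = 4L, config@umi_length,
        seed = deriveSeed(config@seed, paste0("pumis.", rep_i)))
      tabs[[tag]] <- simulateSequencing(
        conds, config, replicate = rep_i, target = target,
        seed = deriveSeed(config@seed, paste0("seq.", tag)))
      mfis[[tag]] <- data.frame(target = target, replicate = rep_i,
                                bin = paste0("bin", 1:4),
                                mfi = unname(sorted$mfi),
                                stringsAsFactors = FALSE)
    }
  }

  counts <- umiCountTable(as.data.frame(rbindlist(tabs)))
  new("ScreenSim", parts = parts, constructs = constructs,
      latent = c(latent, list(construct_truth = truth)),
      plasmid = plasmid, counts = counts,
      mfi = as.data.frame(rbindlist(mfis)), barcode_map = bmap,
      config = config)
}
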