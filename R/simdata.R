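# Synthetic split-luciferase plate screens. The generator reproduces the
# statistical structure the downstream analysis assumes: log-normal protein
# abundances, a latent luminescence signal composed of a true-interaction
# term plus an abundance- and colocalization-dependent fragment
# self-association background, multiplicative plate/day effects (linear in
# log2 space), a luminometer detection floor, and replicate noise.
#
# Latent signal of a bait-prey strain:
#   S = k_int * strength * min(A_bait, A_prey)            (complex formation,
#                                              bounded by the scarcer partner)
#     + k_self * coloc(bait, prey) * A_bait * A_prey      (mass-action
#                                              self-association background)
# coloc = 1 for proteins annotated to the same compartment, a configurable
# value in [0, 1] otherwise. Full-length reporter (NanoLuc) strains read out
# abundance alone: S = k_int * A.

#' Construct a protein universe
#'
#' @param protein_id character vector of unique ids.
#' @param abundance positive numeric vector (arbitrary copy-number units).
#' @param compartment character vector of compartment labels.
#' @return data.frame with columns \code{protein_id}, \code{abundance},
#'   \code{compartment}.
#' @export
#' @examples
#' proteinUniverse(c("A", "B"), c(1000, 50), c("cytoplasm", "nucleus"))
proteinUniverse <- function(protein_id, abundance, compartment) {
  protein_id <- as.character(protein_id)
  if (anyDuplicated(protein_id))
    .stopf("duplicate protein_id: %s",
           protein_id[which(duplicated(protein_id))[1]])
  if (any(!is.finite(abundance) | abundance <= 0))
    .stopf("abundances must be positive and finite")
  if (length(compartment) == 1L)
    compartment <- rep(compartment, length(protein_id))
  if (length(abundance) != length(protein_id) ||
      length(compartment) != length(protein_id))
    .stopf("protein_id, abundance and compartment must have equal length")
  data.frame(protein_id = protein_id, abundance = as.numeric(abundance),
             compartment = as.character(compartment),
             stringsAsFactors = FALSE)
}

#' Sample a random protein universe
#'
#' Abundances are drawn log-normal (yeast-like: median ~1000 copies, spread
#' covering several orders of magnitude); compartments from a categorical
#' distribution.
#'
#' @param n number of proteins.
#' @param meanlog,sdlog log-normal abundance parameters (natural log).
#' @param compartments named numeric vector of compartment probabilities.
#' @param seed integer seed.
#' @param prefix id prefix; ids are \code{prefix} plus a zero-padded index.
#' @return data.frame as in \code{\link{proteinUniverse}}.
#' @export
sampleProteins <- function(n, meanlog = log(1000), sdlog = 2,
                           compartments = c(cytoplasm = 0.6, nucleus = 0.3,
                                            nuclear_pore = 0.1),
                           seed = 1L, prefix = "P") {
  set.seed(seed)
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  proteinUniverse(ids,
                  stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog),
                  sample(names(compartments), n, replace = TRUE,
                         prob = compartments))
}

#' Construct a true interaction network
#'
#' Edges are unordered protein pairs with nonnegative interaction strengths;
#' homodimers (a pair of a protein with itself) are allowed, duplicate edges
#' are not.
#'
#' @param protein_a,protein_b character vectors of protein ids.
#' @param strength nonnegative numeric vector (recycled if scalar).
#' @return data.frame with columns \code{protein_a}, \code{protein_b},
#'   \code{strength}, \code{pair_id}.
#' @export
ppiNetwork <- function(protein_a = character(), protein_b = character(),
                       strength = numeric()) {
  if (length(strength) == 1L) strength <- rep(strength, length(protein_a))
  if (length(protein_a) != length(protein_b) ||
      length(protein_a) != length(strength))
    .stopf("protein_a, protein_b and strength must have equal length")
  if (any(strength < 0)) .stopf("interaction strengths must be >= 0")
  key <- pairKey(protein_a, protein_b)
  if (anyDuplicated(key))
    .stopf("duplicate network edge: %s", key[which(duplicated(key))[1]])
  data.frame(protein_a = as.character(protein_a),
             protein_b = as.character(protein_b),
             strength = as.numeric(strength), pair_id = key,
             stringsAsFactors = FALSE)
}

#' Small deterministic example universe and network
#'
#' Convenience fixtures for examples: \code{exampleUniverse(n)} is a fixed
#' log-spaced universe, \code{exampleNetwork()} three true interactions
#' within it.
#' @param n number of proteins (>= 4).
#' @return see \code{\link{proteinUniverse}} / \code{\link{ppiNetwork}}.
#' @export
exampleUniverse <- function(n = 12) {
  proteinUniverse(sprintf("P%02d", seq_len(n)),
                  10^seq(1.5, 4.5, length.out = n),
                  rep(c("cytoplasm", "nucleus"), length.out = n))
}

#' @rdname exampleUniverse
#' @export
exampleNetwork <- function() {
  ppiNetwork(c("P01", "P01", "P03"), c("P02", "P05", "P04"), c(2, 1, 3))
}

#' Construct a screen design
#'
#' See \code{\linkS4class{ScreenDesign}} for the meaning of each parameter.
#' Defaults describe a realistic arrayed yeast screen: 384-well plates with
#' 16 medium-only blanks, three replicate plate reads, a self-association
#' coefficient calibrated so that roughly one in seven random pairs of a
#' log-normal abundance universe rises above the detection limit, and
#' replicate noise small enough for inter-replicate correlations above 0.9.
#'
#' @param baits,preys character vectors of protein ids.
#' @param replicates integer >= 1.
#' @param plateFormat 96 or 384.
#' @param blanksPerPlate number of wells per plate reserved for blanks.
#' @param plateEffects data.frame(plate_id, replicate_id, slope, offset);
#'   log2-space linear distortion per plate read. Missing reads get (1, 0).
#' @param detectionLimit luminometer floor, in signal units above background.
#' @param noiseSd replicate noise SD, log2 units.
#' @param kInteraction,kSelf,colocalizationOther latent-model coefficients.
#' @param assay \code{"NanoBiT"} or \code{"NanoLuc"}.
#' @param densityChannel \code{"fluorescence"} or \code{"od600"}.
#' @param densityLevel cell-density signal above background.
#' @param backgroundLevel,backgroundSd instrument background counts and the
#'   SD of blank-well readings around them.
#' @param seed integer RNG seed (single stream for all draws).
#' @return a validated \code{ScreenDesign}.
#' @export
screenDesign <- function(baits, preys, replicates = 3L, plateFormat = 384,
                         blanksPerPlate = 16L, plateEffects = NULL,
                         detectionLimit = 2, noiseSd = 0.25,
                         kInteraction = 1, kSelf = 1e-7,
                         colocalizationOther = 0.1,
                         assay = c("NanoBiT", "NanoLuc"),
                         densityChannel = c("fluorescence", "od600"),
                         densityLevel = 500, backgroundLevel = 100,
                         backgroundSd = 0.5, seed = 1L) {
  if (is.null(plateEffects))
    plateEffects <- data.frame(plate_id = character(),
                               replicate_id = character(),
                               slope = numeric(), offset = numeric(),
                               stringsAsFactors = FALSE)
  new("ScreenDesign",
      baits = as.character(baits), preys = as.character(preys),
      replicates = as.integer(replicates),
      plateFormat = as.integer(plateFormat),
      blanksPerPlate = as.integer(blanksPerPlate),
      plateEffects = plateEffects,
      detectionLimit = as.numeric(detectionLimit),
      noiseSd = as.numeric(noiseSd),
      kInteraction = as.numeric(kInteraction),
      kSelf = as.numeric(kSelf),
      colocalizationOther = as.numeric(colocalizationOther),
      assay = match.arg(assay),
      densityChannel = match.arg(densityChannel),
      densityLevel = as.numeric(densityLevel),
      backgroundLevel = as.numeric(backgroundLevel),
      backgroundSd = as.numeric(backgroundSd),
      seed = as.integer(seed))
}

# Latent linear-scale signal for every strain of the design.
.latentSignal <- function(proteins, network, design) {
  if (design@assay == "NanoLuc") {
    ids <- unique(design@baits)
    a <- proteins$abundance[match(ids, proteins$protein_id)]
    strains <- data.frame(strain_id = paste0(ids, ".luc"),
                          bait = ids, prey = ids,
                          tag_config = "NanoLuc",
                          ploidy = "haploid", stringsAsFactors = FALSE)
    return(list(strains = strains, latent = design@kInteraction * a))
  }
  grid <- expand.grid(prey = design@preys, bait = design@baits,
                      stringsAsFactors = FALSE)[, c("bait", "prey")]
  ib <- match(grid$bait, proteins$protein_id)
  ip <- match(grid$prey, proteins$protein_id)
  ab <- proteins$abundance[ib]
  ap <- proteins$abundance[ip]
  coloc <- ifelse(proteins$compartment[ib] == proteins$compartment[ip],
                  1, design@colocalizationOther)
  strength <- network$strength[match(pairKey(grid$bait, grid$prey),
                                     network$pair_id)]
  strength[is.na(strength)] <- 0
  latent <- design@kInteraction * strength * pmin(ab, ap) +
    design@kSelf * coloc * ab * ap
  strains <- data.frame(strain_id = paste(grid$bait, grid$prey, sep = "."),
                        bait = grid$bait, prey = grid$prey,
                        tag_config = "NanoBiT",
                        ploidy = ifelse(grid$bait == grid$prey,
                                        "diploid", "haploid"),
                        stringsAsFactors = FALSE)
  list(strains = strains, latent = latent)
}

#' Simulate a plate screen
#'
#' Generates raw plate readings for every bait-prey strain of the design
#' (plus medium-only blanks) across replicate plate reads. Per strain the
#' latent signal follows the interaction-plus-self-association model (see
#' file header); the observed luminescence applies, in order, the plate
#' read's log2-linear effect, log-normal replicate noise, left-censoring at a
#' jittered detection floor, and the additive instrument background. A
#' matched cell-density channel is emitted per well; blanks read instrument
#' background only. All draws come from one RNG stream seeded from the
#' design.
#'
#' @param proteins a protein universe (\code{\link{proteinUniverse}}).
#' @param network a true interaction network (\code{\link{ppiNetwork}});
#'   ignored for NanoLuc designs.
#' @param design a \code{\link{screenDesign}}.
#' @return a \code{\linkS4class{ScreenSimulation}}.
#' @export
#' @examples
#' sim <- simulateScreen(exampleUniverse(), exampleNetwork(),
#'                       screenDesign(baits = "P01",
#'                                    preys = sprintf("P%02d", 2:12),
#'                                    replicates = 2, seed = 7))
#' sim
simulateScreen <- function(proteins, network, design) {
  validObject(design)
  unknown <- setdiff(c(design@baits, design@preys), proteins$protein_id)
  if (length(unknown))
    .stopf("unknown protein id in design: %s", unknown[1])
  set.seed(design@seed)

  ls <- .latentSignal(proteins, network, design)
  strains <- ls$strains
  latent <- ls$latent
  nStrain <- nrow(strains)

  capacity <- design@plateFormat - design@blanksPerPlate
  if (capacity < 1L) .stopf("blanksPerPlate leaves no measurement wells")
  nPlates <- ceiling(nStrain / capacity)
  wells <- .wellIds(design@plateFormat)
  plateOf <- sprintf("plate%02d", (seq_len(nStrain) - 1L) %/% capacity + 1L)
  wellOf <- wells[(seq_len(nStrain) - 1L) %% capacity + 1L]
  blankWells <- wells[seq(design@plateFormat - design@blanksPerPlate + 1L,
                          design@plateFormat)]

  eff <- design@plateEffects
  effKey <- paste(eff$plate_id, eff$replicate_id, sep = "\r")

  out <- vector("list", design@replicates * 3L)
  k <- 0L
  for (r in seq_len(design@replicates)) {
    rid <- sprintf("rep%d", r)
    idx <- match(paste(plateOf, rid, sep = "\r"), effKey)
    slope <- ifelse(is.na(idx), 1, eff$slope[idx])
    offset <- ifelse(is.na(idx), 0, eff$offset[idx])
    eps <- stats::rnorm(nStrain, 0, design@noiseSd)
    y <- slope * log2(latent) + offset + eps          # -Inf for latent 0
    floorJitter <- if (design@noiseSd > 0)
      stats::rnorm(nStrain, 0, design@noiseSd / 4) else 0
    floorLog2 <- log2(design@detectionLimit) + floorJitter
    lum <- design@backgroundLevel + 2^pmax(y, floorLog2)
    densNoise <- if (design@noiseSd > 0)
      stats::rnorm(nStrain, 0, design@noiseSd / 2) else 0
    dens <- design@backgroundLevel + design@densityLevel * 2^densNoise

    k <- k + 1L
    out[[k]] <- data.frame(plate_id = plateOf, replicate_id = rid,
                           well = wellOf, strain_id = strains$strain_id,
                           channel = "luminescence", value = lum,
                           stringsAsFactors = FALSE)
    k <- k + 1L
    out[[k]] <- data.frame(plate_id = plateOf, replicate_id = rid,
                           well = wellOf, strain_id = strains$strain_id,
                           channel = design@densityChannel, value = dens,
                           stringsAsFactors = FALSE)
    # blanks: every plate carries its reserved medium-only wells
    nb <- nPlates * design@blanksPerPlate
    bl <- expand.grid(well = blankWells,
                      plate_id = sprintf("plate%02d", seq_len(nPlates)),
                      stringsAsFactors = FALSE)
    blLum <- pmax(design@backgroundLevel +
                    stats::rnorm(nb, 0, design@backgroundSd), 0)
    blDens <- pmax(design@backgroundLevel +
                     stats::rnorm(nb, 0, design@backgroundSd), 0)
    k <- k + 1L
    out[[k]] <- data.frame(plate_id = rep(bl$plate_id, 2L),
                           replicate_id = rid,
                           well = rep(bl$well, 2L),
                           strain_id = BLANK_SENTINEL,
                           channel = rep(c("luminescence",
                                           design@densityChannel),
                                         each = nb),
                           value = c(blLum, blDens),
                           stringsAsFactors = FALSE)
  }
  measurements <- do.call(rbind, out[seq_len(k)])
  rownames(measurements) <- NULL
  latentLog2 <- log2(latent)
  names(latentLog2) <- strains$strain_id
  new("ScreenSimulation", measurements = measurements, strainMap = strains,
      latentLog2 = latentLog2, design = design)
}

#' Ground-truth labels for a screened design
#'
#' Screened pairs present in the network with strength > 0 are labeled
#' \code{"positive"}; every other screened pair \code{"negative"}.
#'
#' @param network a \code{\link{ppiNetwork}} (possibly empty).
#' @param design a \code{\link{screenDesign}} (NanoBiT).
#' @return data.frame with columns \code{bait}, \code{prey}, \code{pair_id},
#'   \code{label}.
#' @export
groundTruthLabels <- function(network, design) {
  grid <- expand.grid(prey = design@preys, bait = design@baits,
                      stringsAsFactors = FALSE)[, c("bait", "prey")]
  key <- pairKey(grid$bait, grid$prey)
  strength <- network$strength[match(key, network$pair_id)]
  strength[is.na(strength)] <- 0
  data.frame(bait = grid$bait, prey = grid$prey, pair_id = key,
             label = ifelse(strength > 0, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Write a simulated screen to disk
#'
#' Emits the long-format measurement CSV, the strain map CSV, ground-truth
#' labels as a two-column TSV (\code{pair_id}, \code{label}) and the
#' simulation parameters as a JSON sidecar.
#'
#' @param sim a \code{ScreenSimulation}.
#' @param network the generating network (for labels).
#' @param dir output directory (created if needed).
#' @return named character vector of the paths written.
#' @export
writeScreenSimulation <- function(sim, network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(measurements = file.path(dir, "measurements.csv"),
             strain_map = file.path(dir, "strain_map.csv"),
             labels = file.path(dir, "labels.tsv"),
             params = file.path(dir, "simulation_params.json"))
  writeMeasurements(sim@measurements, paths[["measurements"]])
  writeStrainMap(sim@strainMap, paths[["strain_map"]])
  lab <- groundTruthLabels(network, sim@design)
  writeTable(lab[, c("pair_id", "label")], paths[["labels"]])
  d <- sim@design
  params <- list(assay = d@assay, baits = d@baits, preys = d@preys,
                 replicates = d@replicates, plate_format = d@plateFormat,
                 blanks_per_plate = d@blanksPerPlate,
                 detection_limit = d@detectionLimit, noise_sd = d@noiseSd,
                 k_interaction = d@kInteraction, k_self = d@kSelf,
                 colocalization_other = d@colocalizationOther,
                 density_channel = d@densityChannel,
                 density_level = d@densityLevel,
                 background_level = d@backgroundLevel,
                 background_sd = d@backgroundSd, seed = d@seed,
                 plate_effects = d@plateEffects)
  jsonlite::write_json(params, paths[["params"]], auto_unbox = TRUE,
                       digits = NA)
  paths
}
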