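#' Build a simulation configuration
#'
#' Convenience constructor (with validity checking) for
#' \linkS4class{SimulationConfig}.  The generated compendium mimics an
#' RMA-normalized microarray meta-analysis: most genes fluctuate around a
#' baseline intensity, planted BGC-like groups switch to a higher signal
#' intensity in their active conditions, regulator genes track the mean
#' profile of their target groups, and sparse confounders spike only in a
#' hosting group's few aberrant conditions (the spurious-correlation hazard
#' that the mutual-rank transform is designed to defuse).
#'
#' @param nGenes,nSamples compendium dimensions.
#' @param groups list of planted groups, each a list with \code{size},
#'   \code{activeSamples} (count or explicit sample indices),
#'   \code{signalMean}, \code{signalSd}.  [plantedGroup()] builds one entry.
#' @param globalRegulators list of integer vectors of target group indices,
#'   one per unclustered regulator gene.
#' @param residentRegulators list of \code{list(home =, targets =)} entries,
#'   one per cluster-resident regulator gene.
#' @param nConfounders number of sparse-expression confounder genes.
#' @param confounderSpikes number of shared in-window spike conditions per
#'   hosting group (capped at the group's window size).
#' @param confounderPrivateSpikes number of additional aberrant conditions
#'   per hosting group, drawn outside every group's active window, in which
#'   the group's confounders also spike.
#' @param confounderGroups integer vector of group indices eligible to host
#'   confounders; defaults to all planted groups.
#' @param baselineMean,baselineSd baseline intensity distribution (log-like
#'   scale).
#' @param seed integer seed.
#' @return A validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(50, 20,
#'   groups = list(plantedGroup(5, 10)), seed = 1)
#' @export
simulationConfig <- function(nGenes, nSamples, groups = list(),
                             globalRegulators = list(),
                             residentRegulators = list(),
                             nConfounders = 0L, confounderSpikes = 2L,
                             confounderPrivateSpikes = 2L,
                             confounderGroups = seq_along(groups),
                             baselineMean = 4, baselineSd = 0.5,
                             seed = 1L) {
  methods::new("SimulationConfig",
    nGenes = as.integer(nGenes), nSamples = as.integer(nSamples),
    groups = groups, globalRegulators = globalRegulators,
    residentRegulators = residentRegulators,
    nConfounders = as.integer(nConfounders),
    confounderSpikes = as.integer(confounderSpikes),
    confounderPrivateSpikes = as.integer(confounderPrivateSpikes),
    confounderGroups = as.integer(confounderGroups),
    baselineMean = baselineMean, baselineSd = baselineSd,
    seed = as.integer(seed))
}

#' @rdname simulationConfig
#' @param size group size (genes).
#' @param activeSamples active-condition count or explicit sample indices.
#' @param signalMean,signalSd signal intensity distribution while active.
#' @export
plantedGroup <- function(size, activeSamples, signalMean = 10,
                         signalSd = 0.5) {
  list(size = as.integer(size), activeSamples = activeSamples,
       signalMean = signalMean, signalSd = signalSd)
}

## Ideal (noise-free) per-sample profile of a planted group.
.groupIdealProfile <- function(cfg, active, g) {
  prof <- rep(cfg@baselineMean, cfg@nSamples)
  prof[active] <- g$signalMean
  prof
}

#' Simulate a synthetic expression compendium with planted structure
#'
#' Generates a genes x samples intensity matrix plus the ground truth of the
#' planted structure.  Intensities are independent Gaussians per (gene,
#' sample), clipped at zero; a regulator gene's profile is the mean of its
#' target groups' ideal profiles plus Gaussian noise; confounders sit at
#' baseline except for their hosting group's aberrant conditions - a few
#' drawn once inside the group's active window, a few outside every window -
#' where they spike to the signal level.  Identical configurations,
#' including the seed, yield bit-identical output.
#'
#' Gene ids are laid out contiguously: planted groups first (BGC-like
#' genomic contiguity), then resident regulators, global regulators,
#' confounders, and baseline genes.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A list with elements \code{exprs} (a
#'   \code{SummarizedExperiment} with assay \code{"exprs"}) and \code{truth}
#'   (a \linkS4class{PlantedTruth}).
#' @examples
#' sim <- simulateCompendium(simulationConfig(40, 12,
#'   groups = list(plantedGroup(5, 6)), seed = 7))
#' dim(SummarizedExperiment::assay(sim$exprs))
#' @export
simulateCompendium <- function(config) {
  methods::validObject(config)
  cfg <- config
  nG <- cfg@nGenes
  nS <- cfg@nSamples
  geneIds <- sprintf("gene_%04d", seq_len(nG))
  sampleIds <- sprintf("cond_%03d", seq_len(nS))
  ngrp <- length(cfg@groups)
  groupIds <- if (ngrp) sprintf("grp%02d", seq_len(ngrp)) else character()

  ## gene index layout: groups | resident regulators | global regulators |
  ## confounders | baseline
  sizes <- vapply(cfg@groups, .groupSize, integer(1))
  groupIdx <- vector("list", ngrp)
  at <- 0L
  for (i in seq_len(ngrp)) {
    groupIdx[[i]] <- at + seq_len(sizes[i])
    at <- at + sizes[i]
  }
  nRes <- length(cfg@residentRegulators)
  nGlob <- length(cfg@globalRegulators)
  resIdx <- at + seq_len(nRes); at <- at + nRes
  globIdx <- at + seq_len(nGlob); at <- at + nGlob
  confIdx <- at + seq_len(cfg@nConfounders)

  .withSeed(cfg@seed, {
    m <- matrix(rnorm(nG * nS, cfg@baselineMean, cfg@baselineSd), nrow = nG,
                dimnames = list(geneIds, sampleIds))

    ## active windows (explicit indices respected, counts drawn at random)
    active <- vector("list", ngrp)
    for (i in seq_len(ngrp)) {
      a <- cfg@groups[[i]]$activeSamples
      active[[i]] <- if (length(a) > 1L) as.integer(sort(a))
                     else sort(sample.int(nS, as.integer(a)))
    }

    for (i in seq_len(ngrp)) {
      g <- cfg@groups[[i]]
      k <- length(active[[i]])
      if (k)
        m[groupIdx[[i]], active[[i]]] <-
          rnorm(sizes[i] * k, g$signalMean, g$signalSd)
    }

    regulatorRow <- function(targets) {
      profs <- vapply(targets, function(j)
        .groupIdealProfile(cfg, active[[j]], cfg@groups[[j]]),
        numeric(nS))
      sdNoise <- mean(vapply(targets, function(j) cfg@groups[[j]]$signalSd,
                             numeric(1)))
      rowMeans(profs) + rnorm(nS, 0, sdNoise)
    }
    for (r in seq_len(nRes))
      m[resIdx[r], ] <- regulatorRow(cfg@residentRegulators[[r]]$targets)
    for (r in seq_len(nGlob))
      m[globIdx[r], ] <- regulatorRow(cfg@globalRegulators[[r]])

    ## Each eligible group draws a fixed set of aberrant conditions: some
    ## inside its active window (where its confounders spuriously correlate
    ## with the group members) and some outside every window (where only the
    ## confounders fire, making fellow confounders each other's strongest
    ## partners).  Confounders assigned to the group spike in exactly these
    ## conditions.
    eligible <- cfg@confounderGroups
    outside <- setdiff(seq_len(nS),
                       unique(unlist(active, use.names = FALSE)))
    spikePool <- vector("list", ngrp)
    for (j in eligible) {
      win <- active[[j]]
      nspike <- min(cfg@confounderSpikes, length(win))
      inWin <- if (length(win) == 1L) win else sort(sample(win, nspike))
      nPriv <- min(cfg@confounderPrivateSpikes, length(outside))
      priv <- if (nPriv) sort(sample(outside, nPriv)) else integer()
      spikePool[[j]] <- sort(c(inWin, priv))
    }
    ## round-robin assignment keeps the sparse-gene crowds balanced across
    ## hosting groups
    for (k in seq_along(confIdx)) {
      j <- eligible[((k - 1L) %% length(eligible)) + 1L]
      at2 <- spikePool[[j]]
      m[confIdx[k], at2] <- rnorm(length(at2), cfg@groups[[j]]$signalMean,
                                  cfg@groups[[j]]$signalSd)
    }

    m <- pmax(m, 0)

    truth <- methods::new("PlantedTruth",
      groupMembers = stats::setNames(
        lapply(groupIdx, function(ix) geneIds[ix]), groupIds),
      groupActiveSamples = stats::setNames(
        lapply(active, function(ix) sampleIds[ix]), groupIds),
      regulatorTargets = stats::setNames(
        c(lapply(cfg@residentRegulators, function(rr) groupIds[rr$targets]),
          lapply(cfg@globalRegulators, function(tg) groupIds[tg])),
        geneIds[c(resIdx, globIdx)]),
      confounders = geneIds[confIdx])
    methods::validObject(truth)

    list(exprs = .asSE(m), truth = truth)
  })
}
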