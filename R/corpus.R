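#' Construct a corpus simulator configuration
#'
#' Defaults encode the repository-scale conventions observed on public
#' proteomics data: 70% of projects keep a single gradient and only ~5% use
#' more than two; gradient lengths cluster at 60, 90 and 120 minutes with a
#' long tail (up to 800 minutes); 47% / 43% / 10% of projects use one / two /
#' more than two unique m/z acquisition windows; and the modal (350, 1500)
#' window covers 33.9% of files. The retention model is additive in
#' per-residue coefficients (Kyte-Doolittle hydropathy by default) mapped
#' linearly onto the usable gradient, with separable project-, file- and
#' peptide-level noise. Project and file effects comprise an additive RT
#' shift and a selectivity perturbation of the coefficient vector (see
#' [CorpusConfig-class]); only the latter survives per-file effective-gradient
#' normalization, which cancels additive constants exactly.
#'
#' @param nProjects,filesPerProject,peptidesPerFile corpus dimensions;
#'   ranges are inclusive `c(lo, hi)`.
#' @param seed integer; the corpus is a deterministic function of it.
#' @param pSingleGradient,pManyGradients,gradientModes,gradientTailMin,gradientTailMax
#'   gradient-length model; see [CorpusConfig-class].
#' @param modalFilter,pModalFilter,filterCountProbs m/z window model.
#' @param retentionScale named per-residue retention coefficients.
#' @param sigmaProject,sigmaFile,sigmaPeptide RT noise sd, minutes.
#' @param noiseGradientCoupling,selectivityCoupling,edgeNoiseBoost,deadTimeFrac
#'   see [CorpusConfig-class].
#' @param lengthMean,lengthSd peptide length distribution (truncated 7..30).
#' @param scoreBase,scoreLengthSlope,scoreSd identification score model.
#' @param chargeProbs probabilities of charge 2 and 3.
#' @param spectraPerFile,noisePeakRate,energyRange MS2 simulator settings.
#' @param species project species labels, sampled uniformly.
#' @return a validated [CorpusConfig-class] object.
#' @examples
#' cfg <- corpusConfig(nProjects = 5, seed = 1)
#' cfg
#' @export
corpusConfig <- function(nProjects = 20L,
                         filesPerProject = c(3L, 8L),
                         peptidesPerFile = c(200L, 600L),
                         seed = 1L,
                         pSingleGradient = 0.70,
                         pManyGradients = 0.05,
                         gradientModes = data.frame(
                           minutes = c(60, 90, 120),
                           weight = c(0.25, 0.15, 0.15)),
                         gradientTailMin = 10,
                         gradientTailMax = 800,
                         modalFilter = c(350, 1500),
                         pModalFilter = 0.339,
                         filterCountProbs = c(0.47, 0.43, 0.10),
                         retentionScale = KYTE_DOOLITTLE,
                         sigmaProject = 3,
                         sigmaFile = 1,
                         sigmaPeptide = 0.75,
                         noiseGradientCoupling = 0.5,
                         selectivityCoupling = 0.15,
                         edgeNoiseBoost = 0,
                         deadTimeFrac = 0.05,
                         lengthMean = 14,
                         lengthSd = 4,
                         scoreBase = 70,
                         scoreLengthSlope = 6,
                         scoreSd = 15,
                         chargeProbs = c(0.7, 0.3),
                         spectraPerFile = 5L,
                         noisePeakRate = 10,
                         energyRange = c(0.5, 2.5),
                         species = c("Homo sapiens", "Mus musculus",
                                     "Saccharomyces cerevisiae",
                                     "Escherichia coli")) {
  if (length(filesPerProject) == 1) filesPerProject <- rep(filesPerProject, 2)
  if (length(peptidesPerFile) == 1) peptidesPerFile <- rep(peptidesPerFile, 2)
  new("CorpusConfig",
      nProjects = as.integer(nProjects),
      filesPerProject = as.integer(filesPerProject),
      peptidesPerFile = as.integer(peptidesPerFile),
      seed = as.integer(seed),
      pSingleGradient = pSingleGradient, pManyGradients = pManyGradients,
      gradientModes = gradientModes,
      gradientTailMin = gradientTailMin, gradientTailMax = gradientTailMax,
      modalFilter = as.numeric(modalFilter), pModalFilter = pModalFilter,
      filterCountProbs = filterCountProbs,
      retentionScale = retentionScale,
      sigmaProject = sigmaProject, sigmaFile = sigmaFile,
      sigmaPeptide = sigmaPeptide,
      noiseGradientCoupling = noiseGradientCoupling,
      selectivityCoupling = selectivityCoupling,
      edgeNoiseBoost = edgeNoiseBoost, deadTimeFrac = deadTimeFrac,
      lengthMean = lengthMean, lengthSd = lengthSd,
      scoreBase = scoreBase, scoreLengthSlope = scoreLengthSlope,
      scoreSd = scoreSd, chargeProbs = chargeProbs,
      spectraPerFile = as.integer(spectraPerFile),
      noisePeakRate = noisePeakRate, energyRange = energyRange,
      species = species)
}

# peptide length distribution: rounded Normal(lengthMean, lengthSd)
# truncated to 7..30 residues
.lengthWeights <- function(config) {
  L <- 7:30
  w <- stats::pnorm(L + 0.5, config@lengthMean, config@lengthSd) -
    stats::pnorm(L - 0.5, config@lengthMean, config@lengthSd)
  list(lengths = L, weights = w / sum(w))
}

# population moments of the summed retention coefficients under uniform
# residue usage and the configured length distribution; defines the fixed
# monotone linear map of coefficient sums onto the gradient
.scaleMoments <- function(config) {
  lw <- .lengthWeights(config)
  EL <- sum(lw$lengths * lw$weights)
  VL <- sum(lw$lengths^2 * lw$weights) - EL^2
  coef <- config@retentionScale[RESIDUES]
  mc <- mean(coef)
  vc <- mean((coef - mc)^2)
  mu <- EL * mc
  sigma <- sqrt(EL * vc + VL * mc^2)
  list(mu = mu, sigma = sigma)
}

# relative elution position in [0, 1] from coefficient sums: linear over
# +/- 3 population sd, clamped
.elutionPosition <- function(S, moments) {
  pmin(1, pmax(0, (S - (moments$mu - 3 * moments$sigma)) /
                 (6 * moments$sigma)))
}

.sampleGradients <- function(n, config) {
  modes <- config@gradientModes
  wTail <- 1 - sum(modes$weight)
  comp <- sample.int(nrow(modes) + 1, n, replace = TRUE,
                     prob = c(modes$weight, wTail))
  g <- numeric(n)
  isMode <- comp <= nrow(modes)
  g[isMode] <- modes$minutes[comp[isMode]]
  g[!isMode] <- round(stats::runif(sum(!isMode), config@gradientTailMin,
                                   config@gradientTailMax), 1)
  g
}

# k gradients distinct after rounding to 1 minute (the uniqueness convention)
.distinctGradients <- function(k, config) {
  vals <- numeric(0)
  for (i in 1:200) {
    g <- .sampleGradients(1, config)
    if (!round(g) %in% round(vals)) vals <- c(vals, g)
    if (length(vals) == k) return(vals)
  }
  while (length(vals) < k) vals <- c(vals, max(vals) + 7)
  vals
}

.samplePeptideBatch <- function(n, config) {
  lw <- .lengthWeights(config)
  lens <- sample(lw$lengths, n, replace = TRUE, prob = lw$weights)
  draws <- sample(RESIDUES, sum(lens), replace = TRUE)
  grp <- factor(rep.int(seq_len(n), lens), levels = seq_len(n))
  counts <- unclass(table(grp, factor(draws, levels = RESIDUES)))
  dimnames(counts) <- NULL
  seqs <- vapply(split(draws, grp), paste, character(1), collapse = "")
  names(seqs) <- NULL
  list(sequence = seqs, length = lens, counts = counts)
}

#' Simulate retention times under the additive elution model
#'
#' The coefficient sum of each sequence is mapped linearly onto the usable
#' gradient (between the dead time, a fixed fraction of the gradient, and
#' the gradient end), then shifted by the project and file effects and
#' perturbed by peptide-level Gaussian noise whose sd grows with gradient
#' length (`1 + noiseGradientCoupling * gradient/100`) and, when
#' `edgeNoiseBoost > 0`, towards the gradient extremes. The result is
#' clipped to `[0, gradient_length]`. With all noise components zero the
#' retention time is an exact monotone function of the coefficient sum.
#'
#' @param sequences character vector of peptide sequences (canonical
#'   residues only).
#' @param fileMeta a one-row data.frame (or list) with at least
#'   `gradient_length`.
#' @param projectEffect,fileEffect additive shifts in minutes, drawn once
#'   per project/file by [simulateCorpus()].
#' @param config a [CorpusConfig-class].
#' @param coefficients optional per-residue coefficient vector overriding
#'   `config@retentionScale` (used for project/file selectivity jitter).
#' @return numeric vector of retention times in minutes.
#' @export
simulateRetentionTime <- function(sequences, fileMeta, projectEffect = 0,
                                  fileEffect = 0, config,
                                  coefficients = NULL) {
  bad <- grep(sprintf("^[%s]+$", paste(RESIDUES, collapse = "")),
              sequences, invert = TRUE)
  if (length(bad)) {
    stop("sequences contain non-canonical residues: ",
         paste(utils::head(sequences[bad], 3), collapse = ", "))
  }
  coef <- if (is.null(coefficients)) config@retentionScale else coefficients
  S <- vapply(strsplit(sequences, ""), function(x) sum(coef[x]), numeric(1))
  .rtFromSums(S, fileMeta$gradient_length, projectEffect, fileEffect, config,
              .scaleMoments(config))
}

.rtFromSums <- function(S, gradient, projectEffect, fileEffect, config,
                        moments) {
  u <- .elutionPosition(S, moments)
  dead <- config@deadTimeFrac * gradient
  rtDet <- dead + (gradient - dead) * u
  sdPep <- config@sigmaPeptide *
    (1 + config@noiseGradientCoupling * gradient / 100) *
    (1 + config@edgeNoiseBoost * (2 * abs(u - 0.5))^2)
  rt <- rtDet + projectEffect + fileEffect +
    stats::rnorm(length(S), 0, sdPep)
  pmin(gradient, pmax(0, rt))
}

#' Simulate one MS2 spectrum for a peptide
#'
#' The spectrum contains singly charged b/y backbone ions for every prefix
#' and suffix (masses per the integer-offset convention: +1 for b, +19 for
#' y), low-mass single-residue ions in the 50-250 m/z window whose emission
#' probability increases with the collision-energy proxy, and uniform noise
#' peaks. With zero noise rate and zero energy the spectrum contains exactly
#' the `2 * (L - 1)` backbone ions of a length-`L` peptide.
#'
#' @param record one peptide record (list or one-row data.frame with
#'   `sequence`, `file_id`, `precursor_mz`, `charge`).
#' @param config a [CorpusConfig-class].
#' @param energy collision-energy proxy; drawn from `config@energyRange`
#'   when NULL.
#' @param spectrumId identifier for the spectrum.
#' @return a [SpectrumPeakSet-class].
#' @export
simulateSpectrum <- function(record, config, energy = NULL,
                             spectrumId = "spec_1") {
  seqChars <- strsplit(record$sequence, "")[[1]]
  if (!all(seqChars %in% RESIDUES)) {
    stop("invalid residue in sequence: ", record$sequence)
  }
  if (is.null(energy)) {
    energy <- stats::runif(1, config@energyRange[1], config@energyRange[2])
  }
  L <- length(seqChars)
  masses <- RESIDUE_MASS[seqChars]
  mz <- numeric(0)
  intensity <- numeric(0)
  if (L > 1) {
    bIons <- cumsum(masses)[1:(L - 1)] + ION_OFFSETS[["b"]]
    yIons <- rev(cumsum(rev(masses)))[2:L] + ION_OFFSETS[["y"]]
    mz <- c(bIons, yIons)
    intensity <- stats::runif(2 * (L - 1), 20, 100)
  }
  # single-residue ions, emitted more readily at higher energy
  pIon <- 1 - exp(-0.5 * energy)
  resUnique <- unique(seqChars)
  cand <- as.vector(outer(RESIDUE_MASS[resUnique], ION_OFFSETS, `+`))
  cand <- cand[cand >= 50 & cand <= 250]
  emit <- stats::runif(length(cand)) < pIon
  if (any(emit)) {
    mz <- c(mz, cand[emit])
    intensity <- c(intensity, stats::runif(sum(emit), 30, 150))
  }
  nNoise <- stats::rpois(1, config@noisePeakRate)
  if (nNoise > 0) {
    mz <- c(mz, stats::runif(nNoise, 50, 2000))
    intensity <- c(intensity, stats::rexp(nNoise, 1 / 20) + 0.1)
  }
  ord <- order(mz)
  mz <- mz[ord]
  intensity <- intensity[ord]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, match(mz, unique(mz)), sum))
    mz <- unique(mz)
  }
  names(mz) <- NULL
  names(intensity) <- NULL
  new("SpectrumPeakSet", spectrumId = spectrumId,
      fileId = as.character(record$file_id), mz = mz, intensity = intensity,
      precursorMz = as.numeric(record$precursor_mz),
      charge = as.integer(record$charge), energy = energy)
}

#' Simulate a multi-project LC-MS corpus
#'
#' Generates per-run metadata (gradient lengths with within-project
#' homogeneity, m/z acquisition windows with a modal convention), peptide
#' evidence (additive-coefficient elution with project/file/peptide variance
#' components, length-correlated identification scores, precursors
#' rejection-sampled into the run's acquisition window) and MS2 spectra.
#' The corpus is a deterministic function of `config`, including its seed.
#'
#' @param config a [CorpusConfig-class].
#' @return an [LcmsCorpus-class].
#' @examples
#' corp <- simulateCorpus(corpusConfig(nProjects = 3,
#'   filesPerProject = c(2, 3), peptidesPerFile = c(20, 30), seed = 7))
#' corp
#' @export
simulateCorpus <- function(config) {
  validObject(config)
  withr::with_seed(config@seed, .simulateCorpusImpl(config))
}

.simulateCorpusImpl <- function(config) {
  nP <- config@nProjects
  moments <- .scaleMoments(config)
  baseCoef <- config@retentionScale[RESIDUES]

  # calibration of the modal-window probability of a project's primary
  # filter so the marginal FILE fraction matches pModalFilter, given that
  # each non-primary window is carried by one file and the rest use the
  # primary
  nbar <- mean(config@filesPerProject)
  eShare <- sum(config@filterCountProbs *
                pmax(0.2, (nbar - c(0, 1, 2)) / nbar))
  piModal <- min(1, config@pModalFilter / eShare)

  fileRows <- list()
  pepRows <- list()
  spectra <- list()
  specCount <- 0

  for (p in seq_len(nP)) {
    projectId <- sprintf("P%04d", p)
    nFiles <- if (config@filesPerProject[1] == config@filesPerProject[2]) {
      config@filesPerProject[1]
    } else {
      sample(config@filesPerProject[1]:config@filesPerProject[2], 1)
    }
    speciesP <- sample(config@species, 1)

    # gradient set: 1, 2 or >2 unique gradients, capped by the file count
    uG <- stats::runif(1)
    kG <- if (uG < config@pSingleGradient) 1L
          else if (uG < config@pSingleGradient + config@pManyGradients) {
            sample(3:5, 1, prob = c(0.6, 0.3, 0.1))
          } else 2L
    kG <- min(kG, nFiles)
    grads <- .distinctGradients(kG, config)
    gradAssign <- c(grads, rep(grads[1], nFiles - kG))
    gradAssign <- gradAssign[sample.int(nFiles)]

    # m/z window set
    kF <- min(sample.int(3, 1, prob = config@filterCountProbs), nFiles)
    pool <- ALT_FILTER_POOL[sample.int(length(ALT_FILTER_POOL))]
    if (config@pModalFilter >= 1 - 1e-12) {
      # degenerate configuration: every run records the modal window
      kF <- 1L
      primary <- config@modalFilter
    } else {
      primary <- if (stats::runif(1) < piModal) config@modalFilter else pool[[1]]
    }
    alts <- Filter(function(f) !identical(f, primary), pool)
    filters <- c(list(primary), alts[seq_len(kF - 1)])
    filtAssign <- c(seq_len(kF), rep(1L, nFiles - kF))
    filtAssign <- filtAssign[sample.int(nFiles)]

    projEffect <- stats::rnorm(1, 0, config@sigmaProject)
    projJitter <- stats::rnorm(length(RESIDUES), 0,
                               config@selectivityCoupling * config@sigmaProject)

    for (f in seq_len(nFiles)) {
      fileId <- sprintf("%s_F%03d", projectId, f)
      filt <- filters[[filtAssign[f]]]
      gradient <- gradAssign[f]
      fileEffect <- stats::rnorm(1, 0, config@sigmaFile)
      fileJitter <- stats::rnorm(length(RESIDUES), 0,
                                 config@selectivityCoupling * config@sigmaFile)
      coefVec <- baseCoef + projJitter + fileJitter
      names(coefVec) <- RESIDUES

      nPep <- if (config@peptidesPerFile[1] == config@peptidesPerFile[2]) {
        config@peptidesPerFile[1]
      } else {
        sample(config@peptidesPerFile[1]:config@peptidesPerFile[2], 1)
      }

      # rejection sampling: precursors outside the acquisition window are
      # regenerated, mirroring that the instrument never records them
      batch <- .samplePeptideBatch(nPep, config)
      mass <- drop(batch$counts %*% RESIDUE_MASS[RESIDUES]) + WATER_MASS
      charge <- sample(c(2L, 3L), nPep, replace = TRUE,
                       prob = config@chargeProbs)
      mz <- (mass + charge * PROTON_MASS) / charge
      for (round in 1:200) {
        bad <- which(mz < filt[1] | mz > filt[2])
        if (!length(bad)) break
        if (round == 200) {
          stop("acquisition window (", filt[1], ", ", filt[2],
               ") rejects all candidate peptides")
        }
        redo <- .samplePeptideBatch(length(bad), config)
        batch$sequence[bad] <- redo$sequence
        batch$length[bad] <- redo$length
        batch$counts[bad, ] <- redo$counts
        mass[bad] <- drop(redo$counts %*% RESIDUE_MASS[RESIDUES]) + WATER_MASS
        charge[bad] <- sample(c(2L, 3L), length(bad), replace = TRUE,
                              prob = config@chargeProbs)
        mz[bad] <- (mass[bad] + charge[bad] * PROTON_MASS) / charge[bad]
      }

      S <- drop(batch$counts %*% coefVec)
      rt <- .rtFromSums(S, gradient, projEffect, fileEffect, config, moments)
      score <- pmax(0, config@scoreBase +
                      config@scoreLengthSlope * batch$length +
                      stats::rnorm(nPep, 0, config@scoreSd))

      fileRows[[length(fileRows) + 1]] <- data.frame(
        file_id = fileId, project_id = projectId,
        gradient_length = gradient, mz_lower = filt[1], mz_upper = filt[2],
        species = speciesP, stringsAsFactors = FALSE)
      pepRows[[length(pepRows) + 1]] <- data.frame(
        sequence = batch$sequence, score = score, rt = rt,
        rt_normalized = NA_real_, precursor_mz = mz, charge = charge,
        file_id = fileId, project_id = projectId, stringsAsFactors = FALSE)

      nSpec <- min(config@spectraPerFile, nPep)
      if (nSpec > 0) {
        for (s in seq_len(nSpec)) {
          specCount <- specCount + 1
          spectra[[specCount]] <- simulateSpectrum(
            list(sequence = batch$sequence[s], file_id = fileId,
                 precursor_mz = mz[s], charge = charge[s]),
            config, spectrumId = sprintf("S%06d", specCount))
        }
      }
    }
  }

  files <- do.call(rbind, fileRows)
  peptides <- do.call(rbind, pepRows)
  rownames(files) <- rownames(peptides) <- NULL
  new("LcmsCorpus", files = files, peptides = peptides, spectra = spectra,
      config = config)
}
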