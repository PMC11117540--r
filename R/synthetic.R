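#' @include AllClasses.R
NULL

#' Configuration for the synthetic EEG generator
#'
#' Builds the parameter list consumed by [generateTrial()] and
#' [generateDataset()]. Each synthetic trial is a sum of four band-limited
#' sinusoids (delta 2 Hz, theta 6 Hz, alpha 10 Hz, beta 20 Hz) with
#' per-trial random phases, plus stationary AR(1) background noise, plus
#' optional single-sample artifact spikes. The two classes differ only in
#' their band amplitudes: the alcoholic scatter is more concentrated, so
#' its default amplitudes are half the normal ones (the contrast direction
#' and magnitude are parameters, not facts about real EEG).
#'
#' @param nTrialsPerClass trials generated per class (default 120).
#' @param epochLen samples per trial (default 2048, i.e. 8 s at 256 Hz).
#' @param fs sampling rate in Hz (default 256).
#' @param normalAmplitudes named numeric: sinusoid amplitude in microvolts
#'   per band for the normal class.
#' @param alcoholicAmplitudes same for the alcoholic class; default half
#'   the normal amplitudes.
#' @param arCoeff AR(1) coefficient of the background noise, in [0, 1).
#' @param noiseSd innovation standard deviation of the AR(1) noise
#'   (microvolts).
#' @param spikeRate per-trial probability of one injected artifact spike.
#' @param spikeAmplitude spike amplitude in microvolts (default 200,
#'   well above the 73.3 screening threshold).
#' @param seed integer seed making the whole dataset reproducible.
#' @return A named list of class \code{"synthConfig"}.
#' @examples
#' cfg <- synthConfig(nTrialsPerClass = 4, seed = 1)
#' ds <- generateDataset(cfg)
#' ds
#' @export
synthConfig <- function(nTrialsPerClass = 120L,
                        epochLen = 2048L,
                        fs = 256,
                        normalAmplitudes = c(delta = 15, theta = 8,
                                             alpha = 10, beta = 4),
                        alcoholicAmplitudes = normalAmplitudes / 2,
                        arCoeff = 0.85,
                        noiseSd = 3,
                        spikeRate = 0,
                        spikeAmplitude = 200,
                        seed = 1L) {
  bands <- c("delta", "theta", "alpha", "beta")
  stopifnot(all(bands %in% names(normalAmplitudes)),
            all(bands %in% names(alcoholicAmplitudes)))
  if (any(normalAmplitudes < 0) || any(alcoholicAmplitudes < 0))
    stop("band amplitudes must be non-negative")
  if (arCoeff < 0 || arCoeff >= 1) stop("arCoeff must lie in [0, 1)")
  if (spikeRate < 0 || spikeRate > 1) stop("spikeRate must lie in [0, 1]")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  structure(list(
    nTrialsPerClass = as.integer(nTrialsPerClass),
    epochLen = as.integer(epochLen),
    fs = fs,
    bandFreqs = c(delta = 2, theta = 6, alpha = 10, beta = 20),
    normalAmplitudes = normalAmplitudes[bands],
    alcoholicAmplitudes = alcoholicAmplitudes[bands],
    arCoeff = arCoeff,
    noiseSd = noiseSd,
    spikeRate = spikeRate,
    spikeAmplitude = spikeAmplitude,
    seed = as.integer(seed)
  ), class = "synthConfig")
}

## Run code with a private, restored RNG stream.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(list = ".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## One trial from the current RNG stream; returns its components.
.synthTrialComponents <- function(cfg, label) {
  amps <- if (label == "normal") cfg$normalAmplitudes
          else cfg$alcoholicAmplitudes
  n <- cfg$epochLen
  t <- (seq_len(n) - 1L) / cfg$fs
  phases <- runif(length(amps), 0, 2 * pi)
  sinus <- rep(0, n)
  for (b in seq_along(amps))
    sinus <- sinus + amps[b] * sin(2 * pi * cfg$bandFreqs[b] * t + phases[b])
  noise <- if (cfg$noiseSd > 0) {
    innov <- rnorm(n, sd = cfg$noiseSd)
    as.numeric(stats::filter(innov, cfg$arCoeff, method = "recursive"))
  } else rep(0, n)
  spike <- rep(0, n)
  if (cfg$spikeRate > 0 && runif(1) < cfg$spikeRate) {
    pos <- sample.int(n, 1L)
    spike[pos] <- cfg$spikeAmplitude * sample(c(-1, 1), 1L)
  }
  list(sinusoid = sinus, noise = noise, spike = spike,
       signal = sinus + noise + spike)
}

#' Generate one synthetic EEG trial
#'
#' @param cfg a [synthConfig()] list.
#' @param label class of the trial, \code{"normal"} or \code{"alcoholic"}.
#' @param seed seed for this trial (default: the config seed).
#' @param components when \code{TRUE}, return the list of signal
#'   components (\code{sinusoid}, \code{noise}, \code{spike},
#'   \code{signal}) instead of an \code{EpochSet}; used to test the
#'   generator itself.
#' @return A one-epoch [EpochSet-class] (or a component list).
#' @export
generateTrial <- function(cfg, label = c("normal", "alcoholic"),
                          seed = cfg$seed, components = FALSE) {
  stopifnot(inherits(cfg, "synthConfig"))
  label <- match.arg(label)
  parts <- withSeed(seed, .synthTrialComponents(cfg, label))
  if (components) return(parts)
  EpochSet(matrix(parts$signal, nrow = 1L), label = label)
}

#' Generate a labelled two-class synthetic dataset
#'
#' Draws \code{nTrialsPerClass} trials per class and shuffles their order
#' with the same seeded generator; class balance is exact.
#'
#' @param cfg a [synthConfig()] list.
#' @return An [EpochSet-class] with \code{2 * nTrialsPerClass} epochs.
#' @export
generateDataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthConfig"))
  withSeed(cfg$seed, {
    labels <- rep(.CLASS_LEVELS, each = cfg$nTrialsPerClass)
    trials <- lapply(labels, function(lb) .synthTrialComponents(cfg, lb))
    ord <- sample.int(length(labels))
    samples <- do.call(rbind, lapply(trials[ord], `[[`, "signal"))
    new("EpochSet", samples = samples,
        channel = rep("synth", length(labels)),
        label = labels[ord],
        artifactFlag = rep(FALSE, length(labels)))
  })
}
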