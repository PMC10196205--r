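## Synthetic two-class motor-imagery EEG.
##
## Each channel carries band-limited mu (8-12 Hz) and beta (13-30 Hz)
## oscillations built from sinusoids at randomized in-band frequencies with
## random phases, so band power is analytically known. The class effect is an
## ERD-like attenuation: class-1 trials multiply the mu amplitude on one fixed
## channel subset by (1 - erdDepth), class-2 trials attenuate a disjoint
## subset. Trials are mixed through a per-subject matrix combining log-normal
## channel gains with a near-identity orthogonal rotation (identity base +
## re-orthogonalized Gaussian perturbation, both of scale subjectShiftSd),
## and white noise is added.

# sinusoids per band; variance of the band component is sigma^2 regardless
.N_SINES <- 3L
.SD_MU <- 1
.SD_BETA <- 0.7

.subjectSeed <- function(seed, subjectIndex) {
  as.integer((as.numeric(seed) * 1009 + subjectIndex * 7919) %%
               .Machine$integer.max)
}

# channel subsets carrying the class-specific ERD (disjoint, fixed)
.erdSubsets <- function(nChannels) {
  q <- max(1L, floor(nChannels / 4))
  list(class1 = seq_len(q), class2 = q + seq_len(q))
}

# one band component for one channel: sum of nSines random-frequency,
# random-phase sinusoids with total variance sd^2
.bandComponent <- function(tgrid, band, sd) {
  amp <- sd * sqrt(2 / .N_SINES)
  freqs <- stats::runif(.N_SINES, band[1L], band[2L])
  phases <- stats::runif(.N_SINES, 0, 2 * pi)
  out <- numeric(length(tgrid))
  for (k in seq_len(.N_SINES))
    out <- out + amp * sin(2 * pi * freqs[k] * tgrid + phases[k])
  out
}

# per-subject mixing: log-normal channel gains (electrode/skull variability)
# times the nearest-orthogonal completion of I + sd * E (montage rotation);
# both vanish smoothly as sd -> 0
.subjectMixing <- function(nChannels, sd) {
  if (sd == 0) return(diag(nChannels))
  gains <- exp(stats::rnorm(nChannels, sd = sd))
  E <- matrix(stats::rnorm(nChannels^2, sd = sd), nChannels)
  qrd <- qr(diag(nChannels) + E)
  Q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))), nChannels)
  diag(gains, nChannels) %*% Q
}

#' Generate one synthetic subject
#'
#' Draws `2 * nTrialsPerClass` labeled trials for one subject of a synthetic
#' motor-imagery cohort. Each trial is a per-channel sum of band-limited mu
#' and beta oscillations, attenuated on the class-matched channel subset by
#' `(1 - erdDepth)` in mu amplitude, mixed through the subject-specific
#' near-identity orthogonal matrix, plus white noise. Identical `config` and
#' `subjectIndex` regenerate the trials bit-exactly.
#'
#' @param config a [SyntheticConfig-class].
#' @param subjectIndex 1-based subject index, at most `config@nSubjects`.
#' @return An [EpochSet-class] with balanced labels \{1, 2\}.
#' @examples
#' cfg <- SyntheticConfig(nSubjects = 2, nTrialsPerClass = 4)
#' es <- generateSubject(cfg, 1)
#' nTrials(es)
#' @export
generateSubject <- function(config, subjectIndex) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  if (subjectIndex < 1 || subjectIndex > config@nSubjects)
    stop("subjectIndex must lie in 1..nSubjects")

  k <- as.integer(config@nChannels)
  nPer <- as.integer(config@nTrialsPerClass)
  nSamp <- round(config@trialDuration * config@fs)
  tgrid <- (seq_len(nSamp) - 1L) / config@fs
  subs <- .erdSubsets(k)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.subjectSeed(config@seed, subjectIndex))

  M <- .subjectMixing(k, config@subjectShiftSd)
  labels <- rep(c(1, 2), each = nPer)
  data <- array(0, dim = c(2L * nPer, k, nSamp))
  for (i in seq_along(labels)) {
    erdChannels <- if (labels[i] == 1) subs$class1 else subs$class2
    S <- matrix(0, k, nSamp)
    for (c in seq_len(k)) {
      sdMu <- if (c %in% erdChannels)
        .SD_MU * (1 - config@erdDepth) else .SD_MU
      S[c, ] <- .bandComponent(tgrid, config@muBand, sdMu) +
        .bandComponent(tgrid, config@betaBand, .SD_BETA)
    }
    X <- M %*% S + matrix(stats::rnorm(k * nSamp, sd = config@noiseSd),
                          k, nSamp)
    data[i, , ] <- X
  }
  EpochSet(data, labels, config@fs,
           channelLabels = paste0("ch", seq_len(k)),
           window = c(0, config@trialDuration))
}

#' Generate a multi-subject synthetic cohort
#'
#' Calls [generateSubject()] for each of `config@nSubjects` subjects; all
#' subjects share the class-effect construction but receive independent
#' mixing perturbations, creating source-to-target covariate shift when
#' `subjectShiftSd > 0`.
#'
#' @param config a [SyntheticConfig-class].
#' @return A [Cohort-class] with subjects named `S1, S2, ...`.
#' @examples
#' coh <- generateCohort(SyntheticConfig(nSubjects = 2, nTrialsPerClass = 4))
#' coh
#' @export
generateCohort <- function(config = SyntheticConfig()) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  subjects <- lapply(seq_len(config@nSubjects), function(i)
    generateSubject(config, i))
  names(subjects) <- paste0("S", seq_len(config@nSubjects))
  new("Cohort", subjects = subjects, config = config)
}

# save/restore the global RNG state so generators are pure given their seed
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
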