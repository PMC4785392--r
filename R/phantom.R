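# Synthetic vessel phantoms with closed-form ground truth. The generator
# emulates the study acquisitions (3-min movies at 2.5 frames/s; 8-min
# treatment movies with application at t = 2 min): a tracer-filled
# cylindrical vessel on an autofluorescent background, phasic diameter
# oscillations with optional tonic steps, a Gaussian PSF, and additive
# noise. Every quantity the rest of the package estimates is available here
# in closed form, which is what makes parameter-recovery testing possible.

#' Contraction waveform parameters
#'
#' Ground-truth diameter dynamics D(t) for a phantom vessel.
#'
#' Two waveform families are available. \code{"pulse"} (default) is a
#' powered raised-cosine contraction train: one constriction dip per cycle
#' whose full width at half maximum is \code{pulseDuty} cycle lengths,
#' superimposed on a small linear diastolic refill (\code{refill} fraction
#' of the contraction excursion) so the end-diastolic diameter is maximal
#' just before the next contraction, as in a refilling lymphangion. The
#' refill's sawtooth reset is hidden at the dip centre. \code{"sinusoid"}
#' is retained for closed-form tests.
#'
#' \code{depth} is calibrated so that the peak-to-trough excursion divided
#' by the cycle-mean diameter equals \code{depth} exactly, for either
#' waveform; this is the quantity the percent-amplitude metric estimates.
#'
#' @param d0 baseline inner diameter, micrometres.
#' @param depth per-cycle depth as a fraction of the cycle mean (0 <= depth < 1).
#' @param frequency contractions per minute.
#' @param waveform \code{"pulse"} or \code{"sinusoid"}.
#' @param pulseDuty contraction FWHM as a fraction of the cycle (pulse only).
#' @param refill diastolic refill rise as a fraction of the contraction
#'   excursion (pulse only).
#' @param phase starting phase in cycles. The default 0.75 opens the record
#'   mid-diastole (during refill), so that neither record boundary falls on
#'   a diameter maximum at the canonical acquisition settings; an extremum
#'   straddling a record boundary is undecidable from the samples, so
#'   placing one there by construction would make every simulated recording
#'   a boundary edge case.
#' @param toneProfile optional data.frame(time, mult): piecewise-constant
#'   multiplier of d0 switching at the given times (seconds), e.g. a tone
#'   step at a treatment time.
#' @param freqProfile optional data.frame(time, mult): piecewise-constant
#'   multiplier of \code{frequency}; the phase stays continuous across
#'   switches.
#' @param quiescentUntil seconds of initial quiescence (flat d0) before
#'   oscillation starts.
#' @return An object of class \code{ContractionParams} (a list).
#' @export
contractionParams <- function(d0 = 100, depth = 0.3, frequency = 6,
                              waveform = c("pulse", "sinusoid"),
                              pulseDuty = 0.3, refill = 0.15, phase = 0.75,
                              toneProfile = NULL, freqProfile = NULL,
                              quiescentUntil = 0) {
  waveform <- match.arg(waveform)
  if (!is.finite(depth) || depth < 0 || depth >= 1)
    stopInvalid("depth must be in [0, 1)")
  if (!is.finite(frequency) || frequency < 0)
    stopInvalid("frequency must be non-negative")
  if (!is.finite(d0) || d0 <= 0) stopInvalid("d0 must be positive")
  if (waveform == "pulse" && (pulseDuty < 0.1 || pulseDuty > 0.9))
    stopInvalid("pulseDuty must be in [0.1, 0.9]")
  chk <- function(p, what) {
    if (is.null(p)) return(NULL)
    if (!is.data.frame(p) || !all(c("time", "mult") %in% names(p)))
      stopInvalid(sprintf("%s must be a data.frame(time, mult)", what))
    p[order(p$time), , drop = FALSE]
  }
  structure(list(d0 = d0, depth = depth, frequency = frequency,
                 waveform = waveform, pulseDuty = pulseDuty,
                 refill = refill, phase = phase,
                 toneProfile = chk(toneProfile, "toneProfile"),
                 freqProfile = chk(freqProfile, "freqProfile"),
                 quiescentUntil = quiescentUntil),
            class = "ContractionParams")
}

# Exponent m of the powered raised-cosine ((1 - cos)/2)^m whose FWHM is
# `duty` cycles: FWHM = 1 - acos(1 - 2^(1 - 1/m))/pi, solved for m.
.pulseExponent <- function(duty) {
  stats::uniroot(function(m) (1 - acos(1 - 2^(1 - 1 / m)) / pi) - duty,
                 c(0.22, 200), tol = 1e-10)$root
}

# Mean over one cycle of the powered raised-cosine pulse.
.pulseMean <- function(m) {
  stats::integrate(function(u) ((1 - cos(2 * pi * u)) / 2)^m, 0, 1,
                   rel.tol = 1e-10)$value
}

# Piecewise-constant profile evaluation: mult in effect at time t.
.profileAt <- function(profile, t) {
  if (is.null(profile)) return(rep(1, length(t)))
  mult <- rep(1, length(t))
  for (i in seq_len(nrow(profile)))
    mult[t >= profile$time[i]] <- profile$mult[i]
  mult
}

# Cumulative phase (in cycles) at times t for base frequency f (per min)
# modulated by a piecewise-constant freqProfile. Phase is continuous.
.phaseAt <- function(t, f, profile) {
  if (is.null(profile)) return(f / 60 * t)
  brk <- c(0, profile$time[profile$time > 0], Inf)
  mlt <- c(1, profile$mult[profile$time > 0])
  # cumulative phase at each breakpoint
  ph <- numeric(length(t))
  acc <- 0
  for (s in seq_along(mlt)) {
    lo <- brk[s]; hi <- brk[s + 1]
    inseg <- t >= lo & t < hi
    ph[inseg] <- acc + f * mlt[s] / 60 * (t[inseg] - lo)
    if (is.finite(hi)) acc <- acc + f * mlt[s] / 60 * (hi - lo)
  }
  ph
}

# Inverse of .phaseAt: the time at which cumulative phase reaches `target`.
.timeAtPhase <- function(target, f, profile, tmax) {
  if (f <= 0) return(numeric(0))
  if (is.null(profile)) return(target * 60 / f)
  out <- numeric(length(target))
  brk <- c(0, profile$time[profile$time > 0], tmax)
  mlt <- c(1, profile$mult[profile$time > 0])
  ph0 <- 0
  seg <- 1L
  segPhase <- cumsum(c(0, f * mlt / 60 * diff(brk)))
  for (j in seq_along(target)) {
    s <- findInterval(target[j], segPhase, rightmost.closed = TRUE)
    s <- min(max(s, 1L), length(mlt))
    rate <- f * mlt[s] / 60
    out[j] <- if (rate > 0) brk[s] + (target[j] - segPhase[s]) / rate else NA
  }
  out
}

#' Generate a ground-truth contraction waveform
#'
#' Evaluates D(t) on the acquisition grid and returns it together with the
#' exact event times (diameter maxima and constriction nadirs) and the
#' calibrated excursion. Deterministic: the waveform itself is noise-free
#' (noise belongs to the rendering / trace stage).
#'
#' @param params a [contractionParams()] object.
#' @param frameRate frames per second (default 2.5).
#' @param duration seconds (default 180).
#' @return A list: \code{time}, \code{diameter} (um), \code{peakTimes},
#'   \code{troughTimes} (seconds, events strictly inside the record),
#'   \code{excursion} (peak-to-trough excursion in um at tone multiplier 1),
#'   \code{params}, \code{frameRate}, \code{duration}.
#' @examples
#' w <- contractionWaveform(contractionParams(frequency = 6), 2.5, 180)
#' length(w$peakTimes)   # 18 contractions in 3 min
#' @export
contractionWaveform <- function(params, frameRate = 2.5, duration = 180) {
  stopifnot(inherits(params, "ContractionParams"))
  n <- round(duration * frameRate)
  if (n < 10) stopInvalid("waveform needs at least 10 frames")
  t <- (seq_len(n) - 1) / frameRate
  f <- params$frequency
  tone <- .profileAt(params$toneProfile, t)
  a <- params$depth

  if (a == 0 || f == 0) {
    D <- params$d0 * tone
    return(list(time = t, diameter = D, peakTimes = numeric(0),
                troughTimes = numeric(0), excursion = 0,
                params = params, frameRate = frameRate, duration = duration))
  }

  q <- params$quiescentUntil
  tEff <- pmax(t - q, 0)
  psi <- .phaseAt(tEff, f, params$freqProfile) + params$phase

  if (params$waveform == "sinusoid") {
    # D = d0 tone (1 + a/2 sin 2 pi psi): excursion a*d0, cycle mean d0
    osc <- 1 + a / 2 * sin(2 * pi * psi)
    alpha <- a
    # peaks at psi = 0.25 mod 1, troughs at 0.75 mod 1
    pkPhase <- 0.25; trPhase <- 0.75
    shape <- NULL
  } else {
    m <- .pulseExponent(params$pulseDuty)
    mp <- .pulseMean(m)
    eps <- params$refill
    # solve alpha so that (D_pk - D_tr)/cycle mean = depth exactly;
    # saw has zero mean so the cycle mean is d0 tone (1 - alpha mp)
    saw <- function(u) (u + 0.5) %% 1 - 0.5        # reset at pulse centre
    p <- function(u) ((1 - cos(2 * pi * u)) / 2)^m
    g <- function(u, alpha) -alpha * p(u) + alpha * eps * saw(u)
    cycExtrema <- function(alpha) {
      pk <- stats::optimize(function(u) g(u, alpha), c(0.95, 1.45),
                            maximum = TRUE)
      tr <- stats::optimize(function(u) g(u, alpha), c(1.2, 1.8))
      list(pk = pk$maximum %% 1, tr = tr$minimum %% 1,
           exc = pk$objective - tr$objective)
    }
    root <- stats::uniroot(function(alpha) {
      ex <- cycExtrema(alpha)
      ex$exc / (1 - alpha * mp) - a
    }, c(1e-6, 0.95), tol = 1e-10)
    alpha <- root$root
    ext <- cycExtrema(alpha)
    pkPhase <- ext$pk; trPhase <- ext$tr
    osc <- 1 + g(psi, alpha)
    shape <- list(m = m, mp = mp, alpha = alpha)
  }

  D <- params$d0 * tone * osc
  if (any(D <= 0)) stopInvalid("waveform parameters drive D(t) <= 0")

  # ground-truth event times: solve psi = k + pkPhase / k + trPhase for all
  # integers k that land strictly inside (q, duration)
  psiEnd <- .phaseAt(max(duration - q, 0), f, params$freqProfile) +
    params$phase
  evTimes <- function(ph) {
    ks <- seq(floor(params$phase - ph) - 1, ceiling(psiEnd - ph) + 1)
    tgt <- ks + ph - params$phase
    tt <- .timeAtPhase(tgt[tgt > 0], f, params$freqProfile,
                       duration) + q
    tt[tt > q & tt < duration & is.finite(tt)]
  }
  exc <- if (params$waveform == "sinusoid") a * params$d0 else
    ext$exc * params$d0 / 1            # excursion at tone multiplier 1
  list(time = t, diameter = D,
       peakTimes = evTimes(pkPhase), troughTimes = evTimes(trPhase),
       excursion = exc, params = params, shape = if (is.null(shape)) NULL
       else shape, frameRate = frameRate, duration = duration)
}

#' Phantom optics and acquisition parameters
#'
#' Imaging model for rendered phantom movies: the vessel is a horizontal
#' cylinder on row \code{axisRow}; pixel intensity is
#' \code{background + brightness * pathlength convolved with a Gaussian PSF
#' + noise}, where the chord pathlength through the lumen is integrated
#' exactly over each pixel row. Defaults give a vessel-to-background
#' intensity ratio comfortably above the 6-fold regime of real NIR
#' recordings.
#'
#' @param nrow,ncol image size in pixels.
#' @param axisRow image row of the vessel axis.
#' @param scale micrometres per pixel.
#' @param brightness intensity per micrometre of tracer pathlength.
#' @param background background (autofluorescence) level, intensity units.
#' @param psfSigma Gaussian PSF sigma in pixels.
#' @param noiseSigma additive Gaussian noise SD, intensity units.
#' @param noiseModel \code{"gaussian"} (default) or \code{"poisson"}
#'   (shot-noise option; \code{noiseSigma} is ignored there).
#' @param frameRate frames per second.
#' @param duration seconds.
#' @param seed integer seed for the noise generator.
#' @return An object of class \code{PhantomOptics} (a list).
#' @export
phantomOptics <- function(nrow = 448, ncol = 64, axisRow = 308, scale = 2,
                          brightness = 10, background = 100, psfSigma = 1,
                          noiseSigma = 0, noiseModel = c("gaussian", "poisson"),
                          frameRate = 2.5, duration = 180, seed = 1) {
  noiseModel <- match.arg(noiseModel)
  if (background < 0 || brightness < 0)
    stopInvalid("background and brightness must be non-negative")
  structure(list(nrow = nrow, ncol = ncol, axisRow = axisRow, scale = scale,
                 brightness = brightness, background = background,
                 psfSigma = psfSigma, noiseSigma = noiseSigma,
                 noiseModel = noiseModel, frameRate = frameRate,
                 duration = duration, seed = seed),
            class = "PhantomOptics")
}

# Integral-preserving discrete Gaussian kernel, truncated at 4 sigma.
.gaussKernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- ceiling(4 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Mean chord pathlength (um) through a cylinder of radius R (um) across a
# pixel row spanning [u - s/2, u + s/2] um from the axis; exact integral of
# 2*sqrt(R^2 - u^2) over the pixel, divided by the pixel height.
.pathlengthProfile <- function(R, offsets, s) {
  A <- function(u) {                      # antiderivative of 2 sqrt(R^2-u^2)
    u <- pmax(pmin(u, R), -R)
    u * sqrt(pmax(R^2 - u^2, 0)) + R^2 * asin(u / R)
  }
  (A(offsets + s / 2) - A(offsets - s / 2)) / s
}

#' Render one phantom frame
#'
#' Renders the noiseless image for a given true inner diameter, then adds
#' noise if configured. The cross-section uses the exact per-pixel integral
#' of the cylinder chord function, so background-subtracted column sums
#' equal \code{brightness * pi * (D/2)^2 / scale} up to PSF truncation.
#'
#' @param D true inner diameter, micrometres (positive; the vessel must fit
#'   inside the frame).
#' @param optics a [phantomOptics()] object.
#' @param noise logical; add noise per the optics (default FALSE so the
#'   deterministic image is easy to test against closed forms). Noise uses
#'   the current RNG state; seed handling belongs to [generateMovie()].
#' @return An \code{nrow x ncol} intensity matrix.
#' @export
renderFrame <- function(D, optics, noise = FALSE) {
  stopifnot(inherits(optics, "PhantomOptics"))
  if (!is.finite(D) || D <= 0) stopInvalid("D must be positive")
  Rpx <- D / 2 / optics$scale
  if (optics$axisRow - Rpx < 1 || optics$axisRow + Rpx > optics$nrow)
    stopInvalid("vessel wider than the frame")
  rows <- seq_len(optics$nrow)
  off <- (rows - optics$axisRow) * optics$scale
  prof <- .pathlengthProfile(D / 2, off, optics$scale)
  k <- .gaussKernel(optics$psfSigma)
  if (length(k) > 1) {
    r <- (length(k) - 1) / 2
    padded <- c(numeric(r), prof, numeric(r))
    prof <- stats::filter(padded, k, sides = 2)[(r + 1):(r + optics$nrow)]
  }
  img <- matrix(optics$background + optics$brightness * prof,
                nrow = optics$nrow, ncol = optics$ncol)
  if (noise) {
    if (optics$noiseModel == "poisson") {
      img <- matrix(stats::rpois(length(img), pmax(img, 0)),
                    nrow = optics$nrow)
    } else if (optics$noiseSigma > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, optics$noiseSigma),
                          nrow = optics$nrow)
    }
  }
  img
}

#' Generate a phantom movie with ground truth
#'
#' Renders every frame of the contraction waveform under the given optics,
#' with seeded noise: identical seeds give identical stacks.
#'
#' @param wave a [contractionParams()] object.
#' @param optics a [phantomOptics()] object (its \code{frameRate},
#'   \code{duration} and \code{seed} drive the acquisition).
#' @return A list: \code{stack} (nrow x ncol x nframes array), \code{truth}
#'   (data.frame frame, time_s, true_diameter_um), \code{waveform} (the
#'   [contractionWaveform()] result), \code{optics}.
#' @seealso [writePhantom()] to write the TIFF/CSV/JSON artifact set.
#' @export
generateMovie <- function(wave, optics) {
  stopifnot(inherits(wave, "ContractionParams"),
            inherits(optics, "PhantomOptics"))
  wf <- contractionWaveform(wave, optics$frameRate, optics$duration)
  n <- length(wf$time)
  stack <- array(0, dim = c(optics$nrow, optics$ncol, n))
  withSeed(optics$seed, {
    for (j in seq_len(n))
      stack[, , j] <- renderFrame(wf$diameter[j], optics, noise = TRUE)
  })
  truth <- data.frame(frame = seq_len(n), time_s = wf$time,
                      true_diameter_um = wf$diameter)
  list(stack = stack, truth = truth, waveform = wf, optics = optics)
}

#' Generate a 1-D phantom trace
#'
#' Shortcut for detector and metric tests: returns the contraction waveform
#' directly as a diameter trace, or transformed to a fluorescence trace with
#' the volume-proportional model \code{F(t) = offset + coef * D(t)^2}
#' (background-subtracted MFI of a cylindrical vessel scales with its
#' cross-sectional area). Additive Gaussian noise with SD \code{noiseSigma}
#' (in trace units) is seeded and reproducible.
#'
#' @param wave a [contractionParams()] object.
#' @param model \code{"diameter"} or \code{"fluorescence"}.
#' @param noiseSigma additive Gaussian noise SD in trace units.
#' @param frameRate frames per second.
#' @param duration seconds.
#' @param seed integer seed (NULL = use current RNG state).
#' @param offset,coef fluorescence model parameters.
#' @return A list: \code{trace} (a [Trace-class]), \code{truth} (the
#'   waveform list from [contractionWaveform()], whose \code{excursion} is
#'   in trace units for the chosen model).
#' @export
generateTraces <- function(wave, model = c("diameter", "fluorescence"),
                           noiseSigma = 0, frameRate = 2.5, duration = 180,
                           seed = NULL, offset = 0, coef = 1) {
  model <- match.arg(model)
  wf <- contractionWaveform(wave, frameRate, duration)
  v <- wf$diameter
  if (model == "fluorescence") {
    v <- offset + coef * v^2
    # per-cycle excursion of F in trace units (F is monotone in D so the
    # extrema coincide); evaluated at tone multiplier 1
    if (wf$excursion > 0) {
      hiD <- max(wf$diameter[seq_len(min(length(wf$diameter),
               ceiling(60 / max(wave$frequency, 1e-9) * frameRate)))])
      loD <- hiD - wf$excursion
      wf$excursion <- coef * (hiD^2 - loD^2)
    }
  }
  noisy <- withSeed(seed, v + if (noiseSigma > 0)
    stats::rnorm(length(v), 0, noiseSigma) else 0)
  list(trace = Trace(noisy, frameRate, t0 = 0), truth = wf, model = model)
}
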