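# Independent oracles and shared fixtures, kept deliberately naive so they
# stay independent of the implementation they check.

# Brute-force strict local maxima: interior samples exceeding both immediate
# neighbours.
bruteLocalMaxima <- function(x) {
  n <- length(x)
  which(vapply(seq_len(n), function(i) {
    i > 1 && i < n && x[i] > x[i - 1] && x[i] > x[i + 1]
  }, logical(1)))
}

# Brute-force scalogram row sum at scale k, straight from the definition:
# entries are 1.5 except 0 where both lag-k neighbours exist and are smaller.
bruteGamma <- function(x, k) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) {
    zero <- (i - k) >= 1 && (i + k) <= n && x[i] > x[i - k] && x[i] > x[i + k]
    if (!zero) s <- s + 1.5
  }
  s
}

# Noiseless tie-free periodic test signals for oracle-equivalence checks:
# constant-amplitude sinusoids, powered-cosine pulse trains and mild chirps,
# with irrational-ish phases so samples never tie exactly.
oracleTraceSet <- function(n = 50, seed = 421) {
  set.seed(seed)
  lapply(seq_len(n), function(j) {
    N <- sample(150:400, 1)
    period <- runif(1, 8, min(36, N / 3.2))
    phase <- runif(1)
    kind <- sample(c("sin", "pulse", "chirp"), 1)
    t <- seq_len(N)
    if (kind == "sin") {
      100 + 10 * sin(2 * pi * (t / period + phase))
    } else if (kind == "pulse") {
      m <- runif(1, 1.5, 4)
      100 - 25 * ((1 - cos(2 * pi * (t / period + phase))) / 2)^m
    } else {
      # slow linear frequency drift, +-8%
      inst <- 1 / period * (1 + 0.08 * (t - N / 2) / N)
      100 + 10 * sin(2 * pi * (cumsum(inst) + phase))
    }
  })
}

# Small rendered phantom with matched analysis geometry. The ROI radius
# convention r = 2 * lumen diameter keeps the vessel-ROI mean close to
# background so the moving threshold cuts near the lumen edge.
phantomWithGeometry <- function(d0 = 80, depth = 0.3, frequency = 6,
                                duration = 60, noiseSigma = 0, psf = 1,
                                seed = 1, ncol = 48) {
  scale <- 2
  wave <- contractionParams(d0 = d0, depth = depth, frequency = frequency)
  optics <- phantomOptics(nrow = 448, ncol = ncol, axisRow = 308,
                          scale = scale, psfSigma = psf,
                          noiseSigma = noiseSigma, frameRate = 2.5,
                          duration = duration, seed = seed)
  movie <- generateMovie(wave, optics)
  geometry <- vesselGeometry(center = c(ncol / 2, 308.3), normal = c(0, -1),
                             r = 2 * d0 / scale, scale = scale)
  list(movie = movie, geometry = geometry, optics = optics, wave = wave)
}
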