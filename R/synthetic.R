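# Default structure-process transition matrix over (H, E, C): strong
# self-transitions give geometric run lengths with means 10 (helix),
# ~6.7 (strand), 5 (coil); the leaving mass is split evenly.
.defaultTransition <- function() {
  T <- matrix(c(0.90, 0.050, 0.050,
                0.075, 0.85, 0.075,
                0.10, 0.10, 0.80),
              nrow = 3L, byrow = TRUE, dimnames = list(.STATES, .STATES))
  T
}

# Hand-set residue preferences: helix formers, beta-branched/aromatic
# strand formers, and turn/coil formers each get 3x weight in their
# state's preference distribution.
.statePreferences <- function() {
  aa <- .ALPHABET[1:20]
  enriched <- list(H = c("A", "E", "L", "M", "Q", "K", "R", "H"),
                   E = c("V", "I", "Y", "W", "F", "T", "C"),
                   C = c("G", "N", "P", "S", "D"))
  pref <- t(vapply(enriched, function(set) {
    w <- ifelse(aa %in% set, 3, 1)
    w / sum(w)
  }, numeric(20L)))
  dimnames(pref) <- list(.STATES, aa)
  pref
}

# Emission matrix at contrast kappa: a (1-kappa) share of a shared
# uniform background plus a kappa share of the state preference.
.emissionMatrix <- function(contrast) {
  (1 - contrast) / 20 + contrast * .statePreferences()
}

# Stationary distribution of a 3x3 stochastic matrix.
.stationary <- function(T) {
  e <- eigen(t(T))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

#' Synthetic-data generator configuration
#'
#' The generator emulates the statistical structure the window predictor
#' assumes: per-residue states follow a first-order Markov chain over
#' (H, E, C) started from its stationary distribution, and residues are
#' drawn i.i.d. from a state-specific emission distribution.  The
#' emission contrast `contrast` interpolates between one shared
#' distribution (`contrast = 0`: no signal, so prediction cannot beat
#' the majority state) and fully state-specific preferences
#' (`contrast = 1`).
#'
#' @param nSequences Number of sequences (default 300).
#' @param meanLength Mean sequence length (default 150).
#' @param contrast Emission contrast in `[0, 1]` (default 0.8).
#' @param seed Integer seed; the dataset is a pure function of the
#'   configuration.
#' @param transition Optional 3 x 3 stochastic matrix over (H, E, C);
#'   default self-transitions 0.90 / 0.85 / 0.80 with the rest split
#'   evenly.
#' @param emission Optional 3 x 20 emission matrix (rows H, E, C over
#'   the canonical amino acids); default built from `contrast`.
#' @param lengthModel `"geometric"` (default): lengths are
#'   `17 + Geometric` with the stated mean, so every sequence spans at
#'   least one full window; or `"fixed"`.
#' @return A list of class `GeneratorConfig`.
#' @export
generatorConfig <- function(nSequences = 300L, meanLength = 150,
                            contrast = 0.8, seed = 1L,
                            transition = NULL, emission = NULL,
                            lengthModel = c("geometric", "fixed")) {
  nSequences <- as.integer(nSequences)
  lengthModel <- match.arg(lengthModel)
  if (is.na(nSequences) || nSequences < 1L)
    stop("nSequences must be an integer >= 1", call. = FALSE)
  if (!is.finite(meanLength) || meanLength < .WINDOW)
    stop(sprintf("meanLength must be at least the window width (%d)", .WINDOW),
         call. = FALSE)
  if (!is.finite(contrast) || contrast < 0 || contrast > 1)
    stop("contrast must lie in [0, 1]", call. = FALSE)
  if (is.null(transition)) transition <- .defaultTransition()
  transition <- as.matrix(transition)
  if (!identical(dim(transition), c(3L, 3L)) || any(transition < 0) ||
      any(abs(rowSums(transition) - 1) > 1e-8))
    stop("transition must be a 3 x 3 stochastic matrix (rows sum to 1)",
         call. = FALSE)
  if (is.null(emission)) emission <- .emissionMatrix(contrast)
  emission <- as.matrix(emission)
  if (!identical(dim(emission), c(3L, 20L)) || any(emission < 0) ||
      any(abs(rowSums(emission) - 1) > 1e-8))
    stop("emission must be a 3 x 20 stochastic matrix (rows sum to 1)",
         call. = FALSE)
  structure(list(nSequences = nSequences, meanLength = meanLength,
                 contrast = contrast, seed = as.integer(seed),
                 transition = transition, emission = emission,
                 lengthModel = lengthModel),
            class = "GeneratorConfig")
}

#' @rdname generatorConfig
#' @return `defaultGeneratorConfig(seed)` is `generatorConfig(seed = seed)`
#'   with all defaults.
#' @export
defaultGeneratorConfig <- function(seed = 1L) generatorConfig(seed = seed)

#' Generate a synthetic training database
#'
#' Draws `cfg$nSequences` (sequence, structure) pairs from the Markov
#' structure process and state-specific emissions described in
#' [generatorConfig()].  Fully reproducible: the same configuration
#' (including seed) yields a byte-identical dataset.
#'
#' @param cfg A [generatorConfig()].
#' @param prefix Id prefix for the generated records.
#' @return A list of training records (`sequence`, `structure`), in the
#'   format of [readTrainingDb()].
#' @export
generateDataset <- function(cfg = defaultGeneratorConfig(), prefix = "syn") {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  set.seed(cfg$seed)
  pi0 <- .stationary(cfg$transition)
  cumT <- t(apply(cfg$transition, 1L, cumsum))
  lengths <- if (cfg$lengthModel == "fixed") {
    rep(as.integer(round(cfg$meanLength)), cfg$nSequences)
  } else {
    .WINDOW + rgeom(cfg$nSequences, 1 / (cfg$meanLength - .WINDOW + 1))
  }
  lapply(seq_len(cfg$nSequences), function(i) {
    n <- lengths[i]
    st <- integer(n)
    st[1L] <- findInterval(runif(1L), cumsum(pi0)) + 1L
    u <- runif(n)
    for (t in seq_len(n)[-1L])
      st[t] <- findInterval(u[t], cumT[st[t - 1L], ]) + 1L
    codes <- integer(n)
    for (s in 1:3) {
      idx <- which(st == s)
      if (length(idx))
        codes[idx] <- sample(0:19, length(idx), replace = TRUE,
                             prob = cfg$emission[s, ])
    }
    list(sequence = new("ProteinSequence",
                        id = sprintf("%s%04d", prefix, i), codes = codes),
         structure = .STATES[st])
  })
}
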