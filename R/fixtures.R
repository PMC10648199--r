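#' Packaged block-conditional amino-acid propensity table
#'
#' A fixed 16 x 20 table of relative propensities used by the synthetic
#' sequence generator: each block has one modal residue (propensity 1.0),
#' two weakly favoured residues (0.2) and a flat background (-0.2).  The
#' table is arbitrary but version-pinned so synthetic datasets are stable;
#' it makes no attempt to match real PDB amino-acid statistics.
#'
#' @return numeric matrix, rows = blocks 'a'-'p', columns = the 20 residues.
#' @export
pb_propensities <- function() {
  wide <- read.delim(pblocks_file("extdata", "pb_propensities.tsv"),
                     check.names = FALSE)
  M <- as.matrix(wide[, -1])
  rownames(M) <- wide$letter
  M
}

# first-order transition matrix over the 16 letters: strong self-transition
# for the helix core 'm' (long runs) and the strand core 'd', moderate for
# the rest; the remaining mass is spread uniformly
default_transition <- function() {
  self <- rep(0.5, 16)
  names(self) <- PB_LETTERS
  self["m"] <- 0.9
  self["d"] <- 0.7
  P <- matrix(0, 16, 16, dimnames = list(PB_LETTERS, PB_LETTERS))
  for (i in seq_len(16)) {
    P[i, ] <- (1 - self[i]) / 15
    P[i, i] <- self[i]
  }
  P
}

#' Configuration of the synthetic backbone generator
#'
#' Defines the study conditions emulated by the fixture: chains assembled
#' from protein-block prototypes via a first-order letter chain, wrapped
#' Gaussian dihedral noise (noise lives in dihedral space so every generated
#' fragment is a valid backbone), and a sequence coupled to the structure
#' through a softmax over the packaged propensity table.
#'
#' @param n_chains number of chains.
#' @param length_range inclusive range of chain lengths (residues), sampled
#'   uniformly.
#' @param transition 16 x 16 row-stochastic letter transition matrix.
#' @param noise_sigma dihedral noise standard deviation, degrees.
#' @param beta sequence-structure coupling strength (0 = uniform sequence,
#'   independent of structure).
#' @param seed integer seed.
#' @return a `pb_fixture_config` list.
#' @export
fixture_config <- function(n_chains = 300, length_range = c(30, 80),
                           transition = default_transition(),
                           noise_sigma = 5, beta = 5, seed = 1) {
  if (noise_sigma < 0 || beta < 0) abort("noise_sigma and beta must be non-negative")
  if (any(abs(rowSums(transition) - 1) > 1e-8)) {
    abort("transition matrix rows must sum to 1")
  }
  structure(list(n_chains = n_chains, length_range = length_range,
                 transition = transition, noise_sigma = noise_sigma,
                 beta = beta, seed = seed),
            class = "pb_fixture_config")
}

# consensus per-residue (phi, psi) for a letter sequence: each position takes
# the circular mean of the dihedral constraints imposed by the (up to four)
# letters whose five-residue windows cover it
consensus_angles <- function(lets, definitions) {
  ref <- as.matrix(definitions[, c("psi1", "phi2", "psi2", "phi3", "psi3",
                                   "phi4", "psi4", "phi5")])
  rownames(ref) <- definitions$letter
  L <- length(lets)
  phi <- numeric(L)
  psi <- numeric(L)
  for (i in seq_len(L)) {
    pc <- c(ref[lets[i], "phi3"],
            if (i > 1) ref[lets[i - 1], "phi4"],
            if (i < L) ref[lets[i + 1], "phi2"],
            if (i > 2) ref[lets[i - 2], "phi5"])
    sc <- c(ref[lets[i], "psi3"],
            if (i > 1) ref[lets[i - 1], "psi4"],
            if (i < L) ref[lets[i + 1], "psi2"],
            if (i < L - 1) ref[lets[i + 2], "psi1"])
    phi[i] <- circular_mean(pc)
    psi[i] <- circular_mean(sc)
  }
  list(phi = phi, psi = psi)
}

#' Draw an amino-acid sequence coupled to a block label sequence
#'
#' Residues are drawn independently per position from
#' softmax(beta * propensity[label, ]); beta = 0 gives a uniform sequence
#' independent of the structure.
#'
#' @param labels character vector of block letters.
#' @param beta coupling strength.
#' @param propensities matrix from [pb_propensities()].
#' @param seed optional seed (omit when already inside a seeded context).
#' @return character vector of 1-letter residue codes.
#' @export
couple_sequence <- function(labels, beta, propensities = pb_propensities(),
                            seed = NULL) {
  draw <- function() {
    W <- exp(beta * propensities)
    W <- W / rowSums(W)
    vapply(labels, function(l) {
      sample(colnames(propensities), 1, prob = W[l, ])
    }, character(1), USE.NAMES = FALSE)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# single synthetic chain; assumes an active RNG context
generate_chain_impl <- function(chain_id, L, cfg, definitions, prototypes,
                                propensities, geometry) {
  P <- cfg$transition
  lets <- character(L)
  lets[1] <- sample(PB_LETTERS, 1)
  for (i in 2:L) lets[i] <- sample(PB_LETTERS, 1, prob = P[lets[i - 1], ])
  ang <- consensus_angles(lets, definitions)

  # true labels: RMSD assignment of the noise-free backbone
  clean <- nerf_chain(ang$phi, ang$psi, geometry)
  frags <- tibble(coords = lapply(seq_len(L - 4), function(s) {
    clean[(3 * s - 2):(3 * s + 12), , drop = FALSE]
  }))
  pb_true <- rep(NA_character_, L)
  pb_true[3:(L - 2)] <- assign_pb(frags, prototypes)$pb

  # per-residue label used for sequence coupling: nearest center at termini
  lab <- pb_true
  lab[1:2] <- pb_true[3]
  lab[(L - 1):L] <- pb_true[L - 2]
  aa <- couple_sequence(lab, cfg$beta, propensities)

  phi <- wrap_angle(ang$phi + rnorm(L, 0, cfg$noise_sigma))
  psi <- wrap_angle(ang$psi + rnorm(L, 0, cfg$noise_sigma))
  X <- nerf_chain(phi, psi, geometry)
  tibble(
    chain_id = chain_id,
    pos = seq_len(L),
    resno = seq_len(L),
    insert = "",
    res_name = bio3d::aa123(aa),
    aa = aa,
    coords_known = TRUE,
    n_x = X[seq(1, 3 * L, 3), 1], n_y = X[seq(1, 3 * L, 3), 2], n_z = X[seq(1, 3 * L, 3), 3],
    ca_x = X[seq(2, 3 * L, 3), 1], ca_y = X[seq(2, 3 * L, 3), 2], ca_z = X[seq(2, 3 * L, 3), 3],
    c_x = X[seq(3, 3 * L, 3), 1], c_y = X[seq(3, 3 * L, 3), 2], c_z = X[seq(3, 3 * L, 3), 3],
    pb_markov = lets,
    pb_true = pb_true
  )
}

#' Generate a synthetic dataset of labelled backbone chains
#'
#' Samples a block letter sequence per chain from the first-order transition
#' chain, derives consensus per-residue dihedrals from the block prototypes,
#' defines the true labels as the RMSD assignment of the noise-free backbone
#' (so recovery is exact at zero noise), couples an amino-acid sequence to
#' those labels, and emits coordinates rebuilt from noise-perturbed
#' dihedrals.  Deterministic for a fixed config seed.
#'
#' @param cfg a [fixture_config()].
#' @param definitions,geometry alphabet and geometry used for construction.
#' @return tibble of residues in the [read_structure()] shape, plus columns
#'   `pb_markov` (latent generator letter) and `pb_true` (noise-free RMSD
#'   assignment; NA at the two terminal residues of each end).
#' @export
generate_dataset <- function(cfg = fixture_config(),
                             definitions = pb_definitions(),
                             geometry = backbone_geometry()) {
  prototypes <- pb_prototypes(definitions, geometry)
  propensities <- pb_propensities()
  withr::with_seed(cfg$seed, {
    lens <- sample(cfg$length_range[1]:cfg$length_range[2],
                   cfg$n_chains, replace = TRUE)
    bind_rows(lapply(seq_len(cfg$n_chains), function(k) {
      generate_chain_impl(sprintf("syn%04d", k), lens[k], cfg,
                          definitions, prototypes, propensities, geometry)
    }))
  })
}

#' Generate a single synthetic chain
#'
#' Convenience wrapper around the generator for one chain of a given length
#' (used heavily in tests and examples).
#'
#' @param cfg a [fixture_config()].
#' @param length chain length in residues (>= 5).
#' @param chain_id identifier for the generated chain.
#' @inheritParams generate_dataset
#' @return single-chain residue tibble (see [generate_dataset()]).
#' @export
generate_chain <- function(cfg = fixture_config(), length = 50,
                           chain_id = "syn0001",
                           definitions = pb_definitions(),
                           geometry = backbone_geometry()) {
  if (length < 5) abort("chain length must be at least 5")
  prototypes <- pb_prototypes(definitions, geometry)
  propensities <- pb_propensities()
  withr::with_seed(cfg$seed, {
    generate_chain_impl(chain_id, length, cfg, definitions, prototypes,
                        propensities, geometry)
  })
}

#' Planted-feature regression fixture
#'
#' Standard-normal design with `k_informative` informative columns (named
#' `inf*`), `n_noise` pure-noise columns (`noise*`), and optionally exact
#' duplicates of informative columns (`dup*`, correlation 1 with their
#' source) to exercise the correlation deduplication rule.
#'
#' @param n rows.
#' @param k_informative,n_noise column counts.
#' @param effect_sizes coefficients of the informative columns (length
#'   `k_informative`).
#' @param sigma residual noise standard deviation.
#' @param seed integer seed.
#' @param n_duplicate number of informative columns to duplicate.
#' @param dup_rho correlation of each duplicate with its source column
#'   (1 = exact copy; below 1 adds fresh Gaussian noise to reach the
#'   requested correlation in expectation).
#' @return list with `X` (matrix), `y`, `truth` (informative column names),
#'   `coefficients`.
#' @export
make_regression_fixture <- function(n = 2000, k_informative = 5,
                                    n_noise = 200,
                                    effect_sizes = rep(0.5, k_informative),
                                    sigma = 1, seed = 1, n_duplicate = 0,
                                    dup_rho = 1) {
  if (length(effect_sizes) != k_informative) {
    abort("effect_sizes must have length k_informative")
  }
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * (k_informative + n_noise)), n)
    colnames(X) <- c(paste0("inf", seq_len(k_informative)),
                     paste0("noise", seq_len(n_noise)))
    y <- as.vector(X[, seq_len(k_informative), drop = FALSE] %*% effect_sizes) +
      rnorm(n, 0, sigma)
    if (n_duplicate > 0) {
      D <- X[, seq_len(n_duplicate), drop = FALSE]
      if (dup_rho < 1) {
        D <- dup_rho * D + sqrt(1 - dup_rho^2) *
          matrix(rnorm(n * n_duplicate), n)
      }
      colnames(D) <- paste0("dup", seq_len(n_duplicate))
      X <- cbind(X, D)
    }
    list(X = X, y = y, truth = paste0("inf", seq_len(k_informative)),
         coefficients = effect_sizes)
  })
}
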