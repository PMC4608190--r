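#' @title Seeded synthetic-data generators
#' @description Generators for every input the analyses need: cubes with
#'   planted Tucker3 structure for recovery studies, QIDS-like ordinal
#'   symptom records with person-archetype x symptom-domain x time-phase
#'   structure on top of a shared downward trend, and datasets with known
#'   parameters for the latent class and growth mixture baselines. All
#'   generators are pure functions of their arguments including the seed.
#' @name synthetic_data
NULL

#' Generate a cube with planted Tucker3 structure
#'
#' Draws random orthonormal loadings A (n x P), B (m x Q), C (T x R) and a
#' core G with independent N(0, core_scale^2) entries, forms the trilinear
#' signal and adds white Gaussian noise. Either the noise standard deviation
#' or a target construction fit percentage
#' 100 signal_SS / (signal_SS + noise_SS) may be given; with `target_fit` the
#' noise level is derived from the realized signal sum of squares.
#'
#' @param n,m,T mode sizes. @param P,Q,R planted component numbers.
#' @param core_scale standard deviation of core entries.
#' @param noise_sd white-noise standard deviation (ignored when `target_fit`
#'   is given).
#' @param target_fit expected fit percentage of the correctly sized model,
#'   used to set the noise level.
#' @param seed integer seed.
#' @return list: `cube` (n x m x T array), `truth` (A, B, C, G),
#'   `noise_sd`, `signal_ss`, `expected_fit`.
#' @export
generate_planted_cube <- function(n = 82, m = 12, T = 9, P = 3, Q = 2, R = 2,
                                  core_scale = 1, noise_sd = 0.1,
                                  target_fit = NULL, seed = 1L) {
  check_components(c(n, m, T), P, Q, R)
  if (core_scale <= 0 || (!is.null(noise_sd) && noise_sd < 0))
    stop_hetcube("core_scale must be positive and noise_sd non-negative",
                 class = "hetcube_invalid_input")
  set.seed(derive_seed(seed, 1L))
  A <- fix_column_signs(rand_orth(n, P))
  B <- fix_column_signs(rand_orth(m, Q))
  C <- fix_column_signs(rand_orth(T, R))
  G <- balanced_core(P, Q, R, core_scale)
  signal <- tucker3_reconstruct(A, B, C, G)
  signal_ss <- sum(signal^2)
  # report the ground truth in its canonical (HOSVD, sign-fixed)
  # parameterization: the trilinear model is defined only up to rotations
  # within each mode's column space, so the identifiable planted quantities
  # are the mode subspaces and this canonical basis of them
  A <- leading_lsv(unfold_cube(signal, 1), P)
  B <- leading_lsv(unfold_cube(signal, 2), Q)
  C <- leading_lsv(unfold_cube(signal, 3), R)
  G <- compute_core(signal, A, B, C)
  if (!is.null(target_fit)) {
    stopifnot(target_fit > 0, target_fit <= 100)
    noise_sd <- sqrt(signal_ss * (100 - target_fit) / target_fit / (n * m * T))
  }
  set.seed(derive_seed(seed, 2L))
  cube <- signal + array(stats::rnorm(n * m * T, sd = noise_sd), dim = dim(signal))
  dimnames(cube) <- list(persons = sprintf("p%03d", seq_len(n)),
                         items = sprintf("item%02d", seq_len(m)),
                         times = seq_len(T))
  list(cube = structure(cube, class = c("data_cube", "array")),
       truth = list(A = A, B = B, C = C, G = G),
       noise_sd = noise_sd, signal_ss = signal_ss,
       expected_fit = 100 * signal_ss / (signal_ss + noise_sd^2 * n * m * T))
}

# Random core with well-conditioned mode spectra. A core with iid normal
# entries frequently has a near-zero smallest mode singular value (the
# smallest singular value of a near-square Gaussian matrix), i.e. it fails to
# actually plant one of the advertised components; balancing sweeps replace
# each mode-unfolding's singular values by a mildly decaying profile so every
# planted component carries a material share of the signal. Total sum of
# squares is fixed at P*Q*R*core_scale^2.
balanced_core <- function(P, Q, R, core_scale, decay = 0.85, sweeps = 4L) {
  d <- c(P, Q, R)
  ss_target <- P * Q * R * core_scale^2
  G <- array(stats::rnorm(P * Q * R), dim = d)
  for (sw in seq_len(sweeps)) {
    for (mode in 1:3) {
      Gm <- unfold_cube(G, mode)
      s <- svd(Gm)
      k <- length(s$d)
      prof <- decay^(seq_len(k) - 1)
      prof <- prof * sqrt(ss_target / sum(prof^2))
      G <- refold_cube(s$u %*% (prof * t(s$v)), mode, d)
    }
  }
  G
}

#' Default interaction pattern for the QIDS-like generator
#'
#' A 3 x 2 x 2 array of archetype x symptom-domain x time-phase effects:
#' archetype 1 loads on both domains early and little late (overall quick
#' recovery), archetype 2 keeps a somatic/affective excess in both phases
#' with a cognitive/appetitive deficit (persistent somatic/affective
#' symptomatology), archetype 3 rises from the early to the late phase in
#' both domains (overall increasing symptomatology).
#' @return 3 x 2 x 2 numeric array (archetype, domain, phase).
#' @export
qids_archetype_pattern <- function() {
  W <- array(0, dim = c(3, 2, 2),
             dimnames = list(archetype = c("quick_recovery", "persistent_somatic",
                                           "increasing"),
                             domain = c("somatic_affective", "cognitive_appetitive"),
                             phase = c("early", "late")))
  # relative pattern follows the core-array shape of the study design:
  # rows scaled to order-one latent units
  W[1, , ] <- matrix(c(1.00, 0.42, 0.24, -0.04), 2, 2)   # domain x phase
  W[2, , ] <- matrix(c(0.25, -0.77, 0.11, -0.65), 2, 2)
  W[3, , ] <- matrix(c(0.68, 0.19, 1.17, 0.43), 2, 2)
  W
}

#' Default assignment of the 12 recoded items to symptom domains
#' @return integer vector (1 = somatic/affective, 2 = cognitive/appetitive)
#'   named by recoded item id.
#' @export
qids_item_domains <- function() {
  d <- c("1-3" = 1, "4" = 2, "5" = 1, "6/7" = 2, "8/9" = 2, "10" = 1,
         "11" = 2, "12" = 2, "13" = 1, "14" = 1, "15" = 2, "16" = 1)
  d
}

#' Generate QIDS-like longitudinal ordinal records
#'
#' Builds a continuous latent severity per person-item-time as a shared
#' downward weekly trend plus an archetype x domain x phase interaction, then
#' thresholds it into ordinal scores. Persons belong to one of three
#' archetypes (person-mode profiles); items split into two symptom domains;
#' time splits into an early (weeks 1-5) and a late (weeks 6-9) phase, so the
#' planted multiway structure is (3, 2, 2). Archetype 3 doubles as the slow /
#' worsening severity class for the growth models (archetypes 1-2 form the
#' quick-recovery class), so trajectory heterogeneity needs no extra person
#' dimensions. With `scale = "raw"` 16 raw items on 0-3 are emitted (the
#' mutually exclusive appetite/weight alternatives held at zero) to exercise
#' the recoding rules.
#'
#' @param n,m,T persons, recoded items, weeks.
#' @param archetype_weights simplex weights of the three person archetypes.
#' @param effect_scale multiplier on the interaction pattern.
#' @param loading_jitter SD of person-loading noise around the archetype
#'   one-hot profile.
#' @param trend_start,trend_slope shared latent trend trend_start -
#'   trend_slope (t - 1).
#' @param noise_sd latent white-noise SD.
#' @param cutpoints increasing thresholds mapping the latent scale to
#'   {0,1,2} (recoded) or {0,1,2,3} (raw).
#' @param scale `"recoded"` (12 items, 0-2) or `"raw"` (16 items, 0-3).
#' @param seed integer seed.
#' @return list: `records` (long data frame), `truth` (archetypes, person
#'   loadings, domains, phases, pattern, trend, latent cube).
#' @export
generate_qids_like <- function(n = 82, m = 12, T = 9,
                               archetype_weights = c(0.50, 0.38, 0.12),
                               effect_scale = 1.9,
                               loading_jitter = 0.30,
                               trend_start = 1.45, trend_slope = 0.22,
                               noise_sd = 0.95,
                               cutpoints = c(0.45, 1.55),
                               scale = c("recoded", "raw"), seed = 1L) {
  scale <- match.arg(scale)
  stopifnot(length(archetype_weights) == 3, all(archetype_weights > 0),
            abs(sum(archetype_weights) - 1) < 1e-8,
            all(diff(cutpoints) > 0), noise_sd >= 0, m == 12, T >= 6)
  items <- qids_item_order()
  domains <- qids_item_domains()
  phases <- ifelse(seq_len(T) <= 5, 1L, 2L)
  W <- qids_archetype_pattern() * effect_scale
  set.seed(derive_seed(seed, 11L))
  arch <- sample.int(3L, n, replace = TRUE, prob = archetype_weights)
  loadings <- diag(3)[arch, , drop = FALSE] +
    matrix(stats::rnorm(n * 3, sd = loading_jitter), n, 3)
  trend <- trend_start - trend_slope * (seq_len(T) - 1)
  # latent[i,j,t] = trend_t + sum_p loadings[i,p] W[p, dom(j), phase(t)] + noise
  latent <- array(0, dim = c(n, m, T))
  for (t in seq_len(T)) {
    Wdt <- W[, , phases[t]]                       # 3 x 2
    eff <- loadings %*% Wdt                        # n x 2
    latent[, , t] <- trend[t] + eff[, domains]
  }
  set.seed(derive_seed(seed, 12L))
  latent <- latent + array(stats::rnorm(n * m * T, sd = noise_sd), dim = dim(latent))

  persons <- sprintf("p%03d", seq_len(n))
  if (scale == "recoded") {
    recs <- expand.grid(person_id = persons, item = items, time = seq_len(T),
                        stringsAsFactors = FALSE)
    sc <- array(0L, dim = dim(latent))
    for (cp in cutpoints) sc <- sc + (latent > cp)
    recs$score <- as.integer(as.vector(sc))
    recs <- sort_records(recs[, c("person_id", "time", "item", "score")])
  } else {
    cuts3 <- c(cutpoints, cutpoints[2] + 1.2)      # scarce top category
    raw_items <- as.character(1:16)
    recs_list <- list()
    set.seed(derive_seed(seed, 13L))
    for (t in seq_len(T)) {
      sl <- latent[, , t]                          # n x 12 recoded-latent
      raw <- matrix(0L, n, 16)
      # hyposomnia: three raw items share the "1-3" latent with extra noise
      for (jr in 1:3) {
        z <- sl[, 1] + stats::rnorm(n, sd = 0.3)
        raw[, jr] <- rowSums(outer(z, cuts3, ">"))
      }
      map <- c("4" = 4, "5" = 5, "6/7" = 6, "8/9" = 8, "10" = 10, "11" = 11,
               "12" = 12, "13" = 13, "14" = 14, "15" = 15, "16" = 16)
      for (id in names(map)) {
        j <- which(items == id)
        raw[, map[[id]]] <- rowSums(outer(sl[, j], cuts3, ">"))
      }
      # items 7 and 9 (the mutually exclusive alternatives) stay zero
      recs_list[[t]] <- data.frame(
        person_id = rep(persons, times = 16),
        time = t,
        item = rep(raw_items, each = n),
        score = as.integer(raw))
    }
    recs <- do.call(rbind, recs_list)
    recs <- recs[order(recs$person_id, recs$time, as.integer(recs$item)), ]
    rownames(recs) <- NULL
  }
  list(records = recs,
       truth = list(archetype = arch, severity_class = ifelse(arch == 3L, 2L, 1L),
                    loadings = loadings, domains = domains, phases = phases,
                    pattern = W, trend = trend, latent = latent))
}

#' Generate ordinal item data from a latent class model
#'
#' @param weights class weights on the simplex.
#' @param item_probs K x m x C array of category probabilities (rows sum to
#'   one over the last index).
#' @param n persons. @param seed integer seed.
#' @return list: `data` (n x m matrix of categories 0..C-1), `classes`.
#' @export
generate_lca_data <- function(weights, item_probs, n, seed = 1L) {
  K <- length(weights)
  stopifnot(is.array(item_probs), length(dim(item_probs)) == 3L,
            dim(item_probs)[1] == K)
  if (abs(sum(weights) - 1) > 1e-8 ||
      max(abs(apply(item_probs, c(1, 2), sum) - 1)) > 1e-8)
    stop_hetcube("probabilities must sum to one", class = "hetcube_invalid_input")
  m <- dim(item_probs)[2]; C <- dim(item_probs)[3]
  set.seed(derive_seed(seed, 21L))
  cls <- sample.int(K, n, replace = TRUE, prob = weights)
  dat <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    p <- item_probs[, j, , drop = FALSE]
    dim(p) <- c(K, C)
    u <- stats::runif(n)
    cum <- t(apply(p, 1, cumsum))                  # K x C
    dat[, j] <- as.integer(rowSums(u > cum[cls, , drop = FALSE]))
  }
  list(data = dat, classes = cls)
}

#' Generate sum-score-like trajectories from a growth mixture
#'
#' Per person: a class drawn from the weights, the class's quadratic mean
#' curve beta0 + beta1 t + beta2 t^2 over t = 1..T, plus a person random
#' intercept with variance tau2 and white noise with variance sigma2.
#'
#' @param weights class weights. @param beta K x 3 matrix of class curves.
#' @param n persons. @param T time points (>= 3).
#' @param sigma2 residual variance (>= 0). @param tau2 random-intercept
#'   variance (>= 0; 0 gives latent-class-growth data).
#' @param seed integer seed.
#' @return list: `data` (n x T matrix), `classes`.
#' @export
generate_growth_data <- function(weights, beta, n, T = 9, sigma2 = 4,
                                 tau2 = 0, seed = 1L) {
  stopifnot(T >= 3, nrow(beta) == length(weights), ncol(beta) == 3)
  if (sigma2 < 0 || tau2 < 0)
    stop_hetcube("variances must be non-negative", class = "hetcube_invalid_input")
  if (abs(sum(weights) - 1) > 1e-8)
    stop_hetcube("class weights must sum to one", class = "hetcube_invalid_input")
  tt <- seq_len(T)
  X <- cbind(1, tt, tt^2)
  set.seed(derive_seed(seed, 31L))
  cls <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  mu <- X %*% t(beta)                              # T x K
  y <- t(mu[, cls, drop = FALSE]) +
    stats::rnorm(n, sd = sqrt(tau2)) +
    matrix(stats::rnorm(n * T, sd = sqrt(sigma2)), n, T)
  list(data = y, classes = cls)
}
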