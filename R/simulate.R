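# Synthetic connectome cohorts with planted low-rank structure.
#
# The generator emulates the data layout the motif analysis assumes: a
# cohort of square nonnegative streamline-count matrices (shared base
# connectome plus sparse orthonormal planted motifs whose subject weights
# carry the signal, plus entrywise noise, clipped at zero and rounded to
# integer counts), together with a behavioral table whose day-1
# performance is coupled to one planted motif's baseline weights and
# whose training gain is coupled to another motif's scan-b-minus-scan-a
# weight change.

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulation parameters for a synthetic connectome cohort
#'
#' Defaults mirror the study design: 28 subjects, three scans (a: before
#' training, b: after, c: 3-week follow-up), 185 regions (180 cortical +
#' 5 callosal parcels) per hemisphere, day-1 double-embedding performance
#' in 58-91% and single-embedding in 67-100%, 33 trials per sentence type
#' per day.
#'
#' The planted-motif amplitude is parameterized through `snr`: the ratio
#' of the planted singular value (`weight_sd * sqrt(n_subjects)`) to the
#' noise spectral edge (`noise_eff * (sqrt(n_features) +
#' sqrt(n_subjects))`, Marchenko-Pastur), so recovery difficulty is
#' controlled directly. Set `weight_sd` explicitly to bypass this.
#'
#' @param n_subjects Number of subjects (default 28).
#' @param n_regions Regions per hemisphere (default 185).
#' @param scans Scan ids (default `c("a", "b", "c")`).
#' @param hemisphere `"left"` or `"right"`.
#' @param n_planted_motifs Number of planted orthonormal motifs
#'   (default 2).
#' @param motif_sparsity Fraction of region pairs in each motif's support
#'   (default 0.02; supports are disjoint, hence motifs orthogonal).
#' @param base_meanlog,base_sdlog Log-normal parameters of the shared
#'   base connectome (default meanlog `log(200)`, sdlog 1: the skewed
#'   dynamic range of probabilistic-tractography counts).
#' @param noise_sd Entrywise Gaussian noise SD on raw counts (default 2).
#' @param snr Planted-motif signal-to-noise ratio as defined above. The
#'   expected overlap between a recovered and a planted motif follows
#'   `1 / sqrt(1 + p / (snr^2 (sqrt(p) + sqrt(n))^2))` for feature count
#'   `p` and `n` columns; the default 5 places a lone planted motif well
#'   inside the recoverable regime (expected cosine about 0.98 at the
#'   default geometry).
#' @param weight_sd SD of planted per-subject weights, scalar or one per
#'   motif; `NULL` (default) derives a common value from `snr`.
#' @param delta_sd SD of the plasticity weight change between scans a and
#'   b; `NULL` derives `weight_sd / 2`.
#' @param behavior_coupling List `(motif, rho)`: which planted motif's
#'   scan-a weight drives day-1 double-embedding performance, and the
#'   latent correlation (default motif 1, rho 0.7). `rho = 0` decouples.
#' @param plasticity_coupling List `(motif, rho)`: which motif's
#'   scan-b-minus-a weight change drives the training gain (default
#'   motif 2 when two or more motifs are planted, else motif 1; rho 0.7).
#'   `rho = 0` disables the planted change entirely.
#' @param perf_range_double,perf_range_single Day-1 performance ranges.
#' @param gain_mean,gain_sd Mean and SD of the double-embedding training
#'   gain (defaults 0.12, 0.06); single-embedding gain is fixed small
#'   (ceiling effect).
#' @param n_trials Trials per sentence type per day (default 33).
#' @param round_counts Round matrix entries to integers (default TRUE).
#' @param mode Feature space in which motifs are planted (default
#'   `"symmetric"`).
#' @param seed RNG seed (default 1).
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_subjects = 28L, n_regions = 185L,
                              scans = c("a", "b", "c"),
                              hemisphere = "left",
                              n_planted_motifs = 2L,
                              motif_sparsity = 0.02,
                              base_meanlog = log(200), base_sdlog = 1,
                              noise_sd = 2, snr = 5,
                              weight_sd = NULL, delta_sd = NULL,
                              behavior_coupling = NULL,
                              plasticity_coupling = NULL,
                              perf_range_double = c(0.58, 0.91),
                              perf_range_single = c(0.67, 1.00),
                              gain_mean = 0.12, gain_sd = 0.06,
                              n_trials = 33L, round_counts = TRUE,
                              mode = c("symmetric", "full"),
                              seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_subjects >= 2L, n_regions >= 3L, length(scans) >= 1L,
            noise_sd >= 0, motif_sparsity > 0, motif_sparsity <= 1,
            all(perf_range_double >= 0), all(perf_range_double <= 1),
            all(perf_range_single >= 0), all(perf_range_single <= 1))
  if (is.null(behavior_coupling)) {
    behavior_coupling <- list(motif = 1L, rho = 0.7)
  }
  if (is.null(plasticity_coupling)) {
    plasticity_coupling <- list(motif = min(2L, n_planted_motifs),
                                rho = 0.7)
  }
  for (cp in list(behavior_coupling, plasticity_coupling)) {
    if (!is.null(cp) && cp$rho != 0 &&
        (cp$motif < 1L || cp$motif > n_planted_motifs)) {
      stop("coupling references a motif that is not planted", call. = FALSE)
    }
  }
  p_feat <- n_regions * (n_regions - 1L) / 2
  noise_eff <- sqrt(noise_sd^2 / 2 + if (round_counts) 1 / 24 else 0)
  if (is.null(weight_sd)) {
    edge <- noise_eff * (sqrt(p_feat) + sqrt(n_subjects))
    top <- if (noise_eff > 0) snr * edge / sqrt(n_subjects) else 1
    # decaying amplitudes, as in empirical SVD spectra; equal-amplitude
    # motifs would only be identifiable up to a rotation of the pair
    weight_sd <- top * 0.6^(seq_len(n_planted_motifs) - 1L)
  }
  weight_sd <- rep_len(weight_sd, n_planted_motifs)
  if (is.null(delta_sd)) delta_sd <- weight_sd[1L] / 2
  structure(list(
    n_subjects = as.integer(n_subjects), n_regions = as.integer(n_regions),
    scans = as.character(scans), hemisphere = hemisphere,
    n_planted_motifs = as.integer(n_planted_motifs),
    motif_sparsity = motif_sparsity,
    base_meanlog = base_meanlog, base_sdlog = base_sdlog,
    noise_sd = noise_sd, snr = snr, weight_sd = weight_sd,
    delta_sd = delta_sd,
    behavior_coupling = behavior_coupling,
    plasticity_coupling = plasticity_coupling,
    perf_range_double = perf_range_double,
    perf_range_single = perf_range_single,
    gain_mean = gain_mean, gain_sd = gain_sd,
    n_trials = as.integer(n_trials), round_counts = round_counts,
    mode = mode, seed = as.integer(seed)), class = "simulation_params")
}

# draw K unit-norm feature vectors with disjoint sparse supports
.plant_motifs <- function(p_feat, k, sparsity) {
  support_size <- max(2L, round(sparsity * p_feat))
  if (k * support_size > p_feat) {
    stop("planted motifs do not fit: reduce sparsity or motif count",
         call. = FALSE)
  }
  pool <- sample.int(p_feat, k * support_size)
  motifs <- matrix(0, p_feat, k)
  for (j in seq_len(k)) {
    idx <- pool[((j - 1L) * support_size + 1L):(j * support_size)]
    v <- stats::rnorm(support_size)
    motifs[idx, j] <- v / sqrt(sum(v^2))
  }
  motifs
}

# map a standard-normal latent monotonically into [lo, hi]
.latent_to_range <- function(latent, lo, hi) lo + (hi - lo) * stats::pnorm(latent)

# split a target proportion into (correct, incorrect, missed) counts
.counts_from_performance <- function(p, n_trials) {
  n_correct <- round(n_trials * p)
  n_correct <- pmin(pmax(n_correct, 0L), n_trials)
  rest <- n_trials - n_correct
  n_missed <- stats::rbinom(length(rest), rest, 0.2)
  data.frame(n_correct = n_correct, n_incorrect = rest - n_missed,
             n_missed = n_missed)
}

#' Generate a synthetic cohort with planted motifs
#'
#' Builds `matrix(subject, scan) = base + sum_k w[s, scan, k] * motif_k +
#' noise`, clipped at zero and rounded to integer streamline counts, plus
#' a behavioral table whose day-1 double-embedding performance tracks the
#' behavior-coupled motif's scan-a weight (latent correlation
#' `behavior_coupling$rho`) and whose day-4-minus-day-1 gain tracks the
#' plasticity-coupled motif's scan-b-minus-a weight change
#' (`plasticity_coupling$rho`). Fully reproducible from `params$seed`;
#' the caller's RNG state is untouched.
#'
#' @param params A [simulation_params()] object.
#' @param weights_a Optional `n_subjects x n_planted_motifs` matrix of
#'   scan-a weights, overriding the random draw (for constructed
#'   fixtures).
#' @return List with `cohort` (`connectome_cohort`), `behavior`
#'   (`behavioral_table`), and `truth` (planted `motifs` in feature
#'   space, `weights` array subject x scan x motif, `delta` per-subject
#'   plasticity change, `index_map`, couplings).
#' @export
generate_cohort <- function(params = simulation_params(),
                            weights_a = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  .with_seed(params$seed, {
    d <- params$n_regions
    parc <- default_parcellation(params$hemisphere,
                                 n_cortical = d - min(5L, d - 2L),
                                 n_callosal = min(5L, d - 2L))
    labels <- parc$labels
    im <- feature_index_map(labels, "symmetric")
    p_feat <- nrow(im)
    K <- params$n_planted_motifs
    base <- stats::rlnorm(p_feat, params$base_meanlog, params$base_sdlog)
    motifs <- .plant_motifs(p_feat, K, params$motif_sparsity)
    n <- params$n_subjects
    subjects <- sprintf("S%02d", seq_len(n))
    scans <- params$scans
    if (is.null(weights_a)) {
      weights_a <- matrix(stats::rnorm(n * K), n, K) %*%
        diag(params$weight_sd, K)
    } else {
      weights_a <- as.matrix(weights_a)
      stopifnot(nrow(weights_a) == n, ncol(weights_a) == K)
    }
    pc <- params$plasticity_coupling
    plastic <- !is.null(pc) && pc$rho != 0
    delta <- if (plastic) stats::rnorm(n, 0, params$delta_sd) else rep(0, n)
    weights <- array(0, dim = c(n, length(scans), K),
                     dimnames = list(subjects, scans, NULL))
    for (si in seq_along(scans)) weights[, si, ] <- weights_a
    if (plastic) {
      for (scan_later in intersect(c("b", "c"), scans)) {
        weights[, scan_later, pc$motif] <-
          weights[, scan_later, pc$motif] + delta
      }
    }
    matrices <- vector("list", n * length(scans))
    mi <- 0L
    for (scan in scans) {
      for (s in seq_len(n)) {
        feat <- base + as.numeric(motifs %*% weights[s, scan, ])
        m <- unvectorize(feat, im, labels = labels)
        if (params$noise_sd > 0) {
          m <- m + matrix(stats::rnorm(d * d, 0, params$noise_sd), d, d)
        }
        m[m < 0] <- 0
        if (params$round_counts) m <- round(m)
        diag(m) <- 0
        mi <- mi + 1L
        matrices[[mi]] <- connectivity_matrix(m, subjects[s], scan,
                                              params$hemisphere,
                                              labels = labels)
      }
    }
    cohort <- connectome_cohort(parc, matrices, subjects = subjects,
                                scans = scans)

    # behavior: latent-normal couplings mapped monotonically into the
    # configured performance ranges, then quantized to trial counts
    bc <- params$behavior_coupling
    z_noise1 <- stats::rnorm(n)
    if (!is.null(bc) && bc$rho != 0) {
      zw <- as.numeric(scale(weights_a[, bc$motif]))
      latent1 <- bc$rho * zw + sqrt(1 - bc$rho^2) * z_noise1
    } else {
      latent1 <- z_noise1
    }
    day1_double <- .latent_to_range(latent1, params$perf_range_double[1L],
                                    params$perf_range_double[2L])
    z_noise_g <- stats::rnorm(n)
    if (plastic) {
      zd <- as.numeric(scale(delta))
      latent_g <- pc$rho * zd + sqrt(1 - pc$rho^2) * z_noise_g
    } else {
      latent_g <- z_noise_g
    }
    gain_double <- params$gain_mean + params$gain_sd * latent_g
    day4_double <- pmin(pmax(day1_double + gain_double, 0.02), 0.995)
    day1_single <- .latent_to_range(stats::rnorm(n),
                                    params$perf_range_single[1L],
                                    params$perf_range_single[2L])
    day4_single <- pmin(day1_single + 0.03 + 0.02 * stats::rnorm(n), 0.999)
    recs <- list()
    for (s in seq_len(n)) {
      for (type in c("single", "double")) {
        p1 <- if (type == "double") day1_double[s] else day1_single[s]
        p4 <- if (type == "double") day4_double[s] else day4_single[s]
        pday <- pmin(pmax(
          p1 + (p4 - p1) * c(0, 1 / 3, 2 / 3, 1) +
            c(0, stats::rnorm(2, 0, 0.02), 0), 0.01), 0.999)
        cts <- .counts_from_performance(pday, params$n_trials)
        recs[[length(recs) + 1L]] <-
          data.frame(subject = subjects[s], day = 1:4,
                     sentence_type = type, cts,
                     stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, recs)
    # reading span loosely tracks single-embedding ability; digit span free
    spans <- data.frame(
      subject = subjects,
      reading_span = round(2 + 3 * stats::pnorm(
        0.3 * as.numeric(scale(day1_single)) +
          sqrt(1 - 0.09) * stats::rnorm(n)), 1),
      digit_span = round(stats::runif(n, 5, 9), 1),
      stringsAsFactors = FALSE)
    behavior <- behavioral_table(records, spans)
    truth <- list(motifs = motifs, weights = weights, delta = delta,
                  base = base, index_map = im,
                  behavior_coupling = bc,
                  plasticity_coupling = pc)
    list(cohort = cohort, behavior = behavior, truth = truth)
  })
}

#' Generate a null cohort (no behavior coupling, no plasticity)
#'
#' As [generate_cohort()] but with both couplings zeroed: behavior is
#' statistically independent of every motif weight and scans differ only
#' by noise. Used for type-I-error studies.
#'
#' @param params A [simulation_params()] object; its couplings are
#'   overridden to zero.
#' @return List with `cohort` and `behavior` (and the planted `truth`,
#'   whose couplings are null).
#' @export
generate_null_cohort <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  params$behavior_coupling$rho <- 0
  params$plasticity_coupling$rho <- 0
  generate_cohort(params)
}

#' Write a generated cohort with its behavioral table
#'
#' Writes the cohort via [write_cohort()] plus `behavior.tsv` and
#' `spans.tsv`, producing a directory that [load_cohort()] and
#' [read_behavior()] can round-trip losslessly.
#'
#' @param cohort A `connectome_cohort`.
#' @param behavior A `behavioral_table`.
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_cohort_with_behavior <- function(cohort, behavior, dir) {
  manifest <- write_cohort(cohort, dir)
  write_behavior(behavior, file.path(dir, "behavior.tsv"),
                 if (!is.null(behavior$spans)) file.path(dir, "spans.tsv"))
  invisible(manifest)
}
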