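# Synthetic data: coupled band-limited oscillators for the spectral
# pipeline, and a two-timepoint cohort with a known centrality -> EF
# effect for the statistics pipeline.

# One global seed fans out to per-component substreams via a counter, so
# adding a component never perturbs the draws of another.
substream_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + counter * 16807) %% 2147483647)
}

band_limited_noise <- function(n, f_lo, f_hi, fs) {
  x <- stats::rnorm(n)
  f <- dft_bin_freqs(n, fs)
  mask <- f >= f_lo & f < f_hi
  if (!any(mask)) stop("band [", f_lo, ", ", f_hi, ") contains no DFT bin for n = ", n)
  X <- stats::fft(x)
  X[!mask] <- 0
  y <- Re(stats::fft(X, inverse = TRUE) / n)
  y / stats::sd(y)
}

# rotate every spectral component by -lag radians (a constant phase lag
# across the band): positive-frequency bins times exp(-i lag).
phase_lagged <- function(x, lag) {
  n <- length(x)
  X <- stats::fft(x)
  k <- 0:(n - 1L)
  rot <- ifelse(k == 0 | (n %% 2L == 0L & k == n / 2L), 1 + 0i,
                ifelse(k < n / 2, exp(-1i * lag), exp(1i * lag)))
  Re(stats::fft(X * rot, inverse = TRUE) / n)
}

#' Specification for coupled-oscillator source simulation
#'
#' Describes a multichannel recording with planted band-specific phase
#' coupling: per band, an edge list of region pairs sharing a common
#' band-limited carrier with a constant phase lag.
#'
#' @param n_regions Number of regions N (default 78, a standard cortical
#'   parcellation).
#' @param fs Sampling frequency in Hz (default 1250).
#' @param n_samples Recording length in samples (default 245760 = 60
#'   epochs of 4096).
#' @param bands Band catalogue (default [default_bands()]).
#' @param coupling Named list keyed by band name; each element a data
#'   frame with columns `i`, `j` (1-based region indices), `strength` in
#'   `[0, 1]` and `lag` in `(-pi, pi]`.
#' @param noise_sd Standard deviation of the added broadband white noise
#'   (default 1).
#' @param seed Mandatory integer seed.
#' @return A `coupling_spec` object.
#' @export
coupling_spec <- function(n_regions = 78L, fs = 1250, n_samples = 245760L,
                          bands = default_bands(), coupling = list(),
                          noise_sd = 1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  n_regions <- as.integer(n_regions)
  stopifnot(n_regions >= 2L, fs > 0, n_samples >= 2L, noise_sd >= 0)
  bad_band <- setdiff(names(coupling), names(bands))
  if (length(bad_band)) stop("coupling refers to unknown band(s): ",
                             paste(bad_band, collapse = ", "))
  for (bn in names(coupling)) {
    edges <- coupling[[bn]]
    stopifnot(is.data.frame(edges),
              all(c("i", "j", "strength", "lag") %in% names(edges)))
    if (any(edges$i < 1 | edges$i > n_regions |
            edges$j < 1 | edges$j > n_regions)) {
      stop("coupling edge in band '", bn, "' references a region outside 1..",
           n_regions)
    }
    if (any(edges$i == edges$j)) stop("self-coupling not allowed (band '", bn, "')")
    if (any(edges$strength < 0 | edges$strength > 1)) {
      stop("coupling strengths must lie in [0, 1]")
    }
    if (any(edges$lag <= -pi | edges$lag > pi)) {
      stop("lags must lie in (-pi, pi]")
    }
  }
  structure(list(n_regions = n_regions, fs = fs,
                 n_samples = as.integer(n_samples), bands = bands,
                 coupling = coupling, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "coupling_spec")
}

#' Simulate multichannel sources with planted phase coupling
#'
#' Every region receives, in every band, an independent band-limited
#' Gaussian component (FFT-masked white noise, unit SD). For each coupling
#' edge `(i, j, strength s, lag)` the band component of the pair is
#' replaced by a shared carrier: region i gets
#' `s * c + sqrt(1 - s^2) * indep_i` and region j the same mixture of the
#' phase-lagged carrier, so the expected PLI of the pair is monotone in
#' `s` and the planted phase difference is constant across the band.
#' Broadband white noise of `noise_sd` is added to every channel. Output
#' is a pure function of the spec (same seed, same bits).
#'
#' @param spec A [coupling_spec].
#' @return A [time_series].
#' @export
simulate_sources <- function(spec) {
  stopifnot(inherits(spec, "coupling_spec"))
  n <- spec$n_samples
  N <- spec$n_regions
  out <- matrix(0, n, N)
  counter <- 0L
  for (bi in seq_along(spec$bands)) {
    band <- spec$bands[[bi]]
    edges <- spec$coupling[[band$name]]
    comp <- matrix(0, n, N)
    # independent band-limited component per region
    for (r in seq_len(N)) {
      counter <- counter + 1L
      set.seed(substream_seed(spec$seed, counter))
      comp[, r] <- band_limited_noise(n, band$f_lo, band$f_hi, spec$fs)
    }
    if (!is.null(edges) && nrow(edges) > 0L) {
      for (e in seq_len(nrow(edges))) {
        counter <- counter + 1L
        set.seed(substream_seed(spec$seed, counter))
        carrier <- band_limited_noise(n, band$f_lo, band$f_hi, spec$fs)
        s <- edges$strength[e]
        i <- edges$i[e]; j <- edges$j[e]
        comp[, i] <- s * carrier + sqrt(1 - s^2) * comp[, i]
        comp[, j] <- s * phase_lagged(carrier, edges$lag[e]) +
          sqrt(1 - s^2) * comp[, j]
      }
    }
    out <- out + comp
  }
  counter <- counter + 1L
  set.seed(substream_seed(spec$seed, counter))
  out <- out + matrix(stats::rnorm(n * N, sd = spec$noise_sd), n, N)
  time_series(out, fs = spec$fs,
              region_labels = paste0("R", seq_len(N)))
}

#' Specification for a synthetic two-timepoint cohort
#'
#' Describes a cohort whose executive-function (EF) Z-score depends
#' linearly on frontoparietal multilayer centrality with a configurable
#' standardized effect size, plus categorical and continuous covariates
#' and Gaussian noise. Centrality is drawn on the scale typical of
#' max-normalized multilayer eigenvector centrality averaged over a
#' frontoparietal set (mean 0.41, SD 0.10); that scale is cosmetic, all
#' planted effects are standardized.
#'
#' @param n_subjects Number of subjects (>= 10; default 37).
#' @param beta_ec Standardized effect of T1 centrality on the target EF
#'   score (default 0.4).
#' @param ec_change_coupling Standardized effect linking the T2-T1
#'   centrality change to the EF change (default 0.4).
#' @param target_ef Which EF score carries the planted effect (default
#'   `"ef_set_shifting"`); the other scores are pure noise plus covariate
#'   effects.
#' @param covariate_effects Named numeric vector of standardized covariate
#'   effects on the target EF score (defaults: epilepsy -0.3, others 0).
#'   Names must be covariates the generator declares: `epilepsy`,
#'   `subtype`, `treatment`, `interval_resection_npa`, `age`.
#' @param ec_mean,ec_sd Moments of T1 centrality (defaults 0.41, 0.10).
#' @param noise_sd Residual SD of the EF scores (default: chosen so the
#'   target score has approximately unit variance).
#' @param seed Mandatory integer seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects = 37L, beta_ec = 0.4,
                        ec_change_coupling = 0.4,
                        target_ef = "ef_set_shifting",
                        covariate_effects = c(epilepsy = -0.3),
                        ec_mean = 0.41, ec_sd = 0.10,
                        noise_sd = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 10L) stop("n_subjects must be >= 10")
  declared <- c("epilepsy", "subtype", "treatment",
                "interval_resection_npa", "age")
  bad <- setdiff(names(covariate_effects), declared)
  if (length(bad)) {
    stop("covariate effect(s) for undeclared covariate(s): ",
         paste(bad, collapse = ", "))
  }
  if (is.null(noise_sd)) {
    explained <- beta_ec^2 + sum(covariate_effects^2)
    noise_sd <- sqrt(max(1 - explained, 0.1))
  }
  structure(list(n_subjects = n_subjects, beta_ec = beta_ec,
                 ec_change_coupling = ec_change_coupling,
                 target_ef = target_ef,
                 covariate_effects = covariate_effects,
                 ec_mean = ec_mean, ec_sd = ec_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a two-timepoint cohort with a known centrality -> EF effect
#'
#' Per subject: latent frontoparietal centrality at T1 is
#' `Normal(ec_mean, ec_sd)`; T2 centrality adds a small drift (SD one
#' half of `ec_sd`, zero mean). The target EF Z-score at T1 is a linear
#' combination of standardized centrality, standardized covariate
#' effects, and Gaussian noise; its T2 value adds `ec_change_coupling`
#' times the standardized centrality change plus fresh noise. The
#' remaining EF scores are covariate effects plus noise only. Categorical
#' covariates mirror a realistic glioma cohort (epilepsy prevalence ~0.9,
#' three molecular subtypes, four treatment arms); intervals are months.
#'
#' @param spec A [cohort_spec].
#' @return Long-format data frame, one row per subject x timepoint:
#'   `subject_id`, `timepoint`, `ec_fpn`, `ef_set_shifting`,
#'   `ef_word_fluency`, `ef_inhibition`, `epilepsy`, `subtype`,
#'   `treatment`, `interval_resection_npa`, `age`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  draw <- function(counter, expr) {
    set.seed(substream_seed(spec$seed, counter))
    expr()
  }
  ec_t1 <- draw(1L, function() stats::rnorm(n, spec$ec_mean, spec$ec_sd))
  drift <- draw(2L, function() stats::rnorm(n, 0, spec$ec_sd / 2))
  ec_t2 <- ec_t1 + drift
  epilepsy <- draw(3L, function()
    sample(c("yes", "no"), n, replace = TRUE, prob = c(0.89, 0.11)))
  subtype <- draw(4L, function()
    sample(c("IDH-wildtype", "IDH-mutant-noncodeleted", "IDH-mutant-codeleted"),
           n, replace = TRUE, prob = c(6, 14, 16) / 36))
  treatment <- draw(5L, function()
    sample(c("radiotherapy", "chemoradiation", "radio-then-chemo", "none"),
           n, replace = TRUE, prob = c(4, 6, 14, 13) / 37))
  interval_npa <- draw(6L, function() stats::rnorm(n, 12, 2.5))
  age <- draw(7L, function() stats::rnorm(n, 41.7, 12.3))

  std <- function(v) (v - mean(v)) / stats::sd(v)
  cov_term <- numeric(n)
  eff <- spec$covariate_effects
  cov_numeric <- list(
    epilepsy = as.numeric(epilepsy == "yes"),
    subtype = as.numeric(factor(subtype)),
    treatment = as.numeric(factor(treatment)),
    interval_resection_npa = interval_npa,
    age = age
  )
  for (nm in names(eff)) {
    v <- cov_numeric[[nm]]
    if (stats::sd(v) > 0) cov_term <- cov_term + eff[[nm]] * std(v)
  }

  ef_names <- c("ef_set_shifting", "ef_word_fluency", "ef_inhibition")
  if (!spec$target_ef %in% ef_names) {
    stop("target_ef must be one of: ", paste(ef_names, collapse = ", "))
  }
  ef_t1 <- ef_t2 <- list()
  counter <- 8L
  d_ec_std <- if (stats::sd(drift) > 0) std(drift) else drift
  for (nm in ef_names) {
    counter <- counter + 1L
    e1 <- draw(counter, function() stats::rnorm(n, 0, spec$noise_sd))
    counter <- counter + 1L
    e2 <- draw(counter, function() stats::rnorm(n, 0, spec$noise_sd))
    base <- cov_term
    if (nm == spec$target_ef) {
      t1 <- base + spec$beta_ec * std(ec_t1) + e1
      t2 <- t1 + spec$ec_change_coupling * d_ec_std + e2
    } else {
      t1 <- base + e1
      t2 <- t1 + e2
    }
    ef_t1[[nm]] <- t1
    ef_t2[[nm]] <- t2
  }

  ids <- sprintf("S%03d", seq_len(n))
  one_tp <- function(tp, ec, ef) {
    data.frame(subject_id = ids, timepoint = tp, ec_fpn = ec,
               ef_set_shifting = ef$ef_set_shifting,
               ef_word_fluency = ef$ef_word_fluency,
               ef_inhibition = ef$ef_inhibition,
               epilepsy = epilepsy, subtype = subtype, treatment = treatment,
               interval_resection_npa = interval_npa, age = age,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_tp("T1", ec_t1, ef_t1), one_tp("T2", ec_t2, ef_t2))
  rownames(out) <- NULL
  out
}

#' Simulate a complete study: recordings plus cohort scores
#'
#' Convenience wrapper for end-to-end runs: generates one coupled-source
#' recording per subject per timepoint (sized to the config's epoching:
#' `epoch_length * max_epochs` samples at `fs_hz`), with a fixed planted
#' coupling topology (three lower-alpha edges among the first regions,
#' strength 0.8, lag pi/4), and a two-timepoint cohort supplying EF
#' Z-scores and covariates.
#'
#' @param config A [pipeline_config].
#' @param n_subjects Number of subjects (default 10).
#' @param n_regions Regions per recording (default 12).
#' @param seed Integer seed.
#' @return List: `recordings` (nested subject -> timepoint ->
#'   [time_series]), `ef_scores`, `covariates`, `cohort` (the generator's
#'   own table, including its latent centrality).
#' @export
simulate_study <- function(config, n_subjects = 10L, n_regions = 12L, seed = 1L) {
  stopifnot(inherits(config, "pipeline_config"))
  n_samples <- config$epoch_length * config$max_epochs
  edges <- data.frame(i = c(1L, 2L, 3L), j = c(2L, 3L, 4L),
                      strength = 0.8, lag = pi / 4)
  edges <- edges[edges$j <= n_regions, , drop = FALSE]
  band_cat <- config$bands
  alpha_band <- if ("alpha1" %in% names(band_cat)) "alpha1" else names(band_cat)[1]
  cohort <- simulate_cohort(cohort_spec(n_subjects = max(n_subjects, 10L),
                                        seed = substream_seed(seed, 999L)))
  cohort <- cohort[cohort$subject_id %in%
                     sprintf("S%03d", seq_len(n_subjects)), , drop = FALSE]
  recordings <- list()
  k <- 0L
  for (sid in unique(cohort$subject_id)) {
    recordings[[sid]] <- list()
    for (tp in c("T1", "T2")) {
      k <- k + 1L
      spec <- coupling_spec(
        n_regions = n_regions, fs = config$fs_hz, n_samples = n_samples,
        bands = band_cat,
        coupling = stats::setNames(list(edges), alpha_band),
        seed = substream_seed(seed, k))
      recordings[[sid]][[tp]] <- simulate_sources(spec)
    }
  }
  ef_cols <- grep("^ef_", names(cohort), value = TRUE)
  ef_scores <- cohort[, c("subject_id", "timepoint", ef_cols)]
  cov_cols <- c("epilepsy", "subtype", "treatment",
                "interval_resection_npa", "age")
  covariates <- unique(cohort[cohort$timepoint == "T1",
                              c("subject_id", cov_cols)])
  list(recordings = recordings, ef_scores = ef_scores,
       covariates = covariates, cohort = cohort)
}
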