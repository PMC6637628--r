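#' Configuration for the synthetic arthritis-cohort simulator
#'
#' Builds and validates the parameter set for [simulate_cohort()]. The
#' defaults emulate the study design the pipeline targets: four groups
#' (untreated normal controls, the disease model, a methotrexate arm and a
#' probiotic arm) of seven rats each, sampled at five timepoints, with a
#' compositional species profile whose "disease" community drifts away from
#' the healthy centroid in the model group and partially reverts under
#' treatment.
#'
#' @param n_rats_per_group rats per group; default 7.
#' @param groups ordered group labels; the first is the healthy reference
#'   and the second the untreated disease model.
#' @param timepoints ordered timepoint labels; the first is baseline.
#' @param n_species number of simulated species; default 200.
#' @param n_signal_species number of planted species whose abundances
#'   linearly drive the arthritis score; default 5.
#' @param n_drift_species total species (including the signal set) whose
#'   abundance drifts with disease; default 40.
#' @param signal_effect score units per z-unit of a signal species' log
#'   abundance; default 0.6, scaled so diseased scores span the 0-16
#'   clinical scale without saturating it.
#' @param drift_magnitude fractional abundance shift per timepoint step in
#'   the model group (a species drifting up is multiplied by
#'   `1 + drift_magnitude` per step); default 1, i.e. 16-fold over the
#'   four steps to the final timepoint.
#' @param reversion_fraction fraction of the model-group drift undone in
#'   the treated groups by the final timepoint, in `[0, 1]`; default 0.7.
#'   The treatment effect sets in progressively (zero at baseline, growing
#'   quadratically to this value), emulating a therapy that needs time to
#'   act: treated communities track the disease early and revert late.
#' @param severity_sd SD of the per-rat lognormal disease-severity
#'   multiplier applied to the drift of diseased animals; default 0.1.
#'   This makes sicker animals more dysbiotic and higher-scoring within a
#'   group while keeping the disease-group cluster compact enough that its
#'   fitted plane stays informative about severity.
#' @param response_sd SD of the per-rat treatment response in the treated
#'   groups; default 0.3. Each treated rat draws its own final reversion
#'   from a Beta distribution with mean `reversion_fraction` and this SD,
#'   so a group contains responders lying near the healthy community and
#'   non-responders remaining near the disease community. Set to 0 for a
#'   homogeneous response.
#' @param noise_sd per-sample log10-abundance noise SD; default 0.2.
#' @param score_baseline,score_max,score_noise_sd arthritis-score
#'   generation: diseased-group mean, clip ceiling (0-16 clinical scale)
#'   and noise SD.
#' @param cytokine_couplings data.frame (`signal_index`, `cytokine`,
#'   `sign`, `strength`) coupling cytokine concentrations to signal-species
#'   z-scores; `signal_index` indexes into the planted signal set. Default:
#'   the first three signal species positively coupled to IL17, IL1b and
#'   TNFa with strength 15.
#' @param cytokine_base,cytokine_noise_sd baseline concentration (pg/ml
#'   scale) and lognormal noise SD for all six cytokines.
#' @param n_kos,n_modules size of the simulated KO table and its module
#'   map.
#' @param ko_shifts data.frame (`module`, `group`, `factor`) of planted
#'   multiplicative module shifts at the final timepoint. Default: the
#'   first module x4 up and the second x1/4 down in the model group.
#' @param ko_noise_sd log10 noise SD of the KO table; default 0.15.
#' @param seed integer seed; all tables are reproducible from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_rats_per_group = 7,
                       groups = c("normal", "model", "mtx", "lcasei"),
                       timepoints = paste0("TP", 1:5),
                       n_species = 200,
                       n_signal_species = 5,
                       n_drift_species = 40,
                       signal_effect = 0.6,
                       drift_magnitude = 1,
                       reversion_fraction = 0.7,
                       severity_sd = 0.1,
                       response_sd = 0.3,
                       noise_sd = 0.2,
                       score_baseline = 8,
                       score_max = 16,
                       score_noise_sd = 1,
                       cytokine_couplings = NULL,
                       cytokine_base = 50,
                       cytokine_noise_sd = 0.2,
                       n_kos = 200,
                       n_modules = 20,
                       ko_shifts = NULL,
                       ko_noise_sd = 0.15,
                       seed = 1) {
  chk_count <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 ||
        v != round(v))
      stop_gp("invalid %s: must be a positive integer", nm)
  }
  chk_count(n_rats_per_group, "n_rats_per_group")
  chk_count(n_species, "n_species")
  chk_count(n_signal_species, "n_signal_species")
  chk_count(n_drift_species, "n_drift_species")
  chk_count(n_kos, "n_kos")
  chk_count(n_modules, "n_modules")
  if (length(groups) < 2L || anyDuplicated(groups))
    stop_gp("invalid groups: need >= 2 unique labels")
  if (length(timepoints) < 2L || anyDuplicated(timepoints))
    stop_gp("invalid timepoints: need >= 2 unique labels")
  if (n_signal_species > n_drift_species)
    stop_gp("invalid n_signal_species: exceeds n_drift_species")
  if (n_drift_species > n_species)
    stop_gp("invalid n_drift_species: exceeds n_species")
  if (n_modules > n_kos) stop_gp("invalid n_modules: exceeds n_kos")
  if (!is.numeric(reversion_fraction) || reversion_fraction < 0 ||
      reversion_fraction > 1)
    stop_gp("invalid reversion_fraction: must be in [0, 1]")
  if (!is.numeric(response_sd) || length(response_sd) != 1L ||
      is.na(response_sd) || response_sd < 0 ||
      (response_sd > 0 && reversion_fraction > 0 && reversion_fraction < 1 &&
       response_sd^2 >= reversion_fraction * (1 - reversion_fraction)))
    stop_gp("invalid response_sd: must be >= 0 and compatible with reversion_fraction")
  for (nm in c("signal_effect", "drift_magnitude", "severity_sd", "noise_sd",
               "score_baseline", "score_max", "score_noise_sd",
               "cytokine_base", "cytokine_noise_sd", "ko_noise_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop_gp("invalid %s: must be a single nonnegative number", nm)
  }
  if (is.null(cytokine_couplings)) {
    kc <- min(3L, n_signal_species)
    cytokine_couplings <- data.frame(
      signal_index = seq_len(kc),
      cytokine = c("IL17", "IL1b", "TNFa")[seq_len(kc)],
      sign = 1, strength = 15, stringsAsFactors = FALSE)
  }
  if (!all(c("signal_index", "cytokine", "sign", "strength") %in%
           names(cytokine_couplings)))
    stop_gp("invalid cytokine_couplings: need signal_index, cytokine, sign, strength")
  if (any(cytokine_couplings$signal_index > n_signal_species))
    stop_gp("invalid cytokine_couplings: signal_index exceeds n_signal_species")
  if (is.null(ko_shifts)) {
    ko_shifts <- data.frame(
      module = c("M0001", "M0002"),
      group = groups[2],
      factor = c(4, 0.25), stringsAsFactors = FALSE)
  }
  if (!all(c("module", "group", "factor") %in% names(ko_shifts)))
    stop_gp("invalid ko_shifts: need module, group, factor")
  if (any(ko_shifts$factor <= 0))
    stop_gp("invalid ko_shifts: factors must be positive")
  if (!all(ko_shifts$group %in% groups))
    stop_gp("invalid ko_shifts: unknown group label")
  chk_count(seed, "seed")
  structure(list(n_rats_per_group = n_rats_per_group, groups = groups,
                 timepoints = timepoints, n_species = n_species,
                 n_signal_species = n_signal_species,
                 n_drift_species = n_drift_species,
                 signal_effect = signal_effect,
                 drift_magnitude = drift_magnitude,
                 reversion_fraction = reversion_fraction,
                 severity_sd = severity_sd,
                 response_sd = response_sd,
                 noise_sd = noise_sd, score_baseline = score_baseline,
                 score_max = score_max, score_noise_sd = score_noise_sd,
                 cytokine_couplings = cytokine_couplings,
                 cytokine_base = cytokine_base,
                 cytokine_noise_sd = cytokine_noise_sd,
                 n_kos = n_kos, n_modules = n_modules,
                 ko_shifts = ko_shifts, ko_noise_sd = ko_noise_sd,
                 seed = seed),
            class = "sim_config")
}

cytokine_names <- c("IL17", "IL1b", "TNFa", "IL6", "IFNg", "IL2")

#' Default KO-to-module map for simulated tables
#'
#' Partitions `n_kos` KO ids (`K00001`, ...) evenly into `n_modules`
#' modules (`M0001`, ...).
#'
#' @param n_kos,n_modules table geometry.
#' @return named list module id -> KO ids.
#' @export
default_module_map <- function(n_kos = 200, n_modules = 20) {
  kos <- sprintf("K%05d", seq_len(n_kos))
  split(kos, sprintf("M%04d", rep_len(seq_len(n_modules),
                                      n_kos)[order(rep_len(seq_len(n_modules), n_kos))]))
}

#' Simulate a complete longitudinal arthritis cohort
#'
#' Generates, from one seed, the four linked tables the pipeline consumes:
#' a compositional species profile (each sample closed to 100%), per-sample
#' metadata with arthritis scores, body weights and six serum cytokines, a
#' KO table with planted module shifts, and the ground truth needed to
#' score recovery.
#'
#' The generative model: each species has a lognormal baseline; a "disease"
#' subset drifts multiplicatively per timepoint step in the model group
#' (direction +/-), scaled per animal by a lognormal severity multiplier.
#' Treated groups experience the same drift attenuated by a treatment
#' effect that grows quadratically from zero at baseline to
#' `reversion_fraction` at the final timepoint, so at the final timepoint
#' they sit at `(1 - reversion_fraction)` of the model-group displacement.
#' The healthy group does not drift. The arthritis score of a diseased rat
#' is `score_baseline + sum(signal_effect * z)` over the planted signal
#' species (z-scores of latent log abundance across diseased samples) plus
#' noise, clipped to `[0, score_max]`; healthy animals score 0. Cytokines
#' are lognormal baselines plus linear couplings to designated signal
#' species.
#'
#' @param config a [sim_config()].
#' @return list with `profile` (samples x species matrix), `metadata`
#'   (data.frame), `ko` (samples x KOs matrix), `module_map`, and
#'   `ground_truth` (list: `signal_species`, `drift_directions`,
#'   `score_weights`, `cytokine_couplings`, `ko_shifts`).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop_gp("config must be a sim_config")
  set.seed(config$seed)
  sub_seeds <- sample.int(2^31 - 1, 4)

  ng <- length(config$groups)
  nt <- length(config$timepoints)
  nr <- config$n_rats_per_group
  p <- config$n_species

  meta <- expand.grid(timepoint = config$timepoints,
                      rat_in_group = seq_len(nr),
                      group = config$groups,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$rat_id <- sprintf("%s_r%02d", meta$group, meta$rat_in_group)
  meta$sample_id <- sprintf("%s_%s", meta$rat_id, meta$timepoint)
  meta$tp_index <- match(meta$timepoint, config$timepoints)
  n <- nrow(meta)

  species <- sprintf("k__Bacteria|g__SimGenus%02d|s__sim_species_%03d",
                     rep_len(seq_len(20), p)[seq_len(p)], seq_len(p))

  # latent log10 abundances: baseline + disease drift + noise
  set.seed(sub_seeds[1])
  base <- stats::rnorm(p, mean = 0, sd = 1.2)
  drift_idx <- sample.int(p, config$n_drift_species)
  signal_idx <- drift_idx[seq_len(config$n_signal_species)]
  dirs <- numeric(p)
  dirs[drift_idx] <- sample(c(-1, 1), config$n_drift_species, replace = TRUE)
  dirs[signal_idx] <- 1  # signal species rise with disease (nonneg selection)
  step <- log10(1 + config$drift_magnitude) * dirs

  # per-sample drift multiplier: timepoint progression x treatment
  # attenuation (progressive, reaching reversion_fraction at the final
  # timepoint) x per-rat severity
  diseased_groups <- config$groups[-1]
  treated_groups <- config$groups[-(1:2)]
  rat_ids <- unique(meta$rat_id)
  sev <- stats::setNames(exp(stats::rnorm(length(rat_ids),
                                          sd = config$severity_sd)),
                         rat_ids)
  # per-rat final reversion: Beta with mean reversion_fraction, sd response_sd
  revr <- stats::setNames(rep(0, length(rat_ids)), rat_ids)
  treated_rats <- rat_ids[sub("_r[0-9]+$", "", rat_ids) %in% treated_groups]
  m <- config$reversion_fraction
  s2 <- config$response_sd^2
  if (s2 > 0 && m > 0 && m < 1) {
    nu <- m * (1 - m) / s2 - 1
    revr[treated_rats] <- stats::rbeta(length(treated_rats),
                                       m * nu, (1 - m) * nu)
  } else {
    revr[treated_rats] <- m
  }
  # quadratic onset: little treatment effect early, full reversion at the
  # final timepoint, so treated communities revert late rather than merely
  # drifting slower
  tfrac <- ((meta$tp_index - 1) / (nt - 1))^2
  treat_eff <- 1 - revr[meta$rat_id] * tfrac
  gfac <- ifelse(meta$group %in% diseased_groups,
                 (meta$tp_index - 1) * treat_eff * sev[meta$rat_id], 0)

  L <- matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
  L <- L + matrix(base, n, p, byrow = TRUE) + outer(gfac, step)
  ab <- 10^L
  profile <- ab / rowSums(ab) * 100
  dimnames(profile) <- list(meta$sample_id, species)

  # arthritis score from latent signal-species z-scores (diseased animals)
  set.seed(sub_seeds[2])
  diseased <- meta$group != config$groups[1]
  zsig <- scale(L[diseased, signal_idx, drop = FALSE])
  zsig[is.nan(zsig)] <- 0
  raw <- config$score_baseline +
    zsig %*% rep(config$signal_effect, length(signal_idx)) +
    stats::rnorm(sum(diseased), sd = config$score_noise_sd)
  meta$arthritis_score <- 0
  meta$arthritis_score[diseased] <- pmin(pmax(raw, 0), config$score_max)

  # body weight: growth, blunted in diseased animals
  meta$weight <- 60 + 15 * (meta$tp_index - 1) -
    2 * diseased * (meta$tp_index - 1) +
    stats::rnorm(n, sd = 3)

  # cytokines: lognormal baseline + linear couplings to signal species
  set.seed(sub_seeds[3])
  cyt <- matrix(config$cytokine_base *
                  exp(stats::rnorm(n * length(cytokine_names),
                                   sd = config$cytokine_noise_sd)),
                n, length(cytokine_names),
                dimnames = list(meta$sample_id, cytokine_names))
  zall <- scale(L[, signal_idx, drop = FALSE])
  zall[is.nan(zall)] <- 0
  cc <- config$cytokine_couplings
  for (i in seq_len(nrow(cc))) {
    cyt[, cc$cytokine[i]] <- cyt[, cc$cytokine[i]] +
      cc$sign[i] * cc$strength[i] * zall[, cc$signal_index[i]]
  }
  cyt[cyt < 0] <- 0
  meta <- cbind(meta, as.data.frame(cyt))
  meta <- meta[, c("sample_id", "rat_id", "group", "timepoint", "weight",
                   "arthritis_score", cytokine_names)]

  module_map <- default_module_map(config$n_kos, config$n_modules)
  ko <- simulate_ko_shifts(config, module_map, meta = meta,
                           seed = sub_seeds[4])

  ground_truth <- list(
    signal_species = species[signal_idx],
    drift_directions = stats::setNames(dirs[drift_idx], species[drift_idx]),
    score_weights = stats::setNames(rep(config$signal_effect,
                                        length(signal_idx)),
                                    species[signal_idx]),
    cytokine_couplings = data.frame(
      species = species[signal_idx[cc$signal_index]],
      cytokine = cc$cytokine, sign = cc$sign, strength = cc$strength,
      stringsAsFactors = FALSE),
    ko_shifts = config$ko_shifts,
    severity = sev,
    response = revr)

  list(profile = profile, metadata = meta, ko = ko,
       module_map = module_map, ground_truth = ground_truth)
}

#' Simulate a KO table with planted module shifts
#'
#' Lognormal per-KO baselines with per-sample noise; member KOs of each
#' module listed in `config$ko_shifts` are multiplied by the stated factor
#' in the stated group at the final timepoint; each sample is then closed
#' to a total of 100.
#'
#' @param config a [sim_config()].
#' @param module_map named list module id -> KO ids; KOs must be among the
#'   simulated `K00001...` ids.
#' @param meta metadata to simulate for; defaults to the design implied by
#'   `config`.
#' @param seed seed for this table; defaults to `config$seed + 1`.
#' @return samples x KOs matrix with rows summing to 100.
#' @export
simulate_ko_shifts <- function(config, module_map, meta = NULL, seed = NULL) {
  if (!inherits(config, "sim_config")) stop_gp("config must be a sim_config")
  if (length(module_map) == 0L) stop_gp("module_map is empty")
  kos <- sprintf("K%05d", seq_len(config$n_kos))
  unknown <- setdiff(unlist(module_map), kos)
  if (length(unknown))
    stop_gp("module_map references unknown KOs: %s",
            paste(utils::head(unknown, 5), collapse = ", "))
  bad_mod <- setdiff(config$ko_shifts$module, names(module_map))
  if (length(bad_mod))
    stop_gp("ko_shifts references unknown module(s): %s",
            paste(bad_mod, collapse = ", "))
  if (is.null(meta)) {
    meta <- expand.grid(timepoint = config$timepoints,
                        rat_in_group = seq_len(config$n_rats_per_group),
                        group = config$groups,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    meta$sample_id <- sprintf("%s_r%02d_%s", meta$group, meta$rat_in_group,
                              meta$timepoint)
  }
  if (is.null(seed)) seed <- config$seed + 1
  set.seed(as.integer(seed %% (2^31 - 1)))
  n <- nrow(meta)
  base <- stats::rnorm(config$n_kos, 0, 1)
  L <- matrix(stats::rnorm(n * config$n_kos, sd = config$ko_noise_sd),
              n, config$n_kos)
  L <- L + matrix(base, n, config$n_kos, byrow = TRUE)
  final_tp <- config$timepoints[length(config$timepoints)]
  sh <- config$ko_shifts
  for (i in seq_len(nrow(sh))) {
    rows <- meta$group == sh$group[i] & meta$timepoint == final_tp
    cols <- match(module_map[[sh$module[i]]], kos)
    L[rows, cols] <- L[rows, cols] + log10(sh$factor[i])
  }
  ab <- 10^L
  ko <- ab / rowSums(ab) * 100
  dimnames(ko) <- list(meta$sample_id, kos)
  ko
}
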