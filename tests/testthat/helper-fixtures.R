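# small deterministic fixtures built in code

# a tiny hand-made profile: 4 samples x 3 species, percent scale
tiny_profile <- function() {
  m <- rbind(c(60, 30, 10),
             c(50, 25, 25),
             c(80, 15,  5),
             c(40, 40, 20))
  dimnames(m) <- list(paste0("s", 1:4),
                      paste0("k__Bacteria|s__sp", 1:3))
  m
}

tiny_meta <- function() {
  data.frame(sample_id = paste0("s", 1:4),
             rat_id = c("r1", "r1", "r2", "r2"),
             group = c("normal", "normal", "model", "model"),
             timepoint = c("TP1", "TP2", "TP1", "TP2"),
             weight = c(60, 70, 61, 69),
             arthritis_score = c(0, 0, 5, 9),
             stringsAsFactors = FALSE)
}

# a small but full-design cohort for pipeline tests (fast to simulate)
small_cohort <- function(seed = 1, ...) {
  simulate_cohort(sim_config(seed = seed, n_species = 40,
                             n_drift_species = 12, n_kos = 40,
                             n_modules = 8, ...))
}

# longitudinal metadata for nr rats per group at nt timepoints
grid_meta <- function(groups = c("normal", "model"), nr = 3, nt = 3) {
  g <- expand.grid(timepoint = paste0("TP", seq_len(nt)),
                   rat = seq_len(nr), group = groups,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$rat_id <- sprintf("%s_r%d", g$group, g$rat)
  g$sample_id <- sprintf("%s_%s", g$rat_id, g$timepoint)
  g[, c("sample_id", "rat_id", "group", "timepoint")]
}
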