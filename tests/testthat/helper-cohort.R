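# shared cohort fixtures (built in code, never stored)

# the planted ground truth of the default generator: BMI plus the 12 items
# loading the latent factors
truth_predictors <- function() {
  c("bmi", names(default_latent_loadings()$f1))
}

# small cohort for fast structural tests; keeps all four groups and schema
small_config <- function(seed = 1, ...) {
  cohort_config(group_sizes = c(resistant = 20, responsive = 12,
                                untreated = 12, healthy = 14),
                bmi_missing_count = 3, seed = seed, ...)
}

# null-mode configuration: no planted group effects, no informative items,
# CRP decoupled from the questionnaire block
null_config <- function(seed = 1, ...) {
  cohort_config(effect_size_d = 0,
                latent_loadings = list(f1 = setNames(numeric(0), character(0)),
                                       f2 = setNames(numeric(0), character(0))),
                seed = seed, ...)
}
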