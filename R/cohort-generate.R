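# Internal generator constants (log10 mg/L scale unless noted). The CRP model is
#   log10 CRP = mu0 + a*z_bmi + b1*F1 - b2*F2 + e + contamination,
# where z_bmi is standardised log10 BMI, F1/F2 are the two planted latent
# factors (unit within-group SD, group-shifted means) and the contamination
# term is a rare high-CRP component that fattens the right tail beyond what a
# plain lognormal at this variance produces. The numeric values were fixed once
# by simulation so that, at the default configuration, the marginal moment
# skewness of raw CRP, the BMI-CRP rank correlation and the BMI-corrected
# group effect sizes sit at their configured targets.
.crp_const <- list(
  mu0        = 0.00,  # baseline log10 CRP (median ~1 mg/L)
  a0         = 0.235,  # z_bmi weight at the default rank-correlation target 0.56
  b1         = 0.30, # F1 weight (CRP-positive factor)
  b2         = 0.10,  # F2 weight (CRP-negative factor)
  sigma_e    = 0.14,  # residual SD
  contam_p0  = 0.002, # contamination probability at the default skew target 5.08
  contam_mu  = 0.85,  # contamination shift, log10 units
  contam_sd  = 0.25,
  contam_tilt = 1.2,  # exponential tilt of contamination toward high F1: the
                      # acutely inflamed tail sits among the most severe
                      # participants rather than landing as independent noise
  bmi_shift  = 18,    # BMI = shift + lognormal(meanlog, sdlog): skewness ~1
  bmi_meanlog = log(7),
  bmi_sdlog  = 0.35
)

# Group-level parameters: severity-factor shift (drives questionnaire totals and
# the HAM-D eligibility thresholds) and the F1 mean-shape used to plant the
# BMI-corrected CRP effect-size profile d = (0.47, 0.29, 0.18, 0) relative to
# healthy volunteers. F2 means are solved from the profile at run time.
.group_const <- list(
  severity_shift = c(resistant = 1.37, responsive = -3.93,
                     untreated = 2.16, healthy = -3.93),
  f1_shape       = c(resistant = 1.4, responsive = 0.7,
                     untreated = 0.7, healthy = 0),
  d_profile      = c(resistant = 1, responsive = 0.29 / 0.47,
                     untreated = 0.18 / 0.47, healthy = 0),
  # Enforcing the HAM-D eligibility window by rejection conditions on the
  # informative HAM-D items and therefore on F1, which biases the realised
  # CRP group shifts upward in the depressed groups. The bias (in Cohen's d
  # units, measured once by simulation at the default loadings) is removed
  # when solving the F2 means; it scales with the F1 loading mass on HAM-D
  # items so that it vanishes when no item loads the factors.
  d_selection_bias = c(resistant = 0.15, responsive = 0.0,
                       untreated = 0.16, healthy = 0),
  hamd_lo        = c(resistant = 14, responsive = 0, untreated = 18, healthy = 0),
  hamd_hi        = c(resistant = Inf, responsive = 6, untreated = Inf, healthy = 6)
)

default_latent_loadings <- function() {
  vegetative <- c("hamd_04", "hamd_05", "hamd_06", "hamd_08", "hamd_13",
                  "bdi_15", "bdi_16", "bdi_20")
  anxious <- c("ctq_07", "ctq_10", "stai_01", "stai_05")
  list(
    f1 = c(setNames(rep(0.80, length(vegetative)), vegetative),
           setNames(rep(0.72, length(anxious)), anxious)),
    f2 = setNames(rep(0.40, length(anxious)), anxious)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every tunable of [generate_cohort()]. Defaults
#' reproduce the reference study conditions: group sizes 102/48/48/54
#' (resistant/responsive/untreated/healthy), a heavily right-skewed CRP
#' distribution (raw-scale moment skewness near 5.08) coupled to BMI
#' (Spearman rank correlation near 0.56), a BMI-corrected CRP elevation of
#' Cohen's d = 0.47 in the treatment-resistant group (0.29 responsive, 0.18
#' untreated, scaled proportionally by `effect_size_d`), and a planted
#' two-factor latent structure in which 13 of the 139 predictors (BMI plus 12
#' questionnaire items) carry the CRP signal.
#'
#' @param group_sizes Named integer vector of per-group counts; names must be
#'   the four [group_levels()]. All sizes must be at least 2.
#' @param age_range Length-2 numeric, inclusive age bounds in years.
#' @param informative_items Character vector of predictor names that drive CRP;
#'   must contain `"bmi"` plus the items named in `latent_loadings`.
#' @param effect_size_d Target standardised (BMI-corrected) CRP elevation of
#'   the resistant group versus healthy volunteers; the responsive and
#'   untreated elevations scale proportionally. `0` switches off all planted
#'   group differences in CRP.
#' @param latent_loadings List with elements `f1` and `f2`: named numeric
#'   vectors of item loadings on the two latent factors. Items not named load
#'   only on the shared group-severity factor (correlated nuisance).
#' @param crp_skew_target Dimensionless target for the raw-scale moment
#'   skewness of CRP (default 5.08); controls the heavy-tail contamination
#'   rate. The calibration is designed around the default and degrades
#'   gracefully away from it.
#' @param bmi_crp_rho_target Target Spearman correlation between BMI and
#'   log10 CRP (default 0.56); controls the BMI weight in the CRP model.
#' @param missing_rate Fraction of questionnaire item entries set missing
#'   completely at random (default 0.02).
#' @param bmi_missing_count Number of participants with missing BMI (default
#'   12, reproducing the degrees-of-freedom drop of BMI-corrected contrasts).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration and seed.
#' @param max_attempts Bound on rejection-sampling rounds used to enforce the
#'   per-group HAM-D eligibility thresholds.
#'
#' @return Object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
#' @examples
#' cfg <- cohort_config(seed = 7)
#' cfg$group_sizes
cohort_config <- function(group_sizes = c(resistant = 102, responsive = 48,
                                          untreated = 48, healthy = 54),
                          age_range = c(25, 50),
                          informative_items = NULL,
                          effect_size_d = 0.47,
                          latent_loadings = default_latent_loadings(),
                          crp_skew_target = 5.08,
                          bmi_crp_rho_target = 0.56,
                          missing_rate = 0.02,
                          bmi_missing_count = 12,
                          seed = 1L,
                          max_attempts = 1000L) {
  if (is.null(informative_items)) {
    informative_items <- c("bmi", unique(c(names(latent_loadings$f1),
                                           names(latent_loadings$f2))))
  }
  cfg <- structure(
    list(group_sizes = group_sizes, age_range = age_range,
         informative_items = informative_items, effect_size_d = effect_size_d,
         latent_loadings = latent_loadings, crp_skew_target = crp_skew_target,
         bmi_crp_rho_target = bmi_crp_rho_target, missing_rate = missing_rate,
         bmi_missing_count = bmi_missing_count, seed = as.integer(seed),
         max_attempts = as.integer(max_attempts)),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  gl <- group_levels()
  if (!setequal(names(cfg$group_sizes), gl)) {
    config_error(sprintf("group_sizes must be named exactly: %s",
                         paste(gl, collapse = ", ")))
  }
  if (any(cfg$group_sizes < 2)) config_error("all group sizes must be >= 2")
  if (length(cfg$age_range) != 2 || diff(cfg$age_range) <= 0) {
    config_error("age_range must be an increasing pair of years")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    config_error("missing_rate must be in [0, 1)")
  }
  if (cfg$effect_size_d < 0) config_error("effect_size_d must be >= 0")
  if (!all(cfg$informative_items %in% predictor_names())) {
    config_error("informative_items must be a subset of predictor_names()")
  }
  load_items <- unique(c(names(cfg$latent_loadings$f1),
                         names(cfg$latent_loadings$f2)))
  if (!all(load_items %in% item_names())) {
    config_error("latent_loadings must be named by questionnaire items")
  }
  if (!all(load_items %in% cfg$informative_items)) {
    config_error("every item with a latent loading must be listed informative")
  }
  if (cfg$bmi_missing_count < 0 ||
      cfg$bmi_missing_count >= sum(cfg$group_sizes)) {
    config_error("bmi_missing_count must be in [0, n)")
  }
  # total item communality (severity + latent factors) must stay below 1
  ins <- instrument_table()
  for (it in load_items) {
    instr <- sub("_[0-9]+$", "", it)
    sev <- ins[[instr]]$severity_loading
    l1 <- if (it %in% names(cfg$latent_loadings$f1)) cfg$latent_loadings$f1[[it]] else 0
    l2 <- if (it %in% names(cfg$latent_loadings$f2)) cfg$latent_loadings$f2[[it]] else 0
    if (sev^2 + l1^2 + l2^2 >= 1) {
      config_error(sprintf("loadings of item %s imply communality >= 1", it))
    }
  }
  invisible(cfg)
}

# within-group SD of log10 CRP implied by the generator constants; used to
# convert the Cohen's d profile into absolute log10 shifts
crp_within_sd <- function(contam_p) {
  k <- .crp_const
  cv <- contam_p * (k$contam_mu^2 + k$contam_sd^2) - (contam_p * k$contam_mu)^2
  sqrt(k$b1^2 + k$b2^2 + k$sigma_e^2 + cv)
}

# draw the latent factors and questionnaire item block for n participants of
# one group; returns list(S, F1, F2, items) with items an n x 135 matrix
draw_group_latents <- function(n, group, cfg, f1_mean, f2_mean) {
  ins <- instrument_table()
  gc <- .group_const
  s_shift <- gc$severity_shift[[group]]
  S_resid <- rnorm(n)
  # F1 ("inflamed severity") is right-skewed within groups — the upper tail
  # of CRP belongs to genuinely inflamed participants whose informative items
  # are correspondingly elevated — but with Gaussian tails (skew-normal),
  # so the raw-scale CRP tail stays lognormal-like rather than power-law
  delta <- 0.9
  sn <- delta * abs(rnorm(n)) + sqrt(1 - delta^2) * rnorm(n)
  F1 <- f1_mean + (sn - delta * sqrt(2 / pi)) / sqrt(1 - 2 * delta^2 / pi)
  F2 <- f2_mean + rnorm(n)
  items <- matrix(0L, nrow = n, ncol = length(item_names()),
                  dimnames = list(NULL, item_names()))
  for (instr in names(ins)) {
    meta <- ins[[instr]]
    cols <- sprintf("%s_%02d", instr, seq_len(meta$n_items))
    l1 <- vapply(cols, function(cn) {
      if (cn %in% names(cfg$latent_loadings$f1)) cfg$latent_loadings$f1[[cn]] else 0
    }, numeric(1))
    l2 <- vapply(cols, function(cn) {
      if (cn %in% names(cfg$latent_loadings$f2)) cfg$latent_loadings$f2[[cn]] else 0
    }, numeric(1))
    sev <- rep(meta$severity_loading, length(cols))
    noise_sd <- sqrt(pmax(1 - sev^2 - l1^2 - l2^2, 0.05))
    # all instruments share the within-group severity factor; only HAM-D, the
    # stratifying instrument, carries the full between-group severity shift.
    # The other instruments see a damped shift so that nuisance items are
    # correlated with each other but carry no appreciable CRP linkage through
    # the group-level CRP elevations (the eligibility thresholds force HAM-D
    # apart between groups; CRP group effects are planted; fully group-shifted
    # nuisance items would therefore correlate with CRP by construction).
    latent <- (s_shift * meta$group_sep + S_resid) %o% sev +
      F1 %o% l1 + F2 %o% l2 +
      matrix(rnorm(n * length(cols)), n) * rep(noise_sd, each = n)
    cuts <- qnorm(meta$cut_p)
    scored <- matrix(meta$min, n, length(cols))
    for (cut in cuts) scored <- scored + (latent > cut)
    items[, cols] <- scored
  }
  list(S = S_resid, F1 = F1, F2 = F2, items = items)
}

#' Generate a seeded synthetic cohort
#'
#' Simulates one participant table with the statistical structure the
#' downstream analyses assume: four groups whose HAM-D totals respect the
#' eligibility thresholds (resistant > 13, untreated > 17, responsive and
#' healthy < 7, enforced by rejection sampling of a shifted severity factor);
#' CRP generated on the log10 scale as a linear combination of standardised
#' log BMI, a CRP-positive latent factor F1, a CRP-negative latent factor F2
#' and noise, with a rare heavy-tail contamination component; questionnaire
#' items discretised from Gaussian latents, with only the configured
#' informative items loading on F1/F2 beyond the shared group-severity
#' nuisance factor; and missingness applied last, completely at random.
#'
#' @param config A [cohort_config()] object.
#' @return A `crp_cohort`: a `data.frame` with one row per participant in the
#'   column order of the cohort CSV schema (see [cohort_columns] in the
#'   package sources), carrying the generating `config` as an attribute.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' nrow(cohort)            # 252
#' table(cohort$group)
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  k <- .crp_const
  gc <- .group_const
  gl <- group_levels()
  n_total <- sum(cfg$group_sizes)

  # group-level CRP shifts: F1 means follow the fixed shape, F2 means are
  # solved so that b1*m1 - b2*m2 equals the planted log10 offset per group
  scale_d <- cfg$effect_size_d / 0.47
  contam_p <- min(max(k$contam_p0 * cfg$crp_skew_target / 5.08, 0), 0.5)
  s_within <- crp_within_sd(contam_p)
  f1_mean <- gc$f1_shape * scale_d
  f1 <- cfg$latent_loadings$f1
  hamd_load <- sum(f1[grepl("^hamd_", names(f1))])
  load_ratio <- hamd_load / 3.0   # 3.0 = HAM-D loading mass at default config
  delta <- (gc$d_profile * cfg$effect_size_d -
              gc$d_selection_bias * load_ratio) * s_within
  f2_mean <- (k$b1 * f1_mean - delta) / k$b2

  a <- k$a0 * cfg$bmi_crp_rho_target / 0.56

  rows <- list()
  for (g in gl) {
    n <- cfg$group_sizes[[g]]
    lat <- draw_group_latents(n, g, cfg, f1_mean[[g]], f2_mean[[g]])
    # rejection: redraw participants whose HAM-D total violates the group's
    # eligibility window (equivalent to sampling from the truncated law)
    hamd_cols <- sprintf("hamd_%02d", 1:21)
    for (attempt in seq_len(cfg$max_attempts)) {
      tot <- rowSums(lat$items[, hamd_cols, drop = FALSE])
      bad <- which(tot < gc$hamd_lo[[g]] | tot > gc$hamd_hi[[g]])
      if (!length(bad)) break
      redraw <- draw_group_latents(length(bad), g, cfg, f1_mean[[g]], f2_mean[[g]])
      lat$S[bad] <- redraw$S
      lat$F1[bad] <- redraw$F1
      lat$F2[bad] <- redraw$F2
      lat$items[bad, ] <- redraw$items
    }
    tot <- rowSums(lat$items[, hamd_cols, drop = FALSE])
    if (any(tot < gc$hamd_lo[[g]] | tot > gc$hamd_hi[[g]])) {
      config_error(sprintf(
        "rejection sampling failed for group '%s' after %d attempts; the HAM-D threshold is infeasible under these loadings",
        g, cfg$max_attempts))
    }

    n_failed <- switch(g,
      resistant  = 1L + rpois(n, 2),
      responsive = rpois(n, 0.7),
      untreated  = rbinom(n, 1, 0.583) * (1L + rpois(n, 2.09)),
      healthy    = rep(0L, n)
    )

    rows[[g]] <- data.frame(
      group = g,
      age = sample(seq(cfg$age_range[1], cfg$age_range[2]), n, replace = TRUE),
      gender = rbinom(n, 1, 0.6),
      education = sample(1:5, n, replace = TRUE,
                         prob = c(0.05, 0.20, 0.30, 0.30, 0.15)),
      bmi = k$bmi_shift + rlnorm(n, k$bmi_meanlog, k$bmi_sdlog),
      n_failed_treatments = n_failed,
      F1 = lat$F1, F2 = lat$F2,
      stringsAsFactors = FALSE
    )
    rows[[g]] <- cbind(rows[[g]], as.data.frame(lat$items))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$participant_id <- sprintf("P%03d", seq_len(n_total))

  # CRP on the log10 scale from standardised log10 BMI, F1, F2, noise and the
  # heavy-tail contamination component
  z_bmi <- as.numeric(scale(log10(tab$bmi)))
  # tilt on the within-group F1 residual: the inflamed tail concentrates in
  # participants with high latent inflammation, not in whole groups
  f1_resid <- tab$F1 - f1_mean[tab$group]
  tilt <- exp(k$contam_tilt * f1_resid)
  p_i <- pmin(n_total * contam_p * tilt / sum(tilt), 0.6)
  contam <- (runif(n_total) < p_i) * rnorm(n_total, k$contam_mu, k$contam_sd)
  log10_crp <- k$mu0 + a * z_bmi + k$b1 * tab$F1 - k$b2 * tab$F2 +
    rnorm(n_total, 0, k$sigma_e) + contam
  tab$crp <- 10^log10_crp
  tab$F1 <- NULL
  tab$F2 <- NULL

  # MCAR missingness, applied last: questionnaire items at missing_rate, BMI
  # for exactly bmi_missing_count participants
  if (cfg$missing_rate > 0) {
    im <- as.matrix(tab[, item_names()])
    mask <- matrix(runif(length(im)) < cfg$missing_rate, nrow = nrow(im))
    im[mask] <- NA
    tab[, item_names()] <- im
  }
  if (cfg$bmi_missing_count > 0) {
    tab$bmi[sample.int(n_total, cfg$bmi_missing_count)] <- NA
  }

  tab <- tab[, cohort_columns()]
  structure(tab, config = cfg, class = c("crp_cohort", "data.frame"))
}

#' @export
print.crp_cohort <- function(x, ...) {
  cat(sprintf("<crp_cohort> %d participants, %d columns\n", nrow(x), ncol(x)))
  print(table(factor(x$group, levels = group_levels())))
  invisible(x)
}
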