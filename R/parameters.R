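## Strategy identifiers, in the canonical reporting order.
STRATEGY_IDS <- c("diet", "exercise", "duo", "screen_only", "control")

## Initiation ages for which age-specific models are defined.
INITIATION_AGES <- c(25L, 40L, 60L)

#' Default model parameters
#'
#' Returns the complete baseline parameter set of the model: the screening
#' cascade (negative rate of the 2-h plasma glucose test, positive rate of
#' the confirmatory OGTT, proportion of positives that are IGT), annual
#' transition probabilities shared by all strategies (normal glucose
#' tolerance to IGT, IGT back to normal), the per-strategy IGT-to-diabetes
#' progression rates at initiation ages 25/40/60 and complication
#' incidence/mortality rates, annual costs (US$, societal perspective),
#' health-state utilities by initiation age with the age and comorbidity
#' adjustment coefficients, and the global economic settings (3% discount
#' rate, 40-year horizon, 1-year cycles, 20,000-subject cohort, 6-year
#' intervention tunnel, CHY/USD exchange rate, 1:2.6:8 age-incidence ratio).
#'
#' @return an object of class `dm_parameters`: a named nested list with
#'   components `settings`, `screening`, `shared`, `strategies`, `costs`
#'   and `utilities`.
#' @seealso [load_parameters()] to read a configuration file with
#'   overrides, [validate_parameters()] for the invariant checks.
#' @export
#' @examples
#' p <- default_parameters()
#' p$strategies$control$igt_to_dm[["40"]]  # 0.167
default_parameters <- function() {
  comp_inc_int <- c(cvd = 0.062, nephropathy = 0.001,
                    neuropathy = 0.0043, retinopathy = 0.0046)
  comp_mort_int <- c(cvd = 0.0058, nephropathy = 0.0008)
  comp_inc_ctl <- c(cvd = 0.0675, nephropathy = 0.001,
                    neuropathy = 0.005, retinopathy = 0.0081)
  comp_mort_ctl <- c(cvd = 0.0087, nephropathy = 0.0003)

  strategy <- function(id, rates, ci, cm, cost, screening) {
    list(id = id,
         igt_to_dm = stats::setNames(rates, c("25", "40", "60")),
         complication_incidence = ci,
         complication_mortality = cm,
         annual_intervention_cost = cost,
         has_screening = screening)
  }

  utab <- matrix(
    c(1,     1,     1,
      0.95,  0.95,  0.95,
      0.805, 0.800, 0.794,
      0.679, 0.674, 0.584,
      0.705, 0.700, 0.610,
      0.646, 0.641, 0.551,
      0.667, 0.662, 0.572,
      0,     0,     0),
    nrow = 8, byrow = TRUE,
    dimnames = list(c("normal", "igt", "onset_dm", "cvd", "retinopathy",
                      "nephropathy", "neuropathy", "death"),
                    c("25", "40", "60")))

  params <- list(
    settings = list(
      discount_rate = 0.03,
      horizon = 40L,
      cycle_length = 1L,
      cohort_size = 20000L,
      tunnel_length = 6L,
      fx_rate = 7.6948,
      age_ratio = c("25" = 1, "40" = 2.6, "60" = 8),
      post_tunnel_rate = "control",          # or "last_intervention"
      screen_alone_uses_column_rates = FALSE,
      cost_population = "subgroup",          # or "all"
      eligibility = "baseline_plus_incident",# or "baseline_only"
      range_type = "percentile"              # or "minmax"
    ),
    screening = list(
      neg_rate_2hpg = 0.96,
      ogtt_positive_rate = 0.305,
      igt_fraction_of_positive = 0.478,
      detection_level = 1.0,
      compliance = 1.0
    ),
    shared = list(
      normal_to_igt = 0.0128,
      igt_to_normal = 0.116
    ),
    strategies = list(
      diet = strategy("diet", c(0.0290, 0.0754, 0.2320),
                      comp_inc_int, comp_mort_int, 362, TRUE),
      exercise = strategy("exercise", c(0.0273, 0.0710, 0.2184),
                          comp_inc_int, comp_mort_int, 362, TRUE),
      duo = strategy("duo", c(0.0275, 0.0716, 0.2200),
                     comp_inc_int, comp_mort_int, 371, TRUE),
      screen_only = strategy("screen_only", c(0.0400, 0.104, 0.3600),
                             comp_inc_ctl, comp_mort_ctl, 0, TRUE),
      control = strategy("control", c(0.0644, 0.1670, 0.5778),
                         comp_inc_ctl, comp_mort_ctl, 0, FALSE)
    ),
    costs = list(
      onset_dm = 897, cvd = 2078, nephropathy = 1089,
      neuropathy = 1324, retinopathy = 888,
      screening = 3
    ),
    utilities = list(
      table = utab,
      age_coefficient = -0.0003,
      comorbidity_coefficient = 0.084
    )
  )
  class(params) <- "dm_parameters"
  validate_parameters(params)
}

#' Load model parameters from a configuration file
#'
#' Reads a YAML (or JSON, which is valid YAML) configuration and merges it
#' over the bundled defaults, so a configuration only needs to state the
#' values it changes.  An empty or missing file yields the full default
#' parameter set.
#'
#' @param path path to a YAML/JSON configuration file, or `NULL` for
#'   defaults only.
#' @param overrides a named nested list of in-memory overrides applied after
#'   the file (convenient for programmatic what-if runs).
#' @return a validated `dm_parameters` object.
#' @export
#' @examples
#' p <- load_parameters(overrides = list(settings = list(discount_rate = 0.05)))
#' p$settings$discount_rate
load_parameters <- function(path = NULL, overrides = list()) {
  params <- unclass(default_parameters())
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
      stop("failed to parse configuration '", path, "': ",
           conditionMessage(e), call. = FALSE)
    })
    if (!is.null(cfg) && !is.list(cfg)) {
      stop("configuration '", path, "' must be a mapping of sections")
    }
    params <- merge_lists(params, normalize_config(cfg))
  }
  if (length(overrides)) params <- merge_lists(params, normalize_config(overrides))
  class(params) <- "dm_parameters"
  validate_parameters(params)
}

## Coerce YAML-side representations (lists of scalars keyed by age/state)
## into the named numeric vectors / matrix used internally.
normalize_config <- function(cfg) {
  if (is.null(cfg)) return(list())
  vecify <- function(x) {
    if (is.list(x) && length(x) && all(vapply(x, is.numeric, TRUE)) &&
        !is.null(names(x))) {
      unlist(x)
    } else x
  }
  for (arm in names(cfg$strategies)) {
    for (f in c("igt_to_dm", "complication_incidence", "complication_mortality"))
      if (!is.null(cfg$strategies[[arm]][[f]]))
        cfg$strategies[[arm]][[f]] <- vecify(cfg$strategies[[arm]][[f]])
  }
  if (!is.null(cfg$settings$age_ratio))
    cfg$settings$age_ratio <- vecify(cfg$settings$age_ratio)
  ut <- cfg$utilities$table
  if (is.list(ut)) {
    states <- names(ut)
    m <- do.call(rbind, lapply(ut, unlist))
    rownames(m) <- states
    cfg$utilities$table <- m
  }
  cfg
}

#' Validate a parameter set
#'
#' Checks every probability lies in \[0, 1\], costs are non-negative, the
#' control arm is unscreened, intervention progression/complication rates do
#' not exceed the control rates, and utilities are 1 for normal glucose
#' tolerance, 0 for death, and non-increasing with initiation age for every
#' disease state.
#'
#' @param params a `dm_parameters` object (or plain list with the same
#'   structure).
#' @param clamp if `TRUE`, probabilities and utilities outside \[0, 1\] are
#'   clamped with a warning instead of raising an error (used by the
#'   sensitivity engine where a multiplier can push a probability past 1).
#' @return the validated (possibly clamped) `dm_parameters` object,
#'   invisibly classed.
#' @export
validate_parameters <- function(params, clamp = FALSE) {
  clamp01 <- function(x, field) {
    if (any(x < 0 | x > 1)) {
      if (!clamp) check_probability(x, field)
      warning(sprintf("'%s' clamped to [0, 1]", field), call. = FALSE)
      x <- pmin(pmax(x, 0), 1)
    }
    x
  }
  sc <- params$screening
  for (f in c("neg_rate_2hpg", "ogtt_positive_rate", "igt_fraction_of_positive",
              "detection_level", "compliance")) {
    if (is.null(sc[[f]])) stop("missing screening parameter '", f, "'")
    params$screening[[f]] <- clamp01(sc[[f]], paste0("screening.", f))
  }
  for (f in c("normal_to_igt", "igt_to_normal"))
    params$shared[[f]] <- clamp01(params$shared[[f]], paste0("shared.", f))

  for (arm in names(params$strategies)) {
    st <- params$strategies[[arm]]
    params$strategies[[arm]]$igt_to_dm <-
      clamp01(st$igt_to_dm, paste0("strategies.", arm, ".igt_to_dm"))
    params$strategies[[arm]]$complication_incidence <-
      clamp01(st$complication_incidence,
              paste0("strategies.", arm, ".complication_incidence"))
    params$strategies[[arm]]$complication_mortality <-
      clamp01(st$complication_mortality,
              paste0("strategies.", arm, ".complication_mortality"))
    check_nonnegative(st$annual_intervention_cost,
                      paste0("strategies.", arm, ".annual_intervention_cost"))
  }
  if (isTRUE(params$strategies$control$has_screening))
    stop("the control strategy must not include screening")
  ctl <- params$strategies$control
  for (arm in c("diet", "exercise", "duo")) {
    st <- params$strategies[[arm]]
    if (any(st$igt_to_dm > ctl$igt_to_dm + 1e-12))
      stop("intervention arm '", arm,
           "' has an IGT-to-diabetes rate above the control rate")
  }
  for (f in names(params$costs))
    check_nonnegative(params$costs[[f]], paste0("costs.", f))

  ut <- params$utilities$table
  if (any(ut["normal", ] != 1) || any(ut["death", ] != 0))
    stop("utilities must be 1 for 'normal' and 0 for 'death' at every age")
  ut2 <- matrix(clamp01(as.numeric(ut), "utilities.table"),
                nrow = nrow(ut), dimnames = dimnames(ut))
  params$utilities$table <- ut2
  dis <- setdiff(rownames(ut2), c("normal", "death"))
  if (any(ut2[dis, "60"] > ut2[dis, "40"] + 1e-12) ||
      any(ut2[dis, "40"] > ut2[dis, "25"] + 1e-12))
    stop("disease-state utilities must be non-increasing with initiation age")

  se <- params$settings
  if (se$horizon <= 0) stop("settings.horizon must be positive")
  if (se$tunnel_length > se$horizon)
    stop("settings.tunnel_length must not exceed the horizon")
  if (se$discount_rate < 0) stop("settings.discount_rate must be >= 0")
  class(params) <- "dm_parameters"
  params
}

#' @export
print.dm_parameters <- function(x, ...) {
  cat("<dm_parameters>\n")
  cat(sprintf("  horizon %d y, cycle %d y, cohort %d, tunnel %d y, discount %.1f%%\n",
              x$settings$horizon, x$settings$cycle_length,
              x$settings$cohort_size, x$settings$tunnel_length,
              100 * x$settings$discount_rate))
  r <- vapply(x$strategies, function(s) s$igt_to_dm[["40"]], 0)
  cat("  IGT->DM (age 40):",
      paste(sprintf("%s=%.4f", names(r), r), collapse = ", "), "\n")
  invisible(x)
}

#' Scale an age-40 rate to another initiation age
#'
#' Annual IGT-to-diabetes incidence at initiation ages 25 and 60 is derived
#' from the age-40 baseline using the age-incidence ratio 1:2.6:8
#' (ages 25:40:60), i.e. `rate40 * ratio[age] / ratio[40]`, clamped to
#' \[0, 1\] with a warning if the product exceeds 1.
#'
#' @param rate_age40 annual probability at initiation age 40.
#' @param target_age one of 25, 40, 60.
#' @param age_ratio named ratio triple; default `c("25"=1, "40"=2.6, "60"=8)`.
#' @return the scaled annual probability (unrounded).
#' @export
#' @examples
#' scale_rate_by_age_ratio(0.0754, 25)  # 0.029
#' scale_rate_by_age_ratio(0.0754, 60)  # 0.232
scale_rate_by_age_ratio <- function(rate_age40, target_age,
                                    age_ratio = c("25" = 1, "40" = 2.6, "60" = 8)) {
  check_probability(rate_age40, "rate_age40")
  key <- as.character(target_age)
  if (!key %in% names(age_ratio))
    stop("target_age must be one of ", paste(names(age_ratio), collapse = ", "))
  out <- rate_age40 * age_ratio[[key]] / age_ratio[["40"]]
  if (any(out > 1)) {
    warning("scaled rate exceeds 1; clamped", call. = FALSE)
    out <- pmin(out, 1)
  }
  unname(out)
}

#' Convert a cumulative incidence to an annual probability
#'
#' Inverts the compounding of a constant annual probability over `years`
#' years: `1 - (1 - cum_prob)^(1/years)`.  Used to turn published 3- or
#' 6-year cumulative incidences into the model's annual transition
#' probabilities (e.g. a 3-year cumulative 0.3084 reversion from IGT to
#' normal glucose tolerance gives 0.116 per year).
#'
#' @param cum_prob cumulative probability over the period, in \[0, 1).
#' @param years period length in years (>= 1).
#' @return annual probability.
#' @export
annual_rate_from_cumulative <- function(cum_prob, years) {
  if (!is.numeric(cum_prob) || any(cum_prob < 0) || any(cum_prob >= 1))
    stop("'cum_prob' must lie in [0, 1); annualization is undefined at 1")
  if (any(years < 1)) stop("'years' must be >= 1")
  1 - (1 - cum_prob)^(1 / years)
}

#' Adjust an age-40 utility to another initiation age
#'
#' Disease-state utilities are anchored at initiation age 40 (the median age
#' of the diabetic population the published utilities describe) and adjusted
#' to other ages with a linear age coefficient (-0.0003 utility per year)
#' plus, for the older cohort's complication states, a comorbidity
#' coefficient (0.084) reflecting one additional universal coexisting
#' condition, so that three conditions (diabetes, the complication, and the
#' comorbidity) apply.  For example the diabetes-with-CVD utility at 60 is
#' 0.674 - 0.006 - 0.084 = 0.584.
#'
#' @param base_utility_age40 utility at initiation age 40, in \[0, 1\].
#' @param target_age target initiation age in years.
#' @param extra_comorbidity logical; apply the comorbidity coefficient
#'   (complication states in the age-60 models only).
#' @param age_coefficient utility change per year of age (default -0.0003).
#' @param comorbidity_coefficient utility decrement for the third coexisting
#'   condition (default 0.084).
#' @return adjusted utility, clamped to \[0, 1\] (unrounded; reported values
#'   use [round_half_up()] at 3 decimal places).
#' @export
#' @examples
#' adjust_utility(0.674, 60, TRUE)    # 0.584
#' round_half_up(adjust_utility(0.674, 25, FALSE), 3)  # 0.679
adjust_utility <- function(base_utility_age40, target_age,
                           extra_comorbidity = FALSE,
                           age_coefficient = -0.0003,
                           comorbidity_coefficient = 0.084) {
  check_probability(base_utility_age40, "base_utility_age40")
  out <- base_utility_age40 + (target_age - 40) * age_coefficient -
    ifelse(extra_comorbidity, comorbidity_coefficient, 0)
  pmin(pmax(out, 0), 1)
}

#' Convert Chinese yuan to US dollars
#'
#' Uses the model's fixed exchange rate (US$1 = CHY 7.6948, 15 June 2007).
#'
#' @param amount amount in yuan (>= 0).
#' @param fx_rate yuan per US dollar.
#' @return amount in US dollars.
#' @export
yuan_to_usd <- function(amount, fx_rate = 7.6948) {
  check_nonnegative(amount, "amount")
  amount / fx_rate
}
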