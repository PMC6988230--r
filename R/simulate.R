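#' Simulation configuration for synthetic cohort and incidence generation
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the pooled adult burn cohort the pipeline was built
#' for: group sizes 1587 / 1364 / 450 (severity groups <5%, 5-20%, >20%
#' TBSA), age ~ truncated Normal(41.1, 15.5) on \[18, 90\] years, 70.9%
#' male, an assessment schedule of 0.75, 3, 9, 18 and 60 months post-burn
#' (one assessment per recovery window), true cell means equal to the
#' embedded published disability-weight table, utility noise sd 0.25 and no
#' attrition.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_patients Named integer vector of patients per severity group.
#' @param age_mean,age_sd,age_range Age-at-burn distribution (truncated
#'   normal, years).
#' @param prop_male Probability a patient is male.
#' @param schedule Months post-burn of the scheduled assessments (all > 0).
#' @param true_dw `dw_table` (or data frame with `group`, `window`,
#'   `mean_dw`) of generating cell means.
#' @param noise_sd Standard deviation of the additive utility noise.
#' @param attrition Named per-window probability that a patient drops out
#'   after that window (all later assessments removed).
#' @param lifelong_fraction Optional named per-group fraction; when set, the
#'   two-year (>12-24 month) assessment states are overridden so that
#'   exactly `round(fraction * n)` patients per group carry a
#'   classifier-positive profile (utilities rescored from the state).
#' @param incidence Tibble (`country`, `year`, `group`, `rate`) of expected
#'   incident counts for [generate_incidence()].
#' @param incidence_mode `"fixed"` (counts = rates, deterministic) or
#'   `"poisson"`.
#' @param censor_incidence Emulate registry small-cell censoring: counts in
#'   1-5 are written as the token `"1-5"` by [write_incidence()].
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_patients = c(lt5 = 1587L, `5to20` = 1364L,
                                             gt20 = 450L),
                              age_mean = 41.1, age_sd = 15.5,
                              age_range = c(18, 90),
                              prop_male = 0.709,
                              schedule = c(0.75, 3, 9, 18, 60),
                              true_dw = default_dw_table(),
                              noise_sd = 0.25,
                              attrition = c(m0_1 = 0, m1_6 = 0, m6_12 = 0,
                                            m12_24 = 0, long = 0),
                              lifelong_fraction = NULL,
                              incidence = NULL,
                              incidence_mode = c("fixed", "poisson"),
                              censor_incidence = FALSE) {
  incidence_mode <- match.arg(incidence_mode)
  cfg <- list(seed = as.integer(seed), n_patients = n_patients,
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              prop_male = prop_male, schedule = schedule, true_dw = true_dw,
              noise_sd = noise_sd, attrition = attrition,
              lifelong_fraction = lifelong_fraction, incidence = incidence,
              incidence_mode = incidence_mode,
              censor_incidence = isTRUE(censor_incidence))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid simulation config field '%s': %s", field, why),
         call. = FALSE)
  }
  if (!all(SEVERITY_GROUPS %in% names(cfg$n_patients)) ||
      any(cfg$n_patients < 0)) {
    fail("n_patients", "must name every severity group with counts >= 0")
  }
  if (!(cfg$prop_male >= 0 && cfg$prop_male <= 1)) {
    fail("prop_male", "must lie in [0, 1]")
  }
  if (cfg$noise_sd < 0) fail("noise_sd", "must be >= 0")
  if (any(cfg$schedule <= 0)) fail("schedule", "all months must be > 0")
  if (cfg$age_range[1] < 18) fail("age_range", "adults only (>= 18)")
  if (!all(RECOVERY_WINDOWS %in% names(cfg$attrition)) ||
      any(cfg$attrition < 0 | cfg$attrition > 1)) {
    fail("attrition", "must name every window with probabilities in [0, 1]")
  }
  if (!is.null(cfg$lifelong_fraction) &&
      any(cfg$lifelong_fraction < 0 | cfg$lifelong_fraction > 1)) {
    fail("lifelong_fraction", "fractions must lie in [0, 1]")
  }
  need <- c("group", "window", "mean_dw")
  if (!all(need %in% names(cfg$true_dw))) {
    fail("true_dw", "needs columns group, window, mean_dw")
  }
  invisible(cfg)
}

# tbsa ranges consistent with each severity group
sample_tbsa <- function(group, n) {
  switch(group,
         lt5 = stats::runif(n, 0.5, 4.9),
         `5to20` = stats::runif(n, 5, 20),
         gt20 = stats::runif(n, 20.5, 60))
}

# mean of N(mu, s) censored (clamped) to [a, b]
censored_normal_mean <- function(mu, s, a, b) {
  al <- (a - mu) / s
  be <- (b - mu) / s
  a * stats::pnorm(al) + b * (1 - stats::pnorm(be)) +
    mu * (stats::pnorm(be) - stats::pnorm(al)) -
    s * (stats::dnorm(be) - stats::dnorm(al))
}

# location mu such that the [a, b]-censored N(mu, s) has mean `target`;
# vectorized with memoisation over unique targets
censored_normal_location <- function(target, s, a, b) {
  shape <- dim(target)
  tv <- as.vector(target)
  if (any(tv <= a | tv >= b)) {
    stop("target means must lie strictly inside the censoring bounds",
         call. = FALSE)
  }
  uq <- unique(tv)
  loc <- vapply(uq, function(t) {
    stats::uniroot(function(mu) censored_normal_mean(mu, s, a, b) - t,
                   lower = a - 8 * s, upper = b + 8 * s, tol = 1e-12)$root
  }, numeric(1))
  out <- loc[match(tv, uq)]
  if (!is.null(shape)) dim(out) <- shape
  out
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Map utilities to their nearest EQ-5D-3L tariff state
#'
#' Returns, for each utility, the state among the 243 whose tariff value is
#' closest; ties resolve to the less severe state (smaller level sum, then
#' lexicographically smaller code). Used so generated data are consistent
#' between the utility-level and state-level pipeline paths.
#'
#' @param utility Numeric vector within the tariff bounds.
#' @param vs Value set.
#' @return Character vector of state codes.
#' @export
nearest_state <- function(utility, vs = uk_tto_value_set()) {
  tab <- tariff_lookup(vs)
  lo <- findInterval(utility, tab$u)
  lo <- pmin(pmax(lo, 1L), length(tab$u))
  hi <- pmin(lo + 1L, length(tab$u))
  d_lo <- abs(utility - tab$u[lo])
  d_hi <- abs(utility - tab$u[hi])
  pick_hi <- d_hi < d_lo |
    (d_hi == d_lo & (tab$sev[hi] < tab$sev[lo] |
                       (tab$sev[hi] == tab$sev[lo] &
                          tab$state[hi] < tab$state[lo])))
  tab$state[ifelse(pick_hi, hi, lo)]
}

# sorted unique tariff utilities with, per utility, the least severe state
# (smallest level sum, then lexicographically smallest code)
tariff_lookup <- function(vs) {
  states <- all_health_states()
  u <- unname(score_utility(states, vs))
  sev <- rowSums(eq5d_levels(states))
  ord <- order(u, sev, states)
  states <- states[ord]; u <- u[ord]; sev <- sev[ord]
  keep <- !duplicated(u)
  list(state = states[keep], u = u[keep], sev = sev[keep])
}

#' Generate a synthetic longitudinal burn cohort
#'
#' Per patient and scheduled assessment, the utility is drawn from a
#' censored normal on the tariff bounds \[-0.594, 1\] whose mean is exactly
#' the age/sex population norm minus the configured true disability weight
#' of the patient's (severity group, recovery window) cell, with noise
#' scale `noise_sd`. Plain additive noise clamped at the full-health
#' ceiling would inflate every mild-burn cell mean (the ceiling clips the
#' noise asymmetrically), so the pre-censoring location is solved so that
#' the censored distribution is mean-faithful: the configured cell means
#' are recovered without bias at any noise level, and exactly when
#' `noise_sd = 0`. The emitted health state is the tariff state nearest the
#' drawn utility. Attrition removes all assessments after a window with the
#' configured per-window probability. Fully reproducible under a fixed
#' seed.
#'
#' @param config A `sim_config`.
#' @param norms Population norm table used for the trajectory model (and
#'   which should also be used when re-estimating weights from the output).
#' @param vs Value set.
#' @return Observation tibble with the [load_cohort()] schema plus a
#'   `true_dw` column.
#' @export
generate_cohort <- function(config, norms = default_norm_table(),
                            vs = uk_tto_value_set()) {
  validate_sim_config(config)
  set.seed(config$seed)
  floor_u <- utility_floor(vs)
  K <- length(config$schedule)
  windows <- as.character(assign_window(config$schedule))
  pieces <- list()
  pid0 <- 0L
  for (g in SEVERITY_GROUPS) {
    n <- config$n_patients[[g]]
    if (n == 0) next
    age <- round(rtruncnorm1(n, config$age_mean, config$age_sd,
                             config$age_range[1], config$age_range[2]))
    sex <- ifelse(stats::runif(n) < config$prop_male, "male", "female")
    tbsa <- sample_tbsa(g, n)
    norm_u <- lookup_norm(age, sex, norms)
    true_dw <- stats::setNames(rep(NA_real_, K), windows)
    for (w in unique(windows)) {
      hit <- config$true_dw$group == g & config$true_dw$window == w
      if (any(hit)) true_dw[windows == w] <- config$true_dw$mean_dw[which(hit)[1]]
    }
    if (any(is.na(true_dw))) {
      stop(sprintf("true_dw table lacks cell(s) for group %s, window(s) %s",
                   g, paste(unique(windows[is.na(true_dw)]), collapse = ", ")),
           call. = FALSE)
    }
    noise <- if (config$noise_sd > 0) {
      matrix(stats::rnorm(n * K, 0, config$noise_sd), n, K, byrow = TRUE)
    } else {
      matrix(0, n, K)
    }
    # patient i is retained at assessment k unless an earlier window's
    # attrition draw removed them
    drop_u <- matrix(stats::runif(n * K), n, K, byrow = TRUE)
    if (K == 1L || all(config$attrition == 0)) {
      kept <- matrix(TRUE, n, K)
    } else {
      drop_here <- drop_u < rep(config$attrition[windows], each = n)
      dropped_after <- t(apply(drop_here, 1L, cumsum)) > 0
      kept <- cbind(TRUE, !dropped_after[, -K, drop = FALSE])
    }

    target <- outer(norm_u, unname(true_dw), "-")  # norm - dw, the cell mean
    if (config$noise_sd > 0) {
      loc <- censored_normal_location(target, config$noise_sd, floor_u, 1)
      u <- pmin(pmax(loc + noise, floor_u), 1)
    } else {
      u <- pmin(pmax(target, floor_u), 1)
    }
    # row-major flatten: patient-major, schedule inner, matching file layout
    idx_p <- rep(seq_len(n), each = K)
    idx_k <- rep(seq_len(K), times = n)
    keep_flat <- kept[cbind(idx_p, idx_k)]
    u_flat <- u[cbind(idx_p, idx_k)]
    state <- nearest_state(u_flat, vs)
    if (!is.null(config$lifelong_fraction)) {
      n_pos <- round(config$lifelong_fraction[[g]] * n)
      at_2y <- windows[idx_k] == "m12_24"
      state[at_2y] <- ifelse(idx_p[at_2y] <= n_pos, "11122", "11111")
      u_flat[at_2y] <- unname(score_utility(state[at_2y], vs))
    }
    piece <- tibble::tibble(
      patient_id = sprintf("P%05d", pid0 + idx_p),
      age = age[idx_p], sex = sex[idx_p], tbsa = tbsa[idx_p],
      months_post_burn = config$schedule[idx_k],
      state = state, utility = u_flat,
      true_dw = unname(true_dw[idx_k]))[keep_flat, ]
    pieces[[g]] <- piece
    pid0 <- pid0 + n
  }
  obs <- dplyr::bind_rows(pieces)
  obs$group <- assign_group(obs$tbsa)
  obs$window <- assign_window(obs$months_post_burn)
  obs
}

#' Generate a synthetic incidence table
#'
#' Draws incident case counts per (country, year, severity group) from the
#' config's incidence rates — deterministically (`"fixed"`) or as Poisson
#' counts.
#'
#' @param config A `sim_config` with a non-`NULL` `incidence` element.
#' @return Incidence tibble (`country`, `year`, `group`, `count`) with the
#'   `censor_incidence` flag attached as attribute `censor`.
#' @export
generate_incidence <- function(config) {
  validate_sim_config(config)
  if (is.null(config$incidence)) {
    stop("config carries no incidence rates", call. = FALSE)
  }
  set.seed(config$seed + 1L)
  rates <- config$incidence
  count <- if (config$incidence_mode == "poisson") {
    stats::rpois(nrow(rates), rates$rate)
  } else {
    rates$rate
  }
  out <- tibble::tibble(country = rates$country,
                        year = as.integer(rates$year),
                        group = factor(as.character(rates$group),
                                       levels = SEVERITY_GROUPS),
                        count = as.numeric(count))
  attr(out, "censor") <- config$censor_incidence
  out
}

#' Write an incidence table as delimited text
#'
#' With censoring emulation, counts between 1 and 5 are written as the
#' literal token `"1-5"`, mirroring registry privacy practice; they read
#' back as 2 via [apply_censoring()].
#'
#' @param x Incidence tibble.
#' @param path Output path.
#' @param censor Emit censored tokens; defaults to the tibble's `censor`
#'   attribute.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_incidence <- function(x, path, censor = isTRUE(attr(x, "censor")),
                            sep = ",") {
  out <- data.frame(country = x$country, year = x$year,
                    group = as.character(x$group),
                    count = as.character(x$count), stringsAsFactors = FALSE)
  if (censor) out$count[x$count >= 1 & x$count <= 5] <- "1-5"
  if ("sex" %in% names(x)) out$sex <- x$sex
  if ("age" %in% names(x)) out$age <- x$age
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' The packaged 2017 demonstration profile
#'
#' A `sim_config` whose generating disability weights are the embedded
#' published table, with 500 patients per severity group, and whose
#' incidence rates are the published 2017 incident counts for Australia,
#' New Zealand and the Netherlands (1849/839/162, 244/143/48, 445/259/40),
#' fixed (non-random) by default.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [simulation_config()].
#' @return A `sim_config`.
#' @export
paper2017_config <- function(seed = 1L, ...) {
  pub <- published_yld_2017()$by_group
  incidence <- tibble::tibble(country = pub$country, year = 2017L,
                              group = pub$group, rate = pub$incidence)
  args <- list(seed = seed,
               n_patients = c(lt5 = 500L, `5to20` = 500L, gt20 = 500L),
               incidence = incidence, censor_incidence = FALSE)
  override <- list(...)
  args[names(override)] <- override
  do.call(simulation_config, args)
}

#' Synthetic remaining-life-expectancy life table
#'
#' A deterministic, clearly synthetic life table for demos and tests:
#' 10-year bands over ages 18-100, remaining life expectancy declining
#' linearly from the low 60s at age 20, women 2 years above men.
#'
#' @return A `life_table`.
#' @export
synthetic_life_table <- function() {
  age_min <- c(18L, seq(30L, 90L, by = 10L))
  age_max <- c(seq(29L, 89L, by = 10L), 100L)
  mid <- (age_min + age_max) / 2
  male <- pmax(82 - mid, 2)
  female <- pmax(84 - mid, 2)
  life_table(sex = rep(c("male", "female"), each = length(age_min)),
             age_min = rep(age_min, 2L), age_max = rep(age_max, 2L),
             remaining_le = c(male, female))
}

#' Approximate 2017 national populations for the three demo countries
#'
#' Round national population figures (Australia 24.6M, New Zealand 4.8M,
#' Netherlands 17.1M) for demonstration per-100,000 rates. The published
#' per-100,000 figures used a denominator that is not reconstructible from
#' national populations, so rates computed with these values are
#' illustrative, not a reproduction.
#'
#' @return Named numeric vector.
#' @export
demo_population_2017 <- function() {
  c("Australia" = 24.6e6, "New Zealand" = 4.8e6, "Netherlands" = 17.1e6)
}
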