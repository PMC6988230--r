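#' Resolve censored incidence counts
#'
#' Some registries report small cell counts only as the range "between one
#' and five" for privacy; these are substituted by the assumed average of 2.
#' Accepts numeric counts or character tokens; the literal token `"1-5"`
#' (or `"1–5"`) marks a censored cell.
#'
#' @param x Numeric or character vector of counts.
#' @return Integer-valued numeric vector of resolved counts.
#' @examples
#' apply_censoring(c("12", "1-5", "0"))
#' @export
apply_censoring <- function(x) {
  if (is.numeric(x)) {
    out <- x
  } else {
    x <- trimws(as.character(x))
    censored <- x %in% c("1-5", "1–5")
    out <- suppressWarnings(as.numeric(x))
    out[censored] <- 2
    if (any(is.na(out) & !censored & x != "")) {
      stop(sprintf("unparseable incidence count %s",
                   deparse(x[which(is.na(out) & x != "")[1]])), call. = FALSE)
    }
  }
  if (any(out < 0, na.rm = TRUE)) {
    stop("incidence counts must be non-negative", call. = FALSE)
  }
  out
}

#' Read an incidence table from delimited text
#'
#' Expected columns: `country`, `year`, `group`, `count`; optional stratum
#' columns `sex` and `age`. Censored cells are encoded as the literal token
#' `"1-5"` and resolved by [apply_censoring()].
#'
#' @param path File path.
#' @param sep Field separator.
#' @return Tibble with resolved numeric counts.
#' @export
read_incidence <- function(path, sep = ",") {
  d <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                colClasses = "character")
  need <- c("country", "year", "group", "count")
  if (!all(need %in% names(d))) {
    stop("incidence file must have columns country, year, group, count",
         call. = FALSE)
  }
  bad <- !d$group %in% SEVERITY_GROUPS
  if (any(bad)) {
    stop(sprintf("unknown severity group %s in incidence file",
                 deparse(d$group[which(bad)[1]])), call. = FALSE)
  }
  out <- tibble::tibble(
    country = d$country, year = as.integer(d$year),
    group = factor(d$group, levels = SEVERITY_GROUPS),
    count = apply_censoring(d$count))
  if ("sex" %in% names(d)) out$sex <- d$sex
  if ("age" %in% names(d)) out$age <- as.numeric(d$age)
  key <- paste(out$country, out$year, out$group,
               if ("sex" %in% names(out)) out$sex else "",
               if ("age" %in% names(out)) out$age else "")
  if (anyDuplicated(key)) {
    stop("duplicate (country, year, group, stratum) rows in incidence file",
         call. = FALSE)
  }
  out
}

#' Read a remaining-life-expectancy life table from delimited text
#'
#' Expected columns: `sex`, `age_min`, `age_max`, `remaining_le` (years).
#'
#' @param path File path.
#' @param sep Field separator.
#' @return Tibble of class `life_table`.
#' @export
read_life_table <- function(path, sep = ",") {
  d <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("sex", "age_min", "age_max", "remaining_le")
  if (!all(need %in% names(d))) {
    stop("life-table file must have columns sex, age_min, age_max, remaining_le",
         call. = FALSE)
  }
  life_table(d$sex, d$age_min, d$age_max, d$remaining_le)
}

#' Construct a life table of remaining life expectancy
#'
#' @param sex Character vector, "male"/"female".
#' @param age_min,age_max Closed age-band bounds in years.
#' @param remaining_le Remaining life expectancy (years) per band; must be
#'   positive and non-increasing with age within sex.
#' @return Tibble of class `life_table`.
#' @export
life_table <- function(sex, age_min, age_max, remaining_le) {
  tab <- tibble::tibble(sex = sex, age_min = as.integer(age_min),
                        age_max = as.integer(age_max),
                        remaining_le = as.numeric(remaining_le))
  if (any(tab$remaining_le <= 0)) {
    stop("remaining life expectancy must be > 0", call. = FALSE)
  }
  for (s in unique(tab$sex)) {
    b <- tab[tab$sex == s, ]
    b <- b[order(b$age_min), ]
    if (is.unsorted(rev(b$remaining_le))) {
      stop(sprintf("remaining life expectancy must be non-increasing in age (sex '%s')", s),
           call. = FALSE)
    }
  }
  class(tab) <- c("life_table", class(tab))
  tab
}

lookup_le <- function(age, sex, life) {
  out <- rep(NA_real_, length(age))
  for (i in seq_along(age)) {
    hit <- life$sex == sex[i] & life$age_min <= age[i] & age[i] <= life$age_max
    if (any(hit)) out[i] <- life$remaining_le[which(hit)[1L]]
  }
  out
}

#' Read a population denominator table from delimited text
#'
#' Expected columns: `country`, `population`; optional `year`.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return Tibble.
#' @export
read_population <- function(path, sep = ",") {
  d <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("country", "population") %in% names(d))) {
    stop("population file must have columns country, population", call. = FALSE)
  }
  tibble::as_tibble(d)
}

#' Short-term YLD per incident case
#'
#' The short-term (first two years) YLD of one case is the sum over the four
#' short-term recovery windows of the window's mean disability weight times
#' its duration: `dw(0-1) * 1/12 + dw(>1-6) * 5/12 + dw(>6-12) * 6/12 +
#' dw(>12-24) * 1`.
#'
#' @param dws A `dw_table`.
#' @param group Severity group key.
#' @return Years of YLD per case (scalar).
#' @export
short_term_yld_per_case <- function(dws, group) {
  dur <- window_durations()
  short <- setdiff(RECOVERY_WINDOWS, "long")
  w <- vapply(short, function(win) dw_cell(dws, group, win), numeric(1))
  if (any(is.na(w))) {
    stop(sprintf("missing short-term disability weight cell(s) for group %s: %s",
                 group, paste(short[is.na(w)], collapse = ", ")), call. = FALSE)
  }
  sum(w * dur[short])
}

#' Long-term YLD per incident case
#'
#' The lifelong fraction of cases carries the long-term (>24 month)
#' disability weight for the remaining life expectancy minus the two years
#' already covered by the short-term windows (floored at zero).
#'
#' @param p_lifelong Lifelong-disability proportion in \[0, 1\].
#' @param dw_long Long-term mean disability weight.
#' @param remaining_le Remaining life expectancy at injury, years.
#' @return Years of YLD per case.
#' @export
long_term_yld_per_case <- function(p_lifelong, dw_long, remaining_le) {
  if (any(p_lifelong < 0 | p_lifelong > 1, na.rm = TRUE)) {
    stop("lifelong proportion must lie in [0, 1]", call. = FALSE)
  }
  if (any(remaining_le < 0, na.rm = TRUE)) {
    stop("remaining life expectancy must be >= 0", call. = FALSE)
  }
  p_lifelong * dw_long * pmax(remaining_le - 2, 0)
}

#' Compute incidence-based years lived with disability
#'
#' Combines severity-grouped incidence counts with the disability-weight
#' table, lifelong proportions and remaining life expectancy:
#' `YLD = incident cases x disability weight x duration`, split into the
#' short-term (fixed window durations over the first two years) and the
#' long-term (lifelong fraction x long-term weight x (remaining life
#' expectancy - 2)).
#'
#' @param incidence Incidence tibble (`country`, `year`, `group`, `count`,
#'   optional `sex`/`age` strata), e.g. from [read_incidence()].
#' @param dws Disability weight table; default the embedded published table.
#' @param props Lifelong proportions; default the published 20/25/39%.
#' @param life Either a `life_table` (used when the incidence rows carry
#'   `sex` and `age`) or a named numeric vector of per-country scalar
#'   remaining life expectancy at the mean age at injury. No hidden default:
#'   the duration of lifelong disability is an explicit modelling input.
#' @param population Optional denominators for per-100,000 rates: named
#'   numeric vector (country -> population) or tibble with `country`,
#'   `population` and optionally `year`. When absent, per-100k columns are
#'   `NA` with a warning.
#' @return Object of class `yld_result`: list with tibbles `by_group`
#'   (per country/year/group: incidence, yld_short, yld_long, yld_total,
#'   yld_per_case, yld_per_100k) and `totals` (per country/year).
#' @export
compute_yld <- function(incidence, dws = default_dw_table(),
                        props = default_lifelong_proportions(),
                        life, population = NULL) {
  stopifnot(nrow(incidence) > 0)
  groups_used <- unique(as.character(incidence$group))
  if (!all(groups_used %in% SEVERITY_GROUPS)) {
    stop("incidence contains unknown severity groups", call. = FALSE)
  }
  for (g in groups_used) {
    if (is.na(props[g])) {
      stop(sprintf("no lifelong proportion for group %s", g), call. = FALSE)
    }
  }
  st_per_case <- stats::setNames(
    vapply(groups_used, function(g) short_term_yld_per_case(dws, g), numeric(1)),
    groups_used)
  dw_long <- stats::setNames(
    vapply(groups_used, function(g) dw_cell(dws, g, "long"), numeric(1)),
    groups_used)
  if (any(is.na(dw_long))) {
    stop(sprintf("missing long-term disability weight for group(s): %s",
                 paste(groups_used[is.na(dw_long)], collapse = ", ")),
         call. = FALSE)
  }

  stratified <- all(c("sex", "age") %in% names(incidence))
  if (inherits(life, "life_table")) {
    if (!stratified) {
      stop("a life_table requires sex/age strata in the incidence table; ",
           "supply a named per-country scalar LE for unstratified input",
           call. = FALSE)
    }
    le <- lookup_le(incidence$age, incidence$sex, life)
    if (any(is.na(le))) {
      bad <- unique(paste0(incidence$sex, "/", incidence$age)[is.na(le)])
      stop(sprintf("life table does not cover strata: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  } else if (is.numeric(life) && !is.null(names(life))) {
    miss <- setdiff(unique(incidence$country), names(life))
    if (length(miss)) {
      stop(sprintf("no remaining life expectancy supplied for: %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    le <- unname(life[incidence$country])
  } else {
    stop("'life' must be a life_table or a named per-country numeric vector",
         call. = FALSE)
  }

  g <- as.character(incidence$group)
  rows <- tibble::tibble(
    country = incidence$country, year = incidence$year, group = g,
    count = incidence$count,
    yld_short = incidence$count * unname(st_per_case[g]),
    yld_long = incidence$count *
      long_term_yld_per_case(unname(props[g]), unname(dw_long[g]), le))

  by_group <- rows |>
    dplyr::group_by(.data$country, .data$year, .data$group) |>
    dplyr::summarise(incidence = sum(.data$count),
                     yld_short = sum(.data$yld_short),
                     yld_long = sum(.data$yld_long), .groups = "drop") |>
    dplyr::mutate(yld_total = .data$yld_short + .data$yld_long,
                  yld_per_case = ifelse(.data$incidence > 0,
                                        .data$yld_total / .data$incidence,
                                        NA_real_))
  by_group$group <- factor(by_group$group, levels = SEVERITY_GROUPS)
  by_group <- dplyr::arrange(by_group, .data$country, .data$year, .data$group)

  totals <- by_group |>
    dplyr::group_by(.data$country, .data$year) |>
    dplyr::summarise(incidence = sum(.data$incidence),
                     yld_short = sum(.data$yld_short),
                     yld_long = sum(.data$yld_long),
                     yld_total = sum(.data$yld_total), .groups = "drop") |>
    dplyr::mutate(yld_per_case = ifelse(.data$incidence > 0,
                                        .data$yld_total / .data$incidence,
                                        NA_real_))

  pop_of <- function(country, year) {
    if (is.null(population)) return(NA_real_)
    if (is.numeric(population) && !is.null(names(population))) {
      return(unname(population[country]))
    }
    hit <- population$country == country
    if ("year" %in% names(population)) hit <- hit & population$year == year
    if (!any(hit)) return(NA_real_)
    population$population[which(hit)[1L]]
  }
  if (is.null(population)) {
    warning("no population denominators supplied; per-100,000 rates omitted")
    totals$yld_per_100k <- NA_real_
    by_group$yld_per_100k <- NA_real_
  } else {
    pops_t <- unname(mapply(pop_of, totals$country, totals$year))
    totals$yld_per_100k <- totals$yld_total / pops_t * 1e5
    pops_g <- unname(mapply(pop_of, by_group$country, by_group$year))
    by_group$yld_per_100k <- by_group$yld_total / pops_g * 1e5
  }

  structure(list(by_group = by_group, totals = totals), class = "yld_result")
}

#' @export
print.yld_result <- function(x, ...) {
  for (i in seq_len(nrow(x$totals))) {
    co <- x$totals$country[i]; yr <- x$totals$year[i]
    cat(sprintf("== %s, %d ==\n", co, yr))
    bg <- x$by_group[x$by_group$country == co & x$by_group$year == yr, ]
    for (j in seq_len(nrow(bg))) {
      cat(sprintf("  %-22s incidence %6d  YLD %8.1f  per case %5.2f%s\n",
                  SEVERITY_LABELS[as.character(bg$group[j])], bg$incidence[j],
                  bg$yld_total[j], bg$yld_per_case[j],
                  if (is.na(bg$yld_per_100k[j])) "" else
                    sprintf("  per 100k %6.1f", bg$yld_per_100k[j])))
    }
    cat(sprintf("  %-22s incidence %6d  YLD %8.1f  per case %5.2f%s\n",
                "Total", x$totals$incidence[i], x$totals$yld_total[i],
                x$totals$yld_per_case[i],
                if (is.na(x$totals$yld_per_100k[i])) "" else
                  sprintf("  per 100k %6.1f", x$totals$yld_per_100k[i])))
  }
  invisible(x)
}

#' Write a YLD result to delimited text
#'
#' Emits group-level rows plus per-country `total` rows; reported values
#' are rounded for display (YLD to 1 decimal, per-case to 2, per-100k to 1)
#' unless `round = FALSE`.
#'
#' @param x A `yld_result`.
#' @param path Output path.
#' @param sep Field separator.
#' @param round Apply report rounding.
#' @return `path`, invisibly.
#' @export
write_yld_report <- function(x, path, sep = ",", round = TRUE) {
  bg <- x$by_group
  bg$group <- as.character(bg$group)
  tot <- x$totals
  tot$group <- "total"
  tot <- tot[, names(bg)]
  out <- as.data.frame(rbind(bg, tot))
  out <- out[order(out$country, out$year, match(out$group, c(SEVERITY_GROUPS, "total"))), ]
  if (round) {
    for (col in c("yld_short", "yld_long", "yld_total", "yld_per_100k")) {
      out[[col]] <- round(out[[col]], 1)
    }
    out$yld_per_case <- round(out$yld_per_case, 2)
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

# ---- published reference values ---------------------------------------

#' Published 2017 YLD estimates for Australia, New Zealand, the Netherlands
#'
#' The published application of the method to 2017 incidence data: per
#' severity group and country, incident case counts, total YLDs, YLD per
#' case and YLD per 100,000 population, plus country totals. Embedded as a
#' validation reference (the underlying registry microdata are not
#' redistributable).
#'
#' @return List with tibbles `by_group` and `totals`.
#' @export
published_yld_2017 <- function() {
  by_group <- tibble::tribble(
    ~country,      ~group,  ~incidence, ~yld,   ~yld_per_case, ~yld_per_100k,
    "Australia",   "lt5",   1849L,      1205.7, 0.65,          122.5,
    "Australia",   "5to20", 839L,       1217.0, 1.45,          119.6,
    "Australia",   "gt20",  162L,       419.2,  2.59,          38.8,
    "New Zealand", "lt5",   244L,       166.5,  0.68,          91.4,
    "New Zealand", "5to20", 143L,       233.8,  1.63,          132.6,
    "New Zealand", "gt20",  48L,        122.0,  2.54,          55.2,
    "Netherlands", "lt5",   445L,       288.2,  0.65,          48.3,
    "Netherlands", "5to20", 259L,       402.0,  1.55,          75.7,
    "Netherlands", "gt20",  40L,        80.4,   2.01,          9.3
  )
  totals <- tibble::tribble(
    ~country,      ~incidence, ~yld,   ~yld_per_case, ~yld_per_100k,
    "Australia",   2850L,      2841.9, 1.00,          280.9,
    "New Zealand", 435L,       522.2,  1.20,          279.2,
    "Netherlands", 744L,       770.6,  1.04,          133.3
  )
  by_group$group <- factor(by_group$group, levels = SEVERITY_GROUPS)
  list(by_group = by_group, totals = totals)
}

#' GBD 2017 burn YLD rates per 100,000
#'
#' The Global Burden of Disease study's 2017 burn YLD rates per 100,000 for
#' the same three countries, used to contextualise the method's estimates
#' (which run 1.7-2.1 times higher).
#'
#' @return Named numeric vector.
#' @export
gbd_yld_per_100k_2017 <- function() {
  c("Australia" = 137, "New Zealand" = 165, "Netherlands" = 78)
}
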