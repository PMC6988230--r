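# Severity groups and recovery windows are the pipeline's two stratifiers;
# their codes are used as keys throughout.
SEVERITY_GROUPS <- c("lt5", "5to20", "gt20")
SEVERITY_LABELS <- c(lt5 = "<5% TBSA (or missing)", `5to20` = "5-20% TBSA",
                     gt20 = ">20% TBSA")
RECOVERY_WINDOWS <- c("m0_1", "m1_6", "m6_12", "m12_24", "long")
WINDOW_LABELS <- c(m0_1 = "0-1 months", m1_6 = ">1-6 months",
                   m6_12 = ">6-12 months", m12_24 = ">12-24 months",
                   long = ">24 months")

#' Severity group and recovery window keys
#'
#' Patients are partitioned by burned body surface into three groups —
#' `"lt5"` (<5% TBSA or %TBSA missing), `"5to20"` (5-20% inclusive) and
#' `"gt20"` (>20%) — and observations into five post-burn recovery windows:
#' `"m0_1"` (0-1 months), `"m1_6"`, `"m6_12"`, `"m12_24"` and `"long"`
#' (>24 months).
#'
#' @return Character vector of keys, in severity / time order.
#' @export
severity_groups <- function() SEVERITY_GROUPS

#' @rdname severity_groups
#' @export
recovery_windows <- function() RECOVERY_WINDOWS

#' Durations of the recovery windows, in years
#'
#' The four short-term windows last 1/12, 5/12, 6/12 and 1 year (summing to
#' the 2-year short-term horizon); the long-term window has no fixed
#' duration (it is the remaining life expectancy minus 2 years for the
#' lifelong fraction) and is returned as `NA`.
#'
#' @return Named numeric vector over the five windows.
#' @export
window_durations <- function() {
  c(m0_1 = 1 / 12, m1_6 = 5 / 12, m6_12 = 6 / 12, m12_24 = 1, long = NA_real_)
}

#' Assign %TBSA values to severity groups
#'
#' Missing %TBSA maps to the mildest group, matching registry practice where
#' unrecorded extent overwhelmingly means a small burn. Boundaries: 5 and 20
#' belong to the middle group (inclusive "5-20%" reading).
#'
#' @param tbsa Numeric vector of %TBSA burned in \[0, 100\]; `NA` allowed.
#' @return Factor with levels `severity_groups()`.
#' @examples
#' assign_group(c(4.9, NA, 5, 20, 20.1))
#' @export
assign_group <- function(tbsa) {
  if (any(tbsa < 0 | tbsa > 100, na.rm = TRUE)) {
    stop("tbsa must lie in [0, 100] (or be missing)", call. = FALSE)
  }
  key <- ifelse(is.na(tbsa) | tbsa < 5, "lt5",
                ifelse(tbsa <= 20, "5to20", "gt20"))
  factor(key, levels = SEVERITY_GROUPS)
}

#' Assign months post-burn to recovery windows
#'
#' Windows are half-open on the left, closed on the right: (0,1\], (1,6\],
#' (6,12\], (12,24\], (24, Inf), matching the ">1-6" style labels; 24.0
#' months is still short-term.
#'
#' @param months Numeric vector, months post-burn, strictly positive.
#' @return Factor with levels `recovery_windows()`.
#' @examples
#' assign_window(c(0.75, 6, 6.01, 24, 60))
#' @export
assign_window <- function(months) {
  if (any(is.na(months)) || any(months <= 0)) {
    stop("months post-burn must be > 0 and non-missing", call. = FALSE)
  }
  key <- cut(months, breaks = c(0, 1, 6, 12, 24, Inf),
             labels = RECOVERY_WINDOWS, right = TRUE)
  factor(as.character(key), levels = RECOVERY_WINDOWS)
}

#' Convert day counts to months post-burn
#'
#' Uses the mean Gregorian month, 365.25/12 days.
#'
#' @param days Numeric vector of days post-burn.
#' @return Months post-burn.
#' @export
days_to_months <- function(days) days / (365.25 / 12)

#' Load a longitudinal HRQL cohort from delimited text
#'
#' Expected columns: `patient_id`, `age`, `sex`, `tbsa`, `months_post_burn`,
#' and either the five level columns `mo, sc, ua, pd, ad` or a `utility`
#' column (or both; `utility`, when present, is taken as authoritative).
#' Missing values are empty fields. Rows failing validation (age < 18,
#' levels outside 1-3, non-positive months, tbsa outside \[0,100\], utility
#' out of bounds) are collected — with line numbers — in the `rejected`
#' attribute, never silently dropped.
#'
#' @param path File path.
#' @param sep Field separator, default comma.
#' @param vs Value set used to score states when no `utility` column is
#'   present.
#' @param quiet Suppress the accepted/rejected row count message.
#' @return A tibble of observations (`patient_id`, `age`, `sex`, `tbsa`,
#'   `months_post_burn`, `state` (possibly `NA`), `utility`, `group`,
#'   `window`), with attribute `rejected` (tibble: `line`, `reason`).
#' @export
load_cohort <- function(path, sep = ",", vs = uk_tto_value_set(),
                        quiet = FALSE) {
  d <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                colClasses = "character")
  mandatory <- c("patient_id", "age", "sex", "tbsa", "months_post_burn")
  missing_cols <- setdiff(mandatory, names(d))
  if (length(missing_cols)) {
    stop(sprintf("cohort file lacks mandatory columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  has_levels <- all(c("mo", "sc", "ua", "pd", "ad") %in% names(d))
  has_utility <- "utility" %in% names(d)
  if (!has_levels && !has_utility) {
    stop("cohort file needs either level columns mo,sc,ua,pd,ad or a utility column",
         call. = FALSE)
  }
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))

  rows <- vector("list", nrow(d))
  rejects <- list()
  reject <- function(line, reason) {
    rejects[[length(rejects) + 1L]] <<- tibble::tibble(line = line, reason = reason)
  }
  floor_u <- -0.594
  for (i in seq_len(nrow(d))) {
    line <- i + 1L  # header is line 1
    age <- num(d$age[i]); months <- num(d$months_post_burn[i])
    tbsa <- num(d$tbsa[i]); sex <- d$sex[i]
    if (is.na(age) || age < 18) { reject(line, "age missing or < 18"); next }
    if (!sex %in% c("male", "female")) { reject(line, "sex not male/female"); next }
    if (!is.na(tbsa) && (tbsa < 0 || tbsa > 100)) {
      reject(line, "tbsa outside [0,100]"); next
    }
    if (is.na(months) || months <= 0) {
      reject(line, "months_post_burn missing or <= 0"); next
    }
    state <- NA_character_
    utility <- NA_real_
    if (has_levels && all(d[i, c("mo", "sc", "ua", "pd", "ad")] != "")) {
      code <- paste0(d$mo[i], d$sc[i], d$ua[i], d$pd[i], d$ad[i])
      if (grepl("^[1-3]{5}$", code)) {
        state <- code
      } else {
        reject(line, sprintf("invalid EQ-5D-3L levels '%s'", code)); next
      }
    }
    if (has_utility && d$utility[i] != "") {
      utility <- num(d$utility[i])
      if (is.na(utility) || utility < floor_u - 1e-9 || utility > 1 + 1e-9) {
        reject(line, "utility outside [-0.594, 1]"); next
      }
    } else if (!is.na(state)) {
      utility <- unname(score_utility(state, vs))
    } else {
      reject(line, "neither complete levels nor utility present"); next
    }
    rows[[i]] <- tibble::tibble(
      patient_id = d$patient_id[i], age = age, sex = sex, tbsa = tbsa,
      months_post_burn = months, state = state, utility = utility)
  }
  obs <- dplyr::bind_rows(rows)
  if (nrow(obs) == 0) {
    obs <- tibble::tibble(patient_id = character(), age = numeric(),
                          sex = character(), tbsa = numeric(),
                          months_post_burn = numeric(), state = character(),
                          utility = numeric())
  }
  obs$group <- assign_group(obs$tbsa)
  obs$window <- assign_window(obs$months_post_burn)
  rejected <- if (length(rejects)) dplyr::bind_rows(rejects) else
    tibble::tibble(line = integer(), reason = character())
  if (!quiet) {
    message(sprintf("cohort: %d observation(s) accepted, %d row(s) rejected",
                    nrow(obs), nrow(rejected)))
    if (nrow(rejected)) {
      for (j in seq_len(nrow(rejected))) {
        message(sprintf("  line %d: %s", rejected$line[j], rejected$reason[j]))
      }
    }
  }
  attr(obs, "rejected") <- rejected
  obs
}

#' Write a cohort to delimited text
#'
#' Writes the schema read by [load_cohort()]; level columns are emitted when
#' states are present. Round-trips losslessly.
#'
#' @param obs Observation tibble as returned by [load_cohort()] or
#'   [generate_cohort()].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(obs, path, sep = ",") {
  out <- data.frame(patient_id = obs$patient_id, age = obs$age, sex = obs$sex,
                    tbsa = obs$tbsa, months_post_burn = obs$months_post_burn,
                    stringsAsFactors = FALSE)
  if ("state" %in% names(obs) && any(!is.na(obs$state))) {
    lv <- matrix(NA_integer_, nrow(out), 5L)
    ok <- !is.na(obs$state)
    if (any(ok)) lv[ok, ] <- eq5d_levels(obs$state[ok])
    out$mo <- lv[, 1]; out$sc <- lv[, 2]; out$ua <- lv[, 3]
    out$pd <- lv[, 4]; out$ad <- lv[, 5]
  }
  out$utility <- obs$utility
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}
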