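#' Classify a two-year EQ-5D-3L profile as lifelong disability
#'
#' A patient is assumed to carry lifelong disability when the assessment at
#' two-year follow-up reports a severe problem (level 3) in any of the five
#' dimensions, or mild problems (level 2 or worse) on both pain/discomfort
#' and anxiety/depression — the two dimensions most often affected in the
#' long term after burns.
#'
#' @param state Character vector of 5-digit EQ-5D-3L state codes (the
#'   caller guarantees these are the two-year assessments).
#' @return Logical vector.
#' @examples
#' classify_lifelong(c("11111", "31111", "11122", "11121"))
#' @export
classify_lifelong <- function(state) {
  lv <- eq5d_levels(state)
  any_severe <- rowSums(lv == 3L) > 0L
  both_mild <- lv[, "pain_discomfort"] >= 2L & lv[, "anxiety_depression"] >= 2L
  unname(any_severe | both_mild)
}

#' Estimate lifelong-disability proportions by severity group
#'
#' Selects, per patient, the assessment in the >12-24 month window closest
#' to 24 months (later one on ties), applies [classify_lifelong()], and
#' reports the classified-positive fraction per severity group. Patients
#' without any >12-24 month assessment carrying a health-state profile are
#' excluded (not imputed); groups with no eligible patients get `NA` and a
#' warning, and downstream use should fall back to
#' [default_lifelong_proportions()].
#'
#' @param obs Observation tibble with `patient_id`, `group`, `window`,
#'   `months_post_burn`, `state`.
#' @return Named numeric vector over `severity_groups()` with attribute
#'   `n_patients`.
#' @export
estimate_lifelong_proportions <- function(obs) {
  two_year <- obs[obs$window == "m12_24" & !is.na(obs$state), , drop = FALSE]
  if (nrow(two_year) == 0) {
    warning("no two-year (>12-24 month) assessments with health states; all proportions NA")
    p <- stats::setNames(rep(NA_real_, 3L), SEVERITY_GROUPS)
    attr(p, "n_patients") <- stats::setNames(rep(0L, 3L), SEVERITY_GROUPS)
    return(p)
  }
  picked <- two_year |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::arrange(abs(.data$months_post_burn - 24),
                   dplyr::desc(.data$months_post_burn), .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  picked$lifelong <- classify_lifelong(picked$state)
  p <- stats::setNames(rep(NA_real_, 3L), SEVERITY_GROUPS)
  n <- stats::setNames(rep(0L, 3L), SEVERITY_GROUPS)
  for (g in SEVERITY_GROUPS) {
    sub <- picked[picked$group == g, ]
    n[g] <- nrow(sub)
    if (nrow(sub) > 0) p[g] <- mean(sub$lifelong)
  }
  if (any(n == 0)) {
    warning(sprintf("no eligible two-year patients in group(s): %s",
                    paste(SEVERITY_GROUPS[n == 0], collapse = ", ")))
  }
  attr(p, "n_patients") <- n
  p
}

#' Published lifelong-disability proportions
#'
#' The fractions of patients with lifelong disability per severity group as
#' derived from the pooled burn cohort (and externally validated by expert
#' survey): 20% for <5% TBSA, 25% for 5-20% TBSA, 39% for >20% TBSA.
#'
#' @return Named numeric vector over `severity_groups()`.
#' @export
default_lifelong_proportions <- function() {
  c(lt5 = 0.20, `5to20` = 0.25, gt20 = 0.39)
}

#' Write / read lifelong proportions as delimited text
#'
#' Columns: `group`, `proportion`.
#'
#' @param p Named numeric vector over `severity_groups()`.
#' @param path File path.
#' @param sep Field separator.
#' @return `path` (write) or the named vector (read).
#' @export
write_proportions <- function(p, path, sep = ",") {
  utils::write.table(
    data.frame(group = names(p), proportion = unname(p)),
    path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_proportions
#' @export
read_proportions <- function(path, sep = ",") {
  d <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("group", "proportion") %in% names(d))) {
    stop("proportions file must have columns group, proportion", call. = FALSE)
  }
  if (any(d$proportion < 0 | d$proportion > 1, na.rm = TRUE)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  p <- stats::setNames(d$proportion, d$group)
  p[SEVERITY_GROUPS]
}
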