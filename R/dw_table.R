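#' Estimate the severity-group x recovery-window disability weight table
#'
#' Each observation's disability weight is the age/sex population norm
#' utility minus the observed utility; cell estimates are arithmetic means
#' over the observations (or patients, see `level`) falling in that
#' (severity group, recovery window) cell, with a 95% confidence interval.
#' All 15 cells are always returned; cells without data carry `NA` estimates
#' and `n = 0`, and a cell with a single observation has an undefined CI
#' (`NA` bounds).
#'
#' @param obs Observation tibble with columns `age`, `sex`, `utility`,
#'   `group`, `window` (as from [load_cohort()] or [generate_cohort()]);
#'   a `dw` column, if present, is used directly.
#' @param norms Population norm table for the norm lookup.
#' @param level `"observation"` pools all assessments (matching how the
#'   source registries count outcomes); `"patient"` first averages each
#'   patient's assessments within a cell, then averages across patients.
#' @param ci_method `"normal"` (mean +/- 1.96 SE), `"t"` (Student-t
#'   quantile), or `"bootstrap"` (seeded percentile bootstrap).
#' @param conf Confidence level, default 0.95.
#' @param boot_reps,boot_seed Bootstrap replicates and seed (bootstrap
#'   method only).
#' @return A tibble of class `dw_table` with columns `group`, `window`,
#'   `mean_dw`, `ci_low`, `ci_high`, `n`.
#' @export
estimate_dw_table <- function(obs, norms = default_norm_table(),
                              level = c("observation", "patient"),
                              ci_method = c("normal", "t", "bootstrap"),
                              conf = 0.95, boot_reps = 1000L,
                              boot_seed = 1L) {
  level <- match.arg(level)
  ci_method <- match.arg(ci_method)
  if (is.null(obs) || nrow(obs) == 0) {
    stop("no observations to aggregate", call. = FALSE)
  }
  if (!"dw" %in% names(obs)) {
    obs$dw <- disability_weight(obs$utility, lookup_norm(obs$age, obs$sex, norms))
  }
  if (level == "patient") {
    obs <- obs |>
      dplyr::group_by(.data$patient_id, .data$group, .data$window) |>
      dplyr::summarise(dw = mean(.data$dw), .groups = "drop")
  }
  alpha <- 1 - conf
  cells <- expand.grid(group = SEVERITY_GROUPS, window = RECOVERY_WINDOWS,
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    x <- obs$dw[obs$group == cells$group[i] & obs$window == cells$window[i]]
    n <- length(x)
    if (n == 0) {
      return(tibble::tibble(group = cells$group[i], window = cells$window[i],
                            mean_dw = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, n = 0L))
    }
    m <- mean(x)
    if (n == 1) {
      lo <- hi <- NA_real_
    } else if (ci_method == "normal") {
      se <- stats::sd(x) / sqrt(n)
      z <- stats::qnorm(1 - alpha / 2)
      lo <- m - z * se; hi <- m + z * se
    } else if (ci_method == "t") {
      se <- stats::sd(x) / sqrt(n)
      tq <- stats::qt(1 - alpha / 2, df = n - 1)
      lo <- m - tq * se; hi <- m + tq * se
    } else {
      set.seed(boot_seed)
      boots <- vapply(seq_len(boot_reps),
                      function(b) mean(sample(x, n, replace = TRUE)),
                      numeric(1))
      qs <- stats::quantile(boots, c(alpha / 2, 1 - alpha / 2), names = FALSE)
      lo <- qs[1]; hi <- qs[2]
    }
    tibble::tibble(group = cells$group[i], window = cells$window[i],
                   mean_dw = m, ci_low = lo, ci_high = hi, n = n)
  })
  out <- dplyr::bind_rows(res)
  out$group <- factor(out$group, levels = SEVERITY_GROUPS)
  out$window <- factor(out$window, levels = RECOVERY_WINDOWS)
  out <- dplyr::arrange(out, .data$group, .data$window)
  class(out) <- c("dw_table", class(out))
  out
}

#' Published burn disability weights by severity group and recovery window
#'
#' The embedded default table: mean disability weights with 95% CIs for the
#' three %TBSA severity groups across the five recovery windows, as
#' published for the pooled European / Western Australian adult burn cohort
#' (7159 EQ-5D-3L outcomes from 3401 patients). Cell-level sample sizes were
#' not published; the per-window outcome counts (1056, 3238, 1355, 1001,
#' 509 for the five windows) are attached as attribute
#' `window_outcome_counts`.
#'
#' @return A `dw_table` (15 rows; `n` is `NA`).
#' @export
default_dw_table <- function() {
  tab <- tibble::tribble(
    ~group,   ~window,   ~mean_dw, ~ci_low, ~ci_high,
    "lt5",    "m0_1",    0.173,    0.152,   0.195,
    "lt5",    "m1_6",    0.098,    0.090,   0.106,
    "lt5",    "m6_12",   0.082,    0.067,   0.097,
    "lt5",    "m12_24",  0.102,    0.080,   0.123,
    "lt5",    "long",    0.046,    0.026,   0.067,
    "5to20",  "m0_1",    0.264,    0.238,   0.289,
    "5to20",  "m1_6",    0.139,    0.128,   0.150,
    "5to20",  "m6_12",   0.118,    0.104,   0.133,
    "5to20",  "m12_24",  0.108,    0.092,   0.124,
    "5to20",  "long",    0.099,    0.077,   0.122,
    "gt20",   "m0_1",    0.497,    0.438,   0.557,
    "gt20",   "m1_6",    0.262,    0.235,   0.290,
    "gt20",   "m6_12",   0.231,    0.198,   0.263,
    "gt20",   "m12_24",  0.163,    0.134,   0.191,
    "gt20",   "long",    0.122,    0.092,   0.152
  )
  tab$group <- factor(tab$group, levels = SEVERITY_GROUPS)
  tab$window <- factor(tab$window, levels = RECOVERY_WINDOWS)
  tab$n <- NA_integer_
  attr(tab, "window_outcome_counts") <-
    c(m0_1 = 1056L, m1_6 = 3238L, m6_12 = 1355L, m12_24 = 1001L, long = 509L)
  class(tab) <- c("dw_table", class(tab))
  tab
}

#' Fetch one cell of a disability weight table
#'
#' @param dws A `dw_table`.
#' @param group Severity group key.
#' @param window Recovery window key.
#' @param what Column to return, default `"mean_dw"`.
#' @return Scalar value of that cell (possibly `NA`).
#' @export
dw_cell <- function(dws, group, window, what = "mean_dw") {
  hit <- dws$group == group & dws$window == window
  if (!any(hit)) stop(sprintf("no cell (%s, %s) in table", group, window),
                      call. = FALSE)
  dws[[what]][which(hit)[1L]]
}

#' Write / read a disability weight table as delimited text
#'
#' Columns: `group`, `window`, `mean_dw`, `ci_low`, `ci_high`, `n`.
#'
#' @param dws A `dw_table`.
#' @param path File path.
#' @param sep Field separator.
#' @return `path` (write) or a `dw_table` (read).
#' @export
write_dw_table <- function(dws, path, sep = ",") {
  out <- as.data.frame(dws)
  out$group <- as.character(out$group)
  out$window <- as.character(out$window)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_dw_table
#' @export
read_dw_table <- function(path, sep = ",") {
  d <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("group", "window", "mean_dw", "ci_low", "ci_high")
  if (!all(need %in% names(d))) {
    stop("disability-weight file must have columns group, window, mean_dw, ci_low, ci_high",
         call. = FALSE)
  }
  if (is.null(d$n)) d$n <- NA_integer_
  d$group <- factor(d$group, levels = SEVERITY_GROUPS)
  d$window <- factor(d$window, levels = RECOVERY_WINDOWS)
  tab <- tibble::as_tibble(d[, c(need, "n")])
  class(tab) <- c("dw_table", class(tab))
  tab
}

# ---- Mann-Whitney U ----------------------------------------------------

# U statistic for sample a: number of (a_i, b_j) pairs with a_i > b_j, ties
# counting one half. Equivalent to R_a - n_a(n_a+1)/2 with midranks.
mwu_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Two-sided Mann-Whitney U comparison of two disability-weight samples
#'
#' For combined sample sizes up to `exact_max` the p-value is computed by
#' exact enumeration of all assignments of the pooled values to the two
#' groups (valid under ties); beyond that a tie-corrected normal
#' approximation without continuity correction is used.
#'
#' @param a,b Numeric samples (e.g. per-observation disability weights of
#'   two subgroups).
#' @param labels Length-2 character vector naming the groups.
#' @param exact_max Largest combined n for which enumeration is used.
#' @return A list of class `mwu_result` with `statistic` (U of sample `a`),
#'   `p_value`, `labels` and `method`.
#' @export
compare_subgroups <- function(a, b, labels = c("a", "b"), exact_max = 10L) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  U <- mwu_statistic(a, b)
  mu <- n1 * n2 / 2
  if (N <= exact_max) {
    pooled <- c(a, b)
    idx <- utils::combn(N, n1)
    us <- apply(idx, 2L, function(k) mwu_statistic(pooled[k], pooled[-k]))
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    r <- rank(c(a, b))
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation with tie correction"
  }
  structure(list(statistic = U, p_value = min(p, 1), labels = labels,
                 method = method),
            class = "mwu_result")
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U (%s vs %s): U = %g, p = %.4g [%s]\n",
              x$labels[1], x$labels[2], x$statistic, x$p_value, x$method))
  invisible(x)
}
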