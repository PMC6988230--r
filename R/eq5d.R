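#' @importFrom stats rnorm qnorm qt quantile sd pnorm
#' @importFrom utils read.csv write.csv head
NULL

# Dimension order is fixed throughout: mobility, self-care, usual activities,
# pain/discomfort, anxiety/depression.
EQ5D_DIMENSIONS <- c("mobility", "self_care", "usual_activities",
                     "pain_discomfort", "anxiety_depression")

#' Parse EQ-5D-3L health-state codes into a level matrix
#'
#' A health state is the 5-character digit string of dimension levels in the
#' fixed order mobility, self-care, usual activities, pain/discomfort,
#' anxiety/depression, e.g. `"21232"`. Each level must be 1 (no problems),
#' 2 (some problems) or 3 (severe problems).
#'
#' @param state Character vector of 5-digit state codes.
#' @return Integer matrix with one row per state and one column per dimension.
#' @examples
#' eq5d_levels(c("11111", "21232"))
#' @export
eq5d_levels <- function(state) {
  if (!is.character(state)) {
    stop("health state must be a character vector of 5-digit codes", call. = FALSE)
  }
  bad <- is.na(state) | nchar(state) != 5L | grepl("[^1-3]", state)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf(
      "invalid EQ-5D-3L state code %s at position %d: must be 5 digits, each in 1-3",
      deparse(state[i]), i), call. = FALSE)
  }
  m <- matrix(as.integer(unlist(strsplit(state, "", fixed = TRUE))),
              ncol = 5L, byrow = TRUE)
  colnames(m) <- EQ5D_DIMENSIONS
  m
}

#' Serialize dimension levels to 5-digit state codes
#'
#' Inverse of [eq5d_levels()].
#'
#' @param levels Integer matrix (n x 5) of levels in 1-3, dimension order
#'   mobility, self-care, usual activities, pain/discomfort,
#'   anxiety/depression.
#' @return Character vector of state codes.
#' @export
eq5d_state <- function(levels) {
  levels <- as.matrix(levels)
  if (ncol(levels) != 5L || any(!levels %in% 1:3)) {
    stop("levels must be an n x 5 matrix with entries in 1-3", call. = FALSE)
  }
  apply(levels, 1L, paste0, collapse = "")
}

#' All 243 EQ-5D-3L health states
#'
#' @return Character vector of the 3^5 = 243 state codes, in lexicographic
#'   order ("11111" first, "33333" last).
#' @export
all_health_states <- function() {
  g <- expand.grid(ad = 1:3, pd = 1:3, ua = 1:3, sc = 1:3, mo = 1:3)
  sort(paste0(g$mo, g$sc, g$ua, g$pd, g$ad))
}

#' Construct an EQ-5D-3L value set (tariff)
#'
#' A value set converts a health state into a utility on a scale anchored at
#' 1 (full health) and 0 (death); states worse than death take negative
#' values. The additive model is
#' `utility = full_health - any_dysfunction [if any level > 1]
#'  - sum of per-dimension level decrements - any_level3 [if any level = 3]`.
#'
#' @param name Identifier for the tariff.
#' @param full_health Utility of state "11111" (usually 1).
#' @param any_dysfunction Constant decrement applied once if any dimension is
#'   above level 1.
#' @param level2,level3 Named numeric vectors of per-dimension decrements for
#'   levels 2 and 3; names must be the five dimensions.
#' @param any_level3 Constant decrement applied once if any dimension is at
#'   level 3.
#' @return An object of class `eq5d_value_set`.
#' @seealso [uk_tto_value_set()] for the embedded UK tariff,
#'   [read_value_set()] to load one from file.
#' @export
value_set <- function(name, full_health, any_dysfunction, level2, level3,
                      any_level3) {
  level2 <- level2[EQ5D_DIMENSIONS]
  level3 <- level3[EQ5D_DIMENSIONS]
  dec <- c(any_dysfunction, level2, level3, any_level3)
  if (any(is.na(dec)) || any(dec < 0)) {
    stop("all value-set decrements must be present and >= 0", call. = FALSE)
  }
  structure(list(name = name, full_health = full_health,
                 any_dysfunction = any_dysfunction,
                 level2 = level2, level3 = level3, any_level3 = any_level3),
            class = "eq5d_value_set")
}

#' The UK time trade-off EQ-5D-3L tariff
#'
#' The published UK general-population TTO value set: full health 1.0,
#' any-dysfunction constant 0.081, any-level-3 constant 0.269, and
#' per-dimension decrements of 0.069/0.314 (mobility), 0.104/0.214
#' (self-care), 0.036/0.094 (usual activities), 0.123/0.386
#' (pain/discomfort) and 0.071/0.236 (anxiety/depression) for levels 2/3.
#' The worst state "33333" scores -0.594.
#'
#' @return An `eq5d_value_set`.
#' @export
uk_tto_value_set <- function() {
  value_set(
    name = "UK-TTO",
    full_health = 1.0,
    any_dysfunction = 0.081,
    level2 = c(mobility = 0.069, self_care = 0.104, usual_activities = 0.036,
               pain_discomfort = 0.123, anxiety_depression = 0.071),
    level3 = c(mobility = 0.314, self_care = 0.214, usual_activities = 0.094,
               pain_discomfort = 0.386, anxiety_depression = 0.236),
    any_level3 = 0.269
  )
}

#' Lower utility bound of a value set
#' @param vs An `eq5d_value_set`.
#' @return Utility of the all-threes state.
#' @export
utility_floor <- function(vs = uk_tto_value_set()) {
  unname(score_utility("33333", vs))
}

#' Score EQ-5D-3L health states as utilities
#'
#' @param state Character vector of 5-digit state codes.
#' @param vs Value set, default the UK TTO tariff.
#' @return Numeric vector of utilities, one per state, within the tariff's
#'   bounds (UK: \[-0.594, 1\]).
#' @examples
#' score_utility(c("11111", "21111", "33333"))
#' @export
score_utility <- function(state, vs = uk_tto_value_set()) {
  stopifnot(inherits(vs, "eq5d_value_set"))
  lv <- eq5d_levels(state)
  any_dys <- rowSums(lv > 1L) > 0L
  any_l3 <- rowSums(lv == 3L) > 0L
  dec2 <- (lv == 2L) %*% cbind(vs$level2)
  dec3 <- (lv == 3L) %*% cbind(vs$level3)
  u <- vs$full_health - any_dys * vs$any_dysfunction -
    as.vector(dec2) - as.vector(dec3) - any_l3 * vs$any_level3
  names(u) <- state
  u
}

#' Read a value set from delimited text
#'
#' Expected columns: `term`, `value`. Terms are `full_health`,
#' `any_dysfunction`, `any_level3`, and `<dimension>_l2` / `<dimension>_l3`
#' for each of the five dimensions (`mobility`, `self_care`,
#' `usual_activities`, `pain_discomfort`, `anxiety_depression`).
#'
#' @param path File path.
#' @param name Tariff name; default the file name.
#' @param sep Field separator.
#' @return An `eq5d_value_set`.
#' @export
read_value_set <- function(path, name = basename(path), sep = ",") {
  d <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("term", "value") %in% names(d))) {
    stop("value-set file must have columns 'term' and 'value'", call. = FALSE)
  }
  v <- stats::setNames(d$value, d$term)
  pick <- function(suffix) {
    stats::setNames(v[paste0(EQ5D_DIMENSIONS, suffix)], EQ5D_DIMENSIONS)
  }
  value_set(name, v[["full_health"]], v[["any_dysfunction"]],
            pick("_l2"), pick("_l3"), v[["any_level3"]])
}

# ---- population norms --------------------------------------------------

#' Construct a population norm table
#'
#' Mean general-population utility by sex and closed age band. Bands within
#' each sex must be non-overlapping and jointly cover the supported range.
#'
#' @param sex Character vector, "male"/"female".
#' @param age_min,age_max Integer band bounds (closed interval, years).
#' @param norm Mean utility per band.
#' @return A tibble of class `norm_table`.
#' @export
norm_table <- function(sex, age_min, age_max, norm) {
  tab <- tibble::tibble(sex = sex, age_min = as.integer(age_min),
                        age_max = as.integer(age_max), norm = norm)
  if (!all(tab$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  if (any(tab$age_min > tab$age_max)) {
    stop("age_min must not exceed age_max", call. = FALSE)
  }
  floor_u <- -0.594
  if (any(tab$norm < floor_u | tab$norm > 1)) {
    stop("norm utilities must lie within [-0.594, 1]", call. = FALSE)
  }
  for (s in unique(tab$sex)) {
    b <- tab[tab$sex == s, ]
    b <- b[order(b$age_min), ]
    if (any(b$age_min[-1] <= b$age_max[-nrow(b)])) {
      stop(sprintf("overlapping age bands for sex '%s'", s), call. = FALSE)
    }
    if (nrow(b) > 1 && any(b$age_min[-1] != b$age_max[-nrow(b)] + 1L)) {
      stop(sprintf("age bands for sex '%s' leave gaps", s), call. = FALSE)
    }
  }
  class(tab) <- c("norm_table", class(tab))
  tab
}

#' Illustrative UK-shaped population norm table
#'
#' Mean EQ-5D-3L utilities of the general population by sex and age band,
#' covering ages 18-100. The values are illustrative, shaped like published
#' UK general-population norms (declining from ~0.94 in young adults to
#' ~0.73 beyond 75); they are synthetic defaults, not a transcription of any
#' published norm survey, and real analyses should supply their own table
#' via [read_norm_table()].
#'
#' @return A `norm_table`.
#' @export
default_norm_table <- function() {
  bands <- data.frame(
    age_min = c(18L, 25L, 35L, 45L, 55L, 65L, 75L),
    age_max = c(24L, 34L, 44L, 54L, 64L, 74L, 100L)
  )
  male <-   c(0.94, 0.93, 0.91, 0.84, 0.78, 0.78, 0.75)
  female <- c(0.94, 0.93, 0.91, 0.85, 0.81, 0.78, 0.71)
  norm_table(
    sex = rep(c("male", "female"), each = nrow(bands)),
    age_min = rep(bands$age_min, 2L),
    age_max = rep(bands$age_max, 2L),
    norm = c(male, female)
  )
}

#' Read a population norm table from delimited text
#'
#' Expected columns: `sex`, `age_min`, `age_max`, `norm`.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return A `norm_table`.
#' @export
read_norm_table <- function(path, sep = ",") {
  d <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("sex", "age_min", "age_max", "norm")
  if (!all(need %in% names(d))) {
    stop("norm-table file must have columns sex, age_min, age_max, norm",
         call. = FALSE)
  }
  norm_table(d$sex, d$age_min, d$age_max, d$norm)
}

#' Look up the age/sex population norm utility
#'
#' Band lookup with no interpolation: each (sex, age) resolves to the unique
#' band containing it.
#'
#' @param age Numeric vector of ages in years.
#' @param sex Character vector ("male"/"female"), recycled against `age`.
#' @param norms A `norm_table`, default [default_norm_table()].
#' @return Numeric vector of norm utilities.
#' @export
lookup_norm <- function(age, sex, norms = default_norm_table()) {
  stopifnot(inherits(norms, "norm_table"))
  n <- max(length(age), length(sex))
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  bad_sex <- !sex %in% c("male", "female")
  if (any(bad_sex)) {
    stop(sprintf("unknown sex category %s", deparse(sex[which(bad_sex)[1]])),
         call. = FALSE)
  }
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    hit <- norms$sex == sex[i] & norms$age_min <= age[i] & age[i] <= norms$age_max
    if (!any(hit)) {
      stop(sprintf("age %s (%s) outside the norm table's covered range",
                   format(age[i]), sex[i]), call. = FALSE)
    }
    out[i] <- norms$norm[which(hit)[1L]]
  }
  out
}

#' Per-observation disability weight
#'
#' The empirical disability weight of one observation is the age/sex
#' population norm utility minus the patient's utility. Negative weights
#' (patient above norm) are retained, not clamped: truncating at zero would
#' bias group means upward.
#'
#' @param utility Patient utility (vector).
#' @param norm Matching population norm utility (vector).
#' @return `norm - utility`, elementwise.
#' @export
disability_weight <- function(utility, norm) {
  floor_u <- -0.594
  if (any(utility < floor_u - 1e-9 | utility > 1 + 1e-9, na.rm = TRUE) ||
      any(norm < floor_u - 1e-9 | norm > 1 + 1e-9, na.rm = TRUE)) {
    stop("utility and norm must lie within [-0.594, 1]", call. = FALSE)
  }
  norm - utility
}

# ---- crosswalk machinery ----------------------------------------------

#' Construct a crosswalk (response-mapping) model
#'
#' Generic machinery for mapping another instrument's scores (e.g. SF-36
#' summaries or EQ-5D-5L responses) onto the EQ-5D-3L. For each target
#' dimension the model is a multinomial response model over the three
#' levels: given a source score vector `x`, the linear predictor for level
#' `l` is `coef[[dim]][l, ] %*% c(1, x)` and level probabilities are its
#' softmax. Alternatively fixed per-dimension level probabilities may be
#' supplied directly (`probs`), which is useful for degenerate or tabulated
#' mappings. Published coefficient sets are user-supplied data, not shipped.
#'
#' @param coef List of five 3 x (p+1) coefficient matrices (rows = levels,
#'   first column the intercept), named by dimension, or `NULL`.
#' @param probs 5 x 3 matrix of fixed level probabilities (rows =
#'   dimensions), or `NULL`. Exactly one of `coef`/`probs` must be given.
#' @param mode `"expected_utility"` to return the probability-weighted mean
#'   tariff utility, `"modal_state"` to return the per-dimension most likely
#'   level (ties resolve to the less severe level).
#' @return An object of class `crosswalk_model`.
#' @export
crosswalk_model <- function(coef = NULL, probs = NULL,
                            mode = c("expected_utility", "modal_state")) {
  mode <- match.arg(mode)
  if (is.null(coef) == is.null(probs)) {
    stop("supply exactly one of 'coef' or 'probs'", call. = FALSE)
  }
  if (!is.null(probs)) {
    probs <- as.matrix(probs)
    if (!all(dim(probs) == c(5L, 3L))) {
      stop("'probs' must be a 5 x 3 matrix (dimensions x levels)", call. = FALSE)
    }
    check_prob_rows(probs)
  } else {
    if (!is.list(coef) || length(coef) != 5L ||
        !all(vapply(coef, function(m) is.matrix(m) && nrow(m) == 3L, logical(1)))) {
      stop("'coef' must be a list of five 3-row coefficient matrices", call. = FALSE)
    }
    names(coef) <- EQ5D_DIMENSIONS
  }
  structure(list(coef = coef, probs = probs, mode = mode),
            class = "crosswalk_model")
}

check_prob_rows <- function(p) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("crosswalk probabilities must be finite and non-negative", call. = FALSE)
  }
  if (any(abs(rowSums(p) - 1) > 1e-9)) {
    stop("crosswalk probabilities must sum to 1 per dimension (tol 1e-9)",
         call. = FALSE)
  }
  invisible(p)
}

#' Per-dimension level probabilities of a crosswalk model
#'
#' @param model A `crosswalk_model`.
#' @param source_scores Numeric source score vector (ignored for fixed-probs
#'   models).
#' @return 5 x 3 matrix of probabilities, rows = dimensions.
#' @export
crosswalk_probs <- function(model, source_scores = numeric()) {
  stopifnot(inherits(model, "crosswalk_model"))
  if (!is.null(model$probs)) return(model$probs)
  p <- matrix(NA_real_, 5L, 3L,
              dimnames = list(EQ5D_DIMENSIONS, paste0("l", 1:3)))
  x <- c(1, source_scores)
  for (d in seq_along(model$coef)) {
    B <- model$coef[[d]]
    if (ncol(B) != length(x)) {
      stop(sprintf(
        "crosswalk coefficient matrix for %s has %d columns but source vector implies %d",
        EQ5D_DIMENSIONS[d], ncol(B), length(x)), call. = FALSE)
    }
    eta <- as.vector(B %*% x)
    eta <- eta - max(eta)  # softmax stabilisation
    p[d, ] <- exp(eta) / sum(exp(eta))
  }
  check_prob_rows(p)
}

#' Map source-instrument scores onto the EQ-5D-3L
#'
#' In `expected_utility` mode the result is the expectation of the tariff
#' utility over the per-dimension level distribution (dimensions
#' independent): decrements enter weighted by their level probabilities and
#' the any-dysfunction / any-level-3 constants by the probabilities of those
#' events. This equals the brute-force sum over all 243 states of
#' `P(state) * tariff(state)`. In `modal_state` mode the per-dimension
#' argmax levels are returned as a state code, ties resolving to the less
#' severe level.
#'
#' @param source_scores Numeric source score vector.
#' @param model A `crosswalk_model`.
#' @param vs Value set, default UK TTO.
#' @return A utility (numeric scalar) or a state code (character scalar),
#'   depending on the model's mode.
#' @export
crosswalk_to_3l <- function(source_scores, model, vs = uk_tto_value_set()) {
  p <- crosswalk_probs(model, source_scores)
  if (model$mode == "modal_state") {
    lev <- apply(p, 1L, which.max)  # which.max takes the first (less severe) tie
    return(eq5d_state(matrix(lev, nrow = 1L)))
  }
  p_l1 <- p[, 1L]
  p_l3 <- p[, 3L]
  p_any_dys <- 1 - prod(p_l1)
  p_any_l3 <- 1 - prod(1 - p_l3)
  vs$full_health - vs$any_dysfunction * p_any_dys -
    sum(p[, 2L] * vs$level2) - sum(p_l3 * vs$level3) -
    vs$any_level3 * p_any_l3
}

#' Read a crosswalk model from delimited text
#'
#' Expected columns: `dimension`, `level`, then intercept and slope columns
#' (`b0`, `b1`, ...). One row per (dimension, level).
#'
#' @param path File path.
#' @param mode Model mode, see [crosswalk_model()].
#' @param sep Field separator.
#' @return A `crosswalk_model`.
#' @export
read_crosswalk_model <- function(path, mode = "expected_utility", sep = ",") {
  d <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("dimension", "level") %in% names(d))) {
    stop("crosswalk file must have columns 'dimension' and 'level'", call. = FALSE)
  }
  bcols <- grep("^b[0-9]+$", names(d), value = TRUE)
  if (length(bcols) == 0) stop("no coefficient columns (b0, b1, ...)", call. = FALSE)
  coef <- lapply(EQ5D_DIMENSIONS, function(dim) {
    rows <- d[d$dimension == dim, ]
    rows <- rows[order(rows$level), ]
    if (!identical(as.integer(rows$level), 1:3)) {
      stop(sprintf("crosswalk file must have levels 1-3 for %s", dim), call. = FALSE)
    }
    as.matrix(rows[, bcols, drop = FALSE])
  })
  names(coef) <- EQ5D_DIMENSIONS
  crosswalk_model(coef = coef, mode = mode)
}
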