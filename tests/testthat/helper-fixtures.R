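# Shared fixtures, built in code at test time.

# a small hand-written cohort file: 3 valid rows, 1 invalid level, 1 minor
write_demo_cohort_file <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c(
    "patient_id,age,sex,tbsa,months_post_burn,mo,sc,ua,pd,ad,utility",
    "P1,40,male,3,0.75,2,1,1,1,1,",
    "P1,40,male,3,18,1,1,1,1,1,",
    "P2,55,female,12,3,1,1,1,2,2,",
    "P3,30,male,25,3,1,1,4,1,1,",
    "P4,16,male,2,3,1,1,1,1,1,"
  ), path)
  path
}

# utility-only cohort file (no level columns)
write_utility_cohort_file <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c(
    "patient_id,age,sex,tbsa,months_post_burn,utility",
    "P1,40,male,3,0.75,0.85",
    "P2,55,female,12,3,0.62"
  ), path)
  path
}

# norm table from the documentation examples: male 35-44 -> 0.91, 45-54 -> 0.85
toy_norm_table <- function() {
  norm_table(sex = rep("male", 3),
             age_min = c(18L, 35L, 45L), age_max = c(34L, 44L, 54L),
             norm = c(0.93, 0.91, 0.85))
}

# brute-force Mann-Whitney U (pair counting) and exact p by enumeration;
# independent of the package's implementation
brute_mwu <- function(a, b) {
  U <- 0
  for (x in a) for (y in b) U <- U + (x > y) + 0.5 * (x == y)
  pooled <- c(a, b)
  n1 <- length(a)
  mu <- n1 * length(b) / 2
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(k) {
    aa <- pooled[k]; bb <- pooled[-k]
    u <- 0
    for (x in aa) for (y in bb) u <- u + (x > y) + 0.5 * (x == y)
    u
  })
  p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
  list(U = U, p = p)
}

# closed-form YLD from first principles, for end-to-end checks
hand_yld <- function(counts, dw, props, le) {
  dur <- c(1 / 12, 5 / 12, 6 / 12, 1)
  short <- sum(counts * colSums(t(dw[, 1:4]) * dur))
  long <- sum(counts * props * dw[, 5] * pmax(le - 2, 0))
  c(short = short, long = long, total = short + long)
}
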