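test_that("UK tariff scores match hand-computed utilities", {
  expect_equal(unname(score_utility("11111")), 1.0)
  # one dimension at level 2: full health - any-dysfunction - mobility l2
  expect_equal(unname(score_utility("21111")), 1 - 0.081 - 0.069)
  expect_equal(unname(score_utility("33333")), -0.594)
  # the published rounded bound
  expect_equal(round(unname(score_utility("33333")), 2), -0.59)
  # a mixed state (mo 2, ua 2, pd 3, ad 2), summed by hand from the tariff
  expect_equal(unname(score_utility("21232")),
               1 - 0.081 - 0.069 - 0.036 - 0.386 - 0.071 - 0.269)
})

test_that("state validation names the offending input", {
  expect_error(score_utility("1111"), "invalid EQ-5D-3L state")
  expect_error(score_utility("11114"), "invalid EQ-5D-3L state")
  expect_error(score_utility("1111a"), "invalid EQ-5D-3L state")
  expect_error(eq5d_levels(21111), "character")
  expect_error(eq5d_state(matrix(c(1, 1, 1, 1, 4), 1)), "1-3")
})

test_that("state codes round-trip through the level matrix", {
  states <- all_health_states()
  expect_length(states, 243)
  expect_identical(eq5d_state(eq5d_levels(states)), states)
})

test_that("tariff bounds and monotonicity hold over all 243 states", {
  states <- all_health_states()
  u <- score_utility(states)
  expect_equal(max(u), 1.0)
  expect_equal(min(u), -0.594)
  expect_identical(names(u)[which.max(u)], "11111")
  expect_identical(names(u)[which.min(u)], "33333")
  expect_equal(sum(u == 1.0), 1L, ignore_attr = TRUE)
  expect_equal(sum(u == -0.594), 1L, ignore_attr = TRUE)
  # level-wise worse state never scores higher
  lv <- eq5d_levels(states)
  for (i in seq_along(states)) {
    worse <- rowSums(lv >= rep(lv[i, ], each = 243)) == 5L
    expect_true(all(u[worse] <= u[i] + 1e-12))
  }
})

test_that("norm lookup is band-based with boundary membership and errors", {
  nt <- toy_norm_table()
  expect_equal(lookup_norm(40, "male", nt), 0.91)
  expect_equal(lookup_norm(44, "male", nt), 0.91)
  expect_equal(lookup_norm(45, "male", nt), 0.85)
  expect_error(lookup_norm(17, "male", nt), "outside")
  expect_error(lookup_norm(40, "other", nt), "unknown sex")
})

test_that("norm table construction rejects gaps, overlaps and bad values", {
  expect_error(norm_table("male", c(18, 30), c(30, 40), c(0.9, 0.8)),
               "overlapping")
  expect_error(norm_table("male", c(18, 32), c(30, 40), c(0.9, 0.8)), "gaps")
  expect_error(norm_table("male", 18, 40, 1.2), "within")
  # the shipped default covers 18-100 for both sexes
  dn <- default_norm_table()
  for (s in c("male", "female")) {
    expect_true(all(sapply(18:100, function(a)
      is.finite(lookup_norm(a, s, dn)))))
  }
})

test_that("disability weight is the norm-utility difference, unclamped", {
  expect_equal(disability_weight(0.85, 0.85), 0)
  expect_equal(disability_weight(0.50, 0.88), 0.38)
  expect_equal(disability_weight(1.00, 0.93), -0.07)
  # conservation: dw + utility == norm exactly
  set.seed(11)
  u <- stats::runif(50, -0.594, 1)
  n <- stats::runif(50, -0.594, 1)
  expect_equal(disability_weight(u, n) + u, n)
  expect_error(disability_weight(1.2, 0.9), "within")
})

test_that("value sets load from delimited text", {
  path <- tempfile(fileext = ".csv")
  vs0 <- uk_tto_value_set()
  rows <- c("term,value",
            sprintf("full_health,%g", vs0$full_health),
            sprintf("any_dysfunction,%g", vs0$any_dysfunction),
            sprintf("any_level3,%g", vs0$any_level3),
            sprintf("%s_l2,%g", names(vs0$level2), vs0$level2),
            sprintf("%s_l3,%g", names(vs0$level3), vs0$level3))
  writeLines(rows, path)
  vs1 <- read_value_set(path)
  expect_equal(score_utility(all_health_states(), vs1),
               score_utility(all_health_states(), vs0))
})

test_that("crosswalk expected utility equals brute-force state enumeration", {
  vs <- uk_tto_value_set()
  states <- all_health_states()
  tariff <- score_utility(states, vs)
  lv <- eq5d_levels(states)
  # random per-dimension distributions: factorized result must equal the
  # full 243-state expectation
  set.seed(42)
  for (rep in 1:10) {
    p <- matrix(stats::rexp(15), 5, 3)
    p <- p / rowSums(p)
    m <- crosswalk_model(probs = p, mode = "expected_utility")
    p_state <- sapply(seq_along(states), function(i)
      prod(p[cbind(1:5, lv[i, ])]))
    expect_equal(sum(p_state), 1, tolerance = 1e-12)
    expect_equal(crosswalk_to_3l(numeric(), m, vs),
                 sum(p_state * tariff), tolerance = 1e-12)
  }
})

test_that("degenerate crosswalk distributions reproduce tariff values", {
  vs <- uk_tto_value_set()
  # every one of the 243 states as a point mass
  for (s in all_health_states()) {
    lv <- eq5d_levels(s)[1, ]
    p <- matrix(0, 5, 3)
    p[cbind(1:5, lv)] <- 1
    m <- crosswalk_model(probs = p)
    expect_equal(crosswalk_to_3l(numeric(), m, vs), unname(score_utility(s, vs)),
                 tolerance = 1e-12)
  }
  # the two-state mixture worked example
  p <- matrix(rep(c(1, 0, 0), each = 5), 5, 3)
  p[1, ] <- c(0.5, 0.5, 0)
  expect_equal(crosswalk_to_3l(numeric(), crosswalk_model(probs = p)), 0.925)
})

test_that("modal-state crosswalk resolves ties to the less severe level", {
  p <- matrix(rep(c(1, 0, 0), each = 5), 5, 3)
  p[4, ] <- c(0.4, 0.4, 0.2)   # tie between levels 1 and 2 -> level 1
  p[5, ] <- c(0.2, 0.3, 0.5)
  m <- crosswalk_model(probs = p, mode = "modal_state")
  expect_identical(crosswalk_to_3l(numeric(), m), "11113")
})

test_that("crosswalk models validate probabilities and dimensions", {
  bad <- matrix(rep(c(0.5, 0.4, 0.2), each = 5), 5, 3)
  expect_error(crosswalk_model(probs = bad), "sum to 1")
  expect_error(crosswalk_model(probs = matrix(1, 3, 3)), "5 x 3")
  m <- crosswalk_model(coef = rep(list(matrix(0, 3, 2)), 5))
  expect_error(crosswalk_probs(m, c(1, 2)), "columns")
  # logistic model with zero coefficients: uniform over levels
  expect_equal(crosswalk_probs(m, 1), matrix(1 / 3, 5, 3), ignore_attr = TRUE)
})

test_that("coefficient crosswalk models load from file and respond to scores", {
  path <- tempfile(fileext = ".csv")
  rows <- c("dimension,level,b0,b1")
  for (d in c("mobility", "self_care", "usual_activities",
              "pain_discomfort", "anxiety_depression")) {
    rows <- c(rows, sprintf("%s,1,0,0", d), sprintf("%s,2,-1,1", d),
              sprintf("%s,3,-3,1.5", d))
  }
  writeLines(rows, path)
  m <- read_crosswalk_model(path)
  u_mild <- crosswalk_to_3l(0, m)     # low source score -> mild profile
  u_severe <- crosswalk_to_3l(4, m)   # high source score -> severe profile
  expect_true(u_mild > u_severe)
  expect_true(u_mild <= 1 && u_severe >= -0.594)
})
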