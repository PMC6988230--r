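toy_incidence <- function(counts, country = "X", year = 2017L) {
  tibble::tibble(country = country, year = year,
                 group = factor(severity_groups(), levels = severity_groups()),
                 count = counts)
}

test_that("censored incidence tokens resolve to the assumed average of 2", {
  expect_equal(apply_censoring(c("12", "1-5", "0", "6")), c(12, 2, 0, 6))
  expect_equal(apply_censoring(c(0, 6)), c(0, 6))
  expect_error(apply_censoring(-1), "non-negative")
  expect_error(apply_censoring("abc"), "unparseable")
})

test_that("short-term YLD per case is the duration-weighted window sum", {
  dws <- default_dw_table()
  # hand evaluation for the mildest group
  expect_equal(short_term_yld_per_case(dws, "lt5"),
               0.173 / 12 + 0.098 * 5 / 12 + 0.082 * 6 / 12 + 0.102 * 1)
  expect_equal(short_term_yld_per_case(dws, "lt5"), 0.19825)
  # all-zero weights -> 0; all-one weights -> the 2-year horizon
  zero <- dws; zero$mean_dw <- 0
  expect_equal(short_term_yld_per_case(zero, "gt20"), 0)
  one <- dws; one$mean_dw <- 1
  expect_equal(short_term_yld_per_case(one, "gt20"), 2)
  # a missing cell is an error naming the cell
  holed <- dws
  holed$mean_dw[holed$group == "lt5" & holed$window == "m1_6"] <- NA
  expect_error(short_term_yld_per_case(holed, "lt5"), "m1_6")
})

test_that("long-term YLD per case multiplies proportion, weight and LE - 2", {
  expect_equal(long_term_yld_per_case(0, 0.1, 50), 0)
  expect_equal(long_term_yld_per_case(0.20, 0.046, 47), 0.20 * 0.046 * 45)
  expect_equal(long_term_yld_per_case(0.20, 0.046, 47), 0.4140)
  # remaining LE below the 2-year short-term horizon floors at zero
  expect_equal(long_term_yld_per_case(0.5, 0.3, 1.5), 0)
  expect_error(long_term_yld_per_case(1.2, 0.1, 50), "\\[0, 1\\]")
  expect_error(long_term_yld_per_case(0.5, 0.1, -3), ">= 0")
})

test_that("compute_yld reproduces a hand-computed single stratum", {
  # count 10, all short-term weights 0.1, p = 0.5, dw_long = 0.1, LE = 42
  dws <- default_dw_table()
  dws$mean_dw <- 0.1
  inc <- toy_incidence(c(10, 0, 0))
  res <- suppressWarnings(compute_yld(
    inc, dws = dws, props = c(lt5 = 0.5, `5to20` = 0.25, gt20 = 0.39),
    life = c(X = 42)))
  row <- res$by_group[res$by_group$group == "lt5", ]
  expect_equal(row$yld_short, 10 * 0.1 * 2)       # durations sum to 2
  expect_equal(row$yld_long, 10 * 0.5 * 0.1 * 40)
  expect_equal(row$yld_total, row$yld_short + row$yld_long)
  expect_equal(row$yld_per_case, row$yld_total / 10)
  # zero incidence everywhere -> all YLDs zero
  res0 <- suppressWarnings(compute_yld(toy_incidence(c(0, 0, 0)),
                                       life = c(X = 42)))
  expect_true(all(res0$totals$yld_total == 0))
})

test_that("YLDs are linear in incidence and additive over groups", {
  inc <- toy_incidence(c(445, 259, 40))
  res1 <- suppressWarnings(compute_yld(inc, life = c(X = 47)))
  inc2 <- inc; inc2$count <- inc$count * 2
  res2 <- suppressWarnings(compute_yld(inc2, life = c(X = 47)))
  expect_equal(res2$by_group$yld_total, res1$by_group$yld_total * 2)
  expect_equal(res2$by_group$yld_per_case, res1$by_group$yld_per_case)
  expect_equal(res1$totals$yld_total, sum(res1$by_group$yld_total))
  expect_equal(res1$totals$incidence, sum(res1$by_group$incidence))
})

test_that("YLD is monotone in weights, proportions and life expectancy", {
  inc <- toy_incidence(c(100, 50, 10))
  base <- suppressWarnings(compute_yld(inc, life = c(X = 40)))
  up_dw <- default_dw_table()
  up_dw$mean_dw <- up_dw$mean_dw + 0.05
  res_dw <- suppressWarnings(compute_yld(inc, dws = up_dw, life = c(X = 40)))
  expect_true(all(res_dw$by_group$yld_total >= base$by_group$yld_total))
  props_up <- default_lifelong_proportions() + 0.1
  res_p <- suppressWarnings(compute_yld(inc, props = props_up,
                                        life = c(X = 40)))
  expect_true(all(res_p$by_group$yld_total >= base$by_group$yld_total))
  res_le <- suppressWarnings(compute_yld(inc, life = c(X = 50)))
  expect_true(all(res_le$by_group$yld_total >= base$by_group$yld_total))
})

test_that("stratified runs use the life table and flag uncovered strata", {
  inc <- tibble::tibble(
    country = "X", year = 2017L,
    group = factor(c("lt5", "lt5"), levels = severity_groups()),
    count = c(10, 20), sex = c("male", "female"), age = c(30, 70))
  lt <- synthetic_life_table()
  res <- suppressWarnings(compute_yld(inc, life = lt))
  # group row aggregates both strata; long-term uses each stratum's LE
  le_m <- lt$remaining_le[lt$sex == "male" & lt$age_min <= 30 &
                            30 <= lt$age_max]
  le_f <- lt$remaining_le[lt$sex == "female" & lt$age_min <= 70 &
                            70 <= lt$age_max]
  expect_equal(res$by_group$yld_long,
               10 * 0.2 * 0.046 * (le_m - 2) + 20 * 0.2 * 0.046 * (le_f - 2))
  # an age beyond coverage is reported, not silently dropped
  inc_bad <- inc; inc_bad$age <- c(30, 110)
  expect_error(suppressWarnings(compute_yld(inc_bad, life = lt)),
               "does not cover")
  # unstratified input cannot use a life table
  expect_error(compute_yld(toy_incidence(c(1, 1, 1)), life = lt),
               "scalar")
})

test_that("per-100k rates need explicit denominators", {
  inc <- toy_incidence(c(100, 50, 10))
  expect_warning(res <- compute_yld(inc, life = c(X = 40)), "per-100,000")
  expect_true(all(is.na(res$totals$yld_per_100k)))
  res2 <- suppressWarnings(compute_yld(inc, life = c(X = 40),
                                       population = c(X = 1e6)))
  expect_equal(res2$totals$yld_per_100k,
               res2$totals$yld_total / 1e6 * 1e5)
})

test_that("incidence files round-trip, including censored small cells", {
  inc <- toy_incidence(c(12, 3, 0))
  path <- tempfile(fileext = ".csv")
  write_incidence(inc, path, censor = TRUE)
  txt <- readLines(path)
  expect_true(any(grepl(",1-5$", txt)))
  back <- read_incidence(path)
  expect_equal(back$count, c(12, 2, 0))  # 3 was censored, read back as 2
  # duplicate strata rejected
  writeLines(c("country,year,group,count", "X,2017,lt5,5", "X,2017,lt5,7"),
             path)
  expect_error(read_incidence(path), "duplicate")
})

test_that("life tables validate monotonicity and report files round", {
  expect_error(life_table("male", c(18, 30), c(29, 40), c(50, 55)),
               "non-increasing")
  expect_error(life_table("male", 18, 29, -1), "> 0")
  inc <- toy_incidence(c(445, 259, 40))
  res <- suppressWarnings(compute_yld(inc, life = c(X = 47),
                                      population = c(X = 1e7)))
  path <- tempfile(fileext = ".csv")
  write_yld_report(res, path)
  rep <- read.csv(path)
  expect_equal(nrow(rep), 4)  # 3 groups + total
  tot <- rep[rep$group == "total", ]
  expect_equal(tot$yld_total, round(res$totals$yld_total, 1))
  expect_equal(tot$yld_per_case, round(res$totals$yld_per_case, 2))
})
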