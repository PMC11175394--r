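test_that("the packaged origin-destination counts reproduce the printed table", {
  rep <- reproduce_printed_tables()
  od <- rep$od
  expect_identical(unname(od$row_totals["GAU"]), 27660)
  expect_identical(unname(od$col_pct["WC", "WC"]), 94.9)
  expect_identical(unname(od$col_pct["GAU", "KZN"]), 46.8)
  expect_identical(unname(od$col_pct["GAU", "GAU"]), 87.1)
  expect_identical(unname(od$col_pct["EC", "EC"]), 80.8)
  # column percentages of every column sum to 100 within rounding slack
  expect_true(all(abs(colSums(od$col_pct) - 100) <= 0.5))
})

test_that("a single case yields a one-cell matrix with a 100% column", {
  case <- tibble::tibble(home_province = "EC", diagnosis_province = "EC")
  od <- od_matrix(case)
  expect_identical(unname(od$counts["EC", "EC"]), 1L)
  expect_identical(unname(od$col_pct["EC", "EC"]), 100)
  expect_identical(od$n, 1L)
  expect_error(od_matrix(tibble::tibble(home_province = "XX",
                                        diagnosis_province = "EC")),
               "unknown province")
})

test_that("destination shares follow the off-diagonal definition", {
  all_diag <- od_matrix(tibble::tibble(home_province = rep("GAU", 5),
                                       diagnosis_province = rep("GAU", 5)))
  expect_true(all(is.na(destination_shares(all_diag)$share)))

  # embedded 2x2 counts [[5,3],[2,10]]: off-diagonal total 5, share(EC) = 3/5
  cases <- dplyr::bind_rows(
    tibble::tibble(home_province = rep("EC", 5), diagnosis_province = "EC"),
    tibble::tibble(home_province = rep("FS", 3), diagnosis_province = "EC"),
    tibble::tibble(home_province = rep("EC", 2), diagnosis_province = "FS"),
    tibble::tibble(home_province = rep("FS", 10), diagnosis_province = "FS")
  )
  ds <- destination_shares(od_matrix(cases))
  expect_equal(ds$share[ds$diagnosis_province == "EC"], 3 / 5)

  # printed-table fixture: GAU received (27,660 - 17,682) of 16,225 movers
  rep <- reproduce_printed_tables()
  gau <- rep$destination_shares
  expect_equal(gau$share[gau$diagnosis_province == "GAU"],
               (27660 - 17682) / 16225)
})

test_that("demographics row percentages reproduce the printed values", {
  demo <- reproduce_printed_tables()$demographics
  black <- demo[demo$characteristic == "ethnicity" & demo$level == "Black", ]
  expect_identical(black$pct_outside, 26.2)
  male <- demo[demo$characteristic == "gender" & demo$level == "Male", ]
  expect_identical(male$pct_within, 77.6)
  expect_true(all(demo$outside + demo$within == demo$total))
})

test_that("demographics of a case table count and summarise correctly", {
  cases <- tibble::tibble(
    sex = c("F", "F", "M", "F", "M"),
    race = c("Black", "Black", "White", "Coloured", "Black"),
    age_at_diagnosis = 1:5,
    out_of_province = c(TRUE, FALSE, FALSE, FALSE, TRUE)
  )
  demo <- demographics_table(cases)
  expect_identical(demo$age$median[demo$age$group == "all"], 3)
  tab <- demo$table
  tot <- tab[tab$characteristic == "total", ]
  expect_identical(tot$outside, 2L)
  expect_identical(tot$within, 3L)
  blk <- tab[tab$characteristic == "black_vs_nonblack" & tab$level == "Black", ]
  expect_identical(blk$pct_outside, round_half_up(100 * 2 / 3, 1))
})

test_that("rounding is half away from zero", {
  expect_identical(round_half_up(26.25, 1), 26.3)
  expect_identical(round_half_up(26.24, 1), 26.2)
  expect_identical(round_half_up(-0.15, 1), -0.2)
  expect_identical(round_half_up(2.5, 0), 3)
})

test_that("chi-square matches its definition and flags degenerate input", {
  flat <- matrix(c(10, 30, 10, 30), 2)
  res <- chi_square(flat)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # printed Black vs non-Black by location counts: overwhelming evidence
  counts <- matrix(c(15088, 1198, 42407, 5446), 2)
  expect_lt(chi_square(counts)$p_value, 0.001)

  # independent formula oracle on random tables
  set.seed(14)
  for (i in 1:100) {
    x <- matrix(rpois(6, 30) + 1, 2, 3)
    res <- chi_square(x)
    e <- outer(rowSums(x), colSums(x)) / sum(x)
    expect_lt(abs(res$statistic - sum((x - e)^2 / e)), 1e-9)
    expect_equal(res$df, 2)
  }
  degenerate <- matrix(c(0, 0, 5, 5), 2)
  expect_error(chi_square(degenerate), "expected")
})

test_that("logistic odds ratios agree with the closed-form 2x2 cross-product", {
  make_cases <- function(a, b, c, d) {
    tibble::tibble(
      sex = rep(c("M", "M", "F", "F"), c(a, b, c, d)),
      out_of_province = rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c, d)),
      age_at_diagnosis = 40, race = "Black", cancer_type = "other"
    )
  }
  fit <- logistic_fit(make_cases(20, 80, 10, 90), covariates = "gender")
  expect_equal(tidy(fit)$odds_ratio, (20 * 90) / (80 * 10), tolerance = 1e-6)

  null_fit <- logistic_fit(make_cases(25, 75, 25, 75), covariates = "gender")
  expect_equal(tidy(null_fit)$odds_ratio, 1, tolerance = 1e-6)

  set.seed(22)
  for (i in 1:20) {
    a <- sample(5:50, 4, replace = TRUE)
    fit <- logistic_fit(make_cases(a[1], a[2], a[3], a[4]), covariates = "gender")
    expect_equal(tidy(fit)$odds_ratio, (a[1] * a[4]) / (a[2] * a[3]),
                 tolerance = 1e-6)
  }
  gl <- glance(fit)
  expect_true(gl$converged)
})

test_that("reference levels and interval invariants hold on synthetic cases", {
  set.seed(10)
  n <- 4000
  cases <- tibble::tibble(
    sex = sample(c("F", "M"), n, TRUE, prob = c(0.7, 0.3)),
    race = sample(race_labels(), n, TRUE, prob = c(0.88, 0.05, 0.05, 0.02)),
    age_at_diagnosis = round(rlnorm(n, log(40), 0.28)),
    cancer_type = sample(c("cervix", "breast", "Kaposi sarcoma", "other"),
                         n, TRUE),
    out_of_province = runif(n) < 0.25
  )
  fit <- logistic_fit(cases)
  td <- tidy(fit)
  expect_false(any(grepl("Female|non-Black|cervix", td$term)))
  expect_true(all(td$ci_low <= td$odds_ratio & td$odds_ratio <= td$ci_high))
  expect_true(all(td$odds_ratio > 0))
})

test_that("flows conserve off-diagonal counts and export valid GeoJSON", {
  ident <- od_matrix(tibble::tibble(home_province = rep("GAU", 3),
                                    diagnosis_province = rep("GAU", 3)))
  expect_identical(nrow(export_flows(ident)), 0L)

  od <- reproduce_printed_tables()$od
  flows <- export_flows(od)
  kzn_gau <- flows[flows$origin == "KZN" & flows$destination == "GAU", ]
  expect_identical(kzn_gau$count, 4104L)
  offdiag <- od$counts
  diag(offdiag) <- 0L
  expect_identical(sum(flows$count), sum(offdiag))

  path <- withr::local_tempfile(fileext = ".geojson")
  write_flows_geojson(flows, path)
  gj <- jsonlite::read_json(path)
  expect_identical(gj$type, "FeatureCollection")
  expect_identical(length(gj$features), nrow(flows))
  expect_identical(gj$features[[1]]$geometry$type, "LineString")

  expect_error(export_flows(od, centroids = province_centroids()[-1, ]),
               "missing centroid")
})
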