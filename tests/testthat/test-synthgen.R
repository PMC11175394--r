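test_that("identical config and seed reproduce identical outputs, byte-wise on disk", {
  cfg <- small_config(n = 400, seed = 9)
  s1 <- simulate_records(cfg)
  s2 <- simulate_records(cfg)
  expect_identical(s1$entities, s2$entities)
  expect_identical(s1$hiv, s2$hiv)
  expect_identical(s1$cancer, s2$cancer)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  for (f in c("hiv_records.csv", "cancer_records.csv", "truth.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("degenerate distributions are honoured exactly", {
  all_f <- simulate_population(small_config(n = 200, seed = 3, female_fraction = 1))
  expect_true(all(all_f$sex == "F"))

  no_cancer <- simulate_records(small_config(n = 200, seed = 3, cancer_fraction = 0))
  expect_identical(nrow(no_cancer$cancer), 0L)
})

test_that("province shares at n = 50,000 match uniform weights within 3 binomial SE", {
  w <- setNames(rep(1 / 9, 9), province_codes())
  pop <- simulate_population(sim_config(n_entities = 50000, seed = 21,
                                        province_weights = w))
  shares <- table(factor(pop$home_province, levels = province_codes())) / 50000
  se <- sqrt((1 / 9) * (8 / 9) / 50000)
  expect_true(all(abs(shares - 1 / 9) <= 3 * se))
})

test_that("corrupt_string honours its rate and operation contracts", {
  m0 <- corruption_model(typo_rate = 0)
  expect_identical(corrupt_string(c("NKOSI", "DLAMINI"), m0), c("NKOSI", "DLAMINI"))

  # forced transposition: exactly one adjacent swap
  mt <- corruption_model(typo_rate = 1,
                         typo_ops = c(substitution = 0, transposition = 1,
                                      deletion = 0, insertion = 0))
  set.seed(1)
  for (s in c("NKOSI", "VANDERMERWE", "AB")) {
    out <- corrupt_string(s, mt)
    expect_identical(nchar(out), nchar(s))
    expect_identical(sort(strsplit(out, "")[[1]]), sort(strsplit(s, "")[[1]]))
    diff_pos <- which(strsplit(out, "")[[1]] != strsplit(s, "")[[1]])
    if (length(diff_pos) > 0) {  # swap of two equal letters changes nothing
      expect_identical(length(diff_pos), 2L)
      expect_identical(diff(diff_pos), 1L)
    }
  }

  # binomial oracle on the corruption rate
  set.seed(2)
  m <- corruption_model(typo_rate = 0.2,
                        typo_ops = c(substitution = 1, transposition = 0,
                                     deletion = 0, insertion = 0))
  x <- rep("ABCDEFGH", 10000)
  frac <- mean(corrupt_string(x, m) != x)
  # a substitution can redraw the same letter: adjust the effective rate
  eff <- 0.2 * (25 / 26)
  expect_lt(abs(frac - eff), 3 * sqrt(eff * (1 - eff) / 10000))
})

test_that("identity mobility keeps every diagnosis in the home province", {
  cfg <- small_config(n = 500, seed = 13, cancer_fraction = 1,
                      mobility = mobility_identity(),
                      missing_diagnosis_province_rate = 0)
  sim <- simulate_records(cfg)
  home <- sim$entities$home_province[sim$cancer$entity_id]
  expect_true(all(sim$cancer$diagnosis_province == home))
})

test_that("KZN mobility row reproduces its Gauteng share within 3 binomial SE", {
  mob <- default_mobility()
  p_gau <- mob["KZN", "GAU"]
  expect_equal(round_half_up(100 * p_gau, 1), 46.8)
  cfg <- sim_config(n_entities = 10000, seed = 17, cancer_fraction = 1,
                    province_weights = setNames(c(0, 0, 0, 1, 0, 0, 0, 0, 0),
                                                province_codes()),
                    missing_diagnosis_province_rate = 0,
                    second_report_rate = 0)
  sim <- simulate_records(cfg)
  share <- mean(sim$cancer$diagnosis_province == "GAU")
  expect_lt(abs(share - p_gau), 3 * sqrt(p_gau * (1 - p_gau) / nrow(sim$cancer)))
})

test_that("zero-corruption duplicates are field-identical to their siblings", {
  sim <- simulate_records(small_config(n = 400, seed = 31,
                                       corruption = zero_corruption()))
  per_entity <- dplyr::summarise(
    dplyr::group_by(sim$hiv, entity_id),
    one_first = dplyr::n_distinct(first_name) == 1,
    one_sur = dplyr::n_distinct(surname) == 1,
    one_dob = dplyr::n_distinct(dob) == 1
  )
  expect_true(all(per_entity$one_first & per_entity$one_sur & per_entity$one_dob))
})

test_that("empirical origin-destination frequencies converge to the mobility matrix", {
  cfg <- sim_config(n_entities = 50000, seed = 29, cancer_fraction = 1,
                    missing_diagnosis_province_rate = 0, second_report_rate = 0)
  sim <- simulate_records(cfg)
  home <- sim$entities$home_province[sim$cancer$entity_id]
  mob <- cfg$mobility
  # chi-square goodness of fit per home province, pooled
  stat <- 0; df <- 0
  for (p in province_codes()) {
    obs <- table(factor(sim$cancer$diagnosis_province[home == p],
                        levels = province_codes()))
    exp_p <- sum(obs) * mob[p, ]
    keep <- exp_p > 0
    stat <- stat + sum((obs[keep] - exp_p[keep])^2 / exp_p[keep])
    df <- df + sum(keep) - 1
  }
  expect_gt(pchisq(stat, df, lower.tail = FALSE), 0.01)
})

test_that("invalid probability vectors are configuration errors", {
  expect_error(sim_config(province_weights = setNames(c(2, rep(-0.125, 8)),
                                                      province_codes())),
               "probability vector")
  bad_mob <- mobility_identity()
  bad_mob[1, 1] <- 0.5
  expect_error(sim_config(mobility = bad_mob), "sum to 1")
})

test_that("study window and record invariants hold on generated data", {
  sim <- simulate_records(small_config(n = 300, seed = 8))
  w <- study_window()
  expect_true(all(sim$hiv$test_date >= w[1] & sim$hiv$test_date <= w[2]))
  expect_true(all(sim$hiv$province %in% province_codes()))
  expect_true(all(sim$cancer$diagnosis_date >= w[1] &
                    sim$cancer$diagnosis_date <= w[2]))
  expect_true(all(sim$cancer$basis %in% c("histology", "cytology", "bone-marrow")))
  expect_identical(anyDuplicated(sim$truth$record_id), 0L)
  # every person has at least one HIV record
  expect_setequal(unique(sim$hiv$entity_id), sim$entities$entity_id)
})
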