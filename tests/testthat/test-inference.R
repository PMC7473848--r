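fake_records <- function(larvae, transgenic = NA, males = NA, eggs = NULL) {
  n <- length(larvae)
  if (is.null(eggs)) eggs <- larvae
  data.frame(parent_id = seq_len(n), eggs = eggs, larvae = larvae,
             transgenic = transgenic, males = males,
             females = ifelse(is.na(males), NA, larvae - males))
}

test_that("assay validation enforces the count invariants", {
  expect_error(validate_assay_records(data.frame(eggs = 10)), "lacks column")
  expect_error(validate_assay_records(fake_records(10, eggs = 5)),
               "larvae > eggs")
  expect_error(validate_assay_records(fake_records(10, transgenic = 12)),
               "transgenic > larvae")
  expect_error(validate_assay_records(fake_records(10, males = 8)[
    , c("parent_id", "eggs", "larvae", "transgenic", "males")] |>
      transform(females = 5)), "males \\+ females > larvae")
  ok <- validate_assay_records(fake_records(c(10, 20), transgenic = c(5, 10)))
  expect_equal(nrow(ok), 2)
})

test_that("pooled transmission and its homing-rate conversion", {
  rec <- fake_records(larvae = c(600, 400), transgenic = c(576, 384))
  est <- estimate_transmission(rec)
  expect_equal(est$transmission, 0.96)
  expect_equal(est$n_larvae, 1000)
  expect_true(est$ci["lower"] < 0.96 && est$ci["upper"] > 0.96)
  expect_error(estimate_transmission(fake_records(0, transgenic = 0)),
               "no records")
  # Mendelian and complete-transmission edges
  expect_equal(estimate_transmission(fake_records(100, transgenic = 100))$transmission, 1)
  expect_equal(estimate_transmission(fake_records(100, transgenic = 50))$transmission, 0.5)
  # homing-rate reporting convention: fraction above Mendelian
  expect_equal(homing_rate_from_transmission(0.96), 0.92)
  expect_equal(homing_rate_from_transmission(0.5), 0)
  expect_equal(homing_rate_from_transmission(1), 1)
  expect_warning(h <- homing_rate_from_transmission(0.4), "no super-Mendelian")
  expect_equal(h, 0)
  # exact round trip
  for (d in c(0, 0.25, 0.92, 1))
    expect_equal(homing_rate_from_transmission(transmission_from_homing_rate(d)), d)
})

test_that("pooled sex distortion from sexed progeny", {
  rec <- fake_records(larvae = c(60, 40), males = c(56, 37))
  est <- estimate_sex_distortion(rec)
  expect_equal(est$m, 0.93)
  expect_equal(est$n_sexed, 100)
  expect_equal(estimate_sex_distortion(fake_records(100, males = 50))$m, 0.5)
  expect_equal(estimate_sex_distortion(fake_records(100, males = 100))$m, 1)
  expect_error(estimate_sex_distortion(fake_records(10)), "no records")
})

test_that("relative fitness is a ratio of mean larval outputs", {
  # groups engineered to the printed means: 126.7 vs 140.8
  case <- fake_records(larvae = c(120, 133.4), eggs = c(150, 160))
  ctrl <- fake_records(larvae = c(130, 151.6), eggs = c(140, 165))
  est <- estimate_relative_fitness(case, ctrl, n_boot = 200, seed = 1)
  expect_equal(est$relative_fitness, 126.7 / 140.8, tolerance = 1e-12)
  expect_equal(est$rel_eggs, mean(c(150, 160)) / mean(c(140, 165)))
  expect_true(est$ci["lower"] <= est$relative_fitness + 1e-9)
  # identical groups and degenerate cases
  same <- fake_records(larvae = c(100, 120))
  expect_equal(estimate_relative_fitness(same, same, n_boot = 50)$relative_fitness, 1)
  zero <- fake_records(larvae = c(0, 0))
  expect_equal(estimate_relative_fitness(zero, same, n_boot = 50)$relative_fitness, 0)
  expect_error(estimate_relative_fitness(same, zero, n_boot = 50),
               "zero mean")
})

test_that("parameter assembly from assay groups labels provenance", {
  truth <- sdgd_truth(sdgd_params())
  males <- generate_assay_data(truth, 60, parent = "male", seed = 21)
  females <- generate_assay_data(truth, 40, parent = "female", seed = 22)
  ctrl <- generate_assay_data(truth, 40, parent = "female",
                              genotype = "WW", seed = 23)
  p <- params_from_assays(males, females, ctrl)
  prov <- attr(p, "provenance")
  expect_equal(unname(prov[c("d_f", "d_m", "m")]),
               rep("estimated", 3))
  expect_equal(unname(prov["u_f"]), "default")
  expect_equal(p$d_m, 0.96, tolerance = 0.02)
  expect_equal(p$d_f, 0.999, tolerance = 0.01)
  expect_equal(p$m1, 0.93, tolerance = 0.02)
  expect_equal(unname(p$female_fitness["WD"]), 0.627, tolerance = 0.25)
  # missing groups are reported and left at defaults
  expect_message(p2 <- params_from_assays(males), "keep their defaults")
  expect_equal(p2$d_f, sdgd_params()$d_f)
})

test_that("Mendelian assay data yields a neutral parameter set", {
  truth <- sdgd_truth(sdgd_params(d_f = 0.5, d_m = 0.5, m1 = 0.5, m2 = 0.5,
                                  female_fitness = c(WW = 1, WD = 1, WR = 1,
                                                     DD = 0, DR = 0, RR = 0),
                                  male_fitness = c(WW = 1, WD = 1, WR = 1,
                                                   DD = 1, DR = 1, RR = 1)))
  males <- generate_assay_data(truth, 80, parent = "male", seed = 31)
  females <- generate_assay_data(truth, 80, parent = "female", seed = 32)
  ctrl <- generate_assay_data(truth, 80, parent = "female",
                              genotype = "WW", seed = 33)
  p <- params_from_assays(males, females, ctrl)
  # Mendelian transmission is 1/2 => homing rate 0
  expect_equal(p$d_m, 0.5, tolerance = 0.02)
  expect_equal(homing_rate_from_transmission(round(p$d_m, 1)), 0)
  expect_equal(p$m1, 0.5, tolerance = 0.03)
  expect_equal(unname(p$female_fitness["WD"]), 1, tolerance = 0.2)
})

test_that("estimates cover the truth at the nominal rate on 40-parent assays", {
  truth <- sdgd_truth(sdgd_params())
  n_sim <- 500
  set.seed(404)
  cover_T <- cover_m <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    rec <- generate_assay_data(truth, 40, parent = "male")
    eT <- estimate_transmission(rec)
    em <- estimate_sex_distortion(rec)
    cover_T[i] <- eT$ci["lower"] <= truth$params$d_m &&
      truth$params$d_m <= eT$ci["upper"]
    cover_m[i] <- em$ci["lower"] <= truth$params$m1 &&
      truth$params$m1 <= em$ci["upper"]
  }
  # 95% nominal; binomial noise at 500 replicates spans roughly +/- 3 points
  expect_gt(mean(cover_T), 0.91)
  expect_gt(mean(cover_m), 0.91)
})
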