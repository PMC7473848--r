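test_that("initial states match the release compositions", {
  s50 <- initial_state("50%")
  expect_equal(unname(s50$F[c("WW.xx", "WD.xx")]), c(0.25, 0.25))
  expect_equal(unname(s50$M[c("WW.x", "WD.x")]), c(0.25, 0.25))
  expect_equal(sum(s50$F) + sum(s50$M), 1)

  s10 <- initial_state("10%")
  expect_equal(unname(s10$M[c("WW.x", "WD.x")]), c(9 / 20, 1 / 20))
  expect_equal(unname(s10$F["WW.xx"]), 0.5)

  s0 <- initial_state("none")
  expect_equal(unname(s0$F["WW.xx"]), 0.5)
  expect_equal(unname(s0$M["WW.x"]), 0.5)

  s1 <- initial_state(0.01)  # 1% male release
  expect_equal(unname(s1$M[c("WW.x", "WD.x")]), c(0.99 / 2, 0.01 / 2))

  expect_error(initial_state(c(WW.xx = 0.6, WW.x = 0.6)), "sum to 1")
  expect_error(initial_state("75%"), "unknown named release")
})

test_that("egg and sperm pools are fitness-weighted gamete averages", {
  p <- sdgd_params()
  tab <- build_gamete_tables(p)
  # wild-type-only
  wt <- initial_state("none")
  E <- egg_proportions(wt, tab, p)
  expect_equal(unname(E["W.x"]), 1)
  S <- sperm_proportions(wt, tab, p)
  expect_equal(unname(S[c("W.x", "W.Y")]), c(0.5, 0.5))
  # sterile D/D females contribute nothing
  mix <- initial_state(c(WW.xx = 0.25, DD.xx = 0.25, WW.x = 0.5))
  expect_equal(egg_proportions(mix, tab, p), E)
  # 50:50 W/W and W/D fully fit females, d_f = 0.999, u_f = 0
  p2 <- sdgd_params(d_f = 0.999, u_f = 0,
                    female_fitness = c(WW = 1, WD = 1, WR = 1, DD = 0,
                                       DR = 0, RR = 0))
  tab2 <- build_gamete_tables(p2)
  st <- initial_state(c(WW.xx = 0.25, WD.xx = 0.25, WW.x = 0.5))
  E2 <- egg_proportions(st, tab2, p2)
  expect_equal(unname(E2["D.x"]), 0.999 / 2)
  # all W/D males: S(D,Y) = d_m * m1, and S(D,x) is always zero
  p3 <- sdgd_params(d_m = 0.92, u_m = 0, m1 = 0.93)
  tab3 <- build_gamete_tables(p3)
  stm <- initial_state(c(WW.xx = 0.5, WD.x = 0.5))
  S3 <- sperm_proportions(stm, tab3, p3)
  expect_equal(unname(S3["D.Y"]), 0.92 * 0.93)
  expect_equal(unname(S3["D.x"]), 0)
  # reproductive collapse is signalled, not fatal
  dead <- initial_state(c(DD.xx = 0.5, WW.x = 0.5))
  expect_true(isTRUE(attr(egg_proportions(dead, tab, p), "collapsed")))
})

test_that("one recursion step matches the pair-enumeration oracle", {
  set.seed(7)
  for (rep in 1:3) {
    p <- random_params()
    st <- initial_state(random_state())
    nxt <- step_generation(st, p)
    expect_equal(sum(nxt$F) + sum(nxt$M), 1, tolerance = 1e-12)
    expect_true(all(nxt$F >= 0) && all(nxt$M >= 0))
    oracle <- oracle_step(st, p)
    expect_equal(c(nxt$F, nxt$M), oracle, tolerance = 1e-12)
  }
})

test_that("wild type is a fixed point and neutral drive obeys Hardy-Weinberg", {
  p <- sdgd_params()
  wt <- initial_state("none")
  nxt <- step_generation(wt, p)
  expect_equal(nxt$F, wt$F, tolerance = 1e-14)
  expect_equal(nxt$M, wt$M, tolerance = 1e-14)
  expect_equal(population_load(wt, p), 0)
  # neutral parameters: D behaves as a Mendelian neutral allele, so its
  # frequency is conserved across generations
  pn <- sdgd_params(d_f = 0.5, d_m = 0.5, u_f = 0, u_m = 0,
                    m1 = 0.5, m2 = 0.5,
                    female_fitness = c(WW = 1, WD = 1, WR = 1, DD = 1,
                                       DR = 1, RR = 1),
                    male_fitness = c(WW = 1, WD = 1, WR = 1, DD = 1,
                                     DR = 1, RR = 1))
  st <- initial_state("50%")
  d0 <- d_allele_freq_of(st)
  for (g in 1:10) st <- step_generation(st, pn)
  expect_equal(d_allele_freq_of(st), d0, tolerance = 1e-12)
})

test_that("population load follows 1 - 2 F wbar_f wbar_m", {
  p <- sdgd_params(female_fitness = c(WW = 0.627, WD = 0.627, WR = 1,
                                      DD = 0, DR = 0, RR = 0))
  st <- initial_state(c(WW.xx = 0.5, WW.x = 0.5))
  expect_equal(population_load(st, p), 1 - 2 * 0.5 * 0.627 * 1)
  males <- initial_state(c(WW.x = 1))
  expect_equal(population_load(males, sdgd_params()), 1)
})

test_that("biting females are those with a functional target-gene copy", {
  expect_equal(biting_female_fraction(initial_state("none")), 0.5)
  expect_equal(biting_female_fraction(initial_state(c(DD.xx = 0.5,
                                                      WW.x = 0.5))), 0)
  mix <- initial_state(c(WW.xx = 0.2, WD.xX = 0.1, WR.XX = 0.1,
                         DR.xx = 0.1, WW.x = 0.5))
  expect_equal(biting_female_fraction(mix), 0.4)
})

test_that("trajectories report sensible summaries", {
  p <- sdgd_params()
  tr <- simulate_deterministic(p, "50%", 25)
  expect_s3_class(tr, "sdgd_trajectory")
  expect_equal(nrow(tr), 26)
  expect_equal(tr$rel_egg_output[1], 1)
  expect_equal(tr$female_frac + tr$male_frac, rep(1, 26), tolerance = 1e-12)
  expect_true(all(tr$load >= 0 & tr$load <= 1))
  # transgenic frequency rises monotonically in the early invasion phase
  expect_true(all(diff(tr$transgenic_freq[1:6]) > 0))
  # zero generations: initial summaries only
  expect_equal(nrow(simulate_deterministic(p, "50%", 0)), 1)
  # no distortion, no fitness cost: sex ratio pinned at 1:1
  pn <- sdgd_params(d_f = 0.95, d_m = 0.95, m1 = 0.5, m2 = 0.5,
                    female_fitness = c(WW = 1, WD = 1, WR = 1, DD = 1,
                                       DR = 1, RR = 1),
                    male_fitness = c(WW = 1, WD = 1, WR = 1, DD = 1,
                                     DR = 1, RR = 1))
  trn <- simulate_deterministic(pn, "50%", 15)
  expect_equal(trn$female_frac, rep(0.5, 16), tolerance = 1e-12)
})

test_that("long-run outcomes classify into the three phases", {
  # sterile heterozygous females without sex distortion: drive cannot spread
  p_lost <- sdgd_params(m1 = 0.5, m2 = 0.5,
                        female_fitness = c(WW = 1, WD = 0, WR = 1, DD = 0,
                                           DR = 0, RR = 0))
  expect_equal(classify_outcome(p_lost, "50%", 400)$outcome, "construct_lost")
  # low SDGD male fitness (< ~0.5): construct eventually lost
  p_lowm <- sdgd_params(male_fitness = c(WW = 1, WD = 0.4, WR = 1,
                                         DD = 0.4, DR = 0.4, RR = 1))
  expect_equal(classify_outcome(p_lowm, "50%", 400)$outcome, "construct_lost")
  # reference parameters settle at a suppressed intermediate equilibrium
  res <- classify_outcome(sdgd_params(), "50%", 400)
  expect_equal(res$outcome, "intermediate_equilibrium")
  expect_gt(res$load, 0.5)
  expect_lt(res$load, 1)
  # no release: trivially no drive
  expect_equal(classify_outcome(sdgd_params(), "none", 50)$outcome,
               "construct_lost")
})

test_that("load at complete distortion is invariant to heterozygous female fitness", {
  loads <- sapply(c(0, 0.3, 0.627, 1), function(w) {
    p <- sdgd_params(m1 = 1, m2 = 1,
                     female_fitness = c(WW = 1, WD = w, WR = 1, DD = 0,
                                        DR = 0, RR = 0))
    tr <- simulate_deterministic(p, "10%", 200)
    tr$load[nrow(tr)]
  })
  # at m = 1 no W/D females are ever produced, so their fitness cannot matter
  expect_equal(max(loads) - min(loads), 0, tolerance = 1e-10)
  expect_gt(loads[1], 0)
})
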