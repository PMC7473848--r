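#' Initial genotype-frequency state for a release
#'
#' Constructs the generation-0 state of the discrete-generation model.
#' Releases are specified relative to a wild-type population with equal sex
#' ratio:
#' \itemize{
#'   \item `"50%"` — heterozygous males and females matching the resident
#'     wild types: F(WW.xx) = F(WD.xx) = M(WW.x) = M(WD.x) = 1/4
#'     (25% drive allele frequency);
#'   \item `"10%"` — male-only release at 10% of the male population:
#'     M(WW.x) = 9/20, M(WD.x) = 1/20, F(WW.xx) = 1/2 (2.5% allele
#'     frequency);
#'   \item a single number `r` in `[0, 1)` — male-only release of W/D
#'     heterozygotes as a fraction `r` of the male population;
#'   \item a named numeric vector over genotype labels — explicit
#'     frequencies (must sum to 1).
#' }
#'
#' @param release_spec Release specification as above. Default `"50%"`.
#' @return An object of class `sdgd_state`: list with `F` (18 female
#'   frequencies), `M` (12 male frequencies), `generation = 0`.
#' @export
initial_state <- function(release_spec = "50%") {
  F <- stats::setNames(numeric(18), female_genotypes())
  M <- stats::setNames(numeric(12), male_genotypes())
  if (is.character(release_spec) && length(release_spec) == 1) {
    if (release_spec %in% c("50%", "50")) {
      F["WW.xx"] <- 0.25; F["WD.xx"] <- 0.25
      M["WW.x"] <- 0.25;  M["WD.x"] <- 0.25
    } else if (release_spec %in% c("10%", "10")) {
      F["WW.xx"] <- 0.5
      M["WW.x"] <- 9 / 20; M["WD.x"] <- 1 / 20
    } else if (release_spec %in% c("0%", "none", "wild-type")) {
      F["WW.xx"] <- 0.5; M["WW.x"] <- 0.5
    } else stop("unknown named release: ", release_spec,
                " (use \"10%\", \"50%\", \"none\", a fraction, or a named vector)")
  } else if (is.numeric(release_spec) && length(release_spec) == 1 &&
             is.null(names(release_spec))) {
    r <- release_spec
    if (is.na(r) || r < 0 || r >= 1)
      stop("male release fraction must be in [0, 1)")
    F["WW.xx"] <- 0.5
    M["WW.x"] <- (1 - r) / 2
    M["WD.x"] <- r / 2
  } else if (is.numeric(release_spec) && !is.null(names(release_spec))) {
    bad <- setdiff(names(release_spec),
                   c(female_genotypes(), male_genotypes()))
    if (length(bad)) stop("unknown genotype(s): ", paste(bad, collapse = ", "))
    if (abs(sum(release_spec) - 1) > 1e-8)
      stop("explicit release frequencies must sum to 1 (got ",
           format(sum(release_spec)), ")")
    if (any(release_spec < 0)) stop("frequencies must be non-negative")
    fg <- intersect(names(release_spec), female_genotypes())
    mg <- intersect(names(release_spec), male_genotypes())
    F[fg] <- release_spec[fg]
    M[mg] <- release_spec[mg]
  } else stop("unrecognised release specification")
  new_state(F, M, 0L)
}

new_state <- function(F, M, generation) {
  structure(list(F = F, M = M, generation = as.integer(generation)),
            class = "sdgd_state")
}

#' @export
print.sdgd_state <- function(x, ...) {
  cat(sprintf("sdgd_state (generation %d): %.3f female / %.3f male\n",
              x$generation, sum(x$F), sum(x$M)))
  nz <- c(x$F[x$F > 0], x$M[x$M > 0])
  print(round(nz, 4))
  invisible(x)
}

#' Egg class proportions produced by the current females
#'
#' Fitness-weighted average of the female gamete rows: the proportion of
#' eggs with target allele k and chromosome l is
#' `sum(c * w * F) / sum(w * F)` over female genotypes.
#'
#' @param state An `sdgd_state` (or any list with a female vector `F`).
#' @param tables [build_gamete_tables()] output.
#' @param params An [sdgd_params()] object.
#' @return Named 6-vector over egg classes summing to 1, or all-`NA` with
#'   attribute `collapsed = TRUE` if no female has positive fitness-weighted
#'   mass (reproductive collapse; the caller decides how to terminate).
#' @export
egg_proportions <- function(state, tables, params) {
  w <- female_fitness_vector(params) * state$F
  tot <- sum(w)
  if (tot <= 0) {
    out <- stats::setNames(rep(NA_real_, 6), EGG_CLASSES)
    attr(out, "collapsed") <- TRUE
    return(out)
  }
  drop(crossprod(tables$female, w)) / tot
}

#' Sperm class proportions produced by the current males
#'
#' Symmetric to [egg_proportions()] with male fitness weights; the sperm
#' class (D, x) is identically zero because SDGD males transmit only damaged
#' X chromosomes.
#'
#' @inheritParams egg_proportions
#' @return Named 9-vector over sperm classes (allele x {x, X, Y}) summing to
#'   1, or all-`NA` with attribute `collapsed` on male reproductive collapse.
#' @export
sperm_proportions <- function(state, tables, params) {
  w <- male_fitness_vector(params) * state$M
  tot <- sum(w)
  if (tot <= 0) {
    out <- stats::setNames(rep(NA_real_, 9), colnames(tables$male))
    attr(out, "collapsed") <- TRUE
    return(out)
  }
  drop(crossprod(tables$male, w)) / tot
}

# egg vector as 3x2 matrix [allele, chrom]; sperm vector as 3x3 [allele, chrom]
egg_matrix <- function(E) matrix(E, 3, 2, dimnames = list(TARGET_ALLELES,
                                                          c("x", "X")))
sperm_matrix <- function(S) matrix(S, 3, 3, dimnames = list(TARGET_ALLELES,
                                                            SPERM_CHROM))

#' One generation of the deterministic recursion
#'
#' Random union of egg and sperm classes gives the next generation's
#' genotype frequencies. For a female genotype with target alleles (i, j)
#' and chromosomes (p, q),
#' `F'(ij, pq) = (1 - delta_ij/2) (1 - delta_pq/2) *
#'   (E_ip S_jq + E_jp S_iq + E_iq S_jp + E_jq S_ip)`,
#' and for males `M'(ij, q) = (1 - delta_ij/2) (E_iq S_jY + E_jq S_iY)`,
#' where the Kronecker-delta factors halve the double-counted homozygote
#' combinations. The output sums to 1 by construction; it is renormalized to
#' absorb floating-point drift after asserting the pre-normalization sum.
#'
#' @param state An `sdgd_state`.
#' @param params An [sdgd_params()] object.
#' @param tables Optional precomputed [build_gamete_tables()] (rebuilt from
#'   `params` if missing).
#' @return The next `sdgd_state`. If either sex has zero fitness-weighted
#'   mass the state is returned frozen with attribute `collapsed = TRUE`.
#' @export
step_generation <- function(state, params, tables = build_gamete_tables(params)) {
  E <- egg_proportions(state, tables, params)
  S <- sperm_proportions(state, tables, params)
  if (isTRUE(attr(E, "collapsed")) || isTRUE(attr(S, "collapsed"))) {
    out <- new_state(state$F, state$M, state$generation + 1L)
    attr(out, "collapsed") <- TRUE
    return(out)
  }
  Em <- egg_matrix(E)
  Sm <- sperm_matrix(S)
  Fn <- stats::setNames(numeric(18), female_genotypes())
  for (tc in TARGET_CLASSES) {
    al <- target_pair(tc)
    i <- al[1]; j <- al[2]
    dij <- if (i == j) 0.5 else 1
    for (pq in FEMALE_CHROM) {
      ch <- strsplit(pq, "")[[1]]
      p <- ch[1]; q <- ch[2]
      dpq <- if (p == q) 0.5 else 1
      Fn[paste(tc, pq, sep = ".")] <- dij * dpq *
        (Em[i, p] * Sm[j, q] + Em[j, p] * Sm[i, q] +
         Em[i, q] * Sm[j, p] + Em[j, q] * Sm[i, p])
    }
  }
  Mn <- stats::setNames(numeric(12), male_genotypes())
  for (tc in TARGET_CLASSES) {
    al <- target_pair(tc)
    i <- al[1]; j <- al[2]
    dij <- if (i == j) 0.5 else 1
    for (q in MALE_CHROM) {
      Mn[paste(tc, q, sep = ".")] <- dij *
        (Em[i, q] * Sm[j, "Y"] + Em[j, q] * Sm[i, "Y"])
    }
  }
  tot <- sum(Fn) + sum(Mn)
  if (abs(tot - 1) > 1e-9)
    stop("recursion output sums to ", format(tot), " (expected 1)")
  new_state(Fn / tot, Mn / tot, state$generation + 1L)
}

#' Genetic load on the population
#'
#' `L(t) = 1 - 2 F(t) wbar_f(t) wbar_m(t)`: the reduction in reproductive
#' output relative to an all-wild-type population, combining the deficit of
#' females and the mean fitness of each sex. Zero for pure wild type; 1 when
#' females (or their average fitness, or male fitness) vanish.
#'
#' @param state An `sdgd_state`.
#' @param params An [sdgd_params()] object.
#' @return Load in `[0, 1]` (for m1, m2 >= 0.5 and fitnesses <= 1).
#' @export
population_load <- function(state, params) {
  Ft <- sum(state$F)
  Mt <- sum(state$M)
  wf <- if (Ft > 0) sum(female_fitness_vector(params) * state$F) / Ft else 0
  wm <- if (Mt > 0) sum(male_fitness_vector(params) * state$M) / Mt else 0
  1 - 2 * Ft * wf * wm
}

#' Fraction of transmission-competent (biting) females
#'
#' Females homozygous for disruption of the female-specific target-gene
#' isoform (D/D, D/R, R/R) are viable but cannot bite, so only females with
#' at least one W copy contribute to disease transmission.
#'
#' @param state An `sdgd_state`.
#' @return Total frequency of W-carrying females (equals F(t) in a wild-type
#'   population).
#' @export
biting_female_fraction <- function(state) {
  keep <- has_wild_copy()[geno_target(names(state$F))]
  sum(state$F[keep])
}

# per-generation summary row used by simulate_deterministic
state_summary <- function(state, params) {
  Ft <- sum(state$F); Mt <- sum(state$M)
  dc <- d_copies()
  dF <- dc[geno_target(names(state$F))]
  dM <- dc[geno_target(names(state$M))]
  transgenic <- sum(state$F[dF > 0]) + sum(state$M[dM > 0])
  d_freq <- (sum(state$F * dF) + sum(state$M * dM)) / 2
  wfv <- female_fitness_vector(params)
  wmv <- male_fitness_vector(params)
  wf <- if (Ft > 0) sum(wfv * state$F) / Ft else 0
  wm <- if (Mt > 0) sum(wmv * state$M) / Mt else 0
  relE <- cage_egg_rel(params)
  eggs <- sum(relE$f * state$F) *
    (if (Mt > 0) sum(relE$m * state$M) / Mt else 0) * params$cage$p_mate
  data.frame(generation = state$generation,
             transgenic_freq = transgenic,
             d_allele_freq = d_freq,
             female_frac = Ft, male_frac = Mt,
             wbar_f = wf, wbar_m = wm,
             load = 1 - 2 * Ft * wf * wm,
             egg_output = eggs,
             biting_female_frac = biting_female_fraction(state))
}

#' Simulate the deterministic discrete-generation model
#'
#' Iterates [step_generation()] from an initial release and records
#' per-generation summaries: transgenic (>= 1 drive copy) frequency, drive
#' allele frequency, sex-composition, mean fitnesses, load, expected
#' relative egg output (large-population limit of the stochastic cage
#' model, normalized to generation 0) and the biting-female fraction. If the
#' fitness-weighted mass of either sex reaches zero the trajectory freezes
#' and is flagged as eliminated.
#'
#' @param params An [sdgd_params()] object.
#' @param release_spec See [initial_state()].
#' @param generations Number of generations to simulate (>= 0).
#' @param keep_states If `TRUE`, attach the list of `sdgd_state`s.
#' @return A data.frame of class `sdgd_trajectory` with one row per
#'   generation (column `rel_egg_output` is normalized to generation 0) and
#'   attributes `eliminated` (logical) and optionally `states`.
#' @export
simulate_deterministic <- function(params, release_spec = "50%",
                                   generations = 30, keep_states = FALSE) {
  validate_params(params)
  stopifnot(generations >= 0)
  tables <- build_gamete_tables(params)
  state <- initial_state(release_spec)
  rows <- vector("list", generations + 1)
  states <- if (keep_states) vector("list", generations + 1)
  rows[[1]] <- state_summary(state, params)
  if (keep_states) states[[1]] <- state
  eliminated <- FALSE
  for (g in seq_len(generations)) {
    state <- step_generation(state, params, tables)
    if (isTRUE(attr(state, "collapsed"))) {
      eliminated <- TRUE
      row <- rows[[g]]
      row$generation <- state$generation
      row$load <- 1
      row$egg_output <- 0
      rows[[g + 1]] <- row
    } else {
      rows[[g + 1]] <- state_summary(state, params)
    }
    if (keep_states) states[[g + 1]] <- state
    if (eliminated) {
      # freeze remaining generations at the collapsed state
      for (gg in seq(g + 1, length.out = generations - g)) {
        row <- rows[[g + 1]]
        row$generation <- row$generation + (gg - g)
        rows[[gg + 1]] <- row
        if (keep_states) states[[gg + 1]] <- state
      }
      break
    }
  }
  out <- do.call(rbind, rows)
  e0 <- out$egg_output[1]
  out$rel_egg_output <- if (e0 > 0) out$egg_output / e0 else NA_real_
  attr(out, "eliminated") <- eliminated
  if (keep_states) attr(out, "states") <- states
  class(out) <- c("sdgd_trajectory", "data.frame")
  out
}

# relative egg-production multipliers per genotype (mother f, father m);
# defaults fall back to the composed genotype fitness so that the stochastic
# cage model's large-population limit matches the deterministic weighting
cage_egg_rel <- function(params) {
  f <- params$cage$egg_rel_f
  m <- params$cage$egg_rel_m
  if (is.null(f)) f <- female_fitness_vector(params)
  else f <- f[female_genotypes()]
  if (is.null(m)) m <- male_fitness_vector(params)
  else m <- m[male_genotypes()]
  list(f = f, m = m)
}

cage_hatch_rel <- function(params) {
  f <- params$cage$hatch_rel_f
  m <- params$cage$hatch_rel_m
  if (is.null(f)) f <- stats::setNames(rep(1, 18), female_genotypes())
  else f <- f[female_genotypes()]
  if (is.null(m)) m <- stats::setNames(rep(1, 12), male_genotypes())
  else m <- m[male_genotypes()]
  list(f = f, m = m)
}

#' Classify the long-run outcome of a release
#'
#' Runs the deterministic model to a horizon (default 400 generations) and
#' classifies the end state: `"elimination"` if the load exceeds
#' `1 - eps_load` (or reproduction has collapsed), `"construct_lost"` if the
#' drive allele frequency has fallen below `eps_freq`, otherwise
#' `"intermediate_equilibrium"` if the drive allele frequency has settled
#' (relative change below `1e-6` over the last 20 generations) or
#' `"unresolved"` if it is still moving at the horizon.
#'
#' @param params An [sdgd_params()] object.
#' @param release_spec See [initial_state()].
#' @param horizon Generations to simulate (default 400).
#' @param eps_load Load threshold for elimination (default `1e-6`).
#' @param eps_freq Drive-frequency threshold for loss (default `1e-8`).
#' @return List with `outcome` (one of the four labels), `load`, `d_freq`
#'   and the final summary row `final`.
#' @export
classify_outcome <- function(params, release_spec = "50%", horizon = 400,
                             eps_load = 1e-6, eps_freq = 1e-8) {
  stopifnot(horizon >= 1)
  traj <- simulate_deterministic(params, release_spec, horizon)
  n <- nrow(traj)
  final <- traj[n, ]
  outcome <- if (isTRUE(attr(traj, "eliminated")) ||
                 final$load > 1 - eps_load) {
    "elimination"
  } else if (final$d_allele_freq < eps_freq) {
    "construct_lost"
  } else {
    tail_d <- traj$d_allele_freq[max(1, n - 20):n]
    if (max(tail_d) - min(tail_d) <= 1e-6 * max(tail_d, eps_freq))
      "intermediate_equilibrium" else "unresolved"
  }
  list(outcome = outcome, load = final$load, d_freq = final$d_allele_freq,
       final = final)
}
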