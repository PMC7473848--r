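#' Initial adult composition of a cage trial
#'
#' The two named releases follow the laboratory cage setups:
#' `"10%"` is 300 wild-type females, 270 wild-type males and 30 heterozygous
#' (W/D) males (2.5% drive allele frequency); `"50%"` is 150 wild-type
#' females, 150 wild-type males, 150 heterozygous males and 150 heterozygous
#' females (25% allele frequency). Explicit counts may be given as a list
#' with integer vectors `F` (named by female genotypes) and `M` (named by
#' male genotypes).
#'
#' @param release_spec `"10%"`, `"50%"`, or a list of explicit counts.
#' @return An object of class `cage_state`: integer counts `F` (18) and `M`
#'   (12) plus a generation index.
#' @export
init_cage <- function(release_spec = "10%") {
  F <- stats::setNames(integer(18), female_genotypes())
  M <- stats::setNames(integer(12), male_genotypes())
  if (is.character(release_spec) && length(release_spec) == 1) {
    if (release_spec %in% c("10%", "10")) {
      F["WW.xx"] <- 300L
      M["WW.x"] <- 270L; M["WD.x"] <- 30L
    } else if (release_spec %in% c("50%", "50")) {
      F["WW.xx"] <- 150L; F["WD.xx"] <- 150L
      M["WW.x"] <- 150L;  M["WD.x"] <- 150L
    } else stop("unknown named release: ", release_spec)
  } else if (is.list(release_spec)) {
    for (part in c("F", "M")) {
      v <- release_spec[[part]]
      if (is.null(v)) next
      tgt <- if (part == "F") female_genotypes() else male_genotypes()
      bad <- setdiff(names(v), tgt)
      if (length(bad)) stop("unknown genotype(s): ", paste(bad, collapse = ", "))
      if (any(v < 0)) stop("cage counts must be non-negative")
      if (part == "F") F[names(v)] <- as.integer(v)
      else M[names(v)] <- as.integer(v)
    }
  } else stop("unrecognised cage release specification")
  structure(list(F = F, M = M, generation = 0L), class = "cage_state")
}

# Precomputed machinery for one parameter set: gamete tables, the 216 x 30
# offspring-genotype distribution (one row per mother x father genotype
# pair) and per-pair egg means and hatch probabilities.
build_cage_model <- function(params) {
  validate_params(params)
  tables <- build_gamete_tables(params)
  fg <- female_genotypes(); mg <- male_genotypes()
  offspring <- c(fg, mg)           # 30 offspring classes
  # map egg class (6) x sperm class (9) -> offspring genotype index
  idx <- matrix(0L, 6, 9)
  for (e in 1:6) {
    ek <- sub("\\..*", "", EGG_CLASSES[e])
    el <- sub(".*\\.", "", EGG_CLASSES[e])
    for (s in 1:9) {
      sk <- sub("\\..*", "", colnames(tables$male)[s])
      sl <- sub(".*\\.", "", colnames(tables$male)[s])
      tc <- paste(sort(factor(c(ek, sk), levels = TARGET_ALLELES)),
                  collapse = "")
      if (sl == "Y") {
        idx[e, s] <- 18L + match(paste(tc, el, sep = "."), mg)
      } else {
        pq <- paste(sort(factor(c(el, sl), levels = c("x", "X"))),
                    collapse = "")
        idx[e, s] <- match(paste(tc, pq, sep = "."), fg)
      }
    }
  }
  cross <- matrix(0, 18 * 12, 30,
                  dimnames = list(NULL, offspring))
  for (g in 1:18) for (h in 1:12) {
    joint <- outer(tables$female[g, ], tables$male[h, ])  # 6 x 9
    p <- numeric(30)
    for (k in 1:30) p[k] <- sum(joint[idx == k])
    cross[(g - 1) * 12 + h, ] <- p
  }
  relE <- cage_egg_rel(params)
  relH <- cage_hatch_rel(params)
  egg_mean <- params$cage$mean_eggs * outer(relE$f, relE$m)       # 18 x 12
  hatch_p <- pmin(1, params$cage$hatch_wt * outer(relH$f, relH$m))
  list(params = params, tables = tables, cross = cross,
       egg_mean = as.vector(t(egg_mean)),   # pair-major: (g-1)*12 + h
       hatch_p = as.vector(t(hatch_p)))
}

# multivariate hypergeometric draw: select k items without replacement from
# classes with counts n (vector); returns vector of selected counts
rmvhyper <- function(n, k) {
  out <- integer(length(n))
  remaining <- sum(n)
  if (k >= remaining) return(n)
  for (i in seq_along(n)) {
    if (k <= 0) break
    x <- stats::rhyper(1, n[i], remaining - n[i], k)
    out[i] <- x
    k <- k - x
    remaining <- remaining - n[i]
  }
  out
}

#' Advance a cage by one generation
#'
#' One discrete cage generation: (i) each female mates at most once, with a
#' father genotype drawn by frequency among the males (males mate with
#' replacement); (ii) each mated female lays a Poisson (or negative
#' binomial) number of eggs whose mean is scaled by her own and her mate's
#' relative egg production; (iii) eggs hatch independently with probability
#' given by the product of maternal and paternal hatch values relative to
#' wild type; (iv) offspring genotypes are drawn multinomially from the
#' parental pair's gamete cross; (v) the next generation is seeded with at
#' most `larva_cap` larvae (default 600) selected without replacement;
#' (vi) survival to adulthood is equal across genotypes.
#'
#' @param state A `cage_state`.
#' @param model Output of the internal cage-model builder; pass an
#'   [sdgd_params()] object instead to build it on the fly.
#' @return The next `cage_state`, with fields `eggs_laid`,
#'   `larvae_hatched`, `larvae_selected`, `transgenic_larvae`,
#'   `male_larvae`, `female_larvae` describing the transition, and
#'   `collapsed = TRUE` if the cage produced no next generation (no adults
#'   of one sex, or zero hatched larvae).
#' @export
cage_generation <- function(state, model) {
  if (inherits(model, "sdgd_params")) model <- build_cage_model(model)
  nf <- state$F; nm <- state$M
  collapsed_state <- function(eggs = 0L, hatched = 0L) {
    structure(list(F = stats::setNames(integer(18), female_genotypes()),
                   M = stats::setNames(integer(12), male_genotypes()),
                   generation = state$generation + 1L,
                   eggs_laid = eggs, larvae_hatched = hatched,
                   larvae_selected = 0L, transgenic_larvae = 0L,
                   male_larvae = 0L, female_larvae = 0L,
                   collapsed = TRUE), class = "cage_state")
  }
  if (sum(nf) == 0L || sum(nm) == 0L) return(collapsed_state())
  cg <- model$params$cage
  # mating: mothers by genotype, fathers multinomial by male frequency
  mated <- if (cg$p_mate < 1) stats::rbinom(18, nf, cg$p_mate) else nf
  N <- matrix(0L, 18, 12)
  for (g in which(mated > 0L))
    N[g, ] <- stats::rmultinom(1, mated[g], nm)
  Nv <- as.vector(t(N))                       # pair-major
  mu <- Nv * model$egg_mean
  eggs <- integer(length(mu))
  pos <- mu > 0
  if (any(pos)) {
    if (is.finite(cg$egg_dispersion)) {
      eggs[pos] <- stats::rnbinom(sum(pos),
                                  size = Nv[pos] * cg$egg_dispersion,
                                  mu = mu[pos])
    } else {
      eggs[pos] <- stats::rpois(sum(pos), mu[pos])
    }
  }
  hatched <- integer(length(eggs))
  pos <- eggs > 0L
  if (any(pos))
    hatched[pos] <- stats::rbinom(sum(pos), eggs[pos], model$hatch_p[pos])
  total_eggs <- sum(eggs)
  if (sum(hatched) == 0L) return(collapsed_state(total_eggs, 0L))
  off <- numeric(30)
  for (pair in which(hatched > 0L))
    off <- off + stats::rmultinom(1, hatched[pair], model$cross[pair, ])
  selected <- rmvhyper(off, cg$larva_cap)
  Fn <- stats::setNames(as.integer(selected[1:18]), female_genotypes())
  Mn <- stats::setNames(as.integer(selected[19:30]), male_genotypes())
  transgenic <- sum(selected[has_drive()[geno_target(c(female_genotypes(),
                                                       male_genotypes()))]])
  structure(list(F = Fn, M = Mn, generation = state$generation + 1L,
                 eggs_laid = total_eggs, larvae_hatched = sum(hatched),
                 larvae_selected = sum(selected),
                 transgenic_larvae = as.integer(transgenic),
                 male_larvae = sum(Mn), female_larvae = sum(Fn),
                 # a generation with no adults of one sex cannot reproduce
                 collapsed = sum(Fn) == 0L || sum(Mn) == 0L),
            class = "cage_state")
}

#' Simulate a full cage trial
#'
#' Runs [cage_generation()] for up to `horizon` generations from an initial
#' release, recording the per-generation observables of a cage trial:
#' transgenic fraction, male fraction, egg output (absolute and relative to
#' generation 0) and adult counts. Collapse is declared when a generation
#' hatches zero larvae or lacks adults of either sex.
#'
#' @param params An [sdgd_params()] object.
#' @param release_spec See [init_cage()].
#' @param horizon Maximum number of generations (default 30).
#' @param seed Optional integer seed for reproducibility.
#' @param model Optional prebuilt cage model (for repeated calls).
#' @return A list of class `cage_trajectory`: `summary` data.frame (one row
#'   per generation), `collapsed` flag, `collapse_generation` (`NA` if
#'   none), and `seed`.
#' @export
simulate_cage <- function(params, release_spec = "10%", horizon = 30,
                          seed = NULL, model = NULL) {
  stopifnot(horizon >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(model)) model <- build_cage_model(params)
  state <- init_cage(release_spec)
  dc_f <- has_drive()[geno_target(female_genotypes())]
  dc_m <- has_drive()[geno_target(male_genotypes())]
  rows <- list()
  eggs0 <- NA_real_
  collapse_gen <- NA_integer_
  summarize <- function(state, eggs_next) {
    nF <- sum(state$F); nM <- sum(state$M)
    data.frame(generation = state$generation,
               n_female = nF, n_male = nM,
               transgenic_frac = if (nF + nM > 0)
                 (sum(state$F[dc_f]) + sum(state$M[dc_m])) / (nF + nM)
                 else NA_real_,
               male_frac = if (nF + nM > 0) nM / (nF + nM) else NA_real_,
               eggs = eggs_next)
  }
  for (g in seq_len(horizon)) {
    nxt <- cage_generation(state, model)
    eggs_here <- nxt$eggs_laid  # eggs laid by the adults of `state`
    rows[[g]] <- summarize(state, eggs_here)
    if (g == 1) eggs0 <- eggs_here
    if (isTRUE(nxt$collapsed)) {
      collapse_gen <- nxt$generation
      rows[[g + 1]] <- summarize(nxt, NA_real_)
      break
    }
    state <- nxt
    if (g == horizon) rows[[g + 1]] <- summarize(state, NA_real_)
  }
  summary <- do.call(rbind, rows)
  summary$rel_egg_output <- if (!is.na(eggs0) && eggs0 > 0)
    summary$eggs / eggs0 else NA_real_
  structure(list(summary = summary,
                 collapsed = !is.na(collapse_gen),
                 collapse_generation = collapse_gen,
                 seed = seed),
            class = "cage_trajectory")
}

#' Probability that a cage collapses within a horizon
#'
#' Repeats [simulate_cage()] and reports the fraction of replicates in which
#' the population collapsed (zero hatched larvae, or no adults of one sex)
#' within the horizon, with a 95% Wilson score interval.
#'
#' @param params An [sdgd_params()] object.
#' @param release_spec See [init_cage()].
#' @param n_reps Number of replicates (the reference analysis uses 10,000).
#' @param horizon Generations per replicate (default 30).
#' @param seed Optional integer seed.
#' @return List with `probability`, `ci` (Wilson 95%), `n_collapsed`,
#'   `n_reps`, `horizon`, `seed`.
#' @export
collapse_probability <- function(params, release_spec = "10%",
                                 n_reps = 1000, horizon = 30, seed = NULL) {
  stopifnot(n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  model <- build_cage_model(params)
  n_collapsed <- 0L
  for (r in seq_len(n_reps)) {
    state <- init_cage(release_spec)
    for (g in seq_len(horizon)) {
      state <- cage_generation(state, model)
      if (isTRUE(state$collapsed)) {
        n_collapsed <- n_collapsed + 1L
        break
      }
    }
  }
  list(probability = n_collapsed / n_reps,
       ci = wilson_interval(n_collapsed, n_reps),
       n_collapsed = n_collapsed, n_reps = n_reps,
       horizon = horizon, seed = seed)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
  if (n < 1) stop("n must be >= 1")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, center - half), upper = min(1, center + half))
}
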