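#' Right-hand side of the continuous-time population model
#'
#' Density-dependent dynamics of genotype abundances with one adult life
#' stage. Writing f(t) and m(t) for total female and male abundance and
#' wbar_f, wbar_m for the abundance-weighted mean fitnesses, total
#' recruitment is
#' `2 * R_m / (1 + 2 (R_m - 1) wbar_m wbar_f f) * wbar_m wbar_f f`
#' (logistic density dependence in recruitment), distributed over offspring
#' genotypes through the same egg/sperm-proportion machinery as the discrete
#' model (with abundances in place of frequencies), and every genotype has
#' unit per-capita death rate. Abundances are normalized so that the
#' pre-release wild-type equilibrium has n = f + m = 1.
#'
#' @param y Numeric 30-vector of abundances: 18 female then 12 male
#'   genotypes in canonical order.
#' @param params An [sdgd_params()] object (`R_m` sets the low-density
#'   growth rate per generation).
#' @param tables Optional precomputed [build_gamete_tables()].
#' @return Numeric 30-vector of time derivatives (per generation).
#' @export
ode_rhs <- function(y, params, tables = build_gamete_tables(params)) {
  y <- pmax(y, 0)  # integration guard
  yf <- y[1:18]; ym <- y[19:30]
  f <- sum(yf); m <- sum(ym)
  if (f <= 0 || m <= 0) return(-y)
  wf <- female_fitness_vector(params)
  wm <- male_fitness_vector(params)
  wf_bar <- sum(wf * yf) / f
  wm_bar <- sum(wm * ym) / m
  if (wf_bar <= 0 || wm_bar <= 0) return(-y)
  state <- list(F = stats::setNames(yf, female_genotypes()),
                M = stats::setNames(ym, male_genotypes()))
  E <- egg_proportions(state, tables, params)
  S <- sperm_proportions(state, tables, params)
  Em <- egg_matrix(E)
  Sm <- sperm_matrix(S)
  wff <- wm_bar * wf_bar * f
  rho <- 2 * params$R_m * wff / (1 + 2 * (params$R_m - 1) * wff)
  dy <- numeric(30)
  k <- 0L
  for (tc in TARGET_CLASSES) {
    al <- target_pair(tc); i <- al[1]; j <- al[2]
    dij <- if (i == j) 0.5 else 1
    for (pq in FEMALE_CHROM) {
      ch <- strsplit(pq, "")[[1]]; p <- ch[1]; q <- ch[2]
      dpq <- if (p == q) 0.5 else 1
      k <- k + 1L
      dy[k] <- rho * dij * dpq *
        (Em[i, p] * Sm[j, q] + Em[j, p] * Sm[i, q] +
         Em[i, q] * Sm[j, p] + Em[j, q] * Sm[i, p])
    }
  }
  for (tc in TARGET_CLASSES) {
    al <- target_pair(tc); i <- al[1]; j <- al[2]
    dij <- if (i == j) 0.5 else 1
    for (q in MALE_CHROM) {
      k <- k + 1L
      dy[k] <- rho * dij * (Em[i, q] * Sm[j, "Y"] + Em[j, q] * Sm[i, "Y"])
    }
  }
  dy - y
}

# Adaptive Dormand-Prince RK5(4) integrator (no ODE-solver package is
# available in the target environment). Returns the state at each requested
# output time by integrating with embedded error control and taking an
# exact (clipped) step onto each output point.
rk45_integrate <- function(rhs, y0, times, rtol = 1e-8, atol = 1e-12,
                           h_init = 0.01, h_max = 1) {
  a <- list(c(1 / 5),
            c(3 / 40, 9 / 40),
            c(44 / 45, -56 / 15, 32 / 9),
            c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
            c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
            c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84))
  b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
  b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
          187 / 2100, 1 / 40)
  out <- matrix(NA_real_, length(times), length(y0))
  t <- times[1]
  y <- y0
  out[1, ] <- y
  h <- h_init
  k1 <- rhs(y)
  for (ti in seq_along(times)[-1]) {
    t_target <- times[ti]
    while (t < t_target - 1e-12) {
      h <- min(h, h_max, t_target - t)
      repeat {
        ks <- matrix(0, 7, length(y))
        ks[1, ] <- k1
        for (s in 2:6) {
          yy <- y + h * drop(a[[s - 1]] %*% ks[seq_len(s - 1), , drop = FALSE])
          ks[s, ] <- rhs(yy)
        }
        y5 <- y + h * drop(b5[1:6] %*% ks[1:6, , drop = FALSE])
        ks[7, ] <- rhs(y5)
        y4 <- y + h * drop(b4 %*% ks)
        sc <- atol + rtol * pmax(abs(y), abs(y5))
        err <- sqrt(mean(((y5 - y4) / sc)^2))
        if (err <= 1 || h < 1e-12) {
          t <- t + h
          y <- pmax(y5, 0)
          k1 <- ks[7, ]  # FSAL
          h <- h * min(5, max(0.2, 0.9 * err^(-1 / 5)))
          break
        }
        h <- h * max(0.2, 0.9 * err^(-1 / 5))
      }
    }
    out[ti, ] <- y
  }
  out
}

#' Simulate a field release with the continuous-time model
#'
#' Starts from the wild-type equilibrium (n = 1, equal sexes) plus a single
#' additive pulse of heterozygous W/D males equal to `release_fraction` of
#' the resident male abundance, and integrates the genotype abundances.
#' Reports the total population, sex-specific abundances, transgenic
#' frequency and the abundance of transmission-competent (biting) females
#' (those with at least one functional W copy), all relative to the
#' pre-release population size.
#'
#' @param params An [sdgd_params()] object.
#' @param release_fraction Released W/D males as a fraction of resident
#'   males (e.g. 0.01 for a 1% release).
#' @param t_max End time in generations.
#' @param dt_out Output spacing in generations (default 0.5).
#' @param rtol,atol Integrator tolerances.
#' @return A data.frame of class `sdgd_ode_trajectory` with columns `time`,
#'   `n`, `f`, `m`, `transgenic_freq`, `d_allele_freq`,
#'   `biting_female_abundance`; extinction (n < 1e-10) truncates with zeros.
#' @export
simulate_release <- function(params, release_fraction = 0.01, t_max = 50,
                             dt_out = 0.5, rtol = 1e-8, atol = 1e-12) {
  validate_params(params)
  stopifnot(release_fraction >= 0, t_max > 0)
  tables <- build_gamete_tables(params)
  y0 <- numeric(30)
  names(y0) <- c(female_genotypes(), male_genotypes())
  y0["WW.xx"] <- 0.5
  y0["WW.x"] <- 0.5
  y0["WD.x"] <- 0.5 * release_fraction
  times <- seq(0, t_max, by = dt_out)
  rhs <- function(y) ode_rhs(y, params, tables)
  ys <- rk45_integrate(rhs, y0, times, rtol = rtol, atol = atol)
  f <- rowSums(ys[, 1:18, drop = FALSE])
  m <- rowSums(ys[, 19:30, drop = FALSE])
  n <- f + m
  extinct <- which(n < 1e-10)
  if (length(extinct)) {
    ys[extinct, ] <- 0
    f[extinct] <- 0; m[extinct] <- 0; n[extinct] <- 0
  }
  dc <- d_copies()[geno_target(names(y0))]
  transgenic <- rowSums(ys[, dc > 0, drop = FALSE])
  d_freq <- as.vector(ys %*% dc) / (2 * pmax(n, .Machine$double.eps))
  biting_cols <- which(has_wild_copy()[geno_target(female_genotypes())])
  biting <- rowSums(ys[, biting_cols, drop = FALSE])
  out <- data.frame(time = times, n = n, f = f, m = m,
                    transgenic_freq = ifelse(n > 0, transgenic / n, NA_real_),
                    d_allele_freq = ifelse(n > 0, d_freq, NA_real_),
                    biting_female_abundance = biting)
  class(out) <- c("sdgd_ode_trajectory", "data.frame")
  out
}
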