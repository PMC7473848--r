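# Independent oracles and generators shared across test files.

# Brute-force gamete-row oracle: enumerates discrete meiotic events
# (allele slot choice + homing/repair; chromosome slot choice + shredding
# survival and damage) and accumulates probabilities event by event. Kept
# deliberately different in structure from the outer-product construction
# in the package.
oracle_female_row <- function(genotype, params) {
  tc <- sub("\\..*", "", genotype)
  pq <- strsplit(sub(".*\\.", "", genotype), "")[[1]]
  alleles <- strsplit(tc, "")[[1]]
  out <- numeric(6)
  names(out) <- c("W.x", "D.x", "R.x", "W.X", "D.X", "R.X")
  # allele events
  allele_events <- list()
  if (tc == "WD") {
    d <- params$d_f; u <- params$u_f
    allele_events <- list(c(a = "W", p = (1 - d) * (1 - u)),
                          c(a = "D", p = d),
                          c(a = "R", p = (1 - d) * u))
  } else {
    for (a in alleles)
      allele_events <- c(allele_events, list(c(a = a, p = 0.5)))
  }
  for (ae in allele_events) {
    for (slot in 1:2) {  # which maternal chromosome the egg receives
      cls <- paste(ae[["a"]], pq[slot], sep = ".")
      out[cls] <- out[cls] + as.numeric(ae[["p"]]) * 0.5
    }
  }
  out
}

oracle_male_row <- function(genotype, params) {
  tc <- sub("\\..*", "", genotype)
  q <- sub(".*\\.", "", genotype)
  alleles <- strsplit(tc, "")[[1]]
  classes <- as.vector(outer(c("W", "D", "R"), c("x", "X", "Y"), paste,
                             sep = "."))
  out <- stats::setNames(numeric(9), classes)
  allele_events <- list()
  if (tc == "WD") {
    d <- params$d_m; u <- params$u_m
    allele_events <- list(c(a = "W", p = (1 - d) * (1 - u)),
                          c(a = "D", p = d),
                          c(a = "R", p = (1 - d) * u))
  } else {
    for (a in alleles)
      allele_events <- c(allele_events, list(c(a = a, p = 0.5)))
  }
  shredder <- grepl("D", tc)
  m <- if (tc == "DD") params$m2 else params$m1
  for (ae in allele_events) {
    pa <- as.numeric(ae[["p"]])
    if (shredder) {
      # Y-bearing sperm with probability m; survivors carry a damaged X
      out[paste(ae[["a"]], "Y", sep = ".")] <-
        out[paste(ae[["a"]], "Y", sep = ".")] + pa * m
      out[paste(ae[["a"]], "X", sep = ".")] <-
        out[paste(ae[["a"]], "X", sep = ".")] + pa * (1 - m)
    } else {
      out[paste(ae[["a"]], "Y", sep = ".")] <-
        out[paste(ae[["a"]], "Y", sep = ".")] + pa * 0.5
      out[paste(ae[["a"]], q, sep = ".")] <-
        out[paste(ae[["a"]], q, sep = ".")] + pa * 0.5
    }
  }
  out
}

# random valid parameter set under a supplied RNG state
random_params <- function() {
  sdgd_params(d_f = runif(1), d_m = runif(1),
              u_f = runif(1), u_m = runif(1),
              m1 = runif(1, 0.5, 1), m2 = runif(1, 0.5, 1),
              female_fitness = stats::setNames(runif(6),
                                               c("WW", "WD", "WR", "DD", "DR", "RR")),
              male_fitness = stats::setNames(runif(6),
                                             c("WW", "WD", "WR", "DD", "DR", "RR")),
              s_X_f = runif(1), s_X_m = runif(1), h_X_f = runif(1))
}

# random population state (frequencies over all 30 genotypes)
random_state <- function() {
  v <- runif(30)
  v <- v / sum(v)
  stats::setNames(v, c(female_genotypes(), male_genotypes()))
}

# Independent one-generation oracle: enumerate every (mother, father)
# genotype pair, weight by fitness-weighted parental frequencies, and
# distribute offspring through the egg x sperm cross of that pair. This
# avoids the pooled-gamete recursion and its Kronecker-delta algebra.
oracle_step <- function(state, params) {
  tables <- build_gamete_tables(params)
  fg <- female_genotypes(); mg <- male_genotypes()
  wf <- sapply(fg, genotype_fitness, params = params)
  wm <- sapply(mg, genotype_fitness, params = params)
  pw <- wf * state$F / sum(wf * state$F)
  mw <- wm * state$M / sum(wm * state$M)
  off <- stats::setNames(numeric(30), c(fg, mg))
  for (g in fg) for (h in mg) {
    w <- pw[g] * mw[h]
    if (w == 0) next
    egg <- tables$female[g, ]
    sperm <- tables$male[h, ]
    for (e in names(egg)) for (s in names(sperm)) {
      pr <- w * egg[e] * sperm[s]
      if (pr == 0) next
      ek <- sub("\\..*", "", e); el <- sub(".*\\.", "", e)
      sk <- sub("\\..*", "", s); sl <- sub(".*\\.", "", s)
      tc <- paste(sort(factor(c(ek, sk), levels = c("W", "D", "R"))),
                  collapse = "")
      child <- if (sl == "Y") {
        paste(tc, el, sep = ".")
      } else {
        paste(tc, paste(sort(factor(c(el, sl), levels = c("x", "X"))),
                        collapse = ""), sep = ".")
      }
      off[child] <- off[child] + pr
    }
  }
  off
}

# drive allele frequency of a state (per individual, two target alleles)
d_allele_freq_of <- function(state) {
  nd <- c(WW = 0, WD = 1, WR = 0, DD = 2, DR = 1, RR = 0)
  all_g <- c(state$F, state$M)
  tc <- sub("\\..*", "", names(all_g))
  sum(all_g * nd[tc]) / 2
}
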