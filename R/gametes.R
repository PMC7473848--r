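#' Target-site allele ratios in gametes
#'
#' Gametes of W/D heterozygotes reflect homing: the drive allele D is
#' transmitted to a fraction d of gametes (d_f in females, d_m in males), and
#' the remaining non-drive gametes are split between W and the nonfunctional
#' resistant allele R by the end-joining fraction u, giving
#' W : D : R = (1-d)(1-u) : d : (1-d)u. All other genotypes segregate
#' Mendelian (homing requires one W and one D copy).
#'
#' @param target_class One of `"WW", "WD", "WR", "DD", "DR", "RR"`.
#' @param sex `"female"` or `"male"` (selects d_f/u_f or d_m/u_m).
#' @param params An [sdgd_params()] object.
#' @return Named numeric `c(W=, D=, R=)` summing to 1.
#' @examples
#' p <- sdgd_params(d_f = 0.95, u_f = 0.5)
#' gamete_target_ratios("WD", "female", p)  # W 0.025, D 0.95, R 0.025
#' @export
gamete_target_ratios <- function(target_class, sex = c("female", "male"),
                                 params) {
  sex <- match.arg(sex)
  if (!(is.character(target_class) && length(target_class) == 1 &&
        target_class %in% TARGET_CLASSES))
    stop("invalid target class: ", paste(target_class, collapse = ","))
  out <- c(W = 0, D = 0, R = 0)
  if (target_class == "WD") {
    d <- if (sex == "female") params$d_f else params$d_m
    u <- if (sex == "female") params$u_f else params$u_m
    out["W"] <- (1 - d) * (1 - u)
    out["D"] <- d
    out["R"] <- (1 - d) * u
  } else {
    for (a in target_pair(target_class)) out[a] <- out[a] + 0.5
  }
  out
}

#' Sex-chromosome composition of a male's sperm
#'
#' Males carrying at least one copy of the sex-distorter construct (W/D, D/R
#' or D/D at the target site) shred their X chromosomes during
#' spermatogenesis: a fraction m1 (heterozygotes) or m2 (D/D homozygotes) of
#' their sperm is Y-bearing, and every X that survives shredding is
#' transmitted as a damaged X, regardless of whether the father carried a
#' wild-type x or an already-damaged X. Males without the construct
#' segregate their carried chromosome and Y at 1/2 each, and a damaged X
#' stays damaged (but incurs no further cost).
#'
#' @param male_genotype A male genotype label such as `"WD.x"`; see
#'   [male_genotypes()].
#' @param params An [sdgd_params()] object.
#' @return Named numeric `c(x=, X=, Y=)` summing to 1.
#' @examples
#' p <- sdgd_params(m1 = 0.93)
#' sperm_sex_ratios("WD.x", p)  # x 0, X 0.07, Y 0.93
#' @export
sperm_sex_ratios <- function(male_genotype, params) {
  if (!(is.character(male_genotype) && length(male_genotype) == 1 &&
        male_genotype %in% male_genotypes()))
    stop("invalid male genotype: ", paste(male_genotype, collapse = ","),
         " (female genotypes have a sex-chromosome pair)")
  tc <- geno_target(male_genotype)
  q <- geno_chrom(male_genotype)
  out <- c(x = 0, X = 0, Y = 0)
  if (grepl("D", tc)) {
    m <- if (tc == "DD") params$m2 else params$m1
    out["Y"] <- m
    out["X"] <- 1 - m  # survivors of shredding are damaged, even if q == "x"
  } else {
    out[q] <- 0.5
    out["Y"] <- 0.5
  }
  out
}

#' Composed reproductive fitness of a genotype
#'
#' The fitness of a genotype is the target-class fitness multiplied by the
#' damaged-X factor: `(1 - s_X_m)` for males carrying a damaged X,
#' `(1 - s_X_f)` for XX females, `(1 - h_X_f * s_X_f)` for xX females, and 1
#' otherwise. With the default female fitness map, D/D, D/R and R/R females
#' are sterile (fitness 0) because the drive disrupts a female-fertility
#' gene.
#'
#' @param genotype A genotype label (`"WD.xx"` female or `"WD.x"` male).
#' @param params An [sdgd_params()] object.
#' @return Fitness in `[0, 1]`.
#' @export
genotype_fitness <- function(genotype, params) {
  if (genotype %in% female_genotypes()) {
    unname(female_fitness_vector(params)[genotype])
  } else if (genotype %in% male_genotypes()) {
    unname(male_fitness_vector(params)[genotype])
  } else stop("invalid genotype: ", paste(genotype, collapse = ","))
}

# composed fitness over all 18 female genotypes, canonical order
female_fitness_vector <- function(params) {
  g <- female_genotypes()
  xfac <- c(xx = 1, xX = 1 - params$h_X_f * params$s_X_f,
            XX = 1 - params$s_X_f)
  w <- params$female_fitness[geno_target(g)] * xfac[geno_chrom(g)]
  names(w) <- g
  w
}

# composed fitness over all 12 male genotypes, canonical order
male_fitness_vector <- function(params) {
  g <- male_genotypes()
  xfac <- c(x = 1, X = 1 - params$s_X_m)
  w <- params$male_fitness[geno_target(g)] * xfac[geno_chrom(g)]
  names(w) <- g
  w
}

#' Per-genotype gamete contribution tables
#'
#' Builds the coefficient tables mapping each parental genotype to its gamete
#' class distribution. Target-site and sex-chromosome segregation are
#' independent (the construct is autosomal), so each row is the outer
#' product of [gamete_target_ratios()] with the chromosome segregation:
#' eggs carry one of the mother's two chromosomes with probability 1/2 each
#' (damage state preserved), sperm chromosomes follow [sperm_sex_ratios()].
#'
#' @param params An [sdgd_params()] object.
#' @return A list of class `gamete_tables` with elements `female` (18 x 6
#'   matrix over egg classes W.x, D.x, R.x, W.X, D.X, R.X) and `male`
#'   (12 x 9 matrix over sperm classes allele x {x, X, Y}; the D.x column is
#'   identically zero). Every row sums to 1.
#' @export
build_gamete_tables <- function(params) {
  validate_params(params)
  fg <- female_genotypes()
  female <- matrix(0, length(fg), 6, dimnames = list(fg, EGG_CLASSES))
  for (g in fg) {
    ta <- gamete_target_ratios(geno_target(g), "female", params)
    pq <- strsplit(geno_chrom(g), "")[[1]]
    chrom <- c(x = 0, X = 0)
    for (l in pq) chrom[l] <- chrom[l] + 0.5
    female[g, ] <- as.vector(outer(ta, chrom))  # allele fastest
  }
  mg <- male_genotypes()
  sperm_classes <- as.vector(t(outer(SPERM_CHROM, TARGET_ALLELES,
                                     function(l, k) paste(k, l, sep = "."))))
  male <- matrix(0, length(mg), 9, dimnames = list(mg, sperm_classes))
  for (g in mg) {
    ta <- gamete_target_ratios(geno_target(g), "male", params)
    chrom <- sperm_sex_ratios(g, params)
    male[g, ] <- as.vector(outer(ta, chrom))
  }
  structure(list(female = female, male = male), class = "gamete_tables")
}
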