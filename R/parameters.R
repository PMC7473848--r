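#' Model parameter set for a sex-distorter gene drive
#'
#' Bundles every rate, fitness and cage parameter shared by the deterministic
#' recursion model, the stochastic cage simulator and the continuous-time
#' population model. Defaults are the point estimates for the
#' doublesex-targeting SDGD construct: drive transmission of 0.999 in females
#' and 0.96 in males (the fraction of a heterozygote's gametes carrying the
#' drive allele D), sex distortion m = 0.93, heterozygous female fitness
#' 0.627, SDGD male fitness 0.854, half of non-drive gametes repaired to the
#' resistant allele R, no damaged-X cost, and an intrinsic growth rate of 6
#' per generation.
#'
#' Note the convention: `d_f`/`d_m` are *transmission* fractions (the D share
#' of heterozygote gametes), not the "homing rate" reporting convention
#' (fraction of transgenic progeny above Mendelian, 2T - 1); see
#' [homing_rate_from_transmission()] to convert between the two.
#'
#' @param d_f,d_m Drive transmission in W/D females and males: fraction of
#'   gametes carrying D, in `[0, 1]`. Gametes of a W/D individual are
#'   W : D : R = (1-d)(1-u) : d : (1-d)u.
#' @param u_f,u_m Fraction of non-drive gametes from W/D individuals repaired
#'   by end-joining to the nonfunctional resistant allele R, in `[0, 1]`.
#' @param m1 Fraction of male progeny from SDGD heterozygous fathers
#'   (W/D and D/R), in `[0.5, 1]`.
#' @param m2 Fraction of male progeny from D/D fathers, in `[0.5, 1]`.
#' @param female_fitness Named numeric over the six target classes
#'   (WW, WD, WR, DD, DR, RR): female reproductive
#'   fitness before any damaged-X cost. D/D, D/R and R/R females are sterile
#'   by default (the target is a female-fertility gene).
#' @param male_fitness Named numeric over the six target classes: male
#'   reproductive fitness before any damaged-X cost. Males carrying the
#'   construct (W/D, D/D, D/R) share the SDGD male fitness by default.
#' @param s_X_f,s_X_m Fitness cost of damaged X chromosomes: `(1 - s_X_f)`
#'   for XX females, `(1 - s_X_m)` for X-carrying males, in `[0, 1]`.
#' @param h_X_f Dominance of the damaged-X cost in xX females, in `[0, 1]`
#'   (cost factor `1 - h_X_f * s_X_f`).
#' @param R_m Intrinsic population growth rate per generation at low density
#'   (continuous-time model), > 1.
#' @param cage List of cage/demographic parameters, see [cage_defaults()].
#' @return An object of class `sdgd_params` (a validated list).
#' @examples
#' p <- sdgd_params()                     # SDGD^dsx estimates
#' p0 <- sdgd_params(d_f = 0, d_m = 0, u_f = 0, u_m = 0,
#'                   m1 = 0.5, m2 = 0.5)  # neutral Mendelian limit
#' @export
sdgd_params <- function(d_f = 0.999, d_m = 0.96,
                        u_f = 0.5, u_m = 0.5,
                        m1 = 0.93, m2 = 0.93,
                        female_fitness = c(WW = 1, WD = 0.627, WR = 1,
                                           DD = 0, DR = 0, RR = 0),
                        male_fitness = c(WW = 1, WD = 0.854, WR = 1,
                                         DD = 0.854, DR = 0.854, RR = 1),
                        s_X_f = 0, s_X_m = 0, h_X_f = 0.5,
                        R_m = 6,
                        cage = cage_defaults()) {
  p <- list(d_f = d_f, d_m = d_m, u_f = u_f, u_m = u_m,
            m1 = m1, m2 = m2,
            female_fitness = female_fitness[TARGET_CLASSES],
            male_fitness = male_fitness[TARGET_CLASSES],
            s_X_f = s_X_f, s_X_m = s_X_m, h_X_f = h_X_f,
            R_m = R_m,
            cage = utils::modifyList(cage_defaults(), as.list(cage)))
  class(p) <- "sdgd_params"
  validate_params(p)
  p
}

#' Default cage-trial parameters
#'
#' @param larva_cap Larval carrying capacity per generation (600 in the cage
#'   trials: each generation is seeded from 600 randomly selected larvae).
#' @param mean_eggs Mean eggs laid per mated wild-type female. Default 165.6,
#'   chosen so that with `hatch_wt = 0.85` the wild-type larval output is the
#'   observed 140.8 per female.
#' @param hatch_wt Wild-type egg hatching probability.
#' @param egg_dispersion Negative-binomial size parameter for per-female egg
#'   counts; `Inf` (default) gives Poisson counts.
#' @param p_mate Probability that a female mates (each female mates at most
#'   once; males mate freely).
#' @param egg_rel_f,egg_rel_m Optional named numeric vectors over the 18
#'   female / 12 male genotype labels giving relative egg production (mother)
#'   and the father's relative egg-production multiplier. `NULL` (default)
#'   uses the composed genotype fitness, so the large-population limit of the
#'   cage model reproduces the deterministic fitness weighting exactly.
#' @param hatch_rel_f,hatch_rel_m Optional named relative hatch multipliers
#'   per parental genotype (mother, father); `NULL` means 1 for all.
#' @return Named list of cage parameters.
#' @export
cage_defaults <- function(larva_cap = 600L, mean_eggs = 165.6,
                          hatch_wt = 0.85, egg_dispersion = Inf,
                          p_mate = 1,
                          egg_rel_f = NULL, egg_rel_m = NULL,
                          hatch_rel_f = NULL, hatch_rel_m = NULL) {
  list(larva_cap = larva_cap, mean_eggs = mean_eggs, hatch_wt = hatch_wt,
       egg_dispersion = egg_dispersion, p_mate = p_mate,
       egg_rel_f = egg_rel_f, egg_rel_m = egg_rel_m,
       hatch_rel_f = hatch_rel_f, hatch_rel_m = hatch_rel_m)
}

check_prob <- function(x, nm, lo = 0, hi = 1) {
  if (!is.numeric(x) || anyNA(x) || any(x < lo) || any(x > hi))
    stop(sprintf("parameter '%s' must be in [%g, %g]", nm, lo, hi),
         call. = FALSE)
  invisible(x)
}

validate_params <- function(p) {
  if (!inherits(p, "sdgd_params")) stop("not an 'sdgd_params' object")
  bad <- character()
  chk <- function(expr, msg) if (!isTRUE(expr)) bad <<- c(bad, msg)
  for (nm in c("d_f", "d_m", "u_f", "u_m", "s_X_f", "s_X_m", "h_X_f"))
    chk(is.numeric(p[[nm]]) && length(p[[nm]]) == 1 &&
          !is.na(p[[nm]]) && p[[nm]] >= 0 && p[[nm]] <= 1,
        sprintf("%s must be a single value in [0, 1]", nm))
  for (nm in c("m1", "m2"))
    chk(is.numeric(p[[nm]]) && length(p[[nm]]) == 1 &&
          !is.na(p[[nm]]) && p[[nm]] >= 0.5 && p[[nm]] <= 1,
        sprintf("%s must be in [0.5, 1] (X-shredding cannot bias toward females)", nm))
  for (nm in c("female_fitness", "male_fitness"))
    chk(is.numeric(p[[nm]]) && length(p[[nm]]) == 6 && !anyNA(p[[nm]]) &&
          all(p[[nm]] >= 0) && all(p[[nm]] <= 1) &&
          identical(names(p[[nm]]), TARGET_CLASSES),
        sprintf("%s must be named over %s with values in [0, 1]",
                nm, paste(TARGET_CLASSES, collapse = ", ")))
  chk(is.numeric(p$R_m) && length(p$R_m) == 1 && p$R_m > 1,
      "R_m must be > 1")
  cg <- p$cage
  chk(is.numeric(cg$larva_cap) && cg$larva_cap >= 1,
      "cage$larva_cap must be >= 1")
  chk(is.numeric(cg$mean_eggs) && cg$mean_eggs >= 0,
      "cage$mean_eggs must be >= 0")
  chk(is.numeric(cg$hatch_wt) && cg$hatch_wt >= 0 && cg$hatch_wt <= 1,
      "cage$hatch_wt must be in [0, 1]")
  chk(is.numeric(cg$p_mate) && cg$p_mate >= 0 && cg$p_mate <= 1,
      "cage$p_mate must be in [0, 1]")
  chk(is.numeric(cg$egg_dispersion) && cg$egg_dispersion > 0,
      "cage$egg_dispersion must be > 0 (Inf for Poisson)")
  if (length(bad))
    stop("invalid parameter set:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  invisible(p)
}

#' @export
print.sdgd_params <- function(x, ...) {
  cat("Sex-distorter gene drive parameter set\n")
  cat(sprintf("  transmission d_f = %.4g, d_m = %.4g (resistance u_f = %.3g, u_m = %.3g)\n",
              x$d_f, x$d_m, x$u_f, x$u_m))
  cat(sprintf("  sex distortion m1 = %.3g (het males), m2 = %.3g (D/D males)\n",
              x$m1, x$m2))
  cat("  female fitness:", paste(sprintf("%s=%.3g", TARGET_CLASSES,
                                         x$female_fitness), collapse = " "), "\n")
  cat("  male fitness:  ", paste(sprintf("%s=%.3g", TARGET_CLASSES,
                                         x$male_fitness), collapse = " "), "\n")
  cat(sprintf("  damaged-X costs s_X_f = %.3g (h_X_f = %.3g), s_X_m = %.3g\n",
              x$s_X_f, x$h_X_f, x$s_X_m))
  cat(sprintf("  R_m = %.3g; cage: cap %d larvae, %.4g eggs/female, hatch %.3g\n",
              x$R_m, as.integer(x$cage$larva_cap), x$cage$mean_eggs,
              x$cage$hatch_wt))
  invisible(x)
}

#' Load a parameter file
#'
#' Reads a flat YAML (or JSON) parameter file into an [sdgd_params()] object.
#' Recognised keys are the arguments of [sdgd_params()]; the shorthand key
#' `m` sets `m1 = m2 = m`, and fitness maps may be given partially (missing
#' classes keep their defaults). Unknown keys raise an itemised error. Each
#' parameter's provenance ("user" if set by the file, "default" otherwise) is
#' recorded in the `"provenance"` attribute.
#'
#' A parameter file with the bundled doublesex-SDGD estimates ships with the
#' package: `system.file("extdata", "sdgd_dsx.yaml", package = "sdgdrive")`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file. An empty file yields
#'   an all-defaults parameter set.
#' @return An `sdgd_params` object with a `"provenance"` attribute.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a key-value mapping")
  params_from_list(raw)
}

# build sdgd_params from a plain named list, tracking provenance
params_from_list <- function(raw) {
  known <- c(names(formals(sdgd_params)), "m")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         "\nrecognised keys: ", paste(known, collapse = ", "), call. = FALSE)
  if (!is.null(raw$m)) {
    if (!is.null(raw$m1) || !is.null(raw$m2))
      stop("give either 'm' or 'm1'/'m2', not both")
    raw$m1 <- raw$m2 <- raw$m
    raw$m <- NULL
  }
  args <- list()
  prov <- list()
  defaults <- formals(sdgd_params)
  for (nm in setdiff(known, "m")) {
    if (nm %in% c("female_fitness", "male_fitness")) {
      base <- eval(defaults[[nm]])
      if (!is.null(raw[[nm]])) {
        ov <- unlist(raw[[nm]])
        bad <- setdiff(names(ov), TARGET_CLASSES)
        if (length(bad))
          stop("unknown target class in ", nm, ": ",
               paste(bad, collapse = ", "), call. = FALSE)
        base[names(ov)] <- ov
        prov[[nm]] <- "user"
      } else prov[[nm]] <- "default"
      args[[nm]] <- base
    } else if (nm == "cage") {
      base <- cage_defaults()
      if (!is.null(raw$cage)) {
        bad <- setdiff(names(raw$cage), names(base))
        if (length(bad))
          stop("unknown cage key(s): ", paste(bad, collapse = ", "),
               call. = FALSE)
        base <- utils::modifyList(base, raw$cage)
        prov[[nm]] <- "user"
      } else prov[[nm]] <- "default"
      args[[nm]] <- base
    } else if (!is.null(raw[[nm]])) {
      args[[nm]] <- raw[[nm]]
      prov[[nm]] <- "user"
    } else {
      prov[[nm]] <- "default"
    }
  }
  p <- do.call(sdgd_params, args)
  attr(p, "provenance") <- unlist(prov)
  p
}
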