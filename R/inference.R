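#' Validate a phenotypic assay table
#'
#' An assay table holds one row per parent from heterozygote x wild-type
#' crosses, with columns `eggs`, `larvae`, `transgenic` (marker-positive
#' larvae), `males`, `females` (sexed progeny), and optionally `parent_sex`,
#' `parent_genotype`, `parent_id` and a logical `excluded` flag (parents
#' with no progeny and no evidence of mating, excluded from estimation).
#' `NA` is allowed in count columns that were not recorded.
#'
#' @param records A data.frame.
#' @return The validated data.frame (with `excluded` rows dropped),
#'   invisibly usable downstream.
#' @export
validate_assay_records <- function(records) {
  records <- as.data.frame(records)
  need <- c("eggs", "larvae")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("assay table lacks column(s): ", paste(miss, collapse = ", "))
  for (col in c("transgenic", "males", "females"))
    if (!col %in% names(records)) records[[col]] <- NA_integer_
  if ("excluded" %in% names(records))
    records <- records[!isTRUE_vec(records$excluded), , drop = FALSE]
  with(records, {
    if (any(larvae > eggs, na.rm = TRUE))
      stop("invalid assay records: larvae > eggs")
    if (any(transgenic > larvae, na.rm = TRUE))
      stop("invalid assay records: transgenic > larvae")
    if (any(males + females > larvae, na.rm = TRUE))
      stop("invalid assay records: males + females > larvae")
    if (any(records[need] < 0, na.rm = TRUE))
      stop("invalid assay records: negative counts")
  })
  records
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Pooled transgene transmission fraction
#'
#' Count-weighted (pooled) fraction of marker-positive larvae across
#' parents, with a 95% Wilson interval and the per-parent distribution as
#' a secondary summary. Transmission T relates to the homing-rate reporting
#' convention by d = 2T - 1 ([homing_rate_from_transmission()]) and, in the
#' model's convention, equals the drive-allele gamete fraction `d_f`/`d_m`
#' directly.
#'
#' @param records An assay table (see [validate_assay_records()]).
#' @return List with `transmission`, `ci`, `n_larvae`, `n_transgenic`,
#'   `per_parent` (mean and sd of per-parent fractions).
#' @export
estimate_transmission <- function(records) {
  records <- validate_assay_records(records)
  ok <- !is.na(records$transgenic) & !is.na(records$larvae) &
    records$larvae > 0
  if (!any(ok)) stop("no records with screened larvae")
  x <- sum(records$transgenic[ok])
  n <- sum(records$larvae[ok])
  per <- records$transgenic[ok] / records$larvae[ok]
  list(transmission = x / n, ci = wilson_interval(x, n),
       n_larvae = n, n_transgenic = x,
       per_parent = c(mean = mean(per), sd = stats::sd(per),
                      n_parents = sum(ok)))
}

#' Convert a transmission fraction to a homing rate
#'
#' The homing rate is reported as the fraction of transgenic progeny above
#' Mendelian inheritance: d = 2T - 1, so a transmission of 0.96 corresponds
#' to a 92% homing rate. Transmission below 0.5 carries no super-Mendelian
#' signal and maps to 0 with a warning.
#'
#' @param transmission Transmission fraction T in `[0, 1]`.
#' @return Homing rate in `[0, 1]`.
#' @export
homing_rate_from_transmission <- function(transmission) {
  stopifnot(is.numeric(transmission), all(transmission <= 1),
            all(transmission >= 0))
  out <- 2 * transmission - 1
  if (any(transmission < 0.5)) {
    warning("transmission below 0.5: no super-Mendelian signal, homing rate set to 0")
    out[transmission < 0.5] <- 0
  }
  out
}

#' Inverse of [homing_rate_from_transmission()]
#'
#' @param homing_rate Homing rate d in `[0, 1]`.
#' @return Transmission fraction T = (1 + d) / 2.
#' @export
transmission_from_homing_rate <- function(homing_rate) {
  stopifnot(is.numeric(homing_rate), all(homing_rate >= 0),
            all(homing_rate <= 1))
  (1 + homing_rate) / 2
}

#' Pooled male fraction among progeny (sex distortion)
#'
#' Count-weighted fraction of male progeny across parents with sexed
#' offspring, with a 95% Wilson interval. For progeny of SDGD fathers this
#' estimates the shredding parameter m.
#'
#' @param records An assay table with `males`/`females` counts.
#' @return List with `m`, `ci`, `n_sexed`, `n_male`, `per_parent`.
#' @export
estimate_sex_distortion <- function(records) {
  records <- validate_assay_records(records)
  sexed <- records$males + records$females
  ok <- !is.na(sexed) & sexed > 0
  if (!any(ok)) stop("no records with sexed progeny")
  x <- sum(records$males[ok])
  n <- sum(sexed[ok])
  per <- records$males[ok] / sexed[ok]
  list(m = x / n, ci = wilson_interval(x, n), n_sexed = n, n_male = x,
       per_parent = c(mean = mean(per), sd = stats::sd(per),
                      n_parents = sum(ok)))
}

#' Relative fitness from larval output
#'
#' Ratio of mean larval outputs between a case group (e.g. heterozygous
#' mothers) and a control group (wild-type crosses), with a seeded
#' percentile bootstrap CI over parents. When egg counts are present the
#' ratio is decomposed into relative egg output x relative hatch rate
#' (pooled hatch rates). Both the larval-means ratio (primary) and the
#' decomposition are reported, since a printed "fertility" may follow
#' either convention.
#'
#' @param case_records,control_records Assay tables.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap (default 1).
#' @return List with `relative_fitness` (ratio of mean larvae), `ci`,
#'   `rel_eggs`, `rel_hatch`, group means.
#' @export
estimate_relative_fitness <- function(case_records, control_records,
                                      n_boot = 2000, seed = 1) {
  case <- validate_assay_records(case_records)
  ctrl <- validate_assay_records(control_records)
  if (!nrow(case) || !nrow(ctrl)) stop("both record groups must be non-empty")
  mc <- mean(case$larvae); m0 <- mean(ctrl$larvae)
  if (m0 <= 0) stop("control group has zero mean larval output")
  ratio <- mc / m0
  boot <- local({
    set.seed(seed)
    replicate(n_boot, {
      b1 <- mean(sample(case$larvae, replace = TRUE))
      b0 <- mean(sample(ctrl$larvae, replace = TRUE))
      if (b0 > 0) b1 / b0 else NA_real_
    })
  })
  ci <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  rel_eggs <- rel_hatch <- NA_real_
  if (!anyNA(case$eggs) && !anyNA(ctrl$eggs) &&
      sum(ctrl$eggs) > 0 && sum(case$eggs) > 0) {
    rel_eggs <- mean(case$eggs) / mean(ctrl$eggs)
    h1 <- sum(case$larvae) / sum(case$eggs)
    h0 <- sum(ctrl$larvae) / sum(ctrl$eggs)
    if (h0 > 0) rel_hatch <- h1 / h0
  }
  list(relative_fitness = ratio,
       ci = c(lower = ci[1], upper = ci[2]),
       rel_eggs = rel_eggs, rel_hatch = rel_hatch,
       mean_case = mc, mean_control = m0,
       n_case = nrow(case), n_control = nrow(ctrl))
}

#' Assemble a parameter set from phenotypic assays
#'
#' Estimates the drive transmission in each sex, the sex-distortion
#' fraction m and the heterozygote fitnesses from assay tables of
#' heterozygous fathers, heterozygous mothers and wild-type control
#' crosses, and fills everything not estimable from such assays (the
#' resistant-repair fractions u, damaged-X costs, growth rate, cage
#' demography) from `defaults`. Each parameter is labelled `"estimated"` or
#' `"default"` in the `"provenance"` attribute.
#'
#' @param male_records Assays of W/D fathers x wild-type mothers.
#' @param female_records Assays of W/D mothers x wild-type fathers.
#' @param control_records Wild-type x wild-type assays.
#' @param defaults An [sdgd_params()] supplying non-estimable values.
#' @param seed Seed for bootstrap CIs.
#' @return An `sdgd_params` object with `"provenance"` and `"estimates"`
#'   attributes (the latter holds the full estimator outputs).
#' @export
params_from_assays <- function(male_records = NULL, female_records = NULL,
                               control_records = NULL,
                               defaults = sdgd_params(), seed = 1) {
  est <- list()
  prov <- c(d_f = "default", d_m = "default", m = "default",
            w_WD_female = "default", w_SDGD_male = "default",
            u_f = "default", u_m = "default",
            s_X = "default", R_m = "default")
  p <- defaults
  if (!is.null(male_records)) {
    est$transmission_m <- estimate_transmission(male_records)
    p$d_m <- est$transmission_m$transmission
    prov["d_m"] <- "estimated"
    est$sex_distortion <- estimate_sex_distortion(male_records)
    p$m1 <- p$m2 <- max(0.5, est$sex_distortion$m)
    prov["m"] <- "estimated"
  }
  if (!is.null(female_records)) {
    est$transmission_f <- estimate_transmission(female_records)
    p$d_f <- est$transmission_f$transmission
    prov["d_f"] <- "estimated"
  }
  if (!is.null(control_records)) {
    if (!is.null(female_records)) {
      est$fitness_f <- estimate_relative_fitness(female_records,
                                                 control_records, seed = seed)
      p$female_fitness["WD"] <- min(1, est$fitness_f$relative_fitness)
      prov["w_WD_female"] <- "estimated"
    }
    if (!is.null(male_records)) {
      est$fitness_m <- estimate_relative_fitness(male_records,
                                                 control_records, seed = seed)
      wsd <- min(1, est$fitness_m$relative_fitness)
      p$male_fitness[c("WD", "DD", "DR")] <- wsd
      prov["w_SDGD_male"] <- "estimated"
    }
  }
  missing_groups <- c(males = is.null(male_records),
                      females = is.null(female_records),
                      controls = is.null(control_records))
  if (any(missing_groups))
    message("assay group(s) missing (",
            paste(names(missing_groups)[missing_groups], collapse = ", "),
            "): affected parameters keep their defaults")
  validate_params(p)
  attr(p, "provenance") <- prov
  attr(p, "estimates") <- est
  p
}
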