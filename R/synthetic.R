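#' Ground truth for synthetic data generation
#'
#' Couples a full [sdgd_params()] parameter set with the generative
#' nuisance parameters of the assay design: the egg-count distribution
#' (negative binomial mean and dispersion, reflecting the large spread of
#' per-female counts seen in real assays; `dispersion = Inf` gives
#' Poisson), the wild-type hatch probability and the recorded seed.
#'
#' @param params An [sdgd_params()] object.
#' @param mean_eggs Mean eggs per assayed female (default from
#'   `params$cage`).
#' @param egg_dispersion Negative-binomial size (default 8, matching a
#'   coefficient of variation near the observed per-female spread).
#' @param hatch Wild-type hatch probability (default from `params$cage`).
#' @return List of class `sdgd_truth`.
#' @export
sdgd_truth <- function(params = sdgd_params(),
                       mean_eggs = params$cage$mean_eggs,
                       egg_dispersion = 8,
                       hatch = params$cage$hatch_wt) {
  validate_params(params)
  stopifnot(mean_eggs >= 0, egg_dispersion > 0, hatch >= 0, hatch <= 1)
  structure(list(params = params, mean_eggs = mean_eggs,
                 egg_dispersion = egg_dispersion, hatch = hatch),
            class = "sdgd_truth")
}

#' Generate a synthetic phenotypic assay table
#'
#' Emulates single-parent crosses of heterozygous (W/D) or wild-type
#' parents to wild-type mates: per parent, eggs are negative binomial,
#' larvae binomial in the hatch probability (scaled by the parent's
#' relative fitness), marker-positive larvae binomial in the parent's drive
#' transmission, and male progeny binomial in the sex-distortion fraction
#' (m for SDGD fathers, 1/2 otherwise; all larvae are sexed).
#'
#' @param truth An [sdgd_truth()] object.
#' @param n_parents Number of assayed parents (>= 0).
#' @param parent `"male"` or `"female"`: sex of the heterozygous parent.
#' @param genotype Target-class of the assayed parent, `"WD"` (default) or
#'   `"WW"` for control crosses.
#' @param seed Optional integer seed.
#' @return A data.frame assay table (see [validate_assay_records()]) with
#'   columns `parent_id`, `parent_sex`, `parent_genotype`, `eggs`,
#'   `larvae`, `transgenic`, `males`, `females`.
#' @export
generate_assay_data <- function(truth, n_parents, parent = c("male", "female"),
                                genotype = c("WD", "WW"), seed = NULL) {
  stopifnot(inherits(truth, "sdgd_truth"), n_parents >= 0)
  parent <- match.arg(parent)
  genotype <- match.arg(genotype)
  if (!is.null(seed)) set.seed(seed)
  empty <- data.frame(parent_id = integer(), parent_sex = character(),
                      parent_genotype = character(), eggs = integer(),
                      larvae = integer(), transgenic = integer(),
                      males = integer(), females = integer())
  if (n_parents == 0) return(empty)
  p <- truth$params
  # transmission = drive gamete share of the heterozygous parent
  transmission <- if (genotype == "WD") {
    if (parent == "male") p$d_m else p$d_f
  } else 0
  # X-shredding biases all progeny of an SDGD father, transgenic or not
  male_frac <- if (genotype == "WD" && parent == "male") p$m1 else 0.5
  # the mother's side limits egg output: heterozygous mothers lay at their
  # relative fitness; heterozygous fathers scale the (wild-type) mother's
  # output by the male relative fertility
  rel <- if (genotype == "WW") 1
  else if (parent == "female") p$female_fitness["WD"]
  else p$male_fitness["WD"]
  mu <- truth$mean_eggs * unname(rel)
  eggs <- if (is.finite(truth$egg_dispersion)) {
    stats::rnbinom(n_parents, size = truth$egg_dispersion, mu = mu)
  } else stats::rpois(n_parents, mu)
  larvae <- stats::rbinom(n_parents, eggs, truth$hatch)
  transgenic <- stats::rbinom(n_parents, larvae, transmission)
  males <- stats::rbinom(n_parents, larvae, male_frac)
  data.frame(parent_id = seq_len(n_parents),
             parent_sex = parent,
             parent_genotype = genotype,
             eggs = eggs, larvae = larvae, transgenic = transgenic,
             males = males, females = larvae - males)
}

#' Generate a synthetic cage-trial observation table
#'
#' Runs the stochastic cage model under the ground-truth parameters and
#' returns only the observables a laboratory would record per generation
#' (generation, transgenic fraction, male fraction, eggs, relative egg
#' output) — not the underlying genotype counts. The truth is carried in
#' the `"truth"` attribute so callers can store it separately from the
#' observation file.
#'
#' @param truth An [sdgd_truth()] object.
#' @param release_spec See [init_cage()].
#' @param horizon Maximum generations (default 30).
#' @param seed Optional integer seed.
#' @return A data.frame of observables with attributes `truth`, `collapsed`
#'   and `collapse_generation`.
#' @export
generate_cage_observations <- function(truth, release_spec = "10%",
                                       horizon = 30, seed = NULL) {
  stopifnot(inherits(truth, "sdgd_truth"))
  traj <- simulate_cage(truth$params, release_spec, horizon, seed = seed)
  obs <- traj$summary[, c("generation", "transgenic_frac", "male_frac",
                          "eggs", "rel_egg_output")]
  attr(obs, "truth") <- truth
  attr(obs, "collapsed") <- traj$collapsed
  attr(obs, "collapse_generation") <- traj$collapse_generation
  obs
}
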