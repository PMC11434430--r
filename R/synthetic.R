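## Synthetic RP-TLC plates and descriptor tables with the statistical
## structure the analysis assumes: a linear R_M-vs-modifier law with
## Gaussian noise on the R_M scale, and descriptor tables driven by one
## dominant latent lipophilicity factor plus an independent discrete
## column. Everything is seeded and reproducible.

## evaluate expr under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  force(expr)
}

#' Specification of a simulated TLC plate
#'
#' Describes the data-generating process for one compound's plates:
#' \eqn{R_M = R_{M0} + bC + \varepsilon}, \eqn{\varepsilon \sim N(0,
#' \sigma^2)}, converted to retardation factors via
#' \eqn{R_F = 1/(1 + 10^{R_M})}. Noise lives on the R_M scale, where the
#' retention model is linear and homoscedastic.
#'
#' The default modifier grid (65 to 90% v/v in 5% steps) and replicate
#' count (3 spots per concentration, averaged downstream) mirror routine
#' RP-TLC practice for lipophilic solutes.
#'
#' @param compound_id label for the simulated compound.
#' @param true_rm0 true intercept (R_M at 0% modifier).
#' @param true_b true slope per % v/v (typically negative).
#' @param modifier_pcts modifier concentrations (>= 3 values).
#' @param noise_sd Gaussian sigma on the R_M scale (>= 0).
#' @param n_replicates spots per concentration (default 3).
#' @param seed RNG seed for [simulate_plate()]; `NULL` uses the current
#'   stream.
#' @return an object of class `"plate_sim_spec"`.
#' @export
plate_sim_spec <- function(compound_id, true_rm0, true_b,
                           modifier_pcts = seq(65, 90, by = 5),
                           noise_sd = 0, n_replicates = 3L, seed = NULL) {
  stopifnot(is.character(compound_id), length(compound_id) == 1L,
            is.finite(true_rm0), is.finite(true_b),
            is.numeric(modifier_pcts), length(modifier_pcts) >= 3L,
            is.numeric(noise_sd), noise_sd >= 0, n_replicates >= 1L)
  structure(list(compound_id = compound_id, true_rm0 = true_rm0,
                 true_b = true_b, modifier_pcts = sort(modifier_pcts),
                 noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
                 seed = seed),
            class = "plate_sim_spec")
}

#' Simulate retardation-factor measurements for one compound
#'
#' @param spec a `"plate_sim_spec"`.
#' @return measurements data frame (`compound`, `acetone_pct`, `rf`), one
#'   row per spot, deterministic for a fixed seed.
#' @examples
#' spec <- plate_sim_spec("X", 6.05, -0.07, noise_sd = 0.05, seed = 1)
#' head(simulate_plate(spec))
#' @export
simulate_plate <- function(spec) {
  if (!inherits(spec, "plate_sim_spec")) {
    stop("'spec' must be a plate_sim_spec", call. = FALSE)
  }
  cc <- rep(spec$modifier_pcts, each = spec$n_replicates)
  with_seed(spec$seed, {
    rm_true <- spec$true_rm0 + spec$true_b * cc
    rm_obs <- rm_true + stats::rnorm(length(cc), 0, spec$noise_sd)
    rf <- rm_to_rf(rm_obs)
    bad <- rf <= 0 | rf >= 1 | !is.finite(rf)
    if (any(bad)) {
      stop(sprintf("simulated rf outside (0, 1) at C = %s",
                   paste(unique(cc[bad]), collapse = ", ")), call. = FALSE)
    }
    data.frame(compound = spec$compound_id, acetone_pct = cc, rf = rf,
               stringsAsFactors = FALSE)
  })
}

#' Specification of a simulated descriptor table
#'
#' Continuous descriptors are generated as
#' `loading * latent + intercept + N(0, noise_sd)` from a single standard
#' normal latent lipophilicity factor per compound, reproducing the
#' near-collinear block structure typical of logP calculator panels
#' (pairwise correlations mostly above 0.9). An optional discrete column,
#' drawn independently of the latent factor, emulates a weakly correlated
#' count descriptor such as the number of hydrogen-bond donors.
#'
#' @param n_compounds number of compounds (>= 3).
#' @param loadings named numeric vector: loading of each continuous
#'   descriptor on the latent factor.
#' @param noise_sd per-descriptor Gaussian sigma; scalar recycled.
#' @param intercepts per-descriptor intercepts; scalar recycled (default 0).
#' @param discrete optional `list(name =, values =)`: a column sampled
#'   uniformly (with replacement) from `values`, independent of the latent
#'   factor; `NULL` to omit.
#' @param seed RNG seed for [simulate_descriptor_table()].
#' @return an object of class `"descriptor_sim_spec"`.
#' @export
descriptor_sim_spec <- function(n_compounds, loadings, noise_sd,
                                intercepts = 0,
                                discrete = list(name = "nHBD",
                                                values = 1:2),
                                seed = NULL) {
  stopifnot(n_compounds >= 3L, is.numeric(loadings),
            length(loadings) >= 1L, !is.null(names(loadings)),
            all(is.finite(loadings)), all(noise_sd >= 0))
  noise_sd <- rep_len(noise_sd, length(loadings))
  intercepts <- rep_len(intercepts, length(loadings))
  structure(list(n_compounds = as.integer(n_compounds), loadings = loadings,
                 noise_sd = noise_sd, intercepts = intercepts,
                 discrete = discrete, seed = seed),
            class = "descriptor_sim_spec")
}

#' Simulate a descriptor table from a latent-factor specification
#'
#' @param spec a `"descriptor_sim_spec"`.
#' @return a descriptor table (numeric matrix, compounds `cmp1`, `cmp2`,
#'   ... as row names), deterministic for a fixed seed.
#' @export
simulate_descriptor_table <- function(spec) {
  if (!inherits(spec, "descriptor_sim_spec")) {
    stop("'spec' must be a descriptor_sim_spec", call. = FALSE)
  }
  with_seed(spec$seed, {
    n <- spec$n_compounds
    latent <- stats::rnorm(n)
    cols <- mapply(function(l, s, a) l * latent + a + stats::rnorm(n, 0, s),
                   spec$loadings, spec$noise_sd, spec$intercepts)
    tab <- matrix(cols, nrow = n,
                  dimnames = list(paste0("cmp", seq_len(n)),
                                  names(spec$loadings)))
    if (!is.null(spec$discrete)) {
      disc <- sample(spec$discrete$values, n, replace = TRUE)
      tab <- cbind(tab, matrix(as.numeric(disc), ncol = 1,
                               dimnames = list(NULL, spec$discrete$name)))
    }
    tab
  })
}

#' Monte-Carlo parameter recovery for the lipophilicity pipeline
#'
#' Repeatedly simulates plates from `plate_spec`, runs the retention fit
#' and (if standards or a curve are supplied) the logP_TLC prediction, and
#' summarizes bias and root-mean-square error of the recovered R_M0 and
#' logP_TLC against their generating truths. Replicate r uses seed
#' `plate_spec$seed + r`, so experiments are reproducible and extensible.
#'
#' @param plate_spec a `"plate_sim_spec"` with a non-`NULL` seed.
#' @param n_reps number of replicates (>= 2).
#' @param standards standards data frame or `"calibration_curve"`; `NULL`
#'   to assess R_M0 recovery only.
#' @return list with `n_reps`, `n_low_r` (replicates whose fit fell below
#'   the retention-quality floor), `rm0` (`truth`, `bias`, `rmse`,
#'   `se_bias`) and, when a curve is available, `logp_tlc` (same fields).
#' @export
recovery_experiment <- function(plate_spec, n_reps, standards = NULL) {
  if (!inherits(plate_spec, "plate_sim_spec")) {
    stop("'plate_spec' must be a plate_sim_spec", call. = FALSE)
  }
  if (n_reps < 2L) stop("need n_reps >= 2", call. = FALSE)
  if (is.null(plate_spec$seed)) {
    stop("plate_spec needs a seed for a reproducible experiment",
         call. = FALSE)
  }
  curve <- if (is.null(standards)) NULL
           else if (inherits(standards, "calibration_curve")) standards
           else fit_calibration(standards)
  n_low_r <- 0L
  rm0_hat <- vapply(seq_len(n_reps), function(r) {
    spec_r <- plate_spec
    spec_r$seed <- plate_spec$seed + r
    ## fit-quality warnings are tallied, not re-emitted per replicate
    withCallingHandlers(fit_retention(simulate_plate(spec_r))$rm0,
                        warning = function(w) {
                          n_low_r <<- n_low_r + 1L
                          invokeRestart("muffleWarning")
                        })
  }, numeric(1))
  summarize <- function(est, truth) {
    err <- est - truth
    list(truth = truth, bias = mean(err), rmse = sqrt(mean(err^2)),
         se_bias = stats::sd(err) / sqrt(length(err)))
  }
  out <- list(n_reps = as.integer(n_reps), n_low_r = n_low_r,
              rm0 = summarize(rm0_hat, plate_spec$true_rm0))
  if (!is.null(curve)) {
    out$logp_tlc <- summarize(predict_logp(curve, rm0_hat),
                              predict_logp(curve, plate_spec$true_rm0))
  }
  out
}
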