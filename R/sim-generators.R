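# Generators for every pipeline input, each with recoverable ground truth
# and a deterministic seed-derived RNG sub-stream.

sim_times <- function(config) {
  seq(0, config$t_end, length.out = config$n_timepoints)
}

#' Simulate fermentation temperature and pH series
#'
#' Generates, per replicate, four kinetic series (temperature at the top
#' and mid-box depths; pH of the testa/pulp and of the cotyledon) from the
#' five-parameter generalized logistic with additive Gaussian measurement
#' noise. True per-replicate curve parameters (the configured parameters
#' with a small between-replicate jitter) are recorded as ground truth.
#'
#' @param config A [sim_config()].
#' @return Long tibble with columns `replicate`, `variable`,
#'   `compartment`, `time`, `value`; the per-series true parameters are
#'   attached as the `"truth"` attribute (a tibble).
#' @examples
#' sim <- simulate_kinetics(sim_config(seed = 1, noise_sd = c(
#'   temperature = 0, ph = 0)))
#' head(sim)
#' @export
simulate_kinetics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  times <- sim_times(config)
  kp <- config$kinetic_params
  out <- list()
  truth <- list()
  for (rep_i in seq_len(config$n_replicates)) {
    with_seed(derive_seed(config$seed, "kinetics", rep_i), {
      for (s in seq_len(nrow(kp))) {
        p <- kp[s, ]
        jit <- config$replicate_jitter_sd
        span <- abs(p$yf - p$y0)
        y0 <- p$y0 + rnorm(1, 0, jit * span)
        yf <- p$yf + rnorm(1, 0, jit * span)
        ti <- p$ti + rnorm(1, 0, jit * config$t_end)
        curve <- richards(times, y0, yf, p$k, ti, p$nu)
        sdv <- unname(config$noise_sd[p$variable])
        if (is.na(sdv)) {
          stop("no noise sd configured for variable ", p$variable,
               call. = FALSE)
        }
        value <- curve + rnorm(length(times), 0, sdv)
        out[[length(out) + 1]] <- tibble::tibble(
          replicate = rep_i, variable = p$variable,
          compartment = p$compartment, time = times, value = value
        )
        truth[[length(truth) + 1]] <- tibble::tibble(
          replicate = rep_i, variable = p$variable,
          compartment = p$compartment,
          y0 = y0, yf = yf, k = p$k, ti = ti, nu = p$nu, noise_sd = sdv
        )
      }
    })
  }
  res <- dplyr::bind_rows(out)
  attr(res, "truth") <- dplyr::bind_rows(truth)
  res
}

latent_trajectory <- function(spec_row, times) {
  A <- spec_row$amplitude
  switch(spec_row$shape,
    "rise" = A / (1 + exp(-spec_row$k1 * (times - spec_row$t1))),
    "fall" = A / (1 + exp(spec_row$k1 * (times - spec_row$t1))),
    "rise-fall" = A *
      (1 / (1 + exp(-spec_row$k1 * (times - spec_row$t1)))) *
      (1 / (1 + exp(spec_row$k2 * (times - spec_row$t2)))),
    "flat" = rep(A, length(times)),
    stop("unknown shape: ", spec_row$shape, call. = FALSE)
  )
}

#' Simulate taxon relative-abundance trajectories
#'
#' Builds latent taxon density curves from the configured shapes (rising
#' logistic, falling logistic, their product for rise-fall succession
#' peaks, or flat), adds truncated Gaussian noise, and closes each time
#' point to relative abundances summing to one. A synthetic per-taxon
#' PERMANOVA-style coefficient table is attached (non-flat taxa score
#' above the kingdom marker threshold, flat taxa below), so marker
#' selection has ground truth.
#'
#' @param config A [sim_config()].
#' @return Long tibble with columns `taxon`, `kingdom`, `replicate`,
#'   `time`, `abundance`; attributes `"coefficients"` (tibble `taxon`,
#'   `kingdom`, `coefficient`) and `"latent"` (pre-closure densities).
#' @export
simulate_taxa <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$taxa_spec
  if (nrow(spec) == 0) stop("`taxa_spec` must be non-empty", call. = FALSE)
  if (all(spec$shape == "flat") && sum(spec$amplitude) == 0) {
    stop("all-flat taxa specification with zero total abundance",
         call. = FALSE)
  }
  times <- sim_times(config)
  out <- list()
  latent_out <- list()
  for (rep_i in seq_len(config$n_replicates)) {
    with_seed(derive_seed(config$seed, "taxa", rep_i), {
      latent <- vapply(seq_len(nrow(spec)), function(s) {
        base <- latent_trajectory(spec[s, ], times)
        noisy <- base + rnorm(length(times), 0, config$taxa_noise_sd)
        pmax(noisy, 1e-9)
      }, numeric(length(times)))
      total <- rowSums(latent)
      rel <- latent / total
      for (s in seq_len(nrow(spec))) {
        out[[length(out) + 1]] <- tibble::tibble(
          taxon = spec$taxon[s], kingdom = spec$kingdom[s],
          replicate = rep_i, time = times, abundance = rel[, s]
        )
        latent_out[[length(latent_out) + 1]] <- tibble::tibble(
          taxon = spec$taxon[s], replicate = rep_i, time = times,
          density = latent[, s]
        )
      }
    })
  }
  res <- dplyr::bind_rows(out)
  thresholds <- c(bacteria = 10, fungi = 5)
  attr(res, "coefficients") <- tibble::tibble(
    taxon = spec$taxon,
    kingdom = spec$kingdom,
    coefficient = ifelse(spec$shape == "flat",
                         pmax(thresholds[spec$kingdom] - 5, 0),
                         thresholds[spec$kingdom] + 2 + spec$amplitude)
  )
  attr(res, "latent") <- dplyr::bind_rows(latent_out)
  res
}

#' Simulate sensory panel scores from a feature matrix
#'
#' Generates 0-10 sensory attribute scores as clipped noisy linear
#' combinations of normalized features:
#' `score = clip(sum(coef * feature) + noise, 0, 10)`. The features named
#' with non-zero coefficients are the planted informative features and
#' are recorded as ground truth.
#'
#' @param features Data frame whose numeric columns are features
#'   normalized to `[0, 1]` (see [rescale01()]).
#' @param sensory_spec List of
#'   `list(attribute =, coefficients = <named numeric>, noise_sd =)`.
#' @param seed Integer seed.
#' @return Tibble of instances x attributes with attribute
#'   `"informative"`: a named list of planted feature names per attribute.
#' @export
simulate_sensory <- function(features, sensory_spec, seed = 1L) {
  x <- dplyr::select(tibble::as_tibble(features), dplyr::where(is.numeric))
  if (any(as.matrix(x) < 0 | as.matrix(x) > 1)) {
    stop("features must be normalized to [0, 1] before sensory simulation",
         call. = FALSE)
  }
  scores <- list()
  informative <- list()
  for (spec in sensory_spec) {
    coefs <- spec$coefficients
    if (is.null(names(coefs)) || !all(names(coefs) %in% names(x))) {
      stop("coefficient vector for attribute '", spec$attribute,
           "' does not match the feature columns", call. = FALSE)
    }
    lin <- as.matrix(x[, names(coefs), drop = FALSE]) %*% coefs
    noise <- with_seed(derive_seed(seed, "sensory", spec$attribute),
                       rnorm(nrow(x), 0, spec$noise_sd))
    scores[[spec$attribute]] <- pmin(pmax(drop(lin) + noise, 0), 10)
    informative[[spec$attribute]] <- names(coefs)[coefs != 0]
  }
  res <- tibble::as_tibble(scores)
  attr(res, "informative") <- informative
  res
}

#' Simulate organism metabolic networks with a planted minimal community
#'
#' Builds a pool of random reaction networks over decoy metabolites and
#' plants a cross-feeding chain distributed across exactly
#' `planted_community_size` organisms: each planted member carries one
#' indispensable link from a seed metabolite towards the planted target
#' metabolites, and no other reaction produces chain or target
#' metabolites. The planted community is therefore the unique minimum
#' community reaching the targets, which is verified by
#' [minimal_communities()] before returning.
#'
#' @param config A [sim_config()]; see its `network_spec`.
#' @param seeds Seed metabolites (default [cocoa_pulp_seeds()]).
#' @param max_retries Verification retries before giving up (default 5).
#' @return List with `networks` (network table), `seeds`, and `truth`
#'   (`planted_community`, `planted_targets`).
#' @export
simulate_networks <- function(config, seeds = cocoa_pulp_seeds(),
                              max_retries = 5) {
  stopifnot(inherits(config, "sim_config"))
  ns <- config$network_spec
  for (attempt in seq_len(max_retries)) {
    built <- with_seed(derive_seed(config$seed, "networks", attempt), {
      orgs <- sprintf("org%02d", seq_len(ns$n_organisms))
      mets <- sprintf("M%03d", seq_len(ns$n_metabolites))
      planted <- sort(sample(orgs, ns$planted_community_size))
      targets <- sprintf("target_%02d", seq_len(ns$planted_target_size))
      chain_len <- ns$planted_community_size
      chain_mets <- if (chain_len > 1) {
        sprintf("chain_%02d", seq_len(chain_len - 1))
      } else {
        character(0)
      }
      chain_nodes <- c(sample(seeds, 1), chain_mets)

      rows <- list()
      for (j in seq_len(chain_len)) {
        prods <- if (j == chain_len) targets else chain_nodes[j + 1]
        rows[[length(rows) + 1]] <- tibble::tibble(
          organism = planted[j],
          reaction = sprintf("planted_link_%02d", j),
          substrates = list(chain_nodes[j]),
          products = list(prods),
          reversible = FALSE
        )
      }
      # decoy reactions: substrates from seeds or decoy metabolites,
      # products exclusively decoys, so they can never shortcut the chain
      for (o in orgs) {
        for (r in seq_len(ns$n_reactions_per_organism)) {
          subs <- sample(c(seeds, mets), sample(1:2, 1))
          prods <- sample(mets, sample(1:2, 1))
          rows[[length(rows) + 1]] <- tibble::tibble(
            organism = o,
            reaction = sprintf("rxn_%s_%02d", o, r),
            substrates = list(unique(subs)),
            products = list(unique(prods)),
            reversible = runif(1) < 0.2
          )
        }
      }
      list(networks = dplyr::bind_rows(rows), planted = planted,
           targets = targets)
    })
    check <- tryCatch(
      minimal_communities(built$networks, seeds, targets = built$targets),
      error = function(e) NULL
    )
    ok <- !is.null(check) &&
      check$min_size == ns$planted_community_size &&
      any(vapply(check$communities, identical, logical(1), built$planted))
    if (ok) {
      return(list(
        networks = built$networks,
        seeds = seeds,
        truth = list(planted_community = built$planted,
                     planted_targets = built$targets)
      ))
    }
  }
  stop("failed to construct a verified planted network instance after ",
       max_retries, " attempts", call. = FALSE)
}
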