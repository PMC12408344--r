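# Configuration for the synthetic fermentation study. Defaults describe a
# plausible wooden-box cocoa fermentation: temperature rising sigmoidally
# from ambient (~25 degrees C) to the high-40s over a week, testa/pulp pH
# rising from ~3.5 to ~4.6 as pulp acids are consumed, cotyledon pH
# falling from ~6.5 to ~4.8 as acids diffuse in, and a microbial
# succession from early yeasts through lactic to acetic acid bacteria.

default_kinetic_params <- function() {
  tibble::tibble(
    variable = c("temperature", "temperature", "ph", "ph"),
    compartment = c("top", "mid_box", "testa_pulp", "cotyledon"),
    y0 = c(25, 25, 3.5, 6.5),
    yf = c(46, 48, 4.6, 4.8),
    k = c(0.08, 0.08, 0.06, 0.05),
    ti = c(48, 44, 72, 84),
    nu = c(1, 1, 1, 1)
  )
}

default_taxa_spec <- function() {
  tibble::tibble(
    taxon = c("Hanseniaspora", "Saccharomyces", "Lactiplantibacillus",
              "Acetobacter", "Bacillus", "Unclassified"),
    kingdom = c("fungi", "fungi", "bacteria", "bacteria", "bacteria",
                "bacteria"),
    shape = c("rise-fall", "rise-fall", "rise-fall", "rise", "rise", "flat"),
    amplitude = c(1.0, 0.8, 1.2, 1.5, 0.6, 0.2),
    k1 = c(0.15, 0.12, 0.10, 0.10, 0.08, NA),
    t1 = c(12, 24, 36, 60, 96, NA),
    k2 = c(0.12, 0.10, 0.08, NA, NA, NA),
    t2 = c(48, 72, 96, NA, NA, NA)
  )
}

#' Configuration for the synthetic fermentation study
#'
#' Bundles every knob of the synthetic-data generators with validation.
#' The defaults are the package's reference study conditions: 15 time
#' points over 168 h, additive Gaussian measurement noise on the native
#' scale (0.5 degrees C for temperature, 0.05 pH units), six replicate
#' fermentations, and a six-taxon succession.
#'
#' @param seed Integer RNG seed; every generator derives its own
#'   deterministic sub-stream from it.
#' @param n_timepoints Number of sampling times (default 15, minimum 3).
#' @param t_end Fermentation length in hours (default 168).
#' @param noise_sd Named numeric: per-variable measurement noise sd in
#'   native units.
#' @param n_replicates Number of replicate fermentations (default 6).
#' @param kinetic_params Tibble of true curve parameters per
#'   variable/compartment (columns `variable`, `compartment`, `y0`, `yf`,
#'   `k`, `ti`, `nu`).
#' @param replicate_jitter_sd Between-replicate sd applied to the true
#'   asymptotes and `ti`, as a fraction of their scale (default 0.02).
#' @param taxa_spec Tibble describing taxon trajectories (columns `taxon`,
#'   `kingdom`, `shape` in rise/fall/rise-fall/flat, `amplitude`, shape
#'   parameters `k1`, `t1`, `k2`, `t2`).
#' @param taxa_noise_sd Additive noise sd on the latent abundance curves
#'   before closure (default 0.02).
#' @param sensory_spec Optional list of
#'   `list(attribute =, coefficients = <named numeric>, noise_sd =)`
#'   entries defining how sensory scores derive from normalized features;
#'   `NULL` lets [run_flavour_analysis()] construct a default over the
#'   features it computes.
#' @param network_spec List with `n_organisms`, `n_metabolites`,
#'   `n_reactions_per_organism`, `planted_community_size`,
#'   `planted_target_size`.
#' @return A validated `sim_config` object (list).
#' @export
sim_config <- function(seed = 1L,
                       n_timepoints = 15,
                       t_end = 168,
                       noise_sd = c(temperature = 0.5, ph = 0.05),
                       n_replicates = 6,
                       kinetic_params = default_kinetic_params(),
                       replicate_jitter_sd = 0.02,
                       taxa_spec = default_taxa_spec(),
                       taxa_noise_sd = 0.02,
                       sensory_spec = NULL,
                       network_spec = list(n_organisms = 10,
                                           n_metabolites = 40,
                                           n_reactions_per_organism = 6,
                                           planted_community_size = 3,
                                           planted_target_size = 2)) {
  cfg <- list(seed = as.integer(seed), n_timepoints = n_timepoints,
              t_end = t_end, noise_sd = noise_sd,
              n_replicates = n_replicates, kinetic_params = kinetic_params,
              replicate_jitter_sd = replicate_jitter_sd,
              taxa_spec = taxa_spec, taxa_noise_sd = taxa_noise_sd,
              sensory_spec = sensory_spec, network_spec = network_spec)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_timepoints < 3) {
    stop("`n_timepoints` must be at least 3", call. = FALSE)
  }
  if (cfg$t_end <= 0) stop("`t_end` must be positive", call. = FALSE)
  if (any(cfg$noise_sd < 0) || cfg$taxa_noise_sd < 0) {
    stop("noise standard deviations must be non-negative", call. = FALSE)
  }
  if (cfg$n_replicates < 1) {
    stop("`n_replicates` must be at least 1", call. = FALSE)
  }
  ns <- cfg$network_spec
  need <- c("n_organisms", "n_metabolites", "n_reactions_per_organism",
            "planted_community_size", "planted_target_size")
  if (!all(need %in% names(ns))) {
    stop("`network_spec` needs fields: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (ns$planted_community_size > ns$n_organisms) {
    stop("`planted_community_size` cannot exceed `n_organisms`",
         call. = FALSE)
  }
  if (ns$planted_community_size < 1 || ns$planted_target_size < 1) {
    stop("planted community and target sizes must be at least 1",
         call. = FALSE)
  }
  if (!all(cfg$taxa_spec$shape %in% c("rise", "fall", "rise-fall", "flat"))) {
    stop("taxon shapes must be rise, fall, rise-fall or flat", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic fermentation study configuration\n")
  cat(sprintf("  seed %d, %d time points over %g h, %d replicates\n",
              x$seed, x$n_timepoints, x$t_end, x$n_replicates))
  cat(sprintf("  noise sd: %s\n",
              paste(names(x$noise_sd), signif(x$noise_sd, 3),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  %d taxa; network pool of %d organisms (planted community %d)\n",
              nrow(x$taxa_spec), x$network_spec$n_organisms,
              x$network_spec$planted_community_size))
  invisible(x)
}
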