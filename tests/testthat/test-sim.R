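test_that("zero-noise kinetic series equal the model curve exactly", {
  cfg <- sim_config(seed = 7, noise_sd = c(temperature = 0, ph = 0),
                    n_replicates = 2)
  sim <- simulate_kinetics(cfg)
  truth <- attr(sim, "truth")
  joined <- dplyr::inner_join(sim, truth,
                              by = c("replicate", "variable", "compartment"))
  expect_equal(
    joined$value,
    richards(joined$time, joined$y0, joined$yf, joined$k, joined$ti,
             joined$nu)
  )
})

test_that("generators are deterministic given the seed", {
  cfg <- sim_config(seed = 11, n_replicates = 2)
  expect_identical(simulate_kinetics(cfg), simulate_kinetics(cfg))
  expect_identical(simulate_taxa(cfg), simulate_taxa(cfg))
  n1 <- simulate_networks(cfg)
  n2 <- simulate_networks(cfg)
  expect_identical(n1, n2)
  # and a different seed changes the data
  cfg2 <- sim_config(seed = 12, n_replicates = 2)
  expect_false(identical(simulate_kinetics(cfg)$value,
                         simulate_kinetics(cfg2)$value))
})

test_that("residual spread matches the configured noise sd", {
  cfg <- sim_config(seed = 5, noise_sd = c(temperature = 0.5, ph = 0.05),
                    n_replicates = 100)
  sim <- simulate_kinetics(cfg)
  truth <- attr(sim, "truth")
  joined <- dplyr::inner_join(sim, truth,
                              by = c("replicate", "variable", "compartment"))
  resid <- joined$value -
    richards(joined$time, joined$y0, joined$yf, joined$k, joined$ti,
             joined$nu)
  sd_temp <- sd(resid[joined$variable == "temperature"])
  sd_ph <- sd(resid[joined$variable == "ph"])
  expect_lt(abs(sd_temp - 0.5) / 0.5, 0.1)
  expect_lt(abs(sd_ph - 0.05) / 0.05, 0.1)
})

test_that("temperature rises and the two pH compartments diverge as configured", {
  cfg <- sim_config(seed = 2, noise_sd = c(temperature = 0, ph = 0),
                    n_replicates = 1)
  sim <- simulate_kinetics(cfg)
  by_series <- split(sim, paste(sim$variable, sim$compartment))
  for (nm in names(by_series)) {
    s <- by_series[[nm]][order(by_series[[nm]]$time), ]
    if (grepl("cotyledon", nm)) {
      expect_true(all(diff(s$value) <= 0), info = nm)
    } else {
      expect_true(all(diff(s$value) >= 0), info = nm)
    }
  }
})

test_that("taxa abundances close to one at every time point", {
  cfg <- sim_config(seed = 9, n_replicates = 3)
  taxa <- simulate_taxa(cfg)
  sums <- dplyr::summarise(
    dplyr::group_by(taxa, .data$replicate, .data$time),
    s = sum(.data$abundance), .groups = "drop"
  )
  expect_true(all(abs(sums$s - 1) < 1e-12))
})

test_that("single-taxon spec yields abundance identically one", {
  cfg <- sim_config(
    seed = 1, n_replicates = 1,
    taxa_spec = tibble::tibble(taxon = "Solo", kingdom = "bacteria",
                               shape = "rise", amplitude = 1, k1 = 0.1,
                               t1 = 48, k2 = NA, t2 = NA)
  )
  taxa <- simulate_taxa(cfg)
  expect_equal(taxa$abundance, rep(1, nrow(taxa)))
})

test_that("rise-shape latent trajectory is monotone before closure", {
  cfg <- sim_config(
    seed = 1, n_replicates = 1, taxa_noise_sd = 0,
    taxa_spec = tibble::tibble(
      taxon = c("Riser", "Other"), kingdom = "bacteria",
      shape = c("rise", "flat"), amplitude = c(1, 0.5),
      k1 = c(0.1, NA), t1 = c(48, NA), k2 = NA, t2 = NA
    )
  )
  taxa <- simulate_taxa(cfg)
  latent <- attr(taxa, "latent")
  riser <- latent[latent$taxon == "Riser", ]
  riser <- riser[order(riser$time), ]
  expect_true(all(diff(riser$density) >= 0))
})

test_that("degenerate all-flat zero-abundance taxa spec is rejected", {
  cfg <- sim_config(seed = 1)
  cfg$taxa_spec <- tibble::tibble(taxon = "Ghost", kingdom = "bacteria",
                                  shape = "flat", amplitude = 0,
                                  k1 = NA, t1 = NA, k2 = NA, t2 = NA)
  expect_error(simulate_taxa(cfg), "zero total")
})

test_that("sensory scores follow the planted linear model", {
  feats <- tibble::tibble(f1 = c(0, 0.25, 0.5, 1), f2 = c(1, 0.5, 0, 0.75))
  spec <- list(list(attribute = "sweet", coefficients = c(f1 = 10),
                    noise_sd = 0))
  sn <- simulate_sensory(feats, spec, seed = 1)
  expect_equal(sn$sweet, 10 * feats$f1)
  expect_identical(attr(sn, "informative")$sweet, "f1")

  zero <- simulate_sensory(
    feats, list(list(attribute = "null", coefficients = c(f1 = 0, f2 = 0),
                     noise_sd = 0)), seed = 1)
  expect_equal(zero$null, rep(0, 4))
})

test_that("sensory noise sd matches the specification empirically", {
  feats <- tibble::tibble(f1 = rep(0.5, 1000))
  spec <- list(list(attribute = "a", coefficients = c(f1 = 10),
                    noise_sd = 0.4))
  sn <- simulate_sensory(feats, spec, seed = 3)
  # scores are 5 + noise, far from the clip bounds
  expect_lt(abs(sd(sn$a) - 0.4) / 0.4, 0.15)
})

test_that("sensory coefficients must name existing features", {
  feats <- tibble::tibble(f1 = c(0, 1, 0.5))
  spec <- list(list(attribute = "bad", coefficients = c(nope = 1),
                    noise_sd = 0))
  expect_error(simulate_sensory(feats, spec), "does not match")
  expect_error(
    simulate_sensory(tibble::tibble(f1 = c(0, 2)), spec),
    "normalized"
  )
})

test_that("planted network instances verify their own ground truth", {
  cfg <- sim_config(seed = 21, network_spec = list(
    n_organisms = 8, n_metabolites = 25, n_reactions_per_organism = 5,
    planted_community_size = 3, planted_target_size = 2
  ))
  inst <- simulate_networks(cfg)
  truth <- inst$truth
  expect_length(truth$planted_community, 3)
  scope <- metabolic_scope(inst$networks, inst$seeds,
                           organisms = truth$planted_community)
  expect_true(all(truth$planted_targets %in% scope$reachable))
  red <- minimal_communities(inst$networks, inst$seeds,
                             targets = truth$planted_targets)
  expect_equal(red$min_size, 3)
  expect_true(any(vapply(red$communities, identical, logical(1),
                         truth$planted_community)))
})

test_that("a planted community of one reaches the targets alone", {
  cfg <- sim_config(seed = 4, network_spec = list(
    n_organisms = 5, n_metabolites = 20, n_reactions_per_organism = 4,
    planted_community_size = 1, planted_target_size = 1
  ))
  inst <- simulate_networks(cfg)
  solo <- inst$truth$planted_community
  scope <- metabolic_scope(inst$networks, inst$seeds, organisms = solo)
  expect_true(all(inst$truth$planted_targets %in% scope$reachable))
})

test_that("invalid configurations are rejected with clear messages", {
  expect_error(sim_config(n_timepoints = 2), "n_timepoints")
  expect_error(sim_config(noise_sd = c(temperature = -1, ph = 0)),
               "non-negative")
  expect_error(sim_config(network_spec = list(
    n_organisms = 2, n_metabolites = 10, n_reactions_per_organism = 2,
    planted_community_size = 5, planted_target_size = 1
  )), "planted_community_size")
})
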