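chain_net <- function() {
  tibble::tibble(
    organism = c("org1", "org2"),
    reaction = c("r1", "r2"),
    substrates = list("A", "B"),
    products = list("B", "C"),
    reversible = c(FALSE, FALSE)
  )
}

test_that("scope of an empty network is the seed set", {
  empty <- chain_net()[0, ]
  s <- metabolic_scope(empty, c("A", "X"))
  expect_setequal(s$reachable, c("A", "X"))
  expect_length(s$produced, 0)
})

test_that("chain closure and cross-feeding work as expected", {
  net <- chain_net()
  comm <- metabolic_scope(net, "A")
  expect_setequal(comm$reachable, c("A", "B", "C"))
  expect_setequal(comm$produced, c("B", "C"))

  ind <- individual_scopes(net, "A")
  expect_setequal(ind$reachable[[which(ind$organism == "org1")]], c("A", "B"))
  expect_setequal(ind$reachable[[which(ind$organism == "org2")]], "A")
  expect_setequal(added_value(net, "A"), "C")

  # a single-member community equals that member's individual scope
  solo <- metabolic_scope(net, "A", organisms = "org1")
  expect_identical(solo$reachable,
                   ind$reachable[[which(ind$organism == "org1")]])

  # single organism has no cooperation gain
  expect_length(added_value(net[1, ], "A"), 0)
})

test_that("reversible reactions fire in both directions", {
  net <- tibble::tibble(
    organism = "o", reaction = "r",
    substrates = list("X"), products = list("Y"), reversible = TRUE
  )
  expect_setequal(metabolic_scope(net, "Y")$reachable, c("X", "Y"))
  net$reversible <- FALSE
  expect_setequal(metabolic_scope(net, "Y")$reachable, "Y")
})

test_that("scopes equal the naive fixpoint oracle on random networks", {
  set.seed(55)
  for (i in 1:100) {
    net <- random_network(n_orgs = sample(2:4, 1),
                          n_mets = sample(10:30, 1),
                          n_rxns = sample(5:20, 1))
    seeds <- sample(unique(unlist(net$substrates)),
                    min(3, length(unique(unlist(net$substrates)))))
    got <- metabolic_scope(net, seeds)$reachable
    expect_setequal(got, oracle_scope(net, seeds))
    # per-organism agreement
    for (o in unique(net$organism)) {
      sub <- net[net$organism == o, , drop = FALSE]
      expect_setequal(metabolic_scope(net, seeds, organisms = o)$reachable,
                      oracle_scope(sub, seeds))
    }
  }
})

test_that("scope invariants: monotone, order-independent, idempotent, superset", {
  set.seed(77)
  for (i in 1:60) {
    net <- random_network(n_orgs = 3, n_mets = 18, n_rxns = 14)
    seeds <- sample(unique(unlist(net$substrates)), 2)
    comm <- metabolic_scope(net, seeds)

    # order independence
    shuf <- net[sample(nrow(net)), ]
    expect_identical(metabolic_scope(shuf, seeds)$reachable, comm$reachable)

    # idempotence: expanding from the scope adds nothing
    again <- metabolic_scope(net, comm$reachable)
    expect_identical(again$reachable, comm$reachable)

    # monotonicity in seeds and reactions
    extra_seed <- metabolic_scope(net, union(seeds, "brand_new_seed"))
    expect_true(all(comm$reachable %in% extra_seed$reachable))
    sub <- net[-1, , drop = FALSE]
    smaller <- metabolic_scope(sub, seeds)
    expect_true(all(smaller$reachable %in% comm$reachable))

    # community scope contains every individual scope
    ind <- individual_scopes(net, seeds)
    expect_true(all(unlist(ind$reachable) %in% comm$reachable))

    # cooperation decomposition is exact and disjoint
    av <- added_value(net, seeds)
    indiv_union <- sort(unique(unlist(ind$reachable)))
    expect_length(intersect(av, indiv_union), 0)
    expect_setequal(c(indiv_union, av), comm$reachable)
  }
})

test_that("minimal communities on the chain instance", {
  red <- minimal_communities(chain_net(), "A", targets = "C")
  expect_equal(red$min_size, 2)
  expect_equal(red$communities, list(c("org1", "org2")))
  expect_setequal(red$essential_species, c("org1", "org2"))
  expect_length(red$alternative_species, 0)
})

test_that("targets inside the seeds give the empty community", {
  red <- minimal_communities(chain_net(), c("A", "C"), targets = "C")
  expect_equal(red$min_size, 0)
  expect_equal(red$communities, list(character(0)))
})

test_that("infeasible targets fail loudly, listing the unreachable ones", {
  expect_error(minimal_communities(chain_net(), "A", targets = c("C", "Z")),
               "unreachable.*Z")
})

test_that("enumerated solutions equal the exhaustive powerset oracle", {
  set.seed(91)
  for (i in 1:15) {
    net <- random_network(n_orgs = sample(4:6, 1), n_mets = 15, n_rxns = 18)
    seeds <- sample(unique(unlist(net$substrates)), 2)
    comm <- metabolic_scope(net, seeds)
    if (length(comm$produced) == 0) next
    targets <- sample(comm$produced, min(3, length(comm$produced)))
    red <- minimal_communities(net, seeds, targets = targets)
    want <- oracle_minimal_communities(net, seeds, targets)
    expect_setequal(lapply(red$communities, paste, collapse = "+"),
                    lapply(want, paste, collapse = "+"))
    # every solution is minimal: removing any member breaks coverage
    for (sol in red$communities) {
      for (o in sol) {
        rest <- setdiff(sol, o)
        sub <- net[net$organism %in% rest, , drop = FALSE]
        reach <- if (nrow(sub) == 0) seeds else
          metabolic_scope(sub, seeds)$reachable
        expect_false(all(targets %in% reach))
      }
    }
  }
})

test_that("greedy fallback on a large pool returns a covering community", {
  set.seed(13)
  net <- random_network(n_orgs = 25, n_mets = 40, n_rxns = 120)
  seeds <- sample(unique(unlist(net$substrates)), 3)
  comm <- metabolic_scope(net, seeds)
  expect_gt(length(comm$produced), 0)
  red <- minimal_communities(net, seeds, targets = comm$produced,
                             max_exhaustive = 10, n_restarts = 20, seed = 2)
  expect_false(red$exhaustive)
  got <- metabolic_scope(net, seeds, organisms = red$communities[[1]])
  expect_true(all(red$targets %in% got$reachable))
})

test_that("coverage statistics match direct set arithmetic", {
  expect_equal(coverage_stats(c("a", "b"), c("a", "b"))$pct_shared_of_union,
               100)
  expect_equal(coverage_stats(c("a"), c("b"))$pct_shared_of_union, 0)
  expect_warning(res <- coverage_stats(character(0), character(0)),
                 "empty")
  expect_equal(res$pct_shared_of_union, 0)

  set.seed(3)
  for (i in 1:50) {
    a <- sample(letters, sample(0:15, 1))
    b <- sample(letters, sample(1:15, 1))
    cs <- coverage_stats(a, b)
    expect_equal(cs$n_shared, length(intersect(a, b)))
    expect_equal(cs$n_reference_only, length(setdiff(a, b)))
    expect_equal(cs$n_candidate_only, length(setdiff(b, a)))
    expect_equal(cs$pct_shared_of_union,
                 100 * length(intersect(a, b)) / length(union(a, b)))
    if (length(a) > 0) {
      expect_equal(cs$pct_shared_of_reference,
                   100 * length(intersect(a, b)) / length(a))
    }
  }
})

test_that("network JSON round-trips and seed files parse", {
  net <- chain_net()
  path <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, path)
  back <- read_network_json(path)
  expect_equal(back$organism, net$organism)
  expect_equal(back$substrates, net$substrates)
  expect_equal(back$reversible, net$reversible)

  seedfile <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# pulp components", "glucose", "", "fructose"), seedfile)
  expect_equal(read_seeds(seedfile), c("glucose", "fructose"))
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_error(read_seeds(empty), "empty")
})

test_that("malformed network tables are rejected", {
  bad <- chain_net()
  bad$substrates[[1]] <- character(0)
  expect_error(metabolic_scope(bad, "A"), "at least one substrate")
  dup <- chain_net()
  dup$organism <- "org1"
  dup$reaction <- "r1"
  expect_error(metabolic_scope(dup, "A"), "unique")
})
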