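# Seed-based metabolic network expansion (scopes), added value of
# cooperation, and enumeration of minimal communities whose collective
# scope covers a metabolite target set. Semantics are plain qualitative
# network expansion: no stoichiometry, no flux balance; a reaction fires
# forward once all its substrates are reachable (reversible reactions may
# also fire backward), and community members exchange every metabolite
# freely (union-of-reactions semantics).

# A network table has columns: organism (chr), reaction (chr),
# substrates (list of chr), products (list of chr), reversible (lgl).

validate_network <- function(networks) {
  need <- c("organism", "reaction", "substrates", "products", "reversible")
  if (!all(need %in% names(networks))) {
    stop("network table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(lengths(networks$substrates) == 0) ||
      any(lengths(networks$products) == 0)) {
    stop("every reaction must have at least one substrate and one product",
         call. = FALSE)
  }
  dup <- duplicated(networks[, c("organism", "reaction")])
  if (any(dup)) {
    stop("reaction ids must be unique within an organism", call. = FALSE)
  }
  invisible(networks)
}

# Fixpoint expansion over a set of directed firing rules. Rules are split
# into (inputs -> outputs) pairs; reversible reactions contribute both
# directions. Iterates until no rule adds a new metabolite; the result is
# independent of rule order.
expand_scope <- function(inputs, outputs, seeds) {
  reachable <- unique(seeds)
  pending <- rep(TRUE, length(inputs))
  repeat {
    fired <- FALSE
    for (i in which(pending)) {
      if (all(inputs[[i]] %in% reachable)) {
        new <- setdiff(outputs[[i]], reachable)
        reachable <- c(reachable, new)
        pending[i] <- FALSE
        fired <- TRUE
      }
    }
    if (!fired) break
  }
  sort(reachable)
}

firing_rules <- function(networks) {
  inputs <- c(networks$substrates,
              networks$products[networks$reversible])
  outputs <- c(networks$products,
               networks$substrates[networks$reversible])
  list(inputs = inputs, outputs = outputs)
}

#' Metabolic scope of one organism or a community
#'
#' Computes the set of metabolites reachable from a seed set by iterated
#' network expansion: a reaction fires when all its substrates are already
#' reachable, adding its products (reversible reactions may also fire in
#' the product-to-substrate direction). For a community, expansion runs
#' over the union of all members' reactions, i.e. with unrestricted
#' metabolite exchange.
#'
#' @param networks Network table (columns `organism`, `reaction`,
#'   `substrates`, `products`, `reversible`).
#' @param seeds Character vector of seed metabolite ids (for cocoa
#'   fermentation, the pulp components; see [cocoa_pulp_seeds()]).
#' @param organisms Organism ids to include; `NULL` (default) uses all
#'   organisms as one community.
#' @return A `met_scope` object with `owner`, sorted `reachable`
#'   metabolites and `produced` (`reachable` minus seeds).
#' @examples
#' net <- tibble::tibble(
#'   organism = c("o1", "o2"), reaction = c("r1", "r2"),
#'   substrates = list("A", "B"), products = list("B", "C"),
#'   reversible = FALSE
#' )
#' metabolic_scope(net, "A")$reachable
#' @export
metabolic_scope <- function(networks, seeds, organisms = NULL) {
  validate_network(networks)
  if (length(seeds) == 0) stop("seed set must be non-empty", call. = FALSE)
  if (!is.null(organisms)) {
    networks <- networks[networks$organism %in% organisms, , drop = FALSE]
  }
  owner <- if (is.null(organisms)) {
    "community"
  } else if (length(organisms) == 1) {
    organisms
  } else {
    "community"
  }
  rules <- firing_rules(networks)
  reachable <- expand_scope(rules$inputs, rules$outputs, seeds)
  structure(list(
    owner = owner,
    reachable = reachable,
    produced = setdiff(reachable, seeds)
  ), class = "met_scope")
}

#' @export
print.met_scope <- function(x, ...) {
  cat(sprintf("Scope of %s: %d reachable metabolites (%d produced)\n",
              x$owner, length(x$reachable), length(x$produced)))
  invisible(x)
}

#' Individual scopes of every organism
#'
#' @inheritParams metabolic_scope
#' @return Tibble with one row per organism: `organism`, `n_reachable`,
#'   `n_produced`, and list-columns `reachable` and `produced`.
#' @export
individual_scopes <- function(networks, seeds) {
  validate_network(networks)
  orgs <- unique(networks$organism)
  scopes <- lapply(orgs, function(o) metabolic_scope(networks, seeds, o))
  tibble::tibble(
    organism = orgs,
    n_reachable = vapply(scopes, function(s) length(s$reachable), integer(1)),
    n_produced = vapply(scopes, function(s) length(s$produced), integer(1)),
    reachable = lapply(scopes, `[[`, "reachable"),
    produced = lapply(scopes, `[[`, "produced")
  )
}

#' Added value of metabolic cooperation
#'
#' Metabolites in the community scope that no member reaches alone — the
#' gain from cross-feeding within the community.
#'
#' @inheritParams metabolic_scope
#' @return Sorted character vector of metabolite ids.
#' @export
added_value <- function(networks, seeds) {
  comm <- metabolic_scope(networks, seeds)
  indiv <- individual_scopes(networks, seeds)
  sort(setdiff(comm$reachable, unique(unlist(indiv$reachable))))
}

#' Minimal communities covering a metabolic target set
#'
#' Finds the minimum community size `m` such that some `m`-subset of
#' organisms collectively reaches every target metabolite, and enumerates
#' all `m`-subsets that do. By default the targets encode "equivalent
#' metabolic capabilities": everything the full community can produce
#' beyond the seeds (the union of individual production plus the added
#' value of cooperation); `mode = "added_value"` restricts the target to
#' the cooperative gain only. Enumeration is exhaustive for pools up to
#' `max_exhaustive` organisms; larger pools fall back to a seeded greedy
#' search with random restarts and the result is flagged non-exhaustive.
#'
#' @inheritParams metabolic_scope
#' @param targets Character vector of target metabolites; `NULL` uses the
#'   target implied by `mode`.
#' @param mode `"full"` (community-produced set, default) or
#'   `"added_value"`.
#' @param max_exhaustive Largest pool size searched exhaustively
#'   (default 20).
#' @param n_restarts Greedy restarts beyond that (default 100).
#' @param seed Integer seed for the greedy fallback.
#' @return A `community_reduction` object: `targets`, `min_size`,
#'   `communities` (list of organism-id sets), `key_species` (union),
#'   `essential_species` (intersection), `alternative_species`, and an
#'   `exhaustive` flag.
#' @export
minimal_communities <- function(networks, seeds, targets = NULL,
                                mode = c("full", "added_value"),
                                max_exhaustive = 20, n_restarts = 100,
                                seed = 1L) {
  mode <- match.arg(mode)
  validate_network(networks)
  comm <- metabolic_scope(networks, seeds)
  if (is.null(targets)) {
    targets <- if (mode == "added_value") {
      added_value(networks, seeds)
    } else {
      comm$produced
    }
  }
  unreachable <- setdiff(targets, comm$reachable)
  if (length(unreachable) > 0) {
    stop("infeasible targets, unreachable even by the full community: ",
         paste(sort(unreachable), collapse = ", "), call. = FALSE)
  }

  orgs <- sort(unique(networks$organism))
  n <- length(orgs)
  covers <- function(members) {
    if (length(members) == 0) return(all(targets %in% seeds))
    sub <- networks[networks$organism %in% members, , drop = FALSE]
    rules <- firing_rules(sub)
    all(targets %in% expand_scope(rules$inputs, rules$outputs, seeds))
  }

  solutions <- NULL
  exhaustive <- n <= max_exhaustive
  if (exhaustive) {
    for (m in 0:n) {
      found <- list()
      if (m == 0) {
        if (covers(character(0))) found <- list(character(0))
      } else {
        cmb <- combn(orgs, m, simplify = FALSE)
        found <- cmb[vapply(cmb, covers, logical(1))]
      }
      if (length(found) > 0) {
        solutions <- found
        break
      }
    }
  } else {
    best <- with_seed(seed, {
      best_local <- orgs
      for (r in seq_len(n_restarts)) {
        members <- character(0)
        while (!covers(members)) {
          remaining <- setdiff(orgs, members)
          gains <- vapply(remaining, function(o) {
            sub <- networks[networks$organism %in% c(members, o), ,
                            drop = FALSE]
            rules <- firing_rules(sub)
            sum(targets %in% expand_scope(rules$inputs, rules$outputs, seeds))
          }, numeric(1))
          pick <- remaining[gains == max(gains)]
          members <- c(members, sample(pick, 1))
        }
        # prune redundant members (reverse deletion)
        for (o in rev(members)) {
          if (covers(setdiff(members, o))) members <- setdiff(members, o)
        }
        if (length(members) < length(best_local)) best_local <- members
      }
      best_local
    })
    solutions <- list(sort(best))
  }

  solutions <- lapply(solutions, sort)
  key <- sort(unique(unlist(solutions)))
  essential <- if (length(solutions) == 0) {
    character(0)
  } else {
    sort(Reduce(intersect, solutions))
  }
  structure(list(
    targets = sort(targets),
    min_size = length(solutions[[1]]),
    communities = solutions,
    key_species = key,
    essential_species = essential,
    alternative_species = setdiff(key, essential),
    exhaustive = exhaustive
  ), class = "community_reduction")
}

#' @export
print.community_reduction <- function(x, ...) {
  cat(sprintf(
    "Community reduction: %d target metabolite(s), minimal size %d, %d solution(s)%s\n",
    length(x$targets), x$min_size, length(x$communities),
    if (x$exhaustive) "" else " (greedy, non-exhaustive)"))
  cat("  essential:", paste(x$essential_species, collapse = ", "), "\n")
  if (length(x$alternative_species) > 0) {
    cat("  alternative:", paste(x$alternative_species, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.community_reduction <- function(x, ...) {
  tibble::tibble(
    community = seq_along(x$communities),
    size = lengths(x$communities),
    members = x$communities
  )
}

#' @export
glance.community_reduction <- function(x, ...) {
  tibble::tibble(
    n_targets = length(x$targets),
    min_size = x$min_size,
    n_solutions = length(x$communities),
    n_key = length(x$key_species),
    n_essential = length(x$essential_species),
    exhaustive = x$exhaustive
  )
}

#' Overlap statistics between two metabolite sets
#'
#' Venn-style overlap record between a reference and candidate set (for
#' example, the community scope of the full microbiome versus a reduced
#' defined community): counts of shared and private metabolites and the
#' shared percentages relative to the union and to the reference.
#'
#' @param reference,candidate `met_scope` objects or character vectors
#'   over a shared metabolite namespace.
#' @return One-row tibble with `n_shared`, `n_reference_only`,
#'   `n_candidate_only`, `pct_shared_of_union` and
#'   `pct_shared_of_reference`.
#' @export
coverage_stats <- function(reference, candidate) {
  a <- if (inherits(reference, "met_scope")) reference$reachable else reference
  b <- if (inherits(candidate, "met_scope")) candidate$reachable else candidate
  a <- unique(a)
  b <- unique(b)
  shared <- intersect(a, b)
  uni <- union(a, b)
  if (length(uni) == 0) {
    warning("both sets are empty; percentages defined as 0", call. = FALSE)
    return(tibble::tibble(
      n_shared = 0L, n_reference_only = 0L, n_candidate_only = 0L,
      pct_shared_of_union = 0, pct_shared_of_reference = 0
    ))
  }
  tibble::tibble(
    n_shared = length(shared),
    n_reference_only = length(setdiff(a, b)),
    n_candidate_only = length(setdiff(b, a)),
    pct_shared_of_union = 100 * length(shared) / length(uni),
    pct_shared_of_reference =
      if (length(a) == 0) 0 else 100 * length(shared) / length(a)
  )
}

#' Default cocoa-pulp seed metabolites
#'
#' The components of (artificial) cocoa pulp used to seed network
#' expansion: sugars, organic acids, structural polysaccharides, complex
#' nitrogen sources and mineral salts.
#'
#' @return Character vector of metabolite labels.
#' @export
cocoa_pulp_seeds <- function() {
  c("sucrose", "glucose", "fructose", "citric_acid", "pectin",
    "carboxymethyl_cellulose_high_viscosity",
    "carboxymethyl_cellulose_low_viscosity",
    "yeast_extract", "peptone", "calcium_lactate", "tween_80",
    "magnesium_sulfate", "manganese_sulfate")
}
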