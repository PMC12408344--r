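# Independent oracles, deliberately implemented differently from the
# package internals they check.

# Naive scope oracle: re-scan the full reaction list until a whole pass
# adds nothing, tracking reachability in a named logical vector.
oracle_scope <- function(networks, seeds) {
  rules <- list()
  for (i in seq_len(nrow(networks))) {
    rules[[length(rules) + 1]] <- list(from = networks$substrates[[i]],
                                       to = networks$products[[i]])
    if (networks$reversible[[i]]) {
      rules[[length(rules) + 1]] <- list(from = networks$products[[i]],
                                         to = networks$substrates[[i]])
    }
  }
  mets <- unique(c(seeds, unlist(networks$substrates),
                   unlist(networks$products)))
  reach <- setNames(mets %in% seeds, mets)
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (r in rules) {
      if (all(reach[r$from]) && !all(reach[r$to])) {
        reach[r$to] <- TRUE
        changed <- TRUE
      }
    }
  }
  sort(names(reach)[reach])
}

# Brute-force growth-feature oracle built on generic numeric tools
# (approxfun root finding, pracma trapezoid) rather than index scans.
oracle_growth <- function(times, values, window = 1) {
  n <- length(values)
  if (window > 1) {
    h <- (window - 1) / 2
    values <- sapply(seq_len(n), function(i) {
      mean(values[max(1, i - h):min(n, i + h)])
    })
  }
  is_max <- sapply(seq_len(n), function(i) {
    (i == 1 || values[i] >= values[i - 1]) &&
      (i == n || values[i] >= values[i + 1])
  })
  is_min <- sapply(seq_len(n), function(i) {
    (i == 1 || values[i] <= values[i - 1]) &&
      (i == n || values[i] <= values[i + 1])
  })
  half <- max(values) / 2
  midpoint <- NA_real_
  if (values[1] >= half) {
    midpoint <- times[1]
  } else {
    f <- stats::approxfun(times, values - half)
    for (i in seq_len(n - 1)) {
      lo <- times[i]; hi <- times[i + 1]
      if (f(lo) < 0 && f(hi) >= 0) {
        midpoint <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
        break
      }
    }
    if (is.na(midpoint)) midpoint <- times[n]
  }
  slopes <- (values[-1] - values[-n]) / (times[-1] - times[-n])
  list(
    first_local_max = values[which(is_max)[1]],
    initial_density = values[which(is_min)[1]],
    auc = pracma::trapz(times, values),
    max_density = max(values),
    time_to_max_density = times[which(values == max(values))[1]],
    midpoint = midpoint,
    inflection_point = times[which(slopes == max(slopes))[1]]
  )
}

# Small random network instances for metnet stress tests.
random_network <- function(n_orgs = 3, n_mets = 20, n_rxns = 12,
                           p_reversible = 0.25) {
  mets <- paste0("m", seq_len(n_mets))
  orgs <- paste0("o", seq_len(n_orgs))
  tibble::tibble(
    organism = sample(orgs, n_rxns, replace = TRUE),
    reaction = paste0("r", seq_len(n_rxns)),
    substrates = replicate(n_rxns, sample(mets, sample(1:3, 1)),
                           simplify = FALSE),
    products = replicate(n_rxns, sample(mets, sample(1:3, 1)),
                         simplify = FALSE),
    reversible = runif(n_rxns) < p_reversible
  )
}

# Exhaustive powerset search for minimal covering communities.
oracle_minimal_communities <- function(networks, seeds, targets) {
  orgs <- sort(unique(networks$organism))
  n <- length(orgs)
  best_size <- Inf
  sols <- list()
  for (code in 0:(2^n - 1)) {
    members <- orgs[bitwAnd(code, 2^(seq_len(n) - 1)) > 0]
    sub <- networks[networks$organism %in% members, , drop = FALSE]
    if (all(targets %in% oracle_scope(sub, seeds))) {
      if (length(members) < best_size) {
        best_size <- length(members)
        sols <- list(sort(members))
      } else if (length(members) == best_size) {
        sols <- c(sols, list(sort(members)))
      }
    }
  }
  sols
}
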