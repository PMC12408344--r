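# JSON serialization of organism networks and seed lists. Format:
# {"organisms": [{"id": ..., "reactions": [{"id", "substrates",
# "products", "reversible"}]}]}

#' Write a network table to JSON
#'
#' @param networks Network table (see [metabolic_scope()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(networks, path) {
  validate_network(networks)
  orgs <- lapply(unique(networks$organism), function(o) {
    sub <- networks[networks$organism == o, , drop = FALSE]
    list(
      id = o,
      reactions = purrr::pmap(
        list(sub$reaction, sub$substrates, sub$products, sub$reversible),
        function(id, s, p, rev) {
          list(id = id, substrates = as.list(s), products = as.list(p),
               reversible = rev)
        }
      )
    )
  })
  jsonlite::write_json(list(organisms = orgs), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a network table from JSON
#'
#' @param path JSON file written by [write_network_json()] (or following
#'   the same layout).
#' @return Network table tibble.
#' @export
read_network_json <- function(path) {
  raw <- jsonlite::read_json(path)
  rows <- purrr::map_dfr(raw$organisms, function(org) {
    tibble::tibble(
      organism = org$id,
      reaction = purrr::map_chr(org$reactions, "id"),
      substrates = purrr::map(org$reactions,
                              \(r) unlist(r$substrates, use.names = FALSE)),
      products = purrr::map(org$reactions,
                            \(r) unlist(r$products, use.names = FALSE)),
      reversible = purrr::map_lgl(org$reactions, "reversible")
    )
  })
  validate_network(rows)
  rows
}

#' Read seed metabolites from a file
#'
#' Accepts either a JSON array or a plain text file with one metabolite id
#' per line (blank lines and `#` comments ignored).
#'
#' @param path Input file.
#' @return Character vector of seed ids.
#' @export
read_seeds <- function(path) {
  seeds <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    unlist(jsonlite::read_json(path), use.names = FALSE)
  } else {
    lines <- trimws(readLines(path, warn = FALSE))
    lines[nzchar(lines) & !startsWith(lines, "#")]
  }
  if (length(seeds) == 0) stop("seed file is empty", call. = FALSE)
  as.character(seeds)
}
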