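# Domain layouts: which residues belong to which rigid domain, and where
# the movable inter-domain junctions sit.

#' Domain layout
#'
#' Partition of a (multi-chain) protein into domains, given as residue
#' number ranges per chain.  Every residue of the structure must belong to
#' exactly one domain; ranges must not overlap within a chain.
#'
#' @param chains Character vector giving chain order.
#' @param domains List of domains, each a list with elements `id`
#'   (character), `chain` (one of `chains`), and `ranges` (a list or
#'   2-column matrix of inclusive `[start, end]` residue-number ranges).
#' @return An object of class `"domain_layout"`.
#' @export
#' @examples
#' domain_layout(chains = "A", domains = list(
#'   list(id = "D1", chain = "A", ranges = list(c(1, 34))),
#'   list(id = "D2", chain = "A", ranges = list(c(35, 68)))))
domain_layout <- function(chains, domains) {
  chains <- as.character(chains)
  if (length(domains) < 1L) stop_layout("layout needs at least one domain")
  doms <- lapply(domains, function(d) {
    rg <- d$ranges
    if (is.list(rg)) rg <- do.call(rbind, lapply(rg, as.integer))
    rg <- matrix(as.integer(rg), ncol = 2L)
    if (any(rg[, 2] < rg[, 1])) stop_layout("range end before start in domain %s", d$id)
    list(id = as.character(d$id), chain = as.character(d$chain), ranges = rg)
  })
  ids <- vapply(doms, `[[`, "", "id")
  if (anyDuplicated(ids)) stop_layout("duplicate domain ids")
  if (!all(vapply(doms, `[[`, "", "chain") %in% chains))
    stop_layout("domain chain not listed in layout chains")
  lay <- structure(list(chains = chains, domains = doms),
                   class = "domain_layout")
  lr <- layout_residues(lay)  # errors on overlap
  invisible(lr)
  lay
}

#' @export
print.domain_layout <- function(x, ...) {
  cat(sprintf("<domain layout> %d chain(s), %d domain(s)\n",
              length(x$chains), length(x$domains)))
  for (d in x$domains)
    cat(sprintf("  %s (chain %s): %s\n", d$id, d$chain,
                paste(apply(d$ranges, 1, function(r)
                  sprintf("%d-%d", r[1], r[2])), collapse = ", ")))
  invisible(x)
}

#' Residues enumerated by a layout
#'
#' @param layout A `"domain_layout"`.
#' @return `data.frame(chain, resno, domain)` in layout chain order, residue
#'   numbers ascending within each chain.  Also the definition of the
#'   0-based global residue index used by interaction maps (row `k` has
#'   global index `k - 1`).
#' @export
layout_residues <- function(layout) {
  out <- list()
  for (ch in layout$chains) {
    rows <- list()
    for (d in layout$domains) {
      if (d$chain != ch) next
      for (r in seq_len(nrow(d$ranges)))
        rows[[length(rows) + 1L]] <- data.frame(
          chain = ch, resno = seq.int(d$ranges[r, 1], d$ranges[r, 2]),
          domain = d$id, stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L) next
    df <- do.call(rbind, rows)
    if (anyDuplicated(df$resno))
      stop_layout("overlapping domain ranges in chain %s", ch)
    out[[ch]] <- df[order(df$resno), , drop = FALSE]
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Inter-domain boundaries of a layout
#'
#' Junctions between sequence-adjacent residues of different domains on
#' the same chain, sorted in layout order.
#'
#' @param layout A `"domain_layout"`.
#' @return `data.frame(chain, before, after, resno_before, resno_after)`,
#'   one row per boundary.
#' @export
layout_boundaries <- function(layout) {
  lr <- layout_residues(layout)
  out <- list()
  for (ch in unique(lr$chain)) {
    d <- lr[lr$chain == ch, , drop = FALSE]
    if (nrow(d) < 2L) next
    jump <- which(d$domain[-1] != d$domain[-nrow(d)])
    for (j in jump)
      out[[length(out) + 1L]] <- data.frame(
        chain = ch, before = d$domain[j], after = d$domain[j + 1L],
        resno_before = d$resno[j], resno_after = d$resno[j + 1L],
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(chain = character(), before = character(),
                      after = character(), resno_before = integer(),
                      resno_after = integer(), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Read / write a domain layout as JSON
#'
#' The on-disk form is
#' `{"chains": ["A"], "domains": [{"id": "D1", "chain": "A",
#' "ranges": [[1, 34]]}]}`.
#'
#' @param path JSON file path.
#' @return `read_domain_layout()`: a `"domain_layout"`;
#'   `write_domain_layout()`: invisibly, `path`.
#' @export
read_domain_layout <- function(path) {
  if (!file.exists(path)) stop_io("cannot read layout file: %s", path)
  j <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e) stop_format("invalid layout JSON: %s",
                                                conditionMessage(e)))
  if (is.null(j$chains) || is.null(j$domains))
    stop_format("layout JSON must have 'chains' and 'domains'")
  domain_layout(chains = unlist(j$chains),
                domains = lapply(j$domains, function(d)
                  list(id = d$id, chain = d$chain,
                       ranges = lapply(d$ranges, unlist))))
}

#' @rdname read_domain_layout
#' @param layout A `"domain_layout"`.
#' @export
write_domain_layout <- function(layout, path) {
  obj <- list(
    chains = layout$chains,
    domains = lapply(layout$domains, function(d)
      list(id = d$id, chain = d$chain,
           ranges = lapply(seq_len(nrow(d$ranges)),
                           function(i) as.integer(d$ranges[i, ])))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
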