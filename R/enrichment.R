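#' @include transcriptome.R
NULL

#' Hypergeometric gene-set enrichment with a fold-enrichment filter
#'
#' For every term in the collection whose size falls in
#' `[minTerm, maxTerm]`, computes the hypergeometric upper-tail probability
#' of drawing the observed intersection or larger when `querySize` genes are
#' sampled from the effective domain, the fold enrichment
#' `E = (intersection / query) / (term / domain)`, and Benjamini-Hochberg
#' adjusted p-values across all tested terms. With `filter = TRUE` (default)
#' only terms passing both `p_adjusted <= pThresh` and `E >= eThresh` are
#' returned; the size window always applies before testing, so an undersized
#' or oversized term is never tested at all.
#'
#' @param query character vector of query gene ids (non-empty).
#' @param terms named list: term id -> character vector of member gene ids.
#' @param domain either a character vector of all gene ids in the effective
#'   domain (query and terms must be subsets) or a single number, the
#'   effective domain size.
#' @param minTerm,maxTerm inclusive term-size window (defaults 5 and 3000).
#' @param pThresh adjusted-p threshold (default 0.001).
#' @param eThresh fold-enrichment threshold (default 2.5).
#' @param filter return only passing terms (default) or all tested terms.
#' @return data.frame with columns `term_id`, `term_size`,
#'   `intersection_size`, `query_size`, `effective_domain_size`, `E`,
#'   `p_hyper`, `p_adjusted`, ordered by `p_adjusted`.
#' @examples
#' terms <- list(t1 = paste0("g", 1:200))
#' res <- enrich(paste0("g", 1:100), terms, domain = 20000, filter = FALSE)
#' res$E  # (10/100 intersection would give 10; here 100/100 / (200/20000))
#' @export
enrich <- function(query, terms, domain, minTerm = 5, maxTerm = 3000,
                   pThresh = 0.001, eThresh = 2.5, filter = TRUE) {
  query <- unique(as.character(query))
  if (!length(query)) stop("'query' must not be empty")
  if (!is.list(terms) || is.null(names(terms))) {
    stop("'terms' must be a named list of gene-id vectors")
  }
  if (is.character(domain)) {
    domain_ids <- unique(domain)
    domain_size <- length(domain_ids)
    if (!all(query %in% domain_ids)) {
      stop("'query' must be a subset of the domain")
    }
    bad <- !vapply(terms, function(g) all(g %in% domain_ids), logical(1))
    if (any(bad)) {
      stop(
        "term(s) not contained in the domain: ",
        paste(utils::head(names(terms)[bad], 5), collapse = ", ")
      )
    }
  } else {
    domain_size <- as.numeric(domain)
  }
  term_sizes <- vapply(terms, function(g) length(unique(g)), integer(1))
  if (domain_size < max(c(term_sizes, length(query)))) {
    stop("effective domain is smaller than a gene set it must contain")
  }
  tested <- term_sizes >= minTerm & term_sizes <= maxTerm
  terms <- terms[tested]
  term_sizes <- term_sizes[tested]
  if (!length(terms)) {
    return(data.frame(
      term_id = character(), term_size = integer(),
      intersection_size = integer(), query_size = integer(),
      effective_domain_size = numeric(), E = numeric(),
      p_hyper = numeric(), p_adjusted = numeric()
    ))
  }
  q_size <- length(query)
  inter <- vapply(
    terms, function(g) length(intersect(query, unique(g))), integer(1)
  )
  # upper tail: P(X >= intersection) for X ~ Hypergeom(term, domain-term, query)
  p <- stats::phyper(inter - 1L, term_sizes, domain_size - term_sizes, q_size,
    lower.tail = FALSE
  )
  e <- (inter / q_size) / (term_sizes / domain_size)
  res <- data.frame(
    term_id = names(terms),
    term_size = unname(term_sizes),
    intersection_size = unname(inter),
    query_size = q_size,
    effective_domain_size = domain_size,
    E = unname(e),
    p_hyper = unname(p),
    p_adjusted = unname(stats::p.adjust(p, method = "BH")),
    stringsAsFactors = FALSE
  )
  if (filter) {
    res <- res[res$p_adjusted <= pThresh & res$E >= eThresh, , drop = FALSE]
  }
  res[order(res$p_adjusted, res$p_hyper), , drop = FALSE]
}

#' Read / write gene-set collections in GMT format
#'
#' GMT: one set per line, tab-separated `id <tab> description <tab> genes...`.
#'
#' @param path file path.
#' @return `readGMT`: named list of gene-id vectors with attribute
#'   `description`.
#' @name gmt
NULL

#' @rdname gmt
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1])
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2L)
  sets
}

#' @rdname gmt
#' @param sets named list of gene-id vectors.
#' @param description optional descriptions, recycled.
#' @export
writeGMT <- function(sets, path, description = names(sets)) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- mapply(
    function(id, desc, genes) paste(c(id, desc, genes), collapse = "\t"),
    names(sets), description, sets
  )
  writeLines(lines, path)
  invisible(path)
}
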