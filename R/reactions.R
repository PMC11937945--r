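#' Read a metabolic reaction table
#'
#' Columns: `reaction_id`, `substrates`, `products`, `enzymes`, with the list
#' columns semicolon-separated. A JSON reader with the same fields is available
#' via `format = "json"` (a list of objects with those keys).
#'
#' @param path file path
#' @param format `"tsv"`, `"csv"` or `"json"`
#' @return a `reaction_table`: data.frame with list-columns `substrates`,
#'   `products`, `enzymes`
#' @export
read_reaction_table <- function(path, format = c("tsv", "csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    d <- data.frame(reaction_id = vapply(raw, function(r) as.character(r$reaction_id), ""),
                    stringsAsFactors = FALSE)
    d$substrates <- lapply(raw, function(r) as.character(unlist(r$substrates)))
    d$products <- lapply(raw, function(r) as.character(unlist(r$products)))
    d$enzymes <- lapply(raw, function(r) as.character(unlist(r$enzymes)))
  } else {
    sep <- if (format == "tsv") "\t" else ","
    x <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           stringsAsFactors = FALSE, quote = "")
    need <- c("reaction_id", "substrates", "products", "enzymes")
    if (!all(need %in% names(x)))
      stop(sprintf("reaction table '%s' is missing columns: %s", path,
                   paste(setdiff(need, names(x)), collapse = ", ")))
    splitcol <- function(v) lapply(strsplit(as.character(v), ";", fixed = TRUE),
                                   function(s) s[nzchar(s)])
    d <- data.frame(reaction_id = as.character(x$reaction_id),
                    stringsAsFactors = FALSE)
    d$substrates <- splitcol(x$substrates)
    d$products <- splitcol(x$products)
    d$enzymes <- splitcol(x$enzymes)
  }
  validate_reaction_table(d)
}

validate_reaction_table <- function(rt) {
  for (i in seq_len(nrow(rt))) {
    if (length(rt$substrates[[i]]) == 0 || length(rt$products[[i]]) == 0)
      stop(sprintf("reaction '%s': substrates and products must be non-empty",
                   rt$reaction_id[i]))
    for (col in c("substrates", "products", "enzymes"))
      if (anyDuplicated(rt[[col]][[i]]))
        stop(sprintf("reaction '%s': duplicate entries in %s", rt$reaction_id[i], col))
  }
  class(rt) <- c("reaction_table", class(rt))
  rt
}

#' Build the enzyme-enzyme network from a reaction table
#'
#' Enzymes are connected by a directed edge e1 -> e2 whenever a metabolite
#' produced by a reaction catalyzed by e1 is a substrate of a reaction
#' catalyzed by e2; the linking metabolite becomes the edge type, so enzyme
#' pairs communicating through several metabolites keep distinct parallel
#' typed edges. Ubiquitous (currency) metabolites are removed by listing them
#' in `excluded_metabolites` (see [rank_metabolites()] for choosing the cut).
#'
#' @param rt a `reaction_table` (see [read_reaction_table()])
#' @param excluded_metabolites character vector of metabolites that never link
#' @param reversible if TRUE each reaction is also added in reverse
#' @return a `dmgraph` over enzymes
#' @export
build_enzyme_network <- function(rt, excluded_metabolites = character(),
                                 reversible = FALSE) {
  if (nrow(rt) == 0) return(dmgraph())
  subs <- rt$substrates; prods <- rt$products; enz <- rt$enzymes
  if (reversible) {
    subs <- c(subs, rt$products); prods <- c(prods, rt$substrates)
    enz <- c(enz, rt$enzymes)
  }
  skip <- vapply(enz, length, 0L) == 0
  if (any(skip))
    warning(sprintf("%d reaction(s) reference no enzymes and were skipped", sum(skip)))
  keep <- which(!skip)
  src <- character(); tgt <- character(); typ <- character()
  for (i in keep) {
    pi <- setdiff(prods[[i]], excluded_metabolites)
    if (length(pi) == 0) next
    for (j in keep) {
      m <- intersect(pi, subs[[j]])
      if (length(m) == 0) next
      pairs <- expand.grid(e1 = enz[[i]], e2 = enz[[j]], m = m,
                           stringsAsFactors = FALSE)
      src <- c(src, pairs$e1); tgt <- c(tgt, pairs$e2); typ <- c(typ, pairs$m)
    }
  }
  nodes <- sort(unique(c(src, tgt)))
  if (length(src) == 0) return(dmgraph(nodes = character()))
  dmgraph(data.frame(source = src, target = tgt, edge_type = typ,
                     multiplicity = 1, stringsAsFactors = FALSE), nodes = nodes)
}

#' Rank metabolites by reaction occurrence
#'
#' Counts, for every metabolite, the number of reactions in which it appears
#' as substrate or product, to support discarding the most ubiquitous ones
#' (ATP, H2O, ...) before network construction.
#' @param rt a `reaction_table`
#' @return data.frame `metabolite`, `count`, sorted by decreasing count then
#'   lexicographically
#' @export
rank_metabolites <- function(rt) {
  if (nrow(rt) == 0)
    return(data.frame(metabolite = character(), count = integer(),
                      stringsAsFactors = FALSE))
  per_rxn <- mapply(function(s, p) unique(c(s, p)), rt$substrates, rt$products,
                    SIMPLIFY = FALSE)
  tab <- table(unlist(per_rxn))
  d <- data.frame(metabolite = names(tab), count = as.integer(tab),
                  stringsAsFactors = FALSE)
  d <- d[order(-d$count, d$metabolite), , drop = FALSE]
  rownames(d) <- NULL
  d
}
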