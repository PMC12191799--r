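#' Build a literature-search query string
#'
#' Deterministic query of the shape used for per-gene citation counting:
#' gene symbol, topic clause, and publication-date window, e.g.
#' `"KIT AND [ovarian cancer] AND 1998:2023[PDAT]"`. The string is
#' URL-encoded only at the transport layer, not here.
#'
#' @param gene_id nonempty gene symbol.
#' @param topic topic clause (default `"ovarian cancer"`); empty string
#'   drops the clause.
#' @param from,to inclusive publication-date window in years.
#' @return the query string.
#' @export
build_query <- function(gene_id, topic = "ovarian cancer",
                        from = 1998L, to = 2023L) {
  if (!nzchar(gene_id)) stop("empty gene symbol", call. = FALSE)
  parts <- gene_id
  if (nzchar(topic)) parts <- c(parts, sprintf("[%s]", topic))
  parts <- c(parts, sprintf("%d:%d[PDAT]", from, to))
  paste(parts, collapse = " AND ")
}

#' Offline citation-count client
#'
#' Wraps a fixed gene -> count mapping as a client function usable by
#' [fetch_counts()]. Genes absent from the mapping return `NA` (missing),
#' never a fabricated count. A live literature-API client has the same
#' calling convention (`function(gene_id) count`), so the rest of the
#' pipeline is agnostic to where counts come from.
#'
#' @param counts named numeric vector or a data.frame with columns
#'   `gene_id`, `count`.
#' @return a client `function(gene_id)`.
#' @export
citation_client_fixture <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- stats::setNames(counts$count, counts$gene_id)
  }
  force(counts)
  function(gene_id) {
    if (gene_id %in% names(counts)) unname(counts[[gene_id]]) else NA_integer_
  }
}

#' Fetch per-gene citation counts through a client
#'
#' Queries the client once per unique gene, caching results so repeated
#' genes trigger no duplicate requests. Client failures or absent genes are
#' recorded as missing — counts are never fabricated.
#'
#' @param genes character vector of gene IDs (duplicates allowed).
#' @param client a `function(gene_id) -> count`, e.g.
#'   [citation_client_fixture()].
#' @param topic,from,to stored query metadata, see [build_query()].
#' @return a `citation_table` data.frame: `gene_id`, `count` (`NA` when
#'   missing), `query`. The number of client calls is recorded in the
#'   `n_requests` attribute.
#' @export
fetch_counts <- function(genes, client, topic = "ovarian cancer",
                         from = 1998L, to = 2023L) {
  stopifnot(is.function(client))
  uniq <- unique(as.character(genes))
  cache <- new.env(parent = emptyenv())
  n_requests <- 0L
  counts <- vapply(uniq, function(g) {
    if (!exists(g, envir = cache)) {
      n_requests <<- n_requests + 1L
      val <- tryCatch(client(g), error = function(e) NA_real_)
      assign(g, if (is.null(val)) NA_real_ else as.numeric(val), envir = cache)
    }
    get(g, envir = cache)
  }, numeric(1))
  out <- data.frame(
    gene_id = uniq,
    count = counts,
    query = vapply(uniq, build_query, character(1), topic = topic,
                   from = from, to = to),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("citation_table", "data.frame")
  attr(out, "n_requests") <- n_requests
  out
}

#' Literature-relevance (OVca) score of an enriched function
#'
#' Geometric mean of the citation counts of the function's significant
#' member genes. A pseudocount (default 1) is added inside the geometric
#' mean so zero-count genes do not collapse the score to 0, then
#' subtracted back (floored at 0) so round-number fixtures behave
#' intuitively: counts {100, 100} score exactly 100.
#'
#' @param member_genes character vector of the function's significant
#'   member gene IDs (nonempty).
#' @param counts a [fetch_counts()] table (or any data.frame with
#'   `gene_id`, `count`). Genes missing from the table count as 0.
#' @param pseudocount added inside the geometric mean (default 1).
#' @return the score (non-negative numeric scalar).
#' @export
ovca_score <- function(member_genes, counts, pseudocount = 1) {
  if (length(member_genes) == 0L) stop("empty member gene list", call. = FALSE)
  cnt <- counts$count[match(member_genes, counts$gene_id)]
  cnt[is.na(cnt)] <- 0
  gm <- exp(mean(log(cnt + pseudocount)))
  max(gm - pseudocount, 0)
}

#' Triage enriched functions by literature relevance
#'
#' Scores every function with [ovca_score()], enforces the cluster cap —
#' within any cluster of MORE than four members only the four highest-OVca
#' functions are retained — and ranks the survivors by OVca score
#' descending. Ties break by `p_adjusted` ascending, then `function_id`.
#' The result is a deterministic function of its inputs (no RNG).
#'
#' @param functions a clustered, majority-labeled enrichment table
#'   ([cluster_functions()] output).
#' @param counts a citation table, see [fetch_counts()].
#' @param top_n number of functions to emit (default 30).
#' @param pseudocount passed to [ovca_score()].
#' @return the triage table: the input columns plus `ovca_score` and
#'   `retained`, ranked, truncated to `top_n`.
#' @export
triage <- function(functions, counts, top_n = 30L, pseudocount = 1) {
  if (nrow(functions) == 0L) {
    functions$ovca_score <- numeric(0)
    return(functions)
  }
  functions$ovca_score <- vapply(
    functions$member_hits, ovca_score, numeric(1),
    counts = counts, pseudocount = pseudocount
  )
  ord <- order(
    -functions$ovca_score, functions$p_adjusted, functions$function_id
  )
  functions <- functions[ord, , drop = FALSE]
  retained <- rep(TRUE, nrow(functions))
  if (!is.null(functions$cluster_id)) {
    for (cl in unique(functions$cluster_id)) {
      idx <- which(functions$cluster_id == cl)
      if (length(idx) > 4L) retained[idx[-seq_len(4L)]] <- FALSE
    }
  }
  functions$retained <- retained
  out <- functions[retained, , drop = FALSE]
  out <- utils::head(out, top_n)
  rownames(out) <- NULL
  out
}
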