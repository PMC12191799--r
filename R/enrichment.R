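#' Hypergeometric over-representation test
#'
#' Tests whether a query gene list overlaps a gene set more than chance
#' given a finite universe: `p` is the hypergeometric upper-tail
#' probability of an overlap at least as large as observed, and the fold
#' enrichment is `(k/|query|) / (K/|universe|)` with `k` the overlap and
#' `K` the set size.
#'
#' @param query character vector of significant gene IDs (subset of
#'   `universe`).
#' @param gene_set character vector of set member IDs (subset of
#'   `universe`).
#' @param universe character vector of all testable gene IDs.
#' @return list with `p_value`, `fold_enrichment`, `overlap` (the
#'   overlapping gene IDs), `k`, `K`, `n`, `N`.
#' @export
ora_test <- function(query, gene_set, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0L) stop("empty universe", call. = FALSE)
  query <- unique(intersect(query, universe))
  gene_set <- unique(intersect(gene_set, universe))
  n <- length(query)
  if (n == 0L) stop("empty query", call. = FALSE)
  K <- length(gene_set)
  hits <- intersect(query, gene_set)
  k <- length(hits)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- if (K == 0L) NA_real_ else (k / n) / (K / N)
  list(
    p_value = p, fold_enrichment = fold, overlap = hits,
    k = k, K = K, n = n, N = N
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR-adjusted p-values (monotone, capped at 1).
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Enrichment of survival-significant genes against a gene-set collection
#'
#' Takes a classified screen table ([classify_groups()]), uses the genes in
#' either tail group as the ORA query, every non-skipped tested feature as
#' the universe, and tests each set in the collection. Per-set group
#' composition (`n_opcml_plus`, `n_genei_plus`, counted over the
#' overlapping genes) and the >4x majority label are filled in; functions
#' surviving `p_adjusted <= alpha` are returned.
#'
#' @param records a classified [screen_all()] table.
#' @param collection a [gene_set_collection()].
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param ratio_threshold majority-rule multiplier, see [label_majority()].
#' @return a data.frame of enriched functions: `function_id`,
#'   `description`, `p_value`, `p_adjusted`, `fold_enrichment`,
#'   `member_hits` (list column), `n_opcml_plus`, `n_genei_plus`,
#'   `majority_class`, ordered by `p_value`.
#' @export
enrich_functions <- function(records, collection, alpha = 0.05,
                             ratio_threshold = 4.0) {
  stopifnot(inherits(collection, "gene_set_collection"))
  tested <- records$feature_id[is.na(records$skipped_reason)]
  universe <- intersect(tested, collection$universe)
  sig <- records$feature_id[records$group %in% c("OPCML_plus", "GENEi_plus")]
  sig <- intersect(sig, universe)
  if (length(sig) == 0L) {
    warning("no significant genes to test", call. = FALSE)
    return(.empty_enrichment())
  }
  grp <- stats::setNames(records$group, records$feature_id)
  rows <- lapply(names(collection$sets), function(id) {
    res <- ora_test(sig, collection$sets[[id]], universe)
    hits <- sort(res$overlap)
    n_op <- sum(grp[hits] == "OPCML_plus")
    n_ge <- sum(grp[hits] == "GENEi_plus")
    data.frame(
      function_id = id,
      description = unname(collection$descriptions[id]),
      p_value = res$p_value,
      fold_enrichment = res$fold_enrichment,
      member_hits = I(list(hits)),
      n_opcml_plus = n_op,
      n_genei_plus = n_ge,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out$majority_class <- label_majority(
    out$n_opcml_plus, out$n_genei_plus, ratio_threshold
  )
  out <- out[!is.na(out$p_adjusted) & out$p_adjusted <= alpha, , drop = FALSE]
  out <- out[order(out$p_value, out$function_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_enrichment <- function() {
  data.frame(
    function_id = character(), description = character(),
    p_value = numeric(), fold_enrichment = numeric(),
    member_hits = I(list()), n_opcml_plus = integer(),
    n_genei_plus = integer(), p_adjusted = numeric(),
    majority_class = character(), stringsAsFactors = FALSE
  )
}

#' Collapse repeated functions to the most conservative instance
#'
#' When the same function ID appears more than once (e.g. from several
#' source collections), only the instance with the HIGHEST p-value — the
#' more conservative report — is kept. Ties keep the first occurrence;
#' otherwise order is stable.
#'
#' @param functions an enrichment table with `function_id` and `p_value`.
#' @return the deduplicated table.
#' @export
dedup_functions <- function(functions) {
  if (nrow(functions) == 0L) return(functions)
  keep <- logical(nrow(functions))
  for (id in unique(functions$function_id)) {
    idx <- which(functions$function_id == id)
    keep[idx[which.max(functions$p_value[idx])]] <- TRUE
  }
  out <- functions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label the group composition of an enriched function
#'
#' A function is anchor-pathway `"dependent"` when its `OPCML_plus` member
#' count strictly exceeds `ratio_threshold` times its `GENEi_plus` count
#' (so with zero `GENEi_plus` members, one `OPCML_plus` member suffices);
#' otherwise `"independent"`. With no members in either group the label is
#' undefined (`NA`).
#'
#' @param n_opcml_plus,n_genei_plus member counts per group (vectorized).
#' @param ratio_threshold the majority multiplier (default 4).
#' @return character vector `"dependent"` / `"independent"` / `NA`.
#' @export
label_majority <- function(n_opcml_plus, n_genei_plus, ratio_threshold = 4.0) {
  out <- ifelse(n_opcml_plus > ratio_threshold * n_genei_plus,
    "dependent", "independent"
  )
  out[n_opcml_plus == 0 & n_genei_plus == 0] <- NA_character_
  out
}

#' Cluster enriched functions by shared gene membership
#'
#' Pairwise Jaccard distance on the `member_hits` gene sets, average-linkage
#' agglomeration, cut into `k` top-level clusters. Only the set structure
#' matters: relabeling genes leaves the clustering unchanged, and the
#' result is deterministic for a given input order.
#'
#' @param functions an enrichment table with a `member_hits` list column
#'   (>= 2 rows with nonempty member sets).
#' @param k number of top-level clusters to cut (default 20).
#' @return the table with an integer `cluster_id` column added.
#' @export
cluster_functions <- function(functions, k = 20L) {
  m <- nrow(functions)
  if (m < 2L) stop("need at least 2 functions to cluster", call. = FALSE)
  if (k > m) stop("k exceeds the number of functions", call. = FALSE)
  sets <- functions$member_hits
  if (any(lengths(sets) == 0L)) {
    stop("every function needs nonempty member_hits", call. = FALSE)
  }
  d <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      uni <- length(union(sets[[i]], sets[[j]]))
      d[i, j] <- d[j, i] <- 1 - inter / uni
    }
  }
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  functions$cluster_id <- as.integer(stats::cutree(tree, k = k))
  attr(functions, "cluster_tree") <- tree
  functions
}
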