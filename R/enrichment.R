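#' Read a GMT gene-set collection
#'
#' Tab-separated, one set per line: term id, description, then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors (term -> genes), with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stopf("GMT line(s) with fewer than 3 fields: %s",
          paste(utils::head(bad, 5), collapse = ", "))
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) stopf("duplicated term ids in GMT")
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[[`, character(1), 2), names(sets))
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character vector of term descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% attr(sets, "descriptions") %||%
    stats::setNames(rep("NA", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]] %||% "NA", sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set enrichment
#'
#' For each term, the upper-tail (cumulative) hypergeometric probability of
#' observing at least the realized overlap between the query and the term,
#' given the background universe; terms pass the reporting filters when
#' `p < 0.01`, overlap >= 3 and enrichment factor > 1.5 (the enrichment
#' factor is observed / expected overlap). Gene sets are intersected with
#' the background before testing; the background is caller-supplied (a
#' natural default is the unique gene products of the post-detectability
#' assay list).
#'
#' @param query character vector of query genes (must be a subset of
#'   `background`).
#' @param background character vector: the enrichment universe.
#' @param gene_sets named list of character vectors (see [read_gmt()]).
#' @param p_cut,min_count,min_enrichment reporting filters (defaults 0.01,
#'   3, 1.5).
#' @return data.frame sorted by p: `term`, `term_size`, `overlap`, `p`,
#'   `enrichment_factor`, `passes_filters`, `genes` (comma-joined overlap).
#' @export
hypergeom_enrich <- function(query, background, gene_sets,
                             p_cut = 0.01, min_count = 3,
                             min_enrichment = 1.5) {
  query <- unique(query)
  background <- unique(background)
  offenders <- setdiff(query, background)
  if (length(offenders))
    stopf("query gene(s) absent from background: %s",
          paste(utils::head(offenders, 10), collapse = ", "))
  N <- length(background)
  nq <- length(query)
  rows <- lapply(names(gene_sets), function(term) {
    members <- intersect(gene_sets[[term]], background)
    K <- length(members)
    if (K == 0) return(NULL)
    hits <- intersect(members, query)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, N - K, nq, lower.tail = FALSE)
    expected <- K * nq / N
    ef <- if (expected > 0) k / expected else 0
    data.frame(term = term, term_size = K, overlap = k, p = p,
               enrichment_factor = ef,
               passes_filters = (p < p_cut) && (k >= min_count) &&
                 (ef > min_enrichment),
               genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(
    term = character(), term_size = integer(), overlap = integer(),
    p = numeric(), enrichment_factor = numeric(),
    passes_filters = logical(), genes = character()))
  out[order(out$p), , drop = FALSE]
}

#' Cohen's kappa between two term membership vectors
#'
#' Chance-corrected agreement of two binary membership indicators over a
#' common background universe; 1 for identical memberships, 0 when agreement
#' equals the chance expectation.
#'
#' @param set1,set2 character vectors of member genes.
#' @param background the universe over which membership is compared.
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa_sets <- function(set1, set2, background) {
  m1 <- background %in% set1
  m2 <- background %in% set2
  n <- length(background)
  po <- mean(m1 == m2)
  pe <- mean(m1) * mean(m2) + mean(!m1) * mean(!m2)
  if (abs(1 - pe) < .Machine$double.eps) return(1)
  (po - pe) / (1 - pe)
}

#' Cluster enriched terms by kappa similarity
#'
#' Pairwise Cohen's kappa between the membership vectors of the passing
#' terms is used as the similarity metric for average-linkage hierarchical
#' clustering; subtrees whose average within-subtree similarity exceeds the
#' threshold (default 0.3) form one cluster, and the most significant
#' (minimum-p) term represents each cluster. The cut on subtree-average
#' similarity approximates the reference tool's behavior; a cut on raw
#' pairwise kappa would fragment clusters more.
#'
#' @param enriched result of [hypergeom_enrich()] (only rows with
#'   `passes_filters` are clustered unless `all_terms = TRUE`).
#' @param gene_sets the gene-set list used for enrichment.
#' @param background the enrichment universe.
#' @param threshold kappa similarity above which terms share a cluster
#'   (default 0.3).
#' @param all_terms cluster all tested terms instead of only passing ones.
#' @return `enriched` restricted to the clustered terms, with added columns
#'   `cluster` and `is_cluster_representative`, ordered by p within cluster.
#' @export
kappa_cluster <- function(enriched, gene_sets, background, threshold = 0.3,
                          all_terms = FALSE) {
  keep <- if (all_terms) rep(TRUE, nrow(enriched)) else enriched$passes_filters
  terms <- enriched$term[keep]
  if (length(terms) == 0) stopf("no passing terms to cluster")
  out <- enriched[keep, , drop = FALSE]
  if (length(terms) == 1) {
    out$cluster <- 1L
    out$is_cluster_representative <- TRUE
    return(out)
  }
  memb <- vapply(terms, function(t)
    background %in% intersect(gene_sets[[t]], background),
    logical(length(background)))
  kk <- matrix(1, length(terms), length(terms),
               dimnames = list(terms, terms))
  for (i in seq_len(length(terms) - 1)) for (j in seq.int(i + 1, length(terms))) {
    kij <- cohen_kappa_sets(background[memb[, i]], background[memb[, j]],
                            background)
    kk[i, j] <- kk[j, i] <- kij
  }
  hc <- stats::hclust(stats::as.dist(1 - kk), method = "average")
  cl <- stats::cutree(hc, h = 1 - threshold)
  out$cluster <- unname(cl[out$term])
  out$is_cluster_representative <- FALSE
  for (g in unique(out$cluster)) {
    idx <- which(out$cluster == g)
    out$is_cluster_representative[idx[which.min(out$p[idx])]] <- TRUE
  }
  out[order(out$cluster, out$p), , drop = FALSE]
}
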