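#' Agglomerative clustering of a reserve distance matrix
#'
#' Average-linkage (UPGMA) hierarchical clustering cut at `k` groups. Reserves
#' are ordered lexicographically before clustering so that equal-distance
#' merges resolve to the lexicographically first candidate pair, making the
#' result deterministic and independent of input order.
#'
#' @param d A `flora_distance` matrix (symmetric, zero diagonal).
#' @param k Number of clusters, `2 <= k <= n - 1` (or `n`).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return A named integer label vector in the input reserve order.
#' @export
hcluster <- function(d, k, linkage = "average") {
  n <- nrow(d)
  if (is.null(rownames(d))) {
    abort("distance matrix must carry reserve ids as dimnames",
      class = "qdmflora_domain_error"
    )
  }
  if (k < 2 || k > n) {
    abort(paste0("k = ", k, " out of range [2, ", n, "]"),
      class = "qdmflora_domain_error"
    )
  }
  ord <- order(rownames(d))
  dd <- unclass(d)[ord, ord]
  hc <- hclust(as.dist(dd), method = linkage)
  labels <- cutree(hc, k = k)
  labels[rownames(d)]
}

#' Co-assignment consensus matrix from several labelings
#'
#' Entry (i, j) is the fraction of labelings in which reserves i and j share a
#' cluster label. With three hard per-level clusterings the entries can only
#' take the values 0, 1/3, 2/3, 1.
#'
#' @param labelings A list of named label vectors over an identical reserve set.
#' @return A matrix of class `flora_consensus` with attribute `n_views`.
#' @export
consensus_matrix <- function(labelings) {
  if (length(labelings) < 2) {
    abort("need at least two labelings", class = "qdmflora_domain_error")
  }
  ids <- sort(names(labelings[[1]]))
  for (l in labelings) {
    if (is.null(names(l)) || !identical(sort(names(l)), ids)) {
      abort("labelings must be named over identical reserve sets",
        class = "qdmflora_alignment_error"
      )
    }
  }
  acc <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (l in labelings) {
    l <- l[ids]
    acc <- acc + outer(l, l, `==`)
  }
  cm <- acc / length(labelings)
  diag(cm) <- 1
  structure(cm,
    class = c("flora_consensus", "matrix", "array"),
    n_views = length(labelings)
  )
}

#' Choose the number of clusters by mean silhouette width
#'
#' Clusters the distance matrix at every `k` in `k_range` and scores each
#' partition by the mean silhouette width computed on the same distances;
#' ties go to the smallest `k`. An all-equal (degenerate) distance matrix is
#' flagged with a warning and the smallest `k` returned.
#'
#' @inheritParams hcluster
#' @param k_range Integer vector of candidate cluster counts within `[2, n-1]`.
#' @return A list with elements `k` (the chosen count) and `diagnostics`
#'   (a tibble of `k`, `mean_silhouette`).
#' @export
select_k <- function(d, k_range = 2:10, linkage = "average") {
  n <- nrow(d)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0) {
    abort("k_range contains no feasible k in [2, n-1]", class = "qdmflora_domain_error")
  }
  off <- unclass(d)[lower.tri(d)]
  if (isTRUE(all(abs(off - off[1]) < 1e-12))) {
    warn("degenerate distance matrix (all pairwise distances equal); returning smallest k")
    return(list(
      k = min(k_range),
      diagnostics = tibble::tibble(k = k_range, mean_silhouette = NA_real_)
    ))
  }
  scores <- vapply(k_range, function(k) {
    labels <- hcluster(d, k, linkage)
    sil <- cluster::silhouette(as.integer(labels), dmatrix = unclass(d))
    mean(sil[, "sil_width"])
  }, numeric(1))
  diagnostics <- tibble::tibble(k = k_range, mean_silhouette = scores)
  list(k = k_range[which.max(scores)], diagnostics = diagnostics)
}

#' Multi-level consensus regionalization of reserves
#'
#' The full classification pipeline: each level's distance matrix is clustered
#' at its own silhouette-best `k`; the three hard labelings are fused into a
#' co-assignment consensus matrix; `1 - consensus` is clustered again, with
#' `k` selected on the consensus distances, to give the final regions. Region
#' ids are renumbered 1..k by the westernmost member longitude when reserve
#' metadata is supplied (west = region 1), otherwise by lexicographically
#' first member.
#'
#' @param levels Named list of `flora_distance` matrices over identical
#'   reserves, typically `list(species = ..., genus = ..., areal_type = ...)`.
#' @param k_range Candidate cluster counts for every silhouette selection.
#' @param linkage Agglomeration method.
#' @param meta Optional reserve metadata tibble (for longitude-based region
#'   numbering).
#' @return An object of class `flora_regions`: list with `labels` (named
#'   integer vector), `k`, `per_level_labels`, `per_level_k`, `consensus`,
#'   `k_diagnostics`.
#' @export
regionalize <- function(levels, k_range = 2:10, linkage = "average", meta = NULL) {
  if (length(levels) < 2) {
    abort("need at least two level distance matrices", class = "qdmflora_domain_error")
  }
  ids <- sort(rownames(levels[[1]]))
  for (d in levels) {
    if (!identical(sort(rownames(d)), ids)) {
      abort("level matrices must cover identical reserves",
        class = "qdmflora_alignment_error"
      )
    }
  }
  per_level <- purrr::map(levels, function(d) {
    sel <- select_k(d, k_range, linkage)
    list(k = sel$k, labels = hcluster(d, sel$k, linkage), diagnostics = sel$diagnostics)
  })
  cm <- consensus_matrix(purrr::map(per_level, "labels"))
  cd <- structure(1 - unclass(cm),
    class = c("flora_distance", "matrix", "array"),
    coefficient = "consensus", level = "consensus"
  )
  diag(cd) <- 0
  sel <- select_k(cd, k_range, linkage)
  labels <- hcluster(cd, sel$k, linkage)
  labels <- renumber_regions(labels, meta)
  structure(
    list(
      labels = labels,
      k = sel$k,
      per_level_labels = purrr::map(per_level, "labels"),
      per_level_k = purrr::map_int(per_level, "k"),
      consensus = cm,
      k_diagnostics = sel$diagnostics,
      per_level_diagnostics = purrr::map(per_level, "diagnostics"),
      linkage = linkage
    ),
    class = "flora_regions"
  )
}

# stable 1..k numbering: by westernmost member longitude if available,
# else by lexicographically first member id
renumber_regions <- function(labels, meta = NULL) {
  groups <- split(names(labels), labels)
  key <- if (!is.null(meta) && all(names(labels) %in% meta$reserve_id)) {
    lon <- setNames(meta$lon, meta$reserve_id)
    vapply(groups, function(g) min(lon[g]), numeric(1))
  } else {
    rank(vapply(groups, function(g) min(g), character(1)))
  }
  new_id <- setNames(rank(key, ties.method = "first"), names(groups))
  out <- as.integer(new_id[as.character(labels)])
  names(out) <- names(labels)
  out
}

#' @export
print.flora_regions <- function(x, ...) {
  cat("Consensus floristic regionalization\n")
  cat("  reserves:", length(x$labels), "  regions:", x$k, "\n")
  cat("  per-level k:", paste(names(x$per_level_k), x$per_level_k, sep = "=", collapse = ", "), "\n")
  sizes <- table(x$labels)
  cat("  region sizes:", paste(names(sizes), sizes, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.flora_regions <- function(x, ...) {
  per_level <- tibble::as_tibble(purrr::map(x$per_level_labels, ~ .x[names(x$labels)]))
  names(per_level) <- paste0("label_", names(per_level))
  dplyr::bind_cols(
    tibble::tibble(reserve_id = names(x$labels), region = unname(x$labels)),
    per_level
  )
}

#' @export
glance.flora_regions <- function(x, ...) {
  best <- x$k_diagnostics$mean_silhouette[x$k_diagnostics$k == x$k]
  tibble::tibble(
    k = x$k,
    n_reserves = length(x$labels),
    n_views = attr(x$consensus, "n_views"),
    mean_silhouette = if (length(best)) best else NA_real_,
    linkage = x$linkage
  )
}

#' Consensus-matrix heatmap of a regionalization
#' @param object A `flora_regions` object.
#' @param ... Unused.
#' @return A ggplot object: reserves ordered by region, co-assignment fraction as fill.
#' @export
autoplot.flora_regions <- function(object, ...) {
  ord <- names(sort(object$labels))
  df <- tibble::tibble(
    reserve_a = factor(rep(rownames(object$consensus), ncol(object$consensus)), levels = ord),
    reserve_b = factor(rep(colnames(object$consensus), each = nrow(object$consensus)), levels = ord),
    consensus = as.vector(unclass(object$consensus))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$reserve_a, .data$reserve_b, fill = .data$consensus)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "co-assignment",
      title = paste0("Consensus matrix (k = ", object$k, ")")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' Export the consensus dendrogram as a Newick tree
#'
#' @param regions A `flora_regions` object.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
region_tree_newick <- function(regions, path = NULL) {
  cd <- 1 - unclass(regions$consensus)
  diag(cd) <- 0
  ord <- order(rownames(cd))
  hc <- hclust(as.dist(cd[ord, ord]), method = regions$linkage)
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (is.null(path)) {
    return(txt)
  }
  writeLines(txt, path)
  invisible(txt)
}
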