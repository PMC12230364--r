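as_set <- function(x, arg) {
  x <- unique(as.character(x))
  if (length(x) == 0) {
    abort(paste0(arg, " is an empty set; empty reserves are a data defect"),
      class = "qdmflora_domain_error"
    )
  }
  x
}

#' Sørensen similarity of two incidence sets
#'
#' `2a / (2a + b + c)` where `a` is the number of shared taxa and `b`, `c` the
#' taxa unique to each set. Used at the species level of the regionalization.
#'
#' @param a,b Character vectors of taxon names (duplicates ignored).
#' @return Similarity in `[0, 1]`.
#' @export
sorensen <- function(a, b) {
  a <- as_set(a, "a")
  b <- as_set(b, "b")
  i <- length(intersect(a, b))
  2 * i / (length(a) + length(b))
}

#' Jaccard similarity of two incidence sets
#'
#' `a / (a + b + c)`. Used at the areal-type level of the regionalization.
#' @inheritParams sorensen
#' @return Similarity in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- as_set(a, "a")
  b <- as_set(b, "b")
  i <- length(intersect(a, b))
  i / (length(a) + length(b) - i)
}

#' Szymkiewicz–Simpson overlap similarity of two incidence sets
#'
#' `a / min(|A|, |B|)`: overlap relative to the poorer set, so a flora nested
#' in a richer one scores 1. Used at the genus level of the regionalization.
#' @inheritParams sorensen
#' @return Similarity in `[0, 1]`.
#' @export
szymkiewicz <- function(a, b) {
  a <- as_set(a, "a")
  b <- as_set(b, "b")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Pairwise reserve similarity from a presence matrix
#'
#' Computes the chosen coefficient between every pair of reserve incidence
#' rows via matrix cross-products; the diagonal is exactly 1 and the result
#' symmetric by construction.
#'
#' @param m A `flora_presence` logical matrix (reserves in rows).
#' @param coefficient One of `"sorensen"`, `"jaccard"`, `"szymkiewicz"`.
#' @return A numeric matrix of class `flora_similarity` with attributes
#'   `coefficient` and `level`.
#' @export
similarity_matrix <- function(m, coefficient = c("sorensen", "jaccard", "szymkiewicz")) {
  coefficient <- match.arg(coefficient)
  if (nrow(m) < 2) {
    abort("similarity needs at least two reserves", class = "qdmflora_domain_error")
  }
  sizes <- rowSums(m)
  if (any(sizes == 0)) {
    abort(
      paste0(
        "reserve(s) with empty taxon set: ",
        paste(rownames(m)[sizes == 0], collapse = ", ")
      ),
      class = "qdmflora_domain_error"
    )
  }
  mm <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
  a <- tcrossprod(mm) # pairwise intersection sizes
  ni <- matrix(sizes, nrow(m), nrow(m))
  nj <- t(ni)
  s <- switch(coefficient,
    sorensen = 2 * a / (ni + nj),
    jaccard = a / (ni + nj - a),
    szymkiewicz = a / pmin(ni, nj)
  )
  diag(s) <- 1
  s <- (s + t(s)) / 2
  structure(s,
    class = c("flora_similarity", "matrix", "array"),
    coefficient = coefficient, level = attr(m, "level")
  )
}

#' Convert a similarity matrix to a distance matrix
#'
#' `d = 1 - s`, preserving coefficient and level metadata. Note that
#' 1 - Szymkiewicz can violate the triangle inequality; downstream clustering
#' uses average linkage and never assumes metricity.
#'
#' @param s A `flora_similarity` matrix (or any symmetric matrix in `[0, 1]`
#'   with unit diagonal).
#' @return A matrix of class `flora_distance` with zero diagonal.
#' @export
to_distance <- function(s) {
  d <- 1 - unclass(s)
  diag(d) <- 0
  structure(d,
    class = c("flora_distance", "matrix", "array"),
    coefficient = attr(s, "coefficient"), level = attr(s, "level")
  )
}

#' @rdname to_distance
#' @param d A `flora_distance` matrix.
#' @export
to_similarity <- function(d) {
  s <- 1 - unclass(d)
  diag(s) <- 1
  structure(s,
    class = c("flora_similarity", "matrix", "array"),
    coefficient = attr(d, "coefficient"), level = attr(d, "level")
  )
}

#' @export
tidy.flora_similarity <- function(x, ...) {
  tibble::tibble(
    reserve_a = rep(rownames(x), ncol(x)),
    reserve_b = rep(colnames(x), each = nrow(x)),
    similarity = as.vector(unclass(x)),
    coefficient = attr(x, "coefficient") %||% NA_character_,
    level = attr(x, "level") %||% NA_character_
  ) |>
    dplyr::filter(.data$reserve_a < .data$reserve_b)
}

#' Write a similarity/distance matrix with a JSON sidecar recording provenance
#' @param m `flora_similarity` or `flora_distance` matrix.
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(m, path) {
  write_matrix_csv(m, path)
  jsonlite::write_json(
    list(
      coefficient = attr(m, "coefficient"),
      level = attr(m, "level"),
      kind = if (inherits(m, "flora_distance")) "distance" else "similarity",
      n_reserves = nrow(m)
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
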