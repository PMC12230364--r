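# Independent brute-force oracles and tiny data builders used across tests.

toy_occurrences <- function() {
  tibble::tribble(
    ~reserve_id, ~species, ~genus, ~family, ~areal_type, ~endemic, ~cultivated,
    "east", "Abies fargesii", "Abies", "Pinaceae", "AT08", FALSE, FALSE,
    "east", "Abies chensiensis", "Abies", "Pinaceae", "AT08", FALSE, FALSE,
    "east", "Davidia involucrata", "Davidia", "Nyssaceae", "AT15", TRUE, FALSE,
    "east", "Rosa banksiae", "Rosa", "Rosaceae", "AT08", FALSE, TRUE,
    "west", "Abies fargesii", "Abies", "Pinaceae", "AT08", FALSE, FALSE,
    "west", "Davidia involucrata", "Davidia", "Nyssaceae", "AT15", TRUE, FALSE,
    "west", "Kingdonia uniflora", "Kingdonia", "Circaeasteraceae", "AT15", TRUE, FALSE
  )
}

# set-arithmetic oracle for the three coefficients
oracle_coef <- function(a, b, which) {
  a <- unique(a)
  b <- unique(b)
  i <- sum(a %in% b)
  switch(which,
    sorensen = 2 * i / (2 * i + sum(!(a %in% b)) + sum(!(b %in% a))),
    jaccard = i / (i + sum(!(a %in% b)) + sum(!(b %in% a))),
    szymkiewicz = i / min(length(a), length(b))
  )
}

# elementwise pairwise-call oracle for similarity_matrix
oracle_similarity_matrix <- function(m, which) {
  fn <- switch(which, sorensen = sorensen, jaccard = jaccard, szymkiewicz = szymkiewicz)
  n <- nrow(m)
  out <- diag(n)
  dimnames(out) <- list(rownames(m), rownames(m))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        out[i, j] <- fn(colnames(m)[m[i, ]], colnames(m)[m[j, ]])
      }
    }
  }
  out
}

random_sets <- function(universe = letters, max_n = 20) {
  n <- sample.int(max_n, 1)
  sample(universe, min(n, length(universe)))
}

# one-way F via explicit projection matrices
oracle_anova_F <- function(groups) {
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  X <- model.matrix(~g)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  n <- length(y)
  J <- matrix(1 / n, n, n)
  ssb <- drop(t(y) %*% (H - J) %*% y)
  ssw <- drop(t(y) %*% (diag(n) - H) %*% y)
  dfb <- nlevels(g) - 1
  dfw <- n - nlevels(g)
  (ssb / dfb) / (ssw / dfw)
}

# tie-corrected Kruskal-Wallis H from midranks, written out longhand
oracle_kw_H <- function(groups) {
  y <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(y)
  n <- length(y)
  h <- 12 / (n * (n + 1)) * sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(y)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# spherical law of cosines distance, km, radius 6371.0088 km
oracle_slc_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  p1 <- lat1 * to_rad
  p2 <- lat2 * to_rad
  dl <- (lon2 - lon1) * to_rad
  6371.0088 * acos(pmin(1, pmax(-1, sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl))))
}

# planted block distance matrix with ids
block_dist <- function(sizes, within = 0.1, between = 0.9, ids = NULL) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  d <- matrix(between, n, n)
  d[outer(lab, lab, `==`)] <- within
  diag(d) <- 0
  if (is.null(ids)) ids <- sprintf("r%02d", seq_len(n))
  dimnames(d) <- list(ids, ids)
  structure(d, class = c("flora_distance", "matrix", "array"))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
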