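## The three neighborhood definitions of a mutation site and the Delaunay
## tessellation of the C-alpha point set (Bowyer-Watson incremental insertion
## with a ghost vertex for the hull and a deterministic jitter tie-break).

#' Sequence neighborhood of a site
#'
#' Residues within \code{window} positions upstream and downstream of the
#' site, truncated at the chain termini; the site itself is excluded.
#'
#' @param chainLength Number of residues in the chain.
#' @param site 0-based seq_index of the mutation site.
#' @param window Half-width in residues (default 11, i.e. 11 up + 11 down).
#' @return A \code{\linkS4class{Neighborhood}} of kind \code{"sequence"}.
#' @export
sequenceNeighborhood <- function(chainLength, site, window = 11) {
  stopifnot(site >= 0, site < chainLength)
  lo <- max(0L, as.integer(site - window))
  hi <- min(chainLength - 1L, as.integer(site + window))
  m <- setdiff(lo:hi, site)
  new("Neighborhood", kind = "sequence", site = as.integer(site),
      cutoff = as.numeric(window), members = as.integer(sort(m)))
}

#' Euclidean neighborhood of a site
#'
#' Residues whose C-alpha atom lies within \code{radius} Angstrom of the
#' site's C-alpha (inclusive boundary); the site itself is excluded.
#'
#' @param structure A \code{ProteinStructure}.
#' @param site 0-based seq_index.
#' @param radius Sphere radius in Angstrom (default 13).
#' @return A \code{Neighborhood} of kind \code{"euclidean"}.
#' @export
euclideanNeighborhood <- function(structure, site, radius = 13) {
  ca <- caCoords(structure)
  n <- nrow(ca)
  stopifnot(site >= 0, site < n)
  d <- sqrt(colSums((t(ca) - ca[site + 1L, ])^2))
  m <- which(d <= radius) - 1L
  m <- setdiff(m, site)
  new("Neighborhood", kind = "euclidean", site = as.integer(site),
      cutoff = radius, members = as.integer(sort(m)))
}

## ---- Delaunay tessellation -------------------------------------------------

## Deterministic symbolic-perturbation stand-in: a fixed-seed jitter scaled to
## the point cloud, applied identically wherever tie-breaking must agree.
.dt_jitter <- function(coords, magnitude = 1e-8) {
  scale <- max(apply(coords, 2, function(v) diff(range(v))), 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(20111202L)
  coords + matrix(runif(length(coords), -1, 1), nrow(coords)) * scale * magnitude
}

## vectorized triple product u . (v x w) where each argument is an m x 3 matrix
.triple <- function(u, v, w) {
  u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
  u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
  u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])
}

## orient3d for vertex-index matrix T (m x 4) against coordinates X
.orient_rows <- function(X, T) {
  a <- X[T[, 1], , drop = FALSE]
  .triple(X[T[, 2], , drop = FALSE] - a,
          X[T[, 3], , drop = FALSE] - a,
          X[T[, 4], , drop = FALSE] - a)
}

## insphere predicate, vectorized over tets: positive value means p strictly
## inside the circumsphere of a positively oriented tetrahedron
.insphere_rows <- function(X, T, p) {
  A <- sweep(X[T[, 1], , drop = FALSE], 2, p)
  B <- sweep(X[T[, 2], , drop = FALSE], 2, p)
  C <- sweep(X[T[, 3], , drop = FALSE], 2, p)
  D <- sweep(X[T[, 4], , drop = FALSE], 2, p)
  sa <- rowSums(A^2); sb <- rowSums(B^2); sc <- rowSums(C^2); sd2 <- rowSums(D^2)
  ## expansion of the 4x4 determinant along the squared-norm column, with the
  ## sign fixed so that (value * sign(orient3d)) > 0 means strictly inside
  sa * .triple(B, C, D) - sb * .triple(A, C, D) +
  sc * .triple(A, B, D) - sd2 * .triple(A, B, C)
}

#' Delaunay tessellation of C-alpha coordinates
#'
#' Standard 3-D Delaunay tessellation (every tetrahedron's circumsphere is
#' empty of other points), computed by incremental Bowyer-Watson insertion.
#' Cospherical ties are broken by a deterministic fixed-seed perturbation so
#' results are reproducible.
#'
#' @param ca n x 3 matrix of coordinates (Angstrom), row i = 0-based index
#'   i-1, or a \code{ProteinStructure}.
#' @param jitter Relative magnitude of the tie-breaking perturbation.
#' @return A \code{\linkS4class{Tessellation}}; tetrahedron vertices are
#'   0-based seq_index values.
#' @export
delaunayTessellation <- function(ca, jitter = 1e-8) {
  if (is(ca, "ProteinStructure")) ca <- caCoords(ca)
  ca <- as.matrix(ca)
  n <- nrow(ca)
  if (n < 4) stop("degenerate point set: need at least 4 points")
  sv <- svd(scale(ca, scale = FALSE))$d
  if (sv[3] < 1e-9 * max(sv[1], 1))
    stop("degenerate point set: points are collinear or coplanar")
  X <- .dt_jitter(ca, jitter)

  ## affinely independent seed tetrahedron
  seed <- 1L
  for (i in 2:n) if (sum((X[i, ] - X[seed, ])^2) > 1e-12) { seed <- c(seed, i); break }
  for (i in setdiff(seq_len(n), seed)) {
    u <- X[seed[2], ] - X[seed[1], ]; v <- X[i, ] - X[seed[1], ]
    if (sum((u[c(2,3,1)] * v[c(3,1,2)] - u[c(3,1,2)] * v[c(2,3,1)])^2) > 1e-18) {
      seed <- c(seed, i); break
    }
  }
  for (i in setdiff(seq_len(n), seed)) {
    if (abs(.orient_rows(X, matrix(c(seed, i), 1))) > 1e-12) { seed <- c(seed, i); break }
  }
  if (length(seed) < 4) stop("degenerate point set: points are collinear or coplanar")

  INF <- n + 1L
  t0 <- seed
  if (.orient_rows(X, matrix(t0, 1)) < 0) t0 <- t0[c(1, 2, 4, 3)]
  tets <- rbind(t0,
                c(t0[c(2, 3, 4)], INF), c(t0[c(1, 3, 4)], INF),
                c(t0[c(1, 2, 4)], INF), c(t0[c(1, 2, 3)], INF))
  rownames(tets) <- NULL
  alive <- rep(TRUE, nrow(tets))
  inserted <- seed

  for (pi in setdiff(seq_len(n), seed)) {
    p <- X[pi, ]
    centroid <- colMeans(X[inserted, , drop = FALSE])
    idx <- which(alive)
    Tm <- tets[idx, , drop = FALSE]
    ghost <- Tm[, 4] == INF
    conflict <- logical(length(idx))
    if (any(!ghost)) {
      Tr <- Tm[!ghost, , drop = FALSE]
      ins <- .insphere_rows(X, Tr, p)
      ori <- .orient_rows(X, Tr)
      conflict[!ghost] <- ins * sign(ori) > 0
    }
    if (any(ghost)) {
      Tg <- Tm[ghost, , drop = FALSE]
      a <- X[Tg[, 1], , drop = FALSE]
      nrm <- function(q) .triple(X[Tg[, 2], , drop = FALSE] - a,
                                 X[Tg[, 3], , drop = FALSE] - a,
                                 matrix(q, nrow(Tg), 3, byrow = TRUE) - a)
      conflict[ghost] <- nrm(p) * nrm(centroid) < 0
    }
    bad <- idx[conflict]
    if (!length(bad)) {
      ## numerically ambiguous: fall back to nearest real tet by circumsphere
      ## margin; with the jitter applied this is effectively unreachable
      stop("tessellation insertion failed; increase jitter")
    }
    ## boundary faces of the cavity
    faces <- do.call(rbind, lapply(bad, function(ti) {
      v <- tets[ti, ]
      rbind(v[-1], v[-2], v[-3], v[-4])
    }))
    faces_sorted <- t(apply(faces, 1, sort))
    key <- paste(faces_sorted[, 1], faces_sorted[, 2], faces_sorted[, 3])
    once <- key %in% names(which(table(key) == 1))
    bfaces <- faces_sorted[once, , drop = FALSE]
    alive[bad] <- FALSE
    newt <- cbind(bfaces, pi)
    ## keep INF in the last column
    hasInf <- newt[, 3] == INF
    if (any(hasInf)) newt[hasInf, ] <- cbind(newt[hasInf, 1:2, drop = FALSE],
                                             newt[hasInf, 4, drop = FALSE], INF)
    tets <- rbind(tets, newt)
    alive <- c(alive, rep(TRUE, nrow(newt)))
    inserted <- c(inserted, pi)
  }
  out <- tets[alive & tets[, 4] != INF, , drop = FALSE]
  out <- t(apply(out, 1, sort)) - 1L     # 0-based, sorted vertices
  out <- out[order(out[, 1], out[, 2], out[, 3], out[, 4]), , drop = FALSE]
  dimnames(out) <- NULL
  new("Tessellation", tetrahedra = out,
      dtType = factor(apply(out, 1, classifyDTType),
                      levels = c("I", "II", "III", "IV", "V")))
}

#' Backbone-connectivity class of a Delaunay tetrahedron
#'
#' Sorts the four chain positions and partitions them into maximal runs of
#' consecutive indices; the run-length multiset determines the class:
#' \{4\}=I, \{3,1\}=II, \{2,2\}=III, \{2,1,1\}=IV, \{1,1,1,1\}=V.
#'
#' @param tetra Four distinct chain positions (any order).
#' @return One of \code{"I".."V"}.
#' @export
classifyDTType <- function(tetra) {
  v <- sort(as.integer(tetra))
  stopifnot(length(v) == 4, !anyDuplicated(v))
  runs <- rle(cumsum(c(0L, diff(v) != 1L)))$lengths
  part <- paste(sort(runs, decreasing = TRUE), collapse = ",")
  switch(part, "4" = "I", "3,1" = "II", "2,2" = "III", "2,1,1" = "IV",
         "1,1,1,1" = "V")
}

#' Topological neighborhood of a site
#'
#' Residues that share a Delaunay tetrahedron (hence a Delaunay edge) with
#' the site and lie within \code{radius} Angstrom of it; always a subset of
#' the Euclidean neighborhood at the same radius.
#'
#' @param structure A \code{ProteinStructure}.
#' @param tessellation A \code{Tessellation} built on the same structure.
#' @param site 0-based seq_index.
#' @param radius Radius cap in Angstrom (default 13).
#' @return A \code{Neighborhood} of kind \code{"topological"}.
#' @export
topologicalNeighborhood <- function(structure, tessellation, site, radius = 13) {
  tt <- tetrahedra(tessellation)
  hit <- rowSums(tt == site) > 0
  partners <- setdiff(unique(as.vector(tt[hit, , drop = FALSE])), site)
  euc <- members(euclideanNeighborhood(structure, site, radius))
  m <- intersect(partners, euc)
  new("Neighborhood", kind = "topological", site = as.integer(site),
      cutoff = radius, members = as.integer(sort(m)))
}

#' Tetrahedra incident to a site, with their connectivity classes
#'
#' @param tessellation A \code{Tessellation}.
#' @param site 0-based seq_index.
#' @return list(count = number of incident tetrahedra,
#'   typeCounts = named integer vector over classes I..V).
#' @export
siteTetrahedra <- function(tessellation, site) {
  tt <- tetrahedra(tessellation)
  hit <- rowSums(tt == site) > 0
  list(count = sum(hit),
       typeCounts = table(factor(dtTypes(tessellation)[hit],
                                 levels = c("I", "II", "III", "IV", "V"))))
}

#' Export a neighborhood as a one-row TSV record
#'
#' @param x A \code{Neighborhood}.
#' @param path Output file; appends if it exists.
#' @export
writeNeighborhoodTSV <- function(x, path) {
  line <- paste(x@site, x@kind, x@cutoff,
                paste(x@members, collapse = ","), sep = "\t")
  cat(line, "\n", sep = "", file = path, append = file.exists(path))
  invisible(line)
}
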