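## Cutoff scan: performance of the 20-D residue-count feature of each
## neighborhood kind as a function of the distance cutoff.

#' Neighborhood cutoff scan with the 20-D residue-count classifier
#'
#' For each neighborhood kind and cutoff, computes the 20-dimensional vector
#' of residue counts by type for every mutation, fits a class-weighted
#' logistic classifier on those 20 features, and reports the cross-validated
#' AUC. Mirrors the protocol used to pick the sequence window (11 residues)
#' and the structural radius (13 Angstrom, where the Euclidean curve
#' plateaus while the topological curve is nearly flat from 7 Angstrom on).
#'
#' @param structure A \code{ProteinStructure}.
#' @param mutations Labeled mutation data.frame (author-numbered positions).
#' @param cutoffs Cutoff grid (residues or Angstrom; default 6:15).
#' @param kinds Subset of \code{c("sequence","euclidean","topological")}.
#' @param k CV folds (default 10).
#' @param seed Fold seed.
#' @return data.frame: kind, cutoff, auc, mean_size (mean neighborhood size).
#' @export
scanCutoffs <- function(structure, mutations, cutoffs = 6:15,
                        kinds = c("sequence", "euclidean", "topological"),
                        k = 10, seed = 1) {
  res <- residueData(structure)
  pos_idx <- match(mutations$position, res$author_number)
  stopifnot(!anyNA(pos_idx), all(res$aa[pos_idx] == mutations$wt))
  sites <- res$seq_index[pos_idx]
  y <- .as01(mutations$label)
  tess <- delaunayTessellation(structure)
  nres <- nrow(res)
  out <- list()
  for (kind in kinds) {
    for (ct in cutoffs) {
      usites <- unique(sites)
      counts <- matrix(0, length(usites), 20,
                       dimnames = list(NULL, paste0("count_", aaAlphabet())))
      sizes <- numeric(length(usites))
      for (i in seq_along(usites)) {
        nb <- switch(kind,
          sequence = sequenceNeighborhood(nres, usites[i], ct),
          euclidean = euclideanNeighborhood(structure, usites[i], ct),
          topological = topologicalNeighborhood(structure, tess, usites[i], ct))
        counts[i, ] <- residueCountsByType(structure, nb)
        sizes[i] <- length(members(nb))
      }
      X <- counts[match(sites, usites), , drop = FALSE]
      auc <- tryCatch({
        folds <- .stratified_folds(y, k, seed)
        probs <- numeric(length(y))
        for (f in seq_len(k)) {
          tr <- folds != f
          fit <- suppressWarnings(
            fitWeightedLogistic(X[tr, , drop = FALSE], y[tr],
                                classWeights(y[tr])))
          Xe <- X[!tr, names(fit$beta), drop = FALSE]
          probs[!tr] <- plogis(fit$beta0 + drop(Xe %*% fit$beta))
        }
        rocAuc(probs, y)$auc
      }, error = function(e) NA_real_)
      out[[length(out) + 1]] <- data.frame(kind = kind, cutoff = ct,
                                           auc = auc,
                                           mean_size = mean(sizes))
    }
  }
  do.call(rbind, out)
}
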