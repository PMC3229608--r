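## The feature registry: site features and per-neighborhood features of a
## single amino-acid substitution, assembled into a FeatureMatrix with an
## explicit missing-value mask.

AA_CLASSES <- c("nonpolar", "polar", "charged")

#' The feature registry
#'
#' Stable, ordered names of every feature the package computes: mutation-site
#' features followed by the sequence-, Euclidean- and topological-neighborhood
#' blocks. The order never depends on which inputs (alignments, annotations)
#' are available; unavailable features are masked, not dropped.
#'
#' @return Character vector of feature names.
#' @export
featureRegistryNames <- function() {
  site <- c(
    "ent_sub_site", "relent_sub_site", "ent_super_site", "relent_super_site",
    "hyd_wt", "hyd_mut", "hyd_delta",
    "vol_wt", "vol_mut", "vol_delta",
    "charge_wt", "charge_mut",
    "grantham",
    paste0("wt_", AA_CLASSES), paste0("mut_", AA_CLASSES),
    as.vector(outer(AA_CLASSES, AA_CLASSES,
                    function(a, b) paste0("sub_", a, "_", b))),
    "unusual_wt", "unusual_mut",
    "sasa_wt", "rsa_wt", "sasa_mut", "rsa_mut",
    "buried_charged_wt", "buried_charged_mut",
    "b_residue", "b_sidechain", "b_residue_norm", "b_sidechain_norm",
    "ss_helix", "ss_strand", "ss_coil",
    "helix_breaker", "turn_breaker", "disordered",
    "dist_func_seq", "dist_func_euclid",
    "ddg_popmusic", "ddg_foldx")
  common <- c("n_residues", paste0("count_", aaAlphabet()),
              "mean_hydropathy", "mean_volume", "mean_charge",
              "mean_rsa", "buriedness", "n_buried",
              "mean_b_residue", "mean_b_sidechain",
              "mean_b_residue_norm", "mean_b_sidechain_norm",
              "ent_sub", "relent_sub", "ent_super", "relent_super")
  c(site,
    paste0("seq_", c(common, "hydrophobic_moment")),
    paste0("euc_", c(common, "n_hbond", "n_saltbridge")),
    paste0("top_", c(common, "n_tetrahedra", paste0("dt_", c("I", "II", "III", "IV", "V")))))
}

#' Feature names by group
#'
#' Feature-set definitions used to build the paper-style models: mutation
#' site vs neighborhood, per-neighborhood blocks, and sequence-derivable vs
#' structure-requiring features.
#'
#' @param group One of \code{"site"}, \code{"neighborhood"},
#'   \code{"sequence_neighborhood"}, \code{"euclidean_neighborhood"},
#'   \code{"topological_neighborhood"}, \code{"sequence"},
#'   \code{"structure"}, \code{"all"}.
#' @return Character vector, a subset of \code{\link{featureRegistryNames}}.
#' @export
featureGroup <- function(group = c("all", "site", "neighborhood",
                                   "sequence_neighborhood",
                                   "euclidean_neighborhood",
                                   "topological_neighborhood",
                                   "sequence", "structure")) {
  group <- match.arg(group)
  reg <- featureRegistryNames()
  seqn <- grep("^seq_", reg, value = TRUE)
  eucn <- grep("^euc_", reg, value = TRUE)
  topn <- grep("^top_", reg, value = TRUE)
  site <- setdiff(reg, c(seqn, eucn, topn))
  ## features computable from sequence + alignment alone
  seq_site <- c("ent_sub_site", "relent_sub_site", "ent_super_site",
                "relent_super_site", "hyd_wt", "hyd_mut", "hyd_delta",
                "vol_wt", "vol_mut", "vol_delta", "charge_wt", "charge_mut",
                "grantham", paste0("wt_", AA_CLASSES), paste0("mut_", AA_CLASSES),
                as.vector(outer(AA_CLASSES, AA_CLASSES,
                                function(a, b) paste0("sub_", a, "_", b))),
                "unusual_wt", "unusual_mut", "disordered", "dist_func_seq")
  seq_nbr <- setdiff(seqn, c("seq_mean_rsa", "seq_buriedness", "seq_n_buried",
                             "seq_mean_b_residue", "seq_mean_b_sidechain",
                             "seq_mean_b_residue_norm", "seq_mean_b_sidechain_norm"))
  switch(group,
         all = reg,
         site = site,
         neighborhood = c(seqn, eucn, topn),
         sequence_neighborhood = seqn,
         euclidean_neighborhood = eucn,
         topological_neighborhood = topn,
         sequence = c(seq_site, seq_nbr),
         structure = setdiff(reg, c(seq_site, seq_nbr)))
}

#' Residue counts by type in a neighborhood
#'
#' The 20-dimensional vector of residue counts among the neighborhood
#' members, in fixed alphabetical one-letter order; always sums to the
#' number of members.
#'
#' @param structure A \code{ProteinStructure}.
#' @param neighborhood A \code{Neighborhood} built on the same structure.
#' @return Named integer vector of length 20.
#' @export
residueCountsByType <- function(structure, neighborhood) {
  aa <- structure@residues$aa[match(members(neighborhood),
                                    structure@residues$seq_index)]
  tab <- table(factor(aa, levels = aaAlphabet()))
  setNames(as.integer(tab), aaAlphabet())
}

#' Physicochemical site features of a substitution
#'
#' Hydrophobicity, volume and charge of the wild-type and mutant residues
#' and their differences, the Grantham distance, the three-class membership
#' indicators, the nine class-substitution indicators (exactly one equals 1),
#' and the unusual-residue indicators.
#'
#' @param wt,mut One-letter wild-type and mutant amino acids.
#' @param config A \code{\link{featureConfig}} list.
#' @return Named numeric vector.
#' @export
sitePhyschem <- function(wt, mut, config = featureConfig()) {
  stopifnot(wt %in% aaAlphabet(), mut %in% aaAlphabet())
  h <- config$hydrophobicity
  out <- c(hyd_wt = unname(h[wt]), hyd_mut = unname(h[mut]),
           hyd_delta = unname(h[mut] - h[wt]),
           vol_wt = unname(AA_VOLUME[wt]), vol_mut = unname(AA_VOLUME[mut]),
           vol_delta = unname(AA_VOLUME[mut] - AA_VOLUME[wt]),
           charge_wt = unname(AA_CHARGE[wt]), charge_mut = unname(AA_CHARGE[mut]),
           grantham = granthamDistance(wt, mut))
  for (cl in AA_CLASSES) out[paste0("wt_", cl)] <- as.numeric(AA_CLASS[wt] == cl)
  for (cl in AA_CLASSES) out[paste0("mut_", cl)] <- as.numeric(AA_CLASS[mut] == cl)
  for (a in AA_CLASSES) for (b in AA_CLASSES)
    out[paste0("sub_", a, "_", b)] <-
      as.numeric(AA_CLASS[wt] == a && AA_CLASS[mut] == b)
  out["unusual_wt"] <- as.numeric(wt %in% config$unusualResidues)
  out["unusual_mut"] <- as.numeric(mut %in% config$unusualResidues)
  out
}

#' Hydrophobic moment of a residue window
#'
#' \eqn{\mu = \lVert \sum_k h_k(\cos k\delta, \sin k\delta) \rVert} with turn
#' angle \eqn{\delta} (100 degrees for an alpha helix) and hydrophobicities
#' \eqn{h_k} along the window.
#'
#' @param h Numeric hydrophobicities in window order.
#' @param angle Turn angle per residue in degrees.
#' @return Moment magnitude; 0 for an empty window.
#' @export
hydrophobicMoment <- function(h, angle = 100) {
  if (!length(h)) return(0)
  k <- seq_along(h)
  d <- angle * pi / 180
  sqrt(sum(h * cos(k * d))^2 + sum(h * sin(k * d))^2)
}

#' Buried-and-charged indicators
#'
#' Whether the wild-type (respectively mutant) residue is simultaneously
#' buried (RSA at or below the threshold, inclusive) and in the charged
#' class.
#'
#' @param rsa_wt Relative solvent accessibility of the wild-type residue.
#' @param wt,mut One-letter codes.
#' @param threshold Buried-RSA cutoff (default 0.05).
#' @return Named numeric vector (buried_charged_wt, buried_charged_mut).
#' @export
buriedAndCharged <- function(rsa_wt, wt, mut, threshold = 0.05) {
  buried <- is.finite(rsa_wt) && rsa_wt <= threshold
  c(buried_charged_wt = as.numeric(buried && AA_CLASS[wt] == "charged"),
    buried_charged_mut = as.numeric(buried && AA_CLASS[mut] == "charged"))
}

#' Distance from the mutation site to the nearest functional site
#'
#' @param structure A \code{ProteinStructure}.
#' @param site 0-based seq_index of the mutation site.
#' @param functionalSites Annotated positions in author numbering (may be
#'   empty: returns NA).
#' @param mode \code{"sequence"} (residue separation) or \code{"euclidean"}
#'   (C-alpha distance in Angstrom).
#' @return Minimum distance, or NA when no sites are annotated.
#' @export
distanceToFunctionalSite <- function(structure, site, functionalSites,
                                     mode = c("sequence", "euclidean")) {
  mode <- match.arg(mode)
  if (!length(functionalSites)) return(NA_real_)
  res <- structure@residues
  idx <- res$seq_index[res$author_number %in% functionalSites]
  if (!length(idx)) return(NA_real_)
  if (mode == "sequence") return(min(abs(idx - site)))
  ca <- caCoords(structure)
  min(sqrt(colSums((t(ca[idx + 1L, , drop = FALSE]) - ca[site + 1L, ])^2)))
}

#' Hydrogen-bond and salt-bridge counts in a neighborhood
#'
#' Geometric interaction criteria over all-atom coordinates: an H-bond is an
#' N...O pair below \code{hbondMax} Angstrom between different residues; a
#' salt bridge is a side-chain nitrogen of Lys/Arg/His within
#' \code{saltBridgeMax} of a side-chain carboxyl oxygen of Asp/Glu. Pairs are
#' counted when both residues belong to the neighborhood or one of them is
#' the site.
#'
#' @param structure A \code{ProteinStructure} with all-atom records.
#' @param neighborhood A \code{Neighborhood}.
#' @param hbondMax,saltBridgeMax Distance cutoffs in Angstrom.
#' @return Named vector (n_hbond, n_saltbridge); NA for a C-alpha-only model.
#' @export
interactionCounts <- function(structure, neighborhood,
                              hbondMax = 3.5, saltBridgeMax = 4.0) {
  at <- structure@atoms
  if (!any(!(at$elety %in% c("CA", "CB"))))
    return(c(n_hbond = NA_real_, n_saltbridge = NA_real_))
  resset <- c(neighborhood@site, members(neighborhood))
  at <- at[at$seq_index %in% resset, , drop = FALSE]
  el <- toupper(substr(at$elesy, 1, 1))
  no <- which(el %in% c("N", "O"))
  n_hb <- 0L
  if (length(no) > 1) {
    sub <- at[no, ]; els <- el[no]
    d <- as.matrix(dist(sub[, c("x", "y", "z")]))
    for (i in seq_len(nrow(sub) - 1)) for (j in (i + 1):nrow(sub)) {
      if (sub$seq_index[i] != sub$seq_index[j] &&
          els[i] != els[j] && d[i, j] <= hbondMax)
        n_hb <- n_hb + 1L
    }
  }
  aa <- structure@residues$aa[match(at$seq_index, structure@residues$seq_index)]
  side <- !(at$elety %in% BACKBONE_ATOMS)
  pos <- which(side & el == "N" & aa %in% c("K", "R", "H"))
  neg <- which(side & el == "O" & aa %in% c("D", "E"))
  n_sb <- 0L
  for (i in pos) for (j in neg) {
    if (at$seq_index[i] != at$seq_index[j] &&
        sqrt(sum((at[i, c("x", "y", "z")] - at[j, c("x", "y", "z")])^2)) <=
        saltBridgeMax)
      n_sb <- n_sb + 1L
  }
  c(n_hbond = as.numeric(n_hb), n_saltbridge = as.numeric(n_sb))
}

#' Secondary-structure features of a mutation site
#'
#' Site-in-helix/strand/coil indicators, helix-breaker (mutating Pro or Gly
#' into a helix), turn-breaker (mutating a configured breaker residue into a
#' turn/coil), and the disordered-region indicator. All masked when no
#' secondary-structure annotation is provided.
#'
#' @param mut Mutant one-letter code.
#' @param site 0-based seq_index.
#' @param ss Secondary-structure string (one of H/E/C/T per residue) or NULL.
#' @param disorder Logical per-residue disorder mask or NULL.
#' @param config A \code{\link{featureConfig}} list.
#' @return Named numeric vector with NA where annotation is missing.
#' @export
secondaryStructureFeatures <- function(mut, site, ss = NULL, disorder = NULL,
                                       config = featureConfig()) {
  out <- c(ss_helix = NA_real_, ss_strand = NA_real_, ss_coil = NA_real_,
           helix_breaker = NA_real_, turn_breaker = NA_real_,
           disordered = NA_real_)
  if (!is.null(ss)) {
    s <- substr(ss, site + 1L, site + 1L)
    out["ss_helix"] <- as.numeric(s == "H")
    out["ss_strand"] <- as.numeric(s == "E")
    out["ss_coil"] <- as.numeric(s %in% c("C", "T"))
    out["helix_breaker"] <- as.numeric(s == "H" && mut %in% c("P", "G"))
    out["turn_breaker"] <- as.numeric(s %in% c("C", "T") &&
                                      mut %in% config$turnBreakers)
  }
  if (!is.null(disorder)) out["disordered"] <- as.numeric(disorder[site + 1L])
  out
}

#' Per-residue annotations
#'
#' Bundles optional external annotations consumed by \code{\link{featurize}}:
#' functional/ligand-binding positions, a secondary-structure string, a
#' disorder mask, and precomputed free-energy-change columns from two
#' sources (passed through unmodified).
#'
#' @param functionalSites Author-numbered positions (integer vector).
#' @param ss Secondary-structure string over the chain (H/E/C/T), or NULL.
#' @param disorder Logical vector over the chain, or NULL.
#' @param ddg data.frame with columns position (author numbering),
#'   ddg_popmusic, ddg_foldx; or NULL.
#' @return An annotation list.
#' @export
annotationSet <- function(functionalSites = integer(), ss = NULL,
                          disorder = NULL, ddg = NULL) {
  list(functionalSites = as.integer(functionalSites), ss = ss,
       disorder = disorder, ddg = ddg)
}

#' Aggregate features over a neighborhood
#'
#' Member count, 20-D residue counts, mean physicochemical values, mean RSA
#' and buriedness (1 - mean RSA) plus the buried-member count, mean raw and
#' normalized thermal factors, and mean conservation. Means of an empty
#' neighborhood are masked (the counts are zero).
#'
#' @param structure A \code{ProteinStructure}.
#' @param neighborhood A \code{Neighborhood}.
#' @param accessibility data.frame from \code{\link{computeAccessibility}}.
#' @param consSub,consSuper Optional conservation profiles
#'   (\code{\link{conservationProfile}}).
#' @param config A \code{\link{featureConfig}} list.
#' @return Named numeric vector (unprefixed common block).
#' @export
neighborhoodAggregates <- function(structure, neighborhood, accessibility,
                                   consSub = NULL, consSuper = NULL,
                                   config = featureConfig()) {
  res <- structure@residues
  m <- members(neighborhood)
  if (isTRUE(config$includeSite)) m <- sort(c(m, neighborhood@site))
  counts <- {
    aa <- res$aa[match(m, res$seq_index)]
    tab <- table(factor(aa, levels = aaAlphabet()))
    setNames(as.numeric(tab), paste0("count_", aaAlphabet()))
  }
  out <- c(n_residues = length(m), counts)
  if (!length(m)) {
    out[c("mean_hydropathy", "mean_volume", "mean_charge", "mean_rsa",
          "buriedness", "n_buried", "mean_b_residue", "mean_b_sidechain",
          "mean_b_residue_norm", "mean_b_sidechain_norm",
          "ent_sub", "relent_sub", "ent_super", "relent_super")] <- NA_real_
    return(out)
  }
  i <- match(m, res$seq_index)
  aa <- res$aa[i]
  h <- config$hydrophobicity
  out["mean_hydropathy"] <- mean(h[aa])
  out["mean_volume"] <- mean(AA_VOLUME[aa])
  out["mean_charge"] <- mean(AA_CHARGE[aa])
  rsa <- accessibility$rsa[match(m, accessibility$seq_index)]
  out["mean_rsa"] <- mean(rsa)
  out["buriedness"] <- 1 - mean(rsa)
  out["n_buried"] <- sum(rsa <= config$buriedThreshold)
  zscore <- function(v) {
    s <- sqrt(mean((v - mean(v))^2))
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  out["mean_b_residue"] <- mean(res$b_residue[i])
  out["mean_b_sidechain"] <- mean(res$b_sidechain[i])
  out["mean_b_residue_norm"] <- mean(zscore(res$b_residue)[i])
  out["mean_b_sidechain_norm"] <- mean(zscore(res$b_sidechain)[i])
  for (nm in c("sub", "super")) {
    prof <- if (nm == "sub") consSub else consSuper
    if (is.null(prof)) {
      out[paste0("ent_", nm)] <- NA_real_
      out[paste0("relent_", nm)] <- NA_real_
    } else {
      nc <- neighborhoodConservation(prof, neighborhood)
      out[paste0("ent_", nm)] <- nc$mean_entropy
      out[paste0("relent_", nm)] <- nc$mean_rel_entropy
    }
  }
  out
}

#' Read a mutation list from TSV
#'
#' Dialect: \code{protein_id  chain  position  wt  mut  [label]}, tab
#' separated with a header; \code{position} is author numbering.
#'
#' @param path TSV file.
#' @return data.frame with columns protein_id, chain, position, wt, mut,
#'   label (\code{"TS"}, \code{"neutral"} or \code{"unknown"}).
#' @export
readMutations <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "chain", "position", "wt", "mut")
  if (!all(need %in% names(d)))
    stop("mutation TSV must have columns: ", paste(need, collapse = ", "))
  if (is.null(d$label)) d$label <- "unknown"
  d$label[is.na(d$label) | d$label == ""] <- "unknown"
  stopifnot(all(d$label %in% c("TS", "neutral", "unknown")))
  if (any(d$wt == d$mut)) stop("wt and mut amino acids must differ")
  d
}

#' Compute the full feature matrix for a set of mutations
#'
#' Runs every registry feature for each mutation: conservation at the site
#' and averaged over the three neighborhoods, physicochemical and
#' substitution-class features, solvent accessibility (mutant values
#' approximated by renormalizing the wild-type area), thermal factors,
#' secondary-structure and functional-site annotation features, interaction
#' counts in the Euclidean neighborhood, and Delaunay-tetrahedron counts in
#' the topological neighborhood. Features whose inputs are absent are
#' masked, never invented.
#'
#' @param mutations data.frame as returned by \code{\link{readMutations}}.
#' @param structure A \code{ProteinStructure} for these mutations.
#' @param alignments Named list with optional elements \code{subfamily} and
#'   \code{superfamily}, each an \code{Alignment} mapped to the structure.
#' @param annotations An \code{\link{annotationSet}} or NULL.
#' @param config A \code{\link{featureConfig}} list.
#' @return A \code{\linkS4class{FeatureMatrix}}.
#' @export
featurize <- function(mutations, structure, alignments = list(),
                      annotations = NULL, config = featureConfig()) {
  res <- structure@residues
  reg <- featureRegistryNames()
  pos_idx <- match(mutations$position, res$author_number)
  bad <- which(is.na(pos_idx) | res$aa[pos_idx] != mutations$wt)
  if (length(bad)) {
    msgs <- vapply(bad, function(i) {
      found <- if (is.na(pos_idx[i])) "absent" else res$aa[pos_idx[i]]
      sprintf("row %d: position %s expected wt %s, structure has %s",
              i, mutations$position[i], mutations$wt[i], found)
    }, character(1))
    stop("wild-type mismatch against structure:\n",
         paste(msgs, collapse = "\n"))
  }
  acc <- computeAccessibility(structure)
  tess <- delaunayTessellation(structure)
  consSub <- if (!is.null(alignments$subfamily))
    conservationProfile(alignments$subfamily) else NULL
  consSuper <- if (!is.null(alignments$superfamily))
    conservationProfile(alignments$superfamily) else NULL
  if (is.null(annotations)) annotations <- annotationSet()
  n <- nrow(mutations)
  X <- matrix(NA_real_, n, length(reg), dimnames = list(NULL, reg))
  nbr_cache <- new.env(parent = emptyenv())

  for (r in seq_len(n)) {
    site <- res$seq_index[pos_idx[r]]
    wt <- mutations$wt[r]; mut <- mutations$mut[r]
    key <- as.character(site)
    if (is.null(nbr_cache[[key]])) {
      nbrs <- list(
        seq = sequenceNeighborhood(nrow(res), site, config$seqWindow),
        euc = euclideanNeighborhood(structure, site, config$euclideanRadius),
        top = topologicalNeighborhood(structure, tess, site,
                                      config$topologicalRadius))
      aggs <- lapply(nbrs, function(nb)
        neighborhoodAggregates(structure, nb, acc, consSub, consSuper, config))
      ## site-independent per-site extras
      hseq <- config$hydrophobicity[res$aa[match(members(nbrs$seq),
                                                 res$seq_index)]]
      extras <- list(
        seq_hydrophobic_moment = hydrophobicMoment(hseq, config$momentAngle),
        euc_inter = interactionCounts(structure, nbrs$euc,
                                      config$hbondMax, config$saltBridgeMax),
        top_tet = siteTetrahedra(tess, site))
      nbr_cache[[key]] <- list(nbrs = nbrs, aggs = aggs, extras = extras)
    }
    cache <- nbr_cache[[key]]
    v <- c()
    ## conservation at the site
    for (nm in c("sub", "super")) {
      prof <- if (nm == "sub") consSub else consSuper
      if (is.null(prof)) {
        v[paste0("ent_", nm, "_site")] <- NA_real_
        v[paste0("relent_", nm, "_site")] <- NA_real_
      } else {
        i <- match(site, prof$seq_index)
        v[paste0("ent_", nm, "_site")] <- prof$entropy[i]
        v[paste0("relent_", nm, "_site")] <- prof$rel_entropy[i]
      }
    }
    v <- c(v, sitePhyschem(wt, mut, config))
    rsa_wt <- acc$rsa[match(site, acc$seq_index)]
    sasa_wt <- acc$sasa[match(site, acc$seq_index)]
    v["sasa_wt"] <- sasa_wt
    v["rsa_wt"] <- rsa_wt
    ## mutant accessibility approximated from the wild-type area
    v["sasa_mut"] <- sasa_wt
    v["rsa_mut"] <- sasa_wt / unname(AA_MAX_ASA[mut])
    v <- c(v, buriedAndCharged(rsa_wt, wt, mut, config$buriedThreshold))
    tf <- thermalFactorFeatures(structure, site)
    v["b_residue"] <- tf$b_residue; v["b_sidechain"] <- tf$b_sidechain
    v["b_residue_norm"] <- tf$z_residue; v["b_sidechain_norm"] <- tf$z_sidechain
    v <- c(v, secondaryStructureFeatures(mut, site, annotations$ss,
                                         annotations$disorder, config))
    v["dist_func_seq"] <- distanceToFunctionalSite(
      structure, site, annotations$functionalSites, "sequence")
    v["dist_func_euclid"] <- distanceToFunctionalSite(
      structure, site, annotations$functionalSites, "euclidean")
    for (col in c("ddg_popmusic", "ddg_foldx")) {
      v[col] <- NA_real_
      if (!is.null(annotations$ddg) && col %in% names(annotations$ddg)) {
        sel <- annotations$ddg$position == mutations$position[r]
        if (!is.null(annotations$ddg$mut)) sel <- sel & annotations$ddg$mut == mut
        hit <- which(sel)
        if (length(hit)) v[col] <- annotations$ddg[[col]][hit[1]]
      }
    }
    for (p in c("seq", "euc", "top")) {
      agg <- cache$aggs[[p]]
      names(agg) <- paste0(p, "_", names(agg))
      v <- c(v, agg)
    }
    v["seq_hydrophobic_moment"] <- cache$extras$seq_hydrophobic_moment
    v["euc_n_hbond"] <- cache$extras$euc_inter["n_hbond"]
    v["euc_n_saltbridge"] <- cache$extras$euc_inter["n_saltbridge"]
    v["top_n_tetrahedra"] <- cache$extras$top_tet$count
    tc <- cache$extras$top_tet$typeCounts
    v[paste0("top_dt_", c("I", "II", "III", "IV", "V"))] <- as.numeric(tc)
    X[r, ] <- v[reg]
  }
  new("FeatureMatrix", values = X, mask = is.na(X),
      mutations = mutations, registry = reg)
}

#' Write a FeatureMatrix as TSV with a JSON sidecar
#'
#' The TSV holds the mutation keys and feature values (masked cells empty);
#' the sidecar records the registry and the mask encoding.
#'
#' @param fm A \code{FeatureMatrix}.
#' @param path Output TSV path; the sidecar is \code{<path>.json}.
#' @export
writeFeatureMatrix <- function(fm, path) {
  d <- cbind(fm@mutations, as.data.frame(fm@values))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(registry = fm@registry, n_mutations = nrow(fm@values),
         mask_encoding = "empty cell = masked",
         masked_cells = sum(fm@mask)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a FeatureMatrix written by writeFeatureMatrix
#'
#' @param path TSV path.
#' @return A \code{FeatureMatrix}.
#' @export
readFeatureMatrix <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  reg <- featureRegistryNames()
  stopifnot(all(reg %in% names(d)))
  X <- as.matrix(d[, reg, drop = FALSE])
  dimnames(X) <- list(NULL, reg)
  new("FeatureMatrix", values = X, mask = is.na(X),
      mutations = d[, setdiff(names(d), reg), drop = FALSE], registry = reg)
}

#' All-pairs Pearson correlation of features
#'
#' Correlation of feature values across mutations for every unordered pair
#' of registry features, as in a feature-independence analysis; features
#' with fewer than 3 complete observations or zero variance give NA.
#'
#' @param fm A \code{FeatureMatrix}.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
featureCorrelation <- function(fm) {
  X <- fm@values
  suppressWarnings(cm <- cor(X, use = "pairwise.complete.obs"))
  diag(cm) <- 1
  cm
}
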