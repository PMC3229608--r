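test_that("20-D residue counts sum to the neighborhood size", {
  rows <- data.frame(name = "CA", res3 = c("ALA", "ALA", "GLY", "TRP"),
                     resno = 1:4, x = (0:3) * 3.8, y = 0, z = 0, b = 10,
                     el = "C")
  s <- readStructure(make_pdb(rows), "A")
  nb <- new("Neighborhood", kind = "sequence", site = 3L, cutoff = 3,
            members = 0:2)
  v <- residueCountsByType(s, nb)
  expect_equal(unname(v["A"]), 2)
  expect_equal(unname(v["G"]), 1)
  expect_equal(sum(v), 3)
  nb0 <- new("Neighborhood", kind = "sequence", site = 0L, cutoff = 0,
             members = integer())
  expect_equal(sum(residueCountsByType(s, nb0)), 0)
  ## full-chain neighborhood reproduces the chain composition
  nb_full <- new("Neighborhood", kind = "sequence", site = 0L, cutoff = 99,
                 members = 1:3)
  cmp <- table(factor(c("A", "G", "W"), levels = aaAlphabet()))
  expect_equal(unname(residueCountsByType(s, nb_full)), as.integer(cmp))
})

test_that("physicochemical site features and class one-hots are consistent", {
  v <- sitePhyschem("L", "K")
  expect_equal(unname(v["wt_nonpolar"]), 1)
  expect_equal(unname(v["mut_charged"]), 1)
  expect_equal(unname(v["sub_nonpolar_charged"]), 1)
  subs <- v[grep("^sub_", names(v))]
  expect_length(subs, 9)
  expect_equal(sum(subs), 1)
  expect_equal(unname(v["hyd_delta"]), -3.9 - 3.8)
  ## Grantham values reproduce the published table
  expect_equal(granthamDistance("L", "I"), 5)
  expect_equal(granthamDistance("C", "W"), 215)
  expect_equal(granthamDistance("R", "L"), 102)
  expect_equal(granthamDistance("A", "A"), 0)
  expect_true(all(granthamDistance(c("A", "W"), c("G", "F")) ==
                  c(granthamDistance("A", "G"), granthamDistance("W", "F"))))
})

test_that("hydrophobic moment equals the direct trigonometric sum", {
  expect_equal(hydrophobicMoment(numeric(0)), 0)
  expect_equal(hydrophobicMoment(rep(0, 7)), 0)
  expect_equal(hydrophobicMoment(1), 1)
  h <- rep(c(1, -1), 9)
  d <- 100 * pi / 180
  z <- sum(h * exp(1i * seq_along(h) * d))
  expect_equal(hydrophobicMoment(h, 100), Mod(z))
  ## a perfectly amphipathic helix has a larger moment than a scrambled one
  hp <- rep(c(3, 3, -3, -3), 5)
  set.seed(1)
  expect_gt(hydrophobicMoment(hp[c(1, 5, 9, 13, 17, 2, 6, 10)], 100), 0)
})

test_that("buried-and-charged indicators honor the inclusive threshold", {
  expect_equal(unname(buriedAndCharged(0.01, "D", "A")), c(1, 0))
  expect_equal(unname(buriedAndCharged(0.50, "D", "K")), c(0, 0))
  expect_equal(unname(buriedAndCharged(0.05, "K", "R")), c(1, 1))  # boundary
})

test_that("distance to the nearest functional site works in both modes", {
  s <- readStructure(make_ca_line(50), "A")
  expect_equal(distanceToFunctionalSite(s, 11, c(10, 40), "sequence"), 2)
  expect_equal(distanceToFunctionalSite(s, 9, c(10, 40), "sequence"), 0)
  expect_true(is.na(distanceToFunctionalSite(s, 3, integer(), "sequence")))
  ## euclidean mode equals the brute-force minimum over annotated residues
  got <- distanceToFunctionalSite(s, 11, c(10, 40), "euclidean")
  ca <- caCoords(s)
  want <- min(sqrt(colSums((t(ca[c(10, 40), ]) - ca[12, ])^2)))
  expect_equal(got, want)
})

test_that("interaction counts follow the geometric criteria", {
  ## arranged pairs: one N...O at 3.4 (H-bond), one NZ...OE1 at 3.9 (bridge)
  rows <- data.frame(
    name = c("CA", "N",   "CA", "O",   "CA", "NZ",  "CA", "OE1"),
    res3 = c("ALA", "ALA", "SER", "SER", "LYS", "LYS", "GLU", "GLU"),
    resno = c(1, 1, 2, 2, 3, 3, 4, 4),
    x = c(0, 0,   3.8, 3.4,  20, 20,    24.5, 23.9),
    y = c(0, 1,   0,   1,    0,  1,     0,    1),
    z = 0, b = 10,
    el = c("C", "N", "C", "O", "C", "N", "C", "O"))
  s <- readStructure(make_pdb(rows), "A")
  nb <- new("Neighborhood", kind = "euclidean", site = 0L, cutoff = 50,
            members = 1:3)
  got <- interactionCounts(s, nb)
  ## N(0,1)...O(3.4,1) = 3.4 <= 3.5 counts; NZ(20,1)...OE1(23.9,1) = 3.9 > 3.5
  expect_equal(unname(got["n_hbond"]), 1)
  expect_equal(unname(got["n_saltbridge"]), 1)   # 3.9 <= 4.0
  ## C-alpha-only structures cannot support interaction counts
  s2 <- readStructure(make_ca_line(5), "A")
  nb2 <- new("Neighborhood", kind = "euclidean", site = 0L, cutoff = 50,
             members = 1:4)
  expect_true(all(is.na(interactionCounts(s2, nb2))))
})

test_that("secondary-structure features encode the breaker rules", {
  ss <- "HHHCC"
  v <- secondaryStructureFeatures("P", 1, ss, NULL)
  expect_equal(unname(v["helix_breaker"]), 1)
  expect_equal(unname(v["ss_helix"]), 1)
  v2 <- secondaryStructureFeatures("A", 1, ss, NULL)
  expect_equal(unname(v2["helix_breaker"]), 0)
  v3 <- secondaryStructureFeatures("P", 4, ss, NULL)
  expect_equal(unname(v3["turn_breaker"]), 1)
  v4 <- secondaryStructureFeatures("P", 1, NULL, NULL)
  expect_true(all(is.na(v4)))
})

test_that("neighborhood aggregates equal a direct recomputation", {
  sys <- fixture_system()
  st <- sys$structure
  acc <- computeAccessibility(st)
  prof <- conservationProfile(sys$alignment)
  nb <- euclideanNeighborhood(st, 20, 10)
  agg <- neighborhoodAggregates(st, nb, acc, consSub = prof)
  m <- members(nb)
  res <- residueData(st)
  i <- match(m, res$seq_index)
  expect_equal(unname(agg["n_residues"]), length(m))
  expect_equal(sum(agg[paste0("count_", aaAlphabet())]), length(m))
  expect_equal(unname(agg["mean_hydropathy"]),
               mean(tsmut:::KD_HYDROPATHY[res$aa[i]]))
  expect_equal(unname(agg["mean_rsa"]), mean(acc$rsa[i]))
  expect_equal(unname(agg["buriedness"]), 1 - mean(acc$rsa[i]))
  expect_equal(unname(agg["mean_b_residue"]), mean(res$b_residue[i]))
  expect_equal(unname(agg["ent_sub"]), mean(prof$entropy[i]))
  ## one-member neighborhood: aggregates equal that member's values
  nb1 <- new("Neighborhood", kind = "euclidean", site = 0L, cutoff = 1,
             members = 5L)
  agg1 <- neighborhoodAggregates(st, nb1, acc, consSub = prof)
  expect_equal(unname(agg1["mean_rsa"]), acc$rsa[6])
  expect_equal(unname(agg1["mean_b_sidechain"]), res$b_sidechain[6])
  ## empty neighborhood masks the means but keeps zero counts
  nb0 <- new("Neighborhood", kind = "euclidean", site = 0L, cutoff = 0,
             members = integer())
  agg0 <- neighborhoodAggregates(st, nb0, acc, consSub = prof)
  expect_equal(unname(agg0["n_residues"]), 0)
  expect_true(is.na(agg0["mean_rsa"]))
})

test_that("featurize validates wild types with an itemized report", {
  sys <- fixture_system()
  res <- residueData(sys$structure)
  muts <- data.frame(protein_id = "SYN", chain = "A",
                     position = res$author_number[c(3, 10)],
                     wt = c(res$aa[3], "W"), mut = c("A", "F"),
                     label = "unknown")
  if (muts$wt[2] == "W" && res$aa[10] == "W") muts$wt[2] <- "Y"
  if (muts$wt[1] == muts$mut[1]) muts$mut[1] <- "C"
  expect_error(featurize(muts, sys$structure), "row 2")
})

test_that("featurize is deterministic and satisfies the registry contracts", {
  sys <- fixture_system()
  res <- residueData(sys$structure)
  set.seed(31)
  idx <- sample(nrow(res), 12)
  muts <- data.frame(
    protein_id = "SYN", chain = "A", position = res$author_number[idx],
    wt = res$aa[idx],
    mut = vapply(res$aa[idx], function(a) sample(setdiff(aaAlphabet(), a), 1),
                 character(1)),
    label = rep(c("TS", "neutral"), 6))
  fm1 <- featurize(muts, sys$structure, list(subfamily = sys$alignment))
  fm2 <- featurize(muts, sys$structure, list(subfamily = sys$alignment))
  expect_identical(featureValues(fm1), featureValues(fm2))
  expect_equal(featureRegistry(fm1), featureRegistryNames())
  X <- featureValues(fm1)
  ## the three 20-D count identities per mutation
  for (p in c("seq", "euc", "top"))
    expect_equal(unname(rowSums(X[, paste0(p, "_count_", aaAlphabet())])),
                 unname(X[, paste0(p, "_n_residues")]))
  ## exactly one substitution-class indicator fires
  expect_equal(unname(rowSums(X[, grep("^sub_", colnames(X))])), rep(1, 12))
  ## masked cells are exactly the features whose inputs were absent
  msk <- featureMask(fm1)
  absent <- c("ent_super_site", "relent_super_site", "ss_helix", "ss_strand",
              "ss_coil", "helix_breaker", "turn_breaker", "disordered",
              "dist_func_seq", "dist_func_euclid", "ddg_popmusic", "ddg_foldx",
              "seq_ent_super", "seq_relent_super", "euc_ent_super",
              "euc_relent_super", "top_ent_super", "top_relent_super")
  expect_true(all(msk[, absent]))
  expect_false(any(msk[, setdiff(colnames(X), absent)]))
  ## annotations unlock the annotation-driven features
  ann <- annotationSet(functionalSites = res$author_number[5],
                       ss = paste(rep("H", nrow(res)), collapse = ""),
                       disorder = rep(FALSE, nrow(res)))
  fm3 <- featurize(muts, sys$structure, list(subfamily = sys$alignment), ann)
  expect_false(any(featureMask(fm3)[, c("ss_helix", "dist_func_seq",
                                        "disordered")]))
})

test_that("feature matrices round-trip through TSV", {
  sys <- fixture_system()
  res <- residueData(sys$structure)
  muts <- data.frame(protein_id = "SYN", chain = "A",
                     position = res$author_number[4], wt = res$aa[4],
                     mut = setdiff(aaAlphabet(), res$aa[4])[1],
                     label = "TS")
  fm <- featurize(muts, sys$structure, list(subfamily = sys$alignment))
  tf <- tempfile(fileext = ".tsv")
  writeFeatureMatrix(fm, tf)
  fm2 <- readFeatureMatrix(tf)
  expect_equal(featureValues(fm2), featureValues(fm), tolerance = 1e-9)
  expect_true(file.exists(paste0(tf, ".json")))
})

test_that("feature correlation matrix is symmetric with unit diagonal", {
  set.seed(8)
  X <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  fm <- new("FeatureMatrix", values = X, mask = is.na(X),
            mutations = data.frame(id = 1:40), registry = colnames(X))
  cm <- featureCorrelation(fm)
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, 6))
  expect_equal(cm["f1", "f2"], cor(X[, 1], X[, 2]))
})
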