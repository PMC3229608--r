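## PDB parsing (via bio3d) into the single-chain ProteinStructure model,
## PDB writing for round-trips, Shrake-Rupley solvent accessibility, and
## thermal-factor features.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

.as_pdb_file <- function(pdb) {
  ## accept a file path, a single string with newlines, or a character vector
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) return(pdb)
  tf <- tempfile(fileext = ".pdb")
  writeLines(if (length(pdb) == 1) strsplit(pdb, "\n", fixed = TRUE)[[1]] else pdb, tf)
  tf
}

.parse_resolution <- function(path) {
  ln <- grep("^REMARK   2 RESOLUTION", readLines(path, warn = FALSE), value = TRUE)
  if (!length(ln)) return(NULL)
  m <- regmatches(ln[1], regexpr("[0-9]+\\.[0-9]+", ln[1]))
  if (length(m)) as.numeric(m) else NULL
}

#' Read one chain of a PDB file into a ProteinStructure
#'
#' Parses ATOM records of the requested chain, keeps standard amino acids
#' that possess a C-alpha atom (others are dropped with a warning), keeps the
#' first occurrence of alternate locations, and assigns a contiguous 0-based
#' \code{seq_index} following author residue numbering (insertion codes
#' ordered after their base number). HETATM records are ignored here; see
#' \code{\link{readLigandAtoms}}.
#'
#' @param pdb Path to a PDB file, or PDB text (single string or lines).
#' @param chain Chain identifier, e.g. \code{"A"}.
#' @param sourceId Optional label; defaults to \code{"<file>_<chain>"}.
#' @return A \code{\linkS4class{ProteinStructure}}.
#' @examples
#' s <- generateStructure(syntheticSpec(nResidues = 30, seed = 1))
#' nResidues(s)
#' @export
readStructure <- function(pdb, chain, sourceId = NULL) {
  path <- .as_pdb_file(pdb)
  p <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE,
                                        hex = TRUE))
  at <- p$atom
  at <- at[at$type == "ATOM" & !is.na(at$chain) & at$chain == chain, ,
           drop = FALSE]
  if (!nrow(at)) stop("chain not found: ", chain)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at <- at[at$resid %in% names(AA3TO1), , drop = FALSE]
  ## first altloc occurrence per (residue, atom name), in file order
  key <- paste(at$resno, at$insert, at$elety, sep = "\r")
  at <- at[!duplicated(key), , drop = FALSE]

  ## residue order: author number, insertion codes after the base number
  rkey <- paste(at$resno, at$insert, sep = "\r")
  rids <- unique(rkey)
  rtab <- do.call(rbind, strsplit(rids, "\r"))
  rnum <- as.integer(rtab[, 1])
  rins <- if (ncol(rtab) > 1) rtab[, 2] else rep("", length(rids))
  rins[is.na(rins)] <- ""
  ord <- order(rnum, match(rins, c("", LETTERS)))
  rids <- rids[ord]; rnum <- rnum[ord]; rins <- rins[ord]

  keep <- logical(length(rids))
  res_rows <- vector("list", length(rids))
  atom_rows <- vector("list", length(rids))
  dropped <- character()
  for (i in seq_along(rids)) {
    ai <- at[rkey == rids[i], , drop = FALSE]
    ca <- which(ai$elety == "CA")
    if (!length(ca)) {
      dropped <- c(dropped, paste0(ai$resid[1], rnum[i], rins[i]))
      next
    }
    keep[i] <- TRUE
    side <- !(ai$elety %in% BACKBONE_ATOMS)
    res_rows[[i]] <- data.frame(
      chain = chain, author_number = rnum[i], insert = rins[i],
      aa = unname(AA3TO1[ai$resid[1]]),
      ca_x = ai$x[ca[1]], ca_y = ai$y[ca[1]], ca_z = ai$z[ca[1]],
      b_residue = mean(ai$b),
      b_sidechain = if (any(side)) mean(ai$b[side]) else mean(ai$b),
      stringsAsFactors = FALSE)
    atom_rows[[i]] <- data.frame(
      elety = ai$elety, elesy = ifelse(is.na(ai$elesy) | ai$elesy == "",
                                       substr(gsub("[0-9]", "", ai$elety), 1, 1),
                                       ai$elesy),
      x = ai$x, y = ai$y, z = ai$z, b = ai$b, stringsAsFactors = FALSE)
  }
  if (!any(keep)) stop("empty chain: no residue with a C-alpha atom")
  if (length(dropped))
    warning("dropped ", length(dropped), " residue(s) lacking C-alpha: ",
            paste(dropped, collapse = ", "))
  res <- do.call(rbind, res_rows[keep])
  res$seq_index <- 0:(nrow(res) - 1L)
  res <- res[, c("seq_index", "chain", "author_number", "insert", "aa",
                 "ca_x", "ca_y", "ca_z", "b_residue", "b_sidechain")]
  rownames(res) <- NULL
  atoms <- do.call(rbind, Map(function(d, si) { d$seq_index <- si; d },
                              atom_rows[keep], res$seq_index))
  atoms <- atoms[, c("seq_index", "elety", "elesy", "x", "y", "z", "b")]
  rownames(atoms) <- NULL
  if (is.null(sourceId)) {
    base <- if (length(pdb) == 1 && !grepl("\n", pdb))
      tools::file_path_sans_ext(basename(pdb)) else "structure"
    sourceId <- paste0(base, "_", chain)
  }
  new("ProteinStructure", residues = res, atoms = atoms,
      sourceId = sourceId, resolution = .parse_resolution(path))
}

#' Read ligand heavy atoms from a PDB file
#'
#' Extracts HETATM heavy-atom coordinates (water excluded), for use as
#' functional-site anchors in distance features.
#'
#' @inheritParams readStructure
#' @param chain Optional chain filter; NULL keeps all chains.
#' @return data.frame with columns resid, chain, resno, elety, x, y, z.
#' @export
readLigandAtoms <- function(pdb, chain = NULL) {
  path <- .as_pdb_file(pdb)
  p <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE,
                                        hex = TRUE))
  at <- p$atom
  at <- at[at$type == "HETATM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]
  if (!is.null(chain)) at <- at[!is.na(at$chain) & at$chain == chain, ,
                                drop = FALSE]
  at <- at[is.na(at$elesy) | at$elesy != "H", , drop = FALSE]
  data.frame(resid = at$resid, chain = at$chain, resno = at$resno,
             elety = at$elety, x = at$x, y = at$y, z = at$z,
             stringsAsFactors = FALSE)
}

AA1TO3 <- setNames(names(AA3TO1), unname(AA3TO1))

#' Write a ProteinStructure back to PDB text
#'
#' Emits fixed-format ATOM records for the retained residues; re-reading the
#' text with \code{\link{readStructure}} reproduces the structure.
#'
#' @param structure A \code{ProteinStructure}.
#' @param path Optional output file; if NULL the text lines are returned.
#' @return Invisibly (or visibly when \code{path} is NULL) the PDB lines.
#' @export
writeStructurePDB <- function(structure, path = NULL) {
  res <- structure@residues
  at <- structure@atoms
  lines <- character(nrow(at))
  for (i in seq_len(nrow(at))) {
    r <- res[at$seq_index[i] + 1L, ]
    name <- at$elety[i]
    name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
    lines[i] <- sprintf(
      "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, name4, AA1TO3[r$aa], r$chain, r$author_number,
      ifelse(r$insert == "", " ", r$insert),
      at$x[i], at$y[i], at$z[i], 1.0, at$b[i], at$elesy[i])
  }
  out <- c(lines, "END")
  if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
  out
}

## Deterministic unit sphere point set (generalized spiral); no RNG involved.
.sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  phi <- k * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

.vdw_radius <- function(elesy) {
  r <- VDW_RADII[toupper(substr(elesy, 1, 1))]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

#' Shrake-Rupley solvent accessibility
#'
#' Numerical solvent-accessible surface area per residue, using a fixed
#' deterministic point set on each atom sphere. Relative accessibility (RSA)
#' divides by a bundled maximum-ASA table per residue type; mutant-residue
#' RSA can be approximated by renormalizing the wild-type area with the
#' mutant's maximum ASA.
#'
#' @param structure A \code{ProteinStructure} with all-atom coordinates.
#' @param probeRadius Solvent probe radius in Angstrom (default 1.4).
#' @param nPoints Sphere points per atom (default 960).
#' @param maxAsa Named max-ASA table used for RSA normalization.
#' @return data.frame: seq_index, sasa (A^2), rsa.
#' @export
computeAccessibility <- function(structure, probeRadius = 1.4, nPoints = 960,
                                 maxAsa = AA_MAX_ASA) {
  at <- structure@atoms
  if (nrow(at) < 1) stop("structure has no atoms")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- .vdw_radius(at$elesy) + probeRadius
  sp <- .sphere_points(nPoints)
  n <- nrow(at)
  sasa_atom <- numeric(n)
  ## neighbor prefilter on a coarse grid of pairwise distances
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(d < rad[i] + rad & seq_len(n) != i)
    pts <- sp * rad[i]
    pts <- sweep(pts, 2, xyz[i, ], "+")
    acc <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (pts[acc, 1] - xyz[j, 1])^2 + (pts[acc, 2] - xyz[j, 2])^2 +
             (pts[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dj2 >= rad[j]^2
    }
    sasa_atom[i] <- 4 * pi * rad[i]^2 * sum(acc) / nPoints
  }
  res <- structure@residues
  sasa <- vapply(res$seq_index,
                 function(si) sum(sasa_atom[at$seq_index == si]), numeric(1))
  data.frame(seq_index = res$seq_index, sasa = sasa,
             rsa = sasa / unname(maxAsa[res$aa]))
}

#' Thermal-factor features of a residue
#'
#' Residue and side-chain mean B-factors plus their z-scores over the whole
#' chain. Z-scores use the population standard deviation; a constant-B
#' structure yields z = 0. For Gly the side-chain value equals the residue
#' value.
#'
#' @param structure A \code{ProteinStructure}.
#' @param pos 0-based \code{seq_index} of the residue.
#' @return Named list: b_residue, b_sidechain, z_residue, z_sidechain.
#' @export
thermalFactorFeatures <- function(structure, pos) {
  res <- structure@residues
  stopifnot(pos %in% res$seq_index)
  zscore <- function(v) {
    s <- sqrt(mean((v - mean(v))^2))
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  zr <- zscore(res$b_residue)
  zs <- zscore(res$b_sidechain)
  i <- match(pos, res$seq_index)
  list(b_residue = res$b_residue[i], b_sidechain = res$b_sidechain[i],
       z_residue = zr[i], z_sidechain = zs[i])
}
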