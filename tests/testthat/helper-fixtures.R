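## Fixture builders and independent oracles shared across test files.

## Hand-written PDB text from an atom table.
make_pdb <- function(rows, chain = "A") {
  lines <- vapply(seq_len(nrow(rows)), function(i) sprintf(
    "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    i, sprintf(" %-3s", rows$name[i]), rows$res3[i], chain, rows$resno[i],
    if (!is.null(rows$insert)) rows$insert[i] else " ",
    rows$x[i], rows$y[i], rows$z[i],
    if (!is.null(rows$occ)) rows$occ[i] else 1.0, rows$b[i], rows$el[i]),
    character(1))
  ## optional altloc column (column 17)
  if (!is.null(rows$alt))
    lines <- vapply(seq_along(lines), function(i) {
      substr(lines[i], 17, 17) <- rows$alt[i]; lines[i]
    }, character(1))
  c(lines, "END")
}

## n-residue poly-AA chain of CA atoms along x (spacing in Angstrom)
make_ca_line <- function(n, aa3 = "ALA", spacing = 3.8, b = 20) {
  make_pdb(data.frame(name = "CA", res3 = aa3, resno = seq_len(n),
                      x = (seq_len(n) - 1) * spacing, y = 0, z = 0,
                      b = rep_len(b, n), el = "C"))
}

## brute-force Delaunay: keep every 4-subset whose circumsphere is empty
brute_delaunay <- function(X) {
  n <- nrow(X)
  combs <- utils::combn(n, 4)
  keep <- list()
  for (k in seq_len(ncol(combs))) {
    id <- combs[, k]
    A <- X[id, ]
    M <- 2 * sweep(A[2:4, ], 2, A[1, ])
    rhs <- rowSums(A[2:4, ]^2) - sum(A[1, ]^2)
    cc <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(cc)) next
    r2 <- sum((A[1, ] - cc)^2)
    d2 <- colSums((t(X) - cc)^2)
    if (all(d2[-id] > r2 * (1 + 1e-10))) keep[[length(keep) + 1]] <- sort(id)
  }
  m <- do.call(rbind, keep) - 1L
  m[order(m[, 1], m[, 2], m[, 3], m[, 4]), , drop = FALSE]
}

## brute-force AUC: pairwise comparison with ties counted one half
auc_pairs <- function(probs, y) {
  pos <- probs[y == 1]; neg <- probs[y == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

## Lasso KKT check on the scaled design used inside the LARS path
kkt_violation <- function(Xw, yw, beta) {
  r <- drop(crossprod(Xw, yw - Xw %*% beta))
  act <- which(abs(beta) > 1e-12)
  if (!length(act)) return(0)
  lam <- max(abs(r))
  v <- max(abs(abs(r[act]) - lam))                       # active ties
  ## sign agreement (meaningless at the unpenalized end where r ~ 0)
  sg <- which(abs(r[act]) > 1e-8)
  sgn <- if (length(sg)) max(abs(sign(r[act][sg]) - sign(beta[act][sg]))) else 0
  inact <- setdiff(seq_along(beta), act)
  v2 <- if (length(inact)) max(0, max(abs(r[inact])) - lam) else 0
  max(v, v2) + (sgn > 0) * 1
}

## deterministic small structure + alignment + cohort for reuse
fixture_system <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- syntheticSpec(nResidues = 60, seed = 11)
      s <- generateStructure(spec)
      aln <- generateAlignment(spec, s)
      cache <<- list(spec = spec, structure = s, alignment = aln)
    }
    cache
  }
})
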