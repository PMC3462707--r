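# Structural similarity and accuracy measures.
#
# All superposition-based scores share one search scaffold: rigid fits seeded
# from gapless aligned fragments, refined by iterating "superpose on the
# currently well-fitting residues, rescore".  TM-score and GDT-TS report the
# maximum over all candidate superpositions.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation + translation mapping `mobile` onto `fixed`,
#' reflection excluded.  When `subset` is given the fit and the reported RMSD
#' use only those rows; the returned transform still applies to any
#' coordinates.
#'
#' @param mobile,fixed N x 3 coordinate matrices (Angstroms), N >= 3.
#' @param subset optional integer row indices to fit on.
#' @return object of class `tbm_superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd` (Angstroms, over the fit subset).
#' @export
kabsch <- function(mobile, fixed, subset = NULL) {
  mobile <- as.matrix(mobile); fixed <- as.matrix(fixed)
  if (!all(dim(mobile) == dim(fixed))) stop("coordinate sets differ in shape")
  if (is.null(subset)) subset <- seq_len(nrow(mobile))
  P <- mobile[subset, , drop = FALSE]
  Q <- fixed[subset, , drop = FALSE]
  if (nrow(P) < 3) stop("need at least 3 points to superpose, got ", nrow(P))
  if (any(!is.finite(P)) || any(!is.finite(Q))) stop("non-finite coordinates")
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  H <- crossprod(Pc, Qc)                  # 3x3 cross-covariance
  s <- svd(H)
  # collinear point sets leave the rotation about the line undetermined and
  # invite a silent reflection; refuse instead
  scale2 <- sum(Pc^2) + sum(Qc^2)
  if (scale2 > 0 && s$d[2] / max(s$d[1], .Machine$double.eps) < 1e-9 &&
      s$d[2] < 1e-9 * sqrt(scale2))
    stop("degenerate (collinear) point set: superposition not unique")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(qc - R %*% pc)
  moved <- sweep(Pc %*% t(R), 2, qc, `+`)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "tbm_superposition")
}

#' Apply a superposition to coordinates
#' @param sp a `tbm_superposition`.
#' @param coords N x 3 matrix.
#' @export
apply_superposition <- function(sp, coords) {
  sweep(as.matrix(coords) %*% t(sp$rotation), 2, sp$translation, `+`)
}

#' @export
print.tbm_superposition <- function(x, ...) {
  cat(sprintf("<tbm_superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' TM-score distance scale d0
#'
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8` for the reference length `L`, floored at
#' 0.5 A (the cube-root form turns negative for short chains; for L <= 15 the
#' floor is used directly).
#'
#' @param l_ref reference length (residues).
#' @export
tm_d0 <- function(l_ref) {
  if (l_ref <= 15) return(0.5)
  max(0.5, 1.24 * (l_ref - 15)^(1/3) - 1.8)
}

# Gapless runs of aligned pairs: maximal index runs where both position
# columns advance by exactly 1.
aligned_runs <- function(pairs) {
  n <- nrow(pairs)
  if (n == 0) return(list())
  brk <- which(diff(pairs[, 1]) != 1 | diff(pairs[, 2]) != 1)
  starts <- c(1, brk + 1); ends <- c(brk, n)
  Map(function(s, e) s:e, starts, ends)
}

# Candidate fit subsets: the full set plus sliding fragments of length
# n, n/2, n/4 (>= 4 residues) restricted to gapless runs.  At toy sizes
# (n <= 12) every minimal 4-point fit subset is enumerated as well, making
# the search effectively exhaustive there.
seed_subsets <- function(pairs) {
  n <- nrow(pairs)
  seeds <- list(seq_len(n))
  if (n >= 4 && n <= 12)
    seeds <- c(seeds, utils::combn(n, 4L, simplify = FALSE))
  lens <- unique(pmax(4L, c(n, n %/% 2L, n %/% 4L)))
  for (run in aligned_runs(pairs)) {
    for (len in lens) {
      if (len > length(run) || len < 4L) next
      step <- max(1L, len %/% 2L)
      for (s in unique(c(seq(1L, length(run) - len + 1L, by = step),
                         length(run) - len + 1L)))
        seeds[[length(seeds) + 1L]] <- run[s:(s + len - 1L)]
    }
  }
  unique(seeds)
}

# Shared iterative search: from each seed subset, superpose, select residues
# within `cut`, refit, repeat to convergence; score every visited fit with
# `score_fun(d)` over all pairs and keep the maximum.
superposition_search <- function(X, Y, cut, score_fun, max_iter = 20L) {
  n <- nrow(X)
  best <- -Inf
  for (seed in seed_subsets(cbind(seq_len(n), seq_len(n)))) {
    sel <- seed
    prev <- NULL
    for (iter in seq_len(max_iter)) {
      if (length(sel) < 3) break
      sp <- tryCatch(kabsch(X, Y, subset = sel), error = function(e) NULL)
      if (is.null(sp)) break
      d <- sqrt(rowSums((apply_superposition(sp, X) - Y)^2))
      best <- max(best, score_fun(d))
      sel <- which(d < cut)
      # relax the inclusion distance until enough residues qualify
      k <- 1
      while (length(sel) < 4 && k <= 10) {
        sel <- which(d < cut + 0.5 * k)
        k <- k + 1
      }
      if (identical(sel, prev)) break
      prev <- sel
    }
  }
  best
}

resolve_pairs <- function(model, ref, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) == 0) stop("empty aligned pair set")
  X <- ca_coords(model, pairs[, 1])
  Y <- ca_coords(ref, pairs[, 2])
  ok <- stats::complete.cases(X) & stats::complete.cases(Y)
  list(X = X[ok, , drop = FALSE], Y = Y[ok, , drop = FALSE], n_used = sum(ok))
}

#' TM-score over an aligned residue pair set
#'
#' `TM = max over superpositions of (1/l_ref) sum_i 1 / (1 + (d_i/d0)^2)`,
#' with the distance scale [tm_d0()] of the chosen reference length.  Only
#' the given aligned (model, reference) CA pairs enter the sum; pairs whose
#' residues are incomplete or disordered are dropped.  The maximization uses
#' the fragment-seeded iterative search described in the package vignette.
#'
#' @param model,ref `tbm_structure` objects.
#' @param pairs 2-column matrix of 1-based (model_pos, ref_pos) pairs.
#' @param l_ref reference length used for normalization and d0; convention in
#'   this pipeline: the target sequence length (or, for the final
#'   top-ranker-similarity filter, the top ranker's length).
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(model, ref, pairs, l_ref) {
  if (l_ref <= 0) stop("l_ref must be positive")
  rp <- resolve_pairs(model, ref, pairs)
  if (rp$n_used == 0) stop("no usable aligned CA pairs")
  d0 <- tm_d0(l_ref)
  score_fun <- function(d) sum(1 / (1 + (d / d0)^2)) / l_ref
  if (rp$n_used < 3) {
    # too few pairs for a rigid fit: best case is exact coincidence
    return(min(1, rp$n_used / l_ref))
  }
  min(1, superposition_search(rp$X, rp$Y, cut = d0, score_fun = score_fun))
}

#' GDT-TS over an aligned residue pair set
#'
#' Mean over the distance thresholds 1, 2, 4, 8 A of the maximal percentage
#' of aligned CA pairs that fit under the threshold in some rigid
#' superposition, normalized by the number of reference residues.  The
#' per-threshold maximization uses the same fragment-seeded heuristic as
#' [tm_score()]; it always includes the full-set fit as a candidate, and on
#' toy instances it is validated against exhaustive subset search.
#'
#' @inheritParams tm_score
#' @param l_ref normalization length; defaults to the reference structure's
#'   residue count.
#' @param thresholds distance thresholds in Angstroms.
#' @return score in \[0, 100\].
#' @export
gdt_ts <- function(model, ref, pairs, l_ref = nres(ref),
                   thresholds = c(1, 2, 4, 8)) {
  rp <- resolve_pairs(model, ref, pairs)
  if (rp$n_used < 4) stop("GDT-TS needs at least 4 usable aligned pairs")
  per <- vapply(thresholds, function(t) {
    superposition_search(rp$X, rp$Y, cut = t,
                         score_fun = function(d) sum(d < t))
  }, 1)
  mean(100 * per / l_ref)
}

# ---- side-chain dihedral accuracy --------------------------------------

# chi1/chi2 atom quadruples, standard rotamer-library convention
CHI1_ATOMS <- list(
  ARG = c("N", "CA", "CB", "CG"),  ASN = c("N", "CA", "CB", "CG"),
  ASP = c("N", "CA", "CB", "CG"),  CYS = c("N", "CA", "CB", "SG"),
  GLN = c("N", "CA", "CB", "CG"),  GLU = c("N", "CA", "CB", "CG"),
  HIS = c("N", "CA", "CB", "CG"),  ILE = c("N", "CA", "CB", "CG1"),
  LEU = c("N", "CA", "CB", "CG"),  LYS = c("N", "CA", "CB", "CG"),
  MET = c("N", "CA", "CB", "CG"),  PHE = c("N", "CA", "CB", "CG"),
  PRO = c("N", "CA", "CB", "CG"),  SER = c("N", "CA", "CB", "OG"),
  THR = c("N", "CA", "CB", "OG1"), TRP = c("N", "CA", "CB", "CG"),
  TYR = c("N", "CA", "CB", "CG"),  VAL = c("N", "CA", "CB", "CG1"))
CHI2_ATOMS <- list(
  ARG = c("CA", "CB", "CG", "CD"),  ASN = c("CA", "CB", "CG", "OD1"),
  ASP = c("CA", "CB", "CG", "OD1"), GLN = c("CA", "CB", "CG", "CD"),
  GLU = c("CA", "CB", "CG", "CD"),  HIS = c("CA", "CB", "CG", "ND1"),
  ILE = c("CA", "CB", "CG1", "CD1"), LEU = c("CA", "CB", "CG", "CD1"),
  LYS = c("CA", "CB", "CG", "CD"),  MET = c("CA", "CB", "CG", "SD"),
  PHE = c("CA", "CB", "CG", "CD1"), PRO = c("CA", "CB", "CG", "CD"),
  TRP = c("CA", "CB", "CG", "CD1"), TYR = c("CA", "CB", "CG", "CD1"))
# terminal groups with 180-degree symmetry: compare the dihedral modulo 180
CHI2_SYMMETRIC <- c("ASP", "PHE", "TYR")

#' Dihedral angle of four points
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return angle in degrees, in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

residue_chi <- function(res_atoms, aa3, which = 1L) {
  tab <- if (which == 1L) CHI1_ATOMS else CHI2_ATOMS
  quad <- tab[[aa3]]
  if (is.null(quad) || !all(quad %in% rownames(res_atoms))) return(NA_real_)
  dihedral(res_atoms[quad[1], ], res_atoms[quad[2], ],
           res_atoms[quad[3], ], res_atoms[quad[4], ])
}

circ_diff <- function(a, b, period = 360) {
  d <- (a - b) %% period
  pmin(d, period - d)
}

#' Side-chain dihedral accuracy
#'
#' Percentage of residues whose chi1 (mode `"chi1"`), or both chi1 and chi2
#' (mode `"chi1_chi2"`), lie within `cutoff` degrees of the native values.
#' The denominator counts residues possessing the relevant dihedral(s) in
#' both structures.  Differences are circular; chi2 of residues with a
#' 180-degree-symmetric terminal group (ASP, PHE, TYR) is compared modulo
#' 180.  Returns `NA` with a warning when no residue is eligible.
#'
#' @param model,native `tbm_structure` objects with identical sequences.
#' @param mode `"chi1"` or `"chi1_chi2"`.
#' @param cutoff agreement cutoff in degrees (default 30).
#' @return percentage in \[0, 100\], or `NA` for an empty denominator.
#' @export
chi_accuracy <- function(model, native, mode = c("chi1", "chi1_chi2"),
                         cutoff = 30) {
  mode <- match.arg(mode)
  if (structure_seq(model) != structure_seq(native))
    stop("model and native sequences differ")
  need_chi2 <- mode == "chi1_chi2"
  n_elig <- 0L; n_ok <- 0L
  for (i in seq_along(model$aa)) {
    if (model$disordered[i] || native$disordered[i]) next
    aa3 <- AA3[model$aa[i]]
    if (is.na(aa3)) next
    c1m <- residue_chi(model$atoms[[i]], aa3, 1L)
    c1n <- residue_chi(native$atoms[[i]], aa3, 1L)
    if (is.na(c1m) || is.na(c1n)) next
    if (need_chi2) {
      c2m <- residue_chi(model$atoms[[i]], aa3, 2L)
      c2n <- residue_chi(native$atoms[[i]], aa3, 2L)
      if (is.na(c2m) || is.na(c2n)) next
      per2 <- if (aa3 %in% CHI2_SYMMETRIC) 180 else 360
      ok <- circ_diff(c1m, c1n) <= cutoff && circ_diff(c2m, c2n, per2) <= cutoff
    } else {
      ok <- circ_diff(c1m, c1n) <= cutoff
    }
    n_elig <- n_elig + 1L
    if (ok) n_ok <- n_ok + 1L
  }
  if (n_elig == 0L) {
    warning("no residues with the required side-chain dihedrals; returning NA")
    return(NA_real_)
  }
  100 * n_ok / n_elig
}

#' Paired two-tailed Student's t-test
#'
#' Thin wrapper over [stats::t.test()] (paired, two-sided), with the input
#' validation the pipeline needs.  Uses the sample (n-1) standard deviation
#' of the differences, per the test's definition.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return list with elements `t`, `p`, `df`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  if (sd(d) == 0)
    stop("differences have zero variance; t statistic undefined")
  ht <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}
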