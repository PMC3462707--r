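# Structural metrics: Kabsch superposition, TM-score, GDT-TS, side-chain
# dihedral accuracy, paired t-test.

test_that("kabsch recovers exact rigid transforms", {
  set.seed(1)
  P <- matrix(rnorm(15), 5, 3)
  sp <- kabsch(P, P)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)

  sp2 <- kabsch(P, sweep(P, 2, c(5, 0, 0), `+`))
  expect_equal(sp2$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp2$translation, c(5, 0, 0), tolerance = 1e-8)

  R <- rotation_about(c(0, 0, 1), 90)
  sp3 <- kabsch(P, P %*% t(R))
  expect_equal(sp3$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(sp3$rotation), 1, tolerance = 1e-8)
})

test_that("kabsch rmsd matches the brute-force rotation-grid oracle", {
  # 4 points rotated 90 degrees about z, one perturbed by 1 A
  P <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0), c(0, 3.8, 2))
  Q <- P %*% t(rotation_about(c(0, 0, 1), 90))
  Q[3, ] <- Q[3, ] + c(0, 0, 1)
  got <- kabsch(P, Q)$rmsd
  expect_equal(got, brute_min_rmsd(P, Q), tolerance = 1e-4)
  # independent cross-check against bio3d's least-squares fit
  moved <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(Q)),
                                           mobile = as.vector(t(P))))
  expect_equal(got, bio3d::rmsd(as.vector(t(Q)), moved), tolerance = 1e-3)
})

test_that("kabsch rejects degenerate input instead of reflecting", {
  line <- cbind(seq(0, 4), 0, 0)
  expect_error(kabsch(line, line + 1), "collinear")
  expect_error(kabsch(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
})

test_that("rmsd along a pure-rotation family is identically zero", {
  set.seed(2)
  P <- matrix(rnorm(24), 8, 3)
  for (theta in seq(15, 345, by = 60)) {
    Q <- P %*% t(rotation_about(c(1, 2, 3), theta))
    expect_equal(kabsch(P, Q)$rmsd, 0, tolerance = 1e-9)
  }
})

test_that("d0 follows the cube-root formula with the short-chain floor", {
  expect_equal(tm_d0(100), 1.24 * 85^(1/3) - 1.8, tolerance = 1e-12)
  expect_equal(tm_d0(100), 3.652, tolerance = 1e-3)
  expect_equal(tm_d0(15), 0.5)
  expect_equal(tm_d0(5), 0.5)
  expect_equal(tm_d0(16), 0.5)  # formula gives -0.56, floored
})

test_that("TM-score is 1 on self and under any rigid transform", {
  s <- ideal_structure(strrep("AKELG", 8))
  L <- nres(s)
  pairs <- cbind(1:L, 1:L)
  expect_equal(tm_score(s, s, pairs, l_ref = L), 1, tolerance = 1e-9)
  moved <- transform_structure(s, rotation_about(c(1, -1, 2), 77), c(4, -9, 2))
  expect_equal(tm_score(moved, s, pairs, l_ref = L), 1, tolerance = 1e-6)
  expect_error(tm_score(s, s, matrix(integer(0), ncol = 2), L), "empty")
  expect_error(tm_score(s, s, pairs, 0), "positive")
})

test_that("TM-score decreases in expectation as model noise grows", {
  set.seed(3)
  native <- ca_structure(random_ca(50))
  pairs <- cbind(1:50, 1:50)
  sigmas <- c(0.5, 1.5, 3)
  means <- sapply(sigmas, function(sg) {
    mean(replicate(20, {
      noisy <- ca_structure(ca_coords(native) + matrix(rnorm(150, 0, sg), 50, 3))
      tm_score(noisy, native, pairs, l_ref = 50)
    }))
  })
  expect_true(all(diff(means) < 0))
})

test_that("GDT-TS is 100 on self and rigid copies, and bounds the full fit", {
  s <- ideal_structure(strrep("AKELG", 6))
  L <- nres(s)
  pairs <- cbind(1:L, 1:L)
  expect_identical(gdt_ts(s, s, pairs), 100)
  moved <- transform_structure(s, rotation_about(c(0, 1, 0), 123), c(-3, 8, 1))
  expect_equal(gdt_ts(moved, s, pairs), 100, tolerance = 1e-6)
  expect_error(gdt_ts(s, s, pairs[1:3, ]), "at least 4")

  # heuristic >= the single full-set Kabsch candidate
  set.seed(4)
  X <- random_ca(30); Y <- X + matrix(rnorm(90, 0, 2), 30, 3)
  sp <- kabsch(X, Y)
  d <- sqrt(rowSums((apply_superposition(sp, X) - Y)^2))
  full_fit_score <- mean(sapply(c(1, 2, 4, 8), function(t) 100 * sum(d < t) / 30))
  got <- gdt_ts(ca_structure(X), ca_structure(Y), cbind(1:30, 1:30))
  expect_gte(got + 1e-9, full_fit_score)
})

test_that("GDT heuristic matches exhaustive subset search on toy instances", {
  # 10 residues: rigid 5-residue core + 5 residues displaced 10 A orthogonally
  base <- cbind(seq(0, 36, by = 4), rep(c(0, 2.2), 5), 0)
  model <- base
  model[6:10, 3] <- model[6:10, 3] + 10
  X <- ca_structure(model); Y <- ca_structure(base)
  thr <- c(1, 2, 4, 8)
  oracle <- brute_gdt_counts(model, base, thr)
  got <- gdt_ts(X, Y, cbind(1:10, 1:10))
  expect_equal(got, mean(100 * oracle / 10))

  # on noisy random instances the fragment-seeded heuristic is a documented
  # approximation: never above the exhaustive optimum, and close to it
  set.seed(5)
  A <- random_ca(10)
  B <- A %*% t(rotation_about(c(1, 1, 0), 30)) + matrix(rnorm(30, 0, 1.5), 10, 3)
  oracle2 <- mean(100 * brute_gdt_counts(A, B, thr) / 10)
  got2 <- gdt_ts(ca_structure(A), ca_structure(B), cbind(1:10, 1:10))
  expect_lte(got2, oracle2 + 1e-9)
  expect_gte(got2, oracle2 - 5)
})

test_that("chi1 accuracy counts rotated side chains", {
  # 10 chi-bearing residues, one with chi1 off by 45 degrees
  native <- ideal_structure(strrep("K", 10))
  chi1 <- rep(-60, 10); chi1[4] <- -60 + 45
  model <- ideal_structure(strrep("K", 10), chi1 = chi1)
  expect_equal(chi_accuracy(native, native, "chi1"), 100)
  expect_equal(chi_accuracy(model, native, "chi1"), 90)
  expect_equal(chi_accuracy(model, native, "chi1_chi2"), 90)
  # chi2 rotated by 180 on a non-symmetric residue (LYS) fails the cutoff
  model2 <- ideal_structure(strrep("K", 10), chi2 = c(rep(180, 9), 0))
  expect_equal(chi_accuracy(model2, native, "chi1_chi2"), 90)
  expect_error(chi_accuracy(model, ideal_structure(strrep("Q", 10)), "chi1"),
               "differ")
})

test_that("structures without eligible side chains give NA with a warning", {
  s <- ideal_structure("AGAGAG")
  expect_warning(res <- chi_accuracy(s, s, "chi1"), "NA")
  expect_true(is.na(res))
})

test_that("180-degree-symmetric chi2 groups are compared modulo the symmetry", {
  # hand-built ASP pair whose chi2 differ by exactly 180 degrees
  mk_asp <- function(chi2_deg) {
    th <- chi2_deg * pi / 180
    atoms <- list(rbind(
      N = c(-1, -1, 0), CA = c(-1, 0, 0), CB = c(0, 0, 0), CG = c(0, 1, 0),
      # OD1 placed so dihedral(CA, CB, CG, OD1) = chi2_deg
      OD1 = c(0, 1, 0) + c(-cos(th), 0.3, -sin(th)),
      C = c(-1.5, 0.7, 0)))
    new_structure("D", atoms)
  }
  a <- mk_asp(40); b <- mk_asp(40 + 180)
  expect_equal(dihedral(c(-1, 0, 0), c(0, 0, 0), c(0, 1, 0),
                        a$atoms[[1]]["OD1", ]), 40, tolerance = 1e-6)
  expect_equal(chi_accuracy(a, b, "chi1_chi2"), 100)
})

test_that("paired t-test matches textbook arithmetic and is antisymmetric", {
  x <- c(1, 2, 3); y <- c(0, 0, 0)
  res <- paired_t_test(x, y)
  # d = (1,2,3): mean 2, sd 1, t = 2 / (1/sqrt(3))
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * stats::pt(-2 * sqrt(3), df = 2), tolerance = 1e-10)
  expect_equal(res$p, 0.0742, tolerance = 1e-3)

  swapped <- paired_t_test(y, x)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)

  set.seed(6)
  z <- rnorm(10)
  jitter <- rnorm(10, 0, 0.05)
  expect_gt(paired_t_test(z + 0.5 + jitter, z)$t, 0)
  expect_lt(paired_t_test(z - 0.5 + jitter, z)$t, 0)
  expect_error(paired_t_test(1:3, 1:2), "equal length")
  expect_error(paired_t_test(c(1, 2), c(0, 1)), "zero variance")
})

test_that("all metrics are invariant under a common rigid transform", {
  set.seed(7)
  model <- ideal_structure(strrep("KELAG", 6))
  native <- transform_structure(model, rotation_about(c(2, 1, 1), 33), c(1, 2, 3))
  native <- ca_structure(ca_coords(native) + matrix(rnorm(90, 0, 1), 30, 3),
                         aa = strsplit(strrep("KELAG", 6), "")[[1]])
  pairs <- cbind(1:30, 1:30)
  tm0 <- tm_score(model, native, pairs, 30)
  gdt0 <- gdt_ts(model, native, pairs)
  R <- rotation_about(c(0, 1, 4), -61); tr <- c(-7, 2, 5)
  model2 <- transform_structure(model, R, tr)
  native2 <- transform_structure(native, R, tr)
  expect_equal(tm_score(model2, native2, pairs, 30), tm0, tolerance = 1e-6)
  expect_equal(gdt_ts(model2, native2, pairs), gdt0, tolerance = 1e-6)
})
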