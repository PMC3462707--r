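# Fixture builders shared across test files.  All structures are generated
# in code; nothing binary is stored.

# complete tbm_structure from an L x 3 CA coordinate matrix: N and C are
# fabricated at fixed offsets so residues pass the backbone-completeness
# check while every metric under test only consumes CA
ca_structure <- function(ca, aa = rep("A", nrow(ca))) {
  atoms <- lapply(seq_len(nrow(ca)), function(i) {
    rbind(N = ca[i, ] + c(-1.2, 0.6, 0),
          CA = ca[i, ],
          C = ca[i, ] + c(1.2, 0.6, 0))
  })
  new_structure(aa, atoms)
}

random_ca <- function(L, step = 3.8) {
  # self-avoiding-ish random walk with fixed step, a crude CA trace
  x <- matrix(0, L, 3)
  for (i in 2:L) {
    d <- stats::rnorm(3)
    x[i, ] <- x[i - 1, ] + step * d / sqrt(sum(d^2))
  }
  x
}

rotation_about <- function(axis, theta_deg) {
  ax <- axis / sqrt(sum(axis^2))
  th <- theta_deg * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

transform_structure <- function(x, R, tr) {
  x$atoms <- lapply(x$atoms, function(m)
    if (nrow(m) == 0) m else sweep(m %*% t(R), 2, tr, `+`))
  x
}

# minimal hit with a preassigned rescored score, for selection-stage tests
scored_hit <- function(id, rescored, rank, probability = 50) {
  h <- new_hit(id, 0, 0, probability, matrix(integer(0), ncol = 2),
               rank = rank)
  h$rescored <- rescored
  h
}

# hand-written HHR fixture with two hits (probabilities 99.8 / 88.4)
write_hhr_fixture <- function(path) {
  writeLines(c(
    "Query         target",
    "Match_columns 60",
    "No_of_seqs    10 out of 50",
    "Neff          5.0",
    "Searched_HMMs 100",
    "Date          Thu Jan  1 00:00:00 2026",
    "Command       hhsearch -i target.a3m -d pdb70",
    "",
    " No Hit                             Prob E-value P-value  Score    SS Cols Query HMM  Template HMM",
    "  1 tmpl1 first template           99.8 1.2E-30 3.1E-35  210.5  15.3   16    3-18      2-17  (60)",
    "  2 tmpl2 second template          88.4 2.2E-10 5.0E-14  101.2   8.7   12   10-22     12-23  (62)",
    "",
    "No 1",
    ">tmpl1 first template",
    "Probab=99.80  E-value=1.2e-30  Score=210.50  Aligned_cols=16  Identities=40%  Similarity=0.7  Sum_probs=14.9",
    "",
    "Q target            3 AKELGQRSVDAKELGQ   18 (60)",
    "Q Consensus         3 akelgqrsvdakelgq   18 (60)",
    "T tmpl1             2 AKELGQRSVDAKELGQ   17 (60)",
    "T Consensus         2 akelgqrsvdakelgq   17 (60)",
    "",
    "No 2",
    ">tmpl2 second template",
    "Probab=88.40  E-value=2.2e-10  Score=101.20  Aligned_cols=12  Identities=30%  Similarity=0.4  Sum_probs=9.1",
    "",
    "Q target           10 VDAKE-LGQRSVD   21 (60)",
    "Q Consensus        10 vdake-lgqrsvd   21 (60)",
    "T tmpl2            12 VDAKESLGQ--VD   22 (62)",
    "T Consensus        12 vdakeslgq--vd   22 (62)"
  ), path)
  path
}
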