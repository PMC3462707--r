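# Hit rescoring and multiple-template selection.

test_that("zscore standardizes with population sd and tolerates constants", {
  expect_equal(zscore(c(10, 8, 6)), c(2, 0, -2) / sqrt(8 / 3),
               tolerance = 1e-12)
  expect_equal(zscore(c(10, 8, 6))[1], 1.2247, tolerance = 1e-4)
  expect_equal(zscore(c(5, 5, 5)), c(0, 0, 0))
  expect_error(zscore(3), "at least 2")
  set.seed(8)
  v <- rnorm(20, 50, 7)
  z <- zscore(v)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
})

test_that("weight factor follows the four probability bins exactly", {
  expect_identical(weight_factor(95), 1.0)
  expect_identical(weight_factor(90), 1.0)
  expect_identical(weight_factor(89.99), 1.5)
  expect_identical(weight_factor(85), 1.5)
  expect_identical(weight_factor(80), 1.5)
  expect_identical(weight_factor(79.9), 2.0)
  expect_identical(weight_factor(60), 2.0)
  expect_identical(weight_factor(59.9), 2.6)
  expect_identical(weight_factor(0), 2.6)
  expect_error(weight_factor(-1), "\\[0, 100\\]")
  expect_error(weight_factor(101), "\\[0, 100\\]")
})

test_that("rescoring combines z-scores with the top-ranker weight", {
  # raw scores chosen so z_seq = (1, -1), z_ss = (-1, 1); p_top = 50 -> w 2.6
  hits <- list(new_hit("a", 1, -1, 50, cbind(1:2, 1:2), rank = 1L),
               new_hit("b", -1, 1, 40, cbind(1:2, 1:2), rank = 2L))
  out <- rescore(hits)
  expect_equal(attr(out, "w"), 2.6)
  expect_equal(ids_of <- vapply(out, `[[`, "", "template_id"), c("b", "a"))
  expect_equal(vapply(out, `[[`, 1, "rescored"), c(1.6, -1.6))
})

test_that("ties keep the original search order and w = 0 reduces to raw order", {
  hits <- list(new_hit("first", 5, 5, 95, cbind(1:2, 1:2), rank = 1L),
               new_hit("second", 5, 5, 90, cbind(1:2, 1:2), rank = 2L))
  out <- rescore(hits)
  expect_equal(vapply(out, `[[`, 1, "rescored"), c(0, 0))
  expect_equal(vapply(out, `[[`, "", "template_id"), c("first", "second"))

  set.seed(9)
  hits2 <- lapply(1:6, function(i)
    new_hit(paste0("t", i), rnorm(1), rnorm(1), 95, cbind(1:2, 1:2),
            rank = i))
  zero_w <- data.frame(lower = -Inf, w = 0)
  out2 <- rescore(hits2, zero_w)
  raw_order <- order(-vapply(hits2, `[[`, 1, "raw_seq_score"))
  expect_equal(vapply(out2, `[[`, "", "template_id"),
               vapply(hits2[raw_order], `[[`, "", "template_id"))
  expect_error(rescore(hits2[1]), "at least 2")
})

test_that("high/low split applies the 95% rule with the top always high", {
  ranked <- list(scored_hit("a", 10, 1), scored_hit("b", 9.6, 2),
                 scored_hit("c", 9.4, 3), scored_hit("d", 5, 4))
  sp <- split_rankers(ranked)
  expect_equal(sp$high, c("a", "b"))   # threshold 0.95 * 10 = 9.5
  expect_equal(sp$low, c("c", "d"))

  same <- lapply(1:4, function(i) scored_hit(paste0("t", i), 7, i))
  expect_length(split_rankers(same)$high, 4)
  single <- list(scored_hit("only", 3, 1))
  expect_equal(split_rankers(single)$high, "only")
  expect_length(split_rankers(single)$low, 0)
})

test_that("non-positive top scores fall back to the top-3 high-ranker set", {
  ranked <- list(scored_hit("a", -0.1, 1), scored_hit("b", -0.5, 2),
                 scored_hit("c", -1, 3), scored_hit("d", -2, 4))
  expect_equal(split_rankers(ranked)$high, c("a", "b", "c"))
})

test_that("background pool is the high-rankers or top 3, whichever is larger", {
  ranked <- lapply(1:5, function(i) scored_hit(paste0("t", i), 10 - i, i))
  expect_equal(background_pool(c("t1", "t2"), ranked), c("t1", "t2", "t3"))
  expect_equal(background_pool(paste0("t", 1:4), ranked), paste0("t", 1:4))
  two <- ranked[1:2]
  expect_equal(background_pool("t1", two), c("t1", "t2"))
})

test_that("pool filter retains identical structures and drops a clear outlier", {
  ids <- c("a", "b", "c", "d")
  ranked <- list(scored_hit("a", 10, 1), scored_hit("b", 9.8, 2),
                 scored_hit("c", 9.7, 3), scored_hit("d", 9.6, 4))
  ones <- matrix(1, 4, 4, dimnames = list(ids, ids))
  sims <- list(ids = ids, tm = ones)
  kept <- pool_filter(ids, ids[1:3], sims, ranked, high = ids)
  expect_equal(as.character(kept), ids)  # sigma = 0, sim = cutoff, strict <

  # outlier: TM ~ 0.3 to everyone, pool sims ~ 0.9 +- 0.02
  tm <- matrix(0.3, 4, 4, dimnames = list(ids, ids))
  tm["a", "b"] <- tm["b", "a"] <- 0.92
  tm["a", "c"] <- tm["c", "a"] <- 0.92
  tm["b", "c"] <- tm["c", "b"] <- 0.86
  diag(tm) <- 1
  sims2 <- list(ids = ids, tm = tm)
  kept2 <- pool_filter(ids, c("a", "b", "c"), sims2, ranked,
                       high = c("a", "b", "c"))
  # pool sims: a 0.92, b 0.89, c 0.89; m = 0.90, sigma = sqrt(2e-4)
  # cutoff(alpha = 1) ~ 0.8859; d's sim 0.3 is far below
  expect_equal(as.character(kept2), c("a", "b", "c"))
  st <- attr(kept2, "pool_stats")
  expect_equal(st$m_pool, 0.90, tolerance = 1e-12)
  expect_equal(st$sigma_pool, sqrt(mean(c(0.02, -0.01, -0.01)^2)),
               tolerance = 1e-12)
})

test_that("a low-ranker with the top score is filtered like a high-ranker", {
  ids <- c("a", "b", "c", "d")
  ranked <- list(scored_hit("a", 10, 1), scored_hit("b", 10, 2),
                 scored_hit("c", 9.9, 3), scored_hit("d", 9.8, 4))
  set.seed(10)
  m <- matrix(runif(16, 0.6, 0.9), 4)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  sims <- list(ids = ids, tm = m)
  as_high <- pool_filter(ids, ids[1:3], sims, ranked, high = c("a", "b"))
  as_low <- pool_filter(ids, ids[1:3], sims, ranked, high = "a")
  # b has S = S_top so alpha = 1 either way: same survivors
  expect_equal(as.character(as_high), as.character(as_low))
})

test_that("final top filter applies the strict TM < 0.5 rule", {
  cand <- c("top", "x", "y", "z")
  tm <- c(x = 0.49, y = 0.50, z = 0.80)
  out <- final_top_filter(cand, tm, top_id = "top")
  expect_equal(out, c("top", "y", "z"))
  expect_error(final_top_filter(c("top", "w"), tm, top_id = "top"), "missing")
  # raising the cutoff never grows the output
  set.seed(11)
  for (i in 1:20) {
    tm_r <- setNames(runif(6), paste0("t", 2:7))
    cand_r <- c("t1", names(tm_r))
    sizes <- sapply(c(0.3, 0.5, 0.7, 0.9), function(cut)
      length(final_top_filter(cand_r, tm_r, selection_params(final_tm_cutoff = cut),
                              top_id = "t1")))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("full selection keeps the family and rejects unrelated decoys", {
  spec <- synth_spec(seed = 21, target_length = 40, n_templates = 6,
                     n_decoys = 2)
  gen <- make_structures(spec)
  expect_true(all(gen$tm_truth[paste0("tmpl", 1:6)] > 0.5))
  expect_true(all(gen$tm_truth[paste0("decoy", 1:2)] < 0.5))
  hits <- make_hits(spec, names(gen$structures))
  sel <- select_templates(hits, gen$structures, spec$target_length)
  expect_false(any(grepl("decoy", sel$selected)))
  expect_equal(sel$selected[1], sel$table$template_id[1])
  expect_true(all(c("template_id", "hhsearch_rank", "rescored", "selected",
                    "removal_stage") %in% names(sel$table)))
})

test_that("single-hit tables select that hit", {
  h <- list(new_hit("only", 10, 5, 80, cbind(1:5, 1:5), rank = 1L))
  sel <- select_templates(h, list(), 5)
  expect_equal(sel$selected, "only")
})

test_that("selection set is invariant to the file order of equal-score hits", {
  spec <- synth_spec(seed = 22, target_length = 40, n_templates = 4,
                     n_decoys = 0, template_sigma = 0)
  gen <- make_structures(spec)
  mk <- function(ids) lapply(seq_along(ids), function(i)
    new_hit(ids[i], 50, 20, 90, cbind(1:40, 1:40), rank = i))
  a <- select_templates(mk(paste0("tmpl", 1:4)), gen$structures, 40)
  b <- select_templates(mk(paste0("tmpl", c(2, 1, 4, 3))), gen$structures, 40)
  expect_setequal(a$selected, b$selected)
})

test_that("template similarity matrices are symmetric with unit diagonal", {
  spec <- synth_spec(seed = 23, target_length = 30, n_templates = 3,
                     n_decoys = 1)
  gen <- make_structures(spec)
  hits <- make_hits(spec, names(gen$structures))
  sims <- similarity_matrix(hits, gen$structures, 30)
  expect_equal(sims$tm, t(sims$tm), tolerance = 1e-9)
  expect_equal(unname(diag(sims$tm)), rep(1, 4))
  expect_true(all(sims$tm > 0 & sims$tm <= 1))
})
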