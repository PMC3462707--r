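# Difficulty-weighted rescoring of homology-search hits and consensus-based
# multiple-template selection.
#
# Hits are re-ranked by S = Z_seq + w * Z_ss, where Z_seq and Z_ss are
# population z-scores of the raw sequence and secondary-structure similarity
# scores and the weight w grows as the search probability of the original top
# ranker drops (hard targets lean harder on secondary structure).  Templates
# are then selected from the top 20 re-ranked hits by removing structural
# outliers against a background pool and, finally, structures dissimilar from
# the new top ranker.

#' Default difficulty weight schedule
#'
#' Piecewise-constant weight on the secondary-structure z-score as a function
#' of the search probability `p` (percent) of the original top ranker:
#' `w = 1.0` for `p >= 90`, `1.5` for `80 <= p < 90`, `2.0` for
#' `60 <= p < 80`, and `2.6` for `p < 60`.
#'
#' @return data frame with columns `lower` (inclusive lower probability bound)
#'   and `w`, ordered from easiest to hardest bin.
#' @export
weight_schedule <- function() {
  data.frame(lower = c(90, 80, 60, -Inf), w = c(1.0, 1.5, 2.0, 2.6))
}

#' Difficulty weight for a given top-ranker probability
#' @param p search probability in percent, in \[0, 100\].
#' @param schedule a [weight_schedule()] data frame.
#' @export
weight_factor <- function(p, schedule = weight_schedule()) {
  if (is.na(p) || p < 0 || p > 100) stop("probability must be in [0, 100]")
  schedule$w[which(p >= schedule$lower)[1]]
}

#' Population z-scores
#'
#' Standardizes to mean 0 and unit population (1/n) standard deviation; a
#' constant input yields all zeros.
#'
#' @param values numeric vector, length >= 2.
#' @export
zscore <- function(values) {
  if (length(values) < 2) stop("need at least 2 values to standardize")
  s <- sqrt(mean((values - mean(values))^2))
  if (s == 0) return(rep(0, length(values)))
  (values - mean(values)) / s
}

#' Default selection parameters
#'
#' @param candidate_cap hits considered after re-ranking (top 20).
#' @param high_ranker_fraction high-rankers have S within this fraction of
#'   the top score (0.95).
#' @param min_pool_size background pool falls back to this many top rankers
#'   when there are fewer high-rankers (3).
#' @param final_tm_cutoff templates with TM-score to the top ranker below
#'   this are removed (0.5).
#' @export
selection_params <- function(candidate_cap = 20L, high_ranker_fraction = 0.95,
                             min_pool_size = 3L, final_tm_cutoff = 0.5) {
  stopifnot(high_ranker_fraction > 0, high_ranker_fraction <= 1,
            candidate_cap >= min_pool_size)
  list(candidate_cap = as.integer(candidate_cap),
       high_ranker_fraction = high_ranker_fraction,
       min_pool_size = as.integer(min_pool_size),
       final_tm_cutoff = final_tm_cutoff)
}

#' Rescore and re-rank homology-search hits
#'
#' Computes `S = Z_seq + w * Z_ss` over the hit population, with the weight
#' taken from the probability of the original top ranker (the first hit in
#' search order), and returns the hits sorted by `S` descending.  Ties keep
#' the original search order (stable sort).
#'
#' @param hits list of [new_hit()] records in original search order.
#' @param schedule a [weight_schedule()].
#' @return re-ranked hit list with `z_seq`, `z_ss`, `rescored` filled in;
#'   the applied weight is attached as attribute `"w"`.
#' @export
rescore <- function(hits, schedule = weight_schedule()) {
  if (length(hits) < 2) stop("rescoring needs at least 2 hits")
  seq_raw <- vapply(hits, `[[`, 1, "raw_seq_score")
  ss_raw <- vapply(hits, `[[`, 1, "raw_ss_score")
  if (any(!is.finite(seq_raw)) || any(!is.finite(ss_raw)))
    stop("raw scores must be finite")
  top_rank <- which.min(vapply(hits, `[[`, 1L, "rank"))
  w <- weight_factor(hits[[top_rank]]$probability, schedule)
  zs <- zscore(seq_raw); zss <- zscore(ss_raw)
  for (i in seq_along(hits)) {
    hits[[i]]$z_seq <- zs[i]
    hits[[i]]$z_ss <- zss[i]
    hits[[i]]$rescored <- zs[i] + w * zss[i]
  }
  ord <- order(-vapply(hits, `[[`, 1, "rescored"),
               vapply(hits, `[[`, 1L, "rank"))
  out <- hits[ord]
  attr(out, "w") <- w
  out
}

rescored_of <- function(hits) vapply(hits, `[[`, 1, "rescored")
ids_of <- function(hits) vapply(hits, `[[`, "", "template_id")

#' Split re-ranked hits into high- and low-rankers
#'
#' High-rankers have a rescored score within the configured fraction (default
#' 95%) of the top ranker's score, i.e. `S_i >= 0.95 * S_top`.  The fraction
#' rule presumes a positive top score; when `S_top <= 0` (possible for
#' z-score sums) the high-ranker set is defined as the top
#' `min_pool_size` hits, which collapses to the background-pool fallback.
#'
#' @param ranked re-ranked hit list ([rescore()] output), truncated or not;
#'   only the first `candidate_cap` hits are considered.
#' @param params a [selection_params()].
#' @return list with character vectors `high` and `low` (template ids).
#' @export
split_rankers <- function(ranked, params = selection_params()) {
  if (length(ranked) == 0) stop("no hits to split")
  ranked <- head(ranked, params$candidate_cap)
  s <- rescored_of(ranked)
  ids <- ids_of(ranked)
  if (s[1] > 0) {
    hi <- s >= params$high_ranker_fraction * s[1]
  } else {
    hi <- seq_along(s) <= params$min_pool_size
  }
  hi[1] <- TRUE  # top ranker is always a high-ranker
  list(high = ids[hi], low = ids[!hi])
}

#' Background pool of structures
#'
#' The pool is the high-rankers or the top `min_pool_size` (default 3)
#' re-ranked hits, whichever is larger (all hits when fewer exist).
#'
#' @param high character vector of high-ranker ids.
#' @param ranked re-ranked hit list.
#' @param params a [selection_params()].
#' @export
background_pool <- function(high, ranked, params = selection_params()) {
  if (length(ranked) == 0) stop("no hits")
  if (length(high) >= params$min_pool_size) return(high)
  head(ids_of(ranked), params$min_pool_size)
}

#' Pairwise template similarity matrix
#'
#' TM-score between every pair of candidate template structures, computed
#' over the residue pairs where both templates align to a common target
#' position (their alignments composed through the target), with the target
#' sequence length as the reference length.
#'
#' @param hits hit list (provides the target-template alignments).
#' @param structures named list of `tbm_structure` template structures.
#' @param target_length target sequence length (reference length for TM).
#' @return list with `ids` and symmetric matrix `tm` (diagonal 1).
#' @export
similarity_matrix <- function(hits, structures, target_length) {
  ids <- ids_of(hits)
  missing <- setdiff(ids, names(structures))
  if (length(missing) > 0)
    stop("no structure for template(s): ", paste(missing, collapse = ", "))
  maps <- lapply(hits, function(h)
    setNames(h$aligned_pairs[, 2], h$aligned_pairs[, 1]))
  n <- length(ids)
  tm <- diag(1, n)
  dimnames(tm) <- list(ids, ids)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      common <- intersect(names(maps[[i]]), names(maps[[j]]))
      if (length(common) == 0) { tm[i, j] <- tm[j, i] <- 0; next }
      pairs <- cbind(maps[[i]][common], maps[[j]][common])
      val <- tryCatch(
        tm_score(structures[[ids[i]]], structures[[ids[j]]], pairs,
                 l_ref = target_length),
        error = function(e) 0)
      tm[i, j] <- tm[j, i] <- val
    }
  }
  list(ids = ids, tm = tm)
}

#' Remove structural outliers against the background pool
#'
#' Each candidate's similarity to the pool is its mean TM-score to the pool
#' members (a pool member is excluded from its own mean).  Candidates with
#' similarity below `m_pool - alpha * sigma_pool` are removed, where `m_pool`
#' and `sigma_pool` are the mean and population standard deviation of the
#' pool members' similarities.  `alpha` is 1 for high-rankers and the ratio
#' `S / S_top` (clamped to \[0, 1\]) for low-rankers.  The top ranker is never
#' removed.
#'
#' @param candidates candidate template ids (subset of `sims$ids`).
#' @param pool background pool ids (subset of `candidates`).
#' @param sims a [similarity_matrix()].
#' @param ranked re-ranked hit list (for scores and the top ranker).
#' @param high high-ranker ids (determines `alpha`).
#' @return surviving candidate ids, in the order given; pool statistics
#'   attached as attribute `"pool_stats"`.
#' @export
pool_filter <- function(candidates, pool, sims, ranked, high) {
  if (length(pool) == 0) stop("empty background pool")
  if (!all(candidates %in% sims$ids))
    stop("similarity matrix is missing candidate ids")
  if (!all(pool %in% candidates)) stop("pool must be a subset of candidates")
  s <- setNames(rescored_of(ranked), ids_of(ranked))
  top_id <- ids_of(ranked)[1]
  sim_to_pool <- function(c) {
    others <- setdiff(pool, c)
    if (length(others) == 0) return(1)  # pool of one: trivially similar to itself
    mean(sims$tm[c, others])
  }
  sim <- vapply(candidates, sim_to_pool, 1)
  pool_sims <- vapply(pool, sim_to_pool, 1)
  m_pool <- mean(pool_sims)
  sigma_pool <- sqrt(mean((pool_sims - m_pool)^2))
  alpha <- vapply(candidates, function(c) {
    if (c %in% high) return(1)
    if (s[top_id] == 0) return(1)
    min(1, max(0, unname(s[c] / s[top_id])))
  }, 1)
  keep <- sim >= m_pool - alpha * sigma_pool | candidates == top_id
  out <- candidates[keep]
  attr(out, "pool_stats") <- list(m_pool = m_pool, sigma_pool = sigma_pool,
                                  sim = sim, alpha = alpha)
  out
}

#' Final similarity filter against the top ranker
#'
#' Removes candidates whose TM-score to the (re-ranked) top template is below
#' the cutoff (default 0.5), the top ranker's sequence length being the
#' reference length for those TM-scores.  The top ranker itself always stays.
#'
#' @param candidates candidate ids.
#' @param tm_to_top named numeric vector of TM-scores to the top ranker.
#' @param params a [selection_params()].
#' @param top_id id of the top ranker.
#' @export
final_top_filter <- function(candidates, tm_to_top,
                             params = selection_params(),
                             top_id = candidates[1]) {
  if (!all(candidates %in% c(names(tm_to_top), top_id)))
    stop("tm_to_top is missing candidate ids")
  keep <- candidates == top_id |
    tm_to_top[candidates] >= params$final_tm_cutoff
  candidates[keep]
}

#' Select multiple templates from a homology-search hit list
#'
#' Full selection procedure: rescore and re-rank, truncate to the top
#' `candidate_cap` (20), split into high/low rankers, build the background
#' pool, remove pool outliers, then remove structures dissimilar from the top
#' ranker (TM < 0.5, top-ranker length as reference).  Deterministic: ties
#' everywhere resolve by (rescored score descending, original search rank
#' ascending).
#'
#' @param hits hit list in original search order.
#' @param structures named list of template `tbm_structure`s covering at
#'   least the top `candidate_cap` re-ranked hits.
#' @param target_length target sequence length.
#' @param params a [selection_params()].
#' @param schedule a [weight_schedule()].
#' @return object of class `tbm_selection`: `selected` (ids ordered by
#'   rescored score), `table` (per-candidate data frame with removal stage),
#'   `w`, `pool`, `high`, `pool_stats`.
#' @export
select_templates <- function(hits, structures, target_length,
                             params = selection_params(),
                             schedule = weight_schedule()) {
  if (length(hits) == 0) stop("empty hit list")
  if (length(hits) == 1) {
    only <- hits[[1]]$template_id
    tab <- data.frame(template_id = only, hhsearch_rank = 1L,
                      rescored = NA_real_, selected = TRUE,
                      removal_stage = "", stringsAsFactors = FALSE)
    return(structure(list(selected = only, table = tab, w = NA_real_,
                          high = only, pool = only, pool_stats = NULL),
                     class = "tbm_selection"))
  }
  ranked <- rescore(hits, schedule)
  w <- attr(ranked, "w")
  cand_hits <- head(ranked, params$candidate_cap)
  dropped <- ids_of(ranked)[-seq_along(cand_hits)]
  ids <- ids_of(cand_hits)
  split <- split_rankers(cand_hits, params)
  pool <- background_pool(split$high, cand_hits, params)
  sims <- similarity_matrix(cand_hits, structures, target_length)
  after_pool <- pool_filter(ids, pool, sims, cand_hits, split$high)
  pool_stats <- attr(after_pool, "pool_stats")
  top_id <- ids[1]
  top_hit <- cand_hits[[1]]
  top_len <- nres(structures[[top_id]])
  top_map <- setNames(top_hit$aligned_pairs[, 2], top_hit$aligned_pairs[, 1])
  tm_to_top <- vapply(setdiff(after_pool, top_id), function(c) {
    h <- cand_hits[[match(c, ids)]]
    cmap <- setNames(h$aligned_pairs[, 2], h$aligned_pairs[, 1])
    common <- intersect(names(cmap), names(top_map))
    if (length(common) == 0) return(0)
    tryCatch(tm_score(structures[[c]], structures[[top_id]],
                      cbind(cmap[common], top_map[common]), l_ref = top_len),
             error = function(e) 0)
  }, 1)
  final <- final_top_filter(after_pool, tm_to_top, params, top_id = top_id)

  stage <- setNames(rep("", length(ids)), ids)
  stage[setdiff(ids, after_pool)] <- "pool_filter"
  stage[setdiff(after_pool, final)] <- "top_tm_filter"
  tab <- data.frame(
    template_id = c(ids, dropped),
    hhsearch_rank = c(vapply(cand_hits, `[[`, 1L, "rank"),
                      vapply(ranked[-seq_along(cand_hits)], `[[`, 1L, "rank")),
    rescored = c(rescored_of(cand_hits),
                 rescored_of(ranked[-seq_along(cand_hits)])),
    selected = c(ids %in% final, rep(FALSE, length(dropped))),
    removal_stage = c(unname(stage), rep("rank_cap", length(dropped))),
    stringsAsFactors = FALSE)
  structure(list(selected = final, table = tab, w = w, high = split$high,
                 pool = pool, pool_stats = pool_stats),
            class = "tbm_selection")
}

#' @export
print.tbm_selection <- function(x, ...) {
  cat(sprintf("<tbm_selection> %d template(s): %s (w = %s)\n",
              length(x$selected), paste(x$selected, collapse = ", "),
              ifelse(is.na(x$w), "-", format(x$w))))
  invisible(x)
}
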