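# Operations over an ensemble of candidate models of one target:
# representative selection ("nearest to the largest cluster center") and the
# per-residue consensus fluctuation profile that drives unreliable-region
# detection.

#' Construct a model ensemble
#' @param models list of `tbm_structure` objects with identical sequences.
#' @export
new_ensemble <- function(models) {
  if (length(models) < 2) stop("an ensemble needs at least 2 models")
  seqs <- vapply(models, structure_seq, "")
  if (length(unique(seqs)) != 1)
    stop("all ensemble models must share the same sequence")
  structure(list(models = models, n = length(models)), class = "tbm_ensemble")
}

#' @export
print.tbm_ensemble <- function(x, ...) {
  cat(sprintf("<tbm_ensemble> %d models x %d residues\n",
              x$n, nres(x$models[[1]])))
  invisible(x)
}

#' Pairwise CA-RMSD matrix of an ensemble
#'
#' Full-chain Kabsch superposition between every model pair, over residues
#' with usable CA atoms in both.
#'
#' @param ens a [new_ensemble()].
#' @export
pairwise_rmsd <- function(ens) {
  n <- ens$n
  cas <- lapply(ens$models, ca_coords)
  m <- matrix(0, n, n)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ok <- stats::complete.cases(cas[[i]]) & stats::complete.cases(cas[[j]])
      sp <- kabsch(cas[[i]][ok, , drop = FALSE], cas[[j]][ok, , drop = FALSE])
      m[i, j] <- m[j, i] <- sp$rmsd
    }
  }
  m
}

# Connected components of the graph with edges rmsd <= cutoff (single
# linkage at the cutoff).
single_linkage_clusters <- function(rmsd_mat, cutoff) {
  n <- nrow(rmsd_mat)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      nb <- which(rmsd_mat[v, ] <= cutoff & is.na(comp))
      queue <- c(queue, setdiff(nb, v))
    }
  }
  comp
}

#' Representative model of an ensemble
#'
#' Models are clustered by single linkage on full-chain CA-RMSD at
#' `cluster_cutoff`; within the largest cluster the member with the smallest
#' mean RMSD to its co-members (the one nearest the cluster center) is the
#' representative.  Ties resolve to the lowest model index.
#'
#' @param ens a [new_ensemble()].
#' @param cluster_cutoff single-linkage neighbor cutoff in Angstroms
#'   (default 2.0).
#' @param rmsd_mat optional precomputed [pairwise_rmsd()] matrix.
#' @return 1-based model index; cluster assignment attached as attribute
#'   `"clusters"`.
#' @export
representative <- function(ens, cluster_cutoff = 2.0, rmsd_mat = NULL) {
  if (is.null(rmsd_mat)) rmsd_mat <- pairwise_rmsd(ens)
  comp <- single_linkage_clusters(rmsd_mat, cluster_cutoff)
  sizes <- tabulate(comp)
  # largest cluster; among equal sizes, the one appearing first
  best_cluster <- which(sizes == max(sizes))[1]
  members <- which(comp == best_cluster)
  if (length(members) == 1) {
    idx <- members
  } else {
    mean_r <- vapply(members, function(i) mean(rmsd_mat[i, setdiff(members, i)]), 1)
    idx <- members[which.min(mean_r)]  # which.min takes the first on ties
  }
  structure(idx, clusters = comp)
}

#' Per-residue consensus fluctuation profile
#'
#' Every model is superposed onto the reference model (default: the
#' [representative()]) on a consensus core found by iterative trimming:
#' starting from all residues, residues deviating more than twice the median
#' deviation are dropped and the fit repeated, up to `max_iter` rounds.  The
#' profile is the mean CA deviation from the reference over the other
#' models.  Large values mark residues that fluctuate among models --
#' candidate unreliable local regions.
#'
#' @param ens a [new_ensemble()].
#' @param reference optional 1-based reference model index.
#' @param max_iter trimming iterations per model (default 10).
#' @return object of class `tbm_fluctuation`: numeric `per_residue`
#'   (Angstroms, `NA` where no usable CA) plus the `reference` index.
#' @export
fluctuation <- function(ens, reference = NULL, max_iter = 10L) {
  if (is.null(reference)) reference <- as.integer(representative(ens))
  L <- nres(ens$models[[1]])
  ref_ca <- ca_coords(ens$models[[reference]])
  dev <- matrix(NA_real_, nrow = 0, ncol = L)
  for (m in seq_len(ens$n)) {
    if (m == reference) next
    ca <- ca_coords(ens$models[[m]])
    ok <- which(stats::complete.cases(ca) & stats::complete.cases(ref_ca))
    core <- ok
    d_all <- rep(NA_real_, L)
    for (it in seq_len(max_iter)) {
      if (length(core) < 3) break
      sp <- kabsch(ca[core, , drop = FALSE], ref_ca[core, , drop = FALSE])
      moved <- apply_superposition(sp, ca[ok, , drop = FALSE])
      d_all[ok] <- sqrt(rowSums((moved - ref_ca[ok, , drop = FALSE])^2))
      med <- median(d_all[core])
      new_core <- ok[d_all[ok] <= max(2 * med, 1e-6)]
      if (length(new_core) < 3) break
      if (identical(new_core, core)) break
      core <- new_core
    }
    dev <- rbind(dev, d_all)
  }
  structure(list(per_residue = colMeans(dev, na.rm = TRUE), reference = reference),
            class = "tbm_fluctuation")
}

#' @export
print.tbm_fluctuation <- function(x, ...) {
  cat(sprintf("<tbm_fluctuation> %d residues, mean %.2f A (reference model %d)\n",
              length(x$per_residue), mean(x$per_residue, na.rm = TRUE),
              x$reference))
  invisible(x)
}

#' Write a fluctuation profile as TSV
#' @param profile a [fluctuation()] result.
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  writeLines(c("residue\tfluctuation",
               sprintf("%d\t%.4f", seq_along(profile$per_residue),
                       profile$per_residue)), path)
  invisible(path)
}

#' Read a fluctuation profile TSV
#' @param path file written by [write_profile()].
#' @export
read_profile <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  structure(list(per_residue = tab$fluctuation[order(tab$residue)],
                 reference = NA_integer_),
            class = "tbm_fluctuation")
}
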