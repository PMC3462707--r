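# Unreliable local regions (ULRs): contiguous target stretches -- loops or
# termini -- that fluctuate among candidate models.  They are detected from
# the consensus fluctuation profile, filtered by length (6-20 residues),
# capped at 3 per target (largest fluctuations first), rebuilt externally,
# and grafted back into the fixed core.

#' Build a ULR region table
#' @param start,end inclusive 1-based bounds.
#' @param target_length target length (decides loop vs terminus kind).
#' @param reliability mean fluctuation over the region (Angstroms); larger
#'   means less reliable.
#' @return data frame with columns start, end, length, kind, reliability.
#' @export
ulr_region <- function(start, end, target_length, reliability = NA_real_) {
  stopifnot(all(start >= 1), all(end <= target_length), all(start <= end))
  kind <- ifelse(start == 1 | end == target_length, "terminus", "loop")
  data.frame(start = as.integer(start), end = as.integer(end),
             length = as.integer(end - start + 1L),
             kind = as.character(kind),
             reliability = rep_len(reliability, length(start)),
             stringsAsFactors = FALSE)
}

#' Detect unreliable local regions from a fluctuation profile
#'
#' Maximal runs of residues whose fluctuation is at or above `threshold`;
#' runs separated by at most `merge_gap` residues are merged.  A region
#' touching position 1 or the last residue is a terminus, otherwise a loop.
#' Reliability is the mean fluctuation over the (merged) region.
#'
#' @param profile a [fluctuation()] object or numeric per-residue vector.
#' @param threshold detection threshold in Angstroms (default 2.0).
#' @param merge_gap maximal gap bridged between runs (default 2).
#' @return [ulr_region()] data frame sorted by start (0 rows if none).
#' @export
detect_ulr <- function(profile, threshold = 2.0, merge_gap = 2L) {
  p <- if (inherits(profile, "tbm_fluctuation")) profile$per_residue else profile
  if (length(p) == 0) stop("empty fluctuation profile")
  if (threshold <= 0) stop("threshold must be positive")
  L <- length(p)
  flag <- !is.na(p) & p >= threshold
  if (!any(flag)) return(ulr_region(integer(0), integer(0), L))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      last <- nrow(merged)
      if (runs[i, 1] - merged[last, 2] - 1L <= merge_gap)
        merged[last, 2] <- runs[i, 2]
      else
        merged <- rbind(merged, runs[i, ])
    }
  }
  rel <- vapply(seq_len(nrow(merged)),
                function(i) mean(p[merged[i, 1]:merged[i, 2]], na.rm = TRUE), 1)
  ulr_region(merged[, 1], merged[, 2], L, rel)
}

#' Filter and select ULRs for reconstruction
#'
#' Regions shorter than `min_len` (6) or longer than `max_len` (20) residues
#' are eliminated; of the survivors, the `max_regions` (up to 3) with the
#' largest fluctuations (lowest reliability) are selected for actual
#' reconstruction.  Ties resolve to the earlier start.  Terminus regions can
#' optionally be exempted from the maximum-length rule.
#'
#' @param regions [ulr_region()] data frame (non-overlapping).
#' @param min_len,max_len length bounds in residues (defaults 6, 20).
#' @param max_regions selection cap (default 3).
#' @param exempt_termini_max if `TRUE`, terminus regions skip the `max_len`
#'   rule (default `FALSE`: the filter applies uniformly).
#' @return selected regions, sorted by start.
#' @export
filter_and_select <- function(regions, min_len = 6L, max_len = 20L,
                              max_regions = 3L, exempt_termini_max = FALSE) {
  if (nrow(regions) > 1) {
    o <- order(regions$start)
    if (any(regions$start[o][-1] <= regions$end[o][-nrow(regions)]))
      stop("ULR regions overlap")
  }
  len_ok <- regions$length >= min_len &
    (regions$length <= max_len |
       (exempt_termini_max & regions$kind == "terminus"))
  surv <- regions[len_ok, , drop = FALSE]
  o <- order(-surv$reliability, surv$start)
  sel <- surv[head(o, max_regions), , drop = FALSE]
  sel[order(sel$start), , drop = FALSE]
}

#' Write ULR regions as TSV
#' @param regions [ulr_region()] data frame.
#' @param path output file.
#' @export
write_ulr_table <- function(regions, path) {
  write.table(regions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Graft rebuilt region coordinates into a model
#'
#' Replaces the atoms of each region with externally rebuilt coordinates
#' while leaving every atom outside the grafted regions bit-identical.
#' Peptide-bond continuity at the junctions (C-N distance within
#' \[1.2, 1.5\] A) is checked and reported in the `"junctions"` attribute,
#' not enforced.
#'
#' @param model a `tbm_structure`.
#' @param regions [ulr_region()] data frame (1+ non-overlapping rows).
#' @param new_coords either a `tbm_structure` whose residues cover all region
#'   positions with matching identities, or a list of per-residue atom
#'   matrices named by target position.
#' @return grafted `tbm_structure` with attribute `"junctions"`: data frame
#'   (position of the C-side residue, distance, ok).
#' @export
graft <- function(model, regions, new_coords) {
  if (nrow(regions) == 0) return(model)
  pos <- unlist(Map(seq, regions$start, regions$end))
  if (anyDuplicated(pos)) stop("graft regions overlap")
  coords <- if (inherits(new_coords, "tbm_structure")) {
    setNames(new_coords$atoms, new_coords$seq_pos)
  } else new_coords
  miss <- setdiff(as.character(pos), names(coords))
  if (length(miss) > 0)
    stop("new_coords missing positions: ", paste(miss, collapse = ", "))
  if (inherits(new_coords, "tbm_structure")) {
    ident <- setNames(new_coords$aa, new_coords$seq_pos)
    bad <- pos[model$aa[pos] != ident[as.character(pos)]]
    if (length(bad) > 0)
      stop("residue identity mismatch at position(s): ",
           paste(bad, collapse = ", "))
  }
  out <- model
  for (p in pos) out$atoms[[p]] <- coords[[as.character(p)]]
  out$incomplete <- vapply(out$atoms, function(m)
    !all(BACKBONE_ATOMS %in% rownames(m)), logical(1))
  # junction geometry report: C(i)-N(i+1) across every region boundary
  junctions <- data.frame(position = integer(0), distance = numeric(0),
                          ok = logical(0))
  L <- nres(out)
  bounds <- unique(c(regions$start - 1L, regions$end))
  for (b in bounds) {
    if (b < 1 || b >= L) next
    a1 <- out$atoms[[b]]; a2 <- out$atoms[[b + 1L]]
    if (!("C" %in% rownames(a1)) || !("N" %in% rownames(a2))) next
    d <- sqrt(sum((a1["C", ] - a2["N", ])^2))
    junctions <- rbind(junctions,
                       data.frame(position = b, distance = d,
                                  ok = d >= 1.2 & d <= 1.5))
  }
  attr(out, "junctions") <- junctions
  out
}

#' RMSD of a ULR after whole-structure superposition
#'
#' The model is superposed onto the native structure on all shared
#' non-disordered CA atoms of the whole structures (not just the region),
#' then the RMSD is computed over the region's CA atoms without
#' re-superposition.  Regions with more than half of their native residues
#' disordered are excluded from scoring: the function returns `NA` with a
#' warning.
#'
#' @param model,native `tbm_structure` objects with identical sequences.
#' @param region one [ulr_region()] row.
#' @return RMSD in Angstroms, or `NA` for a mostly-disordered region.
#' @export
ulr_rmsd <- function(model, native, region) {
  if (structure_seq(model) != structure_seq(native))
    stop("model and native sequences differ")
  rpos <- region$start:region$end
  ca_m <- ca_coords(model); ca_n <- ca_coords(native)
  native_ok <- stats::complete.cases(ca_n)
  if (sum(!native_ok[rpos]) > length(rpos) / 2) {
    warning("more than half of the region's native residues are disordered; ",
            "region excluded from scoring")
    return(NA_real_)
  }
  shared <- which(stats::complete.cases(ca_m) & native_ok)
  if (length(setdiff(shared, rpos)) < 3)
    stop("fewer than 3 shared residues outside the region for superposition")
  sp <- kabsch(ca_m[shared, , drop = FALSE], ca_n[shared, , drop = FALSE])
  rsel <- intersect(rpos, shared)
  if (length(rsel) == 0) stop("no usable CA atoms inside the region")
  moved <- apply_superposition(sp, ca_m[rsel, , drop = FALSE])
  sqrt(mean(rowSums((moved - ca_n[rsel, , drop = FALSE])^2)))
}
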