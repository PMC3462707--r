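# Core-region handling around the external multiple sequence alignment:
# target termini aligned to no template are trimmed before the MSA is built,
# then reattached afterwards as all-gap columns (they are left for the later
# unreliable-region modeling).  The core region itself is defined by the
# columns where the top template is aligned.

#' Find terminus trim for the core alignment
#'
#' `n_trim` is the longest prefix of target positions aligned in no template
#' alignment; `c_trim` the analogous suffix.  Interior positions are never
#' trimmed.
#'
#' @param target_seq target amino-acid sequence (one-letter string).
#' @param alignments list of 2-column (target_pos, template_pos) matrices,
#'   one per template (typically `aligned_pairs` of the selected hits).
#' @return object of class `tbm_trim`: `n_trim`, `c_trim`, `trimmed_seq`,
#'   plus the full sequence as `full_seq`.
#' @export
find_trim <- function(target_seq, alignments) {
  L <- nchar(target_seq)
  if (L == 0) stop("empty target sequence")
  if (length(alignments) == 0) stop("need at least one template alignment")
  covered <- rep(FALSE, L)
  for (a in alignments) {
    p <- a[, 1]
    covered[p[p >= 1 & p <= L]] <- TRUE
  }
  if (!any(covered)) stop("no target position aligned to any template")
  first <- which(covered)[1]
  last <- max(which(covered))
  n_trim <- first - 1L
  c_trim <- L - last
  structure(list(n_trim = n_trim, c_trim = c_trim,
                 trimmed_seq = substr(target_seq, first, last),
                 full_seq = target_seq),
            class = "tbm_trim")
}

#' @export
print.tbm_trim <- function(x, ...) {
  cat(sprintf("<tbm_trim> N-terminus %d, C-terminus %d (core %d of %d residues)\n",
              x$n_trim, x$c_trim, nchar(x$trimmed_seq), nchar(x$full_seq)))
  invisible(x)
}

#' Reattach trimmed termini to a core alignment
#'
#' Prepends/appends the trimmed target residues as terminal columns that are
#' gaps in every template row, so the ungapped target row equals the full
#' original sequence and template rows are untouched in their aligned
#' columns.  No alignment of the termini is attempted: they are left for
#' downstream local remodeling.
#'
#' @param msa a [new_alignment()] over the trimmed target sequence.
#' @param trim a [find_trim()] result.
#' @export
reattach <- function(msa, trim) {
  tgt <- aln_sequence(msa, msa$target)
  if (tgt != trim$trimmed_seq)
    stop("MSA target row does not ungap to the trimmed sequence")
  if (trim$n_trim == 0 && trim$c_trim == 0) return(msa)
  L <- nchar(trim$full_seq)
  nseg <- substr(trim$full_seq, 1, trim$n_trim)
  cseg <- substr(trim$full_seq, L - trim$c_trim + 1, L)
  rows <- vapply(msa$names, function(nm) {
    if (nm == msa$target)
      paste0(nseg, msa$rows[[nm]], cseg)
    else
      paste0(strrep("-", trim$n_trim), msa$rows[[nm]], strrep("-", trim$c_trim))
  }, "")
  new_alignment(msa$names, unname(rows), target = msa$target)
}

#' Core-region mask from an alignment
#'
#' The core region is the set of target residues aligned with the single
#' top-ranking template in the MSA: target positions in columns where the
#' top-template row is not a gap.
#'
#' @param msa a `tbm_alignment`.
#' @param top_template name of the top-template row.
#' @return object of class `tbm_core_mask`: `target_length`,
#'   `core_positions` (sorted 1-based), `coverage` (fraction of the target).
#' @export
core_mask <- function(msa, top_template) {
  if (!top_template %in% msa$names)
    stop("template '", top_template, "' not in alignment")
  tpos <- msa$col_to_pos[[msa$target]]
  tmpl <- msa$col_to_pos[[top_template]]
  core <- sort(tpos[!is.na(tpos) & !is.na(tmpl)])
  L <- nchar(aln_sequence(msa, msa$target))
  if (length(core) == 0)
    warning("top-template row is all gaps: empty core region")
  structure(list(target_length = L, core_positions = core,
                 coverage = length(core) / L),
            class = "tbm_core_mask")
}

#' @export
print.tbm_core_mask <- function(x, ...) {
  cat(sprintf("<tbm_core_mask> %d of %d residues (%.0f%% coverage)\n",
              length(x$core_positions), x$target_length, 100 * x$coverage))
  invisible(x)
}

#' Write a core mask as BED-like TSV
#'
#' Columns: target name, 0-based start, end (half-open), label.  Contiguous
#' runs of core positions become one interval each.
#'
#' @param mask a [core_mask()] result.
#' @param path output file.
#' @param target target name for the first column.
#' @export
write_core_mask <- function(mask, path, target = "target") {
  p <- mask$core_positions
  if (length(p) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  brk <- which(diff(p) != 1)
  starts <- p[c(1, brk + 1)]; ends <- p[c(brk, length(p))]
  writeLines(sprintf("%s\t%d\t%d\tcore", target, starts - 1L, ends), path)
  invisible(path)
}
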