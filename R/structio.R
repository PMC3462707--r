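#' @importFrom stats median sd setNames
#' @importFrom utils head read.table write.table
NULL

# Atom names required for a residue to count as backbone-complete.
BACKBONE_ATOMS <- c("N", "CA", "C")

AA1 <- c("ALA" = "A", "ARG" = "R", "ASN" = "N", "ASP" = "D", "CYS" = "C",
         "GLN" = "Q", "GLU" = "E", "GLY" = "G", "HIS" = "H", "ILE" = "I",
         "LEU" = "L", "LYS" = "K", "MET" = "M", "PHE" = "F", "PRO" = "P",
         "SER" = "S", "THR" = "T", "TRP" = "W", "TYR" = "Y", "VAL" = "V")
AA3 <- setNames(names(AA1), AA1)

#' Construct a protein structure object
#'
#' A `tbm_structure` is an ordered chain of residues renumbered 1..L over the
#' target sequence.  Each residue carries a named atom coordinate matrix in
#' Angstroms.  Residues missing any of the N, CA, C backbone atoms are flagged
#' incomplete and are excluded from all metric computations; residues flagged
#' disordered (missing from an experimental file) are likewise excluded.
#'
#' @param aa character vector of one-letter amino-acid codes (or `"X"`).
#' @param atoms list (one element per residue) of numeric matrices with 3
#'   columns and atom names as rownames.
#' @param chain_id single chain identifier.
#' @param author_resno original residue numbering from the source file
#'   (metadata only; all package rules use the 1..L renumbering).
#' @param disordered logical vector marking residues absent from an
#'   experimental structure.
#' @param source_path provenance string.
#' @return object of class `tbm_structure`.
#' @export
new_structure <- function(aa, atoms, chain_id = "A",
                          author_resno = seq_along(aa),
                          disordered = rep(FALSE, length(aa)),
                          source_path = NA_character_) {
  stopifnot(length(aa) == length(atoms), length(aa) == length(disordered))
  if (!all(aa %in% c(names(AA3), "X")))
    stop("amino-acid codes must be one of the 20 standard one-letter codes or 'X'")
  atoms <- lapply(atoms, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (ncol(m) != 3L) stop("atom coordinate matrices must have 3 columns")
    if (nrow(m) > 0 && any(!is.finite(m))) stop("coordinates must be finite")
    m
  })
  incomplete <- vapply(atoms, function(m) !all(BACKBONE_ATOMS %in% rownames(m)),
                       logical(1))
  structure(
    list(aa = as.character(aa),
         seq_pos = seq_along(aa),
         author_resno = as.integer(author_resno),
         atoms = atoms,
         incomplete = incomplete,
         disordered = as.logical(disordered),
         chain_id = chain_id,
         source_path = source_path),
    class = "tbm_structure")
}

#' @export
print.tbm_structure <- function(x, ...) {
  cat(sprintf("<tbm_structure> %d residues, chain %s (%d incomplete, %d disordered)\n",
              length(x$aa), x$chain_id, sum(x$incomplete), sum(x$disordered)))
  invisible(x)
}

#' @export
length.tbm_structure <- function(x) length(x$aa)

#' Number of residues in a structure
#' @param x a `tbm_structure`.
#' @export
nres <- function(x) length(x$aa)

#' One-letter sequence of a structure
#' @param x a `tbm_structure`.
#' @export
structure_seq <- function(x) paste(x$aa, collapse = "")

#' Extract CA coordinates
#'
#' Returns an L x 3 matrix of CA coordinates with `NA` rows for residues that
#' are incomplete, disordered, or lack a CA atom.
#'
#' @param x a `tbm_structure`.
#' @param positions optional 1-based residue positions to extract.
#' @export
ca_coords <- function(x, positions = NULL) {
  if (is.null(positions)) positions <- x$seq_pos
  out <- matrix(NA_real_, nrow = length(positions), ncol = 3,
                dimnames = list(positions, c("x", "y", "z")))
  for (i in seq_along(positions)) {
    p <- positions[i]
    if (p < 1 || p > length(x$aa)) next
    if (x$incomplete[p] || x$disordered[p]) next
    m <- x$atoms[[p]]
    if ("CA" %in% rownames(m)) out[i, ] <- m["CA", ]
  }
  out
}

#' Read a PDB coordinate file
#'
#' Parses ATOM records (via bio3d), drops heteroatoms and waters, resolves
#' alternate locations to the highest-occupancy copy, and renumbers residues
#' 1..L in file order (author numbering kept as metadata).  Files with
#' insertion codes are rejected: the pipeline's interval rules assume a plain
#' sequential numbering.
#'
#' @param path PDB file path.
#' @param chain optional chain identifier; default takes the first chain.
#' @return a [new_structure()] object.
#' @export
read_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0) stop("chain '", chain, "' not present in ", path)
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes are not supported (file ", path, ")")
  # altloc: keep highest occupancy per (resno, atom name)
  has_alt <- !is.na(at$alt) & at$alt != ""
  if (any(has_alt)) {
    key <- paste(at$resno, at$elety)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
      if (length(idx) == 1) return(idx)
      occ <- at$o[idx]
      occ[is.na(occ)] <- 0
      idx[which.max(occ)]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  resno <- unique(at$resno)
  atoms <- vector("list", length(resno))
  aa <- character(length(resno))
  for (i in seq_along(resno)) {
    sub <- at[at$resno == resno[i], , drop = FALSE]
    sub <- sub[!duplicated(sub$elety), , drop = FALSE]
    m <- as.matrix(sub[, c("x", "y", "z")])
    rownames(m) <- sub$elety
    atoms[[i]] <- m
    code <- AA1[sub$resid[1]]
    aa[i] <- if (is.na(code)) "X" else unname(code)
  }
  new_structure(aa, atoms, chain_id = chain, author_resno = resno,
                source_path = path)
}

#' Write a structure as a PDB file
#'
#' @param x a `tbm_structure`.
#' @param path output file.
#' @param author_numbering write original author residue numbers instead of
#'   the internal 1..L numbering.
#' @export
write_pdb <- function(x, path, author_numbering = FALSE) {
  keep <- which(!x$disordered)
  elety <- character(0); resno <- integer(0); resid <- character(0)
  xyz <- numeric(0)
  for (i in keep) {
    m <- x$atoms[[i]]
    if (nrow(m) == 0) next
    elety <- c(elety, rownames(m))
    num <- if (author_numbering) x$author_resno[i] else x$seq_pos[i]
    resno <- c(resno, rep(num, nrow(m)))
    aa3 <- if (x$aa[i] == "X") "UNK" else AA3[x$aa[i]]
    resid <- c(resid, rep(aa3, nrow(m)))
    xyz <- c(xyz, as.vector(t(m)))
  }
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", length(elety)),
                   resno = resno, resid = resid, eleno = seq_along(elety),
                   elety = elety, chain = rep(x$chain_id, length(elety)),
                   o = rep(1, length(elety)), b = rep(0, length(elety)))
  invisible(path)
}

# ---- homology-search hit tables ----------------------------------------

#' Construct a homology-search hit record
#'
#' One hit from a homology search: raw sequence and secondary-structure
#' similarity scores (search-tool units), match probability in percent, and
#' the query-template alignment as 1-based (target_pos, template_pos) pairs.
#' The standardized scores `z_seq`, `z_ss` and the combined score `rescored`
#' are unset until [rescore()] fills them.
#'
#' @param template_id template identifier.
#' @param raw_seq_score,raw_ss_score raw similarity scores.
#' @param probability match probability, percent in \[0, 100\].
#' @param aligned_pairs 2-column integer matrix (target_pos, template_pos);
#'   must be one-to-one and monotone (no crossing pairs).
#' @param rank original rank in the search output (1 = top).
#' @export
new_hit <- function(template_id, raw_seq_score, raw_ss_score, probability,
                    aligned_pairs, rank = NA_integer_) {
  aligned_pairs <- matrix(as.integer(aligned_pairs), ncol = 2,
                          dimnames = list(NULL, c("target", "template")))
  if (nrow(aligned_pairs) > 0) {
    if (anyDuplicated(aligned_pairs[, 1]) || anyDuplicated(aligned_pairs[, 2]))
      stop("aligned_pairs must be one-to-one in both coordinates")
    o <- order(aligned_pairs[, 1])
    if (is.unsorted(aligned_pairs[o, 2], strictly = TRUE))
      stop("aligned_pairs must be monotone (no crossing pairs)")
    aligned_pairs <- aligned_pairs[o, , drop = FALSE]
  }
  if (is.na(probability) || probability < 0 || probability > 100)
    stop("probability must lie in [0, 100], got ", probability)
  structure(
    list(template_id = as.character(template_id),
         raw_seq_score = as.numeric(raw_seq_score),
         raw_ss_score = as.numeric(raw_ss_score),
         probability = as.numeric(probability),
         aligned_pairs = aligned_pairs,
         rank = as.integer(rank),
         z_seq = NA_real_, z_ss = NA_real_, rescored = NA_real_),
    class = "tbm_hit")
}

#' @export
print.tbm_hit <- function(x, ...) {
  cat(sprintf("<tbm_hit> %s p=%.1f seq=%.2f ss=%.2f S=%s (%d aligned)\n",
              x$template_id, x$probability, x$raw_seq_score, x$raw_ss_score,
              ifelse(is.na(x$rescored), "unset", sprintf("%.3f", x$rescored)),
              nrow(x$aligned_pairs)))
  invisible(x)
}

#' Summarize a hit list as a data frame
#' @param hits list of [new_hit()] records.
#' @export
hits_table <- function(hits) {
  data.frame(
    template_id = vapply(hits, `[[`, "", "template_id"),
    rank = vapply(hits, `[[`, 1L, "rank"),
    raw_seq_score = vapply(hits, `[[`, 1, "raw_seq_score"),
    raw_ss_score = vapply(hits, `[[`, 1, "raw_ss_score"),
    probability = vapply(hits, `[[`, 1, "probability"),
    z_seq = vapply(hits, `[[`, 1, "z_seq"),
    z_ss = vapply(hits, `[[`, 1, "z_ss"),
    rescored = vapply(hits, `[[`, 1, "rescored"),
    n_aligned = vapply(hits, function(h) nrow(h$aligned_pairs), 1L),
    stringsAsFactors = FALSE)
}

# Alignment-string dialect used by the 5-column TSV hit format:
# comma-separated "target:template" 1-based pairs, e.g. "1:3,2:4,5:7".
parse_pair_string <- function(s) {
  s <- trimws(s)
  if (s == "" || s == "-") return(matrix(integer(0), ncol = 2))
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  if (any(vapply(parts, length, 1L) != 2))
    stop("malformed alignment pair string: ", s)
  m <- do.call(rbind, lapply(parts, as.integer))
  if (any(is.na(m))) stop("non-integer alignment pair in: ", s)
  m
}

format_pair_string <- function(pairs) {
  if (nrow(pairs) == 0) return("-")
  paste(sprintf("%d:%d", pairs[, 1], pairs[, 2]), collapse = ",")
}

#' Read a homology-search hit table
#'
#' Two dialects are supported.  `"tsv"` is the package's documented 5-column
#' tab-separated format: `template_id`, `raw_seq_score`, `raw_ss_score`,
#' `probability` (percent), and the alignment as comma-separated
#' `target:template` 1-based residue pairs (`-` for none); lines starting with
#' `#` are comments.  `"hhr"` parses HHsearch result files, taking the Score
#' and SS columns of the summary table as the raw sequence and
#' secondary-structure similarity scores and reading the aligned residue pairs
#' from the Q/T alignment blocks; all other HHR content is ignored.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"hhr"`.
#' @return list of [new_hit()] records in file order, ranks 1..n.
#' @export
read_hit_table <- function(path, dialect = c("tsv", "hhr")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("hit file not found: ", path)
  if (dialect == "tsv") read_hits_tsv(path) else read_hits_hhr(path)
}

read_hits_tsv <- function(path) {
  lines <- readLines(path)
  hits <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (grepl("^\\s*(#|$)", line)) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 5)
      stop("malformed hit line ", ln, ": expected 5 tab-separated fields, got ",
           length(f))
    scores <- suppressWarnings(as.numeric(f[2:4]))
    if (any(is.na(scores)))
      stop("malformed hit line ", ln, ": non-numeric score field")
    hit <- tryCatch(
      new_hit(f[1], scores[1], scores[2], scores[3], parse_pair_string(f[5]),
              rank = length(hits) + 1L),
      error = function(e) stop("malformed hit line ", ln, ": ",
                               conditionMessage(e), call. = FALSE))
    hits[[length(hits) + 1L]] <- hit
  }
  hits
}

#' Write hits in the 5-column TSV dialect
#' @param hits list of hit records.
#' @param path output file.
#' @export
write_hit_table <- function(hits, path) {
  lines <- c("# template_id\traw_seq_score\traw_ss_score\tprobability\talignment",
             vapply(hits, function(h) {
               sprintf("%s\t%.6g\t%.6g\t%.6g\t%s", h$template_id,
                       h$raw_seq_score, h$raw_ss_score, h$probability,
                       format_pair_string(h$aligned_pairs))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

read_hits_hhr <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*No Hit", lines)
  if (length(hdr) == 0) stop("not an HHR file (no summary header): ", path)
  # summary table: fixed columns Prob Evalue Pvalue Score SS Cols ...
  i <- hdr[1] + 1
  summ <- list()
  while (i <= length(lines) && grepl("^\\s*\\d+\\s", lines[i])) {
    # numeric tail starts after the free-text hit description
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    toks <- toks[!grepl("^\\(\\d+\\)$", toks)]  # trailing template length
    n <- length(toks)
    if (n < 9) stop("malformed HHR summary line ", i)
    # last 8 tokens: Prob Evalue Pvalue Score SS Cols Query-HMM Template-HMM
    tail8 <- toks[(n - 7):n]
    summ[[length(summ) + 1L]] <- list(
      no = as.integer(toks[1]), id = toks[2],
      prob = as.numeric(tail8[1]), score = as.numeric(tail8[4]),
      ss = as.numeric(tail8[5]))
    i <- i + 1
  }
  # alignment blocks
  blocks <- grep("^No \\d+", lines)
  hits <- vector("list", length(summ))
  for (k in seq_along(summ)) {
    from <- blocks[k]
    to <- if (k < length(blocks)) blocks[k + 1] - 1 else length(lines)
    pairs <- parse_hhr_block(lines[from:to])
    s <- summ[[k]]
    hits[[k]] <- new_hit(s$id, s$score, s$ss, s$prob, pairs, rank = k)
  }
  hits
}

parse_hhr_block <- function(block) {
  skip <- "(ss_pred|ss_dssp|ss_conf|Consensus)"
  qlines <- grep(paste0("^Q (?!", skip, ")\\S+\\s+\\d+"), block,
                 perl = TRUE, value = TRUE)
  tlines <- grep(paste0("^T (?!", skip, ")\\S+\\s+\\d+"), block,
                 perl = TRUE, value = TRUE)
  pairs <- matrix(integer(0), ncol = 2)
  for (j in seq_along(qlines)) {
    qt <- strsplit(trimws(qlines[j]), "\\s+")[[1]]
    tt <- strsplit(trimws(tlines[j]), "\\s+")[[1]]
    qseq <- qt[4]; qstart <- as.integer(qt[3])
    tseq <- tt[4]; tstart <- as.integer(tt[3])
    qc <- strsplit(qseq, "")[[1]]; tc <- strsplit(tseq, "")[[1]]
    qi <- qstart; ti <- tstart
    for (c in seq_along(qc)) {
      qg <- qc[c] == "-"; tg <- tc[c] == "-"
      if (!qg && !tg) pairs <- rbind(pairs, c(qi, ti))
      if (!qg) qi <- qi + 1
      if (!tg) ti <- ti + 1
    }
  }
  pairs
}

# ---- multiple sequence alignments --------------------------------------

#' Construct an alignment set
#'
#' Target-plus-templates multiple alignment.  Rows are equal-length gapped
#' sequences; `col_to_pos` maps each alignment column (1-based internally) to
#' the 1-based residue position in that row, `NA` at gaps.
#'
#' @param names row names, target first by convention.
#' @param rows character vector of gapped sequences (same order as `names`).
#' @param target name of the target row (default: first row).
#' @export
new_alignment <- function(names, rows, target = names[1]) {
  if (length(names) != length(rows)) stop("names/rows length mismatch")
  if (length(rows) < 2) stop("an alignment needs at least 2 rows")
  if (anyDuplicated(names)) stop("duplicate row names in alignment")
  w <- unique(nchar(rows))
  if (length(w) != 1) stop("alignment rows have unequal lengths: ",
                           paste(sort(w), collapse = ", "))
  if (!target %in% names) stop("target row '", target, "' not in alignment")
  col_to_pos <- lapply(rows, function(r) {
    ch <- strsplit(r, "")[[1]]
    pos <- cumsum(ch != "-")
    pos[ch == "-"] <- NA_integer_
    as.integer(pos)
  })
  names(col_to_pos) <- names
  structure(list(names = names, rows = setNames(rows, names),
                 col_to_pos = col_to_pos, target = target, width = w),
            class = "tbm_alignment")
}

#' @export
print.tbm_alignment <- function(x, ...) {
  cat(sprintf("<tbm_alignment> %d rows x %d columns (target: %s)\n",
              length(x$names), x$width, x$target))
  invisible(x)
}

#' Ungapped sequence of one alignment row
#' @param aln a `tbm_alignment`.
#' @param name row name.
#' @export
aln_sequence <- function(aln, name) gsub("-", "", aln$rows[[name]], fixed = TRUE)

#' Read a multiple sequence alignment
#'
#' @param path file path.
#' @param format `"fasta"` (aligned FASTA) or `"clustal"`.
#' @param target name of the target row; defaults to the first row.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"), target = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  msa <- Biostrings::readAAMultipleAlignment(path, format = format)
  rows <- as.character(msa)
  nm <- names(rows)
  # keep only the identifier token of FASTA description lines
  nm <- vapply(strsplit(nm, "\\s+"), `[[`, "", 1)
  if (is.null(target)) target <- nm[1]
  new_alignment(nm, unname(rows), target = target)
}

#' Write a multiple sequence alignment
#' @param aln a `tbm_alignment`.
#' @param path output file.
#' @param format `"fasta"` or `"clustal"`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "fasta") {
    writeLines(as.vector(rbind(paste0(">", aln$names), unname(aln$rows))), path)
  } else {
    wname <- max(nchar(aln$names)) + 3
    out <- c("CLUSTAL W multiple sequence alignment", "", "")
    for (from in seq(1, aln$width, by = 60)) {
      to <- min(from + 59, aln$width)
      block <- sprintf("%-*s%s", wname, aln$names, substr(aln$rows, from, to))
      conservation <- strrep(" ", wname + to - from + 1)  # reader requires it
      out <- c(out, block, conservation, "")
    }
    writeLines(out, path)
  }
  invisible(path)
}

#' Read a single sequence from a FASTA file
#' @param path FASTA file with one (or more; first used) record.
#' @return named character scalar.
#' @export
read_fasta_seq <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  if (length(s) == 0) stop("no sequences in ", path)
  setNames(as.character(s[[1]]), strsplit(names(s)[1], "\\s+")[[1]][1])
}
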