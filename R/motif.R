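# Basal UG motif detection in precursor-context sequences.
#
# The basal UG dinucleotide at the single-strand/stem junction of a
# pri-miRNA hairpin promotes Drosha recognition; it is anchored 14 nt
# upstream of the 5' end of the 5p mature miRNA. Precursors lacking it are
# candidates for heightened sensitivity to reduced Microprocessor dosage.

#' Construct a precursor context
#'
#' @param locus_id Locus identifier.
#' @param sequence RNA or DNA string in transcript (sense) orientation
#'   covering the hairpin plus basal flank; `T` is treated as `U`,
#'   case-insensitively. Allowed alphabet: A, C, G, U, T, N.
#' @param fivep_offset 0-based index of the first nucleotide of the 5p
#'   mature miRNA within `sequence`; must be at least 14 so the motif
#'   window exists.
#' @return A list of class `precursor_context`.
#' @export
precursor_context <- function(locus_id, sequence, fivep_offset) {
  sequence <- toupper(as.character(sequence))
  if (grepl("[^ACGUTN]", sequence)) {
    stop("sequence for ", locus_id,
         " contains letters outside A/C/G/U/T/N")
  }
  fivep_offset <- as.integer(fivep_offset)
  if (is.na(fivep_offset) || fivep_offset < 14L) {
    stop("fivep_offset for ", locus_id,
         " must be >= 14 (motif window at -14/-13 must exist)")
  }
  if (fivep_offset > nchar(sequence)) {
    stop("fivep_offset for ", locus_id, " lies beyond the sequence")
  }
  structure(list(locus_id = locus_id, sequence = sequence,
                 fivep_offset = fivep_offset),
            class = "precursor_context")
}

#' Test for the basal UG motif
#'
#' Returns `TRUE` when the UG dinucleotide occupies positions -14/-13
#' relative to the 5' end of the 5p mature miRNA (position -1 being the
#' nucleotide immediately upstream), `FALSE` when it does not, and `NA`
#' (indeterminate) when the window contains an `N`. With `slack = 1` the
#' anchor may shift by one nucleotide in either direction, accommodating
#' one-off Drosha cleavage annotations across databases; the default is the
#' strict -14 anchor.
#'
#' @param ctx A [precursor_context()].
#' @param slack Non-negative integer anchor slack (default 0).
#' @return `TRUE`, `FALSE`, or `NA` for indeterminate.
#' @export
basal_ug_present <- function(ctx, slack = 0L) {
  stopifnot(is(ctx, "precursor_context"), slack >= 0L)
  chars <- strsplit(chartr("T", "U", ctx$sequence), "")[[1]]
  anchors <- ctx$fivep_offset - 14L + (-slack:slack)   # 0-based index of U
  anchors <- anchors[anchors >= 0L & anchors + 1L < ctx$fivep_offset]
  if (length(anchors) == 0L) stop("motif window does not exist")
  found <- FALSE
  saw_n <- FALSE
  for (a in anchors) {
    w <- chars[c(a + 1L, a + 2L)]   # 1-based
    if (any(w == "N")) { saw_n <- TRUE; next }
    if (w[1] == "U" && w[2] == "G") found <- TRUE
  }
  if (found) TRUE else if (saw_n) NA else FALSE
}

#' Read precursor contexts from FASTA plus an offsets table
#'
#' @param fasta_path FASTA of context sequences; record names are locus
#'   IDs (first whitespace-delimited token).
#' @param offsets_path TSV with header columns `locus_id` and
#'   `fivep_offset` (0-based within the FASTA record).
#' @return A named list of [precursor_context()] objects.
#' @export
read_precursor_contexts <- function(fasta_path, offsets_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  off <- read.table(offsets_path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  if (!all(c("locus_id", "fivep_offset") %in% names(off))) {
    stop("offsets table needs columns locus_id and fivep_offset")
  }
  missing <- setdiff(off$locus_id, names(seqs))
  if (length(missing) > 0L) {
    stop("offsets reference sequences absent from FASTA: ",
         paste(missing, collapse = ", "))
  }
  ctxs <- lapply(seq_len(nrow(off)), function(i) {
    precursor_context(off$locus_id[i],
                      as.character(seqs[[off$locus_id[i]]]),
                      off$fivep_offset[i])
  })
  names(ctxs) <- off$locus_id
  ctxs
}

#' Per-locus motif call table
#'
#' @param contexts List of [precursor_context()] objects.
#' @param slack Passed to [basal_ug_present()].
#' @return Data.frame with columns `locus_id` and `basal_ug` in
#'   `{"present", "absent", "indeterminate"}`.
#' @export
basal_ug_table <- function(contexts, slack = 0L) {
  calls <- vapply(contexts, function(ctx) {
    r <- basal_ug_present(ctx, slack = slack)
    if (is.na(r)) "indeterminate" else if (r) "present" else "absent"
  }, character(1))
  data.frame(locus_id = vapply(contexts, `[[`, character(1), "locus_id"),
             basal_ug = unname(calls), stringsAsFactors = FALSE)
}

#' Motif depletion contrast between two locus groups
#'
#' Cross-tabulates basal-UG presence between two disjoint locus groups
#' (e.g. DGCR8-sensitive primate-specific precursors vs the remainder) and
#' tests association with a two-sided exact test on the 2x2 table.
#' Indeterminate loci are excluded from the table and reported separately.
#'
#' @param contexts List of [precursor_context()] objects.
#' @param group_a,group_b Disjoint character vectors of locus IDs present
#'   in `contexts`.
#' @param slack Passed to [basal_ug_present()].
#' @return A list: `table` (2x2 matrix, rows = groups, columns =
#'   motif-positive/negative), `p_value` (two-sided exact test),
#'   `indeterminate` (locus IDs excluded).
#' @export
motif_depletion_report <- function(contexts, group_a, group_b, slack = 0L) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty")
  }
  if (length(intersect(group_a, group_b)) > 0L) {
    stop("groups must be disjoint")
  }
  ids <- vapply(contexts, `[[`, character(1), "locus_id")
  missing <- setdiff(c(group_a, group_b), ids)
  if (length(missing) > 0L) {
    stop("group locus IDs absent from contexts: ",
         paste(missing, collapse = ", "))
  }
  tab <- basal_ug_table(contexts, slack = slack)
  indet <- tab$locus_id[tab$basal_ug == "indeterminate"]
  count <- function(group) {
    sub <- tab[tab$locus_id %in% group & tab$basal_ug != "indeterminate", ]
    c(positive = sum(sub$basal_ug == "present"),
      negative = sum(sub$basal_ug == "absent"))
  }
  m <- rbind(group_a = count(group_a), group_b = count(group_b))
  p <- stats::fisher.test(m, alternative = "two.sided")$p.value
  list(table = m, p_value = p,
       indeterminate = intersect(indet, c(group_a, group_b)))
}
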