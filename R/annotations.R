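# Annotation loading and scoring-region derivation.
#
# All user-facing file coordinates follow the convention of the format they
# come in (BED: 0-based half-open; GFF3: 1-based inclusive). Internally loci
# are GRanges (1-based inclusive); conversion happens once at the I/O
# boundary so region arithmetic is done in a single convention.

#' Load pre-miRNA hairpin annotations
#'
#' Reads precursor (hairpin) loci from a BED6 file or a miRBase-dialect GFF3
#' file. GFF3 input must contain `miRNA_primary_transcript` features; `miRNA`
#' child features linked by a `Derives_from` attribute populate the mature
#' miRNA IDs of each hairpin. BED6 input carries no hairpin-to-mature
#' mapping, so `mature_ids` is empty for every locus.
#'
#' @param path Path to the annotation file.
#' @param format `"bed6"` or `"gff3"`.
#' @return A [GenomicRanges::GRanges] with one range per hairpin and
#'   metadata columns `locus_id` (unique), `mature_ids`
#'   (a [IRanges::CharacterList]) and `is_mirtron` (all `FALSE`; mirtron
#'   status is supplied separately as an ID list, see [load_id_list()]).
#' @details Strand is required: a `"."` strand raises an error, because MPI
#'   depth extraction is strand-specific. Duplicate locus IDs raise an
#'   error. Malformed BED lines raise an error naming the line number.
#' @seealso [derive_regions()], [export_regions_bed()]
#' @export
load_annotations <- function(path, format = c("bed6", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("annotation file not found: ", path)
  }
  loci <- switch(format,
    bed6 = read_bed6_loci(path),
    gff3 = read_gff3_loci(path)
  )
  dup <- duplicated(loci$locus_id)
  if (any(dup)) {
    stop("duplicate locus_id in ", path, ": ",
         paste(unique(loci$locus_id[dup]), collapse = ", "))
  }
  loci
}

read_bed6_loci <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(new_locus_granges(character(), character(), integer(), integer(),
                             character(), list()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  chrom <- name <- strand <- character(length(idx))
  start0 <- end0 <- integer(length(idx))
  for (i in seq_along(idx)) {
    f <- fields[[i]]
    line_no <- idx[i]
    if (length(f) < 6L) {
      stop("BED6 parse error at line ", line_no, ": expected >= 6 fields, got ",
           length(f))
    }
    s <- suppressWarnings(as.integer(f[2L]))
    e <- suppressWarnings(as.integer(f[3L]))
    if (is.na(s) || is.na(e)) {
      stop("BED6 parse error at line ", line_no, ": non-numeric coordinates")
    }
    if (s < 0L || s >= e) {
      stop("BED6 parse error at line ", line_no,
           ": require 0 <= start < end, got [", s, ",", e, ")")
    }
    if (!f[6L] %in% c("+", "-")) {
      stop("BED6 parse error at line ", line_no,
           ": strand must be '+' or '-', got '", f[6L], "'")
    }
    if (!nzchar(f[4L])) {
      stop("BED6 parse error at line ", line_no, ": empty name field")
    }
    chrom[i] <- f[1L]; start0[i] <- s; end0[i] <- e
    name[i] <- f[4L]; strand[i] <- f[6L]
  }
  new_locus_granges(chrom, name, start0 + 1L, end0, strand,
                    rep(list(character()), length(idx)))
}

read_gff3_loci <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  pri <- gff[gff$type == "miRNA_primary_transcript"]
  if (length(pri) == 0L) {
    stop("no miRNA_primary_transcript features found in ", path)
  }
  if (any(as.character(strand(pri)) == "*")) {
    stop("strand is required for miRNA_primary_transcript features in ", path)
  }
  locus_id <- gff_feature_name(pri)
  parent_key <- if (!is.null(pri$ID)) as.character(pri$ID) else locus_id

  mat <- gff[gff$type == "miRNA"]
  mature_ids <- rep(list(character()), length(pri))
  if (length(mat) > 0L && !is.null(mat$Derives_from)) {
    from <- as.character(mat$Derives_from)
    mat_name <- gff_feature_name(mat)
    hit <- match(from, parent_key)
    for (j in which(!is.na(hit))) {
      i <- hit[j]
      mature_ids[[i]] <- c(mature_ids[[i]], mat_name[j])
    }
  }
  new_locus_granges(as.character(seqnames(pri)), locus_id,
                    start(pri), end(pri), as.character(strand(pri)),
                    mature_ids)
}

gff_feature_name <- function(gr) {
  nm <- if (!is.null(gr$Name)) as.character(gr$Name) else NA_character_
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
  out <- ifelse(is.na(nm) | !nzchar(nm), id, nm)
  if (anyNA(out)) stop("GFF3 feature lacks both Name and ID attributes")
  out
}

new_locus_granges <- function(chrom, locus_id, start1, end1, strand, mature_ids) {
  gr <- GRanges(chrom, IRanges(start = start1, end = end1), strand = strand)
  mcols(gr)$locus_id <- locus_id
  mcols(gr)$mature_ids <- CharacterList(mature_ids)
  mcols(gr)$is_mirtron <- rep(FALSE, length(gr))
  names(gr) <- locus_id
  gr
}

#' Derive trimmed scoring regions for each hairpin
#'
#' For each hairpin the flanking transcript is taken `flank_len` nucleotides
#' on each side, then the outer `trim` nucleotides of both the hairpin and
#' each flank are excluded. This leaves a trimmed hairpin core and two flank
#' cores of `flank_len - trim` nucleotides separated from the hairpin core by
#' a `2 * trim` nucleotide gap (10 nt at defaults) that absorbs alternative
#' Drosha cleavage positions.
#'
#' @param loci Locus `GRanges` from [load_annotations()].
#' @param flank_len Flank length in nucleotides (default 100).
#' @param trim Nucleotides excluded from each end of hairpin and flanks
#'   (default 5).
#' @return A `GRanges` with three ranges per locus and metadata columns
#'   `locus_id` and `region` (one of `"hairpin"`, `"flank_left"`,
#'   `"flank_right"`). Coordinates depend only on hairpin start/end, never on
#'   strand, so MPI is orientation-symmetric.
#' @details Hairpins shorter than `2 * trim + 1` nucleotides and hairpins
#'   whose left flank would run off the chromosome start raise an error
#'   naming the locus; truncated flanks would bias the flank mean, so no
#'   silent truncation is performed.
#' @export
derive_regions <- function(loci, flank_len = 100L, trim = 5L) {
  stopifnot(flank_len > trim, trim >= 0L)
  s <- start(loci)   # 1-based inclusive
  e <- end(loci)
  len <- width(loci)
  ids <- mcols(loci)$locus_id

  short <- len <= 2L * trim
  if (any(short)) {
    stop("hairpin too short for trim=", trim, " (need length > ", 2L * trim,
         "): ", paste(ids[short], collapse = ", "))
  }
  underflow <- (s - flank_len) < 1L
  if (any(underflow)) {
    stop("left flank underflows chromosome start for: ",
         paste(ids[underflow], collapse = ", "))
  }

  chrom <- as.character(seqnames(loci))
  strd <- as.character(strand(loci))
  n <- length(loci)
  out <- GRanges(
    rep(chrom, each = 3L),
    IRanges(
      start = as.vector(rbind(s + trim, s - flank_len, e + trim + 1L)),
      end   = as.vector(rbind(e - trim, s - trim - 1L, e + flank_len))
    ),
    strand = rep(strd, each = 3L)
  )
  mcols(out)$locus_id <- rep(ids, each = 3L)
  mcols(out)$region <- rep(c("hairpin", "flank_left", "flank_right"), n)
  out
}

#' Load a one-identifier-per-line list file
#'
#' Carrier for the mirtron exclusion list, the detected-miRNA allowlist and
#' category membership lists. Lines starting with `#` are comments; blank
#' lines are skipped; duplicates are dropped.
#'
#' @param path Path to the text file.
#' @return A character vector of unique identifiers (possibly empty).
#' @export
load_id_list <- function(path) {
  if (!file.exists(path)) stop("ID list file not found: ", path)
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' Export loci or derived regions as BED6
#'
#' Region rows are named `<locus_id>.hairpin`, `<locus_id>.flankL` and
#' `<locus_id>.flankR`; plain loci keep their `locus_id`. Coordinates are
#' written 0-based half-open, so a BED6 load/export round-trip is bit-exact.
#'
#' @param gr Locus or region `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_regions_bed <- function(gr, path) {
  nm <- if (!is.null(mcols(gr)$region)) {
    suffix <- c(hairpin = ".hairpin", flank_left = ".flankL",
                flank_right = ".flankR")[mcols(gr)$region]
    paste0(mcols(gr)$locus_id, suffix)
  } else {
    mcols(gr)$locus_id
  }
  df <- data.frame(
    chrom = as.character(seqnames(gr)),
    start = format(start(gr) - 1L, scientific = FALSE, trim = TRUE),
    end = format(end(gr), scientific = FALSE, trim = TRUE),
    name = nm,
    score = 0L,
    strand = as.character(strand(gr))
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Report loci whose flanks overlap a neighbouring hairpin
#'
#' Clustered miRNAs can sit closer together than `flank_len`, in which case a
#' flank scoring region overlaps the neighbouring hairpin and its mean depth
#' reflects that hairpin's processing, not local transcription. This is an
#' advisory report, not an automatic filter; the flank-balance filter
#' partially guards against the resulting asymmetry.
#'
#' @inheritParams derive_regions
#' @return A data.frame with columns `locus_id`, `region`,
#'   `overlapping_locus` listing every flank core that intersects another
#'   locus's hairpin on the same strand.
#' @export
flank_overlap_report <- function(loci, flank_len = 100L, trim = 5L) {
  regions <- derive_regions(loci, flank_len = flank_len, trim = trim)
  flanks <- regions[mcols(regions)$region != "hairpin"]
  hits <- findOverlaps(flanks, loci, ignore.strand = FALSE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  keep <- mcols(flanks)$locus_id[qi] != mcols(loci)$locus_id[si]
  data.frame(
    locus_id = mcols(flanks)$locus_id[qi][keep],
    region = mcols(flanks)$region[qi][keep],
    overlapping_locus = mcols(loci)$locus_id[si][keep],
    stringsAsFactors = FALSE
  )
}
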