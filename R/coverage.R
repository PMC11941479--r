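# Strand-resolved per-nucleotide depth extraction and interval means.

#' Construct a stranded coverage object
#'
#' Holds per-chromosome, per-strand, per-nucleotide read depth for one
#' sample as run-length encoded vectors. Querying any interval on any
#' chromosome and strand is defined; unseen chromosomes have zero depth.
#'
#' @param plus,minus Named lists of [S4Vectors::Rle] (or plain numeric)
#'   depth vectors keyed by chromosome, for the plus and minus transcript
#'   strands.
#' @param sample_id Sample identifier.
#' @param orientation Library orientation the depths were derived under.
#' @return An object of class `StrandedCoverage`.
#' @export
stranded_coverage <- function(plus = list(), minus = list(),
                              sample_id = NA_character_,
                              orientation = c("reverse_stranded",
                                              "forward_stranded")) {
  orientation <- match.arg(orientation)
  as_rle_list <- function(x) {
    lapply(x, function(v) {
      v <- if (is(v, "Rle")) v else Rle(as.numeric(v))
      if (length(v) > 0L && min(runValue(v)) < 0) {
        stop("negative depth values are not allowed")
      }
      v
    })
  }
  structure(
    list(sample_id = sample_id, plus = as_rle_list(plus),
         minus = as_rle_list(minus), orientation = orientation),
    class = "StrandedCoverage"
  )
}

#' @export
print.StrandedCoverage <- function(x, ...) {
  cat("StrandedCoverage for sample", x$sample_id,
      "(", x$orientation, ")\n")
  cat("  + strand chromosomes:", paste(names(x$plus), collapse = ", "), "\n")
  cat("  - strand chromosomes:", paste(names(x$minus), collapse = ", "), "\n")
  invisible(x)
}

#' Extract stranded depth from a coordinate-sorted indexed BAM file
#'
#' Counts primary, non-supplementary, non-duplicate-flagged alignments with
#' `MAPQ >= min_mapq` and assigns each read to the transcribed strand
#' according to the library orientation. Under `reverse_stranded` (dUTP)
#' chemistry the first mate maps antisense to the transcript, so its
#' alignment strand is flipped; the second mate keeps its strand. Under
#' `forward_stranded` the assignment is reversed. Unpaired reads are treated
#' like first mates. Every aligned reference position (CIGAR `M`/`=`/`X`,
#' and `D` deletion gaps) increments depth by one; `N` skips, insertions and
#' soft-clips contribute nothing.
#'
#' @param path Path to a coordinate-sorted BAM with a `.bai` index.
#' @param orientation `"reverse_stranded"` (default) or
#'   `"forward_stranded"`.
#' @param min_mapq Minimum mapping quality (default 0).
#' @param sample_id Sample identifier recorded on the result; defaults to
#'   the file name.
#' @return A [stranded_coverage()] object.
#' @export
depth_from_alignment <- function(path,
                                 orientation = c("reverse_stranded",
                                                 "forward_stranded"),
                                 min_mapq = 0L,
                                 sample_id = basename(path)) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (!file.exists(paste0(path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", path))) {
    stop("missing BAM index (.bai) for ", path)
  }
  flag <- scanBamFlag(isSecondaryAlignment = FALSE,
                      isSupplementaryAlignment = FALSE,
                      isDuplicate = FALSE,
                      isUnmappedQuery = FALSE)
  param <- ScanBamParam(flag = flag, what = "flag",
                        mapqFilter = as.integer(min_mapq))
  ga <- readGAlignments(BamFile(path), param = param)

  bits <- mcols(ga)$flag
  is_paired <- bitwAnd(bits, 1L) > 0L
  is_first <- bitwAnd(bits, 64L) > 0L
  aln_strand <- as.character(strand(ga))
  # mate acting as the "sense witness": second mate under dUTP chemistry
  flip <- ifelse(is_paired & !is_first, FALSE, TRUE)
  if (orientation == "forward_stranded") flip <- !flip
  tx_strand <- ifelse(flip, ifelse(aln_strand == "+", "-", "+"), aln_strand)

  cov_for <- function(keep) {
    if (!any(keep)) return(list())
    as.list(coverage(ga[keep]))
  }
  stranded_coverage(plus = cov_for(tx_strand == "+"),
                    minus = cov_for(tx_strand == "-"),
                    sample_id = sample_id, orientation = orientation)
}

#' Build stranded depth from a plus/minus bedGraph pair
#'
#' BedGraph intervals are 0-based half-open and must be non-overlapping
#' within each file; uncovered positions have depth zero.
#'
#' @param plus_path,minus_path Paths to the plus- and minus-strand bedGraph
#'   files.
#' @param sample_id Sample identifier recorded on the result.
#' @return A [stranded_coverage()] object.
#' @export
depth_from_bedgraph <- function(plus_path, minus_path,
                                sample_id = basename(plus_path)) {
  stranded_coverage(plus = read_bedgraph_rle(plus_path),
                    minus = read_bedgraph_rle(minus_path),
                    sample_id = sample_id)
}

read_bedgraph_rle <- function(path) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L) return(list())
  if (any(gr$score < 0)) {
    stop("negative depth values in bedGraph ", path)
  }
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  if (sum(width(red)) != sum(width(gr))) {
    stop("overlapping intervals within bedGraph ", path)
  }
  as.list(coverage(gr, weight = "score"))
}

#' Export a StrandedCoverage as a plus/minus bedGraph pair
#'
#' Writes maximal constant-depth runs with non-zero depth, 0-based
#' half-open, suitable for genome-browser track inspection and for
#' re-loading with [depth_from_bedgraph()].
#'
#' @param cov A [stranded_coverage()] object.
#' @param plus_path,minus_path Output paths.
#' @return A character vector of the two paths, invisibly.
#' @export
export_bedgraph <- function(cov, plus_path, minus_path) {
  write_one <- function(rles, path) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (chrom in names(rles)) {
      r <- rles[[chrom]]
      ends <- cumsum(runLength(r))
      starts <- ends - runLength(r)   # 0-based
      vals <- runValue(r)
      keep <- vals != 0
      if (any(keep)) {
        writeLines(sprintf("%s\t%d\t%d\t%s", chrom, starts[keep], ends[keep],
                           format(vals[keep], scientific = FALSE, trim = TRUE)),
                   con)
      }
    }
  }
  write_one(cov$plus, plus_path)
  write_one(cov$minus, minus_path)
  invisible(c(plus_path, minus_path))
}

#' Mean per-nucleotide depth over scoring intervals
#'
#' Arithmetic mean of depth over every nucleotide of each query interval on
#' the interval's own strand. Intervals on chromosomes absent from the
#' coverage (or extending past its recorded end) count those positions as
#' zero depth, so the mean is always defined.
#'
#' @param cov A [stranded_coverage()] object.
#' @param regions A `GRanges` of query intervals (strand `+` or `-`).
#' @return A numeric vector of means, one per interval.
#' @export
region_mean <- function(cov, regions) {
  stopifnot(is(cov, "StrandedCoverage"), is(regions, "GRanges"))
  strd <- as.character(strand(regions))
  if (any(strd == "*")) stop("regions must be stranded (+ or -)")
  out <- numeric(length(regions))
  chrom <- as.character(seqnames(regions))
  for (i in seq_along(regions)) {
    rles <- if (strd[i] == "+") cov$plus else cov$minus
    r <- rles[[chrom[i]]]
    s <- start(regions)[i]; e <- end(regions)[i]
    if (is.null(r) || s > length(r)) {
      out[i] <- 0
    } else {
      e_in <- min(e, length(r))
      total <- sum(Views(r, start = s, end = e_in))
      out[i] <- total / (e - s + 1)
    }
  }
  out
}

#' Read a sample manifest
#'
#' Tab-separated with header columns `sample_id`, `condition`, `kind`
#' (`alignment` or `bedgraph_pair`), `path_plus` (the BAM path for
#' `alignment` rows) and optionally `path_minus`. Relative paths are
#' resolved against the manifest's directory.
#'
#' @param path Manifest path.
#' @return A data.frame with one row per sample.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  required <- c("sample_id", "condition", "kind", "path_plus")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0L) {
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(m$sample_id)) stop("duplicate sample_id in manifest")
  if (!all(m$kind %in% c("alignment", "bedgraph_pair"))) {
    stop("manifest kind must be 'alignment' or 'bedgraph_pair'")
  }
  base <- dirname(path)
  resolve <- function(p) ifelse(is.na(p) | p == "" | grepl("^/", p),
                                p, file.path(base, p))
  m$path_plus <- resolve(m$path_plus)
  if (!is.null(m$path_minus)) m$path_minus <- resolve(m$path_minus)
  m
}

load_sample_coverage <- function(row, orientation = "reverse_stranded",
                                 min_mapq = 0L) {
  if (row$kind == "bedgraph_pair") {
    if (is.null(row$path_minus) || is.na(row$path_minus) ||
        !nzchar(row$path_minus)) {
      stop("bedgraph_pair sample ", row$sample_id, " lacks path_minus")
    }
    depth_from_bedgraph(row$path_plus, row$path_minus,
                        sample_id = row$sample_id)
  } else {
    depth_from_alignment(row$path_plus, orientation = orientation,
                         min_mapq = min_mapq, sample_id = row$sample_id)
  }
}
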