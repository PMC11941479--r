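# Fixture builders shared across test files. Everything is generated in
# code at test time; nothing binary is stored in the repository.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
  library(IRanges)
})

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# BED6 lines from 0-based half-open coordinates
bed6_line <- function(chrom, start0, end0, name, strand, score = 0) {
  sprintf("%s\t%d\t%d\t%s\t%s\t%s", chrom, start0, end0, name, score, strand)
}

# Minimal locus GRanges (1-based coords) with mature/mirtron metadata,
# for driving apply_filters() without files.
make_loci <- function(ids, chrom = "chr1", start1 = NULL, width = 85,
                      strand = "+", mature = NULL, mirtron = NULL) {
  n <- length(ids)
  if (is.null(start1)) start1 <- 1000 + (seq_len(n) - 1) * 500
  gr <- GRanges(chrom, IRanges(start = start1, width = width),
                strand = rep(strand, length.out = n))
  mcols(gr)$locus_id <- ids
  mcols(gr)$mature_ids <- if (is.null(mature)) {
    CharacterList(rep(list(character()), n))
  } else CharacterList(mature)
  mcols(gr)$is_mirtron <- if (is.null(mirtron)) rep(FALSE, n) else mirtron
  names(gr) <- ids
  gr
}

# Write a bedGraph file from a named list of depth vectors (position 1 of
# the vector = genomic position 0).
write_bedgraph_vec <- function(depths, path = tempfile(fileext = ".bedgraph")) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (chrom in names(depths)) {
    r <- rle(as.numeric(depths[[chrom]]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", chrom, starts[keep], ends[keep],
                         format(r$values[keep], scientific = FALSE,
                                trim = TRUE)), con)
    }
  }
  path
}

empty_bedgraph <- function() write_lines_tmp(character(), ".bedgraph")

# Constant-depth bedGraph pair spanning a locus's hairpin and flanks.
# hairpin0 is c(start0, end0); depths are per-region constants.
flat_locus_bedgraph <- function(chrom, hairpin0, flank_len, hairpin_depth,
                                flank_depth) {
  v <- numeric(hairpin0[2] + flank_len)
  v[(hairpin0[1] - flank_len + 1):hairpin0[1]] <- flank_depth
  v[(hairpin0[1] + 1):hairpin0[2]] <- hairpin_depth
  v[(hairpin0[2] + 1):(hairpin0[2] + flank_len)] <- flank_depth
  setNames(list(v), chrom)
}

# One-sample manifest row pointing at a bedGraph pair.
manifest_row <- function(sample_id, condition, plus, minus) {
  data.frame(sample_id = sample_id, condition = condition,
             kind = "bedgraph_pair", path_plus = plus, path_minus = minus,
             stringsAsFactors = FALSE)
}

# SAM text -> sorted, indexed BAM in tempdir.
sam_to_bam <- function(sam_lines) {
  sam <- tempfile(fileext = ".sam")
  writeLines(sam_lines, sam)
  Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
}

sam_header <- function(chrom = "chr1", len = 2000L) {
  c("@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", chrom, len))
}

# Hand-built five-locus record set exercising each inclusion filter:
#   mirA  - on the mirtron list, otherwise clean
#   lowB  - reference flank mean 1.5 (< 2)
#   ratC  - one sample with flanks 20 vs 110 (pseudocounted ratio > 4)
#   undD  - mature miRNA not on the detected list
#   okE   - clean, survives
five_locus_records <- function() {
  ids <- c("mirA", "lowB", "ratC", "undD", "okE")
  loci <- make_loci(ids,
                    mature = list("mirA-5p", "lowB-5p", "ratC-5p",
                                  "undD-5p", "okE-5p"))
  clean <- list(h = 3, l = 15, r = 17)
  per_sample <- function(locus_id, sample_id, condition, h, l, r) {
    data.frame(locus_id = locus_id, sample_id = sample_id,
               condition = condition, hairpin_mean = h,
               left_flank_mean = l, right_flank_mean = r,
               flank_mean = (l + r) / 2,
               mpi = mpi_sample(h, (l + r) / 2),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (id in ids) {
    for (cond in c("WT", "MUT")) {
      h <- clean$h; l <- clean$l; r <- clean$r
      if (id == "lowB") { l <- 1.4; r <- 1.6 }      # WT flank mean 1.5
      if (id == "ratC" && cond == "MUT") { l <- 20; r <- 110 }
      rows[[paste(id, cond)]] <-
        per_sample(id, paste0(cond, "_rep1"), cond, h, l, r)
    }
  }
  samples <- do.call(rbind, rows)
  rownames(samples) <- NULL
  tab <- data.frame(locus_id = sort(ids), stringsAsFactors = FALSE)
  for (cond in c("WT", "MUT")) {
    sub <- samples[samples$condition == cond, ]
    tab[[paste0("mpi_", cond)]] <-
      as.numeric(tapply(sub$mpi, sub$locus_id, mean)[tab$locus_id])
  }
  list(records = list(samples = samples, loci = tab), loci = loci,
       detected = c("lowB-5p", "ratC-5p", "okE-5p", "mirA-5p"),
       mirtrons = "mirA")
}
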