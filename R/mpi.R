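# The MPI statistic, condition averages, delta-MPI and inclusion filters.

#' Per-sample Microprocessor Processing Index
#'
#' \deqn{MPI = -\log_2\frac{h + 1}{f + 1}}
#' where `h` is the mean read depth over the trimmed hairpin core and `f`
#' the pooled mean over both flank cores. The +1 pseudocount keeps the ratio
#' defined at zero coverage and pulls low-coverage loci towards 0. Positive
#' MPI indicates the hairpin is depleted relative to its flanks, i.e.
#' efficient Microprocessor cleavage; values near zero or negative indicate
#' inefficient or absent processing.
#'
#' @param hairpin_mean,flank_mean Non-negative finite mean depths
#'   (vectorised).
#' @return Numeric MPI values.
#' @examples
#' mpi_sample(3, 15)   # 2: hairpin 4x depleted relative to flanks
#' mpi_sample(15, 3)   # -2: hairpin accumulates reads
#' @export
mpi_sample <- function(hairpin_mean, flank_mean) {
  check_depth <- function(x, what) {
    if (any(!is.finite(x)) || any(x < 0)) {
      stop(what, " must be finite and non-negative")
    }
  }
  check_depth(hairpin_mean, "hairpin_mean")
  check_depth(flank_mean, "flank_mean")
  -log2((hairpin_mean + 1) / (flank_mean + 1))
}

#' Condition-level MPI
#'
#' The MPI of a condition (cell line) is the arithmetic mean of the
#' per-sample MPIs of its replicates — the mean of ratios, not the ratio of
#' mean depths.
#'
#' @param sample_mpis Non-empty numeric vector of per-sample MPI values.
#' @return The mean MPI.
#' @export
mpi_condition <- function(sample_mpis) {
  if (length(sample_mpis) == 0L) stop("at least one sample MPI is required")
  mean(sample_mpis)
}

#' Differential MPI between conditions
#'
#' `delta_mpi = mutant_mpi - reference_mpi`. Negative values mean the locus
#' is less processed in the mutant than in the reference (wild-type)
#' condition.
#'
#' @param mutant_mpi,reference_mpi Condition-level MPI values (vectorised).
#' @return The difference.
#' @export
delta_mpi <- function(mutant_mpi, reference_mpi) {
  mutant_mpi - reference_mpi
}

#' Locus-inclusion filter configuration
#'
#' @param min_ref_flank_depth Minimum mean flank depth, averaged over
#'   reference-condition samples (default 2; inclusive).
#' @param max_flank_ratio Maximum fold difference between the two flank
#'   means, compared as `(max + 1) / (min + 1)` so the ratio is defined for
#'   zero-depth flanks (default 4; inclusive).
#' @param require_detected Require at least one of the locus's mature
#'   miRNAs on the detected allowlist (default `TRUE`).
#' @param exclude_mirtrons Drop loci on the mirtron list or flagged
#'   `is_mirtron` (default `TRUE`). Mirtrons bypass the Microprocessor via
#'   splicing, so their hairpin depletion says nothing about Drosha.
#' @param ref_processed_threshold Reference-condition MPI above which a
#'   locus is flagged `processed_in_ref` (default 0.3). This gates a flag
#'   used for distribution summaries, never removal.
#' @param flank_ratio_scope `"per_sample"` applies the flank-balance rule in
#'   every sample (strictest); `"ref_mean"` applies it to
#'   reference-condition mean flank depths only.
#' @return A list of class `mpi_filter_config`.
#' @export
filter_config <- function(min_ref_flank_depth = 2,
                          max_flank_ratio = 4,
                          require_detected = TRUE,
                          exclude_mirtrons = TRUE,
                          ref_processed_threshold = 0.3,
                          flank_ratio_scope = c("per_sample", "ref_mean")) {
  stopifnot(min_ref_flank_depth > 0, max_flank_ratio > 0,
            ref_processed_threshold > 0)
  structure(
    list(min_ref_flank_depth = min_ref_flank_depth,
         max_flank_ratio = max_flank_ratio,
         require_detected = isTRUE(require_detected),
         exclude_mirtrons = isTRUE(exclude_mirtrons),
         ref_processed_threshold = ref_processed_threshold,
         flank_ratio_scope = match.arg(flank_ratio_scope)),
    class = "mpi_filter_config"
  )
}

#' Apply the locus-inclusion filters
#'
#' A locus is kept only if it (1) is not a mirtron or tailed mirtron, (2)
#' produces at least one mature miRNA on the detected allowlist, (3) has a
#' mean flank depth of at least `min_ref_flank_depth` averaged over
#' reference-condition samples, and (4) has balanced flanks: the
#' pseudocounted ratio of the larger to the smaller flank mean does not
#' exceed `max_flank_ratio` (by default in every sample). Additionally a
#' `processed_in_ref` flag (reference MPI above
#' `ref_processed_threshold`) is set without removing any locus.
#'
#' @param records A list with elements `samples` (long data.frame with
#'   columns `locus_id`, `sample_id`, `condition`, `hairpin_mean`,
#'   `left_flank_mean`, `right_flank_mean`, `flank_mean`, `mpi`) and `loci`
#'   (per-locus data.frame with `locus_id` and `mpi_<condition>` columns),
#'   as produced by [run_mpi()].
#' @param loci Locus `GRanges` from [load_annotations()] (supplies
#'   `mature_ids` and `is_mirtron`).
#' @param detected Character vector of detected mature-miRNA IDs. For loci
#'   that carry no mature IDs (BED6 annotations) the `locus_id` itself is
#'   matched against this list.
#' @param mirtrons Character vector of mirtron locus IDs.
#' @param cfg A [filter_config()].
#' @param reference Reference (wild-type) condition label.
#' @return A list: `loci` (the per-locus table with pass/fail columns
#'   `pass_mirtron`, `pass_detected`, `pass_flank_depth`,
#'   `pass_flank_ratio`, overall `pass`, and `processed_in_ref`),
#'   `survivors` (locus IDs passing all filters) and `audit` (one row per
#'   excluded locus with its `first_fail` and comma-separated `all_fails`).
#' @export
apply_filters <- function(records, loci, detected = character(),
                          mirtrons = character(), cfg = filter_config(),
                          reference) {
  samples <- records$samples
  tab <- records$loci
  if (!reference %in% samples$condition) {
    stop("unknown reference condition: ", reference)
  }
  ids <- tab$locus_id
  locus_idx <- match(ids, mcols(loci)$locus_id)
  if (anyNA(locus_idx)) {
    stop("records contain locus_ids absent from the annotation: ",
         paste(ids[is.na(locus_idx)], collapse = ", "))
  }

  # (1) mirtrons
  is_mir <- mcols(loci)$is_mirtron[locus_idx] | (ids %in% mirtrons)
  pass1 <- if (cfg$exclude_mirtrons) !is_mir else rep(TRUE, length(ids))

  # (2) detected mature miRNAs (locus_id fallback when no matures annotated)
  mature <- as.list(mcols(loci)$mature_ids[locus_idx])
  pass2 <- if (cfg$require_detected) {
    vapply(seq_along(ids), function(i) {
      m <- mature[[i]]
      if (length(m) == 0L) ids[i] %in% detected
      else length(intersect(m, detected)) > 0L
    }, logical(1))
  } else rep(TRUE, length(ids))

  # (3) reference-condition mean flank depth
  ref_rows <- samples[samples$condition == reference, , drop = FALSE]
  ref_flank <- tapply(ref_rows$flank_mean, ref_rows$locus_id, mean)
  pass3 <- as.numeric(ref_flank[ids]) >= cfg$min_ref_flank_depth
  pass3[is.na(pass3)] <- FALSE

  # (4) flank balance
  scope_rows <- if (cfg$flank_ratio_scope == "per_sample") samples else ref_rows
  if (cfg$flank_ratio_scope == "ref_mean") {
    lf <- tapply(scope_rows$left_flank_mean, scope_rows$locus_id, mean)
    rf <- tapply(scope_rows$right_flank_mean, scope_rows$locus_id, mean)
    ratio_by_locus <- pmax(lf + 1, rf + 1) / pmin(lf + 1, rf + 1)
    pass4 <- as.numeric(ratio_by_locus[ids]) <= cfg$max_flank_ratio
  } else {
    ratio <- pmax(scope_rows$left_flank_mean + 1,
                  scope_rows$right_flank_mean + 1) /
             pmin(scope_rows$left_flank_mean + 1,
                  scope_rows$right_flank_mean + 1)
    worst <- tapply(ratio, scope_rows$locus_id, max)
    pass4 <- as.numeric(worst[ids]) <= cfg$max_flank_ratio
  }
  pass4[is.na(pass4)] <- FALSE

  tab$pass_mirtron <- pass1
  tab$pass_detected <- pass2
  tab$pass_flank_depth <- pass3
  tab$pass_flank_ratio <- pass4
  tab$pass <- pass1 & pass2 & pass3 & pass4

  ref_col <- paste0("mpi_", reference)
  if (!ref_col %in% names(tab)) {
    stop("per-locus table lacks column ", ref_col)
  }
  tab$processed_in_ref <- tab[[ref_col]] > cfg$ref_processed_threshold

  fails <- cbind(mirtron = !pass1, detected = !pass2,
                 flank_depth = !pass3, flank_ratio = !pass4)
  excluded <- which(!tab$pass)
  audit <- data.frame(
    locus_id = ids[excluded],
    first_fail = vapply(excluded, function(i) {
      colnames(fails)[which(fails[i, ])[1L]]
    }, character(1)),
    all_fails = vapply(excluded, function(i) {
      paste(colnames(fails)[fails[i, ]], collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  list(loci = tab, survivors = ids[tab$pass], audit = audit)
}

#' Run the full MPI pipeline
#'
#' For every annotated locus: derive scoring regions, compute per-sample
#' region means and MPI, average MPI within conditions, contrast each
#' non-reference condition against the reference (delta-MPI), and apply the
#' inclusion filters. Loci whose regions cannot be derived (too short, or
#' flank off the chromosome edge) are reported in `region_failures`, never
#' silently dropped. Output rows are ordered by `locus_id`.
#'
#' @param manifest Data.frame from [read_manifest()] (or built in code with
#'   the same columns).
#' @param loci Locus `GRanges` from [load_annotations()].
#' @param reference Reference (wild-type) condition label.
#' @param flank_len,trim Region-derivation parameters, see
#'   [derive_regions()].
#' @param cfg A [filter_config()].
#' @param detected,mirtrons ID lists for filters 2 and 1 (see
#'   [apply_filters()]).
#' @param orientation,min_mapq Passed to [depth_from_alignment()] for
#'   `alignment` manifest rows.
#' @return A list of class `mpi_result`: `samples` (long per-sample table),
#'   `loci` (per-locus table with `mpi_<condition>`, `dmpi_<condition>`,
#'   filter columns and `processed_in_ref`), `survivors`, `audit`,
#'   `region_failures`, and the `reference` label.
#' @export
run_mpi <- function(manifest, loci, reference,
                    flank_len = 100L, trim = 5L,
                    cfg = filter_config(),
                    detected = character(), mirtrons = character(),
                    orientation = "reverse_stranded", min_mapq = 0L) {
  stopifnot(nrow(manifest) > 0L, length(loci) > 0L)
  if (!reference %in% manifest$condition) {
    stop("reference condition '", reference, "' not present in manifest")
  }

  # derive regions per locus, collecting failures instead of aborting
  ok <- logical(length(loci))
  reasons <- character(length(loci))
  for (i in seq_along(loci)) {
    res <- tryCatch(derive_regions(loci[i], flank_len, trim),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) reasons[i] <- res else ok[i] <- TRUE
  }
  region_failures <- data.frame(
    locus_id = mcols(loci)$locus_id[!ok],
    reason = reasons[!ok],
    stringsAsFactors = FALSE
  )
  usable <- loci[ok]
  if (length(usable) == 0L) stop("no locus admits region derivation")
  regions <- derive_regions(usable, flank_len, trim)
  ids <- mcols(usable)$locus_id
  hp_ix <- which(mcols(regions)$region == "hairpin")
  lf_ix <- which(mcols(regions)$region == "flank_left")
  rf_ix <- which(mcols(regions)$region == "flank_right")

  samples <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(r) {
    row <- manifest[r, , drop = FALSE]
    cov <- load_sample_coverage(row, orientation = orientation,
                                min_mapq = min_mapq)
    means <- region_mean(cov, regions)
    hp <- means[hp_ix]; lf <- means[lf_ix]; rf <- means[rf_ix]
    fl <- (lf + rf) / 2   # pooled mean; flank cores have equal length
    data.frame(locus_id = ids, sample_id = row$sample_id,
               condition = row$condition,
               hairpin_mean = hp, left_flank_mean = lf,
               right_flank_mean = rf, flank_mean = fl,
               mpi = mpi_sample(hp, fl),
               stringsAsFactors = FALSE)
  }))
  samples <- samples[order(samples$locus_id, samples$sample_id), ]
  rownames(samples) <- NULL

  conditions <- unique(manifest$condition)
  tab <- data.frame(locus_id = sort(ids), stringsAsFactors = FALSE)
  for (cond in conditions) {
    rows <- samples[samples$condition == cond, , drop = FALSE]
    m <- tapply(rows$mpi, rows$locus_id, mpi_condition)
    tab[[paste0("mpi_", cond)]] <- as.numeric(m[tab$locus_id])
  }
  for (cond in setdiff(conditions, reference)) {
    tab[[paste0("dmpi_", cond)]] <-
      delta_mpi(tab[[paste0("mpi_", cond)]],
                tab[[paste0("mpi_", reference)]])
  }

  filtered <- apply_filters(list(samples = samples, loci = tab),
                            loci = usable, detected = detected,
                            mirtrons = mirtrons, cfg = cfg,
                            reference = reference)
  structure(
    list(samples = samples, loci = filtered$loci,
         survivors = filtered$survivors, audit = filtered$audit,
         region_failures = region_failures, reference = reference),
    class = "mpi_result"
  )
}

#' @export
print.mpi_result <- function(x, ...) {
  cat("MPI result: ", nrow(x$loci), " loci, ",
      length(unique(x$samples$sample_id)), " samples, reference '",
      x$reference, "'\n", sep = "")
  cat("  survivors after filters: ", length(x$survivors), "\n", sep = "")
  if (nrow(x$region_failures) > 0L) {
    cat("  loci failing region derivation: ",
        nrow(x$region_failures), "\n", sep = "")
  }
  invisible(x)
}

#' Write MPI result tables to TSV
#'
#' Writes `mpi_samples.tsv` (per-sample region means and MPI),
#' `mpi_loci.tsv` (per-condition MPI, delta-MPI, filter flags,
#' `processed_in_ref`), `mpi_audit.tsv` (excluded loci with failing
#' filters) and, when present, `region_failures.tsv`.
#'
#' @param result An `mpi_result` from [run_mpi()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_mpi_tsv <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, name) {
    write.table(format_num_df(df), file.path(dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  wt(result$samples, "mpi_samples.tsv")
  wt(result$loci, "mpi_loci.tsv")
  wt(result$audit, "mpi_audit.tsv")
  if (nrow(result$region_failures) > 0L) {
    wt(result$region_failures, "region_failures.tsv")
  }
  invisible(dir)
}

# stable numeric formatting so identical results give identical files
format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      df[[j]] <- sprintf("%.6g", df[[j]])
    }
  }
  df
}
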