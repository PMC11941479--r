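test_that("mpi_sample computes the pseudocounted negative log2 ratio", {
  expect_equal(mpi_sample(0, 0), 0)
  expect_equal(mpi_sample(3, 15), 2)     # -log2(4/16)
  expect_equal(mpi_sample(15, 3), -2)
  expect_equal(mpi_sample(7.3, 7.3), 0)  # identity at equal depths
  expect_error(mpi_sample(-1, 5), "non-negative")
  expect_error(mpi_sample(3, Inf), "finite")
})

test_that("mpi_sample matches an independent direct evaluation on 1000 pairs", {
  oracle <- function(h, f) -log2((h + 1) / (f + 1))
  set.seed(101)
  h <- runif(1000, 0, 500)
  f <- runif(1000, 0, 500)
  expect_true(max(abs(mpi_sample(h, f) - oracle(h, f))) < 1e-12)
})

test_that("mpi_sample is antisymmetric and monotone in each argument", {
  set.seed(102)
  h <- runif(200, 0, 100); f <- runif(200, 0, 100)
  expect_equal(mpi_sample(h, f), -mpi_sample(f, h))
  # strictly decreasing in hairpin depth, increasing in flank depth
  expect_true(all(diff(mpi_sample(seq(0, 50, by = 0.5), 10)) < 0))
  expect_true(all(diff(mpi_sample(10, seq(0, 50, by = 0.5))) > 0))
})

test_that("condition MPI is the mean of sample MPIs", {
  expect_equal(mpi_condition(c(2.0, 2.2)), 2.1)
  expect_equal(mpi_condition(0), 0)
  expect_equal(mpi_condition(c(1, -1)), 0)
  expect_error(mpi_condition(numeric()), "at least one")
})

test_that("delta MPI subtracts reference from mutant", {
  expect_equal(delta_mpi(1.1, 2.1), -1)
  expect_equal(delta_mpi(2.5, 1.0), 1.5)
  expect_equal(delta_mpi(0.7, 0.7), 0)
  # invariant under a common shift of both conditions
  set.seed(103)
  m <- runif(50); r <- runif(50); c0 <- runif(1, -5, 5)
  expect_equal(delta_mpi(m + c0, r + c0), delta_mpi(m, r))
})

test_that("each inclusion filter excludes exactly its target locus", {
  fx <- five_locus_records()
  out <- apply_filters(fx$records, fx$loci, detected = fx$detected,
                       mirtrons = fx$mirtrons, reference = "WT")
  expect_equal(out$survivors, "okE")
  audit <- out$audit[order(out$audit$locus_id), ]
  expect_equal(audit$locus_id, c("lowB", "mirA", "ratC", "undD"))
  expect_equal(audit$first_fail[audit$locus_id == "mirA"], "mirtron")
  expect_equal(audit$first_fail[audit$locus_id == "lowB"], "flank_depth")
  expect_equal(audit$first_fail[audit$locus_id == "ratC"], "flank_ratio")
  expect_equal(audit$first_fail[audit$locus_id == "undD"], "detected")
  # each failing locus fails only its targeted filter
  expect_true(all(audit$all_fails == audit$first_fail))
})

test_that("filter audit is exhaustive and survivors have no failing filter", {
  fx <- five_locus_records()
  out <- apply_filters(fx$records, fx$loci, detected = fx$detected,
                       mirtrons = fx$mirtrons, reference = "WT")
  expect_equal(length(out$survivors) + nrow(out$audit), nrow(out$loci))
  surv <- out$loci[out$loci$pass, ]
  expect_true(all(surv$pass_mirtron & surv$pass_detected &
                  surv$pass_flank_depth & surv$pass_flank_ratio))
})

test_that("flank-depth filter is inclusive at the threshold", {
  fx <- five_locus_records()
  rec <- fx$records
  # set lowB's reference flank means so they average exactly 2.0
  sel <- rec$samples$locus_id == "lowB" & rec$samples$condition == "WT"
  rec$samples$left_flank_mean[sel] <- 1.9
  rec$samples$right_flank_mean[sel] <- 2.1
  rec$samples$flank_mean[sel] <- 2.0
  out <- apply_filters(rec, fx$loci, detected = fx$detected,
                       mirtrons = fx$mirtrons, reference = "WT")
  expect_true("lowB" %in% out$survivors)
})

test_that("empty detected list fails every locus when detection is required", {
  fx <- five_locus_records()
  out <- apply_filters(fx$records, fx$loci, detected = character(),
                       mirtrons = character(), reference = "WT")
  expect_length(out$survivors, 0)
  expect_true(all(grepl("detected", out$audit$all_fails)))
  relaxed <- apply_filters(fx$records, fx$loci, detected = character(),
                           mirtrons = character(),
                           cfg = filter_config(require_detected = FALSE),
                           reference = "WT")
  expect_true("okE" %in% relaxed$survivors)
})

test_that("unknown reference condition is an error", {
  fx <- five_locus_records()
  expect_error(apply_filters(fx$records, fx$loci, detected = fx$detected,
                             mirtrons = fx$mirtrons, reference = "XX"),
               "unknown reference")
})

test_that("run_mpi composes region means into condition MPI and delta", {
  # one locus; constant coverage: WT hairpin 3 / flanks 15, MUT 15 / 15
  hairpin0 <- c(1000, 1085)
  bed <- write_lines_tmp(bed6_line("chr1", hairpin0[1], hairpin0[2],
                                   "m1", "+"), ".bed")
  wt <- write_bedgraph_vec(flat_locus_bedgraph("chr1", hairpin0, 100, 3, 15))
  mut <- write_bedgraph_vec(flat_locus_bedgraph("chr1", hairpin0, 100, 15, 15))
  manifest <- rbind(
    manifest_row("wt1", "WT", wt, empty_bedgraph()),
    manifest_row("mut1", "MUT", mut, empty_bedgraph())
  )
  loci <- load_annotations(bed, "bed6")
  res <- run_mpi(manifest, loci, reference = "WT",
                 cfg = filter_config(require_detected = FALSE))
  expect_equal(res$loci$mpi_WT, 2)
  expect_equal(res$loci$mpi_MUT, 0)
  expect_equal(res$loci$dmpi_MUT, -2)
  expect_true(res$loci$processed_in_ref)   # MPI_WT = 2 > 0.3
  expect_equal(res$survivors, "m1")
})

test_that("duplicating a reference sample leaves condition MPI unchanged", {
  hairpin0 <- c(1000, 1085)
  bed <- write_lines_tmp(bed6_line("chr1", hairpin0[1], hairpin0[2],
                                   "m1", "+"), ".bed")
  wt <- write_bedgraph_vec(flat_locus_bedgraph("chr1", hairpin0, 100, 3, 15))
  m1 <- rbind(manifest_row("wt1", "WT", wt, empty_bedgraph()))
  m2 <- rbind(m1, manifest_row("wt2", "WT", wt, empty_bedgraph()))
  loci <- load_annotations(bed, "bed6")
  cfg <- filter_config(require_detected = FALSE)
  r1 <- run_mpi(m1, loci, reference = "WT", cfg = cfg)
  r2 <- run_mpi(m2, loci, reference = "WT", cfg = cfg)
  expect_equal(r1$loci$mpi_WT, r2$loci$mpi_WT)
})

test_that("all-zero coverage gives zero MPI and fails the flank-depth filter", {
  bed <- write_lines_tmp(bed6_line("chr1", 1000, 1085, "m1", "+"), ".bed")
  manifest <- rbind(
    manifest_row("wt1", "WT", empty_bedgraph(), empty_bedgraph()),
    manifest_row("mut1", "MUT", empty_bedgraph(), empty_bedgraph())
  )
  res <- run_mpi(manifest, load_annotations(bed, "bed6"), reference = "WT",
                 cfg = filter_config(require_detected = FALSE))
  expect_equal(res$loci$mpi_WT, 0)
  expect_equal(res$loci$dmpi_MUT, 0)
  expect_length(res$survivors, 0)
  expect_equal(res$audit$first_fail, "flank_depth")
})

test_that("loci failing region derivation are reported, not dropped", {
  bed <- write_lines_tmp(c(
    bed6_line("chr1", 1000, 1085, "good", "+"),
    bed6_line("chr1", 5000, 5010, "short", "+"),
    bed6_line("chr1", 50, 135, "edge", "+")
  ), ".bed")
  wt <- write_bedgraph_vec(flat_locus_bedgraph("chr1", c(1000, 1085),
                                               100, 3, 15))
  manifest <- manifest_row("wt1", "WT", wt, empty_bedgraph())
  res <- run_mpi(manifest, load_annotations(bed, "bed6"), reference = "WT",
                 cfg = filter_config(require_detected = FALSE))
  expect_setequal(res$region_failures$locus_id, c("short", "edge"))
  expect_equal(res$loci$locus_id, "good")
})

test_that("MPI result TSVs are written with the audit trail", {
  fx <- five_locus_records()
  out <- apply_filters(fx$records, fx$loci, detected = fx$detected,
                       mirtrons = fx$mirtrons, reference = "WT")
  res <- structure(list(samples = fx$records$samples, loci = out$loci,
                        survivors = out$survivors, audit = out$audit,
                        region_failures = data.frame(),
                        reference = "WT"), class = "mpi_result")
  dir <- tempfile()
  write_mpi_tsv(res, dir)
  expect_true(all(file.exists(file.path(dir, c("mpi_samples.tsv",
                                               "mpi_loci.tsv",
                                               "mpi_audit.tsv")))))
  reread <- read.table(file.path(dir, "mpi_loci.tsv"), header = TRUE,
                       sep = "\t")
  expect_equal(nrow(reread), 5)
})
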