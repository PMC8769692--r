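test_that("count tables ingest with dialects, manifests and fractions", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "teA\t10\t0", "teB\t3.5\t7"), f)
  tc <- ingest_count_table(f)
  expect_identical(dim(tc$counts), c(2L, 2L))
  expect_identical(tc$counts["teA", "s1"], 10)
  expect_identical(tc$counts["teB", "s1"], 3.5)  # fractional EM output kept

  mf <- data.frame(column = c("s1", "s2"),
                   sample = c("set1_rep1", "set2_rep1"))
  tc2 <- ingest_count_table(f, manifest = mf)
  expect_identical(colnames(tc2$counts), c("set1_rep1", "set2_rep1"))
  expect_error(
    ingest_count_table(f, manifest = data.frame(column = "sX",
                                                sample = "set1_rep1")),
    "missing from table")

  writeLines(c("id\ts1", "teA\t1", "teA\t2"), f)
  expect_error(ingest_count_table(f), "duplicate ids")

  writeLines(c("Name\ts1", "teA\t4"), f)
  expect_identical(rownames(ingest_count_table(f, "salmonte")$counts), "teA")
})

test_that("coordinate matching is one-to-one across id dialects", {
  inst <- toy_instances(5)
  # same 0-based convention, pipe dialect
  res <- match_by_coordinates(
    sprintf("%s|%d|%d|foreign", inst$chrom[1:3], inst$start[1:3],
            inst$end[1:3]),
    inst, base = 0L)
  expect_identical(unname(res$map), inst$te_id[1:3])
  expect_length(res$unmatched, 0L)

  # 1-based foreign ids against the 0-based reference (base-shift dialect)
  res1 <- match_by_coordinates(
    sprintf("%s|%d|%d", inst$chrom[1:3], inst$start[1:3] + 1L,
            inst$end[1:3]),
    inst, base = 1L)
  expect_identical(unname(res1$map), inst$te_id[1:3])

  # unmatched ids are reported, never dropped
  res2 <- match_by_coordinates(c(sprintf("%s|%d|%d", inst$chrom[1L],
                                         inst$start[1L], inst$end[1L]),
                                 "chr9|1|100"), inst, base = 0L)
  expect_identical(res2$unmatched, "chr9|1|100")

  # two foreign ids resolving to one reference id -> error
  dup <- sprintf("%s|%d|%d|v%d", inst$chrom[1L], inst$start[1L],
                 inst$end[1L], 1:2)
  expect_error(match_by_coordinates(dup, inst, base = 0L), "one-to-one")
})

test_that("baseline mapper finds true loci, shared loci and applies the cap", {
  lib <- shared_sequence_library()
  ids <- lib$instances$te_id
  # unique-locus read (from diverged B1)
  rB <- substr(lib$sequences[[ids[3L]]], 51, 150)
  # shared read (A1 and A2 are identical twins)
  rA <- substr(lib$sequences[[ids[1L]]], 101, 200)
  fq <- write_test_fastq(c(rB, rA))
  ca <- map_reads_baseline(fq, lib)
  expect_identical(ca$cand$te[ca$cand$read == 1L], 3L)
  expect_setequal(ca$cand$te[ca$cand$read == 2L], c(1L, 2L))
  expect_identical(ca$n_unmapped, 0L)

  # mismatched read still maps (Hamming verification)
  rB2 <- rB
  substr(rB2, 10, 10) <- chartr("ACGT", "GTAC", substr(rB2, 10, 10))
  ca2 <- map_reads_baseline(write_test_fastq(rB2), lib)
  expect_identical(ca2$cand$te, 3L)
  expect_identical(ca2$cand$mm, 1L)

  # multimap cap discards and counts
  ca3 <- map_reads_baseline(fq, lib, multimap_cap = 1L)
  expect_identical(ca3$n_discarded, 1L)
  expect_false(any(ca3$cand$read == 2L))

  # paired mates must agree on the TE
  rcomp <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  m1 <- substr(lib$sequences[[ids[3L]]], 1, 100)
  m2 <- rcomp(substr(lib$sequences[[ids[3L]]], 201, 300))
  cap <- map_reads_baseline(write_test_fastq(m1), lib,
                            fastq2 = write_test_fastq(m2))
  expect_identical(cap$cand$te, 3L)
})

test_that("EM reassignment matches brute force and conserves read mass", {
  lib <- shared_sequence_library()
  # synthetic candidate structure: A=1, B=2; 10 unique-A, 5 shared
  mk <- function(sets) {
    cand <- do.call(rbind, lapply(seq_along(sets), function(r)
      data.frame(read = r, te = sets[[r]], mm = 0L)))
    structure(list(cand = cand, te_ids = c("A", "B", "C"),
                   n_reads = length(sets), n_unmapped = 0L,
                   n_discarded = 0L), class = "candidate_alignments")
  }
  sets <- c(replicate(10, 1L, simplify = FALSE),
            replicate(5, c(1L, 2L), simplify = FALSE))
  est <- em_reassign(mk(sets))
  oracle <- em_brute_force(sets, 3L)
  expect_equal(unname(est), oracle, tolerance = 1e-6)
  expect_equal(sum(est), 15)                       # mass conservation
  expect_gt(est[["A"]], 14.9)                      # A absorbs the shared reads
  expect_lt(est[["B"]], 0.1)

  # symmetric evidence splits the shared reads evenly
  sym <- c(replicate(5, 1L, simplify = FALSE),
           replicate(5, 2L, simplify = FALSE),
           replicate(4, c(1L, 2L), simplify = FALSE))
  est2 <- em_reassign(mk(sym))
  expect_equal(unname(est2[1:2]), c(7, 7), tolerance = 1e-9)

  # unique-only input equals direct counting after one iteration
  uni <- c(replicate(3, 1L, simplify = FALSE),
           replicate(2, 3L, simplify = FALSE))
  expect_equal(unname(em_reassign(mk(uni))), c(3, 0, 2))

  # likelihood is non-decreasing across iterations
  ll <- attr(em_reassign(mk(sets), trace = TRUE), "loglik")
  expect_true(all(diff(ll) >= -1e-12))

  # property: mass conservation on random instances
  set.seed(99)
  for (rep in 1:5) {
    n_te <- sample(3:8, 1)
    rs <- replicate(sample(20:200, 1),
                    sort(sample(n_te, sample(1:3, 1))), simplify = FALSE)
    cc <- mk(rs); cc$te_ids <- paste0("t", seq_len(n_te))
    e <- em_reassign(cc)
    expect_lt(abs(sum(e) - length(rs)), 1e-9)
  }

  # random hard assignment returns integers summing to the read count
  set.seed(1)
  hard <- em_reassign(mk(sets), assignment = "random")
  expect_true(all(hard == floor(hard)))
  expect_equal(sum(hard), 15)
})

test_that("SAM alignments ingest into candidate structure", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:teA\tLN:600",
    "@SQ\tSN:teB\tLN:600",
    "r1\t0\tteA\t1\t255\t50M\t*\t0\t0\tACGT\tIIII\tNM:i:0",
    "r2\t0\tteA\t1\t255\t50M\t*\t0\t0\tACGT\tIIII\tNM:i:1",
    "r2\t256\tteB\t1\t255\t50M\t*\t0\t0\tACGT\tIIII\tNM:i:2",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\tIIII"), sam)
  ca <- read_sam_candidates(sam)
  expect_identical(ca$n_reads, 3L)
  expect_identical(ca$n_unmapped, 1L)
  expect_identical(sort(ca$te_ids), c("teA", "teB"))
  r2 <- ca$cand[ca$cand$read == 2L, ]
  expect_identical(nrow(r2), 2L)
  counts <- em_reassign(ca)
  expect_equal(sum(counts), 2)   # two mapped reads
})
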