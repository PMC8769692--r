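test_that("instance selection enforces the eligibility rules", {
  inst <- toy_instances(30)
  inst$length[1:5] <- 80L
  inst$end <- inst$start + inst$length
  inst$kimura[6:8] <- NA
  inst$te_id <- make_te_id(inst)
  sel <- select_instances(inst, 10, seed = 1)
  expect_length(sel, 10L)
  expect_length(unique(sel), 10L)
  picked <- inst[match(sel, inst$te_id), ]
  expect_true(all(picked$length >= 100L))
  expect_true(all(!is.na(picked$kimura)))
  expect_false(any(inst$te_id[1:8] %in% sel))
  expect_error(select_instances(inst, 23, seed = 1), "pool too small: 22")
})

test_that("expected reads keep sequenced bases / length at the coverage", {
  # oracle: sequenced bases / L = coverage in both layouts
  expect_identical(expected_reads(1000L, 20, layout = "SE100"), 200)
  expect_identical(expected_reads(1000L, 20, layout = "PE100"), 100)
  expect_identical(expected_reads(1000L, 0, layout = "SE100"), 0)
  expect_identical(expected_reads(1000L, 20, layout = "SE50"), 400)
  expect_warning(expected_reads(80L, 20, layout = "SE100"), "shorter")
})

test_that("spike-in flags are exact and fold changes act on Set 2 means", {
  inst <- toy_instances(200)
  d <- simulation_design(inst, layout = "SE100", seed = 4)
  expect_identical(sum(d$tes$dete == "up"), 5L)    # round(0.025 * 200)
  expect_identical(sum(d$tes$dete == "down"), 5L)
  expect_true(all(d$tes$fold_change[d$tes$dete == "up"] == 2))
  expect_true(all(d$tes$fold_change[d$tes$dete == "down"] == 0.5))

  # deterministic mode: every cell equals its mean
  cm <- simulate_count_matrix(d, deterministic = TRUE)
  none <- d$tes$dete == "none"
  expect_true(all(cm[none, ] == 200L))
  up <- d$tes$dete == "up"
  expect_true(all(cm[up, 6:10] == 400L) && all(cm[up, 1:5] == 200L))

  # stochastic mode: Set2/Set1 mean ratio ~ fold change over many TEs
  d2 <- simulation_design(toy_instances(400), layout = "SE100",
                          dete_frac = 0.5, seed = 5)
  cm2 <- simulate_count_matrix(d2, seed = 6)
  up2 <- d2$tes$dete == "up"
  ratio <- mean(cm2[up2, 6:10]) / mean(cm2[up2, 1:5])
  expect_lt(abs(ratio - 2), 0.15)   # NB sampling tolerance at 100x5 cells

  # determinism end-to-end
  expect_identical(simulate_count_matrix(d, seed = 9),
                   simulate_count_matrix(d, seed = 9))
})

test_that("read emission conserves mass and stays substring-exact", {
  lib <- shared_sequence_library()
  d <- simulation_design(lib$instances, layout = "SE100", coverage = 20,
                         dete_frac = 0, seed = 2)
  cm <- simulate_count_matrix(d, seed = 3)
  rr <- simulate_reads(cm, lib, d, out_dir = tempfile("r_"), seed = 4)

  for (j in seq_len(ncol(cm))) {
    fq <- readLines(rr$files$mate1[j])
    expect_identical(length(fq) / 4L, sum(cm[, j]))   # mass conservation
  }
  # error-free reads are exact substrings of their origin TE
  fq1 <- readLines(rr$files$mate1[1L])
  seqs <- fq1[seq(2, length(fq1), 4)]
  names_ <- sub("^@", "", fq1[seq(1, length(fq1), 4)])
  origin <- vapply(strsplit(names_, ";", fixed = TRUE), `[`, "", 1L)
  hit <- mapply(function(s, te) grepl(s, lib$sequences[[te]], fixed = TRUE),
                seqs, origin)
  expect_true(all(hit))

  # origin log reconciles with the count matrix cell by cell
  for (k in seq_len(nrow(rr$origin))) {
    expect_identical(rr$origin$n[k],
                     as.integer(cm[rr$origin$te_id[k], rr$origin$sample[k]]))
  }

  # paired-end: mate2 is the reverse complement of the fragment end
  dp <- simulation_design(lib$instances, layout = "PE100", coverage = 10,
                          dete_frac = 0, seed = 5)
  cmp_ <- simulate_count_matrix(dp, seed = 6)
  rp <- simulate_reads(cmp_, lib, dp, out_dir = tempfile("p_"), seed = 7)
  m2 <- readLines(rp$files$mate2[1L])
  s2 <- m2[seq(2, length(m2), 4)][1:20]
  n2 <- sub("^@", "", m2[seq(1, length(m2), 4)][1:20])
  o2 <- vapply(strsplit(n2, ";", fixed = TRUE), `[`, "", 1L)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(s2)))
  hit2 <- mapply(function(s, te) grepl(s, lib$sequences[[te]], fixed = TRUE),
                 rc, o2)
  expect_true(all(hit2))
})

test_that("quality profiles are learned per cycle and drive the error rate", {
  # mixed Q20 ('5') / Q40 ('I') at cycle 1, Q40 elsewhere
  n <- 200L
  quals <- paste0(rep(c("5", "I"), n / 2), strrep("I", 49))
  fq <- write_test_fastq(rep(strrep("A", 50), n), quals = quals)
  qp <- learn_quality_profile(fq)
  expect_identical(qp$read_length, 50L)
  expect_equal(sort(qp$cycles[[1L]]$q), c(20L, 40L))
  expect_equal(qp$cycles[[1L]]$p, c(0.5, 0.5))
  expect_identical(qp$cycles[[2L]]$q, 40L)

  expect_error(learn_quality_profile(write_test_fastq(character())),
               "empty FASTQ")
  short <- write_test_fastq(c(strrep("A", 50), "ACGT"))
  expect_error(learn_quality_profile(short, read_length = 50L), "shorter")

  # all-Q40 profile: substitution rate ~ 1e-4 (Phred formula)
  lib <- shared_sequence_library()
  d <- simulation_design(lib$instances, layout = "SE100", coverage = 100,
                         dete_frac = 0, seed = 2)
  cm <- simulate_count_matrix(d, deterministic = TRUE)[, 1L, drop = FALSE]
  q40 <- learn_quality_profile(
    write_test_fastq(rep(strrep("A", 100), 5L)))
  rr <- simulate_reads(cm, lib, d, out_dir = tempfile("q_"), seed = 8,
                       error_model = "profile", quality_profile = q40)
  fq1 <- readLines(rr$files$mate1[1L])
  seqs <- fq1[seq(2, length(fq1), 4)]
  names_ <- sub("^@", "", fq1[seq(1, length(fq1), 4)])
  origin <- vapply(strsplit(names_, ";", fixed = TRUE), `[`, "", 1L)
  exact <- mapply(function(s, te) grepl(s, lib$sequences[[te]], fixed = TRUE),
                  seqs, origin)
  n_bases <- sum(nchar(seqs))
  n_err_reads <- sum(!exact)
  # ~1e-4 per base: expect errors to exist but stay rare (5 sd Poisson band)
  lambda <- n_bases * 1e-4
  expect_lt(abs(n_err_reads - lambda), 5 * sqrt(lambda) + 3)
})
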