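test_that("the read mini-format parses calls, ambiguity sets, and unknowns", {
  rd <- parse_nterm_read("MA{S|T}KXLD")
  expect_identical(length(rd), 7L)
  expect_identical(rd$positions[[3]], c("S", "T"))
  expect_identical(rd$positions[[5]], "X")
  expect_identical(format(rd), "MA{S|T}KXLD")
  expect_error(parse_nterm_read("MA{S|T"), "unclosed")
  expect_error(parse_nterm_read("MAZ"), "invalid residue")
  expect_error(parse_nterm_read(""), "empty")
})

test_that("variant enumeration expands call sets and model additions", {
  no_model <- error_model(cys_loss = FALSE, deamidation = FALSE)
  expect_identical(enumerate_variants("A{S|T}G", no_model)$peptide,
                   c("ASG", "ATG"))
  # deamidation: observed D admits N, observed E admits Q
  expect_identical(enumerate_variants("AD", error_model())$peptide,
                   c("AD", "AN"))
  expect_identical(enumerate_variants("E", error_model())$peptide, c("E", "Q"))
  # two ambiguous positions with 2 options each -> 4 variants
  v <- enumerate_variants("{A|G}M{S|T}LL", no_model)
  expect_identical(nrow(v), 4L)
  # count conservation: product of per-position option counts
  v2 <- enumerate_variants("X{D|N}A", error_model())
  expect_identical(nrow(v2), 20L * 2L * 1L)
})

test_that("variant traces record which model corrections were assumed", {
  v <- enumerate_variants("AD", error_model())
  plain <- v[v$peptide == "AD", ]
  fixed <- v[v$peptide == "AN", ]
  expect_identical(plain$n_corrections, 0L)
  expect_identical(fixed$corrections[[1]]$rule, "deamidation")
  expect_identical(fixed$corrections[[1]]$position, 2L)

  vx <- enumerate_variants("XA", error_model())
  cys <- vx[vx$peptide == "CA", ]
  expect_identical(cys$corrections[[1]]$rule, "cys_loss")
})

test_that("the variant cap errors with the would-be count", {
  expect_error(enumerate_variants("XXX", error_model(variant_cap = 100)),
               "8000")
})

test_that("exact prefix scan finds a planted protein at offset zero", {
  set.seed(5)
  prot <- random_proteome(10)
  target <- prot$sequence[4]
  v <- substr(target, 1, 12)
  hits <- scan_proteome(v, prot, max_mismatch = 0, max_start_offset = 0,
                        met_start = FALSE)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$protein_id, "p004")
  expect_identical(hits$start_offset, 0L)
  expect_identical(hits$mismatches, 0L)
})

test_that("initiator-Met placement is tried when enabled", {
  prot <- data.frame(protein_id = "pM", organism = NA,
                     sequence = "MSTARTPEPTIDEAAAA", stringsAsFactors = FALSE)
  v <- "STARTPEPTIDE"  # mature N-terminus, Met cleaved
  none <- scan_proteome(v, prot, max_mismatch = 0, max_start_offset = 0,
                        met_start = FALSE)
  expect_identical(nrow(none), 0L)
  met <- scan_proteome(v, prot, max_mismatch = 0, max_start_offset = 0,
                       met_start = TRUE)
  expect_identical(met$start_offset, 1L)
})

test_that("scan matches the brute-force placement oracle on random proteomes", {
  set.seed(31)
  for (trial in 1:10) {
    prot <- random_proteome(sample(5:20, 1))
    read <- substr(prot$sequence[sample(nrow(prot), 1)], 1, 10)
    hits <- scan_proteome(read, prot, max_mismatch = 2)
    oracle <- brute_force_scan(read, prot, max_mismatch = 2)
    got <- as.data.frame(hits)[order(hits$protein_id, hits$variant,
                                     hits$start_offset),
                               c("protein_id", "variant", "start_offset",
                                 "mismatches")]
    rownames(got) <- rownames(oracle) <- NULL
    expect_identical(got, oracle)
  }
})

test_that("ranking is stable under proteome permutation", {
  set.seed(77)
  prot <- random_proteome(30)
  read <- substr(prot$sequence[11], 1, 15)
  base <- scan_proteome(read, prot, max_mismatch = 2)
  perm <- scan_proteome(read, prot[sample(nrow(prot)), ], max_mismatch = 2)
  rownames(base) <- rownames(perm) <- NULL
  expect_identical(base, perm)
})

test_that("variants longer than a protein are skipped; empty proteome errors", {
  prot <- data.frame(protein_id = "tiny", organism = NA, sequence = "MKL",
                     stringsAsFactors = FALSE)
  hits <- scan_proteome("MKLVVA", prot, max_mismatch = 2)
  expect_identical(nrow(hits), 0L)
  expect_error(scan_proteome("MKL", prot[0, ]), "empty proteome")
})

test_that("average molecular weight follows the residue-mass table", {
  expect_equal(compute_mw("G"), 75.07, tolerance = 1e-4)
  expect_error(compute_mw(""), "non-empty")
  expect_error(compute_mw("AXA"), "position 2")
  # additivity: mw(ab) == mw(a) + mw(b) - water
  set.seed(9)
  for (i in 1:5) {
    a <- paste(sample(orphanEnzymes:::AA_STANDARD, 8, replace = TRUE), collapse = "")
    b <- paste(sample(orphanEnzymes:::AA_STANDARD, 5, replace = TRUE), collapse = "")
    expect_equal(compute_mw(paste0(a, b)),
                 compute_mw(a) + compute_mw(b) - orphanEnzymes:::MASS_WATER,
                 tolerance = 1e-6)
  }
})

test_that("molecular-weight validation applies the relative tolerance", {
  chk <- mw_check(33, 30)
  expect_equal(chk$rel_dev, 0.1, tolerance = 1e-12)
  expect_true(chk$pass)
  expect_false(mw_check(60, 30)$pass)
  identical_chk <- mw_check(30, 30)
  expect_identical(identical_chk$rel_dev, 0)
  expect_true(identical_chk$pass)
  expect_error(mw_check(33, 0), "positive")
  expect_error(mw_check(33, 30, rel_tolerance = 1.5), "rel_tolerance")

  seqG20 <- paste(rep("G", 20), collapse = "")
  cand <- data.frame(protein_id = "p", start_offset = 0L, mismatches = 0L)
  out <- validate_mw(cand, seqG20, exp_kda = compute_mw(seqG20) / 1000)
  expect_true(out$mw_pass)
  expect_identical(out$mw_rel_dev, 0)
})

test_that("MW-only identification flags uniqueness and matches a recount", {
  set.seed(12)
  prot <- random_proteome(40, len_range = c(30L, 300L))
  masses <- vapply(prot$sequence, compute_mw, numeric(1)) / 1000
  target_kda <- masses[17]
  res <- mw_only_match(target_kda, prot, rel_tolerance = 0.001)
  expect_true(attr(res, "unique"))
  expect_identical(res$protein_id, prot$protein_id[17])

  loose <- mw_only_match(target_kda, prot, rel_tolerance = 0.5)
  oracle_ids <- prot$protein_id[abs(masses - target_kda) / target_kda <= 0.5]
  expect_setequal(loose$protein_id, oracle_ids)
  expect_false(attr(loose, "unique"))
  expect_false(is.unsorted(loose$rel_dev))

  none <- mw_only_match(1e6, prot)
  expect_identical(nrow(none), 0L)
  expect_false(attr(none, "unique"))
})

test_that("proteome FASTA round-trips through Biostrings", {
  prot <- random_proteome(5)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_proteome(prot, path)
  back <- read_proteome(path)
  expect_identical(back, prot)
})
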