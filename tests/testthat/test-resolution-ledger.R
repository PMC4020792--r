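test_that("resolution records enforce the RESOLVED/OPEN contract", {
  ok <- resolution_record("1.1.1.173", "RESOLVED", "SIMILAR_ACTIVITY_REPLACED",
                          "LITERATURE_DATABASE", "XP_001385014")
  expect_identical(ok$category_group, "ANNOTATION_UPDATE")
  open <- resolution_record("1.1.1.1", "OPEN")
  expect_true(is.na(open$category))
  expect_error(resolution_record("1.1.1.1", "RESOLVED"), "category")
  expect_error(resolution_record("1.1.1.1", "RESOLVED", "MISSING_EC"), "method")
  expect_error(resolution_record("1.1.1.1", "RESOLVED", "MISSING_EC",
                                 "LITERATURE_DATABASE"), "accession")
  expect_error(resolution_record("1.1.1.1", "OPEN", category = "MISSING_EC"),
               "OPEN")
})

test_that("category_group is a pure function of category", {
  expect_identical(category_group(c("CLASS_LEVEL_ONLY", "ADDITIONAL_ACTIVITY",
                                    "NO_ACTIVITY_ASSIGNED",
                                    "SIMILAR_ACTIVITY_REPLACED")),
                   rep("ANNOTATION_UPDATE", 4))
  expect_identical(category_group(c("MISSING_EC", "MISSING_SYNONYM", "WRONG_EC")),
                   rep("DATA_LABELING", 3))
  expect_error(category_group("NOT_A_CATEGORY"))
})

test_that("the classification ladder resolves the documented cases", {
  rham <- list(ec = "1.1.1.173",
               official_names = c("L-rhamnose 1-dehydrogenase",
                                  "L-rhamnose-1-dehydrogenase"))
  # activity name matches the official list, EC field empty
  expect_identical(
    classify(list(level = "specific", names = "L-rhamnose 1-dehydrogenase",
                  ec_state = "absent"), rham),
    "MISSING_EC")
  # annotated with a different specific activity that got replaced
  expect_identical(
    classify(list(level = "specific", names = "glucose 1-dehydrogenase II"), rham),
    "SIMILAR_ACTIVITY_REPLACED")
  # class-level annotation only
  expect_identical(
    classify(list(level = "class", names = "aldehyde dehydrogenase"),
             list(ec = "1.2.1.69",
                  official_names = "fluoroacetaldehyde dehydrogenase")),
    "CLASS_LEVEL_ONLY")
  # no annotation at all
  expect_identical(classify(list(level = "none"), rham), "NO_ACTIVITY_ASSIGNED")
  # correct activity, unlisted synonym
  expect_identical(
    classify(list(level = "specific", names = "rhamnose NAD oxidoreductase",
                  same_activity = TRUE, names_listed = FALSE), rham),
    "MISSING_SYNONYM")
  # correct activity, wrong EC attached
  expect_identical(
    classify(list(level = "specific", names = "L-rhamnose 1-dehydrogenase",
                  ec_state = "wrong"), rham),
    "WRONG_EC")
  # a second, genuine activity of the same enzyme
  expect_identical(
    classify(list(level = "specific", names = "some other activity",
                  also_catalyzed = TRUE), rham),
    "ADDITIONAL_ACTIVITY")
})

test_that("contradictory annotation states are rejected", {
  rham <- list(ec = "1.1.1.173", official_names = "L-rhamnose 1-dehydrogenase")
  expect_error(classify(list(level = "none",
                             names = "L-rhamnose 1-dehydrogenase"), rham),
               "contradictory")
  expect_error(classify(list(level = "class", same_activity = TRUE), rham),
               "contradictory")
})

# A ledger with given resolved category counts, method counts, and open count.
build_ledger <- function(cat_counts, method_counts, n_open) {
  cats <- rep(names(cat_counts), cat_counts)
  methods <- rep(names(method_counts), method_counts)
  stopifnot(length(cats) == length(methods))
  n <- length(cats) + n_open
  ecs <- sprintf("1.1.%d.%d", seq_len(n) %/% 100 + 1, seq_len(n) %% 100 + 1)
  rows <- lapply(seq_len(n), function(i) {
    if (i <= length(cats)) {
      resolution_record(ecs[i], "RESOLVED", cats[i], methods[i],
                        sprintf("ACC%04d", i))
    } else resolution_record(ecs[i], "OPEN")
  })
  resolution_ledger(rows)
}

test_that("ledger summary counts, groups, and percentages are conserved", {
  led <- build_ledger(
    c(CLASS_LEVEL_ONLY = 3, MISSING_EC = 2, WRONG_EC = 1),
    c(LITERATURE_DATABASE = 4, NTERM_MATCH = 1, MW_MATCH = 1),
    n_open = 4)
  s <- summary(led)
  expect_identical(s$n_total, 10L)
  expect_identical(s$n_resolved, 6L)
  expect_identical(s$n_open, 4L)
  expect_identical(sum(s$categories$n), s$n_resolved)
  expect_identical(sum(s$groups$n), s$n_resolved)
  expect_identical(sum(s$methods$n), s$n_resolved)
  # subtype counts sum to their group counts
  for (g in s$groups$group) {
    expect_identical(sum(s$categories$n[s$categories$group == g]),
                     s$groups$n[s$groups$group == g])
  }
  expect_equal(s$resolved_pct + s$open_pct, 100, tolerance = 0.011)
  expect_identical(s$denominators$outcome, 10L)
  expect_identical(s$denominators$category, 6L)
})

test_that("a single resolved record summarizes to 100.00%", {
  led <- build_ledger(c(MISSING_SYNONYM = 1), c(LITERATURE_DATABASE = 1), 0)
  s <- summary(led)
  expect_identical(s$categories$pct[s$categories$category == "MISSING_SYNONYM"], 100)
  expect_identical(s$resolved_pct, 100)
})

test_that("summary is invariant to ledger row order", {
  led <- build_ledger(
    c(CLASS_LEVEL_ONLY = 5, ADDITIONAL_ACTIVITY = 2, MISSING_EC = 3),
    c(LITERATURE_DATABASE = 8, NTERM_MATCH = 2), n_open = 7)
  set.seed(3)
  shuffled <- resolution_ledger(led[sample(nrow(led)), ])
  s1 <- summary(led); s2 <- summary(shuffled)
  rownames(s1$categories) <- rownames(s2$categories) <- NULL
  expect_identical(s1$categories, s2$categories)
  expect_identical(s1$resolved_pct, s2$resolved_pct)
})

test_that("ledger TSV and summary outputs round-trip", {
  led <- build_ledger(c(CLASS_LEVEL_ONLY = 2, MISSING_EC = 1),
                      c(LITERATURE_DATABASE = 3), n_open = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ledger_tsv(led, path)
  back <- read_ledger_tsv(path)
  expect_identical(as.data.frame(back), as.data.frame(led))

  s <- summary(led)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  rows <- summary_to_tsv(s, tsv)
  expect_identical(sum(rows$n[rows$section == "category"]), s$n_resolved)
  js <- withr::local_tempfile(fileext = ".json")
  summary_to_json(s, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$n_resolved, 3)
})

test_that("identification tables write the S2 column order and round-trip", {
  rows <- identification_info(
    ec = c("2.8.2.34", "2.8.2.34", "1.1.1.173"),
    citation = c("2757105", "2757105", "18211290"),
    organism = c("Rattus norvegicus", "Rattus norvegicus", "Scheffersomyces stipitis"),
    has_purification = c(TRUE, TRUE, FALSE),
    has_assay = c(TRUE, FALSE, TRUE),
    sequence_info = c("AAA41356.1", NA, "RHA1"),
    mw_kda = c(30, NA, NA),
    isoelectric_point = c(NA, 5.2, NA),
    has_kinetics = c(FALSE, TRUE, FALSE),
    notes = c("N-terminal 31-33 residues reported", "", ""))
  path <- withr::local_tempfile(fileext = ".tsv")
  expect_identical(write_identification_table(rows, path), 3L)
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_identical(header, c("ec", "citation", "organism", "purification",
                             "assay", "sequence", "mw_kda", "pi", "kinetics",
                             "notes"))
  # absent MW is an empty cell, not 0
  line2 <- strsplit(readLines(path)[3], "\t")[[1]]
  expect_identical(line2[7], "")
  back <- read_identification_table(path)
  expect_identical(as.data.frame(back), as.data.frame(rows))
})

test_that("identification rows reject NA booleans and duplicate combinations", {
  expect_error(identification_info("1.1.1.1", "123", "E. coli",
                                   has_purification = NA), "never NA")
  expect_error(identification_info(rep("1.1.1.1", 2), rep("123", 2),
                                   rep("E. coli", 2)), "duplicate")
})

test_that("a 50-row table writes 51 lines", {
  rows <- identification_info(
    ec = rep("1.1.1.1", 50), citation = sprintf("pub%02d", 1:50),
    organism = "E. coli")
  path <- withr::local_tempfile(fileext = ".tsv")
  expect_identical(write_identification_table(rows, path), 50L)
  expect_identical(length(readLines(path)), 51L)
})
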