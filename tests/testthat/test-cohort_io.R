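# cohort_io: matrix text formats, manifests, QC filter, group assignment

test_that("labeled matrix TSV round-trips bitwise and validates kinds", {
  vals <- matrix(c(1, 0.5, 0.5, 0.5, 1, 0.5, 0.5, 0.5, 1), 3, 3)
  m <- labeled_matrix(vals, c("A", "B", "C"), "fc")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_labeled_matrix(m, path)
  back <- read_labeled_matrix(path, "fc")
  expect_identical(unclass(back)[, ], unclass(m)[, ])
  expect_identical(rownames(back), c("A", "B", "C"))

  # second write of the re-read matrix is byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_labeled_matrix(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("round-trip is the identity over random valid matrices", {
  set.seed(42)
  for (i in 1:12) {
    n <- sample(2:8, 1)
    kind <- sample(c("fc", "sc_prob", "distance", "tract_count"), 1)
    m <- switch(kind,
      fc = random_fc(n),
      sc_prob = random_sc_prob(n),
      distance = {
        xyz <- matrix(rnorm(n * 3, sd = 40), n)
        labeled_matrix(as.matrix(dist(xyz)), sprintf("R%02d", 1:n), "distance")
      },
      tract_count = labeled_matrix(matrix(rpois(n * n, 4), n, n),
                                   sprintf("R%02d", 1:n), "tract_count"))
    path <- withr::local_tempfile(fileext = ".tsv")
    write_labeled_matrix(m, path)
    expect_identical(unclass(read_labeled_matrix(path, kind))[, ],
                     unclass(m)[, ], label = sprintf("kind %s rep %d", kind, i))
  }
})

test_that("FATCAT-style whitespace dialect with comments is accepted", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# FATCAT-like output", "# 3 ROIs",
               "A B C",
               "1 0.2 0.3",
               "0.2 1 0.4",
               "0.3 0.4 1"), path)
  m <- read_labeled_matrix(path, "fc")
  expect_identical(rownames(m), c("A", "B", "C"))
  expect_equal(m["A", "C"], 0.3)
})

test_that("format and invariant violations are reported with the cell", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A B C", "1 0.2 0.3", "0.2 1 0.4"), path)
  expect_error(read_labeled_matrix(path, "fc"), "non-square")

  writeLines(c("A B", "1 1.2", "1.2 1"), path)
  expect_error(read_labeled_matrix(path, "fc"), "\\[A, B\\]|\\[B, A\\]")

  writeLines(c("A B", "1 -0.1", "-0.1 1"), path)
  expect_error(read_labeled_matrix(path, "sc_prob"), "outside \\[0, 1\\]")

  expect_error(labeled_matrix(matrix(1, 0, 0), character(0), "fc"), "empty")
  expect_error(read_labeled_matrix(tempfile("nope"), "fc"), "not found")
})

test_that("voxel-count tables round-trip through the long TSV format", {
  labs <- c("A", "B")
  vct <- make_counts(list("A->B" = c(0L, 3L, 5L), "B->A" = c(2L, 0L, 0L, 1L)),
                     c(A = 50, B = 40), labs)
  cp <- withr::local_tempfile(fileext = ".tsv")
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_voxel_counts(vct, cp, tp)
  back <- read_voxel_counts(cp, tp, labs)
  expect_identical(back$pairs, vct$pairs)
  expect_equal(back$total_leaving, vct$total_leaving)
  expect_error(make_counts(list("A->B" = integer(0)), c(A = 1, B = 1), labs),
               "empty voxel-count")
})

test_that("manifest reading enforces structure and yields one record per row", {
  cohort <- generate_cohort(sim_config(seed = 11))
  dir <- withr::local_tempdir()
  manifest <- write_cohort(cohort, dir)
  records <- read_manifest(manifest)
  expect_length(records, 17L)
  expect_identical(vapply(records, `[[`, character(1), "subject_id"),
                   vapply(cohort$subjects, `[[`, character(1), "subject_id"))

  # attached connectome matches what was written
  rec <- read_subject_connectome(records[[3]])
  expect_equal(unclass(rec$connectome$fc)[, ],
               unclass(cohort$subjects[[3]]$connectome$fc)[, ])
  expect_identical(rec$connectome$counts$pairs,
                   cohort$subjects[[3]]$connectome$counts$pairs)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("subject_id\tmean_relative_displacement\tgroup", empty)
  expect_error(read_manifest(empty), "no subjects")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tmean_relative_displacement\tgroup",
               "s1\t0.2\tcontrol", "s1\t0.3\tadversity"), dup)
  expect_error(read_manifest(dup), "duplicate subject_id")

  nocol <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,group", "s1,control"), nocol)
  expect_error(read_manifest(nocol), "mean_relative_displacement")
})

test_that("qc_filter excludes strictly above threshold and partitions", {
  subj <- function(id, d) list(subject_id = id, mean_relative_displacement = d)
  cohort <- list(subj("a", 0.56), subj("b", 0.55), subj("c", 0.1),
                 subj("d", 0.72))
  res <- qc_filter(cohort)
  expect_identical(vapply(res$kept, `[[`, character(1), "subject_id"),
                   c("b", "c"))
  expect_identical(vapply(res$excluded, `[[`, character(1), "subject_id"),
                   c("a", "d"))
  # partition-complete and idempotent
  expect_length(c(res$kept, res$excluded), length(cohort))
  again <- qc_filter(res$kept)
  expect_identical(again$kept, res$kept)
  expect_length(again$excluded, 0L)

  empty <- qc_filter(list())
  expect_length(empty$kept, 0L)
  expect_length(empty$excluded, 0L)

  expect_error(qc_filter(list(subj("x", NA))), "missing.*x")
})

test_that("adversity grouping follows the composite threshold rule", {
  expect_identical(adversity_group(epds = 12), list(score = 1L, group = "adversity"))
  # STAI alone is not enough: HAM-A must also exceed its threshold
  expect_identical(adversity_group(stai = 30, ham_a = 17),
                   list(score = 0L, group = "control"))
  expect_identical(adversity_group(stai = 30, ham_a = 18)$group, "adversity")
  expect_identical(adversity_group(madrs = 7)$group, "adversity")
  expect_identical(adversity_group(epds = 11, stai = 29, ham_a = 17, madrs = 6),
                   list(score = 0L, group = "control"))
  expect_identical(adversity_group(low_income = TRUE)$group, "adversity")
  expect_identical(adversity_group()$group, "control")
  expect_error(adversity_group(epds = NA, strict = TRUE), "missing")
  expect_error(adversity_group(epds = -1), "negative")
})

test_that("adversity grouping is monotone in every input", {
  grid <- expand.grid(epds = c(NA, 5, 12), stai = c(NA, 20, 30),
                      ham_a = c(NA, 10, 18), madrs = c(NA, 2, 7),
                      low_income = c(FALSE, TRUE))
  for (i in seq_len(nrow(grid))) {
    base <- adversity_group(grid$epds[i], grid$stai[i], grid$ham_a[i],
                            grid$madrs[i], grid$low_income[i])
    # raising any score or setting low_income can never lower the score
    for (col in c("epds", "stai", "ham_a", "madrs")) {
      up <- grid[i, ]
      up[[col]] <- if (is.na(up[[col]])) 100 else up[[col]] + 100
      bumped <- adversity_group(up$epds, up$stai, up$ham_a, up$madrs,
                                up$low_income)
      expect_gte(bumped$score, base$score)
    }
    rich <- adversity_group(grid$epds[i], grid$stai[i], grid$ham_a[i],
                            grid$madrs[i], TRUE)
    expect_gte(rich$score, base$score)
  }
})
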