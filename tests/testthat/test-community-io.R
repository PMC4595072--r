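# Community matrix construction, CSV round-trips, OTU-map tallying, and the
# filtering/pooling transforms.

test_that("CSV read-back reproduces counts and rejects malformed cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,o1,o2", "s1,1,2", "s2,3,4"), path)
  cm <- read_community_matrix(path, marker = "toy")
  expect_equal(unname(rowSums(cm$counts)), c(3, 7))
  expect_equal(colnames(cm$counts), c("o1", "o2"))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,o1,o2", "s1,1,-2", "s2,3,4"), bad)
  expect_error(read_community_matrix(bad), "negative.*s1.*o2")

  nonnum <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,o1,o2", "s1,1,x", "s2,3,4"), nonnum)
  expect_error(read_community_matrix(nonnum), "non-numeric")
})

test_that("write then read is a cell-exact round trip", {
  set.seed(42)
  for (k in 1:5) {
    cm <- random_cm(sample(2:8, 1), sample(2:12, 1))
    # mix in non-integer abundances to exercise both formats
    if (k > 3) cm$counts[1, 1] <- cm$counts[1, 1] + 0.125
    path <- withr::local_tempfile(fileext = ".csv")
    write_community_matrix(cm, path)
    back <- read_community_matrix(path, marker = cm$marker)
    expect_identical(back$counts, cm$counts)
    expect_identical(length(readLines(path)), nrow(cm$counts) + 1L)
  }
})

test_that("constructor enforces the matrix invariants", {
  m <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("o1", "o2")))
  expect_s3_class(community_matrix(m), "community_matrix")
  m0 <- m
  m0["a", ] <- 0
  expect_error(community_matrix(m0), "empty sample")
  expect_error(community_matrix(m - 2), "negative")
  dup <- rbind(m, m)
  expect_error(community_matrix(dup), "duplicate sample")
})

test_that("OTU-read maps tally into matrices conserving record counts", {
  map <- data.frame(
    read_label = c("s1_1", "s1_2", "s1_3", "s2_4", "s2_5"),
    otu_id = c("o1", "o1", "o1", "o2", "o2"))
  cm <- build_matrix_from_otu_map(map)
  expect_equal(unname(cm$counts), matrix(c(3, 0, 0, 2), 2, byrow = TRUE))

  one <- build_matrix_from_otu_map(data.frame(r = "s1_1", o = "o1"))
  expect_equal(dim(one$counts), c(1L, 1L))
  expect_equal(sum(one$counts), 1)

  expect_error(build_matrix_from_otu_map(
    data.frame(r = c("s1_1", "noreadnum"), o = c("o1", "o2"))),
    "noreadnum")

  # seeded random record stream: per-sample totals must match label tallies
  set.seed(11)
  samples <- sample(paste0("Plot", 1:4, "-A"), 1000, replace = TRUE)
  map <- data.frame(read_label = paste0(samples, "_", seq_len(1000)),
                    otu_id = sample(paste0("o", 1:10), 1000, replace = TRUE))
  cm <- build_matrix_from_otu_map(map)
  expect_equal(sum(cm$counts), 1000)
  tallies <- table(samples)
  expect_equal(rowSums(cm$counts)[names(tallies)], c(tallies))
  expect_equal(unname(cm$plots), sub("-A$", "", rownames(cm$counts)))
})

test_that("singleton removal drops exactly the total-1 OTUs and is idempotent", {
  m <- matrix(c(1, 2, 5,
                0, 0, 0), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("x", "y", "z")))
  m["b", ] <- c(0, 1, 3)
  cm <- community_matrix(m)
  out <- remove_singleton_otus(cm)
  expect_setequal(colnames(out$counts), c("y", "z"))
  expect_identical(remove_singleton_otus(out)$counts, out$counts)

  # no singletons: identity
  cm2 <- community_matrix(m * 2)
  expect_identical(remove_singleton_otus(cm2)$counts, cm2$counts)

  # sample whose only OTU is a singleton
  m3 <- matrix(c(5, 0, 0, 1), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(remove_singleton_otus(community_matrix(m3)), "emptied.*b")
})

test_that("pooling to plots sums subplots and conserves totals", {
  m <- matrix(c(1, 0, 2, 3), 2, byrow = TRUE,
              dimnames = list(c("P1-A", "P1-B"), c("o1", "o2")))
  cm <- community_matrix(m, plots = c("P1-A" = "P1", "P1-B" = "P1"),
                         subplots = c("P1-A" = "A", "P1-B" = "B"))
  pooled <- pool_to_plots(cm)
  expect_equal(unname(pooled$counts["P1", ]), c(3, 3))

  # already plot-level: identity on counts
  plotlev <- random_cm(4, 6)
  expect_equal(unname(pool_to_plots(plotlev)$counts), unname(plotlev$counts))

  # random 10 plots x 2 subplots: grand and per-OTU totals conserved
  set.seed(3)
  ids <- as.vector(outer(paste0("P", 1:10), c("A", "B"), paste, sep = "-"))
  counts <- random_counts(20, 15)
  rownames(counts) <- ids
  cm <- community_matrix(counts, plots = setNames(rep(paste0("P", 1:10),
                                                      each = 2), ids))
  pooled <- pool_to_plots(cm)
  expect_equal(sum(pooled$counts), sum(counts))
  expect_equal(unname(colSums(pooled$counts)), unname(colSums(counts)))
})

test_that("presence-absence conversion: binary and subplot-frequency modes", {
  m <- matrix(c(0, 7, 2, 0), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("o1", "o2")))
  bin <- to_presence_absence(community_matrix(m))
  expect_equal(unname(bin$counts), matrix(c(0, 1, 1, 0), 2, byrow = TRUE))
  # idempotent
  expect_identical(to_presence_absence(bin)$counts, bin$counts)

  # a species present in all 24 subplots of a plot scores 24
  ids <- paste0("P1-", sprintf("%02d", 1:24))
  counts <- matrix(1, 24, 2, dimnames = list(ids, c("ubiquitous", "rare")))
  counts[2:24, "rare"] <- 0
  cm <- community_matrix(counts,
                         plots = setNames(rep("P1", 24), ids),
                         subplots = setNames(sprintf("%02d", 1:24), ids))
  freq <- to_presence_absence(cm, mode = "subplot-frequency")
  expect_equal(unname(freq$counts["P1", ]), c(24, 1))

  # >24 subplots in a plot is rejected
  ids25 <- paste0("P1-", sprintf("%02d", 1:25))
  counts25 <- matrix(1, 25, 1, dimnames = list(ids25, "o1"))
  cm25 <- community_matrix(counts25,
                           plots = setNames(rep("P1", 25), ids25),
                           subplots = setNames(sprintf("%02d", 1:25), ids25))
  expect_error(to_presence_absence(cm25, mode = "subplot-frequency"),
               "more than 24")
})

test_that("sample labels parse into the plot/subplot hierarchy", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,o1", "Plot4-K,3", "Plot4-P,1", "Plot9-A,2"), path)
  cm <- read_community_matrix(path)
  expect_equal(unname(cm$plots), c("Plot4", "Plot4", "Plot9"))
  expect_equal(unname(cm$subplots), c("K", "P", "A"))

  # strict pattern: unparsable id is a hierarchy error
  flat <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,o1", "Plot4,3", "Plot9,2"), flat)
  expect_error(read_community_matrix(flat, label_pattern = "^(.+)-([A-P])$"),
               "not matching")
  # auto mode treats them as plot-level
  cm2 <- read_community_matrix(flat)
  expect_equal(unname(cm2$plots), c("Plot4", "Plot9"))
  expect_null(cm2$subplots)
})
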