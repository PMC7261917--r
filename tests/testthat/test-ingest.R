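test_that("expression TSV reading handles scale, orientation and NA tokens", {
  p <- write_tsv_fixture(c("feature\ts1\ts2",
                           "f1\t0\t1",
                           "f2\t3\t0",
                           "f3\t1\t3"))
  m <- read_expression_tsv(p, scale = "linear")
  expect_equal(unname(m[, 1]), c(0, 2, 1))
  expect_equal(unname(m["f3", ]), c(1, 2))
  # transposed file with samples-in-rows reads to the identical matrix
  pt <- write_tsv_fixture(c("sample\tf1\tf2\tf3",
                            "s1\t0\t3\t1",
                            "s2\t1\t0\t3"))
  mt <- read_expression_tsv(pt, orientation = "samples-in-rows",
                            scale = "linear")
  expect_equal(m, mt, ignore_attr = TRUE)
  # one NA token -> exactly one missing entry
  pna <- write_tsv_fixture(c("feature\ts1\ts2", "f1\tNA\t1", "f2\t2\t2"))
  mna <- read_expression_tsv(pna)
  expect_equal(sum(is.na(mna)), 1L)
  # duplicate sample IDs and non-numeric cells are format errors
  expect_error(read_expression_tsv(
    write_tsv_fixture(c("feature\ts1\ts1", "f1\t1\t2"))), "duplicate")
  expect_error(read_expression_tsv(
    write_tsv_fixture(c("feature\ts1", "f1\tabc"))), "non-numeric")
})

test_that("round-trip write/read preserves values to 1e-9", {
  set.seed(1)
  m <- matrix(rnorm(20), 4, 5,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:5)))
  p <- tempfile(fileext = ".tsv")
  write_expression_tsv(m, p)
  m2 <- read_expression_tsv(p)
  expect_equal(m, m2, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("missing-value filter drops features first, then samples", {
  m <- matrix(1, 4, 4, dimnames = list(paste0("f", 1:4), paste0("s", 1:4)))
  m[2, 3] <- NA
  out <- filter_missing(m)
  expect_equal(dim(out), c(3L, 4L))   # feature dropped, sample survives
  expect_false(anyNA(out))
  # no NA -> identity; idempotence
  m2 <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z")))
  expect_equal(filter_missing(m2), m2, ignore_attr = TRUE)
  expect_equal(filter_missing(out), out, ignore_attr = TRUE)
  # an all-NA column kills every feature -> empty result with warning
  m3 <- matrix(1, 3, 3, dimnames = list(paste0("f", 1:3), paste0("s", 1:3)))
  m3[, 1] <- NA
  expect_warning(out3 <- filter_missing(m3), "empty")
  expect_equal(nrow(out3), 0L)
})

test_that("isoform aggregation sums on the linear scale then logs", {
  iso <- matrix(c(3, 5, 0), 3, 1,
                dimnames = list(c("i1", "i2", "i3"), "s1"))
  map <- c(i1 = "mature_a", i2 = "mature_a", i3 = "mature_b")
  out <- aggregate_isoforms(iso, map)
  expect_equal(out["mature_a", 1], log2(9))
  expect_equal(out["mature_b", 1], 0)
  iso3 <- matrix(c(1, 1, 1), 3, 1,
                 dimnames = list(c("i1", "i2", "i4"), "s1"))
  expect_warning(out3 <- aggregate_isoforms(iso3, map), "unmapped")
  expect_equal(out3["mature_a", 1], log2(3))
})

test_that("duplicate-ID collapsing averages per sample", {
  m <- matrix(c(2, 4, 1, 2, 6, 9), 3, 2,
              dimnames = list(c("acc1", "acc2", "acc3"), c("s1", "s2")))
  map <- c(acc1 = "id1", acc2 = "id1", acc3 = "id2")
  out <- collapse_duplicate_ids(m, map)
  expect_equal(out["id1", "s1"], 3)
  expect_equal(out["id2", "s2"], 9)
  # injective map leaves the row count unchanged
  out2 <- collapse_duplicate_ids(m, c(acc1 = "x", acc2 = "y", acc3 = "z"))
  expect_equal(nrow(out2), 3L)
  # three rows to one ID -> mean of the three
  m3 <- matrix(c(1, 2, 6), 3, 1,
               dimnames = list(c("a", "b", "c"), "s1"))
  out3 <- collapse_duplicate_ids(m3, c(a = "g", b = "g", c = "g"))
  expect_equal(out3["g", 1], 3)
})

test_that("clinical alignment intersects, drops NA OS and normal tissue", {
  m <- matrix(1, 2, 5,
              dimnames = list(c("f1", "f2"), paste0("s", 1:5)))
  cl <- data.frame(sample = c("s1", "s2", "s3", "s4", "s6"),
                   os_days = c(10, NA, 30, 40, 50),
                   sample_type_code = c("01", "01", "11", "06", "01"),
                   stringsAsFactors = FALSE)
  out <- align_with_clinical(m, cl)
  # s2 (NA OS), s3 (normal code 11), s5/s6 (not shared) all removed
  expect_equal(colnames(out$matrix), c("s1", "s4"))
  expect_equal(out$clinical$sample, colnames(out$matrix))
  # without a code column, only the OS and intersection rules apply
  cl2 <- data.frame(sample = c("s1", "s2", "s3"), os_days = c(1, 2, 3))
  expect_equal(ncol(align_with_clinical(m, cl2)$matrix), 3L)
  expect_error(align_with_clinical(
    m, data.frame(sample = "zz", os_days = 1)), "no samples")
})

test_that("median-OS labeling uses a strict inequality", {
  lab <- label_by_median_os(data.frame(sample = c("a", "b", "c"),
                                       os_days = c(10, 20, 30)))
  expect_equal(lab$median_os, 20)
  expect_equal(unname(lab$labels), c("low-OS", "low-OS", "high-OS"))
  lab4 <- label_by_median_os(data.frame(sample = letters[1:4],
                                        os_days = c(10, 20, 30, 40)))
  expect_equal(lab4$median_os, 25)
  expect_equal(sum(lab4$labels == "high-OS"), 2L)
  expect_warning(
    lab_eq <- label_by_median_os(data.frame(sample = letters[1:3],
                                            os_days = c(7, 7, 7))),
    "low-OS")
  expect_true(all(lab_eq$labels == "low-OS"))
  expect_error(label_by_median_os(data.frame(sample = "a", os_days = 1)),
               "2 samples")
})

test_that("high-OS class size never exceeds floor(n/2)", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(2:40, 1)
    os <- sample(1:15, n, replace = TRUE)
    lab <- suppressWarnings(label_by_median_os(
      data.frame(sample = paste0("s", 1:n), os_days = os)))
    expect_lte(sum(lab$labels == "high-OS"), floor(n / 2))
  }
})

test_that("omics merge row-concatenates over the sample intersection", {
  mi <- matrix(0, 10, 9, dimnames = list(paste0("mir_", 1:10),
                                         paste0("s", 1:9)))
  ln <- matrix(0, 20, 10, dimnames = list(paste0("lnc_", 1:20),
                                          paste0("s", 2:11)))
  out <- merge_omics(mi, ln)
  expect_equal(dim(out), c(30L, 8L))
  expect_equal(attr(out, "omic"), "merged")
  bad <- matrix(0, 1, 9, dimnames = list("mir_1", paste0("s", 1:9)))
  expect_error(merge_omics(mi, bad), "colliding")
  far <- matrix(0, 2, 3, dimnames = list(c("a", "b"), paste0("t", 1:3)))
  expect_error(merge_omics(mi, far), "intersection")
})
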