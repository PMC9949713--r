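mk_mask <- function(mat) {
  mask <- mat >= 1
  attr(mask, "min_umi") <- 1
  mask
}

test_that("binarization thresholds counts and records the threshold", {
  u <- matrix(c(0L, 1L, 2L, 5L), 2, 2,
              dimnames = list(c("gA", "gB"), c("c1", "c2")))
  m1 <- binarize(u)
  expect_equal(unname(m1), matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2),
               ignore_attr = TRUE)
  expect_equal(attr(m1, "min_umi"), 1)
  m2 <- binarize(u, min_umi = 2)
  expect_false(m2["gB", "c1"])   # count 1 below threshold 2
  expect_error(binarize(u, min_umi = 0), "min_umi")
  expect_error(binarize(matrix(0.5, 1, 1)), "integer")

  set.seed(9)
  r <- matrix(rpois(20 * 50, 1), 20, 50,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:50)))
  expect_identical(unname(binarize(r, 2))[TRUE], unname(r >= 2)[TRUE])
})

test_that("per-cell expressed-target histogram buckets 0/1/2/>=3 and sums to 1", {
  counts <- c(0, 0, 1, 1, 1, 2, 2, 3, 5, 9)
  u <- matrix(0L, 10, 10, dimnames = list(paste0("g", 1:10), paste0("c", 1:10)))
  for (j in seq_along(counts)) if (counts[j] > 0) u[seq_len(counts[j]), j] <- 1L
  h <- innexin_count_histogram(mk_mask(u), rownames(u))
  expect_equal(unname(h$fractions), c(0.2, 0.3, 0.2, 0.3))
  expect_equal(h$max_per_cell, 9)

  # all-zero matrix: everything in the 0 bucket
  h0 <- innexin_count_histogram(mk_mask(u * 0L), rownames(u))
  expect_equal(unname(h0$fractions), c(1, 0, 0, 0))

  # each cell expressing exactly one target
  u1 <- u * 0L; u1[cbind(1:10, 1:10)] <- 1L
  expect_equal(unname(innexin_count_histogram(mk_mask(u1),
                                              rownames(u1))$fractions),
               c(0, 1, 0, 0))

  # strict >3 bucketing still covers every cell
  h5 <- innexin_count_histogram(mk_mask(u), rownames(u), bucket3 = ">3")
  expect_equal(sum(h5$fractions), 1)
  expect_equal(unname(h5$fractions), c(0.2, 0.3, 0.2, 0.1, 0.2))

  expect_error(innexin_count_histogram(mk_mask(u), character(0)), "empty")

  set.seed(14)
  r <- mk_mask(matrix(rbinom(50 * 200, 1, 0.2), 50, 200,
                      dimnames = list(paste0("g", 1:50), paste0("c", 1:200))))
  hr <- innexin_count_histogram(r, paste0("g", 1:20))
  expect_equal(sum(hr$fractions), 1)
  pc <- colSums(r[paste0("g", 1:20), ])
  expect_equal(unname(hr$counts),
               c(sum(pc == 0), sum(pc == 1), sum(pc == 2), sum(pc >= 3)))
})

test_that("metacell markers use an inclusive expressed-fraction boundary", {
  u <- matrix(0L, 1, 9, dimnames = list("gA", paste0("c", 1:9)))
  u[1, 1:5] <- 1L
  mask <- mk_mask(u)
  mc <- data.frame(cell = paste0("c", 1:9),
                   metacell = c(rep("M1", 5), rep("M2", 4)))
  # M1: 5/5 expressing; M2: 0/4
  mk <- metacell_markers(mask, mc)
  expect_true(mk$is_marker[mk$metacell == "M1"])
  expect_false(mk$is_marker[mk$metacell == "M2"])

  # exactly 50% (2 of 4) is a marker: "at least 50%" is inclusive
  u2 <- matrix(c(1L, 1L, 0L, 0L), 1, 4,
               dimnames = list("gA", paste0("c", 1:4)))
  mk2 <- metacell_markers(mk_mask(u2),
                          data.frame(cell = paste0("c", 1:4), metacell = "M"))
  expect_equal(mk2$fraction, 0.5)
  expect_true(mk2$is_marker)

  # 3 of 5 expressing: fraction 0.6, marker
  u3 <- matrix(c(1L, 1L, 1L, 0L, 0L), 1, 5,
               dimnames = list("gA", paste0("c", 1:5)))
  mk3 <- metacell_markers(mk_mask(u3),
                          data.frame(cell = paste0("c", 1:5), metacell = "M"))
  expect_equal(mk3$fraction, 0.6)

  # a metacell with no cells in the matrix is skipped with a warning
  expect_warning(metacell_markers(mk_mask(u3),
                                  data.frame(cell = "zz", metacell = "M9")),
                 "skipped")
})

test_that("pairwise coexpression divides the joint count by the smaller marginal", {
  u <- matrix(0L, 2, 8, dimnames = list(c("A", "B"), paste0("c", 1:8)))
  u["A", 1:5] <- 1L
  u["B", 4:7] <- 1L
  cm <- pairwise_coexpression(mk_mask(u), c("A", "B"))
  expect_equal(unname(cm$n), c(5, 4))
  expect_equal(cm$n_both["A", "B"], 2)
  expect_equal(cm$percent["A", "B"], 50.0)
  expect_equal(cm$percent["A", "B"], cm$percent["B", "A"])
  expect_equal(cm$percent["A", "A"], 100)

  # identical expressing sets: 100%; disjoint: 0%; empty margin: NA
  u2 <- matrix(0L, 3, 4, dimnames = list(c("A", "B", "C"), paste0("c", 1:4)))
  u2["A", 1:2] <- 1L; u2["B", 1:2] <- 1L
  cm2 <- pairwise_coexpression(mk_mask(u2), c("A", "B", "C"))
  expect_equal(cm2$percent["A", "B"], 100)
  expect_true(is.na(cm2$percent["A", "C"]))
  u2["C", 3:4] <- 1L
  cm3 <- pairwise_coexpression(mk_mask(u2), c("A", "C"))
  expect_equal(cm3$percent["A", "C"], 0)
})

test_that("coexpression agrees with brute-force set arithmetic on random masks", {
  set.seed(27)
  mask <- mk_mask(matrix(rbinom(15 * 300, 1, 0.25), 15, 300,
                         dimnames = list(paste0("g", 1:15),
                                         paste0("c", 1:300))))
  targets <- paste0("g", 1:15)
  cm <- pairwise_coexpression(mask, targets)
  for (a in targets) {
    for (b in targets) {
      sa <- which(mask[a, ]); sb <- which(mask[b, ])
      nab <- length(intersect(sa, sb))
      expect_equal(unname(cm$n_both[a, b]), nab, ignore_attr = TRUE)
      mn <- min(length(sa), length(sb))
      if (mn > 0) expect_equal(cm$percent[a, b], round(100 * nab / mn, 1))
      else expect_true(is.na(cm$percent[a, b]))
    }
  }
  # threshold filter equals a brute-force scan
  pr <- coexpression_pairs(cm, 50)
  want <- 0L
  for (i in 1:14) for (j in (i + 1):15) {
    p <- cm$percent[targets[i], targets[j]]
    if (!is.na(p) && p >= 50) want <- want + 1L
  }
  expect_identical(nrow(pr), want)
  expect_false(any(pr$geneA == pr$geneB))

  # percentages are invariant to cell and gene reordering
  perm <- sample(ncol(mask))
  cmp <- pairwise_coexpression(mask[rev(targets), perm], rev(targets))
  expect_equal(cmp$percent[targets, targets], cm$percent[targets, targets])
})

test_that("expression ratios summarize per-sample A/B with median and MAD", {
  tpm <- matrix(c(4, 6, 8, 2, 3, 4), 2, 3, byrow = TRUE,
                dimnames = list(c("A", "B"), paste0("s", 1:3)))
  r <- expression_ratio(tpm, "A", "B")
  expect_equal(unname(r$ratios), c(2, 2, 2))
  expect_equal(r$median, 2)
  expect_equal(r$mad, 0)

  expect_equal(expression_ratio(tpm, "A", "A")$median, 1)

  tpm2 <- tpm; tpm2["B", ] <- 0
  expect_error(expression_ratio(tpm2, "A", "B"), "zero in every sample")

  # samples with a zero denominator are skipped, not divided
  tpm3 <- tpm; tpm3["B", 2] <- 0
  r3 <- expression_ratio(tpm3, "A", "B")
  expect_equal(names(r3$ratios), c("s1", "s3"))

  set.seed(31)
  rt <- matrix(runif(2 * 20, 0.5, 10), 2, 20,
               dimnames = list(c("A", "B"), paste0("s", 1:20)))
  rr <- expression_ratio(rt, "A", "B")
  expect_equal(unname(rr$ratios), unname(rt["A", ] / rt["B", ]))
})
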