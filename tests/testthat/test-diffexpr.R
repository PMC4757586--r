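make_ct <- function(counts, totals) {
  libs <- colnames(counts)
  structure(list(counts = counts, totals = setNames(totals, libs),
                 libraries = libs), class = "count_table")
}

test_that("normalization is reads-per-million with a zero pseudo-value", {
  m <- matrix(c(50L, 0L), 2, 1, dimnames = list(c("m1", "m2"), "lib1"))
  ct <- make_ct(m, 1e7)
  rpm <- normalize_counts(ct)
  expect_equal(rpm["m1", "lib1"], 5.0)
  expect_equal(rpm["m2", "lib1"], 0)   # zeros stored as zero
  de <- differential_table(make_ct(cbind(m, m * 0L + c(50L, 10L)) |>
                                     `colnames<-`(c("c", "t")),
                                   c(1e7, 1e7)), "c", "t")
  # pseudo-expression 0.01 RPM enters the ratio only
  expect_equal(de$log2fc[de$mirna == "m2"], log2(1 / 0.01))
  expect_error(normalize_counts(m, totals = 0), "positive")
})

test_that("column RPM sums equal the assigned-fraction scaling", {
  set.seed(5)
  m <- matrix(rpois(40, 50), 10, 4,
              dimnames = list(paste0("m", 1:10), paste0("l", 1:4)))
  tot <- colSums(m) + rpois(4, 2000)
  rpm <- normalize_counts(make_ct(m, tot))
  expect_equal(unname(colSums(rpm)), unname(1e6 * colSums(m) / tot))
})

test_that("the count test depends only on the library-size ratio", {
  expect_equal(audic_claverie_pvalue(0, 0, 1e6, 1e6), 1)
  set.seed(8)
  for (i in 1:20) {
    x <- rpois(1, 50); y <- rpois(1, 50)
    N1 <- sample(1e5:1e6, 1); N2 <- sample(1e5:1e6, 1)
    expect_equal(audic_claverie_pvalue(x, y, N1, N2),
                 audic_claverie_pvalue(x, y, 10 * N1, 10 * N2),
                 tolerance = 1e-12)
  }
  expect_error(audic_claverie_pvalue(-1, 0, 10, 10), "non-negative")
})

test_that("for fixed x the p-value decreases as |y - x| grows", {
  x <- 40
  ys <- c(40, 55, 70, 100, 150)
  p <- audic_claverie_pvalue(x, ys, 1e6, 1e6)
  expect_true(all(diff(p) < 0))
  ys2 <- c(40, 25, 12, 4, 0)
  p2 <- audic_claverie_pvalue(x, ys2, 1e6, 1e6)
  expect_true(all(diff(p2) < 0))
  expect_true(all(c(p, p2) > 0 & c(p, p2) <= 1))
})

test_that("the tail matches the negative-binomial identity", {
  # p(k|x) is the NB(x+1, N1/(N1+N2)) mass, so the one-sided tails must
  # agree with pnbinom; this cross-checks the log-gamma summation
  for (case in list(c(5, 30, 1e6, 1e6), c(0, 7, 2e6, 1e6),
                    c(120, 80, 5e5, 7e5))) {
    x <- case[1]; y <- case[2]; N1 <- case[3]; N2 <- case[4]
    lower <- pnbinom(y, size = x + 1, prob = N1 / (N1 + N2))
    upper <- 1 - pnbinom(y - 1, size = x + 1, prob = N1 / (N1 + N2))
    expect_equal(audic_claverie_pvalue(x, y, N1, N2),
                 min(1, 2 * min(lower, upper)), tolerance = 1e-10)
  }
})

test_that("a single-miRNA comparison leaves the p-value unadjusted", {
  m <- matrix(c(5L, 30L), 1, 2, dimnames = list("m1", c("c", "t")))
  de <- differential_table(make_ct(m, c(1e6, 1e6)), "c", "t")
  expect_equal(de$p_adjusted, de$p)
})

test_that("BH adjustment equals the independent step-up oracle", {
  set.seed(21)
  for (i in 1:10) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
  m <- matrix(rpois(100, 30), 50, 2,
              dimnames = list(paste0("m", 1:50), c("c", "t")))
  de <- differential_table(make_ct(m, c(1e6, 1.2e6)), "c", "t")
  expect_equal(de$p_adjusted, bh_oracle(de$p), tolerance = 1e-12)
})

test_that("selection requires consistent strong fold change and one small p", {
  base <- data.frame(mirna = c("a", "b", "c", "d"),
                     log2fc = c(2, 0.9, 2, 2),
                     p = c(1e-5, 1e-5, 0.02, 1e-5),
                     stringsAsFactors = FALSE)
  rep2 <- base
  rep2$log2fc <- c(1.5, 2, 1.8, -2)   # d flips sign
  rep2$p <- c(1e-4, 1e-4, 0.02, 1e-4)
  sel <- apply_selection_criteria(base, rep2)
  expect_equal(sel$mirna, "a")        # b: weak rep1; c: p >= 0.01 twice; d: sign conflict
  expect_equal(attr(sel, "sign_conflicts"), "d")
  expect_equal(sel$direction, "up")
})

test_that("the read-count criterion uses raw counts in any of 4 samples", {
  r1 <- data.frame(mirna = c("a", "b"), log2fc = c(2, 2), p = c(1e-4, 1e-4),
                   count_control = c(3L, 2L), count_treated = c(12L, 9L))
  r2 <- data.frame(mirna = c("a", "b"), log2fc = c(2, 2), p = c(1e-4, 1e-4),
                   count_control = c(2L, 1L), count_treated = c(8L, 10L))
  sel <- apply_selection_criteria(r1, r2)
  expect_equal(sel$mirna, "a")  # b never exceeds 10 reads (strict)
})

test_that("selection is invariant to swapping replicate labels", {
  reps <- table1_replicates()
  s12 <- apply_selection_criteria(reps$rep1, reps$rep2)
  s21 <- apply_selection_criteria(reps$rep2, reps$rep1)
  expect_setequal(s12$mirna, s21$mirna)
  expect_equal(s12$direction[order(s12$mirna)],
               s21$direction[order(s21$mirna)])
})

test_that("clustering partitions by expression profile, invariant to order", {
  reps <- table1_replicates()
  dems <- apply_selection_criteria(reps$rep1, reps$rep2)
  cl <- cluster_dems(dems)
  expect_equal(unname(cl$cluster[dems$mirna] == 1L),
               dems$direction == "up")
  set.seed(3)
  shuffled <- dems[sample(nrow(dems)), ]
  cl2 <- cluster_dems(shuffled)
  expect_equal(cl2$cluster[names(cl$cluster)], cl$cluster)
  # identical profiles always share a cluster
  two <- matrix(c(1, 1, 5, 5), 2, 2, byrow = FALSE,
                dimnames = list(c("x", "y"), NULL))
  expect_equal(length(unique(cluster_dems(rbind(two, z = c(-4, -4)))$cluster[c("x", "y")])), 1)
  expect_warning(cluster_dems(two[1, , drop = FALSE]), "single cluster")
})
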