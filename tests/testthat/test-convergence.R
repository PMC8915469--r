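make_meta <- function(ids, family = "F01", tp = "T0", role = "puppy",
                      matrix = "rectal") {
  data.frame(sample_id = ids, family_id = family,
             subject_id = paste0(family, "-", ids), subject_role = role,
             matrix = matrix, time_point = tp, stringsAsFactors = FALSE)
}

dist_from <- function(vals, ids) {
  d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  d[lower.tri(d)] <- vals
  d <- d + t(d)
  d
}

test_that("heterogeneity is the mean pairwise distance within a cell", {
  d <- dist_from(0.4, c("a", "b"))
  het <- within_family_heterogeneity(d, make_meta(c("a", "b")))
  expect_equal(het$heterogeneity[het$time_point == "T0"], 0.4)

  d3 <- dist_from(c(0.2, 0.4, 0.6), c("a", "b", "c"))
  het3 <- within_family_heterogeneity(d3, make_meta(c("a", "b", "c")))
  expect_equal(het3$heterogeneity[het3$time_point == "T0"], 0.4)

  # a single sample leaves the cell undefined but counted
  one <- within_family_heterogeneity(dist_from(numeric(0), "a"),
                                     make_meta("a"))
  row <- one[one$time_point == "T0", ]
  expect_equal(row$n_samples, 1L)
  expect_true(is.na(row$heterogeneity))
})

test_that("identical patterns give zero heterogeneity, duplicates change nothing", {
  m <- matrix(rep(c(1L, 0L, 1L, 0L, 1L), 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), paste0("g", 1:5)))
  d <- phi_distance_matrix(m)
  het <- within_family_heterogeneity(d, make_meta(c("a", "b", "c")))
  expect_equal(het$heterogeneity[het$time_point == "T0"], 0)

  m2 <- rbind(m, d2 = m[1, ])
  d2 <- phi_distance_matrix(m2)
  het2 <- within_family_heterogeneity(d2, make_meta(rownames(m2)))
  expect_equal(het2$heterogeneity[het2$time_point == "T0"], 0)
})

test_that("matrix filters select the intended sample sets", {
  meta <- rbind(make_meta("r1"), make_meta("m1", matrix = "meconium"),
                make_meta("v1", role = "dam", matrix = "vaginal"))
  ids <- meta$sample_id
  d <- dist_from(c(0.2, 0.4, 0.6), ids)
  all_f <- within_family_heterogeneity(d, meta, matrix_filter = "all")
  expect_equal(all_f$n_samples[all_f$time_point == "T0"], 3L)
  rect <- within_family_heterogeneity(d, meta, matrix_filter = "rectal_only")
  expect_equal(rect$n_samples[rect$time_point == "T0"], 2L)   # rectal+meconium
  nodam <- within_family_heterogeneity(d, meta, include_dams = FALSE)
  expect_equal(nodam$n_samples[nodam$time_point == "T0"], 2L)
  expect_error(within_family_heterogeneity(d, meta, matrix_filter = "hair"),
               "unknown matrix type")
})

test_that("exact rank-sum reproduces enumerated references", {
  rs <- ranksum_exact(1:3, 4:6)
  expect_equal(rs$statistic_W, 6)
  expect_equal(rs$p_two_sided, 0.1)       # 2/20, all C(6,3) assignments
  expect_equal(rs$method, "exact_enumeration")

  expect_equal(ranksum_exact(c(2, 5, 9), c(9, 2, 5))$p_two_sided, 1)

  sep <- ranksum_exact(1:6, 7:12)
  expect_equal(sep$p_two_sided, 2 / 924)  # attainable minimum at 6 vs 6
  expect_error(ranksum_exact(numeric(0), 1), "non-empty")
})

test_that("exact rank-sum equals the independent enumeration oracle", {
  set.seed(303)
  for (i in 1:60) {
    na <- sample(1:5, 1); nb <- sample(1:5, 1)
    vals <- if (i %% 2 == 0) sample(1:4, na + nb, replace = TRUE) else
      rnorm(na + nb)
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    expect_equal(ranksum_exact(a, b)$p_two_sided, oracle_ranksum_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("the p-value is invariant under monotone transforms of the data", {
  set.seed(404)
  for (i in 1:20) {
    a <- runif(5); b <- runif(4)
    p0 <- ranksum_exact(a, b)$p_two_sided
    expect_equal(ranksum_exact(exp(3 * a), exp(3 * b))$p_two_sided, p0)
    expect_equal(ranksum_exact(rank(c(a, b))[1:5] * 10,
                               rank(c(a, b))[6:9] * 10)$p_two_sided, p0)
  }
})

test_that("large groups fall back to a tie-corrected normal approximation", {
  set.seed(505)
  a <- rnorm(9, 0.5); b <- rnorm(9)
  rs <- ranksum_exact(a, b, exact_limit = 100)   # C(18,9) >> 100
  expect_equal(rs$method, "normal_approx")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(rs$p_two_sided, ref$p.value, tolerance = 1e-8)
})

test_that("birth comparisons test each later time point against T0", {
  het <- data.frame(
    family_id = rep(sprintf("F%02d", 1:6), times = 2),
    time_point = rep(c("T0", "T60"), each = 6),
    n_samples = 5L,
    heterogeneity = c(seq(0.6, 0.7, length.out = 6),
                      seq(0.1, 0.2, length.out = 6)),
    stringsAsFactors = FALSE)
  out <- compare_to_birth(het, times = "T60")
  expect_equal(out$p, 2 / 924)            # full separation, 6 vs 6

  het$heterogeneity <- rep(seq(0.3, 0.4, length.out = 6), 2)
  expect_equal(compare_to_birth(het, times = "T60")$p, 1)

  het$heterogeneity[het$time_point == "T60"] <- NA
  nt <- compare_to_birth(het, times = "T60")
  expect_equal(nt$method, "not_testable")
  expect_true(is.na(nt$p))
})

test_that("Holm adjustment is available but off by default", {
  het <- data.frame(
    family_id = rep(sprintf("F%02d", 1:4), times = 4),
    time_point = rep(tp_levels_for_test <- c("T0", "T2", "T30", "T60"),
                     each = 4),
    n_samples = 5L,
    heterogeneity = runif(16), stringsAsFactors = FALSE)
  raw <- compare_to_birth(het)
  expect_false("p_holm" %in% names(raw))
  adj <- compare_to_birth(het, holm_adjust = TRUE)
  expect_equal(adj$p_holm, p.adjust(adj$p, "holm"))
})
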