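test_that("every printed solubility term maps to its group; others are unclassified", {
  insoluble <- c("insoluble", "almost insoluble", "low soluble",
                 "mostly insoluble", "non-soluble", "not soluble",
                 "poorly soluble")
  soluble <- c("soluble", "easily soluble", "completely soluble",
               "freely soluble", "highly soluble", "very soluble")
  expect_equal(as.character(classify_solubility(insoluble)),
               rep("insoluble", 7))
  expect_equal(as.character(classify_solubility(soluble)),
               rep("soluble", 6))
  # longest-phrase preference: "poorly soluble" must not match "soluble"
  expect_equal(as.character(classify_solubility("Poorly Soluble")),
               "insoluble")
  expect_equal(as.character(classify_solubility(c("slightly soluble",
                                                  "miscible", ""))),
               rep("unclassified", 3))
  # total: every string lands in exactly one of the three classes
  out <- classify_solubility(c(insoluble, soluble, "x", NA))
  expect_false(anyNA(out))
  expect_true(all(levels(out) == c("soluble", "insoluble", "unclassified")))
})

test_that("HIA dichotomizes fraction absorbed at 30% with the boundary absorbable", {
  expect_equal(as.character(classify_hia(c(85, 10, 30, 29.999))),
               c("HIA_plus", "HIA_minus", "HIA_plus", "HIA_minus"))
  expect_error(classify_hia(150), "\\[0, 100\\]")
  expect_error(classify_hia(NA_real_), "finite")
})

test_that("spearman handles perfect monotone data and midranked ties", {
  expect_equal(spearman(1:3, c(1, 4, 9))$rho, 1)
  expect_equal(spearman(1:3, c(3, 2, 1))$rho, -1)
  x <- c(1, 2, 2, 4, 5, 5, 5, 8, 9, 10)
  y <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9)
  s <- spearman(x, y)
  # frozen midrank Pearson-on-ranks oracle values
  expect_equal(s$rho, 0.9108770332, tolerance = 1e-9)
  expect_equal(s$p_value, 0.0002475803, tolerance = 1e-7)
  expect_equal(s$n, 10L)
  # symmetry and monotone-transform invariance
  s2 <- spearman(y, x)
  expect_equal(s2$rho, s$rho)
  s3 <- spearman(exp(x), y^3)
  expect_equal(s3$rho, s$rho)
  expect_equal(s3$p_value, s$p_value)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
  expect_error(spearman(1:2, 1:2), "3 complete pairs")
  # missing values are dropped pairwise
  expect_equal(spearman(c(1:4, NA), c(1, 4, 9, 16, 2))$n, 4L)
})

test_that("Welch t matches its hand-computed statistic and df", {
  a <- c(1.1, 2.3, 3.1, 4.8)
  b <- c(2.0, 4.1, 5.9, 7.7, 9.2)
  r <- two_group_test(a, b, kind = "t_test")
  expect_equal(r$test_name, "t_test_welch")
  expect_equal(r$statistic, -1.9798393196, tolerance = 1e-9)
  expect_equal(r$p_value, 0.0923994869, tolerance = 1e-9)
  expect_equal(r$group_means, c(mean(a), mean(b)))
  # Student's t under equal_var matches the pooled-variance oracle
  rs <- two_group_test(a, b, kind = "t_test", equal_var = TRUE)
  o <- oracle_student(a, b)
  expect_equal(rs$statistic, o$statistic, tolerance = 1e-10)
  expect_equal(rs$p_value, o$p_value, tolerance = 1e-10)
  expect_error(two_group_test(c(1, 1), c(1, 1)), "degenerate")
  expect_error(two_group_test(1, 1:5, kind = "t_test"), "at least 2")
})

test_that("Mann-Whitney on separated groups matches exhaustive enumeration", {
  a <- 1:4; b <- 11:14
  r <- two_group_test(a, b, kind = "wilcoxon")
  o <- oracle_mw_exact(a, b)
  expect_equal(r$statistic, 0)            # complete separation: U = 0
  expect_equal(o$p_value, 2 / choose(8, 4))
  expect_equal(r$p_value, o$p_value, tolerance = 1e-12)
})

test_that("identical samples give a no-difference result", {
  x <- c(1.5, 2.5, 3.5, 4.5, 5.5)
  r <- two_group_test(x, x, kind = "wilcoxon")
  expect_gt(r$p_value, 0.95)
  expect_equal(r$statistic, length(x)^2 / 2)  # U at its null mean
  rt <- two_group_test(x, x, kind = "t_test")
  expect_equal(rt$p_value, 1)
})

test_that("two-group tests are label-symmetric", {
  set.seed(11)
  a <- rnorm(20); b <- rnorm(25, 0.5)
  for (kind in c("t_test", "wilcoxon")) {
    r1 <- two_group_test(a, b, kind = kind)
    r2 <- two_group_test(b, a, kind = kind)
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12, info = kind)
  }
})

test_that("one-way ANOVA matches the hand-computed F and handles degeneracies", {
  g <- list(c(1, 2, 3), c(2, 3, 4, 5), c(6, 7, 8, 9, 10))
  r <- anova_oneway(g)
  expect_equal(r$statistic, 21.4411764706, tolerance = 1e-9)  # MSB/MSW by hand
  expect_equal(r$p_value, 0.0003771402, tolerance = 1e-7)
  expect_equal(r$group_ns, c(3L, 4L, 5L))
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  rs <- anova_oneway(same)
  expect_equal(rs$statistic, 0)
  expect_equal(rs$p_value, 1)
  expect_error(anova_oneway(list(1:3, 4:6)), "3 groups")
  expect_error(anova_oneway(list(1:3, 4:6, 7)), "at least 2")
})

test_that("NBE/property correlation joins on id and reports drops", {
  res <- data.frame(id = as.character(1:10), nbe = c(3, 1, 4, 1.5, 9, 2.6,
                                                     5.3, 5.8, 9.7, 9.3))
  props <- data.frame(id = as.character(1:10), mp = -res$nbe)
  cr <- correlate_nbe_with_property(res, props, "mp")
  expect_equal(cr$rho, -1)
  expect_equal(cr$n, 10L)
  # join keeps only the id intersection
  half <- props[1:5, ]
  cr2 <- correlate_nbe_with_property(res, half, "mp")
  expect_equal(cr2$n, 5L)
  expect_error(correlate_nbe_with_property(res, props[1:2, ], "mp"),
               "fewer than 3")
  expect_error(correlate_nbe_with_property(res, props, "nope"), "not found")
})

test_that("group comparison dispatches by level count", {
  set.seed(42)
  res <- data.frame(id = as.character(1:40), nbe = rnorm(40, 55, 5))
  p2 <- data.frame(id = res$id, grp = rep(c("x", "y"), 20))
  r2 <- compare_nbe_by_group(res, p2, "grp")
  expect_equal(r2$test_name, "t_test_welch")
  p4 <- data.frame(id = res$id, grp = rep(c("a", "b", "c", "d"), 10))
  r4 <- compare_nbe_by_group(res, p4, "grp")
  expect_equal(r4$test_name, "anova")
  expect_equal(r2$p_value,
               two_group_test(res$nbe[p2$grp == "x"],
                              res$nbe[p2$grp == "y"])$p_value)
  p1 <- data.frame(id = res$id, grp = "only")
  expect_error(compare_nbe_by_group(res, p1, "grp"), "fewer than 2")
})

test_that("property tables read with auto-detected separators and id column", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# properties", "id,mp,solubility",
               "drug1,120,freely soluble", "drug2,240,poorly soluble"), f)
  tab <- read_property_table(f)
  expect_equal(tab$id, c("drug1", "drug2"))
  expect_equal(as.character(classify_solubility(tab$solubility)),
               c("soluble", "insoluble"))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tfa", "d1\t85", "d2\t10"), f2)
  tab2 <- read_property_table(f2)
  expect_equal(as.character(classify_hia(tab2$fa)), c("HIA_plus", "HIA_minus"))
  bad <- withr::local_tempfile()
  writeLines(c("name,mp", "a,1"), bad)
  expect_error(read_property_table(bad), "id")
})
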