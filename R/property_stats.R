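# Property classification rules and the statistics relating NBE to
# molecular property data: Spearman correlation, Welch/Student t,
# Wilcoxon rank-sum (Mann-Whitney), one-way ANOVA.

.insoluble_terms <- c("insoluble", "almost insoluble", "low soluble",
                      "mostly insoluble", "non-soluble", "not soluble",
                      "poorly soluble")
.soluble_terms <- c("soluble", "easily soluble", "completely soluble",
                    "freely soluble", "highly soluble", "very soluble")

#' Classify a water-solubility description
#'
#' Maps free-text solubility terms to `soluble` / `insoluble` /
#' `unclassified` using the two fixed term lists common in curated drug
#' property records. Matching is case-insensitive and against the whole
#' (whitespace-normalized) term, so "poorly soluble" is classified insoluble
#' rather than being misread through its "soluble" substring, and terms on
#' neither list (e.g. "slightly soluble") are `unclassified`.
#'
#' @param term character vector of solubility descriptions.
#' @return Factor with levels `soluble`, `insoluble`, `unclassified`.
#' @examples
#' classify_solubility(c("freely soluble", "poorly soluble", "slightly soluble"))
#' @export
classify_solubility <- function(term) {
  stopifnot(is.character(term) | is.factor(term))
  term <- as.character(term)
  phrases <- c(.insoluble_terms, .soluble_terms)
  labels <- rep(c("insoluble", "soluble"),
                c(length(.insoluble_terms), length(.soluble_terms)))
  # match the whole term, longest phrase checked first, so a qualified
  # term ("poorly soluble") can never fall through to its substring
  ord <- order(-nchar(phrases))
  phrases <- phrases[ord]; labels <- labels[ord]
  norm <- gsub("\\s+", " ", tolower(trimws(term)))
  hit <- match(norm, phrases)
  out <- ifelse(is.na(hit), "unclassified", labels[hit])
  factor(out, levels = c("soluble", "insoluble", "unclassified"))
}

#' Dichotomize human intestinal absorption at 30% FA
#'
#' Fraction absorbed (FA%) at or above 30% is classified absorbable
#' (`HIA_plus`), below 30% nonabsorbable (`HIA_minus`). The boundary value
#' 30 is assigned to `HIA_plus`.
#'
#' @param fa_percent numeric vector of FA% values in \[0, 100\].
#' @return Factor with levels `HIA_plus`, `HIA_minus`.
#' @examples
#' classify_hia(c(85, 10, 30))
#' @export
classify_hia <- function(fa_percent) {
  if (!is.numeric(fa_percent) || any(!is.finite(fa_percent)) ||
      any(fa_percent < 0 | fa_percent > 100)) {
    stop("fa_percent must be finite values in [0, 100]", call. = FALSE)
  }
  factor(ifelse(fa_percent >= 30, "HIA_plus", "HIA_minus"),
         levels = c("HIA_plus", "HIA_minus"))
}

#' Spearman rank correlation
#'
#' Rho is the Pearson correlation of midranks (average ranks under ties);
#' the two-sided p-value uses the asymptotic t approximation on
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`. Incomplete pairs are dropped.
#'
#' @param x,y numeric vectors of equal length; at least 3 complete pairs.
#' @return A `correlation_result`: list with `rho`, `p_value`, `n`.
#' @export
spearman <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE,
                                         alternative = "two.sided"))
  structure(list(rho = unname(ct$estimate), p_value = ct$p.value, n = n),
            class = "correlation_result")
}

#' Two-group location test
#'
#' `t_test` is Welch's unequal-variance t by default (`equal_var = TRUE`
#' gives Student's t). `wilcoxon` is the two-sample Mann-Whitney rank-sum
#' on midranks: the p-value is exact (enumeration over rank assignments)
#' when the combined sample size is at most 20 and there are no ties,
#' otherwise a normal approximation with continuity and tie correction.
#' All tests are two-sided.
#'
#' @param a,b numeric vectors, the two groups.
#' @param kind `"t_test"` or `"wilcoxon"`.
#' @param equal_var t-test only: assume equal variances (Student) instead of
#'   Welch.
#' @param labels length-2 character: group names for reporting.
#' @return A `group_comparison`: list with `test_name`, `group_labels`,
#'   `group_ns`, `group_means`, `statistic`, `p_value`.
#' @export
two_group_test <- function(a, b, kind = c("t_test", "wilcoxon"),
                           equal_var = FALSE, labels = c("a", "b")) {
  kind <- match.arg(kind)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (kind == "t_test") {
    if (length(a) < 2L || length(b) < 2L) {
      stop("t-test needs at least 2 observations per group", call. = FALSE)
    }
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      stop("degenerate input: zero variance in both groups", call. = FALSE)
    }
    ht <- stats::t.test(a, b, var.equal = equal_var)
    test_name <- if (equal_var) "t_test" else "t_test_welch"
  } else {
    if (length(a) < 1L || length(b) < 1L || length(a) + length(b) < 4L) {
      stop("wilcoxon needs both groups nonempty and combined n >= 4",
           call. = FALSE)
    }
    ties <- anyDuplicated(c(a, b)) > 0L
    exact <- !ties && (length(a) + length(b)) <= 20L
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = TRUE))
    test_name <- "wilcoxon"
  }
  structure(list(test_name = test_name,
                 group_labels = labels,
                 group_ns = c(length(a), length(b)),
                 group_means = c(mean(a), mean(b)),
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value),
            class = "group_comparison")
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test) across
#' three or more groups. For two groups use [two_group_test()].
#'
#' @param groups list of 3+ numeric vectors, each with at least 2
#'   observations; names are used as group labels.
#' @return A `group_comparison` with `test_name = "anova"`; `statistic` is
#'   the F ratio.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups))
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (length(groups) < 3L) {
    stop("one-way ANOVA needs at least 3 groups; use two_group_test()",
         call. = FALSE)
  }
  if (any(lengths(groups) < 2L)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  labels <- names(groups) %||% as.character(seq_along(groups))
  if (is.null(names(groups))) names(groups) <- labels
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labels, lengths(groups)), levels = labels)
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  structure(list(test_name = "anova",
                 group_labels = labels,
                 group_ns = unname(lengths(groups)),
                 group_means = unname(vapply(groups, mean, 0)),
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value),
            class = "group_comparison")
}

#' Read a molecular property table
#'
#' Delimited text (comma or tab, auto-detected from the header) with an
#' `id` column followed by property columns; `#` comment lines ignored.
#'
#' @param path file path.
#' @return A data frame with a character `id` column.
#' @export
read_property_table <- function(path) {
  if (!file.exists(path)) stop("property table not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2L) stop("property table has no data rows", call. = FALSE)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  tab <- utils::read.table(text = lines, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  if (!"id" %in% names(tab)) {
    stop("property table must have an `id` column", call. = FALSE)
  }
  tab$id <- as.character(tab$id)
  tab
}

#' Correlate NBE scores with a numeric property
#'
#' Joins an NBE result table to a property table on `id`, drops incomplete
#' pairs (count reported via the `n_dropped` attribute) and computes the
#' Spearman rank correlation.
#'
#' @param results data frame from [batch_compute()] (columns `id`, `nbe`).
#' @param properties data frame with an `id` column, e.g. from
#'   [read_property_table()].
#' @param property_name name of the numeric property column.
#' @return A `correlation_result` (see [spearman()]) with attribute
#'   `n_dropped`, the number of joined rows lost to missing values.
#' @export
correlate_nbe_with_property <- function(results, properties, property_name) {
  stopifnot(is.data.frame(results), is.data.frame(properties))
  if (!property_name %in% names(properties)) {
    stop("property column not found: ", property_name, call. = FALSE)
  }
  merged <- merge(results[, c("id", "nbe")],
                  properties[, c("id", property_name)], by = "id")
  prop <- suppressWarnings(as.numeric(merged[[property_name]]))
  ok <- is.finite(merged$nbe) & is.finite(prop)
  if (sum(ok) < 3L) {
    stop("fewer than 3 complete NBE/property pairs after join", call. = FALSE)
  }
  out <- spearman(merged$nbe[ok], prop[ok])
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Compare NBE scores between property-defined groups
#'
#' Joins NBE results to a grouping column and runs the appropriate test:
#' with `test = "auto"`, a two-level grouping uses Welch's t and three or
#' more levels one-way ANOVA.
#'
#' @inheritParams correlate_nbe_with_property
#' @param group_col name of the grouping column in `properties`.
#' @param test `"auto"`, `"t"`, `"wilcoxon"`, or `"anova"`.
#' @return A `group_comparison`.
#' @export
compare_nbe_by_group <- function(results, properties, group_col,
                                 test = c("auto", "t", "wilcoxon", "anova")) {
  test <- match.arg(test)
  stopifnot(is.data.frame(results), is.data.frame(properties))
  if (!group_col %in% names(properties)) {
    stop("grouping column not found: ", group_col, call. = FALSE)
  }
  merged <- merge(results[, c("id", "nbe")],
                  properties[, c("id", group_col)], by = "id")
  merged <- merged[is.finite(merged$nbe) & !is.na(merged[[group_col]]) &
                     nzchar(as.character(merged[[group_col]])), ]
  groups <- split(merged$nbe, as.character(merged[[group_col]]))
  if (length(groups) < 2L) {
    stop("grouping column has fewer than 2 levels after join", call. = FALSE)
  }
  if (test == "auto") test <- if (length(groups) >= 3L) "anova" else "t"
  if (test == "anova") return(anova_oneway(groups))
  if (length(groups) != 2L) {
    stop("two-group test requested but grouping has ", length(groups),
         " levels", call. = FALSE)
  }
  two_group_test(groups[[1L]], groups[[2L]],
                 kind = if (test == "t") "t_test" else "wilcoxon",
                 labels = names(groups))
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: rho = %.4f, p-value = %.4g, n = %d\n",
              x$rho, x$p_value, x$n))
  invisible(x)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p-value = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  for (i in seq_along(x$group_labels)) {
    cat(sprintf("  %s: n = %d, mean = %.4f\n",
                x$group_labels[i], x$group_ns[i], x$group_means[i]))
  }
  invisible(x)
}
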