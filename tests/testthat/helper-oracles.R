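# Independent oracles for the test suite. These deliberately share no code
# with the package: bond energies are frozen here by hand, NBE sums are
# plain arithmetic over committed multisets, and every statistic is written
# out from its textbook formula (or brute-force enumeration).

# -- bond energies used by the fixture molecules, frozen by hand ----------
# (C, H, N, O bonds of the standard average-bond-enthalpy reference)
oracle_energies <- c(
  "C|H|1" = 413, "H|H|1" = 436,
  "C|C|1" = 347, "C|C|2" = 614, "C|C|3" = 839,
  "C|O|1" = 358, "C|O|2" = 745, "H|O|1" = 467,
  "C|N|1" = 305, "C|N|2" = 615, "H|N|1" = 391
)

# canonical "A|B|order" key with the element pair sorted
oracle_bond_key <- function(a, b, order) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  paste(a, b, order, sep = "|")
}

# NBE from a committed bond multiset (columns element_a, element_b, order,
# count) and a hand-computed molecular weight: plain arithmetic.
oracle_nbe <- function(bond_counts, mw) {
  if (nrow(bond_counts) == 0L) return(0)
  key <- oracle_bond_key(bond_counts$element_a, bond_counts$element_b,
                         bond_counts$order)
  e <- oracle_energies[key]
  stopifnot(!anyNA(e))
  sum(bond_counts$count * e) / mw
}

# sorted canonical multiset of a bonds data frame, for set comparisons
canon_multiset <- function(bonds) {
  if (nrow(bonds) == 0L) return(character(0))
  sort(oracle_bond_key(bonds$element_a, bonds$element_b, bonds$order))
}

# expand a counted multiset into one row per bond
expand_counts <- function(bond_counts) {
  bond_counts[rep(seq_len(nrow(bond_counts)), bond_counts$count),
              c("element_a", "element_b", "order")]
}

# -- statistics oracles ---------------------------------------------------

oracle_spearman <- function(x, y) {
  n <- length(x)
  r <- stats::cor(rank(x), rank(y))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(rho = r, p_value = 2 * stats::pt(-abs(t), n - 2))
}

oracle_welch <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(statistic = t, p_value = 2 * stats::pt(-abs(t), df))
}

oracle_student <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = t, p_value = 2 * stats::pt(-abs(t), n1 + n2 - 2))
}

# Mann-Whitney rank-sum statistic (U for the first sample)
oracle_mw_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

# exact two-sided p by enumerating all C(n1+n2, n1) rank assignments
# (requires untied data)
oracle_mw_exact <- function(a, b) {
  n1 <- length(a); N <- n1 + length(b)
  w <- oracle_mw_statistic(a, b)
  sets <- utils::combn(N, n1)
  ws <- colSums(matrix(seq_len(N)[sets], nrow = n1)) - n1 * (n1 + 1) / 2
  p <- 2 * min(mean(ws <= w), mean(ws >= w))
  list(statistic = w, p_value = min(1, p))
}

# normal approximation with continuity correction and tie correction
oracle_mw_normal <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- w - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  list(statistic = w,
       p_value = 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
}

# dispatch matching the documented contract of two_group_test(wilcoxon)
oracle_mannwhitney <- function(a, b) {
  if (anyDuplicated(c(a, b)) == 0L && length(a) + length(b) <= 20L) {
    oracle_mw_exact(a, b)
  } else {
    oracle_mw_normal(a, b)
  }
}

oracle_anova <- function(groups) {
  k <- length(groups); N <- sum(lengths(groups))
  gm <- mean(unlist(groups))
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 0) - gm)^2)
  ssw <- sum(vapply(groups, function(g) (length(g) - 1) * stats::var(g), 0))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(statistic = f,
       p_value = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
}

# -- misc -----------------------------------------------------------------

# quiet wrappers: OpenBabel chatter and skip warnings are not under test
# unless a test asserts them
quiet_parse_smiles <- function(...) suppressWarnings(parse_smiles(...))
quiet_parse_sdf <- function(...) suppressWarnings(parse_sdf(...))

run_cli <- function(args, ...) {
  script <- system.file("cli", "nbe.R", package = "nbescore")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(
    system2(rscript, c(shQuote(script), args), stdout = TRUE, stderr = TRUE,
            env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep)),
            ...))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
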