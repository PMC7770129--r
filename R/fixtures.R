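# Hand-verified fixture molecules and a generator for synthetic property
# data with controlled rank correlation and group separation.

#' Fixture molecule set
#'
#' Thirteen molecules spanning the edge cases of the metric (a bond-free
#' atom, H2, the two-carbon series, alcohols, aromatics, fused heterocycles
#' and four common drugs), each committed with a hand-enumerated bond
#' multiset and hand-computed molecular weight. These committed values are
#' data, independent of the parsing code, so parser regressions are caught
#' against frozen truth.
#'
#' @return A named list of fixtures; each element has `name`, `smiles`,
#'   `bonds` (data frame `element_a`, `element_b`, `order`, `count`),
#'   `mw`, and `nbe_expected` (the committed multiset priced with the
#'   default bond table: `sum(count * energy) / mw`).
#' @export
fixture_set <- function() {
  # full-line comments only: '#' inside a SMILES field is a triple bond
  read_fixture_csv <- function(f) {
    path <- system.file("extdata", f, package = "nbescore", mustWork = TRUE)
    lines <- readLines(path, warn = FALSE)
    utils::read.csv(text = lines[!grepl("^\\s*#", lines)],
                    comment.char = "", stringsAsFactors = FALSE)
  }
  mols <- read_fixture_csv("fixture_molecules.csv")
  bonds <- read_fixture_csv("fixture_bonds.csv")
  tab <- default_bond_table()
  out <- lapply(seq_len(nrow(mols)), function(i) {
    b <- bonds[bonds$name == mols$name[i],
               c("element_a", "element_b", "order", "count")]
    rownames(b) <- NULL
    energies <- if (nrow(b)) {
      lookup_energy(tab, b$element_a, b$element_b, b$order)
    } else numeric(0)
    if (anyNA(energies)) {
      stop("fixture '", mols$name[i], "' uses a bond absent from the ",
           "default table", call. = FALSE)
    }
    list(name = mols$name[i], smiles = mols$smiles[i],
         formula = mols$formula[i], bonds = b, mw = mols$expected_mw[i],
         nbe_expected = sum(b$count * energies) / mols$expected_mw[i])
  })
  names(out) <- mols$name
  out
}

#' Generate synthetic property data tied to an NBE vector
#'
#' Produces, deterministically for a given seed, (a) a numeric property
#' whose population Spearman correlation with the supplied NBE vector is
#' `rank_correlation_target`, and (b) binary group labels with a
#' `group_shift` mean difference in an accompanying numeric variable.
#'
#' The property is built through a Gaussian copula: the NBE values are
#' mapped to normal scores `z = qnorm((rank - 0.5) / n)` and the property
#' drawn as `r * z + sqrt(1 - r^2) * noise` with
#' `r = 2 * sin(pi * rank_correlation_target / 6)`, the Gaussian
#' correlation whose bivariate-normal Spearman correlation is exactly the
#' target (`rho_S = (6 / pi) * asin(r / 2)`). This closed form is what makes
#' the generator testable against an analytic oracle.
#'
#' @param nbe numeric vector of NBE scores (length at least 10); names, if
#'   present, are used as molecule ids.
#' @param rank_correlation_target target Spearman correlation in \[-1, 1\].
#' @param group_shift mean difference between groups `b` and `a` in the
#'   `group_value` column.
#' @param seed integer random seed; required for reproducibility.
#' @return A data frame with columns `id`, `property`, `group` (factor
#'   `a`/`b`, balanced assignment), `group_value` (standard normal within
#'   group `a`, shifted by `group_shift` in group `b`).
#' @export
generate_property_data <- function(nbe, rank_correlation_target = 0,
                                   group_shift = 0, seed) {
  stopifnot(is.numeric(nbe), all(is.finite(nbe)))
  n <- length(nbe)
  if (n < 10L) stop("need at least 10 NBE values", call. = FALSE)
  if (!is.finite(rank_correlation_target) ||
      abs(rank_correlation_target) > 1) {
    stop("rank_correlation_target must be in [-1, 1]", call. = FALSE)
  }
  if (!is.finite(group_shift)) stop("group_shift must be finite", call. = FALSE)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  r <- 2 * sin(pi * rank_correlation_target / 6)
  z <- stats::qnorm((rank(nbe, ties.method = "average") - 0.5) / n)
  noise_scale <- sqrt(max(0, 1 - r^2))
  property <- r * z + noise_scale * stats::rnorm(n)
  group <- factor(sample(rep_len(c("a", "b"), n)), levels = c("a", "b"))
  group_value <- stats::rnorm(n) + ifelse(group == "b", group_shift, 0)
  ids <- names(nbe) %||% as.character(seq_len(n))
  data.frame(id = ids, property = property, group = group,
             group_value = group_value, stringsAsFactors = FALSE)
}
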