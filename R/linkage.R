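#' Tally two-locus genotype classes
#'
#' Counts offspring of the informative backcross into the four two-locus
#' classes formed by transgene carrier status (`Cre+`/`Cre-`) and the floxed
#' locus genotype (`F/F`/`F/W`).
#'
#' @param cre character vector, `"Cre+"` or `"Cre-"` per offspring.
#' @param flox character vector, `"F/F"` or `"F/W"` per offspring.
#' @return named integer vector over the four classes
#'   (`Cre+;F/F`, `Cre+;F/W`, `Cre-;F/F`, `Cre-;F/W`).
#' @export
tallyGenotypes <- function(cre, flox) {
  classes <- genotypeClasses()
  if (length(cre) != length(flox)) stop("cre and flox must have equal length")
  lab <- paste0(cre, ";", flox)
  bad <- setdiff(unique(lab), classes)
  if (length(cre) && length(bad))
    stop("unknown genotype class label(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(lab, levels = classes))
  setNames(as.integer(counts), classes)
}

genotypeClasses <- function() c("Cre+;F/F", "Cre+;F/W", "Cre-;F/F", "Cre-;F/W")

#' Observed genotype-class percentages
#'
#' @param counts named counts over the four genotype classes.
#' @param nTotal denominator; defaults to `sum(counts)` but can be
#'   overridden when the reported litter size differs from the class sum.
#' @param digits rounding for display (1 decimal, the reporting convention).
#' @return named numeric percentages.
#' @export
genotypePercentages <- function(counts, nTotal = sum(counts), digits = 1) {
  if (nTotal <= 0) stop("nTotal must be positive")
  round(100 * counts / nTotal, digits)
}

#' Recombination frequency from genotype counts
#'
#' `theta = (sum of recombinant-class counts) / nTotal`. In the informative
#' backcross the parental classes are `Cre+;F/W` and `Cre-;F/F`; the two
#' recombinant classes are designated explicitly.
#'
#' @inheritParams genotypePercentages
#' @param recombinant labels of the recombinant classes.
#' @return theta (raw; display rounding is left to the caller).
#' @export
estimateTheta <- function(counts,
                          recombinant = c("Cre+;F/F", "Cre-;F/W"),
                          nTotal = sum(counts)) {
  if (nTotal == 0) stop("nTotal is zero; theta undefined")
  if (!all(recombinant %in% names(counts)))
    stop("recombinant class labels not present in counts")
  sum(counts[recombinant]) / nTotal
}

#' Genetic distance in centimorgans
#'
#' At the short distances of a two-point cross the map distance is taken as
#' directly proportional to the recombination frequency: `cM = 100 * theta`
#' (no mapping function).
#'
#' @param theta recombination frequency in `[0, 0.5]`.
#' @return distance in cM.
#' @export
geneticDistance <- function(theta) {
  if (any(theta < 0) || any(theta > 0.5))
    stop("theta must lie in [0, 0.5]")
  100 * theta
}

#' LOD score, literal published-table form
#'
#' Evaluates `Z = log10[ ((1-theta)^n) / ((1/2)^n) ] = n * log10(2*(1-theta))`
#' — the literal form printed in the source linkage table, in which the
#' recombinant term carries exponent zero and therefore drops out. See
#' [lodStandard()] for the textbook two-point statistic; the two differ
#' whenever recombinants were observed.
#'
#' @param theta recombination frequency (`0 <= theta < 1`).
#' @param n number of informative offspring.
#' @return LOD score Z.
#' @export
lodTable <- function(theta, n) {
  if (any(theta < 0) || any(theta >= 1))
    stop("theta must lie in [0, 1)")
  if (any(n < 1)) stop("n must be >= 1")
  n * log10((1 - theta) / 0.5)
}

#' LOD score, standard two-point form
#'
#' `Z = log10[ theta^R * (1-theta)^NR / 0.5^(R+NR) ]` for `R` recombinant and
#' `NR` non-recombinant offspring. Evaluated at `theta = R/(R+NR)` this is
#' the maximum-likelihood LOD. The `R = 0`, `theta = 0` limit is handled
#' exactly (`Z = NR * log10 2`).
#'
#' @param R,NR recombinant and non-recombinant counts (>= 0).
#' @param theta evaluation point; defaults to the MLE `R/(R+NR)`.
#' @return LOD score Z.
#' @export
lodStandard <- function(R, NR, theta = R / (R + NR)) {
  if (R < 0 || NR < 0) stop("counts must be non-negative")
  if (theta < 0 || theta >= 1) stop("theta must lie in [0, 1)")
  if (theta == 0) {
    if (R > 0) stop("theta = 0 with recombinants observed gives LOD = -Inf")
    return(NR * log10(2))
  }
  R * log10(theta) + NR * log10(1 - theta) - (R + NR) * log10(0.5)
}

#' Classify linkage evidence
#'
#' @param lod finite LOD score.
#' @return `"definitive"` when `lod >= 3` (the classical definitive-linkage
#'   threshold), else `"not_definitive"`.
#' @export
classifyLinkage <- function(lod) {
  if (any(!is.finite(lod))) stop("lod must be finite")
  ifelse(lod >= 3, "definitive", "not_definitive")
}

#' Mendelian expectation and goodness of fit
#'
#' Under independent assortment each of the four two-locus backcross classes
#' is expected at 25%. Reports the expected percentages and a descriptive
#' Pearson chi-square against them (3 df); the linkage inference itself is
#' carried by the LOD score.
#'
#' @inheritParams genotypePercentages
#' @return list with `expected_pct` (25 each), `observed_pct`, `chisq`,
#'   `df`, and `p_value`.
#' @export
mendelianExpectation <- function(counts, nTotal = sum(counts)) {
  if (length(counts) != 4) stop("expected the 4 two-locus genotype classes")
  if (nTotal == 0) stop("nTotal is zero")
  e <- nTotal / 4
  chisq <- sum((counts - e)^2 / e)
  list(expected_pct = setNames(rep(25, 4), names(counts)),
       observed_pct = genotypePercentages(counts, nTotal),
       chisq = chisq, df = 3L,
       p_value = stats::pchisq(chisq, df = 3, lower.tail = FALSE))
}

#' Two-point linkage summary table
#'
#' Reproduces the layout of a two-point linkage report: class counts and
#' percentages, recombination frequency, genetic distance, LOD score
#' (published-table form by default, standard form available), and the
#' linkage classification. Display rounding follows the reporting
#' convention (theta 3 decimals, cM and LOD 1 decimal); raw values are kept
#' alongside.
#'
#' @inheritParams estimateTheta
#' @param formula `"table"` (the literal published-table formula) or
#'   `"standard"` (textbook two-point LOD).
#' @return list with the rounded display values (`theta`, `cm`, `lod`,
#'   `classification`, `observed_pct`, `expected_pct`) and a `raw` list of
#'   unrounded values, including both LOD variants.
#' @export
linkageReport <- function(counts,
                          recombinant = c("Cre+;F/F", "Cre-;F/W"),
                          nTotal = sum(counts),
                          formula = c("table", "standard")) {
  formula <- match.arg(formula)
  theta <- estimateTheta(counts, recombinant, nTotal)
  cm <- geneticDistance(theta)
  R <- sum(counts[recombinant])
  NR <- nTotal - R
  zPaper <- lodTable(theta, nTotal)
  zStd <- lodStandard(R, NR, if (R > 0) theta else 0)
  z <- if (formula == "table") zPaper else zStd
  mend <- mendelianExpectation(counts, nTotal)
  list(theta = round(theta, 3), cm = round(cm, 1), lod = round(z, 1),
       formula = formula,
       classification = classifyLinkage(z),
       n = nTotal,
       observed_pct = mend$observed_pct,
       expected_pct = mend$expected_pct,
       raw = list(theta = theta, cm = cm, lod_table = zPaper,
                  lod_standard = zStd, chisq = mend$chisq,
                  recombinants = R, non_recombinants = NR))
}

#' Simulate backcross offspring genotypes
#'
#' Draws offspring from the informative backcross: each offspring is
#' recombinant with probability `theta` and assigned to one of the two
#' recombinant (or parental) classes with equal probability.
#'
#' @param n offspring count.
#' @param theta true recombination frequency.
#' @param seed optional RNG seed.
#' @return named counts over the four genotype classes.
#' @export
simulateBackcross <- function(n, theta, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  recomb <- runif(n) < theta
  half <- runif(n) < 0.5
  cre <- ifelse(recomb == half, "Cre+", "Cre-")
  flox <- ifelse(half, "F/F", "F/W")
  ## parental classes: Cre+;F/W and Cre-;F/F; recombination swaps Cre status
  tallyGenotypes(cre, flox)
}
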