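#' Amplification base from assay efficiency
#'
#' Converts a percent amplification efficiency into the per-cycle
#' amplification base: `E = 1 + efficiency/100` (100% efficiency doubles the
#' template each cycle, `E = 2`). Assays are expected to be optimized into
#' the 50-110% range.
#'
#' @param efficiencyPct amplification efficiency in percent.
#' @return amplification base E.
#' @export
amplificationBase <- function(efficiencyPct) {
  if (any(efficiencyPct < 50) || any(efficiencyPct > 110))
    stop("efficiency must lie in [50, 110] percent")
  1 + efficiencyPct / 100
}

#' Efficiency-corrected relative expression ratio
#'
#' The ratio of target expression in case versus control, normalized to a
#' reference gene, with per-assay amplification bases (the
#' efficiency-corrected ratio form):
#' `ratio = Et^(Cq_t,control - Cq_t,case) / Er^(Cq_r,control - Cq_r,case)`.
#' With both bases equal to 2 this reduces exactly to `2^-ddCq`.
#'
#' @param cqTargetControl,cqTargetCase mean target Cq in control and case.
#' @param cqRefControl,cqRefCase mean reference-gene Cq in control and case.
#' @param eTarget,eRef amplification bases (from [amplificationBase()];
#'   default 2, i.e. 100% efficiency).
#' @return fold-change ratio (> 0).
#' @export
relativeRatio <- function(cqTargetControl, cqTargetCase,
                          cqRefControl, cqRefCase,
                          eTarget = 2, eRef = 2) {
  args <- c(cqTargetControl, cqTargetCase, cqRefControl, cqRefCase)
  if (any(is.na(args))) stop("all four Cq means are required")
  if (any(args <= 0) || any(args >= 45))
    stop("Cq values must lie inside the run's cycle range (0, 45)")
  eTarget^(cqTargetControl - cqTargetCase) / eRef^(cqRefControl - cqRefCase)
}

#' Per-target relative expression from a Cq table
#'
#' Technical replicates are averaged on the Cq scale per sample and target;
#' each case sample's ratio is computed against the control-group mean Cq
#' (target and reference), and biological replicates are summarized by the
#' geometric mean of per-sample ratios.
#'
#' @param cq data.frame with columns `sample_id`, `group` (`case`/`control`),
#'   `target`, `cq`, and optionally `efficiency_pct` (per target; default
#'   100).
#' @param reference reference gene id (must be measured in every sample).
#' @return data.frame per target: `target`, `ratio` (case vs control
#'   fold-change), `n_case`, `n_control`; per-sample ratios in attribute
#'   `per_sample`.
#' @export
relativeExpression <- function(cq, reference = "Tbp") {
  need <- c("sample_id", "group", "target", "cq")
  if (!all(need %in% names(cq))) stop("cq table needs columns: ",
                                      paste(need, collapse = ", "))
  if (!reference %in% cq$target) stop("reference gene '", reference,
                                      "' missing from Cq table")
  if (is.null(cq$efficiency_pct)) cq$efficiency_pct <- 100
  eff <- tapply(cq$efficiency_pct, cq$target, function(x) unique(x)[1])
  E <- amplificationBase(as.numeric(eff))
  names(E) <- names(eff)
  ## technical replicates -> one Cq per sample x target
  m <- aggregate(cq ~ sample_id + group + target, data = cq, FUN = mean)
  refRows <- m[m$target == reference, ]
  if (!all(unique(m$sample_id) %in% refRows$sample_id))
    stop("reference Cq missing for some sample(s)")
  refCtrl <- mean(refRows$cq[refRows$group == "control"])
  targets <- setdiff(unique(m$target), reference)
  perSample <- list()
  rows <- lapply(targets, function(tg) {
    tr <- m[m$target == tg, ]
    ctrlMean <- mean(tr$cq[tr$group == "control"])
    refBySample <- setNames(refRows$cq, refRows$sample_id)
    ratios <- E[[tg]]^(ctrlMean - tr$cq) /
      E[[reference]]^(refCtrl - refBySample[tr$sample_id])
    perSample[[tg]] <<- data.frame(sample_id = tr$sample_id, group = tr$group,
                                   target = tg, ratio = as.numeric(ratios))
    caseR <- ratios[tr$group == "case"]
    data.frame(target = tg,
               ratio = exp(mean(log(caseR))),
               n_case = sum(tr$group == "case"),
               n_control = sum(tr$group == "control"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "per_sample") <- do.call(rbind, perSample)
  out
}
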