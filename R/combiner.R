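# Joint rule-based + machine-learning score:
#   f_joint = ACMG_score + r * (ISV_probability - 0.50)
# The ML probability is always consumed, never computed here; subtracting
# 0.5 centres it so benign predictions pull the score down and pathogenic
# ones push it up, by at most r/2 either way, preserving the ACMG ranges.

#' Combine an ACMG score with an ML pathogenicity probability
#'
#' @param acmg_score Numeric vector of rule-based scores.
#' @param isv_probability Probabilities in \[0, 1\] (recycled against
#'   `acmg_score` if scalar).
#' @param isv_ratio Non-negative weight `r` of the ML term (default 1).
#' @param thresholds Classification thresholds, as from [acmg_thresholds()].
#' @return A data frame of class `combined_scores` with columns `acmg_score`,
#'   `isv_probability`, `isv_ratio`, `joint_score`, `classification`.
#' @examples
#' combine_scores(0.90, 0.99, isv_ratio = 0.19)  # joint score 0.9931 -> P
#' @export
combine_scores <- function(acmg_score, isv_probability, isv_ratio = 1,
                           thresholds = acmg_thresholds()) {
  if (!is.numeric(isv_probability) ||
      any(isv_probability < 0 | isv_probability > 1, na.rm = FALSE) ||
      any(!is.finite(isv_probability))) {
    stop("isv_probability must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(isv_ratio) || length(isv_ratio) != 1L || !is.finite(isv_ratio) ||
      isv_ratio < 0) {
    stop("isv_ratio must be a single non-negative number", call. = FALSE)
  }
  n <- max(length(acmg_score), length(isv_probability))
  acmg_score <- rep_len(acmg_score, n)
  isv_probability <- rep_len(isv_probability, n)
  joint <- acmg_score + isv_ratio * (isv_probability - 0.50)
  out <- data.frame(
    acmg_score = acmg_score, isv_probability = isv_probability,
    isv_ratio = isv_ratio, joint_score = joint,
    classification = classify_score(joint, thresholds),
    stringsAsFactors = FALSE
  )
  class(out) <- c("combined_scores", "data.frame")
  out
}

#' @export
print.combined_scores <- function(x, ...) {
  cat(sprintf("combined scores (r = %g)\n", x$isv_ratio[1]))
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Largest possible ML contribution to the joint score
#'
#' With the probability centred at 0.5, the ML term can move the final score
#' by at most `r * 0.5` in either direction.
#'
#' @param isv_ratio Non-negative ratio `r`.
#' @return `r * 0.5`.
#' @export
max_isv_contribution <- function(isv_ratio) {
  if (any(isv_ratio < 0)) stop("isv_ratio must be non-negative", call. = FALSE)
  isv_ratio * 0.5
}

#' Undecidable ACMG-score band at a given ratio
#'
#' Scans ACMG scores on a centred grid and returns the largest contiguous
#' symmetric band within which no probability in \[0, 1\] can move the joint
#' score into the Pathogenic or Benign range. Because the joint score is
#' monotone in the probability, only the endpoints p = 0 and p = 1 need
#' checking.
#'
#' @param isv_ratio Non-negative ratio `r`.
#' @param grid_step Grid resolution (default 0.01, the granularity at which
#'   scores are reported).
#' @param thresholds Classification thresholds.
#' @param grid_max Half-width of the scanned score grid (default 1.5).
#' @return Numeric `c(lower, upper)` of the band, or `numeric(0)` when every
#'   grid score is decidable by some probability.
#' @examples
#' undecidable_band(1)  # c(-0.48, 0.48)
#' @export
undecidable_band <- function(isv_ratio, grid_step = 0.01,
                             thresholds = acmg_thresholds(), grid_max = 1.5) {
  if (isv_ratio < 0) stop("isv_ratio must be non-negative", call. = FALSE)
  if (grid_step <= 0) stop("grid_step must be positive", call. = FALSE)
  k <- floor(round(grid_max / grid_step, 9))
  s <- (-k:k) * grid_step
  hi <- classify_score(s + isv_ratio * 0.5, thresholds)   # p = 1
  lo <- classify_score(s - isv_ratio * 0.5, thresholds)   # p = 0
  undecidable <- hi != "P" & lo != "B"
  # largest m such that every grid score with |s| <= m is undecidable
  m <- -1L
  for (j in 0:k) {
    if (undecidable[k + 1 + j] && undecidable[k + 1 - j]) m <- j else break
  }
  if (m < 0) return(numeric(0))
  c(-m, m) * grid_step
}

#' Smallest ratio at which a score/probability pair reaches a class
#'
#' Searches upward over the ratio grid `0, step, 2*step, ...` and returns the
#' first ratio whose combined classification equals `target`.
#'
#' @param acmg_score Rule-based score.
#' @param isv_probability ML probability in \[0, 1\].
#' @param target Target class (default `"P"`).
#' @param step Ratio grid step (default 0.01).
#' @param max_ratio Upper search bound (default 5).
#' @param thresholds Classification thresholds.
#' @return The smallest grid ratio reaching `target`, or `NA` when none does.
#' @examples
#' smallest_decisive_ratio(0.90, 0.99)  # 0.19
#' @export
smallest_decisive_ratio <- function(acmg_score, isv_probability, target = "P",
                                    step = 0.01, max_ratio = 5,
                                    thresholds = acmg_thresholds()) {
  ratios <- (0:floor(round(max_ratio / step, 9))) * step
  joint <- acmg_score + ratios * (isv_probability - 0.50)
  cls <- classify_score(joint, thresholds)
  hit <- which(cls == target)
  if (!length(hit)) return(NA_real_)
  ratios[hit[1]]
}

#' Sweep the ML ratio over a labeled CNV set
#'
#' For each ratio, combines every CNV's ACMG score with its ML probability,
#' classifies, and tallies against the truth labels (pathogenic positive;
#' LP/VUS/LB counted as uncertain).
#'
#' @param acmg_scores Numeric vector of rule-based scores.
#' @param isv_probabilities ML probabilities, same length.
#' @param labels Truth labels (`"benign"`/`"pathogenic"`), same length.
#' @param ratios Ratios to sweep (default `seq(0, 3, by = 0.01)`).
#' @param thresholds Classification thresholds.
#' @return Data frame with one row per ratio: `isv_ratio`, `TP`, `TN`, `FP`,
#'   `FN`, `uncertain`, `true`, `false`.
#' @export
ratio_sweep <- function(acmg_scores, isv_probabilities, labels,
                        ratios = seq(0, 3, by = 0.01),
                        thresholds = acmg_thresholds()) {
  n <- length(acmg_scores)
  if (length(isv_probabilities) != n || length(labels) != n) {
    stop("acmg_scores, isv_probabilities and labels must have equal length",
         call. = FALSE)
  }
  rows <- lapply(ratios, function(r) {
    cls <- combine_scores(acmg_scores, isv_probabilities, r, thresholds)$classification
    tl <- tally(cls, labels)
    data.frame(isv_ratio = r, TP = tl$TP, TN = tl$TN, FP = tl$FP, FN = tl$FN,
               uncertain = tl$uncertain, true = tl$TP + tl$TN,
               false = tl$FP + tl$FN)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bundled toy pathogenicity-probability provider
#'
#' A deliberately simple stand-in for an external ML model so end-to-end runs
#' need no model file: a logistic function of the number of protein-coding
#' genes the CNV overlaps. It is not a trained predictor and carries no
#' claim of accuracy.
#'
#' @param cnvs Data frame with `chrom`, `start`, `end` (and `cnv_type`).
#' @param genes A `gene_registry`.
#' @param midpoint Gene count at which the probability is 0.5 (default 8).
#' @param slope Logistic slope per gene (default 0.5).
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
gene_count_probability <- function(cnvs, genes, midpoint = 8, slope = 0.5) {
  vapply(seq_len(nrow(cnvs)), function(i) {
    iv <- genomic_interval(cnvs$chrom[i], cnvs$start[i], cnvs$end[i])
    n <- length(genes_overlapped(genes, iv, biotype = "protein_coding"))
    plogis(slope * (n - midpoint))
  }, numeric(1))
}
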