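# Performance accounting: confusion tallies with pathogenic as the positive
# class, the accuracy and unambiguous-fraction statistics, the McNemar-Bowker
# paired symmetry test, and the benign-database sweep harness.

#' Tally 5-tier predictions against binary truth labels
#'
#' P against pathogenic counts as TP, B against benign as TN, P against
#' benign as FP and B against pathogenic as FN. LP, VUS and LB carry
#' insufficient conclusive evidence and are counted as uncertain regardless
#' of the label.
#'
#' @param predicted Character vector over `c("B","LB","VUS","LP","P")`.
#' @param labels Truth labels, `"benign"` or `"pathogenic"`, same length.
#' @return An object of class `confusion_summary` with fields `TP`, `TN`,
#'   `FP`, `FN`, `uncertain`, `total`.
#' @export
tally <- function(predicted, labels) {
  if (length(predicted) != length(labels)) {
    stop("predicted and labels must have equal length", call. = FALSE)
  }
  bad <- setdiff(unique(labels), c("benign", "pathogenic"))
  if (length(bad)) {
    stop(sprintf("unknown truth label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  coll <- collapse_classes(predicted)
  structure(
    list(TP = sum(coll == "Pathogenic" & labels == "pathogenic"),
         TN = sum(coll == "Benign" & labels == "benign"),
         FP = sum(coll == "Pathogenic" & labels == "benign"),
         FN = sum(coll == "Benign" & labels == "pathogenic"),
         uncertain = sum(coll == "Uncertain"),
         total = length(predicted)),
    class = "confusion_summary"
  )
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("confusion (pathogenic positive): TP=%d TN=%d FP=%d FN=%d uncertain=%d (n=%d)\n",
              x$TP, x$TN, x$FP, x$FN, x$uncertain, x$total))
  acc <- accuracy(x)
  cat(sprintf("accuracy=%s unambiguous=%.4f\n",
              ifelse(is.na(acc), "undefined (no decided CNVs)", sprintf("%.4f", acc)),
              unambiguous(x)))
  invisible(x)
}

#' Accuracy over decided CNVs
#'
#' Correct predictions divided by all decided (B or P) predictions; uncertain
#' CNVs enter neither numerator nor denominator. Undefined (returned as `NA`)
#' when nothing was decided.
#'
#' @param summary A `confusion_summary`.
#' @return Fraction in \[0, 1\], or `NA` when no CNV was decided.
#' @export
accuracy <- function(summary) {
  decided <- summary$TP + summary$TN + summary$FP + summary$FN
  if (decided == 0) return(NA_real_)
  (summary$TP + summary$TN) / decided
}

#' Unambiguous (decided) fraction
#'
#' The share of CNVs predicted outright B or P.
#'
#' @param summary A `confusion_summary`.
#' @return Fraction in \[0, 1\].
#' @export
unambiguous <- function(summary) {
  if (summary$total == 0) stop("empty input: unambiguous fraction undefined", call. = FALSE)
  (summary$TP + summary$TN + summary$FP + summary$FN) / summary$total
}

#' McNemar-Bowker symmetry test on a paired classification table
#'
#' Tests whether two methods classifying the same items disagree
#' symmetrically. The statistic sums `(n_ij - n_ji)^2 / (n_ij + n_ji)` over
#' off-diagonal pairs; pairs with `n_ij + n_ji = 0` contribute nothing and
#' reduce the degrees of freedom (the standard convention). With all pairs
#' contributing, df = k(k-1)/2.
#'
#' @param tab Square matrix (or table) of non-negative integer counts; rows
#'   are method A's classes, columns method B's, in the same order.
#' @return An object of class `htest` with `statistic` (B), `parameter` (df)
#'   and `p.value` (chi-square upper tail). When no off-diagonal pair
#'   contributes, the test is inapplicable and statistic and p-value are `NA`.
#' @examples
#' bowker_test(matrix(c(10, 4, 1, 10), 2, byrow = TRUE))  # B = 1.8, df = 1
#' @export
bowker_test <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) stop("table must be square", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table cells must be non-negative integers", call. = FALSE)
  }
  k <- nrow(tab)
  stat <- 0
  df <- 0L
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      s <- tab[i, j] + tab[j, i]
      if (s > 0) {
        stat <- stat + (tab[i, j] - tab[j, i])^2 / s
        df <- df + 1L
      }
    }
  }
  if (df == 0L) {
    stat <- NA_real_
    p <- NA_real_
    method <- "McNemar-Bowker symmetry test (inapplicable: no discordant pairs)"
  } else {
    p <- pchisq(stat, df = df, lower.tail = FALSE)
    method <- "McNemar-Bowker symmetry test"
  }
  structure(
    list(statistic = c(B = stat), parameter = c(df = df), p.value = p,
         method = method, data.name = deparse(substitute(tab))),
    class = "htest"
  )
}

#' Paired 3-class contingency table of two methods
#'
#' Collapses both 5-tier prediction vectors to Benign/Uncertain/Pathogenic
#' and cross-tabulates them, the shape the paired symmetry test expects.
#'
#' @param classes_a,classes_b Character vectors over
#'   `c("B","LB","VUS","LP","P")`, same length.
#' @return 3x3 integer matrix (rows: method A; columns: method B).
#' @export
paired_class_table <- function(classes_a, classes_b) {
  if (length(classes_a) != length(classes_b)) {
    stop("class vectors must have equal length", call. = FALSE)
  }
  lv <- c("Benign", "Uncertain", "Pathogenic")
  a <- factor(collapse_classes(classes_a), levels = lv)
  b <- factor(collapse_classes(classes_b), levels = lv)
  unclass(table(a, b))
}

#' Sweep benign-database settings over a labeled CNV set
#'
#' Re-scores every CNV under each combination of benign-CNV source and
#' minimum-frequency threshold (the trade-off between accuracy and the
#' fraction of CNVs decided), keeping all other engine settings fixed.
#'
#' @param cnvs Data frame of CNVs (`chrom`, `start`, `end`, `cnv_type`,
#'   optionally `id`) with a `truth_label` column (`benign`/`pathogenic`).
#' @param registries Registries as for [score_cnv()]; the `benign` entry is
#'   replaced per setting.
#' @param benign_records Pooled benign records (a `benign_registry` or its
#'   data frame) from which each setting is built.
#' @param sources List of settings, each `list(name=, source=, flavor=)`.
#'   Default: the four standard sources (GnomAD, DGV, and the curated set in
#'   inner and outer coordinates).
#' @param thresholds Frequency thresholds as fractions; `NA` means no
#'   filtering. Default: no filter plus 0.01\%, 0.1\%, 0.5\%, 1\%, 2\%, 10\%.
#' @param type_filter `"both"` or `"losses_only"`.
#' @param table,options Scoring table and engine options (the benign-related
#'   option fields are overridden per grid cell).
#' @return Data frame with one row per source x threshold: the setting,
#'   confusion counts, `accuracy` and `unambiguous`.
#' @export
sweep_benign_db <- function(cnvs, registries, benign_records,
                            sources = list(
                              list(name = "GnomAD", source = "GnomAD", flavor = "plain"),
                              list(name = "DGV", source = "DGV", flavor = "plain"),
                              list(name = "DGV-GOLD-INNER", source = "DGV_GOLD", flavor = "inner"),
                              list(name = "DGV-GOLD-OUTER", source = "DGV_GOLD", flavor = "outer")
                            ),
                            thresholds = c(NA, 0.0001, 0.001, 0.005, 0.01, 0.02, 0.10),
                            type_filter = "both",
                            table = default_scoring_table(),
                            options = engine_options()) {
  if (!length(sources) || !length(thresholds)) {
    stop("empty sweep grid: need at least one source and one threshold", call. = FALSE)
  }
  if (!"truth_label" %in% names(cnvs)) {
    stop("cnvs must carry a truth_label column", call. = FALSE)
  }
  rows <- list()
  for (src in sources) {
    for (th in thresholds) {
      reg <- build_benign_db(benign_records,
                             maf_threshold = if (is.na(th)) NULL else th,
                             type_filter = type_filter,
                             flavor = src$flavor, source = src$source)
      regs <- registries
      regs$benign <- reg
      scored <- score_cnv_batch(cnvs, regs, table, options)
      tl <- tally(scored$classification, cnvs$truth_label)
      rows[[length(rows) + 1L]] <- data.frame(
        source = src$name, flavor = src$flavor,
        maf_threshold = ifelse(is.na(th), NA_real_, th),
        n_benign_records = registry_size(reg),
        TP = tl$TP, TN = tl$TN, FP = tl$FP, FN = tl$FN,
        uncertain = tl$uncertain,
        decided = tl$TP + tl$TN + tl$FP + tl$FN,
        accuracy = accuracy(tl), unambiguous = unambiguous(tl),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
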