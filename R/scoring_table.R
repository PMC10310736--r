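# Scoring table: per-option point values, 5-tier thresholds and Section-3
# gene-count bands. Shipped as an editable YAML so a corrected point sheet
# never touches code; all engine logic looks points up symbolically.

#' Read a CNV scoring table
#'
#' @param path Path to a YAML scoring table (see the shipped default in
#'   `system.file("extdata", "scoring_acmg_default.yaml", package = "cnvscore")`
#'   for the schema: `thresholds`, `options` (per cnv type, option id ->
#'   points + label), `gene_count_bands`, `unevaluated`).
#' @return An object of class `scoring_table`.
#' @export
read_scoring_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("scoring table not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  for (field in c("thresholds", "options", "gene_count_bands", "unevaluated")) {
    if (is.null(raw[[field]])) {
      stop(sprintf("scoring table is missing the '%s' field", field), call. = FALSE)
    }
  }
  thresholds <- unlist(raw$thresholds)
  needed <- c("pathogenic", "likely_pathogenic", "likely_benign", "benign")
  if (!all(needed %in% names(thresholds))) {
    stop("thresholds must name pathogenic, likely_pathogenic, likely_benign, benign",
         call. = FALSE)
  }
  if (!(thresholds["benign"] <= thresholds["likely_benign"] &&
        thresholds["likely_benign"] < thresholds["likely_pathogenic"] &&
        thresholds["likely_pathogenic"] <= thresholds["pathogenic"])) {
    stop("classification thresholds must be ordered B <= LB < LP <= P", call. = FALSE)
  }
  points <- lapply(raw$options, function(sheet) {
    vapply(sheet, function(opt) as.numeric(opt$points), numeric(1))
  })
  labels <- lapply(raw$options, function(sheet) {
    vapply(sheet, function(opt) as.character(opt$label %||% ""), character(1))
  })
  bands <- lapply(raw$gene_count_bands, as.numeric)
  for (ty in c("loss", "gain")) {
    if (is.null(points[[ty]])) stop(sprintf("no option sheet for type '%s'", ty), call. = FALSE)
    if (length(bands[[ty]]) != 2L || bands[[ty]][1] >= bands[[ty]][2]) {
      stop(sprintf("gene_count_bands$%s must be two increasing lower bounds", ty),
           call. = FALSE)
    }
  }
  structure(
    list(points = points, labels = labels, thresholds = thresholds,
         gene_count_bands = bands,
         unevaluated = lapply(raw$unevaluated, as.character)),
    class = "scoring_table"
  )
}

#' The shipped default ACMG/ClinGen scoring table
#'
#' @return A `scoring_table` with the standard point sheet, the 5-tier
#'   thresholds (P >= 0.99, LP >= 0.90, LB <= -0.90, B <= -0.99) and the
#'   default gene-count bands (loss 0-24/25-34/>=35, gain 0-34/35-49/>=50).
#' @export
default_scoring_table <- function() {
  read_scoring_table(system.file("extdata", "scoring_acmg_default.yaml",
                                 package = "cnvscore"))
}

#' @export
print.scoring_table <- function(x, ...) {
  cat("ACMG/ClinGen CNV scoring table\n")
  cat(sprintf("  thresholds: P >= %.2f, LP >= %.2f, LB <= %.2f, B <= %.2f\n",
              x$thresholds["pathogenic"], x$thresholds["likely_pathogenic"],
              x$thresholds["likely_benign"], x$thresholds["benign"]))
  for (ty in names(x$points)) {
    cat(sprintf("  %s: %d options (%s)\n", ty, length(x$points[[ty]]),
                paste(names(x$points[[ty]]), collapse = " ")))
  }
  invisible(x)
}

#' Look up the points of a scoring option
#'
#' @param table A `scoring_table`.
#' @param option Option id, e.g. `"2A"`.
#' @param cnv_type `"loss"` or `"gain"`.
#' @return Signed numeric points.
#' @export
option_points <- function(table, option, cnv_type) {
  sheet <- table$points[[cnv_type]]
  if (is.null(sheet) || !option %in% names(sheet)) {
    stop(sprintf("option '%s' not present in the %s scoring sheet", option, cnv_type),
         call. = FALSE)
  }
  unname(sheet[[option]])
}

#' Default 5-tier classification thresholds
#'
#' @return Named numeric vector (`pathogenic`, `likely_pathogenic`,
#'   `likely_benign`, `benign`).
#' @export
acmg_thresholds <- function() {
  c(pathogenic = 0.99, likely_pathogenic = 0.90,
    likely_benign = -0.90, benign = -0.99)
}

#' Map a score to the 5-tier classification
#'
#' The partition is: P for score >= 0.99; LP for 0.90 <= score < 0.99;
#' VUS for -0.90 < score < 0.90; LB for -0.99 < score <= -0.90;
#' B for score <= -0.99 (with the shipped default thresholds). Both outer
#' boundaries are inclusive, so 0.99 itself classifies as P and -0.99 as B.
#'
#' @param score Numeric vector of total scores (finite).
#' @param thresholds Named thresholds as from [acmg_thresholds()].
#' @return Character vector over `c("B", "LB", "VUS", "LP", "P")`.
#' @examples
#' classify_score(c(0.9931, 0, -0.99))
#' @export
classify_score <- function(score, thresholds = acmg_thresholds()) {
  if (!is.numeric(score) || any(!is.finite(score))) {
    stop("scores must be finite numbers", call. = FALSE)
  }
  th <- unname(thresholds[c("pathogenic", "likely_pathogenic",
                            "benign", "likely_benign")])
  unname(ifelse(score >= th[1], "P",
         ifelse(score >= th[2], "LP",
         ifelse(score <= th[3], "B",
         ifelse(score <= th[4], "LB", "VUS")))))
}

#' Collapse 5-tier classes to the 3-class decided/uncertain view
#'
#' LP, VUS and LB indicate insufficient conclusive evidence and are pooled as
#' "Uncertain"; only outright B and P count as decided.
#'
#' @param classes Character vector over `c("B","LB","VUS","LP","P")`.
#' @return Character vector over `c("Benign", "Uncertain", "Pathogenic")`.
#' @export
collapse_classes <- function(classes) {
  bad <- setdiff(unique(classes), c("B", "LB", "VUS", "LP", "P"))
  if (length(bad)) {
    stop(sprintf("unknown class label(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  }
  ifelse(classes == "P", "Pathogenic", ifelse(classes == "B", "Benign", "Uncertain"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
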