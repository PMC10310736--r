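# The ACMG/ClinGen scoring engine: Sections 1 and 3 complete, Section 2 to
# the extent the annotation sources allow (2A-2H for losses; 2A-2H plus 2L
# for gains), and option 4O. Options needing patient phenotype or
# sequence-level evidence (loss 2J/2K, gain 2I-2K) are never scored and are
# reported as unevaluated so coverage is explicit.

#' Engine options
#'
#' Bundles the tunable knobs of the scoring engine. The default configuration
#' is the best-performing database setting (curated benign CNVs in their
#' outer-coordinate representation at a minimum population frequency of
#' 0.5\%, both losses and gains searched, established dosage records only).
#'
#' @param dosage_min_scores Dosage scores treated as "established" for
#'   Sections 2A/2B (default `3`; widen to `c(1, 2, 3)` to also admit
#'   lower-confidence HI/TS records).
#' @param benign_source Benign-CNV source: `"DGV"`, `"DGV_GOLD"`, `"GnomAD"`.
#' @param benign_flavor Coordinate flavor of the benign records.
#' @param maf_threshold Minimum population frequency (fraction) for a benign
#'   record to count as established; `NULL` disables filtering.
#' @param benign_type_filter `"both"` or `"losses_only"` (which record types
#'   are searched for the benign-overlap options of a loss).
#' @param common_af_threshold Minimum allele frequency for option 4O
#'   (default 0.01).
#' @param hi_predictor_min Minimum number of concordant haploinsufficiency
#'   predictors for option 2H on losses (default 2).
#' @param preset `"marcnv-best"` (the defaults above) or `"acmg-default"`
#'   (unfiltered plain benign records, established scores only). Explicit
#'   arguments override preset values.
#' @return An object of class `engine_options`.
#' @export
engine_options <- function(dosage_min_scores = 3,
                           benign_source = "DGV_GOLD",
                           benign_flavor = "outer",
                           maf_threshold = 0.005,
                           benign_type_filter = "both",
                           common_af_threshold = 0.01,
                           hi_predictor_min = 2,
                           preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("marcnv-best", "acmg-default"))
    if (preset == "acmg-default") {
      if (missing(benign_source)) benign_source <- "DGV"
      if (missing(benign_flavor)) benign_flavor <- "plain"
      if (missing(maf_threshold)) maf_threshold <- NULL
    }
    # marcnv-best is the argument default
  }
  if (!all(dosage_min_scores %in% c(1, 2, 3))) {
    stop("dosage_min_scores must be a subset of {1, 2, 3}", call. = FALSE)
  }
  if (!3 %in% dosage_min_scores) {
    stop("dosage_min_scores must always include the established score 3", call. = FALSE)
  }
  structure(
    list(dosage_min_scores = sort(unique(dosage_min_scores)),
         benign_source = benign_source,
         benign_flavor = benign_flavor,
         maf_threshold = maf_threshold,
         benign_type_filter = match.arg(benign_type_filter, c("both", "losses_only")),
         common_af_threshold = common_af_threshold,
         hi_predictor_min = hi_predictor_min),
    class = "engine_options"
  )
}

#' @export
print.engine_options <- function(x, ...) {
  cat("CNV engine options\n")
  cat(sprintf("  established dosage scores: {%s}\n",
              paste(x$dosage_min_scores, collapse = ",")))
  cat(sprintf("  benign db: %s/%s, MAF >= %s, %s\n", x$benign_source,
              x$benign_flavor,
              ifelse(is.null(x$maf_threshold), "none", x$maf_threshold),
              x$benign_type_filter))
  cat(sprintf("  4O common AF threshold: %s; 2H predictor minimum: %d\n",
              x$common_af_threshold, x$hi_predictor_min))
  invisible(x)
}

evidence_row <- function(section, option, points, supporting = "", note = "") {
  data.frame(section = section, option = option, points = points,
             supporting = supporting, note = note, stringsAsFactors = FALSE)
}

no_evidence <- function() {
  data.frame(section = character(), option = character(), points = numeric(),
             supporting = character(), note = character(), stringsAsFactors = FALSE)
}

# Choose the most severe candidate: largest |points| first, ties broken
# toward the more pathogenic (larger signed points), then by option id for
# full determinism.
most_severe <- function(cands) {
  if (!nrow(cands)) return(cands)
  ord <- order(-abs(cands$points), -cands$points, cands$option)
  cands[ord[1], , drop = FALSE]
}

#' Section 1: initial assessment of genomic content
#'
#' Option 1A when the CNV overlaps at least one protein-coding gene or known
#' functionally important element; 1B otherwise.
#'
#' @param cnv A `cnv_call`.
#' @param genes A `gene_registry`.
#' @param elements An `element_registry`, or `NULL` when no functional-element
#'   source is available.
#' @param table A `scoring_table`.
#' @return One-row evidence data frame.
#' @export
evaluate_section1 <- function(cnv, genes, elements = NULL,
                              table = default_scoring_table()) {
  iv <- cnv$interval
  pc <- genes_overlapped(genes, iv, biotype = "protein_coding")
  has_element <- !is.null(elements) && length(registry_hits(elements, iv)) > 0
  if (length(pc) || has_element) {
    supporting <- paste(c(pc, if (has_element) "functional_element"), collapse = ",")
    evidence_row("S1", "1A", option_points(table, "1A", cnv$cnv_type), supporting,
                 "protein-coding gene or functional element content")
  } else {
    evidence_row("S1", "1B", option_points(table, "1B", cnv$cnv_type), "",
                 "no protein-coding genes or known functional elements")
  }
}

# Geometry of a loss against one transcript: which end of the transcript
# does the CNV clip? cds_side says which genomic end is the 5' end.
transcript_geometry <- function(iv, tx_start, tx_end, cds_side) {
  covers_left <- iv$start <= tx_start
  covers_right <- iv$end >= tx_end
  if (covers_left && covers_right) return(NA_character_)  # whole transcript gone
  if (!covers_left && !covers_right) return("2E")         # intragenic
  five_prime_left <- cds_side == "left"
  covers_5p <- (covers_left && five_prime_left) || (covers_right && !five_prime_left)
  if (covers_5p) "2C" else "2D"
}

breakpoint_in_transcript <- function(pos, chrom, genes) {
  tx <- genes$records
  any(tx$chrom == chrom & tx$start <= pos & pos <= tx$end)
}

#' Section 2 evidence for a copy-number loss
#'
#' Evaluates, in priority order: 2A (established HI gene/region completely
#' overlapped by the CNV), 2B (partial overlap of an established HI region),
#' 2C/2D/2E (breakpoint geometry of a partially overlapped established HI
#' gene, resolved over all of its transcripts with the most severe kept),
#' 2F (CNV completely contained within an established benign CNV),
#' 2G (CNV overlaps a benign CNV but extends over additional protein-coding
#' genes) and 2H (>= `hi_predictor_min` concordant haploinsufficiency
#' predictor calls for a fully contained gene, considered only when no
#' established-HI evidence fired). At most one dosage-line and one
#' benign-line evidence is emitted; 2J/2K are reported as unevaluated by
#' [score_cnv()].
#'
#' @param cnv A `cnv_call` with `cnv_type == "loss"`.
#' @param dosage A `dosage_registry`.
#' @param benign A filtered `benign_registry` (see [build_benign_db()]).
#' @param genes A `gene_registry`.
#' @param predictors A `predictor_registry`, or `NULL` to skip 2H.
#' @param options An `engine_options`.
#' @param table A `scoring_table`.
#' @return Evidence data frame (0-2 rows).
#' @export
evaluate_section2_loss <- function(cnv, dosage, benign, genes,
                                   predictors = NULL,
                                   options = engine_options(),
                                   table = default_scoring_table()) {
  if (cnv$cnv_type != "loss") stop("evaluate_section2_loss requires a loss", call. = FALSE)
  iv <- cnv$interval
  pts <- function(opt) option_points(table, opt, "loss")
  out <- no_evidence()

  hits <- query_dosage(dosage, iv, min_scores = options$dosage_min_scores, "hi")
  cands <- no_evidence()
  for (i in seq_len(nrow(hits))) {
    rec <- hits[i, ]
    if (rec$overlap_kind == "complete") {
      cands <- rbind(cands, evidence_row("S2", "2A", pts("2A"), rec$symbol,
                                         sprintf("complete overlap of HI %s (score %g)",
                                                 rec$target_kind, rec$hi_score)))
    } else if (rec$target_kind == "region") {
      cands <- rbind(cands, evidence_row("S2", "2B", pts("2B"), rec$symbol,
                                         "partial overlap of HI region"))
    } else {
      # partially overlapped established HI gene: breakpoint geometry over
      # all of its transcripts, most severe kept
      tx <- genes$records[genes$records$symbol == rec$symbol, , drop = FALSE]
      geo <- no_evidence()
      for (j in seq_len(nrow(tx))) {
        if (tx$chrom[j] != iv$chrom ||
            tx$end[j] < iv$start || iv$end < tx$start[j]) next
        opt <- transcript_geometry(iv, tx$start[j], tx$end[j], tx$cds_side[j])
        if (is.na(opt)) next
        geo <- rbind(geo, evidence_row("S2", opt, pts(opt),
                                       paste(rec$symbol, tx$transcript_id[j], sep = "/"),
                                       sprintf("%s overlap geometry of HI gene", opt)))
      }
      cands <- rbind(cands, most_severe(geo))
    }
  }
  dosage_ev <- most_severe(cands)
  out <- rbind(out, dosage_ev)

  # 2H: only when no established-HI evidence fired
  if (!nrow(dosage_ev) && !is.null(predictors)) {
    contained <- query_overlapping_genes(genes, iv)
    contained <- contained[contained$contained & contained$biotype == "protein_coding", ,
                           drop = FALSE]
    for (sym in sort(unique(contained$symbol))) {
      calls <- predictor_calls(predictors, sym)
      if (sum(calls) >= options$hi_predictor_min) {
        out <- rbind(out, evidence_row("S2", "2H", pts("2H"), sym,
                                       sprintf("%d/%d HI predictors concordant",
                                               sum(calls), length(calls))))
        break
      }
    }
  }

  # benign line: 2F / 2G, independent of the dosage line
  bhits <- query_benign(benign, iv, cnv_type = NULL)
  if (nrow(bhits)) {
    if (any(bhits$contains_cnv)) {
      rec <- bhits[bhits$contains_cnv, , drop = FALSE][1, ]
      out <- rbind(out, evidence_row("S2", "2F", pts("2F"),
                                     sprintf("%s:%s-%s", rec$chrom,
                                             format(rec$start, scientific = FALSE),
                                             format(rec$end, scientific = FALSE)),
                                     sprintf("contained in benign %s (freq %g, %s/%s)",
                                             rec$cnv_type, rec$frequency,
                                             rec$source, rec$coordinate_flavor)))
    } else {
      # resolve against the record covering the largest fraction of the CNV
      cov <- (pmin(bhits$end, iv$end) - pmax(bhits$start, iv$start) + 1) /
        interval_length(iv)
      rec <- bhits[which.max(cov), ]
      cnv_genes <- genes_overlapped(genes, iv)
      rec_genes <- genes_overlapped(
        genes, genomic_interval(rec$chrom, rec$start, rec$end))
      extra <- setdiff(cnv_genes, rec_genes)
      if (length(extra)) {
        out <- rbind(out, evidence_row("S2", "2G", pts("2G"),
                                       paste(extra, collapse = ","),
                                       "extends beyond benign CNV over additional protein-coding genes"))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Section 2 evidence for a copy-number gain
#'
#' Evaluates 2A/2B against established triplosensitive records; 2C-2G by
#' comparing the gain's span and protein-coding gene content with established
#' benign gains (identical gene content; smaller and contained with/without
#' breakpoints inside genes; larger with/without additional genes); 2H when
#' an established HI gene is fully contained in the gain; 2L when a
#' breakpoint falls inside any gene. Gain options 2I-2K are reported as
#' unevaluated by [score_cnv()].
#'
#' @param cnv A `cnv_call` with `cnv_type == "gain"`.
#' @param dosage A `dosage_registry`.
#' @param benign A filtered `benign_registry`.
#' @param genes A `gene_registry`.
#' @param options An `engine_options`.
#' @param table A `scoring_table`.
#' @return Evidence data frame.
#' @export
evaluate_section2_gain <- function(cnv, dosage, benign, genes,
                                   options = engine_options(),
                                   table = default_scoring_table()) {
  if (cnv$cnv_type != "gain") stop("evaluate_section2_gain requires a gain", call. = FALSE)
  iv <- cnv$interval
  pts <- function(opt) option_points(table, opt, "gain")
  out <- no_evidence()

  ts_hits <- query_dosage(dosage, iv, min_scores = options$dosage_min_scores, "ts")
  cands <- no_evidence()
  for (i in seq_len(nrow(ts_hits))) {
    rec <- ts_hits[i, ]
    opt <- if (rec$overlap_kind == "complete") "2A" else "2B"
    cands <- rbind(cands, evidence_row("S2", opt, pts(opt), rec$symbol,
                                       sprintf("%s overlap of TS %s (score %g)",
                                               rec$overlap_kind, rec$target_kind,
                                               rec$ts_score)))
  }
  out <- rbind(out, most_severe(cands))

  # benign-gain comparisons (2C-2G), most severe across records
  bhits <- query_benign(benign, iv, cnv_type = "gain")
  cnv_genes <- genes_overlapped(genes, iv)
  cands <- no_evidence()
  for (i in seq_len(nrow(bhits))) {
    rec <- bhits[i, ]
    rec_iv <- genomic_interval(rec$chrom, rec$start, rec$end)
    rec_genes <- genes_overlapped(genes, rec_iv)
    rec_id <- sprintf("%s:%s-%s", rec$chrom,
                      format(rec$start, scientific = FALSE),
                      format(rec$end, scientific = FALSE))
    extra <- setdiff(cnv_genes, rec_genes)
    if (setequal(cnv_genes, rec_genes)) {
      opt <- "2C"; note <- "identical protein-coding gene content to benign gain"
    } else if (rec$contains_cnv) {
      brk <- breakpoint_in_transcript(iv$start, iv$chrom, genes) ||
        breakpoint_in_transcript(iv$end, iv$chrom, genes)
      if (brk) { opt <- "2E"; note <- "smaller than benign gain, breakpoints may interrupt genes" }
      else { opt <- "2D"; note <- "smaller than benign gain, breakpoints outside genes" }
    } else if (rec$start >= iv$start && rec$end <= iv$end) {
      if (length(extra)) { opt <- "2G"; note <- "larger than benign gain with additional protein-coding genes" }
      else { opt <- "2F"; note <- "larger than benign gain, no additional protein-coding genes" }
    } else if (length(extra)) {
      opt <- "2G"; note <- "overlaps benign gain but includes additional protein-coding genes"
    } else next
    cands <- rbind(cands, evidence_row("S2", opt, pts(opt), rec_id, note))
  }
  out <- rbind(out, most_severe(cands))

  # 2H: established HI gene fully contained in the gain
  hi_hits <- query_dosage(dosage, iv, min_scores = options$dosage_min_scores, "hi")
  hi_hits <- hi_hits[hi_hits$overlap_kind == "complete" &
                       hi_hits$target_kind == "gene", , drop = FALSE]
  if (nrow(hi_hits)) {
    out <- rbind(out, evidence_row("S2", "2H", pts("2H"),
                                   paste(sort(hi_hits$symbol), collapse = ","),
                                   "established HI gene fully contained in gain"))
  }

  # 2L: a breakpoint inside any gene
  if (breakpoint_in_transcript(iv$start, iv$chrom, genes) ||
      breakpoint_in_transcript(iv$end, iv$chrom, genes)) {
    out <- rbind(out, evidence_row("S2", "2L", pts("2L"), "",
                                   "breakpoint within a gene"))
  }
  rownames(out) <- NULL
  out
}

#' Section 3: evaluation of gene number
#'
#' Counts distinct protein-coding genes with any overlap and maps the count
#' through the loss- or gain-specific bands of the scoring table (band lower
#' bounds inclusive).
#'
#' @param cnv A `cnv_call`.
#' @param genes A `gene_registry`.
#' @param table A `scoring_table`.
#' @return One-row evidence data frame (option 3A, 3B or 3C).
#' @export
evaluate_section3 <- function(cnv, genes, table = default_scoring_table()) {
  n <- length(genes_overlapped(genes, cnv$interval, biotype = "protein_coding"))
  bands <- table$gene_count_bands[[cnv$cnv_type]]
  opt <- if (n >= bands[2]) "3C" else if (n >= bands[1]) "3B" else "3A"
  evidence_row("S3", opt, option_points(table, opt, cnv$cnv_type), "",
               sprintf("%d protein-coding genes overlapped", n))
}

#' Option 4O: overlap with common population variation
#'
#' Fires when the CNV is completely contained in a same-type population
#' record whose allele frequency reaches `common_af_threshold`.
#'
#' @param cnv A `cnv_call`.
#' @param population A `population_registry`.
#' @param options An `engine_options`.
#' @param table A `scoring_table`.
#' @return One-row evidence data frame, or a zero-row frame when 4O does not
#'   apply.
#' @export
evaluate_section4o <- function(cnv, population, options = engine_options(),
                               table = default_scoring_table()) {
  af <- query_population_frequency(population, cnv$interval, cnv$cnv_type)
  if (af >= options$common_af_threshold) {
    evidence_row("S4", "4O", option_points(table, "4O", cnv$cnv_type), "",
                 sprintf("contained in common population variant (AF %g)", af))
  } else {
    no_evidence()
  }
}

#' Score a CNV against the ACMG/ClinGen scheme
#'
#' Runs Sections 1, 2, 3 and option 4O, sums the evidence points and maps the
#' total through the 5-tier thresholds.
#'
#' @param cnv A `cnv_call`.
#' @param registries Named list of registries: `genes` (required), `dosage`
#'   (required), `benign` (required, already filtered via
#'   [build_benign_db()]), `population` (required), and optionally
#'   `elements` and `predictors`.
#' @param table A `scoring_table`.
#' @param options An `engine_options`.
#' @return An object of class `acmg_result`: the CNV, the evidence table,
#'   `total_score`, `classification` and `unevaluated_options`.
#' @examples
#' \dontrun{
#' bundle <- generate_annotation_bundle(fixture_spec(seed = 1))
#' score_cnv(cnv_call("chr1", 1e5, 2e6, "loss"), bundle$registries)
#' }
#' @export
score_cnv <- function(cnv, registries, table = default_scoring_table(),
                      options = engine_options()) {
  need <- c(genes = "Sections 1 and 3", dosage = "Section 2",
            benign = "Section 2 (benign overlap options)",
            population = "option 4O")
  for (nm in names(need)) {
    if (is.null(registries[[nm]])) {
      stop(sprintf("missing '%s' registry: %s cannot be evaluated", nm, need[[nm]]),
           call. = FALSE)
    }
  }
  ev <- rbind(
    evaluate_section1(cnv, registries$genes, registries$elements, table),
    if (cnv$cnv_type == "loss") {
      evaluate_section2_loss(cnv, registries$dosage, registries$benign,
                             registries$genes, registries$predictors,
                             options, table)
    } else {
      evaluate_section2_gain(cnv, registries$dosage, registries$benign,
                             registries$genes, options, table)
    },
    evaluate_section3(cnv, registries$genes, table),
    evaluate_section4o(cnv, registries$population, options, table)
  )
  rownames(ev) <- NULL
  total <- sum(ev$points)
  structure(
    list(cnv = cnv, evidence = ev, total_score = total,
         classification = classify_score(total, table$thresholds),
         unevaluated_options = table$unevaluated[[cnv$cnv_type]],
         options = options),
    class = "acmg_result"
  )
}

#' @export
print.acmg_result <- function(x, ...) {
  print(x$cnv)
  cat("evidence:\n")
  for (i in seq_len(nrow(x$evidence))) {
    cat(sprintf("  %-3s %+6.2f  %s\n", x$evidence$option[i],
                x$evidence$points[i], x$evidence$note[i]))
  }
  cat(sprintf("total score: %+.2f -> %s\n", x$total_score, x$classification))
  cat(sprintf("not evaluated automatically: %s\n",
              paste(x$unevaluated_options, collapse = ", ")))
  invisible(x)
}

#' Score a batch of CNVs
#'
#' @param cnvs Data frame with columns `chrom`, `start`, `end`, `cnv_type`
#'   and optionally `id`, `copy_number`.
#' @param registries,table,options As for [score_cnv()].
#' @return Data frame with one row per CNV (`id`, location, type,
#'   `total_score`, `classification`, `options` — the selected option ids)
#'   in input order; the full evidence long table is attached as
#'   `attr(, "evidence")`.
#' @export
score_cnv_batch <- function(cnvs, registries, table = default_scoring_table(),
                            options = engine_options()) {
  if (!nrow(cnvs)) stop("empty CNV table", call. = FALSE)
  ids <- if ("id" %in% names(cnvs)) as.character(cnvs$id) else
    sprintf("cnv%04d", seq_len(nrow(cnvs)))
  res <- vector("list", nrow(cnvs))
  details <- vector("list", nrow(cnvs))
  for (i in seq_len(nrow(cnvs))) {
    cn <- if ("copy_number" %in% names(cnvs)) cnvs$copy_number[i] else NA
    call <- cnv_call(cnvs$chrom[i], cnvs$start[i], cnvs$end[i],
                     cnvs$cnv_type[i], copy_number = cn, id = ids[i])
    r <- score_cnv(call, registries, table, options)
    res[[i]] <- data.frame(
      id = ids[i], chrom = call$interval$chrom, start = call$interval$start,
      end = call$interval$end, cnv_type = call$cnv_type,
      total_score = r$total_score, classification = r$classification,
      options = paste(r$evidence$option, collapse = ","),
      stringsAsFactors = FALSE
    )
    dd <- r$evidence
    if (nrow(dd)) dd$id <- ids[i]
    details[[i]] <- dd
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "evidence") <- do.call(rbind, details)
  out
}
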