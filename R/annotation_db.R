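# Annotation registries: readers, writers and overlap queries for the four
# annotation sources the engine consumes (gene models, dosage-sensitivity
# records, benign-CNV databases, population variants) plus optional
# functional elements and haploinsufficiency-predictor calls.
#
# File dialects are plain TSVs with headers, 1-based inclusive coordinates,
# one fixture of each shipped under inst/extdata/. Overlap queries are
# vectorized interval arithmetic over the record table (registries hold a
# few hundred to a few thousand records; a vectorized scan is exact,
# allocation-free and faster at this scale than tree-backed indices with
# per-query dispatch overhead); results are always sorted by
# (chrom, start, end, id) for order independence.

VALID_DOSAGE_SCORES <- c(0, 1, 2, 3, 30, 40)
VALID_BENIGN_SOURCES <- c("DGV", "DGV_GOLD", "GnomAD")
VALID_FLAVORS <- c("plain", "inner", "outer")

new_registry <- function(records, class_name) {
  structure(list(records = records),
            class = c(class_name, "annotation_registry"))
}

#' @export
print.annotation_registry <- function(x, ...) {
  cat(sprintf("<%s> %d records\n", class(x)[1], nrow(x$records)))
  invisible(x)
}

#' Number of records in a registry
#' @param registry An annotation registry.
#' @return Integer record count.
#' @export
registry_size <- function(registry) {
  nrow(registry$records)
}

# Row indices of records overlapping an interval (any shared base).
# Records are kept sorted, so the returned indices are position-ordered.
registry_hits <- function(registry, interval) {
  rec <- registry$records
  if (!nrow(rec)) return(integer(0))
  which(rec$chrom == interval$chrom &
          rec$start <= interval$end &
          rec$end >= interval$start)
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   quote = "", comment.char = "#")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s file %s lacks mandatory column(s): %s",
                 what, path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!nrow(df)) warning(sprintf("%s file %s is empty; registry has no records", what, path))
  df
}

fail_rows <- function(problems, what) {
  if (length(problems)) {
    stop(sprintf("%s: %d malformed row(s):\n%s", what, length(problems),
                 paste(utils::head(problems, 10), collapse = "\n")), call. = FALSE)
  }
}

parse_int_list <- function(x) {
  lapply(strsplit(as.character(x), ",", fixed = TRUE), as.numeric)
}

format_int_list <- function(x) {
  vapply(x, function(v) paste(format(v, scientific = FALSE, trim = TRUE), collapse = ","),
         character(1))
}

sort_records <- function(df, id_col = NULL) {
  if (!nrow(df)) return(df)
  keys <- list(df$chrom, df$start, df$end)
  if (!is.null(id_col)) keys <- c(keys, list(df[[id_col]]))
  out <- df[do.call(order, keys), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# write.table with scientific notation disabled so coordinates stay integral
write_tsv <- function(df, path) {
  old <- options(scipen = 15)
  on.exit(options(old))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# ---- gene models -----------------------------------------------------------

#' Load gene models from a transcript-level TSV
#'
#' Dialect: one row per transcript with columns `gene_id`, `symbol`,
#' `biotype` (`protein_coding` or `other`), `transcript_id`, `chrom`,
#' `start`, `end` (transcript span, 1-based inclusive), `exon_starts`,
#' `exon_ends` (comma-separated, paired) and `cds_side` (`left` or `right`:
#' which genomic end carries the 5' end of the coding sequence).
#'
#' @param path Path to the TSV.
#' @return A `gene_registry`.
#' @export
load_gene_models <- function(path) {
  required <- c("gene_id", "symbol", "biotype", "transcript_id", "chrom",
                "start", "end", "exon_starts", "exon_ends", "cds_side")
  df <- read_tsv_checked(path, required, "gene models")
  build_gene_registry(df)
}

build_gene_registry <- function(df) {
  if (!nrow(df)) {
    df <- data.frame(gene_id = character(), symbol = character(),
                     biotype = character(), transcript_id = character(),
                     chrom = character(), start = numeric(), end = numeric(),
                     cds_side = character())
    df$exon_starts <- list()
    df$exon_ends <- list()
    return(new_registry(df, "gene_registry"))
  }
  df$chrom <- normalize_chrom(df$chrom)
  if (!is.list(df$exon_starts)) df$exon_starts <- parse_int_list(df$exon_starts)
  if (!is.list(df$exon_ends)) df$exon_ends <- parse_int_list(df$exon_ends)
  problems <- character(0)
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    es <- row$exon_starts[[1]]; ee <- row$exon_ends[[1]]
    tag <- sprintf("row %d (transcript %s)", i, row$transcript_id)
    if (!row$biotype %in% c("protein_coding", "other")) {
      problems <- c(problems, paste(tag, "- unknown biotype", row$biotype)); next
    }
    if (!row$cds_side %in% c("left", "right")) {
      problems <- c(problems, paste(tag, "- cds_side must be left or right")); next
    }
    if (is.na(row$start) || is.na(row$end) || row$end < row$start) {
      problems <- c(problems, paste(tag, "- malformed transcript span")); next
    }
    if (length(es) != length(ee) || !length(es)) {
      problems <- c(problems, paste(tag, "- exon start/end lists unpaired or empty")); next
    }
    if (any(ee < es)) {
      problems <- c(problems, paste(tag, "- exon end before exon start")); next
    }
    if (any(es < row$start) || any(ee > row$end)) {
      problems <- c(problems, paste(tag, "- exon outside transcript span")); next
    }
    if (is.unsorted(es, strictly = TRUE) ||
        (length(es) > 1 && any(es[-1] <= ee[-length(ee)]))) {
      problems <- c(problems, paste(tag, "- exons must be sorted and non-overlapping")); next
    }
  }
  fail_rows(problems, "gene models")
  # all transcripts of a gene must share its chromosome
  per_gene <- tapply(df$chrom, df$gene_id, function(x) length(unique(x)))
  split_genes <- names(per_gene)[per_gene > 1]
  if (length(split_genes)) {
    stop(sprintf("gene models: gene(s) with transcripts on multiple chromosomes: %s",
                 paste(split_genes, collapse = ", ")), call. = FALSE)
  }
  new_registry(sort_records(df, "transcript_id"), "gene_registry")
}

#' Write gene models back to the TSV dialect
#' @param registry A `gene_registry`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gene_models <- function(registry, path) {
  df <- registry$records
  out <- df[, c("gene_id", "symbol", "biotype", "transcript_id", "chrom",
                "start", "end"), drop = FALSE]
  out$exon_starts <- format_int_list(df$exon_starts)
  out$exon_ends <- format_int_list(df$exon_ends)
  out$cds_side <- df$cds_side
  write_tsv(out, path)
  invisible(path)
}

# ---- dosage-sensitivity records -------------------------------------------

#' Load ClinGen-style dosage-sensitivity records
#'
#' Dialect: TSV with columns `symbol`, `target_kind` (`gene` or `region`),
#' `chrom`, `start`, `end`, `hi_score`, `ts_score`. Scores take the ClinGen
#' values 0/1/2/3/30/40; an unknown score is written as `NA` (or left empty).
#' Every record must carry at least one of the two scores.
#'
#' @param path Path to the TSV.
#' @return A `dosage_registry`.
#' @export
load_dosage_records <- function(path) {
  required <- c("symbol", "target_kind", "chrom", "start", "end",
                "hi_score", "ts_score")
  df <- read_tsv_checked(path, required, "dosage records")
  if (!nrow(df)) return(new_registry(df, "dosage_registry"))
  df$chrom <- normalize_chrom(df$chrom)
  df$hi_score <- suppressWarnings(as.numeric(df$hi_score))
  df$ts_score <- suppressWarnings(as.numeric(df$ts_score))
  problems <- character(0)
  for (i in seq_len(nrow(df))) {
    tag <- sprintf("row %d (%s)", i, df$symbol[i])
    if (is.na(df$hi_score[i]) && is.na(df$ts_score[i])) {
      problems <- c(problems, paste(tag, "- neither HI nor TS score set")); next
    }
    scr <- c(df$hi_score[i], df$ts_score[i])
    if (any(!is.na(scr) & !scr %in% VALID_DOSAGE_SCORES)) {
      problems <- c(problems, paste(tag, "- dosage scores must be one of 0,1,2,3,30,40")); next
    }
    if (!df$target_kind[i] %in% c("gene", "region")) {
      problems <- c(problems, paste(tag, "- target_kind must be gene or region")); next
    }
    if (is.na(df$start[i]) || is.na(df$end[i]) || df$end[i] < df$start[i]) {
      problems <- c(problems, paste(tag, "- malformed interval"))
    }
  }
  fail_rows(problems, "dosage records")
  new_registry(sort_records(df, "symbol"), "dosage_registry")
}

#' Write dosage records back to the TSV dialect
#' @param registry A `dosage_registry`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dosage_records <- function(registry, path) {
  write_tsv(registry$records[, c("symbol", "target_kind", "chrom", "start",
                                 "end", "hi_score", "ts_score")], path)
  invisible(path)
}

# ---- benign CNV records ----------------------------------------------------

#' Load known-benign CNV records (DGV-style)
#'
#' Dialect: TSV with columns `chrom`, `start`, `end`, `cnv_type`
#' (`loss`/`gain`), `frequency` (population frequency as a fraction in
#' \[0, 1\]), `coordinate_flavor` (`plain`, `inner` or `outer`) and `source`
#' (`DGV`, `DGV_GOLD` or `GnomAD`). Curated records appear twice, once per
#' inner/outer flavor, with the outer span containing the inner span.
#'
#' @param path Path to the TSV.
#' @return A `benign_registry` holding all records (use [build_benign_db()]
#'   to select a source/flavor and apply frequency filtering).
#' @export
load_benign_cnvs <- function(path) {
  required <- c("chrom", "start", "end", "cnv_type", "frequency",
                "coordinate_flavor", "source")
  df <- read_tsv_checked(path, required, "benign CNVs")
  if (!nrow(df)) return(new_registry(df, "benign_registry"))
  df$chrom <- normalize_chrom(df$chrom)
  df$cnv_type <- normalize_cnv_type(df$cnv_type)
  problems <- character(0)
  for (i in seq_len(nrow(df))) {
    tag <- sprintf("row %d", i)
    if (is.na(df$frequency[i]) || df$frequency[i] < 0 || df$frequency[i] > 1) {
      problems <- c(problems, paste(tag, "- frequency must lie in [0, 1]")); next
    }
    if (!df$coordinate_flavor[i] %in% VALID_FLAVORS) {
      problems <- c(problems, paste(tag, "- unknown coordinate flavor",
                                    df$coordinate_flavor[i])); next
    }
    if (!df$source[i] %in% VALID_BENIGN_SOURCES) {
      problems <- c(problems, paste(tag, "- unknown source", df$source[i])); next
    }
    if (is.na(df$start[i]) || is.na(df$end[i]) || df$end[i] < df$start[i]) {
      problems <- c(problems, paste(tag, "- malformed interval"))
    }
  }
  fail_rows(problems, "benign CNVs")
  new_registry(sort_records(df), "benign_registry")
}

#' Write benign CNV records back to the TSV dialect
#' @param registry A `benign_registry`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_benign_cnvs <- function(registry, path) {
  write_tsv(registry$records[, c("chrom", "start", "end", "cnv_type",
                                 "frequency", "coordinate_flavor", "source")], path)
  invisible(path)
}

#' Build a filtered benign-CNV registry
#'
#' Selects one database "setting" out of a pooled record set: a source and
#' coordinate flavor (DGV-GOLD ships distinct inner and outer record sets),
#' a minimum population frequency (records rarer than the threshold are
#' screened out; `NULL` keeps everything) and optionally only loss records.
#'
#' @param records A `benign_registry` or the records data frame.
#' @param maf_threshold Minimum frequency as a fraction (e.g. 0.005 for
#'   "0.5\%"), or `NULL` for no filtering.
#' @param type_filter `"both"` (default) or `"losses_only"`.
#' @param flavor Coordinate flavor to retain: `"plain"`, `"inner"`, `"outer"`.
#' @param source Restrict to one source (`"DGV"`, `"DGV_GOLD"`, `"GnomAD"`),
#'   or `NULL` for any.
#' @return A filtered `benign_registry`.
#' @export
build_benign_db <- function(records, maf_threshold = NULL,
                            type_filter = c("both", "losses_only"),
                            flavor = c("plain", "inner", "outer"),
                            source = NULL) {
  type_filter <- match.arg(type_filter)
  flavor <- match.arg(flavor)
  if (inherits(records, "benign_registry")) records <- records$records
  if (!is.null(maf_threshold)) {
    if (!is.numeric(maf_threshold) || maf_threshold <= 0 || maf_threshold > 1) {
      stop("maf_threshold must be NULL or a fraction in (0, 1]", call. = FALSE)
    }
  }
  if (!is.null(source) && !source %in% VALID_BENIGN_SOURCES) {
    stop(sprintf("unknown benign source '%s'", source), call. = FALSE)
  }
  keep <- records$coordinate_flavor == flavor
  if (!is.null(source)) keep <- keep & records$source == source
  if (!is.null(maf_threshold)) keep <- keep & records$frequency >= maf_threshold
  if (type_filter == "losses_only") keep <- keep & records$cnv_type == "loss"
  new_registry(sort_records(records[keep, , drop = FALSE]), "benign_registry")
}

# ---- population variants ---------------------------------------------------

#' Load population-variant records (GnomAD-style)
#'
#' Dialect: TSV with columns `chrom`, `start`, `end`, `cnv_type`,
#' `allele_frequency` (fraction in \[0, 1\]).
#'
#' @param path Path to the TSV.
#' @return A `population_registry`.
#' @export
load_population_variants <- function(path) {
  required <- c("chrom", "start", "end", "cnv_type", "allele_frequency")
  df <- read_tsv_checked(path, required, "population variants")
  if (!nrow(df)) return(new_registry(df, "population_registry"))
  df$chrom <- normalize_chrom(df$chrom)
  df$cnv_type <- normalize_cnv_type(df$cnv_type)
  bad <- which(is.na(df$allele_frequency) | df$allele_frequency < 0 |
                 df$allele_frequency > 1)
  fail_rows(sprintf("row %d - allele_frequency must lie in [0, 1]", bad),
            "population variants")
  bad <- which(is.na(df$start) | is.na(df$end) | df$end < df$start)
  fail_rows(sprintf("row %d - malformed interval", bad), "population variants")
  new_registry(sort_records(df), "population_registry")
}

#' Write population variants back to the TSV dialect
#' @param registry A `population_registry`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_population_variants <- function(registry, path) {
  write_tsv(registry$records[, c("chrom", "start", "end", "cnv_type",
                                 "allele_frequency")], path)
  invisible(path)
}

# ---- HI predictor calls ----------------------------------------------------

#' Load per-gene haploinsufficiency predictor calls (dbNSFP-style)
#'
#' Dialect: TSV with columns `symbol` and `predictor_calls`, the latter a
#' comma-separated list of 0/1 flags, one per predictor.
#'
#' @param path Path to the TSV.
#' @return A `predictor_registry`.
#' @export
load_hi_predictors <- function(path) {
  df <- read_tsv_checked(path, c("symbol", "predictor_calls"), "HI predictors")
  if (!nrow(df)) {
    df$calls <- list()
    return(structure(list(records = df), class = c("predictor_registry")))
  }
  calls <- parse_int_list(df$predictor_calls)
  problems <- character(0)
  for (i in seq_along(calls)) {
    if (!length(calls[[i]]) || any(!calls[[i]] %in% c(0, 1))) {
      problems <- c(problems,
                    sprintf("row %d (%s) - predictor_calls must be >=1 comma-separated 0/1 flags",
                            i, df$symbol[i]))
    }
  }
  fail_rows(problems, "HI predictors")
  df$calls <- lapply(calls, function(x) x == 1)
  structure(list(records = df), class = "predictor_registry")
}

#' @export
print.predictor_registry <- function(x, ...) {
  cat(sprintf("<predictor_registry> %d genes\n", nrow(x$records)))
  invisible(x)
}

#' Write HI predictor calls back to the TSV dialect
#' @param registry A `predictor_registry`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_hi_predictors <- function(registry, path) {
  out <- registry$records[, c("symbol", "predictor_calls"), drop = FALSE]
  write_tsv(out, path)
  invisible(path)
}

# ---- functional elements ---------------------------------------------------

#' Load known functionally important elements
#'
#' Dialect: TSV with columns `chrom`, `start`, `end`, `element_class`.
#'
#' @param path Path to the TSV.
#' @return An `element_registry`.
#' @export
load_functional_elements <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "element_class"),
                         "functional elements")
  if (nrow(df)) {
    df$chrom <- normalize_chrom(df$chrom)
    bad <- which(is.na(df$start) | is.na(df$end) | df$end < df$start)
    fail_rows(sprintf("row %d - malformed interval", bad), "functional elements")
  }
  new_registry(sort_records(df), "element_registry")
}

#' Write functional elements back to the TSV dialect
#' @param registry An `element_registry`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_functional_elements <- function(registry, path) {
  write_tsv(registry$records[, c("chrom", "start", "end", "element_class")], path)
  invisible(path)
}

# ---- queries ----------------------------------------------------------------

#' Transcripts (and their genes) overlapping an interval
#'
#' @param registry A `gene_registry`.
#' @param interval A `genomic_interval`.
#' @return Data frame, one row per overlapping transcript, with `gene_id`,
#'   `symbol`, `biotype`, `transcript_id`, the transcript span, `coverage`
#'   (fraction of the transcript covered by the interval) and `contained`
#'   (is the transcript fully inside the interval), sorted by position.
#' @export
query_overlapping_genes <- function(registry, interval) {
  idx <- registry_hits(registry, interval)
  df <- registry$records[idx, , drop = FALSE]
  if (nrow(df)) {
    ov <- pmin(df$end, interval$end) - pmax(df$start, interval$start) + 1
    df$coverage <- ov / (df$end - df$start + 1)
    df$contained <- interval$start <= df$start & df$end <= interval$end
  } else {
    df$coverage <- numeric(0)
    df$contained <- logical(0)
  }
  rownames(df) <- NULL
  df[, c("gene_id", "symbol", "biotype", "transcript_id", "chrom", "start",
         "end", "cds_side", "exon_starts", "exon_ends", "coverage", "contained")]
}

#' Distinct genes overlapping an interval
#'
#' @param registry A `gene_registry`.
#' @param interval A `genomic_interval`.
#' @param biotype Restrict to one biotype (default `"protein_coding"`); `NULL`
#'   for all.
#' @return Sorted character vector of distinct `gene_id`s.
#' @export
genes_overlapped <- function(registry, interval, biotype = "protein_coding") {
  hits <- query_overlapping_genes(registry, interval)
  if (!is.null(biotype)) hits <- hits[hits$biotype == biotype, , drop = FALSE]
  sort(unique(hits$gene_id))
}

#' Dosage-sensitivity records overlapping an interval
#'
#' @param registry A `dosage_registry`.
#' @param interval A `genomic_interval`.
#' @param min_scores Set of dosage scores that count as "established"
#'   (default 3; widen to `c(1, 2, 3)` to include lower-confidence records).
#' @param score_type `"hi"` for haploinsufficiency (losses) or `"ts"` for
#'   triplosensitivity (gains).
#' @return Data frame of matching records with an `overlap_kind` column:
#'   `"complete"` when the record is fully contained in the interval,
#'   `"partial"` otherwise; sorted by position.
#' @export
query_dosage <- function(registry, interval, min_scores = 3,
                         score_type = c("hi", "ts")) {
  score_type <- match.arg(score_type)
  idx <- registry_hits(registry, interval)
  df <- registry$records[idx, , drop = FALSE]
  score <- if (score_type == "hi") df$hi_score else df$ts_score
  df <- df[!is.na(score) & score %in% min_scores, , drop = FALSE]
  if (nrow(df)) {
    df$overlap_kind <- ifelse(interval$start <= df$start & df$end <= interval$end,
                              "complete", "partial")
  } else {
    df$overlap_kind <- character(0)
  }
  rownames(df) <- NULL
  df
}

#' Benign CNV records overlapping an interval
#'
#' @param registry A `benign_registry` (typically from [build_benign_db()]).
#' @param interval A `genomic_interval`.
#' @param cnv_type Restrict records to one CNV type, or `NULL` (default) to
#'   search both types, as the standard recommends for Section 2F.
#' @return Data frame of overlapping records with a `contains_cnv` flag
#'   (the interval is completely contained in the record); sorted by position.
#' @export
query_benign <- function(registry, interval, cnv_type = NULL) {
  idx <- registry_hits(registry, interval)
  df <- registry$records[idx, , drop = FALSE]
  if (!is.null(cnv_type)) df <- df[df$cnv_type == cnv_type, , drop = FALSE]
  if (nrow(df)) {
    df$contains_cnv <- df$start <= interval$start & interval$end <= df$end
  } else {
    df$contains_cnv <- logical(0)
  }
  rownames(df) <- NULL
  df
}

#' Best-supported population frequency for an interval
#'
#' The interval must be completely contained in a record of the same CNV type
#' for that record to support it (same containment semantics as Section 2F).
#'
#' @param registry A `population_registry`.
#' @param interval A `genomic_interval`.
#' @param cnv_type `"loss"` or `"gain"`.
#' @return The maximum allele frequency over supporting records; 0 when none.
#' @export
query_population_frequency <- function(registry, interval, cnv_type) {
  idx <- registry_hits(registry, interval)
  df <- registry$records[idx, , drop = FALSE]
  df <- df[df$cnv_type == cnv_type &
             df$start <= interval$start & interval$end <= df$end, , drop = FALSE]
  if (!nrow(df)) return(0)
  max(df$allele_frequency)
}

#' Predictor calls for a gene symbol
#'
#' @param registry A `predictor_registry`.
#' @param symbol Gene symbol.
#' @return Logical vector of per-predictor haploinsufficiency calls
#'   (length 0 when the gene is absent).
#' @export
predictor_calls <- function(registry, symbol) {
  i <- match(symbol, registry$records$symbol)
  if (is.na(i)) return(logical(0))
  registry$records$calls[[i]]
}
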