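# Genomic intervals and CNV calls.
#
# All coordinates are 1-based inclusive (the IRanges/Bioconductor convention),
# on disk and in memory, so an interval of length 1 has start == end.
# CNVs are unstranded; no strand is tracked anywhere.

#' Normalize a chromosome name to its "chr"-prefixed form
#'
#' Annotation exports mix dialects ("1" vs "chr1", "X" vs "chrX"); every
#' constructor funnels names through this so that positional comparisons
#' never miss for dialect reasons.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector with a "chr" prefix guaranteed.
#' @examples
#' normalize_chrom(c("1", "chrX", "MT"))
#' @export
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  if (any(is.na(chrom) | chrom == "")) {
    stop("chromosome names must be non-empty", call. = FALSE)
  }
  paste0("chr", sub("^chr", "", chrom))
}

#' Construct a genomic interval
#'
#' @param chrom Chromosome name (any dialect; normalized to "chr"-prefixed).
#' @param start,end 1-based inclusive coordinates; `end >= start >= 1`.
#' @return An object of class `genomic_interval`.
#' @examples
#' genomic_interval("1", 1001, 2000)
#' @export
genomic_interval <- function(chrom, start, end) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) != 1L || length(start) != 1L || length(end) != 1L) {
    stop("genomic_interval is scalar; use data frames for record sets", call. = FALSE)
  }
  if (!is.finite(start) || !is.finite(end)) {
    stop("interval coordinates must be finite", call. = FALSE)
  }
  if (start < 1) stop("start must be >= 1 (coordinates are 1-based)", call. = FALSE)
  if (end < start) {
    stop(sprintf("malformed interval: end (%s) < start (%s)", end, start), call. = FALSE)
  }
  structure(
    list(chrom = normalize_chrom(chrom), start = start, end = end),
    class = "genomic_interval"
  )
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%s-%s (%s bp)\n", x$chrom,
              format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE),
              format(interval_length(x), scientific = FALSE)))
  invisible(x)
}

#' Interval length in bases
#'
#' @param x A `genomic_interval`.
#' @return Integer-valued length (`end - start + 1`).
#' @export
interval_length <- function(x) {
  x$end - x$start + 1
}

#' Length of the intersection of two intervals
#'
#' Zero when the intervals lie on different chromosomes or do not share any
#' base. Adjacent intervals (e.g. 1-1000 and 1001-2000) do not intersect.
#'
#' @param a,b `genomic_interval` objects.
#' @return Non-negative number of shared bases.
#' @examples
#' intersect_length(genomic_interval("chr1", 1001, 2000),
#'                  genomic_interval("chr1", 1501, 3000))
#' @export
intersect_length <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start) + 1)
}

#' Is one interval completely contained in another?
#'
#' Containment is inclusive: an interval contains itself. This is the
#' geometric test behind "completely contained within an established benign
#' CNV region" (Section 2F) and the population-variation option 4O.
#'
#' @param inner,outer `genomic_interval` objects.
#' @return `TRUE` iff `inner` lies fully within `outer` on the same chromosome.
#' @export
is_contained <- function(inner, outer) {
  inner$chrom == outer$chrom &&
    outer$start <= inner$start &&
    inner$end <= outer$end
}

#' Fraction of a target interval covered by a query interval
#'
#' @param target,query `genomic_interval` objects.
#' @return Fraction in \[0, 1\]; exactly 1 iff `target` is contained in `query`.
#' @export
coverage_fraction <- function(target, query) {
  intersect_length(target, query) / interval_length(target)
}

#' Construct a CNV call
#'
#' @param chrom,start,end Location (1-based inclusive).
#' @param cnv_type `"loss"` or `"gain"`; the synonyms `DEL`/`deletion` and
#'   `DUP`/`duplication` are accepted (case-insensitive).
#' @param copy_number Optional integer copy number; must be < 2 for losses and
#'   > 2 for gains when given.
#' @param id Optional identifier.
#' @return An object of class `cnv_call`.
#' @examples
#' cnv_call("chr1", 150000, 2150000, "loss")
#' @export
cnv_call <- function(chrom, start, end, cnv_type, copy_number = NA, id = NA_character_) {
  interval <- genomic_interval(chrom, start, end)
  cnv_type <- normalize_cnv_type(cnv_type)
  if (!is.na(copy_number)) {
    copy_number <- as.integer(copy_number)
    ok <- (cnv_type == "loss" && copy_number < 2) ||
      (cnv_type == "gain" && copy_number > 2)
    if (!ok) {
      stop(sprintf("copy number %d inconsistent with cnv_type '%s'",
                   copy_number, cnv_type), call. = FALSE)
    }
  }
  structure(
    list(interval = interval, cnv_type = cnv_type,
         copy_number = copy_number, id = as.character(id)),
    class = "cnv_call"
  )
}

#' @export
print.cnv_call <- function(x, ...) {
  cat(sprintf("CNV %s: %s:%s-%s %s%s\n",
              ifelse(is.na(x$id), "(unnamed)", x$id),
              x$interval$chrom,
              format(x$interval$start, scientific = FALSE),
              format(x$interval$end, scientific = FALSE),
              x$cnv_type,
              ifelse(is.na(x$copy_number), "",
                     sprintf(" (copy number %d)", x$copy_number))))
  invisible(x)
}

#' Normalize a CNV type token
#'
#' @param x Token such as "loss", "DEL", "deletion", "gain", "DUP", "duplication".
#' @return `"loss"` or `"gain"`.
#' @export
normalize_cnv_type <- function(x) {
  tok <- tolower(as.character(x))
  out <- ifelse(tok %in% c("loss", "del", "deletion"), "loss",
                ifelse(tok %in% c("gain", "dup", "duplication"), "gain", NA_character_))
  if (any(is.na(out))) {
    stop(sprintf("unrecognized CNV type token(s): %s",
                 paste(unique(x[is.na(out)]), collapse = ", ")), call. = FALSE)
  }
  out
}

#' Parse a CNV region string
#'
#' Accepts the compact form used at the command line, e.g.
#' `"chr1:150000-2150000"`.
#'
#' @param x A single region string.
#' @return A list with `chrom`, `start`, `end`.
#' @export
parse_region <- function(x) {
  m <- regmatches(x, regexec("^([A-Za-z0-9_]+):([0-9,]+)-([0-9,]+)$", x))[[1]]
  if (length(m) != 4L) {
    stop(sprintf("cannot parse region token '%s' (expected chrom:start-end)", x),
         call. = FALSE)
  }
  list(chrom = normalize_chrom(m[2]),
       start = as.numeric(gsub(",", "", m[3])),
       end = as.numeric(gsub(",", "", m[4])))
}
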