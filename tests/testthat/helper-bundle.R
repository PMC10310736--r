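# Shared synthetic bundle used across test files (built once per run).
shared_spec <- fixture_spec(seed = 7)
shared_bundle <- generate_annotation_bundle(shared_spec)
shared_sets <- generate_cnv_sets(shared_spec, shared_bundle)
shared_regs <- scoring_registries(shared_bundle)
shared_table <- default_scoring_table()

# Random query CNVs over the toy genome (not planted; exercise every rule).
random_cnvs <- function(n, seed, min_len = 1e3, max_len = 5e6, L = 1e7) {
  set.seed(seed)
  len <- floor(runif(n, min_len, max_len))
  start <- floor(runif(n, 1, L - len))
  data.frame(
    id = sprintf("q%04d", seq_len(n)),
    chrom = sample(c("chr1", "chr2", "chr3"), n, replace = TRUE),
    start = start, end = start + len - 1,
    cnv_type = sample(c("loss", "gain"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Tiny in-memory registries for unit tests, built from plain data frames
# through the on-disk dialect so the loaders are exercised too.
mk_gene_registry <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  load_gene_models(path)
}

mk_simple_gene_df <- function(gene_id, symbol, chrom, start, end,
                              biotype = "protein_coding", cds_side = "left") {
  data.frame(gene_id = gene_id, symbol = symbol, biotype = biotype,
             transcript_id = paste0(gene_id, ".t1"), chrom = chrom,
             start = start, end = end,
             exon_starts = as.character(start), exon_ends = as.character(end),
             cds_side = cds_side, stringsAsFactors = FALSE)
}

mk_dosage_registry <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  load_dosage_records(path)
}

mk_benign_registry <- function(df, ...) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  build_benign_db(load_benign_cnvs(path), ...)
}

mk_population_registry <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  load_population_variants(path)
}

mk_predictor_registry <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  load_hi_predictors(path)
}

empty_benign <- function() {
  suppressWarnings(mk_benign_registry(data.frame(chrom = character(), start = numeric(),
                                end = numeric(), cnv_type = character(),
                                frequency = numeric(),
                                coordinate_flavor = character(),
                                source = character())))
}

empty_population <- function() {
  suppressWarnings(mk_population_registry(data.frame(chrom = character(), start = numeric(),
                                    end = numeric(), cnv_type = character(),
                                    allele_frequency = numeric())))
}

empty_dosage <- function() {
  suppressWarnings(mk_dosage_registry(data.frame(symbol = character(), target_kind = character(),
                                chrom = character(), start = numeric(),
                                end = numeric(), hi_score = numeric(),
                                ts_score = numeric())))
}
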