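example_file <- function(name) {
  system.file("extdata", "example", name, package = "cnvscore")
}

test_that("gene loader reads the shipped example and enforces invariants", {
  reg <- load_gene_models(example_file("genes.tsv"))
  expect_s3_class(reg, "gene_registry")
  expect_equal(length(unique(reg$records$gene_id)), 3)
  expect_equal(nrow(reg$records), 4)  # transcript-level rows

  bad <- read.delim(example_file("genes.tsv"), stringsAsFactors = FALSE)
  bad$exon_ends[1] <- "110000,125000,150000"  # exon beyond transcript span
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_gene_models(path), "g0001.t1")

  expect_error(load_gene_models(withr::local_tempfile(lines = "x")), "mandatory column")

  hdr <- paste(c("gene_id", "symbol", "biotype", "transcript_id", "chrom",
                 "start", "end", "exon_starts", "exon_ends", "cds_side"),
               collapse = "\t")
  empty <- withr::local_tempfile(lines = hdr)
  expect_warning(reg0 <- load_gene_models(empty), "empty")
  expect_equal(registry_size(reg0), 0)
})

test_that("dosage loader keeps valid scores and rejects scoreless records", {
  reg <- load_dosage_records(example_file("dosage.tsv"))
  expect_equal(registry_size(reg), 4)
  expect_setequal(stats::na.omit(reg$records$hi_score), c(3, 2, 40))

  df <- reg$records[, c("symbol", "target_kind", "chrom", "start", "end",
                        "hi_score", "ts_score")]
  df$hi_score[1] <- NA
  df$ts_score[1] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_dosage_records(path), "neither HI nor TS")

  df <- reg$records[, c("symbol", "target_kind", "chrom", "start", "end",
                        "hi_score", "ts_score")]
  df$hi_score[2] <- 7
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_dosage_records(path), "0,1,2,3,30,40")
})

test_that("population and benign loaders reject out-of-range frequencies", {
  pop <- read.delim(example_file("population.tsv"), stringsAsFactors = FALSE)
  pop$allele_frequency[1] <- 1.5
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(pop, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_population_variants(path), "\\[0, 1\\]")

  ben <- read.delim(example_file("benign.tsv"), stringsAsFactors = FALSE)
  ben$coordinate_flavor[2] <- "middle"
  write.table(ben, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_benign_cnvs(path), "flavor")
})

test_that("benign database filtering applies threshold, flavor and type", {
  df <- data.frame(
    chrom = "chr1", start = c(1e5, 2e5, 3e5, 4e5), end = c(1.5e5, 2.5e5, 3.5e5, 4.5e5),
    cnv_type = c("loss", "loss", "gain", "loss"),
    frequency = c(0.001, 0.02, 0.004, 0.02),
    coordinate_flavor = c("plain", "plain", "plain", "outer"),
    source = c("DGV", "DGV", "DGV", "DGV_GOLD"), stringsAsFactors = FALSE
  )
  expect_equal(registry_size(mk_benign_registry(df, maf_threshold = 0.005)), 1)
  expect_equal(registry_size(mk_benign_registry(df)), 3)  # all plain records
  expect_equal(registry_size(mk_benign_registry(df, type_filter = "losses_only")), 2)
  expect_equal(registry_size(mk_benign_registry(df, flavor = "outer", source = "DGV_GOLD")), 1)
  expect_error(mk_benign_registry(df, maf_threshold = 1.5), "fraction")
  expect_error(build_benign_db(df, flavor = "middle"), "arg")
})

test_that("raising the frequency threshold never adds benign records", {
  pool <- shared_bundle$registries$benign
  sizes <- vapply(c(NA, 0.0001, 0.001, 0.005, 0.01, 0.02, 0.10), function(th) {
    registry_size(build_benign_db(pool, maf_threshold = if (is.na(th)) NULL else th,
                                  flavor = "outer", source = "DGV_GOLD"))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("registry queries match the linear-scan oracle on the seed-7 bundle", {
  regs <- shared_regs
  raw <- shared_bundle$registries
  set.seed(7)
  for (k in 1:20) {
    chrom <- sample(c("chr1", "chr2", "chr3"), 1)
    s <- sample(9e6, 1)
    e <- s + sample(2e6, 1)
    iv <- genomic_interval(chrom, s, e)
    ty <- sample(c("loss", "gain"), 1)

    # genes
    expect_identical(genes_overlapped(regs$genes, iv), o_gene_ids(raw$genes$records, chrom, s, e))

    # dosage
    got <- query_dosage(regs$dosage, iv, min_scores = c(1, 2, 3), "hi")
    dos <- raw$dosage$records
    exp_idx <- which(!is.na(dos$hi_score) & dos$hi_score %in% c(1, 2, 3) &
                       vapply(seq_len(nrow(dos)), function(i)
                         o_overlaps(dos$chrom[i], dos$start[i], dos$end[i], chrom, s, e),
                         logical(1)))
    expect_setequal(got$symbol, dos$symbol[exp_idx])
    if (nrow(got)) {
      expect_identical(got$overlap_kind,
                       ifelse(s <= got$start & got$end <= e, "complete", "partial"))
    }

    # benign (filtered default registry)
    got <- query_benign(regs$benign, iv)
    ben <- regs$benign$records
    exp_n <- sum(vapply(seq_len(nrow(ben)), function(i)
      o_overlaps(ben$chrom[i], ben$start[i], ben$end[i], chrom, s, e), logical(1)))
    expect_equal(nrow(got), exp_n)
    if (nrow(got)) expect_identical(got$contains_cnv, got$start <= s & e <= got$end)

    # population frequency
    pop <- raw$population$records
    afs <- vapply(seq_len(nrow(pop)), function(i) {
      if (pop$cnv_type[i] == ty &&
          o_inside(chrom, s, e, pop$chrom[i], pop$start[i], pop$end[i])) {
        pop$allele_frequency[i]
      } else 0
    }, numeric(1))
    expect_equal(query_population_frequency(regs$population, iv, ty), max(c(0, afs)))
  }
})

test_that("query results are position-sorted and deterministic", {
  iv <- genomic_interval("chr2", 1, 1e7)
  a <- query_benign(shared_regs$benign, iv)
  b <- query_benign(shared_regs$benign, iv)
  expect_identical(a, b)
  expect_true(!is.unsorted(a$start))
})

test_that("registries round-trip through their file dialects", {
  dir <- withr::local_tempdir()
  reloaded <- local({
    generate_annotation_bundle(shared_spec, dir = dir)
    load_annotation_bundle(dir)
  })
  raw <- shared_bundle$registries
  expect_equal(reloaded$genes$records$exon_starts, raw$genes$records$exon_starts)
  expect_equal(reloaded$genes$records$transcript_id, raw$genes$records$transcript_id)
  expect_equal(reloaded$dosage$records, raw$dosage$records)
  expect_equal(reloaded$benign$records, raw$benign$records)
  expect_equal(reloaded$population$records, raw$population$records)
  expect_equal(reloaded$predictors$records$predictor_calls,
               raw$predictors$records$predictor_calls)
})
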