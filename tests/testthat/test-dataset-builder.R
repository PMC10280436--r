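test_that("window extraction follows the 1-based inclusive coordinate convention", {
  # toy chromosome of all A: defaults span reference positions 300..1302
  asm_a <- Biostrings::DNAStringSet(c(chrA = paste(rep("A", 2000), collapse = "")))
  w <- extract_window(asm_a, "chrA", 1000, "+", window_params())
  expect_equal(nchar(w), 1003)

  # hand-enumerated 8-mer examples
  asm <- Biostrings::DNAStringSet(c(chrX = "ACGTACGT"))
  p <- window_params(2, 1)
  expect_equal(extract_window(asm, "chrX", 4, "+", p), "CGTACG")
  expect_equal(extract_window(asm, "chrX", 4, "-", p), "GTACGT")
})

test_that("window position of the TSS base and boundary errors behave as specified", {
  asm <- Biostrings::DNAStringSet(c(c1 = paste(rep(c("A", "C"), 1000), collapse = "")))
  p <- window_params(10, 5)
  w <- extract_window(asm, "c1", 101, "+", p)
  expect_equal(nchar(w), 18)
  # TSS base sits at window position upstream + 1
  expect_equal(substr(w, 11, 11), "A")  # position 101 is odd -> "A"

  expect_error(extract_window(asm, "c1", 5, "+", p), class = "tss_boundary_error")
  expect_error(extract_window(asm, "c1", 1999, "+", p), class = "tss_boundary_error")
  expect_error(extract_window(asm, "nope", 100, "+", p), class = "tss_lookup_error")
})

test_that("ambiguous bases raise a distinct condition for the caller to handle", {
  asm <- Biostrings::DNAStringSet(c(c1 = "ACGTNACGTACGTACGT"))
  expect_error(extract_window(asm, "c1", 5, "+", window_params(2, 1)),
               class = "tss_ambiguity")
  # a span clear of the N is fine
  expect_silent(extract_window(asm, "c1", 10, "+", window_params(2, 1)))
})

test_that("opposite strands give reverse-complement windows when flanks are symmetric", {
  fx <- small_fixture()
  p <- window_params(20, 17)  # symmetric about the codon: 20 + 3 + 17
  revcomp <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  for (pos in c(5000, 12345, 30000)) {
    plus <- extract_window(fx$assembly, "1", pos, "+", p)
    minus <- extract_window(fx$assembly, "1", pos - 1, "-", p)
    # anchors pos and pos-1 cover the same reference span [pos-20, pos+19]:
    # plus reads it forward, minus reads it reverse-complemented
    expect_equal(minus, revcomp(plus))
  }
})

test_that("negative anchors avoid every TSS and respect the requested count", {
  fx <- small_fixture()
  ann <- fx$annotation
  rec <- ann[1, ]
  tss_here <- ann$tss[ann$chromosome == rec$chromosome]
  anchors <- sample_negative_anchors(rec, tss_here, n = 10,
                                     params = window_params(70, 30),
                                     assembly = fx$assembly, seed = 3)
  expect_length(anchors, 10)
  expect_equal(anyDuplicated(anchors), 0)
  expect_false(any(anchors %in% tss_here))
  expect_true(all(anchors >= rec$transcript_start & anchors <= rec$transcript_end))

  # degenerate span: fewer eligible positions than requested
  tiny <- rec
  tiny$transcript_start <- rec$tss
  tiny$transcript_end <- rec$tss + 4
  expect_warning(
    few <- sample_negative_anchors(tiny, tss_here, n = 10,
                                   params = window_params(70, 30),
                                   assembly = fx$assembly, seed = 3),
    "eligible")
  expect_length(few, 4)  # 5 span positions minus the TSS itself
})

test_that("negative anchor sampling is uniform over the eligible set", {
  fx <- small_fixture()
  rec <- fx$annotation[1, ]
  rec$transcript_start <- rec$tss
  rec$transcript_end <- rec$tss + 20
  tss_here <- rec$tss
  eligible <- (rec$tss + 1):(rec$tss + 20)
  counts <- stats::setNames(rep(0, 20), eligible)
  n_draws <- 4000
  for (s in seq_len(n_draws)) {
    a <- sample_negative_anchors(rec, tss_here, n = 5,
                                 params = window_params(70, 30),
                                 assembly = fx$assembly, seed = s)
    counts[as.character(a)] <- counts[as.character(a)] + 1
  }
  # each position included with probability 5/20 per draw
  p <- 5 / 20
  se <- sqrt(p * (1 - p) * n_draws)
  expect_true(all(abs(counts - n_draws * p) < 3 * se))
})

test_that("dataset construction delivers the requested ratio and window geometry", {
  ds <- small_dataset()  # 20 transcripts, ratio 10
  expect_equal(sum(ds$instances$label == "positive"), 20)
  expect_equal(sum(ds$instances$label == "negative"), 200)
  expect_equal(negative_ratio(ds), 10)
  expect_true(all(nchar(ds$instances$sequence) == 103))

  # the 1:1 arm
  ds1 <- small_dataset(n_neg = 1)
  expect_equal(negative_ratio(ds1), 1)

  # default parameters give 1,003-base windows (checked on a small slice)
  fx <- small_fixture()
  ds_full <- build_dataset(fx$assembly, fx$annotation[1:3, ], window_params(),
                           n_negatives_per_positive = 2, seed = 1)
  expect_true(all(nchar(ds_full$instances$sequence) == 1003))
  expect_error(build_dataset(fx$assembly, fx$annotation[0, ], window_params()),
               "empty")
})

test_that("positives carry the planted motif at window position upstream+1", {
  ds <- small_dataset()
  pos <- ds$instances[ds$instances$label == "positive", ]
  at_motif <- substr(pos$sequence, 71, 80)
  # per-base retention (1 - noise + noise/4) = 0.9625 -> intact 10-mer w.p. ~0.68
  expect_gt(mean(at_motif == "TATAAAGGCC"), 0.4)
  neg <- ds$instances[ds$instances$label == "negative", ]
  expect_lt(mean(substr(neg$sequence, 71, 80) == "TATAAAGGCC"), 0.1)
  # no negative anchors on any annotated TSS
  fx <- small_fixture()
  for (chrom in unique(neg$chromosome)) {
    expect_false(any(neg$anchor[neg$chromosome == chrom] %in%
                       fx$annotation$tss[fx$annotation$chromosome == chrom]))
  }
})

test_that("chromosome splits are exhaustive, exclusive and conserve instances", {
  ds <- small_dataset()
  # fixture has chromosomes 1 and 2; defaults put 1 in test, rest in train
  sp <- split_by_chromosome(ds)
  expect_equal(nrow(sp$test$instances) + nrow(sp$train$instances) +
                 nrow(sp$validation$instances), nrow(ds$instances))
  expect_setequal(unique(sp$test$instances$chromosome), "1")
  expect_setequal(unique(sp$train$instances$chromosome), "2")
  expect_equal(nrow(sp$validation$instances), 0)

  sp2 <- split_by_chromosome(ds, validation_chromosomes = "2",
                             test_chromosomes = character(0))
  expect_equal(nrow(sp2$test$instances), 0)
  expect_setequal(unique(sp2$validation$instances$chromosome), "2")

  expect_error(split_by_chromosome(ds, "1", c("1", "2")), "overlap")
})

test_that("undersampling the majority class hits the target ratio deterministically", {
  ds <- small_dataset()
  u <- undersample_majority(ds, 1.0, seed = 5)
  expect_equal(sum(u$instances$label == "positive"), 20)
  expect_equal(sum(u$instances$label == "negative"), 20)
  # idempotent at the current ratio
  same <- undersample_majority(ds, 10, seed = 5)
  expect_identical(same$instances, ds$instances)
  # deterministic given seed
  u2 <- undersample_majority(ds, 1.0, seed = 5)
  expect_identical(u$instances, u2$instances)
  u3 <- undersample_majority(ds, 1.0, seed = 6)
  expect_false(identical(u$instances, u3$instances))
  expect_error(undersample_majority(ds, 0.01, seed = 1), "zero negatives")
})

test_that("datasets round-trip losslessly through CSV plus manifest", {
  ds <- small_dataset()
  path <- tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back$instances, ds$instances)
  expect_equal(back$params$window_length, ds$params$window_length)
  expect_equal(back$provenance$n_positive, ds$provenance$n_positive)

  # corrupt one sequence -> parse error naming the line
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$sequence[3] <- substr(tab$sequence[3], 1, 50)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  expect_error(read_dataset(path), "line 4")

  # empty dataset still round-trips
  empty <- ds
  empty$instances <- ds$instances[0, ]
  path2 <- tempfile(fileext = ".csv")
  write_dataset(empty, path2)
  expect_equal(nrow(read_dataset(path2)$instances), 0)
})

test_that("BioMart-style exports are parsed with null filtering and strand normalization", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "transcript_id\tchromosome\tstrand\ttranscript_start\ttranscript_end\ttss\tgene_name",
    "T1\t1\t1\t100\t500\t100\tfoo",
    "T2\t1\t-1\t600\t900\t900\tbar",
    "T3\t2\t1\t100\t400\tNA\tbaz",
    "T4\t2\t-1\t200\t800\t800\tqux",
    "T5\t2\t1\t\t900\t300\tquux"
  ), path)
  parsed <- read_biomart_export(path)
  expect_equal(parsed$n_dropped, 2)  # null tss and null start
  expect_equal(parsed$annotation$transcript_id, c("T1", "T2", "T4"))
  expect_equal(parsed$annotation$strand, c("+", "-", "-"))

  # missing mapped column -> schema error naming it
  expect_error(read_biomart_export(path, column_map = c(
    transcript_id = "transcript_id", chromosome = "chromosome",
    strand = "strand", transcript_start = "transcript_start",
    transcript_end = "transcript_end", tss = "tss_position")),
    "tss_position")

  # header-only file -> empty annotation with a warning
  path2 <- tempfile(fileext = ".tsv")
  writeLines("transcript_id\tchromosome\tstrand\ttranscript_start\ttranscript_end\ttss",
             path2)
  expect_warning(empty <- read_biomart_export(path2), "no rows")
  expect_equal(nrow(empty$annotation), 0)
})
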