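#' Window geometry parameters
#'
#' A labeled instance is a fixed window around an anchor base: the anchor and
#' the two following bases (in transcript orientation) form the TSS codon,
#' with `upstream_flank` bases before it and `downstream_flank` bases after
#' it. The defaults (700 upstream, 300 downstream) give the 1,003-base
#' windows used throughout.
#'
#' @param upstream_flank Bases before the TSS codon (default 700).
#' @param downstream_flank Bases after the codon (default 300).
#' @return A list of class `window_params` with `upstream_flank`,
#'   `codon_length` (fixed at 3), `downstream_flank` and `window_length`.
#' @export
window_params <- function(upstream_flank = 700L, downstream_flank = 300L) {
  up <- as.integer(upstream_flank)
  down <- as.integer(downstream_flank)
  if (up < 0L || down < 0L) stop("flanks must be non-negative", call. = FALSE)
  structure(list(upstream_flank = up, codon_length = 3L,
                 downstream_flank = down,
                 window_length = up + 3L + down),
            class = "window_params")
}

# Reference-coordinate span of the window anchored at `anchor` on `strand`.
# On "+" the transcript reads left-to-right: span = [anchor - up, anchor + 2 + down].
# On "-" it reads right-to-left: span = [anchor - 2 - down, anchor + up],
# reported 5'->3' on the transcript strand via reverse complement.
window_span <- function(anchor, strand, params) {
  if (strand == "+") {
    c(anchor - params$upstream_flank, anchor + 2L + params$downstream_flank)
  } else {
    c(anchor - 2L - params$downstream_flank, anchor + params$upstream_flank)
  }
}

#' Extract a strand-aware sequence window around an anchor
#'
#' Returns the window 5'->3' on the transcript strand; reading it that way,
#' the anchor (TSS) base sits at window position `upstream_flank + 1` and the
#' TSS codon occupies the three positions starting there. Minus-strand
#' windows are the reverse complement of the corresponding reference span.
#'
#' @param assembly Named [Biostrings::DNAStringSet] (chromosome -> sequence).
#' @param chromosome Chromosome name.
#' @param tss 1-based anchor coordinate on the reference.
#' @param strand `"+"` or `"-"`.
#' @param params A [window_params()].
#' @return Character string of length `params$window_length`. Signals a
#'   condition of class `tss_boundary_error` when the window leaves the
#'   chromosome, `tss_lookup_error` for an unknown chromosome, and
#'   `tss_ambiguity` when the span contains a base outside A,C,G,T (callers
#'   choose the drop policy).
#' @export
extract_window <- function(assembly, chromosome, tss, strand, params = window_params()) {
  if (!chromosome %in% names(assembly)) {
    stop(structure(class = c("tss_lookup_error", "error", "condition"),
                   list(message = sprintf("unknown chromosome '%s'", chromosome),
                        call = NULL)))
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  chrom <- assembly[[chromosome]]
  span <- window_span(as.integer(tss), strand, params)
  if (span[1L] < 1L || span[2L] > length(chrom)) {
    stop(structure(class = c("tss_boundary_error", "error", "condition"),
                   list(message = sprintf(
                     "window [%d, %d] for anchor %d (%s strand) leaves chromosome '%s' (length %d)",
                     span[1L], span[2L], tss, strand, chromosome, length(chrom)),
                     call = NULL)))
  }
  seq <- Biostrings::subseq(chrom, start = span[1L], end = span[2L])
  if (strand == "-") seq <- Biostrings::reverseComplement(seq)
  s <- as.character(seq)
  if (grepl("[^ACGT]", s)) {
    stop(structure(class = c("tss_ambiguity", "error", "condition"),
                   list(message = sprintf(
                     "window at %s:%d (%s) contains a base outside A,C,G,T",
                     chromosome, tss, strand), call = NULL)))
  }
  s
}

#' Sample negative anchor positions inside a transcript
#'
#' Candidate anchors are the positions within `[transcript_start,
#' transcript_end]` that are not an annotated TSS on the chromosome and that
#' admit a full window on the transcript's strand. `n` anchors are drawn
#' uniformly without replacement; when fewer than `n` positions are eligible
#' all of them are returned with a warning.
#'
#' @param record One annotation row (list or single-row data.frame with
#'   `chromosome`, `strand`, `transcript_start`, `transcript_end`).
#' @param all_tss_on_chromosome Integer vector of annotated TSS coordinates
#'   on the record's chromosome (excluded exactly; radius 0 by default).
#' @param n Number of anchors requested.
#' @param params A [window_params()].
#' @param assembly The genome (used for chromosome bounds).
#' @param seed Optional integer; when given, `set.seed(seed)` is applied so
#'   the draw is reproducible in isolation.
#' @param exclusion_radius Non-negative integer; positions within this
#'   distance of any TSS are also excluded (default 0).
#' @return Integer vector of anchor coordinates (possibly empty).
#' @export
sample_negative_anchors <- function(record, all_tss_on_chromosome, n, params,
                                    assembly, seed = NULL, exclusion_radius = 0L) {
  if (n < 1L) stop("n must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  chrom_len <- length(assembly[[record$chromosome]])
  lo <- max(record$transcript_start,
            if (record$strand == "+") params$upstream_flank + 1L
            else 3L + params$downstream_flank)
  hi <- min(record$transcript_end,
            if (record$strand == "+") chrom_len - 2L - params$downstream_flank
            else chrom_len - params$upstream_flank)
  if (hi < lo) {
    warning("no eligible negative anchor positions in transcript ",
            record$transcript_id, call. = FALSE)
    return(integer(0))
  }
  eligible <- lo:hi
  if (length(all_tss_on_chromosome) > 0L) {
    if (exclusion_radius > 0L) {
      banned <- unique(unlist(lapply(all_tss_on_chromosome, function(t) {
        (t - exclusion_radius):(t + exclusion_radius)
      })))
      eligible <- setdiff(eligible, banned)
    } else {
      eligible <- setdiff(eligible, all_tss_on_chromosome)
    }
  }
  if (length(eligible) == 0L) {
    warning("no eligible negative anchor positions in transcript ",
            record$transcript_id, call. = FALSE)
    return(integer(0))
  }
  if (length(eligible) < n) {
    warning(sprintf("transcript %s: only %d eligible positions for %d requested negatives",
                    record$transcript_id, length(eligible), n), call. = FALSE)
    return(sample(eligible))
  }
  sample(eligible, n)
}

new_tss_dataset <- function(instances, params, provenance) {
  structure(list(instances = instances, params = params, provenance = provenance),
            class = "tss_dataset")
}

#' @export
print.tss_dataset <- function(x, ...) {
  n_pos <- sum(x$instances$label == "positive")
  n_neg <- sum(x$instances$label == "negative")
  cat(sprintf("tss_dataset: %d instances (%d positive, %d negative), window length %d\n",
              nrow(x$instances), n_pos, n_neg, x$params$window_length))
  invisible(x)
}

#' Number of negatives per positive in a dataset
#' @param dataset A `tss_dataset`.
#' @return Achieved ratio `n_negative / n_positive`.
#' @export
negative_ratio <- function(dataset) {
  n_pos <- sum(dataset$instances$label == "positive")
  if (n_pos == 0L) return(NA_real_)
  sum(dataset$instances$label == "negative") / n_pos
}

#' Binary labels of a dataset
#' @param dataset A `tss_dataset`.
#' @return Integer vector, 1 = positive.
#' @export
dataset_labels <- function(dataset) as.integer(dataset$instances$label == "positive")

#' Build a labeled window dataset from a genome and annotation
#'
#' One positive instance is extracted per annotation record (anchored exactly
#' on its TSS), and `n_negatives_per_positive` negative anchors are sampled
#' inside each transcript's genomic span. Windows containing a base outside
#' A,C,G,T, or whose span leaves the chromosome, are dropped and counted in
#' the provenance.
#'
#' @param assembly Named [Biostrings::DNAStringSet].
#' @param annotation Annotation data.frame (see [generate_fixture()]).
#' @param params A [window_params()].
#' @param n_negatives_per_positive Negatives attempted per positive
#'   (default 10, the ratio observed to work best for TSS data).
#' @param seed Integer seed for the negative sampling.
#' @param dedup_positives Drop duplicate positives sharing (chromosome,
#'   strand, tss)? Default `FALSE` (one instance per transcript).
#' @return A `tss_dataset`.
#' @export
build_dataset <- function(assembly, annotation, params = window_params(),
                          n_negatives_per_positive = 10L, seed = 1L,
                          dedup_positives = FALSE) {
  if (is.null(annotation) || nrow(annotation) == 0L) {
    stop("annotation is empty: nothing to build", call. = FALSE)
  }
  set.seed(seed)
  if (dedup_positives) {
    key <- paste(annotation$chromosome, annotation$strand, annotation$tss)
    annotation <- annotation[!duplicated(key), , drop = FALSE]
  }
  tss_by_chrom <- split(annotation$tss, annotation$chromosome)
  rows <- vector("list", nrow(annotation) * (1L + n_negatives_per_positive))
  r <- 0L
  dropped_boundary <- 0L
  dropped_ambiguous <- 0L
  for (i in seq_len(nrow(annotation))) {
    rec <- annotation[i, ]
    pos_seq <- tryCatch(
      extract_window(assembly, rec$chromosome, rec$tss, rec$strand, params),
      tss_boundary_error = function(e) { dropped_boundary <<- dropped_boundary + 1L; NULL },
      tss_ambiguity = function(e) { dropped_ambiguous <<- dropped_ambiguous + 1L; NULL }
    )
    if (!is.null(pos_seq)) {
      r <- r + 1L
      rows[[r]] <- data.frame(sequence = pos_seq, label = "positive",
                              chromosome = rec$chromosome, anchor = rec$tss,
                              strand = rec$strand, transcript_id = rec$transcript_id,
                              stringsAsFactors = FALSE)
    }
    anchors <- sample_negative_anchors(rec, tss_by_chrom[[rec$chromosome]],
                                       n = n_negatives_per_positive,
                                       params = params, assembly = assembly)
    for (a in anchors) {
      neg_seq <- tryCatch(
        extract_window(assembly, rec$chromosome, a, rec$strand, params),
        tss_boundary_error = function(e) { dropped_boundary <<- dropped_boundary + 1L; NULL },
        tss_ambiguity = function(e) { dropped_ambiguous <<- dropped_ambiguous + 1L; NULL }
      )
      if (!is.null(neg_seq)) {
        r <- r + 1L
        rows[[r]] <- data.frame(sequence = neg_seq, label = "negative",
                                chromosome = rec$chromosome, anchor = a,
                                strand = rec$strand, transcript_id = rec$transcript_id,
                                stringsAsFactors = FALSE)
      }
    }
  }
  instances <- do.call(rbind, rows[seq_len(r)])
  rownames(instances) <- NULL
  n_pos <- sum(instances$label == "positive")
  n_neg <- sum(instances$label == "negative")
  new_tss_dataset(
    instances, params,
    provenance = list(
      source = "build_dataset", seed = seed,
      n_negatives_per_positive = as.integer(n_negatives_per_positive),
      n_positive = n_pos, n_negative = n_neg,
      negative_ratio = if (n_pos > 0L) n_neg / n_pos else NA_real_,
      dropped_boundary = dropped_boundary,
      dropped_ambiguous = dropped_ambiguous,
      params = unclass(params)
    )
  )
}

#' Split a dataset by chromosome
#'
#' Chromosome-holdout splitting prevents positional leakage between
#' partitions: every instance is assigned to validation, test or train by
#' its chromosome alone. Defaults follow the human-genome protocol
#' (chromosome 16 for validation; 1, 3, 13, 19, 21 for test; everything
#' else trains).
#'
#' @param dataset A `tss_dataset`.
#' @param validation_chromosomes Character vector of chromosome names.
#' @param test_chromosomes Character vector, disjoint from the validation set.
#' @return A list of class `tss_split` with `train`, `validation`, `test`
#'   (`tss_dataset`s) and the two chromosome sets.
#' @export
split_by_chromosome <- function(dataset,
                                validation_chromosomes = c("16"),
                                test_chromosomes = c("1", "3", "13", "19", "21")) {
  validation_chromosomes <- as.character(validation_chromosomes)
  test_chromosomes <- as.character(test_chromosomes)
  if (length(intersect(validation_chromosomes, test_chromosomes)) > 0L) {
    stop("validation and test chromosome sets overlap", call. = FALSE)
  }
  chrom <- dataset$instances$chromosome
  part <- ifelse(chrom %in% validation_chromosomes, "validation",
                 ifelse(chrom %in% test_chromosomes, "test", "train"))
  subset_ds <- function(which_part) {
    inst <- dataset$instances[part == which_part, , drop = FALSE]
    rownames(inst) <- NULL
    prov <- dataset$provenance
    prov$partition <- which_part
    new_tss_dataset(inst, dataset$params, prov)
  }
  structure(list(train = subset_ds("train"),
                 validation = subset_ds("validation"),
                 test = subset_ds("test"),
                 validation_chromosomes = validation_chromosomes,
                 test_chromosomes = test_chromosomes),
            class = "tss_split")
}

#' @export
print.tss_split <- function(x, ...) {
  cat(sprintf("tss_split: train %d / validation %d / test %d instances\n",
              nrow(x$train$instances), nrow(x$validation$instances),
              nrow(x$test$instances)))
  invisible(x)
}

#' Undersample the majority (negative) class
#'
#' Subsamples negatives uniformly without replacement down to
#' `floor(target_ratio * n_positive)`; positives are untouched. This is the
#' 1:1 training arm of the class-ratio experiment; test sets are never
#' resampled.
#'
#' @param dataset A `tss_dataset` containing both classes.
#' @param target_ratio Negatives kept per positive (default 1.0).
#' @param seed Integer seed.
#' @return A `tss_dataset`.
#' @export
undersample_majority <- function(dataset, target_ratio = 1.0, seed = 1L) {
  is_pos <- dataset$instances$label == "positive"
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) stop("dataset must contain both classes", call. = FALSE)
  n_keep <- floor(target_ratio * n_pos)
  if (n_keep < 1L) stop("target_ratio would keep zero negatives", call. = FALSE)
  if (n_keep >= n_neg) return(dataset)
  set.seed(seed)
  neg_idx <- which(!is_pos)
  keep <- sort(sample(neg_idx, n_keep))
  inst <- dataset$instances[sort(c(which(is_pos), keep)), , drop = FALSE]
  rownames(inst) <- NULL
  prov <- dataset$provenance
  prov$undersampled_to_ratio <- target_ratio
  prov$undersample_seed <- seed
  new_tss_dataset(inst, dataset$params, prov)
}

#' Write / read a labeled dataset
#'
#' CSV with columns `sequence,label,chromosome,anchor,strand,transcript_id`
#' plus a sidecar JSON manifest (`<path minus extension>.json`) carrying the
#' window parameters, seed and class counts; the round trip is lossless.
#'
#' @param dataset A `tss_dataset`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(dataset$instances, path, row.names = FALSE, quote = FALSE)
  manifest <- list(params = unclass(dataset$params),
                   provenance = dataset$provenance,
                   n_instances = nrow(dataset$instances))
  jsonlite::write_json(manifest, dataset_manifest_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

dataset_manifest_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path, call. = FALSE)
  inst <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(sequence = "character", label = "character",
                                         chromosome = "character", anchor = "integer",
                                         strand = "character", transcript_id = "character"))
  manifest_path <- dataset_manifest_path(path)
  if (file.exists(manifest_path)) {
    manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    params <- do.call(window_params, manifest$params[c("upstream_flank", "downstream_flank")])
    provenance <- manifest$provenance
  } else {
    up <- if (nrow(inst) > 0L) nchar(inst$sequence[1L]) - 3L else 0L
    params <- window_params(upstream_flank = max(up, 0L), downstream_flank = 0L)
    params$window_length <- if (nrow(inst) > 0L) nchar(inst$sequence[1L]) else 0L
    provenance <- list(source = path)
  }
  if (nrow(inst) > 0L) {
    bad <- which(nchar(inst$sequence) != params$window_length)
    if (length(bad) > 0L) {
      stop(sprintf("parse error in %s, line %d (record %s): sequence length %d, expected %d",
                   path, bad[1L] + 1L, inst$transcript_id[bad[1L]],
                   nchar(inst$sequence[bad[1L]]), params$window_length),
           call. = FALSE)
    }
    bad_lab <- which(!inst$label %in% c("positive", "negative"))
    if (length(bad_lab) > 0L) {
      stop(sprintf("parse error in %s, line %d: unknown label '%s'",
                   path, bad_lab[1L] + 1L, inst$label[bad_lab[1L]]), call. = FALSE)
    }
  }
  new_tss_dataset(inst, params, provenance)
}

#' Parse a BioMart-style transcript export
#'
#' Tab-separated text with a header row. Rows with a null or empty value in
#' any mapped field are dropped and counted. Strand may be encoded as
#' `+`/`-` or Ensembl's `1`/`-1`; both are normalized to `+`/`-`. Unmapped
#' extra columns are ignored.
#'
#' @param path File path.
#' @param column_map Named character vector mapping the canonical fields
#'   (`transcript_id`, `chromosome`, `strand`, `transcript_start`,
#'   `transcript_end`, `tss`) to column names in the file. Defaults to the
#'   identity mapping used by [write_fixture()].
#' @return A list with `annotation` (data.frame) and `n_dropped` (rows
#'   removed for null fields).
#' @export
read_biomart_export <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  fields <- c("transcript_id", "chromosome", "strand",
              "transcript_start", "transcript_end", "tss")
  if (is.null(column_map)) column_map <- stats::setNames(fields, fields)
  missing_fields <- setdiff(fields, names(column_map))
  if (length(missing_fields) > 0L) {
    stop("column_map is missing an entry for field '", missing_fields[1L], "'",
         call. = FALSE)
  }
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  missing_cols <- setdiff(unname(column_map[fields]), names(raw))
  if (length(missing_cols) > 0L) {
    stop("annotation file lacks mapped column '", missing_cols[1L], "'", call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning("annotation file has a header but no rows", call. = FALSE)
    ann <- data.frame(transcript_id = character(0), chromosome = character(0),
                      strand = character(0), transcript_start = integer(0),
                      transcript_end = integer(0), tss = integer(0),
                      stringsAsFactors = FALSE)
    return(list(annotation = ann, n_dropped = 0L))
  }
  sel <- raw[, unname(column_map[fields])]
  names(sel) <- fields
  complete <- stats::complete.cases(sel)
  n_dropped <- sum(!complete)
  sel <- sel[complete, , drop = FALSE]
  sel$strand <- as.character(sel$strand)
  sel$strand <- ifelse(sel$strand %in% c("1", "+"), "+",
                       ifelse(sel$strand %in% c("-1", "-"), "-", NA_character_))
  if (anyNA(sel$strand)) stop("unrecognized strand encoding in annotation", call. = FALSE)
  sel$chromosome <- as.character(sel$chromosome)
  sel$transcript_id <- as.character(sel$transcript_id)
  sel$transcript_start <- as.integer(sel$transcript_start)
  sel$transcript_end <- as.integer(sel$transcript_end)
  sel$tss <- as.integer(sel$tss)
  bad <- which(sel$transcript_start > sel$transcript_end |
                 sel$tss < sel$transcript_start | sel$tss > sel$transcript_end)
  if (length(bad) > 0L) {
    stop(sprintf("annotation record %s has inconsistent coordinates",
                 sel$transcript_id[bad[1L]]), call. = FALSE)
  }
  rownames(sel) <- NULL
  list(annotation = sel, n_dropped = n_dropped)
}
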