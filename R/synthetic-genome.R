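#' Configuration for the synthetic genome fixture generator
#'
#' The generator emulates the real inputs of the pipeline — a multi-chromosome
#' genome plus a transcript annotation with TSS coordinates — while planting a
#' learnable signal: a consensus motif written at every TSS codon position on
#' the transcript's strand, corrupted per base with probability `motif_noise`.
#' Background bases are drawn i.i.d. with `P(G) = P(C) = background_gc / 2`.
#'
#' @param n_chromosomes Number of chromosomes (named "1", "2", ...).
#' @param chromosome_length Length of every chromosome in bases.
#' @param n_transcripts Total number of planted transcripts.
#' @param motif Consensus motif over A,C,G,T planted starting at each TSS.
#' @param motif_noise Probability in `[0, 1]` of replacing each motif base
#'   with a uniformly random base (so each position retains the consensus
#'   base with probability `1 - motif_noise + motif_noise / 4`).
#' @param background_gc GC content of the background, in `[0, 1]`.
#' @param seed Integer seed; identical configs produce identical fixtures.
#' @return A list of class `synthetic_genome_config`.
#' @export
synthetic_genome_config <- function(n_chromosomes = 2L,
                                    chromosome_length = 50000L,
                                    n_transcripts = 20L,
                                    motif = "TATAAAGGCC",
                                    motif_noise = 0.05,
                                    background_gc = 0.41,
                                    seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.integer(chromosome_length),
    n_transcripts = as.integer(n_transcripts),
    motif = toupper(motif),
    motif_noise = motif_noise,
    background_gc = background_gc,
    seed = as.integer(seed)
  )
  validate_genome_config(cfg)
  structure(cfg, class = "synthetic_genome_config")
}

# Margin (bases) each planted TSS keeps free on BOTH sides so that the
# default 700/3/300 window is extractable on either strand.
FIXTURE_TSS_MARGIN <- 703L

validate_genome_config <- function(cfg) {
  err <- function(field, msg) {
    stop(sprintf("invalid synthetic genome config: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (cfg$n_chromosomes < 1L) err("n_chromosomes", "must be positive")
  if (cfg$n_transcripts < 1L) err("n_transcripts", "must be positive")
  if (!grepl("^[ACGT]+$", cfg$motif)) err("motif", "must be a non-empty string over A,C,G,T")
  if (cfg$motif_noise < 0 || cfg$motif_noise > 1) err("motif_noise", "must lie in [0, 1]")
  if (cfg$background_gc < 0 || cfg$background_gc > 1) err("background_gc", "must lie in [0, 1]")
  min_len <- 700L + 300L + nchar(cfg$motif) + 1L
  if (cfg$chromosome_length < min_len) {
    err("chromosome_length",
        sprintf("must be at least %d (default flanks + motif + 1)", min_len))
  }
  if (cfg$chromosome_length < 2L * FIXTURE_TSS_MARGIN + 2L) {
    err("chromosome_length",
        sprintf("must exceed %d so planted TSS keep full flanks on both strands",
                2L * FIXTURE_TSS_MARGIN + 1L))
  }
  invisible(cfg)
}

#' Generate a synthetic genome and transcript annotation
#'
#' Deterministic given the config seed. TSS positions are placed in disjoint
#' slots of the usable chromosome interior (so planted motifs never
#' overwrite one another and every TSS admits a full default window on its
#' strand); strands are assigned by a fair coin; each transcript spans from
#' its TSS into the transcript body (downstream in transcript orientation),
#' with a random length, clipped to the chromosome.
#'
#' @param config A [synthetic_genome_config()].
#' @return A list with `assembly` (a named [Biostrings::DNAStringSet], one
#'   entry per chromosome, alphabet restricted to A,C,G,T) and `annotation`
#'   (a data.frame with columns `transcript_id`, `chromosome`, `strand`,
#'   `transcript_start`, `transcript_end`, `tss`; 1-based inclusive
#'   coordinates).
#' @export
generate_fixture <- function(config) {
  validate_genome_config(config)
  set.seed(config$seed)
  chrom_names <- as.character(seq_len(config$n_chromosomes))
  probs <- c(A = (1 - config$background_gc) / 2, C = config$background_gc / 2,
             G = config$background_gc / 2, T = (1 - config$background_gc) / 2)
  chroms <- lapply(chrom_names, function(nm) {
    sample(DNA_ALPHABET, config$chromosome_length, replace = TRUE, prob = probs)
  })
  names(chroms) <- chrom_names

  # Round-robin assignment of transcripts to chromosomes.
  chrom_of <- rep(chrom_names, length.out = config$n_transcripts)
  motif_chars <- strsplit(config$motif, "", fixed = TRUE)[[1L]]
  mlen <- length(motif_chars)

  ann <- vector("list", config$n_transcripts)
  t_i <- 0L
  for (nm in chrom_names) {
    n_here <- sum(chrom_of == nm)
    if (n_here == 0L) next
    lo <- FIXTURE_TSS_MARGIN + 1L
    hi <- config$chromosome_length - FIXTURE_TSS_MARGIN
    usable <- hi - lo + 1L
    slot <- usable %/% n_here
    if (slot < 2L * mlen + 2L) {
      stop(sprintf("invalid synthetic genome config: field 'n_transcripts' too large for chromosome_length (slot width %d < %d)",
                   slot, 2L * mlen + 2L), call. = FALSE)
    }
    # One TSS per slot, jittered inside the slot but clear of its right edge
    # by the motif length, guaranteeing planted motifs never collide.
    jitter_max <- slot - mlen - 1L
    offsets <- sample.int(jitter_max, n_here, replace = TRUE)
    tss_pos <- lo + (seq_len(n_here) - 1L) * slot + offsets
    strands <- ifelse(stats::runif(n_here) < 0.5, "+", "-")
    span_len <- sample(500:3000, n_here, replace = TRUE)
    for (j in seq_len(n_here)) {
      t_i <- t_i + 1L
      tss <- tss_pos[j]
      if (strands[j] == "+") {
        tstart <- tss
        tend <- min(tss + span_len[j] - 1L, config$chromosome_length)
      } else {
        tend <- tss
        tstart <- max(tss - span_len[j] + 1L, 1L)
      }
      # Plant the motif on the transcript strand at the TSS codon position.
      planted <- motif_chars
      corrupt <- stats::runif(mlen) < config$motif_noise
      if (any(corrupt)) {
        planted[corrupt] <- sample(DNA_ALPHABET, sum(corrupt), replace = TRUE)
      }
      if (strands[j] == "+") {
        chroms[[nm]][tss:(tss + mlen - 1L)] <- planted
      } else {
        chroms[[nm]][(tss - mlen + 1L):tss] <- rev(DNA_COMPLEMENT[planted])
      }
      ann[[t_i]] <- data.frame(
        transcript_id = sprintf("T%05d", t_i),
        chromosome = nm,
        strand = strands[j],
        transcript_start = tstart,
        transcript_end = tend,
        tss = tss,
        stringsAsFactors = FALSE
      )
    }
  }
  annotation <- do.call(rbind, ann)
  rownames(annotation) <- NULL
  assembly <- Biostrings::DNAStringSet(vapply(chroms, paste, character(1), collapse = ""))
  names(assembly) <- chrom_names
  list(assembly = assembly, annotation = annotation)
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Write a fixture to disk
#'
#' The genome is written as a multi-record FASTA (one record per chromosome,
#' headers = chromosome names); the annotation as tab-separated text with the
#' header `transcript_id  chromosome  strand  transcript_start
#' transcript_end  tss`, the layout [read_biomart_export()] parses.
#'
#' @param assembly A named [Biostrings::DNAStringSet].
#' @param annotation Annotation data.frame as from [generate_fixture()].
#' @param genome_path,annotation_path Output file paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_fixture <- function(assembly, annotation, genome_path, annotation_path) {
  Biostrings::writeXStringSet(assembly, filepath = genome_path)
  utils::write.table(annotation, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(genome = genome_path, annotation = annotation_path))
}

#' Read a genome FASTA into the assembly container
#'
#' @param path FASTA path.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path, call. = FALSE)
  Biostrings::readDNAStringSet(path)
}
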