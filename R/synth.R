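# Synthetic labelled-sequence generator. Emulates the signal structure the
# classifier assumes: 251-nt promoter windows with TATA/CAAT/Inr elements
# at canonical offsets from the TSS, fixed-length coding windows with a
# skewed codon-usage table, intron negatives with GT..AG ends, and 3'UTR
# negatives carrying one AATAAA polyadenylation signal.

.default_codon_bias <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  w <- rep(1, 64)
  names(w) <- codons
  third <- substr(codons, 3, 3)
  first <- substr(codons, 1, 1)
  w[third == "C"] <- 6
  w[third == "G"] <- 3
  w[first %in% c("A", "G")] <- w[first %in% c("A", "G")] * 2
  w[c("TAA", "TAG", "TGA")] <- 0          # no in-frame stops
  w / sum(w)
}

#' Synthetic-data configuration
#'
#' Defaults define the study conditions every other module is exercised
#' under: 251-nt promoter windows with the TSS at 0-based position 200
#' (TATA box centred near TSS-30, CAAT box near TSS-75, initiator at the
#' TSS), coding windows over the trained lengths 54/108/162/252/354 nt,
#' and 300-nt intron / 3'UTR negatives.
#'
#' @param seed RNG seed.
#' @param n_per_class Records generated per class.
#' @param promoter_length,intron_length,utr3_length Lengths in nt.
#' @param coding_lengths Coding window lengths cycled over (each divisible
#'   by 3).
#' @param gc_background Background G+C fraction in (0,1).
#' @param tss_pos 0-based TSS position inside the promoter window.
#' @param tata_offset,caat_offset Mean element start offsets relative to
#'   the TSS (negative = upstream).
#' @param tata_jitter,caat_jitter Uniform integer jitter half-widths on the
#'   element offsets.
#' @param codon_bias Named 64-entry probability vector over codons
#'   (in-frame stops should carry 0 mass). Default: skewed to C/G-ending,
#'   purine-starting codons.
#' @param motif_mutation_rate Per-base corruption probability of planted
#'   motif bases.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_per_class = 40L,
                         promoter_length = 251L,
                         coding_lengths = c(54L, 108L, 162L, 252L, 354L),
                         intron_length = 300L, utr3_length = 300L,
                         gc_background = 0.5, tss_pos = 200L,
                         tata_offset = -30L, tata_jitter = 2L,
                         caat_offset = -75L, caat_jitter = 5L,
                         codon_bias = .default_codon_bias(),
                         motif_mutation_rate = 0.05) {
  stopifnot(promoter_length >= 100, all(coding_lengths %% 3 == 0),
            gc_background > 0, gc_background < 1,
            motif_mutation_rate >= 0, motif_mutation_rate <= 1,
            abs(sum(codon_bias) - 1) < 1e-8)
  structure(list(seed = as.integer(seed),
                 n_per_class = as.integer(n_per_class),
                 promoter_length = as.integer(promoter_length),
                 coding_lengths = as.integer(coding_lengths),
                 intron_length = as.integer(intron_length),
                 utr3_length = as.integer(utr3_length),
                 gc_background = gc_background,
                 tss_pos = as.integer(tss_pos),
                 tata_offset = as.integer(tata_offset),
                 tata_jitter = as.integer(tata_jitter),
                 caat_offset = as.integer(caat_offset),
                 caat_jitter = as.integer(caat_jitter),
                 codon_bias = codon_bias,
                 motif_mutation_rate = motif_mutation_rate),
            class = "synth_config")
}

.bg_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

.random_bases <- function(n, gc) {
  if (n <= 0) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = .bg_probs(gc))
}

# Corrupt planted bases independently at rate `rate`; a corrupted base is
# replaced by a uniformly chosen different base.
.corrupt <- function(bases, rate) {
  hit <- stats::runif(length(bases)) < rate
  for (i in which(hit)) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  }
  bases
}

# Instantiate an IUPAC consensus to a concrete sequence.
.instantiate <- function(motif) {
  vapply(strsplit(motif, "")[[1]], function(code) {
    opts <- .IUPAC_SETS[[code]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1))
}

.plant <- function(chars, at0, motif_bases, rate) {
  idx <- at0 + seq_along(motif_bases)       # 1-based positions
  if (any(idx < 1) || any(idx > length(chars))) {
    stop("planted element falls outside the sequence", call. = FALSE)
  }
  chars[idx] <- .corrupt(motif_bases, rate)
  chars
}

#' Generate one synthetic promoter window
#'
#' Background bases at the configured GC with TATAAA planted near
#' TSS+tata_offset, CCAAT near TSS+caat_offset, and an instantiated
#' initiator consensus (YYANWYY) spanning the TSS; each planted base is
#' independently corrupted at `motif_mutation_rate`.
#'
#' @param config A [synth_config()].
#' @param id Record id.
#' @return A [seq_record()] labelled `promoter`. Uses the global RNG.
#' @export
generate_promoter <- function(config = synth_config(), id = "promoter_1") {
  L <- config$promoter_length
  chars <- .random_bases(L, config$gc_background)
  tss <- config$tss_pos
  tata_at <- tss + config$tata_offset +
    sample.int(2L * config$tata_jitter + 1L, 1L) - config$tata_jitter - 1L
  caat_at <- tss + config$caat_offset +
    sample.int(2L * config$caat_jitter + 1L, 1L) - config$caat_jitter - 1L
  rate <- config$motif_mutation_rate
  chars <- .plant(chars, caat_at, strsplit("CCAAT", "")[[1]], rate)
  chars <- .plant(chars, tata_at, strsplit("TATAAA", "")[[1]], rate)
  inr <- .instantiate("YYANWYY")
  chars <- .plant(chars, tss - 2L, inr, rate)
  seq_record(id, paste(chars, collapse = ""), "promoter")
}

#' Generate one synthetic coding window
#'
#' Codons are sampled i.i.d. from the configured codon-usage table (no
#' in-frame stop codons under the default table).
#'
#' @param config A [synth_config()].
#' @param length Window length in nt, divisible by 3.
#' @param id Record id.
#' @param label Label to attach (`coding` by default; the dataset
#'   generator uses `exon`).
#' @return A [seq_record()]. Uses the global RNG.
#' @export
generate_coding <- function(config = synth_config(), length = 162L,
                            id = "coding_1", label = "coding") {
  if (length %% 3 != 0) {
    stop("coding length must be divisible by 3", call. = FALSE)
  }
  codons <- sample(names(config$codon_bias), length %/% 3L, replace = TRUE,
                   prob = config$codon_bias)
  seq_record(id, paste(codons, collapse = ""), label)
}

#' Generate one background (intron or 3'UTR) sequence
#'
#' I.i.d. background at the configured GC. Introns are decorated with the
#' canonical GT..AG splice dinucleotides; 3'UTRs carry one planted AATAAA
#' polyadenylation signal.
#'
#' @param config A [synth_config()].
#' @param length Length in nt (>= 10).
#' @param label `intron`, `utr3`, or `noncoding` (undecorated).
#' @param id Record id.
#' @return A [seq_record()]. Uses the global RNG.
#' @export
generate_background <- function(config = synth_config(), length = 300L,
                                label = "noncoding", id = "bg_1") {
  if (length < 10) stop("background length must be >= 10", call. = FALSE)
  chars <- .random_bases(length, config$gc_background)
  if (label == "intron") {
    chars[1:2] <- c("G", "T")
    chars[(length - 1):length] <- c("A", "G")
  } else if (label == "utr3") {
    at <- sample.int(length - 15L, 1L) + 4L   # keep clear of the ends
    chars <- .plant(chars, at, strsplit("AATAAA", "")[[1]],
                    config$motif_mutation_rate)
  }
  seq_record(id, paste(chars, collapse = ""), label)
}

#' Generate a full labelled dataset with a train/test split
#'
#' Produces `n_per_class` records for each of the four classes (exon
#' lengths cycle over `coding_lengths`), deterministically from
#' `config$seed`, split 70/30 train/test within each class.
#'
#' @param config A [synth_config()].
#' @return List with `train` and `test` (lists of [seq_record()]) and
#'   `records` (all, in generation order).
#' @export
generate_dataset <- function(config = synth_config()) {
  set.seed(config$seed)
  n <- config$n_per_class
  records <- list()
  for (i in seq_len(n)) {
    records[[length(records) + 1L]] <-
      generate_promoter(config, id = sprintf("promoter_%03d", i))
  }
  for (i in seq_len(n)) {
    len <- config$coding_lengths[((i - 1L) %% length(config$coding_lengths))
                                 + 1L]
    records[[length(records) + 1L]] <-
      generate_coding(config, length = len, id = sprintf("exon_%03d", i),
                      label = "exon")
  }
  for (i in seq_len(n)) {
    records[[length(records) + 1L]] <-
      generate_background(config, config$intron_length, "intron",
                          id = sprintf("intron_%03d", i))
  }
  for (i in seq_len(n)) {
    records[[length(records) + 1L]] <-
      generate_background(config, config$utr3_length, "utr3",
                          id = sprintf("utr3_%03d", i))
  }
  n_train <- floor(0.7 * n)
  labs <- .labels_of(records)
  train <- list()
  test <- list()
  for (cl in unique(labs)) {
    idx <- which(labs == cl)
    train <- c(train, records[idx[seq_len(n_train)]])
    test <- c(test, records[idx[(n_train + 1L):n]])
  }
  list(train = train, test = test, records = records)
}
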