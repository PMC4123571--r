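# DNA -> fuzzy-cell encodings and the promoter / coding features used as
# classification substrate: consensus motif scores (TATA, CAAT, Inr), k-mer
# composition, codon position asymmetry and hexamer bias.

.BASE_LEVELS <- c(A = 0.25, C = 0.50, G = 0.75, T = 1.00, N = 0.00)

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 ||
      is.na(sequence)) {
    stop("sequence must be a single character string", call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), names(.BASE_LEVELS))
  if (length(bad) > 0) {
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(bad, collapse = ""), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a sequence record
#'
#' @param id Record identifier.
#' @param sequence Uppercase DNA string over `{A,C,G,T,N}`.
#' @param label Optional class label (`promoter`, `exon`, `intron`, `utr3`,
#'   `coding`, `noncoding`) or `NA`.
#' @return Object of class `seq_record`.
#' @export
seq_record <- function(id, sequence, label = NA_character_) {
  sequence <- toupper(sequence)
  .check_sequence(sequence)
  structure(list(id = as.character(id), sequence = sequence,
                 label = as.character(label)),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("seq_record %s [%s] %d nt\n", x$id,
              ifelse(is.na(x$label), "unlabeled", x$label),
              nchar(x$sequence)))
  invisible(x)
}

.seq_of <- function(x) {
  if (inherits(x, "seq_record")) x$sequence else {
    s <- toupper(as.character(x))
    .check_sequence(s)
    s
  }
}

#' Encode a DNA sequence as fuzzy cell values
#'
#' Per-base mapping A=0.25, C=0.50, G=0.75, T=1.00; N (missing data) maps
#' to 0. Values are chosen nonzero so no base is absorbing under bounded
#' sums.
#'
#' @param record A [seq_record()] or DNA string.
#' @return Numeric vector of cell values, one per base.
#' @export
encode_sequence <- function(record) {
  s <- .seq_of(record)
  if (nchar(s) == 0) stop("empty sequence", call. = FALSE)
  unname(.BASE_LEVELS[strsplit(s, "")[[1]]])
}

#' Overlapping k-mer frequencies
#'
#' Counts every length-k window (k-mers containing N are skipped) and
#' normalizes by the number of valid windows, so frequencies sum to 1
#' whenever at least one window is N-free.
#'
#' @param record A [seq_record()] or DNA string.
#' @param k Word size, 1..6.
#' @return Named numeric vector of length `4^k` over the ACGT alphabet.
#' @export
kmer_frequencies <- function(record, k) {
  s <- .seq_of(record)
  k <- as.integer(k)
  if (k < 1 || k > 6) stop("k must be in 1..6", call. = FALSE)
  if (nchar(s) < k) {
    stop("sequence shorter than k (", nchar(s), " < ", k, ")", call. = FALSE)
  }
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s),
                                                 width = k)
  tot <- sum(counts)
  if (tot == 0) return(counts * 0)
  counts / tot
}

.IUPAC_SETS <- local({
  map <- Biostrings::IUPAC_CODE_MAP
  lapply(strsplit(map, ""), identity)
})

#' Best consensus-motif match in a window
#'
#' Slides an IUPAC consensus motif over a (clipped) window of the sequence
#' and reports the best fraction of matched positions. A sequence `N`
#' matches only the motif code `N`.
#'
#' @param record A [seq_record()] or DNA string.
#' @param motif IUPAC consensus string (e.g. `"TATAAA"`, `"YYANWYY"`).
#' @param search_window Optional 0-based half-open `c(start, end)` interval
#'   restricting the motif start positions searched; clipped to the
#'   sequence. Default: the whole sequence.
#' @return List with `score` in `[0,1]` (0 when no alignment fits) and
#'   `position`, the 0-based offset of the best alignment (`NA` if none).
#' @export
motif_score <- function(record, motif, search_window = NULL) {
  s <- .seq_of(record)
  motif <- toupper(motif)
  mlen <- nchar(motif)
  n <- nchar(s)
  if (mlen == 0) stop("empty motif", call. = FALSE)
  mset <- .IUPAC_SETS[strsplit(motif, "")[[1]]]
  if (any(vapply(mset, is.null, logical(1)))) {
    stop("motif contains non-IUPAC characters", call. = FALSE)
  }
  if (is.null(search_window)) search_window <- c(0L, n)
  lo <- max(0L, as.integer(search_window[1]))
  hi <- min(n, as.integer(search_window[2]))
  starts <- seq.int(lo, hi - 1L)           # candidate 0-based offsets
  starts <- starts[starts + mlen <= n]
  if (lo >= hi || length(starts) == 0) {
    return(list(score = 0, position = NA_integer_))
  }
  chars <- strsplit(s, "")[[1]]
  # per motif position j: logical match vector over the whole sequence;
  # summing shifted slices scores every alignment at once
  hits <- numeric(length(starts))
  for (j in seq_len(mlen)) {
    set_j <- mset[[j]]
    mj <- if (identical(set_j, c("A", "C", "G", "T"))) {
      rep(TRUE, n)                       # code N matches anything
    } else {
      chars %in% set_j                   # a sequence N matches nothing else
    }
    hits <- hits + mj[starts + j]
  }
  best <- which.max(hits)                # earliest best alignment
  list(score = hits[best] / mlen, position = starts[best])
}

#' Codon position asymmetry per base
#'
#' How unevenly each base is distributed over the three codon positions:
#' for base b with position shares p1, p2, p3 (summing to 1), the
#' asymmetry is `(max(p) - 1/3) / (2/3)`, i.e. 0 for a uniform spread and
#' 1 when the base is confined to one frame position. A base absent from
#' the sequence scores 0. Elevated values are characteristic of coding DNA.
#'
#' @param record A [seq_record()] or DNA string, length >= 3.
#' @return Named numeric vector `c(A=, C=, G=, T=)`, each in `[0,1]`.
#' @export
position_asymmetry <- function(record) {
  s <- .seq_of(record)
  n <- nchar(s)
  if (n < 3) stop("sequence shorter than one codon", call. = FALSE)
  chars <- strsplit(s, "")[[1]]
  pos <- ((seq_len(n) - 1L) %% 3L) + 1L
  out <- c(A = 0, C = 0, G = 0, T = 0)
  for (b in names(out)) {
    cnt <- tabulate(pos[chars == b], nbins = 3L)
    tot <- sum(cnt)
    if (tot > 0) out[b] <- (max(cnt / tot) - 1 / 3) / (2 / 3)
  }
  out
}

#' Fit a hexamer log-odds model
#'
#' Builds add-one-smoothed 6-mer frequency tables from coding and
#' background training sequences and stores their log-odds. The model is
#' the reference for [hexamer_bias()].
#'
#' @param coding,background Lists of [seq_record()] (or DNA strings).
#' @return Object of class `hexamer_model` holding the 4096-entry log-odds
#'   table.
#' @export
fit_hexamer_model <- function(coding, background) {
  count_all <- function(records) {
    tot <- NULL
    for (r in records) {
      s <- .seq_of(r)
      if (nchar(s) < 6) next
      cnt <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s),
                                                  width = 6)
      tot <- if (is.null(tot)) cnt else tot + cnt
    }
    if (is.null(tot)) {
      stop("no sequence of length >= 6 in training set", call. = FALSE)
    }
    tot
  }
  cc <- count_all(coding) + 1
  cb <- count_all(background) + 1
  structure(list(log_odds = log(cc / sum(cc)) - log(cb / sum(cb))),
            class = "hexamer_model")
}

#' Hexamer coding bias of a sequence
#'
#' Mean per-hexamer log-odds (coding vs background) over all overlapping
#' N-free 6-mers, squashed to `[0,1]` with a logistic transform; 0.5 means
#' no preference.
#'
#' @param record A [seq_record()] or DNA string of length >= 6.
#' @param coding_model A `hexamer_model` from [fit_hexamer_model()].
#' @param gain Slope of the logistic squash; larger values saturate the
#'   score faster as the mean log-odds moves away from 0.
#' @return Score in `[0,1]`.
#' @export
hexamer_bias <- function(record, coding_model, gain = 1) {
  if (!inherits(coding_model, "hexamer_model")) {
    stop("coding_model must come from fit_hexamer_model()", call. = FALSE)
  }
  s <- .seq_of(record)
  if (nchar(s) < 6) stop("sequence shorter than 6 nt", call. = FALSE)
  cnt <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s),
                                              width = 6)
  tot <- sum(cnt)
  if (tot == 0) return(0.5)
  mean_lo <- sum(cnt * coding_model$log_odds) / tot
  1 / (1 + exp(-gain * mean_lo))
}

#' Feature configuration for the classification substrate
#'
#' Names the features, their order, and the motif consensus strings and
#' 0-based half-open search windows used by [build_feature_state()].
#' Every name in `motifs` is available as a consensus-score feature (the
#' defaults cover the TATA box, CAAT box, initiator and polyadenylation
#' signal); the remaining feature names are `"gc"` (G+C fraction),
#' `"asym"` (4 cells, codon position asymmetry per base), `"hexamer"`
#' (needs `hexamer_model`) and `"kmer"` (`4^kmer_k` cells of k-mer
#' frequencies).
#'
#' @param features Character vector selecting and ordering features.
#' @param motifs Named list of IUPAC consensus strings.
#' @param windows Named list of `c(start, end)` search windows restricting
#'   motif start positions (0-based, half-open). Negative values count
#'   from the sequence end (`-2` = two bases before the end); `NULL`
#'   entries mean whole-sequence search.
#' @param kmer_k Word size for the `"kmer"` feature.
#' @param hexamer_model Optional fitted [fit_hexamer_model()].
#' @param hexamer_gain Logistic slope passed to [hexamer_bias()].
#' @param quantize Grid step the resulting cells are rounded to before CA
#'   evolution (`NA` to disable). Default 0.25.
#' @return Object of class `feature_config`.
#' @export
feature_config <- function(features = c("tata", "caat", "inr", "polya",
                                        "asym", "hexamer"),
                           motifs = list(tata = "TATAAA", caat = "CCAAT",
                                         inr = "YYANWYY", polya = "AATAAA"),
                           windows = list(),
                           kmer_k = 1L,
                           hexamer_model = NULL,
                           hexamer_gain = 1,
                           quantize = 0.25) {
  if (length(features) == 0) stop("empty feature list", call. = FALSE)
  known <- c(names(motifs), "gc", "asym", "hexamer", "kmer")
  bad <- setdiff(features, known)
  if (length(bad) > 0) {
    stop("unknown feature(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(features = features, motifs = motifs, windows = windows,
                 kmer_k = as.integer(kmer_k), hexamer_model = hexamer_model,
                 hexamer_gain = hexamer_gain, quantize = quantize),
            class = "feature_config")
}

#' Snap cell values to a grid
#'
#' Rounds every cell to the nearest multiple of `step`. On the grid,
#' bounded sums are closed, so CA attractor sets are finite and basins
#' are shared between similar sequences.
#'
#' @param state Numeric vector in `[0,1]`.
#' @param step Grid step (default 0.25).
#' @return Quantized state.
#' @export
quantize_state <- function(state, step = 0.25) {
  pmin(1, pmax(0, round(state / step) * step))
}

#' Build the feature-based CA configuration of a sequence
#'
#' Concatenates the configured normalized features into a fixed-length
#' fuzzy state, the substrate the trained CA classifies.
#'
#' @param record A [seq_record()] or DNA string.
#' @param config A [feature_config()].
#' @return Named numeric vector of cell values in `[0,1]`.
#' @export
build_feature_state <- function(record, config = feature_config()) {
  stopifnot(inherits(config, "feature_config"))
  s <- .seq_of(record)
  n <- nchar(s)
  resolve_window <- function(w) {
    if (is.null(w)) return(NULL)
    ifelse(w < 0, n + w, w)
  }
  cells <- numeric(0)
  for (f in config$features) {
    if (f %in% names(config$motifs)) {
      sc <- motif_score(s, config$motifs[[f]],
                        resolve_window(config$windows[[f]]))$score
      cells <- c(cells, stats::setNames(sc, f))
      next
    }
    v <- switch(f,
      gc = {
        fr <- kmer_frequencies(s, 1L)
        c(gc = unname(fr["C"] + fr["G"]))
      },
      asym = stats::setNames(position_asymmetry(s),
                             paste0("asym_", c("A", "C", "G", "T"))),
      hexamer = {
        if (is.null(config$hexamer_model)) {
          stop("feature 'hexamer' requires a fitted hexamer_model",
               call. = FALSE)
        }
        c(hexamer = hexamer_bias(s, config$hexamer_model,
                                 gain = config$hexamer_gain))
      },
      kmer = kmer_frequencies(s, config$kmer_k)
    )
    cells <- c(cells, v)
  }
  if (!is.na(config$quantize)) cells <- quantize_state(cells, config$quantize)
  cells
}

#' Reverse complement of a DNA string (N-preserving)
#'
#' @param sequence DNA string over `{A,C,G,T,N}` or IUPAC codes.
#' @return The reverse complement.
#' @export
reverse_complement <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}
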