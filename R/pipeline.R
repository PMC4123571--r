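# Hierarchical classification pipeline: promoter -> exon -> intron/3'UTR,
# plus a coding-vs-noncoding scanner model used for sliding-window boundary
# calling. Each stage is one trained antibody over feature-encoded states.

.STAGES <- c("promoter_vs_rest", "exon_vs_rest", "intron_vs_utr3",
             "coding_vs_noncoding")

#' Pipeline configuration
#'
#' @param encoders Named list of per-stage [feature_config()]s (names from
#'   `promoter_vs_rest`, `exon_vs_rest`, `intron_vs_utr3`,
#'   `coding_vs_noncoding`); stages not listed get the package defaults:
#'   the promoter stage reads the core promoter elements (TATA box
#'   searched around TSS-30, CAAT around TSS-75, initiator at the TSS,
#'   assuming the TSS at 0-based position 200 of a 251-nt window), the
#'   coding stages read codon position asymmetry plus hexamer bias (model
#'   fitted from the training exons vs the rest), and the intron/3'UTR
#'   stage reads the splice-anchored GT/AG dinucleotides and the poly-A
#'   signal.
#' @param clonal A [clonal_config()] used for every stage (a stage offset
#'   is folded into the seed so stages draw independent streams).
#' @param window,stride Scanner window and stride in nt for
#'   [scan_boundaries()]; default window 54 (the smallest trained coding
#'   length), stride `window / 3`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(encoders = list(), clonal = clonal_config(),
                            window = 54L, stride = max(1L, window %/% 3L)) {
  stopifnot(window >= 1, stride >= 1)
  bad <- setdiff(names(encoders), .STAGES)
  if (length(bad) > 0) {
    stop("unknown stage(s) in encoders: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(encoders = encoders, clonal = clonal,
                 window = as.integer(window), stride = as.integer(stride)),
            class = "pipeline_config")
}

.default_stage_encoders <- function(hexamer_model) {
  promoter_motifs <- list(tata = "TATAAA", caat = "CCAAT", inr = "YYANWYY")
  promoter_windows <- list(tata = c(160L, 196L), caat = c(110L, 151L),
                           inr = c(192L, 209L))
  coding <- feature_config(features = c("asym", "hexamer"),
                           hexamer_model = hexamer_model,
                           hexamer_gain = 4)
  list(
    promoter_vs_rest = feature_config(
      features = c("tata", "caat", "inr"),
      motifs = promoter_motifs, windows = promoter_windows),
    exon_vs_rest = coding,
    intron_vs_utr3 = feature_config(
      features = c("gt_start", "ag_end", "polya"),
      motifs = list(gt_start = "GT", ag_end = "AG", polya = "AATAAA"),
      windows = list(gt_start = c(0L, 1L), ag_end = c(-2L, -1L))),
    coding_vs_noncoding = coding)
}

.encode_records <- function(records, encoder) {
  do.call(cbind, lapply(records, build_feature_state, config = encoder))
}

.labels_of <- function(records) {
  vapply(records, function(r) r$label, character(1))
}

#' Fit the hierarchical region classifier
#'
#' Trains four stage models by clonal selection on feature-encoded
#' sequences: `promoter_vs_rest` on all classes, `exon_vs_rest` on the
#' non-promoter classes, `intron_vs_utr3` on the remaining two, and a
#' `coding_vs_noncoding` scanner (exon windows vs intron/3'UTR) used for
#' boundary calling.
#'
#' @param records List of labelled [seq_record()]s covering all four
#'   classes `promoter`, `exon`, `intron`, `utr3`.
#' @param config A [pipeline_config()].
#' @return Object of class `maca_pipeline`: named list of stage models,
#'   each holding the trained antibody, its training affinity, the encoder
#'   and the positive/negative stage labels.
#' @export
fit_pipeline <- function(records, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  labs <- .labels_of(records)
  need <- c("promoter", "exon", "intron", "utr3")
  missing <- setdiff(need, unique(labs))
  if (length(missing) > 0) {
    stop("training classes absent: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  defaults <- NULL
  need_default <- setdiff(.STAGES, names(config$encoders))
  if (length(need_default) > 0) {
    hm <- fit_hexamer_model(records[labs == "exon"],
                            records[labs != "exon"])
    defaults <- .default_stage_encoders(hm)
  }
  encoders <- config$encoders
  for (st in need_default) encoders[[st]] <- defaults[[st]]

  fit_stage <- function(stage, keep, positive, seed_offset) {
    pos <- labs[keep] == positive
    binlab <- ifelse(pos, positive, "rest")
    if (stage == "intron_vs_utr3") binlab <- labs[keep]
    cfg <- config$clonal
    cfg$seed <- cfg$seed + seed_offset
    states <- .encode_records(records[keep], encoders[[stage]])
    ag <- antigen_set(states, binlab,
                      class_universe = unique(c(positive, binlab)))
    fit <- train_clonal(ag, cfg)
    list(stage = stage, antibody = fit$antibody,
         training_affinity = fit$antibody$affinity,
         history = fit$history, positive = positive,
         encoder = encoders[[stage]])
  }

  models <- list(
    promoter_vs_rest = fit_stage("promoter_vs_rest",
                                 rep(TRUE, length(labs)), "promoter", 101L),
    exon_vs_rest = fit_stage("exon_vs_rest", labs != "promoter", "exon",
                             211L),
    intron_vs_utr3 = fit_stage("intron_vs_utr3",
                               labs %in% c("intron", "utr3"), "intron",
                               307L),
    coding_vs_noncoding = fit_stage("coding_vs_noncoding",
                                    labs != "promoter", "exon", 401L)
  )
  structure(list(models = models, config = config),
            class = "maca_pipeline")
}

#' @export
print.maca_pipeline <- function(x, ...) {
  cat("maca_pipeline with stages:\n")
  for (m in x$models) {
    cat(sprintf("  %-22s training affinity %.3f\n", m$stage,
                m$training_affinity))
  }
  invisible(x)
}

.stage_call <- function(pipeline, stage, record_or_seq) {
  model <- pipeline$models[[stage]]
  state <- build_feature_state(record_or_seq, model$encoder)
  predict_antibody(model$antibody, state,
                   max_steps = pipeline$config$clonal$max_steps)
}

#' Classify one sequence through the stage hierarchy
#'
#' Stages are applied in order — promoter first, then exon, then
#' intron vs 3'UTR — and the first positive stage decides the label
#' (promoter short-circuits the rest). All stage outcomes are kept in the
#' trace.
#'
#' @param pipeline A fitted [fit_pipeline()].
#' @param record A [seq_record()] or DNA string.
#' @return List with `id`, `label` (one of promoter/exon/intron/utr3) and
#'   `trace`, a data.frame of per-stage outcomes.
#' @export
classify_sequence <- function(pipeline, record) {
  stopifnot(inherits(pipeline, "maca_pipeline"))
  id <- if (inherits(record, "seq_record")) record$id else NA_character_
  trace <- data.frame(stage = character(0), outcome = character(0),
                      stringsAsFactors = FALSE)
  p1 <- .stage_call(pipeline, "promoter_vs_rest", record)
  trace <- rbind(trace, data.frame(stage = "promoter_vs_rest", outcome = p1))
  if (p1 == "promoter") {
    return(list(id = id, label = "promoter", trace = trace))
  }
  p2 <- .stage_call(pipeline, "exon_vs_rest", record)
  trace <- rbind(trace, data.frame(stage = "exon_vs_rest", outcome = p2))
  if (p2 == "exon") {
    return(list(id = id, label = "exon", trace = trace))
  }
  p3 <- .stage_call(pipeline, "intron_vs_utr3", record)
  trace <- rbind(trace, data.frame(stage = "intron_vs_utr3", outcome = p3))
  list(id = id, label = if (p3 == "intron") "intron" else "utr3",
       trace = trace)
}

# Width-3 majority smoothing over a logical label run; partial
# neighbourhoods at the ends, ties keep the original label.
.majority_smooth <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  out <- x
  for (i in seq_len(n)) {
    nb <- x[max(1, i - 1):min(n, i + 1)]
    votes <- sum(nb)
    if (votes * 2 > length(nb)) out[i] <- TRUE
    else if (votes * 2 < length(nb)) out[i] <- FALSE
  }
  out
}

#' Call region boundaries by sliding-window scanning
#'
#' Slides the scanner window along the sequence by `stride`, classifies
#' each window with the `coding_vs_noncoding` stage (or a chosen stage),
#' applies a width-3 majority smoothing over the window calls, and merges
#' runs of positive windows into 0-based half-open intervals (first window
#' start to last window end, clipped to the sequence).
#'
#' @param pipeline A fitted [fit_pipeline()].
#' @param record A [seq_record()] or DNA string, at least one window long.
#' @param stage Stage model to scan with (default `coding_vs_noncoding`).
#' @return Data frame with columns `start`, `end` (0-based half-open);
#'   zero rows when no window is positive.
#' @export
scan_boundaries <- function(pipeline, record,
                            stage = "coding_vs_noncoding") {
  stopifnot(inherits(pipeline, "maca_pipeline"),
            stage %in% names(pipeline$models))
  s <- .seq_of(record)
  n <- nchar(s)
  w <- pipeline$config$window
  st <- pipeline$config$stride
  if (n < w) {
    stop("sequence shorter than the scanner window (", n, " < ", w, ")",
         call. = FALSE)
  }
  starts <- seq.int(0L, n - w, by = st)
  positive <- pipeline$models[[stage]]$positive
  calls <- vapply(starts, function(p) {
    win <- substr(s, p + 1L, p + w)
    .stage_call(pipeline, stage, win) == positive
  }, logical(1))
  calls <- .majority_smooth(calls)
  merge_runs(starts, calls, w, n)
}

#' Merge positive window calls into intervals
#'
#' @param starts 0-based window start positions.
#' @param calls Logical vector of positive calls, same length.
#' @param window Window width in nt.
#' @param seq_len_nt Sequence length (intervals are clipped to it).
#' @return Data frame `start`, `end`, sorted, non-overlapping.
#' @export
merge_runs <- function(starts, calls, window, seq_len_nt = Inf) {
  stopifnot(length(starts) == length(calls))
  if (!any(calls)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  r <- rle(calls)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  pos <- which(r$values)
  out <- data.frame(
    start = starts[idx_start[pos]],
    end = pmin(starts[idx_end[pos]] + window, seq_len_nt))
  out[order(out$start), , drop = FALSE]
}

#' Predict labels and boundaries for a set of sequences
#'
#' @param pipeline A fitted [fit_pipeline()].
#' @param records List of [seq_record()]s.
#' @param boundaries Also run [scan_boundaries()] on sequences long enough
#'   for the scanner window.
#' @return Data frame with `id`, `label`, and (when `boundaries`) a list
#'   column `regions` of interval data frames.
#' @export
predict_pipeline <- function(pipeline, records, boundaries = FALSE) {
  res <- lapply(records, classify_sequence, pipeline = pipeline)
  out <- data.frame(id = vapply(res, `[[`, character(1), "id"),
                    label = vapply(res, `[[`, character(1), "label"),
                    stringsAsFactors = FALSE)
  if (boundaries) {
    out$regions <- lapply(records, function(r) {
      if (nchar(r$sequence) < pipeline$config$window) {
        data.frame(start = integer(0), end = integer(0))
      } else {
        scan_boundaries(pipeline, r)
      }
    })
  }
  out
}
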