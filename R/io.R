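# FASTA / label-table / BED-style I/O and model persistence.

.MODEL_SCHEMA_VERSION <- 1L

#' Read sequences from FASTA
#'
#' Labels are taken from a `label=` token in the FASTA header or, if
#' `labels_path` is given, from a two-column (id, label) TSV that overrides
#' header tags.
#'
#' @param path FASTA file.
#' @param labels_path Optional TSV with columns `id` and `label` (no
#'   header, or a `id<TAB>label` header line).
#' @return List of [seq_record()].
#' @export
read_fasta <- function(path, labels_path = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1)
  labels <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("label=[^\\s]+", h, perl = TRUE))
    if (length(m) == 0) NA_character_ else sub("^label=", "", m)
  }, character(1), USE.NAMES = FALSE)
  if (!is.null(labels_path)) {
    tab <- utils::read.delim(labels_path, header = FALSE,
                             stringsAsFactors = FALSE)
    if (identical(tolower(as.character(tab[1, 1])), "id")) {
      tab <- tab[-1, , drop = FALSE]
    }
    lut <- stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
    hit <- ids %in% names(lut)
    labels[hit] <- unname(lut[ids[hit]])
  }
  mapply(function(id, s, lab) seq_record(id, s, lab),
         ids, as.character(set), labels,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequences to FASTA (+ optional label TSV)
#'
#' Round-trip safe with [read_fasta()]: ids and sequences survive a
#' write/read cycle unchanged; labels are carried as `label=` header
#' tokens.
#'
#' @param records List of [seq_record()].
#' @param path Output FASTA path.
#' @param labels_path Optional path for a two-column id/label TSV.
#' @export
write_fasta <- function(records, path, labels_path = NULL) {
  lines <- unlist(lapply(records, function(r) {
    hdr <- paste0(">", r$id,
                  if (!is.na(r$label)) paste0(" label=", r$label) else "")
    c(hdr, r$sequence)
  }))
  writeLines(lines, path)
  if (!is.null(labels_path)) {
    tab <- data.frame(id = vapply(records, `[[`, character(1), "id"),
                      label = vapply(records, `[[`, character(1), "label"))
    utils::write.table(tab, labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write predicted regions as a BED-like table
#'
#' Tab-separated, 0-based half-open: `id`, `start`, `end`, `label`.
#'
#' @param predictions Data frame from [predict_pipeline()] with a
#'   `regions` list column, or a data frame with columns
#'   `id`, `start`, `end`, `label`.
#' @param path Output path.
#' @param region_label Label written for scanned regions (default
#'   `coding`).
#' @export
write_regions <- function(predictions, path, region_label = "coding") {
  if (!is.null(predictions$regions)) {
    rows <- do.call(rbind, lapply(seq_len(nrow(predictions)), function(i) {
      reg <- predictions$regions[[i]]
      if (nrow(reg) == 0) return(NULL)
      data.frame(id = predictions$id[i], start = reg$start, end = reg$end,
                 label = region_label)
    }))
    if (is.null(rows)) {
      rows <- data.frame(id = character(0), start = integer(0),
                         end = integer(0), label = character(0))
    }
  } else {
    rows <- predictions[, c("id", "start", "end", "label")]
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.genome_to_list <- function(g) {
  list(rules = g$rules, complemented = g$complemented)
}

.genome_from_list <- function(x) {
  rule_genome(unlist(x$rules), unlist(x$complemented))
}

.encoder_to_list <- function(enc) {
  list(features = enc$features, motifs = enc$motifs,
       windows = enc$windows, kmer_k = enc$kmer_k,
       hexamer_gain = enc$hexamer_gain, quantize = enc$quantize,
       hexamer_log_odds = if (!is.null(enc$hexamer_model))
         as.list(enc$hexamer_model$log_odds))
}

.encoder_from_list <- function(x) {
  hm <- NULL
  if (!is.null(x$hexamer_log_odds)) {
    hm <- structure(list(log_odds = unlist(x$hexamer_log_odds)),
                    class = "hexamer_model")
  }
  feature_config(
    features = unlist(x$features),
    motifs = lapply(x$motifs, unlist),
    windows = lapply(x$windows,
                     function(w) if (is.null(w)) NULL else unlist(w)),
    kmer_k = x$kmer_k,
    hexamer_model = hm,
    hexamer_gain = if (is.null(x$hexamer_gain)) 1 else x$hexamer_gain,
    quantize = if (is.null(x$quantize)) NA_real_ else x$quantize)
}

#' Save a fitted pipeline to versioned JSON
#'
#' The dump carries every stage's genome, attractor labelling,
#' representative attractor states and encoder (including the hexamer
#' log-odds table), so a loaded model predicts identically.
#'
#' @param pipeline A [fit_pipeline()] result.
#' @param path Output JSON path.
#' @export
save_pipeline <- function(pipeline, path) {
  stopifnot(inherits(pipeline, "maca_pipeline"))
  models <- lapply(pipeline$models, function(m) {
    list(stage = m$stage, positive = m$positive,
         training_affinity = m$training_affinity,
         history = m$history,
         encoder = .encoder_to_list(m$encoder),
         genome = .genome_to_list(m$antibody$genome),
         affinity = m$antibody$affinity,
         attractor_labels = as.list(m$antibody$attractor_labels),
         attractor_reps = if (!is.null(m$antibody$attractor_reps))
           apply(m$antibody$attractor_reps, 2, identity, simplify = FALSE),
         default_label = m$antibody$default_label)
  })
  obj <- list(
    schema_version = .MODEL_SCHEMA_VERSION,
    window = pipeline$config$window,
    stride = pipeline$config$stride,
    clonal = unclass(pipeline$config$clonal),
    models = models)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a fitted pipeline from JSON
#'
#' Refuses to load a model file whose schema version does not match the
#' package's.
#'
#' @param path JSON file written by [save_pipeline()].
#' @return A `maca_pipeline`.
#' @export
load_pipeline <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(as.integer(obj$schema_version), .MODEL_SCHEMA_VERSION)) {
    stop("model schema version ", obj$schema_version,
         " does not match supported version ", .MODEL_SCHEMA_VERSION,
         call. = FALSE)
  }
  cl <- obj$clonal
  clonal <- clonal_config(cl$N_m, cl$N_r, cl$m, cl$beta, cl$p_max, cl$rho,
                          cl$generations, cl$seed, cl$max_steps,
                          cl$recycle_reservoir)
  models <- lapply(obj$models, function(m) {
    ab <- antibody(.genome_from_list(m$genome))
    ab$affinity <- m$affinity
    ab$attractor_labels <- stats::setNames(
      as.character(unlist(m$attractor_labels)),
      names(m$attractor_labels))
    if (!is.null(m$attractor_reps)) {
      ab$attractor_reps <- do.call(cbind, lapply(m$attractor_reps, unlist))
    }
    ab$default_label <- m$default_label
    list(stage = m$stage, antibody = ab,
         training_affinity = m$training_affinity,
         history = unlist(m$history), positive = m$positive,
         encoder = .encoder_from_list(m$encoder))
  })
  names(models) <- vapply(models, `[[`, character(1), "stage")
  encoders <- lapply(models, `[[`, "encoder")
  structure(list(models = models,
                 config = pipeline_config(encoders = encoders,
                                          clonal = clonal,
                                          window = obj$window,
                                          stride = obj$stride)),
            class = "maca_pipeline")
}
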